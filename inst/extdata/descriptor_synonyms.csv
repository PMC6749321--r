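synonym,canonical
toasty,toast
flower,floral
flowery,floral
fruity,fruit
woody,wood
spicy,spice
liquorices,licorice
liquorice,licorice
dried_fruit,dried_fruits
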