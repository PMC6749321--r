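test_that("the synthetic ladder inverts published KIs inside the run", {
  lib <- read_voc_library()
  lad <- generate_ladder(lib)
  expect_equal(range(lad$carbon), c(8, 28))
  expect_equal(compute_ki(lad, lad$rt_min[lad$carbon == 15]), 1500)
  # every library compound's published KI maps to an rt inside the span
  rts <- rt_from_ki(lad, lib$ki_calc)
  expect_true(all(rts >= min(lad$rt_min) & rts <= max(lad$rt_min)))
  # the generator's linalool elutes near the published 22.88 min and its
  # retention time maps back to KI 1537 exactly
  rt_linalool <- rts[lib$compound_id == "linalool"]
  expect_equal(compute_ki(lad, rt_linalool), 1537, tolerance = 0.5 / 1537)
  expect_lt(abs(rt_linalool - 22.88), 0.5)
  # determinism
  expect_identical(generate_ladder(lib, seed = 1), generate_ladder(lib, seed = 2))
})

test_that("the default design emulates the 22-wine cohort", {
  d <- default_study_design()
  expect_equal(nrow(d), 22)
  expect_setequal(unique(d$variety),
                  c("Malvasia", "Bual", "Sercial", "Verdelho", "Tinta Negra"))
  expect_true(all(d$age_years %in% c(3, 5, 10, 15, 17, 18, 19, 20)))
  # declared type is consistent with the sugar bands
  expect_equal(classify_wine_type(d$sugar_g_per_L), d$wine_type)
  # variety-type pairings: nobles are single-type, Tinta Negra spans all four
  noble <- dplyr::filter(d, variety != "Tinta Negra")
  expect_equal(dplyr::n_distinct(noble$wine_type[noble$variety == "Malvasia"]), 1)
  tn <- dplyr::filter(d, variety == "Tinta Negra")
  expect_setequal(unique(tn$wine_type),
                  c("dry", "medium_dry", "medium_sweet", "sweet"))
  # both cohorts for every variety
  classes <- tapply(wine_age_class(d$age_years), d$variety,
                    function(x) length(unique(x)))
  expect_true(all(classes == 2))
})

test_that("truth tables encode the family aging directions", {
  lib <- read_voc_library()
  truth <- generate_truth(default_study_design(), lib)
  with_fam <- dplyr::inner_join(truth,
                                dplyr::select(lib, compound_id, family),
                                by = "compound_id")
  expect_true(all(truth$true_conc_ug_per_L >= 0))
  # varietal & fermentative decline, oak/Maillard families rise
  decl <- c("terpenic", "norisoprenoid", "higher_alcohol", "ester")
  rise <- c("furanic", "lactone", "volatile_phenol")
  coefs <- with_fam |> dplyr::distinct(family, aging_coefficient)
  expect_true(all(coefs$aging_coefficient[coefs$family %in% decl] < 1))
  expect_true(all(coefs$aging_coefficient[coefs$family %in% rise] > 1))
  # ethyl pyruvate variety contrast
  ep <- dplyr::inner_join(truth, default_study_design(), by = "wine_id") |>
    dplyr::filter(compound_id == "ethyl_pyruvate",
                  wine_age_class(age_years) == "young")
  expect_equal(unique(ep$true_conc_ug_per_L[ep$variety == "Verdelho"]), 3.54)
  expect_equal(unique(ep$true_conc_ug_per_L[ep$variety != "Verdelho"]), 1.49)
})

test_that("noiseless generation is inverted exactly by the pipeline stages", {
  lib <- read_voc_library()
  study <- generate_study(replicates = 1, noise_cv = 0, seed = 5)
  expect_equal(length(study$samples), 22)
  for (i in c(1, 9, 22)) {
    pt <- study$samples[[i]]
    ident <- identify_peaks(pt, study$ladder, lib)
    expect_equal(sum(ident$accepted), 82)
    q <- semi_quantify(pt, ident)
    tr <- dplyr::filter(study$truth, wine_id == study$metas$wine_id[i])
    m <- dplyr::inner_join(q, tr, by = "compound_id")
    expect_equal(m$rel_conc_ug_per_L, m$true_conc_ug_per_L, tolerance = 1e-12)
    # OT-exceedance set matches the truth's
    scr <- screen_impact_odorants(q, lib)
    truth_over <- dplyr::inner_join(tr, lib, by = "compound_id") |>
      dplyr::filter(!is.na(ot_ug_per_L), true_conc_ug_per_L > ot_ug_per_L)
    expect_setequal(scr$compound_id[which(scr$is_impact)],
                    truth_over$compound_id)
  }
})

test_that("same seed gives identical studies, different seeds differ", {
  a <- generate_study(replicates = 1, seed = 11)
  b <- generate_study(replicates = 1, seed = 11)
  expect_identical(a, b)
  c <- generate_study(replicates = 1, seed = 12)
  expect_false(identical(a$samples[[1]]$peaks$area, c$samples[[1]]$peaks$area))
  # per-sample streams: replicate 2 is regenerable on its own
  full <- generate_study(replicates = 2, seed = 11)
  meta2 <- full$metas[2, ]
  solo <- generate_sample(meta2,
                          dplyr::filter(full$truth, wine_id == meta2$wine_id),
                          full$ladder, read_voc_library(),
                          seed = aromaprofiler:::sample_seed(11, meta2$sample_id))
  expect_equal(solo$peaks, full$samples[[meta2$sample_id]]$peaks)
})

test_that("decoy peaks with sub-threshold resemblance never identify", {
  lib <- read_voc_library()
  study <- generate_study(replicates = 1, noise_cv = 0, seed = 8,
                          n_decoys = 25)
  pt <- study$samples[[1]]
  expect_equal(nrow(pt$peaks), 82 + 25)
  ident <- identify_peaks(pt, study$ladder, lib)
  acc <- dplyr::filter(ident, accepted)
  expect_equal(nrow(acc), 82)
  expect_true(all(acc$resemblance_pct >= 80))
  # accepted set is exactly the generating compound set: precision = recall = 1
  expect_setequal(acc$compound_id, lib$compound_id)
})

test_that("replicate noise behaves like the requested CV", {
  study <- generate_study(design = default_study_design()[1:2, ],
                          replicates = 6, noise_cv = 0.1, seed = 21)
  areas <- purrr::map_dfr(names(study$samples), function(id) {
    pt <- study$samples[[id]]
    tibble::tibble(sample_id = id,
                   wine_id = pt$meta$wine_id,
                   compound_id = pt$peaks$candidate,
                   area = pt$peaks$area)
  })
  rsd <- areas |>
    dplyr::group_by(wine_id, compound_id) |>
    dplyr::summarise(rsd = 100 * sd(area) / mean(area), .groups = "drop")
  expect_gt(median(rsd$rsd), 0.7 * 10)
  expect_lt(median(rsd$rsd), 1.3 * 10)
})
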