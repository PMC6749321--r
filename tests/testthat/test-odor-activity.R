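test_that("OAV is concentration over threshold with a strict impact rule", {
  v <- compute_oav(8, 4)
  expect_equal(v$oav, 2)
  expect_true(v$is_impact)
  # equality at the threshold is not impact
  expect_false(compute_oav(0.05, 0.05)$is_impact)
  expect_false(compute_oav(35000, 35000)$is_impact)
  # unknown threshold -> undefined OAV, never 0 or Inf
  u <- compute_oav(100, NA)
  expect_true(is.na(u$oav) && is.na(u$is_impact))
  expect_error(compute_oav(10, 0), "positive")
})

test_that("screening equals the brute-force threshold filter", {
  lib <- read_voc_library()
  set.seed(5)
  quant <- tibble::tibble(
    sample_id = "s",
    compound_id = lib$compound_id,
    rel_conc_ug_per_L = lib$ot_ug_per_L * runif(82, 0, 2)
  ) |>
    dplyr::mutate(rel_conc_ug_per_L = ifelse(is.na(rel_conc_ug_per_L),
                                             runif(82, 0, 100),
                                             rel_conc_ug_per_L))
  scr <- screen_impact_odorants(quant, lib)
  expect_equal(nrow(scr), 82)
  brute <- lib$compound_id[!is.na(lib$ot_ug_per_L) &
    quant$rel_conc_ug_per_L[match(lib$compound_id, quant$compound_id)] >
      lib$ot_ug_per_L]
  expect_setequal(scr$compound_id[which(scr$is_impact)], brute)
  # sorted by descending OAV, unknown thresholds last
  known <- scr$oav[!is.na(scr$oav)]
  expect_equal(known, sort(known, decreasing = TRUE))
  expect_true(all(is.na(scr$oav[(length(known) + 1):nrow(scr)])))
  # all-zero concentrations flag nothing
  zq <- dplyr::mutate(quant, rel_conc_ug_per_L = 0)
  expect_equal(sum(screen_impact_odorants(zq, lib)$is_impact, na.rm = TRUE), 0)
})

test_that("impact flags are monotone in concentration and OT-missing stays NA", {
  lib <- read_voc_library()
  set.seed(9)
  conc <- runif(82, 0, 3) * dplyr::coalesce(lib$ot_ug_per_L, 50)
  q1 <- tibble::tibble(sample_id = "s", compound_id = lib$compound_id,
                       rel_conc_ug_per_L = conc)
  q2 <- dplyr::mutate(q1, rel_conc_ug_per_L = rel_conc_ug_per_L * 1.5)
  s1 <- screen_impact_odorants(q1, lib)
  s2 <- screen_impact_odorants(q2, lib)
  flagged1 <- s1$compound_id[which(s1$is_impact)]
  flagged2 <- s2$compound_id[which(s2$is_impact)]
  expect_true(all(flagged1 %in% flagged2))
  no_ot <- lib$compound_id[is.na(lib$ot_ug_per_L)]
  expect_true(all(is.na(s1$is_impact[s1$compound_id %in% no_ot])))
})

caramel_fixture <- function() {
  # one old wine per caramel variety; among caramel-note compounds only
  # ethyl butanoate, gamma-octalactone and (Z)-whiskylactone exceed their OTs
  lib <- read_voc_library()
  caramel <- note_carriers("caramel", lib)
  over <- c("ethyl_butanoate", "gamma_octalactone", "z_whiskylactone")
  conc <- ifelse(lib$compound_id %in% over, 3 * lib$ot_ug_per_L,
                 ifelse(is.na(lib$ot_ug_per_L), 1, 0.5 * lib$ot_ug_per_L))
  metas <- tibble::tibble(
    sample_id = c("mal_o", "bual_o", "tn_o"),
    variety = c("Malvasia", "Bual", "Tinta Negra"),
    age_years = 15)
  screens <- purrr::map(metas$sample_id, function(s) {
    screen_impact_odorants(
      tibble::tibble(sample_id = s, compound_id = lib$compound_id,
                     rel_conc_ug_per_L = conc), lib)
  }) |> dplyr::bind_rows()
  list(lib = lib, caramel = caramel, over = over, metas = metas,
       screens = screens)
}

test_that("the caramel note resolves to exactly the over-threshold lactones/esters", {
  fx <- caramel_fixture()
  sens <- read_sensory_profiles()
  tab <- impact_table(fx$screens, fx$metas, fx$lib, sens, age_class = "old")
  caramel_row <- dplyr::filter(tab, note == "caramel")
  expect_equal(strsplit(caramel_row$odorants, "|", fixed = TRUE)[[1]],
               sort(fx$over))
  expect_equal(caramel_row$wines, "Bual|Malvasia|Tinta Negra")
  # gamma-butyrolactone (OT 35,000 ug/L) stayed under threshold -> excluded
  expect_false(grepl("gamma_butyrolactone", caramel_row$odorants))
})

test_that("toast note isolates whiskylactone when only it exceeds threshold", {
  lib <- read_voc_library()
  toast <- note_carriers("toast", lib)
  conc <- ifelse(lib$compound_id == "z_whiskylactone", 2 * lib$ot_ug_per_L,
                 ifelse(is.na(lib$ot_ug_per_L), 1, 0.5 * lib$ot_ug_per_L))
  metas <- tibble::tibble(sample_id = "old1", variety = "Malvasia",
                          age_years = 17)
  scr <- screen_impact_odorants(
    tibble::tibble(sample_id = "old1", compound_id = lib$compound_id,
                   rel_conc_ug_per_L = conc), lib)
  tab <- impact_table(scr, metas, lib, read_sensory_profiles(),
                      age_class = "old")
  expect_equal(dplyr::filter(tab, note == "toast")$odorants, "z_whiskylactone")
  expect_equal(dplyr::filter(tab, note == "toast")$n_odorants, 1L)
})

test_that("impact table lists note-bearing varieties and supports both views", {
  fx <- caramel_fixture()
  sens <- read_sensory_profiles()
  # young citrus wines per the panel: Malvasia, Sercial, Tinta Negra
  young_metas <- tibble::tibble(
    sample_id = paste0("y", 1:5),
    variety = c("Malvasia", "Bual", "Sercial", "Verdelho", "Tinta Negra"),
    age_years = 3)
  lib <- fx$lib
  screens <- purrr::map(young_metas$sample_id, function(s) {
    screen_impact_odorants(
      tibble::tibble(sample_id = s, compound_id = lib$compound_id,
                     rel_conc_ug_per_L = 2 * dplyr::coalesce(lib$ot_ug_per_L, 1)),
      lib)
  }) |> dplyr::bind_rows()
  tab <- impact_table(screens, young_metas, lib, sens, age_class = "young")
  expect_equal(dplyr::filter(tab, note == "citrus")$wines,
               "Malvasia|Sercial|Tinta Negra")
  pv <- impact_table(screens, young_metas, lib, sens, age_class = "young",
                     per_variety = TRUE)
  expect_true(all(c("variety", "odorants") %in% names(pv)))
  expect_equal(sort(dplyr::filter(pv, note == "citrus")$variety),
               c("Malvasia", "Sercial", "Tinta Negra"))
  # a note absent from all profiles yields no rows rather than an error
  expect_equal(nrow(dplyr::filter(tab, note == "violet")), 0)
})

test_that("OT-missing compounds join the table only on explicit request", {
  lib <- read_voc_library()
  metas <- tibble::tibble(sample_id = "o1", variety = "Verdelho",
                          age_years = 15)
  scr <- screen_impact_odorants(
    tibble::tibble(sample_id = "o1", compound_id = lib$compound_id,
                   rel_conc_ug_per_L = 1e6), lib)
  sens <- read_sensory_profiles()
  # ethereal note carriers include ethyl pyruvate, which has no known OT
  with_u <- impact_table(scr, metas, lib, sens, age_class = "old",
                         include_unknown_ot = TRUE)
  without <- impact_table(scr, metas, lib, sens, age_class = "old")
  eth_with <- dplyr::filter(with_u, note == "ethereal")$odorants
  eth_without <- dplyr::filter(without, note == "ethereal")$odorants
  expect_true(grepl("ethyl_pyruvate", eth_with))
  expect_false(grepl("ethyl_pyruvate", eth_without))
})

test_that("note lookup errors on unknown tokens with a vocabulary hint", {
  lib <- read_voc_library()
  expect_error(note_carriers("petrol", lib), "known notes")
  expect_setequal(note_carriers("dried_fruits", lib),
                  union(note_carriers("almond", lib),
                        note_carriers("nutty", lib)))
})
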