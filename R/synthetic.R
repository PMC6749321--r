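#' Synthetic alkane ladder consistent with the published retention indices
#'
#' Builds an n-alkane ladder whose van den Dool--Kratz mapping is compatible
#' with the reference library: anchor retention times are obtained by
#' piecewise-linear interpolation of the library's (calculated KI, retention
#' time) pairs at KI = 100 x carbon number, extended linearly beyond the
#' library's KI range. The default carbon range C8--C28 deliberately extends
#' the instrument's C8--C20 calibration series so that every library compound
#' (KIs up to 2620) lies inside the ladder span; the synthetic generator then
#' places compounds at [rt_from_ki()] of their published KI, which
#' [compute_ki()] inverts exactly.
#'
#' The construction is deterministic: repeated calls (any `seed`) return
#' identical ladders.
#'
#' @param library A `voc_library` supplying the (KI, rt) cloud.
#' @param carbons Integer carbon numbers for the anchors.
#' @param seed Unused (the ladder is deterministic); kept so callers can
#'   thread one seed through all generator calls.
#' @return An [alkane_ladder()].
#' @export
generate_ladder <- function(library = read_voc_library(), carbons = 8:28,
                            seed = NULL) {
  ki <- library$ki_calc
  rt <- library$rt_min
  ord <- order(ki)
  ki <- ki[ord]; rt <- rt[ord]
  # average duplicated KIs, then require a strictly increasing cloud
  agg <- tapply(rt, ki, mean)
  ki_u <- as.numeric(names(agg)); rt_u <- as.numeric(agg)
  if (any(diff(rt_u) <= 0)) {
    abort("library (KI, rt) pairs are not jointly increasing; cannot build a ladder")
  }
  target <- 100 * carbons
  span <- range(ki_u)
  if (diff(span) <= 0) abort("degenerate KI span; cannot build a ladder")
  anchor_rt <- approx(ki_u, rt_u, xout = target, ties = "ordered")$y
  # linear extension beyond the library's KI range
  slope_lo <- diff(rt_u[1:2]) / diff(ki_u[1:2])
  n <- length(ki_u)
  slope_hi <- diff(rt_u[(n - 1):n]) / diff(ki_u[(n - 1):n])
  below <- which(target < span[1]); above <- which(target > span[2])
  anchor_rt[below] <- rt_u[1] + slope_lo * (target[below] - span[1])
  anchor_rt[above] <- rt_u[n] + slope_hi * (target[above] - span[2])
  if (any(anchor_rt <= 0)) anchor_rt <- anchor_rt - min(anchor_rt) + 0.5
  alkane_ladder(carbons, anchor_rt)
}

wine_type_by_variety <- c(Malvasia = "sweet", Bual = "medium_sweet",
                          Sercial = "dry", Verdelho = "medium_dry")

type_sugar_midpoint <- c(dry = 56.95, medium_dry = 72.6,
                         medium_sweet = 88.25, sweet = 123.05)

#' Default 22-wine study design
#'
#' Emulates the study cohort: 22 monovarietal wines over five grape
#' varieties, aged 3--20 years (blended ages 3, 5, 10, 15; vintage ages
#' 17--20), with wine type tied to variety (Malvasia sweet, Bual medium
#' sweet, Sercial dry, Verdelho medium dry) except for Tinta Negra, which is
#' produced in all four types. Sugar is set to the midpoint of each type's
#' band and ethanol to 18.5% v/v (the study wines span 18--19%). Every
#' variety appears in both age classes.
#'
#' @return Tibble `wine_id`, `variety`, `age_years`, `wine_type`,
#'   `sugar_g_per_L`, `ethanol_pct`.
#' @export
default_study_design <- function() {
  noble <- tibble(
    variety = c(rep("Malvasia", 4), rep("Bual", 3), rep("Sercial", 4),
                rep("Verdelho", 3)),
    age_years = c(3, 5, 10, 17,  5, 15, 18,  3, 5, 10, 19,  5, 15, 20)
  ) %>%
    mutate(wine_type = unname(wine_type_by_variety[.data$variety]))
  tn <- tibble(
    variety = "Tinta Negra",
    wine_type = rep(c("dry", "medium_dry", "medium_sweet", "sweet"), each = 2),
    age_years = c(3, 15, 5, 17, 3, 18, 5, 20)
  )
  bind_rows(noble, tn) %>%
    mutate(
      sugar_g_per_L = unname(type_sugar_midpoint[.data$wine_type]),
      ethanol_pct = 18.5,
      wine_id = sprintf("%s_%s_%02dy",
                        tolower(gsub(" ", "_", .data$variety)),
                        .data$wine_type, .data$age_years)
    ) %>%
    select("wine_id", "variety", "age_years", "wine_type", "sugar_g_per_L",
           "ethanol_pct")
}

# aging multipliers: varietal/fermentative families decline from the young to
# the old class, Maillard- and oak-derived families rise
aging_multipliers <- c(terpenic = 0.5, norisoprenoid = 0.5,
                       higher_alcohol = 0.7, ester = 0.7, sulphur = 1.0,
                       acid = 1.1, acetal = 1.3, furanic = 2.0,
                       lactone = 2.0, volatile_phenol = 1.8)

# fallback concentration scale (ug/L) for compounds without a known OT
family_typical_conc <- c(terpenic = 50, norisoprenoid = 10,
                         higher_alcohol = 2000, sulphur = 10, ester = 500,
                         acid = 5000, acetal = 500, furanic = 1000,
                         lactone = 200, volatile_phenol = 50)

#' Ground-truth concentration table for a study design
#'
#' Assigns every (wine, compound) pair a true concentration: a base level of
#' twice the compound's odor threshold when one is known (so the impact
#' screen is exercised on both sides of the threshold once aging multipliers
#' apply), otherwise a family-typical scale, multiplied for old wines by a
#' family aging coefficient (varietal and fermentative families decline,
#' furanic/lactone/volatile-phenol families rise). Ethyl pyruvate is held at
#' 3.54 ug/L in Verdelho wines versus 1.49 ug/L elsewhere, mirroring the
#' study's reported variety contrast. The table is deterministic given the
#' design.
#'
#' @param design A study design ([default_study_design()]).
#' @param library A `voc_library`.
#' @param noise_cv Replicate coefficient of variation recorded per compound
#'   (consumed by [generate_sample()]).
#' @return Tibble `wine_id`, `compound_id`, `true_conc_ug_per_L`,
#'   `aging_coefficient`, `noise_cv`.
#' @export
generate_truth <- function(design, library, noise_cv = 0.05) {
  base <- library %>%
    mutate(base_conc = dplyr::if_else(
      is.na(.data$ot_ug_per_L),
      unname(family_typical_conc[.data$family]),
      2 * .data$ot_ug_per_L
    ),
    aging_coefficient = unname(aging_multipliers[.data$family])) %>%
    select("compound_id", "base_conc", "aging_coefficient")
  tidyr::crossing(select(design, "wine_id", "variety", "age_years"), base) %>%
    mutate(
      age_class = wine_age_class(.data$age_years),
      base_conc = dplyr::if_else(
        .data$compound_id == "ethyl_pyruvate",
        dplyr::if_else(.data$variety == "Verdelho", 3.54, 1.49),
        .data$base_conc
      ),
      true_conc_ug_per_L = dplyr::if_else(
        .data$age_class == "old",
        .data$base_conc * .data$aging_coefficient,
        .data$base_conc
      ),
      noise_cv = noise_cv
    ) %>%
    select("wine_id", "compound_id", "true_conc_ug_per_L",
           "aging_coefficient", "noise_cv")
}

# stable small-integer seed per sample, derived from the study seed
sample_seed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(sample_id) * seq_along(utf8ToInt(sample_id))) %% 99991L
  (as.integer(seed) %% 20011L) * 99991L + h
}

#' Generate one synthetic peak table
#'
#' Simulates a GC-qMS peak list for one sample from a truth table: each
#' compound elutes at the ladder-inverse of its published calculated KI
#' (plus optional retention-time jitter) with a peak area of
#' (true concentration / IS concentration) x IS area, perturbed by
#' multiplicative Gaussian noise with the compound's `noise_cv` (negative
#' draws truncate at zero area). True compounds carry themselves as spectral
#' candidate with a resemblance drawn at or above 85%; optional decoy peaks
#' carry random candidates with resemblance below 80%, so the resemblance
#' rule must reject them.
#'
#' @param meta Sample metadata (named list or one-row data frame with
#'   `sample_id`, `wine_id`, ...).
#' @param truth Rows of [generate_truth()] for this wine.
#' @param ladder The study ladder ([generate_ladder()]).
#' @param library A `voc_library`.
#' @param seed Integer seed for this sample's RNG stream.
#' @param is_area Internal-standard peak area, arbitrary counts.
#' @param is_conc_ug_per_L Internal-standard concentration, ug/L.
#' @param rt_jitter_sd Gaussian retention-time jitter, minutes.
#' @param n_decoys Number of decoy peaks with sub-threshold resemblance.
#' @return A [peak_table()].
#' @export
generate_sample <- function(meta, truth, ladder, library, seed,
                            is_area = 1e6, is_conc_ug_per_L = 250,
                            rt_jitter_sd = 0, n_decoys = 0) {
  if (is.data.frame(meta)) meta <- as.list(meta[1, , drop = FALSE])
  truth <- inner_join(truth,
                      select(library, "compound_id", "ki_calc"),
                      by = "compound_id")
  set.seed(seed)
  rt <- rt_from_ki(ladder, truth$ki_calc)
  if (rt_jitter_sd > 0) rt <- rt + rnorm(nrow(truth), 0, rt_jitter_sd)
  eps <- if (all(truth$noise_cv == 0)) rep(0, nrow(truth)) else {
    rnorm(nrow(truth), 0, truth$noise_cv)
  }
  area <- truth$true_conc_ug_per_L / is_conc_ug_per_L * is_area * (1 + eps)
  clipped <- area < 0
  if (any(clipped)) {
    warn(paste0(sum(clipped), " negative noise draw(s) truncated to zero area"))
    area[clipped] <- 0
  }
  peaks <- tibble(
    rt_min = rt, area = area, candidate = truth$compound_id,
    resemblance_pct = runif(nrow(truth), 85, 99)
  )
  if (n_decoys > 0) {
    span <- range(ladder$rt_min)
    decoys <- tibble(
      rt_min = runif(n_decoys, span[1], span[2]),
      area = is_area * exp(rnorm(n_decoys, -2, 1)),
      candidate = sample(library$compound_id, n_decoys, replace = TRUE),
      resemblance_pct = runif(n_decoys, 50, 79.9)
    )
    peaks <- bind_rows(peaks, decoys) %>% arrange(.data$rt_min)
  }
  peak_table(peaks, meta,
             is_rt_min = rt_from_ki(ladder, 1131, extrapolate = TRUE),
             is_area = is_area, is_conc_ug_per_L = is_conc_ug_per_L)
}

#' Generate a full synthetic study
#'
#' Produces replicate peak tables for every wine of a design together with
#' the generating truth table, so identification, quantification, screening
#' and aggregation can all be validated against known ground truth. Each
#' sample draws from its own RNG stream derived from (`seed`, sample id), so
#' any single sample can be regenerated independently; the full output is
#' byte-identical under a fixed seed.
#'
#' @inheritParams generate_sample
#' @param design Study design tibble ([default_study_design()]).
#' @param replicates Replicate measurements per wine.
#' @param noise_cv Replicate coefficient of variation (multiplicative
#'   Gaussian).
#' @param seed Study master seed.
#' @return List with `samples` (named list of [peak_table()]s), `truth`,
#'   `design`, `metas` (per-sample metadata tibble) and `ladder`.
#' @export
#' @examples
#' \donttest{
#' study <- generate_study(replicates = 1, noise_cv = 0)
#' length(study$samples)
#' }
generate_study <- function(design = default_study_design(),
                           library = read_voc_library(),
                           ladder = generate_ladder(library),
                           replicates = 3, noise_cv = 0.05, seed = 1,
                           rt_jitter_sd = 0, n_decoys = 0) {
  if (replicates < 1) abort("replicates must be >= 1")
  truth <- generate_truth(design, library, noise_cv = noise_cv)
  metas <- tidyr::crossing(design, replicate = seq_len(replicates)) %>%
    mutate(sample_id = sprintf("%s_r%d", .data$wine_id, .data$replicate))
  samples <- purrr::map(seq_len(nrow(metas)), function(i) {
    m <- as.list(metas[i, , drop = FALSE])
    generate_sample(
      meta = m,
      truth = filter(truth, .data$wine_id == m$wine_id),
      ladder = ladder, library = library,
      seed = sample_seed(seed, m$sample_id),
      rt_jitter_sd = rt_jitter_sd, n_decoys = n_decoys
    )
  })
  names(samples) <- metas$sample_id
  list(samples = samples, truth = truth, design = design, metas = metas,
       ladder = ladder)
}
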