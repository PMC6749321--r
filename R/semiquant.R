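#' Internal-standard semi-quantification
#'
#' Converts accepted identifications' peak areas into concentrations relative
#' to the spiked internal standard:
#' concentration = (compound peak area / IS peak area) x IS concentration.
#' This is a semi-quantification -- linear through the origin in area, with no
#' calibration curve or matrix-effect correction -- which is all the
#' downstream odor-activity screening requires.
#'
#' @param peaks A [peak_table()]; its IS peak area must be positive.
#' @param identified Output of [identify_peaks()] for the same sample; only
#'   rows with `accepted = TRUE` are quantified.
#' @return Tibble `sample_id`, `compound_id`, `rel_conc_ug_per_L`, with the IS
#'   concentration attached as attribute `is_conc_ug_per_L`.
#' @export
semi_quantify <- function(peaks, identified) {
  if (!inherits(peaks, "peak_table")) abort("peaks must be a peak_table")
  is_area <- peaks$is_peak$area
  if (!is.finite(is_area) || is_area <= 0) {
    abort("internal-standard peak area must be positive")
  }
  acc <- filter(identified, .data$accepted, !is.na(.data$compound_id))
  if (any(acc$peak_id > nrow(peaks$peaks) | acc$peak_id < 1)) {
    abort("identifications reference peaks outside the peak table")
  }
  out <- tibble(
    sample_id = peaks$meta$sample_id,
    compound_id = acc$compound_id,
    rel_conc_ug_per_L = acc$area / is_area * peaks$is_conc_ug_per_L
  )
  attr(out, "is_conc_ug_per_L") <- peaks$is_conc_ug_per_L
  out
}

#' Relative standard deviation across replicates
#'
#' Per-compound %RSD (100 x sd / mean, sample standard deviation) over
#' replicate quantifications of the same wine. Compounds whose replicate mean
#' is zero have an undefined RSD and are flagged rather than reported as 0 or
#' infinity.
#'
#' @param quants Long tibble of replicate quantifications
#'   (`sample_id`, `compound_id`, `rel_conc_ug_per_L`), e.g. several
#'   [semi_quantify()] results row-bound together. Compounds absent from a
#'   replicate are treated as 0 ug/L in that replicate.
#' @return Tibble `compound_id`, `n`, `mean`, `sd`, `rsd_pct`, `undefined`.
#' @export
#' @examples
#' q <- tibble::tibble(sample_id = rep(c("a", "b", "c"), each = 1),
#'                     compound_id = "x", rel_conc_ug_per_L = c(90, 100, 110))
#' replicate_rsd(q)
replicate_rsd <- function(quants) {
  reps <- unique(quants$sample_id)
  if (length(reps) < 2) {
    abort("replicate_rsd needs at least 2 replicates (distinct sample_id)")
  }
  quants %>%
    tidyr::complete(sample_id = reps, compound_id = unique(quants$compound_id),
                    fill = list(rel_conc_ug_per_L = 0)) %>%
    group_by(.data$compound_id) %>%
    summarise(n = dplyr::n(),
              mean = mean(.data$rel_conc_ug_per_L),
              sd = sd(.data$rel_conc_ug_per_L), .groups = "drop") %>%
    mutate(undefined = .data$mean == 0,
           rsd_pct = ifelse(.data$undefined, NA_real_,
                            100 * .data$sd / .data$mean)) %>%
    select("compound_id", "n", "mean", "sd", "rsd_pct", "undefined")
}

#' Aggregate concentrations by chemical family and age class
#'
#' Reconstructs family-level aging trends: per chemical family and age class,
#' the total of the member compounds' mean relative concentrations (mean over
#' all samples of that age class, compounds missing from a sample counted as
#' 0). For the old age class a trend flag against the young class is derived:
#' `increase` / `decrease` when the old total differs from the young total by
#' more than `flat_tol_pct` percent, `flat` otherwise; trends are undefined
#' (`NA`) when only one age class is present.
#'
#' @param quants Long quantification tibble (`sample_id`, `compound_id`,
#'   `rel_conc_ug_per_L`) covering many samples.
#' @param metas Tibble with `sample_id` and `age_years` (plus any other
#'   metadata) for every quantified sample.
#' @param library A `voc_library`; every quantified compound must appear in it.
#' @param flat_tol_pct Relative change (percent) below which a trend counts as
#'   flat.
#' @return Tibble `family`, `age_class`, `total_rel_conc_ug_per_L`,
#'   `n_samples`, `trend`.
#' @export
aggregate_families <- function(quants, metas, library, flat_tol_pct = 5) {
  unknown <- setdiff(unique(quants$compound_id), library$compound_id)
  if (length(unknown) > 0) {
    abort(paste0("compound id(s) not in library: ",
                 paste(unknown, collapse = ", ")))
  }
  metas <- mutate(metas, age_class = wine_age_class(.data$age_years))
  missing_meta <- setdiff(unique(quants$sample_id), metas$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("no metadata for sample(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  long <- quants %>%
    inner_join(select(metas, "sample_id", "age_class"), by = "sample_id") %>%
    filter(!is.na(.data$age_class))
  n_per_class <- long %>% distinct(.data$age_class, .data$sample_id) %>%
    dplyr::count(.data$age_class, name = "n_samples")
  totals <- long %>%
    # mean per compound over the class's samples, absentees as zero
    group_by(.data$age_class, .data$compound_id) %>%
    summarise(total_conc = sum(.data$rel_conc_ug_per_L), .groups = "drop") %>%
    left_join(n_per_class, by = "age_class") %>%
    mutate(mean_conc = .data$total_conc / .data$n_samples) %>%
    left_join(select(library, "compound_id", "family"), by = "compound_id") %>%
    group_by(.data$family, .data$age_class, .data$n_samples) %>%
    summarise(total_rel_conc_ug_per_L = sum(.data$mean_conc),
              .groups = "drop")
  both <- all(c("young", "old") %in% totals$age_class)
  young_tot <- totals %>% filter(.data$age_class == "young") %>%
    select("family", young = "total_rel_conc_ug_per_L")
  totals %>%
    left_join(young_tot, by = "family") %>%
    mutate(trend = dplyr::if_else(
      .data$age_class == "old" & both & !is.na(.data$young),
      case_when(
        .data$total_rel_conc_ug_per_L > .data$young * (1 + flat_tol_pct / 100) ~ "increase",
        .data$total_rel_conc_ug_per_L < .data$young * (1 - flat_tol_pct / 100) ~ "decrease",
        TRUE ~ "flat"
      ),
      NA_character_
    )) %>%
    select("family", "age_class", "total_rel_conc_ug_per_L", "n_samples",
           "trend") %>%
    arrange(.data$family, .data$age_class)
}
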