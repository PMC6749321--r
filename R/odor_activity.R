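#' Odor activity value
#'
#' OAV = relative concentration / odor threshold. A compound is flagged a
#' potential impact odorant when its concentration strictly exceeds its odor
#' threshold (OAV > 1); a concentration exactly at threshold is not impact.
#' When the threshold is unknown the OAV and the impact flag are both `NA` --
#' never silently 0 or infinite.
#'
#' @param rel_conc_ug_per_L Relative concentrations, ug/L.
#' @param ot_ug_per_L Odor thresholds, ug/L; `NA` for unknown, must be
#'   positive otherwise.
#' @return Tibble `rel_conc_ug_per_L`, `ot_ug_per_L`, `oav`, `is_impact`.
#' @export
#' @examples
#' compute_oav(8, 4)        # OAV 2, impact
#' compute_oav(0.05, 0.05)  # OAV 1, not impact
compute_oav <- function(rel_conc_ug_per_L, ot_ug_per_L) {
  if (any(!is.na(ot_ug_per_L) & ot_ug_per_L <= 0)) {
    abort("odor thresholds must be positive (or NA when unknown)")
  }
  oav <- rel_conc_ug_per_L / ot_ug_per_L
  tibble(rel_conc_ug_per_L = rel_conc_ug_per_L,
         ot_ug_per_L = ot_ug_per_L,
         oav = oav,
         is_impact = oav > 1)
}

#' Screen quantified compounds against odor thresholds
#'
#' One OAV record per quantified compound of a sample, sorted by descending
#' OAV with threshold-less compounds last. Equivalent to the brute-force
#' filter \{c : conc(c) > OT(c)\} for the impact set.
#'
#' @param quant A [semi_quantify()] result (or any tibble with `sample_id`,
#'   `compound_id`, `rel_conc_ug_per_L`).
#' @param library A `voc_library` supplying thresholds and families.
#' @return Tibble `sample_id`, `compound_id`, `name`, `family`,
#'   `rel_conc_ug_per_L`, `ot_ug_per_L`, `oav`, `is_impact`.
#' @export
screen_impact_odorants <- function(quant, library) {
  unknown <- setdiff(unique(quant$compound_id), library$compound_id)
  if (length(unknown) > 0) {
    abort(paste0("compound id(s) not in library: ",
                 paste(unknown, collapse = ", ")))
  }
  quant %>%
    inner_join(select(library, "compound_id", "name", "family",
                      "ot_ug_per_L"), by = "compound_id") %>%
    mutate(oav = .data$rel_conc_ug_per_L / .data$ot_ug_per_L,
           is_impact = .data$oav > 1) %>%
    arrange(is.na(.data$oav), desc(.data$oav), .data$compound_id) %>%
    select("sample_id", "compound_id", "name", "family",
           "rel_conc_ug_per_L", "ot_ug_per_L", "oav", "is_impact")
}

#' Potential impact odorants per aroma note
#'
#' Rebuilds the note-by-note impact-odorant table: for each aroma note
#' appearing in the sensory profiles of an age class, the varieties whose
#' profiles carry the note, intersected with the compounds that (a) carry the
#' note among their flagged aroma notes (composite notes such as dried fruits
#' expand to their member descriptors first) and (b) were impact-flagged in
#' at least one screened sample of those varieties and that age class.
#' Compounds with no known odor threshold are excluded unless
#' `include_unknown_ot = TRUE`, in which case they join with an
#' `ot_known = FALSE` flag.
#'
#' Because the panel evidence can be merged across varieties in more than one
#' way, both a merged view (one row per note) and a per-variety view are
#' available.
#'
#' @param screens Row-bound [screen_impact_odorants()] results over many
#'   samples.
#' @param metas Tibble with `sample_id`, `variety`, `age_years` for every
#'   screened sample.
#' @param library A `voc_library`.
#' @param sensory Sensory profiles ([read_sensory_profiles()]).
#' @param age_class `"young"`, `"old"`, or both (default).
#' @param per_variety If `TRUE`, one row per (note, variety) instead of the
#'   merged note row.
#' @param include_unknown_ot Admit compounds without a known threshold.
#' @param groups Composite-note expansion map ([note_groups()]).
#' @return Tibble `note`, `age_class`, `wines` (pipe-separated varieties, or a
#'   `variety` column when `per_variety`), `odorants` (pipe-separated
#'   compound ids), `n_odorants`.
#' @export
impact_table <- function(screens, metas, library, sensory,
                         age_class = c("young", "old"), per_variety = FALSE,
                         include_unknown_ot = FALSE, groups = note_groups()) {
  age_class <- match.arg(age_class, several.ok = TRUE)
  # panel-only notes (e.g. mushroom, tea) legitimately have no compound link;
  # they yield empty odorant sets rather than errors
  metas <- mutate(metas, age_class = wine_age_class(.data$age_years))
  screens <- screens %>%
    inner_join(select(metas, "sample_id", "variety", "age_class"),
               by = "sample_id")
  note_rows <- sensory %>%
    filter(.data$age_class %in% !!age_class) %>%
    tidyr::unnest_longer("notes", values_to = "note") %>%
    select("variety", "age_class", "note")

  carriers <- function(note) {
    members <- expand_notes(note, groups)
    library$compound_id[purrr::map_lgl(library$aroma_notes,
                                       ~ length(intersect(.x, members)) > 0)]
  }
  ot_known <- setNames(!is.na(library$ot_ug_per_L), library$compound_id)

  per_rows <- note_rows %>%
    group_by(.data$note, .data$age_class, .data$variety) %>%
    summarise(.groups = "drop") %>%
    mutate(odorants = purrr::pmap(list(.data$note, .data$age_class,
                                       .data$variety),
      function(note, ac, var) {
        cand <- carriers(note)
        if (!include_unknown_ot) cand <- cand[ot_known[cand]]
        hits <- screens %>%
          filter(.data$variety == var, .data$age_class == ac,
                 .data$compound_id %in% cand,
                 # impact-flagged, or threshold unknown when those are admitted
                 .data$is_impact %in% TRUE |
                   (include_unknown_ot & is.na(.data$is_impact)))
        sort(unique(hits$compound_id))
      }))
  if (per_variety) {
    return(per_rows %>%
             mutate(n_odorants = lengths(.data$odorants),
                    odorants = join_tokens(.data$odorants)) %>%
             arrange(.data$age_class, .data$note, .data$variety))
  }
  per_rows %>%
    group_by(.data$note, .data$age_class) %>%
    summarise(wines = paste(sort(unique(.data$variety)), collapse = "|"),
              odorants = list(sort(unique(unlist(.data$odorants)))),
              .groups = "drop") %>%
    mutate(n_odorants = lengths(.data$odorants),
           odorants = join_tokens(.data$odorants)) %>%
    arrange(.data$age_class, .data$note)
}

#' Look up compounds carrying an aroma note
#'
#' Convenience accessor used by the impact table and the network module;
#' errors on a token absent from both the library's note vocabulary and the
#' composite-note groups, suggesting the known vocabulary.
#'
#' @inheritParams impact_table
#' @param note A single descriptor token.
#' @return Character vector of compound ids.
#' @export
note_carriers <- function(note, library, groups = note_groups()) {
  vocab <- sort(unique(c(unlist(library$aroma_notes), names(groups))))
  if (!note %in% vocab) {
    abort(paste0("unknown aroma note '", note, "'; known notes: ",
                 paste(vocab, collapse = ", ")))
  }
  members <- expand_notes(note, groups)
  library$compound_id[purrr::map_lgl(library$aroma_notes,
                                     ~ length(intersect(.x, members)) > 0)]
}
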