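#' Construct an n-alkane retention ladder
#'
#' Anchors for Kovats retention-index computation: straight-chain alkane
#' carbon numbers and their retention times under the chromatographic
#' program. Carbon numbers must be strictly increasing; gaps in the series
#' are tolerated but flagged, since interpolation across a gap spans more
#' than 100 index units.
#'
#' @param carbon Integer vector of alkane carbon numbers (e.g. 8:20).
#' @param rt_min Retention times in minutes, strictly increasing.
#' @return A tibble of class `alkane_ladder` with columns `carbon`, `rt_min`
#'   and attribute `gaps` (carbon numbers missing from the covered range).
#' @export
#' @examples
#' alkane_ladder(8:12, c(2, 5, 9, 14, 20))
alkane_ladder <- function(carbon, rt_min) {
  if (length(carbon) != length(rt_min) || length(carbon) < 2) {
    abort("carbon and rt_min must have equal length >= 2")
  }
  if (any(diff(carbon) <= 0)) abort("carbon numbers must be strictly increasing")
  if (any(diff(rt_min) <= 0)) abort("ladder rt_min must be strictly increasing")
  gaps <- setdiff(seq(min(carbon), max(carbon)), carbon)
  if (length(gaps) > 0) {
    warn(paste0("alkane ladder has gaps at C", paste(gaps, collapse = ", C"),
                "; interpolation across a gap spans >100 KI units"))
  }
  out <- tibble(carbon = as.integer(carbon), rt_min = as.numeric(rt_min))
  attr(out, "gaps") <- gaps
  class(out) <- unique(c("alkane_ladder", class(out)))
  out
}

ladder_check <- function(ladder) {
  if (!inherits(ladder, "alkane_ladder")) {
    ladder <- alkane_ladder(ladder$carbon, ladder$rt_min)
  }
  ladder
}

#' Kovats retention index under a temperature program
#'
#' Computes Kovats indices by the van den Dool--Kratz convention for
#' temperature-programmed GC: between bracketing alkane anchors Cn and Cn+1,
#' KI = 100 n + 100 (rt - rt_n) / (rt_n+1 - rt_n), i.e. piecewise-linear
#' interpolation of 100 x carbon number against retention time. The index is
#' exactly 100 n at each anchor and strictly increasing in retention time.
#'
#' @param ladder An [alkane_ladder()].
#' @param rt_min Retention times (minutes) to convert; vectorized.
#' @param extrapolate Allow linear extrapolation beyond the first/last anchor
#'   using the terminal segment slope. Off by default: out-of-span retention
#'   times then raise an error naming the covered span.
#' @return Numeric vector of Kovats indices.
#' @export
#' @examples
#' lad <- alkane_ladder(8:12, c(2, 5, 9, 14, 20))
#' compute_ki(lad, c(5, 11.5))
compute_ki <- function(ladder, rt_min, extrapolate = FALSE) {
  ladder <- ladder_check(ladder)
  lo <- min(ladder$rt_min); hi <- max(ladder$rt_min)
  out_of_span <- rt_min < lo | rt_min > hi
  if (any(out_of_span, na.rm = TRUE) && !extrapolate) {
    abort(paste0("retention time(s) ",
                 paste(format(rt_min[which(out_of_span)]), collapse = ", "),
                 " min outside ladder span [", format(lo), ", ", format(hi),
                 "] min (C", min(ladder$carbon), "-C", max(ladder$carbon),
                 "); enable extrapolate to allow"))
  }
  ki <- approx(ladder$rt_min, 100 * ladder$carbon, xout = rt_min,
               ties = "ordered")$y
  if (extrapolate && any(out_of_span, na.rm = TRUE)) {
    n <- nrow(ladder)
    slope_lo <- 100 * diff(ladder$carbon[1:2]) / diff(ladder$rt_min[1:2])
    slope_hi <- 100 * diff(ladder$carbon[(n - 1):n]) /
      diff(ladder$rt_min[(n - 1):n])
    below <- which(rt_min < lo)
    above <- which(rt_min > hi)
    ki[below] <- 100 * ladder$carbon[1] + slope_lo * (rt_min[below] - lo)
    ki[above] <- 100 * ladder$carbon[n] + slope_hi * (rt_min[above] - hi)
  }
  ki
}

#' Retention time at a given Kovats index
#'
#' Inverse of [compute_ki()] on the same ladder: maps target indices back to
#' retention times by piecewise-linear interpolation. Used by the synthetic
#' peak generator to place compounds at retention times that reproduce their
#' published calculated KIs exactly.
#'
#' @inheritParams compute_ki
#' @param ki Kovats indices to invert; vectorized.
#' @return Retention times in minutes.
#' @export
rt_from_ki <- function(ladder, ki, extrapolate = FALSE) {
  ladder <- ladder_check(ladder)
  lo <- 100 * min(ladder$carbon); hi <- 100 * max(ladder$carbon)
  out_of_span <- ki < lo | ki > hi
  if (any(out_of_span, na.rm = TRUE) && !extrapolate) {
    abort(paste0("KI value(s) outside ladder span [", lo, ", ", hi,
                 "]; enable extrapolate to allow"))
  }
  rt <- approx(100 * ladder$carbon, ladder$rt_min, xout = ki,
               ties = "ordered")$y
  if (extrapolate && any(out_of_span, na.rm = TRUE)) {
    n <- nrow(ladder)
    slope_lo <- diff(ladder$rt_min[1:2]) / (100 * diff(ladder$carbon[1:2]))
    slope_hi <- diff(ladder$rt_min[(n - 1):n]) /
      (100 * diff(ladder$carbon[(n - 1):n]))
    below <- which(ki < lo); above <- which(ki > hi)
    rt[below] <- ladder$rt_min[1] + slope_lo * (ki[below] - lo)
    rt[above] <- ladder$rt_min[n] + slope_hi * (ki[above] - hi)
  }
  rt
}

#' Rank library compounds against a calculated Kovats index
#'
#' Candidate compounds are library records with a literature KI satisfying
#' both the absolute tolerance |KIcalc - KIlit| <= `abs_tol` (default 35
#' index units) and the relative tolerance 100 |KIcalc - KIlit| / KIlit <=
#' `rel_tol_pct` (default 5%). Candidates are sorted by ascending |deltaKI|,
#' ties broken by `compound_id` lexicographically; an empty result is a valid
#' outcome.
#'
#' @param ki_calc A single calculated Kovats index.
#' @param library A `voc_library` tibble.
#' @param abs_tol Absolute KI tolerance, index units (> 0).
#' @param rel_tol_pct Relative KI tolerance, percent (> 0).
#' @return Tibble `compound_id`, `name`, `ki_lit`, `delta_ki`, `rel_dev_pct`.
#' @export
#' @examples
#' match_compound(1537, read_voc_library())
match_compound <- function(ki_calc, library, abs_tol = 35, rel_tol_pct = 5) {
  stopifnot(length(ki_calc) == 1, is.finite(ki_calc))
  if (abs_tol <= 0 || rel_tol_pct <= 0) abort("tolerances must be positive")
  ki_query <- ki_calc  # the library also has a ki_calc column; avoid masking
  library %>%
    filter(!is.na(.data$ki_lit)) %>%
    mutate(delta_ki = abs(.env$ki_query - .data$ki_lit),
           rel_dev_pct = 100 * .data$delta_ki / .data$ki_lit) %>%
    filter(.data$delta_ki <= abs_tol, .data$rel_dev_pct <= rel_tol_pct) %>%
    arrange(.data$delta_ki, .data$compound_id) %>%
    select("compound_id", "name", "ki_lit", "delta_ki", "rel_dev_pct")
}

#' Identify peaks by spectral resemblance and Kovats-index agreement
#'
#' Applies the study's identification rules to a sample's peak table. A peak
#' is accepted iff (i) when a spectral-match candidate with a resemblance
#' score is present, the resemblance is at least `min_resemblance_pct`
#' (default 80%), and (ii) when the matched compound has a literature KI, the
#' calculated KI agrees within `abs_tol` index units and `rel_tol_pct`
#' percent. Peaks without a spectral candidate are matched by KI alone
#' ([match_compound()]) and flagged as lower-tier (`RI`-only) evidence. Each
#' library compound is assigned to at most one peak: smallest |deltaKI| wins,
#' then largest area, then elution order.
#'
#' The `evidence_tier` records what supported an identification: `MS` when a
#' passing spectral match existed, `RI` when a literature KI was available and
#' agreed, and `Std` when the library record itself is standard-confirmed and
#' the spectral match passed.
#'
#' @param peaks A [peak_table()] (its internal-standard peak must be present)
#'   or a plain tibble with columns `rt_min`, `area`, `candidate`,
#'   `resemblance_pct`.
#' @inheritParams compute_ki
#' @inheritParams match_compound
#' @param min_resemblance_pct Minimum NIST resemblance, percent.
#' @return Tibble with one row per peak: `peak_id`, `compound_id`, `rt_min`,
#'   `area`, `ki_calc`, `delta_ki`, `resemblance_pct`, `evidence_tier`,
#'   `accepted`, `reason`.
#' @export
identify_peaks <- function(peaks, ladder, library, min_resemblance_pct = 80,
                           abs_tol = 35, rel_tol_pct = 5,
                           extrapolate = FALSE) {
  if (inherits(peaks, "peak_table")) {
    if (is.null(peaks$is_peak) || !is.finite(peaks$is_peak$area) ||
        peaks$is_peak$area <= 0) {
      abort("internal-standard peak missing or empty: quantification downstream is impossible")
    }
    tbl <- peaks$peaks
  } else {
    tbl <- as_tibble(peaks)
  }
  if (!"candidate" %in% names(tbl)) tbl$candidate <- NA_character_
  if (!"resemblance_pct" %in% names(tbl)) tbl$resemblance_pct <- NA_real_
  n_pk <- nrow(tbl)
  if (n_pk == 0) {
    return(tibble(peak_id = integer(), compound_id = character(),
                  rt_min = numeric(), area = numeric(), ki_calc = numeric(),
                  delta_ki = numeric(), resemblance_pct = numeric(),
                  evidence_tier = character(), accepted = logical(),
                  reason = character()))
  }
  ki <- compute_ki(ladder, tbl$rt_min, extrapolate = extrapolate)
  lib_ki_lit <- setNames(library$ki_lit, library$compound_id)
  lib_std <- setNames(purrr::map_lgl(library$evidence, ~ "Std" %in% .x),
                      library$compound_id)

  rows <- purrr::map(seq_len(n_pk), function(i) {
    cand <- tbl$candidate[i]
    res <- tbl$resemblance_pct[i]
    if (!is.na(cand)) {
      if (!cand %in% library$compound_id) {
        return(tibble(peak_id = i, compound_id = cand, ki_calc = ki[i],
                      delta_ki = NA_real_, evidence_tier = "",
                      accepted = FALSE, reason = "candidate not in library"))
      }
      ms_ok <- !is.na(res) && res >= min_resemblance_pct
      ki_lit <- lib_ki_lit[[cand]]
      dki <- if (is.na(ki_lit)) NA_real_ else abs(ki[i] - ki_lit)
      ki_ok <- is.na(ki_lit) ||
        (dki <= abs_tol && 100 * dki / ki_lit <= rel_tol_pct)
      tier <- c(if (ms_ok) "MS",
                if (!is.na(ki_lit) && ki_ok) "RI",
                if (ms_ok && lib_std[[cand]]) "Std")
      reason <- if (!ms_ok) {
        if (is.na(res)) "candidate lacks resemblance score"
        else paste0("resemblance ", res, "% below threshold")
      } else if (!ki_ok) "KI outside tolerance" else ""
      tibble(peak_id = i, compound_id = cand, ki_calc = ki[i],
             delta_ki = dki, evidence_tier = paste(tier, collapse = "|"),
             accepted = ms_ok && ki_ok, reason = reason)
    } else {
      cands <- match_compound(ki[i], library, abs_tol, rel_tol_pct)
      if (nrow(cands) == 0) {
        tibble(peak_id = i, compound_id = NA_character_, ki_calc = ki[i],
               delta_ki = NA_real_, evidence_tier = "", accepted = FALSE,
               reason = "no KI match")
      } else {
        tibble(peak_id = i, compound_id = cands$compound_id[1],
               ki_calc = ki[i], delta_ki = cands$delta_ki[1],
               evidence_tier = "RI", accepted = TRUE, reason = "")
      }
    }
  })
  out <- bind_rows(rows) %>%
    mutate(rt_min = tbl$rt_min[.data$peak_id],
           area = tbl$area[.data$peak_id],
           resemblance_pct = tbl$resemblance_pct[.data$peak_id])

  # one peak per library compound: best |deltaKI|, then largest area
  out <- out %>%
    arrange(.data$compound_id, is.na(.data$delta_ki), .data$delta_ki,
            desc(.data$area), .data$peak_id) %>%
    group_by(.data$compound_id) %>%
    mutate(dup = .data$accepted & cumsum(.data$accepted) > 1) %>%
    ungroup() %>%
    mutate(reason = ifelse(.data$dup, "better peak assigned to compound",
                           .data$reason),
           accepted = .data$accepted & !.data$dup) %>%
    select(-"dup") %>%
    arrange(.data$peak_id) %>%
    select("peak_id", "compound_id", "rt_min", "area", "ki_calc", "delta_ki",
           "resemblance_pct", "evidence_tier", "accepted", "reason")
  out
}

#' Library-wide Kovats deviation report
#'
#' Summarizes the agreement between calculated and literature Kovats indices
#' over all library records carrying a literature value: absolute deviation
#' range and the worst relative deviation, with a per-compound table sorted
#' by decreasing |deltaKI|. For the packaged library the deviations fall
#' within the 0--35 index-unit band (below 5% relative) that justifies the
#' default matching tolerances.
#'
#' @param library A `voc_library` tibble.
#' @return Object of class `ki_deviation_report`: list with `summary` (one-row
#'   tibble: `n`, `min_abs`, `max_abs`, `max_rel_pct`) and `table`
#'   (per-compound tibble). [tidy()] returns the table, [glance()] the
#'   summary.
#' @export
#' @examples
#' glance(ki_deviation_report(read_voc_library()))
ki_deviation_report <- function(library) {
  per <- library %>%
    filter(!is.na(.data$ki_lit)) %>%
    mutate(delta_ki = abs(.data$ki_calc - .data$ki_lit),
           rel_dev_pct = 100 * .data$delta_ki / .data$ki_lit) %>%
    arrange(desc(.data$delta_ki), .data$compound_id) %>%
    select("compound_id", "name", "family", "ki_calc", "ki_lit", "delta_ki",
           "rel_dev_pct")
  summary <- tibble(
    n = nrow(per),
    min_abs = min(per$delta_ki),
    max_abs = max(per$delta_ki),
    max_rel_pct = max(per$rel_dev_pct)
  )
  structure(list(summary = summary, table = per),
            class = "ki_deviation_report")
}

#' @export
print.ki_deviation_report <- function(x, ...) {
  cat("<ki_deviation_report>", x$summary$n, "compounds with literature KI\n")
  cat("  |deltaKI| range:", x$summary$min_abs, "-", x$summary$max_abs,
      "index units; worst relative deviation",
      format(x$summary$max_rel_pct, digits = 3), "%\n")
  print(head(x$table, 5))
  invisible(x)
}
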