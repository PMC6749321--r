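#' Construct a per-sample peak table
#'
#' Bundles one sample's detected chromatographic peaks with its internal
#' standard (IS) peak and metadata. Peaks carry a retention time, an area in
#' arbitrary detector counts, and optionally a spectral-match candidate
#' (library `compound_id`) with its NIST resemblance percentage. The IS
#' (4-methyl-2-pentanol, spiked at 250 ug/L unless stated otherwise) anchors
#' all downstream semi-quantification.
#'
#' @param peaks Tibble with columns `rt_min`, `area`, and optionally
#'   `candidate`, `resemblance_pct`.
#' @param meta Named list or one-row data frame of sample metadata; must
#'   contain `sample_id`.
#' @param is_rt_min,is_area Retention time and area of the internal-standard
#'   peak; `is_area` must be positive.
#' @param is_conc_ug_per_L Spiked IS concentration, ug/L.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(peaks, meta, is_rt_min, is_area,
                       is_conc_ug_per_L = 250) {
  peaks <- as_tibble(peaks)
  if (!all(c("rt_min", "area") %in% names(peaks))) {
    abort("peaks must have columns rt_min and area")
  }
  if (!"candidate" %in% names(peaks)) peaks$candidate <- NA_character_
  if (!"resemblance_pct" %in% names(peaks)) peaks$resemblance_pct <- NA_real_
  if (any(peaks$area < 0, na.rm = TRUE)) abort("peak areas must be >= 0")
  bad_res <- !is.na(peaks$resemblance_pct) &
    (peaks$resemblance_pct < 0 | peaks$resemblance_pct > 100)
  if (any(bad_res)) abort("resemblance_pct must lie in [0, 100]")
  if (is.data.frame(meta)) meta <- as.list(meta[1, , drop = FALSE])
  if (is.null(meta$sample_id)) abort("meta must contain sample_id")
  if (!is.finite(is_area) || is_area <= 0) {
    abort("internal-standard peak area must be positive")
  }
  structure(
    list(peaks = peaks, meta = meta,
         is_peak = list(rt_min = is_rt_min, area = is_area),
         is_conc_ug_per_L = is_conc_ug_per_L),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> sample", x$meta$sample_id, "-", nrow(x$peaks), "peaks\n")
  cat("  IS: rt", format(x$is_peak$rt_min), "min, area",
      format(x$is_peak$area), ", conc", x$is_conc_ug_per_L, "ug/L\n")
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra) > 0) {
    cat("  meta:", paste(extra, unlist(x$meta[extra]), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a peak table as CSV plus YAML sidecar
#'
#' The CSV holds the peak list (`sample_id`, `rt_min`, `area`, `candidate`,
#' `resemblance_pct`) including a row for the internal standard flagged by
#' `candidate = "__IS__"`; the YAML sidecar carries the sample metadata and
#' the IS concentration.
#'
#' @param pt A `peak_table`.
#' @param dir Output directory (created if needed).
#' @return `write_peak_table()` the two file paths, invisibly;
#'   `read_peak_table()` a `peak_table`.
#' @export
write_peak_table <- function(pt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- pt$meta$sample_id
  csv <- file.path(dir, paste0(id, ".csv"))
  yml <- file.path(dir, paste0(id, ".yaml"))
  rows <- bind_rows(
    mutate(pt$peaks, sample_id = id),
    tibble(rt_min = pt$is_peak$rt_min, area = pt$is_peak$area,
           candidate = "__IS__", resemblance_pct = NA_real_, sample_id = id)
  )
  readr::write_csv(select(rows, "sample_id", "rt_min", "area", "candidate",
                          "resemblance_pct"), csv, na = "")
  meta <- pt$meta
  meta$is_conc_ug_per_L <- pt$is_conc_ug_per_L
  yaml::write_yaml(meta, yml)
  invisible(c(csv = csv, yaml = yml))
}

#' @rdname write_peak_table
#' @param csv_path,yaml_path Paths written by `write_peak_table()`.
#' @export
read_peak_table <- function(csv_path, yaml_path) {
  rows <- readr::read_csv(csv_path, col_types = readr::cols(
    sample_id = readr::col_character(), rt_min = readr::col_double(),
    area = readr::col_double(), candidate = readr::col_character(),
    resemblance_pct = readr::col_double()
  ), na = "", progress = FALSE)
  meta <- yaml::read_yaml(yaml_path)
  is_conc <- meta$is_conc_ug_per_L %||% 250
  meta$is_conc_ug_per_L <- NULL
  is_row <- which(!is.na(rows$candidate) & rows$candidate == "__IS__")
  if (length(is_row) != 1) {
    abort(paste0("Peak-table file ", csv_path,
                 " must contain exactly one internal-standard row"))
  }
  peak_table(
    peaks = select(rows[-is_row, ], "rt_min", "area", "candidate",
                   "resemblance_pct"),
    meta = meta,
    is_rt_min = rows$rt_min[is_row], is_area = rows$area[is_row],
    is_conc_ug_per_L = is_conc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
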