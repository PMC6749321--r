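#' Read a volatile-compound reference library
#'
#' Loads the packaged 82-compound Madeira-wine reference library (the default)
#' or a user-supplied library in the same dialect. A library row carries the
#' compound identity, chemical family, published retention time, calculated and
#' literature Kovats indices, identification evidence (`MS` spectral match,
#' `RI` retention-index agreement, `Std` authentic standard), the odor
#' threshold in ug/L determined in 10--12% v/v ethanol, the full odor
#' descriptor list, the subset of descriptors flagged as Madeira aroma notes,
#' and whether the compound was detected in every wine of the study.
#'
#' Two dialects are understood: CSV with pipe-separated multi-value fields and
#' an equivalent JSON array of records (chosen by file extension). Empty
#' strings encode missing values; missing odor thresholds and literature KIs
#' are `NA`, never zero.
#'
#' @param path Path to a library CSV or JSON file; `NULL` (default) loads the
#'   packaged library.
#' @return A tibble of class `voc_library`, one row per compound, with
#'   list-columns `evidence`, `descriptors` and `aroma_notes`.
#' @export
#' @examples
#' lib <- read_voc_library()
#' dplyr::count(lib, family)
read_voc_library <- function(path = NULL) {
  if (is.null(path)) path <- aromaprofiler_extdata("madeira_voc_library.csv")
  if (!file.size(path) > 0) abort(paste0("Library file is empty: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    tbl <- as_tibble(raw)
    # JSON already carries arrays for multi-value fields
    for (col in c("evidence", "descriptors", "aroma_notes")) {
      if (!is.list(tbl[[col]])) tbl[[col]] <- as.list(tbl[[col]])
      tbl[[col]] <- purrr::map(tbl[[col]], as.character)
    }
  } else {
    tbl <- readr::read_csv(path, col_types = readr::cols(
      compound_id = readr::col_character(),
      name = readr::col_character(),
      family = readr::col_character(),
      rt_min = readr::col_double(),
      ki_calc = readr::col_double(),
      ki_lit = readr::col_double(),
      evidence = readr::col_character(),
      ot_ug_per_L = readr::col_double(),
      descriptors = readr::col_character(),
      aroma_notes = readr::col_character(),
      common_to_all = readr::col_logical()
    ), na = "", progress = FALSE)
    tbl <- mutate(tbl,
      evidence    = split_tokens(.data$evidence),
      descriptors = split_tokens(.data$descriptors),
      aroma_notes = split_tokens(.data$aroma_notes)
    )
  }
  validate_voc_library(tbl, source = path)
}

split_tokens <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

join_tokens <- function(x) {
  purrr::map_chr(x, function(s) if (length(s) == 0) "" else paste(s, collapse = "|"))
}

voc_families <- c("terpenic", "norisoprenoid", "higher_alcohol", "sulphur",
                  "ester", "acid", "acetal", "furanic", "lactone",
                  "volatile_phenol")

#' Validate a volatile-compound library
#'
#' Checks the structural contract of a library table: required columns,
#' unique compound ids, known chemical families, positive calculated KIs,
#' aroma notes being a subset of the descriptors, and a calculated KI present
#' for every record claiming retention-index evidence. Violations raise an
#' error naming the offending row and field.
#'
#' @param tbl A library tibble (see [read_voc_library()]).
#' @param source Label used in error messages.
#' @return The validated tibble, classed `voc_library`, invisibly unchanged.
#' @export
validate_voc_library <- function(tbl, source = "library") {
  required <- c("compound_id", "name", "family", "rt_min", "ki_calc", "ki_lit",
                "evidence", "ot_ug_per_L", "descriptors", "aroma_notes",
                "common_to_all")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Library parse error [", source, "]: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tbl) == 0) {
    abort(paste0("Library parse error [", source, "]: no compound records"))
  }
  field_error <- function(rows, field, why) {
    abort(paste0("Library parse error [", source, "] row ",
                 paste(rows, collapse = ","), " field '", field, "': ", why))
  }
  dup <- tbl$compound_id[duplicated(tbl$compound_id)]
  if (length(dup) > 0) {
    field_error(which(tbl$compound_id %in% dup), "compound_id",
                paste0("duplicate id(s) ", paste(unique(dup), collapse = ", ")))
  }
  bad <- which(is.na(tbl$compound_id) | !nzchar(tbl$compound_id))
  if (length(bad) > 0) field_error(bad, "compound_id", "empty id")
  bad <- which(!tbl$family %in% voc_families)
  if (length(bad) > 0) {
    field_error(bad, "family", paste0("unknown family; expected one of ",
                                      paste(voc_families, collapse = ", ")))
  }
  bad <- which(!is.finite(tbl$ki_calc) | tbl$ki_calc <= 0)
  if (length(bad) > 0) field_error(bad, "ki_calc", "must be a positive number")
  bad <- which(!is.na(tbl$ot_ug_per_L) & tbl$ot_ug_per_L <= 0)
  if (length(bad) > 0) field_error(bad, "ot_ug_per_L", "must be positive or missing")
  subset_ok <- purrr::map2_lgl(tbl$aroma_notes, tbl$descriptors,
                               ~ all(.x %in% .y))
  if (any(!subset_ok)) {
    field_error(which(!subset_ok), "aroma_notes",
                "aroma notes must be a subset of the descriptors")
  }
  ri_no_ki <- purrr::map_lgl(tbl$evidence, ~ "RI" %in% .x) & is.na(tbl$ki_calc)
  if (any(ri_no_ki)) {
    field_error(which(ri_no_ki), "ki_calc", "RI evidence requires a calculated KI")
  }
  bad_ev <- purrr::map_lgl(tbl$evidence, ~ !all(.x %in% c("MS", "RI", "Std")))
  if (any(bad_ev)) {
    field_error(which(bad_ev), "evidence", "tokens must be among MS, RI, Std")
  }
  class(tbl) <- unique(c("voc_library", class(tbl)))
  tbl
}

#' Write a volatile-compound library
#'
#' Serializes a library to the documented CSV dialect (pipe-separated
#' multi-value fields, empty string for missing) or to the equivalent JSON
#' array of records. [read_voc_library()] on the written file reproduces the
#' input record for record.
#'
#' @param library A `voc_library` tibble.
#' @param path Output path; extension `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_voc_library <- function(library, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(library, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    out <- mutate(library,
      evidence    = join_tokens(.data$evidence),
      descriptors = join_tokens(.data$descriptors),
      aroma_notes = join_tokens(.data$aroma_notes)
    )
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Descriptor synonym map
#'
#' The packaged map collapsing descriptor spelling variants onto canonical
#' tokens (toasty to toast, flower to floral, fruity to fruit, woody to wood,
#' spicy to spice, ...).
#'
#' @return A named character vector: names are synonyms, values canonical
#'   tokens.
#' @export
default_synonym_map <- function() {
  tbl <- readr::read_csv(aromaprofiler_extdata("descriptor_synonyms.csv"),
                         col_types = "cc", progress = FALSE)
  setNames(tbl$canonical, tbl$synonym)
}

#' Normalize free-text odor descriptors
#'
#' Lower-cases, trims, replaces internal whitespace and hyphens with
#' underscores, and applies the synonym map, so that e.g. `"Toasty"` and
#' `"toast"` compare equal.
#'
#' @param x Character vector of descriptor tokens.
#' @param synonyms Named character vector mapping synonyms to canonical tokens.
#' @return Character vector of canonical tokens.
#' @export
normalize_descriptors <- function(x, synonyms = default_synonym_map()) {
  out <- tolower(trimws(x))
  out <- gsub("[\\s-]+", "_", out, perl = TRUE)
  hit <- out %in% names(synonyms)
  out[hit] <- unname(synonyms[out[hit]])
  out
}

#' Controlled descriptor vocabulary of a library
#'
#' The set of canonical descriptor tokens used across a compound library,
#' after synonym normalization.
#'
#' @inheritParams validate_voc_library
#' @param library A `voc_library` tibble.
#' @param synonyms Synonym map applied before collecting tokens.
#' @return Sorted character vector of unique canonical tokens (empty for an
#'   empty library).
#' @export
#' @examples
#' "citrus" %in% descriptor_vocabulary(read_voc_library())
descriptor_vocabulary <- function(library, synonyms = default_synonym_map()) {
  toks <- unlist(library$descriptors, use.names = FALSE)
  sort(unique(normalize_descriptors(toks, synonyms)))
}

#' Aroma-note groups
#'
#' Composite sensory notes that expand to several elementary descriptors
#' before any neighborhood computation. The default maps the panel note
#' "dried fruits" to its member descriptors (almond, coconut, nutty, peanut,
#' walnut).
#'
#' @return Named list of character vectors.
#' @export
note_groups <- function() {
  list(dried_fruits = c("almond", "coconut", "nutty", "peanut", "walnut"))
}

expand_notes <- function(notes, groups = note_groups()) {
  unique(unlist(purrr::map(notes, function(n) {
    if (n %in% names(groups)) groups[[n]] else n
  }), use.names = FALSE))
}

#' Read variety x age-class sensory profiles
#'
#' Loads the packaged sensory panel summary (five grape varieties, each
#' profiled young, 3--5 years, and old, 10--20 years) or an equivalent CSV
#' with columns `variety`, `age_class`, `notes` (pipe-separated).
#'
#' @param path CSV path; `NULL` loads the packaged profiles.
#' @return Tibble with columns `variety`, `age_class` and list-column `notes`.
#' @export
read_sensory_profiles <- function(path = NULL) {
  if (is.null(path)) path <- aromaprofiler_extdata("madeira_sensory_profiles.csv")
  tbl <- readr::read_csv(path, col_types = "ccc", na = "", progress = FALSE)
  bad <- setdiff(unique(tbl$age_class), c("young", "old"))
  if (length(bad) > 0) {
    abort(paste0("Sensory profile parse error: unknown age_class ",
                 paste(bad, collapse = ", ")))
  }
  mutate(tbl, notes = purrr::map(split_tokens(.data$notes),
                                 normalize_descriptors))
}

# sugar class boundaries (g glucose / L); half-open [low, high), top closed
wine_type_breaks <- c(dry = 49.1, medium_dry = 64.8, medium_sweet = 80.4,
                      sweet = 96.1, top = 150)

#' Classify wine type from residual sugar
#'
#' Maps sugar content (g glucose per L) onto the four commercial Madeira wine
#' types: dry \[49.1, 64.8), medium dry \[64.8, 80.4), medium sweet
#' \[80.4, 96.1), sweet \[96.1, 150\]. Boundaries are half-open with the top
#' class closed, so a boundary value such as 64.8 g/L belongs to the sweeter
#' class. Values outside \[49.1, 150\] are flagged `"out_of_range"`.
#'
#' @param sugar_g_per_L Numeric vector of sugar contents, g/L; must be
#'   non-negative.
#' @return Character vector over `dry`, `medium_dry`, `medium_sweet`, `sweet`,
#'   `out_of_range`.
#' @export
#' @examples
#' classify_wine_type(c(120, 64.8, 10))
classify_wine_type <- function(sugar_g_per_L) {
  if (!is.numeric(sugar_g_per_L)) abort("sugar_g_per_L must be numeric")
  if (any(is.na(sugar_g_per_L)) || any(sugar_g_per_L < 0)) {
    abort("sugar_g_per_L must be non-negative and non-missing")
  }
  b <- wine_type_breaks
  case_when(
    sugar_g_per_L < b["dry"]          ~ "out_of_range",
    sugar_g_per_L < b["medium_dry"]   ~ "dry",
    sugar_g_per_L < b["medium_sweet"] ~ "medium_dry",
    sugar_g_per_L < b["sweet"]        ~ "medium_sweet",
    sugar_g_per_L <= b["top"]         ~ "sweet",
    TRUE                              ~ "out_of_range"
  )
}

#' Age class of a wine
#'
#' Young wines are 3--5 years old, old wines 10--20, matching the sensory
#' panel's two cohorts. Ages strictly between 5 and 10 years fall in neither
#' cohort and return `NA`; ages outside \[3, 20\] are rejected.
#'
#' @param age_years Integer vector of wine ages in years.
#' @return Character vector over `young`, `old`, `NA`.
#' @export
wine_age_class <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 3 | age_years > 20)) {
    abort("age_years must lie in [3, 20]")
  }
  case_when(
    age_years <= 5  ~ "young",
    age_years >= 10 ~ "old",
    TRUE            ~ NA_character_
  )
}

wine_varieties <- c("Malvasia", "Bual", "Sercial", "Verdelho", "Tinta Negra")
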