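# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no approx(), no dplyr joins) so that agreement is
# evidence, not tautology.

# van den Dool-Kratz by explicit bracket search and the textbook formula
brute_force_ki <- function(carbon, rt_anchor, rt) {
  vapply(rt, function(r) {
    n <- NA_integer_
    for (i in seq_len(length(carbon) - 1)) {
      if (r >= rt_anchor[i] && r <= rt_anchor[i + 1]) { n <- i; break }
    }
    stopifnot(!is.na(n))
    100 * carbon[n] + 100 * (carbon[n + 1] - carbon[n]) *
      (r - rt_anchor[n]) / (rt_anchor[n + 1] - rt_anchor[n])
  }, numeric(1))
}

# a random valid ladder: increasing carbons, increasing rts
random_ladder <- function(n_anchors = sample(4:12, 1)) {
  carbon <- cumsum(c(sample(6:10, 1), sample(1:2, n_anchors - 1, replace = TRUE)))
  rt <- cumsum(runif(n_anchors, 0.5, 8))
  list(carbon = carbon, rt = rt)
}

# pairwise shared-compound counts by raw set intersection over a note->VOC map
brute_force_projection <- function(sets) {
  nodes <- names(sets)
  out <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i < j) {
        w <- length(intersect(sets[[nodes[i]]], sets[[nodes[j]]]))
        out[[length(out) + 1]] <- data.frame(
          from = nodes[i], to = nodes[j], weight = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# note -> compound map straight from the library list-column, no graph code
library_note_sets <- function(lib) {
  notes <- sort(unique(unlist(lib$aroma_notes)))
  sets <- lapply(notes, function(nt) {
    sort(lib$compound_id[vapply(lib$aroma_notes, function(a) nt %in% a,
                                logical(1))])
  })
  names(sets) <- notes
  sets
}

tiny_library <- function() {
  validate_voc_library(tibble::tibble(
    compound_id = c("aa", "bb", "cc"),
    name = c("Compound A", "Compound B", "Compound C"),
    family = c("ester", "lactone", "terpenic"),
    rt_min = c(5, 10, 20),
    ki_calc = c(1100, 1400, 1900),
    ki_lit = c(1105, NA, 1890),
    evidence = list(c("MS", "RI", "Std"), c("MS", "RI"), c("MS", "RI")),
    ot_ug_per_L = c(10, NA, 100),
    descriptors = list(c("fruit", "caramel"), "wood", c("citrus", "floral")),
    aroma_notes = list("caramel", "wood", "citrus"),
    common_to_all = c(TRUE, FALSE, TRUE)
  ))
}
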