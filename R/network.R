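#' Bipartite compound-to-aroma-note graph
#'
#' One node set holds the library's compounds, the other the aroma notes
#' flagged in the library (the boldfaced subset of each compound's odor
#' descriptors); an edge links a compound to each of its flagged notes.
#' Compounds with no flagged note remain as isolated nodes.
#'
#' @param library A `voc_library` tibble.
#' @return Object of class `aroma_bipartite`: list with `edges` (tibble
#'   `compound_id`, `note`), `voc_nodes`, `note_nodes`.
#' @export
#' @examples
#' bp <- build_bipartite(read_voc_library())
#' length(shared_vocs(bp, "citrus"))
build_bipartite <- function(library) {
  edges <- library %>%
    select("compound_id", note = "aroma_notes") %>%
    tidyr::unnest_longer("note") %>%
    filter(!is.na(.data$note)) %>%
    distinct()
  structure(
    list(edges = edges,
         voc_nodes = library$compound_id,
         note_nodes = sort(unique(edges$note))),
    class = "aroma_bipartite"
  )
}

#' @export
print.aroma_bipartite <- function(x, ...) {
  cat("<aroma_bipartite>", length(x$voc_nodes), "compounds,",
      length(x$note_nodes), "aroma notes,", nrow(x$edges), "edges\n")
  invisible(x)
}

note_neighborhood <- function(bipartite, note) {
  sort(bipartite$edges$compound_id[bipartite$edges$note == note])
}

#' Compounds shared by a set of aroma notes
#'
#' Intersection of the compound neighborhoods of the given notes; a single
#' note returns its full neighborhood, repeated notes are idempotent.
#'
#' @param bipartite An [build_bipartite()] result.
#' @param notes Character vector of note tokens; must be note nodes of the
#'   graph.
#' @return Sorted character vector of compound ids.
#' @export
shared_vocs <- function(bipartite, notes) {
  notes <- unique(notes)
  unknown <- setdiff(notes, bipartite$note_nodes)
  if (length(unknown) > 0) {
    abort(paste0("unknown note(s): ", paste(unknown, collapse = ", "),
                 "; note nodes: ", paste(bipartite$note_nodes, collapse = ", ")))
  }
  Reduce(intersect, purrr::map(notes, ~ note_neighborhood(bipartite, .x)))
}

new_projection <- function(edges, nodes, level) {
  structure(edges, nodes = nodes, level = level,
            class = c("aroma_projection", class(edges)))
}

#' @export
print.aroma_projection <- function(x, ...) {
  cat("<aroma_projection> level:", attr(x, "level"), "-",
      length(attr(x, "nodes")), "nodes,", nrow(x), "edges\n")
  NextMethod()
}

project_pairs <- function(sets) {
  nodes <- names(sets)
  if (length(nodes) < 2) {
    return(tibble(from = character(), to = character(), weight = integer(),
                  shared = list()))
  }
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    sh <- intersect(sets[[p[1]]], sets[[p[2]]])
    tibble(from = p[1], to = p[2], weight = length(sh), shared = list(sort(sh)))
  })
  bind_rows(rows) %>% filter(.data$weight >= 1)
}

#' Note-level projection of the bipartite graph
#'
#' Two aroma notes are linked when they share at least one compound; the edge
#' weight is the number of shared compounds (with the shared set kept as a
#' list-column). Weights are symmetric and self-edges are not emitted.
#'
#' @inheritParams shared_vocs
#' @return An `aroma_projection` tibble: `from`, `to`, `weight`, `shared`.
#' @export
project_notes <- function(bipartite) {
  sets <- setNames(
    purrr::map(bipartite$note_nodes, ~ note_neighborhood(bipartite, .x)),
    bipartite$note_nodes
  )
  new_projection(project_pairs(sets), bipartite$note_nodes, "note")
}

#' Variety-level projection for one age class
#'
#' Each grape variety is represented by the union, over the aroma notes in
#' its sensory profile for the chosen age class, of those notes' compound
#' neighborhoods (composite notes expand to member descriptors first; panel
#' notes with no compound link contribute nothing). Two varieties are linked
#' by the number of compounds their sets share; weight-0 pairs are omitted,
#' so a variety with an empty compound set is an isolated node.
#'
#' @inheritParams shared_vocs
#' @param sensory Sensory profiles ([read_sensory_profiles()]); must contain a
#'   profile for every variety in `varieties` at `age_class`.
#' @param age_class `"young"` or `"old"`.
#' @param groups Composite-note expansion map.
#' @param varieties Varieties to project (default: the five study varieties).
#' @return An `aroma_projection` tibble with attribute `nodes` listing all
#'   varieties (including isolated ones).
#' @export
project_varieties <- function(bipartite, sensory, age_class,
                              groups = note_groups(),
                              varieties = wine_varieties) {
  age_class <- match.arg(age_class, c("young", "old"))
  prof <- filter(sensory, .data$age_class == !!age_class)
  missing <- setdiff(varieties, prof$variety)
  if (length(missing) > 0) {
    abort(paste0("missing ", age_class, " sensory profile for: ",
                 paste(missing, collapse = ", ")))
  }
  sets <- purrr::map(setNames(varieties, varieties), function(v) {
    notes <- expand_notes(unlist(prof$notes[prof$variety == v]), groups)
    notes <- intersect(notes, bipartite$note_nodes)
    sort(unique(unlist(purrr::map(notes,
                                  ~ note_neighborhood(bipartite, .x)))))
  })
  new_projection(project_pairs(sets), varieties, "variety")
}

proj_to_igraph <- function(graph) {
  if (inherits(graph, "aroma_projection")) {
    g <- igraph::graph_from_data_frame(
      select(as_tibble(graph), "from", "to", "weight"),
      directed = FALSE,
      vertices = tibble(name = attr(graph, "nodes"))
    )
    igraph::E(g)$weight <- as.integer(igraph::E(g)$weight)
    g
  } else if (inherits(graph, "aroma_bipartite")) {
    g <- igraph::graph_from_data_frame(
      rename(graph$edges, from = "compound_id", to = "note"),
      directed = FALSE,
      vertices = tibble(name = c(graph$voc_nodes, graph$note_nodes),
                        type = c(rep(FALSE, length(graph$voc_nodes)),
                                 rep(TRUE, length(graph$note_nodes))))
    )
    g
  } else {
    abort("graph must be an aroma_projection or aroma_bipartite")
  }
}

#' Export / import an aroma graph
#'
#' Writes a projection or bipartite graph as GraphML (via igraph) or as a
#' weighted edge-list CSV (`from`, `to`, `weight`); projection weights are
#' preserved as integer attributes, and an empty graph yields a valid empty
#' document. `import_graph()` reads either format back to an edge tibble for
#' round-trip checks.
#'
#' @param graph An `aroma_projection` or `aroma_bipartite`.
#' @param path Output file path.
#' @param format `"graphml"` or `"csv"`.
#' @return `path`, invisibly (`export_graph`); a tibble `from`, `to`,
#'   `weight` plus a `nodes` attribute (`import_graph`).
#' @export
export_graph <- function(graph, path, format = c("graphml", "csv")) {
  if (!is.character(format) || !all(format %in% c("graphml", "csv"))) {
    abort("unsupported graph format; supported formats: graphml, csv")
  }
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(proj_to_igraph(graph), path, format = "graphml")
  } else {
    edges <- if (inherits(graph, "aroma_bipartite")) {
      mutate(rename(graph$edges, from = "compound_id", to = "note"),
             weight = 1L)
    } else {
      mutate(select(as_tibble(graph), "from", "to", "weight"),
             weight = as.integer(.data$weight))
    }
    readr::write_csv(edges, path)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    out <- as_tibble(el)
    if (!"weight" %in% names(out)) out$weight <- 1L
    out <- mutate(select(out, "from", "to", "weight"),
                  weight = as.integer(.data$weight))
    attr(out, "nodes") <- igraph::V(g)$name
    out
  } else {
    out <- readr::read_csv(path, col_types = "cci", progress = FALSE)
    attr(out, "nodes") <- sort(unique(c(out$from, out$to)))
    out
  }
}
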