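#' Construct a GO-style directed acyclic graph of terms
#'
#' The DAG is stored with child-to-parent edges. Acyclicity is verified and a
#' topological order (ancestors before descendants) is computed; the
#' reflexive-transitive ancestor closure is precomputed per term.
#'
#' @param terms character vector of term identifiers.
#' @param parent_edges two-column character matrix/data frame: child, parent.
#' @param namespace named character vector mapping term to its ontology
#'   sub-domain label; unnamed scalar recycles to all terms.
#' @return an object of class `go_dag` with elements `terms` (topologically
#'   ordered, ancestors first), `parents` and `children` (named lists),
#'   `ancestors` (named list, reflexive), `namespace` (named character) and
#'   `graph` (directed igraph, edges child -> parent).
#' @export
go_dag <- function(terms, parent_edges = NULL, namespace = NULL) {
  terms <- unique(as.character(terms))
  if (length(terms) == 0L) pa_parse_error("ontology has no terms")
  if (is.null(parent_edges) || NROW(parent_edges) == 0L) {
    parent_edges <- matrix(character(0), ncol = 2L)
  } else {
    parent_edges <- as.matrix(parent_edges)
    storage.mode(parent_edges) <- "character"
  }
  known <- parent_edges[, 1L] %in% terms & parent_edges[, 2L] %in% terms
  parent_edges <- parent_edges[known, , drop = FALSE]
  parent_edges <- parent_edges[!duplicated(paste(parent_edges[, 1L],
                                                 parent_edges[, 2L])), ,
                               drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(parent_edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) pa_parse_error("cycle detected in ontology")
  # topo order of the child->parent graph lists descendants first; reverse it
  # so ancestors precede descendants.
  topo <- rev(igraph::topo_sort(g, mode = "out")$name)
  parents <- split(parent_edges[, 2L], factor(parent_edges[, 1L], levels = topo))
  children <- split(parent_edges[, 1L], factor(parent_edges[, 2L], levels = topo))
  anc <- lapply(topo, function(t) {
    igraph::subcomponent(g, t, mode = "out")$name
  })
  names(anc) <- topo
  if (is.null(namespace)) {
    ns <- stats::setNames(rep(NA_character_, length(topo)), topo)
  } else if (is.null(names(namespace))) {
    ns <- stats::setNames(rep(namespace[1L], length(topo)), topo)
  } else {
    ns <- stats::setNames(unname(namespace[topo]), topo)
  }
  structure(list(terms = topo, parents = parents, children = children,
                 ancestors = anc, namespace = ns, graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d is_a edges\n",
              length(x$terms), igraph::ecount(x$graph)))
  invisible(x)
}

#' Ancestors of a term (reflexive)
#'
#' @param dag a [go_dag].
#' @param term term identifier.
#' @return character vector of ancestors including `term` itself.
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) pa_config_error(sprintf("unknown term: %s", term))
  dag$ancestors[[term]]
}

#' Descendants of a term (reflexive)
#'
#' @inheritParams term_ancestors
#' @return character vector of descendants including `term` itself.
#' @export
term_descendants <- function(dag, term) {
  if (!term %in% dag$terms) pa_config_error(sprintf("unknown term: %s", term))
  igraph::subcomponent(dag$graph, term, mode = "in")$name
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas keeping `id`, `name`, `namespace`, `is_a` and
#' (optionally) `relationship: part_of`. Obsolete terms are dropped.
#'
#' @param path OBO file path.
#' @param namespace_filter optional namespace label; terms outside it (and
#'   their edges) are removed. An unknown label is a configuration error.
#' @param subtree_root optional term identifier; the DAG is restricted to the
#'   reflexive descendant closure of this term. Applied after the namespace
#'   filter; either filter may be used alone.
#' @param include_part_of also treat `relationship: part_of` as a parent edge
#'   (default `FALSE`: `is_a` only).
#' @return a [go_dag].
#' @export
read_obo <- function(path, namespace_filter = NULL, subtree_root = NULL,
                     include_part_of = FALSE) {
  if (!file.exists(path)) pa_io_error(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  id <- NULL
  recs <- list()
  cur <- NULL
  flush <- function(cur) if (!is.null(cur) && !isTRUE(cur$obsolete)) recs[[length(recs) + 1L]] <<- cur
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)  # strip trailing OBO comments
    if (grepl("^\\[", ln)) {
      flush(cur)
      cur <- NULL
      in_term <- identical(trimws(ln), "[Term]")
      if (in_term) cur <- list(parents = character(0))
      next
    }
    if (!in_term || !nzchar(trimws(ln))) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (include_part_of && grepl("^relationship:\\s*part_of\\s", ln)) {
      cur$parents <- c(cur$parents, trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
    } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  flush(cur)
  if (length(recs) == 0L) pa_parse_error(sprintf("no terms parsed from %s", path))
  ids <- vapply(recs, function(r) r$id %||% NA_character_, character(1))
  if (anyNA(ids)) pa_parse_error("OBO [Term] stanza without id")
  ns <- stats::setNames(vapply(recs, function(r) r$namespace %||% NA_character_,
                               character(1)), ids)
  edges <- do.call(rbind, lapply(recs, function(r) {
    if (length(r$parents)) cbind(r$id, r$parents) else NULL
  }))
  if (!is.null(namespace_filter)) {
    if (!namespace_filter %in% stats::na.omit(unique(ns))) {
      pa_config_error(sprintf("unknown namespace: %s", namespace_filter))
    }
    keep <- names(ns)[!is.na(ns) & ns == namespace_filter]
    ids <- intersect(ids, keep)
    ns <- ns[ids]
  }
  dag <- go_dag(ids, edges, ns)
  if (!is.null(subtree_root)) {
    keep <- term_descendants(dag, subtree_root)
    sub_edges <- if (igraph::ecount(dag$graph)) {
      e <- igraph::as_edgelist(dag$graph)
      e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
    } else NULL
    dag <- go_dag(keep, sub_edges, dag$namespace[keep])
  }
  dag
}

#' Write a DAG in OBO 1.2 format
#'
#' @param dag a [go_dag].
#' @param path output file path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: ", t)), con)
    if (!is.na(dag$namespace[[t]])) {
      writeLines(paste0("namespace: ", dag$namespace[[t]]), con)
    }
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}
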