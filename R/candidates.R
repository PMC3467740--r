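#' Construct a candidate subnetwork
#'
#' A candidate is a connected subgraph whose nodes all carry the generating
#' term in their propagated annotation sets, together with the edges induced
#' from the network. Candidates carry their edge density and (optionally) the
#' specificity of their generating term, which the selection engine uses for
#' scoring.
#'
#' @param nodes character vector of member identifiers.
#' @param edges two-column character matrix of induced edges (row-sorted).
#' @param term generating term identifier.
#' @param specificity optional precomputed specificity of `term` w.r.t. the
#'   candidate.
#' @return an object of class `candidate_subnetwork` with elements `nodes`
#'   (sorted), `edges`, `edge_keys`, `term`, `density`, `specificity`.
#' @export
candidate_subnetwork <- function(nodes, edges, term, specificity = NA_real_) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[!duplicated(edge_key(edges[, 1L], edges[, 2L])), ,
                   drop = FALSE]
  }
  n <- length(nodes)
  dens <- if (n < 2L) 0 else 2 * nrow(edges) / (n * (n - 1))
  structure(list(nodes = nodes, edges = edges,
                 edge_keys = if (nrow(edges)) edge_key(edges[, 1L], edges[, 2L]) else character(0),
                 term = term, density = dens, specificity = specificity),
            class = "candidate_subnetwork")
}

#' @export
print.candidate_subnetwork <- function(x, ...) {
  cat(sprintf("<candidate_subnetwork> term %s: %d nodes, %d edges (density %.3f)\n",
              x$term, length(x$nodes), nrow(x$edges), x$density))
  invisible(x)
}

#' Candidate subnetworks generated by one GO term
#'
#' Induces the subgraph on all network proteins annotated (directly or via a
#' descendant term) with `term`, splits it into connected components and
#' keeps the components with at least `min_size` nodes. Each surviving
#' component becomes a candidate carrying `term` as its generating term.
#'
#' @param term term identifier.
#' @param network a [ppi_network].
#' @param annotations an [annotation_table].
#' @param min_size minimum component size (default 3, the size below which
#'   output modules are conventionally discarded).
#' @return list of [candidate_subnetwork] objects (possibly empty), ordered by
#'   their lexicographically smallest node.
#' @export
candidates_for_term <- function(term, network, annotations, min_size = 3L) {
  member <- vapply(network$vertices, function(v) {
    term %in% (annotations$propagated[[v]] %||% character(0))
  }, logical(1))
  nodes <- network$vertices[member]
  if (length(nodes) == 0L) return(list())
  ek <- network$edges[, 1L] %in% nodes & network$edges[, 2L] %in% nodes
  sub <- network$edges[ek, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(sub, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)
  spec_total <- length(nodes)  # proteins annotated with the term
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < min_size) next
    ce <- sub[sub[, 1L] %in% members, , drop = FALSE]
    out[[length(out) + 1L]] <- candidate_subnetwork(
      members, ce, term, specificity = length(members) / spec_total)
  }
  if (length(out) > 1L) {
    out <- out[order(vapply(out, function(c) c$nodes[1L], character(1)))]
  }
  out
}

#' Generate the full candidate pool
#'
#' Runs [candidates_for_term] for every assignable term (terms with at least
#' one annotated network protein) and concatenates the results. Candidates of
#' different terms may overlap arbitrarily; no cross-term deduplication is
#' performed. The pool is sorted canonically by (term, smallest node) so that
#' all downstream tie-breaking is reproducible.
#'
#' @param network a [ppi_network].
#' @param annotations an [annotation_table].
#' @param dag a [go_dag].
#' @param min_size minimum candidate size (default 3).
#' @return list of [candidate_subnetwork]s with attribute `assignable_terms`
#'   (terms carried by at least one network protein).
#' @export
generate_pool <- function(network, annotations, dag, min_size = 3L) {
  prop <- annotations$propagated[intersect(names(annotations$propagated),
                                           network$vertices)]
  carried <- unique(unlist(prop, use.names = FALSE))
  assignable <- dag$terms[dag$terms %in% carried]
  pool <- list()
  for (t in assignable) {
    pool <- c(pool, candidates_for_term(t, network, annotations, min_size))
  }
  if (length(pool) == 0L) {
    pa_config_error("empty candidate pool: nothing to decompose")
  }
  ord <- order(vapply(pool, `[[`, character(1), "term"),
               vapply(pool, function(c) c$nodes[1L], character(1)))
  pool <- pool[ord]
  attr(pool, "assignable_terms") <- assignable
  pool
}

#' Structural distance between two subnetworks
#'
#' Edge Jaccard distance: `1 - |E1 n E2| / |E1 u E2|`. 0 when the edge sets
#' coincide, 1 when they are disjoint. If both subnetworks are edgeless the
#' distance is 1 unless their node sets are identical (then 0). The
#' min-normalized overlap `1 - |E1 n E2| / min(|E1|, |E2|)` is available as an
#' alternative.
#'
#' @param c1,c2 [candidate_subnetwork] objects (or any list with `edge_keys`
#'   and `nodes`).
#' @param method `"jaccard"` (default) or `"min_overlap"`.
#' @return fraction in \[0, 1\]; symmetric.
#' @export
structural_distance <- function(c1, c2, method = c("jaccard", "min_overlap")) {
  method <- match.arg(method)
  e1 <- c1$edge_keys
  e2 <- c2$edge_keys
  if (length(e1) == 0L && length(e2) == 0L) {
    return(if (setequal(c1$nodes, c2$nodes)) 0 else 1)
  }
  shared <- length(intersect(e1, e2))
  denom <- switch(method,
                  jaccard = length(union(e1, e2)),
                  min_overlap = min(length(e1), length(e2)))
  if (denom == 0L) return(1)
  1 - shared / denom
}
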