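#' Shortest-path functional distance between two GO terms
#'
#' The distance is the minimum over common ancestors `r` of the two terms of
#' the summed shortest directed path lengths `len(t1 -> r) + len(t2 -> r)` in
#' the DAG. The ancestor relation is reflexive, so the distance from a parent
#' to its child is 1 and `d(t, t) = 0`. Symmetric; the triangle inequality is
#' not guaranteed.
#'
#' @param t1,t2 term identifiers.
#' @param dag a [go_dag].
#' @return non-negative integer hop count, or `Inf` if the terms share no
#'   ancestor (cannot happen inside one rooted namespace).
#' @export
functional_distance <- function(t1, t2, dag) {
  for (t in c(t1, t2)) {
    if (!t %in% dag$terms) pa_config_error(sprintf("unknown term: %s", t))
  }
  d <- igraph::distances(dag$graph, v = c(t1, t2), mode = "out")
  min(d[1L, ] + d[2L, ])
}

#' Pairwise functional distance matrix
#'
#' Computes [functional_distance] for every pair of `terms` in one pass
#' (one BFS per term).
#'
#' @param terms character vector of term identifiers.
#' @param dag a [go_dag].
#' @return symmetric numeric matrix with dimnames `terms`.
#' @export
term_distance_matrix <- function(terms, dag) {
  up <- igraph::distances(dag$graph, v = terms, mode = "out")
  n <- length(terms)
  out <- matrix(Inf, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[i, j] <- out[j, i] <- min(up[i, ] + up[j, ])
    }
  }
  out
}

#' Specificity of a shared GO term with respect to a cluster
#'
#' The cluster size divided by the number of network proteins carrying the
#' term (in their propagated annotation sets). Generic terms carried by a
#' large share of the network yield low specificity; e.g. a 5-protein cluster
#' sharing a term annotated to 1000 network proteins scores 0.005.
#'
#' @param nodes cluster member identifiers.
#' @param term shared term identifier.
#' @param annotations an [annotation_table].
#' @param network a [ppi_network]; the denominator counts its vertices only.
#' @return fraction in (0, 1].
#' @export
specificity <- function(nodes, term, annotations, network) {
  carriers <- vapply(network$vertices, function(v) {
    term %in% (annotations$propagated[[v]] %||% character(0))
  }, logical(1))
  n_t <- sum(carriers)
  if (n_t == 0L) pa_config_error(sprintf("no network protein is annotated with %s", term))
  length(nodes) / n_t
}

#' Functional boundedness of a module by a term bundle
#'
#' The fraction of module members annotated (after propagation) with at least
#' one bundle term. A module is bounded by the bundle when the fraction
#' reaches the configured threshold (1 by default).
#'
#' @param nodes non-empty module member identifiers.
#' @param bundle_terms character vector of bundle term identifiers.
#' @param annotations an [annotation_table].
#' @return fraction in \[0, 1\].
#' @export
boundedness <- function(nodes, bundle_terms, annotations) {
  if (length(nodes) == 0L) pa_config_error("boundedness requires a non-empty node set")
  hit <- vapply(nodes, function(v) {
    length(intersect(annotations$propagated[[v]] %||% character(0),
                     bundle_terms)) > 0L
  }, logical(1))
  mean(hit)
}

#' Is a module functionally bounded by a bundle?
#'
#' @inheritParams boundedness
#' @param threshold minimum boundedness fraction (default 1: every member must
#'   carry a bundle term).
#' @return logical scalar.
#' @export
is_bounded <- function(nodes, bundle_terms, annotations, threshold = 1) {
  boundedness(nodes, bundle_terms, annotations) >= threshold
}
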