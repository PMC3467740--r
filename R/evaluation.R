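#' Construct a clustering (a set of possibly overlapping modules)
#'
#' @param modules list of character vectors of node identifiers; empty modules
#'   are dropped.
#' @param universe node universe; defaults to the union of the modules.
#' @param ids optional module identifiers.
#' @return an object of class `clustering` with elements `modules` (named list
#'   of sorted node sets) and `universe`.
#' @export
clustering <- function(modules, universe = NULL, ids = NULL) {
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  if (!is.null(ids)) names(modules) <- ids
  modules <- modules[lengths(modules) > 0L]
  if (is.null(names(modules)) && length(modules)) {
    names(modules) <- sprintf("M%03d", seq_along(modules))
  }
  covered <- unique(unlist(modules, use.names = FALSE))
  universe <- sort(unique(c(as.character(universe %||% character(0)), covered)))
  structure(list(modules = modules, universe = universe), class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> %d modules over %d nodes (universe %d)\n",
              length(x$modules),
              length(unique(unlist(x$modules, use.names = FALSE))),
              length(x$universe)))
  invisible(x)
}

#' Facets of an atlas as clusterings
#'
#' @param atlas a `facet_atlas` (see [run_facets]).
#' @return list of [clustering] objects, one per facet, over the atlas
#'   universe.
#' @export
atlas_clusterings <- function(atlas) {
  lapply(atlas$facets, function(mods) {
    clustering(lapply(mods, `[[`, "nodes"), universe = atlas$universe)
  })
}

# Co-clustered pair keys of a clustering (pairs sharing >= 1 module).
coclustered_pairs <- function(x) {
  unique(unlist(lapply(x$modules, pair_keys), use.names = FALSE))
}

#' Pair-counting Jaccard index between two clusterings
#'
#' Over all unordered node pairs, a pair is co-clustered in a clustering when
#' both nodes share at least one module. The index is `N11 / (N11 + N10 +
#' N01)` where `N11` counts pairs co-clustered in both clusterings and
#' `N10`/`N01` pairs co-clustered in exactly one; an empty ratio (no pair
#' co-clustered anywhere) gives 0.
#'
#' @param x,y [clustering] objects.
#' @return fraction in \[0, 1\]; symmetric; 1 iff the co-clustering relations
#'   coincide.
#' @export
jaccard_index <- function(x, y) {
  if (length(x$modules) == 0L || length(y$modules) == 0L) {
    warning("empty clustering: Jaccard index is 0", call. = FALSE)
    return(0)
  }
  px <- coclustered_pairs(x)
  py <- coclustered_pairs(y)
  n11 <- length(intersect(px, py))
  denom <- length(union(px, py))
  if (denom == 0L) return(0)
  n11 / denom
}

#' Vertex coverage of a clustering
#'
#' @param x a [clustering].
#' @param network a [ppi_network] or character vector supplying the vertex
#'   universe; defaults to the clustering's own universe.
#' @return fraction of universe vertices covered by at least one module.
#' @export
coverage <- function(x, network = NULL) {
  universe <- if (is.null(network)) x$universe
              else if (inherits(network, "ppi_network")) network$vertices
              else as.character(network)
  if (length(universe) == 0L) pa_config_error("empty vertex universe")
  covered <- unique(unlist(x$modules, use.names = FALSE))
  length(intersect(covered, universe)) / length(universe)
}

#' Coverage overlap between two clusterings
#'
#' Jaccard similarity of the two covered vertex sets.
#'
#' @param x,y [clustering] objects over the same universe.
#' @return fraction in \[0, 1\]; 0 when both are empty.
#' @export
coverage_overlap <- function(x, y) {
  cx <- unique(unlist(x$modules, use.names = FALSE))
  cy <- unique(unlist(y$modules, use.names = FALSE))
  denom <- length(union(cx, cy))
  if (denom == 0L) return(0)
  length(intersect(cx, cy)) / denom
}

#' Match facets against gold-standard clusterings
#'
#' Computes the raw pair-counting Jaccard index between every facet and every
#' gold-standard clustering, normalizes each gold column by its maximum (so
#' the best facet per gold scores 1), and maps every gold standard to its
#' best-matching facet. The mapping is injective when no two golds share a
#' best facet.
#'
#' @param facets a `facet_atlas` or list of [clustering]s.
#' @param gold list of gold-standard [clustering]s.
#' @return list with `raw` (facet x gold JI matrix), `normalized` (per-column
#'   max-normalized matrix; all-zero columns are left as is and recorded in
#'   `zero_columns`), `mapping` (named integer: gold -> facet index),
#'   `injective` (logical) and `zero_columns`.
#' @export
best_match <- function(facets, gold) {
  if (inherits(facets, "facet_atlas")) facets <- atlas_clusterings(facets)
  if (length(facets) == 0L || length(gold) == 0L) {
    pa_config_error("best_match needs at least one facet and one gold clustering")
  }
  if (is.null(names(gold))) names(gold) <- sprintf("gold%d", seq_along(gold))
  raw <- matrix(0, length(facets), length(gold),
                dimnames = list(sprintf("facet%d", seq_along(facets)),
                                names(gold)))
  for (i in seq_along(facets)) {
    for (j in seq_along(gold)) {
      raw[i, j] <- suppressWarnings(jaccard_index(facets[[i]], gold[[j]]))
    }
  }
  normalized <- raw
  zero_cols <- colSums(raw) == 0
  for (j in which(!zero_cols)) {
    normalized[, j] <- raw[, j] / max(raw[, j])
  }
  mapping <- apply(raw, 2L, which.max)
  list(raw = raw, normalized = normalized, mapping = mapping,
       injective = !anyDuplicated(mapping), zero_columns = names(which(zero_cols)))
}

#' Randomly delete network edges (edge noise)
#'
#' Uniformly deletes `floor(ratio * |E|)` edges without replacement;
#' deterministic for a fixed seed. Vertices are retained.
#'
#' @param network a [ppi_network].
#' @param ratio fraction of edges to delete, in \[0, 1\].
#' @param seed integer seed.
#' @return a [ppi_network] with the surviving edges.
#' @export
perturb_edges <- function(network, ratio, seed = 1L) {
  if (ratio < 0 || ratio > 1) pa_config_error("ratio must lie in [0, 1]")
  m <- nrow(network$edges)
  k <- floor(ratio * m)
  if (k == 0L) return(network)
  drop <- with_seed(seed, sample.int(m, k))
  ppi_network(network$edges[-drop, , drop = FALSE], vertices = network$vertices)
}

#' Randomly replace direct annotations (node noise)
#'
#' For `floor(ratio * N)` of the `N` direct (protein, term) assignments,
#' chosen uniformly without replacement, the term is replaced by a uniformly
#' drawn different DAG term; propagation is then recomputed, so the result is
#' again ancestor-closed. Annotation volume is conserved up to within-protein
#' duplicate collapsing.
#'
#' @param annotations an [annotation_table].
#' @param ratio fraction of direct assignments to perturb, in \[0, 1\].
#' @param seed integer seed.
#' @param dag a [go_dag] supplying the replacement term universe.
#' @return a perturbed [annotation_table].
#' @export
perturb_annotations <- function(annotations, ratio, seed = 1L, dag) {
  if (ratio < 0 || ratio > 1) pa_config_error("ratio must lie in [0, 1]")
  if (length(dag$terms) < 2L) {
    warning("single-term ontology: annotation perturbation is a no-op",
            call. = FALSE)
    return(annotations)
  }
  prot <- rep(names(annotations$direct), lengths(annotations$direct))
  term <- unlist(annotations$direct, use.names = FALSE)
  n <- length(term)
  k <- floor(ratio * n)
  if (k > 0L) {
    with_seed(seed, {
      hit <- sample.int(n, k)
      for (i in hit) {
        term[i] <- sample(setdiff(dag$terms, term[i]), 1L)
      }
    })
  }
  direct <- split(term, factor(prot, levels = names(annotations$direct)))
  annotation_table(direct, dag)
}

#' Purity of a bundle partition against planted term branches
#'
#' Each planted branch is matched to the bundle containing most of its
#' assigned terms (majority matching); purity is the fraction of all assigned
#' branch terms that land in their branch's matched bundle.
#'
#' @param partition bundle partition (list with `bundles`).
#' @param truth_bundles list of character vectors: the planted disjoint term
#'   branches.
#' @return fraction in \[0, 1\].
#' @export
bundle_purity <- function(partition, truth_bundles) {
  assigned <- unlist(partition$bundles, use.names = FALSE)
  total <- 0L
  good <- 0L
  for (branch in truth_bundles) {
    branch_assigned <- intersect(branch, assigned)
    if (length(branch_assigned) == 0L) next
    counts <- vapply(partition$bundles, function(b) {
      length(intersect(b, branch_assigned))
    }, integer(1))
    total <- total + length(branch_assigned)
    good <- good + max(counts)
  }
  if (total == 0L) return(0)
  good / total
}
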