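#' Build a synthetic ontology with disjoint functional branches
#'
#' One root term with `branches` disjoint subtrees. Each subtree is a chain of
#' `depth` internal terms hanging off the root, with `leaves_per_branch` leaf
#' terms attached to the end of the chain. Term identifiers are deterministic
#' (`SYN:ROOT`, `SYN:B<b>C<d>`, `SYN:B<b>L<l>`); the namespace is
#' `biological_process` throughout.
#'
#' With `depth = 1`, two leaves of the same branch are at functional distance
#' 2 (via the branch head) while leaves of different branches are at distance
#' 4 (via the root).
#'
#' @param branches number of disjoint branches (>= 1).
#' @param depth chain length of each branch (>= 1).
#' @param leaves_per_branch leaf terms per branch (>= 1).
#' @return a [go_dag] with `1 + branches * (depth + leaves_per_branch)` terms.
#' @export
make_dag <- function(branches = 2L, depth = 1L, leaves_per_branch = 6L) {
  if (branches < 1L || depth < 1L || leaves_per_branch < 1L) {
    pa_config_error("branches, depth and leaves_per_branch must all be >= 1")
  }
  root <- "SYN:ROOT"
  terms <- root
  edges <- NULL
  for (b in seq_len(branches)) {
    chain <- sprintf("SYN:B%dC%d", b, seq_len(depth))
    leaves <- sprintf("SYN:B%dL%02d", b, seq_len(leaves_per_branch))
    terms <- c(terms, chain, leaves)
    parents <- c(root, chain[-depth])
    edges <- rbind(edges, cbind(chain, parents),
                   cbind(leaves, chain[depth]))
  }
  go_dag(terms, edges, namespace = "biological_process")
}

# Leaf terms of branch b of a make_dag() ontology.
branch_leaves <- function(dag, b) {
  sort(grep(sprintf("^SYN:B%dL", b), dag$terms, value = TRUE))
}

# All non-root terms of branch b.
branch_terms <- function(dag, b) {
  sort(grep(sprintf("^SYN:B%d", b), dag$terms, value = TRUE))
}

#' Generate a network with planted, mutually orthogonal facet structure
#'
#' Builds an annotated network over `n_nodes` proteins carrying up to two
#' planted decompositions of the same node set. Facet 1 partitions the nodes
#' into `modules_per_facet` contiguous blocks; facet 2 partitions them by node
#' index modulo `modules_per_facet`, so every facet-2 module cuts across every
#' facet-1 module and the two planted views share almost no co-clustered
#' pairs. Each module of facet `f` is directly annotated with a distinct leaf
#' term of ontology branch `f`. Edges are drawn independently with probability
#' `p_in` for node pairs sharing a planted module (per facet) and `p_out` for
#' all other pairs.
#'
#' @param n_nodes number of proteins (>= `branches * modules_per_facet * 3`).
#' @param branches number of planted facets/ontology branches (1 or 2; the
#'   block/modulo construction defines no third orthogonal partition).
#' @param modules_per_facet modules planted per facet.
#' @param p_in within-module edge probability.
#' @param p_out background edge probability (< `p_in`).
#' @param seed integer seed; the instance is deterministic per seed.
#' @return an object of class `planted_atlas`: list with `network`
#'   ([ppi_network]), `annotations` ([annotation_table]), `dag` ([go_dag]),
#'   `truth_facets` (list of [clustering]s), `truth_bundles` (list of branch
#'   term sets) and `params`.
#' @export
make_planted <- function(n_nodes = 300L, branches = 2L, modules_per_facet = 6L,
                         p_in = 0.6, p_out = 0.01, seed = 1L) {
  if (!branches %in% c(1L, 2L)) {
    pa_config_error("branches must be 1 or 2 (no orthogonal construction is defined beyond two planted facets)")
  }
  if (n_nodes < branches * modules_per_facet * 3L) {
    pa_config_error("n_nodes must be at least branches * modules_per_facet * 3")
  }
  if (!(p_in > p_out)) pa_config_error("p_in must exceed p_out")
  nodes <- sprintf("P%04d", seq_len(n_nodes))
  dag <- make_dag(branches, depth = 1L, leaves_per_branch = modules_per_facet)

  # planted memberships: block index (facet 1), modulo index (facet 2)
  block <- ceiling(seq_len(n_nodes) / (n_nodes / modules_per_facet))
  block <- pmin(block, modules_per_facet)
  membership <- list(block)
  if (branches == 2L) {
    membership[[2L]] <- ((seq_len(n_nodes) - 1L) %% modules_per_facet) + 1L
  }

  direct <- lapply(seq_len(n_nodes), function(i) {
    vapply(seq_len(branches), function(f) {
      branch_leaves(dag, f)[membership[[f]][i]]
    }, character(1))
  })
  names(direct) <- nodes
  annotations <- annotation_table(direct, dag)

  # edge sampling: one Bernoulli draw per unordered pair per source
  idx <- utils::combn(n_nodes, 2L)
  same_module <- matrix(FALSE, branches, ncol(idx))
  for (f in seq_len(branches)) {
    same_module[f, ] <- membership[[f]][idx[1L, ]] == membership[[f]][idx[2L, ]]
  }
  edges <- with_seed(seed, {
    keep <- stats::runif(ncol(idx)) < p_out
    for (f in seq_len(branches)) {
      keep <- keep | (same_module[f, ] & stats::runif(ncol(idx)) < p_in)
    }
    keep
  })
  network <- ppi_network(cbind(nodes[idx[1L, edges]], nodes[idx[2L, edges]]),
                         vertices = nodes)

  truth_facets <- lapply(seq_len(branches), function(f) {
    clustering(split(nodes, membership[[f]]), universe = nodes,
               ids = branch_leaves(dag, f))
  })
  truth_bundles <- lapply(seq_len(branches), branch_terms, dag = dag)
  structure(list(network = network, annotations = annotations, dag = dag,
                 truth_facets = truth_facets, truth_bundles = truth_bundles,
                 params = list(n_nodes = n_nodes, branches = branches,
                               modules_per_facet = modules_per_facet,
                               p_in = p_in, p_out = p_out, seed = seed)),
            class = "planted_atlas")
}

#' @export
print.planted_atlas <- function(x, ...) {
  p <- x$params
  cat(sprintf("<planted_atlas> %d nodes, %d edges; %d planted facet(s) x %d modules (p_in %.2f, p_out %.3f, seed %d)\n",
              p$n_nodes, nrow(x$network$edges), p$branches,
              p$modules_per_facet, p$p_in, p$p_out, p$seed))
  invisible(x)
}

#' Write a planted instance to disk
#'
#' Writes `network.tsv` (edge list), `annotations.tsv` (direct annotations),
#' `ontology.obo` and `truth.gmt` (all planted modules of all facets, module
#' identifiers prefixed `facet<f>.`) into `dir`. These are the same formats
#' the readers consume, enabling end-to-end round trips.
#'
#' @param planted a `planted_atlas` (see [make_planted]).
#' @param dir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
write_planted <- function(planted, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("network.tsv", "annotations.tsv", "ontology.obo",
                            "truth.gmt"))
  write_network(planted$network, paths[1L])
  write_annotations(planted$annotations, paths[2L])
  write_obo(planted$dag, paths[3L])
  con <- file(paths[4L], "w")
  for (f in seq_along(planted$truth_facets)) {
    cl <- planted$truth_facets[[f]]
    for (m in names(cl$modules)) {
      writeLines(paste(c(sprintf("facet%d.%s", f, m), m, cl$modules[[m]]),
                       collapse = "\t"), con)
    }
  }
  close(con)
  invisible(paths)
}
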