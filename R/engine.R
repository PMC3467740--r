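#' Configuration for the facet decomposition engine
#'
#' @param n number of facets to extract (>= 1).
#' @param alpha weight of the functional (DAG hop) distance against the
#'   structural (edge Jaccard) distance in all combined distances. The default
#'   0.091 balances a roughly ten-hop functional scale against the \[0, 1\]
#'   structural scale.
#' @param lambda weight of the inter-facet orthogonality half of the objective
#'   against the intra-facet modularity half.
#' @param theta convergence threshold on the per-iteration functional
#'   reassignment count. Values < 1 are interpreted as a fraction of the
#'   assignable term set (default 0.01); values >= 1 as an absolute count.
#' @param gamma weight of the structural-similarity penalty in the profit
#'   model.
#' @param min_size minimum module size; applied both at candidate generation
#'   and to the output modules.
#' @param max_iter maximum number of alternating iterations.
#' @param seed integer seed driving all randomness (initial facet assignment).
#' @param bound_threshold minimum boundedness for a module to count as bounded
#'   by its bundle (default 1).
#' @param struct_method structural distance flavour, see
#'   [structural_distance].
#' @param init_frac fraction of the vertex count used as the initial module
#'   count by the default initializer (default 1/20).
#' @param init_min_dist minimum pairwise structural distance among the initial
#'   modules picked by the default initializer.
#' @param initializer `NULL` for the default density-times-specificity greedy
#'   initializer, or a function `(problem, config) -> integer vector` of pool
#'   indices to use as initial modules.
#' @return an object of class `facets_config`.
#' @export
facets_config <- function(n = 2L, alpha = 0.091, lambda = 0.5, theta = 0.01,
                          gamma = 1, min_size = 3L, max_iter = 30L,
                          seed = 1L, bound_threshold = 1,
                          struct_method = c("jaccard", "min_overlap"),
                          init_frac = 0.05, init_min_dist = 0.5,
                          initializer = NULL) {
  struct_method <- match.arg(struct_method)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) pa_config_error("n must be a positive integer")
  if (alpha < 0 || alpha > 1) pa_config_error("alpha must lie in [0, 1]")
  if (lambda < 0 || lambda > 1) pa_config_error("lambda must lie in [0, 1]")
  if (theta < 0) pa_config_error("theta must be non-negative")
  if (gamma < 0) pa_config_error("gamma must be non-negative")
  if (min_size < 1L) pa_config_error("min_size must be >= 1")
  if (max_iter < 1L) pa_config_error("max_iter must be >= 1")
  structure(list(n = n, alpha = alpha, lambda = lambda, theta = theta,
                 gamma = gamma, min_size = as.integer(min_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 bound_threshold = bound_threshold,
                 struct_method = struct_method, init_frac = init_frac,
                 init_min_dist = init_min_dist, initializer = initializer),
            class = "facets_config")
}

#' Precomputed decomposition problem
#'
#' Bundles the candidate pool with the pairwise structural distance matrix
#' (pool x pool) and the functional distance matrix over the pool's generating
#' terms, so the alternating optimization reduces to index arithmetic.
#'
#' @param network a [ppi_network].
#' @param annotations an [annotation_table].
#' @param dag a [go_dag].
#' @param config a [facets_config].
#' @return an object of class `facet_problem` with elements `pool`,
#'   `cand_term` (generating term per candidate), `terms` (assignable terms
#'   that generated at least one candidate), `dfunc` (term x term),
#'   `dstruct` (candidate x candidate), `density`, `specificity`, `sizes`,
#'   `assignable` (all terms carried by >= 1 network protein), `vertices`,
#'   `network`, `annotations`, `dag`, `config`.
#' @export
facet_problem <- function(network, annotations, dag, config = facets_config()) {
  pool <- generate_pool(network, annotations, dag, config$min_size)
  assignable <- attr(pool, "assignable_terms")
  cand_term <- vapply(pool, `[[`, character(1), "term")
  terms <- unique(cand_term)
  dfunc <- term_distance_matrix(terms, dag)
  p <- length(pool)
  dstruct <- matrix(0, p, p)
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        dstruct[i, j] <- dstruct[j, i] <-
          structural_distance(pool[[i]], pool[[j]], config$struct_method)
      }
    }
  }
  structure(list(
    pool = pool, cand_term = cand_term, terms = terms,
    term_of = match(cand_term, terms),
    dfunc = dfunc, dstruct = dstruct,
    density = vapply(pool, `[[`, numeric(1), "density"),
    specificity = vapply(pool, `[[`, numeric(1), "specificity"),
    sizes = vapply(pool, function(c) length(c$nodes), integer(1)),
    assignable = assignable, vertices = network$vertices,
    network = network, annotations = annotations, dag = dag, config = config
  ), class = "facet_problem")
}

#' @export
print.facet_problem <- function(x, ...) {
  cat(sprintf("<facet_problem> %d candidates over %d terms (%d assignable), %d vertices\n",
              length(x$pool), length(x$terms), length(x$assignable),
              length(x$vertices)))
  invisible(x)
}

# Combined functional/structural distance; the single place where the
# alpha-weighting of hops against edge Jaccard lives.
combine_distance <- function(d_func, d_struct, alpha) {
  alpha * d_func + (1 - alpha) * d_struct
}

#' Average distance from a candidate to a facet's modules
#'
#' The mean over the facet's modules of the alpha-weighted sum of the
#' functional distance between generating terms and the structural distance
#' between edge sets. Empty facets are infinitely far (never nearest).
#'
#' @param cand a [candidate_subnetwork].
#' @param modules list of [candidate_subnetwork]s forming the facet.
#' @param dag a [go_dag].
#' @param config a [facets_config] (uses `alpha`, `struct_method`).
#' @return non-negative real, `Inf` for an empty facet.
#' @export
facet_centroid_distance <- function(cand, modules, dag, config = facets_config()) {
  if (length(modules) == 0L) return(Inf)
  mean(vapply(modules, function(m) {
    combine_distance(functional_distance(cand$term, m$term, dag),
                     structural_distance(cand, m, config$struct_method),
                     config$alpha)
  }, numeric(1)))
}

# Matrix-backed version used inside the engine: distances from every
# candidate to every facet given facets as lists of pool indices.
centroid_distance_matrix <- function(facets, problem) {
  p <- length(problem$pool)
  n <- length(facets)
  out <- matrix(Inf, p, n)
  alpha <- problem$config$alpha
  for (k in seq_len(n)) {
    idx <- facets[[k]]
    if (length(idx) == 0L) next
    df <- problem$dfunc[problem$term_of, problem$term_of[idx], drop = FALSE]
    ds <- problem$dstruct[, idx, drop = FALSE]
    out[, k] <- rowMeans(combine_distance(df, ds, alpha))
  }
  out
}

# Default initializer: rank candidates by density * specificity and greedily
# keep the best ones whose structural distance to every kept candidate is at
# least init_min_dist, up to ceiling(init_frac * |V|) modules.
default_initializer <- function(problem, config) {
  target <- max(1L, floor(config$init_frac * length(problem$vertices)))
  score <- problem$density * problem$specificity
  chosen <- integer(0)
  for (i in order(-score)) {
    if (length(chosen) >= target) break
    if (all(problem$dstruct[i, chosen] >= config$init_min_dist)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

#' Initialize an atlas state
#'
#' Picks an initial module set with the configured initializer, assigns each
#' initial module to one of the `n` facets uniformly at random (driven by
#' `config$seed`), and seeds each facet's function bundle with the generating
#' terms of its modules (a term claimed by several facets goes to the facet
#' holding its largest module, ties to the lowest facet index). All remaining
#' assignable terms start unassigned.
#'
#' @param problem a [facet_problem].
#' @param config a [facets_config].
#' @return atlas state: list with `facets` (list of `n` integer vectors of
#'   pool indices) and `partition` (list with `bundles`, a list of `n`
#'   character vectors, and `unassigned`).
#' @export
initialize_atlas <- function(problem, config = problem$config) {
  init_fun <- config$initializer %||% default_initializer
  chosen <- init_fun(problem, config)
  if (length(chosen) == 0L) pa_state_error("initializer returned no modules")
  if (length(chosen) < config$n) {
    warning(sprintf("only %d initial modules for %d facets; some facets start empty",
                    length(chosen), config$n), call. = FALSE)
  }
  assign_facet <- with_seed(config$seed,
                            sample.int(config$n, length(chosen), replace = TRUE))
  facets <- lapply(seq_len(config$n), function(k) chosen[assign_facet == k])
  bundles <- rep(list(character(0)), config$n)
  for (t in unique(problem$cand_term[chosen])) {
    here <- which(problem$cand_term[chosen] == t)
    best <- here[order(-problem$sizes[chosen[here]], assign_facet[here])][1L]
    k <- assign_facet[best]
    bundles[[k]] <- c(bundles[[k]], t)
  }
  bundles <- lapply(bundles, sort)
  list(facets = facets,
       partition = list(bundles = bundles,
                        unassigned = setdiff(problem$assignable,
                                             unlist(bundles))))
}

#' Step 1: repartition the GO terms across facets
#'
#' Every candidate is assigned to its nearest facet (mean combined distance to
#' the facet's current modules; ties to the lowest facet index). Each term's
#' bundle is then set by majority vote over its candidates' assignments (ties
#' go to the facet holding the term's largest candidate, then to the lowest
#' facet index). Terms without candidates stay unassigned and are excluded
#' from the reassignment count.
#'
#' @param atlas atlas state (see [initialize_atlas]).
#' @param problem a [facet_problem].
#' @param config a [facets_config].
#' @return list with `partition` (new bundle partition), `assignment`
#'   (facet index per pool candidate) and `reassigned` (number of terms whose
#'   bundle changed).
#' @export
update_partition <- function(atlas, problem, config = problem$config) {
  if (all(lengths(atlas$facets) == 0L)) {
    pa_state_error("all facets are empty; cannot compute centroids")
  }
  d <- centroid_distance_matrix(atlas$facets, problem)
  assignment <- apply(d, 1L, which.min)
  n <- config$n
  bundles <- rep(list(character(0)), n)
  for (ti in seq_along(problem$terms)) {
    cand_idx <- which(problem$term_of == ti)
    votes <- assignment[cand_idx]
    tab <- tabulate(votes, nbins = n)
    winners <- which(tab == max(tab))
    if (length(winners) > 1L) {
      in_tie <- cand_idx[votes %in% winners]
      best <- in_tie[order(-problem$sizes[in_tie], assignment[in_tie])][1L]
      k <- assignment[best]
    } else {
      k <- winners
    }
    bundles[[k]] <- c(bundles[[k]], problem$terms[ti])
  }
  bundles <- lapply(bundles, sort)
  old <- bundle_membership(atlas$partition$bundles, problem$terms)
  new <- bundle_membership(bundles, problem$terms)
  list(partition = list(bundles = bundles,
                        unassigned = setdiff(problem$assignable,
                                             unlist(bundles))),
       assignment = assignment,
       reassigned = sum(old != new))
}

# term -> facet index (0 = unassigned), restricted to `terms`.
bundle_membership <- function(bundles, terms) {
  m <- stats::setNames(integer(length(terms)), terms)
  for (k in seq_along(bundles)) {
    m[intersect(bundles[[k]], terms)] <- k
  }
  m
}

# Scoring core of the profit model; the single place where revenue and cost
# are combined.
profit_core <- function(density, specificity, budget_sum, max_similarity, gamma) {
  density * specificity * budget_sum - gamma * max_similarity
}

#' Information profit of a candidate for a facet
#'
#' Revenue is the candidate's edge density times the specificity of its
#' generating term times the remaining vertex information budget it can
#' extract from the facet. Cost penalizes structural similarity to modules
#' already selected in other facets: `gamma` times the maximum edge overlap
#' `1 - structural_distance` over those modules.
#'
#' @param cand a [candidate_subnetwork] (its `density` and `specificity`
#'   fields are used).
#' @param budgets named numeric vector of per-vertex budgets for the target
#'   facet; vertices absent from the vector count as budget 1.
#' @param other_modules list of [candidate_subnetwork]s already selected in
#'   the other facets (may be empty).
#' @param config a [facets_config] (uses `gamma`, `struct_method`).
#' @return real profit (revenue minus cost); may be negative.
#' @export
candidate_profit <- function(cand, budgets = NULL, other_modules = list(),
                             config = facets_config()) {
  b <- rep(1, length(cand$nodes))
  if (!is.null(budgets)) {
    hit <- cand$nodes %in% names(budgets)
    b[hit] <- budgets[cand$nodes[hit]]
  }
  max_sim <- if (length(other_modules) == 0L) 0 else {
    max(vapply(other_modules, function(m) {
      1 - structural_distance(cand, m, config$struct_method)
    }, numeric(1)))
  }
  profit_core(cand$density, cand$specificity, sum(b), max_sim, config$gamma)
}

#' Step 2: rebuild the atlas by greedy profit maximization
#'
#' Facets are rebuilt from scratch. Selection proceeds in rounds visiting the
#' facets in index order; in each round every facet picks its maximum-profit
#' candidate among the candidates whose generating term lies in the facet's
#' bundle (the restriction to the facet candidate bundle) and that it has not
#' selected before, provided the profit is strictly positive. On selection the
#' facet's budgets on the candidate's vertices are set to zero. Rounds repeat
#' until no facet can pick.
#'
#' @param partition bundle partition (list with `bundles`).
#' @param problem a [facet_problem].
#' @param config a [facets_config].
#' @return list of `n` integer vectors of selected pool indices, in selection
#'   order.
#' @export
update_atlas <- function(partition, problem, config = problem$config) {
  n <- config$n
  p <- length(problem$pool)
  membership <- bundle_membership(partition$bundles, problem$terms)
  cand_facet <- membership[problem$cand_term]  # facet owning each candidate's term
  budgets <- matrix(1, n, length(problem$vertices),
                    dimnames = list(NULL, problem$vertices))
  selected <- rep(list(integer(0)), n)
  node_idx <- lapply(problem$pool, function(c) match(c$nodes, problem$vertices))
  sim <- 1 - problem$dstruct
  repeat {
    progress <- FALSE
    for (k in seq_len(n)) {
      eligible <- which(cand_facet == k)
      eligible <- setdiff(eligible, selected[[k]])
      if (length(eligible) == 0L) next
      others <- unlist(selected[-k])
      profits <- vapply(eligible, function(i) {
        max_sim <- if (length(others)) max(sim[i, others]) else 0
        profit_core(problem$density[i], problem$specificity[i],
                    sum(budgets[k, node_idx[[i]]]), max_sim, config$gamma)
      }, numeric(1))
      best <- which.max(profits)
      if (profits[best] <= 0) next
      pick <- eligible[best]
      selected[[k]] <- c(selected[[k]], pick)
      budgets[k, node_idx[[pick]]] <- 0
      progress <- TRUE
    }
    if (!progress) break
  }
  if (any(lengths(selected) == 0L)) {
    empty <- which(lengths(selected) == 0L)
    message(sprintf("facet(s) %s selected no modules", paste(empty, collapse = ", ")))
  }
  selected
}

#' Orthogonality between two facets
#'
#' The alpha-weighted sum of the mean pairwise functional distance between the
#' two bundles' terms and the mean pairwise structural distance between the
#' two facets' modules. Higher values mean more distinct views.
#'
#' @param i,j distinct facet indices.
#' @param atlas atlas state (list with `facets`, `partition`).
#' @param problem a [facet_problem].
#' @param config a [facets_config].
#' @param warn emit a warning when a bundle is empty (the score is then 0).
#' @return non-negative real.
#' @export
bundle_orthogonality <- function(i, j, atlas, problem,
                                 config = problem$config, warn = TRUE) {
  if (i == j) pa_config_error("bundle_orthogonality requires i != j")
  bi <- intersect(atlas$partition$bundles[[i]], problem$terms)
  bj <- intersect(atlas$partition$bundles[[j]], problem$terms)
  if (length(bi) == 0L || length(bj) == 0L) {
    if (warn) warning("empty bundle: orthogonality is 0", call. = FALSE)
    return(0)
  }
  d_func <- mean(problem$dfunc[bi, bj])
  fi <- atlas$facets[[i]]
  fj <- atlas$facets[[j]]
  d_struct <- if (length(fi) && length(fj)) {
    mean(problem$dstruct[fi, fj, drop = FALSE])
  } else 0
  combine_distance(d_func, d_struct, config$alpha)
}

#' Joint objective of an atlas state
#'
#' `lambda` times the mean pairwise facet orthogonality plus `1 - lambda`
#' times the total intra-facet modularity (sum over selected modules of
#' density times specificity). With a single facet the orthogonality half is
#' defined as 0.
#'
#' @inheritParams bundle_orthogonality
#' @return real objective value (higher is better).
#' @export
atlas_objective <- function(atlas, problem, config = problem$config) {
  n <- config$n
  orth <- 0
  if (n > 1L) {
    tot <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tot <- tot + bundle_orthogonality(i, j, atlas, problem, config,
                                          warn = FALSE)
      }
    }
    orth <- 2 * tot / (n * (n - 1))
  }
  modularity <- sum(unlist(lapply(atlas$facets, function(idx) {
    problem$density[idx] * problem$specificity[idx]
  })))
  config$lambda * orth + (1 - config$lambda) * modularity
}

#' Run the full alternating decomposition
#'
#' Initializes an atlas, then alternates Step 1 (term repartitioning) and
#' Step 2 (greedy profit-maximizing module selection) until the number of
#' terms reassigned in Step 1 drops below the convergence threshold or
#' `max_iter` is reached. Deterministic for a fixed seed and inputs.
#'
#' @param network a [ppi_network].
#' @param annotations an [annotation_table].
#' @param dag a [go_dag].
#' @param config a [facets_config].
#' @return an object of class `facet_atlas`: list with `facets` (list of
#'   module lists, each module a [candidate_subnetwork]), `partition`
#'   (`bundles` + `unassigned`), `trace` (data frame with per-iteration
#'   `reassigned` and `objective`), `converged`, `iterations`, `objective`,
#'   `theta_count` (resolved absolute threshold), `universe` (network
#'   vertices), `config` and `problem`.
#' @export
run_facets <- function(network, annotations, dag, config = facets_config()) {
  problem <- facet_problem(network, annotations, dag, config)
  thr <- if (config$theta < 1) config$theta * length(problem$assignable)
         else config$theta
  atlas <- initialize_atlas(problem, config)
  trace <- data.frame(iteration = integer(0), reassigned = integer(0),
                      objective = numeric(0))
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    st1 <- update_partition(atlas, problem, config)
    atlas$partition <- st1$partition
    atlas$facets <- update_atlas(st1$partition, problem, config)
    trace <- rbind(trace, data.frame(
      iteration = it, reassigned = st1$reassigned,
      objective = atlas_objective(atlas, problem, config)))
    if (st1$reassigned < thr) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    facets = lapply(atlas$facets, function(idx) problem$pool[idx]),
    facet_indices = atlas$facets,
    partition = atlas$partition,
    trace = trace,
    converged = converged,
    iterations = nrow(trace),
    objective = trace$objective[nrow(trace)],
    theta_count = thr,
    universe = network$vertices,
    config = config,
    problem = problem
  ), class = "facet_atlas")
}

#' @export
print.facet_atlas <- function(x, ...) {
  cat(sprintf("<facet_atlas> %d facets (%s modules), %s after %d iteration(s)\n",
              length(x$facets),
              paste(lengths(x$facets), collapse = "/"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  objective %.4f; bundle sizes %s; %d unassigned term(s)\n",
              x$objective,
              paste(lengths(x$partition$bundles), collapse = "/"),
              length(x$partition$unassigned)))
  invisible(x)
}
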