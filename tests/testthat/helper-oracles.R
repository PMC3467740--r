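# Independent brute-force oracles. These deliberately avoid the package's
# igraph-backed code paths: ancestor closure by iterative expansion, shortest
# paths by hand-rolled BFS, components by union-find, clustering agreement by
# full pair enumeration.

# Reflexive ancestor set by iterative parent expansion over dag$parents.
oracle_ancestors <- function(dag, term) {
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# Shortest upward hop counts from `term` to every reachable ancestor (BFS).
oracle_dist_up <- function(dag, term) {
  dist <- stats::setNames(rep(Inf, length(dag$terms)), dag$terms)
  dist[term] <- 0
  frontier <- term
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                   names(dist)[is.finite(dist)])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Exhaustive common-ancestor shortest-path distance.
oracle_functional_distance <- function(t1, t2, dag) {
  common <- intersect(oracle_ancestors(dag, t1), oracle_ancestors(dag, t2))
  if (length(common) == 0L) return(Inf)
  d1 <- oracle_dist_up(dag, t1)
  d2 <- oracle_dist_up(dag, t2)
  min(d1[common] + d2[common])
}

# Random rooted DAG: term i > 1 draws 1-2 parents among terms 1..(i-1),
# so term 1 is a shared root and every pair has a common ancestor.
random_dag <- function(n_terms, seed) {
  terms <- sprintf("T%02d", seq_len(n_terms))
  edges <- NULL
  set.seed(seed)
  for (i in 2:n_terms) {
    k <- sample(1:2, 1)
    parents <- sample(terms[seq_len(i - 1L)], min(k, i - 1L))
    edges <- rbind(edges, cbind(terms[i], parents))
  }
  go_dag(terms, edges, namespace = "test")
}

# Connected components by union-find over an edge matrix.
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (NROW(edges)) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1L])
      rb <- find(edges[r, 2L])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

# Pair-counting Jaccard by explicit enumeration of every unordered pair.
oracle_ji <- function(x, y) {
  nodes <- sort(union(unlist(x$modules, use.names = FALSE),
                      unlist(y$modules, use.names = FALSE)))
  co <- function(cl, a, b) {
    any(vapply(cl$modules, function(m) a %in% m && b %in% m, logical(1)))
  }
  n11 <- n10 <- n01 <- 0L
  n <- length(nodes)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        cx <- co(x, nodes[i], nodes[j])
        cy <- co(y, nodes[i], nodes[j])
        if (cx && cy) n11 <- n11 + 1L
        else if (cx) n10 <- n10 + 1L
        else if (cy) n01 <- n01 + 1L
      }
    }
  }
  if (n11 + n10 + n01 == 0L) return(0)
  n11 / (n11 + n10 + n01)
}

# Independent round-robin greedy selection, recomputing every profit from the
# definitions (budget sums over named vectors, pairwise structural distances)
# rather than the engine's precomputed matrices.
oracle_step2 <- function(pool, bundles, vertices, config) {
  n <- length(bundles)
  budgets <- lapply(seq_len(n), function(k) stats::setNames(rep(1, length(vertices)), vertices))
  selected <- rep(list(integer(0)), n)
  terms <- vapply(pool, `[[`, character(1), "term")
  repeat {
    progress <- FALSE
    for (k in seq_len(n)) {
      eligible <- setdiff(which(terms %in% bundles[[k]]), selected[[k]])
      if (!length(eligible)) next
      others <- pool[unlist(selected[-k])]
      profits <- vapply(eligible, function(i) {
        c <- pool[[i]]
        rev <- c$density * c$specificity * sum(budgets[[k]][c$nodes])
        cost <- if (length(others)) {
          config$gamma * max(vapply(others, function(m) 1 - structural_distance(c, m), numeric(1)))
        } else 0
        rev - cost
      }, numeric(1))
      best <- which.max(profits)
      if (profits[best] <= 0) next
      pick <- eligible[best]
      selected[[k]] <- c(selected[[k]], pick)
      budgets[[k]][pool[[pick]]$nodes] <- 0
      progress <- TRUE
    }
    if (!progress) break
  }
  selected
}
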