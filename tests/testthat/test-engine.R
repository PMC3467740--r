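test_that("configuration validation rejects out-of-range parameters", {
  expect_error(facets_config(n = 0), class = "ppiatlas_config_error")
  expect_error(facets_config(alpha = 1.2), class = "ppiatlas_config_error")
  expect_error(facets_config(lambda = -0.1), class = "ppiatlas_config_error")
  expect_error(facets_config(theta = -1), class = "ppiatlas_config_error")
  expect_equal(facets_config()$alpha, 0.091)
})

test_that("initialization assigns modules to facets reproducibly", {
  fx <- two_clique_fixture()
  cfg1 <- facets_config(n = 1, min_size = 3, seed = 5)
  pr <- facet_problem(fx$network, fx$annotations, fx$dag, cfg1)
  init1 <- initialize_atlas(pr, cfg1)
  expect_length(init1$facets, 1L)
  expect_gt(length(init1$facets[[1]]), 0L)

  cfg2 <- facets_config(n = 2, seed = 42,
                        initializer = function(problem, config) 1:4)
  a <- initialize_atlas(pr, cfg2)
  b <- initialize_atlas(pr, cfg2)
  expect_identical(a, b)
  # bundles are disjoint and cover only chosen modules' terms
  expect_equal(anyDuplicated(unlist(a$partition$bundles)), 0L)

  cfg_many <- facets_config(n = 20, seed = 1,
                            initializer = function(problem, config) 1:3)
  expect_warning(init3 <- initialize_atlas(pr, cfg_many), "start empty")
  expect_equal(sum(lengths(init3$facets)), 3L)
})

test_that("random facet assignment leaves both facets non-empty in nearly all seeds", {
  pl <- make_planted(n_nodes = 60, modules_per_facet = 4, seed = 1)
  cfg0 <- facets_config(n = 2, initializer = function(problem, config) 1:10)
  pr <- facet_problem(pl$network, pl$annotations, pl$dag, cfg0)
  ok <- vapply(1:100, function(s) {
    cfg <- facets_config(n = 2, seed = s,
                         initializer = function(problem, config) 1:10)
    init <- initialize_atlas(pr, cfg)
    all(lengths(init$facets) > 0L)
  }, logical(1))
  # P(some facet empty) = 2 * 2^-10 per seed; >= 95 of 100 is conservative
  expect_gte(sum(ok), 95L)
})

test_that("centroid distance averages the combined functional/structural distance", {
  cfg <- facets_config()
  dag <- make_dag(branches = 2, depth = 1, leaves_per_branch = 1)
  m1 <- candidate_subnetwork(c("a", "b"), rbind(c("a", "b")), "SYN:B1L01")
  same <- candidate_subnetwork(c("a", "b"), rbind(c("a", "b")), "SYN:B1L01")
  far <- candidate_subnetwork(c("x", "y"), rbind(c("x", "y")), "SYN:B2L01")
  expect_equal(facet_centroid_distance(same, list(m1), dag, cfg), 0)
  expect_equal(facet_centroid_distance(far, list(m1), dag, cfg),
               cfg$alpha * 4 + (1 - cfg$alpha) * 1)
  expect_equal(facet_centroid_distance(far, list(), dag, cfg), Inf)

  m2 <- candidate_subnetwork(c("a", "c"), rbind(c("a", "c")), "SYN:B1C1")
  m3 <- candidate_subnetwork(c("x", "y", "z"),
                             rbind(c("x", "y"), c("y", "z")), "SYN:B2C1")
  mods <- list(m1, m2, m3)
  want <- mean(vapply(mods, function(m) {
    cfg$alpha * functional_distance(far$term, m$term, dag) +
      (1 - cfg$alpha) * structural_distance(far, m)
  }, numeric(1)))
  expect_equal(facet_centroid_distance(far, mods, dag, cfg), want)
})

test_that("partition update reassigns terms to their nearest facet and reaches a fixed point", {
  fx <- two_clique_fixture()
  cfg <- facets_config(n = 2, seed = 1)
  pr <- facet_problem(fx$network, fx$annotations, fx$dag, cfg)
  iA <- which(pr$cand_term == "A")
  iB <- which(pr$cand_term == "B")
  atlas <- list(facets = list(iA, iB),
                partition = list(bundles = list("A", "B"),
                                 unassigned = c("C", "r")))
  st <- update_partition(atlas, pr, cfg)
  # expected assignment recomputed through the standalone distance definition
  for (i in seq_along(pr$pool)) {
    d1 <- facet_centroid_distance(pr$pool[[i]], pr$pool[iA], fx$dag, cfg)
    d2 <- facet_centroid_distance(pr$pool[[i]], pr$pool[iB], fx$dag, cfg)
    expect_equal(st$assignment[i], which.min(c(d1, d2)), info = paste("cand", i))
  }
  expect_true("A" %in% st$partition$bundles[[1]])
  expect_true("B" %in% st$partition$bundles[[2]])
  expect_equal(st$reassigned, 2L)  # C and r leave the unassigned state

  atlas2 <- list(facets = atlas$facets, partition = st$partition)
  st2 <- update_partition(atlas2, pr, cfg)
  expect_equal(st2$reassigned, 0L)
  expect_equal(st2$partition, st$partition)

  expect_error(update_partition(list(facets = list(integer(0), integer(0)),
                                     partition = st$partition), pr, cfg),
               class = "ppiatlas_state_error")
})

test_that("a 1/1 vote tie goes to the facet holding the larger candidate", {
  # term S annotated to a 4-clique and a 3-clique; seeds placed so that the
  # larger S-candidate sides with facet 2.
  dag <- go_dag(c("r", "A", "B", "S"), cbind(c("A", "B", "S"), "r"),
                namespace = "test")
  an <- paste0("a", 1:4); bn <- paste0("b", 1:3)
  clique <- function(nodes) t(utils::combn(nodes, 2))
  net <- ppi_network(rbind(clique(an), clique(bn)))
  direct <- c(stats::setNames(lapply(an, function(x) c("A", "S")), an),
              stats::setNames(lapply(bn, function(x) c("B", "S")), bn))
  ann <- annotation_table(direct, dag)
  cfg <- facets_config(n = 2, seed = 1)
  pr <- facet_problem(net, ann, dag, cfg)
  iA <- which(pr$cand_term == "A")  # 4-clique
  iB <- which(pr$cand_term == "B")  # 3-clique
  atlas <- list(facets = list(iB, iA),
                partition = list(bundles = list("B", "A"), unassigned = c("S", "r")))
  st <- update_partition(atlas, pr, cfg)
  iS <- which(pr$cand_term == "S")
  expect_setequal(st$assignment[iS], c(1L, 2L))  # genuinely split
  expect_true("S" %in% st$partition$bundles[[2]])  # larger candidate wins
})

test_that("candidate profit follows the revenue-minus-cost model", {
  cfg <- facets_config(gamma = 1)
  clique3 <- candidate_subnetwork(c("a", "b", "c"),
                                  rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                                  "t", specificity = 0.5)
  expect_equal(candidate_profit(clique3, config = cfg), 3 * 0.5)
  # identical module already selected elsewhere costs gamma
  expect_equal(candidate_profit(clique3, other_modules = list(clique3), config = cfg),
               1.5 - 1)
  cfg2 <- facets_config(gamma = 2.5)
  expect_equal(candidate_profit(clique3, other_modules = list(clique3), config = cfg2),
               1.5 - 2.5)
  # spent budgets reduce revenue vertex by vertex
  expect_equal(candidate_profit(clique3, budgets = c(a = 0, b = 1, c = 0.5),
                                config = cfg),
               1 * 0.5 * 1.5)
  # partial structural similarity scales the cost
  half <- candidate_subnetwork(c("a", "b", "d"), rbind(c("a", "b"), c("a", "d")), "u",
                               specificity = 1)
  sim <- 1 - structural_distance(clique3, half)
  expect_equal(candidate_profit(clique3, other_modules = list(half), config = cfg),
               1.5 - sim)
})

test_that("atlas update selects whole cliques and respects bundle restriction", {
  fx <- two_clique_fixture()
  cfg <- facets_config(n = 1, seed = 1)
  pr <- facet_problem(fx$network, fx$annotations, fx$dag, cfg)
  sel <- suppressMessages(update_atlas(list(bundles = list("A")), pr, cfg))
  expect_equal(pr$cand_term[sel[[1]]], "A")

  cfg2 <- facets_config(n = 2, seed = 1)
  pr2 <- facet_problem(fx$network, fx$annotations, fx$dag, cfg2)
  sel2 <- suppressMessages(update_atlas(list(bundles = list("A", "B")), pr2, cfg2))
  expect_equal(pr2$cand_term[sel2[[1]]], "A")
  expect_equal(pr2$cand_term[sel2[[2]]], "B")
  expect_length(intersect(sel2[[1]], sel2[[2]]), 0L)
})

test_that("greedy selection matches the independent profit-recomputation oracle", {
  fx <- two_clique_fixture()
  partitions <- list(list(bundles = list(c("A", "C"), c("B", "r"))),
                     list(bundles = list(c("A", "B"), c("C", "r"))),
                     list(bundles = list(c("A", "B", "C", "r"), character(0))))
  for (g in c(0.5, 1, 2)) {
    cfg <- facets_config(n = 2, gamma = g, seed = 1)
    pr <- facet_problem(fx$network, fx$annotations, fx$dag, cfg)
    for (part in partitions) {
      got <- suppressMessages(update_atlas(part, pr, cfg))
      want <- oracle_step2(pr$pool, part$bundles, pr$vertices, cfg)
      expect_equal(got, want, info = sprintf("gamma=%g", g))
    }
  }
  # and on a planted instance with overlapping candidates
  pl <- make_planted(n_nodes = 36, modules_per_facet = 2, seed = 2)
  cfg <- facets_config(n = 2, seed = 2)
  pr <- facet_problem(pl$network, pl$annotations, pl$dag, cfg)
  part <- list(bundles = list(branch_terms_of(pr$terms, 1),
                              c(branch_terms_of(pr$terms, 2), "SYN:ROOT")))
  got <- suppressMessages(update_atlas(part, pr, cfg))
  want <- oracle_step2(pr$pool, part$bundles, pr$vertices, cfg)
  expect_equal(got, want)
})

test_that("orthogonality combines mean term distance and mean module distance", {
  cfg <- facets_config()
  dfunc <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  dstruct <- matrix(c(0, 1, 1, 0), 2, 2)
  prob <- list(terms = c("t1", "t2"), dfunc = dfunc, dstruct = dstruct, config = cfg)
  atlas_same <- list(facets = list(1L, 1L),
                     partition = list(bundles = list("t1", "t1")))
  expect_equal(bundle_orthogonality(1, 2, atlas_same, prob, cfg), 0)
  atlas_far <- list(facets = list(1L, 2L),
                    partition = list(bundles = list("t1", "t2")))
  expect_equal(bundle_orthogonality(1, 2, atlas_far, prob, cfg),
               cfg$alpha * 4 + (1 - cfg$alpha) * 1)
  expect_warning(
    expect_equal(bundle_orthogonality(
      1, 2, list(facets = list(1L, integer(0)),
                 partition = list(bundles = list("t1", character(0)))),
      prob, cfg), 0),
    "empty bundle")
  expect_error(bundle_orthogonality(1, 1, atlas_far, prob, cfg),
               class = "ppiatlas_config_error")

  # 2x2-term bundles: double mean recomputed by hand
  terms <- c("u1", "u2", "v1", "v2")
  set.seed(3)
  df <- matrix(sample(0:6, 16, TRUE), 4, 4, dimnames = list(terms, terms))
  df <- (df + t(df)) / 2
  ds <- matrix(stats::runif(16), 4, 4); ds <- (ds + t(ds)) / 2; diag(ds) <- 0
  prob2 <- list(terms = terms, dfunc = df, dstruct = ds, config = cfg)
  atlas2 <- list(facets = list(c(1L, 2L), c(3L, 4L)),
                 partition = list(bundles = list(c("u1", "u2"), c("v1", "v2"))))
  want <- cfg$alpha * mean(df[c("u1", "u2"), c("v1", "v2")]) +
    (1 - cfg$alpha) * mean(ds[1:2, 3:4])
  expect_equal(bundle_orthogonality(1, 2, atlas2, prob2, cfg), want)
})

test_that("the objective sums weighted orthogonality and modularity halves", {
  cfg <- facets_config(n = 2, lambda = 0.5)
  prob <- list(terms = c("t1", "t2"),
               dfunc = matrix(c(0, 4, 4, 0), 2, 2,
                              dimnames = list(c("t1", "t2"), c("t1", "t2"))),
               dstruct = matrix(c(0, 1, 1, 0), 2, 2),
               density = c(1, 0.5), specificity = c(0.8, 0.6), config = cfg)
  empty <- list(facets = list(integer(0), integer(0)),
                partition = list(bundles = list(character(0), character(0))))
  expect_equal(atlas_objective(empty, prob, cfg), 0)

  cfg1 <- facets_config(n = 1, lambda = 0.3)
  one <- list(facets = list(1L), partition = list(bundles = list("t1")))
  expect_equal(atlas_objective(one, prob, cfg1), (1 - 0.3) * 1 * 0.8)

  two <- list(facets = list(1L, 2L),
              partition = list(bundles = list("t1", "t2")))
  orth <- bundle_orthogonality(1, 2, two, prob, cfg)
  expect_equal(atlas_objective(two, prob, cfg),
               0.5 * orth + 0.5 * (1 * 0.8 + 0.5 * 0.6))
})

test_that("a generous threshold terminates the run after one iteration", {
  pl <- make_planted(n_nodes = 60, modules_per_facet = 4, seed = 4)
  at <- suppressMessages(run_facets(pl$network, pl$annotations, pl$dag,
                   facets_config(n = 2, seed = 4, theta = 1000)))
  expect_equal(at$iterations, 1L)
  expect_true(at$converged)
})

test_that("runs are bit-reproducible for a fixed seed", {
  pl <- make_planted(n_nodes = 60, modules_per_facet = 4, seed = 6)
  cfg <- facets_config(n = 2, seed = 6)
  a1 <- suppressMessages(run_facets(pl$network, pl$annotations, pl$dag, cfg))
  a2 <- suppressMessages(run_facets(pl$network, pl$annotations, pl$dag, cfg))
  expect_identical(a1$facets, a2$facets)
  expect_identical(a1$partition, a2$partition)
  expect_identical(a1$trace, a2$trace)
})

test_that("converged atlases satisfy the restriction, disjointness and steady-state invariants", {
  pl <- make_planted(n_nodes = 60, modules_per_facet = 4, seed = 8)
  cfg <- facets_config(n = 2, seed = 8)
  at <- suppressMessages(run_facets(pl$network, pl$annotations, pl$dag, cfg))
  expect_true(at$converged)
  # bundles partition the assigned terms
  expect_equal(anyDuplicated(unlist(at$partition$bundles)), 0L)
  # every module's term lies in its facet's bundle and bounds the module
  for (k in seq_along(at$facets)) {
    for (m in at$facets[[k]]) {
      expect_true(m$term %in% at$partition$bundles[[k]])
      expect_equal(boundedness(m$nodes, at$partition$bundles[[k]],
                               pl$annotations), 1)
    }
  }
  # steady state: one more alternation changes nothing
  state <- list(facets = at$facet_indices, partition = at$partition)
  st <- update_partition(state, at$problem, cfg)
  expect_equal(st$reassigned, 0L)
  expect_identical(suppressMessages(update_atlas(st$partition, at$problem, cfg)),
                   at$facet_indices)
})
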