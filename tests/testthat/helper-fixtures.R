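# Small fixtures built in code.

# Chain ontology: leaf -> mid -> root.
chain_dag <- function() {
  go_dag(c("root", "mid", "leaf"),
         rbind(c("mid", "root"), c("leaf", "mid")),
         namespace = "test")
}

# Diamond: d -> {b, c} -> a (a is the root).
diamond_dag <- function() {
  go_dag(c("a", "b", "c", "d"),
         rbind(c("b", "a"), c("c", "a"), c("d", "b"), c("d", "c")),
         namespace = "test")
}

# Root r with children A..D; two 4-cliques carrying A and B respectively,
# C shared by all clique members. Yields a 6-candidate pool at min_size 3:
# one per clique for A and B, two components each for C and r.
two_clique_fixture <- function() {
  dag <- go_dag(c("r", "A", "B", "C", "D"),
                cbind(c("A", "B", "C", "D"), "r"),
                namespace = "test")
  an <- paste0("a", 1:4)
  bn <- paste0("b", 1:4)
  clique <- function(nodes) t(utils::combn(nodes, 2))
  net <- ppi_network(rbind(clique(an), clique(bn)))
  direct <- c(
    stats::setNames(lapply(an, function(x) c("A", "C")), an),
    stats::setNames(lapply(bn, function(x) c("B", "C")), bn)
  )
  list(network = net, dag = dag,
       annotations = annotation_table(direct, dag))
}

# Terms of one synthetic ontology branch, from a term id vector.
branch_terms_of <- function(terms, b) {
  sort(grep(sprintf("^SYN:B%d", b), terms, value = TRUE))
}

# Deterministic overlapping clusterings over six nodes.
six_node_clusterings <- function() {
  u <- letters[1:6]
  list(
    x = clustering(list(c("a", "b", "c"), c("c", "d")), universe = u),
    y = clustering(list(c("b", "c", "d"), c("e", "f")), universe = u),
    z = clustering(list(c("a", "b"), c("b", "c", "d"), c("d", "e", "f")), universe = u)
  )
}
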