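#' Construct an undirected protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph: no self-loops, no duplicate
#' edges, unordered endpoints. Vertices mentioned only in `vertices` (isolated
#' proteins) are retained.
#'
#' @param edges two-column character matrix or data frame of interacting pairs.
#' @param vertices optional character vector of vertex identifiers; the edge
#'   endpoints are always included.
#' @return an object of class `ppi_network` with elements `vertices` (sorted
#'   character vector) and `edges` (two-column character matrix, each row
#'   sorted, rows deduplicated and ordered).
#' @export
ppi_network <- function(edges, vertices = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) pa_parse_error("edges must have exactly two columns")
    storage.mode(edges) <- "character"
  }
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[!duplicated(edge_key(edges[, 1L], edges[, 2L])), ,
                   drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  vertices <- sort(unique(c(as.character(vertices %||% character(0)),
                            as.vector(edges))))
  structure(list(vertices = vertices, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

# Canonical edge keys of a network or candidate edge matrix.
network_edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  edge_key(net$edges[, 1L], net$edges[, 2L])
}

#' Read a protein interaction network from a file
#'
#' Supports a two-column tab-separated edge list and PSI-MI TAB 2.5 (only the
#' interactor identifier columns 1-2 are used). Lines starting with `!` or `#`
#' are comments. Self-loops and duplicate edges are removed; identifier case
#' is preserved.
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"psimitab"`.
#' @return a [ppi_network].
#' @export
read_network <- function(path, dialect = c("edgelist", "psimitab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pa_io_error(sprintf("network file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[!#]", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) pa_parse_error(sprintf("empty network file: %s", path))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nfields <- lengths(parts)
  min_fields <- 2L
  bad <- which(nfields < min_fields)
  if (length(bad)) {
    pa_parse_error(sprintf("malformed row at line %d of %s (expected >= 2 tab-separated fields)",
                           rows[bad[1L]], path))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(a) | !nzchar(b))) {
    bad <- which(!nzchar(a) | !nzchar(b))[1L]
    pa_parse_error(sprintf("malformed row at line %d of %s (empty identifier)",
                           rows[bad], path))
  }
  # endpoints of removed self-loops still name vertices
  ppi_network(cbind(a, b), vertices = unique(c(a, b)))
}

#' Write a network as a two-column tab-separated edge list
#'
#' Isolated vertices are written as comment lines so that a round trip
#' preserves the vertex set.
#'
#' @param network a [ppi_network].
#' @param path output file path.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  isolated <- setdiff(network$vertices, as.vector(network$edges))
  if (length(isolated)) {
    writeLines(paste0("# isolated\t", isolated), con)
  }
  if (nrow(network$edges)) {
    writeLines(paste(network$edges[, 1L], network$edges[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

# igraph view of a ppi_network (isolated vertices included).
as_igraph_network <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$vertices, stringsAsFactors = FALSE)
  )
}
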