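#' Construct an annotation table with ancestor propagation
#'
#' Direct protein-to-term assignments are propagated upward through the DAG:
#' term `t` is flagged for protein `v` iff `t` or one of its descendants is
#' directly annotated to `v` (the true-path rule).
#'
#' @param direct named list: protein identifier -> character vector of
#'   directly annotated term identifiers. Terms absent from `dag` are dropped
#'   with a warning.
#' @param dag a [go_dag].
#' @return an object of class `annotation_table` with elements `direct` and
#'   `propagated` (both named lists of term sets; `direct` is a subset of
#'   `propagated` per protein).
#' @export
annotation_table <- function(direct, dag) {
  if (length(direct) == 0L) pa_parse_error("no annotations supplied")
  direct <- lapply(direct, function(ts) sort(unique(as.character(ts))))
  unknown <- setdiff(unique(unlist(direct, use.names = FALSE)), dag$terms)
  if (length(unknown)) {
    warning(sprintf("%d annotated term(s) absent from the DAG were skipped (e.g. %s)",
                    length(unknown), unknown[1L]), call. = FALSE)
    direct <- lapply(direct, setdiff, y = unknown)
  }
  propagated <- lapply(direct, function(ts) {
    if (length(ts) == 0L) return(character(0))
    sort(unique(unlist(dag$ancestors[ts], use.names = FALSE)))
  })
  structure(list(direct = direct, propagated = propagated),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d proteins, %d direct assignments\n",
              length(x$direct), sum(lengths(x$direct))))
  invisible(x)
}

#' Read protein-to-GO annotations
#'
#' Supports GAF 2.x (DB object identifier in column 2, GO identifier in column
#' 5; rows whose qualifier column contains `NOT` are excluded) and a plain
#' two-column `protein<TAB>term` TSV. Lines starting with `!` or `#` are
#' comments.
#'
#' @param path annotation file path.
#' @param dag a [go_dag]; terms absent from it are skipped with a warning.
#' @param dialect `"tsv"` or `"gaf"`.
#' @return an [annotation_table].
#' @export
read_annotations <- function(path, dag, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pa_io_error(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) pa_parse_error(sprintf("no parseable annotation rows in %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "tsv") {
    ok <- lengths(parts) >= 2L
    if (!any(ok)) pa_parse_error(sprintf("no parseable annotation rows in %s", path))
    prot <- vapply(parts[ok], `[[`, character(1), 1L)
    term <- vapply(parts[ok], `[[`, character(1), 2L)
  } else {
    ok <- lengths(parts) >= 5L
    parts <- parts[ok]
    if (length(parts) == 0L) pa_parse_error(sprintf("no parseable annotation rows in %s", path))
    qual <- vapply(parts, `[[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    parts <- parts[keep]
    if (length(parts) == 0L) pa_parse_error(sprintf("no annotation rows survive the qualifier filter in %s", path))
    prot <- vapply(parts, `[[`, character(1), 2L)
    term <- vapply(parts, `[[`, character(1), 5L)
  }
  annotation_table(split(term, prot), dag)
}

#' Write direct annotations as a two-column TSV
#'
#' @param annotations an [annotation_table].
#' @param path output file path.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations$direct), lengths(annotations$direct))
  term <- unlist(annotations$direct, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}

#' Binary function association vector of a protein
#'
#' Indicator over the DAG's topologically ordered terms: entry for term `t` is
#' 1 iff `t` is in the protein's propagated annotation set.
#'
#' @param protein protein identifier (must be known to `annotations`).
#' @param dag a [go_dag].
#' @param annotations an [annotation_table].
#' @return named integer vector of length `length(dag$terms)`.
#' @export
association_vector <- function(protein, dag, annotations) {
  if (!protein %in% names(annotations$propagated)) {
    pa_config_error(sprintf("unknown protein: %s", protein))
  }
  stats::setNames(as.integer(dag$terms %in% annotations$propagated[[protein]]),
                  dag$terms)
}

#' Terms shared by every protein of a node set
#'
#' @param nodes non-empty character vector of protein identifiers.
#' @param annotations an [annotation_table]; proteins absent from it
#'   contribute an empty set.
#' @return character vector: the intersection of the propagated term sets.
#' @export
shared_terms <- function(nodes, annotations) {
  if (length(nodes) == 0L) pa_config_error("shared_terms requires a non-empty node set")
  sets <- lapply(nodes, function(v) annotations$propagated[[v]] %||% character(0))
  Reduce(intersect, sets)
}
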