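#' Read a GMT-style module file as a clustering
#'
#' Rows are `module_id<TAB>description<TAB>member1<TAB>member2...`. Lines
#' starting with `!` or `#` are comments. Rows with fewer than three fields
#' (no members) are a parse error naming the line.
#'
#' @param path GMT file path.
#' @param universe optional node universe for the resulting clustering.
#' @return a [clustering]; the module descriptions are kept in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) pa_io_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[!#]", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) {
    return(clustering(list(), universe = universe))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    pa_parse_error(sprintf("malformed GMT row at line %d of %s (expected id, description, members)",
                           rows[short[1L]], path))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  modules <- lapply(parts, function(p) p[-(1:2)])
  cl <- clustering(modules, universe = universe, ids = ids)
  attr(cl, "descriptions") <- stats::setNames(desc, ids)
  cl
}

#' Write an atlas to disk
#'
#' Produces one GMT-style file per facet (`facet<k>.gmt`, rows
#' `module_id<TAB>generating_term<TAB>members...`), a JSON summary
#' (`summary.json`: per-facet module counts and coverage, pairwise facet
#' Jaccard index matrix and coverage-overlap matrix) and a run log
#' (`runlog.tsv`: per-iteration functional reassignment counts and objective
#' values).
#'
#' @param atlas a `facet_atlas` (see [run_facets]).
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_atlas <- function(atlas, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) pa_io_error(sprintf("cannot create output directory: %s", dir))
  n <- length(atlas$facets)
  gmt_paths <- file.path(dir, sprintf("facet%d.gmt", seq_len(n)))
  for (k in seq_len(n)) {
    con <- file(gmt_paths[k], "w")
    mods <- atlas$facets[[k]]
    for (j in seq_along(mods)) {
      writeLines(paste(c(sprintf("F%dM%03d", k, j), mods[[j]]$term,
                         mods[[j]]$nodes), collapse = "\t"), con)
    }
    close(con)
  }
  cls <- atlas_clusterings(atlas)
  ji <- matrix(1, n, n)
  cov_overlap <- matrix(1, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ji[i, j] <- ji[j, i] <-
          suppressWarnings(jaccard_index(cls[[i]], cls[[j]]))
        cov_overlap[i, j] <- cov_overlap[j, i] <-
          coverage_overlap(cls[[i]], cls[[j]])
      }
    }
  }
  summary <- list(
    n_facets = n,
    modules = lengths(atlas$facets),
    coverage = vapply(cls, coverage, numeric(1), network = atlas$universe),
    jaccard_index = ji,
    coverage_overlap = cov_overlap,
    bundle_sizes = lengths(atlas$partition$bundles),
    unassigned_terms = length(atlas$partition$unassigned),
    converged = atlas$converged,
    iterations = atlas$iterations,
    objective = atlas$objective
  )
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  runlog_path <- file.path(dir, "runlog.tsv")
  utils::write.table(atlas$trace, runlog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gmt_paths, summary_path, runlog_path))
}
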