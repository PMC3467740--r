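# Internal helpers shared across modules.

# Classed conditions so the CLI can map failures to exit codes.
pa_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ppiatlas_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pa_parse_error  <- function(msg) pa_error(msg, "ppiatlas_parse_error")
pa_config_error <- function(msg) pa_error(msg, "ppiatlas_config_error")
pa_state_error  <- function(msg) pa_error(msg, "ppiatlas_state_error")
pa_io_error     <- function(msg) pa_error(msg, "ppiatlas_io_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Canonical key for an undirected edge; endpoints sorted so {a,b} == {b,a}.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonical keys for an unordered node pair set (same encoding as edges).
pair_keys <- function(nodes) {
  n <- length(nodes)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  edge_key(nodes[idx[1L, ]], nodes[idx[2L, ]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
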