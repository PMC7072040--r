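# Internal helpers shared across modules.

# Classed conditions so callers can distinguish anatomy violations,
# insufficient-spine inputs etc. from generic errors.
stop_dxascol <- function(type, msg, ...) {
  stop(structure(class = c(paste0("dxascol_", type), "dxascol_error",
                           "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1L))))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One-decimal percentage, the reporting convention used throughout.
pct1 <- function(x) round(100 * x, 1)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Runs of TRUE in a logical vector: matrix with columns start, end.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
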