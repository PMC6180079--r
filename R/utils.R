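# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  `seed = NULL` runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# log(2*cosh(t)) without overflow: |t| + log1p(exp(-2|t|)).
log2cosh <- function(t) {
  at <- abs(t)
  at + log1p(exp(-2 * at))
}

# States with |sign-layer output| at or below this are excluded from all
# weighted averages: the wavefunction weight s^2 * P vanishes quadratically
# there while E_loc and the log-derivatives divide by s.
S_FLOOR <- 1e-12

stop_rbmqs <- function(..., class) {
  stop(structure(
    class = c(class, "rbmqs_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
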