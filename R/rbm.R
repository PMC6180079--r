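# Three-layer RBM trial wavefunction.
#
# Amplitude: phi(x) = sqrt(P(x)) with the hidden layer marginalized in
# closed form,
#   Ptilde(x) = exp(sum_i a_i s_i) * prod_j 2 cosh(b_j + sum_i w_ij s_i),
# all arithmetic in log space.  Sign layer: s(x) = tanh(sum_i d_i s_i + c),
# a smooth multiplicative factor in (-1, 1).  The wavefunction coefficient
# is psi(x) = sqrt(Ptilde(x)) * s(x) up to normalization.

#' RBM parameter set
#'
#' Visible biases `a` (length `n`), hidden biases `b` (length `m`), couplings
#' `w` (`n x m`), sign-layer weights `d` (length `n`) and offset `c`.
#'
#' @param a,b,w,d,c Numeric parameter blocks, dimensions as above.
#' @return An object of class `rbm_params`.
#' @export
rbm_params <- function(a, b, w, d, c) {
  n <- length(a); m <- length(b)
  w <- matrix(as.numeric(w), n, m)
  if (length(d) != n || length(c) != 1L) {
    stop_rbmqs("inconsistent parameter dimensions",
               class = "rbmqs_validation_error")
  }
  if (!all(is.finite(c(a, b, w, d, c)))) {
    stop_rbmqs("parameters must be finite", class = "rbmqs_validation_error")
  }
  structure(list(n = n, m = m, a = as.numeric(a), b = as.numeric(b),
                 w = w, d = as.numeric(d), c = as.numeric(c)),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat("RBM parameters: n =", x$n, "visible, m =", x$m, "hidden,",
      n_params(x), "trainable weights\n")
  invisible(x)
}

n_params <- function(p) p$n + p$m + p$n * p$m + p$n + 1L

#' Random initialization of RBM parameters
#'
#' Every weight is drawn i.i.d. uniform on `(-range, range)`; the default
#' range 0.02 keeps the tanh sign layer away from its vanishing-gradient
#' regime at the start of training.
#'
#' @param n,m Visible and hidden unit counts (positive).
#' @param seed Optional integer seed; the ambient RNG stream is preserved.
#' @param range Half-width of the uniform support.
#' @return An [rbm_params()] object.
#' @export
rbm_init <- function(n, m, seed = NULL, range = 0.02) {
  if (n < 1L || m < 1L) {
    stop_rbmqs("n and m must be positive", class = "rbmqs_validation_error")
  }
  k <- n + m + n * m + n + 1L
  v <- with_seed(seed, stats::runif(k, -range, range))
  unpack_params(v, n, m)
}

#' Pack / unpack parameters to a flat vector
#'
#' Order: `a`, `b`, `w` (column-major, visible index fastest), `d`, `c`.
#'
#' @param p An [rbm_params()].
#' @return `pack_params()` a numeric vector; `unpack_params()` an
#'   [rbm_params()].
#' @export
pack_params <- function(p) c(p$a, p$b, as.numeric(p$w), p$d, p$c)

#' @rdname pack_params
#' @param v Flat parameter vector.
#' @param n,m Dimensions.
#' @export
unpack_params <- function(v, n, m) {
  stopifnot(length(v) == n + m + n * m + n + 1L)
  i <- 0L
  a <- v[i + seq_len(n)]; i <- i + n
  b <- v[i + seq_len(m)]; i <- i + m
  w <- matrix(v[i + seq_len(n * m)], n, m); i <- i + n * m
  d <- v[i + seq_len(n)]; i <- i + n
  rbm_params(a, b, w, d, v[i + 1L])
}

as_spin_matrix <- function(x, n) {
  s <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(s) != n) {
    stop_rbmqs("state has ", ncol(s), " spins but model has ", n,
               " visible units", class = "rbmqs_validation_error")
  }
  s
}

# log Ptilde(x) for a matrix of states (rows).  m = 0 is allowed (no hidden
# units: pure product distribution).
rbm_log_ptilde <- function(p, s_mat) {
  out <- as.numeric(s_mat %*% p$a)
  if (p$m > 0L) {
    theta <- sweep(s_mat %*% p$w, 2L, p$b, "+")
    out <- out + rowSums(log2cosh(theta))
  }
  out
}

#' Unnormalized RBM probability
#'
#' The hidden-layer sum evaluated in closed form,
#' \eqn{\tilde P(x) = e^{\sum_i a_i \sigma_i} \prod_j 2\cosh(b_j + \sum_i
#' w_{ij}\sigma_i)}, computed in log space.
#'
#' @param p An [rbm_params()].
#' @param x Spin vector (or matrix of row states) over \{-1, +1\}.
#' @param log Return the logarithm?
#' @return Nonnegative value(s), or their logs.
#' @export
rbm_prob <- function(p, x, log = FALSE) {
  lp <- rbm_log_ptilde(p, as_spin_matrix(x, p$n))
  if (log) lp else exp(lp)
}

#' Sign-layer output
#'
#' \eqn{s(x) = \tanh(\sum_i d_i \sigma_i + c)}, strictly inside (-1, 1) for
#' finite parameters; used as a smooth multiplicative factor on the
#' amplitude.
#'
#' @inheritParams rbm_prob
#' @return Value(s) in (-1, 1).
#' @export
rbm_sign <- function(p, x) {
  s_mat <- as_spin_matrix(x, p$n)
  tanh(as.numeric(s_mat %*% p$d) + p$c)
}

# Log-derivative matrix D over (a, b, w, d, c) for a matrix of states:
# D_pk(x) = d/d pk log( sqrt(Ptilde(x)) * s(x) ).  States with |s| <= S_FLOOR
# get NA rows (excluded-state signal handled by callers).
rbm_log_derivs_matrix <- function(p, s_mat) {
  nst <- nrow(s_mat)
  sgn <- tanh(as.numeric(s_mat %*% p$d) + p$c)
  ok <- abs(sgn) > S_FLOOR
  da <- s_mat / 2
  if (p$m > 0L) {
    th <- tanh(sweep(s_mat %*% p$w, 2L, p$b, "+"))
    db <- th / 2
    dw <- s_mat[, rep(seq_len(p$n), p$m), drop = FALSE] *
      th[, rep(seq_len(p$m), each = p$n), drop = FALSE] / 2
  } else {
    db <- matrix(0, nst, 0L); dw <- matrix(0, nst, 0L)
  }
  fac <- ifelse(ok, (1 - sgn^2) / sgn, NA_real_)
  dd <- s_mat * fac
  dc <- matrix(fac, nst, 1L)
  list(D = cbind(da, db, dw, dd, dc), ok = ok)
}

#' Log-derivatives of the wavefunction coefficient
#'
#' The vector \eqn{D_{p_k}(x) = \partial_{p_k}(\phi(x)s(x)) / (\phi(x)s(x))}
#' for every trainable parameter, in [pack_params()] order.  States where
#' the sign output is numerically zero are flagged rather than returned
#' (they carry vanishing weight but undefined derivatives).
#'
#' @inheritParams rbm_prob
#' @return A numeric vector (single state) or matrix (one row per state);
#'   excluded states are `NA` rows with attribute `excluded`.
#' @export
rbm_log_derivs <- function(p, x) {
  s_mat <- as_spin_matrix(x, p$n)
  r <- rbm_log_derivs_matrix(p, s_mat)
  if (nrow(s_mat) == 1L) {
    if (!r$ok[1]) {
      stop_rbmqs("sign-layer output is numerically zero at this state; ",
                 "log-derivatives are undefined (excluded-state signal)",
                 class = "rbmqs_excluded_state")
    }
    return(drop(r$D))
  }
  structure(r$D, excluded = !r$ok)
}

#' Full amplitude table over all basis states
#'
#' Enumerates all `2^n` basis states and tabulates the unnormalized
#' probability, the sign output and the weight `Ptilde(x) * s(x)^2` that
#' defines the joint sampling distribution of the energy functional.
#'
#' @param p An [rbm_params()].
#' @param cap Visible-unit cap (resource guard).
#' @return An object of class `amplitude_table`: list with `spins`
#'   (`2^n x n`), `log_ptilde`, `sign`, normalized `weight`, logical
#'   `effective` (|sign| above floor) and `degenerate` flag.
#' @export
rbm_table <- function(p, cap = DEFAULT_QUBIT_CAP) {
  check_cap(p$n, cap)
  s_mat <- all_spins(p$n)
  lp <- rbm_log_ptilde(p, s_mat)
  sg <- tanh(as.numeric(s_mat %*% p$d) + p$c)
  eff <- abs(sg) > S_FLOOR
  lw <- lp + 2 * log(pmax(abs(sg), .Machine$double.xmin))
  lw[!eff] <- -Inf
  degenerate <- !any(eff)
  w <- if (degenerate) rep(0, length(lw)) else {
    u <- exp(lw - max(lw[eff]))
    u / sum(u)
  }
  structure(list(spins = s_mat, log_ptilde = lp, sign = sg,
                 weight = w, effective = eff, degenerate = degenerate),
            class = "amplitude_table")
}

#' @export
print.amplitude_table <- function(x, ...) {
  cat("Amplitude table:", nrow(x$spins), "basis states,",
      sum(x$effective), "effective\n")
  if (x$degenerate) cat("  DEGENERATE: sign layer vanishes everywhere\n")
  invisible(x)
}

#' Save / load an RBM parameter checkpoint
#'
#' Flat JSON document with fields `n`, `m`, `a`, `b`, `w` (row-major), `d`,
#' `c`, `rng_seed` and `format_version`; round-trips losslessly.
#'
#' @param p An [rbm_params()].
#' @param path File path.
#' @param rng_seed Optional seed to record alongside the parameters.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   the [rbm_params()] with attribute `rng_seed`.
#' @export
write_checkpoint <- function(p, path, rng_seed = NULL) {
  doc <- list(format_version = 1L, n = p$n, m = p$m,
              a = p$a, b = p$b, w = as.numeric(t(p$w)), d = p$d, c = p$c,
              rng_seed = rng_seed)
  # digits = I(17): full IEEE double precision, so checkpoints are lossless
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- rbm_params(doc$a, doc$b,
                  t(matrix(doc$w, doc$m, doc$n)),
                  doc$d, doc$c)
  attr(p, "rng_seed") <- doc$rng_seed
  p
}
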