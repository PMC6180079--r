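# Classical simulation of the controlled-rotation Gibbs sampling circuit.
#
# The target joint distribution over y = (sigma, h) is the RBM Gibbs law
#   P(y) ~ exp( a.sigma + b.h + sigma' W h ).
# The circuit samples the flattened law Q(y) ~ P(y)^(1/k): single-qubit R_y
# rotations prepare the independent product O(y) ~ exp((a.sigma + b.h)/k),
# then one ancilla rotation per coupling (i,j) succeeds with probability
# exp((w_ij sigma_i h_j - |w_ij|)/k); any failed ancilla measurement restarts
# the whole attempt.  Accepted configurations therefore occur with
# probability proportional to O(y) * prod_ij exp((w_ij sigma_i h_j -
# |w_ij|)/k) = Q(y).  Raising accepted frequencies to the power k and
# normalizing recovers the Gibbs distribution.
#
# The simulation reproduces the measurement statistics of the state-vector
# circuit exactly (independent Bernoulli draws plus per-coupling acceptance)
# at O(nm) cost per attempt.
#
# Joint index convention: y = (sigma_1..sigma_n, h_1..h_m) with the first
# visible unit as the most significant bit; the visible index is
# floor(y / 2^m).

#' Rotation angles for the sampling circuit
#'
#' \eqn{\theta_i = 2\arcsin\sqrt{e^{a_i/k}/(e^{a_i/k}+e^{-a_i/k})}} for the
#' visible units, the analogous \eqn{\gamma_j} for hidden units, and per
#' coupling the pair \eqn{\theta_{ij,1} = 2\arcsin\sqrt{e^{w_{ij}/k} /
#' e^{|w_{ij}|/k}}} (equal spins), \eqn{\theta_{ij,2}} with \eqn{-w_{ij}}
#' (opposite spins).  All angles lie in \eqn{[0, \pi]}.
#'
#' @param p An [rbm_params()].
#' @param k Positive temperature-like divisor.
#' @return An object of class `rotation_plan`.
#' @export
rotation_plan <- function(p, k) {
  if (k <= 0) {
    stop_rbmqs("k must be positive", class = "rbmqs_validation_error")
  }
  structure(list(
    n = p$n, m = p$m, k = k,
    theta = 2 * asin(sqrt(stats::plogis(2 * p$a / k))),
    gamma = 2 * asin(sqrt(stats::plogis(2 * p$b / k))),
    theta1 = 2 * asin(sqrt(exp((p$w - abs(p$w)) / k))),
    theta2 = 2 * asin(sqrt(exp((-p$w - abs(p$w)) / k))),
    w = p$w  # couplings kept for the vectorized acceptance path
  ), class = "rotation_plan")
}

#' Single circuit attempt
#'
#' Draws each visible and hidden spin independently from its preparation
#' rotation, then walks the couplings in order: the ancilla acceptance
#' probability is \eqn{\sin^2(\theta_{ij,1}/2)} when the two spins agree and
#' \eqn{\sin^2(\theta_{ij,2}/2)} otherwise.  The first failed measurement
#' rejects the whole attempt (restart semantics).  Uses the ambient RNG
#' stream.
#'
#' @param plan A [rotation_plan()].
#' @return List with `accepted` (logical) and, when accepted, `sigma` and
#'   `h` spin vectors.
#' @export
run_circuit_once <- function(plan) {
  sigma <- 2 * (stats::runif(plan$n) < sin(plan$theta / 2)^2) - 1
  h <- 2 * (stats::runif(plan$m) < sin(plan$gamma / 2)^2) - 1
  for (i in seq_len(plan$n)) {
    for (j in seq_len(plan$m)) {
      ang <- if (sigma[i] * h[j] > 0) plan$theta1[i, j] else plan$theta2[i, j]
      if (stats::runif(1) >= sin(ang / 2)^2) {
        return(list(accepted = FALSE))
      }
    }
  }
  list(accepted = TRUE, sigma = sigma, h = h)
}

#' Run the sampler until a target number of acceptances
#'
#' Vectorized over attempts: the product of the per-coupling acceptance
#' probabilities equals \eqn{\exp((\sigma' W h - \sum|w|)/k)}, so each
#' attempt is accepted with that single Bernoulli draw — the same law as the
#' sequential per-ancilla measurements of [run_circuit_once()].
#'
#' @param plan A [rotation_plan()] (from parameters `p` and constant `k`).
#' @param n_samples Accepted configurations to collect.
#' @param max_attempts Hard cap on total circuit runs.
#' @param seed Optional RNG seed.
#' @return A `sample_batch`: list with `counts` (named by 0-based joint
#'   index), `n`, `m`, `n_attempts`, `n_accepted`, `acceptance_rate`.
#' @export
run_sampler <- function(plan, n_samples, max_attempts = 1e7, seed = NULL) {
  n <- plan$n; m <- plan$m
  pv <- sin(plan$theta / 2)^2
  ph <- sin(plan$gamma / 2)^2
  w <- plan$w
  sum_abs_w <- sum(abs(w))
  counts <- integer(2^(n + m))
  with_seed(seed, {
    n_att <- 0L; n_acc <- 0L
    while (n_acc < n_samples && n_att < max_attempts) {
      chunk <- min(max(2L * (n_samples - n_acc), 1000L),
                   max_attempts - n_att)
      sig <- matrix(2 * (stats::runif(chunk * n) < rep(pv, each = chunk)) - 1,
                    chunk, n)
      hid <- matrix(2 * (stats::runif(chunk * m) < rep(ph, each = chunk)) - 1,
                    chunk, m)
      # log acceptance probability per attempt
      la <- (rowSums((sig %*% w) * hid) - sum_abs_w) / plan$k
      acc <- stats::runif(chunk) < exp(la)
      needed <- n_samples - n_acc
      if (sum(acc) > needed) {
        # stop at the attempt that produced the needed-th acceptance so the
        # recorded attempt count (and hence the rate) stays unbiased
        last <- which(acc)[needed]
        acc <- acc[seq_len(last)]
        keep <- seq_len(last)
        n_att <- n_att + last
      } else {
        keep <- seq_len(chunk)
        n_att <- n_att + chunk
      }
      if (any(acc)) {
        sb <- (sig[keep, , drop = FALSE][acc, , drop = FALSE] + 1) / 2
        hb <- (hid[keep, , drop = FALSE][acc, , drop = FALSE] + 1) / 2
        idx <- as.numeric(sb %*% 2^((n + m - 1):(m))) +
          as.numeric(hb %*% 2^((m - 1):0))
        counts <- counts + tabulate(idx + 1, nbins = 2^(n + m))
        n_acc <- n_acc + length(idx)
      }
    }
    if (n_acc == 0L) {
      stop_rbmqs("no accepted samples within max_attempts; increase k",
                 class = "rbmqs_sampler_error")
    }
    structure(list(counts = counts, n = n, m = m,
                   n_attempts = n_att, n_accepted = n_acc,
                   acceptance_rate = n_acc / n_att),
              class = "sample_batch")
  })
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("Sample batch: %d accepted / %d attempts (rate %.3f), n=%d m=%d\n",
              x$n_accepted, x$n_attempts, x$acceptance_rate, x$n, x$m))
  invisible(x)
}

# Joint RBM energy a.sigma + b.h + sigma' W h for all 2^(n+m) configurations.
joint_energies <- function(p) {
  sv <- all_spins(p$n + p$m)
  sig <- sv[, seq_len(p$n), drop = FALSE]
  hid <- sv[, p$n + seq_len(p$m), drop = FALSE]
  as.numeric(sig %*% p$a) + as.numeric(hid %*% p$b) +
    rowSums((sig %*% p$w) * hid)
}

#' Exact flattened distribution Q(y)
#'
#' \eqn{Q(y) \propto \exp(E(y)/k)} over all joint configurations, by direct
#' enumeration (`n + m` capped at 20).
#'
#' @param p An [rbm_params()].
#' @param k Positive divisor.
#' @return Probability vector of length `2^(n+m)`, joint index order.
#' @export
exact_q_distribution <- function(p, k) {
  if (k <= 0) stop_rbmqs("k must be positive", class = "rbmqs_validation_error")
  if (p$n + p$m > 20L) {
    stop_rbmqs("n + m above enumeration cap of 20",
               class = "rbmqs_resource_error")
  }
  e <- joint_energies(p) / k
  u <- exp(e - max(e))
  u / sum(u)
}

#' Exact Gibbs distribution P(y)
#'
#' The RBM joint law \eqn{P(y) \propto \exp(E(y))}; equals
#' [exact_q_distribution()] at `k = 1`.
#'
#' @param p An [rbm_params()].
#' @return Probability vector of length `2^(n+m)`.
#' @export
exact_gibbs_distribution <- function(p) exact_q_distribution(p, 1)

#' Recover the Gibbs distribution from accepted samples
#'
#' Raises the empirical (or supplied) frequencies to the power `k` and
#' normalizes; configurations never observed keep probability zero.  Also
#' returns the visible marginal used by the variational solver, and an
#' effective-sample-size diagnostic (power-`k` recovery is biased for rare
#' states at finite sample size; exact enumeration is the reference).
#'
#' @param batch A `sample_batch` from [run_sampler()], or a numeric frequency
#'   vector of length `2^(n+m)` (then `n`, `m` must be given).
#' @param k The divisor used when sampling.
#' @param n,m Dimensions when `batch` is a plain vector.
#' @return List with `joint` (length `2^(n+m)`), `visible` (length `2^n`),
#'   `ess`.
#' @export
recover_gibbs <- function(batch, k, n = NULL, m = NULL) {
  if (inherits(batch, "sample_batch")) {
    if (batch$n_accepted == 0L) {
      stop_rbmqs("empty sample batch", class = "rbmqs_validation_error")
    }
    f <- batch$counts / batch$n_accepted
    n <- batch$n; m <- batch$m
  } else {
    f <- as.numeric(batch)
    if (is.null(n) || is.null(m) || length(f) != 2^(n + m)) {
      stop_rbmqs("frequency vector requires matching n and m",
                 class = "rbmqs_validation_error")
    }
    if (sum(f) <= 0) {
      stop_rbmqs("empty frequency vector", class = "rbmqs_validation_error")
    }
  }
  g <- ifelse(f > 0, f^k, 0)
  g <- g / sum(g)
  visible <- rowsum(g, rep(0:(2^n - 1L), each = 2^m))[, 1]
  list(joint = g, visible = as.numeric(visible),
       ess = 1 / sum(g[g > 0]^2))
}

#' Lower bound on the circuit acceptance probability
#'
#' \eqn{\exp(-(1/k)\sum_{ij} 2|w_{ij}|)}: every coupling's acceptance factor
#' is at least \eqn{e^{-2|w_{ij}|/k}}.
#'
#' @param p An [rbm_params()].
#' @param k Positive divisor.
#' @return Probability lower bound in (0, 1].
#' @export
acceptance_bound <- function(p, k) {
  if (k <= 0) stop_rbmqs("k must be positive", class = "rbmqs_validation_error")
  exp(-(1 / k) * sum(2 * abs(p$w)))
}

#' Automatic choice of the rescaling constant k
#'
#' `k = multiplier * max(floor, sum |w_ij|)`: scaling `k` with the total
#' coupling weight gives the acceptance rate a constant lower bound
#' (`exp(-2)` at `multiplier = 1`).  Recomputed from the current weights at
#' every training iteration.
#'
#' @param p An [rbm_params()].
#' @param multiplier Scale factor.
#' @param floor Minimum k (guards the early-training regime where all
#'   weights are near zero).
#' @return Positive scalar k.
#' @export
choose_k <- function(p, multiplier = 1, floor = 1) {
  multiplier * max(floor, sum(abs(p$w)))
}
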