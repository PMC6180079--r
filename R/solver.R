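# Variational energy, covariance gradient, and the gradient-descent loop.
#
# The objective is the Rayleigh quotient
#   <H> = sum_{x,x'} psi(x) <x|H|x'> psi(x') / sum_x psi(x)^2,
# psi(x) = sqrt(Ptilde(x)) s(x), all real.  Expectations are taken under the
# joint weight Ptilde(x) s(x)^2 (exact mode) or an empirical estimate of the
# visible distribution times s(x)^2 (sampled mode).  The gradient for each
# parameter is the covariance estimator 2(<E_loc D> - <E_loc><D>).

#' Local energy at a basis state
#'
#' \eqn{E_{loc}(x) = \langle x|H|\psi\rangle / \psi(x)} with
#' \eqn{\psi = \phi\, s}; only the states connected to `x` by some Pauli
#' string contribute.
#'
#' @param h A [qubit_hamiltonian()].
#' @param p An [rbm_params()] with `n` equal to the qubit count.
#' @param x Spin vector over \{-1, +1\}.
#' @return Local energy in Hartree.
#' @export
local_energy <- function(h, p, x) {
  if (p$n != h$n_qubits) {
    stop_rbmqs("parameter set has ", p$n, " visible units but Hamiltonian ",
               "has ", h$n_qubits, " qubits", class = "rbmqs_validation_error")
  }
  sg_x <- rbm_sign(p, x)
  lp_x <- rbm_prob(p, x, log = TRUE)
  if (abs(sg_x) <= S_FLOOR || !is.finite(lp_x)) {
    stop_rbmqs("state excluded: sign output or probability numerically zero",
               class = "rbmqs_excluded_state")
  }
  row <- ham_row(h, x)
  sp <- t(vapply(row$index, index_to_spins, numeric(h$n_qubits),
                 n = h$n_qubits))
  ratio <- exp(0.5 * (rbm_prob(p, sp, log = TRUE) - lp_x)) *
    rbm_sign(p, sp) / sg_x
  sum(row$value * ratio)
}

# Shared per-iteration state: basis spins and Hamiltonian matrix.
solver_setup <- function(h, cap = DEFAULT_QUBIT_CAP) {
  check_cap(h$n_qubits, cap)
  list(n = h$n_qubits,
       spins = all_spins(h$n_qubits),
       hmat = ham_matrix(h, cap = cap))
}

# Energy, local energies and normalized weights at parameters p.
# `visible_freq`: optional empirical visible distribution (length 2^n)
# replacing the exact Ptilde weights.
eval_state <- function(setup, p, visible_freq = NULL) {
  lp <- rbm_log_ptilde(p, setup$spins)
  sg <- tanh(as.numeric(setup$spins %*% p$d) + p$c)
  eff <- abs(sg) > S_FLOOR
  if (!is.null(visible_freq)) eff <- eff & visible_freq > 0
  if (!any(eff)) {
    stop_rbmqs("degenerate amplitude table: no state carries weight",
               class = "rbmqs_degenerate_table")
  }
  lpm <- max(lp)
  psi <- exp(0.5 * (lp - lpm)) * sg
  eloc <- as.numeric(setup$hmat %*% psi)[eff] / psi[eff]
  logw <- if (is.null(visible_freq)) {
    lp[eff] + 2 * log(abs(sg[eff]))
  } else {
    log(visible_freq[eff]) + 2 * log(abs(sg[eff]))
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  list(lp = lp, sg = sg, eff = eff, psi = psi, eloc = eloc, w = w,
       energy = sum(w * eloc))
}

#' Exact variational energy by full enumeration
#'
#' @inheritParams local_energy
#' @param cap Qubit cap (resource guard).
#' @return An `energy_estimate`: list with `value` (Hartree), `mode`
#'   (`"exact"`), `n_samples = 0`, `std_error = 0`.
#' @export
exact_energy <- function(h, p, cap = DEFAULT_QUBIT_CAP) {
  st <- eval_state(solver_setup(h, cap), p)
  structure(list(value = st$energy, mode = "exact",
                 n_samples = 0L, std_error = 0),
            class = "energy_estimate")
}

#' @export
print.energy_estimate <- function(x, ...) {
  cat(sprintf("<H> = %.8f Ha (%s mode", x$value, x$mode))
  if (x$mode == "sampled") {
    cat(sprintf(", %d samples, se %.2e", x$n_samples, x$std_error))
  }
  cat(")\n")
  invisible(x)
}

#' Energy estimate in exact or sampled mode
#'
#' Sampled mode estimates the visible distribution from the configured
#' sampler, then averages the local energy under the empirical joint weights.
#'
#' @inheritParams exact_energy
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples Accepted samples for sampled mode.
#' @param sampler `"enumerate"` (multinomial from the exact distribution) or
#'   `"circuit"` (classically simulated controlled-rotation Gibbs circuit).
#' @param seed Optional RNG seed.
#' @param k_multiplier Multiplier on the automatic rescaling constant `k`.
#' @param max_attempts Circuit-attempt guard per batch.
#' @return An `energy_estimate`.
#' @export
estimate_energy <- function(h, p, mode = c("exact", "sampled"),
                            n_samples = 2000L,
                            sampler = c("circuit", "enumerate"),
                            seed = NULL, k_multiplier = 1,
                            max_attempts = 1e7, cap = DEFAULT_QUBIT_CAP) {
  mode <- match.arg(mode)
  sampler <- match.arg(sampler)
  if (mode == "exact") return(exact_energy(h, p, cap))
  setup <- solver_setup(h, cap)
  with_seed(seed, {
    f <- sample_visible_freq(p, n_samples, sampler, k_multiplier, max_attempts)
    st <- eval_state(setup, p, visible_freq = f)
    ess <- 1 / sum(st$w^2)
    se <- sqrt(sum(st$w * (st$eloc - st$energy)^2) / max(ess, 1))
    structure(list(value = st$energy, mode = "sampled",
                   n_samples = as.integer(n_samples), std_error = se),
              class = "energy_estimate")
  })
}

# Empirical visible distribution (length 2^n) from the configured sampler,
# using the ambient RNG stream.
sample_visible_freq <- function(p, n_samples, sampler, k_multiplier,
                                max_attempts) {
  if (sampler == "enumerate") {
    lp <- rbm_log_ptilde(p, all_spins(p$n))
    prob <- exp(lp - max(lp))
    counts <- as.numeric(stats::rmultinom(1L, n_samples, prob))
    return(counts / n_samples)
  }
  k <- k_multiplier * choose_k(p)
  plan <- rotation_plan(p, k)
  batch <- run_sampler(plan, n_samples, max_attempts = max_attempts)
  recover_gibbs(batch, k)$visible
}

#' Covariance gradient of the energy
#'
#' The estimator \eqn{2(\langle E_{loc} D_{p_k}\rangle - \langle
#' E_{loc}\rangle\langle D_{p_k}\rangle)} applied component-wise over
#' `(a, b, w, d, c)`, with expectations under weights proportional to
#' \eqn{\tilde P(x) s(x)^2} (or an empirical visible distribution times
#' \eqn{s^2}).
#'
#' @inheritParams exact_energy
#' @param distribution `NULL` for exact enumeration, or a numeric vector of
#'   visible-state probabilities (length `2^n`, e.g. from
#'   [recover_gibbs()]`$visible`).
#' @return Numeric gradient vector in [pack_params()] order, with attribute
#'   `energy`.
#' @export
energy_gradient <- function(h, p, distribution = NULL,
                            cap = DEFAULT_QUBIT_CAP) {
  setup <- solver_setup(h, cap)
  grad_at(setup, p, visible_freq = distribution)
}

grad_at <- function(setup, p, visible_freq = NULL) {
  st <- eval_state(setup, p, visible_freq)
  if (sum(st$eff) < 2L) {
    stop_rbmqs("fewer than two effective states: gradient is degenerate",
               class = "rbmqs_degenerate_gradient")
  }
  D <- rbm_log_derivs_matrix(p, setup$spins[st$eff, , drop = FALSE])$D
  we <- st$w * st$eloc
  g <- 2 * (as.numeric(crossprod(D, we)) -
              st$energy * as.numeric(crossprod(D, st$w)))
  structure(g, energy = st$energy, n_effective = sum(st$eff))
}

#' Training configuration
#'
#' @param learning_rate Constant gradient-descent step (default 0.01).
#' @param iterations Iteration count; defaults to 20000 in exact mode and
#'   2000 in sampled mode.
#' @param mode `"exact"` (full enumeration each step) or `"sampled"`.
#' @param samples_per_iteration Accepted samples per step in sampled mode.
#' @param sampler `"circuit"` or `"enumerate"` (sampled mode).
#' @param seed Base RNG seed for initialization and sampling.
#' @param m Hidden-unit count; default `2 * n_qubits`.
#' @param restarts Independent seeds to try, keeping the run with the lowest
#'   minimum energy (local-minimum guard).
#' @param warm_start Optional [rbm_params()] (or checkpoint path) to start
#'   from instead of random initialization.
#' @param warm_start_iteration_fraction Iteration fraction used by
#'   [transfer_train()] (default 1/40).
#' @param k_multiplier,max_attempts Sampler controls (see [choose_k()]).
#' @param init_range Half-width of random initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, iterations = NULL,
                         mode = c("exact", "sampled"),
                         samples_per_iteration = 2000L,
                         sampler = c("circuit", "enumerate"),
                         seed = NULL, m = NULL, restarts = 1L,
                         warm_start = NULL,
                         warm_start_iteration_fraction = 1 / 40,
                         k_multiplier = 1, max_attempts = 1e7,
                         init_range = 0.02) {
  mode <- match.arg(mode)
  sampler <- match.arg(sampler)
  if (learning_rate <= 0) {
    stop_rbmqs("learning_rate must be positive",
               class = "rbmqs_validation_error")
  }
  if (is.null(iterations)) {
    iterations <- if (mode == "exact") 20000L else 2000L
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop_rbmqs("iterations must be at least 1",
               class = "rbmqs_validation_error")
  }
  structure(list(learning_rate = learning_rate, iterations = iterations,
                 mode = mode, samples_per_iteration = as.integer(samples_per_iteration),
                 sampler = sampler, seed = seed, m = m,
                 restarts = as.integer(restarts), warm_start = warm_start,
                 warm_start_iteration_fraction = warm_start_iteration_fraction,
                 k_multiplier = k_multiplier, max_attempts = max_attempts,
                 init_range = init_range),
            class = "train_config")
}

#' Gradient-descent training of the three-layer RBM
#'
#' Iterates `p <- p - learning_rate * gradient`, recording the energy, the
#' gradient norm and the effective-state count at every step.  The reported
#' observable is the minimum energy over all iterations (not the final
#' iterate).  Exact mode is bitwise reproducible for a given seed.
#'
#' @param h A [qubit_hamiltonian()].
#' @param config A [train_config()].
#' @return An `rbm_trace`: list with `trace` (data.frame of per-iteration
#'   records), `min_energy`, `min_iteration`, `best_params` (parameters at
#'   the minimum), `final_params`, `seed`, `mode`.
#' @export
train_rbm <- function(h, config = train_config()) {
  if (!is.null(config$warm_start) || config$restarts <= 1L) {
    return(train_once(h, config, config$seed))
  }
  seeds <- if (is.null(config$seed)) {
    sample.int(.Machine$integer.max, config$restarts)
  } else {
    config$seed + 1000L * (seq_len(config$restarts) - 1L)
  }
  runs <- lapply(seeds, function(s) train_once(h, config, s))
  best <- which.min(vapply(runs, function(r) r$min_energy, numeric(1)))
  out <- runs[[best]]
  out$restart_min_energies <- vapply(runs, function(r) r$min_energy, numeric(1))
  out
}

train_once <- function(h, config, seed) {
  setup <- solver_setup(h)
  n <- h$n_qubits
  with_seed(seed, {
    p <- config$warm_start
    if (is.character(p)) p <- read_checkpoint(p)
    if (is.null(p)) {
      m <- if (is.null(config$m)) 2L * n else as.integer(config$m)
      p <- rbm_init(n, m, seed = NULL, range = config$init_range)
    } else if (p$n != n) {
      stop_rbmqs("warm-start checkpoint has ", p$n,
                 " visible units but Hamiltonian has ", n, " qubits",
                 class = "rbmqs_validation_error")
    }
    iters <- config$iterations
    energy <- numeric(iters); gnorm <- numeric(iters); neff <- integer(iters)
    best_e <- Inf; best_it <- NA_integer_; best_p <- p
    for (it in seq_len(iters)) {
      f <- if (config$mode == "sampled") {
        sample_visible_freq(p, config$samples_per_iteration, config$sampler,
                            config$k_multiplier, config$max_attempts)
      }
      # a single effective state (e.g. the sign layer crossing zero on a
      # negligible-weight state) has zero covariance gradient, not an abort
      g <- tryCatch(grad_at(setup, p, visible_freq = f),
                    rbmqs_degenerate_gradient = function(e) {
                      st <- eval_state(setup, p, visible_freq = f)
                      structure(rep(0, n_params(p)), energy = st$energy,
                                n_effective = sum(st$eff))
                    })
      energy[it] <- attr(g, "energy")
      gnorm[it] <- sqrt(sum(g^2))
      neff[it] <- attr(g, "n_effective")
      if (energy[it] < best_e) {
        best_e <- energy[it]; best_it <- it; best_p <- p
      }
      v <- pack_params(p) - config$learning_rate * as.numeric(g)
      if (!all(is.finite(v))) {
        stop_rbmqs("parameters diverged (NaN/Inf) at iteration ", it,
                   "; last energy ", format(energy[it]),
                   class = "rbmqs_divergence_error")
      }
      p <- unpack_params(v, p$n, p$m)
    }
    structure(list(
      trace = data.frame(iteration = seq_len(iters), energy = energy,
                         grad_norm = gnorm, n_effective = neff),
      min_energy = best_e, min_iteration = best_it,
      best_params = best_p, final_params = p,
      seed = seed, mode = config$mode, config = config
    ), class = "rbm_trace")
  })
}

#' @export
print.rbm_trace <- function(x, ...) {
  cat(sprintf("RBM training trace: %d iterations (%s mode)\n",
              nrow(x$trace), x$mode))
  cat(sprintf("  min energy %.8f Ha at iteration %d\n",
              x$min_energy, x$min_iteration))
  invisible(x)
}

#' Transfer-learning warm start
#'
#' Identical to [train_rbm()] but initialized from a previous checkpoint and
#' run for `ceiling(fraction * iterations)` steps — the reduced-budget
#' protocol used along a potential-energy surface, with default fraction
#' 1/40.
#'
#' @param h_new Hamiltonian of the new scan point.
#' @param checkpoint An [rbm_params()] object or checkpoint file path.
#' @param config A [train_config()]; its `iterations` is the full budget.
#' @param fraction Iteration fraction (default from `config`).
#' @return An `rbm_trace`.
#' @export
transfer_train <- function(h_new, checkpoint, config = train_config(),
                           fraction = config$warm_start_iteration_fraction) {
  p <- if (is.character(checkpoint)) read_checkpoint(checkpoint) else checkpoint
  if (!inherits(p, "rbm_params")) {
    stop_rbmqs("checkpoint must be an rbm_params object or file path",
               class = "rbmqs_validation_error")
  }
  if (p$n != h_new$n_qubits) {
    stop_rbmqs("checkpoint has ", p$n, " visible units but Hamiltonian has ",
               h_new$n_qubits, " qubits", class = "rbmqs_validation_error")
  }
  config$warm_start <- p
  config$iterations <- as.integer(ceiling(fraction * config$iterations))
  train_rbm(h_new, config)
}

#' Write a training trace to CSV and a JSON summary
#'
#' @param trace An `rbm_trace` from [train_rbm()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @param exact_ground Optional exact ground energy to include.
#' @return Invisibly, the summary list.
#' @export
write_trace <- function(trace, csv_path = NULL, json_path = NULL,
                        exact_ground = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(trace$trace, csv_path, row.names = FALSE)
  }
  summary <- list(format_version = 1L,
                  min_energy = trace$min_energy,
                  min_iteration = trace$min_iteration,
                  exact_ground_energy = exact_ground,
                  seed = trace$seed, mode = trace$mode)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = I(17), null = "null")
  }
  invisible(summary)
}
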