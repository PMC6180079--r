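# Workbench: resource accounting, fixture generation, PES scan driver.

#' Qubit resource accounting
#'
#' Total qubits for one sampling circuit: `n + m + 1` when the single
#' ancilla is measured and reused across couplings, `n + m + n*m` when every
#' coupling gets its own ancilla.
#'
#' @param n Visible units (= spin orbitals after Jordan-Wigner).
#' @param m Hidden units.
#' @param reuse_ancilla Reuse one ancilla qubit across all couplings?
#' @return Integer qubit count.
#' @examples
#' qubit_requirement(4, 8)   # 13
#' qubit_requirement(6, 6)   # 13
#' @export
qubit_requirement <- function(n, m, reuse_ancilla = TRUE) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || n < 1L || m < 1L) {
    stop_rbmqs("n and m must be positive integers",
               class = "rbmqs_validation_error")
  }
  if (reuse_ancilla) n + m + 1L else n + m + n * m
}

#' Generate a random Pauli Hamiltonian fixture
#'
#' Seeded, reproducible synthetic Hamiltonians for testing and benchmarks:
#' `n_terms` Pauli strings, each acting on 1 to `max_locality` distinct
#' qubits with uniform coefficients on `(-scale, scale)`.  With
#' `require_real` (default) every term carries an even number of Y factors,
#' so the matrix is real symmetric — the family the real-amplitude ansatz
#' targets.
#'
#' @param n_qubits Number of qubits.
#' @param n_terms Number of Pauli terms (before merging of collisions).
#' @param max_locality Maximum factors per term.
#' @param scale Coefficient half-width (Hartree).
#' @param seed RNG seed (ambient stream preserved).
#' @param require_real Force an even Y count per term.
#' @param file Optional path; the fixture is also written as `.ham` text.
#' @return A [qubit_hamiltonian()].
#' @export
generate_fixture <- function(n_qubits, n_terms = 2L * n_qubits,
                             max_locality = 2L, scale = 1, seed = NULL,
                             require_real = TRUE, file = NULL) {
  n_qubits <- as.integer(n_qubits)
  n_terms <- as.integer(n_terms)
  max_locality <- as.integer(max_locality)
  if (n_terms < 1L) {
    stop_rbmqs("n_terms must be at least 1", class = "rbmqs_validation_error")
  }
  if (max_locality < 1L || max_locality > n_qubits) {
    stop_rbmqs("max_locality must be between 1 and n_qubits",
               class = "rbmqs_validation_error")
  }
  h <- with_seed(seed, {
    terms <- lapply(seq_len(n_terms), function(i) {
      loc <- sample.int(max_locality, 1L)
      qb <- sort(sample.int(n_qubits, loc) - 1L)
      lab <- sample(c("X", "Y", "Z"), loc, replace = TRUE)
      if (require_real && sum(lab == "Y") %% 2L == 1L) {
        lab[match("Y", lab)] <- "X"
      }
      pauli_term(stats::runif(1, -scale, scale), qb, lab)
    })
    qubit_hamiltonian(n_qubits, terms)
  })
  h <- sort_ham(h)
  if (!is.null(file)) write_ham(h, file)
  h
}

#' Potential-energy-surface scan
#'
#' Trains the RBM at an ordered series of Hamiltonians (one per geometry
#' label).  With transfer learning on, point `i > 1` warm-starts from the
#' best parameters of point `i - 1` and runs for the configured fraction of
#' the iteration budget (default 1/40); the first point always gets the full
#' budget.
#'
#' @param points Named list of [qubit_hamiltonian()] objects or `.ham` file
#'   paths; names are the geometry labels (e.g. bond length in Angstrom).
#' @param config A [train_config()].
#' @param transfer Use transfer-learning warm starts?
#' @param transfer_fraction Iteration fraction for warm-started points.
#' @param csv_path Optional path for the results table.
#' @return List with `results` (data.frame: label, min_energy,
#'   exact_energy, error, iterations) and `traces`.
#' @export
run_scan <- function(points, config = train_config(), transfer = TRUE,
                     transfer_fraction = config$warm_start_iteration_fraction,
                     csv_path = NULL) {
  if (!length(points)) {
    stop_rbmqs("scan needs at least one point", class = "rbmqs_validation_error")
  }
  hams <- lapply(points, function(p) if (is.character(p)) read_ham(p) else p)
  labels <- names(points)
  if (is.null(labels)) labels <- as.character(seq_along(points))
  nq <- vapply(hams, function(h) h$n_qubits, integer(1))
  if (length(unique(nq)) != 1L) {
    stop_rbmqs("all scan points must have the same qubit count (got ",
               paste(unique(nq), collapse = ", "), ")",
               class = "rbmqs_validation_error")
  }
  traces <- vector("list", length(hams))
  res <- data.frame(label = labels, min_energy = NA_real_,
                    exact_energy = NA_real_, error = NA_real_,
                    iterations = NA_integer_)
  prev <- NULL
  for (i in seq_along(hams)) {
    tr <- if (transfer && i > 1L) {
      transfer_train(hams[[i]], prev, config, fraction = transfer_fraction)
    } else {
      train_rbm(hams[[i]], config)
    }
    prev <- tr$best_params
    exact <- exact_ground_state(hams[[i]])$energy
    traces[[i]] <- tr
    res$min_energy[i] <- tr$min_energy
    res$exact_energy[i] <- exact
    res$error[i] <- tr$min_energy - exact
    res$iterations[i] <- nrow(tr$trace)
  }
  if (!is.null(csv_path)) utils::write.csv(res, csv_path, row.names = FALSE)
  list(results = res, traces = traces)
}
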