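test_that("local energy reduces to constants and eigenvalues in limiting cases", {
  # identity Hamiltonian: E_loc = c everywhere
  hc <- parse_ham(c("qubits 2", "1.7"))
  p <- rand_params(2, 2, seed = 1, scale = 0.5)
  for (idx in 0:3) {
    expect_equal(local_energy(hc, p, index_to_spins(idx, 2)), 1.7,
                 tolerance = 1e-12)
  }
  # diagonal Hamiltonian with the amplitude concentrated on one basis state
  hz <- parse_ham(c("qubits 1", "1.0 Z0"))
  pc <- rbm_params(a = 30, b = 0.1, w = 0.01, d = 0.3, c = 0.2)
  # a = +30 concentrates on sigma = +1 = |1>, where Z has eigenvalue -1
  expect_equal(local_energy(hz, pc, 1), -1, tolerance = 1e-6)
  # excluded-state signal where the sign output vanishes
  p0 <- rbm_params(a = 0, b = 0, w = 0, d = 0, c = 0)
  expect_error(local_energy(hz, p0, 1), class = "rbmqs_excluded_state")
})

test_that("weighted local energies reproduce the dense quadratic form", {
  h <- generate_fixture(3, n_terms = 6, max_locality = 3, seed = 5)
  p <- rand_params(3, 3, seed = 6, scale = 0.6)
  tab <- rbm_table(p)
  eloc <- vapply(seq_len(8), function(i) {
    local_energy(h, p, tab$spins[i, ])
  }, numeric(1))
  lhs <- sum(tab$weight * eloc)
  psi <- exp(0.5 * (tab$log_ptilde - max(tab$log_ptilde))) * tab$sign
  m <- Re(oracle_dense_matrix(h))
  rhs <- as.numeric(t(psi) %*% m %*% psi / sum(psi^2))
  expect_lt(abs(lhs - rhs), 1e-10)
  expect_lt(abs(exact_energy(h, p)$value - rhs), 1e-10)
})

test_that("the exact energy obeys the variational principle", {
  h <- generate_fixture(3, seed = 8)
  e0 <- exact_ground_state(h)$energy
  for (seed in 1:10) {
    p <- rand_params(3, 3, seed = 300 + seed, scale = 1)
    expect_gte(exact_energy(h, p)$value, e0 - 1e-10)
  }
  # identity Hamiltonian: energy is the constant for any nondegenerate p
  expect_equal(exact_energy(parse_ham(c("qubits 2", "2.0")),
                            rand_params(2, 2, seed = 3))$value, 2.0,
               tolerance = 1e-12)
})

test_that("covariance gradient vanishes for the identity and matches finite differences", {
  hc <- parse_ham(c("qubits 2", "0.9"))
  p <- rand_params(2, 2, seed = 11, scale = 0.5)
  expect_lt(max(abs(energy_gradient(hc, p))), 1e-12)
  h <- generate_fixture(3, n_terms = 6, seed = 12)
  worst <- 0
  for (case in 1:20) {
    p <- rand_params(3, 2, seed = 400 + case, scale = 0.6)
    g <- as.numeric(energy_gradient(h, p))
    fd <- fd_gradient(h, p)
    worst <- max(worst, sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)))
  }
  expect_lt(worst, 1e-5)
})

test_that("sampled-mode gradients agree with exact mode at large sample size", {
  h <- generate_fixture(2, seed = 14)
  p <- rand_params(2, 2, seed = 15, scale = 0.6)
  g_exact <- as.numeric(energy_gradient(h, p))
  f <- with_seed(16, rbmqs:::sample_visible_freq(p, 1e5, "enumerate", 1, 1e7))
  g_samp <- as.numeric(energy_gradient(h, p, distribution = f))
  # loose 4-sigma-style band: empirical weights at N = 1e5 have relative
  # fluctuations ~ 1/sqrt(N)
  expect_lt(max(abs(g_samp - g_exact)), 4 * max(abs(g_exact)) / sqrt(1e5) * 10)
})

test_that("sampled energy estimates converge as the sample size grows", {
  h <- generate_fixture(2, seed = 17)
  p <- rand_params(2, 3, seed = 18, scale = 0.7)
  e_exact <- exact_energy(h, p)$value
  errs <- vapply(c(1e2, 1e5), function(N) {
    est <- estimate_energy(h, p, mode = "sampled", n_samples = N,
                           sampler = "enumerate", seed = 19)
    abs(est$value - e_exact)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 5e-3)
  est <- estimate_energy(h, p, mode = "sampled", n_samples = 1000,
                         sampler = "enumerate", seed = 20)
  expect_identical(est$mode, "sampled")
  expect_gt(est$std_error, 0)
})

test_that("training finds the single-qubit ground state and concentrates weight", {
  h <- parse_ham(c("qubits 1", "-1.0 Z0"))
  tr <- train_rbm(h, train_config(iterations = 500, seed = 2, m = 2))
  expect_lt(abs(tr$min_energy - (-1)), 1e-3)
  # -Z0 has ground state |0> (sigma = -1) under the declared encoding;
  # the trained distribution concentrates there
  tab <- rbm_table(tr$best_params)
  expect_gte(tab$weight[spins_to_index(-1) + 1L], 0.99)
})

test_that("training validates input and aborts cleanly on divergence", {
  h <- parse_ham(c("qubits 1", "-1.0 Z0"))
  expect_error(train_config(iterations = 0), class = "rbmqs_validation_error")
  expect_error(train_config(learning_rate = -1), class = "rbmqs_validation_error")
})

test_that("exact-mode training is bitwise reproducible per seed and variational", {
  h <- generate_fixture(2, seed = 1)
  cfg <- train_config(iterations = 300, seed = 33)
  tr1 <- train_rbm(h, cfg)
  tr2 <- train_rbm(h, cfg)
  expect_identical(tr1$trace$energy, tr2$trace$energy)
  expect_identical(pack_params(tr1$final_params), pack_params(tr2$final_params))
  e0 <- exact_ground_state(h)$energy
  expect_true(all(tr1$trace$energy >= e0 - 1e-10))
  expect_equal(tr1$min_energy, min(tr1$trace$energy))
  expect_equal(tr1$trace$energy[tr1$min_iteration], tr1$min_energy)
})

test_that("transfer training reuses checkpoints and validates dimensions", {
  h <- parse_ham(c("qubits 1", "-0.6 Z0", "-0.4 X0"))
  cfg <- train_config(iterations = 400, seed = 3)
  tr <- train_rbm(h, cfg)
  # fraction = 1 behaves exactly like a warm-started full run
  cfg_ws <- cfg; cfg_ws$warm_start <- tr$best_params
  full <- train_rbm(h, cfg_ws)
  via_transfer <- transfer_train(h, tr$best_params, cfg, fraction = 1)
  expect_identical(full$trace$energy, via_transfer$trace$energy)
  # 1/40 default budget
  short <- transfer_train(h, tr$best_params, cfg)
  expect_equal(nrow(short$trace), ceiling(400 / 40))
  # dimension mismatch
  h2q <- generate_fixture(2, seed = 4)
  expect_error(transfer_train(h2q, tr$best_params, cfg),
               class = "rbmqs_validation_error")
})

test_that("warm starts outperform cold starts at the reduced budget", {
  mk <- function(l) qubit_hamiltonian(1, list(pauli_term(-l, 0L, "Z"),
                                              pauli_term(-(1 - l), 0L, "X")))
  h_a <- mk(0.50); h_b <- mk(0.55)
  e_b <- exact_ground_state(h_b)$energy
  warm_ok <- 0L; cold_ok <- 0L
  for (s in 1:10) {
    base <- train_rbm(h_a, train_config(iterations = 4000, seed = s))
    warm <- transfer_train(h_b, base$best_params,
                           train_config(iterations = 4000, seed = s))
    cold <- train_rbm(h_b, train_config(iterations = 100, seed = s))
    if (abs(warm$min_energy - e_b) < 5e-3) warm_ok <- warm_ok + 1L
    if (abs(cold$min_energy - e_b) < 5e-3) cold_ok <- cold_ok + 1L
  }
  expect_gte(warm_ok, 8L)
  expect_gte(warm_ok, cold_ok)
})

test_that("training traces export to CSV and JSON summaries", {
  h <- parse_ham(c("qubits 1", "-1.0 Z0"))
  tr <- train_rbm(h, train_config(iterations = 50, seed = 5))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, csv_path = csv, json_path = js, exact_ground = -1)
  back <- utils::read.csv(csv)
  expect_identical(names(back),
                   c("iteration", "energy", "grad_norm", "n_effective"))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$min_energy, tr$min_energy)
})
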