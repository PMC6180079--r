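test_that("closed-form hidden marginalization matches the brute-force sum", {
  # zero parameters: Ptilde = 2^m, normalized P uniform
  p0 <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0, 0), c = 0)
  for (idx in 0:3) {
    expect_equal(rbm_prob(p0, index_to_spins(idx, 2)), 2.0)
  }
  # property: random parameters, all n, m <= 4
  case <- 0L
  for (n in 2:4) for (m in 2:4) {
    case <- case + 1L
    p <- rand_params(n, m, seed = 100 + case, scale = 0.8)
    for (idx in c(0L, 2^n - 1L, case %% 2^n)) {
      x <- index_to_spins(idx, n)
      expect_equal(rbm_prob(p, x), oracle_hidden_sum(p, x),
                   tolerance = 1e-12)
    }
  }
})

test_that("with no hidden units the visible bias gives the logistic law", {
  t <- 0.8
  p <- rbm_params(a = t, b = numeric(0), w = numeric(0), d = 0.1, c = 0)
  pr <- rbm_prob(p, matrix(c(1, -1), ncol = 1))
  expect_equal(pr[1] / sum(pr), exp(t) / (exp(t) + exp(-t)), tolerance = 1e-14)
})

test_that("the sign layer is the bounded tanh classifier", {
  pz <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0, 0), c = 0)
  expect_equal(rbm_sign(pz, c(1, -1)), 0)
  psat <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0, 0), c = 100)
  expect_equal(rbm_sign(psat, c(1, 1)), 1, tolerance = 1e-15)
  pd <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0.5, -0.5), c = 0.1)
  expect_equal(rbm_sign(pd, c(1, 1)), tanh(0.1))
  # strictly inside (-1, 1) for finite parameters
  p <- rand_params(3, 2, seed = 7, scale = 2)
  s <- rbm_sign(p, rbmqs:::all_spins(3))
  expect_true(all(abs(s) < 1))
})

test_that("log-derivatives match hand formulas and finite differences", {
  # D_c at zero weights: d/dc log tanh(c)
  p <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0, 0), c = 0.5)
  g <- rbm_log_derivs(p, c(1, -1))
  expect_equal(unname(g[length(g)]), (1 - tanh(0.5)^2) / tanh(0.5),
               tolerance = 1e-12)
  # D_a = sigma/2; with w = 0, D_w = sigma_i tanh(b_j)/2
  p2 <- rbm_params(a = c(0.3, -0.1), b = c(0.4, -0.2), w = rep(0, 4),
                   d = c(0.05, 0.02), c = 0.1)
  x <- c(1, -1)
  g2 <- rbm_log_derivs(p2, x)
  expect_equal(g2[1:2], x / 2)
  expect_equal(g2[5:8],
               as.numeric(outer(x, tanh(p2$b)) / 2), tolerance = 1e-12)
  # finite-difference oracle over random (p, x) pairs
  worst <- 0
  for (case in 1:100) {
    n <- 2L + case %% 3L
    m <- 1L + case %% 3L
    p <- rand_params(n, m, seed = 200 + case, scale = 0.6)
    x <- index_to_spins(case %% 2^n, n)
    g <- rbm_log_derivs(p, x)
    v <- pack_params(p)
    eps <- 1e-6
    fd <- vapply(seq_along(v), function(i) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      pp <- unpack_params(vp, n, m); pm <- unpack_params(vm, n, m)
      (0.5 * rbm_prob(pp, x, log = TRUE) + log(abs(rbm_sign(pp, x))) -
         0.5 * rbm_prob(pm, x, log = TRUE) - log(abs(rbm_sign(pm, x)))) / (2 * eps)
    }, numeric(1))
    worst <- max(worst, sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)))
  }
  expect_lt(worst, 1e-6)
})

test_that("initialization is seeded, bounded uniform with zero mean", {
  p1 <- rbm_init(3, 4, seed = 5)
  p2 <- rbm_init(3, 4, seed = 5)
  expect_identical(pack_params(p1), pack_params(p2))
  draws <- pack_params(rbm_init(99, 99, seed = 6))  # ~10^4 values
  expect_gt(min(draws), -0.02)
  expect_lt(max(draws), 0.02)
  big <- rbm_init(315, 315, seed = 7)  # ~10^5 values
  v <- pack_params(big)
  se <- 0.02 / sqrt(3) / sqrt(length(v))
  expect_lt(abs(mean(v)), 3 * se)
  expect_error(rbm_init(0, 2), class = "rbmqs_validation_error")
})

test_that("the amplitude table flags degeneracy and normalizes weights", {
  pz <- rbm_params(a = c(0, 0), b = 0, w = c(0, 0), d = c(0, 0), c = 0)
  tab <- rbm_table(pz)
  expect_true(tab$degenerate)   # sign layer identically zero
  p <- rand_params(3, 3, seed = 9, scale = 0.7)
  tab <- rbm_table(p)
  expect_false(tab$degenerate)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  # independent per-state recomputation
  for (idx in 0:7) {
    x <- index_to_spins(idx, 3)
    w_direct <- oracle_hidden_sum(p, x) * rbm_sign(p, x)^2
    expect_equal(tab$weight[idx + 1L] / tab$weight[1L],
                 w_direct / (oracle_hidden_sum(p, index_to_spins(0, 3)) *
                               rbm_sign(p, index_to_spins(0, 3))^2),
                 tolerance = 1e-10)
  }
})

test_that("rescaling the unnormalized distribution is a gauge freedom", {
  # appending a decoupled hidden unit with bias beta multiplies Ptilde by
  # 2 cosh(beta) everywhere; energy and gradients must not move.
  h <- generate_fixture(3, seed = 13)
  p <- rand_params(3, 2, seed = 14, scale = 0.5)
  for (beta in c(0.7, -2, 5)) {
    paug <- rbm_params(p$a, c(p$b, beta), cbind(p$w, 0), p$d, p$c)
    expect_equal(exact_energy(h, paug)$value, exact_energy(h, p)$value,
                 tolerance = 1e-12)
    g <- energy_gradient(h, p)
    gaug <- energy_gradient(h, paug)
    # shared coordinates in the augmented packing (n=3, m=3):
    # a = 1:3, original b = 4:5, original w columns = 7:12, d & c = 16:19
    orig <- c(1:3, 4:5, 7:12, 16:19)
    expect_equal(as.numeric(gaug)[orig], as.numeric(g), tolerance = 1e-10)
  }
})

test_that("checkpoints round-trip parameters losslessly", {
  p <- rand_params(3, 4, seed = 15, scale = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(p, path, rng_seed = 42L)
  q <- read_checkpoint(path)
  expect_identical(pack_params(q), pack_params(p))
  expect_equal(attr(q, "rng_seed"), 42L)
})
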