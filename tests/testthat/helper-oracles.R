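# Independent oracles used throughout the suite.  These deliberately take
# the slow, literal route (dense complex kronecker products, explicit sums)
# so they share no code path with the package implementations they check.

# Dense complex matrix of a qubit Hamiltonian by naive per-term kron loop.
oracle_dense_matrix <- function(h) {
  mats <- list(
    I = diag(2) + 0i,
    X = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    Y = matrix(c(0, 1i, -1i, 0), 2, 2),  # column-major: Y[1,2] = -i, Y[2,1] = i
    Z = diag(c(1, -1)) + 0i
  )
  n <- h$n_qubits
  out <- matrix(0i, 2^n, 2^n)
  for (t in h$terms) {
    factors <- rep("I", n)
    factors[t$qubits + 1L] <- t$labels
    out <- out + t$coefficient * Reduce(kronecker, mats[factors])
  }
  out
}

# Dense ladder matrices on N qubits (|1> = occupied, qubit 0 = MSB) with the
# Jordan-Wigner parity string written as an explicit Z kron product.
oracle_ladders <- function(N) {
  A <- matrix(c(0, 0, 1, 0), 2, 2)  # annihilation: |1> -> |0> (column-major)
  Z <- diag(c(1, -1)); I2 <- diag(2)
  a <- lapply(0:(N - 1L), function(p) {
    Reduce(kronecker, lapply(0:(N - 1L), function(q) {
      if (q < p) Z else if (q == p) A else I2
    }))
  })
  list(a = a, ad = lapply(a, t))
}

# Fock-space matrix of an integral set assembled directly from ladder
# matrices (spin orbitals interleaved: alpha0, beta0, alpha1, ...).
oracle_fock_matrix <- function(ints) {
  M <- ints$n_spatial
  N <- 2L * M
  ld <- oracle_ladders(N)
  H <- ints$e_const * diag(2^N)
  for (p in 1:M) for (q in 1:M) {
    if (ints$h1[p, q] == 0) next
    for (s in 0:1) {
      P <- 2L * (p - 1L) + s + 1L
      Q <- 2L * (q - 1L) + s + 1L
      H <- H + ints$h1[p, q] * ld$ad[[P]] %*% ld$a[[Q]]
    }
  }
  for (p in 1:M) for (q in 1:M) for (r in 1:M) for (s in 1:M) {
    v <- ints$h2[p, q, r, s]
    if (v == 0) next
    for (s1 in 0:1) for (s2 in 0:1) {
      P <- 2L * (p - 1L) + s1 + 1L
      Q <- 2L * (q - 1L) + s2 + 1L
      R <- 2L * (r - 1L) + s2 + 1L
      S <- 2L * (s - 1L) + s1 + 1L
      H <- H + 0.5 * v * ld$ad[[P]] %*% ld$ad[[Q]] %*% ld$a[[R]] %*% ld$a[[S]]
    }
  }
  H
}

# Random integral set with the proper chemists' 8-fold symmetry.
rand_integrals <- function(M, seed, n_electrons = 2L) {
  set.seed(seed)
  h1 <- matrix(rnorm(M * M, sd = 0.5), M, M)
  h1 <- (h1 + t(h1)) / 2
  chem <- array(rnorm(M^4, sd = 0.2), rep(M, 4L))
  sym <- array(0, rep(M, 4L))
  for (i in 1:M) for (j in 1:M) for (k in 1:M) for (l in 1:M) {
    perms <- list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                  c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i))
    sym[i, j, k, l] <- mean(vapply(perms, function(p) {
      chem[p[1], p[2], p[3], p[4]]
    }, numeric(1)))
  }
  integral_set(h1, rbmqs:::phys_from_chem(sym),
               e_const = rnorm(1), n_electrons = n_electrons)
}

# Random RBM parameters at a given scale (larger than the training init so
# the tables are well away from the degenerate all-zero-sign point).
rand_params <- function(n, m, seed, scale = 0.5) {
  set.seed(seed)
  k <- n + m + n * m + n + 1L
  unpack_params(runif(k, -scale, scale), n, m)
}

# Brute-force hidden-configuration sum for the unnormalized probability.
oracle_hidden_sum <- function(p, x) {
  total <- 0
  for (idx in 0:(2^p$m - 1L)) {
    hvec <- 2 * bitwAnd(bitwShiftR(idx, (p$m - 1L):0L), 1L) - 1
    total <- total + exp(sum(p$a * x) + sum(p$b * hvec) +
                           sum((x %*% p$w) * hvec))
  }
  total
}

# Central finite differences of the exact energy, in pack_params order.
fd_gradient <- function(h, p, eps = 1e-6) {
  v <- pack_params(p)
  vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    (exact_energy(h, unpack_params(vp, p$n, p$m))$value -
       exact_energy(h, unpack_params(vm, p$n, p$m))$value) / (2 * eps)
  }, numeric(1))
}

# Is a sign pattern over the 2^n basis states representable by the linear
# threshold sign layer?  Perceptron feasibility on the high-weight states.
sign_separable <- function(amplitudes, n, amp_floor = 1e-3) {
  spins <- rbmqs:::all_spins(n)
  keep <- abs(amplitudes) > amp_floor
  X <- cbind(spins[keep, , drop = FALSE], 1)
  y <- sign(amplitudes[keep])
  w <- rep(0, ncol(X))
  for (epoch in seq_len(20000L)) {
    pred <- sign(X %*% w)
    pred[pred == 0] <- 1
    bad <- which(pred != y)
    if (!length(bad)) return(TRUE)
    w <- w + y[bad[1]] * X[bad[1], ]
  }
  FALSE
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# The synthetic hydrogen-like 4-qubit molecular Hamiltonian used in the
# ground-state recovery tests.
h2_like_hamiltonian <- function() {
  jordan_wigner(read_fcidump(system.file(
    "extdata", "h2_sto3g_like_synthetic.fcidump", package = "rbmqs")))
}
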