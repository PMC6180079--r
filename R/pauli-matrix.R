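# Matrix backing for qubit Hamiltonians.
#
# Basis convention (fixed package-wide): spin sigma_i = +1 means qubit i is in
# |1>, sigma_i = -1 means |0>.  Hence <x|Z_i|x> = -sigma_i (Z|1> = -|1>).
# Integer index of a basis state: qubit 0 is the most significant bit,
# index = sum_i bit_i * 2^(n-1-i), with bit_i = 1 for |1>.

DEFAULT_QUBIT_CAP <- 14L

check_cap <- function(n, cap) {
  if (n > cap) {
    stop_rbmqs("Hamiltonian acts on ", n, " qubits, above the cap of ", cap,
               " (raise `cap` explicitly if you really want a 2^", n,
               " dimensional matrix)", class = "rbmqs_resource_error")
  }
}

#' Basis-state encoding
#'
#' Maps between spin vectors over \{+1, -1\} (one entry per qubit,
#' `+1` = qubit state `|1>`) and 0-based integer indices with qubit 0 as the
#' most significant bit.
#'
#' @param spins Numeric vector over \{-1, +1\}.
#' @return `spins_to_index()` a 0-based integer; `index_to_spins()` a spin
#'   vector.
#' @examples
#' spins_to_index(c(1, -1))   # |10> -> 2
#' index_to_spins(2, 2)
#' @export
spins_to_index <- function(spins) {
  n <- length(spins)
  bits <- (spins + 1) / 2
  if (!all(bits %in% c(0, 1))) {
    stop_rbmqs("spins must be +1 or -1", class = "rbmqs_validation_error")
  }
  as.integer(sum(bits * 2^(n - seq_len(n))))
}

#' @rdname spins_to_index
#' @param index 0-based basis index.
#' @param n Number of qubits.
#' @export
index_to_spins <- function(index, n) {
  bits <- bitwAnd(bitwShiftR(as.integer(index), (n - 1L):0L), 1L)
  2 * bits - 1
}

# All 2^n basis states as a matrix of spins, row r = index r-1.
all_spins <- function(n) {
  idx <- 0:(2^n - 1L)
  vapply(seq_len(n), function(i) {
    2 * bitwAnd(bitwShiftR(idx, n - i), 1L) - 1
  }, numeric(2^n))
}

# Per-term bit masks: xmask flips (X and Y factors), plus index vectors.
term_masks <- function(t, n) {
  bitval <- function(q) bitwShiftL(1L, n - 1L - q)  # qubit 0 = MSB
  xq <- t$qubits[t$labels %in% c("X", "Y")]
  list(
    xmask = if (length(xq)) Reduce(bitwOr, vapply(xq, bitval, integer(1))) else 0L,
    zq = t$qubits[t$labels == "Z"],
    yq = t$qubits[t$labels == "Y"]
  )
}

# Vectorized matrix elements <row | term | row XOR xmask> for 0-based rows.
term_values <- function(t, n, rows) {
  mk <- term_masks(t, n)
  val <- rep(t$coefficient, length(rows))
  ny <- length(mk$yq)
  if (ny) val <- val * (-1)^(ny / 2)           # i^(#Y), even #Y enforced
  for (q in mk$zq) {
    b <- bitwAnd(bitwShiftR(rows, n - 1L - q), 1L)
    val <- val * (1 - 2 * b)                   # <b|Z|b> = (-1)^b
  }
  for (q in mk$yq) {
    b <- bitwAnd(bitwShiftR(rows, n - 1L - q), 1L)
    val <- val * (2 * b - 1)                   # <b|Y|1-b> = i(2b-1)
  }
  list(cols = bitwXor(rows, mk$xmask), values = val)
}

#' Full matrix of a qubit Hamiltonian
#'
#' Assembles \eqn{\sum_t c_t \bigotimes_i P_i} in the computational basis
#' (qubit 0 = most significant bit).  The result is real symmetric; dense up
#' to 10 qubits, a sparse `Matrix::dgCMatrix` above (override with `sparse`).
#'
#' @param h A [qubit_hamiltonian()].
#' @param sparse Return a sparse matrix?  Default: only above 10 qubits.
#' @param cap Refuse more than `cap` qubits (resource guard).
#' @return A `2^n x 2^n` real symmetric matrix.
#' @export
ham_matrix <- function(h, sparse = h$n_qubits > 10L, cap = DEFAULT_QUBIT_CAP) {
  n <- h$n_qubits
  check_cap(n, cap)
  dim <- 2^n
  rows <- 0:(dim - 1L)
  is <- integer(0); js <- integer(0); xs <- numeric(0)
  for (t in h$terms) {
    tv <- term_values(t, n, rows)
    is <- c(is, rows); js <- c(js, tv$cols); xs <- c(xs, tv$values)
  }
  m <- Matrix::sparseMatrix(i = is + 1L, j = js + 1L, x = xs,
                            dims = c(dim, dim))
  if (sparse) m else as.matrix(m)
}

#' Sparse row of the Hamiltonian matrix
#'
#' Each Pauli string connects a basis state `x` to exactly one partner (the
#' X/Y flip pattern); this returns the nonzero entries
#' \eqn{\langle x|H|x'\rangle} of row `x` without building the full matrix.
#'
#' @param h A [qubit_hamiltonian()].
#' @param spins Spin vector of the row state.
#' @return A data.frame with columns `index` (0-based column) and `value`.
#' @export
ham_row <- function(h, spins) {
  n <- h$n_qubits
  if (length(spins) != n) {
    stop_rbmqs("state has ", length(spins), " spins but Hamiltonian has ",
               n, " qubits", class = "rbmqs_validation_error")
  }
  row <- spins_to_index(spins)
  cols <- integer(length(h$terms)); vals <- numeric(length(h$terms))
  for (i in seq_along(h$terms)) {
    tv <- term_values(h$terms[[i]], n, row)
    cols[i] <- tv$cols; vals[i] <- tv$values
  }
  agg <- rowsum(vals, cols)
  out <- data.frame(index = as.integer(rownames(agg)), value = as.numeric(agg))
  out[out$value != 0 | out$index == row, , drop = FALSE]
}

#' Exact ground state by diagonalization
#'
#' The ground-truth oracle: lowest eigenvalue and normalized eigenvector of
#' [ham_matrix()].  Dense `eigen()` up to 10 qubits; a Lanczos iteration on
#' the sparse matrix above that.
#'
#' @param h A [qubit_hamiltonian()].
#' @param cap Qubit cap (resource guard).
#' @return List with `energy` (Hartree) and `vector` (length `2^n`, unit norm).
#' @export
exact_ground_state <- function(h, cap = DEFAULT_QUBIT_CAP) {
  n <- h$n_qubits
  check_cap(n, cap)
  if (n <= 10L) {
    m <- ham_matrix(h, sparse = FALSE, cap = cap)
    e <- eigen(m, symmetric = TRUE)
    k <- ncol(m)
    v <- e$vectors[, k]
    return(list(energy = e$values[k], vector = v / sqrt(sum(v^2))))
  }
  lanczos_ground(ham_matrix(h, sparse = TRUE, cap = cap))
}

# Lanczos iteration with full reorthogonalization for the lowest eigenpair
# of a symmetric sparse matrix.  Used only above the dense cutoff.
lanczos_ground <- function(m, max_iter = 300L, tol = 1e-12, seed = 1L) {
  dim <- nrow(m)
  max_iter <- min(max_iter, dim)
  v <- with_seed(seed, stats::rnorm(dim))
  v <- v / sqrt(sum(v^2))
  V <- matrix(0, dim, max_iter)
  alpha <- numeric(max_iter); beta <- numeric(max_iter)
  V[, 1] <- v
  prev_e <- Inf
  for (j in seq_len(max_iter)) {
    w <- as.numeric(m %*% V[, j])
    alpha[j] <- sum(w * V[, j])
    w <- w - alpha[j] * V[, j]
    if (j > 1L) w <- w - beta[j - 1L] * V[, j - 1L]
    # full reorthogonalization
    w <- w - V[, seq_len(j), drop = FALSE] %*%
      crossprod(V[, seq_len(j), drop = FALSE], w)
    b <- sqrt(sum(w^2))
    tri <- tridiag_eigen(alpha[seq_len(j)], beta[seq_len(j - 1L)])
    if (abs(tri$value - prev_e) < tol || b < tol || j == max_iter) {
      vec <- as.numeric(V[, seq_len(j), drop = FALSE] %*% tri$vector)
      return(list(energy = tri$value, vector = vec / sqrt(sum(vec^2))))
    }
    prev_e <- tri$value
    beta[j] <- b
    V[, j + 1L] <- w / b
  }
}

tridiag_eigen <- function(alpha, beta) {
  k <- length(alpha)
  tm <- diag(alpha, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      tm[i, i + 1L] <- beta[i]
      tm[i + 1L, i] <- beta[i]
    }
  }
  e <- eigen(tm, symmetric = TRUE)
  list(value = e$values[k], vector = e$vectors[, k])
}
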