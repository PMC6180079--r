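# Jordan-Wigner transformation: second-quantized electronic Hamiltonian ->
# qubit Hamiltonian, one qubit per spin orbital (|1> = occupied).
#
# Ladder operators:  a+_p = (prod_{q<p} Z_q) (X_p - iY_p)/2
#                    a_p  = (prod_{q<p} Z_q) (X_p + iY_p)/2
# The Z parity string acts on lower qubit indices.  Products are expanded in
# a symbolic Pauli algebra with complex coefficients; after collecting like
# strings the imaginary parts cancel (real integrals), which is checked.

# Pauli codes 0=I, 1=X, 2=Y, 3=Z.  Product tables P*Q = phase * R.
PAULI_MULT_CODE <- matrix(c(
  0L, 1L, 2L, 3L,
  1L, 0L, 3L, 2L,
  2L, 3L, 0L, 1L,
  3L, 2L, 1L, 0L), 4L, 4L, byrow = TRUE)
PAULI_MULT_PHASE <- matrix(c(
  1,   1,   1,  1,
  1,   1,  1i, -1i,
  1, -1i,   1,  1i,
  1,  1i, -1i,  1), 4L, 4L, byrow = TRUE)

# A symbolic term: complex coeff + integer code vector (length = n qubits).
# Multiply two terms qubit-wise.
pstr_mult <- function(t1, t2) {
  c1 <- t1$codes; c2 <- t2$codes
  phase <- prod(PAULI_MULT_PHASE[cbind(c1 + 1L, c2 + 1L)])
  list(coeff = t1$coeff * t2$coeff * phase,
       codes = PAULI_MULT_CODE[cbind(c1 + 1L, c2 + 1L)])
}

# Expand the product of operator sums (each a list of symbolic terms).
pstr_mult_sums <- function(sums) {
  Reduce(function(acc, s) {
    out <- vector("list", length(acc) * length(s))
    k <- 1L
    for (t1 in acc) for (t2 in s) {
      out[[k]] <- pstr_mult(t1, t2)
      k <- k + 1L
    }
    out
  }, sums)
}

# Ladder operator as a sum of two symbolic Pauli terms on n qubits.
jw_ladder <- function(p, dagger, n) {
  codes <- integer(n)
  if (p > 0L) codes[seq_len(p)] <- 3L          # Z string on qubits 0..p-1
  cx <- codes; cx[p + 1L] <- 1L                # X_p
  cy <- codes; cy[p + 1L] <- 2L                # Y_p
  s <- if (dagger) -1i else 1i
  list(list(coeff = 0.5 + 0i, codes = cx),
       list(coeff = 0.5 * s, codes = cy))
}

#' Spin-orbital to qubit ordering
#'
#' Interleaved convention: qubit index = `2 * spatial + (spin == "beta")`,
#' i.e. alpha0, beta0, alpha1, beta1, ...
#'
#' @param spatial 0-based spatial orbital index (vectorized).
#' @param spin `"alpha"` or `"beta"` (recycled).
#' @return 0-based qubit index.
#' @examples
#' spin_orbital_order(0, "alpha")  # 0
#' spin_orbital_order(1, "beta")   # 3
#' @export
spin_orbital_order <- function(spatial, spin = c("alpha", "beta")) {
  spin <- match.arg(spin, several.ok = TRUE)
  as.integer(2L * as.integer(spatial) + (rep_len(spin, length(spatial)) == "beta"))
}

#' Jordan-Wigner transformation of an integral set
#'
#' Builds the second-quantized Hamiltonian
#' \deqn{H = \sum_{pq} h_{pq} a^\dagger_p a_q +
#'       \tfrac12 \sum_{pqrs} h_{pqrs} a^\dagger_p a^\dagger_q a_r a_s + E_0}
#' over spin orbitals (physicists' index ordering, spins interleaved per
#' [spin_orbital_order()]) and maps it to Pauli strings.  Like terms are
#' merged, coefficients below `tol` dropped, and the result is checked to be
#' real.
#'
#' @param ints An [integral_set()].
#' @param tol Drop terms with |coefficient| below this (Hartree).
#' @param cap Qubit cap; `2 * n_spatial` must not exceed it.
#' @return A [qubit_hamiltonian()] on `2 * n_spatial` qubits.
#' @export
jordan_wigner <- function(ints, tol = 1e-12, cap = DEFAULT_QUBIT_CAP) {
  M <- ints$n_spatial
  n <- 2L * M
  check_cap(n, cap)
  acc <- new.env(parent = emptyenv())
  add_terms <- function(terms, scale) {
    for (t in terms) {
      key <- paste(t$codes, collapse = "")
      val <- t$coeff * scale
      if (is.null(acc[[key]])) acc[[key]] <- val else
        acc[[key]] <- acc[[key]] + val
    }
  }
  add_terms(list(list(coeff = 1 + 0i, codes = integer(n))), ints$e_const)

  # spin-orbital one-electron part: h1[p,q] delta(spin)
  for (ps in seq_len(M)) for (qs in seq_len(M)) {
    v <- ints$h1[ps, qs]
    if (v == 0) next
    for (sp in 0:1) {
      P <- 2L * (ps - 1L) + sp
      Q <- 2L * (qs - 1L) + sp
      add_terms(pstr_mult_sums(list(jw_ladder(P, TRUE, n),
                                    jw_ladder(Q, FALSE, n))), v)
    }
  }
  # two-electron part: 1/2 h2[p,q,r,s] a+_{p,s1} a+_{q,s2} a_{r,s2} a_{s,s1}
  for (ps in seq_len(M)) for (qs in seq_len(M)) {
    for (rs in seq_len(M)) for (ss in seq_len(M)) {
      v <- ints$h2[ps, qs, rs, ss]
      if (v == 0) next
      for (s1 in 0:1) for (s2 in 0:1) {
        P <- 2L * (ps - 1L) + s1
        Q <- 2L * (qs - 1L) + s2
        R <- 2L * (rs - 1L) + s2
        S <- 2L * (ss - 1L) + s1
        if (P == Q || R == S) next          # a+a+ / aa on same mode vanish
        add_terms(pstr_mult_sums(list(jw_ladder(P, TRUE, n),
                                      jw_ladder(Q, TRUE, n),
                                      jw_ladder(R, FALSE, n),
                                      jw_ladder(S, FALSE, n))), 0.5 * v)
      }
    }
  }

  keys <- ls(acc)
  terms <- list()
  for (key in keys) {
    co <- acc[[key]]
    if (abs(co) < tol) next
    if (abs(Im(co)) > 1e-10) {
      stop_rbmqs("Jordan-Wigner produced a complex coefficient (",
                 format(co), "); integrals are not real-symmetric",
                 class = "rbmqs_validation_error")
    }
    codes <- as.integer(strsplit(key, "", fixed = TRUE)[[1]])
    qb <- which(codes != 0L) - 1L
    terms <- c(terms, list(pauli_term(Re(co), qb,
                                      c("I", "X", "Y", "Z")[codes[qb + 1L] + 1L])))
  }
  if (!length(terms)) terms <- list(pauli_term(0))
  sort_ham(qubit_hamiltonian(n, terms))
}
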