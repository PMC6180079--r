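# Molecular integral sets and FCIDUMP I/O.
#
# Index conventions.  The FCIDUMP file stores spatial-orbital integrals in
# chemists' notation: a record "value i j k l" with k,l > 0 is
# (ij|kl) = integral of phi_i(1) phi_j(1) r12^-1 phi_k(2) phi_l(2), with the
# real-integral 8-fold permutation symmetry.  Internally the two-electron
# tensor is stored in physicists' ordering h2[p,q,r,s], defined so that the
# second-quantized Hamiltonian is literally
#   H = sum_pq h1[p,q] a+_p a_q + 1/2 sum_pqrs h2[p,q,r,s] a+_p a+_q a_r a_s
# over spin orbitals, with the spin rule delta(spin_p, spin_s) *
# delta(spin_q, spin_r).  The two layouts are related by
# h2_phys[p,q,r,s] = (p s|q r), i.e. aperm(chem, c(1,3,4,2)) and back with
# aperm(phys, c(1,4,2,3)).

phys_from_chem <- function(g) aperm(g, c(1, 3, 4, 2))
chem_from_phys <- function(g) aperm(g, c(1, 4, 2, 3))

#' Molecular integral set
#'
#' One- and two-electron integrals over spatial orbitals (Hartree), a scalar
#' constant (nuclear repulsion plus any frozen-core shift) and the electron
#' count.  `h2` is stored in physicists' index ordering (see the FCIDUMP
#' reader for the conversion from chemists' notation).
#'
#' @param h1 Symmetric `n x n` one-electron integral matrix.
#' @param h2 `n x n x n x n` two-electron tensor, physicists' ordering.
#' @param e_const Scalar constant energy (Hartree).
#' @param n_electrons Number of electrons.
#' @return An object of class `integral_set`.
#' @export
integral_set <- function(h1, h2, e_const = 0, n_electrons = 0L) {
  h1 <- as.matrix(h1)
  n <- nrow(h1)
  if (ncol(h1) != n) {
    stop_rbmqs("h1 must be square", class = "rbmqs_validation_error")
  }
  if (max(abs(h1 - t(h1))) > 1e-10) {
    stop_rbmqs("h1 must be symmetric", class = "rbmqs_validation_error")
  }
  if (is.null(h2)) h2 <- array(0, c(n, n, n, n))
  if (!identical(dim(h2), rep(n, 4L) * 1L) && !identical(dim(h2), rep(n, 4L))) {
    stop_rbmqs("h2 must be an n^4 array", class = "rbmqs_validation_error")
  }
  if (!all(is.finite(h1)) || !all(is.finite(h2)) || !is.finite(e_const)) {
    stop_rbmqs("integrals must be finite", class = "rbmqs_validation_error")
  }
  structure(
    list(n_spatial = n, h1 = h1, h2 = h2,
         e_const = as.numeric(e_const), n_electrons = as.integer(n_electrons)),
    class = "integral_set"
  )
}

#' @export
print.integral_set <- function(x, ...) {
  cat("Integral set:", x$n_spatial, "spatial orbitals,",
      x$n_electrons, "electrons, e_const =",
      format(x$e_const, digits = 8), "Ha\n")
  invisible(x)
}

#' Read an FCIDUMP integral file
#'
#' Standard Molpro dialect: a `&FCI NORB=..., NELEC=..., MS2=...` namelist
#' header terminated by `&END` or `/`, then records `value i j k l` with
#' 1-based orbital indices.  `i j k l = 0 0 0 0` is the core energy,
#' `k = l = 0` a one-electron integral `h1[i,j]`, anything else a chemists'
#' two-electron integral `(ij|kl)`; the 8-fold permutation symmetry is applied
#' on read and the tensor converted to the internal physicists' layout.
#'
#' @param path FCIDUMP file path (or a character vector of lines).
#' @return An [integral_set()].
#' @export
read_fcidump <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  txt <- paste(lines, collapse = "\n")
  hdr_end <- regexpr("(&END|/)", txt)
  if (hdr_end < 0) {
    stop_rbmqs("FCIDUMP: missing end of namelist header",
               class = "rbmqs_format_error")
  }
  header <- substr(txt, 1L, hdr_end - 1L)
  get_field <- function(name) {
    m <- regmatches(header,
                    regexec(paste0(name, "[[:space:]]*=[[:space:]]*([0-9-]+)"),
                            header))[[1]]
    if (length(m) != 2L) return(NA_integer_)
    as.integer(m[2])
  }
  norb <- get_field("NORB")
  nelec <- get_field("NELEC")
  if (is.na(norb) || is.na(nelec)) {
    stop_rbmqs("FCIDUMP: header must define NORB and NELEC",
               class = "rbmqs_format_error")
  }
  body <- substr(txt, hdr_end + attr(hdr_end, "match.length"), nchar(txt))
  toks <- scan(text = body, what = double(), quiet = TRUE)
  if (length(toks) %% 5L != 0L) {
    stop_rbmqs("FCIDUMP: integral records must be 'value i j k l'",
               class = "rbmqs_format_error")
  }
  rec <- matrix(toks, ncol = 5L, byrow = TRUE)
  h1 <- matrix(0, norb, norb)
  chem <- array(0, rep(norb, 4L))
  e_const <- 0
  for (r in seq_len(nrow(rec))) {
    v <- rec[r, 1]; ii <- rec[r, 2]; jj <- rec[r, 3]
    kk <- rec[r, 4]; ll <- rec[r, 5]
    idx <- c(ii, jj, kk, ll)
    if (any(idx > norb) || any(idx < 0)) {
      stop_rbmqs("FCIDUMP: orbital index out of range in record ", r,
                 class = "rbmqs_format_error")
    }
    if (all(idx == 0)) {
      e_const <- v
    } else if (kk == 0 && ll == 0) {
      if (ii == 0 || jj == 0) {
        stop_rbmqs("FCIDUMP: bad one-electron record ", r,
                   class = "rbmqs_format_error")
      }
      h1[ii, jj] <- v; h1[jj, ii] <- v
    } else {
      if (any(idx == 0)) {
        stop_rbmqs("FCIDUMP: bad two-electron record ", r,
                   class = "rbmqs_format_error")
      }
      for (p in eightfold(ii, jj, kk, ll)) {
        chem[p[1], p[2], p[3], p[4]] <- v
      }
    }
  }
  integral_set(h1, phys_from_chem(chem), e_const, nelec)
}

eightfold <- function(i, j, k, l) {
  list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
       c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i))
}

#' Write an FCIDUMP integral file
#'
#' Emits the unique chemists'-notation integrals of an [integral_set()] so
#' that [read_fcidump()] round-trips the values exactly.
#'
#' @param ints An [integral_set()].
#' @param path Output path.
#' @param ms2 Value for the MS2 header field.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(ints, path, ms2 = 0L) {
  n <- ints$n_spatial
  out <- c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n, ints$n_electrons, ms2),
           " &END")
  chem <- chem_from_phys(ints$h2)
  seen <- array(FALSE, rep(n, 4L))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    for (k in seq_len(i)) for (l in seq_len(k)) {
      if (seen[i, j, k, l] || chem[i, j, k, l] == 0) next
      for (p in eightfold(i, j, k, l)) seen[p[1], p[2], p[3], p[4]] <- TRUE
      out <- c(out, sprintf("%.17g %d %d %d %d", chem[i, j, k, l], i, j, k, l))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (ints$h1[i, j] != 0) {
      out <- c(out, sprintf("%.17g %d %d 0 0", ints$h1[i, j], i, j))
    }
  }
  out <- c(out, sprintf("%.17g 0 0 0 0", ints$e_const))
  writeLines(out, path)
  invisible(path)
}

#' Active-space specification
#'
#' Spatial orbitals held doubly occupied (frozen core) or removed as always
#' empty (discarded virtuals), by 0-based index.
#'
#' @param frozen_occupied Integer vector of frozen doubly-occupied orbitals.
#' @param discarded_virtual Integer vector of removed virtual orbitals.
#' @return An object of class `active_space`.
#' @export
active_space <- function(frozen_occupied = integer(0),
                         discarded_virtual = integer(0)) {
  fo <- as.integer(frozen_occupied); dv <- as.integer(discarded_virtual)
  if (length(intersect(fo, dv))) {
    stop_rbmqs("frozen and discarded orbital lists overlap",
               class = "rbmqs_validation_error")
  }
  structure(list(frozen_occupied = fo, discarded_virtual = dv),
            class = "active_space")
}

#' Reduce an integral set to an active space
#'
#' Standard frozen-core construction: the constant absorbs the frozen-orbital
#' energy (one-electron part plus frozen-frozen Coulomb/exchange), the
#' effective one-electron integrals over active orbitals gain the mean field
#' of the frozen electrons, discarded virtuals are simply removed, and the
#' electron count drops by two per frozen orbital.
#'
#' @param ints An [integral_set()].
#' @param spec An [active_space()].
#' @return A reduced [integral_set()] over the active orbitals.
#' @export
apply_active_space <- function(ints, spec) {
  n <- ints$n_spatial
  fo <- spec$frozen_occupied + 1L   # to 1-based
  dv <- spec$discarded_virtual + 1L
  if (length(fo) && (min(fo) < 1L || max(fo) > n)) {
    stop_rbmqs("frozen orbital index out of range",
               class = "rbmqs_validation_error")
  }
  if (length(dv) && (min(dv) < 1L || max(dv) > n)) {
    stop_rbmqs("discarded orbital index out of range",
               class = "rbmqs_validation_error")
  }
  if (2L * length(fo) > ints$n_electrons) {
    stop_rbmqs("cannot freeze more orbitals than electron pairs",
               class = "rbmqs_validation_error")
  }
  act <- setdiff(seq_len(n), c(fo, dv))
  if (!length(act)) {
    # all orbitals frozen/discarded: constant Hamiltonian
    chem <- chem_from_phys(ints$h2)
    e <- ints$e_const + core_energy(ints$h1, chem, fo)
    return(integral_set(matrix(0, 1, 1), array(0, rep(1, 4L)), e, 0L))
  }
  chem <- chem_from_phys(ints$h2)
  e <- ints$e_const + core_energy(ints$h1, chem, fo)
  h1_eff <- ints$h1[act, act, drop = FALSE]
  for (f in fo) {
    h1_eff <- h1_eff + 2 * chem[act, act, f, f] - chem[act, f, f, act]
  }
  integral_set(h1_eff,
               phys_from_chem(chem[act, act, act, act, drop = FALSE]),
               e, ints$n_electrons - 2L * length(fo))
}

core_energy <- function(h1, chem, fo) {
  e <- 0
  for (f in fo) e <- e + 2 * h1[f, f]
  for (f in fo) for (g in fo) {
    e <- e + 2 * chem[f, f, g, g] - chem[f, g, g, f]
  }
  e
}
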