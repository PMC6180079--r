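#' Single Pauli-string term
#'
#' One tensor product of single-qubit Pauli operators with a real coefficient
#' in Hartree.  Qubits not listed carry the identity; an empty factor list is
#' the identity term.  Terms whose matrix elements would be imaginary in the
#' computational basis (an odd number of Y factors with a real coefficient)
#' are rejected, because the real-amplitude ansatz cannot represent complex
#' ground states.
#'
#' @param coefficient Real, finite coefficient (Hartree).
#' @param qubits Integer vector of 0-based qubit indices (no duplicates).
#' @param labels Character vector over `"X"`, `"Y"`, `"Z"`, same length as
#'   `qubits`.
#' @return An object of class `pauli_term`.
#' @examples
#' pauli_term(-0.4804, c(0L, 2L), c("Z", "Z"))
#' pauli_term(0.5)  # identity term
#' @export
pauli_term <- function(coefficient, qubits = integer(0), labels = character(0)) {
  if (length(coefficient) != 1L || !is.finite(coefficient)) {
    stop_rbmqs("coefficient must be a single finite number",
               class = "rbmqs_validation_error")
  }
  qubits <- as.integer(qubits)
  labels <- as.character(labels)
  if (length(qubits) != length(labels)) {
    stop_rbmqs("qubits and labels must have equal length",
               class = "rbmqs_validation_error")
  }
  if (anyDuplicated(qubits)) {
    stop_rbmqs("duplicate qubit index in Pauli term",
               class = "rbmqs_validation_error")
  }
  if (length(qubits) && (any(qubits < 0L) || any(is.na(qubits)))) {
    stop_rbmqs("qubit indices must be nonnegative integers",
               class = "rbmqs_validation_error")
  }
  if (!all(labels %in% c("X", "Y", "Z"))) {
    stop_rbmqs("factor labels must be X, Y or Z",
               class = "rbmqs_validation_error")
  }
  ord <- order(qubits)
  structure(
    list(coefficient = as.numeric(coefficient),
         qubits = qubits[ord], labels = labels[ord]),
    class = "pauli_term"
  )
}

#' Qubit Hamiltonian as a weighted sum of Pauli strings
#'
#' @param n_qubits Number of qubits.
#' @param terms List of [pauli_term()] objects.
#' @return An object of class `qubit_hamiltonian`.
#' @examples
#' qubit_hamiltonian(1, list(pauli_term(-1, 0L, "Z")))
#' @export
qubit_hamiltonian <- function(n_qubits, terms) {
  n_qubits <- as.integer(n_qubits)
  if (length(n_qubits) != 1L || is.na(n_qubits) || n_qubits < 1L) {
    stop_rbmqs("n_qubits must be a positive integer",
               class = "rbmqs_validation_error")
  }
  if (!is.list(terms)) terms <- list(terms)
  for (t in terms) {
    if (!inherits(t, "pauli_term")) {
      stop_rbmqs("terms must be pauli_term objects",
                 class = "rbmqs_validation_error")
    }
    if (length(t$qubits) && max(t$qubits) >= n_qubits) {
      stop_rbmqs("term acts on qubit ", max(t$qubits),
                 " but Hamiltonian has only ", n_qubits, " qubits",
                 class = "rbmqs_validation_error")
    }
    if (sum(t$labels == "Y") %% 2L == 1L) {
      stop_rbmqs("term with an odd number of Y factors has imaginary ",
                 "matrix elements; such Hamiltonians are not supported",
                 class = "rbmqs_validation_error")
    }
  }
  structure(list(n_qubits = n_qubits, terms = terms),
            class = "qubit_hamiltonian")
}

#' @export
print.qubit_hamiltonian <- function(x, ...) {
  cat("Qubit Hamiltonian:", x$n_qubits, "qubits,",
      length(x$terms), "Pauli terms\n")
  lines <- format_ham(x)
  body <- lines[-seq_len(2L)]
  show <- utils::head(body, 8L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(body) > 8L) cat("  ... (", length(body) - 8L, " more)\n", sep = "")
  invisible(x)
}

term_key <- function(t) {
  if (!length(t$qubits)) return("I")
  paste0(t$labels, t$qubits, collapse = " ")
}

#' Merge like terms and drop negligible coefficients
#'
#' @param h A [qubit_hamiltonian()].
#' @param tol Coefficients with absolute value below `tol` are dropped.
#' @return A `qubit_hamiltonian` with unique factor sets, canonically sorted.
#' @export
merge_ham_terms <- function(h, tol = 1e-12) {
  keys <- vapply(h$terms, term_key, character(1))
  coefs <- vapply(h$terms, function(t) t$coefficient, numeric(1))
  agg <- tapply(coefs, keys, sum)
  keep <- abs(agg) >= tol
  terms <- lapply(names(agg)[keep], function(k) {
    if (k == "I") return(pauli_term(agg[[k]]))
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    pauli_term(agg[[k]],
               qubits = as.integer(sub("^[XYZ]", "", parts)),
               labels = substr(parts, 1L, 1L))
  })
  if (!length(terms)) terms <- list(pauli_term(0))
  sort_ham(qubit_hamiltonian(h$n_qubits, terms))
}

# Canonical term order: (number of factors, lexicographic factor list).
sort_ham <- function(h) {
  nf <- vapply(h$terms, function(t) length(t$qubits), integer(1))
  keys <- vapply(h$terms, term_key, character(1))
  h$terms <- h$terms[order(nf, keys, method = "radix")]
  h
}

fmt_coef <- function(x) sprintf("%.17g", x)

#' Serialize a Hamiltonian to Pauli text lines
#'
#' The `.ham` format: `#` starts a comment, the first non-comment line is
#' `qubits N`, and every other line is `<coeff> [<P><idx> ...]` with
#' `P` one of X, Y, Z and 0-based indices.  The writer emits terms sorted by
#' (number of factors, lexicographic factor list), so output is deterministic.
#'
#' @param h A [qubit_hamiltonian()].
#' @return Character vector of lines.
#' @export
format_ham <- function(h) {
  h <- sort_ham(h)
  body <- vapply(h$terms, function(t) {
    if (!length(t$qubits)) return(fmt_coef(t$coefficient))
    paste(fmt_coef(t$coefficient),
          paste0(t$labels, t$qubits, collapse = " "))
  }, character(1))
  c("# Pauli Hamiltonian (.ham format_version 1)",
    paste("qubits", h$n_qubits),
    body)
}

#' Parse Pauli text into a Hamiltonian
#'
#' Inverse of [format_ham()]; the term list is returned exactly as written
#' (no merging).
#'
#' @param lines Character vector of `.ham` lines.
#' @return A [qubit_hamiltonian()].
#' @export
parse_ham <- function(lines) {
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  if (!length(keep)) {
    stop_rbmqs("empty Hamiltonian text", class = "rbmqs_parse_error")
  }
  first <- trimws(stripped[keep[1]])
  m <- regmatches(first, regexec("^qubits[[:space:]]+([0-9]+)$", first))[[1]]
  if (length(m) != 2L) {
    stop_rbmqs("line ", keep[1], ": expected 'qubits N', got '", first, "'",
               class = "rbmqs_parse_error")
  }
  n <- as.integer(m[2])
  terms <- vector("list", length(keep) - 1L)
  for (i in seq_along(terms)) {
    ln <- keep[i + 1L]
    toks <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1]]
    coef <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(coef)) {
      stop_rbmqs("line ", ln, ": malformed coefficient '", toks[1], "'",
                 class = "rbmqs_parse_error")
    }
    facs <- toks[-1]
    if (length(facs)) {
      ok <- grepl("^[XYZ][0-9]+$", facs)
      if (!all(ok)) {
        stop_rbmqs("line ", ln, ": malformed factor '", facs[!ok][1], "'",
                   class = "rbmqs_parse_error")
      }
    }
    terms[[i]] <- withCallingHandlers(
      pauli_term(coef,
                 qubits = as.integer(sub("^[XYZ]", "", facs)),
                 labels = substr(facs, 1L, 1L)),
      rbmqs_validation_error = function(e) {
        stop_rbmqs("line ", ln, ": ", conditionMessage(e),
                   class = "rbmqs_parse_error")
      }
    )
  }
  if (!length(terms)) terms <- list(pauli_term(0))
  qubit_hamiltonian(n, terms)
}

#' Read / write `.ham` Hamiltonian files
#'
#' @param path File path.
#' @return `read_ham()` returns a [qubit_hamiltonian()]; `write_ham()` returns
#'   `path` invisibly.
#' @export
read_ham <- function(path) {
  if (!file.exists(path)) {
    stop_rbmqs("cannot open Hamiltonian file '", path, "'",
               class = "rbmqs_io_error")
  }
  parse_ham(readLines(path, warn = FALSE))
}

#' @rdname read_ham
#' @param h A [qubit_hamiltonian()].
#' @export
write_ham <- function(h, path) {
  writeLines(format_ham(h), path)
  invisible(path)
}
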