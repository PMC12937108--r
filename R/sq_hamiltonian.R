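# Second-quantized vibronic Hamiltonian as a symbolic term list.
# Every term is  coeff * a^dag_alpha a_beta  x  prod over at most two modes of
# the composite operator E_{kh} = b^dag_k b_h  (an N_i x N_i matrix unit).
# Terms are stored in a data frame with columns
#   coeff, a, b, i1, k1, h1, i2, k2, h2   (NA where a factor is absent,
#   mode indices strictly increasing within a term), with the lattice
#   specification attached.

.sq_df <- function(coeff = numeric(), a = integer(), b = integer(),
                   i1 = integer(), k1 = integer(), h1 = integer(),
                   i2 = integer(), k2 = integer(), h2 = integer()) {
  data.frame(coeff = coeff, a = a, b = b, i1 = i1, k1 = k1, h1 = h1,
             i2 = i2, k2 = k2, h2 = h2)
}

#' Second-quantized vibronic Hamiltonian
#'
#' Container pairing a term data frame with the lattice specification
#' (`n_el` electronic sites followed by `M` vibrational sites of dimensions
#' `N`).  Construct via [assemble_hamiltonian()] or [read_term_list()].
#'
#' @param terms term data frame (see package source for the column layout).
#' @param n_el number of electronic states.
#' @param N integer vector of per-mode basis sizes.
#' @return an object of class `sq_hamiltonian`.
#' @export
sq_hamiltonian <- function(terms, n_el, N) {
  n_el <- as.integer(n_el); N <- as.integer(N)
  stopifnot(n_el >= 1, all(N >= 1) || length(N) == 0)
  stopifnot(all(terms$a >= 1 & terms$a <= n_el), all(terms$b >= 1 & terms$b <= n_el))
  if (nrow(terms)) {
    has1 <- !is.na(terms$i1); has2 <- !is.na(terms$i2)
    stopifnot(all(terms$i1[has1] >= 1 & terms$i1[has1] <= length(N)))
    stopifnot(all(terms$k1[has1] >= 1 & terms$k1[has1] <= N[terms$i1[has1]]))
    stopifnot(all(terms$h1[has1] >= 1 & terms$h1[has1] <= N[terms$i1[has1]]))
    stopifnot(all(has1[has2]), all(terms$i1[has2] < terms$i2[has2]))
    stopifnot(all(is.finite(terms$coeff)))
  }
  structure(list(terms = terms, n_el = n_el, N = N, M = length(N)),
            class = "sq_hamiltonian")
}

#' @export
print.sq_hamiltonian <- function(x, ...) {
  cat(sprintf("<sq_hamiltonian> %d term(s), %d electronic state(s), %d mode(s) [%s]\n",
              nrow(x$terms), x$n_el, x$M, paste(x$N, collapse = ",")))
  invisible(x)
}

#' Assemble the second-quantized vibronic Hamiltonian
#'
#' Converts the integral tables of a vibronic model into a term list over
#' the MPS lattice.  Diagonal blocks of state `alpha` produce terms with the
#' electronic transfer pair `(alpha, alpha)`: the constant term with an empty
#' bosonic factor list, one-body blocks as single composite factors
#' `E_{kh}` per mode, and two-body blocks as products of two composite
#' factors on distinct modes.  Off-diagonal coupling blocks produce the
#' analogous potential-only terms for the transfer pairs `(a,b)` and `(b,a)`
#' with equal real coefficients, closing the list under Hermitian
#' conjugation.  Coefficients smaller in magnitude than `screen` are
#' dropped.
#'
#' @param model a `vibronic_model`.
#' @param bases list of per-mode `modal_basis` objects.
#' @param tables optional precomputed [compute_integral_tables()] result.
#' @param screen screening threshold (hartree) below which terms are dropped.
#' @return an `sq_hamiltonian`.
#' @export
assemble_hamiltonian <- function(model, bases, tables = NULL, screen = 1e-12) {
  stopifnot(inherits(model, "vibronic_model"))
  if (is.null(tables)) tables <- compute_integral_tables(model, bases)
  for (nm in names(model$offdiag))
    if (is.null(tables$offdiag[[nm]]))
      stop("missing integral table for coupling pair ", nm)
  N <- tables$meta$N
  M <- model$M
  pieces <- list()
  emit_block <- function(blk, a, b) {
    res <- list()
    if (abs(blk$F0) > screen)
      res[[length(res) + 1L]] <- .sq_df(blk$F0, a, b, NA_integer_, NA_integer_,
                                        NA_integer_, NA_integer_, NA_integer_, NA_integer_)
    for (i in seq_len(M)) {
      Hm <- blk$one[[i]]
      if (is.null(Hm)) next
      keep <- which(abs(Hm) > screen, arr.ind = TRUE)
      if (nrow(keep))
        res[[length(res) + 1L]] <- .sq_df(Hm[keep], a, b, i, keep[, 1], keep[, 2],
                                          NA_integer_, NA_integer_, NA_integer_)
    }
    for (nm in names(blk$two)) {
      p <- as.integer(strsplit(nm, ",")[[1]])
      A <- blk$two[[nm]]           # [k_i, k_j, h_i, h_j]
      keep <- which(abs(A) > screen, arr.ind = TRUE)
      if (nrow(keep))
        res[[length(res) + 1L]] <- .sq_df(A[keep], a, b, p[1], keep[, 1], keep[, 3],
                                          p[2], keep[, 2], keep[, 4])
    }
    res
  }
  for (al in seq_len(model$n_el))
    pieces <- c(pieces, emit_block(tables$diag[[al]], al, al))
  for (nm in names(model$offdiag)) {
    p <- as.integer(strsplit(nm, ",")[[1]])
    pieces <- c(pieces, emit_block(tables$offdiag[[nm]], p[1], p[2]))
    pieces <- c(pieces, emit_block(tables$offdiag[[nm]], p[2], p[1]))
  }
  terms <- if (length(pieces)) do.call(rbind, pieces) else .sq_df()
  rownames(terms) <- NULL
  sq_hamiltonian(terms, model$n_el, N)
}

#' Check closure of a term list under Hermitian conjugation
#'
#' Verifies that for every term the conjugate term (electronic pair and all
#' bosonic `(k,h)` indices transposed) is present with an equal coefficient.
#'
#' @param sqh an `sq_hamiltonian`.
#' @param tol coefficient tolerance.
#' @return `TRUE` invisibly; errors if the closure fails.
#' @export
check_hermitian_closure <- function(sqh, tol = 1e-12) {
  tm <- sqh$terms
  key <- function(a, b, i1, k1, h1, i2, k2, h2)
    paste(a, b, i1, k1, h1, i2, k2, h2, sep = "|")
  agg <- function(keys, coeffs) {
    s <- rowsum(coeffs, keys)
    stats::setNames(as.numeric(s), rownames(s))
  }
  fwd <- agg(key(tm$a, tm$b, tm$i1, tm$k1, tm$h1, tm$i2, tm$k2, tm$h2), tm$coeff)
  cnj <- agg(key(tm$b, tm$a, tm$i1, tm$h1, tm$k1, tm$i2, tm$h2, tm$k2), tm$coeff)
  all_keys <- union(names(fwd), names(cnj))
  f <- ifelse(all_keys %in% names(fwd), fwd[all_keys], 0)
  g <- ifelse(all_keys %in% names(cnj), cnj[all_keys], 0)
  if (max(abs(f - g)) > tol)
    stop("term list is not closed under Hermitian conjugation")
  invisible(TRUE)
}

#' Write / read the plain-text term-list interchange format
#'
#' One term per line: `coeff alpha beta [i k h [j k j h j]]`, preceded by a
#' header line `# vibronmps-terms v1 n_el M N_1 ... N_M`.  Coefficients are
#' printed with 17 significant digits so the round trip is bit-exact.
#'
#' @param sqh an `sq_hamiltonian`.
#' @param path file path.
#' @return `read_term_list` returns the restored `sq_hamiltonian`.
#' @export
write_term_list <- function(sqh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vibronmps-terms v1 %d %d%s", sqh$n_el, sqh$M,
                     if (sqh$M) paste0(" ", paste(sqh$N, collapse = " ")) else ""), con)
  tm <- sqh$terms
  fmt <- function(x) ifelse(is.na(x), "", sprintf(" %d", x))
  lines <- sprintf("%.17g %d %d%s%s%s%s%s%s", tm$coeff, tm$a, tm$b,
                   fmt(tm$i1), fmt(tm$k1), fmt(tm$h1),
                   fmt(tm$i2), fmt(tm$k2), fmt(tm$h2))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_term_list
#' @export
read_term_list <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (length(hdr) < 5 || hdr[1] != "#" || hdr[2] != "vibronmps-terms")
    stop("not a vibronmps term-list file")
  n_el <- as.integer(hdr[4]); M <- as.integer(hdr[5])
  N <- if (M) as.integer(hdr[6:(5 + M)]) else integer()
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  n <- vapply(fields, length, integer(1))
  if (any(!n %in% c(3L, 6L, 9L))) stop("malformed term line")
  get <- function(f, j) if (length(f) >= j) f[j] else NA_character_
  tm <- .sq_df(
    coeff = as.numeric(vapply(fields, `[`, "", 1)),
    a = as.integer(vapply(fields, `[`, "", 2)),
    b = as.integer(vapply(fields, `[`, "", 3)),
    i1 = as.integer(vapply(fields, get, "", 4)),
    k1 = as.integer(vapply(fields, get, "", 5)),
    h1 = as.integer(vapply(fields, get, "", 6)),
    i2 = as.integer(vapply(fields, get, "", 7)),
    k2 = as.integer(vapply(fields, get, "", 8)),
    h2 = as.integer(vapply(fields, get, "", 9)))
  sq_hamiltonian(tm, n_el, N)
}
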