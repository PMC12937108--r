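# Model files, run configuration, and the end-to-end workflow:
# bases -> integrals -> term list -> MPO -> Condon state -> TDVP -> spectrum.
# Model and run files are YAML; tabular outputs are CSV; run metadata is
# JSON; tensors checkpoint to a versioned binary container.

.term1_to_list <- function(t) {
  switch(t$type,
    poly = list(type = "poly", coef = t$coef),
    morse = list(type = "morse", D = t$D, a = t$a, Q0 = t$Q0),
    grid = list(type = "grid", Q = t$Q, V = t$V),
    stop("term type '", t$type, "' cannot be serialized to a model file"))
}
.term1_from_list <- function(l) {
  switch(l$type,
    poly = nm_poly(unlist(l$coef)),
    morse = nm_morse(l$D, l$a, if (is.null(l$Q0)) 0 else l$Q0),
    grid = nm_grid(unlist(l$Q), unlist(l$V)),
    stop("unknown one-body term type ", l$type))
}
.term2_to_list <- function(t) {
  switch(t$type,
    poly2 = list(type = "poly2", coef = apply(t$coef, 1, as.list, simplify = FALSE)),
    sprod = list(type = "sprod", f1 = .term1_to_list(t$f1), f2 = .term1_to_list(t$f2)),
    stop("term type '", t$type, "' cannot be serialized to a model file"))
}
.term2_from_list <- function(l) {
  switch(l$type,
    poly2 = nm_poly2(do.call(rbind, lapply(l$coef, unlist))),
    sprod = nm_sprod(.term1_from_list(l$f1), .term1_from_list(l$f2)),
    stop("unknown two-body term type ", l$type))
}
.nmode_to_list <- function(f, constant_name = "energy") {
  out <- list()
  out[[constant_name]] <- f$F0
  if (length(f$one))
    out$one_body <- lapply(names(f$one), function(i)
      c(list(mode = as.integer(i)), .term1_to_list(f$one[[i]])))
  if (length(f$two))
    out$two_body <- lapply(names(f$two), function(p)
      c(list(modes = as.integer(strsplit(p, ",")[[1]])), .term2_to_list(f$two[[p]])))
  out
}
.nmode_from_list <- function(l, M, constant_name = "energy") {
  one <- list(); two <- list()
  for (t in l$one_body)
    one[[as.character(t$mode)]] <- .term1_from_list(t)
  for (t in l$two_body)
    two[[paste(unlist(t$modes), collapse = ",")]] <- .term2_from_list(t)
  F0 <- l[[constant_name]]
  nmode_function(M, F0 = if (is.null(F0)) 0 else F0, one = one, two = two)
}

#' Write / read a vibronic model file
#'
#' Serializes a `vibronic_model` to a YAML document with sections
#' `frequencies_cm`, `states` (each with `energy`, `one_body`, `two_body`
#' term lists) and `couplings` (each with `states`, `constant`, and term
#' lists).  Only declarative term types (`poly`, `morse`, `grid`, `poly2`,
#' `sprod`) round-trip; opaque function terms are rejected.
#'
#' @param model a `vibronic_model`.
#' @param path file path.
#' @return `read_model` returns the restored `vibronic_model`.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "vibronmps-model",
    version = 1L,
    n_el = model$n_el,
    frequencies_cm = model$freqs_cm,
    states = lapply(model$diag, .nmode_to_list, constant_name = "energy"),
    couplings = lapply(names(model$offdiag), function(p)
      c(list(states = as.integer(strsplit(p, ",")[[1]])),
        .nmode_to_list(model$offdiag[[p]], constant_name = "constant")))
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "vibronmps-model")) stop("not a vibronmps model file")
  M <- length(doc$frequencies_cm)
  diag <- lapply(doc$states, .nmode_from_list, M = M, constant_name = "energy")
  offdiag <- list()
  for (cp in doc$couplings)
    offdiag[[paste(unlist(cp$states), collapse = ",")]] <-
      .nmode_from_list(cp, M, constant_name = "constant")
  vibronic_model(unlist(doc$frequencies_cm), diag, offdiag)
}

#' Run configuration
#'
#' Validates the settings of an end-to-end calculation.  Fields:
#' `model` (a `vibronic_model` or path to a model file), `basis`
#' (`type` = `"relaxed"` ground-state eigenbasis of state 1 or
#' `"harmonic"`; `N` per-mode basis sizes, recycled; optional `n_grid`),
#' `dynamics` (`dt_fs`, `n_steps`, `m_max`, `cutoff`, `expand`),
#' `excitation` (`state`, zero-based `occ` optional), `spectrum`
#' (`shift`, `unit`), `outdir` (optional: artifacts written there), `seed`.
#'
#' @param ... configuration fields, or a single named list / YAML file path.
#' @return validated config of class `run_config`.
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1]]) && is.null(names(args)))
    args <- yaml::read_yaml(args[[1]])
  else if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args))) args <- args[[1]]
  cfg <- utils::modifyList(list(
    model = NULL,
    basis = list(type = "relaxed", N = 6L, n_grid = 301L),
    dynamics = list(dt_fs = 0.5, n_steps = 800L, m_max = 20L, cutoff = 1e-12,
                    expand = "none"),
    excitation = list(state = 2L),
    spectrum = list(shift = 0, unit = "ev"),
    outdir = NULL,
    seed = 1L
  ), args)
  if (is.character(cfg$model)) cfg$model <- read_model(cfg$model)
  if (!inherits(cfg$model, "vibronic_model")) stop("config requires a model (object or file path)")
  stopifnot(cfg$dynamics$dt_fs > 0, cfg$dynamics$n_steps >= 1,
            cfg$dynamics$m_max >= 1, cfg$basis$type %in% c("relaxed", "harmonic"),
            cfg$excitation$state >= 1, cfg$excitation$state <= cfg$model$n_el)
  class(cfg) <- "run_config"
  cfg
}

#' Build the per-mode modal bases of a configuration
#'
#' The default follows the ground-state-eigenbasis choice: the basis of
#' mode `i` is the eigenbasis of `T + v1` where `v1` is the one-body term
#' of the first electronic state's potential (harmonic fallback when a mode
#' has no one-body term).
#'
#' @param cfg a `run_config`.
#' @return list of `modal_basis`.
#' @export
build_bases <- function(cfg) {
  model <- cfg$model
  N <- rep_len(as.integer(cfg$basis$N), model$M)
  lapply(seq_len(model$M), function(i) {
    if (cfg$basis$type == "harmonic")
      return(harmonic_basis(model$omega[i], N[i]))
    v1 <- model$diag[[1]]$one[[as.character(i)]]
    if (is.null(v1)) v1 <- nm_poly(c(0, 0, 0.5 * model$omega[i]^2))
    relaxed_basis(v1, model$omega[i], N[i],
                  n_grid = if (is.null(cfg$basis$n_grid)) 301L else cfg$basis$n_grid)
  })
}

#' Run the full pipeline
#'
#' Deterministic end-to-end workflow: modal bases, integral tables, term
#' list, MPO compilation, Condon initial state, two-site TDVP propagation,
#' and the absorption spectrum.  When `cfg$outdir` is set, each artifact is
#' written there (`terms.txt`, `record.csv`, `spectrum.csv`, `run.json`,
#' and an MPS checkpoint) and reused notes are logged.
#'
#' @param cfg a `run_config` (or arguments forwarded to [run_config()]).
#' @return list with `bases`, `sqh`, `mpo`, `psi0`, `psi`, `record`,
#'   `spectrum`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  set.seed(as.integer(cfg$seed))
  model <- cfg$model
  bases <- build_bases(cfg)
  sqh <- assemble_hamiltonian(model, bases)
  mpo <- compile_mpo(sqh)
  lat <- mps_lattice(model$n_el, sqh$N)
  psi0 <- condon_initial_state(lat, cfg$excitation$state,
                               occ = cfg$excitation$occ)
  out <- tdvp_propagate(psi0, mpo, dt = cfg$dynamics$dt_fs,
                        n_steps = cfg$dynamics$n_steps,
                        m_max = cfg$dynamics$m_max,
                        cutoff = cfg$dynamics$cutoff,
                        expand = if (is.null(cfg$dynamics$expand)) "none" else cfg$dynamics$expand)
  spec <- absorption_spectrum(out$record, shift = cfg$spectrum$shift,
                              unit = cfg$spectrum$unit)
  res <- list(bases = bases, sqh = sqh, mpo = mpo, psi0 = psi0,
              psi = out$psi, record = out$record, spectrum = spec)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_term_list(sqh, file.path(cfg$outdir, "terms.txt"))
    write_record_csv(out$record, file.path(cfg$outdir, "record.csv"))
    write_spectrum_csv(spec, file.path(cfg$outdir, "spectrum.csv"))
    write_mps(out$psi, file.path(cfg$outdir, "final_mps.rds"))
    meta <- unclass(cfg)
    meta$model <- NULL
    jsonlite::write_json(
      list(config = meta, lattice = list(n_el = lat$n_el, N = lat$N),
           n_terms = nrow(sqh$terms), mpo_bonds = mpo_bond_dims(mpo),
           final_bonds = mps_bond_dims(out$psi)),
      file.path(cfg$outdir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Write a propagation record / spectrum to CSV
#'
#' @param record a `propagation_record`.
#' @param spectrum a `vib_spectrum`.
#' @param path output file.
#' @name output_csv
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' @rdname output_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore an MPS checkpoint
#'
#' Versioned binary container holding the lattice, sector labels and site
#' tensors.
#'
#' @param psi a `vibronic_mps`.
#' @param path file path.
#' @return `read_mps` returns the restored `vibronic_mps`.
#' @export
write_mps <- function(psi, path) {
  saveRDS(list(container = "vibronmps_mps", version = 1L,
               lattice = unclass(psi$lattice), A = psi$A, bq = psi$bq,
               center = psi$center), path)
  invisible(path)
}

#' @rdname write_mps
#' @export
read_mps <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "vibronmps_mps")) stop("not an MPS container")
  .new_mps(structure(obj$lattice, class = "vib_lattice"), obj$A, obj$bq, obj$center)
}
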