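# Minimal multi-model PDB (MODEL/ENDMDL + ATOM records) reader/writer.
# Coordinates are stored internally in nm (PDB Angstrom values are
# converted on read and back on write). Only the fixed-column fields the
# ensemble analyses need are handled.

.ATOM_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06)

#' Construct a weighted structural ensemble
#'
#' @param atoms Data frame with columns `name` (atom name), `element`,
#'   `resid` (residue number), `resname`, `chain`; one row per atom,
#'   identical across models.
#' @param coords Numeric array `n_atoms x 3 x n_models`, in nm.
#' @param weights Probability vector over models (default uniform).
#' @param domains Named character vector mapping chain id to domain
#'   name (e.g. `c(A = "CID", B = "NCBD")`).
#' @return A `structural_ensemble` object.
#' @export
structural_ensemble <- function(atoms, coords, weights = NULL,
                                domains = NULL) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3)
  nm <- dim(coords)[3]
  if (is.null(weights)) weights <- rep(1 / nm, nm)
  if (length(weights) != nm) stop("one weight per model required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  weights <- weights / sum(weights)
  if (is.null(domains)) {
    ch <- unique(atoms$chain)
    domains <- stats::setNames(ch, ch)
  }
  structure(list(atoms = atoms, coords = coords, weights = weights,
                 domains = domains),
            class = "structural_ensemble")
}

#' @export
print.structural_ensemble <- function(x, ...) {
  cat(sprintf(
    "structural_ensemble: %d models, %d atoms, %d chains (%s)\n",
    dim(x$coords)[3], nrow(x$atoms), length(unique(x$atoms$chain)),
    paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens A `structural_ensemble`.
#' @export
n_models <- function(ens) dim(ens$coords)[3]

#' Read a multi-model PDB file into a structural ensemble
#'
#' @param path PDB file with MODEL/ENDMDL blocks (a file without MODEL
#'   records is read as a single model).
#' @param weights,bias Optional per-model weights or bias values
#'   (kJ/mol); a bias vector is converted to weights via [reweight()].
#' @param kT Thermal energy (kJ/mol) used when `bias` is given.
#' @param domains Chain-to-domain map passed to
#'   [structural_ensemble()].
#' @return A `structural_ensemble` (coordinates in nm).
#' @export
read_ensemble_pdb <- function(path, weights = NULL, bias = NULL,
                              kT = 2.48, domains = NULL) {
  lines <- readLines(path)
  model_breaks <- grepl("^MODEL", lines)
  atom_sel <- grepl("^ATOM  |^HETATM", lines)
  model_id <- cumsum(model_breaks)
  if (!any(model_breaks)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L
  atoms_by_model <- split(lines[atom_sel], model_id[atom_sel])
  nmod <- length(atoms_by_model)
  if (nmod == 0) stop("no ATOM records in ", path)
  parse_block <- function(bl) {
    data.frame(
      name = trimws(substr(bl, 13, 16)),
      resname = trimws(substr(bl, 18, 20)),
      chain = trimws(substr(bl, 22, 22)),
      resid = as.integer(substr(bl, 23, 26)),
      x = as.numeric(substr(bl, 31, 38)),
      y = as.numeric(substr(bl, 39, 46)),
      z = as.numeric(substr(bl, 47, 54)),
      element = trimws(substr(bl, 77, 78)),
      stringsAsFactors = FALSE)
  }
  first <- parse_block(atoms_by_model[[1]])
  # infer element from the atom name when column 77-78 is blank
  blank <- !nzchar(first$element)
  first$element[blank] <- substr(gsub("[0-9]", "", first$name[blank]), 1, 1)
  natom <- nrow(first)
  coords <- array(NA_real_, c(natom, 3, nmod))
  for (m in seq_len(nmod)) {
    bl <- parse_block(atoms_by_model[[m]])
    if (nrow(bl) != natom)
      stop("model ", m, " has a different atom count: shared topology ",
           "required")
    coords[, , m] <- as.matrix(bl[, c("x", "y", "z")]) / 10  # A -> nm
  }
  if (!is.null(bias)) {
    if (!is.null(weights)) stop("give either weights or bias, not both")
    weights <- reweight(bias, kT)
  }
  structural_ensemble(first[, c("name", "element", "resid", "resname",
                                "chain")],
                      coords, weights = weights, domains = domains)
}

#' Write a structural ensemble as a multi-model PDB file
#'
#' @param ens A `structural_ensemble` (coordinates in nm; written in
#'   Angstrom).
#' @param path Output file.
#' @export
write_ensemble_pdb <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ens$atoms
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$coords[, , m] * 10  # nm -> A
    rec <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
      at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element)
    writeLines(rec, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
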