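#' Read a protein structure from PDB or mmCIF
#'
#' Ingests a structure file (via \pkg{bio3d}) into a flat atom table. When
#' several alternate locations are present for an atom, the highest
#' occupancy is kept (ties resolved in favour of alt-loc 'A').
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param model model number to keep for the atom table (default 1).
#' @return object of class `mol_structure`: `atoms` (data frame with
#'   `elety` atom name, `elesy` element, `resno`, `insert`, `resid` residue
#'   name, `chain`, `alt`, `o` occupancy, `x`, `y`, `z` in Angstrom) and
#'   `n_models`.
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) input_error("structure file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path)
         else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE)
  at <- pdb$atom
  nm <- nrow(pdb$xyz)
  if (model > 1) {
    if (model > nm) input_error("model %d not present (%d models)", model, nm)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # alt-loc resolution: best occupancy per (chain, resno, insert, elety)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), ]
  at <- at[order(as.numeric(rownames(at))), ]
  rownames(at) <- NULL
  structure(list(atoms = at, n_models = nm, source = path),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, chains %s, %d model(s)\n",
              nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ","), x$n_models))
  invisible(x)
}

#' Atom selections
#'
#' Declarative atom selection by chain, residue number, residue name and
#' atom name. All given criteria are combined with AND; `NULL` means "any".
#' `selection_presets()` returns named selections for chemical groups used
#' in active-site distance measurements (C20 aldehyde carbon and oxygen of
#' the macrolide substrate, the nicotinamide para-carbon of the cofactor,
#' and the Tyr53 phenolic hydroxyl); the substrate het-code varies between
#' depositions, so the ligand residue name is a parameter.
#'
#' @param chain chain id(s).
#' @param resno residue number(s).
#' @param resid residue name(s) (e.g. `"NAP"`, a ligand het-code).
#' @param elety atom name(s) (e.g. `"CA"`, `"OH"`).
#' @return an `atom_selection` object.
#' @export
sel <- function(chain = NULL, resno = NULL, resid = NULL, elety = NULL) {
  structure(list(chain = chain, resno = resno, resid = resid,
                 elety = elety), class = "atom_selection")
}

#' @rdname sel
#' @param tylosin_resid het-code of the bound macrolide in the deposition.
#' @param cofactor_resid het-code of the cofactor (default `"NAP"`).
#' @export
selection_presets <- function(tylosin_resid = "TYL", cofactor_resid = "NAP") {
  list(
    c20_aldehyde_carbon = sel(resid = tylosin_resid, elety = "C20"),
    aldehyde_oxygen = sel(resid = tylosin_resid, elety = "O1"),
    nicotinamide_para_carbon = sel(resid = cofactor_resid, elety = "C4N"),
    tyr53_hydroxyl = sel(resno = 53, resid = "TYR", elety = "OH")
  )
}

resolve_selection <- function(s, selection) {
  at <- s$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & at$resno %in% selection$resno
  if (!is.null(selection$resid)) keep <- keep & at$resid %in% selection$resid
  if (!is.null(selection$elety)) keep <- keep & at$elety %in% selection$elety
  idx <- which(keep)
  if (!length(idx)) {
    hint <- if (!is.null(selection$chain) &&
                !any(at$chain %in% selection$chain))
      sprintf(" (available chains: %s)",
              paste(unique(at$chain), collapse = ", "))
    else ""
    input_error("selection matched no atoms%s", hint)
  }
  idx
}

#' Interatomic distance
#'
#' Euclidean distance between selected atoms. `mode = "single"` requires
#' each selection to resolve to exactly one atom; `mode = "min"` returns the
#' minimum over the selection cross-product (the distance between two named
#' chemical groups).
#'
#' @param s a [read_structure()] result.
#' @param a,b [sel()] selections.
#' @param mode `"single"` or `"min"`.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(s, a, b, mode = c("single", "min")) {
  mode <- match.arg(mode)
  ia <- resolve_selection(s, a)
  ib <- resolve_selection(s, b)
  if (mode == "single" && (length(ia) != 1 || length(ib) != 1))
    input_error("mode 'single' requires exactly one atom per selection (got %d and %d)",
                length(ia), length(ib))
  xa <- as.matrix(s$atoms[ia, c("x", "y", "z")])
  xb <- as.matrix(s$atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  sqrt(max(min(d2), 0))
}

#' Read a multi-model PDB as a C-alpha ensemble
#'
#' Treats each MODEL block of a PDB file as one frame and extracts C-alpha
#' coordinates, labelling residues by one-letter code + residue number
#' (e.g. `"R257"`).
#'
#' @param path multi-model PDB file.
#' @param chain optional chain filter.
#' @return a [ca_ensemble()].
#' @export
read_ensemble_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) input_error("ensemble file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  keep <- pdb$atom$elety == "CA"
  if (!is.null(chain)) keep <- keep & pdb$atom$chain %in% chain
  if (!any(keep)) input_error("no C-alpha atoms found in %s", path)
  at <- pdb$atom[keep, ]
  xyz_cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                              3 * which(keep)))
  X <- pdb$xyz[, xyz_cols, drop = FALSE]
  f <- nrow(X); r <- sum(keep)
  coords <- array(0, c(f, r, 3))
  for (a in 1:3) coords[, , a] <- X[, seq(a, by = 3, length.out = r),
                                    drop = FALSE]
  labels <- paste0(bio3d::aa321(at$resid), at$resno)
  ca_ensemble(coords, labels)
}

#' Write a C-alpha ensemble as a multi-model PDB
#'
#' Serialises every frame as one MODEL block of C-alpha ATOM records
#' (residue type ALA, chain A), readable by [read_ensemble_pdb()] and by
#' standard structure viewers.
#'
#' @param e a [ca_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(e, path) {
  stopifnot(inherits(e, "ca_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  resno <- resno_from_labels(e$labels)
  for (f in seq_len(n_frames(e))) {
    cat(sprintf("MODEL     %4d\n", f), file = con)
    for (r in seq_len(n_residues(e))) {
      cat(sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C\n",
                  r, resno[r], e$coords[f, r, 1], e$coords[f, r, 2],
                  e$coords[f, r, 3]), file = con)
    }
    cat("ENDMDL\n", file = con)
  }
  cat("END\n", file = con)
  invisible(path)
}

resno_from_labels <- function(labels) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", labels)))
  if (anyNA(n) || anyDuplicated(n)) seq_along(labels) else n
}
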