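#' Single-chain conformation objects
#'
#' A `fold_chain` holds one polypeptide conformation: heavy-atom coordinates
#' (in Angstrom) indexed by residue and atom name.  Residues are numbered
#' contiguously `1..L` internally; original PDB residue numbers, when the
#' chain was read from a file, are retained as metadata only, since all
#' downstream descriptors (contact order, contact locality, sequence
#' separation) are defined on the contiguous index.
#'
#' @param atom character vector of atom names (one per atom), e.g. `"CA"`.
#' @param resid integer vector of residue indices (one per atom), contiguous
#'   `1..L`.
#' @param xyz numeric matrix (`n_atoms` x 3) of coordinates in Angstrom.
#' @param res_name character vector of 3-letter residue names, length `L`.
#' @param pdb_resno optional integer vector of original PDB residue numbers
#'   (length `L`), kept as metadata.
#' @param validate check the chain invariants (backbone completeness,
#'   contiguous indices, finite coordinates, CA-CA virtual-bond band)?
#' @return An object of class `fold_chain`.
#' @export
fold_chain <- function(atom, resid, xyz, res_name, pdb_resno = NULL,
                       validate = TRUE) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  ch <- structure(
    list(atom = as.character(atom), resid = as.integer(resid), xyz = xyz,
         res_name = as.character(res_name),
         pdb_resno = if (is.null(pdb_resno)) NULL else as.integer(pdb_resno)),
    class = "fold_chain")
  if (validate) validate_chain(ch)
  ch
}

#' @export
print.fold_chain <- function(x, ...) {
  cat(sprintf("<fold_chain> %d residues, %d heavy atoms\n",
              chain_length(x), nrow(x$xyz)))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `fold_chain`.
#' @return Integer chain length `L`.
#' @export
chain_length <- function(chain) {
  if (length(chain$resid) == 0L) return(0L)
  max(chain$resid)
}

#' Validate the chain invariants
#'
#' Checks that every residue carries at least the N, CA and C backbone atoms,
#' that residue indices are contiguous `1..L`, that all coordinates are
#' finite, and that consecutive CA-CA distances fall in the 2.5-4.5 Angstrom
#' virtual-bond sanity band.
#'
#' @param chain a `fold_chain`.
#' @param bond_band also enforce the CA-CA virtual-bond band?  Generators
#'   keep it; trajectory frames carrying coordinate noise may stretch
#'   virtual bonds slightly, so file ingestion checks only completeness.
#' @return The chain, invisibly; errors describe the first violation found.
#' @export
validate_chain <- function(chain, bond_band = TRUE) {
  L <- chain_length(chain)
  if (L < 1L) stopf("chain has no residues")
  if (!all(sort(unique(chain$resid)) == seq_len(L)))
    stopf("residue indices are not contiguous 1..%d", L)
  if (length(chain$res_name) != L)
    stopf("res_name length %d != chain length %d", length(chain$res_name), L)
  if (!all(is.finite(chain$xyz)))
    stopf("non-finite coordinates in chain")
  for (bb in c("N", "CA", "C")) {
    have <- unique(chain$resid[chain$atom == bb])
    miss <- setdiff(seq_len(L), have)
    if (length(miss) > 0)
      stopf("residue %d (%s) is missing backbone atom %s",
            miss[1], chain$res_name[miss[1]], bb)
  }
  ca <- ca_xyz(chain)
  if (bond_band && L > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
    bad <- which(d < 2.5 | d > 4.5)
    if (length(bad) > 0)
      stopf("CA-CA distance %.2f A between residues %d and %d outside [2.5, 4.5]",
            d[bad[1]], bad[1], bad[1] + 1L)
  }
  invisible(chain)
}

#' Extract coordinates of one named atom per residue
#'
#' @param chain a `fold_chain`.
#' @param atom atom name, default `"CA"`.
#' @return `L` x 3 matrix; rows of residues lacking the atom are `NA`.
#' @export
atom_xyz <- function(chain, atom = "CA") {
  L <- chain_length(chain)
  out <- matrix(NA_real_, L, 3)
  sel <- chain$atom == atom
  out[chain$resid[sel], ] <- chain$xyz[sel, , drop = FALSE]
  out
}

#' @rdname atom_xyz
#' @export
ca_xyz <- function(chain) atom_xyz(chain, "CA")

# Backbone coordinates for residues `res` stacked atom-major per residue in
# the order given by `atoms`; errors if any is missing.
backbone_xyz <- function(chain, res = seq_len(chain_length(chain)),
                         atoms = c("N", "CA", "C", "O")) {
  mats <- lapply(atoms, function(a) atom_xyz(chain, a)[res, , drop = FALSE])
  out <- matrix(NA_real_, length(res) * length(atoms), 3)
  for (k in seq_along(atoms)) {
    out[seq(k, by = length(atoms), length.out = length(res)), ] <- mats[[k]]
  }
  if (anyNA(out)) stopf("chain is missing one of the backbone atoms %s",
                        paste(atoms, collapse = "/"))
  out
}

#' Backbone dihedral angles
#'
#' Computes per-residue (phi, psi) from the N-CA-C backbone trace by the
#' standard four-point dihedral construction.  `phi` is undefined (`NA`) for
#' the first residue and `psi` for the last.
#'
#' @param chain a `fold_chain` with at least 2 residues.
#' @return data.frame with columns `phi`, `psi` in degrees, in (-180, 180].
#' @export
phi_psi <- function(chain) {
  L <- chain_length(chain)
  if (L < 2) stopf("phi/psi need at least 2 residues")
  N <- atom_xyz(chain, "N"); CA <- atom_xyz(chain, "CA")
  C <- atom_xyz(chain, "C")
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1) phi[i] <- torsion_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < L) psi[i] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

# Apply a rigid transformation (rotation matrix R, then translation t) to all
# atoms of a chain; used heavily by the synthetic builders and in tests.
transform_chain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  chain$xyz <- chain$xyz %*% R + matrix(t, nrow(chain$xyz), 3, byrow = TRUE)
  chain
}
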