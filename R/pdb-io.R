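#' Read a PDB file into a structure set
#'
#' Parses a single- or multi-model PDB file (one polypeptide chain per
#' model).  Only heavy atoms are retained -- hydrogens are dropped, since all
#' descriptors here (contacts, secondary structure, superposition) are
#' defined on heavy atoms and backbone amide hydrogens are reconstructed
#' geometrically where needed.  For alternate locations the highest-occupancy
#' copy is kept (first on ties).  Residue indices are renumbered to a
#' contiguous `1..L`; the original numbering is kept as metadata.
#'
#' @param path path to a PDB file containing ATOM records, optionally split
#'   into MODEL/ENDMDL blocks.
#' @return A [structure_set] with one member per model, labelled
#'   `model_1..model_n`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM", lines)
  if (length(atom_idx) == 0) stopf("no ATOM records in %s", path)
  for (i in atom_idx) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))) &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stopf("unparseable ATOM record at line %d of %s", i, path)
  }

  model_starts <- grep("^MODEL", lines)
  n_atoms_per_model <- if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    mapply(function(s, e) sum(atom_idx > s & atom_idx < e), model_starts,
           ends[seq_along(model_starts)])
  } else {
    length(atom_idx)
  }

  if (length(unique(n_atoms_per_model)) == 1) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    chains <- lapply(seq_len(nrow(pdb$xyz)), function(m)
      pdb_model_chain(pdb, matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)))
  } else {
    # models with differing atom layouts: parse each MODEL block separately
    ends <- grep("^ENDMDL", lines)
    chains <- lapply(seq_along(model_starts), function(m) {
      tf <- tempfile(fileext = ".pdb")
      on.exit(unlink(tf), add = TRUE)
      writeLines(c(lines[(model_starts[m] + 1):(ends[m] - 1)], "END"), tf)
      pdb <- bio3d::read.pdb(tf, verbose = FALSE)
      pdb_model_chain(pdb, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
    })
  }
  structure_set(chains, labels = sprintf("model_%d", seq_along(chains)))
}

# Convert one model of a bio3d pdb object (atom table + coordinate matrix)
# into a fold_chain: heavy ATOM records only, best alternate location,
# contiguous residue renumbering.
pdb_model_chain <- function(pdb, xyz_all) {
  at <- pdb$atom
  keep <- at$type == "ATOM"
  # drop hydrogens (element H/D, or H-led atom names like 1HB, HG11)
  elesy <- toupper(trimws(at$elesy %||% ""))
  is_h <- elesy %in% c("H", "D") | grepl("^[0-9]*[HD]", trimws(at$elety))
  keep <- keep & !is_h
  if (length(unique(at$chain[keep])) > 1)
    stopf("multi-chain files are not supported (found chains: %s)",
          paste(unique(at$chain[keep]), collapse = ", "))
  # alternate locations: highest occupancy wins, first on tie
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety)
  ord <- order(-occ[keep])
  keep_rows <- which(keep)[ord]
  keep_rows <- keep_rows[!duplicated(key[keep_rows])]
  keep_rows <- sort(keep_rows)

  resno <- at$resno[keep_rows]
  ukeys <- unique(resno)
  resid <- match(resno, ukeys)
  res_name <- at$resid[keep_rows][!duplicated(resid)]
  atoms <- trimws(at$elety[keep_rows])
  ch <- fold_chain(atom = atoms, resid = resid,
                   xyz = xyz_all[keep_rows, , drop = FALSE],
                   res_name = res_name, pdb_resno = ukeys, validate = FALSE)
  validate_chain(ch, bond_band = FALSE)
  ch
}

#' Write a structure set to a PDB file
#'
#' Writes standard fixed-column ATOM records; sets with more than one member
#' are written as MODEL/ENDMDL blocks.  Coordinates survive a read/write
#' round trip to the PDB column precision of 1e-3 Angstrom.
#'
#' @param set a non-empty [structure_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(set, path) {
  if (!inherits(set, "structure_set") || length(set) == 0)
    stopf("set must be a non-empty structure_set")
  ref <- set$chains[[1]]
  homogeneous <- all(vapply(set$chains, function(ch) {
    identical(ch$atom, ref$atom) && identical(ch$resid, ref$resid)
  }, logical(1)))
  wr <- function(...) {
    ok <- tryCatch({ bio3d::write.pdb(...); TRUE },
                   error = function(e) stopf("cannot write PDB to %s: %s",
                                             path, conditionMessage(e)))
    invisible(ok)
  }
  if (homogeneous) {
    xyz <- do.call(rbind, lapply(set$chains, function(ch) as.vector(t(ch$xyz))))
    resno <- (ref$pdb_resno %||% seq_len(chain_length(ref)))[ref$resid]
    wr(file = path, xyz = xyz, resno = resno,
       resid = ref$res_name[ref$resid], elety = ref$atom,
       chain = rep("A", length(ref$atom)))
  } else {
    blocks <- lapply(seq_along(set$chains), function(m) {
      ch <- set$chains[[m]]
      tf <- tempfile(fileext = ".pdb")
      on.exit(unlink(tf), add = TRUE)
      resno <- (ch$pdb_resno %||% seq_len(chain_length(ch)))[ch$resid]
      bio3d::write.pdb(file = tf, xyz = as.vector(t(ch$xyz)), resno = resno,
                       resid = ch$res_name[ch$resid], elety = ch$atom,
                       chain = rep("A", length(ch$atom)))
      body <- grep("^(ATOM|TER)", readLines(tf), value = TRUE)
      c(sprintf("MODEL     %4d", m), body, "ENDMDL")
    })
    ok <- tryCatch({
      writeLines(c(unlist(blocks), "END"), path)
      TRUE
    }, error = function(e) stopf("cannot write PDB to %s: %s", path,
                                 conditionMessage(e)))
  }
  invisible(path)
}
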