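# Coordinate data model: ordered atom records plus named cofactor groups.
# All downstream analyses consume this container, never raw PDB files.

#' Heavy side-chain atom names of the twenty standard amino acids
#'
#' Backbone atoms (N, CA, C, O, OXT) and hydrogens are excluded throughout
#' the package: relaxation protocols re-place hydrogens, so RMSD on them is
#' noise. Glycine maps to an empty vector.
#'
#' @format Named list; names are 3-letter residue codes, values character
#'   vectors of PDB atom names.
#' @export
aa_sidechain_atoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure object
#'
#' A `cpr_structure` is an ordered table of atom records together with a
#' registry of cofactor groups (e.g. FMN, HEM) pointing at atom indices.
#' Residue iteration order is the atom order of the input.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer), `insert` (character, `""` when absent), `resid` (3-letter
#'   residue name), `elety` (atom name), `elesy` (element symbol), `x`,
#'   `y`, `z` (Angstrom), `het` (logical, HETATM flag).
#' @param title optional title string.
#' @param cofactor_groups named list of integer atom-index vectors; when
#'   `NULL`, every non-water HETATM residue is registered under its residue
#'   name.
#' @return object of class `cpr_structure`.
#' @export
new_structure <- function(atoms, title = "", cofactor_groups = NULL) {
  req <- c("chain", "resno", "insert", "resid", "elety", "elesy",
           "x", "y", "z", "het")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, req]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert <- as.character(atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[anyDuplicated(key)])
  }
  rownames(atoms) <- NULL
  if (is.null(cofactor_groups)) {
    cofactor_groups <- list()
    het <- which(atoms$het & !(atoms$resid %in% c("HOH", "WAT")))
    if (length(het) > 0L) {
      cofactor_groups <- split(het, atoms$resid[het])
    }
  } else {
    for (g in names(cofactor_groups)) {
      idx <- cofactor_groups[[g]]
      if (any(idx < 1L | idx > nrow(atoms))) {
        stop("cofactor group '", g, "' references atoms outside the structure")
      }
    }
  }
  structure(
    list(atoms = atoms, title = title, cofactor_groups = cofactor_groups),
    class = "cpr_structure"
  )
}

#' @export
print.cpr_structure <- function(x, ...) {
  rk <- residue_table(x)
  cat("cpr_structure: ", nrow(x$atoms), " atoms, ", nrow(rk), " residues, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  if (length(x$cofactor_groups) > 0L) {
    cat("  cofactor groups: ",
        paste(names(x$cofactor_groups), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param s `cpr_structure`.
#' @param idx optional atom indices.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param s `cpr_structure`.
#' @param xyz n x 3 matrix matching the atom count (or `length(idx)` rows).
#' @param idx optional atom indices to replace.
#' @return modified `cpr_structure`.
#' @export
set_coords <- function(s, xyz, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(s$atoms))
  stopifnot(nrow(xyz) == length(idx), ncol(xyz) == 3L)
  s$atoms[idx, c("x", "y", "z")] <- xyz
  s
}

#' Unique residues in iteration (atom) order
#' @param s `cpr_structure`.
#' @return data.frame with columns chain, resno, insert, resid, het.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], het = a$het[first],
    stringsAsFactors = FALSE
  )
}

# internal: atom indices of one residue
.residue_atoms <- function(s, chain, resno, insert = "") {
  which(s$atoms$chain == chain & s$atoms$resno == resno &
          s$atoms$insert == insert)
}

#' Heavy side-chain atom indices of one residue
#'
#' Returns the indices of non-hydrogen atoms excluding the backbone
#' (N, CA, C, O, OXT). Glycine yields an empty vector.
#'
#' @param s `cpr_structure`.
#' @param chain,resno,insert residue identity.
#' @return integer vector of atom indices (possibly empty for glycine).
#' @export
sidechain_atoms <- function(s, chain, resno, insert = "") {
  idx <- .residue_atoms(s, chain, resno, insert)
  if (length(idx) == 0L) {
    stop("residue ", chain, ":", resno, insert, " not found")
  }
  resid <- s$atoms$resid[idx[1L]]
  if (s$atoms$het[idx[1L]]) {
    stop("residue ", chain, ":", resno, insert, " is a hetero group (",
         resid, ")")
  }
  if (!resid %in% names(aa_sidechain_atoms)) {
    stop("residue ", chain, ":", resno, insert,
         " is not a standard amino acid (", resid, ")")
  }
  allowed <- aa_sidechain_atoms[[resid]]
  idx[s$atoms$elety[idx] %in% allowed & s$atoms$elesy[idx] != "H"]
}

# internal: logical mask over all atoms marking heavy side-chain atoms of
# standard residues
.sidechain_mask <- function(s) {
  a <- s$atoms
  std <- !a$het & a$resid %in% names(aa_sidechain_atoms)
  allowed <- rep(FALSE, nrow(a))
  if (any(std)) {
    allowed[std] <- mapply(
      function(ty, re) ty %in% aa_sidechain_atoms[[re]],
      a$elety[std], a$resid[std]
    )
  }
  allowed & a$elesy != "H"
}

#' Read a PDB-format structure file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}. Alternate locations are
#' reduced to the highest-occupancy conformer (ties broken by altloc
#' letter). Non-water HETATM residues (e.g. FMN, HEM) are registered in
#' `cofactor_groups` under their residue name.
#'
#' @param path PDB file.
#' @return `cpr_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54)
    )))
    if (any(is.na(xyz))) {
      stop("unparseable coordinate field at line ", i, " of ", path)
    }
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  o <- a$o
  o[is.na(o)] <- 1
  alt <- a$alt
  alt[is.na(alt)] <- ""
  ins <- a$insert
  ins[is.na(ins)] <- ""
  ch <- a$chain
  ch[is.na(ch)] <- ""
  # keep highest-occupancy altloc per (residue, atom name); tie-break on
  # altloc letter so the choice is deterministic
  akey <- paste(ch, a$resno, ins, a$elety, sep = "\r")
  ord <- order(akey, -o, alt)
  keep <- sort(ord[!duplicated(akey[ord])])
  elesy <- a$elesy[keep]
  no_sym <- is.na(elesy) | elesy == ""
  if (any(no_sym)) {
    elesy[no_sym] <- substr(gsub("[0-9']", "", a$elety[keep][no_sym]), 1, 1)
  }
  atoms <- data.frame(
    chain = ch[keep], resno = a$resno[keep], insert = ins[keep],
    resid = a$resid[keep], elety = a$elety[keep], elesy = elesy,
    x = a$x[keep], y = a$y[keep], z = a$z[keep],
    het = a$type[keep] == "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, title = basename(path))
}

#' Write a structure to a PDB-format file
#'
#' Coordinates are written at PDB precision (3 decimals); a read/write
#' round trip is the identity on atom fields at that precision.
#'
#' @param s `cpr_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  type <- ifelse(a$het, "HETATM", "ATOM")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = type, resno = a$resno, resid = a$resid,
    eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    elesy = a$elesy, o = rep(1, nrow(a)), b = rep(0, nrow(a))
  )
  invisible(path)
}

#' Split a complex into labelled domains plus the unchanged complex
#'
#' Every chain must be assigned a domain label. Coordinates are copied
#' verbatim: no re-centering and no relaxation, so the union of the split
#' atom sets equals the complex atom set exactly.
#'
#' @param s `cpr_structure` of the complex.
#' @param partition named character vector mapping chain id -> domain label,
#'   e.g. `c(A = "CYP", B = "FD")`.
#' @return named list: one `cpr_structure` per domain label, plus
#'   `$complex` (the unchanged input).
#' @export
split_complex <- function(s, partition) {
  chains <- unique(s$atoms$chain)
  unassigned <- setdiff(chains, names(partition))
  if (length(unassigned) > 0L) {
    stop("chains with no domain label: ", paste(unassigned, collapse = ", "))
  }
  out <- list()
  for (lab in unique(unname(partition))) {
    ch <- names(partition)[partition == lab]
    idx <- which(s$atoms$chain %in% ch)
    if (length(idx) == 0L) next
    out[[lab]] <- new_structure(s$atoms[idx, , drop = FALSE],
                                title = paste(s$title, lab))
  }
  out$complex <- s
  out
}

# internal: restrict a structure to the chains of one domain label
.domain_structure <- function(s, partition, domain) {
  ch <- names(partition)[partition == domain]
  idx <- which(s$atoms$chain %in% ch)
  if (length(idx) == 0L) stop("no atoms in domain '", domain, "'")
  new_structure(s$atoms[idx, , drop = FALSE], title = s$title,
                cofactor_groups = list())
}

# internal: indices of C-alpha atoms of standard residues
.calpha_idx <- function(s) {
  which(!s$atoms$het & s$atoms$elety == "CA" &
          s$atoms$resid %in% names(aa_sidechain_atoms))
}

# internal: indices of heavy backbone atoms of standard residues
.backbone_idx <- function(s) {
  which(!s$atoms$het & s$atoms$elety %in% c("N", "CA", "C", "O") &
          s$atoms$resid %in% names(aa_sidechain_atoms))
}
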