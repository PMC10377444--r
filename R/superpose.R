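# Rigid-body superposition (Kabsch), per-residue normalized side-chain
# RMSD, and cofactor grafting by anchor-residue RMSD minimization.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference`. Reflections are rejected, so the returned
#' rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, equal sizes,
#'   not all collinear.
#' @return list of class `rigid_transform` with elements `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom). The transform maps a
#'   point row-vector `x` to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("point sets differ in size (", nrow(mobile), " vs ",
         nrow(reference), ")")
  }
  if (nrow(mobile) < 3L) stop("need at least 3 points, got ", nrow(mobile))
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  if (sum(svd(Q)$d > 1e-8) < 2L) stop("reference points are collinear")
  H <- crossprod(P, Q) # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(cr - R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param tf `rigid_transform`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  sweep(as.matrix(xyz) %*% t(tf$rotation), 2, tf$translation, "+")
}

# internal: superpose structure b onto a using shared C-alphas; returns b
# with transformed coordinates
.prealign_calpha <- function(a, b) {
  ia <- .calpha_idx(a)
  ib <- .calpha_idx(b)
  ka <- paste(a$atoms$chain[ia], a$atoms$resno[ia], a$atoms$insert[ia])
  kb <- paste(b$atoms$chain[ib], b$atoms$resno[ib], b$atoms$insert[ib])
  shared <- intersect(ka, kb)
  if (length(shared) < 3L) stop("fewer than 3 shared C-alpha atoms")
  ia <- ia[match(shared, ka)]
  ib <- ib[match(shared, kb)]
  tf <- kabsch_superpose(coords(b, ib), coords(a, ia))
  set_coords(b, apply_transform(coords(b), tf))
}

#' Per-residue normalized side-chain RMSD between two structures
#'
#' For each residue the raw side-chain RMSD, `sqrt(mean(d_i^2))` over heavy
#' side-chain atoms matched by name, is normalized by division by the
#' side-chain atom count (units Angstrom per atom). The alternative reading
#' of that normalization, the mean per-atom displacement
#' `mean(|d_i|)`, is selectable via `normalization = "mean-displacement"`.
#' Glycine has no side chain and is omitted from the profile.
#'
#' @param a,b `cpr_structure`s sharing residue numbering; for each compared
#'   residue the side-chain atom name sets must be identical.
#' @param residues optional data.frame (chain, resno, insert) restricting
#'   the profile; default: all standard residues shared by `a` and `b`.
#' @param prealign `"calpha"` (default) superposes `b` onto `a` on shared
#'   C-alphas first; `"none"` compares coordinates as given.
#' @param normalization `"per-atom-count"` (RMSD / atom count, default) or
#'   `"mean-displacement"`.
#' @return data.frame (chain, resno, insert, resid, n_atoms, value) with
#'   attribute `normalization`.
#' @export
per_residue_sidechain_rmsd <- function(a, b, residues = NULL,
                                       prealign = c("calpha", "none"),
                                       normalization = c("per-atom-count",
                                                         "mean-displacement")) {
  prealign <- match.arg(prealign)
  normalization <- match.arg(normalization)
  if (prealign == "calpha") b <- .prealign_calpha(a, b)
  if (is.null(residues)) {
    ra <- residue_table(a)
    rb <- residue_table(b)
    ra <- ra[!ra$het & ra$resid %in% names(aa_sidechain_atoms), ]
    shared <- paste(rb$chain, rb$resno, rb$insert)
    residues <- ra[paste(ra$chain, ra$resno, ra$insert) %in% shared, ]
  }
  n <- nrow(residues)
  out <- data.frame(
    chain = character(n), resno = integer(n), insert = character(n),
    resid = character(n), n_atoms = integer(n), value = numeric(n),
    stringsAsFactors = FALSE
  )
  keep <- logical(n)
  for (i in seq_len(n)) {
    ch <- residues$chain[i]; rn <- residues$resno[i]
    ic <- if ("insert" %in% names(residues)) residues$insert[i] else ""
    ia <- sidechain_atoms(a, ch, rn, ic)
    ib <- sidechain_atoms(b, ch, rn, ic)
    na_names <- sort(a$atoms$elety[ia])
    nb_names <- sort(b$atoms$elety[ib])
    if (!identical(na_names, nb_names)) {
      stop("side-chain atom sets differ for residue ", ch, ":", rn, ic)
    }
    if (length(ia) == 0L) next # glycine: omitted
    ib <- ib[match(a$atoms$elety[ia], b$atoms$elety[ib])]
    d <- sqrt(rowSums((coords(a, ia) - coords(b, ib))^2))
    value <- switch(normalization,
      "per-atom-count" = sqrt(mean(d^2)) / length(d),
      "mean-displacement" = mean(d)
    )
    out[i, ] <- list(ch, rn, ic, a$atoms$resid[ia[1L]], length(d), value)
    keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normalization") <- normalization
  out
}

#' Graft a cofactor from a donor structure by anchor-residue superposition
#'
#' The rigid transform that superposes the donor's anchor-residue C-alphas
#' onto the model's is applied to the donor's cofactor atoms, which are
#' then appended to the model as HETATM records. Model protein atoms are
#' untouched. This mirrors re-placing flavin/heme cofactors from reference
#' crystal structures onto modelled complexes whose docking step dropped
#' them.
#'
#' @param model `cpr_structure` receiving the cofactor.
#' @param donor `cpr_structure` containing the cofactor group.
#' @param cofactor group name in `donor$cofactor_groups` (e.g. `"FMN"`).
#' @param anchors data.frame (chain, resno, insert optional) of anchor
#'   residues present in both structures.
#' @return `cpr_structure` with the grafted cofactor appended.
#' @export
graft_cofactor <- function(model, donor, cofactor, anchors) {
  if (!cofactor %in% names(donor$cofactor_groups)) {
    stop("donor has no cofactor group '", cofactor, "'")
  }
  if (is.null(anchors$insert)) anchors$insert <- ""
  ca_model <- ca_donor <- integer(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    im <- .residue_atoms(model, anchors$chain[i], anchors$resno[i],
                         anchors$insert[i])
    id <- .residue_atoms(donor, anchors$chain[i], anchors$resno[i],
                         anchors$insert[i])
    im <- im[model$atoms$elety[im] == "CA"]
    id <- id[donor$atoms$elety[id] == "CA"]
    if (length(im) != 1L || length(id) != 1L) {
      stop("anchor residue ", anchors$chain[i], ":", anchors$resno[i],
           " lacks a C-alpha in model or donor")
    }
    ca_model[i] <- im
    ca_donor[i] <- id
  }
  tf <- kabsch_superpose(coords(donor, ca_donor), coords(model, ca_model))
  cof_idx <- donor$cofactor_groups[[cofactor]]
  cof <- donor$atoms[cof_idx, , drop = FALSE]
  cof[, c("x", "y", "z")] <- apply_transform(as.matrix(cof[, c("x", "y", "z")]),
                                             tf)
  atoms <- rbind(model$atoms, cof)
  groups <- model$cofactor_groups
  groups[[cofactor]] <- nrow(model$atoms) + seq_len(nrow(cof))
  new_structure(atoms, title = model$title, cofactor_groups = groups)
}
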