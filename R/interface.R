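# Cross-domain side-chain contact detection, consensus across docked pose
# ensembles, and flavin/heme cofactor geometry.

#' Cross-domain side-chain contacts in a complex
#'
#' Reports every cross-domain residue pair whose minimum heavy side-chain
#' atom distance is less than or equal to `cutoff` (inclusive). Glycine,
#' having no side-chain atoms, can never contact. Exactly two domains must
#' be present.
#'
#' @param s `cpr_structure` of the complex.
#' @param partition named chain -> domain label map.
#' @param cutoff contact distance in Angstrom (default 3.0).
#' @return data.frame with one row per contacting residue pair: chain_a,
#'   resno_a, insert_a, resid_a, chain_b, resno_b, insert_b, resid_b,
#'   min_distance; attribute `domains` gives the two labels (a, b).
#' @export
contact_pairs <- function(s, partition, cutoff = 3.0) {
  chains <- unique(s$atoms$chain)
  unassigned <- setdiff(chains, names(partition))
  if (length(unassigned) > 0L) {
    stop("chains with no domain label: ", paste(unassigned, collapse = ", "))
  }
  labs <- unique(unname(partition[chains]))
  if (length(labs) < 2L) stop("contact analysis needs two domains, got ",
                              length(labs))
  if (length(labs) > 2L) stop("contact analysis supports exactly two domains")
  mask <- .sidechain_mask(s)
  dom <- unname(partition[s$atoms$chain])
  ia <- which(mask & dom == labs[1L])
  ib <- which(mask & dom == labs[2L])
  empty <- data.frame(
    chain_a = character(0), resno_a = integer(0), insert_a = character(0),
    resid_a = character(0), chain_b = character(0), resno_b = integer(0),
    insert_b = character(0), resid_b = character(0),
    min_distance = numeric(0), stringsAsFactors = FALSE
  )
  attr(empty, "domains") <- stats::setNames(labs, c("a", "b"))
  if (length(ia) == 0L || length(ib) == 0L) return(empty)
  xa <- coords(s, ia)
  xb <- coords(s, ib)
  # squared cross-distance matrix, |ia| x |ib|
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  a <- s$atoms
  key_a <- paste(a$chain[ia], a$resno[ia], a$insert[ia], sep = "\r")
  key_b <- paste(a$chain[ib], a$resno[ib], a$insert[ib], sep = "\r")
  ra <- unique(key_a)
  rb <- unique(key_b)
  rows <- list()
  for (ka in ra) {
    sel_a <- key_a == ka
    for (kb in rb) {
      sel_b <- key_b == kb
      dmin <- sqrt(min(d2[sel_a, sel_b]))
      if (dmin <= cutoff) {
        fa <- ia[sel_a][1L]
        fb <- ib[sel_b][1L]
        rows[[length(rows) + 1L]] <- data.frame(
          chain_a = a$chain[fa], resno_a = a$resno[fa],
          insert_a = a$insert[fa], resid_a = a$resid[fa],
          chain_b = a$chain[fb], resno_b = a$resno[fb],
          insert_b = a$insert[fb], resid_b = a$resid[fb],
          min_distance = dmin, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "domains") <- stats::setNames(labs, c("a", "b"))
  out
}

#' Consensus contacts across a pose ensemble
#'
#' A residue scores a hit in a pose when it has at least one cross-domain
#' side-chain contact there. Residues with hits in at least
#' `ceiling(threshold * n_poses)` poses form the consensus set; residues
#' with at least one hit but below consensus form the secondary tier (the
#' "less frequent contacts" class). Pair-level hit counts are also
#' returned.
#'
#' @param poses list of per-pose contact tables from [contact_pairs()].
#' @param threshold consensus fraction (default 0.5, i.e. "at least 50
#'   percent of considered poses").
#' @return object of class `consensus_contacts`: list with `$residues`
#'   (data.frame domain, chain, resno, insert, resid, n_hits, consensus,
#'   secondary), `$pairs` (pair-level hit counts), `$n_poses`,
#'   `$threshold`, `$min_hits`.
#' @export
consensus_contacts <- function(poses, threshold = 0.5) {
  if (length(poses) == 0L) stop("no poses given")
  n_poses <- length(poses)
  min_hits <- ceiling(threshold * n_poses)
  res_rows <- list()
  pair_rows <- list()
  for (p in seq_len(n_poses)) {
    ct <- poses[[p]]
    if (nrow(ct) == 0L) next
    doms <- attr(ct, "domains")
    da <- if (!is.null(doms)) doms[["a"]] else "A"
    db <- if (!is.null(doms)) doms[["b"]] else "B"
    both <- rbind(
      data.frame(domain = da, chain = ct$chain_a, resno = ct$resno_a,
                 insert = ct$insert_a, resid = ct$resid_a,
                 stringsAsFactors = FALSE),
      data.frame(domain = db, chain = ct$chain_b, resno = ct$resno_b,
                 insert = ct$insert_b, resid = ct$resid_b,
                 stringsAsFactors = FALSE)
    )
    both <- both[!duplicated(paste(both$chain, both$resno, both$insert)), ]
    both$pose <- p
    res_rows[[length(res_rows) + 1L]] <- both
    pr <- ct[, c("chain_a", "resno_a", "insert_a", "resid_a",
                 "chain_b", "resno_b", "insert_b", "resid_b")]
    pr$pose <- p
    pair_rows[[length(pair_rows) + 1L]] <- pr
  }
  if (length(res_rows) == 0L) {
    residues <- data.frame(
      domain = character(0), chain = character(0), resno = integer(0),
      insert = character(0), resid = character(0), n_hits = integer(0),
      consensus = logical(0), secondary = logical(0), stringsAsFactors = FALSE
    )
    pairs <- data.frame()
  } else {
    all_res <- do.call(rbind, res_rows)
    key <- paste(all_res$chain, all_res$resno, all_res$insert, sep = "\r")
    counts <- table(key)
    first <- !duplicated(key)
    residues <- all_res[first, c("domain", "chain", "resno", "insert", "resid")]
    residues$n_hits <- as.integer(counts[key[first]])
    residues$consensus <- residues$n_hits >= min_hits
    residues$secondary <- residues$n_hits >= 1L & !residues$consensus
    residues <- residues[order(residues$domain, residues$chain,
                               residues$resno, residues$insert), ]
    rownames(residues) <- NULL
    all_pairs <- do.call(rbind, pair_rows)
    pkey <- paste(all_pairs$chain_a, all_pairs$resno_a, all_pairs$insert_a,
                  all_pairs$chain_b, all_pairs$resno_b, all_pairs$insert_b,
                  sep = "\r")
    pcount <- table(pkey)
    pfirst <- !duplicated(pkey)
    pairs <- all_pairs[pfirst, names(all_pairs) != "pose"]
    pairs$n_hits <- as.integer(pcount[pkey[pfirst]])
    pairs$consensus <- pairs$n_hits >= min_hits
    rownames(pairs) <- NULL
  }
  structure(
    list(residues = residues, pairs = pairs, n_poses = n_poses,
         threshold = threshold, min_hits = as.integer(min_hits)),
    class = "consensus_contacts"
  )
}

#' @export
print.consensus_contacts <- function(x, ...) {
  cat("consensus_contacts: ", sum(x$residues$consensus), " consensus and ",
      sum(x$residues$secondary), " secondary residues over ", x$n_poses,
      " poses (>= ", x$min_hits, " hits)\n", sep = "")
  invisible(x)
}

# internal: unit normal of the least-squares plane through points (the
# singular vector of the smallest singular value of the centered set)
.plane_normal <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("plane fit needs at least 3 points")
  centered <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centered)
  if (sv$d[2] < 1e-8) stop("plane fit points are collinear")
  sv$v[, 3L]
}

# FMN isoalloxazine ring and heme porphyrin core atom names (PDB chemical
# component conventions)
.fmn_ring_atoms <- c("N1", "C2", "N3", "C4", "C4A", "N5", "C5A", "C6",
                     "C7", "C8", "C9", "C9A", "N10")
.heme_ring_atoms <- c("NA", "NB", "NC", "ND",
                      "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B",
                      "C1C", "C2C", "C3C", "C4C", "C1D", "C2D", "C3D", "C4D")

#' Flavin/heme cofactor geometry of a complex
#'
#' Computes the electron-transfer-relevant geometry: Euclidean distances
#' from each flavin methyl carbon (C7M, C8M: the 7-alpha/8-alpha methyls of
#' the isoalloxazine ring) to the heme iron and to the heme-ligating
#' cysteine S-gamma, and the acute dihedral angle between the least-squares
#' planes of the FMN isoalloxazine ring and the heme porphyrin core.
#'
#' @param s `cpr_structure` containing both cofactor groups.
#' @param fmn_group,heme_group cofactor group names (defaults `"FMN"`,
#'   `"HEM"`).
#' @return list of class `cofactor_geometry`: `methyl_to_iron` (named,
#'   Angstrom), `methyl_to_cys_thiol` (named, Angstrom; `NA` when no
#'   cysteine S-gamma is present), `plane_dihedral` (degrees in [0, 90]).
#' @export
cofactor_geometry <- function(s, fmn_group = "FMN", heme_group = "HEM") {
  for (g in c(fmn_group, heme_group)) {
    if (!g %in% names(s$cofactor_groups)) {
      stop("structure has no cofactor group '", g, "'")
    }
  }
  fmn_idx <- s$cofactor_groups[[fmn_group]]
  hem_idx <- s$cofactor_groups[[heme_group]]
  fmn_name <- s$atoms$elety[fmn_idx]
  hem_name <- s$atoms$elety[hem_idx]
  fe <- hem_idx[hem_name == "FE"]
  if (length(fe) != 1L) stop("heme group lacks an FE atom")
  methyls <- fmn_idx[fmn_name %in% c("C7M", "C8M")]
  if (length(methyls) == 0L) stop("FMN group lacks methyl carbons C7M/C8M")
  fmn_ring <- fmn_idx[fmn_name %in% .fmn_ring_atoms]
  hem_ring <- hem_idx[hem_name %in% .heme_ring_atoms]
  if (length(fmn_ring) < 3L) stop("FMN group lacks isoalloxazine ring atoms")
  if (length(hem_ring) < 3L) stop("heme group lacks porphyrin ring atoms")
  fe_xyz <- coords(s, fe)[1L, ]
  m_xyz <- coords(s, methyls)
  methyl_to_iron <- stats::setNames(
    sqrt(rowSums(sweep(m_xyz, 2, fe_xyz)^2)),
    s$atoms$elety[methyls]
  )
  # heme-ligating cysteine: the S-gamma closest to the iron
  sg <- which(!s$atoms$het & s$atoms$resid == "CYS" & s$atoms$elety == "SG")
  if (length(sg) > 0L) {
    dsg <- sqrt(rowSums(sweep(coords(s, sg), 2, fe_xyz)^2))
    sg_xyz <- coords(s, sg[which.min(dsg)])[1L, ]
    methyl_to_cys_thiol <- stats::setNames(
      sqrt(rowSums(sweep(m_xyz, 2, sg_xyz)^2)),
      s$atoms$elety[methyls]
    )
  } else {
    methyl_to_cys_thiol <- stats::setNames(rep(NA_real_, length(methyls)),
                                           s$atoms$elety[methyls])
  }
  n1 <- .plane_normal(coords(s, fmn_ring))
  n2 <- .plane_normal(coords(s, hem_ring))
  cosang <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  dihedral <- acos(min(max(cosang, -1), 1)) * 180 / pi
  structure(
    list(methyl_to_iron = methyl_to_iron,
         methyl_to_cys_thiol = methyl_to_cys_thiol,
         plane_dihedral = dihedral),
    class = "cofactor_geometry"
  )
}

#' @export
print.cofactor_geometry <- function(x, ...) {
  cat("cofactor_geometry\n")
  cat("  methyl -> Fe:   ",
      paste(sprintf("%s %.2f A", names(x$methyl_to_iron), x$methyl_to_iron),
            collapse = ", "), "\n", sep = "")
  cat("  methyl -> SG:   ",
      paste(sprintf("%s %.2f A", names(x$methyl_to_cys_thiol),
                    x$methyl_to_cys_thiol), collapse = ", "), "\n", sep = "")
  cat(sprintf("  plane dihedral: %.1f deg\n", x$plane_dihedral))
  invisible(x)
}
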