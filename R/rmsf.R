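# Per-residue RMSF from multi-frame trajectories, replica averaging, and
# caffeine-bound-minus-free differences restricted to interface residues.

#' Construct a trajectory object
#'
#' @param topology `cpr_structure` giving atom identities.
#' @param frames numeric array n_frames x n_atoms x 3 (Angstrom); n_frames
#'   >= 2 and the atom count must match the topology.
#' @param frame_interval time between frames (metadata only, any unit).
#' @param label free-text label, e.g. `"caffeine-free"` or `"pose-1"`.
#' @return object of class `cpr_trajectory`.
#' @export
new_trajectory <- function(topology, frames, frame_interval = NA_real_,
                           label = "") {
  if (!inherits(topology, "cpr_structure")) {
    stop("topology must be a cpr_structure")
  }
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L) {
    stop("frames must be an n_frames x n_atoms x 3 array")
  }
  if (dim(frames)[2] != nrow(topology$atoms)) {
    stop("frames have ", dim(frames)[2], " atoms but topology has ",
         nrow(topology$atoms))
  }
  if (dim(frames)[1] < 2L) stop("need at least 2 frames")
  if (!all(is.finite(frames))) stop("non-finite frame coordinates")
  structure(
    list(topology = topology, frames = frames,
         frame_interval = frame_interval, label = label),
    class = "cpr_trajectory"
  )
}

#' @export
print.cpr_trajectory <- function(x, ...) {
  cat("cpr_trajectory: ", dim(x$frames)[1], " frames x ", dim(x$frames)[2],
      " atoms", if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n",
      sep = "")
  invisible(x)
}

# internal: atom indices for a named selection
.selection_idx <- function(topology, selection = c("backbone", "calpha",
                                                   "all")) {
  selection <- match.arg(selection)
  idx <- switch(selection,
    backbone = .backbone_idx(topology),
    calpha = .calpha_idx(topology),
    all = seq_len(nrow(topology$atoms))
  )
  if (length(idx) == 0L) stop("empty atom selection '", selection, "'")
  idx
}

#' Rigidly align every frame onto a reference frame
#'
#' Each frame is superposed (Kabsch) onto the chosen reference frame using
#' the given atom selection; the transform is applied to all atoms of the
#' frame. A standard pre-step before RMSF so that global tumbling does not
#' inflate fluctuations.
#'
#' @param t `cpr_trajectory`.
#' @param reference frame index used as the reference (default 1).
#' @param selection atoms used for the fit: `"backbone"` (N, CA, C, O;
#'   default), `"calpha"` or `"all"`.
#' @return aligned `cpr_trajectory`.
#' @export
align_trajectory <- function(t, reference = 1L, selection = "backbone") {
  idx <- .selection_idx(t$topology, selection)
  nf <- dim(t$frames)[1]
  if (reference < 1L || reference > nf) stop("reference frame out of range")
  ref <- t$frames[reference, idx, , drop = TRUE]
  out <- t$frames
  for (f in seq_len(nf)) {
    tf <- kabsch_superpose(out[f, idx, , drop = TRUE], ref)
    out[f, , ] <- apply_transform(out[f, , , drop = TRUE], tf)
  }
  t$frames <- out
  t
}

# internal: per-atom RMSF of one trajectory: sqrt(mean_t |r_t - <r>|^2)
.atom_rmsf <- function(t) {
  nf <- dim(t$frames)[1]
  mean_xyz <- apply(t$frames, c(2, 3), mean)
  dev2 <- matrix(0, nrow = dim(t$frames)[2], ncol = nf)
  for (f in seq_len(nf)) {
    dev2[, f] <- rowSums((t$frames[f, , , drop = TRUE] - mean_xyz)^2)
  }
  sqrt(rowMeans(dev2))
}

#' Per-residue RMSF profile, averaged over replicas
#'
#' Per atom, RMSF is the root-mean-square deviation from that atom's
#' time-mean position; per residue, the unweighted mean over the residue's
#' atoms in the chosen set; per profile, the mean over replicas. Hetero
#' residues are excluded. Trajectories should be aligned first (see
#' [align_trajectory()]).
#'
#' @param replicas a `cpr_trajectory` or list of replicas sharing one
#'   topology.
#' @param atom_set `"backbone"` (N, CA, C, O) or `"all"` heavy atoms.
#' @return data.frame (chain, resno, insert, resid, rmsf) with attributes
#'   `atom_set`, `n_replicas` and `label` (from the first replica).
#' @export
rmsf_profile <- function(replicas, atom_set = c("backbone", "all")) {
  atom_set <- match.arg(atom_set)
  if (inherits(replicas, "cpr_trajectory")) replicas <- list(replicas)
  if (length(replicas) == 0L) stop("no replicas given")
  topo <- replicas[[1L]]$topology
  for (r in replicas[-1L]) {
    if (!identical(r$topology$atoms[, c("chain", "resno", "insert", "elety")],
                   topo$atoms[, c("chain", "resno", "insert", "elety")])) {
      stop("replicas do not share a topology")
    }
  }
  a <- topo$atoms
  in_set <- !a$het & a$resid %in% names(aa_sidechain_atoms) & a$elesy != "H"
  if (atom_set == "backbone") in_set <- in_set & a$elety %in% c("N", "CA",
                                                                "C", "O")
  if (!any(in_set)) stop("no atoms in atom set '", atom_set, "'")
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  per_rep <- vapply(replicas, function(t) {
    atom_vals <- .atom_rmsf(t)
    tapply(atom_vals[in_set], key[in_set], mean)
  }, numeric(length(unique(key[in_set]))))
  per_rep <- matrix(per_rep, ncol = length(replicas))
  res_keys <- sort(unique(key[in_set])) # tapply sorts by key
  vals <- rowMeans(per_rep)
  first <- match(res_keys, key)
  out <- data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], rmsf = vals, stringsAsFactors = FALSE
  )
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  attr(out, "atom_set") <- atom_set
  attr(out, "n_replicas") <- length(replicas)
  attr(out, "label") <- sub("-rep[0-9]+$", "", replicas[[1L]]$label)
  out
}

#' Bound-minus-free RMSF difference
#'
#' Signed per-residue difference `bound - free`: positive values mean the
#' residue is more mobile in the bound (e.g. caffeine-bound) simulations.
#' Defined exactly on the residues common to both profiles; both profiles
#' must use the same atom set.
#'
#' @param bound,free RMSF profiles from [rmsf_profile()].
#' @return data.frame (chain, resno, insert, resid, rmsf_bound, rmsf_free,
#'   difference) with attributes `atom_set` and `bound_label`.
#' @export
rmsf_difference <- function(bound, free) {
  if (!identical(attr(bound, "atom_set"), attr(free, "atom_set"))) {
    stop("profiles use different atom sets (",
         attr(bound, "atom_set"), " vs ", attr(free, "atom_set"), ")")
  }
  kb <- paste(bound$chain, bound$resno, bound$insert, sep = "\r")
  kf <- paste(free$chain, free$resno, free$insert, sep = "\r")
  shared <- intersect(kb, kf)
  if (length(shared) == 0L) stop("profiles share no residues")
  ib <- match(shared, kb)
  if_ <- match(shared, kf)
  out <- data.frame(
    chain = bound$chain[ib], resno = bound$resno[ib],
    insert = bound$insert[ib], resid = bound$resid[ib],
    rmsf_bound = bound$rmsf[ib], rmsf_free = free$rmsf[if_],
    difference = bound$rmsf[ib] - free$rmsf[if_],
    stringsAsFactors = FALSE
  )
  attr(out, "atom_set") <- attr(bound, "atom_set")
  attr(out, "bound_label") <- attr(bound, "label")
  out
}

#' Restrict an RMSF difference to interface residues
#'
#' Filters the difference profile to the consensus interface residues of a
#' pose ensemble (optionally including the secondary, below-consensus
#' tier).
#'
#' @param d RMSF difference from [rmsf_difference()].
#' @param consensus `consensus_contacts` object.
#' @param include_secondary also keep secondary-tier residues.
#' @return filtered data.frame (same columns and attributes as `d`).
#' @export
restrict_to_interface <- function(d, consensus, include_secondary = FALSE) {
  res <- consensus$residues
  keep <- res$consensus
  if (include_secondary) keep <- keep | res$secondary
  res <- res[keep, , drop = FALSE]
  kd <- paste(d$chain, d$resno, d$insert, sep = "\r")
  kr <- paste(res$chain, res$resno, res$insert, sep = "\r")
  sel <- kd %in% kr
  if (!any(sel)) {
    stop("no overlap between the RMSF difference (", nrow(d),
         " residues) and the interface set (", nrow(res), " residues)")
  }
  out <- d[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "atom_set") <- attr(d, "atom_set")
  attr(out, "bound_label") <- attr(d, "bound_label")
  out
}
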