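# Synthetic structures, relaxation perturbations, trajectories and assay
# tables. These generators carry the statistical structure the analyses
# assume (relaxation noise on side chains, targeted induced-fit
# displacements, per-residue Gaussian positional fluctuation, metabolite
# tables with stated WT fractions), so every pipeline stage is testable
# without external modelling software. All are pure functions of their
# arguments and a seed.

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# straight-chain pseudo side chains with standard residue names, so
# sidechain_atoms() works unchanged on toy structures
.toy_sidechain_names <- list(
  ALA = "CB",
  LEU = c("CB", "CG", "CD1", "CD2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
)

# internal: atom rows for one toy residue
.toy_residue <- function(chain, resno, resid, origin_y, bb_x, sc_dir) {
  jig <- function(i) c(0.4 * sin(i * 2.1), 0.4 * cos(i * 1.3))
  j <- jig(resno)
  bb <- data.frame(
    elety = c("N", "CA", "C", "O"),
    x = bb_x + c(0.2, j[1], -0.2, -0.2),
    y = origin_y + c(0.9, 0, -0.9, -0.9),
    z = c(0.8, j[2], -0.6, -1.8)
  )
  scn <- .toy_sidechain_names[[resid]]
  sc <- data.frame(
    elety = scn,
    x = bb_x + sc_dir * 1.5 * seq_along(scn),
    y = origin_y,
    z = 0
  )
  a <- rbind(bb, sc)
  data.frame(
    chain = chain, resno = resno, insert = "", resid = resid,
    elety = a$elety, elesy = substr(a$elety, 1, 1),
    x = a$x, y = a$y, z = a$z, het = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate a two-domain toy complex
#'
#' Builds two mini-domains (chains A and B) facing each other across a gap.
#' The first residue of each domain is an alanine whose CB atoms face each
#' other at exactly `gap` Angstrom (the guaranteed contact or non-contact
#' pair); all other side chains point away from the interface, so their
#' cross-domain distances exceed 5 Angstrom. Deterministic given `seed`,
#' which shuffles the residue composition of positions 2..n.
#'
#' @param n_res residues per domain (>= 3).
#' @param composition pool of toy residue types (subset of ALA/LEU/TYR:
#'   1-, 4- and 8-atom side chains).
#' @param gap Angstrom between the facing CB atoms (> 0).
#' @param seed integer.
#' @return list with `$structure` (`cpr_structure`), `$partition`
#'   (`c(A = "CYP", B = "FD")`) and `$seed`.
#' @export
make_toy_complex <- function(n_res = 4, composition = c("ALA", "LEU", "TYR"),
                             gap = 2.5, seed = 1) {
  if (n_res < 3L) stop("need at least 3 residues per domain")
  if (gap <= 0) stop("gap must be positive")
  if (!all(composition %in% names(.toy_sidechain_names))) {
    stop("composition must be drawn from ",
         paste(names(.toy_sidechain_names), collapse = ", "))
  }
  d_backbone <- gap + 2 * 1.5 # facing ALA CB atoms sit 1.5 A off each backbone
  resids <- .with_seed(seed, list(
    a = sample(composition, n_res - 1L, replace = TRUE),
    b = sample(composition, n_res - 1L, replace = TRUE)
  ))
  rows <- list(.toy_residue("A", 1L, "ALA", 0, 0, +1),
               .toy_residue("B", 1L, "ALA", 0, d_backbone, -1))
  for (i in seq_len(n_res - 1L)) {
    y <- 5 * i
    rows[[length(rows) + 1L]] <- .toy_residue("A", i + 1L, resids$a[i], y, 0, -1)
    rows[[length(rows) + 1L]] <- .toy_residue("B", i + 1L, resids$b[i], y,
                                              d_backbone, +1)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  s <- new_structure(atoms, title = sprintf("toy complex (seed %d)", seed))
  list(structure = s, partition = c(A = "CYP", B = "FD"), seed = seed)
}

#' Perturb a structure: side-chain noise plus targeted displacements
#'
#' Adds i.i.d. Gaussian noise (sd `noise_sd`, per coordinate) to heavy
#' side-chain atoms of standard residues and applies rigid displacement
#' vectors to the side chains of targeted residues. Backbone atoms are
#' never touched. Stands in for a relaxation step whose noise the
#' induced-fit baseline subtraction is designed to remove.
#'
#' @param s `cpr_structure`.
#' @param noise_sd Gaussian sd in Angstrom (>= 0).
#' @param displacements optional data.frame (chain, resno, insert optional,
#'   dx, dy, dz) of targeted side-chain displacements.
#' @param applied_to `"both"`, `"complex-only"` or `"free-only"`: which
#'   ensemble forms receive the targeted displacements (noise is always
#'   applied).
#' @param seed integer.
#' @param form the ensemble form being perturbed (`"complex"` or a domain
#'   label); `NULL` (standalone use) applies displacements unconditionally.
#' @return perturbed `cpr_structure`.
#' @export
perturb <- function(s, noise_sd = 0, displacements = NULL,
                    applied_to = c("both", "complex-only", "free-only"),
                    seed = 1, form = NULL) {
  applied_to <- match.arg(applied_to)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mask <- .sidechain_mask(s)
  if (noise_sd > 0 && any(mask)) {
    xyz <- coords(s, which(mask))
    noise <- .with_seed(seed, matrix(stats::rnorm(length(xyz), 0, noise_sd),
                                     ncol = 3))
    s <- set_coords(s, xyz + noise, which(mask))
  }
  apply_disp <- is.null(form) ||
    applied_to == "both" ||
    (applied_to == "complex-only" && identical(form, "complex")) ||
    (applied_to == "free-only" && !identical(form, "complex"))
  if (!is.null(displacements) && apply_disp) {
    if (is.null(displacements$insert)) displacements$insert <- ""
    for (i in seq_len(nrow(displacements))) {
      idx <- sidechain_atoms(s, displacements$chain[i], displacements$resno[i],
                             displacements$insert[i])
      if (length(idx) == 0L) next # glycine target: nothing to move
      shift <- c(displacements$dx[i], displacements$dy[i], displacements$dz[i])
      s <- set_coords(s, sweep(coords(s, idx), 2, shift, "+"), idx)
    }
  }
  s
}

#' Generate synthetic trajectories around a topology
#'
#' Frames are the topology coordinates plus i.i.d. Gaussian displacement
#' per atom and frame, with a residue-specific sd. Expected per-atom RMSF
#' is therefore `sqrt(3) * sd`. Replicas differ only by a seed offset.
#'
#' @param topology `cpr_structure`.
#' @param sd default fluctuation sd in Angstrom.
#' @param residue_sd optional data.frame (chain, resno, insert optional, sd)
#'   overriding `sd` per residue.
#' @param n_frames frames per replica (>= 2).
#' @param n_replicas number of replicas.
#' @param label trajectory label (e.g. `"caffeine-free"`).
#' @param seed integer.
#' @return list of `cpr_trajectory` objects (see [new_trajectory()]).
#' @export
make_trajectories <- function(topology, sd = 0.1, residue_sd = NULL,
                              n_frames = 100, n_replicas = 4,
                              label = "", seed = 1) {
  if (n_frames < 2L) stop("need at least 2 frames")
  if (sd < 0) stop("sd must be >= 0")
  a <- topology$atoms
  atom_sd <- rep(sd, nrow(a))
  if (!is.null(residue_sd)) {
    if (is.null(residue_sd$insert)) residue_sd$insert <- ""
    if (any(residue_sd$sd < 0)) stop("residue sd must be >= 0")
    key <- paste(a$chain, a$resno, a$insert)
    rkey <- paste(residue_sd$chain, residue_sd$resno, residue_sd$insert)
    if (!all(rkey %in% key)) {
      stop("residue_sd names residues absent from the topology")
    }
    hit <- match(key, rkey)
    atom_sd[!is.na(hit)] <- residue_sd$sd[hit[!is.na(hit)]]
  }
  base <- coords(topology)
  lapply(seq_len(n_replicas), function(r) {
    frames <- .with_seed(seed + 7919L * r, {
      fr <- array(0, dim = c(n_frames, nrow(base), 3))
      for (f in seq_len(n_frames)) {
        # column-major fill recycles atom_sd once per coordinate column,
        # so each atom keeps its own sd on x, y and z
        fr[f, , ] <- base + matrix(stats::rnorm(length(base), 0, atom_sd),
                                   ncol = 3)
      }
      fr
    })
    new_trajectory(topology, frames,
                   label = if (nzchar(label)) sprintf("%s-rep%d", label, r)
                           else sprintf("rep%d", r))
  })
}

#' Generate a synthetic membrane-fraction assay table
#'
#' Emulates the characterization table of CPR-variant/CYP1A2 membrane
#' fractions: wild-type rows draw their metabolite fractions around
#' `wt_fractions`, variant rows apply multiplicative effects to fractions
#' (renormalized) and/or consumption, and caffeine consumption is defined
#' as the metabolite sum, so mass balance holds exactly by construction.
#'
#' @param n_variants number of variant rows.
#' @param wt_fractions named fractions (theophylline, theobromine,
#'   paraxanthine) summing to 1; default is the wild-type caffeine
#'   regiospecificity profile (7.8, 6.2, 86.0 percent).
#' @param consumption_mean mean caffeine consumption in uM.
#' @param effects named list: variant id -> named multipliers among
#'   `theophylline`, `theobromine`, `paraxanthine` (on fractions) and
#'   `consumption`. Variants not listed get no effect.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param n_wt number of wild-type reference rows.
#' @param seed integer.
#' @return data.frame in the membrane-fraction table layout (see
#'   [read_membrane_table()]).
#' @export
make_metabolite_table <- function(n_variants = 10,
                                  wt_fractions = c(theophylline = 0.078,
                                                   theobromine = 0.062,
                                                   paraxanthine = 0.860),
                                  consumption_mean = 10,
                                  effects = NULL, cv = 0.05, n_wt = 3,
                                  seed = 1) {
  mets <- c("theophylline", "theobromine", "paraxanthine")
  if (cv < 0) stop("cv must be >= 0")
  if (abs(sum(wt_fractions) - 1) > 1e-9) stop("wt_fractions must sum to 1")
  wt_fractions <- wt_fractions[mets]
  for (eff in effects) {
    if (any(eff < 0)) stop("effects must be non-negative multipliers")
  }
  wt_ids <- paste0("WT_", LETTERS[seq_len(n_wt)])
  var_ids <- sprintf("VAR%02d", seq_len(n_variants))
  if (!is.null(names(effects))) {
    k <- min(length(effects), n_variants)
    var_ids[seq_len(k)] <- names(effects)[seq_len(k)]
  }
  ids <- c(wt_ids, var_ids)
  .with_seed(seed, {
    rows <- lapply(seq_along(ids), function(i) {
      id <- ids[i]
      is_wt <- id %in% wt_ids
      fr <- wt_fractions
      cons_mu <- consumption_mean
      if (!is_wt && !is.null(effects[[id]])) {
        eff <- effects[[id]]
        fe <- eff[names(eff) %in% mets]
        fr[names(fe)] <- fr[names(fe)] * fe
        fr <- fr / sum(fr)
        if ("consumption" %in% names(eff)) cons_mu <- cons_mu * eff[["consumption"]]
      }
      cons <- cons_mu * max(1 + stats::rnorm(1, 0, cv), 0.05)
      amounts <- cons * fr * pmax(1 + stats::rnorm(3, 0, cv), 0)
      data.frame(
        variant_id = id,
        cpr_region = if (is_wt) "wildtype" else "synthetic variant",
        wt_reference_id = if (is_wt) id else
          wt_ids[1L + (match(id, var_ids) - 1L) %% n_wt],
        cyp_content = 150 * max(1 + stats::rnorm(1, 0, cv), 0.05),
        cpr_content = 20 * max(1 + stats::rnorm(1, 0, cv), 0.05),
        stability_ratio = 1,
        caffeine_consumed = sum(amounts),
        theophylline = amounts[["theophylline"]],
        theobromine = amounts[["theobromine"]],
        paraxanthine = amounts[["paraxanthine"]],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    out
  })
}
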