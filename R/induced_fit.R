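# Induced-fit differential RMSD over relaxation ensembles.
#
# The procedure: a small set of representative complex poses is each split
# into the unchanged complex and its isolated domains; every split form is
# independently relaxed several times; after global C-alpha alignment, the
# per-residue normalized side-chain RMSD averaged over all complexed-vs-free
# pairs is corrected by the average intradomain (within-form) RMSD, leaving
# the side-chain rearrangement attributable to complex formation.

#' Identity relaxer backend
#'
#' Returns structures unchanged; useful for exercising the ensemble
#' machinery without noise.
#' @return relaxer function `(structure, seed, form) -> structure` with a
#'   `tag` attribute.
#' @export
relaxer_identity <- function() {
  f <- function(s, seed, form) s
  attr(f, "tag") <- "identity"
  f
}

#' Gaussian-noise relaxer backend
#'
#' A stochastic stand-in for a structure-relaxation program: adds i.i.d.
#' Gaussian noise to heavy side-chain atoms (backbone untouched) and,
#' optionally, targeted side-chain displacements restricted to particular
#' ensemble forms — the mechanism used to inject known induced-fit signals
#' into synthetic ensembles.
#'
#' @inheritParams perturb
#' @return relaxer function `(structure, seed, form) -> structure`.
#' @export
relaxer_noise <- function(noise_sd = 0.05, displacements = NULL,
                          applied_to = "both") {
  f <- function(s, seed, form) {
    perturb(s, noise_sd = noise_sd, displacements = displacements,
            applied_to = applied_to, seed = seed, form = form)
  }
  attr(f, "tag") <- sprintf("gaussian-noise sd=%g", noise_sd)
  f
}

#' Relaxer backend reading externally produced relaxed structures
#'
#' Adapter for real use, where relaxation is done by external software and
#' the relaxed poses are provided as PDB files. The callback receives
#' `(seed_index, form, relax_index)` and must return a file path.
#'
#' @param path_fun function `(seed_index, form, relax_index) -> file path`.
#' @return relaxer function; the structure argument is ignored, the file
#'   is read instead.
#' @export
relaxer_from_files <- function(path_fun) {
  f <- function(s, seed, form) {
    meta <- attr(seed, "member")
    read_structure(path_fun(meta$seed_index, form, meta$relax_index))
  }
  attr(f, "tag") <- "external-files"
  f
}

#' Build a relaxation ensemble from seed complex poses
#'
#' Each seed complex is split (see [split_complex()]) into the unchanged
#' complex plus one isolated structure per domain label, and every split
#' form is independently relaxed `n_relax` times. With 3 seeds and
#' `n_relax = 3` over complex + 2 domains this yields the canonical
#' 27-member (3 x 3 x 3) ensemble.
#'
#' @param seed_complexes list of `cpr_structure` complexes.
#' @param partition named chain -> domain label map (see [split_complex()]).
#' @param relaxer relaxer backend, e.g. [relaxer_noise()]; must be
#'   deterministic given its seed argument.
#' @param n_relax independent relaxations per (seed, form) (>= 1).
#' @param seed integer master seed; member seeds are derived from it.
#' @return object of class `relax_ensemble`: list with `$members` (list of
#'   structures), `$index` (data.frame seed_index, form, relax_index),
#'   `$partition`, `$forms`, `$relaxer_tag`.
#' @export
build_ensemble <- function(seed_complexes, partition, relaxer,
                           n_relax = 3, seed = 1) {
  if (n_relax < 1L) stop("n_relax must be >= 1")
  if (!is.list(seed_complexes)) seed_complexes <- list(seed_complexes)
  forms <- c("complex", unique(unname(partition)))
  members <- list()
  index <- NULL
  for (i in seq_along(seed_complexes)) {
    splits <- split_complex(seed_complexes[[i]], partition)
    for (f in seq_along(forms)) {
      form <- forms[f]
      base <- if (form == "complex") splits$complex else splits[[form]]
      for (j in seq_len(n_relax)) {
        member_seed <- (abs(as.numeric(seed)) * 97 + i * 100003 +
                          f * 1009 + j * 13) %% .Machine$integer.max
        attr(member_seed, "member") <- list(seed_index = i, relax_index = j)
        relaxed <- tryCatch(
          relaxer(base, member_seed, form),
          error = function(e) {
            stop("relaxer failed at seed ", i, ", form '", form,
                 "', relaxation ", j, ": ", conditionMessage(e))
          }
        )
        members[[length(members) + 1L]] <- relaxed
        index <- rbind(index, data.frame(
          seed_index = i, form = form, relax_index = j,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  structure(
    list(members = members, index = index, partition = partition,
         forms = forms, n_relax = n_relax, seed = seed,
         relaxer_tag = attr(relaxer, "tag") %||% "unknown"),
    class = "relax_ensemble"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.relax_ensemble <- function(x, ...) {
  cat("relax_ensemble: ", length(x$members), " members (",
      length(unique(x$index$seed_index)), " seeds x ",
      length(x$forms), " forms x ", x$n_relax, " relaxations), relaxer: ",
      x$relaxer_tag, "\n", sep = "")
  invisible(x)
}

# internal: ensemble members of one form, restricted to a domain when the
# form is the full complex; all aligned on C-alphas to `reference`
.domain_members <- function(e, form, domain, reference = NULL) {
  idx <- which(e$index$form == form)
  out <- lapply(idx, function(i) {
    m <- e$members[[i]]
    if (form == "complex") m <- .domain_structure(m, e$partition, domain)
    m
  })
  if (!is.null(reference)) out <- lapply(out, .prealign_calpha, a = reference)
  out
}

# internal: average per-residue profiles (matched on residue key)
.average_profiles <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  ref <- profiles[[1L]]
  key <- paste(ref$chain, ref$resno, ref$insert)
  acc <- matrix(0, nrow = nrow(ref), ncol = length(profiles))
  for (p in seq_along(profiles)) {
    pr <- profiles[[p]]
    m <- match(key, paste(pr$chain, pr$resno, pr$insert))
    if (any(is.na(m))) stop("profiles cover different residue sets")
    acc[, p] <- pr$value[m]
  }
  out <- ref
  out$value <- rowMeans(acc)
  out$n_pairs <- length(profiles)
  out
}

#' Inter-model (complexed vs. free) side-chain RMSD profile
#'
#' After aligning every structure on C-alphas to the reference (the
#' domain part of the first complex member), averages the per-residue
#' normalized side-chain RMSD over all (complex member, isolated-domain
#' member) pairs.
#'
#' @param e `relax_ensemble`.
#' @param domain domain label (e.g. `"FD"` or `"CYP"`).
#' @param normalization passed to [per_residue_sidechain_rmsd()].
#' @return data.frame profile with columns chain, resno, insert, resid,
#'   n_atoms, value, n_pairs.
#' @export
intermodel_rmsd <- function(e, domain,
                            normalization = "per-atom-count") {
  if (!domain %in% e$forms) stop("unknown domain '", domain, "'")
  first_complex <- e$members[[which(e$index$form == "complex")[1L]]]
  reference <- .domain_structure(first_complex, e$partition, domain)
  cplx <- .domain_members(e, "complex", domain, reference)
  free <- .domain_members(e, domain, domain, reference)
  if (length(cplx) == 0L || length(free) == 0L) {
    stop("empty pair set for domain '", domain, "'")
  }
  profiles <- list()
  for (a in cplx) {
    for (b in free) {
      profiles[[length(profiles) + 1L]] <-
        per_residue_sidechain_rmsd(a, b, prealign = "none",
                                   normalization = normalization)
    }
  }
  .average_profiles(profiles)
}

#' Intradomain baseline side-chain RMSD profile
#'
#' Average normalized side-chain RMSD over all unordered pairs of members
#' within one relaxed form. This is the relaxation-noise floor subtracted
#' from the inter-model profile.
#'
#' @param e `relax_ensemble`.
#' @param form `"complex"` or a domain label.
#' @param domain when `form = "complex"`, the domain to restrict residues
#'   to (defaults to `form` otherwise).
#' @param normalization passed to [per_residue_sidechain_rmsd()].
#' @return data.frame profile as in [intermodel_rmsd()].
#' @export
intradomain_baseline <- function(e, form, domain = NULL,
                                 normalization = "per-atom-count") {
  if (!form %in% e$forms) stop("unknown form '", form, "'")
  if (is.null(domain)) {
    domain <- if (form == "complex") stop("domain required for form 'complex'")
              else form
  }
  first <- e$members[[which(e$index$form == form)[1L]]]
  reference <- if (form == "complex") {
    .domain_structure(first, e$partition, domain)
  } else {
    first
  }
  members <- .domain_members(e, form, domain, reference)
  if (length(members) < 2L) {
    stop("need at least 2 members of form '", form, "' for a baseline")
  }
  profiles <- list()
  for (i in seq_len(length(members) - 1L)) {
    for (j in seq(i + 1L, length(members))) {
      profiles[[length(profiles) + 1L]] <-
        per_residue_sidechain_rmsd(members[[i]], members[[j]],
                                   prealign = "none",
                                   normalization = normalization)
    }
  }
  .average_profiles(profiles)
}

#' Induced-fit differential RMSD profile
#'
#' The per-residue inter-model (complexed vs. free) average minus the
#' intradomain relaxation baseline. Residues whose side chains rearrange
#' on complex formation stand out as positive peaks; pure relaxation noise
#' cancels in expectation, so a null ensemble gives values scattered
#' around zero (they may be negative).
#'
#' @param e `relax_ensemble`.
#' @param domain domain label.
#' @param baseline which intradomain comparison to subtract: `"both"`
#'   (default: mean of the within-complex and within-free baselines),
#'   `"free"` or `"complex"`.
#' @param normalization passed to [per_residue_sidechain_rmsd()].
#' @return data.frame (chain, resno, insert, resid, n_atoms,
#'   differential_rmsd, intermodel, baseline, n_pairs, domain).
#' @export
differential_profile <- function(e, domain,
                                 baseline = c("both", "free", "complex"),
                                 normalization = "per-atom-count") {
  baseline <- match.arg(baseline)
  inter <- intermodel_rmsd(e, domain, normalization)
  base_free <- if (baseline != "complex") {
    intradomain_baseline(e, domain, domain, normalization)
  }
  base_cplx <- if (baseline != "free") {
    intradomain_baseline(e, "complex", domain, normalization)
  }
  key <- paste(inter$chain, inter$resno, inter$insert)
  base_val <- switch(baseline,
    free = base_free$value[match(key, paste(base_free$chain, base_free$resno,
                                            base_free$insert))],
    complex = base_cplx$value[match(key, paste(base_cplx$chain,
                                               base_cplx$resno,
                                               base_cplx$insert))],
    both = {
      vf <- base_free$value[match(key, paste(base_free$chain, base_free$resno,
                                             base_free$insert))]
      vc <- base_cplx$value[match(key, paste(base_cplx$chain, base_cplx$resno,
                                             base_cplx$insert))]
      (vf + vc) / 2
    }
  )
  data.frame(
    chain = inter$chain, resno = inter$resno, insert = inter$insert,
    resid = inter$resid, n_atoms = inter$n_atoms,
    differential_rmsd = inter$value - base_val,
    intermodel = inter$value, baseline = base_val,
    n_pairs = inter$n_pairs, domain = domain,
    stringsAsFactors = FALSE
  )
}
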