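# Relaxation ensembles and the induced-fit differential RMSD statistic

test_that("ensemble bookkeeping: forms, counts, determinism", {
  tc <- make_toy_complex(n_res = 4, seed = 1)
  e1 <- build_ensemble(list(tc$structure), tc$partition, relaxer_identity(),
                       n_relax = 1, seed = 5)
  expect_equal(length(e1$members), 3L) # complex + CYP + FD
  expect_setequal(unique(e1$index$form), c("complex", "CYP", "FD"))
  # identity relaxer: members equal the seed splits
  splits <- split_complex(tc$structure, tc$partition)
  expect_identical(e1$members[[which(e1$index$form == "FD")]]$atoms,
                   splits$FD$atoms)

  seeds3 <- lapply(1:3, function(i) make_toy_complex(n_res = 4,
                                                     seed = i)$structure)
  e27 <- build_ensemble(seeds3, tc$partition, relaxer_noise(0.05),
                        n_relax = 3, seed = 11)
  expect_equal(length(e27$members), 27L) # 3 seeds x 3 forms x 3 relaxations

  e27b <- build_ensemble(seeds3, tc$partition, relaxer_noise(0.05),
                         n_relax = 3, seed = 11)
  expect_identical(lapply(e27$members, coords), lapply(e27b$members, coords))
})

test_that("relaxer failures carry the member coordinates", {
  tc <- make_toy_complex(seed = 2)
  boom <- function(s, seed, form) {
    if (form == "FD") stop("backend exploded") else s
  }
  expect_error(
    build_ensemble(list(tc$structure), tc$partition, boom, n_relax = 2),
    "form 'FD', relaxation 1"
  )
})

test_that("identity relaxer on a rigid seed gives all-zero profiles", {
  tc <- make_toy_complex(n_res = 4, seed = 3)
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer_identity(),
                      n_relax = 2, seed = 1)
  inter <- intermodel_rmsd(e, "FD")
  expect_true(all(inter$value == 0))
  base <- intradomain_baseline(e, "FD")
  expect_true(all(base$value == 0))
  dp <- differential_profile(e, "FD")
  expect_true(all(dp$differential_rmsd == 0))
})

test_that("a complex-only displacement appears at its forced value", {
  tc <- make_toy_complex(n_res = 4, seed = 4)
  disp <- data.frame(chain = "B", resno = 2, dx = 1.0, dy = 0, dz = 0)
  relaxer <- relaxer_noise(noise_sd = 0, displacements = disp,
                           applied_to = "complex-only")
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer,
                      n_relax = 2, seed = 1)
  inter <- intermodel_rmsd(e, "FD")
  n_at <- inter$n_atoms[inter$resno == 2]
  expect_equal(inter$value[inter$resno == 2], 1.0 / n_at, tolerance = 1e-9)
  expect_equal(inter$value[inter$resno != 2], rep(0, 3), tolerance = 1e-12)
  # zero-noise baseline, so the differential equals the intermodel signal
  dp <- differential_profile(e, "FD")
  expect_equal(dp$differential_rmsd[dp$resno == 2], 1.0 / n_at,
               tolerance = 1e-9)
})

test_that("ensemble averages equal independent nested-loop oracles", {
  tc <- make_toy_complex(n_res = 4, seed = 5)
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer_noise(0.1),
                      n_relax = 3, seed = 7)
  # oracle: explicit loops over member pairs; alignment is a no-op here
  # because relaxation noise never touches backbone atoms, so compare raw
  # atom tables with the naive per-residue summation
  is_form <- function(f) which(e$index$form == f)
  fd_part <- function(i) {
    m <- e$members[[i]]
    if (e$index$form[i] == "complex") {
      new_structure(m$atoms[m$atoms$chain == "B", ])
    } else m
  }
  cplx <- is_form("complex")
  free <- is_form("FD")
  acc <- NULL
  for (i in cplx) {
    for (j in free) {
      pr <- naive_sidechain_rmsd(fd_part(i)$atoms, fd_part(j)$atoms)
      acc <- if (is.null(acc)) pr else {
        stopifnot(all(acc$resno == pr$resno))
        transform(acc, value = value + pr$value)
      }
    }
  }
  acc$value <- acc$value / (length(cplx) * length(free))
  inter <- intermodel_rmsd(e, "FD")
  m <- match(paste(inter$chain, inter$resno), paste(acc$chain, acc$resno))
  expect_equal(inter$value, acc$value[m], tolerance = 1e-9)
  expect_equal(unique(inter$n_pairs), length(cplx) * length(free))

  # intradomain baseline against an unordered-pair loop
  acc2 <- NULL
  npair <- 0
  for (a in seq_along(free)) {
    for (b in seq_along(free)) {
      if (b <= a) next
      pr <- naive_sidechain_rmsd(fd_part(free[a])$atoms, fd_part(free[b])$atoms)
      acc2 <- if (is.null(acc2)) pr else transform(acc2, value = value + pr$value)
      npair <- npair + 1
    }
  }
  acc2$value <- acc2$value / npair
  base <- intradomain_baseline(e, "FD")
  m2 <- match(paste(base$chain, base$resno), paste(acc2$chain, acc2$resno))
  expect_equal(base$value, acc2$value[m2], tolerance = 1e-9)
})

test_that("null ensembles give baseline-centred profiles at several depths", {
  tc <- make_toy_complex(n_res = 6, seed = 6)
  for (n_relax in c(2, 3, 5)) {
    e <- build_ensemble(list(tc$structure), tc$partition, relaxer_noise(0.05),
                        n_relax = n_relax, seed = 100 + n_relax)
    dp <- differential_profile(e, "FD")
    se <- stats::sd(dp$differential_rmsd) / sqrt(nrow(dp))
    expect_lt(abs(mean(dp$differential_rmsd)), 3 * se + 1e-12)
  }
})

test_that("injected displacements dominate the profile ranking", {
  tc <- make_toy_complex(n_res = 6, seed = 8)
  targets <- data.frame(chain = "B", resno = c(2, 5),
                        dx = c(0.8, 0), dy = c(0, 0.9), dz = 0)
  relaxer <- relaxer_noise(noise_sd = 0.05, displacements = targets,
                           applied_to = "complex-only")
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer,
                      n_relax = 3, seed = 9)
  dp <- differential_profile(e, "FD")
  top2 <- dp$resno[order(-abs(dp$differential_rmsd))][1:2]
  expect_setequal(top2, c(2, 5))
  # peak within 10% of the noise-free forced value
  n_at <- dp$n_atoms[dp$resno == 2]
  expect_equal(dp$differential_rmsd[dp$resno == 2], 0.8 / n_at,
               tolerance = 0.1)
})

test_that("the differential profile is invariant to a global rigid motion", {
  tc <- make_toy_complex(n_res = 4, seed = 10)
  relaxer <- relaxer_noise(0.08)
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer,
                      n_relax = 2, seed = 12)
  dp <- differential_profile(e, "FD")
  R <- random_rotation(55)
  e_mov <- e
  e_mov$members <- lapply(e$members, rigid_move, R = R, shift = c(3, -7, 1))
  dp_mov <- differential_profile(e_mov, "FD")
  expect_equal(dp_mov$differential_rmsd, dp$differential_rmsd,
               tolerance = 1e-8)
})

test_that("baseline variants and error paths behave", {
  tc <- make_toy_complex(n_res = 4, seed = 13)
  e <- build_ensemble(list(tc$structure), tc$partition, relaxer_noise(0.05),
                      n_relax = 2, seed = 2)
  for (b in c("both", "free", "complex")) {
    dp <- differential_profile(e, "FD", baseline = b)
    expect_equal(nrow(dp), 4L)
  }
  e1 <- build_ensemble(list(tc$structure), tc$partition, relaxer_noise(0.05),
                       n_relax = 1, seed = 2)
  expect_error(intradomain_baseline(e1, "FD"), "at least 2")
  expect_error(intermodel_rmsd(e, "nope"), "unknown domain")
})
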