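# Kabsch superposition, per-residue side-chain RMSD, cofactor grafting

rot_z90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)

test_that("superposing a set onto itself gives zero rmsd and identity", {
  set.seed(11)
  pts <- matrix(rnorm(30), ncol = 3)
  tf <- kabsch_superpose(pts, pts)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-8)
})

test_that("rigid motions are recovered exactly", {
  set.seed(12)
  ref <- matrix(rnorm(24), ncol = 3)
  mobile <- sweep(ref %*% t(rot_z90), 2, c(1, 2, 3), "+")
  tf <- kabsch_superpose(mobile, ref)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(mobile, tf), ref, tolerance = 1e-8)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
})

test_that("kabsch equals the brute-force rotation-grid minimum", {
  ref <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2),
                ncol = 3, byrow = TRUE)
  mobile <- ref
  mobile[4, ] <- mobile[4, ] + c(0.3, -0.3, 0.2) # ~0.5 A perturbation
  mobile <- sweep(mobile %*% t(rot_z90), 2, c(-1, 4, 0.5), "+")
  tf <- kabsch_superpose(mobile, ref)
  oracle <- grid_superpose(mobile, ref)
  expect_equal(tf$rmsd, oracle$rmsd, tolerance = 1e-4)
  # and never worse than the unaligned RMSD
  expect_lte(tf$rmsd, sqrt(mean(rowSums((mobile - ref)^2))))
})

test_that("kabsch agrees with bio3d's least-squares fit", {
  set.seed(13)
  ref <- matrix(rnorm(36), ncol = 3)
  mobile <- ref + matrix(rnorm(36, sd = 0.2), ncol = 3)
  tf <- kabsch_superpose(mobile, ref)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mobile)))
  )
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(tf$rmsd, rmsd_bio3d, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 3, 3)), "size")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

.two_atom_structure <- function(shift = 0) {
  names <- c("N", "CA", "C", "O", "CB", "OG")
  data.frame(chain = "A", resno = 1L, insert = "", resid = "SER",
             elety = names, elesy = substr(names, 1, 1),
             x = c(0.3, 0, -0.4, -0.4, 1.5, 2.9),
             y = c(1, 0, -0.9, -0.9, 0, 0) + c(0, 0, 0, 0, shift, shift),
             z = c(0.8, 0, -0.6, -1.8, 0, 0), het = FALSE,
             stringsAsFactors = FALSE) |> new_structure()
}

test_that("per-residue value is RMSD divided by the atom count", {
  a <- .two_atom_structure(0)
  b <- .two_atom_structure(0.2) # both side-chain atoms displaced 0.2 A
  pr <- per_residue_sidechain_rmsd(a, b, prealign = "none")
  expect_equal(pr$n_atoms, 2L)
  expect_equal(pr$value, 0.2 / 2, tolerance = 1e-12)
  # alternative normalization: mean per-atom displacement
  pr2 <- per_residue_sidechain_rmsd(a, b, prealign = "none",
                                    normalization = "mean-displacement")
  expect_equal(pr2$value, 0.2, tolerance = 1e-12)
  # identical structures give zero
  expect_equal(per_residue_sidechain_rmsd(a, a, prealign = "none")$value, 0)
})

test_that("profiles match a naive per-atom oracle and are symmetric", {
  tc <- make_toy_complex(n_res = 5, seed = 21)
  a <- tc$structure
  b <- perturb(a, noise_sd = 0.3, seed = 99)
  pr <- per_residue_sidechain_rmsd(a, b, prealign = "none")
  oracle <- naive_sidechain_rmsd(a$atoms, b$atoms)
  m <- match(paste(pr$chain, pr$resno, pr$insert),
             paste(oracle$chain, oracle$resno, oracle$insert))
  expect_false(anyNA(m))
  expect_equal(pr$value, oracle$value[m], tolerance = 1e-9)
  rev <- per_residue_sidechain_rmsd(b, a, prealign = "none")
  expect_equal(rev$value, pr$value, tolerance = 1e-12)
})

test_that("profile with C-alpha prealign is invariant to a common rigid motion", {
  tc <- make_toy_complex(n_res = 4, seed = 22)
  a <- tc$structure
  b <- perturb(a, noise_sd = 0.2, seed = 5)
  base <- per_residue_sidechain_rmsd(a, b, prealign = "calpha")
  R <- random_rotation(31)
  moved <- per_residue_sidechain_rmsd(a, rigid_move(b, R, c(4, -2, 9)),
                                      prealign = "calpha")
  expect_equal(moved$value, base$value, tolerance = 1e-8)
})

test_that("atom-set mismatches are reported with the residue", {
  a <- .two_atom_structure(0)
  b <- a
  b$atoms <- b$atoms[b$atoms$elety != "OG", ]
  expect_error(per_residue_sidechain_rmsd(a, new_structure(b$atoms),
                                          prealign = "none"),
               "A:1")
})

.donor_with_fmn <- function() {
  tc <- make_toy_complex(n_res = 4, seed = 41)
  fmn <- data.frame(
    chain = "F", resno = 900L, insert = "", resid = "FMN",
    elety = c("N5", "N10", "C4A", "C10"), elesy = c("N", "N", "C", "C"),
    x = c(3, 4, 3.5, 4.5), y = c(10, 10.5, 11, 9.5), z = c(2, 2.5, 1.5, 2),
    het = TRUE, stringsAsFactors = FALSE
  )
  new_structure(rbind(tc$structure$atoms, fmn))
}

test_that("grafting with model = donor leaves the cofactor in place", {
  donor <- .donor_with_fmn()
  model <- new_structure(donor$atoms[!donor$atoms$het, ])
  anchors <- data.frame(chain = "A", resno = 1:3)
  out <- graft_cofactor(model, donor, "FMN", anchors)
  expect_equal(coords(out, out$cofactor_groups$FMN),
               coords(donor, donor$cofactor_groups$FMN), tolerance = 1e-6)
  # protein atoms untouched
  expect_identical(out$atoms[seq_len(nrow(model$atoms)), ], model$atoms)
})

test_that("grafting is equivariant under rigid motion of the model", {
  donor <- .donor_with_fmn()
  R <- random_rotation(7)
  shift <- c(5, -3, 2)
  model <- new_structure(
    rigid_move(new_structure(donor$atoms[!donor$atoms$het, ]), R, shift)$atoms
  )
  anchors <- data.frame(chain = "A", resno = 1:4)
  out <- graft_cofactor(model, donor, "FMN", anchors)
  expected <- sweep(coords(donor, donor$cofactor_groups$FMN) %*% t(R), 2,
                    shift, "+")
  expect_equal(coords(out, out$cofactor_groups$FMN), expected,
               tolerance = 1e-6)
})

test_that("grafting under anchor noise matches the rotation-grid oracle", {
  donor <- .donor_with_fmn()
  model0 <- new_structure(donor$atoms[!donor$atoms$het, ])
  model <- rigid_move(model0, random_rotation(9), c(1, 2, -1))
  # jitter the anchor C-alphas so the fit is non-trivial
  set.seed(17)
  ca <- which(model$atoms$elety == "CA")
  model <- set_coords(model, coords(model, ca) +
                        matrix(rnorm(3 * length(ca), sd = 0.1), ncol = 3), ca)
  anchors <- data.frame(chain = c("A", "A", "A", "B"), resno = c(1, 2, 3, 1))
  out <- graft_cofactor(model, donor, "FMN", anchors)
  ca_of <- function(s, df) {
    idx <- integer(nrow(df))
    for (i in seq_len(nrow(df))) {
      ri <- which(s$atoms$chain == df$chain[i] & s$atoms$resno == df$resno[i] &
                    s$atoms$elety == "CA")
      idx[i] <- ri
    }
    coords(s, idx)
  }
  oracle <- grid_superpose(ca_of(donor, anchors), ca_of(model, anchors))
  expected <- oracle$transform(coords(donor, donor$cofactor_groups$FMN))
  expect_equal(coords(out, out$cofactor_groups$FMN), expected,
               tolerance = 1e-3)
})

test_that("missing cofactor or anchors are rejected", {
  donor <- .donor_with_fmn()
  model <- new_structure(donor$atoms[!donor$atoms$het, ])
  expect_error(graft_cofactor(model, donor, "HEM", data.frame(chain = "A",
                                                              resno = 1:3)),
               "no cofactor group")
  expect_error(graft_cofactor(model, donor, "FMN",
                              data.frame(chain = "A", resno = c(1, 2, 99))),
               "anchor")
})
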