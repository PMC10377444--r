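# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's computation paths: superposition
# by brute-force rotation-grid search, averaging by explicit nested loops,
# contacts by an all-atom double loop.

# --- brute-force rigid superposition ---------------------------------------

.euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# minimum RMSD of mobile onto reference over proper rotations, by coarse
# Euler-angle grid search plus iterative zoom refinement; ties broken by
# first-found in fixed grid order. Also returns the winning rotation and
# the centroid-matching translation.
grid_superpose <- function(mobile, reference, levels = 7L) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  rmsd_of <- function(R) sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  best <- list(ang = c(0, 0, 0), rmsd = Inf)
  step <- pi / 6
  grids <- list(
    a = seq(0, 2 * pi - step, by = step),
    b = seq(0, pi, by = step),
    c = seq(0, 2 * pi - step, by = step)
  )
  for (a in grids$a) for (b in grids$b) for (c in grids$c) {
    r <- rmsd_of(.euler_rot(a, b, c))
    if (r < best$rmsd - 1e-15) best <- list(ang = c(a, b, c), rmsd = r)
  }
  for (lev in seq_len(levels - 1L)) {
    newstep <- step / 4
    offs <- seq(-step, step, by = newstep)
    center <- best$ang
    for (da in offs) for (db in offs) for (dc in offs) {
      ang <- center + c(da, db, dc)
      r <- rmsd_of(.euler_rot(ang[1], ang[2], ang[3]))
      if (r < best$rmsd - 1e-15) best <- list(ang = ang, rmsd = r)
    }
    step <- newstep
  }
  R <- .euler_rot(best$ang[1], best$ang[2], best$ang[3])
  list(
    rmsd = best$rmsd, rotation = R,
    transform = function(xyz) {
      sweep(sweep(as.matrix(xyz), 2, colMeans(mobile)) %*% t(R), 2,
            colMeans(reference), "+")
    }
  )
}

# --- independent per-residue side-chain RMSD (naive hand summation) --------

sidechain_table <- list(
  ALA = "CB", LEU = c("CB", "CG", "CD1", "CD2"), SER = c("CB", "OG"),
  CYS = c("CB", "SG"), GLY = character(0),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
)

naive_sidechain_rmsd <- function(atoms_a, atoms_b) {
  # atoms_*: data.frames with chain, resno, insert, resid, elety, x, y, z
  keys <- unique(paste(atoms_a$chain, atoms_a$resno, atoms_a$insert,
                       sep = "\r"))
  out <- NULL
  for (k in keys) {
    pa <- atoms_a[paste(atoms_a$chain, atoms_a$resno, atoms_a$insert,
                        sep = "\r") == k, ]
    pb <- atoms_b[paste(atoms_b$chain, atoms_b$resno, atoms_b$insert,
                        sep = "\r") == k, ]
    scn <- sidechain_table[[pa$resid[1]]]
    if (is.null(scn) || length(scn) == 0) next
    ss <- 0
    n <- 0
    for (nm in scn) {
      ra <- pa[pa$elety == nm, ]
      rb <- pb[pb$elety == nm, ]
      if (nrow(ra) != 1 || nrow(rb) != 1) next
      ss <- ss + (ra$x - rb$x)^2 + (ra$y - rb$y)^2 + (ra$z - rb$z)^2
      n <- n + 1
    }
    if (n == 0) next
    out <- rbind(out, data.frame(
      chain = pa$chain[1], resno = pa$resno[1], insert = pa$insert[1],
      value = sqrt(ss / n) / n, stringsAsFactors = FALSE
    ))
  }
  out
}

# --- brute-force contact detection -----------------------------------------

double_loop_contacts <- function(s, partition, cutoff = 3.0) {
  a <- s$atoms
  best <- new.env()
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq(i + 1L, nrow(a))) {
      di <- partition[[a$chain[i]]]
      dj <- partition[[a$chain[j]]]
      if (identical(di, dj)) next
      sci <- sidechain_table[[a$resid[i]]]
      scj <- sidechain_table[[a$resid[j]]]
      if (a$het[i] || a$het[j]) next
      if (!(a$elety[i] %in% sci) || !(a$elety[j] %in% scj)) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      # order pair by domain label of the first partition level
      if (di == unname(partition)[1]) {
        key <- paste(a$chain[i], a$resno[i], a$insert[i],
                     a$chain[j], a$resno[j], a$insert[j], sep = "\r")
      } else {
        key <- paste(a$chain[j], a$resno[j], a$insert[j],
                     a$chain[i], a$resno[i], a$insert[i], sep = "\r")
      }
      cur <- mget(key, envir = best, ifnotfound = Inf)[[1]]
      if (d < cur) assign(key, d, envir = best)
    }
  }
  keys <- ls(best)
  found <- vapply(keys, get, numeric(1), envir = best)
  keep <- found <= cutoff
  data.frame(key = keys[keep], min_distance = unname(found[keep]),
             stringsAsFactors = FALSE)
}

# --- synthetic cofactor pair for geometry tests ----------------------------

# HEM in the xy-plane with FE at the origin, plus an FMN isoalloxazine ring
# centered at (15, 0, 0) tilted by `tilt_deg` about the y axis, plus a CYS
# stub below the heme. The FMN C8M methyl sits exactly at (15, 0, 0).
make_cofactor_fixture <- function(tilt_deg = 0) {
  circle <- function(names, r, cx = 0, cy = 0) {
    t <- seq(0, 2 * pi, length.out = length(names) + 1L)[seq_along(names)]
    data.frame(elety = names, x = cx + r * cos(t), y = cy + r * sin(t), z = 0)
  }
  hem <- rbind(
    data.frame(elety = "FE", x = 0, y = 0, z = 0),
    circle(c("NA", "NB", "NC", "ND"), 2),
    circle(c("C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"), 3.3)
  )
  fmn_flat <- rbind(
    circle(c("N1", "C2", "N3", "C4", "C4A", "N5", "C5A", "C6", "C7", "C8",
             "C9", "C9A", "N10"), 2.2),
    data.frame(elety = c("C7M", "C8M"), x = c(3.4, 0), y = c(1.2, 0), z = 0)
  )
  th <- tilt_deg * pi / 180
  fmn <- data.frame(
    elety = fmn_flat$elety,
    x = 15 + fmn_flat$x * cos(th),
    y = fmn_flat$y,
    z = fmn_flat$x * sin(th)
  )
  cys <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "SG"),
    x = c(0.3, 0, -0.4, -0.4, 0.8, 0),
    y = c(1.0, 0, -0.9, -0.9, 0.3, 0.4),
    z = c(-4.9, -4.2, -4.6, -5.8, -3.2, -2.3)
  )
  atoms <- rbind(
    data.frame(chain = "A", resno = 400L, insert = "", resid = "CYS",
               elety = cys$elety, elesy = substr(cys$elety, 1, 1),
               x = cys$x, y = cys$y, z = cys$z, het = FALSE,
               stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 501L, insert = "", resid = "HEM",
               elety = hem$elety, elesy = ifelse(hem$elety == "FE", "FE",
                                                 substr(hem$elety, 1, 1)),
               x = hem$x, y = hem$y, z = hem$z, het = TRUE,
               stringsAsFactors = FALSE),
    data.frame(chain = "B", resno = 601L, insert = "", resid = "FMN",
               elety = fmn$elety, elesy = substr(fmn$elety, 1, 1),
               x = fmn$x, y = fmn$y, z = fmn$z, het = TRUE,
               stringsAsFactors = FALSE)
  )
  new_structure(atoms, title = sprintf("cofactor fixture tilt=%g", tilt_deg))
}

# random proper rotation from a seed (for rigid-motion invariance checks)
random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(s, R, shift) {
  set_coords(s, sweep(coords(s) %*% t(R), 2, shift, "+"))
}
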