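# Field engine checks against independent scalar re-implementations
# (oracles live in helper-oracles.R).

test_that("field values equal the naive pairwise sum to 1e-9", {
  fx <- cav_pair()
  at <- fx$complex$receptor$atoms
  at <- at[order(rowSums(coords(fx$complex$receptor)^2))[1:20], ]
  at$serial <- seq_len(nrow(at))
  st <- new_structure(at)
  grid <- grid_spec(c(-2.5, -2.5, -2.5), 0.5, c(10, 10, 10))
  for (probe in list(c("OH2", 0.60, 3.20, 0, TRUE),
                     c("C1=", 1.00, 3.70, 0, FALSE),
                     c("C3", 1.00, 3.90, 0, FALSE))) {
    f <- compute_probe_field(st, probe[[1]], grid)
    oracle <- naive_probe_energy(grid_points(grid), at,
                                 as.numeric(probe[[2]]),
                                 as.numeric(probe[[3]]),
                                 as.numeric(probe[[4]]),
                                 as.logical(probe[[5]]), vdw_tab)
    expect_lt(max(abs(as.vector(f$values) - oracle)), 1e-9)
  }
})

test_that("single neutral atom reproduces the closed-form LJ curve", {
  at <- data.frame(serial = 1L, name = "C", element = "C", resname = "WAL",
                   resno = 1L, chain = "A", x = 0, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  st <- assign_atom_types(new_structure(at))
  r <- c(3.0, 3.95, 5.0, 8.0)
  e <- probe_energy_at_points(cbind(r, 0, 0), st$atoms, "C3")
  rmin_ij <- (4.0 + 3.9) / 2
  eps_ij <- sqrt(0.066 * 1.0)
  expect_lt(max(abs(e - eps_ij * ((rmin_ij / r)^12 - 2 * (rmin_ij / r)^6))),
            1e-9)
  # the minimum sits at the combined rmin with depth -eps_ij
  expect_lt(abs(probe_energy_at_points(cbind(rmin_ij, 0, 0), st$atoms, "C3") +
                eps_ij), 1e-12)
})

test_that("empty environment yields an all-zero field", {
  st <- new_structure(empty_atoms())
  f <- compute_probe_field(st, "OH2", grid_spec(c(0, 0, 0), 1, c(4, 4, 4)))
  expect_true(all(f$values == 0))
})

test_that("fields are invariant under a rigid rotation of the frame", {
  fx <- cav_pair()
  at <- fx$complex$receptor$atoms[1:15, ]
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  pts <- matrix(stats::rnorm(60, sd = 3), ncol = 3)
  e1 <- probe_energy_at_points(pts, at, "OH2")
  at2 <- at
  rot <- t(R %*% t(as.matrix(at[, c("x", "y", "z")])))
  at2$x <- rot[, 1]; at2$y <- rot[, 2]; at2$z <- rot[, 3]
  e2 <- probe_energy_at_points(t(R %*% t(pts)), at2, "OH2")
  expect_lt(max(abs(e1 - e2)), 1e-6)
})

test_that("removing an atom never deepens an LJ-only field", {
  fx <- cav_pair()
  at <- fx$complex$receptor$atoms
  at <- at[at$vdw_class == "carbon_sp3", ][1:12, ]
  pts <- matrix(stats::rnorm(90, sd = 4), ncol = 3)
  full <- probe_energy_at_points(pts, at, "C3", clamp = FALSE)
  for (drop in c(1, 5, 12)) {
    less <- probe_energy_at_points(pts, at[-drop, ], "C3", clamp = FALSE)
    # an attractive tail removed can only raise the energy wherever the
    # removed atom contributed attraction; at worst it removes repulsion,
    # so check the defining inequality contribution-wise
    contrib <- probe_energy_at_points(pts, at[drop, , drop = FALSE], "C3",
                                      clamp = FALSE)
    expect_lt(max(abs(full - less - contrib)), 1e-9)
    expect_true(all(less >= full | contrib > 0))
  }
})

test_that("CRY is the pointwise minimum of C1= and DRY", {
  fx <- cav_pair()
  grid <- grid_around(c(0, 0, 0), 5)
  c1 <- compute_probe_field(fx$complex, "C1=", grid)
  dry <- compute_probe_field(fx$complex, "DRY", grid)
  cry <- cry_field(c1, dry)
  expect_identical(cry$values, pmin(c1$values, dry$values))
  expect_equal(cry$probe, "CRY")
  expect_true(all(cry$values <= c1$values))
  # identical inputs are a fixed point
  expect_identical(cry_field(c1, c1)$values, c1$values)
  # grid mismatch rejected
  expect_error(cry_field(c1, compute_probe_field(fx$complex, "DRY",
                                                 grid_around(c(1, 0, 0), 5))),
               "mismatch")
  # composite via compute_probe_field agrees
  expect_identical(compute_probe_field(fx$complex, "CRY", grid)$values,
                   cry$values)
})

test_that("hotspot detection finds planted sites and suppresses twins", {
  fx <- cav_multi()
  m <- fx$manifest
  grid <- grid_around(c(0, 0, 0), 11)
  oh2 <- compute_probe_field(fx$complex, "OH2", grid)
  hs <- find_hotspots(oh2, -6)
  for (i in which(m$character == "polar")) {
    p <- as.numeric(m[i, 1:3])
    expect_lt(min(sqrt((hs$x - p[1])^2 + (hs$y - p[2])^2 +
                       (hs$z - p[3])^2)), 0.75)
  }
  # exhaustive-scan oracle: every reported hotspot is the deepest grid
  # value within the suppression radius
  pts <- grid_points(grid)
  v <- as.vector(oh2$values)
  for (k in seq_len(nrow(hs))) {
    d2 <- (pts[, 1] - hs$x[k])^2 + (pts[, 2] - hs$y[k])^2 +
      (pts[, 3] - hs$z[k])^2
    expect_lte(hs$energy[k], min(v[d2 <= 1.5^2]) + 1e-12)
  }
  # sorted ascending, all at or below threshold
  expect_true(all(diff(hs$energy) >= 0))
  expect_true(all(hs$energy <= -6))
  # all-zero field: nothing to find
  zero <- compute_probe_field(new_structure(empty_atoms()),
                              "OH2", grid_spec(c(0, 0, 0), 1, c(4, 4, 4)))
  expect_equal(nrow(find_hotspots(zero, -1)), 0)
  # two minima 1.0 A apart: only the deeper is kept
  vv <- array(0, c(9, 9, 9))
  vv[3, 5, 5] <- -5; vv[5, 5, 5] <- -4  # 1.0 A apart at 0.5 A spacing
  f <- structure(list(grid = grid_spec(c(0, 0, 0), 0.5, c(9, 9, 9)),
                      values = vv, probe = "OH2", environment_hash = ""),
                 class = "ScalarField")
  found <- find_hotspots(f, -1)
  expect_equal(nrow(found), 1)
  expect_equal(found$energy, -5)
})

test_that("pocket surface marks the cavity open and the wall closed", {
  fx <- cav_pair()
  grid <- grid_around(c(0, 0, 0), 9)
  c3 <- compute_probe_field(fx$complex, "C3", grid)
  mask <- pocket_surface(c3, 1)
  ctr_idx <- (dim(mask) + 1) / 2
  expect_true(mask[ctr_idx[1], ctr_idx[2], ctr_idx[3]])
  # a point inside a wall atom is inaccessible
  wal <- fx$complex$receptor$atoms[1, c("x", "y", "z")]
  e <- probe_energy_at_points(as.matrix(wal), fx$complex$receptor$atoms, "C3")
  expect_gte(e, 1)
  # removing the ligand opens volume
  holo <- holo_complex(TRUE)
  c3_holo <- compute_probe_field(holo, "C3", grid)
  v_holo <- pocket_volume(c3_holo, 1, c(0, 0, 0), 9)
  v_apo <- pocket_volume(c3, 1, c(0, 0, 0), 9)
  expect_gt(v_apo, v_holo)
})

test_that("OpenDX export is well-formed and value-faithful", {
  fx <- cav_pair()
  f <- compute_probe_field(fx$complex, "C3", grid_spec(c(0, 0, 0), 1,
                                                      c(5, 5, 5)))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(f, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions counts 5 5 5")
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[8:(7 + ceiling(125 / 3))]), "\\s+")))
  # dx is z-fastest; the first value is the grid origin corner either way
  expect_equal(vals[1], f$values[1, 1, 1], tolerance = 1e-4)
  expect_equal(length(vals), 125)
})
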