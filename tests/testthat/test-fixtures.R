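test_that("cavity generator is deterministic and plants separated sites", {
  a <- make_toy_cavity(3, 2, seed = 7)
  b <- make_toy_cavity(3, 2, seed = 7)
  expect_identical(a$complex$receptor$atoms, b$complex$receptor$atoms)
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 5)
  expect_gte(min(stats::dist(as.matrix(a$manifest[, 1:3]))), 3.0)
  # no two heavy atoms closer than the structural floor
  expect_gte(min(stats::dist(coords(a$complex$receptor))), 0.8)
})

test_that("a bare cavity has no strong water hotspot", {
  fx <- make_toy_cavity(0, 0, seed = 2)
  f <- compute_probe_field(fx$complex, "OH2",
                          grid_around(c(0, 0, 0), 8))
  expect_gt(min(f$values), -6)
})

test_that("ligand construction covers its sites and pairs differ by one atom", {
  m <- cav_pair()$manifest
  with_m <- make_toy_ligand(m[c(1, 3), ], with_methyl = TRUE)
  without <- make_toy_ligand(m[c(1, 3), ], with_methyl = FALSE)
  expect_equal(sum(with_m$atoms$is_heavy) - sum(without$atoms$is_heavy), 1)
  # anchor nitrogen sits on the polar site, methyl on the lipophilic site
  n1 <- as.numeric(with_m$atoms[with_m$atoms$name == "N1", c("x", "y", "z")])
  expect_lt(sqrt(sum((n1 - as.numeric(m[1, 1:3]))^2)), 0.5)
  cm <- as.numeric(with_m$atoms[with_m$atoms$name == "CM", c("x", "y", "z")])
  expect_lt(sqrt(sum((cm - as.numeric(m[3, 1:3]))^2)), 0.5)
  expect_true(with_m$atoms$hbond_role[with_m$atoms$name == "N1"] != "none")
  expect_error(make_toy_ligand(m[0, ]), "at least one")
})

test_that("bulk box matches the stated density and stays clash-free", {
  box <- make_bulk_box(15, seed = 4)
  expect_equal(nrow(box), round(0.0334 * 15^3))  # 113 molecules
  expect_gte(min(stats::dist(water_o(box))), 2.4)
  expect_true(check_water_geometry(box))
  expect_identical(box, make_bulk_box(15, seed = 4))
  expect_error(make_bulk_box(10, 1), "12")
})

test_that("landscape manifest equals an independent quadrature", {
  land <- make_binding_landscape(-3, 4, 0, temperature = 300)
  expect_lt(abs(land$manifest$delta_f - riemann_delta_f(land)), 1e-6)
  # sign and monotonicity of the perturbation
  l5 <- make_binding_landscape(-5, 3, 0)
  expect_lt(l5$manifest$delta_f, 0)
  l5p <- make_binding_landscape(-5, 3, 2)
  expect_gt(l5p$manifest$delta_f, l5$manifest$delta_f)
})

test_that("planted polar sites are local minima of the water field", {
  fx <- cav_pair()
  f <- compute_probe_field(fx$complex, "OH2", grid_around(c(0, 0, 0), 9))
  hs <- find_hotspots(f, -6)
  for (i in which(fx$manifest$character == "polar")) {
    p <- as.numeric(fx$manifest[i, 1:3])
    d <- sqrt((hs$x - p[1])^2 + (hs$y - p[2])^2 + (hs$z - p[3])^2)
    expect_lt(min(d), 0.75)
  }
})
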