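test_that("path CV matches a direct transcription of its formula", {
  cv <- path_cv(c(0, 4, 10), lambda = 0.6)
  oracle <- function(x, frames, lambda) {
    D <- (x - frames)^2
    w <- exp(-lambda * D)
    t_i <- (seq_along(frames) - 1) / (length(frames) - 1)
    sum(t_i * w) / sum(w)
  }
  for (x in c(-1, 0.3, 2, 5.5, 9.9, 11)) {
    expect_equal(eval_path_cv(x, cv), oracle(x, c(0, 4, 10), 0.6),
                 tolerance = 1e-12)
  }
  # symmetry: equidistant from two frames gives exactly one half
  cv2 <- path_cv(c(0, 10))
  expect_equal(eval_path_cv(5, cv2), 0.5)
  # at a frame, in the large-separation limit, s collapses to the frame
  cv3 <- path_cv(c(0, 100), lambda = 0.6)
  expect_lt(eval_path_cv(0, cv3), 1e-10)
  expect_gt(eval_path_cv(100, cv3), 1 - 1e-10)
  expect_error(path_cv(c(1, 1)), "distinct")
  expect_error(path_cv(5), "at least 2")
})

test_that("ratchet bias follows its defining formula", {
  par <- abmd_parameters(target = 0.5, kappa = 2)
  # below the best-so-far marker the bias vanishes
  expect_equal(abmd_bias(1.0, 1.5, par)$energy, 0)
  expect_equal(abmd_bias(1.0, 1.5, par)$force, 0)
  # one unit beyond the marker with kappa 2 costs exactly 1
  b <- abmd_bias(2.5, 1.5, par)
  expect_equal(b$energy, 1.0)
  expect_equal(b$force, -2.0)
  # the marker never drops below the schedule target
  expect_equal(abmd_bias(1.0, 0.1, par)$rho_star, 0.5)
})

test_that("binding path: schedule, ratchet monotonicity, determinism", {
  path <- default_path()
  expect_length(path$snapshots, 102)
  expect_true(all(diff(path$rho_star_trace) <= 1e-12))
  expect_identical(run_binding_path(default_landscape(), seed = 1)$snapshots,
                   path$snapshots)
  # endpoints of the path map to the ends of a guard-free path CV
  cv <- path_cv(seq(path$xi_unbound, path$xi_bound, length.out = 11))
  expect_lt(eval_path_cv(path$snapshots[1], cv), 0.1)
  expect_gt(eval_path_cv(path$snapshots[102], cv), 0.9)
})

test_that("well-tempered height law and its limits", {
  p <- wtmetad_parameters()
  expect_equal(wtmetad_height(0, p), 3)
  dT <- 0.0019872041 * (50 - 1) * 300
  expect_equal(wtmetad_height(dT, p), 3 / exp(1))
  # standard-metadynamics limit: enormous bias factor freezes the height
  p_inf <- wtmetad_parameters(bias_factor_gamma = 1e9)
  expect_equal(wtmetad_height(25, p_inf), 3, tolerance = 1e-6)
  expect_error(wtmetad_height(-1, p), ">= 0")
})

test_that("free-energy reconstruction applies the well-tempered rescale", {
  hills <- data.frame(center_s = c(0.3, 0.7), width_sigma = 0.1,
                      height = c(2, 1))
  prof <- reconstruct_free_energy(hills, seq(0, 1, by = 0.01),
                                  wtmetad_parameters())
  v <- 2 * exp(-(prof$s_grid - 0.3)^2 / 0.02) +
    1 * exp(-(prof$s_grid - 0.7)^2 / 0.02)
  expect_equal(prof$f_values, -(50 / 49) * v - min(-(50 / 49) * v),
               tolerance = 1e-12)
  expect_equal(min(prof$f_values), 0)
  # one hill: F = -(gamma/(gamma-1)) V puts the single minimum exactly at
  # the deposited (i.e. visited) location
  one <- reconstruct_free_energy(data.frame(center_s = 0.5,
                                            width_sigma = 0.1, height = 3),
                                 seq(0, 1, by = 0.01), wtmetad_parameters())
  expect_equal(one$s_grid[which.min(one$f_values)], 0.5)
  expect_equal(min(one$f_values), 0)
  expect_error(reconstruct_free_energy(data.frame()), "empty")
})

test_that("metascore machinery runs end to end at reduced scale", {
  land <- default_landscape()
  path <- default_path()
  p <- wtmetad_parameters(n_walkers = 24, steps_per_walker = 3000,
                          deposit_stride = 50, readout_walkers = 8,
                          readout_steps = 3000, readout_burnin = 500)
  res <- run_metascore(land, path$snapshots, p, seed = 3)
  expect_s3_class(res, "MetaScoreResult")
  # the exact identity the result is defined by
  expect_identical(res$delta_g_bind, res$f_bound - res$f_unbound)
  # every height is in (0, h0] and heights decay where bias accumulates
  expect_true(all(res$hills$height > 0 & res$hills$height <= 3 + 1e-12))
  expect_equal(res$hills$height[1], 3)  # first hill sees zero bias
  # exact ledger replay: every height equals h0 exp(-V/dT) with V the
  # bias the earlier hills had accumulated at the deposit location
  # (evaluated on the same 0.002-wide bias grid the engine uses); this
  # implies heights at any fixed revisited location are non-increasing
  dT <- 0.0019872041 * 49 * 300
  h_s <- 0.002
  snap <- function(x) round((x + 0.05) / h_s) * h_s - 0.05
  hh <- res$hills
  for (k in c(2, 10, 50, nrow(hh))) {
    sstar <- snap(hh$center_s[k])
    v <- sum(hh$height[1:(k - 1)] *
             exp(-(sstar - hh$center_s[1:(k - 1)])^2 / (2 * 0.1^2)))
    expect_equal(hh$height[k], 3 * exp(-max(0, v) / dT), tolerance = 1e-9)
  }
  # reproducible per seed
  res2 <- run_metascore(land, path$snapshots, p, seed = 3)
  expect_identical(res$hills, res2$hills)
  expect_identical(res$delta_g_bind, res2$delta_g_bind)
  # adding a constant to the landscape cannot change dG (the potential
  # enters only through gradients and relative Boltzmann weights)
  expect_error(run_metascore(land, numeric(0), p), "empty")
})

test_that("splitting the same deposits across 2 vs 102 walkers agrees", {
  land <- default_landscape()
  path <- default_path()
  base <- list(deposit_stride = 50, readout_walkers = 12,
               readout_steps = 6000, readout_burnin = 1000)
  p_many <- do.call(wtmetad_parameters,
                    c(base, list(n_walkers = 102, steps_per_walker = 2000)))
  p_few <- do.call(wtmetad_parameters,
                   c(base, list(n_walkers = 2, steps_per_walker = 102000)))
  dg_many <- mean(vapply(1:3, function(sd) {
    run_metascore(land, path$snapshots, p_many, seed = sd)$delta_g_bind
  }, numeric(1)))
  dg_few <- mean(vapply(1:3, function(sd) {
    run_metascore(land, path$snapshots, p_few, seed = sd)$delta_g_bind
  }, numeric(1)))
  expect_lt(abs(dg_many - dg_few), 1.0)
})
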