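# Binding free energies on toy landscapes: adiabatic-bias ratchet dynamics
# to generate a binding path, then shared-hills well-tempered metadynamics
# over a path collective variable, reconstructing the free-energy profile
# and the bound/unbound difference.

#' Path collective variable
#'
#' Progress coordinate between reference configurations: for a
#' configuration with squared deviations `D_i` from the `N` frames,
#'
#'   `s = sum_i ((i-1)/(N-1)) exp(-lambda D_i) / sum_i exp(-lambda D_i)`
#'
#' normalised to the unit interval (0 at the first frame, 1 at the last).
#'
#' @param frames reference configurations: numeric vector (1D) or matrix
#'   (one row per frame), in Angstrom; at least 2 distinct frames.
#' @param lambda inverse squared-distance smoothing, 1/A^2.
#' @return a `PathCV`.
#' @export
path_cv <- function(frames, lambda = 0.6) {
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1)
  if (nrow(frames) < 2) stop("need at least 2 reference frames")
  if (any(duplicated(frames))) stop("reference frames must be distinct")
  stopifnot(lambda > 0)
  structure(list(frames = frames, lambda = lambda,
                 n = nrow(frames)), class = "PathCV")
}

#' Evaluate the path collective variable
#'
#' @param config configuration: numeric vector of the same dimension as one
#'   frame (or a scalar for 1D paths).
#' @param cv a `PathCV`.
#' @return progress value in `[0, 1]`.
#' @export
eval_path_cv <- function(config, cv) {
  D <- rowSums((cv$frames - matrix(config, cv$n, ncol(cv$frames),
                                   byrow = TRUE))^2)
  lD <- cv$lambda * D
  if (!all(is.finite(lD))) stop("non-finite deviations in path CV")
  w <- exp(-(lD - min(lD)))
  t_i <- (seq_len(cv$n) - 1) / (cv$n - 1)
  sum(t_i * w) / sum(w)
}

# s and ds/dxi of a 1D path CV, vectorised over xi
path_cv_profile <- function(cv, xi) {
  f <- cv$frames[, 1]
  t_i <- (seq_len(cv$n) - 1) / (cv$n - 1)
  s <- numeric(length(xi)); ds <- numeric(length(xi))
  for (k in seq_along(xi)) {
    D <- (xi[k] - f)^2
    lD <- cv$lambda * D
    w <- exp(-(lD - min(lD)))
    sw <- sum(w); stw <- sum(t_i * w)
    s[k] <- stw / sw
    dw <- -2 * cv$lambda * (xi[k] - f) * w
    ds[k] <- (sum(t_i * dw) * sw - stw * sum(dw)) / sw^2
  }
  list(s = s, ds = ds)
}

#' Adiabatic-bias parameters
#'
#' @param target distance target the ratchet drives toward (the floor for
#'   the best-so-far marker), A.
#' @param kappa spring constant, kcal/mol/A^2.  The conventional starting
#'   value 1 kJ mol^-1 nm^-2 converts to 2.39e-3 kcal mol^-1 A^-2.
#' @param segment_length steps per simulation segment.
#' @export
abmd_parameters <- function(target = 10, kappa = 1 * 0.239006 / 100,
                            segment_length = 5000) {
  stopifnot(kappa > 0, target >= 0, segment_length >= 1)
  structure(list(target = target, kappa = kappa,
                 segment_length = segment_length),
            class = "ABMDParameters")
}

#' Adiabatic-bias schedule
#'
#' Six consecutive segments; after each one the target is divided by 100
#' and the spring constant multiplied by 100; 102 snapshots are resampled
#' from the concatenated binding trajectory.
#'
#' @param n_segments number of consecutive biased segments.
#' @param target_divisor,kappa_multiplier per-segment schedule updates.
#' @param n_snapshots snapshots resampled from the full trajectory.
#' @param initial [abmd_parameters()] for the first segment.
#' @export
abmd_schedule <- function(n_segments = 6, target_divisor = 100,
                          kappa_multiplier = 100, n_snapshots = 102,
                          initial = abmd_parameters()) {
  stopifnot(n_segments >= 1, n_snapshots >= 2)
  structure(list(n_segments = n_segments, target_divisor = target_divisor,
                 kappa_multiplier = kappa_multiplier,
                 n_snapshots = n_snapshots, initial = initial),
            class = "ABMDSchedule")
}

#' Ratchet bias energy and force
#'
#' The harmonic bias acts only when the distance to the target state
#' exceeds the smallest value reached so far (floored at the schedule
#' target): `E = kappa/2 (rho - rho*)^2` for `rho > rho*`, zero otherwise.
#' The returned force is `-dE/drho`.
#'
#' @param rho current distance to the bound state, A (>= 0).
#' @param rho_min_so_far smallest distance previously reached, A.
#' @param params `ABMDParameters`.
#' @return list with `energy` (kcal/mol), `force` (kcal/mol/A) and the
#'   effective `rho_star`.
#' @export
abmd_bias <- function(rho, rho_min_so_far, params) {
  stopifnot(rho >= 0)
  rho_star <- max(params$target, min(rho_min_so_far, rho))
  if (rho > rho_star) {
    list(energy = 0.5 * params$kappa * (rho - rho_star)^2,
         force = -params$kappa * (rho - rho_star),
         rho_star = rho_star)
  } else {
    list(energy = 0, force = 0, rho_star = rho_star)
  }
}

# overdamped Langevin parameters shared by both stages: the time step is
# the conventional 0.002 reduced units with mobility 40 A^2 mol/kcal per
# unit time (mobility*dt = 0.08 A^2 mol/kcal per step, i.e. a per-step
# thermal displacement of ~0.3 A), plus a cap on per-step displacement
# that keeps the stiff late-stage ratchet springs stable under the
# explicit Euler-Maruyama update
.dyn_mu_dt <- 0.08
.dyn_max_step <- 0.5

#' Generate a binding path with adiabatic-bias ratchet dynamics
#'
#' Runs consecutive overdamped Langevin segments on the landscape (in
#' physical Angstrom units, one progress unit = `length_scale` A).  The
#' ratchet distance is `rho = |xi - xi_bound|`; after every segment the
#' target is divided and the spring constant multiplied per the schedule.
#' The best-so-far marker `rho*` never increases.  The concatenated
#' trajectory is resampled uniformly in step index to exactly
#' `n_snapshots` configurations running from the unbound start to the
#' bound state.
#'
#' @param system a `ToyLandscape`.
#' @param schedule an [abmd_schedule()].
#' @param seed RNG seed.
#' @param bind_tolerance maximum acceptable final distance from the bound
#'   state, A: about three per-step thermal displacements (the literal
#'   final target after six hundredfold divisions is far below thermal
#'   noise, so the check is against thermal jitter around the ratchet
#'   floor).
#' @return a `BindingPath`: `snapshots` (xi, A), `trajectory`, `rho_star_trace`,
#'   `schedule`, `seed`.
#' @export
run_binding_path <- function(system, schedule = abmd_schedule(), seed = 1,
                             bind_tolerance = 1.0) {
  stopifnot(inherits(system, "ToyLandscape"))
  L <- system$length_scale
  xi_bound <- system$x_bound * L
  xi <- system$x_unbound * L
  kT <- .kB * system$temperature
  noise_amp <- sqrt(2 * kT * .dyn_mu_dt)
  n_total <- schedule$n_segments * schedule$initial$segment_length
  traj <- numeric(n_total)
  rho_star_trace <- numeric(n_total)
  withr::with_seed(seed, {
    eta <- stats::rnorm(n_total)
    target <- schedule$initial$target
    kappa <- schedule$initial$kappa
    seg_len <- schedule$initial$segment_length
    rho_min <- Inf
    idx <- 0
    for (seg in seq_len(schedule$n_segments)) {
      par <- abmd_parameters(target, kappa, seg_len)
      for (step in seq_len(seg_len)) {
        idx <- idx + 1
        rho <- abs(xi - xi_bound)
        b <- abmd_bias(rho, rho_min, par)
        rho_min <- min(rho_min, rho)
        rho_star_trace[idx] <- b$rho_star
        # chain rule: force on xi from the rho-space ratchet force
        f_xi <- b$force * sign(xi - xi_bound)
        gpot <- landscape_gradient(system, xi / L) / L
        drift <- (-gpot + f_xi) * .dyn_mu_dt
        drift <- max(-.dyn_max_step, min(.dyn_max_step, drift))
        xi <- xi + drift + noise_amp * eta[idx]
        traj[idx] <- xi
      }
      target <- target / schedule$target_divisor
      kappa <- kappa * schedule$kappa_multiplier
    }
  })
  rho_final <- abs(traj[n_total] - xi_bound)
  final_target <- schedule$initial$target /
    schedule$target_divisor^(schedule$n_segments - 1)
  if (rho_final > max(final_target, bind_tolerance)) {
    stop(sprintf("binding not reached: final rho %.3f A exceeds %.3f A",
                 rho_final, max(final_target, bind_tolerance)))
  }
  snap_idx <- unique(round(seq(1, n_total, length.out = schedule$n_snapshots)))
  # uniform resampling in step index; force exact endpoint inclusion
  snap_idx <- round(seq(1, n_total, length.out = schedule$n_snapshots))
  snapshots <- c(system$x_unbound * L, traj[snap_idx[-c(1, length(snap_idx))]],
                 traj[n_total])
  structure(list(snapshots = snapshots, trajectory = traj,
                 rho_star_trace = rho_star_trace, schedule = schedule,
                 seed = seed, xi_bound = xi_bound,
                 xi_unbound = system$x_unbound * L),
            class = "BindingPath")
}

#' Well-tempered metadynamics parameters
#'
#' Defaults follow the conventional protocol: 300 K, bias factor 50,
#' initial Gaussian height 3 kcal/mol, width 0.1 in path-CV units, one
#' walker per binding-path snapshot.
#'
#' @param temperature K.
#' @param bias_factor_gamma well-tempered bias factor (> 1).
#' @param h0 initial Gaussian height, kcal/mol.
#' @param sigma Gaussian width in CV units.
#' @param deposit_stride steps between deposits.
#' @param n_walkers number of independent walkers sharing one hill ledger.
#' @param steps_per_walker biased steps per walker (calibrated for
#'   convergence on desk-scale landscapes).
#' @param equil_steps unbiased burn-in steps per walker.
#' @param lambda path-CV smoothing, 1/A^2.
#' @param n_path_frames reference frames drawn from the binding path.
#' @param bound_window,unbound_window state windows on the path CV.
#' @export
wtmetad_parameters <- function(temperature = 300, bias_factor_gamma = 50,
                               h0 = 3, sigma = 0.1, deposit_stride = 50,
                               n_walkers = 102, steps_per_walker = 20000,
                               equil_steps = 100, lambda = 0.6,
                               readout_walkers = 24,
                               readout_steps = 16000,
                               readout_burnin = 2000,
                               readout_iters = 1,
                               n_path_frames = 19, path_guard = 4,
                               bound_window = NULL,
                               unbound_window = NULL,
                               reflect_margin = 0.5) {
  stopifnot(bias_factor_gamma > 1, h0 > 0, sigma > 0)
  structure(list(temperature = temperature,
                 bias_factor_gamma = bias_factor_gamma, h0 = h0,
                 sigma = sigma, deposit_stride = deposit_stride,
                 n_walkers = n_walkers, steps_per_walker = steps_per_walker,
                 equil_steps = equil_steps, lambda = lambda,
                 readout_walkers = readout_walkers,
                 readout_steps = readout_steps,
                 readout_burnin = readout_burnin,
                 readout_iters = readout_iters,
                 n_path_frames = n_path_frames, path_guard = path_guard,
                 bound_window = bound_window,
                 unbound_window = unbound_window,
                 reflect_margin = reflect_margin),
            class = "WTMetaDParameters")
}

#' Well-tempered Gaussian height
#'
#' `h = h0 exp(-V(s) / (kB (gamma - 1) T))`: the deposit height decays
#' exponentially with the bias already accumulated at the current CV
#' value, which is what makes the well-tempered estimate convergent.
#'
#' @param v_at_s accumulated bias at the current CV value, kcal/mol (>= 0).
#' @param params `WTMetaDParameters`.
#' @return height, kcal/mol.
#' @export
wtmetad_height <- function(v_at_s, params) {
  stopifnot(all(v_at_s >= 0))
  dT <- .kB * (params$bias_factor_gamma - 1) * params$temperature
  params$h0 * exp(-v_at_s / dT)
}

#' Build a path CV from a binding path
#'
#' Lays `n_path_frames` reference configurations equally spaced along the
#' physical path coordinate covered by the binding trajectory, extended by
#' `path_guard` Angstrom on both sides.  The guard frames keep the
#' progress variable responsive (non-zero gradient) inside both end
#' states; without them the variable saturates exactly where the bound
#' well sits and the metadynamics bias loses its grip there.  The mapped
#' locations of the unbound and bound states are stored on the CV.
#'
#' @param path a `BindingPath`.
#' @param params `WTMetaDParameters` (supplies `n_path_frames`,
#'   `path_guard`, `lambda`).
#' @export
path_cv_from_binding_path <- function(path, params = wtmetad_parameters()) {
  frames <- seq(path$xi_unbound - params$path_guard,
                path$xi_bound + params$path_guard,
                length.out = params$n_path_frames)
  cv <- path_cv(frames, params$lambda)
  cv$s_unbound <- eval_path_cv(path$xi_unbound, cv)
  cv$s_bound <- eval_path_cv(path$xi_bound, cv)
  cv
}

#' Reconstruct the free-energy profile from the hill ledger
#'
#' Sums the deposited Gaussians into the bias potential `V(s)` and applies
#' the well-tempered rescaling `F(s) = -(gamma/(gamma-1)) V(s)`, re-zeroed
#' to a zero minimum.
#'
#' @param hills hill ledger (data frame with `center_s`, `width_sigma`,
#'   `height`).
#' @param s_grid CV grid for the profile.
#' @param params `WTMetaDParameters` (supplies gamma).
#' @return a `FreeEnergyProfile`: `s_grid`, `f_values`, `gamma`.
#' @export
reconstruct_free_energy <- function(hills, s_grid = seq(0, 1, by = 0.005),
                                    params = wtmetad_parameters()) {
  if (is.null(hills) || nrow(hills) == 0) stop("empty hill ledger")
  v <- numeric(length(s_grid))
  for (k in seq_len(nrow(hills))) {
    v <- v + hills$height[k] *
      exp(-(s_grid - hills$center_s[k])^2 / (2 * hills$width_sigma[k]^2))
  }
  g <- params$bias_factor_gamma
  f <- -(g / (g - 1)) * v
  f <- f - min(f)
  structure(list(s_grid = s_grid, f_values = f, gamma = g),
            class = "FreeEnergyProfile")
}

# State free energies from a profile: Boltzmann integral of exp(-F/kT)
# over each state window on the CV.  When the landscape state windows are
# mapped through the CV, this reproduces the configuration-space Boltzmann
# integral exactly (the Jacobian of the CV cancels), so the estimate is
# directly comparable to the quadrature ground truth.
profile_state_values <- function(profile, params, bound_window,
                                 unbound_window) {
  s <- profile$s_grid; f <- profile$f_values
  kT <- .kB * params$temperature
  ds <- diff(s[1:2])
  boltz <- function(w) {
    sel <- s >= w[1] & s <= w[2]
    if (!any(sel)) stop("empty state window on the CV grid")
    -kT * log(sum(exp(-f[sel] / kT)) * ds)
  }
  list(f_bound = boltz(bound_window), f_unbound = boltz(unbound_window))
}

#' MetaScore: shared-hills well-tempered metadynamics over a binding path
#'
#' Every snapshot of the binding path seeds one walker.  Walkers run
#' sequentially: a short unbiased burn-in, then overdamped Langevin
#' dynamics on the landscape plus the accumulated shared bias on the path
#' CV; every `deposit_stride` steps a Gaussian is appended to the single
#' shared ledger with its height set by [wtmetad_height()] against the
#' bias already present at the current CV value.  Afterwards the
#' free-energy profile is reconstructed from the ledger and
#'
#'   `dG_bind = F(bound) - F(unbound)`
#'
#' with the state windows of the parameter object.
#'
#' @param system a `ToyLandscape` (optionally with a variant perturbation).
#' @param snapshots numeric vector of starting configurations (A), normally
#'   `path$snapshots` from [run_binding_path()].
#' @param params `WTMetaDParameters`.
#' @param seed RNG seed.
#' @param perturbation optional override of the landscape perturbation,
#'   kcal/mol.
#' @param cv optional `PathCV`; by default built from the snapshots.
#' @return a `MetaScoreResult`.
#' @export
run_metascore <- function(system, snapshots, params = wtmetad_parameters(),
                          seed = 1, perturbation = NULL, cv = NULL) {
  stopifnot(inherits(system, "ToyLandscape"))
  if (length(snapshots) == 0) stop("empty snapshot list")
  L <- system$length_scale
  kT <- .kB * params$temperature
  noise_amp <- sqrt(2 * kT * .dyn_mu_dt)
  dT <- .kB * (params$bias_factor_gamma - 1) * params$temperature

  if (is.null(cv)) {
    fake_path <- structure(list(snapshots = snapshots,
                                xi_unbound = snapshots[1],
                                xi_bound = snapshots[length(snapshots)]),
                           class = "BindingPath")
    cv <- path_cv_from_binding_path(fake_path, params)
  }
  # state windows on the CV: either explicit in the parameters or the
  # landscape state windows mapped through the CV
  if (!is.null(params$bound_window)) {
    bw <- params$bound_window; uw <- params$unbound_window
  } else {
    mw <- system$manifest
    bw <- sort(c(eval_path_cv(mw$bound_window[1] * L, cv),
                 eval_path_cv(mw$bound_window[2] * L, cv)))
    uw <- sort(c(eval_path_cv(mw$unbound_window[1] * L, cv),
                 eval_path_cv(mw$unbound_window[2] * L, cv)))
  }

  # cached lookup tables: landscape and path CV on a fine xi grid
  xi_lo <- (system$bounds[1] - 0.1) * L
  xi_hi <- (system$bounds[2] + 0.1) * L
  h_xi <- 0.02
  xi_grid <- seq(xi_lo, xi_hi, by = h_xi)
  gpot_grid <- landscape_gradient(system, xi_grid / L, perturbation) / L
  pcv <- path_cv_profile(cv, xi_grid)
  s_of_xi <- pcv$s; ds_of_xi <- pcv$ds

  # shared bias tables over s
  h_s <- 0.002
  s_grid_b <- seq(-0.05, 1.05, by = h_s)
  vb <- numeric(length(s_grid_b))
  dvb <- numeric(length(s_grid_b))

  # reflecting boundaries confine walkers to the landscape domain, which
  # lies well inside the guard-extended frame range so the path CV keeps a
  # usable gradient everywhere the walkers can go
  lo <- system$bounds[1] * L
  hi <- system$bounds[2] * L
  reflect <- function(x) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
    min(max(x, lo), hi)
  }
  n_walk <- min(params$n_walkers, length(snapshots))
  starts <- snapshots[round(seq(1, length(snapshots), length.out = n_walk))]
  starts <- pmin(pmax(starts, lo), hi)

  max_hills <- n_walk * ceiling(params$steps_per_walker /
                                params$deposit_stride)
  hc <- numeric(max_hills); hh <- numeric(max_hills)
  hw <- integer(max_hills); nh <- 0

  sig <- params$sigma
  visits <- integer(length(s_grid_b))
  corr <- numeric(length(s_grid_b))
  withr::with_seed(seed, {
    for (w in seq_len(n_walk)) {
      xi <- starts[w]
      eta <- stats::rnorm(params$equil_steps + params$steps_per_walker)
      for (step in seq_len(params$equil_steps)) {
        ix <- max(1, min(length(xi_grid),
                         round((xi - xi_lo) / h_xi) + 1))
        drift <- -gpot_grid[ix] * .dyn_mu_dt
        drift <- max(-.dyn_max_step, min(.dyn_max_step, drift))
        xi <- reflect(xi + drift + noise_amp * eta[step])
      }
      for (step in seq_len(params$steps_per_walker)) {
        ix <- max(1, min(length(xi_grid),
                         round((xi - xi_lo) / h_xi) + 1))
        s_cur <- s_of_xi[ix]
        is_ <- max(1, min(length(s_grid_b),
                          round((s_cur + 0.05) / h_s) + 1))
        f_bias <- -dvb[is_] * ds_of_xi[ix]
        drift <- (-gpot_grid[ix] + f_bias) * .dyn_mu_dt
        drift <- max(-.dyn_max_step, min(.dyn_max_step, drift))
        xi <- reflect(xi + drift + noise_amp * eta[params$equil_steps + step])
        if (step %% params$deposit_stride == 0) {
          ix2 <- max(1, min(length(xi_grid),
                            round((xi - xi_lo) / h_xi) + 1))
          s_dep <- s_of_xi[ix2]
          is2 <- max(1, min(length(s_grid_b),
                            round((s_dep + 0.05) / h_s) + 1))
          h <- params$h0 * exp(-max(0, vb[is2]) / dT)
          nh <- nh + 1
          hc[nh] <- s_dep; hh[nh] <- h; hw[nh] <- w
          gau <- exp(-(s_grid_b - s_dep)^2 / (2 * sig^2))
          vb <- vb + h * gau
          dvb <- dvb - h * (s_grid_b - s_dep) / sig^2 * gau
        }
      }
    }
    # Frozen-bias read-out: deposition stops and walkers sample the
    # biased surface in equilibrium.  Because the deposition history can
    # leave multi-kT lumps in V that equilibrium sampling cannot cross,
    # the read-out is iterated adaptive-umbrella style: each pass turns
    # its histogram into an additional flattening correction, so by the
    # last pass the sampled surface is flat to about kT and the histogram
    # estimate F(s) = -kT log rho(s) - V(s) - corr(s) is reliable
    # everywhere the states live.
    corr <- numeric(length(s_grid_b))
    dcorr <- numeric(length(s_grid_b))
    ro_starts <- seq(lo, hi, length.out = params$readout_walkers)
    for (iter in seq_len(params$readout_iters)) {
      visits <- integer(length(s_grid_b))
      for (w in seq_len(params$readout_walkers)) {
        xi <- ro_starts[w]
        eta <- stats::rnorm(params$readout_burnin + params$readout_steps)
        for (step in seq_len(params$readout_burnin + params$readout_steps)) {
          ix <- max(1, min(length(xi_grid),
                           round((xi - xi_lo) / h_xi) + 1))
          s_cur <- s_of_xi[ix]
          is_ <- max(1, min(length(s_grid_b),
                            round((s_cur + 0.05) / h_s) + 1))
          f_bias <- -(dvb[is_] + dcorr[is_]) * ds_of_xi[ix]
          drift <- (-gpot_grid[ix] + f_bias) * .dyn_mu_dt
          drift <- max(-.dyn_max_step, min(.dyn_max_step, drift))
          xi <- reflect(xi + drift + noise_amp * eta[step])
          if (step > params$readout_burnin && step %% 10 == 0) {
            visits[is_] <- visits[is_] + 1L
          }
        }
      }
      if (iter < params$readout_iters) {
        # flattening update: the lumps to remove are at least one hill
        # width wide, so the per-bin log-count noise is removed with a
        # matching broad kernel before it is fed back, with a damped gain
        delta <- ifelse(visits > 0, -kT * log(visits / sum(visits)),
                        NA_real_)
        cap <- min(delta, na.rm = TRUE) + 6
        delta[is.na(delta) | delta > cap] <- cap
        kern <- round(params$sigma / h_s)
        kern <- kern + (kern %% 2 == 0)
        delta <- stats::filter(delta, rep(1 / kern, kern), sides = 2)
        delta[is.na(delta)] <- 0
        delta <- delta - mean(delta)
        corr <- corr + 0.8 * as.numeric(delta)
        dcorr <- c(0, diff(corr)) / h_s
      }
    }
  })
  hills <- data.frame(center_s = hc[seq_len(nh)],
                      width_sigma = sig,
                      height = hh[seq_len(nh)],
                      walker_id = hw[seq_len(nh)],
                      deposit_index = seq_len(nh))
  profile <- reconstruct_free_energy(hills, params = params)
  # Reweighted state estimate: the late walkers sample the biased surface
  # F(s) + V(s) in quasi-equilibrium, so F = -kT ln rho(s) - V(s) up to a
  # constant.  This histogram estimate cancels any residual imbalance the
  # deposition history left in V, and the Boltzmann window integrals make
  # it directly comparable to the quadrature ground truth.
  dens <- visits / max(1, sum(visits))
  f_rew <- ifelse(dens > 0, -kT * log(dens) - vb - corr, NA_real_)
  f_rew <- f_rew - min(f_rew, na.rm = TRUE)
  # transfer onto the profile grid
  f_on_grid <- stats::approx(s_grid_b, f_rew, xout = profile$s_grid,
                             rule = 2)$y
  ok <- is.finite(f_on_grid)
  f_on_grid[!ok] <- max(f_on_grid[ok]) + 10
  pk <- structure(list(s_grid = profile$s_grid, f_values = f_on_grid,
                       gamma = params$bias_factor_gamma),
                  class = "FreeEnergyProfile")
  st <- profile_state_values(pk, params, bw, uw)
  structure(list(delta_g_bind = st$f_bound - st$f_unbound,
                 f_bound = st$f_bound, f_unbound = st$f_unbound,
                 bound_window = bw, unbound_window = uw,
                 profile = profile, hills = hills, cv = cv,
                 params = params, seed = seed),
            class = "MetaScoreResult")
}

#' @export
print.MetaScoreResult <- function(x, ...) {
  cat(sprintf(paste0("MetaScoreResult: dG_bind = %.2f kcal/mol ",
                     "(bound %.2f, unbound %.2f; %d hills)\n"),
              x$delta_g_bind, x$f_bound, x$f_unbound, nrow(x$hills)))
  invisible(x)
}

#' Compare binding-site variants on a shared binding path
#'
#' Runs MetaScore for a named set of landscape perturbations, reusing the
#' same reference binding path for every variant, and reports the
#' free-energy shift against the unperturbed reference together with
#' whether its sign matches the quadrature ground truth.
#'
#' @param system the reference `ToyLandscape`.
#' @param variants named numeric vector of perturbations (kcal/mol);
#'   the reference (0) is always included as `"reference"`.
#' @param schedule [abmd_schedule()] for the shared path.
#' @param params [wtmetad_parameters()].
#' @param seeds integer vector of seeds; results are averaged and signs
#'   tallied per seed.
#' @return data frame: variant, perturbation, mean dG, mean ddG vs
#'   reference, expected sign, fraction of seeds with the correct sign,
#'   sign_correct (majority vote).
#' @export
compare_variants <- function(system, variants, schedule = abmd_schedule(),
                             params = wtmetad_parameters(),
                             seeds = 1:5) {
  stopifnot(length(variants) > 0, !is.null(names(variants)))
  ref_df <- landscape_delta_f(system, perturbation = 0)
  dg <- matrix(NA_real_, length(seeds), length(variants) + 1,
               dimnames = list(NULL, c("reference", names(variants))))
  for (k in seq_along(seeds)) {
    path <- run_binding_path(system, schedule, seed = seeds[k])
    cv <- path_cv_from_binding_path(path, params)
    dg[k, "reference"] <- run_metascore(system, path$snapshots, params,
                                        seed = seeds[k] * 1000 + 1,
                                        perturbation = 0,
                                        cv = cv)$delta_g_bind
    for (v in seq_along(variants)) {
      dg[k, v + 1] <- run_metascore(system, path$snapshots, params,
                                    seed = seeds[k] * 1000 + 1 + v,
                                    perturbation = variants[v],
                                    cv = cv)$delta_g_bind
    }
  }
  out <- data.frame(variant = c("reference", names(variants)),
                    perturbation = c(0, unname(variants)))
  out$delta_g_bind <- colMeans(dg)
  out$ddg_vs_reference <- out$delta_g_bind - out$delta_g_bind[1]
  out$expected_sign <- vapply(out$perturbation, function(p) {
    truth <- landscape_delta_f(system, perturbation = p) - ref_df
    sign(truth)
  }, numeric(1))
  ddg_per_seed <- dg[, -1, drop = FALSE] - dg[, 1]
  frac <- vapply(seq_along(variants), function(v) {
    es <- out$expected_sign[v + 1]
    if (es == 0) return(NA_real_)
    mean(sign(ddg_per_seed[, v]) == es)
  }, numeric(1))
  out$sign_fraction <- c(NA, frac)
  out$sign_correct <- c(NA, frac >= 0.5)
  out
}
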