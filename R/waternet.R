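# Explicit water networks: iterative hotspot-driven placement, Monte-Carlo
# relaxation, in-context rescoring against a bulk reference, happy/unhappy
# classification, hydrogen-bond graphs and network comparison.

#' Placement schedule
#'
#' Controls the iterative placement loop.  The defaults follow the
#' established protocol: waters are seeded from water-probe hotspots within
#' 10 A of the ligand, starting at a -8 kcal/mol cutoff that is raised by
#' `step` each level until -1 kcal/mol, and rescored within 8 A.
#'
#' @param initial_cutoff,final_cutoff energy cutoffs, kcal/mol
#'   (initial < final < 0).
#' @param step cutoff increment per level, kcal/mol.
#' @param placement_radius radius around the centre in which waters may be
#'   placed, A.
#' @param rescore_radius radius around the ligand (or pocket centre) in
#'   which waters are scored, A.
#' @param clash_distance minimum O-O and O-heavy-atom distance, A.
#' @return a `PlacementSchedule`.
#' @export
placement_schedule <- function(initial_cutoff = -8, final_cutoff = -1,
                               step = 1, placement_radius = 10,
                               rescore_radius = 8, clash_distance = 2.4) {
  if (!(initial_cutoff < final_cutoff && final_cutoff < 0)) {
    stop("need initial_cutoff < final_cutoff < 0")
  }
  stopifnot(step > 0, placement_radius > 0, rescore_radius > 0,
            clash_distance > 0)
  structure(list(initial_cutoff = initial_cutoff,
                 final_cutoff = final_cutoff, step = step,
                 placement_radius = placement_radius,
                 rescore_radius = rescore_radius,
                 clash_distance = clash_distance),
            class = "PlacementSchedule")
}

#' Water free-energy classification scheme
#'
#' Waters are binned by estimated transfer free energy relative to bulk:
#' red (unhappy) above `red_above`, yellow between `yellow_above` and
#' `red_above`, grey between `grey_above` and `yellow_above`, blue (happy)
#' below `grey_above`.
#'
#' @param red_above,yellow_above,grey_above band edges, kcal/mol
#'   (strictly decreasing).
#' @return a `ClassificationScheme`.
#' @export
classification_scheme <- function(red_above = 3.5, yellow_above = 2.0,
                                  grey_above = -1.0) {
  if (!(red_above > yellow_above && yellow_above > grey_above)) {
    stop("need red_above > yellow_above > grey_above")
  }
  structure(list(red_above = red_above, yellow_above = yellow_above,
                 grey_above = grey_above), class = "ClassificationScheme")
}

#' Construct a water network container
#'
#' @param waters water data frame.
#' @param schedule a `PlacementSchedule`.
#' @param center pocket/ligand centre the network was built around, A.
#' @param scores optional score table.
#' @param bulk_reference bulk reference energy, kcal/mol.
#' @return a `WaterNetwork`.
#' @export
new_network <- function(waters, schedule, center, scores = NULL,
                        bulk_reference = NA_real_) {
  structure(list(waters = waters, scores = scores,
                 bulk_reference = bulk_reference, schedule = schedule,
                 center = center), class = "WaterNetwork")
}

#' @export
print.WaterNetwork <- function(x, ...) {
  cat(sprintf("WaterNetwork: %d waters%s\n", nrow(x$waters),
              if (is.null(x$scores)) " (unscored)" else
                sprintf(", %d scored (classes: %s)", nrow(x$scores),
                        paste(names(table(x$scores$class_label)),
                              table(x$scores$class_label),
                              collapse = " ", sep = ":"))))
  invisible(x)
}

# fast hydrogen-bond directions for a water table, matching the atom order
# of water_atoms() (O,H1,H2 per water)
water_hb_dirs <- function(waters) {
  n <- nrow(waters)
  if (n == 0) return(list(idx = integer(0), dirs = list()))
  o <- water_o(waters)
  h1 <- as.matrix(waters[, c("h1x", "h1y", "h1z")])
  h2 <- as.matrix(waters[, c("h2x", "h2y", "h2z")])
  v1 <- (h1 - o) / .tip3p_oh
  v2 <- (h2 - o) / .tip3p_oh
  dirs <- lapply(seq_len(n), function(i) {
    bis <- v1[i, ] + v2[i, ]
    bis <- bis / sqrt(sum(bis^2))
    rbind(v1[i, ], v2[i, ], -bis)
  })
  list(idx = 3 * seq_len(n) - 2, dirs = dirs)
}

#' Calibrate the bulk-solvent reference energy
#'
#' Mean in-context water-probe energy over the interior waters (at least
#' 4 A from every box face) of a bulk box: each interior oxygen is scored
#' with the OH2 probe against all other waters.  Scores of pocket waters
#' are later expressed relative to this value.
#'
#' @param box water table from [make_bulk_box()].
#' @return bulk reference energy, kcal/mol (negative).
#' @export
calibrate_bulk_reference <- function(box) {
  edge <- attr(box, "edge")
  if (is.null(edge)) stop("box must come from make_bulk_box()")
  o <- water_o(box)
  interior <- which(apply(o >= 4 & o <= edge - 4, 1, all))
  if (length(interior) < 20) {
    stop("only ", length(interior),
         " interior waters; use a larger box (need >= 20)")
  }
  atoms <- water_atoms(box)
  hb <- water_hb_dirs(box)
  vapply(interior, function(i) {
    rows <- setdiff(seq_len(nrow(box)), i)
    arows <- as.vector(t(outer(3 * rows - 3, 1:3, "+")))
    sub <- atoms[arows, , drop = FALSE]
    keep <- match(3 * rows - 2, arows)
    subhb <- list(idx = keep, dirs = hb$dirs[rows])
    probe_energy_at_points(o[i, , drop = FALSE], sub, "OH2", hb = subhb)
  }, numeric(1)) |> mean()
}

# clash test: candidate O positions vs existing O and heavy atoms
clash_free <- function(cand, heavy_xyz, o_xyz, clash) {
  ok <- rep(TRUE, nrow(cand))
  for (m in list(heavy_xyz, o_xyz)) {
    if (is.null(m) || nrow(m) == 0) next
    for (i in which(ok)) {
      d2 <- (m[, 1] - cand[i, 1])^2 + (m[, 2] - cand[i, 2])^2 +
        (m[, 3] - cand[i, 3])^2
      if (any(d2 < clash^2)) ok[i] <- FALSE
    }
  }
  ok
}

# deterministic trial rotations (quasi-uniform) for water orientation;
# built lazily to avoid collation-order issues
.rotation_cache <- new.env(parent = emptyenv())
trial_rotations <- function() {
  if (is.null(.rotation_cache$rot)) {
    axes <- fibonacci_sphere(20)
    out <- list()
    for (i in seq_len(20)) {
      for (ang in c(0.4, 2.1, 3.8) + 0.1 * i) {
        out[[length(out) + 1]] <- rotation_matrix(axes[i, ], ang)
      }
    }
    .rotation_cache$rot <- out
  }
  .rotation_cache$rot
}

# Orient one water to minimise its explicit interaction energy with the
# environment pack: 60 trial orientations plus Nelder-Mead refinement.
orient_water <- function(o, env_pack) {
  if (env_pack$n == 0) return(make_water(o))
  escore <- function(R) {
    h <- .water_h_template %*% t(R)
    pair_energy_packed(water_pack(o, o + h[1, ], o + h[2, ]), env_pack)
  }
  rots <- trial_rotations()
  es <- vapply(rots, escore, numeric(1))
  best <- rots[[which.min(es)]]
  opt <- stats::optim(c(0, 0, 0),
                      function(a) escore(euler_matrix(a) %*% best),
                      method = "Nelder-Mead",
                      control = list(maxit = 40, reltol = 1e-4))
  make_water(o, euler_matrix(opt$par) %*% best)
}

#' Iterative hotspot-driven water placement
#'
#' Builds a water network by looping over energy cutoff levels from the
#' initial to the final cutoff: at each level the water-probe field is
#' recomputed with the environment plus all waters placed so far, hotspots
#' at or below the cutoff and within the placement radius of the centre
#' are accepted in order of increasing energy (skipping clashes), and each
#' accepted water's hydrogens are oriented to minimise its interaction
#' energy.  A level terminates when it adds nothing; the loop then raises
#' the cutoff, and the procedure converges when the final level adds
#' nothing.
#'
#' @param environment a typed `ReceptorComplex` (existing waters are kept
#'   and act as environment).
#' @param schedule a [placement_schedule()].
#' @param center placement centre: the ligand centroid for holo input, the
#'   pocket centroid for apo (defaults to the ligand centroid when a
#'   ligand is present).
#' @param max_iterations safety bound on placement rounds.
#' @return a `WaterNetwork` (placed waters only; metadata records the
#'   accepting cutoff level and round).
#' @export
place_waters_iterative <- function(environment, schedule = placement_schedule(),
                                   center = NULL, max_iterations = 200) {
  if (is.null(center)) {
    if (is_apo(environment)) stop("apo environment: supply the pocket centre")
    lx <- environment$ligand$atoms
    center <- c(mean(lx$x), mean(lx$y), mean(lx$z))
  }
  env_at <- env_atoms(environment)
  if (nrow(env_at) == 0 || anyNA(env_at$vdw_class)) {
    stop("environment must contain typed atoms")
  }
  grid <- grid_around(center, schedule$placement_radius + 2)
  pts <- grid_points(grid)
  in_sphere <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2 <= schedule$placement_radius^2

  hb_env <- hb_directions(env_at)
  vals <- probe_energy_at_points(pts, env_at, "OH2", hb = hb_env,
                                 clamp = FALSE)
  heavy_xyz <- as.matrix(env_at[env_at$is_heavy, c("x", "y", "z")])

  waters <- new_waters()
  cutoff_trace <- numeric(0)
  # mutable context pack for orientation scoring
  ctx_pack <- pack_atoms(env_at, dirs = hb_env)

  levels <- seq(schedule$initial_cutoff, schedule$final_cutoff,
                by = schedule$step)
  iteration <- 0
  for (cutoff in levels) {
    repeat {
      iteration <- iteration + 1
      if (iteration > max_iterations) {
        stop("water placement did not converge after ", max_iterations,
             " rounds (", nrow(waters), " waters placed, cutoff ", cutoff, ")")
      }
      varr <- array(ifelse(in_sphere, pmin(vals, .energy_clamp), Inf),
                    grid$shape)
      f <- structure(list(grid = grid, values = varr, probe = "OH2",
                          environment_hash = ""), class = "ScalarField")
      hs <- find_hotspots(f, cutoff)
      added <- 0
      if (nrow(hs) > 0) {
        o_xyz <- water_o(waters)
        cand <- as.matrix(hs[, c("x", "y", "z")])
        ok <- clash_free(cand, heavy_xyz, o_xyz, schedule$clash_distance)
        for (i in which(ok)) {
          o <- cand[i, ]
          if (nrow(waters) > 0) {
            d2 <- (waters$ox - o[1])^2 + (waters$oy - o[2])^2 +
              (waters$oz - o[3])^2
            if (any(d2 < schedule$clash_distance^2)) next
          }
          w <- orient_water(o, ctx_pack)
          w$placement_iteration <- iteration
          w$placement_energy <- hs$energy[i]
          waters <- rbind(waters, w)
          cutoff_trace <- c(cutoff_trace, cutoff)
          added <- added + 1
          wa <- water_atoms(w)
          vals <- vals + probe_energy_at_points(pts, wa, "OH2",
                                                hb = water_hb_dirs(w),
                                                clamp = FALSE)
          ctx_pack <- pack_append(ctx_pack, water_pack(
            as.numeric(w[1, c("ox", "oy", "oz")]),
            as.numeric(w[1, c("h1x", "h1y", "h1z")]),
            as.numeric(w[1, c("h2x", "h2y", "h2z")])))
        }
      }
      if (added == 0) break
    }
  }
  if (nrow(waters) > 0) waters$placement_cutoff <- cutoff_trace
  new_network(waters, schedule, center)
}

# ---- Monte-Carlo relaxation -------------------------------------------------

# context for relaxation: one pack holding receptor (+ligand) and all
# waters, with row bookkeeping for the movers
relax_context <- function(receptor_atoms, ligand_atoms, waters) {
  fixed <- receptor_atoms
  lig_rows <- integer(0)
  if (!is.null(ligand_atoms) && nrow(ligand_atoms)) {
    lig_rows <- nrow(fixed) + seq_len(nrow(ligand_atoms))
    fixed <- rbind(fixed, ligand_atoms)
  }
  fixed$serial <- seq_len(nrow(fixed))
  pk <- pack_atoms(fixed)
  base <- pk$n
  wat_rows <- list()
  for (i in seq_len(nrow(waters))) {
    pk <- pack_append(pk, water_pack(
      as.numeric(waters[i, c("ox", "oy", "oz")]),
      as.numeric(waters[i, c("h1x", "h1y", "h1z")]),
      as.numeric(waters[i, c("h2x", "h2y", "h2z")])))
    wat_rows[[i]] <- base + 3 * (i - 1) + 1:3
  }
  list(pack = pk, lig_rows = lig_rows, wat_rows = wat_rows)
}

#' Relax a water network by Metropolis Monte Carlo
#'
#' Rigid-body water moves (translations up to 0.2 A, rotations up to 15
#' degrees) and, optionally, rigid-body ligand moves (0.1 A / 5 degrees)
#' are accepted by the Metropolis criterion at the given temperature.  The
#' receptor is fixed.  The move energy is the explicit pairwise model of
#' [interaction_energy()]; clash-violating moves are rejected outright.
#' This plays the role of the short restrained molecular-dynamics
#' equilibration of the original protocol: it anneals the hydrogen-bond
#' network (and, with a mobile ligand, lets the ligand respond to the water
#' network) while keeping every molecule near its placement site.
#'
#' @param complex the typed `ReceptorComplex` the network was built in.
#' @param network a `WaterNetwork`.
#' @param n_sweeps Monte-Carlo sweeps (one attempted move per water - and
#'   per ligand when mobile - each sweep); 0 returns the input unchanged.
#' @param mobile_ligand allow rigid-body ligand moves.
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with the relaxed `network` and the (possibly displaced)
#'   `ligand` structure (NULL for apo input).
#' @export
relax_network <- function(complex, network, n_sweeps = 200,
                          mobile_ligand = FALSE, temperature = 300,
                          seed = 1) {
  if (n_sweeps < 0) stop("n_sweeps must be >= 0")
  if (nrow(network$waters) == 0 && !mobile_ligand) {
    stop("nothing to relax: empty network and fixed ligand")
  }
  if (n_sweeps == 0) return(list(network = network, ligand = complex$ligand))
  kT <- .kB * temperature
  clash <- network$schedule$clash_distance

  withr::with_seed(seed, {
    waters <- network$waters
    ligand <- complex$ligand
    ctx <- relax_context(complex$receptor$atoms,
                         if (is.null(ligand)) NULL else ligand$atoms,
                         waters)
    pk <- ctx$pack
    rec_heavy <- as.matrix(
      complex$receptor$atoms[complex$receptor$atoms$is_heavy,
                             c("x", "y", "z")])
    nw <- nrow(waters)
    o_rows <- vapply(ctx$wat_rows, function(r) as.integer(r[1]), 0L)
    # per-water environment subpacks, refreshed every few sweeps (movers
    # drift at most 0.2 A per sweep; the 2.5 A margin keeps them valid)
    env_cache <- vector("list", nw)
    refresh_every <- 5
    for (sweep in seq_len(n_sweeps)) {
      refresh <- (sweep - 1) %% refresh_every == 0
      for (i in seq_len(nw)) {
        rows <- ctx$wat_rows[[i]]
        xyz <- pk$pos[rows, , drop = FALSE]
        if (refresh || is.null(env_cache[[i]])) {
          env_cache[[i]] <- pack_near(pk, xyz[1, ], 8.5 + 2.5, rows)
        }
        tr <- stats::runif(3, -1, 1)
        tr <- tr / max(1, sqrt(sum(tr^2))) * stats::runif(1, 0, 0.2)
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        R <- rotation_matrix(ax, stats::runif(1, -1, 1) * 15 * pi / 180)
        o_old <- xyz[1, ]
        new_xyz <- t(R %*% (t(xyz) - o_old) + o_old + tr)
        o_new <- new_xyz[1, ]
        hv <- rec_heavy
        if (length(ctx$lig_rows)) {
          hv <- rbind(hv, pk$pos[ctx$lig_rows, , drop = FALSE][
            pk$heavy[ctx$lig_rows], , drop = FALSE])
        }
        o_others <- pk$pos[o_rows[-i], , drop = FALSE]
        if (!clash_free(matrix(o_new, 1, 3), hv,
                        if (nw > 1) o_others else NULL, clash)) next
        env <- env_cache[[i]]
        w_old <- water_pack(xyz[1, ], xyz[2, ], xyz[3, ])
        w_new <- water_pack(new_xyz[1, ], new_xyz[2, ], new_xyz[3, ])
        de <- pair_energy_packed(w_new, env) - pair_energy_packed(w_old, env)
        if (de <= 0 || stats::runif(1) < exp(-de / kT)) {
          pk <- pack_set_rows(pk, rows, new_xyz)
        }
      }
      if (mobile_ligand && length(ctx$lig_rows)) {
        rows <- ctx$lig_rows
        xyz <- pk$pos[rows, , drop = FALSE]
        tr <- stats::runif(3, -1, 1)
        tr <- tr / max(1, sqrt(sum(tr^2))) * stats::runif(1, 0, 0.1)
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        R <- rotation_matrix(ax, stats::runif(1, -1, 1) * 5 * pi / 180)
        ctr <- colMeans(xyz)
        new_xyz <- t(R %*% (t(xyz) - ctr) + ctr + tr)
        heavy_new <- new_xyz[pk$heavy[rows], , drop = FALSE]
        o_all <- pk$pos[o_rows, , drop = FALSE]
        if (all(clash_free(heavy_new, rec_heavy,
                           if (nw > 0) o_all else NULL, clash))) {
          env <- pack_drop_rows(pk, rows)
          sub_old <- pack_drop_rows(pk, setdiff(seq_len(pk$n), rows))
          sub_new <- pack_set_rows(sub_old, seq_along(rows), new_xyz)
          # rotate bare-donor ideal directions with the rigid body
          if (length(sub_new$bare)) {
            sub_new$bare_dir <- lapply(sub_new$bare_dir, function(d) {
              if (is.null(d)) NULL else d %*% t(R)
            })
          }
          de <- pair_energy_packed(sub_new, env) -
            pair_energy_packed(sub_old, env)
          if (de <= 0 || stats::runif(1) < exp(-de / kT)) {
            pk <- pack_set_rows(pk, rows, new_xyz)
            for (k in seq_along(pk$bare)) {
              if (pk$bare[k] %in% rows) {
                d <- pk$bare_dir[[k]]
                if (!is.null(d)) pk$bare_dir[[k]] <- d %*% t(R)
              }
            }
          }
        }
      }
    }
    # read back
    for (i in seq_len(nw)) {
      m <- pk$pos[ctx$wat_rows[[i]], , drop = FALSE]
      waters$ox[i] <- m[1, 1]; waters$oy[i] <- m[1, 2]; waters$oz[i] <- m[1, 3]
      waters$h1x[i] <- m[2, 1]; waters$h1y[i] <- m[2, 2]; waters$h1z[i] <- m[2, 3]
      waters$h2x[i] <- m[3, 1]; waters$h2y[i] <- m[3, 2]; waters$h2z[i] <- m[3, 3]
    }
    if (!is.null(ligand) && length(ctx$lig_rows)) {
      ligand$atoms[, c("x", "y", "z")] <- pk$pos[ctx$lig_rows, , drop = FALSE]
    }
    network$waters <- waters
    list(network = network, ligand = ligand)
  })
}

#' Total explicit energy of the water network system
#'
#' Sum of all water-water pair energies, water-environment energies, and
#' (when a ligand is present) the ligand-receptor energy, under the same
#' pairwise model the Monte-Carlo relaxation samples.
#'
#' @param complex a typed `ReceptorComplex`.
#' @param network a `WaterNetwork`.
#' @return energy, kcal/mol.
#' @export
system_energy <- function(complex, network) {
  waters <- network$waters
  ctx <- relax_context(complex$receptor$atoms,
                       if (is.null(complex$ligand)) NULL else
                         complex$ligand$atoms,
                       waters)
  pk <- ctx$pack
  e <- 0
  nw <- nrow(waters)
  wpacks <- lapply(seq_len(nw), function(i) {
    rows <- ctx$wat_rows[[i]]
    water_pack(pk$pos[rows[1], ], pk$pos[rows[2], ], pk$pos[rows[3], ])
  })
  fixed_rows <- setdiff(seq_len(pk$n), unlist(ctx$wat_rows))
  fixed <- pack_drop_rows(pk, unlist(ctx$wat_rows))
  for (i in seq_len(nw)) {
    e <- e + pair_energy_packed(wpacks[[i]], fixed)
    for (j in seq_len(nw)) {
      if (j > i) e <- e + pair_energy_packed(wpacks[[i]], wpacks[[j]])
    }
  }
  if (!is.null(complex$ligand)) {
    e <- e + interaction_energy(complex$ligand$atoms, complex$receptor$atoms)
  }
  e
}

# ---- scoring and classification --------------------------------------------

#' Rescore waters in context
#'
#' For every water within the rescore radius of the ligand (or of the
#' pocket centre for apo input), computes its in-context water-probe energy
#' (receptor + ligand + all other waters), the lipophilic CRY energy at the
#' oxygen (receptor + ligand only), and the free-energy estimate
#'
#'   `dG = (E_OH2,context - E_bulk) + lambda_lip * max(0, -E_CRY)`
#'
#' so that waters sitting in strong lipophilic hotspots are penalised even
#' when reasonably hydrogen bonded - the unhappy-water signature.
#'
#' @param complex typed `ReceptorComplex`.
#' @param network a `WaterNetwork`.
#' @param bulk_reference kcal/mol, from [calibrate_bulk_reference()].
#' @param lambda_lip weight of the lipophilic penalty.
#' @return the network with a `scores` table attached.
#' @export
rescore_waters <- function(complex, network, bulk_reference,
                           lambda_lip = 0.5) {
  if (is.na(bulk_reference)) stop("bulk_reference has not been calibrated")
  waters <- network$waters
  n <- nrow(waters)
  if (n == 0) {
    network$scores <- data.frame(water_index = integer(0),
                                 e_oh2_context = numeric(0),
                                 e_cry = numeric(0),
                                 delta_g_est = numeric(0),
                                 class_label = character(0))
    network$bulk_reference <- bulk_reference
    return(network)
  }
  o <- water_o(waters)
  if (!is.null(complex$ligand)) {
    lx <- complex$ligand$atoms
    lh <- as.matrix(lx[lx$is_heavy, c("x", "y", "z")])
    dist_ref <- vapply(seq_len(n), function(i) {
      min(sqrt((lh[, 1] - o[i, 1])^2 + (lh[, 2] - o[i, 2])^2 +
               (lh[, 3] - o[i, 3])^2))
    }, numeric(1))
  } else {
    ctr <- network$center
    dist_ref <- sqrt((o[, 1] - ctr[1])^2 + (o[, 2] - ctr[2])^2 +
                     (o[, 3] - ctr[3])^2)
  }
  sel <- which(dist_ref <= network$schedule$rescore_radius)

  env_fix <- env_atoms(complex, include = c("receptor", "ligand"))
  hb_fix <- hb_directions(env_fix)
  wa <- water_atoms(waters)
  whb <- water_hb_dirs(waters)

  rowsets <- lapply(seq_len(n), function(i) 3 * (i - 1) + 1:3)
  scores <- do.call(rbind, lapply(sel, function(i) {
    others <- setdiff(seq_len(n), i)
    arows <- unlist(rowsets[others])
    ctx <- rbind(env_fix, wa[arows, , drop = FALSE])
    ctx$serial <- seq_len(nrow(ctx))
    hb <- list(idx = c(hb_fix$idx,
                       nrow(env_fix) + match(3 * others - 2, arows)),
               dirs = c(hb_fix$dirs, whb$dirs[others]))
    e_oh2 <- probe_energy_at_points(o[i, , drop = FALSE], ctx, "OH2",
                                    hb = hb)
    e_cry <- cry_energy_at_points(o[i, , drop = FALSE], env_fix, hb = hb_fix)
    data.frame(water_index = i, e_oh2_context = e_oh2, e_cry = e_cry,
               delta_g_est = (e_oh2 - bulk_reference) +
                 lambda_lip * max(0, -e_cry),
               class_label = NA_character_)
  }))
  if (is.null(scores)) {
    scores <- data.frame(water_index = integer(0), e_oh2_context = numeric(0),
                         e_cry = numeric(0), delta_g_est = numeric(0),
                         class_label = character(0))
  }
  network$scores <- scores
  network$bulk_reference <- bulk_reference
  network
}

#' Classify scored waters
#'
#' Partitions the estimated free energies into the four canonical bands:
#' red above 3.5 kcal/mol, yellow in (2.0, 3.5], grey in [-1.0, 2.0], blue
#' below -1.0 kcal/mol (defaults of [classification_scheme()]).
#'
#' @param network a scored `WaterNetwork`.
#' @param scheme a `ClassificationScheme`.
#' @return the network with `class_label` filled in.
#' @export
classify_waters <- function(network, scheme = classification_scheme()) {
  if (is.null(network$scores)) stop("network has no scores; rescore first")
  dg <- network$scores$delta_g_est
  network$scores$class_label <- ifelse(
    dg > scheme$red_above, "red",
    ifelse(dg > scheme$yellow_above, "yellow",
           ifelse(dg >= scheme$grey_above, "grey", "blue")))
  network
}

#' Hydrogen-bond graph of a solvated complex
#'
#' Nodes are waters plus the polar (donor/acceptor) heavy atoms of receptor
#' and ligand; an edge is drawn when the donor-acceptor heavy-atom distance
#' is at most 3.5 A and the D-H...A angle is at least 120 degrees (donors
#' without explicit hydrogens fall back to a 60-degree cone around their
#' ideal direction).  Node degree is attached as a vertex attribute.
#'
#' @param complex typed `ReceptorComplex`.
#' @param network a `WaterNetwork`.
#' @return an igraph undirected graph.
#' @export
hbond_graph <- function(complex, network) {
  env_fix <- env_atoms(complex, include = c("receptor", "ligand"))
  polar <- env_fix[env_fix$hbond_role != "none" & env_fix$is_heavy, ,
                   drop = FALSE]
  waters <- network$waters
  nw <- nrow(waters)
  wnames <- if (nw > 0) paste0("W", seq_len(nw)) else character(0)
  pnames <- if (nrow(polar) > 0) {
    paste0(polar$chain, "/", polar$resname, polar$resno, "/", polar$name)
  } else character(0)
  all_atoms <- rbind(
    if (nw > 0) water_atoms(waters) else empty_atoms(), polar)
  all_atoms$serial <- seq_len(max(1, nrow(all_atoms)))
  dh <- donor_hydrogens(all_atoms)
  dirs <- hb_directions(all_atoms)
  heavy_ids <- c(if (nw > 0) 3 * seq_len(nw) - 2 else integer(0),
                 if (nrow(polar) > 0) 3 * nw + seq_len(nrow(polar)))
  node_names <- c(wnames, pnames)
  xyz <- as.matrix(all_atoms[, c("x", "y", "z")])
  edges <- character(0)
  nn <- length(heavy_ids)
  for (a in seq_len(nn)) {
    for (b in seq_len(nn)) {
      if (b <= a) next
      i <- heavy_ids[a]; j <- heavy_ids[b]
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > 3.5 || r < 0.5) next
      bonded <- FALSE
      for (pair in list(c(i, j), c(j, i))) {
        d <- pair[1]; acc <- pair[2]
        if (!(all_atoms$hbond_role[d] %in% c("donor", "both"))) next
        if (!(all_atoms$hbond_role[acc] %in% c("acceptor", "both"))) next
        hs <- dh$h[dh$d == d]
        if (length(hs) > 0) {
          for (h in hs) {
            v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
            cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            if (cth < -0.5) { bonded <- TRUE; break }
          }
        } else {
          di <- dirs$dirs[[match(d, dirs$idx)]]
          if (is.null(di)) { bonded <- TRUE } else {
            u <- (xyz[acc, ] - xyz[d, ]) / r
            if (max(u %*% t(di)) > 0.5) bonded <- TRUE
          }
        }
        if (bonded) break
      }
      if (bonded) edges <- c(edges, node_names[a], node_names[b])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_names), name = node_names,
                            kind = c(rep("water", nw),
                                     rep("polar_atom", length(pnames))))
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Compare two scored water networks
#'
#' Waters are matched greedily by oxygen-oxygen distance (closest pairs
#' first, 1.0 A cap); unmatched waters are reported as gained (present in
#' `b` only) or lost (in `a` only), matched waters with different class
#' labels as re-classified.  The change in summed free-energy estimates
#' over a spherical region of interest is also reported.
#'
#' @param a,b scored (and classified) `WaterNetwork`s.
#' @param region list with `center` (3-vector) and `radius` (A); defaults
#'   to the whole network.
#' @return a `NetworkDiff` list: `matched` (index pairs), `gained`, `lost`
#'   (indices), `reclassified` (data frame), `delta_sum_dg` (kcal/mol,
#'   b minus a over the region).
#' @export
compare_networks <- function(a, b, region = NULL) {
  if (is.null(a$scores) || is.null(b$scores)) {
    stop("both networks must be scored before comparison")
  }
  oa <- water_o(a$waters); ob <- water_o(b$waters)
  na <- nrow(oa); nb <- nrow(ob)
  pairs <- expand.grid(i = seq_len(na), j = seq_len(nb))
  if (nrow(pairs) > 0) {
    pairs$d <- sqrt(rowSums((oa[pairs$i, , drop = FALSE] -
                             ob[pairs$j, , drop = FALSE])^2))
    pairs <- pairs[pairs$d <= 1.0, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
  }
  used_a <- logical(na); used_b <- logical(nb)
  mi <- integer(0); mj <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  cls <- function(net, idx) {
    m <- match(idx, net$scores$water_index)
    net$scores$class_label[m]
  }
  recl <- data.frame(a_index = mi, b_index = mj,
                     class_a = cls(a, mi), class_b = cls(b, mj))
  recl <- recl[!is.na(recl$class_a) & !is.na(recl$class_b) &
               recl$class_a != recl$class_b, , drop = FALSE]
  sum_region <- function(net, o) {
    s <- net$scores
    if (nrow(s) == 0) return(0)
    keep <- rep(TRUE, nrow(s))
    if (!is.null(region)) {
      pos <- o[s$water_index, , drop = FALSE]
      keep <- sqrt((pos[, 1] - region$center[1])^2 +
                   (pos[, 2] - region$center[2])^2 +
                   (pos[, 3] - region$center[3])^2) <= region$radius
    }
    sum(s$delta_g_est[keep])
  }
  structure(list(
    matched = data.frame(a_index = mi, b_index = mj),
    gained = which(!used_b),
    lost = which(!used_a),
    reclassified = recl,
    delta_sum_dg = sum_region(b, ob) - sum_region(a, oa)
  ), class = "NetworkDiff")
}

#' @export
print.NetworkDiff <- function(x, ...) {
  cat(sprintf(paste0("NetworkDiff: %d matched, %d gained, %d lost, ",
                     "%d re-classified; sum dG change %.2f kcal/mol\n"),
              nrow(x$matched), length(x$gained), length(x$lost),
              nrow(x$reclassified), x$delta_sum_dg))
  invisible(x)
}

#' Validate network clash invariants
#'
#' TRUE when no O-O pair and no O vs environment heavy atom violates the
#' schedule's clash distance.
#'
#' @param complex typed `ReceptorComplex`.
#' @param network a `WaterNetwork`.
#' @export
network_is_valid <- function(complex, network) {
  waters <- network$waters
  if (nrow(waters) == 0) return(TRUE)
  o <- water_o(waters)
  clash <- network$schedule$clash_distance
  if (nrow(waters) > 1 && min(stats::dist(o)) < clash) return(FALSE)
  env <- env_atoms(complex, include = c("receptor", "ligand"))
  hv <- as.matrix(env[env$is_heavy, c("x", "y", "z")])
  for (i in seq_len(nrow(o))) {
    d2 <- (hv[, 1] - o[i, 1])^2 + (hv[, 2] - o[i, 2])^2 +
      (hv[, 3] - o[i, 3])^2
    if (any(d2 < clash^2)) return(FALSE)
  }
  TRUE
}
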