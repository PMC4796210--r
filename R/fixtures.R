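# Synthetic fixtures: toy cavity receptors with planted sites, rigid toy
# ligands, bulk water boxes, and analytic binding landscapes with known
# free-energy differences.  All generators are deterministic per seed.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

orthonormal_tangents <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Generate a toy cavity receptor with planted sites
#'
#' Builds a spherical shell of apolar pseudo-atoms (radius ~12 A) that
#' encloses a solvent cavity, then plants polar hydration sites and
#' lipophilic subpockets on an inner sphere:
#'
#' * a polar site is a pair of serine-like hydroxyl groups (OG + CB stem,
#'   two pseudo-residues) aimed at the planted position from 2.9 A, so the
#'   position is a strong water (OH2) hotspot (about -8 kcal/mol, two
#'   ideal hydrogen bonds);
#' * a lipophilic site is a cup of aromatic carbons all at the
#'   Lennard-Jones optimum distance from the planted position, so the
#'   position is a C1=/CRY hotspot below the -2.7 kcal/mol contour but not
#'   an OH2 hotspot.
#'
#' Shell atoms overlapping planted clusters are carved away.  The ground
#' truth (positions, character, intended role) is returned as a manifest.
#'
#' @param n_polar_sites,n_lipophilic_sites number of planted sites (>= 0).
#' @param seed RNG seed; output is bit-deterministic per seed.
#' @param shell_radius,site_radius geometry knobs, A.
#' @param adjacent_pair when TRUE (requires at least one site of each
#'   character) the first polar and first lipophilic site are planted
#'   `pair_separation` A apart - a druggable-subpocket motif - with the
#'   cup opened on the polar-facing side; all other separations stay at
#'   >= 7 A.
#' @param pair_separation distance between the paired sites, A.  The
#'   default 4.0 is tuned for the methyl/des-methyl scenario; 3.6 with
#'   `cup_clearance = 3.1` brings the subpocket inside the 4 A hotspot
#'   adjacency used by the druggability analysis.
#' @param cup_clearance cup atoms closer than this to the paired polar
#'   site are carved away, A.
#' @return list with elements `complex` (a typed `ReceptorComplex`),
#'   `manifest` (data frame: x, y, z, character, intended_role, resno of
#'   the first host residue for polar sites) and `center` (pocket centre).
#' @export
make_toy_cavity <- function(n_polar_sites, n_lipophilic_sites, seed = 1,
                            shell_radius = 12, site_radius = 8.5,
                            adjacent_pair = FALSE, pair_separation = 4.0,
                            cup_clearance = 2.6) {
  stopifnot(n_polar_sites >= 0, n_lipophilic_sites >= 0)
  if (adjacent_pair && (n_polar_sites < 1 || n_lipophilic_sites < 1)) {
    stop("adjacent_pair needs at least one polar and one lipophilic site")
  }
  n_sites <- n_polar_sites + n_lipophilic_sites
  withr::with_seed(seed, {
    # pick well-separated site directions (chord >= 7 A at site_radius)
    dirs <- matrix(numeric(0), 0, 3)
    tries <- 0
    while (nrow(dirs) < n_sites && tries < 5000) {
      tries <- tries + 1
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      if (nrow(dirs) == 0 ||
          min(sqrt(rowSums((dirs * site_radius -
                            matrix(v * site_radius, nrow(dirs), 3,
                                   byrow = TRUE))^2))) >= 7) {
        dirs <- rbind(dirs, v)
      }
    }
    if (nrow(dirs) < n_sites) {
      stop("could not separate ", n_sites, " planted sites by >= 3 A")
    }
    pair_lip_index <- NA_integer_
    if (adjacent_pair) {
      # move the first lipophilic site next to the first polar site
      # (chord ~4 A on the site sphere)
      u1 <- dirs[1, ]
      tb0 <- orthonormal_tangents(u1)
      ang <- 2 * asin(pair_separation / (2 * site_radius))
      v <- cos(ang) * u1 + sin(ang) * tb0$t2
      dirs[n_polar_sites + 1, ] <- v / sqrt(sum(v^2))
      pair_lip_index <- n_polar_sites + 1L
    }

    rows <- list()
    resno <- 0L
    serial <- 0L
    add_atom <- function(name, element, resname, pos, new_res = TRUE) {
      if (new_res) resno <<- resno + 1L
      serial <<- serial + 1L
      rows[[length(rows) + 1]] <<- data.frame(
        serial = serial, name = name, element = element, resname = resname,
        resno = resno, chain = "A", x = pos[1], y = pos[2], z = pos[3],
        is_heavy = TRUE, stringsAsFactors = FALSE)
    }

    manifest <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                           character = character(0),
                           intended_role = character(0),
                           host_resno = integer(0))
    site_atoms_start <- length(rows)

    for (i in seq_len(n_sites)) {
      u <- dirs[i, ]
      p <- u * site_radius
      tb <- orthonormal_tangents(u)
      if (i <= n_polar_sites) {
        first_host <- resno + 1L
        for (sgn in c(1, -1)) {
          # for the adjacent pair, bias both anchor hosts away from the
          # cup: a ligand sliding into the subpocket then stretches its
          # anchor hydrogen bonds (the toy's version of the repositioning
          # that accompanies substituent removal)
          ax <- if (adjacent_pair && i == 1) {
            v <- -0.6 * tb$t2 + sgn * 0.8 * tb$t1
            v / sqrt(sum(v^2))
          } else {
            sgn * tb$t1
          }
          w <- cos(38 * pi / 180) * u + sin(38 * pi / 180) * ax
          add_atom("OG", "O", "SER", p + 2.9 * w, new_res = TRUE)
          add_atom("CB", "C", "SER", p + 4.4 * w, new_res = FALSE)
        }
        manifest <- rbind(manifest, data.frame(
          x = p[1], y = p[2], z = p[3], character = "polar",
          intended_role = "hydration-site", host_resno = first_host))
      } else {
        # cup of 13 aromatic carbons, all 3.83 A from p (the C1= LJ optimum)
        r_opt <- 3.83
        ring <- function(a, nring, phase) {
          rr <- sqrt(r_opt^2 - a^2)
          for (k in seq_len(nring)) {
            ang <- 2 * pi * (k - 1) / nring + phase
            pos <- p + a * u + rr * (cos(ang) * tb$t1 + sin(ang) * tb$t2)
            add_atom("C", "C", "LIP", pos, new_res = TRUE)
          }
        }
        ring(1.6, 6, 0)
        ring(3.0, 6, pi / 6)
        add_atom("C", "C", "LIP", p + r_opt * u, new_res = TRUE)
        manifest <- rbind(manifest, data.frame(
          x = p[1], y = p[2], z = p[3], character = "lipophilic",
          intended_role = "hotspot", host_resno = NA_integer_))
      }
    }
    site_at <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(site_at) && adjacent_pair) {
      # open the cup towards the adjacent polar site so the two clusters
      # do not collide and the hydration site keeps its geometry
      pol <- site_at[site_at$resname == "SER", , drop = FALSE]
      ppos <- as.numeric(manifest[1, c("x", "y", "z")])
      drop_lip <- site_at$resname == "LIP" &
        vapply(seq_len(nrow(site_at)), function(k) {
          p <- c(site_at$x[k], site_at$y[k], site_at$z[k])
          min(sqrt((pol$x - p[1])^2 + (pol$y - p[2])^2 +
                   (pol$z - p[3])^2)) < 2.4 ||
            sqrt(sum((p - ppos)^2)) < cup_clearance
        }, logical(1))
      site_at <- site_at[!drop_lip, , drop = FALSE]
      rows <- lapply(seq_len(nrow(site_at)), function(k) site_at[k, ])
    }

    # wall shell, carved around the planted clusters
    n_shell <- round(4 * pi * shell_radius^2 / 3.0^2)
    shell <- fibonacci_sphere(n_shell) * shell_radius
    if (!is.null(site_at) && nrow(site_at) > 0) {
      sxyz <- as.matrix(site_at[, c("x", "y", "z")])
      keep <- vapply(seq_len(nrow(shell)), function(k) {
        min(sqrt(rowSums((sxyz - matrix(shell[k, ], nrow(sxyz), 3,
                                        byrow = TRUE))^2))) >= 2.8
      }, logical(1))
      shell <- shell[keep, , drop = FALSE]
    }
    for (k in seq_len(nrow(shell))) {
      add_atom("C", "C", "WAL", shell[k, ], new_res = TRUE)
    }
    at <- do.call(rbind, rows)
    rownames(at) <- NULL

    # integrity: no two heavy atoms closer than 0.8 A
    xyz <- as.matrix(at[, c("x", "y", "z")])
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.8) stop("degenerate cavity geometry (atoms ", round(dmin, 2),
                         " A apart); use a different seed")

    receptor <- assign_atom_types(new_structure(
      at, role = "receptor",
      provenance = sprintf("make_toy_cavity(%d,%d,seed=%d)",
                           n_polar_sites, n_lipophilic_sites, seed)))
    list(complex = new_complex(receptor), manifest = manifest,
         center = c(0, 0, 0))
  })
}

#' Build a rigid toy ligand over planted sites
#'
#' The ligand anchors a polar nitrogen on the first polar site (forming
#' hydrogen bonds with that site's serine hosts), runs a chain of aliphatic
#' linker carbons towards each remaining site, and - when `with_methyl` is
#' TRUE - ends with a terminal methyl carbon sitting exactly on the first
#' lipophilic site.  With `with_methyl = FALSE` the methyl is omitted and
#' the chain stops one bond short, leaving the subpocket vacated: the
#' methyl/des-methyl pair differs by exactly one heavy atom.
#'
#' @param occupies manifest rows (from [make_toy_cavity()]) to occupy; must
#'   contain at least one site.
#' @param with_methyl place the terminal methyl on the first lipophilic
#'   site.
#' @return a typed `MolecularStructure` with role ligand.
#' @export
make_toy_ligand <- function(occupies, with_methyl = TRUE) {
  if (is.null(occupies) || nrow(occupies) == 0) {
    stop("need at least one site to occupy")
  }
  polar <- occupies[occupies$character == "polar", , drop = FALSE]
  lipo <- occupies[occupies$character == "lipophilic", , drop = FALSE]
  ord <- rbind(polar, lipo)  # anchor first, methyl target last
  targets <- as.matrix(ord[, c("x", "y", "z")])
  pos <- list(); nm <- list(); el <- list()
  push <- function(p, name, element) {
    pos[[length(pos) + 1]] <<- p
    nm[[length(nm) + 1]] <<- name
    el[[length(el) + 1]] <<- element
  }
  if (nrow(polar) > 0) {
    push(targets[1, ], "N1", "N")
  } else {
    push(targets[1, ], "C2", "C")
  }
  ci <- 2L
  for (k in seq_len(nrow(ord))[-1]) {
    a <- targets[k - 1, ]; b <- targets[k, ]
    d <- sqrt(sum((b - a)^2))
    nseg <- ceiling(d / 1.5)
    for (j in seq_len(nseg)) {
      q <- a + (b - a) * j / nseg
      is_last <- (j == nseg)
      if (is_last && k == nrow(ord) && nrow(lipo) > 0) {
        if (with_methyl) push(q, "CM", "C")
        # des-methyl: chain simply stops one bond short
      } else {
        ci <- ci + 1L
        push(q, paste0("C", ci), "C")
      }
    }
  }
  at <- data.frame(
    serial = seq_along(pos),
    name = unlist(nm), element = unlist(el),
    resname = "LIG", resno = 1L, chain = "L",
    x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
    z = vapply(pos, `[`, 0, 3),
    is_heavy = TRUE, stringsAsFactors = FALSE)
  assign_atom_types(new_structure(at, role = "ligand",
                                  provenance = "make_toy_ligand"))
}

#' Generate a bulk water box
#'
#' Waters on a jittered cubic lattice at the bulk number density
#' 0.0334 molecules/A^3 (about 1 g/cm^3) with randomised orientations.
#' The jitter amplitude is capped so that no O-O pair can come closer than
#' 2.4 A.  Used to calibrate the bulk reference energy that water scores
#' are measured against.
#'
#' @param edge box edge, A (>= 12).
#' @param seed RNG seed.
#' @return water data frame with attributes `edge` and `seed`.
#' @export
make_bulk_box <- function(edge, seed = 1) {
  if (edge < 12) stop("box edge must be at least 12 A")
  n <- round(.water_density * edge^3)
  m <- ceiling(n^(1 / 3))
  spacing <- edge / m
  jit <- max(0, min(0.25, (spacing - 2.45) / (2 * sqrt(3))))
  withr::with_seed(seed, {
    g <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
    g <- g[seq_len(n), , drop = FALSE]
    ctr <- (as.matrix(g) - 0.5) * spacing
    ctr <- ctr + matrix(stats::runif(3 * n, -jit, jit), n, 3)
    ws <- do.call(rbind, lapply(seq_len(n), function(i) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      make_water(ctr[i, ], rotation_matrix(ax, stats::runif(1, 0, 2 * pi)))
    }))
    attr(ws, "edge") <- edge
    attr(ws, "seed") <- seed
    ws
  })
}

# ---- analytic binding landscapes -------------------------------------------

#' Analytic toy binding landscape
#'
#' A one-dimensional double-well surrogate for a ligand binding event: the
#' unbound state is a flat reference region around progress coordinate 0,
#' the bound state a Gaussian well of the stated depth at coordinate 1,
#' with a Gaussian barrier between and soft walls outside.  One progress
#' unit corresponds to `length_scale` (default 10) Angstroms of physical
#' binding-path length, so the adiabatic-bias machinery works in Angstroms
#' with its conventional parameter values.  An optional perturbation term
#' added at the bound well models a binding-site mutation.  The analytic
#' free-energy difference between the two states is computed by numerical
#' quadrature of the Boltzmann integral and stored in the manifest.
#'
#' @param depth_bound bound-well depth, kcal/mol (< 0).
#' @param barrier barrier height, kcal/mol (>= 0).
#' @param perturbation additive Gaussian at the bound well, kcal/mol
#'   (positive destabilises binding).
#' @param seed recorded for provenance (the landscape itself is analytic
#'   and deterministic).
#' @param temperature K.
#' @return a `ToyLandscape` with a `manifest` holding the quadrature
#'   `delta_f`.
#' @export
make_binding_landscape <- function(depth_bound = -5, barrier = 3,
                                   perturbation = 0, seed = 1,
                                   temperature = 300) {
  stopifnot(depth_bound < 0, barrier >= 0)
  land <- structure(list(
    dimension = 1L,
    depth_bound = depth_bound,
    barrier = barrier,
    perturbation = perturbation,
    well_width = 0.1,       # progress units
    barrier_width = 0.15,
    x_unbound = 0, x_bound = 1,
    bounds = c(-0.25, 1.25),
    wall_k = 400,           # kcal/mol per unit^2
    length_scale = 10,      # Angstrom per progress unit
    temperature = temperature,
    seed = seed
  ), class = "ToyLandscape")
  land$manifest <- list(
    delta_f = landscape_delta_f(land),
    unbound_window = c(-0.25, 0.25),
    bound_window = c(0.75, 1.25)
  )
  land
}

#' Landscape potential
#'
#' Potential energy at progress coordinate `x` (units of the landscape),
#' optionally with a variant perturbation overriding the built-in one.
#'
#' @param land a `ToyLandscape`.
#' @param x numeric vector of progress coordinates.
#' @param perturbation override for the bound-well perturbation, kcal/mol.
#' @return energies, kcal/mol.
#' @export
landscape_potential <- function(land, x, perturbation = NULL) {
  p <- if (is.null(perturbation)) land$perturbation else perturbation
  w <- land$well_width; bw <- land$barrier_width
  v <- (land$depth_bound + p) * exp(-(x - land$x_bound)^2 / (2 * w^2)) +
    land$barrier * exp(-(x - 0.5)^2 / (2 * bw^2))
  lo <- land$bounds[1]; hi <- land$bounds[2]
  v + land$wall_k * (pmax(0, lo - x)^2 + pmax(0, x - hi)^2)
}

# derivative dV/dx (progress units)
landscape_gradient <- function(land, x, perturbation = NULL) {
  p <- if (is.null(perturbation)) land$perturbation else perturbation
  w <- land$well_width; bw <- land$barrier_width
  g <- (land$depth_bound + p) * exp(-(x - land$x_bound)^2 / (2 * w^2)) *
    (-(x - land$x_bound) / w^2) +
    land$barrier * exp(-(x - 0.5)^2 / (2 * bw^2)) * (-(x - 0.5) / bw^2)
  lo <- land$bounds[1]; hi <- land$bounds[2]
  g - 2 * land$wall_k * pmax(0, lo - x) + 2 * land$wall_k * pmax(0, x - hi)
}

#' Quadrature free-energy difference of a landscape
#'
#' `dF = -kT log(Z_bound / Z_unbound)` with the Boltzmann integrals taken
#' over the stated state windows.  This is the ground truth the enhanced-
#' sampling estimate is compared against.
#'
#' @param land a `ToyLandscape`.
#' @param perturbation optional perturbation override.
#' @export
landscape_delta_f <- function(land, perturbation = NULL) {
  kT <- .kB * land$temperature
  f <- function(x) exp(-landscape_potential(land, x, perturbation) / kT)
  zb <- stats::integrate(f, 0.75, 1.25, rel.tol = 1e-10)$value
  zu <- stats::integrate(f, -0.25, 0.25, rel.tol = 1e-10)$value
  -kT * log(zb / zu)
}

#' @export
print.ToyLandscape <- function(x, ...) {
  cat(sprintf(paste0("ToyLandscape: bound depth %.2f, barrier %.2f, ",
                     "perturbation %.2f kcal/mol; quadrature dF = %.3f\n"),
              x$depth_bound, x$barrier, x$perturbation, x$manifest$delta_f))
  invisible(x)
}
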