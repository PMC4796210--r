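# Molecular interaction fields on a lattice: probe maps, hotspots,
# pocket surfaces, OpenDX export.

#' Lattice geometry
#'
#' @param origin 3-vector, A; position of grid point (1,1,1).
#' @param spacing grid spacing, A (> 0).
#' @param shape integer 3-vector of grid dimensions (each >= 2).
#' @return a `GridSpec` object.
#' @export
grid_spec <- function(origin, spacing, shape) {
  stopifnot(spacing > 0, length(shape) == 3, all(shape >= 2))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = as.integer(shape)), class = "GridSpec")
}

#' Auto-fit a grid around an environment
#'
#' Bounding box of all heavy atoms plus a margin, at the default half-
#' Angstrom spacing.
#'
#' @param complex complex or structure supplying atoms.
#' @param spacing grid spacing, A.
#' @param margin padding beyond the atom bounding box, A.
#' @export
fit_grid <- function(complex, spacing = 0.5, margin = 4) {
  at <- env_atoms(complex)
  if (nrow(at) == 0) stop("cannot fit a grid to an empty environment")
  lo <- c(min(at$x), min(at$y), min(at$z)) - margin
  hi <- c(max(at$x), max(at$y), max(at$z)) + margin
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, shape)
}

#' Grid around a sphere of interest
#'
#' Cubic grid covering `center +- radius`, used by the placement loop.
#'
#' @export
grid_around <- function(center, radius, spacing = 0.5) {
  n <- as.integer(2 * ceiling(radius / spacing) + 1)
  grid_spec(center - (n - 1) / 2 * spacing, spacing, c(n, n, n))
}

#' Lattice point coordinates
#'
#' @param grid a `GridSpec`.
#' @return matrix (prod(shape) x 3) in x-fastest order.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k) {
    grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

new_field <- function(grid, values, probe_name, atoms) {
  structure(list(
    grid = grid,
    values = array(values, dim = grid$shape),
    probe = probe_name,
    environment_hash = sprintf("%d:%.6f", nrow(atoms),
                               sum(atoms$x + atoms$y + atoms$z))
  ), class = "ScalarField")
}

#' @export
print.ScalarField <- function(x, ...) {
  cat(sprintf("ScalarField %s: %d x %d x %d @ %.2f A, min %.2f kcal/mol\n",
              x$probe, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing, min(x$values)))
  invisible(x)
}

# 26-neighbour shifts of a 3D array, padded with `fill`
shift_array <- function(a, off, fill = Inf) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      src[[k]] <- seq_len(d[k] - off[k])
      dst[[k]] <- seq_len(d[k] - off[k]) + off[k]
    } else {
      src[[k]] <- seq_len(d[k] + off[k]) - off[k]
      dst[[k]] <- seq_len(d[k] + off[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Compute a probe interaction field
#'
#' Evaluates the probe energy model on every lattice point against all
#' atoms of the environment (receptor plus ligand plus any waters present).
#' `"DRY"` adds the buried-point entropy reward and the water hydrogen-bond
#' penalty; `"CRY"` is computed as the pointwise minimum of the C1= and DRY
#' fields.  Values are clamped at +100 kcal/mol.
#'
#' @param environment a `ReceptorComplex` or `MolecularStructure`; atoms
#'   must be typed.
#' @param probe probe name (`"OH2"`, `"C1="`, `"C3"`, `"DRY"`, `"CRY"`) or
#'   a definition list.
#' @param grid a `GridSpec`; fitted automatically when `NULL`.
#' @return a `ScalarField`.
#' @export
compute_probe_field <- function(environment, probe = "OH2", grid = NULL) {
  atoms <- env_atoms(environment)
  if (nrow(atoms) > 0 && anyNA(atoms$vdw_class)) {
    stop("environment contains untyped atoms; run assign_atom_types() first")
  }
  if (is.null(grid)) grid <- fit_grid(environment)
  pname <- if (is.character(probe)) probe else probe$name
  if (identical(pname, "CRY")) {
    c1 <- compute_probe_field(environment, "C1=", grid)
    dry <- compute_probe_field(environment, "DRY", grid)
    return(cry_field(c1, dry))
  }
  pts <- grid_points(grid)
  if (nrow(atoms) == 0) {
    return(new_field(grid, numeric(nrow(pts)), pname, atoms))
  }
  hb <- hb_directions(atoms)
  if (identical(pname, "DRY")) {
    dry <- .probe_table$DRY
    lj <- probe_energy_at_points(pts, atoms, dry, clamp = FALSE)
    c3lj <- probe_energy_at_points(pts, atoms, .probe_table$C3, clamp = FALSE)
    inacc <- array(c3lj > 1, dim = grid$shape)
    cnt <- array(0, grid$shape); tot <- array(0, grid$shape)
    for (k in seq_len(nrow(.burial_offsets))) {
      s <- shift_array(inacc, .burial_offsets[k, ], fill = NA)
      cnt <- cnt + ifelse(is.na(s), 0, s)
      tot <- tot + !is.na(s)
    }
    buried <- (cnt / pmax(tot, 1)) >= 0.5
    hb_oh2 <- probe_hb_at_points(pts, atoms, hb)
    vals <- lj + dry$entropy_reward * as.vector(buried) +
      dry$hb_weight * abs(pmin(hb_oh2, 0))
    return(new_field(grid, pmin(vals, .energy_clamp), "DRY", atoms))
  }
  pr <- if (is.character(probe)) probe_definition(probe) else probe
  vals <- probe_energy_at_points(pts, atoms, pr, hb = hb, clamp = TRUE)
  new_field(grid, vals, pname, atoms)
}

#' Combine C1= and DRY fields into the composite CRY field
#'
#' The CRY probe takes, at every lattice point, the more favourable
#' (smaller) of the lipophilic C1= and hydrophobic DRY energies, giving a
#' single map of lipophilic/hydrophobic character used for scoring waters
#' and surveying binding sites.
#'
#' @param c1_field,dry_field `ScalarField`s on the identical grid.
#' @return a `ScalarField` named CRY.
#' @export
cry_field <- function(c1_field, dry_field) {
  g1 <- c1_field$grid; g2 <- dry_field$grid
  if (!isTRUE(all.equal(g1$origin, g2$origin)) ||
      g1$spacing != g2$spacing || !identical(g1$shape, g2$shape)) {
    stop("grid mismatch between C1= and DRY fields")
  }
  out <- c1_field
  out$values <- pmin(c1_field$values, dry_field$values)
  out$probe <- "CRY"
  out
}

#' Detect hotspots in a probe field
#'
#' Grid-local minima over the 26-neighbourhood with energy at or below the
#' threshold, followed by greedy non-maximum suppression that keeps only
#' the deepest minimum within 1.5 A.  Results are sorted by energy
#' (deepest first).
#'
#' @param field a `ScalarField`.
#' @param threshold detection threshold, kcal/mol (negative for attractive
#'   probes; the conventional contour levels are -2.7 for C1=/CRY and -6.0
#'   for OH2).
#' @param min_separation suppression radius, A.
#' @return data frame with columns `x`, `y`, `z`, `energy`, `probe`.
#' @export
find_hotspots <- function(field, threshold, min_separation = 1.5) {
  v <- field$values
  is_min <- array(TRUE, dim(v))
  for (k in seq_len(nrow(.burial_offsets))) {
    s <- shift_array(v, .burial_offsets[k, ], fill = Inf)
    is_min <- is_min & (v < s)
  }
  cand <- which(is_min & v <= threshold, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      energy = numeric(0), probe = character(0))
  if (nrow(cand) == 0) return(empty)
  g <- field$grid
  pos <- sweep((cand - 1) * g$spacing, 2, g$origin, "+")
  e <- v[cand]
  o <- order(e)
  pos <- pos[o, , drop = FALSE]; e <- e[o]
  keep <- integer(0)
  for (i in seq_along(e)) {
    if (length(keep) == 0 ||
        min(sqrt(rowSums((pos[keep, , drop = FALSE] -
                          matrix(pos[i, ], length(keep), 3,
                                 byrow = TRUE))^2))) >= min_separation) {
      keep <- c(keep, i)
    }
  }
  data.frame(x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
             energy = e[keep], probe = field$probe)
}

#' Pocket surface mask from a C3 field
#'
#' The methyl-probe isosurface at +1 kcal/mol marks how close a ligand
#' carbon can approach; the mask is TRUE where the region is accessible
#' (energy below the level).
#'
#' @param c3_field a C3 `ScalarField`.
#' @param level isolevel, kcal/mol.
#' @return logical 3D array on the field grid.
#' @export
pocket_surface <- function(c3_field, level = 1) {
  stopifnot(is.finite(level))
  c3_field$values < level
}

#' Accessible pocket volume
#'
#' Counts accessible lattice points (optionally restricted to a sphere) and
#' converts to cubic Angstroms.
#'
#' @param c3_field C3 field.
#' @param level isolevel, kcal/mol.
#' @param center,radius optional restriction sphere.
#' @export
pocket_volume <- function(c3_field, level = 1, center = NULL, radius = NULL) {
  mask <- pocket_surface(c3_field, level)
  if (!is.null(center)) {
    pts <- grid_points(c3_field$grid)
    d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
      (pts[, 3] - center[3])^2
    mask <- mask & array(d2 <= radius^2, dim(mask))
  }
  sum(mask) * c3_field$grid$spacing^3
}

#' Export a field as OpenDX
#'
#' Writes the standard text OpenDX volumetric format readable by PyMOL,
#' VMD and Chimera.
#'
#' @param field a `ScalarField`.
#' @param path output path.
#' @export
write_dx <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$shape[1], g$shape[2], g$shape[3]),
    sprintf("origin %.4f %.4f %.4f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$shape[1], g$shape[2], g$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(g$shape))
  ), con)
  # dx wants z-fastest ordering
  v <- aperm(field$values, c(3, 2, 1))
  vals <- sprintf("%.5e", as.vector(v))
  pad <- (3 - length(vals) %% 3) %% 3
  if (pad) vals <- c(vals, rep("", pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  writeLines(trimws(paste(m[, 1], m[, 2], m[, 3])), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
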