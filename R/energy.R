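# Pairwise energy engine.
#
# Two evaluation paths share the same physics constants:
#  * probe energies: a probe group at arbitrary points against a typed
#    environment (used for lattice fields, hotspot placement, rescoring);
#  * explicit pair energies: typed atom set vs typed atom set (used for
#    water orientation and Monte-Carlo relaxation).
#
# Model: E = E_LJ + E_elec + E_hb with
#   E_LJ   = eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ],  Lorentz-Berthelot
#   E_elec = 332.06 q_i q_j / (4 r^2)          (distance-dependent dielectric)
#   E_hb   = 4.0 [ 5 (r0/r)^12 - 6 (r0/r)^10 ] cos^2(theta)  within 120 deg
# with r0 = 2.9 A; the hydrogen-bond well depth at ideal geometry is
# -4.0 kcal/mol.  Lattice values are clamped at +100 kcal/mol.

# Ideal hydrogen-bond directions for every polar heavy atom in an atom
# table.  Water oxygens get three directions (two O-H donor vectors and the
# anti-bisector acceptor vector); other polar atoms point away from the
# centroid of their bonded heavy neighbours (within 1.8 A); atoms with no
# neighbours are isotropic (NULL entry).
hb_directions <- function(atoms) {
  n <- nrow(atoms)
  polar <- which(atoms$hbond_role != "none" & atoms$is_heavy)
  if (length(polar) == 0) return(list(idx = integer(0), dirs = list()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dirs <- vector("list", length(polar))
  for (k in seq_along(polar)) {
    i <- polar[k]
    p <- xyz[i, ]
    if (atoms$resname[i] == "HOH" && atoms$name[i] == "O") {
      h <- which(atoms$resname == "HOH" & atoms$element == "H" &
                 atoms$resno == atoms$resno[i] & atoms$chain == atoms$chain[i])
      if (length(h) == 2) {
        v1 <- xyz[h[1], ] - p; v1 <- v1 / sqrt(sum(v1^2))
        v2 <- xyz[h[2], ] - p; v2 <- v2 / sqrt(sum(v2^2))
        bis <- v1 + v2; bis <- bis / sqrt(sum(bis^2))
        dirs[[k]] <- rbind(v1, v2, -bis)
        next
      }
    }
    d2 <- colSums((t(xyz) - p)^2)
    nb <- which(d2 > 1e-6 & d2 < 1.8^2 & atoms$is_heavy)
    if (length(nb) == 0) {
      dirs[k] <- list(NULL)   # isotropic; keep the slot
    } else {
      ctr <- if (length(nb) == 1) xyz[nb, ] else colMeans(xyz[nb, , drop = FALSE])
      v <- p - ctr
      nv <- sqrt(sum(v^2))
      dirs[k] <- if (nv < 1e-6) list(NULL) else list(matrix(v / nv, nrow = 1))
    }
  }
  list(idx = polar, dirs = dirs)
}

# Hydrogen-bond component of a probe field: sum over polar environment
# atoms of the directional 10-12 term.  `hb` is the output of
# hb_directions() for `atoms`.
probe_hb_at_points <- function(points, atoms, hb) {
  n <- nrow(points)
  e <- numeric(n)
  if (length(hb$idx) == 0) return(e)
  for (k in seq_along(hb$idx)) {
    i <- hb$idx[k]
    p <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    dx <- points[, 1] - p[1]; dy <- points[, 2] - p[2]; dz <- points[, 3] - p[3]
    r2 <- dx * dx + dy * dy + dz * dz
    near <- r2 < 36  # 6 A cutoff on the 10-12 term (negligible beyond)
    if (!any(near)) next
    r2n <- pmax(r2[near], 1e-12)
    x2 <- (.hb_r0 * .hb_r0) / r2n
    radial <- .hb_depth * (5 * x2^6 - 6 * x2^5)
    D <- hb$dirs[[k]]
    if (is.null(D)) {
      f <- 1
    } else {
      rn <- sqrt(r2n)
      ux <- dx[near] / rn; uy <- dy[near] / rn; uz <- dz[near] / rn
      f <- 0
      for (d in seq_len(nrow(D))) {
        cth <- ux * D[d, 1] + uy * D[d, 2] + uz * D[d, 3]
        f <- pmax(f, ifelse(cth > .hb_cos_cut, cth * cth, 0))
      }
    }
    e[near] <- e[near] + radial * f
  }
  e
}

#' Probe interaction energy at arbitrary points
#'
#' Evaluates the probe energy model (Lennard-Jones + electrostatics +
#' directional hydrogen bonds) at each point against a typed atom table.
#' This is the same kernel that [compute_probe_field()] evaluates on a
#' lattice.  The composite probes are handled by dedicated helpers
#' ([dry_energy_at_points()], [cry_energy_at_points()]).
#'
#' @param points numeric matrix (n x 3), A.
#' @param atoms typed atom data frame (see [assign_atom_types()]).
#' @param probe probe definition list or name (see [probe_definition()]).
#' @param hb optional precomputed [hb_directions()] result for `atoms`.
#' @param clamp clamp values at +100 kcal/mol (lattice convention).
#' @return numeric vector of energies, kcal/mol.
#' @export
probe_energy_at_points <- function(points, atoms, probe, hb = NULL,
                                   clamp = TRUE) {
  if (is.character(probe)) probe <- probe_definition(probe)
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (nrow(atoms) == 0) return(numeric(n))
  if (anyNA(atoms$vdw_class)) stop("environment atoms are not typed")
  vp <- .vdw_params(atoms$vdw_class)
  e <- numeric(n)
  for (i in seq_len(nrow(atoms))) {
    dx <- points[, 1] - atoms$x[i]
    dy <- points[, 2] - atoms$y[i]
    dz <- points[, 3] - atoms$z[i]
    r2 <- pmax(dx * dx + dy * dy + dz * dz, 1e-12)
    rmin_ij <- (vp$rmin[i] + probe$rmin) / 2
    eps_ij <- sqrt(vp$eps[i] * probe$eps)
    x6 <- (rmin_ij * rmin_ij / r2)^3
    e <- e + eps_ij * (x6 * x6 - 2 * x6)
    if (probe$charge != 0 && atoms$charge[i] != 0) {
      e <- e + .coulomb_k * probe$charge * atoms$charge[i] / (4 * r2)
    }
  }
  if (isTRUE(probe$hbond_capable)) {
    if (is.null(hb)) hb <- hb_directions(atoms)
    e <- e + probe_hb_at_points(points, atoms, hb)
  }
  if (clamp) e <- pmin(e, .energy_clamp)
  e
}

.burial_offsets <- local({
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  as.matrix(g[!(g$x == 0 & g$y == 0 & g$z == 0), ])
})

# Fraction of the 26 half-Angstrom neighbour directions that are sterically
# inaccessible (C3 Lennard-Jones energy above +1 kcal/mol).
burial_fraction_at_points <- function(points, atoms, spacing = 0.5) {
  points <- matrix(as.numeric(points), ncol = 3)
  c3 <- .probe_table$C3
  inacc <- matrix(FALSE, nrow(points), 26)
  for (k in 1:26) {
    shifted <- sweep(points, 2, .burial_offsets[k, ] * spacing, "+")
    inacc[, k] <- probe_energy_at_points(shifted, atoms, c3, clamp = TRUE) > 1
  }
  rowMeans(inacc)
}

#' DRY (hydrophobic) probe energy at arbitrary points
#'
#' `E_DRY = E_LJ(neutral sp3 probe) + S_dry * buried + w |E_hb(OH2)|`:
#' the entropy reward `S_dry = -0.85` kcal/mol applies where at least half
#' of the 26 neighbouring half-Angstrom directions are inaccessible, and
#' the water hydrogen-bond magnitude enters as a penalty (w = 1) that
#' keeps the hydrophobic probe out of H-bonding regions.
#'
#' @inheritParams probe_energy_at_points
#' @param burial optional precomputed burial fraction per point.
#' @export
dry_energy_at_points <- function(points, atoms, hb = NULL, burial = NULL,
                                 clamp = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3)
  dry <- .probe_table$DRY
  lj <- probe_energy_at_points(points, atoms, dry, clamp = FALSE)
  if (is.null(hb)) hb <- hb_directions(atoms)
  hb_oh2 <- probe_hb_at_points(points, atoms, hb)
  if (is.null(burial)) burial <- burial_fraction_at_points(points, atoms)
  e <- lj + dry$entropy_reward * (burial >= 0.5) +
    dry$hb_weight * abs(pmin(hb_oh2, 0))
  if (clamp) e <- pmin(e, .energy_clamp)
  e
}

#' CRY composite probe energy at arbitrary points
#'
#' Pointwise minimum (most favourable) of the C1= and DRY energies.
#'
#' @inheritParams dry_energy_at_points
#' @export
cry_energy_at_points <- function(points, atoms, hb = NULL, clamp = TRUE) {
  c1 <- probe_energy_at_points(points, atoms, .probe_table$`C1=`, hb = hb,
                               clamp = clamp)
  dry <- dry_energy_at_points(points, atoms, hb = hb, clamp = clamp)
  pmin(c1, dry)
}

# ---- explicit pair energies -------------------------------------------------

#' Pack a typed atom table for fast pairwise evaluation
#'
#' Precomputes position/parameter arrays, donor-hydrogen pairs, acceptor
#' lists and bare-donor ideal directions.  [interaction_energy()] and the
#' Monte-Carlo relaxation consume packs instead of data frames.
#'
#' @param atoms typed atom data frame.
#' @param dirs optional precomputed [hb_directions()].
#' @return an `AtomPack` list.
#' @export
pack_atoms <- function(atoms, dirs = NULL) {
  n <- nrow(atoms)
  if (n == 0) {
    return(structure(list(n = 0L), class = "AtomPack"))
  }
  vp <- .vdw_params(atoms$vdw_class)
  pos <- cbind(atoms$x, atoms$y, atoms$z)
  if (is.null(dirs)) dirs <- hb_directions(atoms)
  dh <- donor_hydrogens(atoms)
  acc <- which(atoms$hbond_role %in% c("acceptor", "both") & atoms$is_heavy)
  bare <- setdiff(which(atoms$hbond_role %in% c("donor", "both") &
                        atoms$is_heavy), dh$d)
  bared_dir <- NULL
  if (length(bare)) {
    bared_dir <- lapply(bare, function(i) {
      d <- dirs$dirs[[match(i, dirs$idx)]]
      if (is.null(d)) NULL else d
    })
  }
  structure(list(
    n = n, pos = pos, q = atoms$charge, eps = vp$eps, rmin = vp$rmin,
    heavy = atoms$is_heavy,
    acc = acc, acc_pos = pos[acc, , drop = FALSE],
    donh_d = dh$d, donh_h = dh$h,
    donh_dpos = pos[dh$d, , drop = FALSE],
    donh_hpos = pos[dh$h, , drop = FALSE],
    bare = bare, bare_pos = pos[bare, , drop = FALSE],
    bare_dir = bared_dir
  ), class = "AtomPack")
}

.hb_radial <- function(r) {
  x2 <- (.hb_r0 / r)^2
  .hb_depth * (5 * x2^6 - 6 * x2^5)
}

# scalar pair energy between two packs (no intra-pack terms); A should be
# the smaller set
pair_energy_packed <- function(A, B) {
  if (A$n == 0 || B$n == 0) return(0)
  e <- 0
  for (i in seq_len(A$n)) {
    dx <- B$pos[, 1] - A$pos[i, 1]
    dy <- B$pos[, 2] - A$pos[i, 2]
    dz <- B$pos[, 3] - A$pos[i, 3]
    r2 <- pmax(dx * dx + dy * dy + dz * dz, 1e-12)
    rmin_ij <- (B$rmin + A$rmin[i]) / 2
    eps_ij <- sqrt(B$eps * A$eps[i])
    x6 <- (rmin_ij * rmin_ij / r2)^3
    e <- e + sum(eps_ij * (x6 * x6 - 2 * x6))
    if (A$q[i] != 0) {
      e <- e + sum(.coulomb_k * A$q[i] * B$q / (4 * r2))
    }
  }
  hb_one_way <- function(D, Acc) {
    # explicit donor hydrogens of D vs acceptors of Acc; vectorised over
    # whichever side is larger
    ee <- 0
    nd <- length(D$donh_d); na_ <- length(Acc$acc)
    if (nd && na_) {
      if (na_ <= nd) {
        for (j in seq_len(na_)) {
          a <- Acc$acc_pos[j, ]
          ddx <- a[1] - D$donh_dpos[, 1]; ddy <- a[2] - D$donh_dpos[, 2]
          ddz <- a[3] - D$donh_dpos[, 3]
          rda2 <- ddx^2 + ddy^2 + ddz^2
          sel <- rda2 <= 4.5^2 & rda2 > 1e-12
          if (!any(sel)) next
          dp <- D$donh_dpos[sel, , drop = FALSE]
          hp <- D$donh_hpos[sel, , drop = FALSE]
          v1 <- dp - hp
          v2x <- a[1] - hp[, 1]; v2y <- a[2] - hp[, 2]; v2z <- a[3] - hp[, 3]
          cth <- (v1[, 1] * v2x + v1[, 2] * v2y + v1[, 3] * v2z) /
            pmax(sqrt(rowSums(v1^2)) * sqrt(v2x^2 + v2y^2 + v2z^2), 1e-12)
          ok <- cth < -0.5
          if (any(ok)) {
            ee <- ee + sum(.hb_radial(sqrt(rda2[sel][ok])) * cth[ok]^2)
          }
        }
      } else {
        for (k in seq_len(nd)) {
          dpos <- D$donh_dpos[k, ]; hpos <- D$donh_hpos[k, ]
          w <- Acc$acc_pos
          rda2 <- (w[, 1] - dpos[1])^2 + (w[, 2] - dpos[2])^2 +
            (w[, 3] - dpos[3])^2
          sel <- rda2 <= 4.5^2 & rda2 > 1e-12
          if (!any(sel)) next
          ws <- w[sel, , drop = FALSE]
          v1 <- dpos - hpos
          v2x <- ws[, 1] - hpos[1]; v2y <- ws[, 2] - hpos[2]
          v2z <- ws[, 3] - hpos[3]
          nv2 <- sqrt(v2x^2 + v2y^2 + v2z^2)
          cth <- (v1[1] * v2x + v1[2] * v2y + v1[3] * v2z) /
            (sqrt(sum(v1^2)) * pmax(nv2, 1e-12))
          ok <- cth < -0.5
          if (any(ok)) {
            ee <- ee + sum(.hb_radial(sqrt(rda2[sel][ok])) * cth[ok]^2)
          }
        }
      }
    }
    # bare donors of D (ideal-direction fallback) vs acceptors of Acc
    if (length(D$bare) && length(Acc$acc)) {
      for (k in seq_along(D$bare)) {
        dpos <- D$bare_pos[k, ]
        w <- Acc$acc_pos
        dxx <- w[, 1] - dpos[1]; dyy <- w[, 2] - dpos[2]
        dzz <- w[, 3] - dpos[3]
        rda <- sqrt(dxx^2 + dyy^2 + dzz^2)
        sel <- rda <= 4.5 & rda > 1e-6
        if (!any(sel)) next
        dir <- D$bare_dir[[k]]
        if (is.null(dir)) {
          f <- rep(1, sum(sel))
        } else {
          ux <- dxx[sel] / rda[sel]; uy <- dyy[sel] / rda[sel]
          uz <- dzz[sel] / rda[sel]
          cbest <- rep(-1, sum(sel))
          for (d in seq_len(nrow(dir))) {
            cbest <- pmax(cbest, ux * dir[d, 1] + uy * dir[d, 2] +
                          uz * dir[d, 3])
          }
          f <- ifelse(cbest > 0.5, cbest^2, 0)
        }
        ee <- ee + sum(.hb_radial(rda[sel]) * f)
      }
    }
    ee
  }
  e + hb_one_way(A, B) + hb_one_way(B, A)
}

# Donor-hydrogen pairing: for each hydrogen, its donor is the nearest heavy
# atom within 1.2 A, provided that atom can donate.
donor_hydrogens <- function(atoms) {
  h <- which(!atoms$is_heavy)
  if (length(h) == 0) {
    return(data.frame(d = integer(0), h = integer(0)))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  heavy <- which(atoms$is_heavy)
  out_d <- integer(0); out_h <- integer(0)
  for (i in h) {
    d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[i, ])^2)
    j <- heavy[which.min(d2)]
    if (length(j) && d2[which.min(d2)] < 1.2^2 &&
        atoms$hbond_role[j] %in% c("donor", "both")) {
      out_d <- c(out_d, j); out_h <- c(out_h, i)
    }
  }
  data.frame(d = out_d, h = out_h)
}

# fast pack constructor for a single three-site water
water_pack <- function(o, h1, h2) {
  pos <- rbind(o, h1, h2)
  structure(list(
    n = 3L, pos = pos, q = c(-0.834, 0.417, 0.417),
    eps = c(.vdw_table["polar_O", "eps"], rep(.vdw_table["hydrogen", "eps"], 2)),
    rmin = c(.vdw_table["polar_O", "rmin"], rep(.vdw_table["hydrogen", "rmin"], 2)),
    heavy = c(TRUE, FALSE, FALSE),
    acc = 1L, acc_pos = pos[1, , drop = FALSE],
    donh_d = c(1L, 1L), donh_h = c(2L, 3L),
    donh_dpos = pos[c(1, 1), , drop = FALSE],
    donh_hpos = pos[2:3, , drop = FALSE],
    bare = integer(0), bare_pos = pos[0, , drop = FALSE], bare_dir = NULL
  ), class = "AtomPack")
}

# concatenate two packs (index bookkeeping only)
pack_append <- function(a, b) {
  if (a$n == 0) return(b)
  if (b$n == 0) return(a)
  off <- a$n
  structure(list(
    n = a$n + b$n,
    pos = rbind(a$pos, b$pos), q = c(a$q, b$q),
    eps = c(a$eps, b$eps), rmin = c(a$rmin, b$rmin),
    heavy = c(a$heavy, b$heavy),
    acc = c(a$acc, b$acc + off),
    acc_pos = rbind(a$acc_pos, b$acc_pos),
    donh_d = c(a$donh_d, b$donh_d + off),
    donh_h = c(a$donh_h, b$donh_h + off),
    donh_dpos = rbind(a$donh_dpos, b$donh_dpos),
    donh_hpos = rbind(a$donh_hpos, b$donh_hpos),
    bare = c(a$bare, b$bare + off),
    bare_pos = rbind(a$bare_pos, b$bare_pos),
    bare_dir = c(a$bare_dir, b$bare_dir)
  ), class = "AtomPack")
}

# drop a set of atom rows from a pack
pack_drop_rows <- function(p, rows) {
  keep <- setdiff(seq_len(p$n), rows)
  map <- integer(p$n); map[keep] <- seq_along(keep)
  ka <- which(p$acc %in% keep)
  kd <- which(p$donh_d %in% keep & p$donh_h %in% keep)
  kb <- which(p$bare %in% keep)
  structure(list(
    n = length(keep),
    pos = p$pos[keep, , drop = FALSE], q = p$q[keep],
    eps = p$eps[keep], rmin = p$rmin[keep], heavy = p$heavy[keep],
    acc = map[p$acc[ka]], acc_pos = p$acc_pos[ka, , drop = FALSE],
    donh_d = map[p$donh_d[kd]], donh_h = map[p$donh_h[kd]],
    donh_dpos = p$donh_dpos[kd, , drop = FALSE],
    donh_hpos = p$donh_hpos[kd, , drop = FALSE],
    bare = map[p$bare[kb]], bare_pos = p$bare_pos[kb, , drop = FALSE],
    bare_dir = p$bare_dir[kb]
  ), class = "AtomPack")
}

# subset a pack to atoms within `rcut` of `center`, excluding given rows
pack_near <- function(p, center, rcut, exclude_rows = integer(0)) {
  d2 <- (p$pos[, 1] - center[1])^2 + (p$pos[, 2] - center[2])^2 +
    (p$pos[, 3] - center[3])^2
  keep <- which(d2 < rcut^2)
  if (length(exclude_rows)) keep <- setdiff(keep, exclude_rows)
  pack_drop_rows(p, setdiff(seq_len(p$n), keep))
}

# overwrite the coordinates of a set of pack rows, refreshing the derived
# position arrays
pack_set_rows <- function(p, rows, newpos) {
  p$pos[rows, ] <- newpos
  ka <- which(p$acc %in% rows)
  if (length(ka)) p$acc_pos[ka, ] <- p$pos[p$acc[ka], ]
  kd <- which(p$donh_d %in% rows)
  if (length(kd)) p$donh_dpos[kd, ] <- p$pos[p$donh_d[kd], ]
  kh <- which(p$donh_h %in% rows)
  if (length(kh)) p$donh_hpos[kh, ] <- p$pos[p$donh_h[kh], ]
  kb <- which(p$bare %in% rows)
  if (length(kb)) p$bare_pos[kb, ] <- p$pos[p$bare[kb], ]
  p
}

#' Explicit interaction energy between two typed atom sets
#'
#' Lennard-Jones plus screened Coulomb plus directional hydrogen-bond terms
#' between every atom of `A` and every atom of `B` (no intra-set terms).
#' Donors with explicit hydrogens use the D-H...A angle; bare donors use
#' their ideal-direction fallback.  This is the energy function of the
#' water orientation search and the Monte-Carlo relaxation.
#'
#' @param A,B typed atom data frames (or `AtomPack`s from [pack_atoms()]).
#' @param dirsA,dirsB optional precomputed [hb_directions()] for A and B.
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(A, B, dirsA = NULL, dirsB = NULL) {
  pa <- if (inherits(A, "AtomPack")) A else pack_atoms(A, dirsA)
  pb <- if (inherits(B, "AtomPack")) B else pack_atoms(B, dirsB)
  pair_energy_packed(pa, pb)
}
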