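# Independent scalar oracles shared by the field tests and the
# acceptance suite.

# naive oracle: scalar double loop over points and atoms, with its own
# ideal-direction logic (kept deliberately separate from the package code)
naive_probe_energy <- function(points, atoms, eps_p, rmin_p, q_p, hbond_p,
                               vdw_tab) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dirs <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    if (atoms$hbond_role[i] == "none" || !atoms$is_heavy[i]) next
    nb <- c()
    for (j in seq_len(nrow(atoms))) {
      if (j == i) next
      if (atoms$is_heavy[j] &&
          sqrt(sum((xyz[j, ] - xyz[i, ])^2)) < 1.8) nb <- c(nb, j)
    }
    if (length(nb) > 0) {
      ctr <- colMeans(xyz[nb, , drop = FALSE])
      v <- xyz[i, ] - ctr
      if (sqrt(sum(v^2)) > 1e-6) dirs[[i]] <- v / sqrt(sum(v^2))
    }
  }
  out <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    e <- 0
    for (i in seq_len(nrow(atoms))) {
      d <- points[k, ] - xyz[i, ]
      r2 <- max(sum(d * d), 1e-12)
      vp <- vdw_tab[atoms$vdw_class[i], ]
      rmin_ij <- (vp$rmin + rmin_p) / 2
      eps_ij <- sqrt(vp$eps * eps_p)
      x6 <- (rmin_ij^2 / r2)^3
      e <- e + eps_ij * (x6 * x6 - 2 * x6)
      if (q_p != 0 && atoms$charge[i] != 0) {
        e <- e + 332.06 * q_p * atoms$charge[i] / (4 * r2)
      }
      if (hbond_p && atoms$hbond_role[i] != "none" && atoms$is_heavy[i] &&
          r2 < 36) {
        r <- sqrt(r2)
        x2 <- (2.9 / r)^2
        radial <- 4.0 * (5 * x2^6 - 6 * x2^5)
        f <- 1
        if (!is.null(dirs[[i]])) {
          cth <- sum(d / r * dirs[[i]])
          f <- if (cth > cos(120 * pi / 180)) cth^2 else 0
        }
        e <- e + radial * f
      }
    }
    out[k] <- min(e, 100)
  }
  out
}

vdw_tab <- data.frame(
  row.names = c("carbon_sp3", "carbon_sp2_aromatic", "polar_N", "polar_O",
                "sulfur", "hydrogen"),
  eps = c(0.066, 0.120, 0.170, 0.210, 0.250, 0.0157),
  rmin = c(4.00, 3.96, 3.66, 3.34, 4.00, 1.20))

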