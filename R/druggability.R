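# Druggability assessment: lipophilic hotspots adjacent to water hotspots
# and occupied by unhappy waters mark subpockets worth targeting.

#' Assess binding-site druggability
#'
#' For every lipophilic (CRY) hotspot at or below the lipophilic
#' threshold, records the distance to the nearest water-probe hotspot,
#' counts the red/yellow (unhappy) waters within the adjacency radius, and
#' flags the subpocket druggable when both a polar hotspot and at least
#' one unhappy water sit within adjacency - the signature of a pocket
#' where a drug-like ligand can gain binding energy by displacing
#' frustrated water.  The pocket volume is measured from the methyl-probe
#' surface within the placement sphere.
#'
#' @param complex typed `ReceptorComplex` (fields are computed on
#'   receptor + ligand).
#' @param network a scored and classified `WaterNetwork`.
#' @param c1_threshold lipophilic hotspot threshold, kcal/mol (the
#'   conventional contour; -2.5 is also in common use).
#' @param oh2_threshold water hotspot threshold, kcal/mol.
#' @param adjacency adjacency radius, A.
#' @return a `DruggabilityReport`: `subpockets` data frame (sorted by
#'   hotspot energy), `pocket_volume` (A^3), `summary_flags`.
#' @export
assess_druggability <- function(complex, network, c1_threshold = -2.7,
                                oh2_threshold = -6, adjacency = 4) {
  if (is.null(network$scores) || anyNA(network$scores$class_label)) {
    stop("network must be scored and classified first")
  }
  center <- network$center
  grid <- grid_around(center, network$schedule$placement_radius + 2)
  env <- list(receptor = complex$receptor, ligand = complex$ligand,
              waters = new_waters())
  class(env) <- "ReceptorComplex"
  cry <- compute_probe_field(env, "CRY", grid)
  oh2 <- compute_probe_field(env, "OH2", grid)
  c3 <- compute_probe_field(env, "C3", grid)
  lip_hs <- find_hotspots(cry, c1_threshold)
  oh2_hs <- find_hotspots(oh2, oh2_threshold)

  # restrict to the pocket
  keep_sphere <- function(hs, r) {
    if (nrow(hs) == 0) return(hs)
    d <- sqrt((hs$x - center[1])^2 + (hs$y - center[2])^2 +
              (hs$z - center[3])^2)
    hs[d <= r, , drop = FALSE]
  }
  lip_hs <- keep_sphere(lip_hs, network$schedule$placement_radius)
  oh2_hs <- keep_sphere(oh2_hs, network$schedule$placement_radius)

  o <- water_o(network$waters)
  sc <- network$scores
  unhappy_pos <- o[sc$water_index[sc$class_label %in% c("red", "yellow")], ,
                   drop = FALSE]

  sub <- lapply(seq_len(nrow(lip_hs)), function(i) {
    p <- as.numeric(lip_hs[i, c("x", "y", "z")])
    if (nrow(oh2_hs) > 0) {
      dpol <- min(sqrt((oh2_hs$x - p[1])^2 + (oh2_hs$y - p[2])^2 +
                       (oh2_hs$z - p[3])^2))
    } else {
      dpol <- NA_real_
    }
    n_unhappy <- if (nrow(unhappy_pos) > 0) {
      sum(sqrt((unhappy_pos[, 1] - p[1])^2 + (unhappy_pos[, 2] - p[2])^2 +
               (unhappy_pos[, 3] - p[3])^2) <= adjacency)
    } else 0L
    data.frame(x = p[1], y = p[2], z = p[3],
               hotspot_energy = lip_hs$energy[i],
               nearest_polar_hotspot_distance = dpol,
               unhappy_water_count = n_unhappy,
               druggable = !is.na(dpol) && dpol <= adjacency &&
                 n_unhappy >= 1)
  })
  sub <- if (length(sub)) do.call(rbind, sub) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               hotspot_energy = numeric(0),
               nearest_polar_hotspot_distance = numeric(0),
               unhappy_water_count = integer(0), druggable = logical(0))
  sub <- sub[order(sub$hotspot_energy), , drop = FALSE]
  rownames(sub) <- NULL

  flags <- character(0)
  if (nrow(sub) == 0) {
    flags <- c(flags, "no lipophilic hotspots at threshold")
  } else {
    flags <- c(flags, sprintf("%d druggable of %d lipophilic subpockets",
                              sum(sub$druggable), nrow(sub)))
    if (nrow(sub) > 1) {
      span <- max(stats::dist(as.matrix(sub[, c("x", "y", "z")])))
      flags <- c(flags, sprintf("hotspots span %.1f Angstrom", span))
    }
    if (any(!sub$druggable)) {
      flags <- c(flags, sprintf("%d lipophilic-only subpocket(s)",
                                sum(is.na(sub$nearest_polar_hotspot_distance) |
                                    sub$nearest_polar_hotspot_distance >
                                      adjacency)))
    }
  }
  structure(list(
    subpockets = sub,
    pocket_volume = pocket_volume(c3, 1, center,
                                  network$schedule$placement_radius),
    summary_flags = flags,
    thresholds = list(c1 = c1_threshold, oh2 = oh2_threshold,
                      adjacency = adjacency)
  ), class = "DruggabilityReport")
}

#' @export
print.DruggabilityReport <- function(x, ...) {
  cat("DruggabilityReport:\n")
  for (f in x$summary_flags) cat(" -", f, "\n")
  cat(sprintf(" pocket volume %.0f A^3\n", x$pocket_volume))
  if (nrow(x$subpockets)) {
    print(x$subpockets[, c("hotspot_energy",
                           "nearest_polar_hotspot_distance",
                           "unhappy_water_count", "druggable")])
  }
  invisible(x)
}

#' Serialise a druggability report as JSON
#'
#' @param report a `DruggabilityReport`.
#' @param path output file.
#' @export
write_druggability_json <- function(report, path) {
  jsonlite::write_json(list(
    subpockets = report$subpockets,
    pocket_volume = report$pocket_volume,
    summary_flags = report$summary_flags,
    thresholds = report$thresholds
  ), path, auto_unbox = TRUE, digits = 6, pretty = TRUE, na = "null")
  invisible(path)
}
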