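# Internal physical constants and parameter tables.
#
# Energies are kcal/mol and distances Angstrom throughout the package.

.kB <- 0.0019872041        # Boltzmann constant, kcal/mol/K
.coulomb_k <- 332.06       # Coulomb prefactor, kcal*A/(mol*e^2)
.hb_r0 <- 2.9              # ideal donor-acceptor heavy-atom distance, A
.hb_depth <- 4.0           # depth of the 10-12 hydrogen-bond well, kcal/mol
.hb_cos_cut <- cos(120 * pi / 180)  # angular cutoff of the directional term
.energy_clamp <- 100       # cap on lattice energies, kcal/mol
.water_density <- 0.0334   # bulk water number density, molecules/A^3
.tip3p_oh <- 0.9572        # O-H bond length, A
.tip3p_hoh <- 104.52 * pi / 180  # H-O-H angle, rad

# Lennard-Jones classes for environment atoms.  rmin is the self-pair
# minimum-energy distance; cross terms use Lorentz-Berthelot combination.
.vdw_table <- data.frame(
  row.names = c("carbon_sp3", "carbon_sp2_aromatic", "polar_N", "polar_O",
                "sulfur", "hydrogen"),
  eps  = c(0.066, 0.120, 0.170, 0.210, 0.250, 0.0157),
  rmin = c(4.00, 3.96, 3.66, 3.34, 4.00, 1.20)
)

# Probe groups.  Epsilons are group-level (a whole methyl / aromatic CH /
# water), which is why they are an order of magnitude above per-atom values:
# probe energies are meant to approximate the interaction of the full
# chemical group placed at the lattice point.
.probe_table <- list(
  OH2   = list(name = "OH2", eps = 0.60, rmin = 3.20, charge = 0,
               hbond_capable = TRUE),
  `C1=` = list(name = "C1=", eps = 1.00, rmin = 3.70, charge = 0,
               hbond_capable = FALSE),
  C3    = list(name = "C3", eps = 1.00, rmin = 3.90, charge = 0,
               hbond_capable = FALSE),
  DRY   = list(name = "DRY", eps = 1.00, rmin = 3.90, charge = 0,
               hbond_capable = FALSE, entropy_reward = -0.85, hb_weight = 1)
)

#' Probe definitions
#'
#' Returns the parameter set of one of the built-in probes used for
#' interaction fields: `"OH2"` (water), `"C1="` (aromatic/sp2 carbon,
#' lipophilic), `"C3"` (methyl, pocket surface), `"DRY"` (hydrophobic, with
#' a buried-point entropy reward and a penalty proportional to the local
#' water hydrogen-bond energy).  `"CRY"` has no parameters of its own: it is
#' the pointwise minimum of the C1= and DRY fields (see [cry_field()]).
#'
#' @param name probe name.
#' @return a list with elements `name`, `eps`, `rmin`, `charge`,
#'   `hbond_capable` (and for DRY, `entropy_reward`, `hb_weight`).
#' @export
probe_definition <- function(name) {
  if (identical(name, "CRY")) {
    stop("CRY is a composite probe; compute C1= and DRY fields and combine ",
         "them with cry_field(), or use compute_probe_field(..., 'CRY')")
  }
  p <- .probe_table[[name]]
  if (is.null(p)) stop("unknown probe: ", name)
  p
}

.vdw_params <- function(classes) {
  i <- match(classes, rownames(.vdw_table))
  if (anyNA(i)) stop("unknown vdw class: ",
                     paste(unique(classes[is.na(i)]), collapse = ", "))
  list(eps = .vdw_table$eps[i], rmin = .vdw_table$rmin[i])
}
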