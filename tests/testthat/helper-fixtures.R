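# Shared fixtures, memoised across test files (placement runs are the
# expensive step; every consumer sees the identical deterministic object).

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- fn()
  .fx_cache[[key]]
}

# compact cavity with an adjacent polar/lipophilic pair plus one remote
# polar site - the magic-methyl / displacement fixture (4.0 A pair)
cav_pair <- function() memo("cav_pair", function() {
  make_toy_cavity(2, 1, seed = 5, shell_radius = 10, site_radius = 6.5,
                  adjacent_pair = TRUE)
})

# tighter pair (3.6 A, wide-open cup) whose lipophilic hotspot falls
# inside the 4 A polar-hotspot adjacency - the druggable-subpocket fixture
cav_drug <- function() memo("cav_drug", function() {
  make_toy_cavity(2, 1, seed = 5, shell_radius = 10, site_radius = 6.5,
                  adjacent_pair = TRUE, pair_separation = 3.6,
                  cup_clearance = 3.1)
})

net_drug_scored <- function() memo("net_drug_scored", function() {
  fx <- cav_drug()
  net <- place_waters_iterative(fx$complex, center = fx$center)
  classify_waters(rescore_waters(fx$complex, net, bulk_ref18()))
})

# full-size cavity with 3 polar and 2 lipophilic sites, well separated
cav_multi <- function() memo("cav_multi", function() {
  make_toy_cavity(3, 2, seed = 1)
})

pair_ligand <- function(with_methyl) {
  m <- cav_pair()$manifest
  make_toy_ligand(m[c(1, 3), ], with_methyl = with_methyl)
}

holo_complex <- function(with_methyl = TRUE) {
  cx <- cav_pair()$complex
  cx$ligand <- pair_ligand(with_methyl)
  cx
}

# deterministic placement runs (no RNG involved)
net_holo <- function(with_methyl = TRUE) {
  key <- paste0("net_holo_", with_methyl)
  memo(key, function() place_waters_iterative(holo_complex(with_methyl)))
}

net_apo <- function() memo("net_apo", function() {
  place_waters_iterative(cav_pair()$complex, center = cav_pair()$center)
})

bulk_box18 <- function() memo("bulk_box18", function() make_bulk_box(18, 1))

bulk_ref18 <- function() memo("bulk_ref18", function() {
  calibrate_bulk_reference(bulk_box18())
})

# scored + classified apo network on the pair cavity
net_apo_scored <- function() memo("net_apo_scored", function() {
  classify_waters(rescore_waters(cav_pair()$complex, net_apo(), bulk_ref18()))
})

default_landscape <- function() memo("landscape", function() {
  make_binding_landscape(-5, 3, 0)
})

default_path <- function() memo("path", function() {
  run_binding_path(default_landscape(), seed = 1)
})

# independent quadrature for landscape state free energies (test oracle,
# simple Riemann sum - deliberately not the package's integrate() path)
riemann_delta_f <- function(land, perturbation = NULL) {
  kT <- 0.0019872041 * land$temperature
  h <- 0.5 / 2e5
  mid <- function(a, b) seq(a + h / 2, b - h / 2, by = h)
  zu <- sum(exp(-landscape_potential(land, mid(-0.25, 0.25),
                                     perturbation) / kT)) * h
  zb <- sum(exp(-landscape_potential(land, mid(0.75, 1.25),
                                     perturbation) / kT)) * h
  -kT * log(zb / zu)
}
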