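small_config <- function(out_dir, ligand = "methyl", seed = 1,
                         n_sweeps = 15) {
  # the fixed pocket centre keeps holo and pseudo-apo placement windows
  # identical (and inside the cavity shell)
  run_config(fixture = list(n_polar = 2, n_lipophilic = 1, seed = 5,
                            adjacent_pair = TRUE, pair_separation = 3.6,
                            cup_clearance = 3.1, shell_radius = 10,
                            site_radius = 6.5, ligand = ligand),
             relax = list(n_sweeps = n_sweeps, mobile_ligand = FALSE,
                          temperature = 300),
             center = c(0, 0, 0),
             seed = seed, out_dir = out_dir)
}

test_that("waterflap pipeline produces a complete, valid, reproducible
           bundle", {
  out <- withr::local_tempdir()
  res <- run_waterflap_pipeline(small_config(file.path(out, "a")))
  expect_true(file.exists(file.path(res$bundle_dir, "network.pdb")))
  expect_true(file.exists(file.path(res$bundle_dir, "scores.csv")))
  expect_true(file.exists(file.path(res$bundle_dir, "hbond_edges.csv")))
  expect_true(file.exists(file.path(res$bundle_dir, "config.yaml")))
  expect_true(network_is_valid(res$complex, res$network))
  expect_false(anyNA(res$network$scores$class_label))

  # identical config (down to the seed) reproduces the score table exactly
  res2 <- run_waterflap_pipeline(small_config(file.path(out, "b")))
  a <- utils::read.csv(file.path(res$bundle_dir, "scores.csv"))
  b <- utils::read.csv(file.path(res2$bundle_dir, "scores.csv"))
  expect_identical(a, b)

  # the archived config round-trips through YAML
  cfg <- read_run_config(file.path(res$bundle_dir, "config.yaml"))
  expect_equal(cfg$fixture$seed, 5)
  expect_equal(cfg$seed, 1)
})

test_that("pseudo-apo run recovers more waters than the holo run", {
  out <- withr::local_tempdir()
  holo <- run_waterflap_pipeline(small_config(file.path(out, "holo")))
  apo_cfg <- small_config(file.path(out, "apo"), ligand = "none")
  apo <- run_waterflap_pipeline(apo_cfg)
  expect_gt(nrow(apo$network$waters), nrow(holo$network$waters))
})

test_that("druggability pipeline emits a schema-valid JSON report", {
  out <- withr::local_tempdir()
  res <- run_druggability_pipeline(small_config(file.path(out, "drg"),
                                                ligand = "none"))
  json_path <- file.path(res$bundle_dir, "druggability.json")
  expect_true(file.exists(json_path))
  expect_true(validate_druggability_json(json_path))
  expect_gte(sum(res$report$subpockets$druggable), 1)
})

test_that("mutation-interpretation pipeline links water-network and
           free-energy directions", {
  out <- withr::local_tempdir()
  cfg <- small_config(file.path(out, "bpm"), ligand = "none", n_sweeps = 0)
  cfg$metadyn <- list(wtmetad = list(n_walkers = 16,
                                     steps_per_walker = 4000,
                                     deposit_stride = 50,
                                     readout_walkers = 8,
                                     readout_steps = 4000,
                                     readout_burnin = 500))
  # empty mutation list: reference-only bundle
  ref_only <- run_bpm_interpretation(cfg, mutations = list())
  expect_named(ref_only, c("reference", "mutations"))

  host <- cav_drug()$manifest$host_resno[2]
  res <- run_bpm_interpretation(
    cfg,
    mutations = list(list(type = "receptor_ala", chain = "A", resno = host,
                          perturbation = 2)),
    metadyn_seeds = 1:2)
  expect_true(file.exists(file.path(cfg$out_dir, "bpm_report.json")))
  mut <- res$mutations[[1]]
  # losing a hydrogen-bond partner makes the local network unhappier
  expect_gt(mut$diff$delta_sum_dg, 0)
  # and the destabilising perturbation raises the binding free energy
  ddg <- res$metascore$ddg_vs_reference[res$metascore$variant != "reference"]
  expect_gt(ddg, 0)
})
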