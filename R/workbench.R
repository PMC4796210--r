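# End-to-end pipelines tying fixtures, fields, water networks,
# druggability and MetaScore together, with serialisable run configs.

#' Run configuration
#'
#' A fully serialisable description of one pipeline run: either an input
#' PDB path or a fixture recipe, plus the schedule/scheme/metadynamics
#' parameter blocks and the seed.  A run can be reproduced exactly from
#' its archived config.
#'
#' @param input path to a PDB file, or NULL to use `fixture`.
#' @param fixture list(n_polar, n_lipophilic, seed, adjacent_pair,
#'   pair_separation, cup_clearance, shell_radius, site_radius,
#'   ligand = "none"|"methyl"|"des-methyl").
#' @param center optional placement-centre override (3-vector, A); when
#'   NULL the ligand centroid (holo) or pocket origin (apo) is used.
#' @param schedule placement schedule overrides (named list).
#' @param scheme classification scheme overrides (named list).
#' @param relax list(n_sweeps, mobile_ligand, temperature).
#' @param bulk list(edge, seed) for the reference box.
#' @param metadyn landscape/metadynamics overrides (named list).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a `RunConfig`.
#' @export
run_config <- function(input = NULL, fixture = list(n_polar = 2,
                                                    n_lipophilic = 1,
                                                    seed = 5,
                                                    adjacent_pair = TRUE,
                                                    shell_radius = 10,
                                                    site_radius = 6.5,
                                                    ligand = "methyl"),
                       schedule = list(), scheme = list(),
                       relax = list(n_sweeps = 100, mobile_ligand = FALSE,
                                    temperature = 300),
                       bulk = list(edge = 18, seed = 1),
                       metadyn = list(), center = NULL, seed = 1,
                       out_dir = tempfile("hydrosite_run_")) {
  if (!is.null(center)) center <- as.numeric(unlist(center))
  structure(list(input = input, fixture = fixture, schedule = schedule,
                 scheme = scheme, relax = relax, bulk = bulk,
                 metadyn = metadyn, center = center, seed = seed,
                 out_dir = out_dir),
            class = "RunConfig")
}

#' Write / read a run configuration as YAML
#'
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

config_complex <- function(config) {
  if (!is.null(config$input)) {
    cx <- read_pdb(config$input)
    return(list(complex = cx, manifest = NULL,
                center = if (is_apo(cx)) NULL else NULL))
  }
  fx <- config$fixture
  cav <- make_toy_cavity(fx$n_polar, fx$n_lipophilic, seed = fx$seed,
                         shell_radius = fx$shell_radius %||% 12,
                         site_radius = fx$site_radius %||% 8.5,
                         adjacent_pair = isTRUE(fx$adjacent_pair),
                         pair_separation = fx$pair_separation %||% 4.0,
                         cup_clearance = fx$cup_clearance %||% 2.6)
  lig_kind <- fx$ligand %||% "none"
  if (lig_kind != "none") {
    m <- cav$manifest
    occ <- rbind(m[m$character == "polar", , drop = FALSE][1, ],
                 m[m$character == "lipophilic", , drop = FALSE][1, ])
    occ <- occ[!is.na(occ$x), , drop = FALSE]
    cav$complex$ligand <- make_toy_ligand(occ,
                                          with_methyl = lig_kind == "methyl")
  }
  cav
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full water-network pipeline
#'
#' Builds (or reads) the system, places waters iteratively, relaxes the
#' network by Monte Carlo, rescores against a calibrated bulk box and
#' classifies the waters.  All artifacts - the solvated PDB, the score
#' table, the hydrogen-bond graph edge list, the archived config and a
#' stage log - are written to the output directory.
#'
#' @param config a `RunConfig`.
#' @return invisibly, a list with `complex`, `network`, `graph`,
#'   `bundle_dir` and the stage `log`.
#' @export
run_waterflap_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  tic <- function() Sys.time()
  stage <- function(name, t0, ...) {
    log[[length(log) + 1]] <<- list(stage = name,
                                    seconds = round(as.numeric(
                                      Sys.time() - t0, units = "secs"), 2),
                                    ...)
  }
  t0 <- tic()
  sys <- config_complex(config)
  cx <- sys$complex
  stage("build", t0, atoms = nrow(cx$receptor$atoms))

  sched <- do.call(placement_schedule, config$schedule)
  center <- config$center %||%
    (if (!is.null(cx$ligand)) NULL else sys$center %||% c(0, 0, 0))
  t0 <- tic()
  net <- place_waters_iterative(cx, sched, center = center)
  stage("place", t0, waters = nrow(net$waters))

  t0 <- tic()
  rl <- relax_network(cx, net,
                      n_sweeps = config$relax$n_sweeps %||% 100,
                      mobile_ligand = isTRUE(config$relax$mobile_ligand),
                      temperature = config$relax$temperature %||% 300,
                      seed = config$seed)
  net <- rl$network
  cx$ligand <- rl$ligand
  stage("relax", t0, sweeps = config$relax$n_sweeps %||% 100)

  t0 <- tic()
  box <- make_bulk_box(config$bulk$edge %||% 18, config$bulk$seed %||% 1)
  bulk_ref <- calibrate_bulk_reference(box)
  net <- rescore_waters(cx, net, bulk_ref)
  net <- classify_waters(net, do.call(classification_scheme, config$scheme))
  stage("rescore", t0, bulk_reference = round(bulk_ref, 3),
        scored = nrow(net$scores))

  t0 <- tic()
  g <- hbond_graph(cx, net)
  stage("hbond_graph", t0, edges = igraph::ecount(g))

  out <- config$out_dir
  solvated <- cx
  solvated$waters <- net$waters
  write_pdb(solvated, file.path(out, "network.pdb"))
  utils::write.csv(cbind(net$scores,
                         net$waters[net$scores$water_index,
                                    c("ox", "oy", "oz",
                                      "placement_iteration",
                                      "placement_energy")]),
                   file.path(out, "scores.csv"), row.names = FALSE)
  el <- igraph::as_edgelist(g)
  utils::write.csv(data.frame(from = el[, 1], to = el[, 2]),
                   file.path(out, "hbond_edges.csv"), row.names = FALSE)
  write_run_config(config, file.path(out, "config.yaml"))
  jsonlite::write_json(log, file.path(out, "log.json"), auto_unbox = TRUE)

  invisible(list(complex = cx, network = net, graph = g,
                 bundle_dir = out, log = log))
}

#' Druggability pipeline
#'
#' Runs the water-network pipeline and then the druggability assessment;
#' writes the JSON report next to the network bundle.
#'
#' @param config a `RunConfig`.
#' @param c1_threshold,oh2_threshold,adjacency see [assess_druggability()].
#' @return invisibly, list with `report` and everything from
#'   [run_waterflap_pipeline()].
#' @export
run_druggability_pipeline <- function(config = run_config(),
                                      c1_threshold = -2.7,
                                      oh2_threshold = -6, adjacency = 4) {
  wf <- run_waterflap_pipeline(config)
  report <- assess_druggability(wf$complex, wf$network,
                                c1_threshold = c1_threshold,
                                oh2_threshold = oh2_threshold,
                                adjacency = adjacency)
  write_druggability_json(report,
                          file.path(wf$bundle_dir, "druggability.json"))
  invisible(c(list(report = report), wf))
}

#' Validate a druggability report structure
#'
#' Checks the JSON report against the packaged schema (required fields and
#' types).
#'
#' @param path JSON report path.
#' @return TRUE (invisibly) or an error describing the violation.
#' @export
validate_druggability_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema_path <- system.file("extdata", "druggability_schema.json",
                             package = "hydrosite")
  if (!nzchar(schema_path)) {
    schema_path <- file.path("inst", "extdata", "druggability_schema.json")
  }
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  for (f in schema$required) {
    if (is.null(x[[f]])) stop("report missing required field: ", f)
  }
  if (!is.numeric(x$pocket_volume)) stop("pocket_volume must be numeric")
  if (length(x$subpockets) > 0) {
    for (col in schema$subpocket_columns) {
      if (is.null(x$subpockets[[col]])) {
        stop("subpockets missing column: ", col)
      }
    }
  }
  invisible(TRUE)
}

#' Mutation-interpretation pipeline
#'
#' The computational protocol for interpreting binding-site mutation data:
#' for each mutation the receptor is edited (serine-host alanine mutation
#' removes one hydrogen-bond partner; the ligand methyl/des-methyl switch
#' models a ligand edit), the water network is rebuilt and compared
#' against the reference network around the mutation site, and the
#' matching landscape perturbation is pushed through MetaScore on the
#' shared reference binding path.
#'
#' @param config a `RunConfig` (fixture-based).
#' @param mutations list of mutation descriptors:
#'   `list(type = "receptor_ala", chain, resno, perturbation)` or
#'   `list(type = "ligand_desmethyl", perturbation)`; `perturbation` is
#'   the matching bound-well perturbation in kcal/mol (positive =
#'   destabilising).
#' @param metadyn_seeds seeds for the MetaScore comparison.
#' @return invisibly, list with `reference` (waterflap bundle), and per
#'   mutation `diffs` (NetworkDiff) and `metascore` (variant table).
#' @export
run_bpm_interpretation <- function(config = run_config(),
                                   mutations = list(),
                                   metadyn_seeds = 1:3) {
  ref <- run_waterflap_pipeline(config)
  out <- list(reference = ref, mutations = list())
  if (length(mutations) == 0) return(invisible(out))

  perts <- vapply(mutations, function(m) m$perturbation %||% 0, numeric(1))
  names(perts) <- vapply(seq_along(mutations), function(i) {
    m <- mutations[[i]]
    if (m$type == "receptor_ala") sprintf("%s%d_ALA", m$chain, m$resno)
    else m$type
  }, character(1))

  land <- make_binding_landscape(
    depth_bound = config$metadyn$depth_bound %||% -5,
    barrier = config$metadyn$barrier %||% 3,
    seed = config$seed)
  sched <- do.call(abmd_schedule, config$metadyn$abmd %||% list())
  params <- do.call(wtmetad_parameters, config$metadyn$wtmetad %||% list())
  ms <- compare_variants(land, perts, schedule = sched, params = params,
                         seeds = metadyn_seeds)

  for (i in seq_along(mutations)) {
    m <- mutations[[i]]
    cfg_mut <- config
    cfg_mut$out_dir <- file.path(config$out_dir, names(perts)[i])
    if (m$type == "receptor_ala") {
      sysm <- config_complex(cfg_mut)
      cxm <- mutate_to_alanine(sysm$complex, m$chain, m$resno)
      region_center <- {
        # the waters affected by the mutation sit at the residue's
        # hydrogen-bonding position, ~2.9 A pocket-ward of the hydroxyl
        at <- config_complex(config)$complex$receptor$atoms
        og <- at[at$chain == m$chain & at$resno == m$resno &
                 at$name == "OG", , drop = FALSE]
        if (nrow(og)) {
          p <- as.numeric(og[1, c("x", "y", "z")])
          ctr <- config$center %||% c(0, 0, 0)
          u <- ctr - p
          p + 2.9 * u / max(sqrt(sum(u^2)), 1e-9)
        } else c(0, 0, 0)
      }
      mut_bundle <- run_waterflap_pipeline_on(cxm, sysm, cfg_mut)
    } else if (m$type == "ligand_desmethyl") {
      cfg_mut$fixture$ligand <- "des-methyl"
      sysm <- config_complex(cfg_mut)
      mm <- sysm$manifest
      region_center <- as.numeric(
        mm[mm$character == "lipophilic", , drop = FALSE][1, c("x", "y", "z")])
      mut_bundle <- run_waterflap_pipeline(cfg_mut)
    } else {
      stop("unknown mutation type: ", m$type)
    }
    diff <- compare_networks(ref$network, mut_bundle$network,
                             region = list(center = region_center,
                                           radius = 5))
    out$mutations[[names(perts)[i]]] <- list(diff = diff,
                                             bundle = mut_bundle)
  }
  out$metascore <- ms
  jsonlite::write_json(
    list(metascore = ms,
         diffs = lapply(out$mutations, function(x) {
           list(gained = length(x$diff$gained), lost = length(x$diff$lost),
                reclassified = nrow(x$diff$reclassified),
                delta_sum_dg = x$diff$delta_sum_dg)
         })),
    file.path(config$out_dir, "bpm_report.json"), auto_unbox = TRUE,
    digits = 6)
  invisible(out)
}

# waterflap stages on an already-built (possibly mutated) complex
run_waterflap_pipeline_on <- function(cx, sys, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- do.call(placement_schedule, config$schedule)
  center <- config$center %||%
    (if (!is.null(cx$ligand)) NULL else sys$center %||% c(0, 0, 0))
  net <- place_waters_iterative(cx, sched, center = center)
  rl <- relax_network(cx, net,
                      n_sweeps = config$relax$n_sweeps %||% 100,
                      mobile_ligand = isTRUE(config$relax$mobile_ligand),
                      temperature = config$relax$temperature %||% 300,
                      seed = config$seed)
  net <- rl$network
  cx$ligand <- rl$ligand
  box <- make_bulk_box(config$bulk$edge %||% 18, config$bulk$seed %||% 1)
  net <- rescore_waters(cx, net, calibrate_bulk_reference(box))
  net <- classify_waters(net, do.call(classification_scheme, config$scheme))
  list(complex = cx, network = net, bundle_dir = config$out_dir)
}
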