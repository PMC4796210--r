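test_that("schedule and scheme constructors validate their invariants", {
  s <- placement_schedule()
  expect_lt(s$initial_cutoff, s$final_cutoff)
  expect_error(placement_schedule(initial_cutoff = -1, final_cutoff = -8),
               "initial_cutoff")
  expect_error(classification_scheme(red_above = 1, yellow_above = 2),
               "red_above")
})

test_that("bulk calibration is negative, stable in box size, deterministic", {
  ref <- bulk_ref18()
  expect_lt(ref, 0)
  expect_identical(ref, calibrate_bulk_reference(make_bulk_box(18, 1)))
  # a substantially larger box moves the reference by little
  ref_big <- calibrate_bulk_reference(make_bulk_box(24, 1))
  expect_lt(abs(ref_big - ref), 0.3)
  # too-small interior refuses to calibrate
  expect_error(calibrate_bulk_reference(make_bulk_box(13, 1)), "interior")
})

test_that("placement fills planted polar sites and respects its contract", {
  fx <- cav_pair()
  net <- net_apo()
  expect_gte(nrow(net$waters), 3)
  o <- water_o(net$waters)
  for (i in which(fx$manifest$character == "polar")) {
    p <- as.numeric(fx$manifest[i, 1:3])
    expect_lt(min(sqrt((o[, 1] - p[1])^2 + (o[, 2] - p[2])^2 +
                       (o[, 3] - p[3])^2)), 0.75)
  }
  # soundness: every water was accepted at or below its active cutoff
  expect_true(all(net$waters$placement_energy <=
                  net$waters$placement_cutoff + 1e-9))
  # validity: no clash against the environment or between waters
  expect_true(network_is_valid(fx$complex, net))
  # waters stay inside the placement sphere
  d <- sqrt(rowSums(sweep(o, 2, net$center)^2))
  expect_true(all(d <= net$schedule$placement_radius + 1e-9))
  # geometry of every placed water is a rigid three-site water
  expect_true(check_water_geometry(net$waters))
})

test_that("an environment with no hotspot below the final cutoff stays dry", {
  fx <- make_toy_cavity(0, 0, seed = 2, shell_radius = 10, site_radius = 6.5)
  # shrink the window so only the (empty) deep cavity centre is eligible
  net <- place_waters_iterative(fx$complex,
                                placement_schedule(placement_radius = 3),
                                center = c(0, 0, 0))
  expect_equal(nrow(net$waters), 0)
})

test_that("relaxation lowers the energy on average and keeps validity", {
  fx <- cav_pair()
  net <- net_apo()
  e0 <- system_energy(fx$complex, net)
  de <- vapply(1:5, function(sd) {
    rl <- relax_network(fx$complex, net, n_sweeps = 40, seed = sd)
    expect_true(network_is_valid(fx$complex, rl$network))
    system_energy(fx$complex, rl$network) - e0
  }, numeric(1))
  expect_lt(mean(de), 0)
  # zero sweeps is the identity
  rl0 <- relax_network(fx$complex, net, n_sweeps = 0)
  expect_identical(rl0$network$waters, net$waters)
  expect_error(relax_network(fx$complex,
                             new_network(new_waters(), placement_schedule(),
                                         c(0, 0, 0))),
               "nothing to relax")
})

test_that("rescoring is bulk-consistent, radius-limited and penalises
           lipophilic positions", {
  fx <- cav_pair()
  # self-consistency: interior bulk waters re-scored against the box
  # itself sit near zero
  box <- bulk_box18()
  edge <- attr(box, "edge")
  fake <- new_complex(new_structure(empty_atoms()))
  netb <- new_network(box, placement_schedule(), center = rep(edge / 2, 3))
  netb <- rescore_waters(fake, netb, bulk_ref18())
  o <- water_o(box)
  interior <- which(apply(o >= 4 & o <= edge - 4, 1, all))
  dg <- netb$scores$delta_g_est[netb$scores$water_index %in% interior]
  expect_lt(abs(stats::median(dg)), 0.5)

  # radius rule: only waters within the rescore radius carry scores
  net <- net_apo_scored()
  o2 <- water_o(net$waters)
  d <- sqrt(rowSums(sweep(o2, 2, net$center)^2))
  expect_setequal(net$scores$water_index,
                  which(d <= net$schedule$rescore_radius))

  # a water forced into the lipophilic-only cup scores unhappy
  lip_p <- as.numeric(fx$manifest[fx$manifest$character == "lipophilic",
                                  1:3][1, ])
  extra <- make_water(lip_p)
  extra$placement_cutoff <- NA_real_
  forced <- rbind(net$waters, extra)
  netf <- new_network(forced, net$schedule, net$center)
  netf <- rescore_waters(fx$complex, netf, bulk_ref18())
  dg_forced <- netf$scores$delta_g_est[netf$scores$water_index ==
                                       nrow(forced)]
  expect_gt(dg_forced, 0)
  expect_error(rescore_waters(fx$complex, net, NA_real_), "calibrated")
})

test_that("classification partitions the free-energy axis as stated", {
  waters <- do.call(rbind, lapply(1:7, function(i) make_water(c(3 * i, 0, 0))))
  net <- new_network(waters, placement_schedule(), c(0, 0, 0))
  net$scores <- data.frame(water_index = 1:7,
                           e_oh2_context = 0, e_cry = 0,
                           delta_g_est = c(4.0, 3.5, 3.0, 0, -1.0, -1.001,
                                           2.0),
                           class_label = NA_character_)
  out <- classify_waters(net)
  expect_equal(out$scores$class_label,
               c("red", "yellow", "yellow", "grey", "grey", "blue", "grey"))
  # totality over a dense sweep: exactly one class everywhere
  net$scores <- data.frame(water_index = 1, e_oh2_context = 0, e_cry = 0,
                           delta_g_est = 0, class_label = NA_character_)
  for (dg in seq(-5, 6, by = 0.25)) {
    net$scores$delta_g_est <- dg
    lab <- classify_waters(net)$scores$class_label
    expect_true(lab %in% c("red", "yellow", "grey", "blue"))
  }
  expect_error(classify_waters(new_network(waters, placement_schedule(),
                                           c(0, 0, 0))),
               "no scores")
})

test_that("hydrogen-bond graph edges match a brute-force enumeration", {
  # two waters at ideal separation with an aligned donor hydrogen:
  # rotate the canonical template so one O-H bond points straight at the
  # acceptor oxygen (linear D-H...A geometry)
  w1 <- make_water(c(0, 0, 0))
  half <- 104.52 / 2 * pi / 180
  R <- rotation_matrix(c(0, 1, 0), pi - half)
  w2 <- make_water(c(0, 0, 2.8), R)
  net <- new_network(rbind(w1, w2), placement_schedule(), c(0, 0, 0))
  g <- hbond_graph(new_complex(new_structure(empty_atoms())), net)
  expect_equal(igraph::ecount(g), 1)
  # an isolated water has degree zero
  w3 <- make_water(c(10, 10, 10))
  net3 <- new_network(rbind(w1, w2, w3), placement_schedule(), c(0, 0, 0))
  g3 <- hbond_graph(new_complex(new_structure(empty_atoms())), net3)
  expect_equal(igraph::degree(g3)[["W3"]], 0)

  # bulk box: mean degree equals an independent double-loop count
  box <- make_bulk_box(14, 2)
  netb <- new_network(box, placement_schedule(), c(7, 7, 7))
  gb <- hbond_graph(new_complex(new_structure(empty_atoms())), netb)
  o <- water_o(box)
  h <- list(as.matrix(box[, c("h1x", "h1y", "h1z")]),
            as.matrix(box[, c("h2x", "h2y", "h2z")]))
  n_edges <- 0
  for (i in seq_len(nrow(box))) {
    for (j in seq_len(nrow(box))) {
      if (j <= i) next
      r <- sqrt(sum((o[i, ] - o[j, ])^2))
      if (r > 3.5) next
      bonded <- FALSE
      for (pair in list(c(i, j), c(j, i))) {
        d <- pair[1]; a <- pair[2]
        for (hh in h) {
          v1 <- o[d, ] - hh[d, ]; v2 <- o[a, ] - hh[d, ]
          cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          if (cth < -0.5) { bonded <- TRUE; break }
        }
        if (bonded) break
      }
      if (bonded) n_edges <- n_edges + 1
    }
  }
  expect_equal(igraph::ecount(gb), n_edges)
})

test_that("network comparison reports identity, gains and region sums", {
  net <- net_apo_scored()
  self <- compare_networks(net, net)
  expect_equal(length(self$gained), 0)
  expect_equal(length(self$lost), 0)
  expect_equal(nrow(self$reclassified), 0)
  expect_equal(self$delta_sum_dg, 0)

  # dropping one scored water shows up as lost
  drop_i <- net$scores$water_index[1]
  less <- net
  less$waters <- less$waters[-drop_i, ]
  less$scores <- less$scores[less$scores$water_index != drop_i, ]
  less$scores$water_index <- ifelse(less$scores$water_index > drop_i,
                                    less$scores$water_index - 1L,
                                    less$scores$water_index)
  diff <- compare_networks(net, less)
  expect_equal(length(diff$lost), 1)
  expect_equal(diff$lost, drop_i)
  expect_error(compare_networks(net, new_network(net$waters, net$schedule,
                                                 net$center)),
               "scored")
})

test_that("serine-to-alanine mutation makes nearby waters unhappier", {
  fx <- cav_pair()
  host <- fx$manifest$host_resno[2]  # the remote polar site
  site_p <- as.numeric(fx$manifest[2, 1:3])
  mut <- mutate_to_alanine(fx$complex, "A", host)
  net_ref <- net_apo_scored()
  net_mut <- place_waters_iterative(mut, center = cav_pair()$center)
  net_mut <- classify_waters(rescore_waters(mut, net_mut, bulk_ref18()))
  diff <- compare_networks(net_ref, net_mut,
                           region = list(center = site_p, radius = 5))
  expect_gt(diff$delta_sum_dg, 0)
  ranks <- c(blue = 1, grey = 2, yellow = 3, red = 4)
  worse <- sum(ranks[diff$reclassified$class_b] >
               ranks[diff$reclassified$class_a])
  expect_gte(worse + length(diff$gained), 1)
})
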