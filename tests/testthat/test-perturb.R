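test_that("graph observables match closed forms and the brute-force oracle", {
  two <- graph_from_edges(c("a", "b"), "a", "b", 1)
  expect_equal(graph_observable(two, "aspl"), 1)
  # complete graph with uniform distance d -> aspl = d
  labs <- paste0("n", 1:5)
  pr <- combn(labs, 2)
  comp <- graph_from_edges(labs, pr[1, ], pr[2, ], rep(0.8, 10))
  expect_equal(graph_observable(comp, "aspl"), 0.8)
  for (seed in 1:25) {
    gr <- random_connected_graph(sample(4:8, 1), seed + 900)
    expect_equal(graph_observable(gr, "aspl"), oracle_aspl(gr),
                 tolerance = 1e-9)
  }
  expect_error(graph_observable(residue_graph(
    data.frame(label = character(0), chain = character(0),
               resno = integer(0), resname = character(0)),
    data.frame())), "empty")
})

test_that("node perturbation follows the remove/reweight contracts", {
  gr <- random_connected_graph(6, seed = 31)
  # reweight with similarity identically 1 leaves the graph unchanged
  s1 <- substitution_similarity(matrix(1, 20, 20,
                                       dimnames = list(aa_alphabet(),
                                                       aa_alphabet())))
  wt <- aa_three_to_one(gr$nodes$resname[1])
  mut <- setdiff(aa_alphabet(), wt)[1]
  pg <- perturb_node(gr, gr$nodes$label[1], mut, "reweight", s1)
  expect_equal(pg$edges, gr$edges)
  # s = 0.5 increases incident distances by ln 2 exactly (pre-clamp)
  s5 <- substitution_similarity({
    m <- matrix(0.5, 20, 20); diag(m) <- 1
    dimnames(m) <- list(aa_alphabet(), aa_alphabet()); m
  })
  pg2 <- perturb_node(gr, gr$nodes$label[1], mut, "reweight", s5)
  inc <- gr$edges$i == gr$nodes$label[1] | gr$edges$j == gr$nodes$label[1]
  unclamped <- gr$edges$g[inc] * 0.5 >= 0.01
  expect_equal(pg2$edges$distance[inc][unclamped],
               gr$edges$distance[inc][unclamped] + log(2),
               tolerance = 1e-12)
  expect_equal(pg2$edges$distance[!inc], gr$edges$distance[!inc])
  # remove deletes the node and incident edges
  rg <- perturb_node(gr, gr$nodes$label[2], mode = "remove")
  expect_false(gr$nodes$label[2] %in% rg$nodes$label)
  expect_false(any(rg$edges$i == gr$nodes$label[2] |
                     rg$edges$j == gr$nodes$label[2]))
  expect_error(perturb_node(gr, "nope", mode = "remove"), "unknown node")
  expect_error(perturb_node(gr, gr$nodes$label[1], wt, "reweight", s5),
               "wild-type")
})

test_that("star leaf/center removal changes ASPL by its closed form", {
  # uniform star with n leaves has ASPL = 2dn/(n+1) over reachable pairs
  st <- star_graph(6, d = 1.2)
  expect_equal(graph_observable(st, "aspl"), 2 * 1.2 * 6 / 7)
  leafless <- perturb_node(st, "lf01", mode = "remove")
  expect_equal(graph_observable(leafless, "aspl"), 2 * 1.2 * 5 / 6)
})

test_that("perturbation profiles standardize correctly and respect symmetry", {
  # uniform cycle: all removals equivalent -> sigma = 0 -> z all zero
  labs <- paste0("c", 1:6)
  cyc <- graph_from_edges(labs, labs, labs[c(2:6, 1)], rep(1, 6))
  prof <- profile_perturbations(cyc, mode = "remove")
  expect_equal(max(abs(diff(prof$delta_L))), 0, tolerance = 1e-12)
  expect_equal(prof$z, rep(0, 6))
  # remove mode: identical delta across all 19 substitutions
  gr <- random_connected_graph(7, seed = 55)
  p2 <- profile_perturbations(gr, mode = "remove")
  expect_equal(apply(p2$per_mutation_delta, 1, function(r) max(r) - min(r)),
               rep(0, 7), ignore_attr = TRUE)
  # sigma > 0 case: mean(z) = 0, population sd(z) = 1 to 1e-10
  expect_lt(abs(mean(p2$z)), 1e-10)
  expect_lt(abs(sqrt(mean((p2$z - mean(p2$z))^2)) - 1), 1e-10)
  # z invariant under affine rescaling of delta_L
  z2 <- allonet:::standardize_z(3 * p2$delta_L + 7)
  expect_equal(z2, p2$z, tolerance = 1e-10)
})

test_that("reweight profiles differentiate substitutions via the similarity table", {
  gr <- random_connected_graph(6, seed = 77)
  prof <- profile_perturbations(gr, mode = "reweight")
  # different substitutions at a node give different deltas
  spread <- apply(prof$per_mutation_delta, 1, function(r) max(r) - min(r))
  expect_gt(max(spread), 0)
  expect_lt(abs(mean(prof$z)), 1e-10)
})

test_that("profiles equal brute-force recomputation on random graphs", {
  for (seed in 1:20) {
    gr <- random_connected_graph(sample(5:8, 1), seed + 40)
    prof <- profile_perturbations(gr, mode = "remove",
                                  observable = "aspl")
    want <- vapply(gr$nodes$label, function(nd) {
      pg <- perturb_node(gr, nd, mode = "remove")
      (oracle_aspl(pg) - oracle_aspl(gr))^2
    }, numeric(1))
    expect_equal(prof$delta_L, unname(want), tolerance = 1e-9)
  }
})

test_that("aggregation variants apply their documented formulas", {
  gr <- random_connected_graph(6, seed = 91)
  pm <- profile_perturbations(gr, mode = "reweight",
                              aggregation = "mean_square")
  pr <- profile_perturbations(gr, mode = "reweight", aggregation = "rms")
  pa <- profile_perturbations(gr, mode = "reweight",
                              aggregation = "mean_abs")
  expect_equal(pr$delta_L, sqrt(pm$delta_L), tolerance = 1e-12)
  expect_equal(pa$delta_L, rowMeans(abs(pm$per_mutation_delta)),
               ignore_attr = TRUE)
  expect_true(all(pm$delta_L >= 0))
})

test_that("ensemble averaging of profiles is exact and scale-aware", {
  gr <- random_connected_graph(6, seed = 12)
  p <- profile_perturbations(gr, mode = "remove")
  expect_equal(ensemble_average_profile(list(p))$z, p$z)
  expect_equal(ensemble_average_profile(list(p, p))$delta_L, p$delta_L)
  # delta_L of v and 3v average to 2v with unchanged Z
  p3 <- p
  p3$delta_L <- 3 * p$delta_L
  p3$per_mutation_delta <- 3 * p$per_mutation_delta
  avg <- ensemble_average_profile(list(p, p3))
  expect_equal(avg$delta_L, 2 * p$delta_L)
  expect_equal(avg$z, p$z, tolerance = 1e-10)
  p_bad <- profile_perturbations(gr, mode = "reweight")
  expect_error(ensemble_average_profile(list(p, p_bad)), "mix")
})

test_that("hotspot ranking filters and orders by Z", {
  gr <- random_connected_graph(6, seed = 5)
  prof <- profile_perturbations(gr, mode = "remove")
  prof$z <- rep(0, 6)
  expect_identical(rank_hotspots(prof), character(0))
  prof$z <- c(-1, 3, -0.5, -0.5, -0.5, -0.5)
  expect_identical(rank_hotspots(prof), prof$residue_labels[2])
  prof$z <- c(2, 3, 1.5, -1, -1, -1)
  expect_identical(rank_hotspots(prof, 1.0),
                   prof$residue_labels[c(2, 1, 3)])
})

test_that("planted bottlenecks are recovered as the top-Z hotspot", {
  hits <- 0L
  for (seed in 1:20) {
    pb <- plant_bottleneck_graph(c(6, 6), seed = seed)
    prof <- profile_perturbations(pb$graph, mode = "remove",
                                  observable = "aspl")
    if (prof$residue_labels[which.max(prof$z)] ==
        pb$ground_truth$planted_bottleneck) hits <- hits + 1L
    expect_identical(rank_hotspots(prof, z_min = max(prof$z) - 1e-9)[1],
                     pb$ground_truth$planted_bottleneck)
  }
  expect_equal(hits, 20L)
})
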