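test_that("interface detection respects cutoff, occupancy and planted truth", {
  far <- make_toy_complex(8, 6, 0, seed = 1, n_frames = 20)
  expect_identical(identify_interface_residues(far$ensemble, "A", "B"),
                   character(0))
  near <- make_toy_complex(10, 8, 3, seed = 2, n_frames = 50)
  expect_identical(identify_interface_residues(near$ensemble, "A", "B"),
                   near$ground_truth$planted_interface)
  expect_error(identify_interface_residues(near$ensemble, "A", "A"),
               "overlap")
})

test_that("built-in contact scorer follows its documented arithmetic", {
  # single cross-chain contact pair with a crafted table:
  # e(L,L) = -1, e(A,L) = -0.4  =>  L -> A scores +0.6
  e <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  e["L", "L"] <- -1
  e["A", "L"] <- e["L", "A"] <- -0.4
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), icode = "",
    resname = "LEU", atom = "CA", element = "C",
    x = c(0, 4), y = 0, z = 0, stringsAsFactors = FALSE)
  ref <- reference_structure(atoms)
  frames <- array(c(0, 4, 0, 0, 0, 0), c(1, 2, 3))
  ens <- conformational_ensemble(ref, frames)
  sc <- builtin_contact_scorer(e, burial_weight = 0, cutoff = 5)
  out <- sc$score_frame(ens, 1, 1L)
  expect_equal(out[1, "A"], 0.6)
  expect_equal(out[1, "L"], 0)
  # zero cross-interface contacts and burial 0 -> all zero
  frames2 <- frames; frames2[1, 2, 1] <- 50
  ens2 <- conformational_ensemble(ref, frames2)
  expect_equal(unname(sc$score_frame(ens2, 1, 1L)), matrix(0, 1, 20))
  # e == 0 -> pure burial term
  sc2 <- builtin_contact_scorer(matrix(0, 20, 20), burial_weight = 2,
                                cutoff = 5)
  out2 <- sc2$score_frame(ens, 1, 1L)
  h <- c(A = 1.8, L = 3.8) / 4.5
  burial <- min(1, 1 / 10)
  expect_equal(out2[1, "A"], 2 * (h[["A"]] - h[["L"]]) * burial)
  expect_error(builtin_contact_scorer(matrix(rnorm(400), 20, 20)),
               "symmetric")
})

test_that("ensemble scan equals the mean of hand-computed per-frame scores", {
  res <- make_toy_complex(8, 6, 3, seed = 5, n_frames = 2)
  ens <- res$ensemble
  iface <- res$ground_truth$planted_interface
  sc <- builtin_contact_scorer(burial_weight = 0.5)
  scan <- scan_mutations(ens, sc, iface, n_samples = 2)
  ords <- match(iface, ens$reference$residues$label)
  hand <- (sc$score_frame(ens, 1, ords) + sc$score_frame(ens, 2, ords)) / 2
  wt_cols <- cbind(seq_along(iface), match(scan$wt, aa_alphabet()))
  hand[wt_cols] <- 0
  expect_equal(scan$ddg, hand)
  # wild-type column exactly zero
  expect_true(all(scan$ddg[wt_cols] == 0))
  # constant scorer: ddg = c, se = 0
  const <- structure(list(
    name = "const", parameters = list(),
    score_frame = function(ens, f, ords) {
      m <- matrix(3, length(ords), 20,
                  dimnames = list(ens$reference$residues$label[ords],
                                  aa_alphabet()))
      wt <- aa_three_to_one(ens$reference$residues$resname[ords])
      m[cbind(seq_along(ords), match(wt, aa_alphabet()))] <- 0
      m
    }), class = "SubstitutionScorer")
  scan_c <- scan_mutations(ens, const, iface, n_samples = 2)
  non_wt <- scan_c$ddg
  non_wt[wt_cols] <- NA
  expect_true(all(non_wt == 3, na.rm = TRUE))
  expect_equal(max(scan_c$ddg_se), 0)
  expect_error(scan_mutations(ens, sc, "Z:99"), "unknown position")
})

test_that("scan averaging is linear over concatenated ensembles", {
  r1 <- make_toy_complex(8, 6, 2, seed = 8, n_frames = 6)
  r2 <- make_toy_complex(8, 6, 2, seed = 9, n_frames = 6)
  iface <- r1$ground_truth$planted_interface
  sc <- builtin_contact_scorer(burial_weight = 0.3)
  both <- concat_ensembles(r1$ensemble, r2$ensemble)
  s12 <- scan_mutations(both, sc, iface, n_samples = 12)
  sa <- scan_mutations(r1$ensemble, sc, iface, n_samples = 6)
  sb <- scan_mutations(r2$ensemble, sc, iface, n_samples = 6)
  expect_equal(s12$ddg, (sa$ddg + sb$ddg) / 2, tolerance = 1e-12)
})

test_that("standard error shrinks as 1/sqrt(n) on i.i.d. frames", {
  res <- make_toy_complex(10, 8, 3, seed = 13, n_frames = 2)
  # i.i.d. jitter frames around the complex reference
  ens <- jitter_ensemble(res$ensemble$reference, 1024, 0.35, seed = 14)
  iface <- res$ground_truth$planted_interface
  # continuous per-frame scorer (mean distance to the partner chain,
  # scaled per substitution) so every frame contributes smooth variation
  sc <- continuous_distance_scorer()
  ns <- c(64, 256, 1024)
  scans <- lapply(ns, function(n)
    scan_mutations(ens, sc, iface, n_samples = n)$ddg_se)
  keep <- Reduce(`&`, lapply(scans, function(m) m > 0))
  mean_se <- vapply(scans, function(m) mean(m[keep]), numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[2]
  expect_lt(abs(slope - (-0.5)), 0.1)
})

test_that("energy decomposition aggregation averages and validates labels", {
  t1 <- data.frame(residue = c("A:1", "A:2", "A:3"),
                   total = c(-2, 0, 1), vdw = c(-1, 0, 0.5),
                   elec = c(-1, 0, 0.5))
  agg <- aggregate_energy_decomposition(list(t1, t1, t1))
  expect_equal(agg$total_mean, sort(t1$total))
  expect_equal(agg$total_se, rep(0, 3))
  t2 <- t1; t2[, 2:4] <- -t1[, 2:4]
  agg2 <- aggregate_energy_decomposition(list(t1, t2))
  expect_equal(agg2$total_mean, rep(0, 3))
  t3 <- t1; t3$residue[2] <- "B:9"
  expect_error(aggregate_energy_decomposition(list(t1, t3)), "row 2")
  # sampling distribution: mean within 3 se of truth for >= 95% of cases
  set.seed(21)
  truth <- rnorm(30)
  tabs <- lapply(1:100, function(k)
    data.frame(residue = paste0("A:", 1:30), total = truth + rnorm(30),
               vdw = 0, elec = 0))
  agg3 <- aggregate_energy_decomposition(tabs)
  ok <- abs(agg3$total_mean - truth[match(agg3$residue,
                                          paste0("A:", 1:30))]) <=
    3 * agg3$total_se
  expect_gte(mean(ok), 0.95)
})

test_that("heatmap CSV export uses figure orientation and round-trips", {
  res <- make_toy_complex(8, 6, 2, seed = 4, n_frames = 4)
  iface <- res$ground_truth$planted_interface
  sc <- builtin_contact_scorer(burial_weight = 0.5)
  scan <- scan_mutations(res$ensemble, sc, iface, n_samples = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  export_heatmap(scan, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(dim(back), c(20L, length(iface) + 1L))
  expect_equal(as.matrix(back[, -1]), t(scan$ddg), tolerance = 1e-9,
               ignore_attr = TRUE)
  # all-zero table renders without error
  scan0 <- scan
  scan0$ddg[] <- 0
  img <- withr::local_tempfile(fileext = ".png")
  expect_no_error(export_heatmap(scan0, f, image = img))
  expect_true(file.exists(img))
})
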