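test_that("superposition removes exact rigid motion and matches the quaternion oracle", {
  s <- build_toy_structure(10, "helix")
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 5, seed = 2))
  moved <- rigid_transform_ensemble(enm$ensemble)
  fit <- superpose_frames(moved)
  # pure rigid motion on top of the sampled frames: after refit, per-frame
  # RMSD to reference equals that of the unmoved ensemble's optimal fit
  r_fit <- compute_rmsd_series(fit)
  ca <- s$ca_index
  ref <- as.matrix(s$atoms[ca, c("x", "y", "z")])
  r_oracle <- vapply(seq_len(5), function(f)
    quaternion_rmsd(ref, matrix(moved$frames[f, ca, ], ncol = 3)),
    numeric(1))
  expect_equal(r_fit, r_oracle, tolerance = 1e-8)
  # frames that ARE rigid motions of the reference fit back to ~0
  ref_ens <- conformational_ensemble(
    s, aperm(array(as.matrix(s$atoms[, c("x", "y", "z")]),
                   c(nrow(s$atoms), 3, 4)), c(3, 1, 2)))
  moved_ref <- rigid_transform_ensemble(ref_ens, angle = 1.2)
  expect_lt(max(compute_rmsd_series(superpose_frames(moved_ref))), 1e-8)
  expect_error(superpose_frames(enm$ensemble, selection = 1:2),
               "at least 3")
})

test_that("RMSD series matches the direct per-frame formula", {
  s <- build_toy_structure(8, "helix")
  ref_xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  frames <- aperm(array(ref_xyz, c(nrow(ref_xyz), 3, 3)), c(3, 1, 2))
  ens <- conformational_ensemble(s, frames)
  expect_equal(compute_rmsd_series(ens), rep(0, 3))
  # one frame displaced +1 A in x on every atom, no refit
  frames[2, , 1] <- frames[2, , 1] + 1
  ens2 <- conformational_ensemble(s, frames)
  expect_equal(compute_rmsd_series(ens2), c(0, 1, 0))
  # brute-force formula on an ENM ensemble
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 20, seed = 9))
  got <- compute_rmsd_series(enm$ensemble)
  ca <- s$ca_index
  want <- vapply(1:20, function(f) {
    d <- matrix(enm$ensemble$frames[f, ca, ], ncol = 3) - ref_xyz[ca, ]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("RMSF matches its closed-form expectation and the covariance oracle", {
  s <- build_toy_structure(6, "helix")
  expect_error(compute_rmsf(conformational_ensemble(
    s, array(as.matrix(s$atoms[, c("x", "y", "z")]),
             c(1, nrow(s$atoms), 3)))), "2 frames")
  static <- jitter_ensemble(s, 5, 0)
  expect_equal(compute_rmsf(static)$value, rep(0, 6))
  # isotropic jitter sigma = 0.5: RMSF -> sigma * sqrt(3)
  jit <- jitter_ensemble(s, 10000, 0.5, seed = 4)
  expect_equal(mean(compute_rmsf(jit)$value), 0.5 * sqrt(3),
               tolerance = 0.02)
  # ENM: RMSF^2 ~ 3 * diagonal of the analytic per-coordinate covariance
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 20000, seed = 5))
  rmsf <- compute_rmsf(enm$ensemble)$value
  want <- sqrt(3 * diag(enm$ground_truth$covariance_block))
  expect_equal(rmsf, want, tolerance = 0.05)
})

test_that("DCCM satisfies its definition on planted displacements", {
  s <- build_toy_structure(5, "helix")
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 200, seed = 6))
  ens <- enm$ensemble
  ca <- s$ca_index
  # residue 3 copies residue 1's motion; residue 4 negates it
  for (d in 1:3) {
    base <- ens$frames[, ca[1], d] - mean(ens$frames[, ca[1], d])
    ens$frames[, ca[3], d] <- 10 + base
    ens$frames[, ca[4], d] <- -5 - base
  }
  ens <- conformational_ensemble(s, ens$frames)
  C <- compute_dccm(ens)$values
  expect_equal(diag(C), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(C[1, 3], 1, tolerance = 1e-10)
  expect_equal(C[1, 4], -1, tolerance = 1e-10)
  # zero-fluctuation residue: zero row with warning
  ens$frames[, ca[5], ] <- 0
  ens2 <- conformational_ensemble(s, ens$frames)
  expect_warning(C2 <- compute_dccm(ens2)$values, "zero fluctuation")
  expect_equal(C2[5, -5], rep(0, 4), ignore_attr = TRUE)
  expect_equal(C2[5, 5], 1)
})

test_that("estimated DCCM converges to the analytic covariance DCCM", {
  s <- build_toy_structure(20, "helix", seed = 2)
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 5000, seed = 8))
  C <- compute_dccm(enm$ensemble)$values
  expect_lt(max(abs(C - enm$ground_truth$analytic_dccm)), 0.05)
  # independent cross-check of the estimator itself against bio3d
  ca <- s$ca_index
  xyz <- matrix(NA_real_, 5000, 3 * length(ca))
  for (d in 1:3) xyz[, seq(d, 3 * length(ca), by = 3)] <-
      enm$ensemble$frames[, ca, d]
  ref <- suppressWarnings(bio3d::dccm.xyz(xyz, fit = FALSE))
  expect_equal(unname(C), unname(ref[, ]), tolerance = 1e-6)
})

test_that("generalized correlation reproduces its closed form and bounds |DCCM|", {
  # two residues, 3x3 identity marginals, cross-block rho * I:
  # I = -(3/2) ln(1 - rho^2)  =>  r = |rho| exactly
  rho <- 0.6
  sig <- diag(6)
  sig[cbind(1:3, 4:6)] <- sig[cbind(4:6, 1:3)] <- rho
  r <- generalized_correlation_from_covariance(sig, c("A:1", "A:2"))
  expect_equal(r$values[1, 2], rho, tolerance = 1e-10)
  expect_equal(diag(r$values), c(1, 1), ignore_attr = TRUE)
  # independent residues -> r ~ 0; perfectly coupled -> r -> 1
  sig0 <- diag(6)
  expect_equal(generalized_correlation_from_covariance(
    sig0, c("A:1", "A:2"))$values[1, 2], 0)
  sig1 <- diag(6); sig1[cbind(1:3, 4:6)] <- sig1[cbind(4:6, 1:3)] <- 0.999999
  expect_gt(generalized_correlation_from_covariance(
    sig1, c("A:1", "A:2"))$values[1, 2], 0.99)
  # Gaussian ensembles: r_ij dominates |C_ij|
  s <- build_toy_structure(12, "helix")
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 5000, seed = 10))
  C <- compute_dccm(enm$ensemble)$values
  r2 <- compute_generalized_correlation(enm$ensemble)$values
  expect_true(all(abs(C) <= r2 + 0.1))
})

test_that("RMSF and DCCM are invariant under a global rigid motion", {
  s <- build_toy_structure(8, "helix")
  enm <- sample_enm_ensemble(s, enm_spec(n_frames = 300, seed = 11))
  base <- superpose_frames(enm$ensemble)
  moved <- superpose_frames(rigid_transform_ensemble(enm$ensemble))
  expect_equal(compute_rmsf(moved)$value, compute_rmsf(base)$value,
               tolerance = 1e-8)
  expect_equal(compute_dccm(moved)$values, compute_dccm(base)$values,
               tolerance = 1e-8)
})

test_that("correlation matrices stay symmetric and bounded over many seeds", {
  s <- build_toy_structure(6, "helix")
  for (seed in 1:100) {
    enm <- sample_enm_ensemble(s, enm_spec(n_frames = 30, seed = seed))
    C <- compute_dccm(enm$ensemble)$values
    expect_true(isSymmetric(C, tol = 1e-10))
    expect_true(all(C >= -1 & C <= 1))
    expect_equal(diag(C), rep(1, 6), ignore_attr = TRUE)
  }
  r <- compute_generalized_correlation(
    sample_enm_ensemble(s, enm_spec(n_frames = 50, seed = 1))$ensemble)
  expect_true(all(r$values >= 0 & r$values <= 1))
})

test_that("contact occupancy counts frames within the cutoff", {
  # two fixed residues: 4 A apart -> 1.0 at cutoff 5; 10 A -> 0.0
  s <- build_toy_structure(4, "extended", sequence = "GGGG")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])  # Calpha only (all Gly)
  xyz[2, ] <- xyz[1, ] + c(4, 0, 0)
  xyz[3, ] <- xyz[1, ] + c(50, 0, 0)
  xyz[4, ] <- xyz[3, ] + c(10, 0, 0)
  frames <- aperm(array(xyz, c(4, 3, 6)), c(3, 1, 2))
  # pair (1,2) at 4 A in half the frames, 8 A in the other half
  frames[4:6, 2, 1] <- frames[4:6, 1, 1] + 8
  ens <- conformational_ensemble(s, frames)
  occ <- compute_contact_occupancy(ens, cutoff = 5)
  expect_equal(occ$values[1, 2], 0.5)
  expect_equal(occ$values[3, 4], 0)
  expect_equal(diag(occ$values), rep(0, 4), ignore_attr = TRUE)
  occ2 <- compute_contact_occupancy(ens, cutoff = 9)
  expect_true(all(occ2$values >= occ$values))  # monotone in cutoff
})

test_that("subsampling follows the stride convention and seeded determinism", {
  s <- build_toy_structure(4, "helix")
  ens <- jitter_ensemble(s, 4, 0.1)
  expect_equal(subsample(ens, 4)$frame_labels, 1:4)
  expect_equal(subsample(ens, 2)$frame_labels, c(2L, 4L))
  expect_error(subsample(ens, 5), "between 1 and")
  ens2 <- jitter_ensemble(s, 50, 0.1)
  a <- subsample(ens2, 10, "random", seed = 42)
  b <- subsample(ens2, 10, "random", seed = 42)
  expect_identical(a$frame_labels, b$frame_labels)
  expect_error(subsample(ens2, 10, "random"), "seed")
})
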