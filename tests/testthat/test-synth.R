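smallConfig <- function(...) {
  cohortConfig(nPerGroup = 2L, contexts = defaultContexts("rest"), ...)
}

blockMean <- function(A, nets, label) {
  inEff <- nets == label
  sel <- outer(inEff, inEff, "&")
  diag(sel) <- FALSE
  mean(A[sel])
}

test_that("cohort generation is deterministic under a fixed seed", {
  c1 <- makeCohort(smallConfig(seed = 42L))
  c2 <- makeCohort(smallConfig(seed = 42L))
  expect_identical(c1@manifest, c2@manifest)
  expect_identical(c1@groundTruth, c2@groundTruth)
  r1 <- simulateSession(c1, "sub-001", 1, "rest")
  r2 <- simulateSession(c2, "sub-001", 1, "rest")
  expect_identical(r1, r2)
  c3 <- makeCohort(smallConfig(seed = 43L))
  expect_false(identical(c1@groundTruth, c3@groundTruth))
})

test_that("manifest covers the crossover design with counterbalanced order", {
  cfg <- cohortConfig(nPerGroup = 3L)
  coh <- makeCohort(cfg)
  m <- coh@manifest
  # 6 subjects x 2 sessions x (2 + 2 + 4) runs
  expect_equal(nrow(m), 6 * 2 * 8)
  expect_setequal(unique(m$context), c("rest", "gonogo", "rewarded_gonogo"))
  expect_true(all(m$condition[m$group == "TD"] == "placebo"))
  # ADHD: one MPH and one placebo session each, order alternating by parity
  ad <- unique(m[m$group == "ADHD", c("subject_id", "session_index", "condition")])
  byS <- split(ad$condition[order(ad$session_index)], ad$subject_id[order(ad$session_index)])
  expect_true(all(vapply(byS, function(x) setequal(x, c("MPH", "placebo")), logical(1))))
  first <- vapply(split(ad, ad$subject_id), function(d)
    d$condition[d$session_index == 1][1], character(1))
  expect_true(length(unique(first)) == 2L)
})

test_that("paper-scale context grid is available", {
  ctx <- defaultContexts()
  expect_equal(ctx$n_runs, c(2L, 2L, 4L))
  expect_equal(ctx$volumes, c(150L, 195L, 185L))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(cohortConfig(effectNetworks = "not_a_network"), "not_a_network")
  expect_error(cohortConfig(drugRecoveryFraction = 1.5), "drugRecoveryFraction")
  expect_error(cohortConfig(groupEffectSize = -0.1), "groupEffectSize")
})

test_that("null construction: zero effect makes the two ADHD sessions identical", {
  coh <- makeCohort(smallConfig(seed = 7L, groupEffectSize = 0))
  g <- coh@groundTruth[["sub-001"]]
  expect_equal(g$sessions[["1"]]$A, g$sessions[["2"]]$A)
})

test_that("full drug recovery removes the coupling increment exactly", {
  cEff <- makeCohort(smallConfig(seed = 7L, groupEffectSize = 0.2,
                                 drugRecoveryFraction = 1.0))
  cNull <- makeCohort(smallConfig(seed = 7L, groupEffectSize = 0))
  gE <- cEff@groundTruth[["sub-001"]]
  gN <- cNull@groundTruth[["sub-001"]]
  mphE <- Filter(function(s) s$condition == "MPH", gE$sessions)[[1]]
  expect_equal(mphE$A, gN$sessions[["1"]]$A)
})

test_that("effect-network coupling is ordered placebo > MPH > baseline", {
  cfg <- smallConfig(seed = 9L, groupEffectSize = 0.2,
                     drugRecoveryFraction = 0.5)
  coh <- makeCohort(cfg)
  nets <- cfg@networkAssignment
  cNull <- makeCohort(smallConfig(seed = 9L, groupEffectSize = 0))
  g <- coh@groundTruth[["sub-001"]]
  Apl <- Filter(function(s) s$condition == "placebo", g$sessions)[[1]]$A
  Amp <- Filter(function(s) s$condition == "MPH", g$sessions)[[1]]$A
  Abase <- cNull@groundTruth[["sub-001"]]$sessions[["1"]]$A
  bp <- blockMean(Apl, nets, "somatomotor_dorsal")
  bm <- blockMean(Amp, nets, "somatomotor_dorsal")
  b0 <- blockMean(Abase, nets, "somatomotor_dorsal")
  expect_gt(bp, bm)
  expect_gt(bm, b0)
})

test_that("every generated coupling matrix is stationary (radius < 1)", {
  coh <- makeCohort(smallConfig(seed = 3L))
  for (g in coh@groundTruth)
    for (s in g$sessions) {
      rho <- max(abs(eigen(s$A, symmetric = TRUE, only.values = TRUE)$values))
      expect_lt(rho, 1)
      expect_equal(rho, 0.6, tolerance = 1e-8)
    }
})

test_that("simulateSession refuses an unstable coupling matrix", {
  coh <- makeCohort(smallConfig(seed = 3L))
  coh@groundTruth[["sub-001"]]$sessions[["1"]]$A <-
    diag(1.2, coh@config@nRois)
  expect_error(simulateSession(coh, "sub-001", 1, "rest"), "spectral radius")
})

test_that("degenerate generator settings give the expected fixed points", {
  loadings <- list(global = rep(1, 5), wm = rep(1, 5), csf = rep(1, 5),
                   driftSlope = rep(1, 5), motionArtifact = rep(1, 5))
  A <- matrix(0, 5, 5)
  # no innovations, no nuisance, no motion -> identically zero output
  run <- funcontrol:::.simulateRun(A, loadings, Tn = 50, tr = 2, seed = 1L,
                                   spikeRate = 0, mmScale = 0, noise = 0,
                                   driftScale = 0, nuisanceScale = 0,
                                   artifactScale = 0)
  expect_true(all(run$data == 0))
  # A = 0, unit innovations -> white noise with variance 1 (3 SE at T = 2000)
  run2 <- funcontrol:::.simulateRun(A, loadings, Tn = 2000, tr = 2, seed = 2L,
                                    spikeRate = 0, mmScale = 0, noise = 1,
                                    driftScale = 0, nuisanceScale = 0,
                                    artifactScale = 0)
  v <- apply(run2$data, 1, var)
  se <- sqrt(2 / (2000 - 1))
  expect_true(all(abs(v - 1) < 3 * se))
})

test_that("without spikes and with low jitter no frames are censored", {
  cfg <- smallConfig(seed = 5L, motionSpikeRate = 0,
                     motionScale = c(ADHD.placebo = 0.004, ADHD.MPH = 0.004,
                                     TD.placebo = 0.004))
  coh <- makeCohort(cfg)
  runs <- simulateSession(coh, "sub-001", 1, "rest")
  for (r in runs) {
    fdn <- framewiseDisplacement(notchFilterMotion(r$motion, trSeconds = 2))
    expect_true(all(censorMask(fdn, 0.2, 5L)))
  }
})

test_that("long simulated runs match the stated VAR(1) law", {
  cfg <- cohortConfig(nPerGroup = 2L, seed = 13L, nRois = 10L,
                      networkAssignment = rep(c("somatomotor_dorsal",
                                                "default_mode"), each = 5),
                      contexts = data.frame(context = "rest", n_runs = 1L,
                                            volumes = 6000L))
  coh <- makeCohort(cfg)
  runs <- simulateSession(coh, "sub-001", 1, "rest", driftScale = 0,
                          nuisanceScale = 0, artifactScale = 0)
  X <- runs[[1]]$data
  A <- coh@groundTruth[["sub-001"]]$sessions[["1"]]$A
  Tn <- ncol(X)
  Sig <- tcrossprod(X) / Tn
  lag1 <- X[, 2:Tn] %*% t(X[, 1:(Tn - 1)]) / (Tn - 1)
  # E[x(t+1) x(t)'] = A Sigma for a stationary VAR(1)
  expect_lt(max(abs(lag1 - A %*% Sig)), 0.12)
})

test_that("written cohorts round-trip through the TSV interchange layout", {
  dir <- withr::local_tempdir()
  cfg <- cohortConfig(nPerGroup = 1L,
                      contexts = data.frame(context = "rest", n_runs = 1L,
                                            volumes = 60L),
                      seed = 21L)
  coh <- makeCohort(cfg)
  m <- writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  expect_true(all(file.exists(m$timeseries_path)))
  ts <- read.delim(m$timeseries_path[1])
  expect_equal(dim(ts), c(60L, 40L))
  mo <- read.delim(m$motion_path[1])
  expect_equal(names(mo), c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z"))
  atlas <- read.delim(file.path(dir, "atlas.tsv"))
  expect_equal(names(atlas), c("roi_id", "x", "y", "z", "network_label"))
  expect_equal(nrow(atlas), 40L)
})
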