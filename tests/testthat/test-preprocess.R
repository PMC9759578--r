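test_that("framewise displacement follows the sum-of-absolute-differences convention", {
  p <- matrix(1.5, 10, 6)
  expect_equal(framewiseDisplacement(p), rep(0, 10))
  # a single 0.1 mm x-translation step between frames 3 and 4
  p <- matrix(0, 10, 6); p[4:10, 1] <- 0.1
  fd <- framewiseDisplacement(p)
  expect_equal(fd[4], 0.1)
  expect_equal(fd[-4], rep(0, 9))
  # a 0.002 rad rotation step at 50 mm radius contributes 0.1 mm arc
  p <- matrix(0, 10, 6); p[4:10, 5] <- 0.002
  expect_equal(framewiseDisplacement(p, rotationRadius = 50)[4], 0.1)
  expect_error(framewiseDisplacement(matrix(0, 10, 5)), "6 columns")
  expect_error(framewiseDisplacement(matrix(0, 1, 6)), "2 frames")
})

test_that("censor mask applies the threshold and the contiguity rule", {
  expect_true(all(censorMask(rep(0.1, 20), 0.2, 5L)))
  fd <- c(0.1, 0.1, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(censorMask(fd, 0.2, 5L),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  # alternating high/low never yields a 5-frame segment
  fd2 <- rep(c(0.1, 0.3), 10)
  expect_true(all(!censorMask(fd2, 0.2, 5L)))
})

test_that("censoring is idempotent", {
  set.seed(1)
  fd <- runif(200, 0, 0.4)
  m <- censorMask(fd, 0.2, 5L)
  fd2 <- ifelse(m, 0.1, 0.3)
  expect_identical(censorMask(fd2, 0.2, 5L), m)
})

test_that("confound matrix holds exactly 36 labelled columns with the stated expansions", {
  Tn <- 50
  set.seed(2)
  motion <- matrix(rnorm(Tn * 6), Tn, 6)
  g <- rnorm(Tn); w <- rnorm(Tn); cs <- rep(2, Tn)
  X <- buildConfoundMatrix(motion, g, w, cs)
  expect_equal(ncol(X), 36L)
  expect_equal(nrow(X), Tn)
  # constant base signal: derivative and squared derivative identically zero
  expect_true(all(X[, "csf_deriv"] == 0))
  expect_true(all(X[, "csf_deriv_sq"] == 0))
  # square column is the elementwise square
  expect_equal(X[, "global_sq"], g^2, ignore_attr = TRUE)
  # derivative is a backward difference with leading zero
  expect_equal(X[, "global_deriv"], c(0, diff(g)), ignore_attr = TRUE)
  expect_error(buildConfoundMatrix(motion, g[-1], w, cs), "length")
})

test_that("spectral interpolation reconstructs censored frames of band-limited signals", {
  tr <- 2; Tn <- 400
  t <- seq_len(Tn) * tr
  set.seed(3)
  mask <- runif(Tn) > 0.2
  sig <- matrix(sin(2 * pi * 0.03 * t), 1)
  out <- spectralInterpolate(sig, mask, tr)
  expect_equal(out[, mask], sig[, mask])  # retained untouched
  rms <- sqrt(mean((out[1, !mask] - sig[1, !mask])^2))
  expect_lt(rms, 0.1)  # < 10% of unit amplitude
  # all-true mask: identity
  expect_identical(spectralInterpolate(sig, rep(TRUE, Tn), tr), sig)
  # constant signal: interpolated values equal the constant
  const <- matrix(7, 2, Tn)
  expect_equal(spectralInterpolate(const, mask, tr), const)
  expect_error(spectralInterpolate(sig, c(TRUE, rep(FALSE, Tn - 1)), tr),
               "retained")
})

test_that("band-pass filter passes the BOLD band and rejects DC and high frequencies", {
  tr <- 2; Tn <- 400
  dc <- matrix(3, 1, Tn)
  expect_lt(max(abs(bandpassFilter(dc, c(0.009, 0.08), tr))), 1e-10)
  t <- seq_len(Tn) * tr
  inBand <- sin(2 * pi * 0.04 * t)
  outBand <- sin(2 * pi * 0.2 * t)
  expect_gt(fitAmplitude(bandpassFilter(matrix(inBand, 1), c(0.009, 0.08), tr)[1, ],
                         0.04, tr), 0.9)
  expect_lt(fitAmplitude(bandpassFilter(matrix(outBand, 1), c(0.009, 0.08), tr)[1, ],
                         0.2, tr), 0.1)
  expect_error(bandpassFilter(dc, c(0.08, 0.009), tr), "Nyquist|satisfy")
})

test_that("motion notch maps the respiration band through aliasing and attenuates it", {
  tr <- 2; Tn <- 400
  cst <- matrix(5, Tn, 6)
  out <- notchFilterMotion(cst, c(0.31, 0.41), tr)
  expect_equal(max(abs(out - 5)), 0, tolerance = 1e-8)  # DC preserved
  expect_equal(attr(out, "band"), c(0.09, 0.19), tolerance = 1e-12)
  t <- seq_len(Tn) * tr
  mk <- function(f) cbind(sin(2 * pi * f * t), matrix(0, Tn, 5))
  # aliased stop-band center 0.14 Hz: strongly attenuated
  atCenter <- notchFilterMotion(mk(0.14), c(0.31, 0.41), tr)[, 1]
  expect_lt(fitAmplitude(atCenter, 0.14, tr), 0.1)
  # 0.05 Hz: essentially untouched
  slow <- notchFilterMotion(mk(0.05), c(0.31, 0.41), tr)[, 1]
  expect_gt(fitAmplitude(slow, 0.05, tr), 0.9)
})

test_that("nuisance regression is exact, rank-safe, and orthogonal on retained frames", {
  Tn <- 120
  set.seed(4)
  conf <- buildConfoundMatrix(matrix(rnorm(Tn * 6), Tn, 6), rnorm(Tn),
                              rnorm(Tn), rnorm(Tn))
  mask <- rep(TRUE, Tn); mask[sample(Tn, 15)] <- FALSE
  # data equal to a confound column: residual ~ 0 on retained frames
  d <- matrix(conf[, "global"], 1, Tn)
  r <- nuisanceRegress(d, conf, mask)
  expect_lt(max(abs(r[, mask])), 1e-10)
  # all-zero confounds: residuals equal the input (after the drop warning)
  z <- matrix(0, Tn, 4, dimnames = list(NULL, paste0("z", 1:4)))
  d2 <- matrix(rnorm(2 * Tn), 2, Tn)
  expect_warning(r2 <- nuisanceRegress(d2, z, mask), "collinear")
  expect_equal(unclass(r2), d2, ignore_attr = TRUE)
  # duplicated column: dropped by label, fit unchanged
  confDup <- cbind(conf, dup = conf[, "wm"])
  expect_warning(r3 <- nuisanceRegress(d2, confDup, mask), "dup")
  expect_equal(attr(r3, "dropped"), "dup")
  # orthogonality of residuals to every kept column on retained frames
  r4 <- nuisanceRegress(d2, conf, mask)
  g <- abs(t(conf[mask, ]) %*% t(r4[, mask, drop = FALSE]))
  expect_lt(max(g) / max(abs(d2)), 1e-8)
})

test_that("run- and task-level QC rules apply the stated thresholds", {
  fdHigh <- rep(0.6, 100)
  q <- qcRun(fdHigh, rep(TRUE, 100))
  expect_false(q$included); expect_equal(q$reason, "mean FD")
  fdOk <- rep(0.1, 100)
  q2 <- qcRun(fdOk, c(rep(TRUE, 49), rep(FALSE, 51)))
  expect_false(q2$included); expect_equal(q2$reason, "good timepoints")
  q3 <- qcRun(fdOk, rep(TRUE, 100) , minGood = 50L)
  expect_true(q3$included)
  expect_true(qcTask(c(80, 80), 150L))
  expect_false(qcTask(c(80, 60), 150L))
})

test_that("finalize detrends, standardizes on retained frames, and concatenates", {
  set.seed(5)
  Tn <- 80
  mk <- function(data) new("RunTimeseries", data = data,
                           censorMask = rep(TRUE, Tn), trSeconds = 2,
                           motion = NULL, qc = list())
  d <- matrix(rnorm(3 * Tn), 3, Tn)
  one <- finalizeTaskTimeseries(list(mk(d)))
  expect_equal(rowMeans(one$data), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(one$data, 1, sd), rep(1, 3), tolerance = 1e-12)
  two <- finalizeTaskTimeseries(list(mk(d), mk(d)))
  expect_equal(ncol(two$data), 2 * Tn)
  expect_equal(two$data[, 1:Tn], two$data[, (Tn + 1):(2 * Tn)])
  ramp <- matrix(rep(seq_len(Tn), each = 3), 3, Tn, byrow = FALSE)
  out <- finalizeTaskTimeseries(list(mk(ramp)))
  expect_lt(max(abs(out$data)), 1e-8)
  bad <- mk(d[1:2, ])
  expect_error(finalizeTaskTimeseries(list(mk(d), bad)), "ROI")
})

test_that("full cleaning reduces the motion-signal coupling", {
  cfg <- cohortConfig(nPerGroup = 1L, contexts = defaultContexts("rest"),
                      seed = 31L, motionSpikeRate = 0.05)
  coh <- makeCohort(cfg)
  runs <- simulateSession(coh, "sub-001", 1, "rest", artifactScale = 3)
  r <- runs[[1]]
  fdRaw <- framewiseDisplacement(r$motion)
  corBefore <- abs(cor(fdRaw, colMeans(r$data)))
  rt <- preprocessRun(r$data, r$motion, r$nuisance, pipelineConfig())
  m <- retained(rt)
  corAfter <- abs(cor(rt@motion@fdRaw[m], colMeans(rt@data[, m])))
  expect_lt(corAfter, corBefore)
})

test_that("spherical ROI extraction averages in-bounds voxels and flags missing ROIs", {
  skip_if_not_installed("RNifti")
  dims <- c(20L, 20L, 12L, 4L)
  arr <- array(2.5, dim = dims)
  img <- RNifti::asNifti(arr, reference = NULL)
  # default affine: world coordinates equal voxel indices (1 mm isotropic)
  atlas <- data.frame(roi_id = c("a", "b", "oob"),
                      x = c(10, 15, 10), y = c(10, 15, 10),
                      z = c(6, 8, -500),
                      network_label = "visual")
  ext <- extractRoiTimeseries(img, atlas, radiusMm = 2)
  expect_equal(ext$missing, "oob")
  expect_equal(ext$usable, 2L)
  expect_true(all(ext$data["a", ] == 2.5))
  # single-voxel sphere equals that voxel's series
  arr2 <- array(rnorm(prod(dims)), dim = dims)
  img2 <- RNifti::asNifti(arr2, reference = NULL)
  atlas2 <- data.frame(roi_id = "v", x = 5, y = 5, z = 5,
                       network_label = "visual")
  ext2 <- extractRoiTimeseries(img2, atlas2, radiusMm = 0.4)
  expect_equal(as.numeric(ext2$data["v", ]), arr2[6, 6, 6, ])
})
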