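#' @include AllClasses.R
NULL

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum over the six parameters of the absolute backward
#' difference, with the three rotations (radians) converted to arc length at
#' `rotationRadius` mm. The first frame is defined as 0.
#'
#' @param params T x 6 numeric matrix: translations x/y/z in mm then
#'   rotations x/y/z in radians.
#' @param rotationRadius head radius for the rotation arc, mm.
#' @return numeric vector of length T, mm.
#' @examples
#' p <- matrix(0, 10, 6); p[5:10, 1] <- 0.1
#' framewiseDisplacement(p)  # 0.1 at frame 5, 0 elsewhere
#' @export
framewiseDisplacement <- function(params, rotationRadius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("motion parameter table must have exactly 6 columns")
  if (nrow(params) < 2L)
    stop("at least 2 frames are required to compute FD")
  scaled <- params %*% diag(c(1, 1, 1, rep(rotationRadius, 3)))
  c(0, rowSums(abs(diff(scaled))))
}

## fold a frequency through aliasing into [0, fs/2]
.aliasFrequency <- function(f, fs) {
  abs(f - fs * round(f / fs))
}

#' Band-stop (notch) filter motion parameters
#'
#' Zero-phase second-order Butterworth band-stop applied per parameter.
#' The notch targets respiration-driven pseudo-motion; when the requested
#' band lies above the sampling Nyquist frequency (as a 0.31-0.41 Hz band
#' does at TR = 2 s, Nyquist 0.25 Hz), each edge is mapped through aliasing
#' to its representable image below Nyquist before filter design, because
#' respiration aliases into the sampled parameters. The mapped band is
#' attached as attribute `"band"`.
#'
#' @param params T x 6 motion parameter matrix (or any T x k numeric matrix).
#' @param bandHz stop band, Hz (pre-aliasing).
#' @param trSeconds repetition time, seconds.
#' @return filtered matrix, same shape, with attribute `band` (the mapped
#'   stop band actually used, Hz).
#' @export
notchFilterMotion <- function(params, bandHz = c(0.31, 0.41), trSeconds = 2) {
  params <- as.matrix(params)
  fs <- 1 / trSeconds
  nyq <- fs / 2
  band <- sort(vapply(bandHz, .aliasFrequency, numeric(1), fs = fs))
  if (diff(band) <= 0 || band[1] <= 0 || band[2] >= nyq)
    stop(sprintf(
      "notch band (%.3f, %.3f) Hz maps to unusable (%.3f, %.3f) at fs=%.3f Hz",
      bandHz[1], bandHz[2], band[1], band[2], fs))
  bf <- signal::butter(2, band / nyq, type = "stop")
  # filter around the column mean: DC is in the pass band, and demeaning
  # avoids forward-backward edge transients on offset parameters
  out <- apply(params, 2, function(col)
    signal::filtfilt(bf, col - mean(col)) + mean(col))
  dimnames(out) <- dimnames(params)
  attr(out, "band") <- band
  out
}

#' Motion censor mask
#'
#' Frames with FD above `thresholdMm` are censored; afterwards every maximal
#' retained segment shorter than `minContiguous` frames is censored as well.
#'
#' @param fd FD series, mm.
#' @param thresholdMm censoring threshold, mm.
#' @param minContiguous minimum length of a retained segment, frames.
#' @return logical vector, TRUE = retained.
#' @examples
#' censorMask(c(.1, .1, .3, .1, .1, .1, .1, .1), 0.2, 5)
#' @export
censorMask <- function(fd, thresholdMm = 0.2, minContiguous = 5L) {
  stopifnot(thresholdMm > 0, minContiguous >= 1L)
  keep <- fd <= thresholdMm
  r <- rle(keep)
  r$values[r$values & r$lengths < minContiguous] <- FALSE
  inverse.rle(r)
}

## backward difference, first element 0
.bdiff <- function(x) c(0, diff(x))

#' Build the 36-parameter confound matrix
#'
#' Nine base signals (6 motion parameters, global, white matter, CSF), each
#' expanded with its temporal derivative (backward difference, first element
#' 0), its square, and its squared derivative: 36 columns.
#'
#' @param motion T x 6 motion parameter matrix.
#' @param globalSig,wm,csf length-T nuisance signal vectors.
#' @return T x 36 matrix with labelled columns.
#' @export
buildConfoundMatrix <- function(motion, globalSig, wm, csf) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  Tn <- nrow(motion)
  if (length(globalSig) != Tn || length(wm) != Tn || length(csf) != Tn)
    stop("nuisance signal lengths must match the motion table")
  base <- cbind(motion, globalSig, wm, csf)
  colnames(base) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z", "global", "wm", "csf")
  d <- apply(base, 2, .bdiff)
  out <- cbind(base, d, base^2, d^2)
  colnames(out) <- c(colnames(base),
                     paste0(colnames(base), "_deriv"),
                     paste0(colnames(base), "_sq"),
                     paste0(colnames(base), "_deriv_sq"))
  out
}

#' Spectral interpolation of censored frames
#'
#' Least-squares spectral (Lomb-Scargle-type) fit on retained frames,
#' evaluated at censored frames, so temporal filters can be applied without
#' gap artifacts. The basis holds sine/cosine pairs at frequencies
#' `k / span` up to `hifac` times the mean Nyquist frequency of the
#' retained (irregular) sampling, and the fit is solved jointly for all
#' frequencies by rank-revealing QR, shared across ROIs. Retained frames
#' are returned unchanged. Capping the basis below the retained-sampling
#' Nyquist keeps the extrapolation to censored frames well conditioned;
#' the pipeline band-pass that follows removes any frequency content above
#' the BOLD band regardless.
#'
#' @param data ROI x T matrix.
#' @param mask logical length T, TRUE = retained.
#' @param trSeconds repetition time, seconds.
#' @param hifac highest fitted frequency as a fraction of the mean Nyquist
#'   frequency of the retained sampling.
#' @return ROI x T matrix with censored frames replaced.
#' @export
spectralInterpolate <- function(data, mask, trSeconds, hifac = 0.5) {
  data <- as.matrix(data)
  Tn <- ncol(data)
  stopifnot(length(mask) == Tn)
  if (all(mask)) return(data)
  if (sum(mask) < 2L) stop("QC error: fewer than 2 retained frames")
  tAll <- seq_len(Tn) * trSeconds
  tRet <- tAll[mask]
  mu <- rowMeans(data[, mask, drop = FALSE])
  D <- t(data[, mask, drop = FALSE] - mu)      # Tret x ROI
  span <- max(tRet) - min(tRet)
  fmax <- min(hifac * length(tRet) / (2 * span), 1 / (2 * trSeconds))
  K <- floor(fmax * span)
  if (K < 1L) stop("QC error: too few retained frames for a spectral fit")
  w <- 2 * pi * seq_len(K) / span
  Br <- cbind(cos(outer(tRet, w)), sin(outer(tRet, w)))
  beta <- qr.coef(qr(Br), D)
  beta[is.na(beta)] <- 0
  Ba <- cbind(cos(outer(tAll, w)), sin(outer(tAll, w)))
  H <- t(Ba %*% beta) + mu
  out <- data
  out[, !mask] <- H[, !mask]
  out
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward-backward per row.
#' The same filter must be applied to the data and to every confound
#' column before nuisance regression.
#'
#' @param data ROI x T matrix (rows filtered) or numeric vector.
#' @param bandHz pass band, Hz.
#' @param trSeconds repetition time, seconds.
#' @return filtered data, same shape.
#' @export
bandpassFilter <- function(data, bandHz = c(0.009, 0.08), trSeconds = 2) {
  nyq <- 1 / (2 * trSeconds)
  if (!(bandHz[1] > 0 && bandHz[1] < bandHz[2] && bandHz[2] < nyq))
    stop(sprintf("band (%.4f, %.4f) Hz must satisfy 0 < low < high < Nyquist %.4f",
                 bandHz[1], bandHz[2], nyq))
  bf <- signal::butter(2, bandHz / nyq, type = "pass")
  # remove the mean first: DC is outside the pass band, and demeaning
  # avoids forward-backward edge transients on offset signals
  if (is.null(dim(data))) return(signal::filtfilt(bf, data - mean(data)))
  out <- t(apply(data, 1, function(row) signal::filtfilt(bf, row - mean(row))))
  dimnames(out) <- dimnames(data)
  out
}

#' Nuisance regression on retained frames
#'
#' Ordinary least squares of every ROI series on the confound columns, fit
#' using retained frames only; the fitted model is evaluated at all frames
#' and residuals are returned everywhere. Residuals on retained frames are
#' orthogonal to every (kept) confound column. Collinear columns are
#' dropped with a warning; dropped labels are recorded in attribute
#' `"dropped"`.
#'
#' @param data ROI x T matrix (already filtered).
#' @param confounds T x k confound matrix, filtered with the same band.
#' @param mask logical length T, TRUE = retained.
#' @return ROI x T residual matrix.
#' @export
nuisanceRegress <- function(data, confounds,
                            mask = rep(TRUE, ncol(data))) {
  data <- as.matrix(data)
  X <- as.matrix(confounds)
  if (nrow(X) != ncol(data)) stop("confound rows must match data frames")
  stopifnot(length(mask) == ncol(data))
  Xr <- X[mask, , drop = FALSE]
  qrX <- qr(Xr)
  r <- qrX$rank
  dropped <- character()
  if (r < ncol(Xr)) {
    keep <- qrX$pivot[seq_len(r)]
    labs <- colnames(X)
    if (is.null(labs)) labs <- paste0("V", seq_len(ncol(X)))
    dropped <- labs[qrX$pivot[-seq_len(r)]]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
  } else keep <- seq_len(ncol(Xr))
  if (r == 0L) {
    res <- data
  } else {
    Xk <- X[, keep, drop = FALSE]
    beta <- qr.coef(qr(Xk[mask, , drop = FALSE]), t(data[, mask, drop = FALSE]))
    beta[is.na(beta)] <- 0
    res <- data - t(Xk %*% beta)
  }
  attr(res, "dropped") <- dropped
  res
}

#' Run-level quality control
#'
#' A run is excluded when its mean notch-filtered FD exceeds
#' `meanFdLimit` (0.5 mm) or when fewer than `minGood` (50) frames survive
#' censoring.
#'
#' @param fdNotch notch-filtered FD series, mm.
#' @param mask censor mask.
#' @param meanFdLimit run-exclusion limit on mean notch FD, mm.
#' @param minGood minimum retained frames.
#' @return list with `included`, `reason`, `mean_fd_notch`, `n_good`.
#' @export
qcRun <- function(fdNotch, mask, meanFdLimit = 0.5, minGood = 50L) {
  mfd <- mean(fdNotch)
  ng <- sum(mask)
  if (mfd > meanFdLimit)
    list(included = FALSE, reason = "mean FD", mean_fd_notch = mfd, n_good = ng)
  else if (ng < minGood)
    list(included = FALSE, reason = "good timepoints", mean_fd_notch = mfd,
         n_good = ng)
  else
    list(included = TRUE, reason = "ok", mean_fd_notch = mfd, n_good = ng)
}

#' Task-level quality control
#'
#' A (subject, session, context) cell is analyzable only when the retained
#' frames summed over its included runs reach `minGoodPerTask` (150).
#'
#' @param nGoodIncluded retained-frame counts of the included runs.
#' @param minGoodPerTask minimum total retained frames.
#' @return logical flag.
#' @export
qcTask <- function(nGoodIncluded, minGoodPerTask = 150L) {
  sum(nGoodIncluded) >= minGoodPerTask
}

#' Detrend, standardize, and concatenate runs within a task
#'
#' Per run: linear detrend (trend fit on retained frames, subtracted
#' everywhere) and z-scoring using retained-frame mean and standard
#' deviation; runs are then concatenated in acquisition order. Censored
#' frames remain flagged so they never enter covariance estimation.
#'
#' @param runs list of [RunTimeseries-class] objects sharing the ROI set
#'   and TR.
#' @return list with `data` (ROI x T_task), `mask` (combined censor mask)
#'   and `trSeconds`.
#' @export
finalizeTaskTimeseries <- function(runs) {
  stopifnot(length(runs) >= 1L)
  p <- nrow(runs[[1]]@data)
  tr <- runs[[1]]@trSeconds
  rois <- rownames(runs[[1]]@data)
  pieces <- lapply(runs, function(run) {
    if (nrow(run@data) != p || !identical(rownames(run@data), rois))
      stop("ROI set mismatch across runs")
    if (run@trSeconds != tr) stop("TR mismatch across runs")
    m <- run@censorMask
    D <- run@data
    Tn <- ncol(D)
    tgrid <- seq_len(Tn)
    Xr <- cbind(1, tgrid[m])
    B <- qr.coef(qr(Xr), t(D[, m, drop = FALSE]))   # 2 x p
    D <- D - t(cbind(1, tgrid) %*% B)
    mu <- rowMeans(D[, m, drop = FALSE])
    sdv <- apply(D[, m, drop = FALSE], 1, stats::sd)
    # near-constant residuals (e.g. a pure trend) stay at zero rather than
    # being blown up by a numerically tiny standard deviation
    sdv[sdv < 1e-8] <- 1
    list(data = (D - mu) / sdv, mask = m)
  })
  list(data = do.call(cbind, lapply(pieces, `[[`, "data")),
       mask = do.call(c, lapply(pieces, `[[`, "mask")),
       trSeconds = tr)
}

#' Full postprocessing of one run
#'
#' Applies the motion-aware cleaning chain in its fixed order: raw FD,
#' notch-filtered motion parameters and notch FD, censor mask, run QC,
#' then (for included runs) spectral interpolation of censored frames,
#' band-pass filtering of data and of the 36-parameter confound matrix,
#' nuisance regression on retained frames, and re-censoring. The order is
#' part of the contract: changing it changes results.
#'
#' @param data ROI x T raw matrix.
#' @param motion T x 6 motion parameter matrix.
#' @param nuisance data.frame with `global`, `wm`, `csf` columns.
#' @param config a [PipelineConfig-class].
#' @param trSeconds repetition time, seconds.
#' @return a [RunTimeseries-class] with QC filled in; excluded runs carry
#'   their raw data.
#' @export
preprocessRun <- function(data, motion, nuisance, config = pipelineConfig(),
                          trSeconds = 2) {
  data <- as.matrix(data)
  motion <- as.matrix(motion)
  fdRaw <- framewiseDisplacement(motion, config@rotationRadius)
  mNotch <- notchFilterMotion(motion, config@notch, trSeconds)
  fdNotch <- framewiseDisplacement(mNotch, config@rotationRadius)
  mask <- censorMask(fdNotch, config@fdThreshold, config@minContiguous)
  qc <- qcRun(fdNotch, mask, config@runMeanFdLimit, config@minGoodPerRun)
  qc$mean_fd_raw <- mean(fdRaw)
  mot <- new("MotionRecord", params = motion, fdRaw = fdRaw, fdNotch = fdNotch)
  if (qc$included && sum(mask) >= 2L) {
    conf <- buildConfoundMatrix(motion, nuisance$global, nuisance$wm,
                                nuisance$csf)
    dataI <- spectralInterpolate(data, mask, trSeconds)
    dataF <- bandpassFilter(dataI, config@bandpass, trSeconds)
    confF <- t(bandpassFilter(t(conf), config@bandpass, trSeconds))
    colnames(confF) <- colnames(conf)
    clean <- suppressWarnings(nuisanceRegress(dataF, confF, mask))
  } else {
    clean <- data
  }
  new("RunTimeseries", data = clean, censorMask = mask,
      trSeconds = trSeconds, motion = mot, qc = qc)
}

#' Extract spherical-ROI mean timeseries from a 4D NIfTI image
#'
#' Per frame, the mean over voxels whose world coordinates lie within
#' `radiusMm` of each atlas ROI center. ROIs with no in-bounds voxel are
#' flagged missing (supporting field-of-view reductions of an atlas).
#' Requires the RNifti package.
#'
#' @param image path to a 4D NIfTI file or an `niftiImage`.
#' @param atlas data.frame with `roi_id`, `x`, `y`, `z` (mm),
#'   `network_label`.
#' @param radiusMm ROI sphere radius, mm.
#' @return list with `data` (ROI x T, NA rows for missing ROIs),
#'   `missing` (roi ids) and `usable` (count of non-missing ROIs).
#' @export
extractRoiTimeseries <- function(image, atlas, radiusMm = 4) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("extractRoiTimeseries requires the RNifti package")
  img <- if (is.character(image)) RNifti::readNifti(image) else image
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  dims <- dim(arr)
  Tn <- dims[4]
  xfm <- RNifti::xform(img)          # voxel (0-based) -> world, mm
  inv <- solve(xfm)
  vox <- RNifti::pixdim(img)[1:3]
  p <- nrow(atlas)
  out <- matrix(NA_real_, p, Tn, dimnames = list(atlas$roi_id, NULL))
  missing <- character()
  rng <- ceiling(radiusMm / vox)
  for (i in seq_len(p)) {
    ctr <- inv %*% c(atlas$x[i], atlas$y[i], atlas$z[i], 1)
    c0 <- round(ctr[1:3])
    cand <- expand.grid(x = (c0[1] - rng[1]):(c0[1] + rng[1]),
                        y = (c0[2] - rng[2]):(c0[2] + rng[2]),
                        z = (c0[3] - rng[3]):(c0[3] + rng[3]))
    inb <- cand$x >= 0 & cand$x < dims[1] &
           cand$y >= 0 & cand$y < dims[2] &
           cand$z >= 0 & cand$z < dims[3]
    cand <- cand[inb, , drop = FALSE]
    if (nrow(cand)) {
      world <- t(xfm %*% rbind(t(as.matrix(cand)), 1))[, 1:3, drop = FALSE]
      d2 <- (world[, 1] - atlas$x[i])^2 + (world[, 2] - atlas$y[i])^2 +
            (world[, 3] - atlas$z[i])^2
      cand <- cand[d2 <= radiusMm^2, , drop = FALSE]
    }
    if (!nrow(cand)) {
      missing <- c(missing, atlas$roi_id[i])
      next
    }
    idx <- as.matrix(cand) + 1L
    series <- vapply(seq_len(Tn), function(t)
      mean(arr[cbind(idx, t)]), numeric(1))
    out[i, ] <- series
  }
  list(data = out, missing = missing, usable = p - length(missing))
}
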