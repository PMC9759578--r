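#' @import methods
NULL

#' The 13 canonical functional network labels
#'
#' Network labels used by the 300-ROI functional parcellation this package
#' targets: 13 assigned networks plus a pool of unassigned ROIs.
#'
#' @return Character vector of the 13 network labels (the `"unassigned"`
#'   label is handled separately throughout).
#' @export
networkLabels <- function() {
  c("cingulo_opercular", "fronto_parietal", "dorsal_attention",
    "ventral_attention", "salience", "somatomotor_dorsal",
    "somatomotor_ventral", "visual", "auditory", "medial_temporal",
    "reward", "parietal_memory", "default_mode")
}

#' Cohort configuration for the synthetic generator
#'
#' Describes a synthetic crossover cohort: two groups (ADHD, TD), two scan
#' sessions per subject (methylphenidate/placebo for ADHD, two unmedicated
#' sessions coded placebo for TD), a set of scan contexts with their run
#' grid, the ROI/network layout, and the generative effect and motion
#' parameters.
#'
#' @slot nPerGroup subjects per diagnostic group.
#' @slot contexts data.frame with columns `context`, `n_runs`,
#'   `volumes` (frames per run).
#' @slot trSeconds repetition time in seconds.
#' @slot nRois number of ROIs.
#' @slot networkAssignment character vector of length `nRois`; network label
#'   per ROI (one of [networkLabels()] or `"unassigned"`).
#' @slot effectNetworks networks carrying the group/drug coupling effect.
#' @slot groupEffectSize dimensionless within-network coupling increment for
#'   the ADHD-placebo condition.
#' @slot drugRecoveryFraction fraction in \[0, 1\] of the group effect removed
#'   on drug.
#' @slot motionSpikeRate expected motion spikes per volume.
#' @slot motionScale named numeric, mm jitter scale per
#'   `"<group>.<condition>"` cell.
#' @slot seed integer master seed.
#' @export
setClass("CohortConfig",
  representation(
    nPerGroup = "integer",
    contexts = "data.frame",
    trSeconds = "numeric",
    nRois = "integer",
    networkAssignment = "character",
    effectNetworks = "character",
    groupEffectSize = "numeric",
    drugRecoveryFraction = "numeric",
    motionSpikeRate = "numeric",
    motionScale = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  need <- c("context", "n_runs", "volumes")
  if (!all(need %in% names(object@contexts)))
    msg <- c(msg, "contexts must have columns context, n_runs, volumes")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (length(object@networkAssignment) != object@nRois)
    msg <- c(msg, "networkAssignment must have one label per ROI")
  legal <- c(networkLabels(), "unassigned")
  bad <- setdiff(unique(object@networkAssignment), legal)
  if (length(bad))
    msg <- c(msg, paste0("unknown network label(s): ",
                         paste(bad, collapse = ", ")))
  badEff <- setdiff(object@effectNetworks, unique(object@networkAssignment))
  if (length(badEff))
    msg <- c(msg, paste0("effect network(s) not present in assignment: ",
                         paste(badEff, collapse = ", ")))
  if (object@groupEffectSize < 0) msg <- c(msg, "groupEffectSize must be >= 0")
  if (object@drugRecoveryFraction < 0 || object@drugRecoveryFraction > 1)
    msg <- c(msg, "drugRecoveryFraction must lie in [0, 1]")
  if (object@motionSpikeRate < 0) msg <- c(msg, "motionSpikeRate must be >= 0")
  cells <- c("ADHD.placebo", "ADHD.MPH", "TD.placebo")
  if (!all(cells %in% names(object@motionScale)))
    msg <- c(msg, "motionScale must name cells ADHD.placebo, ADHD.MPH, TD.placebo")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort container
#'
#' Holds the cohort manifest (one row per run), the per-subject/session
#' generative ground truth, and the configuration that produced them.
#'
#' @slot manifest data.frame, one row per (subject, session, context, run).
#' @slot groundTruth named list per subject holding per-session coupling
#'   matrices, nuisance loadings and motion artifact loadings.
#' @slot config the [CohortConfig-class] used.
#' @export
setClass("SyntheticCohort",
  representation(manifest = "data.frame", groundTruth = "list",
                 config = "CohortConfig"))

#' Per-run head-motion record
#'
#' Six rigid-body parameters per frame (3 translations in mm, 3 rotations in
#' radians) with the derived framewise-displacement series: raw FD and FD
#' after band-stop (notch) filtering of the parameters.
#'
#' @slot params T x 6 numeric matrix.
#' @slot fdRaw raw framewise displacement, mm; first frame 0.
#' @slot fdNotch notch-filtered framewise displacement, mm; first frame 0.
#' @export
setClass("MotionRecord",
  representation(params = "matrix", fdRaw = "numeric", fdNotch = "numeric"))

setValidity("MotionRecord", function(object) {
  msg <- character()
  if (ncol(object@params) != 6L)
    msg <- c(msg, "params must have 6 columns")
  Tn <- nrow(object@params)
  for (nm in c("fdRaw", "fdNotch")) {
    v <- slot(object, nm)
    if (length(v)) {
      if (length(v) != Tn) msg <- c(msg, paste(nm, "length must match params"))
      if (any(v < 0)) msg <- c(msg, paste(nm, "must be non-negative"))
      if (v[1] != 0) msg <- c(msg, paste(nm, "must be 0 at the first frame"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ROI-by-time series for one run
#'
#' @slot data ROI x T numeric matrix.
#' @slot censorMask logical length T; TRUE marks retained frames.
#' @slot trSeconds repetition time, seconds.
#' @slot motion a [MotionRecord-class] (may be empty for derived objects).
#' @slot qc list with `included` (flag), `reason`, `mean_fd_notch` (mm),
#'   `n_good` (count).
#' @export
setClass("RunTimeseries",
  representation(data = "matrix", censorMask = "logical",
                 trSeconds = "numeric", motion = "ANY", qc = "list"))

setValidity("RunTimeseries", function(object) {
  msg <- character()
  if (length(object@censorMask) != ncol(object@data))
    msg <- c(msg, "censorMask length must equal number of frames")
  if (length(object@qc) && !is.null(object@qc$n_good) &&
      object@qc$n_good != sum(object@censorMask))
    msg <- c(msg, "qc n_good must equal number of retained frames")
  if (length(msg)) msg else TRUE
})

#' Sparse signed partial-correlation connectome
#'
#' Symmetric ROI x ROI matrix of regularized partial correlations for one
#' (subject, session, scan context); both signs retained, zero diagonal.
#'
#' @slot partialCorr ROI x ROI symmetric numeric matrix in \[-1, 1\].
#' @slot lambda graphical-LASSO penalty used.
#' @slot nFramesUsed retained frames entering the correlation.
#' @slot roiIds character ROI identifiers.
#' @slot networks character network label per ROI.
#' @export
setClass("FunctionalConnectome",
  representation(partialCorr = "matrix", lambda = "numeric",
                 nFramesUsed = "integer", roiIds = "character",
                 networks = "character"))

setValidity("FunctionalConnectome", function(object) {
  msg <- character()
  W <- object@partialCorr
  if (nrow(W) != ncol(W)) msg <- c(msg, "partialCorr must be square")
  else {
    if (max(abs(W - t(W))) > 0) msg <- c(msg, "partialCorr must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "partialCorr diagonal must be zero")
    if (any(abs(W) > 1 + 1e-12)) msg <- c(msg, "|partial correlations| must be <= 1")
  }
  if (length(object@roiIds) && length(object@roiIds) != nrow(W))
    msg <- c(msg, "roiIds length must match matrix")
  if (length(object@networks) && length(object@networks) != nrow(W))
    msg <- c(msg, "networks length must match matrix")
  if (length(msg)) msg else TRUE
})

#' Stabilized linear system for controllability analysis
#'
#' Discrete-time system x(t+1) = A x(t) + B u(t) with A a stabilized
#' functional connectome (spectral radius < 1) and B the canonical basis
#' (one input per ROI, applied one at a time).
#'
#' @slot A ROI x ROI symmetric matrix, spectral radius strictly < 1.
#' @slot normalization list recording the stabilization applied.
#' @export
setClass("ControlSystem",
  representation(A = "matrix", normalization = "list"))

setValidity("ControlSystem", function(object) {
  msg <- character()
  A <- object@A
  if (nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
  else {
    if (max(abs(A - t(A))) > 1e-10) msg <- c(msg, "A must be symmetric")
    rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    if (rho >= 1) msg <- c(msg, sprintf("spectral radius %.4f must be < 1", rho))
  }
  if (length(msg)) msg else TRUE
})

#' Per-ROI and per-network controllability profile
#'
#' @slot avgCtrb per-ROI average controllability (trace of the single-input
#'   controllability Gramian); always >= 1.
#' @slot modalCtrb per-ROI modal controllability in (0, 1\].
#' @slot networkAvg per-network mean of `avgCtrb`.
#' @slot networkModal per-network mean of `modalCtrb`.
#' @slot networks network label per ROI.
#' @export
setClass("ControllabilityProfile",
  representation(avgCtrb = "numeric", modalCtrb = "numeric",
                 networkAvg = "numeric", networkModal = "numeric",
                 networks = "character"))

setValidity("ControllabilityProfile", function(object) {
  msg <- character()
  if (length(object@avgCtrb) != length(object@modalCtrb))
    msg <- c(msg, "avgCtrb and modalCtrb must have equal length")
  if (any(object@avgCtrb < 1 - 1e-9))
    msg <- c(msg, "average controllability must be >= 1")
  if (any(object@modalCtrb <= 0 | object@modalCtrb > 1 + 1e-9))
    msg <- c(msg, "modal controllability must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' All thresholds and bands of the postprocessing/connectome chain, with
#' defaults matching the analysis this package implements: FD censoring at
#' 0.2 mm with 5 contiguous retained frames required, run exclusion at mean
#' notch-FD 0.5 mm, at least 50 good frames per run and 150 per task,
#' band-pass 0.009-0.08 Hz, motion notch band 0.31-0.41 Hz, graphical-LASSO
#' penalty 0.1, rotation radius 50 mm.
#'
#' @slot fdThreshold censoring threshold, mm.
#' @slot minContiguous minimum retained-segment length, frames.
#' @slot runMeanFdLimit run-exclusion mean notch-FD limit, mm.
#' @slot minGoodPerRun minimum retained frames per run.
#' @slot minGoodPerTask minimum retained frames per task (summed over runs).
#' @slot bandpass BOLD pass band, Hz.
#' @slot notch respiration notch band, Hz (aliased below Nyquist as needed).
#' @slot lambda graphical-LASSO penalty.
#' @slot rotationRadius head radius for rotation-to-arc conversion, mm.
#' @slot seed integer seed for any stochastic stage.
#' @export
setClass("PipelineConfig",
  representation(fdThreshold = "numeric", minContiguous = "integer",
                 runMeanFdLimit = "numeric", minGoodPerRun = "integer",
                 minGoodPerTask = "integer", bandpass = "numeric",
                 notch = "numeric", lambda = "numeric",
                 rotationRadius = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@fdThreshold <= 0) msg <- c(msg, "fdThreshold must be > 0")
  if (object@minContiguous < 1L) msg <- c(msg, "minContiguous must be >= 1")
  if (length(object@bandpass) != 2L || any(object@bandpass <= 0) ||
      diff(object@bandpass) <= 0)
    msg <- c(msg, "bandpass must be an increasing positive pair (Hz)")
  if (length(object@notch) != 2L || diff(object@notch) <= 0)
    msg <- c(msg, "notch must be an increasing pair (Hz)")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})
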