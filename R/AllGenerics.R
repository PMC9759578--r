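#' @include AllClasses.R
NULL

#' Accessors for funcontrol objects
#'
#' `partialCorr` returns the signed partial-correlation matrix of a
#' connectome; `penalty` its graphical-LASSO penalty; `systemMatrix` the
#' stabilized A of a [ControlSystem-class]; `avgCtrb`/`modalCtrb` the
#' per-ROI controllability values; `networkMeans` the per-network means of a
#' profile; `retained` the censor mask of a [RunTimeseries-class];
#' `roiNetworks` the network label per ROI.
#'
#' @param x object.
#' @param metric `"average"` or `"modal"` (for `networkMeans`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("partialCorr", function(x) standardGeneric("partialCorr"))
#' @rdname accessors
#' @export
setMethod("partialCorr", "FunctionalConnectome", function(x) x@partialCorr)

#' @rdname accessors
#' @export
setGeneric("penalty", function(x) standardGeneric("penalty"))
#' @rdname accessors
#' @export
setMethod("penalty", "FunctionalConnectome", function(x) x@lambda)

#' @rdname accessors
#' @export
setGeneric("systemMatrix", function(x) standardGeneric("systemMatrix"))
#' @rdname accessors
#' @export
setMethod("systemMatrix", "ControlSystem", function(x) x@A)

#' @rdname accessors
#' @export
setGeneric("avgCtrb", function(x) standardGeneric("avgCtrb"))
#' @rdname accessors
#' @export
setMethod("avgCtrb", "ControllabilityProfile", function(x) x@avgCtrb)

#' @rdname accessors
#' @export
setGeneric("modalCtrb", function(x) standardGeneric("modalCtrb"))
#' @rdname accessors
#' @export
setMethod("modalCtrb", "ControllabilityProfile", function(x) x@modalCtrb)

#' @rdname accessors
#' @export
setGeneric("networkMeans", function(x, metric = c("average", "modal"))
  standardGeneric("networkMeans"))
#' @rdname accessors
#' @export
setMethod("networkMeans", "ControllabilityProfile",
  function(x, metric = c("average", "modal")) {
    metric <- match.arg(metric)
    if (metric == "average") x@networkAvg else x@networkModal
  })

#' @rdname accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))
#' @rdname accessors
#' @export
setMethod("retained", "RunTimeseries", function(x) x@censorMask)

#' @rdname accessors
#' @export
setGeneric("roiNetworks", function(x) standardGeneric("roiNetworks"))
#' @rdname accessors
#' @export
setMethod("roiNetworks", "FunctionalConnectome", function(x) x@networks)
#' @rdname accessors
#' @export
setMethod("roiNetworks", "ControllabilityProfile", function(x) x@networks)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPerGroup, "subjects/group,",
      object@nRois, "ROIs,",
      length(setdiff(unique(object@networkAssignment), "unassigned")),
      "networks\n")
  cat("  contexts:", paste(sprintf("%s (%dx%d)", object@contexts$context,
      object@contexts$n_runs, object@contexts$volumes), collapse = ", "), "\n")
  cat(sprintf("  effect %.3g in [%s], drug recovery %.2f, seed %d\n",
      object@groupEffectSize, paste(object@effectNetworks, collapse = ", "),
      object@drugRecoveryFraction, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  m <- object@manifest
  cat("SyntheticCohort:", length(unique(m$subject_id)), "subjects,",
      nrow(m), "runs\n")
})

setMethod("show", "MotionRecord", function(object) {
  cat(sprintf("MotionRecord: %d frames, mean raw FD %.3f mm\n",
      nrow(object@params),
      if (length(object@fdRaw)) mean(object@fdRaw) else NA_real_))
})

setMethod("show", "RunTimeseries", function(object) {
  cat(sprintf("RunTimeseries: %d ROIs x %d frames (TR %.1fs), %d retained\n",
      nrow(object@data), ncol(object@data), object@trSeconds,
      sum(object@censorMask)))
  if (length(object@qc))
    cat(sprintf("  QC: included=%s (%s)\n", object@qc$included, object@qc$reason))
})

setMethod("show", "FunctionalConnectome", function(object) {
  W <- object@partialCorr
  nz <- sum(W[upper.tri(W)] != 0)
  cat(sprintf(
    "FunctionalConnectome: %d ROIs, lambda %.3g, %d/%d nonzero edges, %d frames\n",
    nrow(W), object@lambda, nz, choose(nrow(W), 2), object@nFramesUsed))
})

setMethod("show", "ControlSystem", function(object) {
  rho <- max(abs(eigen(object@A, symmetric = TRUE, only.values = TRUE)$values))
  cat(sprintf("ControlSystem: %d nodes, spectral radius %.4f (%s)\n",
      nrow(object@A), rho,
      if (!is.null(object@normalization$method)) object@normalization$method
      else "unrecorded"))
})

setMethod("show", "ControllabilityProfile", function(object) {
  cat(sprintf(
    "ControllabilityProfile: %d ROIs; avg ctrb [%.3f, %.3f]; modal [%.3f, %.3f]\n",
    length(object@avgCtrb), min(object@avgCtrb), max(object@avgCtrb),
    min(object@modalCtrb), max(object@modalCtrb)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: FD>%.2gmm censor (min %d contiguous); run mean FD limit %.2gmm;\n",
    object@fdThreshold, object@minContiguous, object@runMeanFdLimit))
  cat(sprintf("  >=%d good/run, >=%d good/task; bandpass %.3g-%.3g Hz; notch %.2f-%.2f Hz; lambda %.2g\n",
      object@minGoodPerRun, object@minGoodPerTask, object@bandpass[1],
      object@bandpass[2], object@notch[1], object@notch[2], object@lambda))
})
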