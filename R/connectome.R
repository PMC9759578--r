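#' @include AllClasses.R
#' @useDynLib funcontrol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' L1-penalized precision estimation (graphical LASSO)
#'
#' Estimates the positive-definite precision matrix maximizing the
#' L1-penalized Gaussian log-likelihood
#' \deqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \|\Theta\|_{1,\mathrm{off}}}
#' with the penalty on off-diagonal entries only, by block coordinate
#' descent. The working covariance is the sample correlation matrix of the
#' retained frames (the data are z-scored upstream), which makes `lambda`
#' scale-free. Convergence is verified against the optimality (KKT)
#' conditions; see [kktResidual()].
#'
#' @param timeseries ROI x T matrix; only columns flagged by `mask` are
#'   used.
#' @param lambda penalty, default 0.1.
#' @param mask optional logical length-T censor mask (default all frames).
#' @param tol,maxit solver tolerances.
#' @param kktTol maximum admissible KKT residual before erroring.
#' @return precision matrix with attributes `lambda`, `nFrames`, `S` (the
#'   working correlation), `iterations`.
#' @export
estimatePrecision <- function(timeseries, lambda = 0.1, mask = NULL,
                              tol = 1e-9, maxit = 500, kktTol = 1e-4) {
  X <- as.matrix(timeseries)
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  Xr <- X[, mask, drop = FALSE]
  Tn <- ncol(Xr)
  p <- nrow(Xr)
  if (Tn <= 2L) stop("need more than 2 retained frames")
  if (Tn < p)
    message(sprintf("retained frames (%d) < ROI count (%d); relying on regularization",
                    Tn, p))
  S <- stats::cor(t(Xr))
  fit <- .glassoCd(S, lambda, tol = tol, maxit = maxit)
  if (!fit$converged)
    stop(sprintf("graphical LASSO did not converge in %d sweeps (lambda=%g, p=%d)",
                 maxit, lambda, p))
  theta <- fit$theta
  kkt <- kktResidual(theta, S, lambda)
  if (kkt > kktTol)
    stop(sprintf("KKT residual %.2e exceeds tolerance %.1e", kkt, kktTol))
  dimnames(theta) <- dimnames(S)
  attr(theta, "lambda") <- lambda
  attr(theta, "nFrames") <- Tn
  attr(theta, "S") <- S
  attr(theta, "iterations") <- fit$iterations
  theta
}

#' KKT residual of a penalized precision estimate
#'
#' Independent optimality check for the graphical-LASSO problem: at the
#' optimum, \eqn{\Theta^{-1} - S = \lambda\,\Gamma} with
#' \eqn{\Gamma_{ij} = \mathrm{sign}(\theta_{ij})} for nonzero off-diagonal
#' entries, \eqn{|\Gamma_{ij}| \le 1} for zero entries, and
#' \eqn{\Gamma_{ii} = 0}. Returns the maximum violation over all entries.
#'
#' @param theta precision matrix.
#' @param S sample correlation (or covariance) matrix used in the fit.
#' @param lambda penalty.
#' @param zeroTol entries with absolute value below this are treated as
#'   zero.
#' @return maximum KKT violation (scalar).
#' @export
kktResidual <- function(theta, S, lambda, zeroTol = 1e-10) {
  G <- solve(theta) - S
  off <- row(G) != col(G)
  nz <- off & abs(theta) > zeroTol
  z <- off & !nz
  v <- abs(diag(G))
  if (any(nz)) v <- c(v, abs(G[nz] - lambda * sign(theta[nz])))
  if (any(z)) v <- c(v, pmax(0, abs(G[z]) - lambda))
  max(v)
}

#' Convert a precision matrix to a signed partial-correlation connectome
#'
#' Off-diagonal entries \eqn{w_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}},
#' zero diagonal; both positive and negative partial correlations are
#' retained.
#'
#' @param precision symmetric positive-definite precision matrix (as from
#'   [estimatePrecision()]).
#' @param roiIds,networks optional ROI labels carried into the connectome.
#' @return a [FunctionalConnectome-class].
#' @export
precisionToPartialCorrelation <- function(precision, roiIds = NULL,
                                          networks = NULL) {
  P <- as.matrix(precision)
  d <- diag(P)
  if (any(d <= 0)) stop("numerical error: non-positive precision diagonal")
  W <- -P / sqrt(outer(d, d))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  lam <- attr(precision, "lambda")
  nfr <- attr(precision, "nFrames")
  if (is.null(roiIds)) roiIds <- rownames(P)
  if (is.null(roiIds)) roiIds <- sprintf("roi-%03d", seq_len(nrow(P)))
  dimnames(W) <- list(roiIds, roiIds)
  new("FunctionalConnectome", partialCorr = W,
      lambda = if (is.null(lam)) NA_real_ else lam,
      nFramesUsed = if (is.null(nfr)) NA_integer_ else as.integer(nfr),
      roiIds = roiIds,
      networks = if (is.null(networks)) character() else networks)
}

#' Estimate a functional connectome from cleaned timeseries
#'
#' Convenience wrapper: graphical-LASSO precision on retained frames, then
#' partial-correlation conversion.
#'
#' @param timeseries ROI x T matrix (cleaned, standardized).
#' @param mask censor mask (censored frames never enter the covariance).
#' @param lambda penalty.
#' @param networks optional network label per ROI.
#' @param ... passed to [estimatePrecision()].
#' @return a [FunctionalConnectome-class].
#' @export
buildConnectome <- function(timeseries, mask = NULL, lambda = 0.1,
                            networks = NULL, ...) {
  prec <- estimatePrecision(timeseries, lambda = lambda, mask = mask, ...)
  precisionToPartialCorrelation(prec, networks = networks)
}
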