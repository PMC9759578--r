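#' @include AllClasses.R AllGenerics.R
NULL

#' Stabilize a connectome into a discrete-time linear system
#'
#' Normalizes the signed connectome W by \eqn{A = W / (1 + \sigma_{max}(W))}
#' where \eqn{\sigma_{max}} is the largest singular value, guaranteeing a
#' spectral radius strictly below 1 so the infinite-horizon controllability
#' Gramian exists. The normalization is recorded in the returned system.
#'
#' @param W symmetric zero-diagonal connectome matrix, or a
#'   [FunctionalConnectome-class].
#' @return a [ControlSystem-class].
#' @export
stabilizeConnectome <- function(W) {
  if (is(W, "FunctionalConnectome")) W <- partialCorr(W)
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10)
    stop("connectome matrix must be symmetric")
  sigmaMax <- if (all(W == 0)) 0 else max(abs(
    eigen(W, symmetric = TRUE, only.values = TRUE)$values))
  A <- W / (1 + sigmaMax)
  new("ControlSystem", A = A,
      normalization = list(method = "divide by 1 + largest singular value",
                           sigmaMax = sigmaMax, denominator = 1 + sigmaMax))
}

## eigendecomposition of the (symmetric) system matrix, shared by the two
## controllability metrics
.sysEigen <- function(system) {
  A <- if (is(system, "ControlSystem")) systemMatrix(system) else as.matrix(system)
  if (max(abs(A - t(A))) > 1e-10)
    stop("controllability metrics require a symmetric system matrix")
  e <- eigen(A, symmetric = TRUE)
  if (max(abs(e$values)) >= 1)
    stop("unstable system: spectral radius >= 1")
  e
}

#' Average controllability per ROI
#'
#' For each ROI i, the trace of the infinite-horizon controllability
#' Gramian \eqn{W_i = \sum_{t \ge 0} A^t b_i b_i' (A')^t} with the canonical
#' basis input \eqn{b_i}, i.e. the solution of the discrete Lyapunov
#' equation \eqn{W_i = A W_i A' + b_i b_i'}. The Lyapunov equation is solved
#' exactly through the eigendecomposition of the symmetric A:
#' \eqn{\mathrm{tr}\,W_i = \sum_j v_{ij}^2/(1 - \lambda_j^2)}. Values are
#' always at least 1.
#'
#' @param system a [ControlSystem-class] (or symmetric stable matrix).
#' @return named numeric vector, one value per ROI.
#' @examples
#' averageControllability(diag(c(0.5, 0.2)))  # 4/3, 25/24
#' @export
averageControllability <- function(system) {
  e <- .sysEigen(system)
  vals <- as.numeric((e$vectors^2) %*% (1 / (1 - e$values^2)))
  names(vals) <- rownames(if (is(system, "ControlSystem")) systemMatrix(system)
                          else system)
  vals
}

#' Modal controllability per ROI
#'
#' \eqn{\phi_i = \sum_j (1 - \lambda_j^2)\, v_{ij}^2}, with
#' \eqn{\lambda_j} the eigenvalues of the symmetric system matrix and
#' \eqn{v_{ij}} the i-th entry of the j-th orthonormal eigenvector. High
#' values mark ROIs whose input can excite the system's fast-decaying
#' (hard-to-reach) modes. Values lie in \eqn{(1 - \rho(A)^2, 1]}.
#'
#' @param system a [ControlSystem-class] (or symmetric stable matrix).
#' @return named numeric vector, one value per ROI.
#' @examples
#' modalControllability(diag(c(0.5, 0.2)))  # 0.75, 0.96
#' @export
modalControllability <- function(system) {
  e <- .sysEigen(system)
  vals <- as.numeric((e$vectors^2) %*% (1 - e$values^2))
  names(vals) <- rownames(if (is(system, "ControlSystem")) systemMatrix(system)
                          else system)
  vals
}

#' Solve a discrete Lyapunov equation for a symmetric system matrix
#'
#' Returns W satisfying \eqn{W = A W A' + Q}, computed through the
#' eigendecomposition of A: with \eqn{A = V \Lambda V'},
#' \eqn{W = V \,[ (V'QV) \oslash (1 - \lambda\lambda') ]\, V'}.
#'
#' @param A symmetric matrix with spectral radius < 1.
#' @param Q symmetric right-hand side.
#' @return the solution matrix W.
#' @export
solveDiscreteLyapunov <- function(A, Q) {
  e <- .sysEigen(A)
  M <- t(e$vectors) %*% Q %*% e$vectors
  M <- M / (1 - outer(e$values, e$values))
  e$vectors %*% M %*% t(e$vectors)
}

#' Network-level controllability means
#'
#' Unweighted mean of per-ROI values within each network label. The
#' `"unassigned"` pool is reported alongside the named networks but is not
#' one of the 13 modeled networks. Labels with no ROI are omitted with a
#' warning.
#'
#' @param values per-ROI controllability values.
#' @param networks network label per ROI.
#' @param expected optional label set to check for empty networks.
#' @return named numeric vector of per-network means.
#' @export
networkControllability <- function(values, networks, expected = NULL) {
  if (length(values) != length(networks))
    stop("every ROI must have a network label")
  means <- tapply(values, networks, mean)
  if (!is.null(expected)) {
    empty <- setdiff(expected, names(means))
    if (length(empty))
      warning("network(s) with no ROI omitted: ", paste(empty, collapse = ", "))
  }
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Controllability profile of a functional connectome
#'
#' Stabilizes the connectome, computes per-ROI average and modal
#' controllability, and aggregates both as unweighted means per network.
#'
#' @param connectome a [FunctionalConnectome-class].
#' @return a [ControllabilityProfile-class].
#' @export
controllabilityProfile <- function(connectome) {
  stopifnot(is(connectome, "FunctionalConnectome"))
  sys <- stabilizeConnectome(connectome)
  avg <- averageControllability(sys)
  mod <- modalControllability(sys)
  nets <- roiNetworks(connectome)
  if (!length(nets)) nets <- rep("unassigned", length(avg))
  new("ControllabilityProfile",
      avgCtrb = avg, modalCtrb = mod,
      networkAvg = networkControllability(avg, nets),
      networkModal = networkControllability(mod, nets),
      networks = nets)
}
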