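# shared fixture builders (all seeded by the caller)

# random symmetric zero-diagonal matrix, stabilized to spectral radius `rho`
randomStableSym <- function(p, rho = 0.6) {
  M <- matrix(rnorm(p * p), p, p)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  ev <- max(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
  M * (rho / ev)
}

# brute-force truncated-series oracle for the single-input Gramian trace
seriesGramianTrace <- function(A, i, nTerms = 500) {
  b <- rep(0, nrow(A)); b[i] <- 1
  x <- b
  acc <- sum(x^2)
  for (t in seq_len(nTerms)) {
    x <- A %*% x
    acc <- acc + sum(x^2)
  }
  as.numeric(acc)
}

# VAR(1) realization with unit innovations
simVar <- function(A, Tn) {
  p <- nrow(A)
  X <- matrix(0, p, Tn)
  e <- matrix(rnorm(p * Tn), p, Tn)
  X[, 1] <- e[, 1]
  for (t in seq_len(Tn - 1)) X[, t + 1] <- A %*% X[, t] + e[, t + 1]
  X
}

# least-squares amplitude of a sinusoid of frequency f in series y (TR tr)
fitAmplitude <- function(y, f, tr) {
  t <- seq_along(y) * tr
  fit <- stats::lm(y ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# partial correlation of variables i,j given the rest, from the covariance:
# conditional covariance of (i,j) given others (regression-residual oracle)
partialCorOracle <- function(Sigma, i, j) {
  o <- setdiff(seq_len(nrow(Sigma)), c(i, j))
  S11 <- Sigma[c(i, j), c(i, j)]
  S12 <- Sigma[c(i, j), o, drop = FALSE]
  S22 <- Sigma[o, o]
  Sc <- S11 - S12 %*% solve(S22, t(S12))
  Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
}

# small null metric table: no group effect, subject random intercepts
nullMetricTable <- function(nPerGroup = 20, tau = 1, sigma = 1,
                            network = "somatomotor_dorsal",
                            context = "rest", metric = "average") {
  rows <- list()
  sid <- 0
  for (grp in c("ADHD", "TD")) {
    for (k in seq_len(nPerGroup)) {
      sid <- sid + 1
      subj <- sprintf("s%03d", sid)
      u <- rnorm(1, 0, tau)
      age <- runif(1, 8, 12)
      sex <- sample(c("F", "M"), 1)
      conds <- if (grp == "ADHD") c("placebo", "MPH") else c("placebo", "placebo")
      for (s in 1:2) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, group = grp, session = s, condition = conds[s],
          context = context, network = network, metric = metric,
          value = u + rnorm(1, 0, sigma), age = age, sex = sex,
          mean_fd_raw = runif(1, 0.05, 0.2), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
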