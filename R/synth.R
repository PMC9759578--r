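#' @include AllClasses.R
NULL

#' Default scan-context grid
#'
#' The acquisition grid the generator emulates: two 150-volume resting-state
#' runs, two 195-volume go/no-go runs and four 185-volume rewarded go/no-go
#' runs, all at TR = 2 s.
#'
#' @param scale `"full"` for the complete grid, `"rest"` for the
#'   resting-state context only (convenient for fast tests).
#' @return data.frame with columns `context`, `n_runs`, `volumes`.
#' @export
defaultContexts <- function(scale = c("full", "rest")) {
  scale <- match.arg(scale)
  ctx <- data.frame(
    context = c("rest", "gonogo", "rewarded_gonogo"),
    n_runs  = c(2L, 2L, 4L),
    volumes = c(150L, 195L, 185L),
    stringsAsFactors = FALSE)
  if (scale == "rest") ctx[1L, , drop = FALSE] else ctx
}

#' Construct a cohort configuration
#'
#' Desk-scale defaults: 40 ROIs over 4 networks, 10 subjects per group. The
#' full-scale layout (284 usable ROIs over 13 networks) is available through
#' `nRois`/`networkAssignment`.
#'
#' @param nPerGroup subjects per group (ADHD and TD).
#' @param contexts scan-context grid, see [defaultContexts()].
#' @param trSeconds repetition time, seconds.
#' @param nRois number of ROIs.
#' @param nNetworks number of networks the default assignment spreads the
#'   ROIs over (ignored when `networkAssignment` is given).
#' @param networkAssignment optional explicit label per ROI.
#' @param effectNetworks networks carrying the group/drug coupling effect.
#' @param groupEffectSize within-network coupling increment in the
#'   ADHD-placebo condition (dimensionless, on the pre-normalization
#'   coupling scale where within-network weights are 0.2).
#' @param drugRecoveryFraction fraction of the group effect removed on drug.
#' @param motionSpikeRate expected motion spikes per volume.
#' @param motionScale mm jitter scale per `"<group>.<condition>"` cell; the
#'   ADHD-placebo default is elevated, emulating higher in-scanner motion
#'   off drug.
#' @param seed master seed.
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(nPerGroup = 10L,
                         contexts = defaultContexts(),
                         trSeconds = 2.0,
                         nRois = 40L,
                         nNetworks = 4L,
                         networkAssignment = NULL,
                         effectNetworks = "somatomotor_dorsal",
                         groupEffectSize = 0.2,
                         drugRecoveryFraction = 1.0,
                         motionSpikeRate = 0.005,
                         motionScale = c(ADHD.placebo = 0.016,
                                         ADHD.MPH = 0.012,
                                         TD.placebo = 0.014),
                         seed = 1L) {
  if (is.null(networkAssignment)) {
    labs <- c("somatomotor_dorsal", "default_mode", "fronto_parietal",
              "visual", networkLabels()[!networkLabels() %in%
                c("somatomotor_dorsal", "default_mode", "fronto_parietal",
                  "visual")])[seq_len(nNetworks)]
    networkAssignment <- rep(labs, length.out = nRois)
    networkAssignment <- networkAssignment[order(match(networkAssignment, labs))]
  }
  new("CohortConfig", nPerGroup = as.integer(nPerGroup), contexts = contexts,
      trSeconds = trSeconds, nRois = as.integer(nRois),
      networkAssignment = networkAssignment, effectNetworks = effectNetworks,
      groupEffectSize = groupEffectSize,
      drugRecoveryFraction = drugRecoveryFraction,
      motionSpikeRate = motionSpikeRate, motionScale = motionScale,
      seed = as.integer(seed))
}

## deterministic sub-seed stream: distinct, reproducible, below 2^31
.subSeed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (ch in utf8ToInt(as.character(p))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

## block-structured symmetric coupling matrix, rescaled to spectral radius
## `radius`; within-network off-diagonal weights dominate between-network ones
.baseCoupling <- function(networks, within = 0.2, between = 0.02,
                          jitterSd = 0.02, radius = 0.6) {
  p <- length(networks)
  same <- outer(networks, networks, "==")
  A <- ifelse(same, within, between)
  J <- matrix(stats::rnorm(p * p, 0, jitterSd), p, p)
  A <- A + (J + t(J)) / 2
  diag(A) <- 0
  attr(A, "radius") <- radius
  A
}

.rescaleRadius <- function(A, radius) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  rho <- max(abs(ev))
  if (rho > 0) A <- A * (radius / rho)
  A
}

## add `delta` to every within-network off-diagonal coupling of the effect
## networks, then rescale to the target spectral radius. Keeping the radius
## fixed across conditions means the increment raises the effect network's
## coupling RELATIVE to the rest of the connectome (the mean block weight
## stays strictly increasing in delta), while the dynamics remain equally
## stationary in every condition, so estimation quality is matched across
## groups.
.applyEffect <- function(Abase, networks, effectNetworks, delta) {
  A <- Abase
  if (delta != 0) {
    inEff <- networks %in% effectNetworks
    same <- outer(networks, networks, "==") & outer(inEff, inEff, "&")
    diag(same) <- FALSE
    A[same] <- A[same] + delta
  }
  .rescaleRadius(A, attr(Abase, "radius"))
}

#' Generate a synthetic crossover cohort
#'
#' Builds the cohort manifest and the per-subject/session generative ground
#' truth. TD subjects get two sessions with identical generative parameters
#' (both coded `"placebo"`); ADHD subjects get a placebo session whose
#' effect-network coupling is incremented by `groupEffectSize` and a
#' methylphenidate (`"MPH"`) session with that increment scaled by
#' `(1 - drugRecoveryFraction)`. Session order (which session index carries
#' the drug) is counterbalanced by subject index parity.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- makeCohort(cohortConfig(nPerGroup = 2L, contexts = defaultContexts("rest")))
#' head(coh@manifest)
#' @export
makeCohort <- function(config) {
  validObject(config)
  nets <- config@networkAssignment
  p <- config@nRois
  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(2L * config@nPerGroup)),
    group = rep(c("ADHD", "TD"), each = config@nPerGroup),
    stringsAsFactors = FALSE)

  set.seed(.subSeed(config@seed, "cohort"))
  subjects$age <- round(pmin(12, pmax(8, stats::rnorm(nrow(subjects), 10.2, 1.3))), 2)
  subjects$sex <- ifelse(stats::runif(nrow(subjects)) < 0.45, "F", "M")

  gt <- vector("list", nrow(subjects))
  names(gt) <- subjects$subject_id
  manifest <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    set.seed(.subSeed(config@seed, "gt", sid))
    Abase <- .baseCoupling(nets)
    # subject-level motion propensity around the cell-level mm scale, and a
    # subject-level drug motion-reduction factor (most, not all, subjects
    # move less on drug -> acute behavioral responders)
    motionProp <- stats::rlnorm(1, 0, 0.3)
    mphRatio <- config@motionScale[["ADHD.MPH"]] /
      config@motionScale[["ADHD.placebo"]]
    drugFactor <- stats::rlnorm(1, log(mphRatio), 0.2)
    # nuisance and artifact loadings, fixed per subject
    loadings <- list(
      global = stats::rnorm(p, 0.6, 0.15),
      wm = stats::rnorm(p, 0.3, 0.1),
      csf = stats::rnorm(p, 0.2, 0.1),
      driftSlope = stats::rnorm(p, 0, 1),
      motionArtifact = stats::rnorm(p, 1, 0.3))
    if (grp == "TD") {
      A1 <- .rescaleRadius(Abase, attr(Abase, "radius"))
      mmTd <- config@motionScale[["TD.placebo"]] * motionProp
      sess <- list(`1` = list(A = A1, condition = "placebo", mmScale = mmTd),
                   `2` = list(A = A1, condition = "placebo", mmScale = mmTd))
    } else {
      dPlacebo <- config@groupEffectSize
      dMph <- config@groupEffectSize * (1 - config@drugRecoveryFraction)
      Apl <- .applyEffect(Abase, nets, config@effectNetworks, dPlacebo)
      Amp <- .applyEffect(Abase, nets, config@effectNetworks, dMph)
      mmPl <- config@motionScale[["ADHD.placebo"]] * motionProp
      mmMph <- mmPl * drugFactor
      mphFirst <- (i %% 2L) == 0L
      sess <- if (mphFirst)
        list(`1` = list(A = Amp, condition = "MPH", mmScale = mmMph),
             `2` = list(A = Apl, condition = "placebo", mmScale = mmPl))
      else
        list(`1` = list(A = Apl, condition = "placebo", mmScale = mmPl),
             `2` = list(A = Amp, condition = "MPH", mmScale = mmMph))
    }
    gt[[sid]] <- list(sessions = sess, loadings = loadings, group = grp)

    for (s in 1:2) {
      cond <- sess[[as.character(s)]]$condition
      for (k in seq_len(nrow(config@contexts))) {
        ctx <- config@contexts$context[k]
        for (r in seq_len(config@contexts$n_runs[k])) {
          manifest[[length(manifest) + 1L]] <- data.frame(
            subject_id = sid, group = grp, session_index = s,
            condition = cond, context = ctx, run_index = r,
            volumes = config@contexts$volumes[k],
            run_seed = .subSeed(config@seed, "run", sid, s, ctx, r),
            age = subjects$age[i], sex = subjects$sex[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  new("SyntheticCohort", manifest = manifest, groundTruth = gt,
      config = config)
}

#' Simulate all runs of one (subject, session, context)
#'
#' Realizes the stated VAR(1) system per run: x(t+1) = A x(t) + innovation,
#' with independent unit-variance Gaussian innovations, plus additive slow
#' drift, global/white-matter/CSF nuisance components, and a rank-one
#' motion-locked artifact whose spikes match the generated motion
#' parameters, so framewise displacement computed downstream reflects the
#' injected events.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param subjectId,sessionIndex,context identify the session cell.
#' @param noise standard deviation of the VAR innovations.
#' @param driftScale amplitude of the slow scanner drift (signal units).
#' @param nuisanceScale amplitude of global/tissue components.
#' @param artifactScale signal units of artifact per mm of motion spike.
#' @return list with one element per run, each holding `data` (ROI x T raw
#'   matrix), `motion` (T x 6 parameter matrix) and `nuisance` (data.frame
#'   with `global`, `wm`, `csf`).
#' @export
simulateSession <- function(cohort, subjectId, sessionIndex, context,
                            noise = 1.0, driftScale = 1.5,
                            nuisanceScale = 1.0, artifactScale = 1.5) {
  stopifnot(is(cohort, "SyntheticCohort"))
  gt <- cohort@groundTruth[[subjectId]]
  if (is.null(gt)) stop("unknown subject: ", subjectId)
  sess <- gt$sessions[[as.character(sessionIndex)]]
  A <- sess$A
  rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable coupling matrix: spectral radius %.4f >= 1", rho))
  rows <- cohort@manifest[cohort@manifest$subject_id == subjectId &
                          cohort@manifest$session_index == sessionIndex &
                          cohort@manifest$context == context, , drop = FALSE]
  if (!nrow(rows)) stop("no runs for that subject/session/context")
  cfg <- cohort@config
  mmScale <- sess$mmScale
  if (is.null(mmScale))
    mmScale <- unname(cfg@motionScale[paste(gt$group, sess$condition,
                                            sep = ".")])
  lapply(seq_len(nrow(rows)), function(j) {
    .simulateRun(A, gt$loadings, Tn = rows$volumes[j],
                 tr = cfg@trSeconds, seed = rows$run_seed[j],
                 spikeRate = cfg@motionSpikeRate, mmScale = mmScale,
                 noise = noise, driftScale = driftScale,
                 nuisanceScale = nuisanceScale,
                 artifactScale = artifactScale)
  })
}

.simulateRun <- function(A, loadings, Tn, tr, seed, spikeRate, mmScale,
                         noise, driftScale, nuisanceScale, artifactScale) {
  set.seed(seed)
  p <- nrow(A)
  # VAR(1) realization
  X <- matrix(0, p, Tn)
  if (noise > 0) {
    eps <- matrix(stats::rnorm(p * Tn, 0, noise), p, Tn)
    X[, 1] <- eps[, 1]
    for (t in seq_len(Tn - 1)) X[, t + 1] <- A %*% X[, t] + eps[, t + 1]
  }
  # slow drift: per-ROI linear trend plus a slow cosine
  tgrid <- seq_len(Tn) / Tn
  drift <- outer(loadings$driftSlope * driftScale, tgrid) +
    driftScale * 0.5 * outer(rep(1, p), cos(2 * pi * 0.004 * seq_len(Tn) * tr))
  # nuisance: AR(1)-smoothed shared signals
  ar1 <- function(n, phi = 0.8) as.numeric(stats::filter(stats::rnorm(n), phi,
                                                         method = "recursive"))
  g <- ar1(Tn); wm <- ar1(Tn); csf <- ar1(Tn)
  nuis <- nuisanceScale * (outer(loadings$global, g) +
                           outer(loadings$wm, wm) +
                           outer(loadings$csf, csf))
  # motion: random-walk jitter on 6 parameters + spike displacements
  stepSd <- c(rep(mmScale, 3), rep(mmScale / 50, 3))
  steps <- matrix(stats::rnorm(Tn * 6), Tn, 6) %*% diag(stepSd)
  params <- apply(steps, 2, cumsum)
  spike <- numeric(Tn)
  nspk <- stats::rbinom(1L, Tn, min(1, spikeRate))
  if (nspk > 0 && mmScale > 0) {
    at <- sample(2:Tn, min(nspk, Tn - 1L))
    # spike magnitudes are drawn on an absolute mm scale, independent of the
    # per-cell jitter scale: the censoring load is then matched across
    # group/condition cells, while baseline FD still reflects the jitter
    mag <- 0.3 + stats::rexp(length(at), rate = 1 / 0.3)
    spike[at] <- mag
    # one-frame displacement of the x-translation at each spike frame
    params[cbind(at, 1L)] <- params[cbind(at, 1L)] + mag
  }
  art <- artifactScale * outer(loadings$motionArtifact, spike)
  list(data = X + drift + nuis + art, motion = params,
       nuisance = data.frame(global = g, wm = wm, csf = csf),
       spikes = spike)
}

#' Synthetic atlas table
#'
#' ROI table in the external-interface layout: `roi_id`, `x`, `y`, `z`
#' (mm) and `network_label`. Coordinates are drawn inside a box; if
#' `nOutOfBounds > 0`, that many ROI centers are placed outside the box so
#' downstream extraction flags them missing (emulating a limited field of
#' view).
#'
#' @param config a [CohortConfig-class] (supplies ROI count and labels), or
#'   NULL with explicit `networkAssignment`.
#' @param networkAssignment label per ROI when `config` is NULL.
#' @param boxMm half-width of the in-bounds coordinate box, mm.
#' @param nOutOfBounds number of trailing ROIs pushed out of bounds.
#' @param seed seed for coordinate draws.
#' @return data.frame atlas table.
#' @export
makeAtlas <- function(config = NULL, networkAssignment = NULL, boxMm = 60,
                      nOutOfBounds = 0L, seed = 1L) {
  if (!is.null(config)) networkAssignment <- config@networkAssignment
  p <- length(networkAssignment)
  set.seed(.subSeed(seed, "atlas"))
  xyz <- matrix(stats::runif(3 * p, -boxMm * 0.9, boxMm * 0.9), p, 3)
  if (nOutOfBounds > 0L) {
    idx <- seq.int(p - nOutOfBounds + 1L, p)
    xyz[idx, 3] <- -boxMm * 3  # below the imaged volume
  }
  data.frame(roi_id = sprintf("roi-%03d", seq_len(p)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             network_label = networkAssignment, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to TSV files
#'
#' Emits the external interchange layout: `manifest.tsv` (with file paths),
#' `atlas.tsv`, and per run a timeseries TSV (ROIs as columns, frames as
#' rows), a 6-column motion TSV (translations mm, rotations radians) and a
#' nuisance TSV (global/wm/csf).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @param ... passed to [simulateSession()].
#' @return invisibly, the manifest with `timeseries_path`, `motion_path`,
#'   `nuisance_path` columns.
#' @export
writeCohort <- function(cohort, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort@manifest
  m$timeseries_path <- NA_character_
  m$motion_path <- NA_character_
  m$nuisance_path <- NA_character_
  cells <- unique(m[c("subject_id", "session_index", "context")])
  for (i in seq_len(nrow(cells))) {
    runs <- simulateSession(cohort, cells$subject_id[i],
                            cells$session_index[i], cells$context[i], ...)
    sel <- which(m$subject_id == cells$subject_id[i] &
                 m$session_index == cells$session_index[i] &
                 m$context == cells$context[i])
    for (j in seq_along(sel)) {
      stem <- sprintf("%s_ses-%d_%s_run-%d", cells$subject_id[i],
                      cells$session_index[i], cells$context[i], j)
      tsPath <- file.path(dir, paste0(stem, "_timeseries.tsv"))
      moPath <- file.path(dir, paste0(stem, "_motion.tsv"))
      nuPath <- file.path(dir, paste0(stem, "_nuisance.tsv"))
      ts <- as.data.frame(t(runs[[j]]$data))
      names(ts) <- sprintf("roi-%03d", seq_len(nrow(runs[[j]]$data)))
      utils::write.table(ts, tsPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      mo <- as.data.frame(runs[[j]]$motion)
      names(mo) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
      utils::write.table(mo, moPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(runs[[j]]$nuisance, nuPath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      m$timeseries_path[sel[j]] <- tsPath
      m$motion_path[sel[j]] <- moPath
      m$nuisance_path[sel[j]] <- nuPath
    }
  }
  utils::write.table(makeAtlas(cohort@config, seed = cohort@config@seed),
                     file.path(dir, "atlas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(m)
}
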