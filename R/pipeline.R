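#' @include AllClasses.R
NULL

#' Construct a pipeline configuration
#'
#' Defaults are the analysis constants this package implements; every run
#' of [runPipeline()] stamps the resolved configuration hash into each
#' output file header for provenance.
#'
#' @param fdThreshold censoring threshold, mm.
#' @param minContiguous minimum retained-segment length, frames.
#' @param runMeanFdLimit run-exclusion mean notch-FD limit, mm.
#' @param minGoodPerRun minimum retained frames per run.
#' @param minGoodPerTask minimum retained frames per task.
#' @param bandpass BOLD pass band, Hz.
#' @param notch respiration notch band, Hz.
#' @param lambda graphical-LASSO penalty.
#' @param rotationRadius rotation-to-arc radius, mm.
#' @param seed seed for stochastic stages.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(fdThreshold = 0.2, minContiguous = 5L,
                           runMeanFdLimit = 0.5, minGoodPerRun = 50L,
                           minGoodPerTask = 150L,
                           bandpass = c(0.009, 0.08),
                           notch = c(0.31, 0.41), lambda = 0.1,
                           rotationRadius = 50, seed = 1L) {
  new("PipelineConfig", fdThreshold = fdThreshold,
      minContiguous = as.integer(minContiguous),
      runMeanFdLimit = runMeanFdLimit,
      minGoodPerRun = as.integer(minGoodPerRun),
      minGoodPerTask = as.integer(minGoodPerTask),
      bandpass = bandpass, notch = notch, lambda = lambda,
      rotationRadius = rotationRadius, seed = as.integer(seed))
}

#' Hash of a resolved configuration
#'
#' MD5 of the deparsed slot values; stamped into every output header so
#' results are traceable to the exact configuration.
#'
#' @param config a [PipelineConfig-class] (or any object).
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  txt <- if (isVirtualClass(class(config)) || !isS4(config))
    deparse(config)
  else
    unlist(lapply(slotNames(config), function(s)
      c(s, deparse(slot(config, s)))))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.writeStamped <- function(df, path, hash, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# funcontrol %s",
                       as.character(utils::packageVersion("funcontrol"))),
               sprintf("# config_hash=%s", hash),
               sprintf("# stage=%s", stage)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a pipeline TSV (skipping provenance headers)
#'
#' @param path file path.
#' @return data.frame.
#' @export
readStamped <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## obtain the raw runs of one (subject, session, context) cell, either by
## simulation or from files written by writeCohort()
.cellRuns <- function(x, rows) {
  if (is(x, "SyntheticCohort")) {
    return(simulateSession(x, rows$subject_id[1], rows$session_index[1],
                           rows$context[1]))
  }
  lapply(seq_len(nrow(rows)), function(j) {
    for (col in c("timeseries_path", "motion_path", "nuisance_path")) {
      if (!file.exists(rows[[col]][j]))
        stop("missing input file: ", rows[[col]][j])
    }
    ts <- utils::read.delim(rows$timeseries_path[j])
    list(data = t(as.matrix(ts)),
         motion = as.matrix(utils::read.delim(rows$motion_path[j])),
         nuisance = utils::read.delim(rows$nuisance_path[j]))
  })
}

#' Run the full functional-controllability pipeline
#'
#' Orchestrates the stages for every (subject, session, scan context) cell
#' of a cohort: per-run postprocessing (FD, notch, censoring, spectral
#' interpolation, band-pass, 36-parameter nuisance regression), run- and
#' task-level QC, detrend/standardize/concatenate, graphical-LASSO
#' connectome, average and modal controllability with network aggregation,
#' acute-responder filtering, and the two mixed-effects model sets over the
#' full model grid. Deterministic given the cohort and configuration:
#' re-running writes byte-identical outputs.
#'
#' @param x a [SyntheticCohort-class], or the path to a directory written
#'   by [writeCohort()] (its `manifest.tsv` is read; missing files fail
#'   fast naming the path).
#' @param config a [PipelineConfig-class].
#' @param outDir optional output directory; when given, stage outputs are
#'   written as TSV with provenance headers plus a `checksums.tsv`.
#' @return (invisibly) list with `metricTable`, `qcReport`, `responders`,
#'   `modelResults`, `profiles`, `configHash` and output `paths`.
#' @export
runPipeline <- function(x, config = pipelineConfig(), outDir = NULL) {
  if (is.character(x)) {
    mpath <- file.path(x, "manifest.tsv")
    if (!file.exists(mpath)) stop("missing input file: ", mpath)
    manifest <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  } else {
    stopifnot(is(x, "SyntheticCohort"))
    manifest <- x@manifest
  }
  if (!nrow(manifest)) stop("validation error: empty manifest")
  validObject(config)
  hash <- configHash(config)
  tr <- if (is(x, "SyntheticCohort")) x@config@trSeconds else 2
  networksByRoi <- if (is(x, "SyntheticCohort")) {
    x@config@networkAssignment
  } else {
    apath <- file.path(x, "atlas.tsv")
    if (file.exists(apath)) utils::read.delim(apath)$network_label else NULL
  }

  cells <- unique(manifest[c("subject_id", "group", "session_index",
                             "condition", "context", "age", "sex")])
  qcRows <- list(); metricRows <- list(); profileRows <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    rows <- manifest[manifest$subject_id == cl$subject_id &
                     manifest$session_index == cl$session_index &
                     manifest$context == cl$context, , drop = FALSE]
    raw <- .cellRuns(x, rows)
    runs <- lapply(raw, function(r)
      preprocessRun(r$data, r$motion, r$nuisance, config, trSeconds = tr))
    meanFdRaw <- mean(vapply(runs, function(r) r@qc$mean_fd_raw, numeric(1)))
    for (j in seq_along(runs)) {
      q <- runs[[j]]@qc
      qcRows[[length(qcRows) + 1L]] <- data.frame(
        subject = cl$subject_id, group = cl$group,
        session = cl$session_index, condition = cl$condition,
        context = cl$context, run = j, included = q$included,
        reason = q$reason, mean_fd_notch = q$mean_fd_notch,
        mean_fd_raw = q$mean_fd_raw, n_good = q$n_good,
        stringsAsFactors = FALSE)
    }
    inc <- vapply(runs, function(r) r@qc$included, logical(1))
    good <- vapply(runs[inc], function(r) r@qc$n_good, integer(1))
    if (!any(inc) || !qcTask(good, config@minGoodPerTask)) next
    task <- finalizeTaskTimeseries(runs[inc])
    if (is.null(networksByRoi))
      networksByRoi <- rep("unassigned", nrow(task$data))
    conn <- buildConnectome(task$data, mask = task$mask,
                            lambda = config@lambda,
                            networks = networksByRoi)
    prof <- controllabilityProfile(conn)
    profileRows[[length(profileRows) + 1L]] <- data.frame(
      subject = cl$subject_id, session = cl$session_index,
      condition = cl$condition, context = cl$context,
      roi = conn@roiIds, network = networksByRoi,
      avg_ctrb = avgCtrb(prof), modal_ctrb = modalCtrb(prof),
      stringsAsFactors = FALSE)
    for (metric in c("average", "modal")) {
      nm <- networkMeans(prof, metric)
      nm <- nm[names(nm) != "unassigned"]
      metricRows[[length(metricRows) + 1L]] <- data.frame(
        subject = cl$subject_id, group = cl$group,
        session = cl$session_index, condition = cl$condition,
        context = cl$context, network = names(nm), metric = metric,
        value = as.numeric(nm), age = cl$age, sex = cl$sex,
        mean_fd_raw = meanFdRaw, stringsAsFactors = FALSE)
    }
  }
  qcReport <- do.call(rbind, qcRows)
  metricTable <- do.call(rbind, metricRows)
  profiles <- do.call(rbind, profileRows)
  if (is.null(metricTable) || !nrow(metricTable))
    stop("no analyzable cells survived QC")

  # responder filtering on raw FD per (subject, condition, context)
  fdTab <- stats::aggregate(mean_fd_raw ~ subject + group + condition + context,
                            data = qcReport, FUN = mean)
  responders <- acuteResponders(fdTab)
  keep <- vapply(seq_len(nrow(metricTable)), function(i)
    metricTable$subject[i] %in% responders[[metricTable$context[i]]]$included,
    logical(1))
  modelTable <- metricTable[keep, , drop = FALSE]
  grid <- enumerateModels(networks = sort(unique(modelTable$network)),
                          contexts = sort(unique(modelTable$context)))
  modelResults <- fitAllModels(modelTable, grid)

  out <- list(metricTable = metricTable, qcReport = qcReport,
              responders = do.call(rbind, lapply(responders, `[[`, "log")),
              modelResults = modelResults, profiles = profiles,
              configHash = hash, paths = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(qc_report = file.path(outDir, "qc_report.tsv"),
               metric_table = file.path(outDir, "metric_table.tsv"),
               responders = file.path(outDir, "responders.tsv"),
               profiles = file.path(outDir, "profiles.tsv"),
               model_results = file.path(outDir, "model_results.tsv"))
    .writeStamped(qcReport, paths["qc_report"], hash, "preprocess")
    .writeStamped(metricTable, paths["metric_table"], hash, "control")
    .writeStamped(out$responders, paths["responders"], hash, "models")
    .writeStamped(profiles, paths["profiles"], hash, "control")
    .writeStamped(modelResults, paths["model_results"], hash, "models")
    sums <- data.frame(file = basename(paths),
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE)
    utils::write.table(sums, file.path(outDir, "checksums.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- c(paths, checksums = file.path(outDir, "checksums.tsv"))
  }
  invisible(out)
}
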