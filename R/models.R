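#' @include AllClasses.R
#' @importFrom stats pt pchisq as.formula coef
NULL

#' Acute behavioral responder selection
#'
#' A drug trial participant counts as an acute behavioral responder for a
#' scan context when their mean raw framewise displacement (before notch
#' filtering, censoring, and processing) on drug is strictly lower than on
#' placebo for that context. The criterion is applied to each scan context
#' separately; comparison (TD) subjects are always included. Equal FD is a
#' non-response (a "reduction" must be strict); a missing condition
#' excludes the subject for that context with a logged reason.
#'
#' @param fdTable data.frame with columns `subject`, `group` (`"ADHD"` /
#'   `"TD"`), `condition` (`"MPH"` / `"placebo"`), `context`,
#'   `mean_fd_raw` (mm). One row per (subject, condition, context); multiple
#'   rows are averaged.
#' @return named list per context, each with `included` (subject ids) and
#'   `log` (data.frame of per-subject decisions and reasons).
#' @export
acuteResponders <- function(fdTable) {
  need <- c("subject", "group", "condition", "context", "mean_fd_raw")
  if (!all(need %in% names(fdTable)))
    stop("fdTable must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (ctx in unique(fdTable$context)) {
    sub <- fdTable[fdTable$context == ctx, , drop = FALSE]
    logRows <- list()
    included <- character()
    for (sid in unique(sub$subject)) {
      rows <- sub[sub$subject == sid, , drop = FALSE]
      grp <- rows$group[1]
      if (grp == "TD") {
        status <- TRUE; reason <- "comparison group"
      } else {
        fdM <- rows$mean_fd_raw[rows$condition == "MPH"]
        fdP <- rows$mean_fd_raw[rows$condition == "placebo"]
        if (!length(fdM) || !length(fdP)) {
          status <- FALSE
          reason <- paste("missing condition:",
                          if (!length(fdM)) "MPH" else "placebo")
        } else if (mean(fdM) < mean(fdP)) {
          status <- TRUE; reason <- "FD reduced on MPH"
        } else {
          status <- FALSE; reason <- "no FD reduction on MPH"
        }
      }
      if (status) included <- c(included, sid)
      logRows[[length(logRows) + 1L]] <- data.frame(
        subject = sid, context = ctx, included = status, reason = reason,
        stringsAsFactors = FALSE)
    }
    out[[ctx]] <- list(included = included, log = do.call(rbind, logRows))
  }
  out
}

#' Enumerate the model grid
#'
#' Full Cartesian enumeration of (model set, metric, scan context, network)
#' cells. With 2 sets, 2 metrics, 3 contexts and 13 networks this yields
#' 156 model specifications. No multiple-comparisons correction is applied
#' anywhere downstream.
#'
#' @param networks character vector of network labels.
#' @param contexts character vector of scan contexts.
#' @param metrics controllability metrics.
#' @param sets model sets.
#' @return data.frame, one row per model cell.
#' @export
enumerateModels <- function(networks,
                            contexts = c("rest", "gonogo", "rewarded_gonogo"),
                            metrics = c("average", "modal"),
                            sets = c("group_comparison", "within_adhd")) {
  out <- expand.grid(model_set = sets, metric = metrics, context = contexts,
                     network = networks, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$model_set, out$metric, out$context, out$network), ,
      drop = FALSE]
}

.pFromT <- function(tval, df) 2 * pt(-abs(tval), df)

## fit one mixed model and pull the requested fixed-effect rows
.fitCell <- function(dat, form, contrastMap) {
  singular <- FALSE
  variant <- "lmm"
  fit <- tryCatch({
    f <- lme4::lmer(as.formula(paste(form, "+ (1 | subject)")), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    singular <- lme4::isSingular(f)
    f
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # simplified variance structure: fixed effects only
    variant <- "fixed_only"
    fit <- stats::lm(as.formula(form), data = dat)
    cf <- summary(fit)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
    df <- fit$df.residual
  } else {
    cf <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    est <- cf; se <- sqrt(diag(vc))
    df <- nrow(dat) - length(cf)
  }
  rows <- lapply(names(contrastMap), function(term) {
    if (!term %in% names(est)) return(NULL)
    tv <- est[[term]] / se[[term]]
    data.frame(contrast = contrastMap[[term]], estimate = est[[term]],
               se = se[[term]], t = tv, p = .pFromT(tv, df),
               df = df, singular = singular, variant = variant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit one model cell
#'
#' Linear mixed-effects model for one (model set, metric, scan context,
#' network) cell: outcome is the network-level controllability value; fixed
#' effects are the condition coding plus age, biological sex and mean raw
#' framewise displacement; a random intercept per participant absorbs
#' participant-specific differences. The `group_comparison` set uses a
#' 3-level factor (TD reference, ADHD-placebo, ADHD-MPH), yielding the two
#' group contrasts; `within_adhd` uses ADHD rows only with a binary MPH
#' indicator. Estimation is by REML (lme4); p-values come from t statistics
#' on the fixed-effect coefficients with residual-based degrees of freedom.
#' Singular fits are refit with a simplified (fixed-effects-only) variance
#' structure only when the mixed fit fails outright; otherwise they are
#' flagged in the result.
#'
#' @param table metric table: columns `subject`, `group`, `condition`,
#'   `context`, `network`, `metric`, `value`, `age`, `sex`, `mean_fd_raw`.
#' @param modelSet `"group_comparison"` or `"within_adhd"`.
#' @param metric `"average"` or `"modal"`.
#' @param context scan context.
#' @param network network label.
#' @return data.frame of model-result rows (one per contrast).
#' @export
fitModelSet <- function(table, modelSet = c("group_comparison", "within_adhd"),
                        metric, context, network) {
  modelSet <- match.arg(modelSet)
  dat <- table[table$metric == metric & table$context == context &
               table$network == network, , drop = FALSE]
  if (modelSet == "within_adhd") dat <- dat[dat$group == "ADHD", , drop = FALSE]
  if (!nrow(dat)) stop("no rows for the requested cell")
  dat$sex <- factor(dat$sex)
  # covariates that are constant in the cell carry no information; drop them
  # rather than failing on a single-level factor
  covs <- c("age", if (nlevels(dat$sex) > 1L) "sex", "mean_fd_raw")
  covTerm <- paste(covs, collapse = " + ")
  if (modelSet == "group_comparison") {
    if (length(unique(dat$subject[dat$group == "ADHD"])) < 2L ||
        length(unique(dat$subject[dat$group == "TD"])) < 2L)
      stop("need at least 2 subjects per modeled group")
    dat$cell <- factor(ifelse(dat$group == "TD", "TD",
                              paste0("ADHD_", dat$condition)),
                       levels = c("TD", "ADHD_placebo", "ADHD_MPH"))
    res <- .fitCell(dat, paste("value ~ cell +", covTerm),
                    list(cellADHD_placebo = "ADHD_placebo_vs_TD",
                         cellADHD_MPH = "ADHD_MPH_vs_TD"))
  } else {
    if (length(unique(dat$subject)) < 2L)
      stop("need at least 2 subjects per modeled group")
    dat$mph <- as.integer(dat$condition == "MPH")
    res <- .fitCell(dat, paste("value ~ mph +", covTerm),
                    list(mph = "MPH_vs_placebo"))
  }
  if (is.null(res) || !nrow(res)) stop("contrast term missing from fit")
  cbind(data.frame(model_set = modelSet, metric = metric, context = context,
                   network = network, stringsAsFactors = FALSE),
        res,
        data.frame(n_obs = nrow(dat),
                   n_subjects = length(unique(dat$subject))))
}

#' Fit every enumerated model cell
#'
#' Runs [fitModelSet()] over the full model grid. Cells that fail are
#' recorded with `status = "error"` and the condition message, never
#' silently dropped, so enumerate-times-fit conserves the model count.
#'
#' @param table metric table (see [fitModelSet()]).
#' @param grid model grid from [enumerateModels()]; defaults to the grid
#'   spanned by the table itself.
#' @return data.frame with one or more result rows per cell plus a
#'   `status` column.
#' @export
fitAllModels <- function(table, grid = NULL) {
  if (is.null(grid))
    grid <- enumerateModels(networks = sort(unique(table$network)),
                            contexts = sort(unique(table$context)))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tryCatch(
      cbind(fitModelSet(table, g$model_set, g$metric, g$context, g$network),
            data.frame(status = "ok", stringsAsFactors = FALSE)),
      error = function(e)
        data.frame(model_set = g$model_set, metric = g$metric,
                   context = g$context, network = g$network,
                   contrast = NA_character_, estimate = NA_real_,
                   se = NA_real_, t = NA_real_, p = NA_real_, df = NA_real_,
                   singular = NA, variant = NA_character_,
                   n_obs = NA_integer_, n_subjects = NA_integer_,
                   status = paste("error:", conditionMessage(e)),
                   stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided two-sample t-test from group means, standard
#' deviations and sizes. The pooled-variance (Student) form is the default;
#' the Welch form is available via `varEqual = FALSE`.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param varEqual pool the variances (default TRUE).
#' @return list with `t`, `df`, `p`.
#' @examples
#' summaryTtest(10.00, 1.20, 23, 10.38, 1.45, 27)$p  # ~0.32
#' @export
summaryTtest <- function(mean1, sd1, n1, mean2, sd2, n2, varEqual = TRUE) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (varEqual) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = .pFromT(tval, df))
}

#' Pearson chi-squared test of independence (2 x 2, no correction)
#'
#' @param tab 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chisqIndependence(matrix(c(11, 12, 11, 16), 2, byrow = TRUE))$p
#' @export
chisqIndependence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: zero margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
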