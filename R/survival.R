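#' @include utils.R
NULL

#' Validate a survival table
#'
#' @param table data.frame with columns `time` (> 0, years), `event`
#'   (0/1), and any covariates used downstream (`age`, `sex`,
#'   `subgroup`).
#' @return the validated data.frame.
#' @export
survivalTable <- function(table) {
  stopifnot(is.data.frame(table), all(c("time", "event") %in% colnames(table)))
  if (any(table$time <= 0)) stopMsg("all survival times must be > 0")
  if (!all(table$event %in% c(0, 1))) stopMsg("event must be 0 or 1")
  table
}

#' Multivariate Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. The default
#' adjustment set is age, sex and subgroup (one-hot against a
#' configurable reference class); covariates are included only when
#' present in the table, and a zero-variance covariate is an error.
#'
#' @param table a [survivalTable()] containing a `group` column (the
#'   dichotomized methylation group) unless `covariates` says otherwise.
#' @param covariates model terms besides `group` (default: those of
#'   age/sex/subgroup present in the table).
#' @param refSubgroup reference class for the subgroup factor
#'   (default "WNT" when present).
#' @return list with `coefficients` (data.frame: term, coef, HR, CI,
#'   wald_p), `lr_p` (model likelihood-ratio p), `n`, `events`, and the
#'   underlying `survival::coxph` fit.
#' @export
coxFit <- function(table, covariates = NULL, refSubgroup = "WNT") {
  table <- survivalTable(table)
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", "subgroup"), colnames(table))
  terms <- c("group"[!is.null(table$group)], covariates)
  if (!length(terms)) stopMsg("no model terms")
  for (tm in terms) {
    v <- table[[tm]]
    if (length(unique(v)) < 2L)
      stopMsg("covariate '%s' has zero variance", tm)
  }
  if ("subgroup" %in% terms) {
    lev <- unique(as.character(table$subgroup))
    ref <- if (refSubgroup %in% lev) refSubgroup else lev[1L]
    table$subgroup <- stats::relevel(factor(table$subgroup), ref = ref)
  }
  if ("group" %in% terms) table$group <- factor(table$group)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = table, ties = "efron")
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info)))
    stopMsg("Cox model did not converge")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  coefs <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    HR = co[, "exp(coef)"],
    lower95 = ci[, "lower .95"],
    upper95 = ci[, "upper .95"],
    wald_p = co[, "Pr(>|z|)"],
    row.names = NULL)
  nEvents <- sum(table$event)
  if (nEvents < 5 * nrow(coefs))
    warning(sprintf("only %d events for %d coefficients", nEvents,
                    nrow(coefs)), call. = FALSE)
  list(coefficients = coefs,
       lr_p = as.numeric(s$logtest["pvalue"]),
       n = nrow(table), events = nEvents, fit = fit)
}

#' Dichotomize a methylation marker at the best cut-off
#'
#' Splits samples into high/low methylation at each candidate cut-off
#' (mean, median, lower and upper quartile of the marker), fits the
#' adjusted Cox model for each, and returns the cut-off maximizing the
#' absolute log hazard ratio of the methylation-group coefficient,
#' subject to both groups holding at least `minGroupFrac` of the
#' samples. Maximizing |log HR| (rather than HR) also captures
#' protective markers.
#'
#' @param marker per-sample beta values of the biomarker.
#' @param table a [survivalTable()] (>= 20 samples, >= 5 events).
#' @param candidates named cut-off values; default the four quantile
#'   candidates of the marker.
#' @param minGroupFrac group-size floor as a fraction of samples
#'   (default 0.1).
#' @param covariates passed to [coxFit()].
#' @return list with `group` (factor High/Low), `cutoff` (name),
#'   `cutoffValue`, and `fit` (the winning [coxFit()] result, group HR
#'   in `fit$coefficients`).
#' @export
dichotomizeBest <- function(marker, table, candidates = NULL,
                            minGroupFrac = 0.1, covariates = NULL) {
  table <- survivalTable(table)
  if (length(marker) != nrow(table)) stopMsg("marker and table disagree")
  if (nrow(table) < 20L) stopMsg("need >= 20 samples")
  if (sum(table$event) < 5L) stopMsg("need >= 5 events")
  if (is.null(candidates))
    candidates <- c(mean = mean(marker), median = median(marker),
                    q25 = unname(quantile(marker, 0.25)),
                    q75 = unname(quantile(marker, 0.75)))
  best <- NULL
  for (nm in names(candidates)) {
    cut <- candidates[[nm]]
    grp <- factor(ifelse(marker > cut, "High", "Low"),
                  levels = c("Low", "High"))
    if (min(table(grp)) < minGroupFrac * length(marker)) next
    tb <- table; tb$group <- grp
    res <- tryCatch(coxFit(tb, covariates = covariates),
                    error = function(e) NULL)
    if (is.null(res)) next
    gi <- grep("^group", res$coefficients$term)[1L]
    if (is.na(gi)) next
    score <- abs(res$coefficients$coef[gi])
    if (is.null(best) || score > best$score)
      best <- list(group = grp, cutoff = nm, cutoffValue = unname(cut),
                   fit = res, score = score)
  }
  if (is.null(best))
    stopMsg("no candidate cut-off satisfies the group-size floor")
  best$score <- NULL
  best
}

#' Log-rank test between groups
#'
#' Standard log-rank chi-square (1 df for two groups, k-1 df for k).
#'
#' @param table a [survivalTable()].
#' @param groups group label per sample (>= 2 groups, >= 1 event).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank <- function(table, groups) {
  table <- survivalTable(table)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopMsg("need >= 2 groups")
  if (sum(table$event) < 1L) stopMsg("need >= 1 event")
  sd <- survival::survdiff(survival::Surv(table$time, table$event) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = as.numeric(sd$chisq), df = df,
       p = as.numeric(pchisq(sd$chisq, df, lower.tail = FALSE)))
}

#' Kaplan-Meier curves per group
#'
#' Product-limit survival estimates: non-increasing step functions
#' starting at 1.
#'
#' @param table a [survivalTable()].
#' @param groups group label per sample (single group allowed).
#' @return data.frame with group, time, surv, n_risk, n_event.
#' @export
kmCurve <- function(table, groups = NULL) {
  table <- survivalTable(table)
  if (is.null(groups)) groups <- rep("all", nrow(table))
  groups <- factor(groups)
  fit <- survival::survfit(survival::Surv(table$time, table$event) ~ groups)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1L], length(sm$time))
         else sub("^groups=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, surv = sm$surv,
             n_risk = sm$n.risk, n_event = sm$n.event)
}

#' Survival screen over a panel of markers
#'
#' Runs [dichotomizeBest()] plus [logrank()] for each marker row and
#' tabulates HR, CI and p-values. Raw p-values are reported; multiplicity
#' correction across markers is left to the caller.
#'
#' @param markers markers x samples beta matrix.
#' @param table a [survivalTable()] aligned with the samples.
#' @param covariates passed to [coxFit()].
#' @return data.frame: marker, cutoff, HR, lower95, upper95, wald_p,
#'   lr_p, logrank_p.
#' @export
survivalScreen <- function(markers, table, covariates = NULL) {
  checkMatrix(markers, "markers")
  rows <- lapply(rownames(markers), function(mk) {
    res <- tryCatch(
      dichotomizeBest(markers[mk, ], table, covariates = covariates),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(marker = mk, cutoff = NA, HR = NA, lower95 = NA,
                        upper95 = NA, wald_p = NA, lr_p = NA,
                        logrank_p = NA))
    gi <- grep("^group", res$fit$coefficients$term)[1L]
    co <- res$fit$coefficients[gi, ]
    lr <- logrank(table, res$group)
    data.frame(marker = mk, cutoff = res$cutoff, HR = co$HR,
               lower95 = co$lower95, upper95 = co$upper95,
               wald_p = co$wald_p, lr_p = res$fit$lr_p,
               logrank_p = lr$p)
  })
  do.call(rbind, rows)
}
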