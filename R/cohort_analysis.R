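# Cohort-level association of the g-score with survival: arm comparisons,
# pooled quartile strata (dx held separately as the no-growth stratum),
# Kaplan-Meier and Cox summaries, Harrell concordance vs RECIST-style
# response, and early-look interim analyses.

modeled <- function(results) {
  results[results$classification %in% MODEL_CLASSES, , drop = FALSE]
}

#' Compare g-scores between treatment arms
#'
#' Median and IQR of the g-score per arm over subjects whose trajectory fit
#' one of the four models (dx contributes g = 0), with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test of the arm difference.
#'
#' @param results Data frame from [fit_cohort()] with an `arm` column.
#' @param positive_only Restrict to subjects with tumor growth (g > 0),
#'   as in the published within-growth summaries.
#' @return List with `summary` (per-arm n, median, quartiles, in /day and
#'   in the 1e-2/day display unit) and `p_value`.
#' @export
compare_arms_g <- function(results, positive_only = FALSE) {
  res <- modeled(results)
  if (positive_only) res <- res[res$g > 0, , drop = FALSE]
  arms <- unique(res$arm)
  if (length(arms) != 2L) stop("expected exactly two arms", call. = FALSE)
  if (any(table(res$arm) < 2L)) stop("need >= 2 modeled subjects per arm",
                                     call. = FALSE)
  smry <- do.call(rbind, lapply(arms, function(a) {
    g <- res$g[res$arm == a]
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(arm = a, n = length(g), median_g = q[2], q1_g = q[1],
               q3_g = q[3], median_g_display = g_display(q[2]),
               stringsAsFactors = FALSE)
  }))
  p <- if (length(unique(res$g)) == 1L) 1 else
    stats::wilcox.test(g ~ arm, data = res, exact = FALSE)$p.value
  list(summary = smry, p_value = p)
}

#' Assign pooled quartile strata
#'
#' Computes quartile cutpoints of the chosen rate over subjects pooled
#' across arms and assigns each subject a stratum. By default the cutpoints
#' are computed over subjects with value > 0 and the zero-rate (dx,
#' no-growth) subjects form their own stratum; setting
#' `zero_in_quartiles = TRUE` instead includes the zeros in the cutpoint
#' computation and quartile assignment. Values at a cutpoint go to the
#' lower stratum; cutpoints are type-7 sample quantiles.
#'
#' @param results Data frame from [fit_cohort()].
#' @param value Column to stratify on: `"g"` (default) or `"d"`.
#' @param zero_in_quartiles Include zero values in the quartiles instead of
#'   a separate stratum.
#' @param zero_label Stratum label for zero values (default `"dx"`).
#' @return List with `thresholds` (3 cutpoints) and `assignment` (data
#'   frame `subject_id`, `arm`, `value`, `stratum`; stratum is a factor
#'   with levels zero_label, Q1..Q4, Q1 = slowest).
#' @export
assign_quartiles <- function(results, value = c("g", "d"),
                             zero_in_quartiles = FALSE, zero_label = "dx") {
  value <- match.arg(value)
  res <- modeled(results)
  v <- res[[value]]
  keep <- !is.na(v)
  res <- res[keep, , drop = FALSE]
  v <- v[keep]
  pos <- if (zero_in_quartiles) rep(TRUE, length(v)) else v > 0
  if (sum(pos) < 4L) stop("need >= 4 subjects with positive ", value,
                          call. = FALSE)
  if (length(unique(v[pos])) < 4L) stop("need >= 4 distinct values",
                                        call. = FALSE)
  thr <- stats::quantile(v[pos], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qlab <- paste0("Q", 1:4)
  stratum <- character(length(v))
  stratum[!pos] <- zero_label
  stratum[pos] <- ifelse(v[pos] <= thr[1], "Q1",
                  ifelse(v[pos] <= thr[2], "Q2",
                  ifelse(v[pos] <= thr[3], "Q3", "Q4")))
  levs <- c(if (!zero_in_quartiles) zero_label, qlab)
  out <- data.frame(subject_id = res$subject_id,
                    arm = if ("arm" %in% names(res)) res$arm else NA_character_,
                    value = v,
                    stratum = factor(stratum, levels = levs),
                    stringsAsFactors = FALSE)
  list(thresholds = thr, assignment = out)
}

merge_surv <- function(assignment, survival, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_days"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(survival))) {
    stop("survival table lacks ", tcol, "/", ecol, call. = FALSE)
  }
  d <- merge(assignment, survival[, c("subject_id", tcol, ecol)],
             by = "subject_id")
  d$time <- d[[tcol]]; d$event <- d[[ecol]]
  d
}

#' Kaplan-Meier summaries by stratum
#'
#' Product-limit estimates per stratum with the median survival time
#' (first time the KM curve drops to or below 0.5; `NA` when not reached)
#' and the 1-year survival rate in percent.
#'
#' @param assignment The `assignment` data frame from [assign_quartiles()]
#'   (or any data frame with `subject_id` and `stratum`).
#' @param survival Per-subject survival table with `subject_id`,
#'   `<endpoint>_days`, `<endpoint>_event`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param rate_time Time (days) of the reported survival rate (default 365).
#' @return Data frame: stratum, n, events, median_days, rate_pct; attribute
#'   `survfit` holds the [survival::survfit] object.
#' @export
km_by_stratum <- function(assignment, survival, endpoint = c("os", "pfs"),
                          rate_time = 365) {
  d <- merge_surv(assignment, survival, endpoint)
  d <- d[!is.na(d$stratum), , drop = FALSE]
  empty <- setdiff(levels(d$stratum), as.character(unique(d$stratum)))
  if (length(empty) > 0) {
    warning("empty stratum omitted: ", paste(empty, collapse = ", "))
  }
  d$stratum <- droplevels(d$stratum)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = d)
  strata_names <- if (is.null(fit$strata)) levels(d$stratum) else
    sub("^stratum=", "", names(fit$strata))
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(strata_names, names(tab)))
  rownames(tab) <- sub("^stratum=", "", rownames(tab))
  s1 <- summary(fit, times = rate_time, extend = TRUE)
  rate <- stats::setNames(s1$surv * 100,
                          if (is.null(fit$strata)) strata_names else
                            sub("^stratum=", "", as.character(s1$strata)))
  out <- data.frame(
    stratum = rownames(tab),
    n = tab[, "records"], events = tab[, "events"],
    median_days = tab[, "median"],
    rate_pct = rate[rownames(tab)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "survfit") <- fit
  out
}

#' Cox hazard ratios by stratum vs the fastest quartile
#'
#' Fits a stratum-indicator Cox proportional-hazards model (Efron ties)
#' with Q4 (fastest growth) as the reference and reports hazard ratios with
#' Wald 95% confidence intervals for each other stratum. A stratum with no
#' events is reported as HR 0 with CI (0, Inf) rather than dropped.
#'
#' @inheritParams km_by_stratum
#' @param reference Reference stratum label (default `"Q4"`).
#' @return Data frame: stratum, n, events, hr, ci_lower, ci_upper (the
#'   reference row has hr 1 by construction).
#' @export
cox_by_stratum <- function(assignment, survival, endpoint = c("os", "pfs"),
                           reference = "Q4") {
  d <- merge_surv(assignment, survival, endpoint)
  d <- d[!is.na(d$stratum), , drop = FALSE]
  d$stratum <- droplevels(d$stratum)
  if (sum(d$event) == 0) stop("no events in any stratum", call. = FALSE)
  ev <- tapply(d$event, d$stratum, sum)
  nn <- table(d$stratum)
  d$stratum <- stats::relevel(d$stratum, ref = reference)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ stratum, data = d,
                    ties = "efron"))
  cf <- summary(fit)$coefficients
  ci <- suppressWarnings(summary(fit)$conf.int)
  labs <- sub("^stratum", "", rownames(cf))
  out <- data.frame(stratum = names(nn), n = as.integer(nn),
                    events = as.integer(ev), hr = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    stringsAsFactors = FALSE)
  out$hr[out$stratum == reference] <- 1
  for (i in seq_along(labs)) {
    j <- which(out$stratum == labs[i])
    out$hr[j] <- ci[i, "exp(coef)"]
    out$ci_lower[j] <- ci[i, "lower .95"]
    out$ci_upper[j] <- ci[i, "upper .95"]
  }
  # zero-event strata: monotone-likelihood estimates; present as 0 (0-Inf)
  zero <- out$events == 0 & out$stratum != reference
  out$hr[zero] <- 0
  out$ci_lower[zero] <- 0
  out$ci_upper[zero] <- Inf
  attr(out, "coxph") <- fit
  out
}

#' Concordance of g vs tumor response for survival
#'
#' Among subjects with tumor growth (g > 0), fits two Cox models — one on
#' the continuous g-score (optionally log g) and one on the RECIST-style
#' response category — and returns Harrell's concordance of each with the
#' survival endpoint.
#'
#' @param results Data frame from [fit_cohort()].
#' @param survival Survival table; must carry `response_category` or it is
#'   derived by the caller and merged in.
#' @param endpoint `"os"` or `"pfs"`.
#' @param log_g Use log(g) as the Cox covariate (default `FALSE`).
#' @param response_coding `"three_level"` (responder/stable/progression,
#'   default) or `"binary"` (responder vs not).
#' @return Named vector `c(concordance_g, concordance_response)`.
#' @export
concordance_comparison <- function(results, survival,
                                   endpoint = c("os", "pfs"),
                                   log_g = FALSE,
                                   response_coding = c("three_level", "binary")) {
  endpoint <- match.arg(endpoint)
  response_coding <- match.arg(response_coding)
  res <- modeled(results)
  res <- res[res$g > 0, , drop = FALSE]
  d <- merge(res[, c("subject_id", "g")], survival, by = "subject_id")
  d$time <- d[[paste0(endpoint, "_days")]]
  d$event <- d[[paste0(endpoint, "_event")]]
  if (nrow(d) < 2L || sum(d$event) < 1L) {
    stop("too few comparable subjects", call. = FALSE)
  }
  d$gcov <- if (log_g) log(d$g) else d$g
  resp <- d$response_category
  d$resp <- if (response_coding == "binary") {
    factor(ifelse(resp == "responder", "responder", "non_responder"))
  } else factor(resp, levels = c("responder", "stable", "progression"))
  fit_g <- survival::coxph(survival::Surv(time, event) ~ gcov, data = d)
  fit_r <- survival::coxph(survival::Surv(time, event) ~ resp, data = d)
  c(concordance_g = unname(survival::concordance(fit_g)$concordance),
    concordance_response = unname(survival::concordance(fit_r)$concordance))
}

#' Early-look interim analysis
#'
#' Reproduces an interim data cut: the cutoff is the calendar day on which
#' the k-th randomized subject reaches `followup_floor` days (14 weeks by
#' default) of follow-up. The first k randomized subjects are included,
#' each subject's scans are truncated to those on or before the cutoff, the
#' cohort is refitted from the truncated trajectories, and the arms are
#' compared as in the full analysis.
#'
#' @param measurements Long measurement table (`subject_id`, `arm`, `day`,
#'   `sod_mm`); `day` is days from the subject's baseline scan.
#' @param subjects Per-subject table with `subject_id` and `accrual_day`
#'   (randomization day on the trial calendar).
#' @param k Number of randomized subjects included.
#' @param followup_floor Follow-up (days) the k-th subject must reach
#'   (default 98 = 14 weeks).
#' @param ... Passed to [fit_cohort()].
#' @return List: `cutoff_day`, `results` (refit on truncated data),
#'   `comparison` (from [compare_arms_g()]), `n_included`.
#' @export
early_look <- function(measurements, subjects, k, followup_floor = 98, ...) {
  ord <- order(subjects$accrual_day)
  subjects <- subjects[ord, , drop = FALSE]
  if (k > nrow(subjects)) stop("k exceeds cohort size", call. = FALSE)
  cutoff <- subjects$accrual_day[k] + followup_floor
  inc <- subjects[seq_len(k), , drop = FALSE]
  m <- merge(measurements, inc[, c("subject_id", "accrual_day")],
             by = "subject_id")
  m <- m[m$accrual_day + m$day <= cutoff, , drop = FALSE]
  results <- fit_cohort(m[, setdiff(names(m), "accrual_day")], ...)
  comparison <- compare_arms_g(results)
  list(cutoff_day = cutoff, results = results, comparison = comparison,
       n_included = k)
}

#' Full cohort analysis
#'
#' Bundles the cohort-level statistics: per-arm g summaries with the
#' Mann-Whitney comparison, classification counts, pooled quartile strata
#' (dx separate), per-stratum KM and Cox summaries for OS and PFS on the
#' pooled cohort and per arm, and the g-vs-response concordance per arm.
#'
#' @param results Data frame from [fit_cohort()] with `arm`.
#' @param survival Per-subject survival table (as from [simulate_cohort()]
#'   `$subjects` or [read_survival()]).
#' @param zero_in_quartiles Quartile convention, see [assign_quartiles()].
#' @param log_g,response_coding Passed to [concordance_comparison()].
#' @return A `cohort_analysis` list; see the individual components.
#' @export
analyze_cohort <- function(results, survival, zero_in_quartiles = FALSE,
                           log_g = FALSE,
                           response_coding = c("three_level", "binary")) {
  response_coding <- match.arg(response_coding)
  arms <- unique(results$arm)
  qa <- assign_quartiles(results, "g", zero_in_quartiles = zero_in_quartiles)
  per_arm <- function(fun) {
    out <- lapply(arms, function(a) {
      asg <- qa$assignment[qa$assignment$arm == a, , drop = FALSE]
      fun(asg, a)
    })
    stats::setNames(out, arms)
  }
  conc <- lapply(arms, function(a) {
    tryCatch(
      concordance_comparison(results[results$arm == a, , drop = FALSE],
                             survival, "os", log_g = log_g,
                             response_coding = response_coding),
      error = function(e) {
        warning(sprintf("arm %s: concordance not estimable (%s)", a,
                        conditionMessage(e)), call. = FALSE)
        c(concordance_g = NA_real_, concordance_response = NA_real_)
      })
  })
  conc_pooled <- concordance_comparison(results, survival, "os",
                                        log_g = log_g,
                                        response_coding = response_coding)
  structure(list(
    arm_comparison = compare_arms_g(results),
    arm_comparison_positive = compare_arms_g(results, positive_only = TRUE),
    counts = classification_counts(results),
    quartiles = qa,
    km_os_pooled = km_by_stratum(qa$assignment, survival, "os"),
    cox_os_pooled = cox_by_stratum(qa$assignment, survival, "os"),
    km_os_by_arm = per_arm(function(asg, a) km_by_stratum(asg, survival, "os")),
    cox_os_by_arm = per_arm(function(asg, a) cox_by_stratum(asg, survival, "os")),
    km_pfs_pooled = km_by_stratum(qa$assignment, survival, "pfs"),
    cox_pfs_pooled = cox_by_stratum(qa$assignment, survival, "pfs"),
    concordance_pooled = conc_pooled,
    concordance = stats::setNames(conc, arms)
  ), class = "cohort_analysis")
}
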