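# Per-subject nonlinear regression of normalized tumor burden against the
# four kinetic models, Wald inference, and AIC/p-value model selection.

RATE_UPPER <- 0.5          # /day; doubling in 1.4 days, beyond clinical range
RSS_FLOOR  <- 1e-12        # keeps AIC/SEs finite on exact (noise-free) fits

#' Construct a tumor trajectory
#'
#' Packages one subject's longitudinal sum-of-diameters (SOD) measurements
#' as a trajectory normalized to baseline. Rows are sorted by day; day 0 is
#' the baseline scan used for normalization.
#'
#' @param subject_id Subject identifier.
#' @param day Integer-valued days since the baseline scan; must contain 0
#'   and be unique.
#' @param sod_mm Sum of target-lesion diameters in mm at each day; the
#'   baseline value must be positive.
#' @param zero_floor Measurements of exactly 0 mm (complete disappearance of
#'   target lesions) break relative-burden machinery; when `TRUE` (default)
#'   they are floored at half the smallest positive measurement of the
#'   subject and the trajectory is flagged.
#' @return An object of class `tumor_trajectory`: a list with `subject_id`,
#'   `days`, `sod_mm`, `normalized` (SOD / baseline SOD) and `flags`.
#' @export
tumor_trajectory <- function(subject_id, day, sod_mm, zero_floor = TRUE) {
  if (length(day) != length(sod_mm)) stop("day and sod_mm lengths differ")
  ord <- order(day)
  day <- as.numeric(day)[ord]
  sod <- as.numeric(sod_mm)[ord]
  if (anyDuplicated(day)) {
    stop(sprintf("subject %s: duplicate assessment days", subject_id),
         call. = FALSE)
  }
  if (!any(day == 0)) {
    stop(sprintf("subject %s: no baseline (day 0) assessment", subject_id),
         call. = FALSE)
  }
  if (any(sod < 0) || any(!is.finite(sod))) {
    stop(sprintf("subject %s: invalid SOD values", subject_id), call. = FALSE)
  }
  flags <- character(0)
  if (any(sod == 0)) {
    if (!zero_floor || all(sod == 0)) {
      stop(sprintf("subject %s: zero SOD measurement", subject_id),
           call. = FALSE)
    }
    sod[sod == 0] <- 0.5 * min(sod[sod > 0])
    flags <- c(flags, "zero_sod_floored")
  }
  if (sod[day == 0] <= 0) {
    stop(sprintf("subject %s: non-positive baseline SOD", subject_id),
         call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), days = day, sod_mm = sod,
         normalized = sod / sod[day == 0], flags = flags),
    class = "tumor_trajectory"
  )
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf("<tumor_trajectory> subject %s: %d assessments over %g days\n",
              x$subject_id, length(x$days), max(x$days)))
  invisible(x)
}

# Post-baseline observations; the baseline point is structural (f(0) = 1
# exactly after normalization) and contributes no residual.
post_baseline <- function(traj) {
  keep <- traj$days > 0
  list(t = traj$days[keep], y = traj$normalized[keep])
}

model_rss <- function(model, theta, t, y, log_scale = FALSE) {
  f <- evaluate_model(model, theta, t)
  if (log_scale) sum((log(y) - log(pmax(f, 1e-12)))^2) else sum((y - f)^2)
}

# Multi-start grids (rates /day). gdphi shares the rate grid with a phi grid.
START_RATES <- c(1e-4, 1e-3, 1e-2)
START_PHI   <- c(0.2, 0.5, 0.8)

model_starts <- function(model) {
  switch(model,
    dx    = lapply(START_RATES, function(d) c(d = d)),
    gx    = lapply(START_RATES, function(g) c(g = g)),
    gd    = {
      gr <- expand.grid(g = START_RATES, d = START_RATES)
      lapply(seq_len(nrow(gr)), function(i) c(g = gr$g[i], d = gr$d[i]))
    },
    gdphi = {
      gr <- expand.grid(g = START_RATES, d = START_RATES, phi = START_PHI)
      lapply(seq_len(nrow(gr)), function(i)
        c(g = gr$g[i], d = gr$d[i], phi = gr$phi[i]))
    }
  )
}

# Best point of a coarse log grid over the parameter box, as an extra
# start. Vectorized through outer-product identities on the natural-scale
# RSS, so the scan costs a handful of small matrix products.
coarse_scan <- function(model, t, y) {
  Eg <- exp(outer(t, COARSE_RATES))    # n x m growth terms
  Ed <- exp(-outer(t, COARSE_RATES))   # n x m decay terms
  n <- length(t)
  yy <- sum(y^2)
  yg <- drop(crossprod(y, Eg)); yd <- drop(crossprod(y, Ed))
  sg <- colSums(Eg); sd_ <- colSums(Ed)
  Sgg <- colSums(Eg^2); Sdd <- colSums(Ed^2)
  Sdg <- crossprod(Ed, Eg)             # m x m cross terms
  if (model == "gd") {
    # pred = Ed[,j] + Eg[,i] - 1
    rss <- matrix(yy + n, length(COARSE_RATES), length(COARSE_RATES))
    rss <- rss + outer(Sdd - 2 * yd - 2 * sd_, rep(1, ncol(rss))) +
      outer(rep(1, nrow(rss)), Sgg - 2 * yg - 2 * sg) +
      2 * Sdg + 2 * sum(y)
    ij <- arrayInd(which.min(rss), dim(rss))
    c(g = COARSE_RATES[ij[2]], d = COARSE_RATES[ij[1]])
  } else {
    best <- NULL
    for (phi in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      # pred = phi Ed[,j] + (1-phi) Eg[,i]
      rss <- yy +
        outer(phi^2 * Sdd - 2 * phi * yd, rep(1, length(COARSE_RATES))) +
        outer(rep(1, length(COARSE_RATES)),
              (1 - phi)^2 * Sgg - 2 * (1 - phi) * yg) +
        2 * phi * (1 - phi) * Sdg
      ij <- arrayInd(which.min(rss), dim(rss))
      if (is.null(best) || rss[ij] < best$rss) {
        best <- list(par = c(g = COARSE_RATES[ij[2]], d = COARSE_RATES[ij[1]],
                             phi = phi), rss = rss[ij])
      }
    }
    best$par
  }
}

param_bounds <- function(model) {
  pn <- model_params(model)
  lower <- stats::setNames(rep(0, length(pn)), pn)
  upper <- stats::setNames(ifelse(pn == "phi", 1, RATE_UPPER), pn)
  list(lower = lower, upper = upper)
}

# Bounded least squares. 1-parameter models use Brent line search on the
# bounded interval (the RSS profile is well behaved); >= 2 parameters use
# Levenberg-Marquardt with box bounds from each grid start, best RSS wins.
COARSE_RATES <- c(0, exp(seq(log(1e-6), log(0.5), length.out = 24)))

minimize_rss <- function(model, t, y, log_scale = FALSE) {
  b <- param_bounds(model)
  pn <- model_params(model)
  if (length(pn) == 1L) {
    obj <- function(x) {
      th <- stats::setNames(x, pn)
      model_rss(model, th, t, y, log_scale)
    }
    # coarse log-grid scan to bracket the optimum, then Brent refinement
    grid <- c(0, exp(seq(log(1e-6), log(RATE_UPPER), length.out = 80)))
    rg <- vapply(grid, obj, numeric(1))
    i <- which.min(rg)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-12)
    est <- stats::setNames(opt$minimum, pn)
    best_rss <- opt$objective
    if (rg[i] < best_rss) {        # grid point beat the refinement
      est[] <- grid[i]
      best_rss <- rg[i]
    }
    if (est < 1e-10 && obj(stats::setNames(0, pn)) <= best_rss) {
      est[] <- 0                    # snap near-boundary optimum to the bound
      best_rss <- obj(est)
    }
    return(list(par = est, rss = best_rss, converged = TRUE))
  }
  resid_fn <- function(x) {
    th <- stats::setNames(x, pn)
    f <- evaluate_model(model, th, t)
    if (log_scale) log(y) - log(pmax(f, 1e-12)) else y - f
  }
  # candidate starts: the design multi-start grid, the best point of a
  # coarse log-grid scan (guards against local minima far from the grid),
  # and the nested one-parameter optima at the model's reduction limits
  # (gd|_{d=0} = gx, gd|_{g=0} = dx; gdphi|_{phi=0} = gx,
  # gdphi|_{phi=1} = dx), so the richer model never loses to a model it
  # nests
  starts <- model_starts(model)
  if (!log_scale) starts <- c(starts, list(coarse_scan(model, t, y)))
  gx_opt <- minimize_rss("gx", t, y, log_scale)$par[["g"]]
  dx_opt <- minimize_rss("dx", t, y, log_scale)$par[["d"]]
  if (model == "gd") {
    starts <- c(starts, list(c(g = gx_opt, d = 0), c(g = 0, d = dx_opt)))
  } else {
    starts <- c(starts, list(c(g = gx_opt, d = 1e-3, phi = 0),
                             c(g = 1e-3, d = dx_opt, phi = 1)))
  }
  rss0 <- vapply(starts, function(s) sum(resid_fn(s)^2), numeric(1))
  keep <- unique(c(order(rss0)[seq_len(min(5L, length(starts)))],
                   which.min(rss0)))
  best_start <- list(par = stats::setNames(as.numeric(starts[[which.min(rss0)]]), pn),
                     rss = min(rss0), converged = TRUE)
  starts <- starts[keep]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = b$lower, upper = b$upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = stats::setNames(as.numeric(fit$par), pn), rss = rss,
                   converged = fit$info %in% 1:4)
    }
  }
  # a start is itself a feasible point (often a nested-limit optimum); the
  # local optimizer must never report worse
  if (is.null(best) || best_start$rss < best$rss) best <- best_start
  best
}

#' Fit one kinetic model to a trajectory
#'
#' Bounded nonlinear least squares of the model's normalized burden f(t)
#' against the observed post-baseline measurements (the baseline point is
#' structural and contributes no residual). Standard errors come from the
#' Gauss-Newton approximation `RSS/(n-k) (J'J)^-1`; each parameter gets a
#' two-sided Wald p-value against 0 referred to t with n-k degrees of
#' freedom (`phi` uses the same convention). The Gaussian-likelihood AIC is
#' `n log(RSS/n) + 2k`.
#'
#' @param traj A [tumor_trajectory()].
#' @param model Model class label.
#' @param log_scale Fit on log burden instead of the natural scale
#'   (default `FALSE`; the models are stated on the natural normalized
#'   scale).
#' @param aicc Use the small-sample corrected AICc instead of AIC.
#' @return A `model_fit` list: `model`, `estimate`, `se`, `pvalue`, `rss`,
#'   `aic`, `n_points` (post-baseline observations), `df`, `converged`.
#' @export
fit_single_model <- function(traj, model, log_scale = FALSE, aicc = FALSE) {
  model <- match.arg(model, MODEL_CLASSES)
  ob <- post_baseline(traj)
  n <- length(ob$t)
  k <- n_params(model)
  if (n < k) {
    stop(sprintf("subject %s: %d post-baseline point(s) cannot support the %d-parameter %s model",
                 traj$subject_id, n, k, model), call. = FALSE)
  }
  opt <- minimize_rss(model, ob$t, ob$y, log_scale)
  if (!opt$converged || !is.finite(opt$rss)) {
    return(structure(list(model = model, estimate = opt$par,
                          se = opt$par * NA_real_, pvalue = opt$par * NA_real_,
                          rss = opt$rss, aic = NA_real_, n_points = n,
                          df = n - k, converged = FALSE),
                     class = "model_fit"))
  }
  rss <- max(opt$rss, RSS_FLOOR)
  aic <- n * log(rss / n) + 2 * k
  if (aicc) {
    aic <- aic + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  }
  df <- n - k
  se <- pv <- stats::setNames(rep(NA_real_, k), names(opt$par))
  if (df > 0) {
    J <- model_jacobian(model, opt$par, ob$t)
    if (log_scale) {
      f <- evaluate_model(model, opt$par, ob$t)
      J <- J / pmax(f, 1e-12)
    }
    sigma2 <- rss / df
    cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(cov)
      se <- sqrt(pmax(v, 0))
      tval <- ifelse(se > 0, opt$par / se, ifelse(opt$par > 0, Inf, 0))
      pv <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    } else {
      pv[] <- 1  # singular information: parameters not identifiable
      se[] <- Inf
    }
    names(se) <- names(pv) <- names(opt$par)
  }
  structure(list(model = model, estimate = opt$par, se = se, pvalue = pv,
                 rss = opt$rss, aic = aic, n_points = n, df = df,
                 converged = TRUE),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: RSS=%.4g AIC=%.2f converged=%s\n",
              x$model, x$rss, x$aic, x$converged))
  est <- rbind(estimate = x$estimate, se = x$se, p = x$pvalue)
  print(signif(est, 4))
  invisible(x)
}

#' Select among fitted models
#'
#' A model is admissible when it converged, has at least one residual
#' degree of freedom, and every fitted parameter is retained at p < 0.1.
#' Among admissible models the smallest AIC wins; exact AIC ties (within
#' 1e-9) resolve toward the model with fewer parameters. When no model has
#' all parameters significant the subject is "not fit" and `NULL` is
#' returned.
#'
#' @param fits List of `model_fit` objects (one per attempted model).
#' @param p_threshold Retention threshold for each parameter (default 0.1).
#' @return The selected `model_fit`, or `NULL` (not fit).
#' @export
select_model <- function(fits, p_threshold = 0.1) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  ok <- vapply(fits, function(f) {
    isTRUE(f$converged) && f$df >= 1 && all(is.finite(f$pvalue)) &&
      all(f$pvalue < p_threshold)
  }, logical(1))
  if (!any(ok)) return(NULL)
  cand <- fits[ok]
  aic <- vapply(cand, `[[`, numeric(1), "aic")
  k <- vapply(cand, function(f) length(f$estimate), numeric(1))
  best <- which(aic <= min(aic) + 1e-9)
  cand[[best[which.min(k[best])]]]
}

# Closed-form classification for subjects with exactly one post-baseline
# assessment (after the 20% gate): growth only or decay only.
single_point_fit <- function(traj) {
  ob <- post_baseline(traj)
  t1 <- ob$t[1]; y1 <- ob$y[1]
  if (y1 >= 1) {
    model <- "gx"; est <- c(g = log(y1) / t1)
  } else {
    model <- "dx"; est <- c(d = -log(y1) / t1)
  }
  structure(list(model = model, estimate = est,
                 se = stats::setNames(NA_real_, names(est)),
                 pvalue = stats::setNames(NA_real_, names(est)),
                 rss = 0, aic = 1 * log(RSS_FLOOR) + 2, n_points = 1L,
                 df = 0L, converged = TRUE),
            class = "model_fit")
}

#' Classify a subject's tumor trajectory
#'
#' Applies the full per-subject procedure: subjects with exactly one
#' post-baseline assessment and less than a 20% change from baseline are
#' excluded (`single_scan_small_change`; the 20% threshold aligns with the
#' RECIST progression definition for a single assessment); subjects with
#' one qualifying assessment are modeled as growth only or decay only;
#' otherwise every model with enough post-baseline points is fitted and
#' [select_model()] picks the class. dx subjects receive a g-score of
#' exactly 0; the tumor doubling time is reported for g > 0 only.
#'
#' @param traj A [tumor_trajectory()].
#' @param apply_20pct_rule Apply the single-scan < 20%-change exclusion
#'   (default `TRUE`).
#' @param p_threshold Parameter-retention threshold (default 0.1).
#' @inheritParams fit_single_model
#' @return A `subject_result` list: `subject_id`, `classification` (one of
#'   dx/gx/gd/gdphi/not_fit/single_scan_small_change), `g`, `d`, `phi`,
#'   `tdt_days`, `aic`, `n_points`, `flags`, and `selected_fit`.
#' @export
classify_subject <- function(traj, apply_20pct_rule = TRUE,
                             p_threshold = 0.1, log_scale = FALSE,
                             aicc = FALSE) {
  stopifnot(inherits(traj, "tumor_trajectory"))
  ob <- post_baseline(traj)
  n <- length(ob$t)
  if (n < 1L) {
    stop(sprintf("subject %s has no post-baseline assessment",
                 traj$subject_id), call. = FALSE)
  }
  res <- list(subject_id = traj$subject_id, classification = NA_character_,
              g = NA_real_, d = NA_real_, phi = NA_real_,
              tdt_days = NA_real_, aic = NA_real_, n_points = n,
              flags = paste(traj$flags, collapse = ";"), selected_fit = NULL)
  if (n == 1L && apply_20pct_rule && abs(ob$y[1] - 1) < 0.20) {
    res$classification <- "single_scan_small_change"
    class(res) <- "subject_result"
    return(res)
  }
  if (n == 1L) {
    sel <- single_point_fit(traj)
  } else {
    models <- MODEL_CLASSES[vapply(MODEL_CLASSES, n_params, numeric(1)) <= n]
    fits <- lapply(models, function(m)
      fit_single_model(traj, m, log_scale = log_scale, aicc = aicc))
    sel <- select_model(fits, p_threshold = p_threshold)
  }
  if (is.null(sel)) {
    res$classification <- "not_fit"
    class(res) <- "subject_result"
    return(res)
  }
  res$classification <- sel$model
  res$selected_fit <- sel
  res$aic <- sel$aic
  est <- sel$estimate
  res$g <- if (sel$model == "dx") 0 else unname(est[["g"]])
  if ("d" %in% names(est)) res$d <- unname(est[["d"]])
  if ("phi" %in% names(est)) res$phi <- unname(est[["phi"]])
  if (res$g > 0) res$tdt_days <- doubling_time(res$g)
  class(res) <- "subject_result"
  res
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: %s (g=%s/day)\n", x$subject_id,
              x$classification,
              if (is.na(x$g)) "NA" else signif(x$g, 3)))
  invisible(x)
}

#' Fit a whole cohort
#'
#' Runs [classify_subject()] over every evaluable subject of a long-format
#' measurement table. Evaluable subjects have a baseline and at least one
#' post-baseline assessment; others are listed in the `non_evaluable`
#' attribute of the result.
#'
#' @param measurements Data frame with columns `subject_id`, `day`,
#'   `sod_mm` and optionally `arm` (carried through).
#' @param apply_20pct_rule,p_threshold,log_scale,aicc Passed to
#'   [classify_subject()].
#' @return Data frame with one row per evaluable subject: `subject_id`,
#'   (`arm`,) `classification`, `g`, `d`, `phi`, `tdt_days`, `aic`,
#'   `n_points`, `flags`. Attribute `non_evaluable` holds the ids of
#'   subjects with no post-baseline scan.
#' @export
fit_cohort <- function(measurements, apply_20pct_rule = TRUE,
                       p_threshold = 0.1, log_scale = FALSE, aicc = FALSE) {
  req <- c("subject_id", "day", "sod_mm")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0L) {
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_arm <- "arm" %in% names(measurements)
  ids <- unique(as.character(measurements$subject_id))
  rows <- vector("list", length(ids))
  non_eval <- character(0)
  for (i in seq_along(ids)) {
    mi <- measurements[measurements$subject_id == ids[i], , drop = FALSE]
    if (has_arm && length(unique(mi$arm)) > 1L) {
      stop(sprintf("subject %s appears in more than one arm", ids[i]),
           call. = FALSE)
    }
    traj <- tumor_trajectory(ids[i], mi$day, mi$sod_mm)
    if (sum(traj$days > 0) < 1L) {
      non_eval <- c(non_eval, ids[i])
      next
    }
    r <- classify_subject(traj, apply_20pct_rule = apply_20pct_rule,
                          p_threshold = p_threshold, log_scale = log_scale,
                          aicc = aicc)
    rows[[i]] <- data.frame(
      subject_id = r$subject_id,
      arm = if (has_arm) as.character(mi$arm[1]) else NA_character_,
      classification = r$classification, g = r$g, d = r$d, phi = r$phi,
      tdt_days = r$tdt_days, aic = r$aic, n_points = r$n_points,
      flags = r$flags, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), arm = character(0),
                      classification = character(0), g = numeric(0),
                      d = numeric(0), phi = numeric(0), tdt_days = numeric(0),
                      aic = numeric(0), n_points = integer(0),
                      flags = character(0), stringsAsFactors = FALSE)
  }
  if (!has_arm) out$arm <- NULL
  rownames(out) <- NULL
  attr(out, "non_evaluable") <- non_eval
  out
}

#' Tabulate classification counts
#'
#' Counts subjects per classification (and per arm when present), in the
#' style of a trial's model-classification table.
#'
#' @param results Data frame from [fit_cohort()].
#' @return Data frame of counts with one row per classification.
#' @export
classification_counts <- function(results) {
  lev <- c(MODEL_CLASSES, "not_fit", "single_scan_small_change")
  cls <- factor(results$classification, levels = lev)
  if ("arm" %in% names(results)) {
    tab <- table(classification = cls, arm = results$arm)
    as.data.frame.matrix(tab)
  } else {
    as.data.frame(table(classification = cls), responseName = "n")
  }
}
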