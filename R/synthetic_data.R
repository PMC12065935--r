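# Trial-like synthetic cohorts with known kinetic ground truth and
# g-linked survival, emulating the structure of a two-arm metastatic
# breast cancer trial: 6-weekly (+/- 7 day) scans from randomization until
# RECIST-style progression or database lock, baseline-normalized burden
# with multiplicative measurement noise, and OS/PFS whose log-hazard is
# linear in the subject's true growth rate.

#' Define a simulation scenario
#'
#' The defaults mimic a DESTINY-Breast03-like two-arm trial: 232 control
#' (T-DM1-like) vs 245 experimental (T-DXd-like) subjects, model-class
#' mixtures matching the published classification proportions, growth-rate
#' medians among growth-bearing subjects of 0.0018 vs 0.0007/day (so the
#' arm-level medians including regression-only subjects land near
#' 0.0009 vs 0.0002/day), 6-weekly scans with +/- 7-day jitter, a
#' progression-triggered assessment stop, and exponential OS/PFS with
#' log-hazard slope on true g calibrated to the published quartile hazard
#' ratios.
#'
#' @param n_per_arm Named integer vector, subjects per arm (names are arm
#'   labels; first arm is the control).
#' @param mixture Matrix (arms x classes dx/gd/gdphi/gx) of model-class
#'   probabilities per arm; rows must sum to 1.
#' @param g_median,g_sdlog,g_max Log-normal distribution of the true growth
#'   rate g (/day) for growth-bearing classes: per-arm median, common log-sd
#'   and truncation cap.
#' @param d_median,d_sdlog,d_max Log-normal distribution of the true decay
#'   rate d (/day) for decay-bearing classes.
#' @param phi_shape Beta shape parameters for the treatment-sensitive
#'   fraction phi (gdphi subjects).
#' @param noise_sd SD of multiplicative log-normal measurement noise on
#'   burden (0.05 = ~5% radiology error; radiographic error scales with
#'   lesion size).
#' @param baseline_sod_median,baseline_sod_sdlog Log-normal baseline sum of
#'   diameters (mm).
#' @param scan_interval,scan_jitter Nominal days between scans and uniform
#'   jitter half-width ("every 6 weeks (+/- 7 days)").
#' @param progression_threshold Scans stop at the first assessment at or
#'   above this multiple of the nadir (1.2 = RECIST-like +20% from nadir).
#' @param lock_day Database lock, days from first accrual; follow-up and
#'   scans are truncated there.
#' @param accrual_per_week Steady-state accrual rate, subjects/week
#'   (randomization order defines accrual days, used by early-look
#'   analyses).
#' @param accrual_ramp_weeks Site-activation ramp: the accrual rate grows
#'   linearly from 0 to `accrual_per_week` over this many weeks, as in a
#'   multicenter trial's enrollment curve, so early-randomized subjects
#'   carry disproportionately long follow-up at interim cuts.
#' @param single_scan_fraction Per-arm probability that a subject
#'   contributes only the first post-baseline scan (early discontinuation).
#' @param os_base_hazard,os_loghr_per_g Exponential OS hazard at g = 0
#'   (/day) and log-hazard slope per unit g.
#' @param pfs_base_hazard,pfs_loghr_per_g Same for PFS.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(
    n_per_arm = c("T-DM1" = 232, "T-DXd" = 245),
    mixture = rbind(
      "T-DM1" = c(dx = 0.28, gd = 0.41, gdphi = 0.12, gx = 0.19),
      "T-DXd" = c(dx = 0.49, gd = 0.44, gdphi = 0.05, gx = 0.02)
    ),
    g_median = c(0.0018, 0.0007), g_sdlog = 1.5, g_max = 0.01,
    d_median = c(0.010, 0.018), d_sdlog = 0.8, d_max = 0.15,
    phi_shape = c(8, 2),
    noise_sd = 0.05,
    baseline_sod_median = 60, baseline_sod_sdlog = 0.6,
    scan_interval = 42, scan_jitter = 7,
    progression_threshold = 1.2,
    lock_day = 1000, accrual_per_week = 5, accrual_ramp_weeks = 26,
    single_scan_fraction = c(0.10, 0.02),
    os_base_hazard = 1.1e-4, os_loghr_per_g = 650,
    pfs_base_hazard = 5e-4, pfs_loghr_per_g = 650) {
  arms <- names(n_per_arm)
  if (is.null(arms) || any(arms == "")) stop("n_per_arm must be named by arm")
  mixture <- as.matrix(mixture)
  if (!all(arms %in% rownames(mixture))) {
    if (nrow(mixture) == length(arms)) rownames(mixture) <- arms else
      stop("mixture rows must be named by arm", call. = FALSE)
  }
  mixture <- mixture[arms, c("dx", "gd", "gdphi", "gx"), drop = FALSE]
  g_median <- rep_len(g_median, length(arms))
  d_median <- rep_len(d_median, length(arms))
  single_scan_fraction <- rep_len(single_scan_fraction, length(arms))
  if (any(abs(rowSums(mixture) - 1) > 1e-8)) {
    stop("mixture rows must sum to 1", call. = FALSE)
  }
  if (any(c(g_median, d_median, noise_sd) < 0)) {
    stop("rates and noise_sd must be >= 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_scenario")
}

# Upper-truncated log-normal via the inverse CDF (no atom at the cap).
rlnorm_trunc <- function(n, median, sdlog, cap) {
  pmax_u <- stats::plnorm(cap, meanlog = log(median), sdlog = sdlog)
  stats::qlnorm(stats::runif(n, 0, pmax_u), meanlog = log(median),
                sdlog = sdlog)
}

# Scan days for one subject: 6-weekly with uniform jitter, truncated at the
# subject's follow-up horizon.
# Accrual day of the i-th randomized subject under a linear ramp from 0 to
# rate r (subjects/week) over R weeks, then constant r: invert the
# cumulative enrollment curve C(w) = r w^2 / (2R) for w <= R,
# C(w) = r (w - R/2) beyond.
accrual_days <- function(n, r, ramp_weeks) {
  i <- seq_len(n)
  if (ramp_weeks <= 0) return(round((i - 1) * 7 / r))
  n_ramp <- r * ramp_weeks / 2
  w <- ifelse(i <= n_ramp, sqrt(2 * ramp_weeks * i / r), i / r + ramp_weeks / 2)
  round((w - w[1]) * 7)
}

scan_days <- function(followup, interval, jitter) {
  k <- max(0L, floor((followup + jitter) / interval))
  if (k == 0L) return(numeric(0))
  d <- round(interval * seq_len(k) + stats::runif(k, -jitter, jitter))
  d <- d[d > 0 & d <= followup]
  sort(unique(d))
}

#' Simulate a two-arm trial cohort
#'
#' Draws, per subject: arm (permuted-block 1:1 over `n_per_arm`), true model
#' class and kinetic parameters, a jittered 6-weekly scan grid up to the
#' database lock, noiseless normalized burden f(t), multiplicative
#' log-normal measurement noise, a progression-triggered assessment stop
#' (first scan at >= +20% from the nadir), optional truncation to a single
#' post-baseline scan, and OS/PFS from exponential hazards with log-hazard
#' linear in the true g, censored at the subject's lock horizon.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (mandatory; the generator is deterministic given
#'   the seed and scenario).
#' @return List with `measurements` (long data frame: `subject_id`, `arm`,
#'   `day`, `sod_mm`) and `subjects` (one row per subject: arm, accrual day,
#'   OS/PFS times and event flags, true model/g/d/phi, baseline SOD, and
#'   the RECIST-style `response_category` derived from the observed
#'   trajectory).
#' @export
simulate_cohort <- function(scenario, seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  sc <- scenario
  arms <- names(sc$n_per_arm)
  n <- sum(sc$n_per_arm)
  # randomization sequence: permuted assignment respecting arm totals
  arm_seq <- sample(rep(arms, times = sc$n_per_arm))
  accrual <- accrual_days(n, sc$accrual_per_week, sc$accrual_ramp_weeks)
  ids <- sprintf("S%04d", seq_len(n))

  meas <- vector("list", n)
  subj <- vector("list", n)
  for (i in seq_len(n)) {
    a <- arm_seq[i]
    ai <- match(a, arms)
    cls <- sample(colnames(sc$mixture), 1, prob = sc$mixture[a, ])
    g <- if (cls %in% c("gx", "gd", "gdphi"))
      rlnorm_trunc(1, sc$g_median[ai], sc$g_sdlog, sc$g_max) else 0
    d <- if (cls %in% c("dx", "gd", "gdphi"))
      rlnorm_trunc(1, sc$d_median[ai], sc$d_sdlog, sc$d_max) else 0
    phi <- if (cls == "gdphi") stats::rbeta(1, sc$phi_shape[1], sc$phi_shape[2]) else NA_real_
    params <- switch(cls,
      dx = c(d = d), gx = c(g = g), gd = c(g = g, d = d),
      gdphi = c(g = g, d = d, phi = phi))
    base_sod <- stats::rlnorm(1, log(sc$baseline_sod_median),
                              sc$baseline_sod_sdlog)
    followup <- sc$lock_day - accrual[i]
    days <- scan_days(followup, sc$scan_interval, sc$scan_jitter)
    f <- evaluate_model(cls, params, days)
    noise <- if (sc$noise_sd > 0) exp(stats::rnorm(length(days), 0, sc$noise_sd)) else 1
    sod <- base_sod * f * noise
    # progression-triggered stop: first scan >= threshold x running nadir
    if (length(days) > 0) {
      nadir <- c(base_sod, cummin(sod))[seq_along(sod)]  # nadir before scan j
      prog <- which(sod >= sc$progression_threshold * nadir)
      if (length(prog) > 0) {
        keep <- seq_len(prog[1])
        days <- days[keep]; sod <- sod[keep]
      }
    }
    if (length(days) > 1 && stats::runif(1) < sc$single_scan_fraction[ai]) {
      days <- days[1]; sod <- sod[1]
    }
    h_os <- sc$os_base_hazard * exp(sc$os_loghr_per_g * g)
    h_pfs <- sc$pfs_base_hazard * exp(sc$pfs_loghr_per_g * g)
    os_raw <- stats::rexp(1, h_os)
    pfs_raw <- stats::rexp(1, h_pfs)
    os_days <- min(os_raw, followup)
    os_event <- as.integer(os_raw <= followup)
    pfs_days <- min(pfs_raw, os_days)
    pfs_event <- as.integer(pfs_raw <= os_days)
    resp <- if (length(days) > 0) {
      response_from_changes(min(sod / base_sod) - 1)
    } else NA_character_
    meas[[i]] <- data.frame(
      subject_id = ids[i], arm = a,
      day = c(0, days), sod_mm = c(base_sod, sod),
      stringsAsFactors = FALSE)
    subj[[i]] <- data.frame(
      subject_id = ids[i], arm = a, accrual_day = accrual[i],
      os_days = os_days, os_event = os_event,
      pfs_days = pfs_days, pfs_event = pfs_event,
      true_model = cls, true_g = g, true_d = d, true_phi = phi,
      baseline_sod = base_sod, response_category = resp,
      stringsAsFactors = FALSE)
  }
  list(measurements = do.call(rbind, meas), subjects = do.call(rbind, subj))
}

response_from_changes <- function(best_change) {
  if (best_change <= -0.30) "responder"
  else if (best_change >= 0.20) "progression"
  else "stable"
}

#' RECIST-style response category of a trajectory
#'
#' Bins the best percent change from baseline of the observed sum of
#' diameters: <= -30% responder, >= +20% progression, otherwise stable.
#'
#' @param traj A [tumor_trajectory()], or a numeric vector of normalized
#'   burdens (baseline = 1) with at least one post-baseline value.
#' @return `"responder"`, `"stable"` or `"progression"`.
#' @export
derive_response_category <- function(traj) {
  y <- if (inherits(traj, "tumor_trajectory")) {
    post_baseline(traj)$y
  } else as.numeric(traj[-1])
  if (length(y) < 1L) stop("needs at least one post-baseline scan",
                           call. = FALSE)
  response_from_changes(min(y) - 1)
}
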