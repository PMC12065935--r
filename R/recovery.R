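# Calibration experiments for the per-subject estimator: parameter
# recovery on a fixed protocol scan grid, and replicated early-look power.
# These are run as designed experiments without the progression-triggered
# stop, to isolate estimator behavior from trial stopping mechanics.

#' Simulate one trajectory on the protocol scan grid
#'
#' Generates a single subject's trajectory from a given model class and
#' parameters on the 6-weekly (+/- 7-day jitter) schedule over a fixed
#' follow-up, with multiplicative log-normal noise and no
#' progression-triggered stop.
#'
#' @param model Model class label.
#' @param params Named parameter vector for the model.
#' @param noise_sd Multiplicative log-normal noise SD.
#' @param followup Follow-up in days (default 378 = nine 6-week cycles).
#' @param baseline_sod Baseline sum of diameters in mm.
#' @param subject_id Identifier for the trajectory.
#' @return A [tumor_trajectory()].
#' @export
simulate_trajectory <- function(model, params, noise_sd = 0.05,
                                followup = 378, baseline_sod = 60,
                                subject_id = "S1") {
  days <- scan_days(followup, 42, 7)
  f <- evaluate_model(model, params, days)
  noise <- if (noise_sd > 0) exp(stats::rnorm(length(days), 0, noise_sd)) else 1
  tumor_trajectory(subject_id, c(0, days), baseline_sod * c(1, f * noise))
}

#' Parameter-recovery study
#'
#' For each model class, simulates `n_per_class` trajectories on the
#' protocol scan grid with parameters drawn from the scenario's truncated
#' log-normal/beta distributions, classifies each with the full per-subject
#' procedure, and summarizes classification agreement with the generating
#' class and the relative error of the recovered g.
#'
#' @param n_per_class Trajectories per model class.
#' @param noise_sd Multiplicative measurement noise SD (0 for noise-free).
#' @param seed Integer seed.
#' @param scenario A [sim_scenario()] supplying the parameter
#'   distributions (first arm's medians are used).
#' @param followup Follow-up in days.
#' @return List with `table` (one row per trajectory: true class/params,
#'   classification, fitted g, relative g error) and `summary` (per-class
#'   agreement and median |relative g error|).
#' @export
recovery_study <- function(n_per_class = 500, noise_sd = 0.05, seed = 1,
                           scenario = sim_scenario(), followup = 378) {
  set.seed(as.integer(seed))
  sc <- scenario
  rows <- list()
  for (cls in MODEL_CLASSES) {
    for (i in seq_len(n_per_class)) {
      g <- if (cls != "dx") rlnorm_trunc(1, sc$g_median[1], sc$g_sdlog, sc$g_max) else 0
      d <- if (cls != "gx") rlnorm_trunc(1, sc$d_median[1], sc$d_sdlog, sc$d_max) else 0
      phi <- if (cls == "gdphi") stats::rbeta(1, sc$phi_shape[1], sc$phi_shape[2]) else NA
      params <- switch(cls, dx = c(d = d), gx = c(g = g),
                       gd = c(g = g, d = d), gdphi = c(g = g, d = d, phi = phi))
      traj <- simulate_trajectory(cls, params, noise_sd = noise_sd,
                                  followup = followup,
                                  subject_id = sprintf("%s_%04d", cls, i))
      r <- classify_subject(traj)
      rows[[length(rows) + 1L]] <- data.frame(
        true_model = cls, true_g = g, true_d = d, true_phi = phi,
        classification = r$classification, g_hat = r$g,
        rel_g_error = if (g > 0 && !is.na(r$g)) (r$g - g) / g else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(MODEL_CLASSES, function(cls) {
    ti <- tab[tab$true_model == cls, , drop = FALSE]
    data.frame(true_model = cls, n = nrow(ti),
               agreement = mean(ti$classification == cls),
               median_abs_rel_g_error = stats::median(abs(ti$rel_g_error),
                                                      na.rm = TRUE),
               median_rel_g_error = stats::median(ti$rel_g_error, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = smry)
}

#' Replicated early-look power
#'
#' Repeats the simulate / early-look / Mann-Whitney pipeline over
#' independently seeded replicates of a scenario and reports how often the
#' k-subject interim analysis detects the arm difference.
#'
#' @param scenario A [sim_scenario()].
#' @param k Subjects in each interim look.
#' @param n_reps Number of replicates.
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param followup_floor Follow-up floor in days (default 98 = 14 weeks).
#' @return List with `p_values` (length `n_reps`) and `power`.
#' @export
early_look_power <- function(scenario, k = 60, n_reps = 100, alpha = 0.05,
                             seed = 1, followup_floor = 98) {
  pv <- vapply(seq_len(n_reps), function(r) {
    cohort <- simulate_cohort(scenario, seed = as.integer(seed) + r)
    el <- early_look(cohort$measurements, cohort$subjects, k = k,
                     followup_floor = followup_floor)
    el$comparison$p_value
  }, numeric(1))
  list(p_values = pv, power = mean(pv < alpha))
}
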