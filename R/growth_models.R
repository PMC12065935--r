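#' @keywords internal
"_PACKAGE"

# The four candidate kinetic models for baseline-normalized tumor burden
# f(t), t in days since the baseline scan:
#   dx     : f(t) = exp(-d t)                          (regression only)
#   gx     : f(t) = exp(g t)                           (growth only)
#   gd     : f(t) = exp(-d t) + exp(g t) - 1           (additive mixture)
#   gdphi  : f(t) = phi exp(-d t) + (1 - phi) exp(g t) (convex mixture;
#            phi = treatment-sensitive tumor fraction)
# All satisfy f(0) = 1 for any valid parameters.

MODEL_CLASSES <- c("dx", "gx", "gd", "gdphi")

#' Model classes for tumor burden kinetics
#'
#' Returns the labels of the four candidate bi-exponential models of
#' baseline-normalized tumor burden: `dx` (exponential regression only),
#' `gx` (exponential growth only), `gd` (additive regression + regrowth)
#' and `gdphi` (convex mixture with a treatment-sensitive fraction `phi`).
#'
#' @return Character vector of the four model labels.
#' @export
model_classes <- function() MODEL_CLASSES

#' @rdname model_classes
#' @param model One of `"dx"`, `"gx"`, `"gd"`, `"gdphi"`.
#' @return `model_params()` returns the names of the free parameters of
#'   `model`; `n_params()` returns how many there are (1, 1, 2, 3).
#' @export
model_params <- function(model) {
  switch(match.arg(model, MODEL_CLASSES),
    dx    = "d",
    gx    = "g",
    gd    = c("g", "d"),
    gdphi = c("g", "d", "phi")
  )
}

#' @rdname model_classes
#' @export
n_params <- function(model) length(model_params(model))

check_params <- function(model, params) {
  need <- model_params(model)
  miss <- setdiff(need, names(params))
  if (length(miss) > 0L) {
    stop(sprintf("model '%s' requires parameter(s): %s",
                 model, paste(miss, collapse = ", ")), call. = FALSE)
  }
  p <- as.numeric(params[need])
  names(p) <- need
  if (any(!is.finite(p))) stop("non-finite model parameter", call. = FALSE)
  if (any(p[intersect(need, c("g", "d"))] < 0)) {
    stop("rates g and d must be >= 0", call. = FALSE)
  }
  if ("phi" %in% need && (p[["phi"]] < 0 || p[["phi"]] > 1)) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' Evaluate a tumor burden model
#'
#' Computes the baseline-normalized tumor burden f(t) for one of the four
#' kinetic model classes. Time is measured in days since the baseline scan
#' and burden is unitless (f(0) = 1 by construction). Rates `g` and `d` are
#' per day; `phi` is the treatment-sensitive fraction of the tumor.
#'
#' @param model Model class label, one of [model_classes()].
#' @param params Named numeric vector or list supplying the parameters the
#'   model uses (`g`, `d`, `phi` as applicable). Parameters the model does
#'   not use are ignored; missing required parameters are an error.
#' @param t Numeric vector of times in days, `t >= 0`.
#' @return Numeric vector of normalized burdens, same length as `t`.
#' @examples
#' evaluate_model("gd", c(g = 0.002, d = 0.02), t = c(0, 42, 84))
#' evaluate_model("dx", c(d = log(2) / 693.147), t = 693.147) # 0.5
#' @export
evaluate_model <- function(model, params, t) {
  model <- match.arg(model, MODEL_CLASSES)
  p <- check_params(model, params)
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  switch(model,
    dx    = exp(-p[["d"]] * t),
    gx    = exp(p[["g"]] * t),
    gd    = exp(-p[["d"]] * t) + exp(p[["g"]] * t) - 1,
    gdphi = p[["phi"]] * exp(-p[["d"]] * t) +
            (1 - p[["phi"]]) * exp(p[["g"]] * t)
  )
}

# Jacobian of f(t) wrt the model's free parameters (columns in
# model_params() order). Used for Gauss-Newton covariance / Wald tests.
model_jacobian <- function(model, p, t) {
  switch(model,
    dx    = cbind(d = -t * exp(-p[["d"]] * t)),
    gx    = cbind(g = t * exp(p[["g"]] * t)),
    gd    = cbind(g = t * exp(p[["g"]] * t),
                  d = -t * exp(-p[["d"]] * t)),
    gdphi = cbind(g = (1 - p[["phi"]]) * t * exp(p[["g"]] * t),
                  d = -p[["phi"]] * t * exp(-p[["d"]] * t),
                  phi = exp(-p[["d"]] * t) - exp(p[["g"]] * t))
  )
}

#' Tumor doubling time
#'
#' Converts a growth rate `g` (per day) into the tumor doubling time
#' ln(2)/g in days. Defined only for subjects with detectable growth
#' (g > 0); regression-only (dx) subjects have no doubling time.
#'
#' @param g Growth rate per day, strictly positive.
#' @return Doubling time in days.
#' @examples
#' doubling_time(0.00693147) # 100 days
#' @export
doubling_time <- function(g) {
  g <- as.numeric(g)
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("doubling time is defined only for g > 0", call. = FALSE)
  }
  log(2) / g
}

#' Extract the g-score from a subject result
#'
#' The g-score is the fitted growth rate of the selected model: `g` for
#' gx/gd/gdphi subjects and exactly 0 for dx subjects, whose data show
#' regression with no detectable growth. Subjects that could not be
#' classified to a model (`not_fit`, `single_scan_small_change`,
#' non-evaluable) have no g-score.
#'
#' @param result A single-subject result: either a row of the data frame
#'   returned by [fit_cohort()] or the list returned by
#'   [classify_subject()].
#' @return Growth rate per day (0 for dx).
#' @export
gscore_of <- function(result) {
  cls <- if (is.data.frame(result)) result$classification[1] else result$classification
  if (!cls %in% MODEL_CLASSES) {
    stop(sprintf("subject with classification '%s' has no g-score", cls),
         call. = FALSE)
  }
  if (cls == "dx") return(0)
  g <- if (is.data.frame(result)) result$g[1] else result$g
  as.numeric(g)
}

#' Display helpers for rate units
#'
#' Rates are stored per day; published tables display g in units of
#' 1e-2/day and doubling times in units of 100 days. These helpers apply
#' that display convention.
#'
#' @param g Rate per day.
#' @param tdt Doubling time in days.
#' @return Rescaled numeric value.
#' @export
g_display <- function(g) g * 100

#' @rdname g_display
#' @export
tdt_display <- function(tdt) tdt / 100
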