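# Independent oracles used across the suite. These deliberately avoid the
# package's own optimization / survival code paths.

# Dense log-grid least-squares search for the 1- and 2-parameter models:
# a coarse pass over the whole box, then a 10x finer local pass around the
# coarse optimum (narrow curved valleys in the gd surface need it).
grid_search_fit <- function(model, t, y, n_grid = 200,
                            lo = 1e-5, hi = 0.3) {
  step <- log(hi / lo) / (n_grid - 1)
  axis <- function(center = NULL) {
    if (is.null(center)) c(0, exp(seq(log(lo), log(hi), length.out = n_grid)))
    else if (center == 0) c(0, exp(seq(log(lo), log(lo) + 3 * step,
                                       length.out = 31)))
    else c(0, exp(seq(log(center) - 3 * step, min(log(center) + 3 * step,
                                                  log(hi)),
                      length.out = 61)))
  }
  rss_of <- function(params) sum((y - evaluate_model(model, params, t))^2)
  search1 <- function(pn, grid) {
    rss <- vapply(grid, function(v) rss_of(stats::setNames(v, pn)), numeric(1))
    i <- which.min(rss)
    list(par = stats::setNames(grid[i], pn), rss = rss[i])
  }
  search2 <- function(ggrid, dgrid) {
    best <- NULL
    for (g in ggrid) {
      rss <- vapply(dgrid, function(d) rss_of(c(g = g, d = d)), numeric(1))
      i <- which.min(rss)
      if (is.null(best) || rss[i] < best$rss) {
        best <- list(par = c(g = g, d = dgrid[i]), rss = rss[i])
      }
    }
    best
  }
  if (model %in% c("dx", "gx")) {
    pn <- if (model == "dx") "d" else "g"
    best <- search1(pn, axis())
    for (it in 1:3) best <- search1(pn, axis(best$par[[pn]]))
    best$step <- step  # agreement judged at coarse-grid resolution
    best
  } else if (model == "gd") {
    # iterate the local refinement: the gd RSS surface has narrow diagonal
    # valleys that a single local pass can miss
    best <- search2(axis(), axis())
    for (it in 1:4) {
      best <- search2(axis(best$par[["g"]]), axis(best$par[["d"]]))
    }
    best$step <- step
    best
  } else stop("grid oracle covers dx/gx/gd only")
}

# Hand product-limit estimator: returns step function values at event times.
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

km_surv_at <- function(km, t0) {
  if (nrow(km) == 0 || t0 < km$time[1]) return(1)
  km$surv[max(which(km$time <= t0))]
}

# Brute-force Cox partial likelihood (Breslow form; fixtures use distinct
# event times so Breslow = Efron = exact).
cox_brute <- function(time, event, x) {
  nll <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -ll
  }
  stats::optimize(nll, interval = c(-20, 20), tol = 1e-10)$minimum
}

# Exhaustive pair-counting Harrell concordance for a risk score (higher
# score = worse prognosis expected, i.e. shorter time).
concordance_pairs <- function(time, event, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # order the pair by time; the earlier must be an event to compare
      a <- i; b <- j
      if (time[b] < time[a]) { a <- j; b <- i }
      if (time[a] == time[b]) next  # fixtures use distinct times
      if (event[a] == 0) next
      if (risk[a] > risk[b]) conc <- conc + 1
      else if (risk[a] < risk[b]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# Small deterministic survival fixture generator.
make_surv_fixture <- function(n, seed, p_censor = 0.3, beta = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, rate = 0.01 * exp(beta * x))
  cens <- stats::rexp(n, rate = 0.01 * p_censor / (1 - p_censor))
  time <- pmin(t_ev, cens)
  time <- time + stats::runif(n, 0, 1e-3)  # break ties
  data.frame(time = time, event = as.integer(t_ev <= cens), x = x)
}

# A parameter direction is identifiable at grid resolution if moving it two
# coarse steps off the oracle optimum visibly degrades the fit; flat
# directions (e.g. d in a gd fit of near-pure growth) carry no information
# and are excluded from parameter-agreement checks.
oracle_param_identifiable <- function(model, par, pn, step, t, y) {
  rss_of <- function(p) sum((y - evaluate_model(model, p, t))^2)
  base <- rss_of(par)
  worst <- Inf
  for (fac in c(exp(-2 * step), exp(2 * step))) {
    p2 <- par
    p2[[pn]] <- par[[pn]] * fac
    worst <- min(worst, rss_of(p2))
  }
  worst > base * 1.02 + 1e-12
}

# First seed at or above `from` whose n-subject fixture has an interior
# partial-likelihood optimum (no monotone likelihood / separation), judged
# by the brute-force oracle alone.
nonseparated_fixture <- function(n, from, beta = 1) {
  for (s in from:(from + 50)) {
    fx <- make_surv_fixture(n, seed = s, beta = beta)
    b <- cox_brute(fx$time, fx$event, fx$x)
    if (abs(b) < 5 && sum(fx$event) >= 3) return(fx)
  }
  stop("no non-separated fixture found")
}
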