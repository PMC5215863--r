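#' Negative binomial log-pmf with library-size scaling
#'
#' Mean-size parameterization: a state's emission has mean `mu * s` under
#' size factor `s` and dispersion `size` r, so
#' `pmf(x) = Gamma(r+x) / (x! Gamma(r)) * (mu*s/(r+mu*s))^x * (r/(r+mu*s))^r`
#' with variance `mu*s + (mu*s)^2 / r` (always above the mean; the Poisson
#' limit is approached as r grows).
#'
#' @param x non-negative integer count(s).
#' @param mu emission mean at size factor 1 (> 0).
#' @param size dispersion r (> 0).
#' @param s size factor (> 0); multiplies the mean.
#' @return Log-probability, vectorized over `x`.
#' @export
nb_log_pmf <- function(x, mu, size, s = 1) {
  if (any(x < 0) || any(x != floor(x))) stop("`x` must be non-negative integers")
  if (any(mu <= 0) || any(size <= 0) || any(s <= 0))
    stop("`mu`, `size` and `s` must be positive")
  dnbinom(x, size = size, mu = mu * s, log = TRUE)
}

# unit Gauss-Legendre nodes/weights on [0, 1], cached per node count
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_cache[[key]]
}

# log integrand of the Poisson-lognormal in m = log(lambda):
#   h(m) = x*m - exp(m) - lgamma(x+1) - (m - mu)^2 / (2 sigma^2) - log(sigma sqrt(2 pi))
# h is strictly concave (h'' = -exp(m) - 1/sigma^2), so the mode is unique,
# Newton iteration on h' converges, and the sub-level set {h > h(mode) - drop}
# is an interval found by bisection. Gauss-Legendre on that interval then
# converges spectrally for this smooth integrand.
.poilog_log_pmf_one <- function(x, mu, sigma, nodes, drop = 45) {
  h <- function(m) x * m - exp(m) - (m - mu)^2 / (2 * sigma^2)
  m <- if (x > 0) log(x) else mu # start near the dominant factor's mode
  for (i in 1:100) {
    em <- exp(m)
    step <- (x - em - (m - mu) / sigma^2) / (-em - 1 / sigma^2)
    m <- m - step
    if (abs(step) < 1e-12) break
  }
  h0 <- h(m)
  cut <- h0 - drop
  bracket <- function(dir) { # dir = +1 / -1: side of the mode
    w <- 1
    while (h(m + dir * w) > cut) w <- w * 2
    lo <- 0; hi <- w
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (h(m + dir * mid) > cut) lo <- mid else hi <- mid
    }
    m + dir * hi
  }
  a <- bracket(-1); b <- bracket(1)
  z <- a + (b - a) * nodes$x
  hz <- h(z) - h0
  h0 + log(sum(nodes$w * exp(hz))) + log(b - a) -
    lgamma(x + 1) - log(sigma) - 0.5 * log(2 * pi)
}

#' Poisson-lognormal log-pmf with library-size scaling
#'
#' The Poisson-lognormal is a Poisson whose rate is lognormal:
#' `pmf(x) = integral Poisson(x | lambda) * Normal(log lambda | mu_log + log s, sigma) dlambda`.
#' No closed form exists; the integral is evaluated by deterministic
#' fixed-node Gauss-Legendre quadrature in log-rate space over the
#' bracketed support of the (strictly concave) log integrand, accurate to
#' well below 1e-8 in absolute pmf error for x <= 100, sigma <= 4.
#'
#' @param x non-negative integer count(s).
#' @param mu_log mean of log rate at size factor 1.
#' @param sigma standard deviation of log rate (> 0).
#' @param s size factor (> 0); shifts `mu_log` by `log(s)` so the rate
#'   scale, and hence the mean `exp(mu_log + sigma^2/2) * s`, is multiplied
#'   by `s`.
#' @param n_nodes Gauss-Legendre node count (default 60).
#' @return Log-probability, vectorized over `x`.
#' @export
poilog_log_pmf <- function(x, mu_log, sigma, s = 1, n_nodes = 60) {
  if (any(x < 0) || any(x != floor(x))) stop("`x` must be non-negative integers")
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  if (any(s <= 0)) stop("`s` must be positive")
  nodes <- .gl_nodes(n_nodes)
  mu <- mu_log + log(s)
  vapply(x, .poilog_log_pmf_one, 0.0, mu = mu, sigma = sigma, nodes = nodes)
}

#' Group bin counts for the weighted emission objective
#'
#' The per-state emission M-step objective `sum_t w_t log psi(o_t)` touches
#' every bin; because the pmf depends on a bin only through its count (and
#' its cell type's size factor), pooling the posterior weights of equal
#' counts first gives the identical objective
#' `sum_c f_c log psi(c)` over the far smaller set of unique counts,
#' with `f_c = sum over bins with count c of w_t`.
#'
#' @param counts integer vector (one track's binned counts, possibly
#'   concatenated over cell types).
#' @param weights non-negative per-bin weights (state posteriors); same
#'   length as `counts`.
#' @param cell_type optional per-bin cell-type labels; when supplied,
#'   grouping keys are (count, cell type) pairs so per-cell-type size
#'   factors stay applicable.
#' @return A tibble with columns `count`, `f` and (if given) `cell_type`.
#' @export
group_counts <- function(counts, weights, cell_type = NULL) {
  if (length(counts) != length(weights))
    stop("`counts` and `weights` must have the same length")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  key <- if (is.null(cell_type)) {
    tibble::tibble(count = counts, f = weights)
  } else {
    if (length(cell_type) != length(counts))
      stop("`cell_type` must match `counts` in length")
    tibble::tibble(count = counts, cell_type = cell_type, f = weights)
  }
  grp <- if (is.null(cell_type)) "count" else c("count", "cell_type")
  out <- dplyr::summarise(dplyr::group_by(key, dplyr::across(dplyr::all_of(grp))),
                          f = sum(.data$f), .groups = "drop")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(grp)))
}

# weighted log-likelihood of grouped counts under one emission family;
# sf maps cell_type -> emission-mean multiplier (scalar 1 if absent)
.grouped_loglik <- function(grouped, family, pars, sf = NULL) {
  s <- if (is.null(sf) || is.null(grouped[["cell_type"]])) 1 else unname(sf[grouped[["cell_type"]]])
  lp <- if (family == "negbinom") {
    nb_log_pmf(grouped$count, pars[1], pars[2], s = s)
  } else {
    if (length(unique(s)) == 1) {
      poilog_log_pmf(grouped$count, pars[1], pars[2], s = s[1])
    } else {
      vapply(seq_along(grouped$count), function(i)
        poilog_log_pmf(grouped$count[i], pars[1], pars[2], s = s[i]), 0.0)
    }
  }
  sum(grouped$f * pmax(lp, .PROB_FLOOR_LOG))
}

#' Weighted maximum-likelihood fit of one emission distribution
#'
#' Maximizes the grouped weighted log-likelihood
#' `sum_c f_c log psi(c)` over the emission parameters by bounded
#' quasi-Newton (L-BFGS-B) in log-parameter space (negative binomial:
#' `(log mu, log r)`; Poisson-lognormal: `(mu_log, log sigma)`), with three
#' restarts from perturbed initial values. The returned parameters never
#' score below the initial ones.
#'
#' @param grouped output of [group_counts()].
#' @param family `"negbinom"` or `"poilog"`.
#' @param init named initial parameters (`mu`/`size` or `mu_log`/`sigma`).
#' @param size_factors optional named vector mapping cell types to
#'   emission-mean multipliers (used when `grouped` carries cell types).
#' @return Named parameter vector of the same shape as `init`, with the
#'   achieved objective in attribute `objective`.
#' @export
fit_emission <- function(grouped, family = c("negbinom", "poilog"),
                         init = NULL, size_factors = NULL) {
  family <- match.arg(family)
  if (sum(grouped$f) <= 0) stop("grouped weights sum to zero")
  s <- if (is.null(size_factors) || is.null(grouped[["cell_type"]])) {
    rep(1, nrow(grouped))
  } else unname(size_factors[grouped[["cell_type"]]])
  wmean <- sum(grouped$f * grouped$count / s) / sum(grouped$f)
  if (wmean <= 0) { # all posterior weight on zero counts: clamp the mean
    mu_floor <- 1e-3
    pars <- if (family == "negbinom") c(mu = mu_floor, size = 10) else
      c(mu_log = log(mu_floor), sigma = 0.5)
    attr(pars, "objective") <- .grouped_loglik(
      grouped, family, pars, setNames(s, grouped[["cell_type"]]))
    return(pars)
  }
  sf <- setNames(s, if (is.null(grouped[["cell_type"]])) NULL else grouped[["cell_type"]])

  if (family == "negbinom") {
    wvar <- sum(grouped$f * (grouped$count / s - wmean)^2) / sum(grouped$f)
    r0 <- if (is.null(init)) {
      if (wvar > wmean) wmean^2 / (wvar - wmean) else 100
    } else unname(init["size"])
    r0 <- min(max(r0, 1e-4), 1e8)
    if (length(unique(s)) == 1) {
      # stationarity: the weighted MLE of mu is the weighted sample mean for
      # every r, so mu is profiled out exactly and only r is optimized
      mu_hat <- wmean
      obj1 <- function(lr) -.grouped_loglik(grouped, family, c(mu_hat, exp(lr)), sf)
      best <- list(par = log(r0), value = obj1(log(r0)))
      for (st in log(r0) + c(0, 1.5, -1.5, 3)) {
        fit <- tryCatch(
          optim(st, obj1, method = "L-BFGS-B", lower = log(1e-4),
                upper = log(1e8), control = list(maxit = 200)),
          error = function(e) NULL)
        if (!is.null(fit) && is.finite(fit$value) && fit$value < best$value)
          best <- fit
      }
      pars <- c(mu = mu_hat, size = exp(best$par[1]))
      attr(pars, "objective") <- -best$value
      return(pars)
    }
    if (is.null(init)) init <- c(mu = wmean, size = r0)
    theta0 <- log(pmax(unname(init[c("mu", "size")]), 1e-8))
    lower <- c(log(1e-6), log(1e-4)); upper <- c(log(1e8), log(1e8))
    obj <- function(th) -.grouped_loglik(grouped, family, exp(th), sf)
    wrap <- function(p) setNames(exp(p), c("mu", "size"))
  } else {
    if (is.null(init)) {
      lm0 <- log(wmean)
      init <- c(mu_log = lm0 - 0.125, sigma = 0.5)
    }
    theta0 <- c(unname(init["mu_log"]), log(max(unname(init["sigma"]), 0.05)))
    lower <- c(-30, log(0.05)); upper <- c(30, log(6))
    obj <- function(th) -.grouped_loglik(grouped, family, c(th[1], exp(th[2])), sf)
    wrap <- function(p) setNames(c(p[1], exp(p[2])), c("mu_log", "sigma"))
  }

  # fixed perturbation pattern: deterministic without touching the RNG stream
  perturb <- list(c(0, 0), c(0.4, -0.4), c(-0.4, 0.4), c(0.2, 0.2))
  starts <- lapply(perturb, function(p) pmin(pmax(theta0 + p, lower), upper))
  best <- list(par = theta0, value = obj(theta0))
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best$value) best <- fit
  }
  pars <- wrap(best$par)
  attr(pars, "objective") <- -best$value
  pars
}

#' Mean of an emission distribution at size factor 1
#'
#' Negative binomial: `mu`. Poisson-lognormal:
#' `exp(mu_log + sigma^2 / 2)` (the lognormal rate's mean).
#'
#' @param params named parameter vector.
#' @param family emission family.
#' @return The distribution mean.
#' @export
emission_mean <- function(params, family = c("negbinom", "poilog")) {
  family <- match.arg(family)
  if (family == "negbinom") unname(params["mu"])
  else unname(exp(params["mu_log"] + params["sigma"]^2 / 2))
}
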