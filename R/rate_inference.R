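# Estimation of cutting/repair rates from observed vial counts:
# closed-form inversions of the viability model, binomial / beta-binomial
# maximum likelihood with profile-likelihood intervals, and exact tests.

#' Closed-form germline cut-rate estimate
#'
#' In a male drive-parent cross there is no maternal deposition, so the
#' only source of excess egg mortality under the any-cut-lethal model is
#' germline disruption of the single transmitted target allele:
#' `v_drive_male = v_control * (1 - c_germline)`, hence
#' `c_germline = 1 - v_drive_male / v_control`.
#'
#' @param v_drive_male Egg-to-adult viability of male drive-parent crosses.
#' @param v_control Egg-to-adult viability of control crosses (> 0).
#' @return Estimated germline cut rate in \[0, 1\].
#' @export
#' @examples
#' estimate_germline_rate(0.75, 0.83)  # ~0.096, the "~10%" estimate
estimate_germline_rate <- function(v_drive_male, v_control) {
  if (!is.numeric(v_control) || v_control <= 0 || v_control > 1)
    stop("`v_control` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(v_drive_male) || v_drive_male < 0 || v_drive_male > 1)
    stop("`v_drive_male` must lie in [0, 1]", call. = FALSE)
  if (v_drive_male > v_control) {
    warning("drive-cross viability exceeds control; clamping estimate to 0")
    return(0)
  }
  1 - v_drive_male / v_control
}

#' Closed-form embryo cut-rate estimate
#'
#' In a female drive-parent cross both the maternally and paternally
#' inherited wild-type target alleles are exposed to maternally deposited
#' Cas9/gRNA, so under the any-cut-lethal model
#' `v_drive_female = v_control * (1 - c_germline) * (1 - c_embryo)^2`,
#' giving the per-allele rate
#' `c_embryo = 1 - sqrt(v_drive_female / (v_control * (1 - c_germline)))`.
#'
#' @param v_drive_female Egg-to-adult viability of female drive crosses.
#' @param v_control Control viability.
#' @param c_germline Germline cut rate (e.g. from
#'   [estimate_germline_rate()]).
#' @return Estimated per-allele embryo cut rate.
#' @export
#' @examples
#' cg <- estimate_germline_rate(0.75, 0.83)
#' estimate_embryo_rate(0.72, 0.83, cg)  # ~0.02, the "~2%" estimate
estimate_embryo_rate <- function(v_drive_female, v_control, c_germline) {
  stopifnot(is.numeric(v_drive_female), is.numeric(v_control),
            is.numeric(c_germline))
  if (v_control * (1 - c_germline) <= 0)
    stop("expected viability v_control * (1 - c_germline) must be > 0",
         call. = FALSE)
  ratio <- v_drive_female / (v_control * (1 - c_germline))
  if (ratio > 1) {
    warning("female drive-cross viability above expectation; returning 0")
    return(0)
  }
  1 - sqrt(ratio)
}

#' Closed-form embryo resistance-allele formation rate
#'
#' For a drive whose germline cuts are repaired to functional recoded
#' alleles (so male crosses show full viability), reduced female-cross
#' viability reflects embryo resistance-allele formation, where a single
#' disrupted allele kills the egg (haplolethal target).  With `n_cut_sites`
#' independent sites per allele and per-site rate `r`, the egg dies with
#' probability `1 - (1 - r)^n_cut_sites`, so
#' `r = 1 - (v_drive_female / v_control)^(1 / n_cut_sites)`.
#'
#' @param v_drive_female Female drive-cross viability.
#' @param v_control Control viability (> 0).
#' @param n_cut_sites Number of available cut sites (>= 1).
#' @return Estimated per-site embryo resistance rate.
#' @export
#' @examples
#' estimate_embryo_resistance_rate(0.66, 0.83, 1)  # ~0.205 ("20%")
#' estimate_embryo_resistance_rate(0.66, 0.83, 2)  # ~0.108 ("10%")
estimate_embryo_resistance_rate <- function(v_drive_female, v_control,
                                            n_cut_sites) {
  n_cut_sites <- as.integer(n_cut_sites)
  if (is.na(n_cut_sites) || n_cut_sites < 1L)
    stop("`n_cut_sites` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(v_control) || v_control <= 0 || v_control > 1)
    stop("`v_control` must lie in (0, 1]", call. = FALSE)
  ratio <- v_drive_female / v_control
  if (ratio > 1) {
    warning("female drive-cross viability above control; returning 0")
    return(0)
  }
  1 - ratio^(1 / n_cut_sites)
}

# --- likelihood machinery -------------------------------------------------

# Binomial log-density tolerant of non-integer counts (used so that
# noiseless expected-count fixtures are handled exactly); the lgamma form
# of the binomial coefficient avoids integer-rounding warnings.
.lcoef <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

.lbinom <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  .lcoef(n, k) + k * log(p) + (n - k) * log1p(-p)
}

# Beta-binomial log-density parameterized by mean p and intra-class
# correlation rho in (0, 1): alpha = p(1-rho)/rho, beta = (1-p)(1-rho)/rho.
.lbetabinom <- function(k, n, p, rho) {
  if (rho <= 0) return(.lbinom(k, n, p))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  s <- (1 - rho) / rho
  a <- p * s
  b <- (1 - p) * s
  .lcoef(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

.ml_free_params <- c("c_germline", "c_embryo", "p_hdr_functional",
                     "baseline_viability")

# Build the log-likelihood closure for a vial dataset.  theta is a named
# vector of free parameters on the raw [0,1] scale (plus "rho" when
# overdispersed).
.make_loglik <- function(dataset, cross_specs, arch, free, base_params,
                         overdispersion) {
  # hoist per-cross observation vectors out of the optimization loop
  obs <- lapply(split(dataset, dataset$cross_id), function(rows) {
    mk <- !is.na(rows$dsred_adults) & rows$adults > 0
    gk <- !is.na(rows$egfp_adults) & rows$adults > 0
    list(eggs = rows$eggs, adults = rows$adults,
         dsred = rows$dsred_adults[mk], dsred_n = rows$adults[mk],
         egfp = rows$egfp_adults[gk], egfp_n = rows$adults[gk])
  })
  specs <- cross_specs[names(obs)]
  force(base_params)
  function(theta) {
    par <- base_params
    for (nm in setdiff(names(theta), "rho")) par[[nm]] <- theta[[nm]]
    par <- structure(par, class = "rate_params")
    rho <- if (overdispersion) theta[["rho"]] else 0
    ll <- 0
    for (i in seq_along(obs)) {
      o <- obs[[i]]
      k <- .cross_kernel(specs[[i]]$mother, specs[[i]]$father, par, arch)
      ll <- ll + sum(.lbetabinom(o$adults, o$eggs,
                                 k$absolute_viability, rho))
      if (k$relative_viability > 0) {
        if (length(o$dsred) > 0)
          ll <- ll + sum(.lbinom(o$dsred, o$dsred_n, k$inheritance_rate))
        if (length(o$egfp) > 0)
          ll <- ll + sum(.lbinom(o$egfp, o$egfp_n,
                                 k$cas9_transmission_rate))
      }
    }
    ll
  }
}

# Maximize over the free parameters; simple box-constrained search on the
# raw scale with a coordinate-polish pass for high precision.
.ml_optimize <- function(loglik, free_names, start) {
  eps <- 1e-9
  if (length(free_names) == 1L) {
    opt <- stats::optimize(function(x) {
      th <- stats::setNames(x, free_names)
      loglik(th)
    }, c(eps, 1 - eps), maximum = TRUE, tol = 1e-10)
    est <- stats::setNames(opt$maximum, free_names)
    return(list(par = est, value = opt$objective))
  }
  fn <- function(x) {
    x <- pmin(pmax(x, eps), 1 - eps)
    -loglik(stats::setNames(x, free_names))
  }
  opt <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- pmin(pmax(opt$par, eps), 1 - eps)
  # coordinate polish: one-dimensional refinements to tighten each estimate
  for (pass in 1:3) {
    for (j in seq_along(par)) {
      lo <- max(eps, par[j] - 0.05)
      hi <- min(1 - eps, par[j] + 0.05)
      o <- stats::optimize(function(x) {
        xx <- par
        xx[j] <- x
        -fn(xx)
      }, c(lo, hi), maximum = TRUE, tol = 1e-12)
      par[j] <- o$maximum
    }
  }
  list(par = stats::setNames(par, free_names), value = -fn(par))
}

# Profile-likelihood 95% interval for one parameter (chi-square, 1 df).
.profile_ci <- function(loglik, free_names, mle, llmax, target_name,
                        level = 0.95) {
  crit <- stats::qchisq(level, df = 1) / 2
  others <- setdiff(free_names, target_name)
  eps <- 1e-9
  prof <- function(x) {
    if (length(others) == 0L) {
      return(loglik(stats::setNames(x, target_name)))
    }
    if (length(others) == 1L) {
      o <- stats::optimize(function(y) {
        th <- stats::setNames(c(x, y), c(target_name, others))
        loglik(th)
      }, c(eps, 1 - eps), maximum = TRUE, tol = 1e-7)
      return(o$objective)
    }
    fn <- function(y) {
      y <- pmin(pmax(y, eps), 1 - eps)
      -loglik(stats::setNames(c(x, y), c(target_name, others)))
    }
    -stats::optim(mle[others], fn, method = "Nelder-Mead",
                  control = list(maxit = 500, reltol = 1e-9))$value
  }
  dev <- function(x) llmax - prof(x) - crit
  x0 <- mle[[target_name]]
  lo <- if (dev(eps) < 0) 0 else
    stats::uniroot(dev, c(eps, x0), tol = 2e-5)$root
  hi <- if (dev(1 - eps) < 0) 1 else
    stats::uniroot(dev, c(x0, 1 - eps), tol = 2e-5)$root
  c(lo, hi)
}

#' Maximum-likelihood estimation of drive rate parameters from vial counts
#'
#' Fits the cross-model forward predictions to vial-level counts by
#' maximizing the product over vials of `Binomial(adults | eggs,
#' absolute_viability)` -- or a beta-binomial with intra-class correlation
#' `rho` when `overdispersion = TRUE`, absorbing between-vial (batch)
#' variance -- where the absolute viability of each cross is computed by
#' [offspring_distribution()].  Marker counts contribute
#' `Binomial(dsred_adults | adults, inheritance_rate)` and analogously for
#' EGFP.  Confidence intervals are 95% profile-likelihood intervals
#' (chi-square with 1 df), appropriate for estimates near the \[0, 1\]
#' boundary.
#'
#' @param dataset A vial-count data frame as returned by
#'   [read_vial_csv()] or [generate_dataset()].
#' @param cross_specs Named list mapping each `cross_id` in `dataset` to a
#'   [cross_spec()].
#' @param arch A [drive_architecture()].
#' @param free_params Character vector of parameters to estimate, a subset
#'   of `c("c_germline", "c_embryo", "p_hdr_functional",
#'   "baseline_viability")`.
#' @param overdispersion Fit a beta-binomial vial-level dispersion
#'   parameter `rho` (substituting for a per-vial random intercept)?
#' @param fixed Named list of parameter values overriding the
#'   [rate_params()] defaults for parameters not being estimated.
#' @param compute_ci Compute profile-likelihood intervals (can be disabled
#'   for speed in simulation studies)?
#' @return An object of class `"estimation_result"`: list with `estimates`,
#'   `confidence_intervals` (named list of `c(low, high)`),
#'   `log_likelihood`, `method` and `boundary` (names of estimates within
#'   1e-6 of 0 or 1).
#' @export
fit_ml <- function(dataset, cross_specs, arch, free_params,
                   overdispersion = FALSE, fixed = list(),
                   compute_ci = TRUE) {
  stopifnot(is.data.frame(dataset), inherits(arch, "drive_architecture"))
  if (!all(free_params %in% .ml_free_params))
    stop("free_params must be a subset of: ",
         paste(.ml_free_params, collapse = ", "), call. = FALSE)
  missing_ids <- setdiff(unique(dataset$cross_id), names(cross_specs))
  if (length(missing_ids) > 0)
    stop("no cross_spec for cross_id: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  base <- unclass(do.call(rate_params, fixed))
  free <- free_params
  if (overdispersion) free <- c(free, "rho")
  loglik <- .make_loglik(dataset, cross_specs, arch, free, base,
                         overdispersion)
  start <- stats::setNames(rep(0.1, length(free)), free)
  start[free == "baseline_viability"] <- 0.8
  start[free == "rho"] <- 0.02
  fit <- .ml_optimize(loglik, free, start)
  est <- fit$par
  cis <- NULL
  if (compute_ci) {
    cis <- lapply(free, function(nm)
      .profile_ci(loglik, free, est, fit$value, nm))
    names(cis) <- free
  }
  boundary <- names(est)[est < 1e-6 | est > 1 - 1e-6]
  structure(
    list(estimates = as.list(est),
         confidence_intervals = cis,
         log_likelihood = fit$value,
         method = if (overdispersion) "ml_betabinomial" else "ml_binomial",
         boundary = boundary),
    class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result> method:", x$method, "\n")
  for (nm in names(x$estimates)) {
    ci <- x$confidence_intervals[[nm]]
    cat(sprintf("  %-20s %.5f", nm, x$estimates[[nm]]))
    if (!is.null(ci)) cat(sprintf("  [%.5f, %.5f]", ci[1], ci[2]))
    cat("\n")
  }
  cat(sprintf("  log-likelihood: %.3f\n", x$log_likelihood))
  if (length(x$boundary) > 0)
    cat("  note: boundary estimate(s):",
        paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood convention: the p-value sums the `Binomial(n, p0)`
#' probabilities of all outcomes whose point probability does not exceed
#' that of the observed count `k` (with a small relative tolerance for
#' floating-point ties), matching the common implementation of the exact
#' test.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return The two-sided p-value.
#' @export
binomial_exact_test <- function(k, n, p0) {
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || is.na(n) || k < 0 || n < 0 || k > n)
    stop("need 0 <= k <= n", call. = FALSE)
  if (!is.numeric(p0) || p0 < 0 || p0 > 1)
    stop("`p0` must lie in [0, 1]", call. = FALSE)
  if (n == 0L) return(1)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities that do not exceed the observed table's probability
#' (minimum-likelihood convention).
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value.
#' @export
fisher_exact_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  if (m + n2 == 0L) return(1)
  x <- max(0, k - n2):min(k, m)
  d_all <- stats::dhyper(x, m, n2, k)
  d_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
}
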