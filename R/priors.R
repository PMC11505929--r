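#' Empirical-Bayes priors on transition rates
#'
#' For each rate parameter with MLE above 0.01 per Myr, the prior is
#' LogNormal(meanlog = log(MLE), sdlog = 1): its median equals the MLE and
#' about 98% of its mass (exactly `pnorm(log 10) - pnorm(-log 10)` = 0.9786)
#' lies between one tenth of the MLE and ten times the MLE. Parameters with
#' MLE <= 0.01 get an Exponential prior with rate 100 per Myr^-1 — the same
#' low-rates prior used, on both rates, for the LR habitat model.
#'
#' @param mle numeric vector of rate MLEs (per Myr), optionally named.
#' @param threshold MLE below/at which the exponential prior is used
#'   (default 0.01).
#' @param lambda rate of the exponential prior (default 100).
#' @param sdlog sd of the log-normal prior in log-units (default 1).
#' @return an object of class `prior_spec`: a list with one entry per
#'   parameter, each `list(type, ...)`.
#' @export
empirical_bayes_priors <- function(mle, threshold = 0.01, lambda = 100,
                                   sdlog = 1) {
  stopifnot(all(mle >= 0))
  out <- lapply(seq_along(mle), function(i) {
    if (mle[i] > threshold)
      list(type = "lognormal", meanlog = log(mle[i]), sdlog = sdlog)
    else
      list(type = "exponential", rate = lambda)
  })
  names(out) <- names(mle)
  structure(out, class = "prior_spec")
}

#' @rdname empirical_bayes_priors
#' @param lambda rate of the exponential prior applied to every parameter.
#' @param n_par number of rate parameters.
#' @export
low_rates_priors <- function(n_par, lambda = 100) {
  structure(rep(list(list(type = "exponential", rate = lambda)), n_par),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  for (i in seq_along(x)) {
    p <- x[[i]]
    nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i] else i
    if (p$type == "lognormal")
      cat("  ", nm, ": LogNormal(meanlog=", format(p$meanlog, digits = 4),
          ", sdlog=", p$sdlog, ")\n", sep = "")
    else
      cat("  ", nm, ": Exponential(rate=", p$rate, ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname empirical_bayes_priors
#' @param priors a `prior_spec`.
#' @param x vector of rate values (one per parameter).
#' @return `prior_log_density()`: the joint log prior density.
#' @export
prior_log_density <- function(priors, x) {
  stopifnot(length(x) == length(priors))
  ll <- 0
  for (i in seq_along(priors)) {
    p <- priors[[i]]
    ll <- ll + switch(p$type,
      lognormal = stats::dlnorm(x[i], p$meanlog, p$sdlog, log = TRUE),
      exponential = stats::dexp(x[i], p$rate, log = TRUE),
      stop("unknown prior type ", p$type))
  }
  ll
}

#' @rdname empirical_bayes_priors
#' @param n number of draws.
#' @return `prior_sample()`: an `n x n_par` matrix of draws.
#' @export
prior_sample <- function(priors, n) {
  out <- matrix(0, n, length(priors))
  for (i in seq_along(priors)) {
    p <- priors[[i]]
    out[, i] <- switch(p$type,
      lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
      exponential = stats::rexp(n, p$rate))
  }
  colnames(out) <- names(priors)
  out
}

#' @rdname empirical_bayes_priors
#' @param lower,upper interval bounds.
#' @return `prior_mass()`: vector of per-parameter prior masses on
#'   `[lower, upper]`.
#' @export
prior_mass <- function(priors, lower, upper) {
  lower <- rep_len(lower, length(priors))
  upper <- rep_len(upper, length(priors))
  vapply(seq_along(priors), function(i) {
    p <- priors[[i]]
    switch(p$type,
      lognormal = stats::plnorm(upper[i], p$meanlog, p$sdlog) -
        stats::plnorm(lower[i], p$meanlog, p$sdlog),
      exponential = stats::pexp(upper[i], p$rate) -
        stats::pexp(lower[i], p$rate))
  }, 0)
}

#' Mass of a Gamma prior parameterized by mean and standard deviation
#'
#' Convenience used to express root-age priors of molecular-clock analyses
#' (e.g. a root age with mean 2639 Ma and sd 179 Myr) and check how much
#' density an interval carries.
#'
#' @param mean,sd mean and standard deviation of the Gamma distribution.
#' @param lower,upper interval bounds (same units as `mean`).
#' @return the probability mass on `[lower, upper]`.
#' @export
gamma_interval_mass <- function(mean, sd, lower, upper) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  stats::pgamma(upper, shape, rate) - stats::pgamma(lower, shape, rate)
}
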