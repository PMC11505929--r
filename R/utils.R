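## small numerical helpers shared across the package

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  x / rowSums(x)
}

ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples (exhaustive window search). A warning attribute flags possible
#' multimodality when the shortest window is more than 10% shorter than the
#' central interval.
#'
#' @param samples numeric vector (>= 100 values recommended).
#' @param mass posterior mass, strictly between 0 and 1 (defaults used in the
#'   analyses are 0.89 and 0.95).
#' @return numeric vector `c(lower, upper)` with attribute
#'   `possibly_multimodal`.
#' @export
hpd_interval <- function(samples, mass = 0.89) {
  stopifnot(mass > 0, mass < 1, length(samples) >= 2L)
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) m <- n
  k <- n - m + 1L
  widths <- x[m:n] - x[1:k]
  i <- which.min(widths)
  out <- c(x[i], x[i + m - 1L])
  lo <- x[max(1L, floor(n * (1 - mass) / 2))]
  hi <- x[min(n, ceiling(n * (1 + mass) / 2))]
  central <- hi - lo
  attr(out, "possibly_multimodal") <-
    is.finite(central) && central > 0 && (out[2] - out[1]) < 0.9 * central
  names(out) <- c("lower", "upper")
  out
}

## effective sample size via initial positive sequence of autocorrelations
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  max(1, n / (1 + 2 * s))
}

## rank-normalized split-Rhat (two or more chains given as a list of vectors)
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch) %/% 2L
    if (n < 2L) return(NA_real_)
    halves <- c(halves, list(ch[seq_len(n)]), list(ch[(n + 1L):(2L * n)]))
  }
  all <- unlist(halves)
  z <- stats::qnorm((rank(all) - 0.5) / length(all))
  zs <- split(z, rep(seq_along(halves), lengths(halves)))
  m <- length(zs); n <- length(zs[[1L]])
  means <- vapply(zs, mean, 0)
  vars <- vapply(zs, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
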