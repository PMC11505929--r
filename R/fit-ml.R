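## internal: pick the reference tree for ML fitting from a tree sample.
## With a shared topology the node ages are averaged across the sample;
## otherwise the first tree is used.
reference_tree <- function(trees) {
  trees <- as_tree_sample(trees)
  t1 <- trees$trees[[1L]]
  if (length(trees$trees) == 1L) return(t1)
  topo1 <- ape::write.tree(structure(
    c(t1[c("edge", "tip.label", "Nnode")], list(edge.length = NULL)),
    class = "phylo"))
  same <- all(vapply(trees$trees, function(t) {
    identical(t$edge, t1$edge) && identical(t$tip.label, t1$tip.label)
  }, TRUE))
  if (!same) return(t1)
  ages <- rowMeans(vapply(trees$trees, node_ages,
                          numeric(length(t1$node.ages))))
  out <- t1
  out$node.ages <- ages
  out$edge.length <- ages[out$edge[, 1L]] - ages[out$edge[, 2L]]
  out
}

## internal: closed-form MLE of a conditional probability table when every
## conditioning tip state and focal tip state is unambiguous: row-wise
## multinomial proportions of the observed focal states. Unobserved rows are
## left uniform.
table_mle_closed_form <- function(tree, data, model) {
  cond <- model$conditioned
  taxa <- tree$tip.label
  tipps <- lapply(model$blocks, block_tip_partials, data = data, taxa = taxa)
  jidx <- tip_joint_index(tipps)
  focal <- data[[cond$focal]]
  fidx <- vapply(taxa, function(tx) {
    s <- focal$tips[[tx]]
    if (length(s) == 1L) match(s, cond$focal_states) else NA_integer_
  }, 1L)
  if (anyNA(jidx) || anyNA(fidx)) return(NULL)
  nr <- length(cond$cond_states); nc <- length(cond$focal_states)
  counts <- matrix(0, nr, nc, dimnames = list(cond$cond_states,
                                              cond$focal_states))
  for (i in seq_along(taxa))
    counts[jidx[i], fidx[i]] <- counts[jidx[i], fidx[i]] + 1
  tab <- counts
  empty <- rowSums(counts) == 0
  tab[!empty, ] <- counts[!empty, , drop = FALSE] /
    rowSums(counts)[!empty]
  tab[empty, ] <- 1 / nc
  tab
}

#' Maximum-likelihood estimation of trait-model parameters
#'
#' Multi-start Nelder-Mead (Brent for a single parameter) on log-rates, with
#' rates bounded to `[1e-9, 1e3]` per Myr. For a conditioned model whose
#' conditioning and focal tip states are all unambiguous the conditional
#' probability table has the closed-form row-wise multinomial MLE and the
#' rate/table estimation separates exactly; otherwise the table rows are
#' optimized jointly with the rates through a softmax parameterization.
#'
#' @param trees a [dated_tree()] or [tree_sample()] (reference tree: mean
#'   node ages for a shared topology, else the first tree).
#' @param data named list of [character_matrix()].
#' @param model a [trait_model()].
#' @param n_starts number of optimizer restarts (default 5).
#' @param start_range log10-range from which starting rates are drawn.
#' @return a list of class `solutemap_mle`: `par` (named rate vector),
#'   `table` (if conditioned), `loglik`, `k` (free-parameter count),
#'   `convergence`.
#' @export
mle_fit <- function(trees, data, model, n_starts = 5,
                    start_range = c(-4, 0)) {
  tree <- reference_tree(trees)
  npar <- total_free_rates(model)
  cond <- model$conditioned
  lb <- log(1e-9); ub <- log(1e3)
  tab <- NULL
  tab_free <- FALSE
  if (!is.null(cond)) {
    tab <- cond$table
    if (is.null(tab)) {
      tab <- table_mle_closed_form(tree, data, model)
      if (is.null(tab)) tab_free <- TRUE # ambiguous: optimize jointly
    }
  }
  nr <- if (!is.null(cond)) length(cond$cond_states) else 0L
  nc <- if (!is.null(cond)) length(cond$focal_states) else 0L
  prep <- prepare_tip_structures(tree$tip.label, data, model)
  unpack <- function(par) {
    rates <- exp(pmin(pmax(par[seq_len(npar)], lb), ub))
    tb <- tab
    if (tab_free) {
      z <- matrix(par[npar + seq_len(nr * (nc - 1L))], nr, nc - 1L)
      e <- cbind(exp(z), 1)
      tb <- e / rowSums(e)
      dimnames(tb) <- list(cond$cond_states, cond$focal_states)
    }
    list(rates = rates, table = tb)
  }
  negll <- function(par) {
    u <- unpack(par)
    pen <- sum(pmax(par[seq_len(npar)] - ub, 0)^2 +
               pmax(lb - par[seq_len(npar)], 0)^2)
    ll <- tryCatch(tree_loglik(tree, data, model, rates = u$rates,
                               table = u$table, prep = prep),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll + 100 * pen
  }
  ndim <- npar + if (tab_free) nr * (nc - 1L) else 0L
  best <- NULL
  for (st in seq_len(n_starts)) {
    p0 <- c(log(10^stats::runif(npar, start_range[1L], start_range[2L])),
            if (tab_free) stats::rnorm(nr * (nc - 1L), 0, 0.5))
    fit <- if (ndim == 1L) {
      o <- stats::optim(p0, negll, method = "Brent", lower = lb, upper = ub)
      o
    } else {
      stats::optim(p0, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("optimizer failed to find a finite-likelihood point")
  u <- unpack(best$par)
  names(u$rates) <- rate_par_names(model)
  k <- npar + if (!is.null(cond)) nr * (nc - 1L) else 0L
  structure(list(par = u$rates, table = u$table, loglik = -best$value,
                 k = k, convergence = best$convergence),
            class = "solutemap_mle")
}

#' @export
print.solutemap_mle <- function(x, ...) {
  cat("ML fit: log-likelihood", format(x$loglik, digits = 8),
      "(", x$k, "free parameters )\n")
  print(format(x$par, digits = 4), quote = FALSE)
  if (!is.null(x$table)) {
    cat("Conditional probability table:\n")
    print(round(x$table, 4))
  }
  invisible(x)
}

#' Model posterior probabilities, information criteria, and averaging
#'
#' Normalizes per-model log marginal likelihoods under a model prior
#' (uniform by default) into model posterior probabilities (mPPs), optionally
#' computes AIC = 2k - 2 lnL and BIC = k ln(n) - 2 lnL with their weights
#' `exp(-delta/2)` normalized, and blends per-model summaries as
#' `sum_m w_m * summary_m`.
#'
#' @param logml numeric vector of per-model log marginal likelihoods (may
#'   contain `NA`/`-Inf`; such models are excluded with a warning).
#' @param prior model prior probabilities (default uniform).
#' @param loglik,k,n optional per-model max log-likelihoods, parameter counts,
#'   and the sample size (taxa), to compute AIC/BIC weights.
#' @return an object of class `model_weights`: data frame with columns
#'   `model`, `logml`, `prior`, `posterior`, and if available `AIC`, `BIC`,
#'   `wAIC`, `wBIC`.
#' @export
model_weights <- function(logml, prior = NULL, loglik = NULL, k = NULL,
                          n = NULL) {
  m <- length(logml)
  stopifnot(m >= 1L)
  nms <- names(logml)
  if (is.null(nms)) nms <- paste0("m", seq_len(m))
  if (is.null(prior)) prior <- rep(1 / m, m)
  prior <- prior / sum(prior)
  bad <- !is.finite(logml)
  if (any(bad)) {
    warning("excluding models with non-finite log marginal likelihood: ",
            paste(nms[bad], collapse = ", "))
  }
  lp <- logml + log(prior)
  lp[bad] <- -Inf
  w <- exp(lp - max(lp[!bad]))
  w <- w / sum(w)
  out <- data.frame(model = nms, logml = logml, prior = prior,
                    posterior = w, stringsAsFactors = FALSE)
  if (!is.null(loglik) && !is.null(k) && !is.null(n)) {
    out$AIC <- 2 * k - 2 * loglik
    out$BIC <- k * log(n) - 2 * loglik
    dA <- out$AIC - min(out$AIC); dB <- out$BIC - min(out$BIC)
    out$wAIC <- exp(-dA / 2) / sum(exp(-dA / 2))
    out$wBIC <- exp(-dB / 2) / sum(exp(-dB / 2))
  }
  class(out) <- c("model_weights", "data.frame")
  out
}

#' @rdname model_weights
#' @param weights a `model_weights` object (or bare numeric weights).
#' @param summaries per-model summaries: a numeric vector, or a list of
#'   equal-shape numeric vectors/matrices.
#' @return `model_average()`: the weighted blend of the summaries.
#' @export
model_average <- function(weights, summaries) {
  w <- if (inherits(weights, "model_weights")) weights$posterior else weights
  w <- w / sum(w)
  if (is.numeric(summaries) && length(summaries) == length(w))
    return(sum(w * summaries))
  stopifnot(is.list(summaries), length(summaries) == length(w))
  out <- summaries[[1L]] * w[1L]
  for (i in seq_along(summaries)[-1L]) out <- out + summaries[[i]] * w[i]
  out
}
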