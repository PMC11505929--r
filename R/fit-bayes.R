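#' Chain configuration for the Metropolis-Hastings samplers
#'
#' @param n_iter proposals per chain.
#' @param chains number of chains.
#' @param burnin fraction of each chain discarded.
#' @param n_retain retained (thinned) draws per chain.
#' @param mult_lambda width of the log-multiplier proposal on rates.
#' @param dir_conc concentration of the Dirichlet proposal on table rows.
#' @param seed integer seed (chains use `seed + chain - 1`).
#' @param ess_floor warn when any parameter's ESS falls below this.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 1e5, chains = 2, burnin = 0.25,
                        n_retain = 1000, mult_lambda = 1.4, dir_conc = 100,
                        seed = 1, ess_floor = 100) {
  structure(list(n_iter = n_iter, chains = chains, burnin = burnin,
                 n_retain = n_retain, mult_lambda = mult_lambda,
                 dir_conc = dir_conc, seed = seed, ess_floor = ess_floor),
            class = "mcmc_config")
}

## internal: one Metropolis-Hastings chain on (rates, table, tree index) at
## likelihood power beta. `f(k, rates, table)` returns the log-likelihood.
## Returns recorded draws and the final state.
run_mh_chain <- function(f, n_trees, priors, table_free, nr, nc, beta,
                         n_iter, init, mult_lambda, dir_conc,
                         record_from = 1L, thin = 1L) {
  rates <- init$rates
  table <- init$table
  k <- init$k
  ll <- f(k, rates, table)
  lp <- prior_log_density(priors, rates)
  npar <- length(rates)
  ## single-rate multipliers, table-row moves, and (for multi-rate models) a
  ## joint scale move that multiplies all rates by one factor — the slow
  ## direction when the likelihood has a rate-scale ridge
  nmove <- npar + (if (table_free) nr else 0L) + (npar > 1L)
  n_rec <- length(seq.int(record_from, n_iter, by = thin))
  rec_rates <- matrix(NA_real_, n_rec, npar)
  rec_ll <- numeric(n_rec); rec_lp <- numeric(n_rec)
  rec_k <- integer(n_rec)
  rec_tab <- if (table_free) array(NA_real_, c(n_rec, nr, nc)) else NULL
  acc <- c(tree = 0, rate = 0, table = 0)
  prop <- c(tree = 0, rate = 0, table = 0)
  ri <- 0L
  for (it in seq_len(n_iter)) {
    if (n_trees > 1L) {
      prop["tree"] <- prop["tree"] + 1
      k2 <- sample.int(n_trees, 1L)
      if (k2 != k) {
        ll2 <- f(k2, rates, table)
        if (is.finite(ll2) && log(stats::runif(1)) < beta * (ll2 - ll)) {
          k <- k2; ll <- ll2
          acc["tree"] <- acc["tree"] + 1
        }
      } else acc["tree"] <- acc["tree"] + 1
    }
    i <- if (nmove > 1L) sample.int(nmove, 1L) else 1L
    if (i <= npar || i == nmove && npar > 1L) {
      prop["rate"] <- prop["rate"] + 1
      r2 <- rates
      fac <- exp(mult_lambda * (stats::runif(1) - 0.5))
      scale_move <- i > npar
      if (scale_move) r2 <- rates * fac else r2[i] <- rates[i] * fac
      ll2 <- tryCatch(f(k, r2, table), error = function(e) -Inf)
      lp2 <- prior_log_density(priors, r2)
      hast <- if (scale_move) npar * log(fac) else log(fac)
      if (is.finite(ll2) &&
          log(stats::runif(1)) < beta * (ll2 - ll) + (lp2 - lp) + hast) {
        rates <- r2; ll <- ll2; lp <- lp2
        acc["rate"] <- acc["rate"] + 1
      }
    } else {
      prop["table"] <- prop["table"] + 1
      r <- i - npar
      row <- table[r, ]
      a_fwd <- dir_conc * row + 0.5
      row2 <- as.vector(rdirichlet(1L, a_fwd))
      a_rev <- dir_conc * row2 + 0.5
      t2 <- table; t2[r, ] <- row2
      ll2 <- tryCatch(f(k, rates, t2), error = function(e) -Inf)
      lh <- ddirichlet_log(row, a_rev) - ddirichlet_log(row2, a_fwd)
      if (is.finite(ll2) && log(stats::runif(1)) < beta * (ll2 - ll) + lh) {
        table <- t2; ll <- ll2
        acc["table"] <- acc["table"] + 1
      }
    }
    if (it >= record_from && (it - record_from) %% thin == 0L) {
      ri <- ri + 1L
      rec_rates[ri, ] <- rates
      rec_ll[ri] <- ll; rec_lp[ri] <- lp; rec_k[ri] <- k
      if (table_free) rec_tab[ri, , ] <- table
    }
  }
  list(rates = rec_rates[seq_len(ri), , drop = FALSE],
       loglik = rec_ll[seq_len(ri)], logprior = rec_lp[seq_len(ri)],
       tree = rec_k[seq_len(ri)],
       tables = if (table_free) rec_tab[seq_len(ri), , , drop = FALSE],
       accept = ifelse(prop > 0, acc / prop, NA),
       state = list(rates = rates, table = table, k = k))
}

## internal: draw an initial state from the priors
prior_init <- function(priors, table_free, nr, nc, table_fixed) {
  rates <- as.vector(prior_sample(priors, 1L))
  table <- if (table_free) rdirichlet(nr, rep(1, nc)) else table_fixed
  list(rates = rates, table = table, k = 1L)
}

#' Posterior sampling of trait-model parameters by Metropolis-Hastings
#'
#' Multiplier proposals on rates, Dirichlet proposals on conditional-table
#' rows (flat Dirichlet prior), and uniform resampling of the tree index each
#' iteration, so that the tree sample is integrated over as a nuisance
#' parameter. Deterministic under a fixed seed.
#'
#' @param trees a [dated_tree()] or [tree_sample()].
#' @param data named list of [character_matrix()].
#' @param model a [trait_model()].
#' @param priors a [empirical_bayes_priors()] `prior_spec`, one entry per
#'   free rate.
#' @param config an [mcmc_config()].
#' @param init optional numeric vector of starting rates (e.g. the MLE);
#'   by default each chain starts from a prior draw.
#' @return an object of class `posterior_sample`: `draws` (data frame with
#'   `chain`, `tree`, `loglik`, `logprior` and one column per rate), `tables`
#'   (draws x rows x cols array, when the table is sampled), and `meta`
#'   (acceptance rates, per-parameter ESS, split R-hat, the config).
#' @export
mcmc_sample <- function(trees, data, model, priors, config = mcmc_config(),
                        init = NULL) {
  ts <- as_tree_sample(trees)
  stopifnot(length(priors) == total_free_rates(model))
  cond <- model$conditioned
  table_free <- !is.null(cond) && is.null(cond$table)
  nr <- if (!is.null(cond)) length(cond$cond_states) else 0L
  nc <- if (!is.null(cond)) length(cond$focal_states) else 0L
  prep <- prepare_tip_structures(ts$trees[[1L]]$tip.label, data, model)
  f <- function(k, rates, table)
    tree_loglik(ts$trees[[k]], data, model, rates = rates, table = table,
                prep = prep)
  burn <- ceiling(config$n_iter * config$burnin)
  thin <- max(1L, floor((config$n_iter - burn) / config$n_retain))
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1L)
    state <- prior_init(priors, table_free, nr, nc, cond$table)
    if (!is.null(init))
      state$rates <- pmin(pmax(as.numeric(init), 1e-8), 1e3)
    state$k <- sample.int(length(ts$trees), 1L)
    chains[[ch]] <- run_mh_chain(
      f, length(ts$trees), priors, table_free, nr, nc, beta = 1,
      n_iter = config$n_iter, init = state,
      mult_lambda = config$mult_lambda, dir_conc = config$dir_conc,
      record_from = burn + 1L, thin = thin)
  }
  rates <- do.call(rbind, lapply(chains, `[[`, "rates"))
  colnames(rates) <- rate_par_names(model)
  draws <- data.frame(
    chain = rep(seq_len(config$chains),
                vapply(chains, function(c) length(c$loglik), 1L)),
    tree = unlist(lapply(chains, `[[`, "tree")),
    loglik = unlist(lapply(chains, `[[`, "loglik")),
    logprior = unlist(lapply(chains, `[[`, "logprior")))
  draws <- cbind(draws, as.data.frame(rates))
  tables <- NULL
  if (table_free) {
    tabs <- lapply(chains, `[[`, "tables")
    tables <- array(NA_real_, c(nrow(draws), nr, nc),
                    dimnames = list(NULL, cond$cond_states,
                                    cond$focal_states))
    at <- 0L
    for (tb in tabs) {
      tables[at + seq_len(dim(tb)[1L]), , ] <- tb
      at <- at + dim(tb)[1L]
    }
  }
  par_ess <- apply(rates, 2L, ess)
  rhat <- vapply(seq_len(ncol(rates)), function(j)
    split_rhat(lapply(chains, function(c) c$rates[, j])), 0)
  warn <- character(0)
  if (any(par_ess < config$ess_floor))
    warn <- paste0("ESS below floor for: ",
                   paste(colnames(rates)[par_ess < config$ess_floor],
                         collapse = ", "))
  meta <- list(accept = Reduce(`+`, lapply(chains, `[[`, "accept")) /
                 config$chains,
               ess = par_ess, rhat = rhat, config = config,
               warnings = warn)
  structure(list(draws = draws, tables = tables, meta = meta,
                 par_names = colnames(rates)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", nrow(x$draws), "draws,",
      length(x$par_names), "rate parameter(s)\n")
  med <- apply(x$draws[, x$par_names, drop = FALSE], 2L, stats::median)
  cat("posterior medians:\n")
  print(format(med, digits = 4), quote = FALSE)
  if (length(x$meta$warnings)) cat("warnings:", x$meta$warnings, "\n")
  invisible(x)
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Power-posterior ladder with rungs `beta_j = (j/K)^(1/0.3)` (quantiles of a
#' Beta(0.3, 1), concentrating rungs near the prior). The prior rung is
#' sampled i.i.d.; every later rung continues a Metropolis-Hastings chain at
#' its power. The log marginal likelihood is the sum over rungs of the log
#' mean importance ratio, with a Monte-Carlo standard error from the
#' effective sample size of each rung's weights.
#'
#' @inheritParams mcmc_sample
#' @param K number of rungs (>= 8).
#' @param n_per_rung recorded samples per rung.
#' @param alpha shape of the rung schedule (default 0.3).
#' @param seed integer seed.
#' @param mult_lambda,dir_conc proposal tuning, as in [mcmc_config()].
#' @return a list of class `stepping_stone`: `logml`, `se`, `K`,
#'   `n_per_rung`, `betas`.
#' @export
stepping_stone_logml <- function(trees, data, model, priors, K = 32,
                                 n_per_rung = 1e4, alpha = 0.3, seed = 1,
                                 mult_lambda = 1.4, dir_conc = 100) {
  stopifnot(K >= 8)
  ts <- as_tree_sample(trees)
  cond <- model$conditioned
  table_free <- !is.null(cond) && is.null(cond$table)
  nr <- if (!is.null(cond)) length(cond$cond_states) else 0L
  nc <- if (!is.null(cond)) length(cond$focal_states) else 0L
  prep <- prepare_tip_structures(ts$trees[[1L]]$tip.label, data, model)
  f <- function(k, rates, table)
    tree_loglik(ts$trees[[k]], data, model, rates = rates, table = table,
                prep = prep)
  set.seed(seed)
  betas <- (0:K / K)^(1 / alpha)
  n_trees <- length(ts$trees)
  ## prior rung: i.i.d. draws
  rates0 <- prior_sample(priors, n_per_rung)
  lls <- numeric(n_per_rung)
  tabs0 <- if (table_free) lapply(seq_len(n_per_rung), function(i)
    rdirichlet(nr, rep(1, nc))) else NULL
  ks <- sample.int(n_trees, n_per_rung, replace = TRUE)
  for (i in seq_len(n_per_rung)) {
    tb <- if (table_free) tabs0[[i]] else cond$table
    lls[i] <- tryCatch(f(ks[i], rates0[i, ], tb), error = function(e) -Inf)
  }
  if (all(!is.finite(lls))) stop("rung with zero effective samples")
  logml <- 0; se2 <- 0
  add_rung <- function(lls, dbeta) {
    w <- dbeta * lls
    lm <- logmeanexp(w)
    wt <- exp(w - max(w[is.finite(w)]))
    ne <- ess(wt)
    v <- stats::var(wt) / (ne * mean(wt)^2)
    list(lm = lm, v = v)
  }
  r <- add_rung(lls, betas[2L] - betas[1L])
  logml <- logml + r$lm; se2 <- se2 + r$v
  ## pick a starting state near the prior-rung best
  ibest <- which.max(lls)
  state <- list(rates = rates0[ibest, ],
                table = if (table_free) tabs0[[ibest]] else cond$table,
                k = ks[ibest])
  for (j in 2L:K) {
    beta <- betas[j]
    out <- run_mh_chain(f, n_trees, priors, table_free, nr, nc, beta,
                        n_iter = n_per_rung, init = state,
                        mult_lambda = mult_lambda, dir_conc = dir_conc,
                        record_from = 1L, thin = 1L)
    state <- out$state
    if (all(!is.finite(out$loglik))) stop("rung with zero effective samples")
    r <- add_rung(out$loglik, betas[j + 1L] - betas[j])
    logml <- logml + r$lm; se2 <- se2 + r$v
  }
  structure(list(logml = logml, se = sqrt(se2), K = K,
                 n_per_rung = n_per_rung, betas = betas),
            class = "stepping_stone")
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat("Stepping-stone log marginal likelihood:",
      format(x$logml, digits = 8), "+/-", format(x$se, digits = 3),
      "(", x$K, "rungs )\n")
  invisible(x)
}
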