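#' Control settings for the fitting pipelines
#'
#' Desk-scale defaults; raise `n_iter`, `ss_samples`, and `n_histories` for
#' production analyses.
#'
#' @param n_iter MCMC proposals per chain.
#' @param chains MCMC chains.
#' @param n_retain retained draws per chain.
#' @param ss_K stepping-stone rungs.
#' @param ss_samples stepping-stone samples per rung.
#' @param n_histories default stochastic-mapping draws.
#' @param mle_starts optimizer restarts.
#' @param seed integer seed.
#' @return a list of class `fit_control`.
#' @export
fit_control <- function(n_iter = 2e4, chains = 2, n_retain = 1000,
                        ss_K = 16, ss_samples = 1000, n_histories = 1000,
                        mle_starts = 5, seed = 1) {
  structure(list(n_iter = n_iter, chains = chains, n_retain = n_retain,
                 ss_K = ss_K, ss_samples = ss_samples,
                 n_histories = n_histories, mle_starts = mle_starts,
                 seed = seed),
            class = "fit_control")
}

## internal: stepping stone for a trait model; independent multi-block models
## factorize, so the combined log marginal likelihood is the sum of per-block
## log marginal likelihoods (cheaper and exact for the product model).
model_logml <- function(trees, data, model, priors, control) {
  if (length(model$blocks) > 1L && is.null(model$conditioned)) {
    ns <- vapply(model$blocks, function(b) b$model$n_free, 1L)
    offs <- c(0L, cumsum(ns))
    total <- 0; se2 <- 0
    for (b in seq_along(model$blocks)) {
      sub <- trait_model(stats::setNames(list(model$blocks[[b]]$model),
                                         names(model$blocks)[b]),
                         root = model$root)
      ## single-char blocks need the block name to be the character name
      sub$blocks[[1L]]$chars <- model$blocks[[b]]$chars
      pr <- structure(priors[offs[b] + seq_len(ns[b])], class = "prior_spec")
      ss <- stepping_stone_logml(trees, data, sub, pr, K = control$ss_K,
                                 n_per_rung = control$ss_samples,
                                 seed = control$seed + b)
      total <- total + ss$logml; se2 <- se2 + ss$se^2
    }
    return(list(logml = total, se = sqrt(se2)))
  }
  ss <- stepping_stone_logml(trees, data, model, priors, K = control$ss_K,
                             n_per_rung = control$ss_samples,
                             seed = control$seed)
  list(logml = ss$logml, se = ss$se)
}

#' Fit competing trait models to one character (or gene pathway)
#'
#' The single-character pipeline: maximum-likelihood estimation, empirical
#' Bayes priors centered on the MLEs, Metropolis-Hastings posterior sampling,
#' stepping-stone marginal likelihoods, and model posterior probabilities
#' (mPPs) under a uniform model prior. Results of the competing models are
#' blended by the mPPs (Bayesian model averaging). The cost is linear in the
#' number of characters analyzed this way.
#'
#' @param trees a [dated_tree()] or [tree_sample()].
#' @param data named list of [character_matrix()].
#' @param chars character name (binary character) or vector of gene names (a
#'   pathway; candidate models come from [enumerate_pathway_models()]).
#' @param models optional named list of [trait_model()] candidates overriding
#'   the defaults (`ER`/`ARD` for a single character; the enumerated pathway
#'   model space for 2-3 genes).
#' @param alphabet state alphabet of the individual characters.
#' @param control a [fit_control()].
#' @return an object of class `solutemap_fit` with components `models`
#'   (per candidate: `model`, `mle`, `priors`, `posterior`, `logml`,
#'   `logml_se`), `weights` (a [model_weights()] table), `trees`, `data`,
#'   `chars`, `control`.
#' @export
fit_character <- function(trees, data, chars, models = NULL,
                          alphabet = NULL, control = fit_control()) {
  trees <- as_tree_sample(trees)
  if (is.null(models)) {
    if (length(chars) == 1L) {
      alpha <- if (!is.null(alphabet)) alphabet else data[[chars]]$states
      models <- list(
        ER = trait_model(stats::setNames(
          list(rate_model(alpha, "ER")), chars)),
        ARD = trait_model(stats::setNames(
          list(rate_model(alpha, "ARD")), chars)))
    } else {
      alpha <- if (!is.null(alphabet)) alphabet else c("A", "P")
      space <- enumerate_pathway_models(chars)
      models <- list()
      for (cand in space$candidates) {
        blocks <- candidate_blocks(chars, cand, alpha)
        ms <- lapply(blocks, `[[`, "model")
        names(ms) <- names(blocks)
        tm <- trait_model(ms)
        for (b in seq_along(blocks)) tm$blocks[[b]]$chars <- blocks[[b]]$chars
        models[[cand$label]] <- tm
      }
    }
  }
  n_taxa <- length(trees$trees[[1L]]$tip.label)
  fits <- list()
  logml <- loglik <- k <- numeric(length(models))
  names(logml) <- names(models)
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    set.seed(control$seed + 1000 * mi)
    mle <- mle_fit(trees, data, model, n_starts = control$mle_starts)
    priors <- empirical_bayes_priors(mle$par)
    post <- mcmc_sample(trees, data, model, priors,
                        mcmc_config(n_iter = control$n_iter,
                                    chains = control$chains,
                                    n_retain = control$n_retain,
                                    seed = control$seed + 1000 * mi),
                        init = mle$par)
    ml <- tryCatch(model_logml(trees, data, model, priors, control),
                   error = function(e) list(logml = NA_real_, se = NA_real_))
    fits[[names(models)[mi]]] <- list(model = model, mle = mle,
                                      priors = priors, posterior = post,
                                      logml = ml$logml, logml_se = ml$se)
    logml[mi] <- ml$logml
    loglik[mi] <- mle$loglik
    k[mi] <- mle$k
  }
  w <- model_weights(logml, loglik = loglik, k = k, n = n_taxa)
  structure(list(models = fits, weights = w, trees = trees, data = data,
                 chars = chars, control = control,
                 conditioned = NULL),
            class = "solutemap_fit")
}

#' Conditioned multi-character analysis
#'
#' Fits a joint model in which Markov blocks drive the conditioning
#' characters and the focal character is conditioned on their joint state
#' through a probability table (flat Dirichlet prior in the Bayesian case).
#' One analysis is run per combination of candidate models for the blocks.
#' Combination weights come from exact stepping-stone marginal likelihoods
#' (`weights_from = "stepping_stone"`), or — when the joint model is too
#' large for that to be practical — from the per-character marginal
#' likelihoods of the alternatives (`"component"`; the difference in marginal
#' likelihood between composite models is approximately the difference
#' between the individual models), or from AIC/BIC weights of ML fits.
#'
#' @param trees a [dated_tree()] or [tree_sample()].
#' @param data named list of [character_matrix()].
#' @param focal focal character name.
#' @param focal_states focal alphabet.
#' @param blocks named list: each element a [rate_model()] (fixed choice) or
#'   a named list of alternative [rate_model()]s.
#' @param method `"bayes"` (posterior sampling of rates and table; practical
#'   for <= 2 conditioning blocks) or `"ml"` (maximum likelihood for rates
#'   and conditioned probabilities).
#' @param weights_from `"stepping_stone"`, `"component"`, `"aic"`, `"bic"`.
#' @param component_logml for `"component"`: named list, one element per
#'   block with alternatives, each a named numeric vector of per-alternative
#'   log marginal likelihoods (from the single-character analyses).
#' @param control a [fit_control()].
#' @return a `solutemap_fit` whose `conditioned` element names the focal
#'   character; each model entry additionally carries `table` (ML or
#'   posterior-mean conditional probability table).
#' @export
fit_conditioned <- function(trees, data, focal, focal_states, blocks,
                            method = c("bayes", "ml"),
                            weights_from = c("stepping_stone", "component",
                                             "aic", "bic"),
                            component_logml = NULL,
                            control = fit_control()) {
  method <- match.arg(method)
  weights_from <- match.arg(weights_from)
  trees <- as_tree_sample(trees)
  ## expand combinations over blocks with alternatives
  alt <- lapply(blocks, function(b)
    if (inherits(b, "rate_model")) list(fixed = b) else b)
  combo_grid <- expand.grid(lapply(alt, names), stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
  models <- list()
  for (ci in seq_len(nrow(combo_grid))) {
    ms <- list()
    for (bn in names(alt)) ms[[bn]] <- alt[[bn]][[combo_grid[ci, bn]]]
    joint <- joint_state_labels(lapply(ms, function(m) list(model = m)))
    tm <- trait_model(ms, conditioned = conditioned_model(
      focal, focal_states, joint, table = NULL))
    lbl <- paste(paste0(names(alt), "=", unlist(combo_grid[ci, ])),
                 collapse = ",")
    models[[lbl]] <- tm
  }
  n_taxa <- length(trees$trees[[1L]]$tip.label)
  fits <- list()
  logml <- loglik <- k <- numeric(length(models))
  names(logml) <- names(models)
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    set.seed(control$seed + 2000 * mi)
    mle <- mle_fit(trees, data, model, n_starts = control$mle_starts)
    priors <- empirical_bayes_priors(mle$par)
    post <- NULL; tab <- mle$table
    if (method == "bayes") {
      post <- mcmc_sample(trees, data, model, priors,
                          mcmc_config(n_iter = control$n_iter,
                                      chains = control$chains,
                                      n_retain = control$n_retain,
                                      seed = control$seed + 2000 * mi),
                          init = mle$par)
      if (!is.null(post$tables)) tab <- apply(post$tables, c(2, 3), mean)
    }
    ml <- NA_real_; ml_se <- NA_real_
    if (weights_from == "stepping_stone") {
      ss <- stepping_stone_logml(trees, data, model, priors,
                                 K = control$ss_K,
                                 n_per_rung = control$ss_samples,
                                 seed = control$seed + 2000 * mi)
      ml <- ss$logml; ml_se <- ss$se
    } else if (weights_from == "component") {
      if (is.null(component_logml))
        stop("component weights require component_logml")
      ml <- 0
      for (bn in names(component_logml))
        ml <- ml + component_logml[[bn]][[combo_grid[mi, bn]]]
    }
    fits[[names(models)[mi]]] <- list(model = model, mle = mle,
                                      priors = priors, posterior = post,
                                      table = tab, logml = ml,
                                      logml_se = ml_se)
    logml[mi] <- ml
    loglik[mi] <- mle$loglik
    k[mi] <- mle$k
  }
  w <- if (weights_from %in% c("aic", "bic")) {
    mw <- model_weights(rep(0, length(models)), loglik = loglik, k = k,
                        n = n_taxa)
    mw$logml <- NA_real_
    mw$posterior <- if (weights_from == "aic") mw$wAIC else mw$wBIC
    mw
  } else {
    model_weights(logml, loglik = loglik, k = k, n = n_taxa)
  }
  structure(list(models = fits, weights = w, trees = trees, data = data,
                 chars = names(blocks), control = control,
                 conditioned = list(focal = focal,
                                    focal_states = focal_states)),
            class = "solutemap_fit")
}

#' Stochastic mapping from a fitted model (or model set)
#'
#' Draws full character histories: per draw, a model is picked proportionally
#' to its posterior probability, a retained posterior draw supplies the
#' parameters (and its tree index the tree), node states are sampled
#' conditioned on the tip data, and endpoint-conditioned branch paths are
#' filled in by uniformization. A conditioned focal character is overlaid on
#' the conditioning histories from its probability table, with tip segments
#' clamped to the observed focal states. For ML fits (no posterior) the MLE
#' parameters are reused in every draw with trees cycled uniformly.
#'
#' @param fit a `solutemap_fit`.
#' @param n number of history draws (study-scale analyses exported 5000).
#' @param seed integer seed.
#' @return a `history_set` whose draws contain one mapped history per block
#'   (named by block) plus the focal character when conditioned.
#' @export
sample_histories <- function(fit, n = 1000, seed = 1) {
  stopifnot(inherits(fit, "solutemap_fit"))
  set.seed(seed)
  trees <- fit$trees
  data <- fit$data
  wts <- fit$weights$posterior
  n_models <- length(fit$models)
  draws <- vector("list", n)
  tree_idx <- integer(n)
  pick <- sample.int(n_models, n, replace = TRUE, prob = wts)
  ## cache tip partials per model
  preps <- lapply(fit$models, function(f)
    prepare_tip_structures(trees$trees[[1L]]$tip.label, data, f$model))
  for (i in seq_len(n)) {
    mi <- pick[i]
    f <- fit$models[[mi]]
    model <- f$model
    post <- f$posterior
    if (!is.null(post)) {
      j <- sample.int(nrow(post$draws), 1L)
      rates <- as.numeric(post$draws[j, post$par_names])
      ki <- post$draws$tree[j]
      tab <- if (!is.null(post$tables)) post$tables[j, , ] else f$table
      if (!is.null(tab) && is.null(dim(tab)))
        tab <- matrix(tab, ncol = length(model$conditioned$focal_states))
    } else {
      rates <- as.numeric(f$mle$par)
      ki <- sample.int(length(trees$trees), 1L)
      tab <- f$table %||% f$mle$table
    }
    if (!is.null(tab) && !is.null(model$conditioned))
      dimnames(tab) <- list(model$conditioned$cond_states,
                            model$conditioned$focal_states)
    tree <- trees$trees[[ki]]
    tree_idx[i] <- ki
    rs <- split_rates(model, rates)
    per_char <- list()
    for (b in seq_along(model$blocks)) {
      bl <- model$blocks[[b]]
      Q <- build_rate_matrix(bl$model, rs[[b]])
      rp <- resolve_root_prior(model$root, bl$model)
      ns <- sample_joint_node_states(tree, preps[[mi]]$tipps[[b]], Q, rp,
                                     n = 1L)
      per_char[[names(model$blocks)[b]]] <-
        branch_histories(tree, ns[1L, ], Q, bl$model$states)
    }
    if (!is.null(model$conditioned)) {
      cond <- model$conditioned
      per_char[[cond$focal]] <- overlay_conditioned(
        per_char[names(model$blocks)], tree, tab,
        focal_data = data[[cond$focal]])
    }
    draws[[i]] <- per_char
  }
  structure(list(draws = draws, tree = tree_idx, trees = trees,
                 model_pick = pick),
            class = "history_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior-predictive (null) histories for D-test replicates
#'
#' Per replicate, draws parameters (and a tree) exactly as
#' [sample_histories()] does, then simulates the characters forward without
#' tip conditioning — the null of independent evolution with the focal
#' character (if any) detached from its conditioning table and simulated from
#' its own fitted model.
#'
#' @param fit a `solutemap_fit` for one character (used per character).
#' @param n replicates.
#' @param seed integer seed.
#' @return a `history_set`.
#' @export
simulate_null_histories <- function(fit, n = 1000, seed = 1) {
  stopifnot(inherits(fit, "solutemap_fit"))
  set.seed(seed)
  trees <- fit$trees
  wts <- fit$weights$posterior
  draws <- vector("list", n)
  tree_idx <- integer(n)
  pick <- sample.int(length(fit$models), n, replace = TRUE, prob = wts)
  for (i in seq_len(n)) {
    f <- fit$models[[pick[i]]]
    model <- f$model
    post <- f$posterior
    if (!is.null(post)) {
      j <- sample.int(nrow(post$draws), 1L)
      rates <- as.numeric(post$draws[j, post$par_names])
      ki <- post$draws$tree[j]
    } else {
      rates <- as.numeric(f$mle$par)
      ki <- sample.int(length(trees$trees), 1L)
    }
    tree <- trees$trees[[ki]]
    tree_idx[i] <- ki
    rs <- split_rates(model, rates)
    per_char <- list()
    for (b in seq_along(model$blocks)) {
      bl <- model$blocks[[b]]
      Q <- build_rate_matrix(bl$model, rs[[b]])
      rp <- resolve_root_prior(model$root, bl$model)
      per_char[[names(model$blocks)[b]]] <-
        simulate_unconditioned(tree, Q, rp, labels = bl$model$states)
    }
    draws[[i]] <- per_char
  }
  structure(list(draws = draws, tree = tree_idx, trees = trees,
                 model_pick = pick),
            class = "history_set")
}

#' Run the full multi-character workflow
#'
#' Stage 1 fits every candidate character (and the focal character)
#' independently; stage 2 runs D-tests of each candidate against the focal
#' character and ranks them by significance; stage 3 re-analyzes the focal
#' character conditioned on the top-ranked candidates; stage 4 produces
#' summaries (root posterior, first-occurrence ages, transition rates through
#' time) and a machine-readable report. Raw P values are reported with the
#' 5% threshold flag and no multiple-testing correction. With an `out_dir`,
#' per-stage checkpoints are written and reused on resume, and the report is
#' written as JSON alongside TSV tables.
#'
#' @param trees a [tree_sample()].
#' @param data named list of [character_matrix()].
#' @param focal focal character name.
#' @param candidates named list of candidate character specs: each a
#'   character vector of data columns (length 1 = binary character, 2-3 =
#'   gene pathway).
#' @param n_top how many top-ranked candidates enter the conditioned stage.
#' @param n_histories history draws per D-test side.
#' @param control a [fit_control()].
#' @param out_dir optional output/checkpoint directory.
#' @param resume reuse existing checkpoints in `out_dir`?
#' @return a list of class `solutemap_report`.
#' @export
run_workflow <- function(trees, data, focal, candidates, n_top = 2,
                         n_histories = 500, control = fit_control(),
                         out_dir = NULL, resume = FALSE) {
  trees <- as_tree_sample(trees)
  ckpt <- function(name, expr) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(name, ".rds"))
      if (resume && file.exists(path)) return(readRDS(path))
      val <- expr
      saveRDS(val, path)
      return(val)
    }
    expr
  }
  ## stage 1: independent per-character fits
  stage1 <- ckpt("stage1", {
    fits <- list()
    fits[[focal]] <- fit_character(trees, data, focal, control = control)
    for (nm in names(candidates))
      fits[[nm]] <- fit_character(trees, data, candidates[[nm]],
                                  control = control)
    fits
  })
  ## stage 2: D-tests vs the focal character, ranked by P
  stage2 <- ckpt("stage2", {
    hf <- sample_histories(stage1[[focal]], n = n_histories,
                           seed = control$seed + 11)
    nf <- simulate_null_histories(stage1[[focal]], n = n_histories,
                                  seed = control$seed + 12)
    dts <- list()
    for (nm in names(candidates)) {
      hc <- sample_histories(stage1[[nm]], n = n_histories,
                             seed = control$seed + 13)
      nc <- simulate_null_histories(stage1[[nm]], n = n_histories,
                                    seed = control$seed + 14)
      block <- names(stage1[[nm]]$models[[1L]]$model$blocks)[1L]
      ## highest-weight model's block naming is shared across candidates
      obs <- lapply(seq_len(n_histories), function(i)
        list(combined_history(hc$draws[[i]]), hf$draws[[i]][[focal]]))
      nul <- lapply(seq_len(n_histories), function(i)
        list(combined_history(nc$draws[[i]]), nf$draws[[i]][[focal]]))
      st1 <- sort(unique(unlist(lapply(obs, function(p)
        unique(p[[1L]]$state)))))
      st2 <- stage1[[focal]]$data[[focal]]$states
      dts[[nm]] <- d_test(obs, nul, trees, obs_tree = hc$tree,
                          null_tree = nc$tree,
                          states1 = st1, states2 = st2)
    }
    dts
  })
  ranking <- names(stage2)[order(vapply(stage2, `[[`, 0, "P"))]
  ## stage 3: conditioned analysis on the top-ranked candidates
  top <- ranking[seq_len(min(n_top, length(ranking)))]
  stage3 <- ckpt("stage3", {
    blocks <- list()
    comp_logml <- list()
    for (nm in top) {
      spec <- candidates[[nm]]
      if (length(spec) == 1L) {
        alpha <- data[[spec]]$states
        blocks[[nm]] <- list(ER = rate_model(alpha, "ER"),
                             ARD = rate_model(alpha, "ARD"))
        lm <- stats::setNames(stage1[[nm]]$weights$logml,
                              stage1[[nm]]$weights$model)
        comp_logml[[nm]] <- lm[c("ER", "ARD")]
      } else {
        ## pathway: fix the top-weight model's (single-block) structure
        wbest <- which.max(stage1[[nm]]$weights$posterior)
        bm <- stage1[[nm]]$models[[wbest]]$model
        if (length(bm$blocks) > 1L) {
          ## fall back to the all-dependent ARD supercharacter
          space <- product_states(stats::setNames(
            rep(list(c("A", "P")), length(spec)), spec))
          m <- rate_model(space, "ARD")
          m$components <- stats::setNames(rep(list(c("A", "P")),
                                              length(spec)), spec)
          blocks[[nm]] <- m
        } else {
          blocks[[nm]] <- bm$blocks[[1L]]$model
        }
      }
    }
    use_bayes <- length(top) <= 2L
    fit_conditioned(trees, data, focal, data[[focal]]$states, blocks,
                    method = if (use_bayes) "bayes" else "ml",
                    weights_from = if (use_bayes) "stepping_stone"
                                   else "component",
                    component_logml = if (!use_bayes) comp_logml,
                    control = control)
  })
  ## stage 4: summaries
  stage4 <- ckpt("stage4", {
    hist3 <- sample_histories(stage3, n = n_histories,
                              seed = control$seed + 15)
    prof <- state_probability_profiles(hist3, focal)
    foc_states <- data[[focal]]$states
    first <- lapply(foc_states, function(s)
      first_occurrence_ages(hist3, focal, s))
    names(first) <- foc_states
    rtt <- transitions_through_time(hist3, focal, foc_states[1L],
                                    foc_states[2L])
    list(profile = prof, first_occurrence = first, rates_through_time = rtt)
  })
  ntip <- length(trees$trees[[1L]]$tip.label)
  report <- list(
    focal = focal,
    dtest = lapply(stage2, function(d)
      list(D = d$D, P = d$P, significant = d$P < d$threshold)),
    ranking = ranking,
    conditioned_on = top,
    stage1_weights = lapply(stage1, function(f)
      stats::setNames(f$weights$posterior, f$weights$model)),
    conditioned_weights = stats::setNames(stage3$weights$posterior,
                                          stage3$weights$model),
    root_posterior = stage4$profile$nodes[ntip + 1L, ],
    first_occurrence_median = vapply(stage4$first_occurrence, function(e)
      stats::median(e$ages, na.rm = TRUE), 0))
  out <- structure(list(report = report, stage1 = stage1, stage2 = stage2,
                        stage3 = stage3, stage4 = stage4),
                   class = "solutemap_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dt <- do.call(rbind, lapply(names(stage2), function(nm)
      cbind(character = nm, d_test_table(stage2[[nm]]))))
    utils::write.table(dt, file.path(out_dir, "dtest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

## internal: merge the per-block histories of a draw into one joint-state
## history (used when a candidate pathway has multiple blocks)
combined_history <- function(per_char) {
  hs <- per_char
  if (length(hs) == 1L) return(hs[[1L]])
  edges <- sort(unique(hs[[1L]]$branch))
  rows <- lapply(edges, function(e) {
    seg <- joint_edge_segments(hs, e)
    cbind(branch = e, seg)
  })
  do.call(rbind, rows)
}

#' @export
print.solutemap_report <- function(x, ...) {
  r <- x$report
  cat("Workflow report - focal character:", r$focal, "\n")
  cat("D-test ranking:", paste(r$ranking, collapse = " > "), "\n")
  for (nm in names(r$dtest))
    cat(sprintf("  %s: D = %.1f%%, P = %.4g%s\n", nm, r$dtest[[nm]]$D,
                r$dtest[[nm]]$P,
                if (r$dtest[[nm]]$significant) " *" else ""))
  cat("Conditioned on:", paste(r$conditioned_on, collapse = ", "), "\n")
  cat("Focal root posterior:\n")
  print(round(r$root_posterior, 4))
  invisible(x)
}
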