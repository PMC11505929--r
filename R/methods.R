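#' @export
print.solutemap_fit <- function(x, ...) {
  cat("solutemap fit:",
      if (length(x$chars) == 1L) paste("character", x$chars)
      else paste("pathway (", paste(x$chars, collapse = ", "), ")"),
      "\n")
  if (!is.null(x$conditioned))
    cat("focal character", x$conditioned$focal,
        "conditioned on the block states\n")
  w <- x$weights
  cat(length(x$models), "model(s); posterior probabilities:\n")
  for (i in seq_len(nrow(w)))
    cat(sprintf("  %-28s logml %10.3f  mPP %.3f\n", w$model[i], w$logml[i],
                w$posterior[i]))
  invisible(x)
}

#' @export
summary.solutemap_fit <- function(object, ...) {
  w <- object$weights
  par_summ <- lapply(object$models, function(f) {
    if (!is.null(f$posterior)) {
      d <- f$posterior$draws[, f$posterior$par_names, drop = FALSE]
      cbind(mle = f$mle$par,
            median = apply(d, 2L, stats::median),
            lower89 = apply(d, 2L, function(x) hpd_interval(x, 0.89)[1L]),
            upper89 = apply(d, 2L, function(x) hpd_interval(x, 0.89)[2L]))
    } else {
      cbind(mle = f$mle$par)
    }
  })
  structure(list(weights = w, parameters = par_summ,
                 chars = object$chars, conditioned = object$conditioned),
            class = "summary.solutemap_fit")
}

#' @export
print.summary.solutemap_fit <- function(x, ...) {
  cat("Model comparison:\n")
  print(as.data.frame(x$weights), digits = 4, row.names = FALSE)
  for (nm in names(x$parameters)) {
    cat("\nModel", nm, "- rates (per Myr):\n")
    print(signif(x$parameters[[nm]], 4))
  }
  invisible(x)
}

#' @export
coef.solutemap_fit <- function(object, type = c("median", "mle"), ...) {
  type <- match.arg(type)
  lapply(object$models, function(f) {
    if (type == "mle" || is.null(f$posterior)) f$mle$par
    else apply(f$posterior$draws[, f$posterior$par_names, drop = FALSE],
               2L, stats::median)
  })
}

#' @export
logLik.solutemap_fit <- function(object, ...) {
  best <- which.max(object$weights$posterior)
  ll <- object$models[[best]]$mle$loglik
  attr(ll, "df") <- object$models[[best]]$mle$k
  class(ll) <- "logLik"
  ll
}

#' @export
simulate.solutemap_fit <- function(object, nsim = 1000, seed = 1, ...) {
  sample_histories(object, n = nsim, seed = seed)
}

#' @export
predict.solutemap_fit <- function(object, histories = NULL,
                                  character = NULL, nsim = 1000,
                                  seed = 1, grid_step = 10, ...) {
  if (is.null(histories)) histories <- sample_histories(object, n = nsim,
                                                        seed = seed)
  if (is.null(character)) {
    character <- if (!is.null(object$conditioned)) object$conditioned$focal
                 else names(object$models[[1L]]$model$blocks)[1L]
  }
  state_probability_profiles(histories, character, grid_step = grid_step)
}

#' @export
plot.solutemap_fit <- function(x, histories = NULL, character = NULL,
                               nsim = 200, seed = 1, threshold = 0.6, ...) {
  prof <- predict(x, histories = histories, character = character,
                  nsim = nsim, seed = seed)
  plot(prof, threshold = threshold, ...)
}

#' @export
plot.state_profile <- function(x, state = x$states[length(x$states)],
                               threshold = 0.6, ...) {
  tree <- x$tree
  bip <- edge_bipartitions(tree)
  ## mean probability of `state` along each edge from the branch grid
  pcol <- rep(0.5, nrow(tree$edge))
  if (nrow(x$branches) > 0) {
    for (e in seq_len(nrow(tree$edge))) {
      sub <- x$branches[x$branches$bipartition == bip[e], ]
      if (nrow(sub) > 0) pcol[e] <- mean(sub[[state]])
    }
  }
  cols <- ifelse(pcol > threshold, "darkorange",
                 ifelse(pcol < 1 - threshold, "steelblue", "grey60"))
  phy <- tree; phy$node.ages <- NULL; class(phy) <- "phylo"
  ape::plot.phylo(phy, edge.color = cols, edge.width = 2, ...)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("darkorange", "grey60", "steelblue"),
                   legend = c(paste0("P(", state, ") > ", threshold),
                              "uncertain",
                              paste0("P(", state, ") < ", 1 - threshold)))
  invisible(pcol)
}

#' @export
plot.rate_through_time <- function(x, ...) {
  mid <- (x$bin_old + x$bin_young) / 2
  graphics::plot(mid, x$rate, type = "s", xlim = rev(range(c(x$bin_old,
                                                             x$bin_young))),
                 xlab = "Age (Ma)",
                 ylab = "Transitions per lineage per Gyr",
                 main = attr(x, "direction"), ...)
  invisible(x)
}

#' @export
plot.event_ages <- function(x, ...) {
  ok <- !is.na(x$ages)
  graphics::hist(x$ages[ok], breaks = 30,
                 xlim = rev(range(x$ages[ok])),
                 xlab = "Age (Ma)", main = paste("First occurrence:",
                                                 x$character), ...)
  if (!is.null(x$reference_age))
    graphics::abline(v = x$reference_age, lty = 2, col = "red")
  invisible(x)
}
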