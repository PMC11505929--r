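#' Node and branch-time posterior state probabilities
#'
#' Node probabilities are the draw frequencies of node states; branch-grid
#' probabilities are the draw frequencies of the state at a regular grid of
#' ages along each branch. Branches are matched across trees of the sample by
#' tip-set bipartition, so draws on trees lacking a bipartition contribute
#' only to the branches they have.
#'
#' @param histories a `history_set`.
#' @param character character (block) name to summarize.
#' @param states state alphabet (default: all states seen).
#' @param grid_step grid spacing along branches in Myr (default 10).
#' @return an object of class `state_profile`: `nodes` (node x state
#'   probability matrix for the first tree's node numbering), `branches`
#'   (data frame `bipartition`, `age`, one probability column per state,
#'   `n_draws`), and `states`.
#' @export
state_probability_profiles <- function(histories, character,
                                       states = NULL, grid_step = 10) {
  stopifnot(inherits(histories, "history_set"))
  if (length(histories$draws) == 0L) stop("empty history collection")
  if (!character %in% names(histories$draws[[1L]]))
    stop("character ", character, " absent from histories")
  trees <- histories$trees$trees
  if (is.null(states)) {
    states <- sort(unique(unlist(lapply(histories$draws, function(d)
      unique(d[[character]]$state)))))
  }
  ## node probabilities on the reference (first) tree's numbering, matched by
  ## bipartition of the subtending edge
  ref <- trees[[1L]]
  ref_bip <- edge_bipartitions(ref)
  ntip <- length(ref$tip.label)
  node_counts <- matrix(0, ntip + ref$Nnode, length(states),
                        dimnames = list(NULL, states))
  node_n <- numeric(ntip + ref$Nnode)
  ## branch grid accumulators keyed by bipartition
  grid_acc <- new.env(parent = emptyenv())
  for (di in seq_along(histories$draws)) {
    h <- histories$draws[[di]][[character]]
    tree <- trees[[histories$tree[di]]]
    bip <- edge_bipartitions(tree)
    ages <- node_ages(tree)
    ## node states: state at the older end of each edge = parent node state;
    ## at the younger end = child node state
    for (e in seq_len(nrow(tree$edge))) {
      seg <- h[h$branch == e, ]
      child <- tree$edge[e, 2L]
      parent <- tree$edge[e, 1L]
      ref_edge <- match(bip[e], ref_bip)
      if (!is.na(ref_edge)) {
        rc <- ref$edge[ref_edge, 2L]
        node_counts[rc, seg$state[nrow(seg)]] <-
          node_counts[rc, seg$state[nrow(seg)]] + 1
        node_n[rc] <- node_n[rc] + 1
      }
      if (parent == ntip + 1L && e == which(tree$edge[, 1L] == parent)[1L]) {
        ## root handled once per draw via its first child edge
        node_counts[ntip + 1L, seg$state[1L]] <-
          node_counts[ntip + 1L, seg$state[1L]] + 1
        node_n[ntip + 1L] <- node_n[ntip + 1L] + 1
      }
      ## branch grid
      gr <- seq(floor(ages[tree$edge[e, 2L]] / grid_step) * grid_step,
                ages[parent], by = grid_step)
      gr <- gr[gr >= ages[child] & gr <= ages[parent]]
      if (length(gr) == 0L) next
      key <- bip[e]
      acc <- grid_acc[[key]]
      if (is.null(acc))
        acc <- list(ages = numeric(0), counts = NULL)
      for (g in gr) {
        st <- seg$state[which(seg$start >= g & seg$end <= g)[1L]]
        row <- match(g, acc$ages)
        if (is.na(row)) {
          acc$ages <- c(acc$ages, g)
          newrow <- stats::setNames(rep(0, length(states) + 1L),
                                    c(states, ".n"))
          acc$counts <- rbind(acc$counts, newrow)
          row <- length(acc$ages)
        }
        acc$counts[row, st] <- acc$counts[row, st] + 1
        acc$counts[row, ".n"] <- acc$counts[row, ".n"] + 1
      }
      grid_acc[[key]] <- acc
    }
  }
  nodes <- node_counts / pmax(node_n, 1)
  nodes[node_n == 0, ] <- NA
  branch_rows <- list()
  for (key in ls(grid_acc)) {
    acc <- grid_acc[[key]]
    ord <- order(-acc$ages)
    probs <- acc$counts[ord, states, drop = FALSE] /
      acc$counts[ord, ".n"]
    branch_rows[[length(branch_rows) + 1L]] <- data.frame(
      bipartition = key, age = acc$ages[ord],
      probs, n_draws = acc$counts[ord, ".n"], row.names = NULL,
      check.names = FALSE)
  }
  branches <- if (length(branch_rows)) do.call(rbind, branch_rows)
              else data.frame()
  structure(list(nodes = nodes, branches = branches, states = states,
                 tree = ref),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("State profile over {", paste(x$states, collapse = ", "), "}\n")
  cat("root posterior:\n")
  print(round(x$nodes[ntip + 1L, ], 4))
  invisible(x)
}

#' First-occurrence age of a state condition across a history collection
#'
#' Per draw, the oldest age (Ma) at which any lineage satisfies the state
#' predicate: the root age when satisfied at the root, `NA` when never
#' satisfied.
#'
#' @param histories a `history_set`.
#' @param character character name.
#' @param predicate a function of a state-label vector returning a logical
#'   vector (e.g. `function(s) s == "H"`), or a character vector of
#'   satisfying states.
#' @param reference_age optional age (Ma); the returned object then reports
#'   the probability that the event predates it (e.g. the GOE at 2460 Ma).
#' @return an object of class `event_ages`: `ages` (one per draw, `NA` =
#'   never), `p_before_reference`, `reference_age`.
#' @export
first_occurrence_ages <- function(histories, character, predicate,
                                  reference_age = NULL) {
  stopifnot(inherits(histories, "history_set"))
  if (is.character(predicate)) {
    okset <- predicate
    predicate <- function(s) s %in% okset
  }
  ages <- vapply(seq_along(histories$draws), function(di) {
    h <- histories$draws[[di]][[character]]
    if (is.null(h)) stop("character ", character, " absent from histories")
    ok <- predicate(h$state)
    if (!any(ok)) return(NA_real_)
    max(h$start[ok])
  }, 0)
  p_ref <- if (!is.null(reference_age)) mean(ages > reference_age,
                                             na.rm = TRUE)
  structure(list(ages = ages, reference_age = reference_age,
                 p_before_reference = p_ref, character = character),
            class = "event_ages")
}

#' @export
print.event_ages <- function(x, ...) {
  ok <- !is.na(x$ages)
  cat("First-occurrence ages for ", x$character, ": median ",
      format(stats::median(x$ages[ok]), digits = 5), " Ma (",
      sum(!ok), " draws never)\n", sep = "")
  if (ok0 <- sum(ok)) {
    h <- hpd_interval(x$ages[ok], 0.89)
    cat("89% HPD: [", format(h[1], digits = 5), ", ",
        format(h[2], digits = 5), "] Ma\n", sep = "")
  }
  if (!is.null(x$reference_age))
    cat("P(age > ", x$reference_age, " Ma) = ",
        format(x$p_before_reference, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Transition rates through time
#'
#' Per draw and time bin: the number of direction-matching transitions in the
#' bin divided by the lineage-time in the bin (the integral of the number of
#' contemporaneous branches, expressed in lineage-Gyr), averaged across
#' draws. Totals across bins conserve each draw's transition count.
#'
#' @param histories a `history_set`.
#' @param character character name.
#' @param from,to ordered state pair defining the direction.
#' @param bins bin edges in Ma (decreasing or increasing; default 100-Myr
#'   bins spanning the oldest root).
#' @return an object of class `rate_through_time`: data frame `bin_old`,
#'   `bin_young`, `rate` (mean transitions per lineage per Gyr), `n_events`
#'   (mean per draw), `lineage_gyr` (mean per draw).
#' @export
transitions_through_time <- function(histories, character, from, to,
                                     bins = NULL) {
  stopifnot(inherits(histories, "history_set"))
  trees <- histories$trees$trees
  max_root <- max(vapply(trees, root_age, 0))
  if (is.null(bins)) bins <- seq(0, ceiling(max_root / 100) * 100, by = 100)
  bins <- sort(unique(bins))
  nb <- length(bins) - 1L
  rate_sum <- numeric(nb); ev_sum <- numeric(nb); lt_sum <- numeric(nb)
  n_def <- numeric(nb)
  for (di in seq_along(histories$draws)) {
    h <- histories$draws[[di]][[character]]
    tree <- trees[[histories$tree[di]]]
    ages <- node_ages(tree)
    tr <- history_transitions(h)
    tr <- tr[tr$from == from & tr$to == to, , drop = FALSE]
    for (b in seq_len(nb)) {
      young <- bins[b]; old <- bins[b + 1L]
      cnt <- sum(tr$age > young & tr$age <= old)
      ## lineage-time: sum over edges of overlap with the bin, Myr -> Gyr
      ov <- pmin(ages[tree$edge[, 1L]], old) -
            pmax(ages[tree$edge[, 2L]], young)
      lt <- sum(ov[ov > 0]) / 1000
      ev_sum[b] <- ev_sum[b] + cnt
      lt_sum[b] <- lt_sum[b] + lt
      if (lt > 0) {
        rate_sum[b] <- rate_sum[b] + cnt / lt
        n_def[b] <- n_def[b] + 1
      }
    }
  }
  n <- length(histories$draws)
  out <- data.frame(bin_old = bins[-1L], bin_young = bins[-length(bins)],
                    rate = ifelse(n_def > 0, rate_sum / n_def, NA),
                    n_events = ev_sum / n, lineage_gyr = lt_sum / n)
  structure(out, class = c("rate_through_time", "data.frame"),
            direction = paste0(from, "->", to))
}

#' Gain/loss/exchange rate-class ratios from a posterior sample
#'
#' For pathway supercharacters the gain rate G is the summed rate out of the
#' all-absent state into any state with at least one gene, the loss rate L the
#' summed rate from the all-present state into any state with a loss, and the
#' exchange rate E the summed rate between incomplete states. Ratios are
#' formed per posterior draw (models blended by their weights when several
#' fits are given) and summarized by the median and HPD intervals.
#'
#' @param posteriors a [mcmc_sample()] `posterior_sample`, or a list of them
#'   (one per model) with `weights`.
#' @param model a [trait_model()] (or list of them matching `posteriors`).
#' @param block block name holding the pathway character.
#' @param classes named list of class cell sets; each a 2-column matrix of
#'   (from, to) state labels. Helper [pathway_rate_classes()] builds the
#'   standard G/L/E sets.
#' @param ratios character vector of `"num/den"` class ratios to compute.
#' @param weights model weights for blending (default single model).
#' @param n_draws number of blended draws (default: all available).
#' @return a list of class `rate_ratios`: `draws` (data frame of per-draw
#'   class sums and ratios), `medians`, `hpd89`.
#' @export
rate_ratios <- function(posteriors, model, block, classes,
                        ratios = c("L/G", "L/E", "G/E"), weights = NULL,
                        n_draws = NULL) {
  if (inherits(posteriors, "posterior_sample")) {
    posteriors <- list(posteriors); model <- list(model); weights <- 1
  }
  if (is.null(weights)) weights <- rep(1 / length(posteriors),
                                       length(posteriors))
  weights <- weights / sum(weights)
  if (is.null(n_draws))
    n_draws <- sum(vapply(posteriors, function(p) nrow(p$draws), 1L))
  pick_model <- sample.int(length(posteriors), n_draws, replace = TRUE,
                           prob = weights)
  class_names <- names(classes)
  sums <- matrix(NA_real_, n_draws, length(classes),
                 dimnames = list(NULL, class_names))
  for (i in seq_len(n_draws)) {
    mi <- pick_model[i]
    ps <- posteriors[[mi]]
    mo <- model[[mi]]
    j <- sample.int(nrow(ps$draws), 1L)
    rates <- as.numeric(ps$draws[j, ps$par_names])
    rs <- split_rates(mo, rates)
    bm <- mo$blocks[[block]]$model
    bi <- match(block, names(mo$blocks))
    Q <- build_rate_matrix(bm, rs[[bi]])
    for (cl in class_names) {
      cells <- classes[[cl]]
      s <- 0
      for (r in seq_len(nrow(cells))) {
        fi <- match(cells[r, 1L], bm$states)
        ti <- match(cells[r, 2L], bm$states)
        if (!is.na(fi) && !is.na(ti)) s <- s + Q[fi, ti]
      }
      sums[i, cl] <- s
    }
  }
  draws <- as.data.frame(sums)
  for (rt in ratios) {
    parts <- strsplit(rt, "/", fixed = TRUE)[[1L]]
    num <- sums[, parts[1L]]; den <- sums[, parts[2L]]
    draws[[rt]] <- ifelse(den > 0, num / den,
                          ifelse(num == den, 1, NA))
  }
  med <- vapply(draws, stats::median, 0, USE.NAMES = TRUE)
  hpd <- lapply(draws, function(x) hpd_interval(x[is.finite(x)], 0.89))
  structure(list(draws = draws, medians = med, hpd89 = hpd),
            class = "rate_ratios")
}

#' @export
print.rate_ratios <- function(x, ...) {
  cat("Rate-class posterior medians:\n")
  print(format(x$medians, digits = 4), quote = FALSE)
  invisible(x)
}

#' @rdname rate_ratios
#' @param states pathway state labels (e.g. `c("AA","AP","PA","PP")`).
#' @param functional states counting as a complete pathway (default: the
#'   all-present state); for the gain/loss definition of 2-gene pathways the
#'   G class is all transitions out of the all-absent state and the L class
#'   all transitions out of the all-present state.
#' @export
pathway_rate_classes <- function(states) {
  k <- nchar(states[1L])
  absent <- paste(rep("A", k), collapse = "")
  present <- paste(rep("P", k), collapse = "")
  incomplete <- setdiff(states, c(absent, present))
  G <- cbind(absent, setdiff(states, absent))
  L <- cbind(present, setdiff(states, present))
  E <- NULL
  for (i in incomplete) for (j in incomplete)
    if (i != j) E <- rbind(E, c(i, j))
  out <- list(G = G, L = L)
  if (!is.null(E)) out$E <- E
  out
}
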