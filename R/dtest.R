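#' Joint dwell-time association fractions of two mapped histories
#'
#' For one draw, computes the fractions of total tree length (sum of branch
#' lengths) spent in each marginal and joint state of two characters, by
#' merging segment boundaries branch-wise.
#'
#' @param h1,h2 mapped-history data frames on the same tree.
#' @param tree the [dated_tree()] both histories live on.
#' @param states1,states2 state alphabets (default: observed states, sorted).
#' @return a list with `a` (marginals of character 1), `b` (marginals of
#'   character 2), and `A` (joint fraction matrix); all sum to 1 and the
#'   row/column sums of `A` equal the marginals.
#' @export
association_fractions <- function(h1, h2, tree,
                                  states1 = sort(unique(h1$state)),
                                  states2 = sort(unique(h2$state))) {
  if (!setequal(unique(h1$branch), unique(h2$branch)))
    stop("histories cover different branch sets (mismatched trees?)")
  A <- matrix(0, length(states1), length(states2),
              dimnames = list(states1, states2))
  i1 <- match(h1$state, states1)
  i2 <- match(h2$state, states2)
  if (anyNA(i1) || anyNA(i2)) stop("history state outside the state space")
  ## branches where neither character changes state are handled in one
  ## vectorized pass; only branches with transitions need segment merging
  nb <- max(h1$branch, h2$branch)
  t1 <- tabulate(h1$branch, nb)
  t2 <- tabulate(h2$branch, nb)
  simple <- which(t1 == 1L & t2 == 1L)
  if (length(simple)) {
    r1s <- which(h1$branch %in% simple)
    r2s <- which(h2$branch %in% simple)
    r1s <- r1s[order(h1$branch[r1s])]
    r2s <- r2s[order(h2$branch[r2s])]
    w <- h1$start[r1s] - h1$end[r1s]
    cell <- (i2[r2s] - 1L) * length(states1) + i1[r1s]
    agg <- rowsum(w, cell)
    A[as.integer(rownames(agg))] <- A[as.integer(rownames(agg))] + agg[, 1L]
  }
  keep1 <- !(h1$branch %in% simple)
  keep2 <- !(h2$branch %in% simple)
  sp1 <- split(which(keep1), h1$branch[keep1])
  sp2 <- split(which(keep2), h2$branch[keep2])
  for (e in names(sp1)) {
    r1 <- sp1[[e]]; r2 <- sp2[[e]]
    st1 <- h1$start[r1]; st2 <- h2$start[r2]
    bounds <- sort(unique(c(st1, h1$end[r1[length(r1)]],
                            st2, h2$end[r2[length(r2)]])),
                   decreasing = TRUE)
    starts <- bounds[-length(bounds)]; ends <- bounds[-1L]
    mids <- (starts + ends) / 2
    ## segments are stored oldest-first: the covering segment is the last
    ## whose start is >= mid
    k1 <- findInterval(-mids, -st1)
    k2 <- findInterval(-mids, -st2)
    w <- starts - ends
    for (i in seq_along(mids)) {
      a <- i1[r1[k1[i]]]; b <- i2[r2[k2[i]]]
      A[a, b] <- A[a, b] + w[i]
    }
  }
  tot <- sum(A)
  if (tot <= 0) stop("histories have zero total dwell time")
  A <- A / tot
  list(a = rowSums(A), b = colSums(A), A = A, tree_length = tot)
}

#' D-test for correlation between two mapped characters
#'
#' For each posterior draw `k`, the deviation of the joint dwell-time
#' fractions from the independence expectation is
#' `Delta_ij^k = A_ij^k - a_i^k b_j^k`; the reported effect `d_ij` is the
#' posterior mean deviation (in percent) and `D = sum_ij |d_ij|`. Significance
#' is posterior-predictive: each null replicate simulates the two characters
#' independently (tip data and all) under one posterior parameter/tree draw
#' and recomputes the same statistic; a replicate that carries several
#' history draws contributes the mean of their deviations, mirroring the
#' observed posterior-mean statistic so the two are exchangeable under the
#' null. `P_ij` (`P`) is the fraction of replicates whose `|Delta_ij|`
#' (`sum_ij |Delta_ij|`) reaches the observed `|d_ij|` (`D`). Positive `d_ij` means states `i` and `j` co-occur
#' more than expected. For a pair of binary characters the row/column
#' zero-sum constraints force `d_11 = d_22 = -d_12 = -d_21` (so
#' `D = 4 |d_11|`) and all `P_ij` to coincide.
#'
#' @param obs list of draws; each draw a list of two mapped histories
#'   (observed, i.e. conditioned on tip data) on the same tree.
#' @param null list of null replicates: each either a single pair of
#'   histories, or a list of pairs (a batch of draws whose mean deviation is
#'   that replicate's statistic).
#' @param trees a [tree_sample()]; `obs_tree`/`null_tree` give each draw's
#'   tree index (default all 1).
#' @param obs_tree,null_tree integer vectors of tree indices.
#' @param states1,states2 state alphabets of the two characters.
#' @param threshold significance threshold on `P` (default 0.05).
#' @return an object of class `d_test`: `D`, `d` (matrix, percent), `P`,
#'   `P_matrix`, draw counts, and the threshold.
#' @export
d_test <- function(obs, null, trees, obs_tree = NULL, null_tree = NULL,
                   states1, states2, threshold = 0.05) {
  trees <- as_tree_sample(trees)
  if (is.null(obs_tree)) obs_tree <- rep(1L, length(obs))
  if (is.null(null_tree)) null_tree <- rep(1L, length(null))
  stopifnot(length(obs) >= 1L, length(null) >= 1L)
  dev_of <- function(pair, ti) {
    fr <- association_fractions(pair[[1L]], pair[[2L]], trees$trees[[ti]],
                                states1, states2)
    fr$A - outer(fr$a, fr$b)
  }
  obs_dev <- mapply(dev_of, obs, obs_tree, SIMPLIFY = FALSE)
  d <- Reduce(`+`, obs_dev) / length(obs_dev)
  D <- sum(abs(d))
  rep_dev <- function(rep, ti) {
    if (is.data.frame(rep[[1L]])) return(dev_of(rep, ti)) # single pair
    devs <- lapply(rep, dev_of, ti = ti)
    Reduce(`+`, devs) / length(devs)
  }
  null_dev <- mapply(rep_dev, null, null_tree, SIMPLIFY = FALSE)
  Pm <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  Pg <- 0
  for (nd in null_dev) {
    Pm <- Pm + (abs(nd) >= abs(d) - 1e-15)
    Pg <- Pg + (sum(abs(nd)) >= D - 1e-15)
  }
  Pm <- Pm / length(null_dev)
  Pg <- Pg / length(null_dev)
  structure(list(D = 100 * D, d = 100 * d, P = Pg, P_matrix = Pm,
                 n_obs = length(obs), n_null = length(null),
                 threshold = threshold),
            class = "d_test")
}

#' @export
print.d_test <- function(x, ...) {
  cat("D-test: D = ", format(x$D, digits = 3), "%, P = ",
      format(x$P, digits = 3),
      if (x$P < x$threshold) "  (significant)" else "", "\n", sep = "")
  cat("d_ij (%):\n"); print(round(x$d, 2))
  cat("P_ij:\n"); print(round(x$P_matrix, 4))
  cat("(", x$n_obs, "observed draws,", x$n_null, "null replicates )\n")
  invisible(x)
}

#' @rdname d_test
#' @param x a `d_test`.
#' @return `d_test_table()`: a data frame mirroring the per-pair layout of
#'   published D-test tables (overall row then per-state-pair rows).
#' @export
d_test_table <- function(x) {
  stopifnot(inherits(x, "d_test"))
  rows <- data.frame(comparison = "Overall",
                     d = x$D, P = x$P, stringsAsFactors = FALSE)
  for (i in rownames(x$d)) for (j in colnames(x$d)) {
    rows <- rbind(rows, data.frame(
      comparison = paste(i, "vs", j),
      d = x$d[i, j], P = x$P_matrix[i, j]))
  }
  rows
}
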