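#' Transition probability matrix of a CTMC
#'
#' Computes `exp(Q t)`. Binary generators use the closed form; larger
#' matrices go through [Matrix::expm()] (scaling-and-squaring).
#'
#' @param Q generator matrix (rows sum to 0, off-diagonals >= 0).
#' @param t elapsed time in Myr (>= 0).
#' @return a stochastic matrix with rows summing to 1.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(t >= 0)
  s <- nrow(Q)
  if (t == 0) return(diag(s))
  if (s == 2L) {
    a <- Q[1L, 2L]; b <- Q[2L, 1L]
    tot <- a + b
    if (tot == 0) return(diag(2L))
    e <- exp(-tot * t)
    P <- matrix(c(b + a * e, b - b * e,
                  a - a * e, a + b * e) / tot, 2L, 2L)
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

## internal: stationary distribution of a generator (null left eigenvector)
stationary_distribution <- function(Q) {
  s <- nrow(Q)
  A <- rbind(t(Q), rep(1, s))
  b <- c(rep(0, s), 1)
  pi <- stats::coef(stats::lm.fit(A, b))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

## internal: 0/1 tip partial matrix (ntip x s) for one character
char_tip_partials <- function(char, taxa) {
  s <- length(char$states)
  M <- matrix(0, length(taxa), s,
              dimnames = list(taxa, char$states))
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    st <- char$tips[[tx]]
    if (is.null(st)) stop("taxon ", tx, " missing from character ", char$name)
    M[i, match(st, char$states)] <- 1
  }
  M
}

## internal: tip partials for a block = row-wise Kronecker over its characters
## (first character varies slowest, matching product_states ordering)
block_tip_partials <- function(block, data, taxa) {
  mats <- lapply(block$chars, function(ch) {
    cm <- data[[ch]]
    if (is.null(cm)) stop("character ", ch, " absent from data")
    char_tip_partials(cm, taxa)
  })
  out <- mats[[1L]]
  if (length(mats) > 1L)
    for (k in 2L:length(mats)) {
      a <- out; b <- mats[[k]]
      out <- matrix(0, nrow(a), ncol(a) * ncol(b))
      for (i in seq_len(nrow(a)))
        out[i, ] <- kronecker(a[i, ], b[i, ])
    }
  colnames(out) <- block$model$states
  rownames(out) <- taxa
  out
}

## internal: Felsenstein pruning. Returns log-likelihood and, optionally, the
## normalized node partials and per-edge transition matrices (in tree$edge
## row order) for node-state sampling.
pruning_engine <- function(tree, tipp, Q, root_prior, keep = FALSE) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  s <- nrow(Q)
  po <- postorder_edges(tree)
  L <- matrix(1, nn, s)
  L[seq_len(ntip), ] <- tipp
  lognorm <- numeric(nn)
  Pedges <- if (keep) vector("list", nrow(tree$edge)) else NULL
  po_to_orig <- po$map
  if (s == 2L) {
    ## vectorized closed-form transition probabilities for all edges
    a <- Q[1L, 2L]; b <- Q[2L, 1L]; tot <- a + b
    ex <- if (tot > 0) exp(-tot * po$el)
          else rep(1, length(po$el))
    if (tot > 0) {
      p11 <- (b + a * ex) / tot; p12 <- (a - a * ex) / tot
      p21 <- (b - b * ex) / tot; p22 <- (a + b * ex) / tot
    } else {
      p11 <- p22 <- rep(1, length(ex)); p12 <- p21 <- rep(0, length(ex))
    }
    ep <- po$edge[, 1L]; ec <- po$edge[, 2L]
    for (k in seq_along(ep)) {
      p <- ep[k]; c <- ec[k]
      if (keep) Pedges[[po_to_orig[k]]] <-
          matrix(c(p11[k], p21[k], p12[k], p22[k]), 2L, 2L)
      v1 <- p11[k] * L[c, 1L] + p12[k] * L[c, 2L]
      v2 <- p21[k] * L[c, 1L] + p22[k] * L[c, 2L]
      l1 <- L[p, 1L] * v1; l2 <- L[p, 2L] * v2
      sc <- l1 + l2
      if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
      L[p, 1L] <- l1 / sc; L[p, 2L] <- l2 / sc
      lognorm[p] <- lognorm[p] + lognorm[c] + log(sc)
    }
  } else if (all(abs(Q[row(Q) != col(Q)] - Q[1L, 2L]) <=
                 1e-13 * max(Q[1L, 2L], 1e-300))) {
    ## equal-rates generator on s states (complete graph):
    ## P(t) = e^{-srt} I + (1 - e^{-srt})/s J
    r <- Q[1L, 2L]
    ex <- exp(-s * r * po$el)
    ep <- po$edge[, 1L]; ec <- po$edge[, 2L]
    for (k in seq_along(ep)) {
      p <- ep[k]; c <- ec[k]
      if (keep) Pedges[[po_to_orig[k]]] <-
          diag(ex[k], s) + (1 - ex[k]) / s
      v <- ex[k] * L[c, ] + (1 - ex[k]) / s * sum(L[c, ])
      L[p, ] <- L[p, ] * v
      sc <- sum(L[p, ])
      if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
      L[p, ] <- L[p, ] / sc
      lognorm[p] <- lognorm[p] + lognorm[c] + log(sc)
    }
  } else {
  ## one eigendecomposition per pass; per-edge exponentials are then cheap.
  ## Falls back to scaling-and-squaring when Q is defective.
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  eig_ok <- !is.null(Vi) &&
    max(Mod(eg$vectors %*% (eg$values * Vi) - Q)) <
      1e-8 * max(1, max(abs(Q)))
  Pfun <- if (eig_ok) {
    function(t) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) transition_matrix(Q, t)
  }
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; c <- po$edge[k, 2L]
    P <- Pfun(po$el[k])
    if (keep) Pedges[[po_to_orig[k]]] <- P
    v <- as.vector(P %*% L[c, ])
    L[p, ] <- L[p, ] * v
    sc <- sum(L[p, ])
    if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
    L[p, ] <- L[p, ] / sc
    lognorm[p] <- lognorm[p] + lognorm[c] + log(sc)
  }
  }
  root <- ntip + 1L
  lik_root <- sum(root_prior * L[root, ])
  loglik <- log(lik_root) + lognorm[root]
  if (!keep) return(list(loglik = loglik))
  list(loglik = loglik, partials = L, lognorm = lognorm, P = Pedges,
       postorder = po_to_orig, root_prior = root_prior)
}

## internal: resolve a root prior spec to a vector for a block
resolve_root_prior <- function(root, model) {
  s <- length(model$states)
  if (is.character(root)) {
    switch(match.arg(root, c("uniform", "stationary")),
           uniform = rep(1 / s, s),
           stationary = stationary_distribution(build_rate_matrix(model)))
  } else {
    stopifnot(length(root) == s, all(root >= 0))
    root / sum(root)
  }
}

#' Conditioned focal-character model
#'
#' The focal character has no rate parameters of its own: its state is drawn
#' from a conditional probability table given the joint state of the
#' conditioning characters (one row per joint state, first block varying
#' slowest).
#'
#' @param focal name of the focal character.
#' @param focal_states focal state alphabet.
#' @param cond_states joint conditioning state labels (row order of `table`).
#' @param table conditional probability table (rows on the simplex), or `NULL`
#'   if it is to be estimated.
#' @return an object of class `conditioned_model`.
#' @export
conditioned_model <- function(focal, focal_states, cond_states, table = NULL) {
  if (!is.null(table)) {
    table <- as.matrix(table)
    stopifnot(nrow(table) == length(cond_states),
              ncol(table) == length(focal_states),
              all(table >= 0))
    if (any(abs(rowSums(table) - 1) > 1e-8))
      stop("conditional probability table rows must sum to 1")
    dimnames(table) <- list(cond_states, focal_states)
  }
  structure(list(focal = focal, focal_states = focal_states,
                 cond_states = cond_states, table = table),
            class = "conditioned_model")
}

#' Joint trait models
#'
#' Bundles independent blocks of Markov characters (each block a
#' [rate_model()], possibly on a product "supercharacter" space) with an
#' optional [conditioned_model()] for a focal character, and a root prior.
#'
#' @param blocks named list of [rate_model()]s. A block covering several
#'   characters must carry a `components` attribute naming them (as produced
#'   by [product_states()] / [build_product_model()]); otherwise the block
#'   name is taken as the character name.
#' @param conditioned optional [conditioned_model()]. Its `cond_states` must
#'   equal the joint states of the blocks (first block varying slowest).
#' @param root `"uniform"` (default), `"stationary"`, or a list of per-block
#'   probability vectors.
#' @return an object of class `trait_model`.
#' @export
trait_model <- function(blocks, conditioned = NULL, root = "uniform") {
  stopifnot(is.list(blocks), length(blocks) >= 1L, !is.null(names(blocks)))
  bl <- list()
  for (nm in names(blocks)) {
    m <- blocks[[nm]]
    stopifnot(inherits(m, "rate_model"))
    chars <- if (!is.null(m$components)) names(m$components) else nm
    bl[[nm]] <- list(chars = chars, model = m)
  }
  joint <- joint_state_labels(bl)
  if (!is.null(conditioned)) {
    stopifnot(inherits(conditioned, "conditioned_model"))
    if (!identical(as.character(conditioned$cond_states), joint))
      stop("conditioned model rows must match the joint block states: ",
           paste(joint, collapse = ", "))
  }
  structure(list(blocks = bl, conditioned = conditioned, root = root,
                 joint_states = joint),
            class = "trait_model")
}

## internal: joint labels over blocks, first block slowest
joint_state_labels <- function(blocks) {
  labs <- lapply(blocks, function(b) b$model$states)
  if (length(labs) == 1L) return(as.character(labs[[1L]]))
  as.character(product_states(labs))
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Trait model:", length(x$blocks), "block(s),",
      total_free_rates(x), "free rate(s)\n")
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat("  block ", nm, " [", paste(b$chars, collapse = ", "), "]: ",
        b$model$type, ", ", b$model$n_free, " rate(s)\n", sep = "")
  }
  if (!is.null(x$conditioned))
    cat("  conditioned focal:", x$conditioned$focal, "on",
        length(x$conditioned$cond_states), "joint states\n")
  invisible(x)
}

## internal: total number of free rates across blocks
total_free_rates <- function(model) {
  sum(vapply(model$blocks, function(b) b$model$n_free, 1L))
}

## internal: split a concatenated rate vector into per-block vectors
split_rates <- function(model, rates) {
  ns <- vapply(model$blocks, function(b) b$model$n_free, 1L)
  stopifnot(length(rates) == sum(ns))
  split(rates, rep(seq_along(ns), ns))
}

## internal: names of all free parameters
rate_par_names <- function(model) {
  unlist(lapply(names(model$blocks), function(nm)
    paste0(nm, ":", model$blocks[[nm]]$model$par_names)), use.names = FALSE)
}

## internal: per-tip joint conditioning state index, or NA when ambiguous.
## tipps = list of per-block tip partial matrices.
tip_joint_index <- function(tipps) {
  ntip <- nrow(tipps[[1L]])
  sizes <- vapply(tipps, ncol, 1L)
  idx <- rep(1L, ntip)
  amb <- rep(FALSE, ntip)
  for (b in seq_along(tipps)) {
    one <- apply(tipps[[b]] > 0, 1L, function(r) {
      w <- which(r); if (length(w) == 1L) w else NA_integer_
    })
    amb <- amb | is.na(one)
    idx <- (idx - 1L) * sizes[b] + ifelse(is.na(one), 1L, one)
  }
  idx[amb] <- NA_integer_
  idx
}

#' Log-likelihood of a trait model on a dated tree
#'
#' Felsenstein pruning over the Markov blocks; ambiguous tips contribute the
#' sum over their allowed states. When the model carries a conditioned focal
#' character, each tip contributes the factor `pi(observed focal | joint
#' conditioning state)`; if any conditioning tip is ambiguous the sum over its
#' allowed states is carried inside a single pruning pass on the joint state
#' space (Kronecker-sum generator), otherwise the likelihood factorizes over
#' blocks and the focal factors multiply in directly.
#'
#' @param tree a [dated_tree()].
#' @param data named list of [character_matrix()] covering every character of
#'   the model (including the focal character if conditioned).
#' @param model a [trait_model()].
#' @param rates optional concatenated rate vector overriding the block rates.
#' @param table optional conditional probability table overriding the model's.
#' @param prep internal: precomputed tip structures from
#'   [prepare_tip_structures()] (avoids rebuilding tip partials in samplers).
#' @return the natural-log likelihood.
#' @export
tree_loglik <- function(tree, data, model, rates = NULL, table = NULL,
                        prep = NULL) {
  stopifnot(inherits(tree, "dated_tree"), inherits(model, "trait_model"))
  taxa <- tree$tip.label
  blocks <- model$blocks
  if (!is.null(rates)) {
    rs <- split_rates(model, rates)
    for (b in seq_along(blocks)) blocks[[b]]$model$rates <- rs[[b]]
  }
  tipps <- if (!is.null(prep)) prep$tipps
           else lapply(blocks, block_tip_partials, data = data, taxa = taxa)
  Qs <- lapply(blocks, function(b) build_rate_matrix(b$model))
  roots <- lapply(blocks, function(b)
    resolve_root_prior(model$root, b$model))
  cond <- model$conditioned
  if (!is.null(cond) && is.null(table)) table <- cond$table
  if (is.null(cond)) {
    ll <- 0
    for (b in seq_along(blocks)) {
      r <- pruning_engine(tree, tipps[[b]], Qs[[b]], roots[[b]])
      ll <- ll + r$loglik
    }
    if (!is.finite(ll)) stop("non-finite log-likelihood")
    return(ll)
  }
  if (is.null(table)) stop("conditioned model has no probability table")
  if (!is.null(prep)) {
    fp <- prep$fp
    jidx <- prep$jidx
  } else {
    focal <- data[[cond$focal]]
    if (is.null(focal)) stop("focal character ", cond$focal,
                             " absent from data")
    fp <- char_tip_partials(focal, taxa) # ntip x nf (allowed focal indicator)
    jidx <- tip_joint_index(tipps)
  }
  if (!anyNA(jidx)) {
    ## factorized path: Markov blocks + per-tip table factors
    ll <- 0
    for (b in seq_along(blocks)) {
      r <- pruning_engine(tree, tipps[[b]], Qs[[b]], roots[[b]])
      ll <- ll + r$loglik
    }
    f <- rowSums(table[jidx, , drop = FALSE] * fp)
    if (any(f <= 0))
      stop("observed focal state has zero conditional probability at tip ",
           taxa[which(f <= 0)[1L]])
    return(ll + sum(log(f)))
  }
  ## joint path over the product of all blocks
  Qj <- kronecker_sum(Qs)
  tip_joint <- if (!is.null(prep) && !is.null(prep$tip_joint)) prep$tip_joint
  else {
    tj <- tipps[[1L]]
    if (length(tipps) > 1L)
      for (b in 2L:length(tipps)) {
        a <- tj; bb <- tipps[[b]]
        tj <- matrix(0, nrow(a), ncol(a) * ncol(bb))
        for (i in seq_len(nrow(a)))
          tj[i, ] <- kronecker(a[i, ], bb[i, ])
      }
    tj
  }
  w <- fp %*% t(table) # ntip x S: sum over allowed focal states of pi(f|js)
  jp <- tip_joint * w
  rootj <- Reduce(kronecker, roots)
  r <- pruning_engine(tree, jp, Qj, rootj)
  if (!is.finite(r$loglik)) stop("non-finite log-likelihood")
  r$loglik
}

#' Precompute tip structures for repeated likelihood evaluation
#'
#' Internal helper used by the samplers: tip partials do not depend on the
#' tree (trees in a sample share the taxon set) or on the rates, so they are
#' computed once.
#'
#' @param taxa tip labels (defines row order).
#' @param data named list of [character_matrix()].
#' @param model a [trait_model()].
#' @return a list with `tipps`, and for conditioned models `fp`, `jidx`,
#'   `tip_joint`.
#' @keywords internal
#' @export
prepare_tip_structures <- function(taxa, data, model) {
  tipps <- lapply(model$blocks, block_tip_partials, data = data, taxa = taxa)
  out <- list(tipps = tipps, fp = NULL, jidx = NULL, tip_joint = NULL)
  cond <- model$conditioned
  if (!is.null(cond)) {
    focal <- data[[cond$focal]]
    if (is.null(focal)) stop("focal character ", cond$focal,
                             " absent from data")
    out$fp <- char_tip_partials(focal, taxa)
    out$jidx <- tip_joint_index(tipps)
    if (anyNA(out$jidx)) {
      tj <- tipps[[1L]]
      if (length(tipps) > 1L)
        for (b in 2L:length(tipps)) {
          a <- tj; bb <- tipps[[b]]
          tj <- matrix(0, nrow(a), ncol(a) * ncol(bb))
          for (i in seq_len(nrow(a)))
            tj[i, ] <- kronecker(a[i, ], bb[i, ])
        }
      out$tip_joint <- tj
    }
  }
  out
}

## internal: Kronecker sum of a list of generators (first factor slowest)
kronecker_sum <- function(Qs) {
  if (length(Qs) == 1L) return(Qs[[1L]])
  sizes <- vapply(Qs, nrow, 1L)
  S <- prod(sizes)
  out <- matrix(0, S, S)
  for (b in seq_along(Qs)) {
    left <- if (b > 1L) diag(prod(sizes[seq_len(b - 1L)])) else NULL
    right <- if (b < length(Qs)) diag(prod(sizes[(b + 1L):length(sizes)])) else NULL
    term <- Qs[[b]]
    if (!is.null(left)) term <- kronecker(left, term)
    if (!is.null(right)) term <- kronecker(term, right)
    out <- out + term
  }
  out
}

#' Likelihood and root-posterior landscape over a 2-parameter rate grid
#'
#' Evaluates the log-likelihood and the root-state marginal posterior on a
#' log-spaced grid of the two free rates, flagging cells within 2, 5, and 10
#' natural-log units of the grid maximum.
#'
#' @param tree a [dated_tree()].
#' @param data named list of [character_matrix()].
#' @param model a [trait_model()] with exactly 2 free rates.
#' @param r1,r2 grid values for the first and second rate (log-spaced
#'   recommended).
#' @return a data frame with one row per grid cell: `r1`, `r2`, `loglik`,
#'   one `root_<state>` posterior column per state, and logical flags
#'   `within2`, `within5`, `within10`.
#' @export
rate_grid_scan <- function(tree, data, model,
                           r1 = 10^seq(-5, 0, length.out = 21),
                           r2 = 10^seq(-5, 0, length.out = 21)) {
  stopifnot(total_free_rates(model) == 2L, is.null(model$conditioned),
            length(model$blocks) == 1L)
  b <- model$blocks[[1L]]
  taxa <- tree$tip.label
  tipp <- block_tip_partials(b, data, taxa)
  grid <- expand.grid(r1 = r1, r2 = r2)
  s <- length(b$model$states)
  res <- matrix(NA_real_, nrow(grid), 1L + s)
  for (i in seq_len(nrow(grid))) {
    Q <- build_rate_matrix(b$model, c(grid$r1[i], grid$r2[i]))
    rp <- resolve_root_prior(model$root, b$model)
    pr <- pruning_engine(tree, tipp, Q, rp, keep = TRUE)
    post <- rp * pr$partials[length(taxa) + 1L, ]
    res[i, ] <- c(pr$loglik, post / sum(post))
  }
  out <- cbind(grid, loglik = res[, 1L],
               stats::setNames(as.data.frame(res[, -1L, drop = FALSE]),
                               paste0("root_", b$model$states)))
  mx <- max(out$loglik)
  out$within2 <- out$loglik >= mx - 2
  out$within5 <- out$loglik >= mx - 5
  out$within10 <- out$loglik >= mx - 10
  out
}
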