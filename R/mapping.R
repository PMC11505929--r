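## A mapped history for one (block) character on one dated tree is a data
## frame with columns branch (row of tree$edge), start, end (ages in Ma,
## start > end), state (label). Segments are contiguous and span each branch;
## the state at a node equals the first segment state of its outgoing edges.

#' Sample joint node states conditioned on tip data
#'
#' Draws ancestral states for every node from the exact joint conditional
#' distribution: the root is drawn proportionally to root prior x root
#' partial, then a pre-order descent draws each node proportionally to
#' `P(parent -> state, branch length) x` node partial. Node-state frequencies
#' over draws converge to the exact marginal posteriors.
#'
#' @param tree a [dated_tree()].
#' @param tipp tip partial matrix (tips x states; from a
#'   [character_matrix()] via the block machinery).
#' @param Q generator matrix.
#' @param root_prior probability vector over states.
#' @param n number of draws.
#' @return an `n x (Ntip + Nnode)` integer matrix of state indices.
#' @export
sample_joint_node_states <- function(tree, tipp, Q, root_prior, n = 1L) {
  pr <- pruning_engine(tree, tipp, Q, root_prior, keep = TRUE)
  if (!is.finite(pr$loglik))
    stop("zero-probability configuration: data impossible under the model")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  s <- nrow(Q)
  states <- matrix(0L, n, nn)
  p0 <- root_prior * pr$partials[root, ]
  states[, root] <- sample.int(s, n, replace = TRUE, prob = p0)
  ## pre-order = reverse postorder over original edge indices
  po_orig <- postorder_edges(tree)$map
  for (k in rev(seq_along(po_orig))) {
    e <- po_orig[k]
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    W <- pr$P[[e]] * rep(pr$partials[c, ], each = s)
    rs <- rowSums(W)
    if (any(rs <= 0)) {
      zero <- which(rs <= 0)
      if (any(states[, p] %in% zero))
        stop("zero-probability configuration on edge ", e)
    }
    W <- W / rs
    for (a in unique(states[, p])) {
      sel <- states[, p] == a
      states[sel, c] <- sample.int(s, sum(sel), replace = TRUE,
                                   prob = W[a, ])
    }
  }
  states
}

## internal: cache of R = I + Q/Omega matrix powers
rpower_cache <- function(R) {
  env <- new.env(parent = emptyenv())
  env$pows <- list(diag(nrow(R)), R)
  function(n) { # returns R^n
    while (length(env$pows) < n + 1L)
      env$pows[[length(env$pows) + 1L]] <-
        env$pows[[length(env$pows)]] %*% R
    env$pows[[n + 1L]]
  }
}

## internal: reusable uniformization structures for one generator
unif_cache <- function(Q, omega_factor = 1.05) {
  omega <- omega_factor * max(abs(diag(Q)))
  if (omega <= 0)
    return(list(omega = 0, R = NULL, rpow = NULL, Q = Q))
  R <- diag(nrow(Q)) + Q / omega
  list(omega = omega, R = R, rpow = rpower_cache(R), Q = Q)
}

#' Endpoint-conditioned CTMC path on a single branch
#'
#' Samples a path conditioned to start in state `a` and end in state `b`
#' after time `t`, by uniformization: the number of virtual jumps is drawn
#' from its conditional law, the jump chain is sampled backward-conditioned,
#' jump times are uniform order statistics, and self-jumps are dropped. A
#' plain rejection sampler (forward simulation until the endpoint matches) is
#' available as an independent oracle.
#'
#' @param a,b start and end state indices.
#' @param t branch duration in Myr.
#' @param Q generator matrix.
#' @param method `"uniformization"` or `"rejection"`.
#' @param omega_factor uniformization constant is
#'   `omega_factor * max |q_ii|` (default 1.05).
#' @param max_tries rejection-sampler retry cap.
#' @param cache internal: reusable uniformization structures for `Q`.
#' @return a list with `times` (jump times in (0, t), increasing) and
#'   `states` (state index after each jump); both length 0 when no real
#'   transition occurs.
#' @export
sample_branch_history <- function(a, b, t, Q,
                                  method = c("uniformization", "rejection"),
                                  omega_factor = 1.05, max_tries = 1e6,
                                  cache = NULL) {
  method <- match.arg(method)
  s <- nrow(Q)
  a <- as.integer(a); b <- as.integer(b)
  if (t <= 0) {
    if (a != b) stop("zero-length branch with differing endpoint states")
    return(list(times = numeric(0), states = integer(0)))
  }
  if (method == "rejection") {
    for (try in seq_len(max_tries)) {
      path <- forward_path(a, t, Q)
      end <- if (length(path$states)) path$states[length(path$states)] else a
      if (end == b) return(path)
    }
    stop("rejection sampler failed after ", max_tries, " tries")
  }
  if (is.null(cache)) cache <- unif_cache(Q, omega_factor)
  unif_path(a, b, t, Q, cache)
}

## internal: uniformization core (no argument dispatch; hot path)
unif_path <- function(a, b, t, Q, cache) {
  s <- nrow(Q)
  omega <- cache$omega
  if (omega <= 0) {
    if (a != b) stop("numerically zero transition probability")
    return(list(times = numeric(0), states = integer(0)))
  }
  if (omega * t > 5e4)
    stop("uniformization would need > 5e4 expected jumps on one branch ",
         "(rate x duration = ", format(omega * t, digits = 3),
         "); the rates are implausibly high for this time scale")
  R <- cache$R
  rpow <- cache$rpow
  Pab <- transition_matrix(Q, t)[a, b]
  if (Pab <= 0) stop("numerically zero transition probability from ", a,
                     " to ", b, " over t = ", t)
  ## draw the number of uniformized jumps n | a, b, t
  u <- stats::runif(1) * Pab
  n <- -1L
  cum <- 0
  lambda <- omega * t
  repeat {
    n <- n + 1L
    cum <- cum + stats::dpois(n, lambda) * rpow(n)[a, b]
    if (cum >= u || n > 10000L) break
  }
  if (n == 0L) return(list(times = numeric(0), states = integer(0)))
  ## conditioned jump chain
  v <- integer(n + 1L)
  v[1L] <- a; v[n + 1L] <- b
  if (n > 1L) for (i in 2L:n) {
    w <- R[v[i - 1L], ] * rpow(n - i + 1L)[, b]
    v[i] <- sample.int(s, 1L, prob = w)
  }
  times <- sort(stats::runif(n)) * t
  ## drop self-jumps
  keep <- v[-1L] != v[-(n + 1L)]
  list(times = times[keep], states = v[-1L][keep])
}

## internal: unconditioned forward path over duration t from state a
forward_path <- function(a, t, Q) {
  cur <- a
  tm <- 0
  times <- numeric(0); states <- integer(0)
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break
    w <- stats::rexp(1, rate)
    if (tm + w >= t) break
    tm <- tm + w
    p <- Q[cur, ]; p[cur] <- 0
    cur <- sample.int(nrow(Q), 1L, prob = p)
    times <- c(times, tm); states <- c(states, cur)
  }
  list(times = times, states = states)
}

## internal: assemble a mapped-history data frame for one draw of node states
## on one tree. node_states: integer vector over all nodes.
branch_histories <- function(tree, node_states, Q, labels,
                             method = "uniformization") {
  ages <- node_ages(tree)
  ne <- nrow(tree$edge)
  cache <- if (method == "uniformization") unif_cache(Q) else NULL
  br <- st_i <- vector("list", ne)
  s0 <- s1 <- vector("list", ne)
  for (e in seq_len(ne)) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    t <- ages[p] - ages[c]
    path <- if (is.null(cache))
      sample_branch_history(node_states[p], node_states[c], t, Q,
                            method = method)
    else unif_path(node_states[p], node_states[c], t, Q, cache)
    bounds <- c(0, path$times, t)
    br[[e]] <- rep.int(e, length(bounds) - 1L)
    s0[[e]] <- ages[p] - bounds[-length(bounds)]
    s1[[e]] <- ages[p] - bounds[-1L]
    st_i[[e]] <- c(node_states[p], path$states)
  }
  h <- data.frame(branch = unlist(br), start = unlist(s0),
                  end = unlist(s1), state = labels[unlist(st_i)])
  attr(h, "root_state") <- labels[node_states[length(tree$tip.label) + 1L]]
  h
}

#' Forward (unconditioned) simulation of a character history
#'
#' Simulates evolution from a root state drawn from the root prior, with no
#' conditioning on tip data. Used for posterior-predictive null simulations
#' in the D-test and by the synthetic-data generator.
#'
#' @param tree a [dated_tree()].
#' @param Q generator matrix.
#' @param root_prior probability vector over states.
#' @param labels state labels (default from `Q` dimnames).
#' @return a mapped-history data frame (`branch`, `start`, `end`, `state`)
#'   with attributes `root_state` and `tip_states` (named vector of tip state
#'   labels).
#' @export
simulate_unconditioned <- function(tree, Q, root_prior = NULL,
                                   labels = rownames(Q)) {
  s <- nrow(Q)
  if (is.null(labels)) labels <- as.character(seq_len(s))
  if (is.null(root_prior)) root_prior <- rep(1 / s, s)
  ages <- node_ages(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  node_state <- integer(nn)
  root <- ntip + 1L
  node_state[root] <- sample.int(s, 1L, prob = root_prior)
  po_orig <- postorder_edges(tree)$map
  ne <- nrow(tree$edge)
  br <- st_i <- s0 <- s1 <- vector("list", ne)
  for (k in rev(seq_along(po_orig))) {
    e <- po_orig[k]
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    t <- ages[p] - ages[c]
    path <- forward_path(node_state[p], t, Q)
    end_state <- if (length(path$states)) path$states[length(path$states)]
                 else node_state[p]
    node_state[c] <- end_state
    bounds <- c(0, path$times, t)
    br[[e]] <- rep.int(e, length(bounds) - 1L)
    s0[[e]] <- ages[p] - bounds[-length(bounds)]
    s1[[e]] <- ages[p] - bounds[-1L]
    st_i[[e]] <- c(node_state[p], path$states)
  }
  h <- data.frame(branch = unlist(br), start = unlist(s0),
                  end = unlist(s1), state = labels[unlist(st_i)])
  attr(h, "root_state") <- labels[node_state[root]]
  attr(h, "node_states") <- labels[node_state]
  attr(h, "tip_states") <- stats::setNames(labels[node_state[seq_len(ntip)]],
                                           tree$tip.label)
  h
}

## internal: state of a history at a given age on a given branch (the segment
## containing the age; boundaries resolve to the older segment).
history_state_at <- function(history, branch, age) {
  seg <- history[history$branch == branch, ]
  i <- which(seg$start >= age - 1e-9 & seg$end <= age + 1e-9)
  if (length(i) == 0L) return(NA_character_)
  seg$state[i[1L]]
}

## internal: merged joint segments of several block histories on one edge.
## Returns list(start, end, state) with state = pasted block labels, oldest
## first. `splits` holds per-history row indices by branch (as character).
joint_edge_segments_fast <- function(histories, splits, e) {
  ec <- as.character(e)
  rows <- lapply(splits, function(s) s[[ec]])
  starts_l <- mapply(function(h, r) h$start[r], histories, rows,
                     SIMPLIFY = FALSE)
  bounds <- sort(unique(c(unlist(starts_l),
                          histories[[1L]]$end[rows[[1L]][length(rows[[1L]])]])),
                 decreasing = TRUE)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  mids <- (starts + ends) / 2
  parts <- vapply(seq_along(histories), function(b) {
    k <- findInterval(-mids, -starts_l[[b]])
    histories[[b]]$state[rows[[b]][k]]
  }, character(length(mids)))
  state <- if (length(histories) == 1L) as.character(parts)
           else apply(matrix(parts, ncol = length(histories)), 1L, paste,
                      collapse = "")
  list(start = starts, end = ends, state = state)
}

## internal: back-compatible wrapper used by combined_history
joint_edge_segments <- function(histories, e) {
  splits <- lapply(histories, function(h)
    split(seq_len(nrow(h)), h$branch))
  out <- joint_edge_segments_fast(histories, splits, e)
  data.frame(start = out$start, end = out$end, state = out$state)
}

#' Overlay a conditioned focal character on conditioning histories
#'
#' The joint conditioning state is piecewise constant along the tree; on each
#' maximal constant segment the focal state is drawn once from the
#' conditional probability table row for that joint state, independently
#' across segments — except the segment abutting each tip, whose focal state
#' is set to the observed focal tip state (drawn from the table row restricted
#' to the allowed set when the observation is ambiguous).
#'
#' @param histories named list of mapped histories, one per conditioning
#'   block, in the row-label order of `table` (first block varying slowest).
#' @param tree the [dated_tree()] the histories live on.
#' @param table conditional probability table (rows = joint states, columns =
#'   focal states).
#' @param focal_data [character_matrix()] of observed focal tip states, or
#'   `NULL` to skip tip clamping (posterior-predictive mode).
#' @return a mapped-history data frame for the focal character.
#' @export
overlay_conditioned <- function(histories, tree, table, focal_data = NULL) {
  focal_states <- colnames(table)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  pre <- rev(postorder_edges(tree)$map)
  splits <- lapply(histories, function(h) split(seq_len(nrow(h)), h$branch))
  jsegs <- lapply(seq_len(nrow(tree$edge)), function(e)
    joint_edge_segments_fast(histories, splits, e))
  draw_focal <- function(js, allowed = NULL) {
    p <- table[js, ]
    if (!is.null(allowed)) {
      keep <- focal_states %in% allowed
      p <- p * keep
      if (sum(p) <= 0)
        stop("observed focal state has zero conditional probability under ",
             "joint conditioning state ", js)
    }
    sample(focal_states, 1L, prob = p)
  }
  ## root joint state = state at start of any root child edge
  root_edge <- which(tree$edge[, 1L] == root)[1L]
  js_root <- jsegs[[root_edge]]$state[1L]
  focal_at_node <- character(nn)
  js_at_node <- character(nn)
  focal_at_node[root] <- draw_focal(js_root)
  js_at_node[root] <- js_root
  ne <- nrow(tree$edge)
  o_br <- o_s0 <- o_s1 <- o_st <- vector("list", ne)
  for (e in pre) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    seg <- jsegs[[e]]
    nseg <- length(seg$start)
    fs <- focal_at_node[p]
    js <- js_at_node[p]
    starts <- ends <- numeric(0); states <- character(0)
    cur_start <- seg$start[1L]
    is_tip <- c <= ntip
    for (i in seq_len(nseg)) {
      if (seg$state[i] != js) {
        js <- seg$state[i]
        new_fs <- draw_focal(js)
        if (new_fs != fs) {
          starts <- c(starts, cur_start); ends <- c(ends, seg$start[i])
          states <- c(states, fs)
          cur_start <- seg$start[i]
          fs <- new_fs
        }
      }
      ## clamp the tip-abutting segment to the observation
      if (is_tip && i == nseg && !is.null(focal_data)) {
        obs <- focal_data$tips[[tree$tip.label[c]]]
        if (!(fs %in% obs)) {
          new_fs <- draw_focal(js, allowed = obs)
          starts <- c(starts, cur_start); ends <- c(ends, seg$start[i])
          states <- c(states, fs)
          cur_start <- seg$start[i]
          fs <- new_fs
        }
      }
    }
    starts <- c(starts, cur_start); ends <- c(ends, seg$end[nseg])
    states <- c(states, fs)
    ## drop any zero-length leading piece created by a change at the edge top
    keep <- starts > ends | (starts == ends & length(starts) == 1L)
    o_br[[e]] <- rep.int(e, sum(keep))
    o_s0[[e]] <- starts[keep]; o_s1[[e]] <- ends[keep]
    o_st[[e]] <- states[keep]
    focal_at_node[c] <- fs
    js_at_node[c] <- js
  }
  h <- data.frame(branch = unlist(o_br), start = unlist(o_s0),
                  end = unlist(o_s1), state = unlist(o_st))
  attr(h, "root_state") <- focal_at_node[root]
  attr(h, "node_states") <- focal_at_node
  h
}

## internal: transitions (jump events) of a history as a data frame
## (age, from, to)
history_transitions <- function(history) {
  out <- list()
  for (e in unique(history$branch)) {
    seg <- history[history$branch == e, ]
    if (nrow(seg) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      age = seg$end[-nrow(seg)],
      from = seg$state[-nrow(seg)],
      to = seg$state[-1L])
  }
  if (length(out) == 0L)
    return(data.frame(age = numeric(0), from = character(0),
                      to = character(0)))
  do.call(rbind, out)
}
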