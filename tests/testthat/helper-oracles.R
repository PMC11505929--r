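## Independent oracles used across the suite: brute-force likelihood and
## marginals by enumeration of internal-node states, and quadrature marginal
## likelihoods for 1-parameter models. These deliberately avoid the package's
## pruning machinery.

## enumerate internal-node states; tipp is a 0/1 tips x states matrix
brute_force_likelihood <- function(tree, tipp, Q, root_prior) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  s <- nrow(Q)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    solutemap::transition_matrix(Q, tree$edge.length[e]))
  internals <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(seq_len(s)), length(internals)))
  total <- 0
  node_tot <- matrix(0, nn, s)
  for (g in seq_len(nrow(grid))) {
    state <- integer(nn)
    state[internals] <- as.integer(grid[g, ])
    p <- root_prior[state[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- state[tree$edge[e, 1L]]
      ch <- tree$edge[e, 2L]
      if (ch <= ntip) p <- p * sum(P[[e]][par, ] * tipp[ch, ])
      else p <- p * P[[e]][par, state[ch]]
    }
    total <- total + p
    for (nd in internals) node_tot[nd, state[nd]] <-
        node_tot[nd, state[nd]] + p
  }
  list(likelihood = total,
       node_marginals = node_tot / total)
}

## quadrature marginal likelihood for a 1-rate model under a prior_spec
quadrature_logml <- function(tree, data, model, prior) {
  dens <- function(r) {
    p <- prior[[1L]]
    if (p$type == "lognormal") stats::dlnorm(r, p$meanlog, p$sdlog)
    else stats::dexp(r, p$rate)
  }
  f <- function(r) vapply(r, function(x)
    exp(solutemap::tree_loglik(tree, data, model, rates = x)) * dens(x), 0)
  ## integrate in two pieces for numerical safety
  i1 <- stats::integrate(f, 0, 0.05, rel.tol = 1e-10,
                         subdivisions = 500L)$value
  i2 <- stats::integrate(f, 0.05, Inf, rel.tol = 1e-10,
                         subdivisions = 500L)$value
  log(i1 + i2)
}

## a fixed, hand-dated 4-tip tree used by several tests
fixture_tree4 <- function() {
  solutemap::dated_tree(ape::read.tree(
    text = "((A:100,B:100):100,(C:150,D:150):50);"))
}

fixture_tree5 <- function() {
  solutemap::dated_tree(ape::read.tree(
    text = "(((A:50,B:50):100,(C:120,D:120):30):50,E:200);"))
}

## posterior-predictive D-test with exchangeable null replicates: the
## observed statistic averages deviations over tip-conditioned maps of the
## data; each null replicate simulates a fresh independent tip dataset and
## averages over tip-conditioned maps of it the same way.
pp_dtest <- function(tree, Q1, Q2, d1, d2, labels1 = c("A", "P"),
                     labels2 = c("L", "H"), n_draw = 15, n_null = 40) {
  map_pairs <- function(dd1, dd2, n) {
    tp1 <- solutemap:::char_tip_partials(dd1, tree$tip.label)
    tp2 <- solutemap:::char_tip_partials(dd2, tree$tip.label)
    ns1 <- solutemap::sample_joint_node_states(tree, tp1, Q1,
                                               rep(0.5, 2), n = n)
    ns2 <- solutemap::sample_joint_node_states(tree, tp2, Q2,
                                               rep(0.5, 2), n = n)
    lapply(seq_len(n), function(i) list(
      solutemap:::branch_histories(tree, ns1[i, ], Q1, labels1),
      solutemap:::branch_histories(tree, ns2[i, ], Q2, labels2)))
  }
  obs <- map_pairs(d1, d2, n_draw)
  nul <- lapply(seq_len(n_null), function(r) {
    h1 <- solutemap::simulate_unconditioned(tree, Q1, labels = labels1)
    h2 <- solutemap::simulate_unconditioned(tree, Q2, labels = labels2)
    dd1 <- solutemap::character_matrix("g", labels1,
                                       as.list(attr(h1, "tip_states")))
    dd2 <- solutemap::character_matrix("h", labels2,
                                       as.list(attr(h2, "tip_states")))
    map_pairs(dd1, dd2, n_draw)
  })
  solutemap::d_test(obs, nul, tree, states1 = labels1, states2 = labels2)
}

## random generator on s states with a fixed seed
random_generator <- function(s, seed, scale = 0.01) {
  set.seed(seed)
  m <- solutemap::rate_model(LETTERS[seq_len(s)], "ARD")
  solutemap::build_rate_matrix(m, stats::runif(m$n_free, 0.1, 1) * scale)
}
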