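test_that("node-state draws converge to exact marginals (4-tip tree)", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ARD",
                                    rates = c(0.003, 0.006)))
  tipp <- rbind(c(1, 0), c(0, 1), c(0, 1), c(1, 0))
  root_prior <- c(0.5, 0.5)
  bf <- brute_force_likelihood(tr, tipp, Q, root_prior)
  set.seed(31)
  n <- 1e4
  draws <- sample_joint_node_states(tr, tipp, Q, root_prior, n = n)
  for (node in 5:7) {
    p_exact <- bf$node_marginals[node, 1L]
    p_hat <- mean(draws[, node] == 1L)
    se <- sqrt(p_exact * (1 - p_exact) / n)
    expect_lt(abs(p_hat - p_exact), 3 * max(se, 1e-4))
  }
})

test_that("node sampling respects degenerate and reproducible cases", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 1e-12))
  tipp <- matrix(rep(c(1, 0), each = 4), 4)
  set.seed(1)
  d <- sample_joint_node_states(tr, tipp, Q, c(0.5, 0.5), n = 50)
  expect_true(all(d[, 5:7] == 1L)) # rate ~ 0, all tips L -> all nodes L
  set.seed(17)
  d1 <- sample_joint_node_states(tr, tipp, Q, c(0.5, 0.5), n = 10)
  set.seed(17)
  d2 <- sample_joint_node_states(tr, tipp, Q, c(0.5, 0.5), n = 10)
  expect_identical(d1, d2)
})

test_that("endpoint-conditioned paths have correct structure", {
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.5))
  set.seed(5)
  ## a = b with negligible rate: no transitions
  Q0 <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 1e-12))
  p <- sample_branch_history(1, 1, 1, Q0)
  expect_length(p$times, 0L)
  ## differing endpoints: odd transition count for 2 states
  for (i in 1:50) {
    p <- sample_branch_history(1, 2, 2, Q)
    expect_gte(length(p$times), 1L)
    expect_identical(length(p$times) %% 2L, 1L)
    expect_identical(p$states[length(p$states)], 2L)
    expect_true(all(diff(p$times) >= 0))
  }
  ## equal endpoints: even count
  for (i in 1:50)
    expect_identical(length(sample_branch_history(1, 1, 2, Q)$times) %% 2L,
                     0L)
})

test_that("uniformization and rejection samplers agree in distribution", {
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.5))
  set.seed(9)
  n <- 1e4
  cu <- vapply(seq_len(n), function(i)
    length(sample_branch_history(1, 1, 1, Q)$times), 1L)
  cr <- vapply(seq_len(n), function(i)
    length(sample_branch_history(1, 1, 1, Q, method = "rejection")$times),
    1L)
  ## mean transition counts within 3 SE of each other
  se <- sqrt(stats::var(cu) / n + stats::var(cr) / n)
  expect_lt(abs(mean(cu) - mean(cr)), 3 * se)
  ## full distributions agree (chi-squared on pooled counts)
  tab <- table(factor(c(cu, cr), levels = 0:max(c(cu, cr))),
               rep(c("u", "r"), each = n))
  keep <- rowSums(tab) >= 10
  chi <- suppressWarnings(stats::chisq.test(tab[keep, ]))
  expect_gt(chi$p.value, 0.001)
})

test_that("forward simulation matches transition-matrix tip marginals", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ARD",
                                    rates = c(0.004, 0.002)))
  set.seed(13)
  n <- 2500
  tipL <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    h <- simulate_unconditioned(tr, Q, c(1, 0)) # root fixed at L
    tipL[i, ] <- attr(h, "tip_states") == "L"
  }
  ages <- node_ages(tr)
  for (tip in 1:4) {
    p_exact <- transition_matrix(Q, ages[5] - 0)[1, 1] # root-to-tip time
    ## exact marginal: P(root -> tip state L) over the root-to-tip path,
    ## which is just exp(Q * root_age) since the tree is ultrametric
    p_hat <- mean(tipL[, tip])
    se <- sqrt(p_exact * (1 - p_exact) / n)
    expect_lt(abs(p_hat - p_exact), 4 * se)
  }
  ## rate 0: the whole tree inherits the root state
  h0 <- simulate_unconditioned(tr, build_rate_matrix(
    rate_model(c("L", "H"), "ER", rates = 0)), c(0, 1))
  expect_true(all(h0$state == "H"))
})

test_that("sampled histories are consistent with tip data by construction", {
  set.seed(23)
  sc <- simulation_scenario(
    n_taxa = 20, n_trees = 5,
    characters = list(x = list(model = rate_model(c("L", "H"), "ER",
                                                  rates = 1e-3))),
    seed = 23)
  ts <- simulate_tree_sample(sc)
  sim <- simulate_characters(sc, ts[[1L]])
  m <- trait_model(list(x = rate_model(c("L", "H"), "ER", rates = 1e-3)))
  prep <- prepare_tip_structures(ts[[1L]]$tip.label, sim$data, m)
  Q <- build_rate_matrix(m$blocks$x$model)
  for (k in 1:3) {
    tree <- ts[[k]]
    ns <- sample_joint_node_states(tree, prep$tipps[[1L]], Q, c(0.5, 0.5),
                                   n = 20)
    for (i in 1:20) {
      h <- solutemap:::branch_histories(tree, ns[i, ], Q, c("L", "H"))
      solutemap:::validate_history(h, tree)
      ## tip segment state equals the observed state
      for (e in which(tree$edge[, 2L] <= 20)) {
        seg <- h[h$branch == e, ]
        tip <- tree$tip.label[tree$edge[e, 2L]]
        expect_identical(seg$state[nrow(seg)], sim$data$x$tips[[tip]])
      }
      ## child initial state equals parent final state across every edge
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]
        pe <- which(tree$edge[, 2L] == p)
        if (length(pe) == 0L) next
        seg_p <- h[h$branch == pe, ]
        seg_c <- h[h$branch == e, ]
        expect_identical(seg_c$state[1L], seg_p$state[nrow(seg_p)])
      }
    }
  }
})

test_that("conditioned overlay reproduces the table mixture at interior points", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("A", "P"), "ER", rates = 0.004))
  tab <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE,
                dimnames = list(c("A", "P"), c("L", "H")))
  set.seed(41)
  n <- 2500
  probe_branch <- 1L # the A-tip branch, probe its midpoint
  ages <- node_ages(tr)
  mid <- (ages[tr$edge[probe_branch, 1L]] +
          ages[tr$edge[probe_branch, 2L]]) / 2
  hitL <- 0; hitA <- 0
  for (i in seq_len(n)) {
    hc <- simulate_unconditioned(tr, Q, c(0.5, 0.5))
    foc <- overlay_conditioned(list(gg = hc), tr, tab, focal_data = NULL)
    sc <- solutemap:::history_state_at(hc, probe_branch, mid)
    sf <- solutemap:::history_state_at(foc, probe_branch, mid)
    hitA <- hitA + (sc == "A")
    hitL <- hitL + (sf == "L")
  }
  pA <- hitA / n
  p_exp <- pA * tab["A", "L"] + (1 - pA) * tab["P", "L"]
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(hitL / n - p_exp), 4 * se)
})

test_that("deterministic tables relabel and tip clamping binds", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("A", "P"), "ER", rates = 0.004))
  det <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                dimnames = list(c("A", "P"), c("L", "H")))
  set.seed(3)
  hc <- simulate_unconditioned(tr, Q, c(0.5, 0.5))
  foc <- overlay_conditioned(list(gg = hc), tr, det, focal_data = NULL)
  expect_identical(ifelse(hc$state == "A", "L", "H"), foc$state)
  ## clamped tips match observations even under a near-deterministic table
  soft <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE,
                 dimnames = list(c("A", "P"), c("L", "H")))
  obs <- character_matrix("habitat", c("L", "H"),
                          list(A = "H", B = "L", C = "H", D = "L"))
  for (i in 1:10) {
    hc <- simulate_unconditioned(tr, Q, c(0.5, 0.5))
    foc <- overlay_conditioned(list(gg = hc), tr, soft, focal_data = obs)
    for (e in which(tr$edge[, 2L] <= 4)) {
      seg <- foc[foc$branch == e, ]
      expect_identical(seg$state[nrow(seg)],
                       obs$tips[[tr$tip.label[tr$edge[e, 2L]]]])
    }
  }
  ## a zero-probability observation is a model-misfit error
  zero <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE,
                 dimnames = list(c("A", "P"), c("L", "H")))
  expect_error(
    overlay_conditioned(list(gg = hc), tr, zero, focal_data = obs),
    "zero conditional probability")
})
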