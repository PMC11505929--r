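test_that("pruning equals brute-force enumeration on small trees", {
  ## 4 tips x {2,3,4} states, including ambiguous and missing tips
  tr <- fixture_tree4()
  for (s in 2:4) {
    Q <- random_generator(s, seed = 100 + s)
    states <- LETTERS[seq_len(s)]
    set.seed(s)
    tips <- lapply(tr$tip.label, function(tx) {
      k <- sample(c(1L, 1L, 1L, 2L, s), 1L)
      sample(states, min(k, s))
    })
    names(tips) <- tr$tip.label
    cm <- character_matrix("x", states, tips)
    ## inject Q through an ARD model built from its cells
    rm <- rate_model(states, "ARD")
    rates <- numeric(rm$n_free)
    for (i in seq_len(s)) for (j in seq_len(s)) if (i != j)
      rates[rm$class_map[i, j]] <- Q[i, j]
    m <- trait_model(list(x = rate_model(states, "ARD", rates = rates)))
    ll <- tree_loglik(tr, list(x = cm), m)
    tipp <- matrix(0, length(tips), s)
    for (i in seq_along(tips)) tipp[i, match(tips[[i]], states)] <- 1
    bf <- brute_force_likelihood(tr, tipp, Q, rep(1 / s, s))
    expect_equal(ll, log(bf$likelihood), tolerance = 1e-10)
  }
  ## and a 5-tip case
  tr5 <- fixture_tree5()
  Q <- random_generator(3, seed = 42)
  states <- LETTERS[1:3]
  cm <- character_matrix("x", states,
                         stats::setNames(list("A", "B", c("A", "C"), "C",
                                              states),
                                         tr5$tip.label))
  rm <- rate_model(states, "ARD")
  rates <- numeric(rm$n_free)
  for (i in 1:3) for (j in 1:3) if (i != j)
    rates[rm$class_map[i, j]] <- Q[i, j]
  ll <- tree_loglik(tr5, list(x = cm),
                    trait_model(list(x = rate_model(states, "ARD",
                                                    rates = rates))))
  tipp <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 1), c(0, 0, 1), c(1, 1, 1))
  bf <- brute_force_likelihood(tr5, tipp, Q, rep(1 / 3, 3))
  expect_equal(ll, log(bf$likelihood), tolerance = 1e-10)
})

test_that("textbook two-tip likelihood is exact", {
  t2 <- dated_tree(ape::read.tree(
    text = sprintf("(A:%.12f,B:%.12f);", log(2), log(2))))
  cm <- character_matrix("x", c("L", "H"), list(A = "L", B = "L"))
  m <- trait_model(list(x = rate_model(c("L", "H"), "ER", rates = 0.5)))
  expect_equal(tree_loglik(t2, list(x = cm), m), log(0.3125),
               tolerance = 1e-12)
  ## rate 0: only the shared-state likelihood survives
  m0 <- trait_model(list(x = rate_model(c("L", "H"), "ER", rates = 0)))
  expect_equal(tree_loglik(t2, list(x = cm), m0), log(0.5),
               tolerance = 1e-12)
})

test_that("conditioned likelihood factorizes for unambiguous tips", {
  tr <- fixture_tree4()
  gg <- character_matrix("gg", c("A", "P"),
                         list(A = "P", B = "P", C = "A", D = "P"))
  hab <- character_matrix("habitat", c("L", "H"),
                          list(A = "H", B = "H", C = "L", D = "L"))
  tab <- matrix(c(0.9, 0.1, 0.25, 0.75), 2, byrow = TRUE,
                dimnames = list(c("A", "P"), c("L", "H")))
  cmod <- conditioned_model("habitat", c("L", "H"), c("A", "P"), tab)
  base <- trait_model(list(gg = rate_model(c("A", "P"), "ER", rates = 0.003)))
  jm <- trait_model(list(gg = rate_model(c("A", "P"), "ER", rates = 0.003)),
                    conditioned = cmod)
  ll_joint <- tree_loglik(tr, list(gg = gg, habitat = hab), jm)
  ll_markov <- tree_loglik(tr, list(gg = gg), base)
  focal_factor <- log(0.75) + log(0.75) + log(0.9) + log(0.25)
  expect_equal(ll_joint, ll_markov + focal_factor, tolerance = 1e-12)

  ## deterministic table, consistent data -> focal factor 1
  det <- conditioned_model("habitat", c("L", "H"), c("A", "P"),
                           matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  hab2 <- character_matrix("habitat", c("L", "H"),
                           list(A = "H", B = "H", C = "L", D = "H"))
  jm2 <- trait_model(list(gg = rate_model(c("A", "P"), "ER", rates = 0.003)),
                     conditioned = det)
  expect_equal(tree_loglik(tr, list(gg = gg, habitat = hab2), jm2),
               ll_markov, tolerance = 1e-12)
  ## inconsistent observation has probability zero
  expect_error(tree_loglik(tr, list(gg = gg, habitat = hab), jm2),
               "zero conditional probability")
})

test_that("ambiguous conditioning tips run through the joint state space", {
  tr <- fixture_tree4()
  gg <- character_matrix("gg", c("A", "P"),
                         list(A = "P", B = "P", C = c("A", "P"), D = "P"))
  hab <- character_matrix("habitat", c("L", "H"),
                          list(A = "H", B = "H", C = "L", D = "L"))
  tab <- matrix(c(0.9, 0.1, 0.25, 0.75), 2, byrow = TRUE,
                dimnames = list(c("A", "P"), c("L", "H")))
  jm <- trait_model(list(gg = rate_model(c("A", "P"), "ER", rates = 0.003)),
                    conditioned = conditioned_model("habitat", c("L", "H"),
                                                    c("A", "P"), tab))
  lla <- tree_loglik(tr, list(gg = gg, habitat = hab), jm)
  ## manual sum over the ambiguous tip's states
  ggA <- character_matrix("gg", c("A", "P"),
                          list(A = "P", B = "P", C = "A", D = "P"))
  ggP <- character_matrix("gg", c("A", "P"),
                          list(A = "P", B = "P", C = "P", D = "P"))
  llA <- tree_loglik(tr, list(gg = ggA, habitat = hab), jm)
  llP <- tree_loglik(tr, list(gg = ggP, habitat = hab), jm)
  expect_equal(lla, log(exp(llA) + exp(llP)), tolerance = 1e-10)
})

test_that("MLE recovers simulated rates and hits closed forms", {
  set.seed(21)
  sc <- simulation_scenario(
    n_taxa = 200, n_trees = 1, age_jitter_sd = 0,
    characters = list(x = list(model = rate_model(c("L", "H"), "ER",
                                                  rates = 0.01))),
    seed = 21)
  ts <- simulate_tree_sample(sc)
  sim <- simulate_characters(sc, ts[[1L]])
  fit <- mle_fit(ts, sim$data, trait_model(list(x = rate_model(c("L", "H"),
                                                               "ER"))))
  expect_gt(fit$par, 0.005)
  expect_lt(fit$par, 0.02)

  ## all tips identical: ER MLE at the lower optimization bound
  cm <- character_matrix("x", c("L", "H"),
                         stats::setNames(rep(list("L"), 4),
                                         fixture_tree4()$tip.label))
  flat <- mle_fit(fixture_tree4(), list(x = cm),
                  trait_model(list(x = rate_model(c("L", "H"), "ER"))))
  expect_lt(flat$par, 1e-8)

  ## deterministic conditioned data: table MLE = observed frequencies
  tr <- fixture_tree4()
  gg <- character_matrix("gg", c("A", "P"),
                         list(A = "P", B = "P", C = "A", D = "P"))
  hab <- character_matrix("habitat", c("L", "H"),
                          list(A = "H", B = "H", C = "L", D = "L"))
  jm <- trait_model(list(gg = rate_model(c("A", "P"), "ER")),
                    conditioned = conditioned_model("habitat", c("L", "H"),
                                                    c("A", "P")))
  cf <- mle_fit(tr, list(gg = gg, habitat = hab), jm)
  expect_equal(unname(cf$table["A", ]), c(1, 0))
  expect_equal(unname(cf$table["P", ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("empirical-Bayes priors follow the MLE-threshold rule", {
  pr <- empirical_bayes_priors(c(a = 0.5, b = 0.005))
  expect_identical(pr[[1L]]$type, "lognormal")
  expect_equal(unname(pr[[1L]]$meanlog), log(0.5))
  expect_identical(pr[[2L]]$type, "exponential")
  expect_equal(pr[[2L]]$rate, 100)
  ## ~98% of log-normal mass within a factor 10 of the MLE; median = MLE
  expect_equal(unname(prior_mass(pr, c(0.05, 0), c(5, Inf))[1L]),
               stats::pnorm(log(10)) - stats::pnorm(-log(10)),
               tolerance = 1e-12)
  expect_equal(stats::qlnorm(0.5, pr[[1L]]$meanlog, 1), 0.5)
  ## boundary: exactly 0.01 uses the exponential
  expect_identical(empirical_bayes_priors(0.01)[[1L]]$type, "exponential")
})

test_that("rate grid scan matches pointwise likelihoods and flags bands", {
  tr <- fixture_tree4()
  cm <- character_matrix("x", c("L", "H"),
                         list(A = "L", B = "H", C = "H", D = "L"))
  m <- trait_model(list(x = rate_model(c("L", "H"), "ARD")))
  g <- rate_grid_scan(tr, list(x = cm), m,
                      r1 = 10^seq(-4, -1, length.out = 5),
                      r2 = 10^seq(-4, -1, length.out = 5))
  i <- sample(nrow(g), 3L)
  for (j in i) {
    expect_equal(g$loglik[j],
                 tree_loglik(tr, list(x = cm), m,
                             rates = c(g$r1[j], g$r2[j])),
                 tolerance = 1e-12)
    expect_equal(g$root_L[j] + g$root_H[j], 1, tolerance = 1e-12)
  }
  expect_true(g$within2[which.max(g$loglik)])
  expect_true(all(g$within10[g$within5]))
  ## symmetric data on a symmetric tree: ER diagonal gives root posterior 1/2
  trs <- dated_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  cms <- character_matrix("x", c("L", "H"),
                          list(A = "L", B = "H", C = "H", D = "L"))
  gs <- rate_grid_scan(trs, list(x = cms), m, r1 = 0.3, r2 = 0.3)
  expect_equal(gs$root_L, 0.5, tolerance = 1e-10)
})

test_that("ML fits agree with an independent Mk implementation", {
  ## phytools::fitMk as external oracle on the same data and uniform root
  set.seed(91)
  sc <- simulation_scenario(
    n_taxa = 40, n_trees = 1, age_jitter_sd = 0,
    characters = list(x = list(model = rate_model(c("L", "H"), "ARD",
                                                  rates = c(4e-4, 1e-3)))),
    seed = 91)
  ts <- simulate_tree_sample(sc)
  sim <- simulate_characters(sc, ts[[1L]])
  ## rescale to unit height so both optimizers face well-scaled rates
  tr <- ts[[1L]]
  tr$node.ages <- tr$node.ages / root_age(tr)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(ts[[1L]]))
  tr <- dated_tree(structure(tr[c("edge", "edge.length", "tip.label",
                                  "Nnode")], class = "phylo"))
  states <- vapply(sim$data$x$tips, `[[`, "", 1L)[tr$tip.label]
  phy <- tr; phy$node.ages <- NULL; class(phy) <- "phylo"
  for (model in c("ER", "ARD")) {
    ours <- mle_fit(tr, list(x = character_matrix("x", c("L", "H"),
                                                  as.list(states))),
                    trait_model(list(x = rate_model(c("L", "H"), model))),
                    n_starts = 4)
    theirs <- phytools::fitMk(phy, states, model = model, pi = "equal")
    expect_equal(ours$loglik, as.numeric(stats::logLik(theirs)),
                 tolerance = 1e-3)
  }
})
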