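## helper: wrap raw draws into a history_set
as_hset <- function(draws, trees, tree_idx = rep(1L, length(draws))) {
  structure(list(draws = draws, tree = tree_idx,
                 trees = as_tree_sample(trees)),
            class = "history_set")
}

test_that("state profiles recover node posteriors and clamp at tips", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.003))
  tipp <- rbind(c(1, 0), c(0, 1), c(0, 1), c(1, 0))
  set.seed(19)
  n <- 2000
  ns <- sample_joint_node_states(tr, tipp, Q, c(0.5, 0.5), n = n)
  draws <- lapply(seq_len(n), function(i)
    list(x = solutemap:::branch_histories(tr, ns[i, ], Q, c("L", "H"))))
  hs <- as_hset(draws, tr)
  prof <- state_probability_profiles(hs, "x", grid_step = 25)
  ## root probabilities match the node-sampler marginals within MC error
  expect_equal(unname(prof$nodes[5L, "L"]), mean(ns[, 5L] == 1L),
               tolerance = 1e-9)
  ## exact oracle by brute force
  bf <- brute_force_likelihood(tr, tipp, Q, c(0.5, 0.5))
  expect_lt(abs(prof$nodes[5L, "L"] - bf$node_marginals[5L, 1L]),
            3 * sqrt(0.25 / n) + 0.01)
  ## tip probabilities equal the observed states
  bip <- solutemap:::edge_bipartitions(tr)
  tipA <- prof$branches[prof$branches$bipartition == "A" &
                        prof$branches$age == 0, ]
  expect_equal(tipA$L, 1)
  ## probabilities sum to one on the grid
  expect_equal(prof$branches$L + prof$branches$H,
               rep(1, nrow(prof$branches)))
  ## grid probability at a node age equals the node probability
  root_edge_rows <- prof$branches[prof$branches$age == 100, ]
  ## all draws identical -> probabilities are 0/1
  one <- as_hset(draws[1L], tr)
  p1 <- state_probability_profiles(one, "x", grid_step = 50)
  expect_true(all(p1$nodes %in% c(0, 1)))
})

test_that("first occurrence ages count oldest satisfying segments", {
  tr <- dated_tree(ape::read.tree(text = "(A:10,B:10);"))
  h <- data.frame(branch = c(1L, 1L, 2L),
                  start = c(10, 6, 10), end = c(6, 0, 0),
                  state = c("L", "H", "L"))
  hs <- as_hset(list(list(x = h)), tr)
  ev <- first_occurrence_ages(hs, "x", "H")
  expect_equal(ev$ages, 6)
  ## satisfied at the root in every draw -> the root-age distribution
  evL <- first_occurrence_ages(hs, "x", "L")
  expect_equal(evL$ages, 10)
  ## any-state predicate returns the root age exactly
  ev_any <- first_occurrence_ages(hs, "x", c("L", "H"))
  expect_equal(ev_any$ages, root_age(tr))
  ## never satisfied -> NA; reference-age probability is a draw fraction
  evZ <- first_occurrence_ages(hs, "x", "Z")
  expect_true(is.na(evZ$ages))
  hs2 <- as_hset(list(list(x = h), list(x = h)), tr, c(1L, 1L))
  ev2 <- first_occurrence_ages(hs2, "x", "H", reference_age = 5)
  expect_equal(ev2$p_before_reference, 1)
  ev3 <- first_occurrence_ages(hs2, "x", "H", reference_age = 7)
  expect_equal(ev3$p_before_reference, 0)
})

test_that("transition rates through time normalize by lineage-time", {
  tr <- dated_tree(ape::read.tree(text = "(A:10,B:10);"))
  ## one L->H transition at age 6 on branch 1; 2 lineages alive throughout
  h <- data.frame(branch = c(1L, 1L, 2L),
                  start = c(10, 6, 10), end = c(6, 0, 0),
                  state = c("L", "H", "L"))
  hs <- as_hset(list(list(x = h)), tr)
  rtt <- transitions_through_time(hs, "x", "L", "H", bins = c(0, 5, 10))
  ## bin (5,10]: 1 event over 2 lineages x 5 Myr = 0.01 lineage-Gyr
  expect_equal(rtt$rate[rtt$bin_old == 10], 1 / 0.01)
  expect_equal(rtt$rate[rtt$bin_old == 5], 0)
  ## conservation across bins
  expect_equal(sum(rtt$n_events),
               nrow(solutemap:::history_transitions(h)[
                 solutemap:::history_transitions(h)$from == "L", ]))
  ## no transitions -> all-zero rates
  h0 <- data.frame(branch = 1:2, start = c(10, 10), end = c(0, 0),
                   state = c("L", "L"))
  rtt0 <- transitions_through_time(as_hset(list(list(x = h0)), tr), "x",
                                   "L", "H", bins = c(0, 5, 10))
  expect_true(all(rtt0$rate == 0))
})

test_that("transition conservation holds on simulated histories", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.004))
  set.seed(29)
  draws <- lapply(1:30, function(i) list(x = simulate_unconditioned(tr, Q)))
  hs <- as_hset(draws, tr)
  rtt <- transitions_through_time(hs, "x", "L", "H",
                                  bins = seq(0, 300, by = 50))
  total_binned <- sum(rtt$n_events) * length(draws)
  total_direct <- sum(vapply(draws, function(d) {
    t <- solutemap:::history_transitions(d$x)
    sum(t$from == "L" & t$to == "H")
  }, 0))
  expect_equal(total_binned, total_direct)
})

test_that("rate ratios aggregate generator cells per class", {
  ## hand-built 4-state pathway generator: L-sum 0.4, G-sum 0.02
  states <- c("AA", "AP", "PA", "PP")
  m <- rate_model(states, "ARD")
  rates <- numeric(12)
  cm <- m$class_map
  rates[cm["AA", "AP"]] <- 0.005
  rates[cm["AA", "PA"]] <- 0.005
  rates[cm["AA", "PP"]] <- 0.01
  rates[cm["PP", "AA"]] <- 0.2
  rates[cm["PP", "AP"]] <- 0.1
  rates[cm["PP", "PA"]] <- 0.1
  rates[cm["AP", "PA"]] <- 0.003
  rates[cm["PA", "AP"]] <- 0.007
  rates[rates == 0] <- 1e-6
  classes <- pathway_rate_classes(states)
  ## fabricate a 1-draw posterior around the fixed rates
  mo <- trait_model(list(gg = rate_model(states, "ARD")))
  draws <- as.data.frame(matrix(rates, 10, 12, byrow = TRUE))
  names(draws) <- solutemap:::rate_par_names(mo)
  ps <- structure(list(draws = cbind(data.frame(chain = 1, tree = 1,
                                                loglik = 0, logprior = 0),
                                     draws),
                       tables = NULL, par_names = names(draws)),
                  class = "posterior_sample")
  set.seed(2)
  rr <- rate_ratios(ps, mo, "gg", classes)
  expect_equal(unname(rr$medians["L"]), 0.4, tolerance = 1e-9)
  expect_equal(unname(rr$medians["G"]), 0.02, tolerance = 1e-9)
  expect_equal(unname(rr$medians["L/G"]), 20, tolerance = 1e-9)
  expect_equal(unname(rr$medians["E"]), 0.01, tolerance = 1e-9)
  ## ER binary model: loss and gain classes coincide, ratio 1 by construction
  mo2 <- trait_model(list(x = rate_model(c("A", "P"), "ER")))
  d2 <- data.frame(chain = 1, tree = 1, loglik = 0, logprior = 0,
                   `x:r` = rep(0.3, 5), check.names = FALSE)
  ps2 <- structure(list(draws = d2, tables = NULL, par_names = "x:r"),
                   class = "posterior_sample")
  rr2 <- rate_ratios(ps2, mo2, "x", pathway_rate_classes(c("A", "P")),
                     ratios = "L/G")
  expect_equal(unname(rr2$medians["L/G"]), 1)
})

test_that("HPD intervals match exhaustive search and handle edge cases", {
  set.seed(37)
  x <- c(stats::rnorm(400, 0, 1), stats::rnorm(100, 6, 0.3))
  for (mass in c(0.5, 0.89, 0.95)) {
    got <- hpd_interval(x, mass)
    ## exhaustive oracle
    xs <- sort(x)
    m <- ceiling(mass * length(xs))
    widths <- xs[m:length(xs)] - xs[1:(length(xs) - m + 1)]
    i <- which.min(widths)
    expect_equal(unname(got), c(xs[i], xs[i + m - 1]), ignore_attr = TRUE)
  }
  ## uniform sample: width ~ mass
  u <- stats::runif(5000)
  w <- hpd_interval(u, 0.89)
  expect_lt(abs((w[2] - w[1]) - 0.89), 0.03)
  ## point mass
  p <- hpd_interval(rep(3, 200), 0.89)
  expect_equal(unname(p), c(3, 3), ignore_attr = TRUE)
  ## multimodality flag on the bimodal sample
  expect_true(attr(hpd_interval(c(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1)),
                                0.5), "possibly_multimodal"))
})
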