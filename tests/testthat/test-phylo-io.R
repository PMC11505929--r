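test_that("newick trees are read with ages reconstructed from branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", path)
  ts <- read_tree_sample(path)
  expect_length(ts, 1L)
  tr <- ts[[1L]]
  expect_equal(root_age(tr), 1)
  expect_equal(unname(node_ages(tr)[1:2]), c(0, 0))

  writeLines(rep("((A:1,B:1):1,C:2);", 3L), path)
  ts3 <- read_tree_sample(path)
  expect_length(ts3, 3L)
  expect_identical(sort(ts3[[2L]]$tip.label), c("A", "B", "C"))

  ts2 <- read_tree_sample(path, max_trees = 2)
  expect_length(ts2, 2L)
})

test_that("non-ultrametric input is rejected by default and repairable", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2);", path)
  expect_error(read_tree_sample(path), "ultrametric")
  ts <- read_tree_sample(path, nonultrametric = "repair")
  expect_equal(unname(node_ages(ts[[1L]])[1:2]), c(0, 0))
})

test_that("parse and taxon-set errors are informative", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("(A:1,B:1);", "(A:1,B:1;"), path)
  expect_error(read_tree_sample(path), "line 2")
  writeLines(c("(A:1,B:1);", "(A:1,C:1);"), path)
  expect_error(read_tree_sample(path), "C")
})

test_that("tree round trip preserves topology and ages", {
  set.seed(4)
  sc <- simulation_scenario(n_taxa = 12, n_trees = 3, seed = 4)
  ts <- simulate_tree_sample(sc)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_sample(ts, path)
  back <- read_tree_sample(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    m <- match(back[[i]]$tip.label, ts[[i]]$tip.label)
    expect_equal(root_age(back[[i]]), root_age(ts[[i]]), tolerance = 1e-8)
    expect_equal(ape::dist.nodes(back[[i]])[1, 2],
                 ape::dist.nodes(ts[[i]])[m[1], m[2]], tolerance = 1e-8)
  }
})

test_that("prune_taxa removes tips, keeps retained node ages, validates", {
  tr <- dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  pr <- prune_taxa(tr, "C")
  expect_identical(sort(pr$tip.label), c("A", "B"))
  expect_equal(root_age(pr), 1)
  expect_identical(prune_taxa(tr, character(0)), tr)
  expect_error(prune_taxa(tr, "Z"), "unknown taxa")
  expect_error(prune_taxa(tr, c("A", "B")), "fewer than 2")

  tr5 <- fixture_tree5()
  pr5 <- prune_taxa(tr5, "E")
  ages_before <- node_ages(tr5)
  expect_equal(root_age(pr5), 150) # age of the retained internal node
  expect_true(all(abs(pr5$edge.length -
    (node_ages(pr5)[pr5$edge[, 1]] - node_ages(pr5)[pr5$edge[, 2]])) < 1e-9))
})

test_that("character tables parse states, ambiguity sets, and missing cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\thabitat", "StrainX\tH", "StrainY\t?", "StrainZ\tH/L"),
             path)
  cm <- read_character_table(path, c("H", "L"))[["habitat"]]
  expect_identical(cm$tips$StrainX, "H")
  expect_setequal(cm$tips$StrainY, c("H", "L"))
  expect_setequal(cm$tips$StrainZ, c("H", "L"))

  writeLines(c("taxon\thabitat", "StrainX\tQ"), path)
  expect_error(read_character_table(path, c("H", "L")), "StrainX")
  writeLines(c("taxon\thabitat", "StrainX\tH", "StrainX\tL"), path)
  expect_error(read_character_table(path, c("H", "L")), "duplicate")
})

test_that("character table round trip is lossless", {
  cm <- character_matrix("habitat", c("H", "L"),
                         list(A = "H", B = c("H", "L"), C = "L"))
  gg <- character_matrix("ggpS", c("A", "P"), list(A = "P", B = "A", C = "P"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_character_table(list(habitat = cm, ggpS = gg), path)
  back <- read_character_table(path, list(habitat = c("H", "L"),
                                          ggpS = c("A", "P")))
  expect_equal(back$habitat$tips, cm$tips)
  expect_equal(back$ggpS$tips, gg$tips)
})

test_that("history files round-trip exactly and are validated", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.004))
  set.seed(11)
  h <- simulate_unconditioned(tr, Q)
  hs <- structure(list(draws = list(list(habitat = h)), tree = 1L,
                       trees = tree_sample(list(tr))),
                  class = "history_set")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_histories(hs, path)
  back <- read_histories(path, tree_sample(list(tr)))
  hb <- back$draws[[1L]]$habitat
  expect_equal(hb$start, h$start, tolerance = 1e-9)
  expect_equal(hb$end, h$end, tolerance = 1e-9)
  expect_identical(hb$state, h$state)

  ## empty collection -> header-only file
  write_histories(structure(list(draws = list(), tree = integer(0),
                                 trees = tree_sample(list(tr))),
                            class = "history_set"), path)
  expect_length(readLines(path), 1L)
  expect_length(read_histories(path, tree_sample(list(tr)))$draws, 0L)

  ## corrupted segment ordering is rejected
  bad <- h
  bad$start[1] <- bad$end[1] - 1
  hs_bad <- structure(list(draws = list(list(habitat = bad)), tree = 1L,
                           trees = tree_sample(list(tr))),
                      class = "history_set")
  write_histories(hs_bad, path)
  expect_error(read_histories(path, tree_sample(list(tr))))
})

test_that("simmap export writes one annotated tree with full branch spans", {
  tr <- fixture_tree4()
  Q <- build_rate_matrix(rate_model(c("L", "H"), "ER", rates = 0.004))
  set.seed(2)
  h <- simulate_unconditioned(tr, Q)
  hs <- structure(list(draws = list(list(habitat = h)), tree = 1L,
                       trees = tree_sample(list(tr))),
                  class = "history_set")
  path <- withr::local_tempfile(fileext = ".tre")
  write_simmap(hs, path)
  txt <- readLines(path)
  expect_length(txt, 1L)
  expect_match(txt, "^\\(.*\\);$")
  expect_match(txt, "\\{[LH],")
})
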