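#' Simulation scenarios with known ground truth
#'
#' Defines the conditions under which synthetic dated-tree samples and
#' character data are generated: a single birth-death topology scaled to a
#' target root age, a sample of trees obtained by log-normal jitter of the
#' internal node ages (emulating a molecular-clock posterior), Markov
#' characters evolved under known rates, and optionally a focal character
#' drawn from a known conditional probability table.
#'
#' @param n_taxa number of tips (>= 4).
#' @param root_age root age in Ma (default 3200, the scale of the
#'   cyanobacteria analyses).
#' @param n_trees trees in the jittered sample.
#' @param birth,death birth-death rates for the topology simulation (per
#'   lineage per unit time before rescaling).
#' @param age_jitter_sd sd of the log-normal age jitter (log-units).
#' @param characters named list of true models: each element
#'   `list(model = rate_model with rates set, root = optional prior vector)`.
#' @param conditioned optional
#'   `list(focal, focal_states, table)` — a true conditional probability
#'   table over the joint states of `characters` (first character slowest).
#' @param seed integer seed.
#' @return a list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_taxa = 50, root_age = 3200, n_trees = 100,
                                birth = 1, death = 0.5, age_jitter_sd = 0.05,
                                characters = NULL, conditioned = NULL,
                                seed = 1) {
  stopifnot(n_taxa >= 4L, root_age > 0, n_trees >= 1L,
            birth > 0, death >= 0, age_jitter_sd >= 0)
  if (is.null(characters))
    characters <- list(
      habitat = list(model = rate_model(c("L", "H"), "ER", rates = 2e-3)))
  for (ch in characters) {
    stopifnot(inherits(ch$model, "rate_model"))
    if (is.null(ch$model$rates)) stop("true models must carry rates")
  }
  structure(list(n_taxa = n_taxa, root_age = root_age, n_trees = n_trees,
                 birth = birth, death = death,
                 age_jitter_sd = age_jitter_sd,
                 characters = characters, conditioned = conditioned,
                 seed = seed),
            class = "simulation_scenario")
}

#' Simulate a sample of dated trees with a shared topology
#'
#' One birth-death topology conditioned on the taxon count is scaled to the
#' scenario root age. The first tree of the sample is this reference tree
#' (the ground truth that characters are simulated on); the remaining trees
#' jitter the node ages to emulate draws saved from a relaxed-clock chain:
#' in postorder, each internal node's age gap above its oldest child is
#' multiplied by independent log-normal noise, which preserves
#' parent-older-than-child ordering by construction while letting all ages
#' (including the root's) vary. Deterministic under the scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return a [tree_sample()].
#' @export
simulate_tree_sample <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  phy <- ape::rphylo(scenario$n_taxa, scenario$birth, scenario$death)
  phy$tip.label <- sprintf("t%03d", seq_len(scenario$n_taxa))
  base <- dated_tree(phy)
  sc <- scenario$root_age / root_age(base)
  base$node.ages <- base$node.ages * sc
  base$edge.length <- base$edge.length * sc
  po <- postorder_edges(base)
  trees <- vector("list", scenario$n_trees)
  trees[[1L]] <- base
  for (i in seq_len(scenario$n_trees)[-1L]) {
    if (scenario$age_jitter_sd == 0) {
      trees[[i]] <- base
      next
    }
    ages <- base$node.ages
    new_ages <- numeric(length(ages)) # tips stay 0
    ## finalize each parent only once all its children are finalized
    n_kids <- tabulate(po$edge[, 1L], nbins = length(ages))
    seen <- integer(length(ages))
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1L]
      seen[p] <- seen[p] + 1L
      if (seen[p] < n_kids[p]) next
      kids <- po$edge[po$edge[, 1L] == p, 2L]
      gap <- ages[p] - max(ages[kids])
      new_ages[p] <- max(new_ages[kids]) +
        gap * stats::rlnorm(1L, 0, scenario$age_jitter_sd)
    }
    t <- base
    t$node.ages <- new_ages
    t$edge.length <- new_ages[t$edge[, 1L]] - new_ages[t$edge[, 2L]]
    trees[[i]] <- t
  }
  tree_sample(trees)
}

#' Simulate character data (and true histories) on a dated tree
#'
#' Markov characters are simulated forward with
#' [simulate_unconditioned()]; a conditioned focal character, when present,
#' is drawn from the true table over the simulated conditioning histories
#' (without tip clamping — the tips are the data). Both tip data and the
#' generating histories are returned so that downstream summaries can be
#' checked against the truth.
#'
#' @param scenario a [simulation_scenario()].
#' @param tree the [dated_tree()] to simulate on (default: first tree of
#'   [simulate_tree_sample()] output must be passed explicitly).
#' @param seed seed (default `scenario$seed + 1`).
#' @return a list: `data` (named list of [character_matrix()]), `histories`
#'   (named list of mapped histories), `tree`.
#' @export
simulate_characters <- function(scenario, tree, seed = scenario$seed + 1) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(tree, "dated_tree"))
  set.seed(seed)
  taxa <- tree$tip.label
  histories <- list()
  data <- list()
  for (nm in names(scenario$characters)) {
    ch <- scenario$characters[[nm]]
    Q <- build_rate_matrix(ch$model)
    root <- if (!is.null(ch$root)) ch$root
            else rep(1 / length(ch$model$states), length(ch$model$states))
    h <- simulate_unconditioned(tree, Q, root, labels = ch$model$states)
    histories[[nm]] <- h
    tips <- attr(h, "tip_states")
    comp <- ch$model$components
    if (is.null(comp)) {
      data[[nm]] <- character_matrix(nm, ch$model$states,
                                     as.list(tips))
    } else {
      ## split the supercharacter tip states into per-gene characters
      for (g in seq_along(comp)) {
        gname <- names(comp)[g]
        gstates <- substr(tips, g, g)
        data[[gname]] <- character_matrix(gname, comp[[g]],
                                          as.list(stats::setNames(gstates,
                                                                  taxa)))
      }
    }
  }
  cond <- scenario$conditioned
  if (!is.null(cond)) {
    focal_h <- overlay_conditioned(histories, tree, cond$table,
                                   focal_data = NULL)
    histories[[cond$focal]] <- focal_h
    tip_states <- attr(focal_h, "node_states")[seq_along(taxa)]
    data[[cond$focal]] <- character_matrix(
      cond$focal, cond$focal_states,
      as.list(stats::setNames(tip_states, taxa)))
  }
  list(data = data, histories = histories, tree = tree)
}

#' Ready-made benchmark datasets
#'
#' Presets: `"tiny"` (8 tips, 10 trees, one habitat-like binary character),
#' `"small"` (50 tips, 100 trees, habitat + a 2-gene pathway), and
#' `"study_scale"` (189 tips, 1000 trees, 2-gene GG-like pathway, binary
#' GGA/GB/Tre-like characters, a 3-gene Suc-like pathway, and a habitat
#' character drawn from a table favouring high salinity when the GG-like and
#' GGA-like pathways are present). True rates are in the 1e-3 - 1e-2 per-Myr
#' range implied by a 3200-Ma root. When `out_dir` is given, writes
#' `trees.nwk`, `characters.tsv`, and `truth.json` (the scenario, round-trip
#' loadable).
#'
#' @param preset `"tiny"`, `"small"`, or `"study_scale"`.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return a list: `scenario`, `trees` ([tree_sample()]), `data`,
#'   `histories`, and (if written) `paths`.
#' @export
benchmark_dataset <- function(preset = c("tiny", "small", "study_scale"),
                              seed = 1, out_dir = NULL) {
  preset <- match.arg(preset)
  scenario <- switch(preset,
    tiny = simulation_scenario(
      n_taxa = 8, root_age = 3200, n_trees = 10, age_jitter_sd = 0.05,
      characters = list(
        habitat = list(model = rate_model(c("L", "H"), "ER",
                                          rates = 1e-3))),
      seed = seed),
    small = simulation_scenario(
      n_taxa = 50, root_age = 3200, n_trees = 100, age_jitter_sd = 0.05,
      characters = list(
        habitat = list(model = rate_model(c("L", "H"), "ARD",
                                          rates = c(1e-3, 3e-3))),
        GG = list(model = {
          m <- rate_model(product_states(
            list(ggpS = c("A", "P"), ggpP = c("A", "P"))), "ER",
            rates = 1e-3)
          m$components <- list(ggpS = c("A", "P"), ggpP = c("A", "P"))
          m
        })),
      seed = seed),
    study_scale = {
      gg <- rate_model(product_states(
        list(ggpS = c("A", "P"), ggpP = c("A", "P"))), "ARD",
        rates = c(1e-3, 1e-3, 2e-3, 3e-4,
                  4e-3, 3e-4, 5e-4, 2e-3,
                  4e-3, 5e-4, 2e-3, 1e-3))
      gg$components <- list(ggpS = c("A", "P"), ggpP = c("A", "P"))
      suc <- rate_model(product_states(
        list(spsA = c("A", "P"), spp = c("A", "P"),
             `spsA*` = c("A", "P"))), "ER", rates = 1e-3)
      suc$components <- list(spsA = c("A", "P"), spp = c("A", "P"),
                             `spsA*` = c("A", "P"))
      chars <- list(
        GG = list(model = gg),
        GGA = list(model = rate_model(c("A", "P"), "ARD",
                                      rates = c(1e-3, 5e-3))),
        GB = list(model = rate_model(c("A", "P"), "ARD",
                                     rates = c(1e-3, 4e-3))),
        Tre = list(model = rate_model(c("A", "P"), "ER", rates = 2e-3)),
        Suc = list(model = suc))
      ## habitat favours H when the GG pathway is complete or GGA present;
      ## table rows follow joint states of (GG, GGA, GB, Tre, Suc), first
      ## block slowest
      joint <- as.character(product_states(
        list(GG = gg$states, GGA = c("A", "P"), GB = c("A", "P"),
             Tre = c("A", "P"), Suc = suc$states)))
      tab <- t(vapply(joint, function(js) {
        gg_state <- substr(js, 1, 2)
        gga <- substr(js, 3, 3)
        pH <- 0.15 + 0.45 * (gg_state == "PP") + 0.3 * (gga == "P")
        c(1 - pH, pH)
      }, numeric(2)))
      dimnames(tab) <- list(joint, c("L", "H"))
      simulation_scenario(
        n_taxa = 189, root_age = 3200, n_trees = 1000,
        age_jitter_sd = 0.05, characters = chars,
        conditioned = list(focal = "habitat",
                           focal_states = c("L", "H"), table = tab),
        seed = seed)
    })
  trees <- simulate_tree_sample(scenario)
  sim <- simulate_characters(scenario, trees$trees[[1L]])
  out <- list(scenario = scenario, trees = trees, data = sim$data,
              histories = sim$histories)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p_trees <- file.path(out_dir, "trees.nwk")
    p_chars <- file.path(out_dir, "characters.tsv")
    p_truth <- file.path(out_dir, "truth.json")
    write_tree_sample(trees, p_trees)
    write_character_table(sim$data, p_chars)
    jsonlite::write_json(scenario_to_json(scenario), p_truth,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- c(trees = p_trees, characters = p_chars, truth = p_truth)
  }
  out
}

## internal: JSON-serializable form of a scenario, and its inverse
scenario_to_json <- function(s) {
  list(n_taxa = s$n_taxa, root_age = s$root_age, n_trees = s$n_trees,
       birth = s$birth, death = s$death, age_jitter_sd = s$age_jitter_sd,
       seed = s$seed,
       characters = lapply(s$characters, function(ch) list(
         states = ch$model$states,
         type = ch$model$type,
         rates = ch$model$rates,
         components = ch$model$components)),
       conditioned = if (!is.null(s$conditioned)) list(
         focal = s$conditioned$focal,
         focal_states = s$conditioned$focal_states,
         table = apply(s$conditioned$table, 1L, identity,
                       simplify = FALSE)))
}

#' @rdname benchmark_dataset
#' @param path path to a `truth.json` written by [benchmark_dataset()].
#' @export
read_scenario <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chars <- lapply(j$characters, function(ch) {
    states <- ch$states
    if (!is.null(ch$components) && length(ch$components))
      states <- structure(states, components = as.list(ch$components))
    m <- rate_model(states, ch$type, rates = ch$rates)
    if (!is.null(ch$components) && length(ch$components))
      m$components <- as.list(ch$components)
    list(model = m)
  })
  cond <- NULL
  if (!is.null(j$conditioned) && length(j$conditioned)) {
    tab <- do.call(rbind, j$conditioned$table)
    colnames(tab) <- j$conditioned$focal_states
    cond <- list(focal = j$conditioned$focal,
                 focal_states = j$conditioned$focal_states, table = tab)
  }
  simulation_scenario(n_taxa = j$n_taxa, root_age = j$root_age,
                      n_trees = j$n_trees, birth = j$birth,
                      death = j$death, age_jitter_sd = j$age_jitter_sd,
                      characters = chars, conditioned = cond, seed = j$seed)
}
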