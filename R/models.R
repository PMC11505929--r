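#' State spaces and CTMC rate-model parameterizations
#'
#' `rate_model()` defines a continuous-time Markov model on a discrete state
#' space by assigning every off-diagonal cell of the generator matrix to a
#' free-parameter class or to the zero class:
#'
#' * `"ER"` (equal rates): one class for all transitions (1 free rate);
#' * `"SYM"` (symmetric): one class per unordered state pair
#'   (`(s^2 - s)/2` free rates);
#' * `"ARD"` (all rates different): one class per ordered pair
#'   (`s^2 - s` free rates);
#' * `"UNI"` (unidirectional, binary states only): a single nonzero class for
#'   one direction, the reverse rate fixed at 0.
#'
#' @param states ordered state alphabet, or a `state_space` from
#'   [product_states()].
#' @param type one of `"ER"`, `"SYM"`, `"ARD"`, `"UNI"`.
#' @param rates optional numeric vector of free rates (per Myr).
#' @param uni_from,uni_to direction of the permitted transition for `"UNI"`.
#' @return an object of class `rate_model` with elements `states`, `type`,
#'   `class_map` (s x s integer matrix; 0 = structural zero), `n_free`,
#'   `rates`, `par_names`, and (for product spaces) `components`.
#' @export
rate_model <- function(states, type = c("ER", "SYM", "ARD", "UNI"),
                       rates = NULL, uni_from = NULL, uni_to = NULL) {
  type <- match.arg(type)
  components <- attr(states, "components")
  states <- as.character(states)
  s <- length(states)
  stopifnot(s >= 2L, !anyDuplicated(states))
  cm <- matrix(0L, s, s, dimnames = list(states, states))
  if (type == "ER") {
    cm[] <- 1L; diag(cm) <- 0L
    pn <- "r"
  } else if (type == "SYM") {
    k <- 0L; pn <- character(0)
    for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
      k <- k + 1L
      cm[i, j] <- k; cm[j, i] <- k
      pn <- c(pn, paste0(states[i], "<->", states[j]))
    }
  } else if (type == "ARD") {
    k <- 0L; pn <- character(0)
    for (i in seq_len(s)) for (j in seq_len(s)) {
      if (i == j) next
      k <- k + 1L
      cm[i, j] <- k
      pn <- c(pn, paste0(states[i], "->", states[j]))
    }
  } else { # UNI
    if (s != 2L) stop("UNI models are defined for binary characters only")
    if (is.null(uni_from)) { uni_from <- states[1L]; uni_to <- states[2L] }
    i <- match(uni_from, states); j <- match(uni_to, states)
    if (is.na(i) || is.na(j) || i == j) stop("invalid UNI direction")
    cm[i, j] <- 1L
    pn <- paste0(uni_from, "->", uni_to)
  }
  n_free <- max(cm)
  if (!is.null(rates)) {
    if (length(rates) != n_free) stop("expected ", n_free, " rates")
    if (any(rates < 0)) stop("negative rate parameter")
  }
  structure(list(states = states, type = type, class_map = cm,
                 n_free = n_free, rates = rates, par_names = pn,
                 components = components),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Rate model ", x$type, " on {", paste(x$states, collapse = ", "),
      "}: ", x$n_free, " free rate(s)",
      if (!is.null(x$rates)) paste0(" = ",
        paste(format(x$rates, digits = 4), collapse = ", ")) else " (unset)",
      "\n", sep = "")
  invisible(x)
}

#' @rdname rate_model
#' @param model a `rate_model`.
#' @export
n_free_rates <- function(model) model$n_free

#' Product state spaces
#'
#' Builds the joint state space of several characters in declared component
#' order; labels are the concatenated component states with the first
#' component varying slowest, e.g. two presence/absence genes give
#' `(AA, AP, PA, PP)`. The gain/loss/exchange rate classes used in the
#' pathway analyses index into this ordering.
#'
#' @param components named list of component alphabets.
#' @param sep separator for labels (default `""`).
#' @return character vector of joint labels with attributes `components`.
#' @export
product_states <- function(components, sep = "") {
  stopifnot(is.list(components), length(components) >= 1L)
  grid <- expand.grid(rev(components), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(components)), drop = FALSE]
  labels <- apply(grid, 1L, paste, collapse = sep)
  structure(labels, components = components)
}

## internal: decompose joint index into component indices (first slowest)
joint_index_split <- function(idx, sizes) {
  k <- length(sizes)
  out <- integer(k)
  rem <- idx - 1L
  for (c in k:1) {
    out[c] <- rem %% sizes[c] + 1L
    rem <- rem %/% sizes[c]
  }
  out
}

#' Combine component models into a product ("supercharacter") model
#'
#' In independent mode the generator is the Kronecker sum of the component
#' generators: only single-component changes have nonzero rate, equal to the
#' component rate, and the free parameters are the union of the component
#' parameters. In dependent mode a fresh ER/SYM/ARD parameterization is laid
#' over the full product space, including simultaneous-change cells such as
#' `PA <-> AP`.
#'
#' @param components named list of component [rate_model()]s (>= 2).
#' @param dependent logical; merge into a dependent supercharacter?
#' @param type parameterization for the dependent case.
#' @return a [rate_model()] on the product space.
#' @export
build_product_model <- function(components, dependent = FALSE,
                                type = c("ARD", "ER", "SYM")) {
  type <- match.arg(type)
  stopifnot(length(components) >= 2L)
  if (is.null(names(components)))
    names(components) <- paste0("c", seq_along(components))
  alphabets <- lapply(components, `[[`, "states")
  space <- product_states(alphabets)
  if (dependent) return(rate_model(space, type))
  sizes <- vapply(alphabets, length, 1L)
  S <- length(space)
  cm <- matrix(0L, S, S, dimnames = list(space, space))
  offs <- c(0L, cumsum(vapply(components, `[[`, 1L, "n_free")))
  pn <- character(0)
  for (c in seq_along(components))
    pn <- c(pn, paste0(names(components)[c], ":", components[[c]]$par_names))
  for (i in seq_len(S)) {
    ii <- joint_index_split(i, sizes)
    for (j in seq_len(S)) {
      if (i == j) next
      jj <- joint_index_split(j, sizes)
      diff <- which(ii != jj)
      if (length(diff) != 1L) next
      c <- diff
      cls <- components[[c]]$class_map[ii[c], jj[c]]
      if (cls > 0L) cm[i, j] <- offs[c] + cls
    }
  }
  rates <- NULL
  if (all(!vapply(components, function(m) is.null(m$rates), TRUE)))
    rates <- unlist(lapply(components, `[[`, "rates"), use.names = FALSE)
  out <- rate_model(space, "ARD") # placeholder structure, then overwrite
  out$type <- "INDEP"
  out$class_map <- cm
  out$n_free <- max(cm)
  out$rates <- rates
  out$par_names <- pn
  out$components <- alphabets
  out
}

#' Build a generator matrix from a rate model
#'
#' Off-diagonal cells are filled from the free-parameter classes; each
#' diagonal entry is minus its row sum, so rows sum to zero.
#'
#' @param model a [rate_model()].
#' @param rates free-rate vector (defaults to `model$rates`).
#' @return the s x s generator matrix Q (per Myr).
#' @export
build_rate_matrix <- function(model, rates = model$rates) {
  stopifnot(inherits(model, "rate_model"))
  if (is.null(rates)) stop("model has no rates set")
  if (length(rates) != model$n_free) stop("expected ", model$n_free, " rates")
  if (any(rates < 0) || any(!is.finite(rates))) stop("invalid rate parameter")
  Q <- matrix(0, nrow(model$class_map), ncol(model$class_map),
              dimnames = dimnames(model$class_map))
  nz <- model$class_map > 0L
  Q[nz] <- rates[model$class_map[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Pathway definitions and functional-state classification
#'
#' A pathway is an ordered gene list together with a predicate saying which
#' gene-presence combinations constitute a complete (functional) pathway.
#' Built-in predicates: `"all"` (every gene required; the two-gene GG, GGA,
#' GB, Tre rule), `"any"` (at least one gene), and `"sucrose"` (functional iff
#' `spsA` is present, or `spp` and `spsA*` are both present — the rule used
#' for the three-gene Suc pathway).
#'
#' @param name pathway name.
#' @param genes ordered character vector of gene names.
#' @param predicate `"all"`, `"any"`, `"sucrose"`, or a function taking a
#'   named logical vector of gene presences and returning `TRUE`/`FALSE`.
#' @return an object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, genes, predicate = "all") {
  stopifnot(is.character(genes), length(genes) >= 1L)
  if (is.character(predicate)) {
    predicate <- switch(match.arg(predicate, c("all", "any", "sucrose")),
      all = function(p) all(p),
      any = function(p) any(p),
      sucrose = function(p) {
        isTRUE(p[[1L]]) || (isTRUE(p[[2L]]) && isTRUE(p[[3L]]))
      })
  }
  stopifnot(is.function(predicate))
  structure(list(name = name, genes = genes, predicate = predicate),
            class = "pathway_definition")
}

#' @rdname pathway_definition
#' @param presence per-gene presence: logical vector, or character vector of
#'   `"P"`/`"A"`, in the pathway's gene order.
#' @param pathway a `pathway_definition`.
#' @return `classify_pathway_state()`: one of `"functional"`, `"incomplete"`,
#'   `"absent"`.
#' @export
classify_pathway_state <- function(presence, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (is.character(presence)) presence <- presence == "P"
  if (length(presence) != length(pathway$genes))
    stop("presence tuple length must equal the gene count")
  names(presence) <- pathway$genes
  if (isTRUE(pathway$predicate(presence))) "functional"
  else if (!any(presence)) "absent"
  else "incomplete"
}

## all set partitions of 1..n (n <= 3 is all that is needed; generic anyway)
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  prev <- set_partitions(n - 1L)
  out <- list()
  for (p in prev) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

#' Enumerate candidate model spaces for a multi-gene pathway
#'
#' Candidates are (dependency partition, parameterization) pairs. The same
#' parameterization tag is applied uniformly across all blocks of a partition,
#' and SYM is offered only when some block has more than 2 states (i.e.
#' contains >= 2 genes). For 2 genes this yields the 5 candidates used for
#' the glucosylglycerol pathway (independent x \{ER, ARD\}; dependent x
#' \{ER, SYM, ARD\}); for 3 genes the 14 candidates used for sucrose.
#'
#' @param genes character vector of 2 or 3 gene names.
#' @return an object of class `model_space`: a list of candidates, each with
#'   `partition` (list of integer vectors), `type`, and `label`.
#' @export
enumerate_pathway_models <- function(genes) {
  n <- length(genes)
  if (n < 2L || n > 3L)
    stop("pathway model enumeration supports 2 or 3 genes, got ", n)
  parts <- set_partitions(n)
  cands <- list()
  for (p in parts) {
    has_big_block <- any(vapply(p, length, 1L) >= 2L)
    types <- if (has_big_block) c("ER", "SYM", "ARD") else c("ER", "ARD")
    for (ty in types) {
      lbl <- paste0(
        paste(vapply(p, function(b) paste0("(", paste(genes[b], collapse = "+"), ")"),
                     character(1)), collapse = ""),
        "/", ty)
      cands[[length(cands) + 1L]] <-
        list(partition = p, type = ty, label = lbl)
    }
  }
  structure(list(genes = genes, candidates = cands), class = "model_space")
}

#' @export
length.model_space <- function(x) length(x$candidates)

#' @export
print.model_space <- function(x, ...) {
  cat("Model space over genes (", paste(x$genes, collapse = ", "), "): ",
      length(x$candidates), " candidates\n", sep = "")
  for (cand in x$candidates) cat("  ", cand$label, "\n", sep = "")
  invisible(x)
}

## internal: instantiate the rate_model blocks of a model-space candidate
candidate_blocks <- function(genes, candidate, alphabet = c("A", "P")) {
  blocks <- list()
  for (b in candidate$partition) {
    gs <- genes[b]
    if (length(gs) == 1L) {
      ty <- if (candidate$type == "SYM") "ER" else candidate$type
      m <- rate_model(alphabet, ty)
    } else {
      space <- product_states(stats::setNames(rep(list(alphabet), length(gs)), gs))
      m <- rate_model(space, candidate$type)
      m$components <- stats::setNames(rep(list(alphabet), length(gs)), gs)
    }
    blocks[[paste(gs, collapse = "+")]] <- list(chars = gs, model = m)
  }
  blocks
}
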