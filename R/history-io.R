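#' Write and read mapped-history collections
#'
#' The on-disk format is a TSV with columns
#' `draw<TAB>tree<TAB>character<TAB>branch<TAB>start<TAB>end<TAB>state`
#' (ages in Ma, `start > end` except for zero-length roots of tip segments);
#' the round trip is lossless. An annotated-newick (simmap-style) writer is
#' provided for interoperability with other stochastic-mapping tools.
#'
#' @param histories a `history_set` (see [sample_histories()]) or a list of
#'   draws, each draw a named list of mapped-history data frames.
#' @param path output TSV path.
#' @param trees the [tree_sample()] the histories reference (stored indices
#'   must be valid); required for validation on read.
#' @return `write_histories()`: the path, invisibly.
#' @export
write_histories <- function(histories, path) {
  draws <- if (inherits(histories, "history_set")) histories$draws
           else histories
  tree_idx <- if (inherits(histories, "history_set")) histories$tree
              else rep(1L, length(draws))
  rows <- list()
  for (d in seq_along(draws)) {
    for (ch in names(draws[[d]])) {
      h <- draws[[d]][[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        draw = d, tree = tree_idx[d], character = ch,
        branch = h$branch, start = h$start, end = h$end, state = h$state)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(draw = integer(0), tree = integer(0),
                         character = character(0), branch = integer(0),
                         start = numeric(0), end = numeric(0),
                         state = character(0))
  utils::write.table(format(tab, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @return `read_histories()`: a `history_set`.
#' @export
read_histories <- function(path, trees) {
  trees <- as_tree_sample(trees)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("draw", "tree", "character", "branch", "start", "end", "state")
  if (!all(need %in% names(tab)))
    stop("history file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) == 0L)
    return(structure(list(draws = list(), tree = integer(0), trees = trees),
                     class = "history_set"))
  if (any(tab$tree < 1L | tab$tree > length(trees$trees)))
    stop("history references a tree index outside the sample")
  draws <- list()
  tree_idx <- integer(0)
  for (d in sort(unique(tab$draw))) {
    sub <- tab[tab$draw == d, ]
    tree_idx[length(tree_idx) + 1L] <- sub$tree[1L]
    tree <- trees$trees[[sub$tree[1L]]]
    per_char <- list()
    for (ch in unique(sub$character)) {
      h <- sub[sub$character == ch, c("branch", "start", "end", "state")]
      rownames(h) <- NULL
      validate_history(h, tree)
      per_char[[ch]] <- h
    }
    draws[[length(draws) + 1L]] <- per_char
  }
  structure(list(draws = draws, tree = tree_idx, trees = trees),
            class = "history_set")
}

## internal: check contiguity and branch-span coverage of a history
validate_history <- function(h, tree, tol = 1e-6) {
  ages <- node_ages(tree)
  if (any(h$start < h$end - tol))
    stop("history segment with end older than start (ages must decrease ",
         "toward the present)")
  for (e in unique(h$branch)) {
    seg <- h[h$branch == e, ]
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    span_tol <- max(tol, tol * ages[p])
    if (abs(seg$start[1L] - ages[p]) > span_tol ||
        abs(seg$end[nrow(seg)] - ages[c]) > span_tol)
      stop("history does not span branch ", e)
    if (nrow(seg) > 1L &&
        any(abs(seg$end[-nrow(seg)] - seg$start[-1L]) > span_tol))
      stop("history segments not contiguous on branch ", e)
  }
  invisible(TRUE)
}

#' @export
print.history_set <- function(x, ...) {
  cat("History set:", length(x$draws), "draws over",
      length(x$trees$trees), "tree(s);",
      if (length(x$draws)) paste(names(x$draws[[1L]]), collapse = ", ")
      else "no characters", "\n")
  invisible(x)
}

#' @export
length.history_set <- function(x) length(x$draws)

#' @rdname write_histories
#' @param draw draw index to export.
#' @param character character name to export.
#' @return `write_simmap()`: the path, invisibly. One annotated-newick tree
#'   per call, with per-branch state segments in
#'   `{state,duration:...}` order from the young end of the branch, following
#'   the convention of simmap-style files.
#' @export
write_simmap <- function(histories, path, draw = 1L,
                         character = names(histories$draws[[1L]])[1L]) {
  stopifnot(inherits(histories, "history_set"))
  h <- histories$draws[[draw]][[character]]
  tree <- histories$trees$trees[[histories$tree[draw]]]
  ntip <- length(tree$tip.label)
  lab <- function(n) if (n <= ntip) tree$tip.label[n] else ""
  annot <- function(e) {
    seg <- h[h$branch == e, ]
    seg <- seg[order(-seg$start), ]
    parts <- paste0(rev(seg$state), ",",
                    format(rev(seg$start - seg$end), digits = 10,
                           trim = TRUE))
    paste0(":{", paste(parts, collapse = ":"), "}")
  }
  build <- function(node) {
    kids <- which(tree$edge[, 1L] == node)
    if (length(kids) == 0L) return(lab(node))
    inner <- vapply(kids, function(e)
      paste0(build(tree$edge[e, 2L]), annot(e)), character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  writeLines(paste0(build(ntip + 1L), ";"), path)
  invisible(path)
}
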