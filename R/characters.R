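#' Discrete character matrices
#'
#' A `character_matrix` stores, for one named character, the set of states
#' each taxon may be in: a singleton set is a certain observation, a larger
#' set encodes ambiguity, and the full alphabet encodes a missing value.
#'
#' @param name character name (e.g. `"habitat"`, `"ggpS"`).
#' @param states ordered state alphabet (e.g. `c("L", "H")` or `c("A", "P")`).
#' @param tips named list; each element a non-empty subset of `states`.
#' @return an object of class `character_matrix`.
#' @export
character_matrix <- function(name, states, tips) {
  stopifnot(is.character(states), length(states) >= 2L,
            !anyDuplicated(states))
  if (is.null(names(tips)) || anyDuplicated(names(tips)))
    stop("tips must be a uniquely named list")
  tips <- lapply(tips, as.character)
  for (tx in names(tips)) {
    s <- tips[[tx]]
    if (length(s) == 0L || !all(s %in% states))
      stop("invalid state set for taxon ", tx, ": ",
           paste(s, collapse = "/"))
  }
  structure(list(name = name, states = states, tips = tips),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  amb <- sum(vapply(x$tips, length, 1L) > 1L)
  cat("Character \"", x$name, "\": states {",
      paste(x$states, collapse = ", "), "}, ",
      length(x$tips), " taxa (", amb, " ambiguous)\n", sep = "")
  invisible(x)
}

#' Read discrete characters from a TSV table
#'
#' The file must have a header row `taxon<TAB><character>...`. Cells contain a
#' state label, a slash-separated ambiguity set (`H/L`), or `?` for missing
#' (mapped to the full alphabet).
#'
#' @param path TSV file.
#' @param alphabet state alphabet: a character vector applied to every column,
#'   or a named list with one alphabet per character column.
#' @return a named list of [character_matrix()] objects, one per column.
#' @export
read_character_table <- function(path, alphabet) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("character table needs a taxon column and >=1 character column")
  taxa <- tab[[1L]]
  if (anyDuplicated(taxa))
    stop("duplicate taxon rows: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  chars <- names(tab)[-1L]
  if (!is.list(alphabet)) alphabet <- stats::setNames(rep(list(alphabet), length(chars)), chars)
  out <- list()
  for (ch in chars) {
    alpha <- alphabet[[ch]]
    if (is.null(alpha)) stop("no alphabet given for character ", ch)
    cells <- tab[[ch]]
    tips <- vector("list", length(taxa))
    names(tips) <- taxa
    for (i in seq_along(taxa)) {
      cell <- trimws(cells[i])
      if (cell == "?" || cell == "") {
        tips[[i]] <- alpha
      } else {
        s <- strsplit(cell, "/", fixed = TRUE)[[1L]]
        if (!all(s %in% alpha))
          stop("unknown state \"", cell, "\" for taxon ", taxa[i],
               " in character ", ch)
        tips[[i]] <- s
      }
    }
    out[[ch]] <- character_matrix(ch, alpha, tips)
  }
  out
}

#' Write characters to a TSV table
#'
#' Inverse of [read_character_table()]: ambiguity sets are slash-separated and
#' full-alphabet sets are written as `?`.
#'
#' @param chars a named list of [character_matrix()] (or a single one).
#' @param path output TSV path.
#' @export
write_character_table <- function(chars, path) {
  if (inherits(chars, "character_matrix")) chars <- list(chars)
  taxa <- names(chars[[1L]]$tips)
  cols <- lapply(chars, function(cm) {
    stopifnot(identical(sort(names(cm$tips)), sort(taxa)))
    vapply(taxa, function(tx) {
      s <- cm$tips[[tx]]
      if (length(s) == length(cm$states)) "?" else paste(s, collapse = "/")
    }, character(1))
  })
  tab <- data.frame(taxon = taxa, cols, check.names = FALSE)
  names(tab) <- c("taxon", vapply(chars, `[[`, "", "name"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse gene presence/absence characters to one pathway character
#'
#' Codes a strain as able to produce the compatible solute if it has at least
#' one of the genes involved in the pathway (the binary coding used for Tre,
#' GGA, and GB). Ambiguity propagates: if presence cannot be decided from the
#' allowed gene-state combinations, both states are retained.
#'
#' @param genes list of binary [character_matrix()] objects over the same
#'   taxa, with alphabet `c("A", "P")`.
#' @param name name for the collapsed character (default `"pathway"`).
#' @param present,absent output state labels.
#' @return a binary [character_matrix()].
#' @export
binarize_gene_presence <- function(genes, name = "pathway",
                                   present = "P", absent = "A") {
  stopifnot(length(genes) >= 1L)
  taxa <- names(genes[[1L]]$tips)
  for (g in genes) {
    if (!identical(sort(names(g$tips)), sort(taxa)))
      stop("taxon mismatch between gene matrices")
    if (!setequal(g$states, c("A", "P")))
      stop("gene characters must be binary over {A, P}")
  }
  tips <- lapply(taxa, function(tx) {
    sets <- lapply(genes, function(g) g$tips[[tx]])
    combos <- expand.grid(sets, stringsAsFactors = FALSE)
    out <- unique(ifelse(apply(combos == "P", 1L, any), present, absent))
    sort(out)
  })
  names(tips) <- taxa
  character_matrix(name, sort(c(absent, present)), tips)
}
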