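# File input/output and species-name standardization. Newick handling is
# delegated to ape; tabular inputs are delimiter-sniffed CSV/TSV with a
# header row.

#' Read a phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with validation: the file must contain exactly
#' one well-formed tree, tip labels must be unique, and branch lengths (when
#' present) must be nonnegative. Polytomies are preserved, never resolved.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) {
      stop(path, " contains ", length(tree), " trees; expected exactly one",
           call. = FALSE)
    }
    tree <- tree[[1L]]
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch lengths in ", path, call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' Round-trip safe: `read_newick(write_newick(t, f))` reproduces the
#' topology, branch lengths, and labels of `t` (labels containing spaces
#' survive via underscore encoding, the Newick convention ape applies).
#'
#' @param tree an [ape::phylo] object with at least 2 tips.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  assert_phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a two-column synonym map
#'
#' @param path CSV/TSV file with columns `synonym` and `accepted`.
#' @return a named character vector: accepted binomials keyed by synonym.
#' @export
read_name_map <- function(path) {
  tab <- read_table_auto(path)
  if (!all(c("synonym", "accepted") %in% names(tab))) {
    stop("name map needs columns 'synonym' and 'accepted'", call. = FALSE)
  }
  syn <- normalize_separators(tab$synonym)
  acc <- normalize_separators(tab$accepted)
  if (anyDuplicated(syn)) {
    stop("name map is not functional: duplicated synonyms ",
         paste(unique(syn[duplicated(syn)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(acc, syn)
}

#' @noRd
normalize_separators <- function(x) {
  x <- gsub("_", " ", trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Standardize species names
#'
#' Unifies separators (underscores and repeated whitespace become single
#' spaces), replaces synonyms through the supplied map, and handles
#' infraspecific names: a name with more than two tokens is truncated to its
#' binomial unless that binomial already occurs among the standardized
#' names, in which case it is dropped. The operation is idempotent and every
#' change or drop is listed in the report.
#'
#' @param labels character vector of raw names (nonempty strings).
#' @param name_map optional named character vector (synonym -> accepted),
#'   e.g. from [read_name_map()].
#' @return list with `names` (accepted binomials, drops removed) and
#'   `report`, a data frame with one row per input: `raw`, `accepted` (NA if
#'   dropped) and `action` (`unchanged`, `separators`, `synonym`,
#'   `truncated`, `dropped`).
#' @examples
#' standardize_names(c("Alouatta_palliata", "Gorilla gorilla gorilla"))
#' @export
standardize_names <- function(labels, name_map = NULL) {
  if (!length(labels) || any(is.na(labels)) || any(!nzchar(trimws(labels)))) {
    stop("labels must be nonempty strings", call. = FALSE)
  }
  raw <- labels
  out <- normalize_separators(raw)
  action <- ifelse(out == raw, "unchanged", "separators")
  if (!is.null(name_map)) {
    hit <- out %in% names(name_map)
    out[hit] <- unname(name_map[out[hit]])
    action[hit] <- "synonym"
  }
  tokens <- strsplit(out, " ", fixed = TRUE)
  n_tok <- lengths(tokens)
  binomial_pool <- unique(out[n_tok <= 2L])
  infra <- which(n_tok > 2L)
  for (i in infra) {
    binom <- paste(tokens[[i]][1:2], collapse = " ")
    if (binom %in% binomial_pool) {
      out[i] <- NA_character_
      action[i] <- "dropped"
    } else {
      out[i] <- binom
      action[i] <- "truncated"
      binomial_pool <- c(binomial_pool, binom)
    }
  }
  report <- data.frame(raw = raw, accepted = out, action = action,
                       stringsAsFactors = FALSE)
  list(names = out[!is.na(out)], report = report)
}

#' Read a delimited table, sniffing comma vs. tab
#'
#' @param path path to a CSV or TSV file with a header row.
#' @return a data frame.
#' @export
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
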