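# Internal tree indexing helpers shared by the D-statistic machinery.
# All functions operate on ape "phylo" objects; tips are addressed by their
# position in tree$tip.label (ape convention: tip ids 1..n, root n+1).

#' @keywords internal
#' @noRd
assert_phylo <- function(tree, require_lengths = FALSE) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  }
  if (length(tree$tip.label) < 2L) {
    stop("tree must have at least 2 tips", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (require_lengths) {
    if (is.null(tree$edge.length)) {
      stop("tree has no branch lengths; they are required here", call. = FALSE)
    }
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0)) {
      stop("all branch lengths must be positive and finite", call. = FALSE)
    }
  }
  invisible(tree)
}

# Precomputed traversal index reused across many trait vectors on one tree.
# $postorder_parents: internal node ids in children-first order
# $children: list keyed by node id (as character) of child node ids
#' @noRd
tree_index <- function(tree) {
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  parents <- unique(edge[, 1L]) # postorder: children edges precede parents
  children <- split(edge[, 2L], factor(edge[, 1L], levels = parents))
  list(
    n_tip = length(tre$tip.label),
    tip_label = tre$tip.label,
    edge = edge,
    parents = parents,
    children = children
  )
}

# Nodal-value estimation + sum of edgewise absolute differences, vectorised
# over columns of `states` (n_tip x R matrix, rows in tip.label order).
# Each internal node takes the unweighted mean of its children's values
# (polytomies: mean over all children); Sigma-d is the sum over all edges of
# |value(parent) - value(child)|.
#' @noRd
sumd_matrix <- function(idx, states) {
  n_tip <- idx$n_tip
  n_rep <- ncol(states)
  n_node_total <- max(idx$edge)
  V <- matrix(NA_real_, n_node_total, n_rep)
  V[seq_len(n_tip), ] <- states
  ch <- idx$children
  parents <- idx$parents
  for (i in seq_along(parents)) {
    kids <- ch[[i]]
    if (length(kids) == 2L) {
      V[parents[i], ] <- (V[kids[1L], ] + V[kids[2L], ]) / 2
    } else {
      V[parents[i], ] <- .colMeans(V[kids, , drop = FALSE], length(kids), n_rep)
    }
  }
  .colSums(abs(V[idx$edge[, 1L], , drop = FALSE] - V[idx$edge[, 2L], , drop = FALSE]),
           nrow(idx$edge), n_rep)
}

# Simulate Brownian motion along the tree, returning an n_tip x n_rep matrix
# of tip values; variance of each increment equals the branch length
# (rate fixed at 1; rank thresholding makes downstream statistics
# rate-invariant). Rows follow tree$tip.label order.
#' @noRd
bm_tip_values <- function(tree, n_rep) {
  assert_phylo(tree, require_lengths = TRUE)
  tre <- ape::reorder.phylo(tree, "cladewise") # parents before children
  edge <- tre$edge
  len <- tre$edge.length
  n_tip <- length(tre$tip.label)
  V <- matrix(0, max(edge), n_rep)
  sd_len <- sqrt(len)
  for (i in seq_len(nrow(edge))) {
    V[edge[i, 2L], ] <- V[edge[i, 1L], ] + stats::rnorm(n_rep, 0, sd_len[i])
  }
  V[seq_len(n_tip), , drop = FALSE]
}

# Rank-threshold each column of a continuous-value matrix to a 0/1 matrix
# with exactly k ones per column (ties broken by first occurrence).
#' @noRd
threshold_top_k <- function(values, k) {
  n <- nrow(values)
  if (k < 1L || k > n - 1L) {
    stop("prevalence k must satisfy 1 <= k <= n - 1", call. = FALSE)
  }
  cut_pos <- n - k + 1L
  out <- apply(values, 2L, function(x) {
    thr <- sort(x, partial = cut_pos)[cut_pos]
    s <- x > thr
    need <- k - sum(s) # ties at the cutoff: keep first occurrences
    if (need > 0L) s[which(x == thr)[seq_len(need)]] <- TRUE
    as.integer(s)
  })
  matrix(out, nrow = n)
}

# Reorder a named binary trait vector into tree tip order, with validation.
#' @noRd
align_trait <- function(tree, trait) {
  n <- length(tree$tip.label)
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing)) {
      stop("tips without a trait state: ", paste(utils::head(missing, 5L), collapse = ", "),
           call. = FALSE)
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n) {
    stop("unnamed trait vector must have one state per tip", call. = FALSE)
  }
  trait <- as.integer(trait)
  if (anyNA(trait) || !all(trait %in% c(0L, 1L))) {
    stop("trait states must all be 0 or 1", call. = FALSE)
  }
  if (length(unique(trait)) < 2L) {
    stop("trait is monomorphic: both states must be present", call. = FALSE)
  }
  names(trait) <- tree$tip.label
  trait
}

# Derive a small positive integer seed from a base seed and a string key,
# stably across R sessions (used so results do not depend on iteration order).
#' @noRd
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}
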