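#' Sum of sister-clade differences for a binary trait
#'
#' Estimates a value at every internal node by a single leaf-to-root pass in
#' which each node takes the unweighted arithmetic mean of its children's
#' values (polytomies take the mean over all children), then sums the absolute
#' difference in estimated values across every edge of the tree. This edgewise
#' sum, written \eqn{\Sigma d}, is the raw quantity that the D statistic
#' rescales: clumped traits change value along few edges and give small
#' \eqn{\Sigma d}; traits scattered over the tree give large \eqn{\Sigma d}.
#'
#' The estimator uses topology only, so \eqn{\Sigma d} is invariant to
#' rescaling branch lengths and to the order of children. Replacing a trait
#' by its complement leaves \eqn{\Sigma d} unchanged.
#'
#' @param tree an [ape::phylo] tree with at least 4 tips.
#' @param trait binary (0/1) states: a vector named by tip label (or in
#'   `tree$tip.label` order), or a matrix with one column per replicate and
#'   rows in tip order.
#' @return a single \eqn{\Sigma d} value, or a vector of values (one per
#'   column) when `trait` is a matrix.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' sum_sister_differences(tr, c(A = 1, B = 1, C = 0, D = 0)) # 1: one clade
#' sum_sister_differences(tr, c(A = 1, B = 0, C = 1, D = 0)) # 2: alternating
#' @export
sum_sister_differences <- function(tree, trait) {
  assert_phylo(tree)
  if (length(tree$tip.label) < 4L) {
    stop("tree must have at least 4 tips", call. = FALSE)
  }
  idx <- tree_index(tree)
  if (is.matrix(trait)) {
    if (nrow(trait) != idx$n_tip) {
      stop("trait matrix must have one row per tip", call. = FALSE)
    }
    if (!all(trait %in% c(0L, 1L))) {
      stop("trait states must all be 0 or 1", call. = FALSE)
    }
    if (any(colSums(trait) %in% c(0L, idx$n_tip))) {
      stop("trait is monomorphic: both states must be present", call. = FALSE)
    }
    return(sumd_matrix(idx, trait))
  }
  trait <- align_trait(tree, trait)
  sumd_matrix(idx, matrix(as.numeric(trait), ncol = 1L))[1L]
}

#' Tip-shuffle (random) null distribution of \eqn{\Sigma d}
#'
#' Permutes the observed states across the tips of the tree `B` times,
#' preserving prevalence exactly, and returns \eqn{\Sigma d} for each
#' permutation. Under this null the trait carries no phylogenetic structure.
#'
#' @inheritParams sum_sister_differences
#' @param B number of permutations (default 9999).
#' @param seed optional integer seed; when supplied the result is reproducible
#'   and the caller's RNG state is left untouched.
#' @return numeric vector of length `B`.
#' @export
permutation_null <- function(tree, trait, B = 9999, seed = NULL) {
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  trait <- align_trait(tree, trait)
  idx <- tree_index(tree)
  draw <- function() {
    perms <- matrix(replicate(B, sample(as.numeric(trait))), ncol = B)
    sumd_matrix(idx, perms)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Brownian-threshold null distribution of \eqn{\Sigma d}
#'
#' Simulates `B` binary traits under the Brownian-motion threshold model at
#' the observed prevalence (a continuous character evolves by Brownian motion
#' along the branches; the `k` tips with the largest values take state 1) and
#' returns \eqn{\Sigma d} for each. Under this null the trait is as clumped
#' as inheritance of a continuous liability would make it.
#'
#' @inheritParams permutation_null
#' @param k prevalence: number of tips assigned state 1 in every replicate
#'   (1 to n-1).
#' @return numeric vector of length `B`.
#' @export
brownian_null <- function(tree, k, B = 9999, seed = NULL) {
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  assert_phylo(tree, require_lengths = TRUE)
  idx <- tree_index(tree)
  draw <- function() {
    vals <- bm_tip_values(tree, B)
    sumd_matrix(idx, threshold_top_k(vals, k))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Rescale an observed \eqn{\Sigma d} against its two null means
#'
#' The D statistic places the observed sum of sister-clade differences on a
#' scale anchored at the means of its two null distributions:
#' \deqn{D = \frac{\Sigma d_{obs} - \overline{\Sigma d_b}}
#'                {\overline{\Sigma d_r} - \overline{\Sigma d_b}}}
#' so that D = 0 when the trait is as clumped as the Brownian-threshold
#' expectation and D = 1 when it looks randomly shuffled.
#'
#' @param sumd_obs observed \eqn{\Sigma d}.
#' @param sumd_r vector of tip-shuffle null sums.
#' @param sumd_b vector of Brownian-threshold null sums.
#' @param tol denominator tolerance; the scaling is refused (error) when the
#'   two null means differ by less than `tol` (default `1e-10 * mean(sumd_r)`),
#'   as on star-like trees where the two nulls coincide.
#' @return the scaled D value.
#' @export
scale_d <- function(sumd_obs, sumd_r, sumd_b, tol = NULL) {
  mean_r <- mean(sumd_r)
  mean_b <- mean(sumd_b)
  if (is.null(tol)) tol <- 1e-10 * mean_r
  if (abs(mean_r - mean_b) <= tol) {
    stop("degenerate D denominator: random and Brownian null means coincide ",
         "(star-like tree?)", call. = FALSE)
  }
  (sumd_obs - mean_b) / (mean_r - mean_b)
}

#' Phylogenetic signal in a binary trait: the D statistic
#'
#' Computes the observed \eqn{\Sigma d}, its tip-shuffle and
#' Brownian-threshold null distributions, the scaled D statistic, and two
#' one-sided randomization p-values:
#' \itemize{
#'   \item `p_d0` — P(D = 0): the fraction of Brownian-threshold replicates at
#'     least as dispersed as the observation,
#'     \eqn{(1 + \#\{\Sigma d_b \ge \Sigma d_{obs}\})/(B+1)}. Small values are
#'     evidence against Brownian-like clumping.
#'   \item `p_d1` — P(D = 1): the fraction of shuffle replicates at least as
#'     clumped as the observation,
#'     \eqn{(1 + \#\{\Sigma d_r \le \Sigma d_{obs}\})/(B+1)}. Small values are
#'     evidence against a random spread.
#' }
#' The add-one correction keeps both p-values in \eqn{[1/(B+1), 1]}.
#'
#' @inheritParams permutation_null
#' @param tol denominator tolerance passed to [scale_d()].
#' @param keep_null keep the two null vectors in the result (default TRUE).
#' @return an object of class `alc_d`: a list with `sumd_obs`, `D`, `p_d0`,
#'   `p_d1`, `B`, `seed`, `k`, `n_tip`, and (optionally) `sumd_r`, `sumd_b`.
#' @examples
#' tr <- ape::rphylo(30, 1, 0)
#' trait <- stats::setNames(rep(c(1, 0), c(10, 20)), tr$tip.label)
#' d <- d_statistic(tr, trait, B = 199, seed = 1)
#' d$D
#' @export
d_statistic <- function(tree, trait, B = 9999, seed = NULL, tol = NULL,
                        keep_null = TRUE) {
  assert_phylo(tree, require_lengths = TRUE)
  if (length(tree$tip.label) < 4L) {
    stop("tree must have at least 4 tips", call. = FALSE)
  }
  trait <- align_trait(tree, trait)
  k <- sum(trait)
  idx <- tree_index(tree)
  sumd_obs <- sumd_matrix(idx, matrix(as.numeric(trait), ncol = 1L))[1L]
  run <- function() {
    sumd_r <- sumd_matrix(idx, matrix(replicate(B, sample(as.numeric(trait))), ncol = B))
    sumd_b <- sumd_matrix(idx, threshold_top_k(bm_tip_values(tree, B), k))
    list(r = sumd_r, b = sumd_b)
  }
  nulls <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  D <- scale_d(sumd_obs, nulls$r, nulls$b, tol = tol)
  out <- list(
    sumd_obs = sumd_obs,
    D = D,
    p_d1 = (1 + sum(nulls$r <= sumd_obs)) / (B + 1),
    p_d0 = (1 + sum(nulls$b >= sumd_obs)) / (B + 1),
    mean_sumd_r = mean(nulls$r),
    mean_sumd_b = mean(nulls$b),
    B = as.integer(B),
    seed = seed,
    k = k,
    n_tip = length(tree$tip.label)
  )
  if (keep_null) {
    out$sumd_r <- nulls$r
    out$sumd_b <- nulls$b
  }
  structure(out, class = "alc_d")
}

#' @export
print.alc_d <- function(x, ...) {
  cat("D statistic for phylogenetic signal in a binary trait\n")
  cat(sprintf("  tips: %d   state-1 tips (k): %d   permutations: %d\n",
              x$n_tip, x$k, x$B))
  cat(sprintf("  Sigma-d observed: %.4f  (random null mean %.4f, Brownian null mean %.4f)\n",
              x$sumd_obs, x$mean_sumd_r, x$mean_sumd_b))
  cat(sprintf("  D = %.4f   P(D=0) = %.4g   P(D=1) = %.4g\n", x$D, x$p_d0, x$p_d1))
  invisible(x)
}

#' @export
as.data.frame.alc_d <- function(x, ...) {
  data.frame(
    n_tip = x$n_tip, k = x$k, B = x$B,
    sumd_obs = x$sumd_obs,
    mean_sumd_random = x$mean_sumd_r,
    mean_sumd_brownian = x$mean_sumd_b,
    D = x$D, p_d0 = x$p_d0, p_d1 = x$p_d1
  )
}
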