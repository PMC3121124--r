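#' Pseudocounted residue frequencies of one alignment column
#'
#' Counts over the `M` paired rows are regularized by a count-based
#' pseudocount that spreads `eta` pseudo-observations uniformly over the
#' alphabet, `(count + eta/21) / (M + eta)`: every entry is strictly
#' positive (for `eta > 0`), the total is 1, and the regularization
#' fades as the alignment deepens, so deep alignments keep the full
#' mutual-information scale.  The default pseudocount weight is
#' `eta = 1` (one pseudo-observation).
#'
#' @param pa A [pair_rows()] result with `M >= 1`.
#' @param which `"a"` or `"b"`: which alignment the column belongs to.
#' @param i Column index (1-based).
#' @param eta Pseudocount weight, `>= 0`.
#' @return Named numeric vector over the 21 symbols of [aa_alphabet()],
#'   summing to 1.
#' @export
column_frequencies <- function(pa, which = c("a", "b"), i, eta = 1) {
  which <- match.arg(which)
  if (pa$M < 1L) stop("undefined frequencies: no paired rows (M = 0)")
  stopifnot(eta >= 0)
  mat <- if (which == "a") pa$a_mat else pa$b_mat
  if (i < 1L || i > ncol(mat)) stop("column index out of range: ", i)
  counts <- tabulate(mat[, i], nbins = 21L)
  f <- (counts + eta / 21) / (pa$M + eta)
  stats::setNames(f, AA_SYMBOLS)
}

#' Pseudocounted joint residue frequencies of a column pair
#'
#' The joint table over the 21 x 21 symbol pairs of column `i` of the
#' first domain and column `j` of the second, counted across paired rows
#' and pseudocounted as `(count + eta/441) / (M + eta)`.
#'
#' @inheritParams column_frequencies
#' @param i Column index in the first domain's alignment.
#' @param j Column index in the second domain's alignment.
#' @return 21 x 21 numeric matrix (rows: symbol in `a`; columns: symbol in
#'   `b`) summing to 1.
#' @export
joint_frequencies <- function(pa, i, j, eta = 1) {
  if (pa$M < 1L) stop("undefined frequencies: no paired rows (M = 0)")
  stopifnot(eta >= 0)
  if (i < 1L || i > ncol(pa$a_mat)) stop("column index i out of range: ", i)
  if (j < 1L || j > ncol(pa$b_mat)) stop("column index j out of range: ", j)
  codes <- (pa$a_mat[, i] - 1L) * 21L + pa$b_mat[, j]
  counts <- tabulate(codes, nbins = 441L)
  f <- (counts + eta / 441) / (pa$M + eta)
  matrix(f, nrow = 21L, ncol = 21L, byrow = TRUE,
         dimnames = list(AA_SYMBOLS, AA_SYMBOLS))
}

#' Mutual information of a column pair
#'
#' The Kullback-Leibler divergence between the joint frequencies and the
#' product of the marginals, in nats:
#' \deqn{MI_{ij} = \sum_{A,B} f_{ij}(A,B)\,
#'   \ln\frac{f_{ij}(A,B)}{f_i(A) f_j(B)}.}
#' Cells with `f_ij = 0` (possible only at `eta = 0`) contribute zero by
#' the usual `0 log 0` convention.  Tiny negative rounding noise is
#' clamped to 0.
#'
#' @param f_i,f_j Marginal frequency vectors from [column_frequencies()].
#' @param f_ij Joint frequency matrix from [joint_frequencies()] (rows
#'   indexed by the symbol of `f_i`).
#' @return Non-negative scalar, at most `log(21)`.
#' @export
mi_position_pair <- function(f_i, f_j, f_ij) {
  if (any(f_i < 0) || any(f_j < 0) || any(f_ij < 0))
    stop("negative frequency supplied")
  prod_marg <- outer(f_i, f_j)
  nz <- f_ij > 0
  if (any(prod_marg[nz] == 0))
    stop("joint frequency positive where a marginal is zero")
  mi <- sum(f_ij[nz] * log(f_ij[nz] / prod_marg[nz]))
  max(mi, 0)
}

#' Average mutual information under random re-pairing (shuffle null)
#'
#' Mutual information is biased upward by the shapes of the marginal
#' distributions even for independent columns.  The null level is
#' estimated by repeatedly permuting which row of the second alignment is
#' paired with which row of the first (the marginals are unchanged, the
#' joint structure is destroyed), recomputing MI with the same
#' pseudocounts, and averaging.
#'
#' @inheritParams joint_frequencies
#' @param n_shuffles Number of random permutations; default 400.
#' @param seed Optional integer seed making the estimate reproducible.
#' @return The mean MI over the shuffled pairings.
#' @export
shuffle_null <- function(pa, i, j, eta = 1, n_shuffles = 400, seed = NULL) {
  if (pa$M < 2L) stop("shuffle null undefined for M < 2")
  stopifnot(n_shuffles >= 1)
  f_i <- column_frequencies(pa, "a", i, eta)
  f_j <- column_frequencies(pa, "b", j, eta)
  run <- function() {
    total <- 0
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(pa$M)
      codes <- (pa$a_mat[, i] - 1L) * 21L + pa$b_mat[perm, j]
      counts <- tabulate(codes, nbins = 441L)
      f <- matrix((counts + eta / 441) / (pa$M + eta),
                  nrow = 21L, ncol = 21L, byrow = TRUE)
      total <- total + mi_position_pair(f_i, f_j, f)
    }
    total / n_shuffles
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}
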