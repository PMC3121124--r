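#' Pair the rows of two domain alignments by organism
#'
#' Joint residue frequencies between two domain families require knowing
#' which sequence of one alignment goes with which sequence of the other.
#' Rows are matched through their organism tag: within each organism, rows
#' are paired greedily in file order, up to the smaller of the two per-
#' organism counts.  Rows left without a partner are dropped and contribute
#' nothing to any frequency.
#'
#' @param a,b [domain_alignment()] objects.  `a` and `b` may be the same
#'   alignment (self-pairing), in which case every row pairs with itself.
#' @return An object of class `paired_alignment`: `domain_a`, `domain_b`,
#'   `idx_a`, `idx_b` (row indices into `a` and `b`), `M` (number of
#'   pairs), `a_mat`, `b_mat` (integer residue matrices restricted to the
#'   paired rows, row k of each being the k-th pair), and `organisms`.
#'   `M = 0` is a valid, empty pairing.
#' @export
pair_rows <- function(a, b) {
  stopifnot(inherits(a, "domain_alignment"), inherits(b, "domain_alignment"))
  idx_a <- integer(0)
  idx_b <- integer(0)
  for (org in unique(a$organisms)) {
    ra <- which(a$organisms == org)
    rb <- which(b$organisms == org)
    k <- min(length(ra), length(rb))
    if (k > 0L) {
      idx_a <- c(idx_a, ra[seq_len(k)])
      idx_b <- c(idx_b, rb[seq_len(k)])
    }
  }
  structure(
    list(domain_a = a$domain_id, domain_b = b$domain_id,
         idx_a = idx_a, idx_b = idx_b, M = length(idx_a),
         a_mat = a$mat[idx_a, , drop = FALSE],
         b_mat = b$mat[idx_b, , drop = FALSE],
         organisms = a$organisms[idx_a]),
    class = "paired_alignment")
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat("paired_alignment ", x$domain_a, " x ", x$domain_b, ": M = ", x$M,
      " paired rows\n", sep = "")
  invisible(x)
}

#' Mask alignment columns with too many gaps
#'
#' Columns whose gap fraction among the *paired* rows exceeds the
#' threshold are excluded from the domain-level score: gap-heavy columns
#' inflate mutual information spuriously.  The fraction is computed on the
#' paired rows only, because those are the rows the frequencies count.
#'
#' @param pa A [pair_rows()] result.
#' @param which `"a"` or `"b"`: which side's columns to assess.
#' @param threshold Gap fraction above which (strictly) a column is
#'   masked; default 0.20.
#' @return Logical vector, `TRUE` for masked (excluded) columns.
#' @export
gap_mask <- function(pa, which = c("a", "b"), threshold = 0.2) {
  which <- match.arg(which)
  stopifnot(threshold >= 0, threshold <= 1)
  mat <- if (which == "a") pa$a_mat else pa$b_mat
  if (pa$M == 0L) return(rep(FALSE, ncol(mat)))
  colMeans(mat == aa_gap_index()) > threshold
}
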