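#' Shuffle-corrected mutual information between two domain families
#'
#' The domain-pair coevolution score is the maximum, over all unmasked
#' column pairs (i, j), of the raw column-pair MI minus its shuffle-null
#' mean:
#' \deqn{M_{mn} = \max_{i,j}\; \big( MI_{ij} - \langle MI_{ij}^{\mathrm{shuffle}} \rangle \big).}
#' Rows are paired by organism ([pair_rows()]), frequencies are
#' pseudocounted ([column_frequencies()]), columns with a gap fraction
#' above `gap_threshold` are excluded ([gap_mask()]), and the null is the
#' mean MI over `n_shuffles` random re-pairings of the second alignment's
#' rows.  The correction is applied per position pair, before the max;
#' negative corrected values are not clamped, so `m_mn` can be negative
#' if every position pair corrects below its null.
#'
#' The computation is symmetric: the two alignments are put in canonical
#' (sorted domain id) order and the shuffle seed is derived from the
#' sorted pair of ids, so `compute_domain_mi(a, b)` and
#' `compute_domain_mi(b, a)` are bit-identical.  For a domain paired with
#' itself the diagonal i = j is excluded from the max (its MI is the
#' column entropy, not coevolution).
#'
#' If fewer than 2 rows can be paired, or every column is masked on
#' either side, the score is unavailable: `m_mn` is `NA` and `available`
#' is `FALSE`.  Downstream, the CRF falls back to the MI-free feature for
#' such pairs.
#'
#' @param a,b [domain_alignment()] objects.
#' @param eta Pseudocount weight (default 1).
#' @param gap_threshold Gap-fraction mask threshold (default 0.20).
#' @param n_shuffles Shuffle repetitions for the null (default 400).
#' @param seed Global integer seed; the per-pair stream is derived from it
#'   and the sorted domain ids, so results do not depend on computation
#'   order.
#' @param keep_matrices Keep the full MI and null matrices in the result.
#' @return Object of class `domain_mi_score`: `domain_a`, `domain_b`
#'   (sorted), `m_mn`, `n_positions_used`, `M`, `n_shuffles`, `seed`
#'   (the derived per-pair seed), `available`, and optionally `mi`,
#'   `null_mean`, `corrected`.
#' @export
compute_domain_mi <- function(a, b, eta = 1, gap_threshold = 0.2,
                              n_shuffles = 400, seed = 1L,
                              keep_matrices = FALSE) {
  stopifnot(inherits(a, "domain_alignment"), inherits(b, "domain_alignment"))
  if (a$domain_id > b$domain_id) { tmp <- a; a <- b; b <- tmp }
  derived <- pair_seed(seed, a$domain_id, b$domain_id)
  unavailable <- function(M) {
    structure(list(domain_a = a$domain_id, domain_b = b$domain_id,
                   m_mn = NA_real_, n_positions_used = 0L, M = M,
                   n_shuffles = n_shuffles, seed = derived,
                   available = FALSE),
              class = "domain_mi_score")
  }
  pa <- pair_rows(a, b)
  if (pa$M < 2L) return(unavailable(pa$M))
  mask_a <- gap_mask(pa, "a", gap_threshold)
  mask_b <- gap_mask(pa, "b", gap_threshold)
  if (all(mask_a) || all(mask_b)) return(unavailable(pa$M))

  res <- with_rng_seed(derived,
    mi_shuffle_core(pa$a_mat, pa$b_mat, eta, as.integer(n_shuffles),
                    mask_a, mask_b))
  corrected <- res$mi - res$null_mean
  if (a$domain_id == b$domain_id) {
    k <- min(nrow(corrected), ncol(corrected))
    corrected[cbind(seq_len(k), seq_len(k))] <- NA_real_
  }
  valid <- !is.na(corrected)
  if (!any(valid)) return(unavailable(pa$M))
  out <- structure(
    list(domain_a = a$domain_id, domain_b = b$domain_id,
         m_mn = max(corrected[valid]),
         n_positions_used = sum(valid),
         M = pa$M, n_shuffles = n_shuffles, seed = derived,
         available = TRUE),
    class = "domain_mi_score")
  if (keep_matrices) {
    out$mi <- res$mi
    out$null_mean <- res$null_mean
    out$corrected <- corrected
  }
  out
}

#' @export
print.domain_mi_score <- function(x, ...) {
  cat("domain_mi_score ", x$domain_a, " x ", x$domain_b, ": ", sep = "")
  if (x$available)
    cat(sprintf("m_mn = %.4f (M = %d, %d position pairs)\n",
                x$m_mn, x$M, x$n_positions_used))
  else cat("unavailable (M = ", x$M, ")\n", sep = "")
  invisible(x)
}

#' Domain-pair MI scores for a table of pairs
#'
#' @param alignments Named list of [domain_alignment()] objects.
#' @param pairs Data frame with columns `domain_a`, `domain_b`, or `NULL`
#'   for all unordered pairs (including self pairs) of the alignments.
#' @inheritParams compute_domain_mi
#' @return Data frame with columns `domain_a`, `domain_b`, `m_mn`,
#'   `n_positions_used`, `M`, `seed` (one row per unordered pair;
#'   unavailable scores have `m_mn = NA`).
#' @export
domain_mi_table <- function(alignments, pairs = NULL, eta = 1,
                            gap_threshold = 0.2, n_shuffles = 400,
                            seed = 1L) {
  ids <- names(alignments)
  if (is.null(pairs)) {
    grid <- which(upper.tri(matrix(0, length(ids), length(ids)), diag = TRUE),
                  arr.ind = TRUE)
    pairs <- data.frame(domain_a = ids[grid[, "row"]],
                        domain_b = ids[grid[, "col"]],
                        stringsAsFactors = FALSE)
  }
  da <- pmin(pairs$domain_a, pairs$domain_b)
  db <- pmax(pairs$domain_a, pairs$domain_b)
  keep <- !duplicated(paste(da, db, sep = "\r"))
  da <- da[keep]; db <- db[keep]
  missing <- setdiff(unique(c(da, db)), ids)
  if (length(missing) > 0L)
    stop("no alignment for domain(s): ", paste(missing, collapse = ", "))
  rows <- lapply(seq_along(da), function(k) {
    s <- compute_domain_mi(alignments[[da[k]]], alignments[[db[k]]],
                           eta = eta, gap_threshold = gap_threshold,
                           n_shuffles = n_shuffles, seed = seed)
    data.frame(domain_a = s$domain_a, domain_b = s$domain_b, m_mn = s$m_mn,
               n_positions_used = s$n_positions_used, M = s$M,
               seed = s$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of domain-pair MI scores
#'
#' Bins the `m_mn` column of a [domain_mi_table()] result into fixed-width
#' bins, the summary used to choose the feature threshold `c` (scores
#' below the bulk of the distribution are unlikely to mark interacting
#' domains).
#'
#' @param mi_table Data frame with an `m_mn` column.
#' @param binwidth Bin width in nats (default 0.1).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
mi_histogram <- function(mi_table, binwidth = 0.1) {
  v <- mi_table$m_mn
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  if (breaks[length(breaks)] < hi - 1e-12) breaks <- c(breaks, hi)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             count = tabulate(bin, nbins = length(breaks) - 1L))
}

#' Extract a named MI-score vector from a [domain_mi_table()] result
#'
#' @param mi_table Data frame with `domain_a`, `domain_b`, `m_mn`.
#' @return Named numeric vector keyed by canonical domain-pair id
#'   (see [dp_id()]); unavailable scores are `NA`.
#' @export
mi_scores_from_table <- function(mi_table) {
  stats::setNames(mi_table$m_mn, dp_id(mi_table$domain_a, mi_table$domain_b))
}
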