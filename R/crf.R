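# Conditional random field over protein-pair labels p_ij and latent
# domain-pair interaction variables d_mn, conditioned on the domain MI
# scores.  Because the exponent is additive over the domain pairs of a
# protein pair, the sum over latent states factorizes exactly:
#   S_p   = prod_mn ( e^{lambda_mn g(p,0)} + e^{lambda_mn g(p,1)} )
#   Z_ij  = S_1 + S_0,   Pr(P_ij = 1 | M) = S_1 / Z_ij.
# Everything is held in log space.

logaddexp <- function(x, y) {
  m <- pmax(x, y)
  m + log1p(exp(-abs(x - y)))
}

#' Local feature value g(s, t)
#'
#' The feature coupling the protein-pair label `s` to a latent domain-pair
#' state `t`.  With the MI-conditioned variant, `g(1,1) = sigma(m_mn - c)`
#' where `sigma` is the logistic function and `c` a positive threshold
#' (default 0.8): the more a domain pair's coevolution score exceeds the
#' bulk of the MI distribution, the stronger the reward for the
#' "both interact" configuration.  `g(0,1) = -1` in both variants: a
#' domain pair interacting while its protein pair does not is penalized.
#' `g(1,0) = g(0,0) = 0`.  The MI-free variant replaces the sigmoid by a
#' constant `+1`.  If `m_mn` is unavailable (`NA`), the MI variant falls
#' back to the MI-free value for that pair.
#'
#' @param variant `"with_mi"` or `"without_mi"`.
#' @param s,t Protein-pair label and domain-pair state, each 0 or 1.
#' @param m_mn Domain-pair MI score (only used by `"with_mi"` at
#'   `s = t = 1`); may be `NA`.
#' @param c Positive threshold on the MI scale (nats), default 0.8.
#' @return The feature value, a finite scalar.
#' @export
#' @examples
#' feature_value("with_mi", 1, 1, m_mn = 0.8)  # sigma(0) = 0.5
feature_value <- function(variant = c("with_mi", "without_mi"), s, t,
                          m_mn = NA_real_, c = 0.8) {
  variant <- match.arg(variant)
  stopifnot(s %in% c(0, 1), t %in% c(0, 1))
  if (t == 0) return(0)
  if (s == 0) return(-1)
  if (variant == "without_mi" || is.na(m_mn)) return(1)
  plogis(m_mn - c)
}

# Feature table for every domain pair of a factor graph (or any dp id
# vector): the four g(s,t) values, vectorized over domain pairs.
crf_features <- function(dp_ids, variant = c("with_mi", "without_mi"),
                         mi_scores = NULL, c = 0.8) {
  variant <- match.arg(variant)
  n <- length(dp_ids)
  g11 <- rep(1, n)
  n_fallback <- 0L
  if (variant == "with_mi") {
    if (is.null(mi_scores))
      stop("variant 'with_mi' requires mi_scores (see domain_mi_table)")
    m <- unname(mi_scores[dp_ids])
    miss <- is.na(m)
    n_fallback <- sum(miss)
    g11[!miss] <- plogis(m[!miss] - c)
  }
  list(variant = variant, c = c,
       g11 = g11, g01 = rep(-1, n), g10 = rep(0, n), g00 = rep(0, n),
       dp_ids = dp_ids, n_fallback = n_fallback)
}

#' Log-space likelihood terms of one protein pair
#'
#' The factorized per-pair quantities `log S_1`, `log S_0` and
#' `log Z = logaddexp(log S_1, log S_0)` for a single protein pair, given
#' the weights and feature values of its domain pairs.
#'
#' @param lambda Numeric vector of weights, one per domain pair of this
#'   protein pair.
#' @param g11,g01,g10,g00 Feature values `g(s,t)` per domain pair
#'   (defaults: the standard table with `g11 = 1`).
#' @return List with `log_s1`, `log_s0`, `log_z` and
#'   `prob = exp(log_s1 - log_z)`.
#' @export
pair_log_terms <- function(lambda, g11 = rep(1, length(lambda)),
                           g01 = rep(-1, length(lambda)),
                           g10 = rep(0, length(lambda)),
                           g00 = rep(0, length(lambda))) {
  if (length(lambda) == 0L)
    stop("protein pair has no domain pairs; cannot score")
  log_s1 <- sum(logaddexp(lambda * g10, lambda * g11))
  log_s0 <- sum(logaddexp(lambda * g00, lambda * g01))
  log_z <- logaddexp(log_s1, log_s0)
  list(log_s1 = log_s1, log_s0 = log_s0, log_z = log_z,
       prob = exp(log_s1 - log_z))
}

# Vectorized per-edge and per-pair terms over a whole factor graph.
# Returns edge-level log factors and pair-level log S1/S0/Z.
crf_terms <- function(lambda, fg, feats) {
  ep <- fg$edge_pair
  ed <- fg$edge_dp
  lam <- lambda[ed]
  le1 <- logaddexp(lam * feats$g10[ed], lam * feats$g11[ed])
  le0 <- logaddexp(lam * feats$g00[ed], lam * feats$g01[ed])
  n_pairs <- nrow(fg$labels)
  log_s1 <- as.vector(rowsum(le1, ep, reorder = TRUE))
  log_s0 <- as.vector(rowsum(le0, ep, reorder = TRUE))
  log_z <- logaddexp(log_s1, log_s0)
  list(log_s1 = log_s1, log_s0 = log_s0, log_z = log_z,
       prob1 = exp(log_s1 - log_z))
}

#' Conditional log-likelihood of the CRF
#'
#' \eqn{l(\lambda) = \sum_{ij} ( \log S_{p_{ij}} - \log Z_{ij} )}, always
#' \eqn{\le 0}.  An optional l1 penalty `- l1 * sum(|lambda|)` can be
#' added (off by default).
#'
#' @param lambda Named (or `dp_ids`-ordered) weight vector over
#'   `fg$dp_ids`.
#' @param fg A [build_factor_graph()] result.
#' @param feats Feature table from the trained variant (internal; built
#'   by [train_crf()] via its `variant`, `mi_scores` and `c` arguments).
#' @param l1 Non-negative l1 penalty weight.
#' @return Scalar log-likelihood.
#' @export
crf_log_likelihood <- function(lambda, fg, feats, l1 = 0) {
  tm <- crf_terms(lambda, fg, feats)
  obs <- ifelse(fg$labels$label == 1L, tm$log_s1, tm$log_s0)
  sum(obs - tm$log_z) - l1 * sum(abs(lambda))
}

#' Analytic gradient of the CRF log-likelihood
#'
#' The observed-minus-expected sufficient-statistic form: for each domain
#' pair, each protein pair containing it contributes
#' \eqn{E[g(p_{ij}, t) | p_{ij}] - \sum_p \Pr(p) E[g(p, t) | p]},
#' where the inner expectation over the latent state t uses the per-factor
#' Boltzmann weights.
#'
#' @inheritParams crf_log_likelihood
#' @return Numeric gradient vector over `fg$dp_ids`.
#' @export
crf_gradient <- function(lambda, fg, feats, l1 = 0) {
  ep <- fg$edge_pair
  ed <- fg$edge_dp
  lam <- lambda[ed]
  g11 <- feats$g11[ed]; g01 <- feats$g01[ed]
  g10 <- feats$g10[ed]; g00 <- feats$g00[ed]
  # E[g(p, t) | p] per edge; written to be stable for any g values
  e1 <- g10 + (g11 - g10) * plogis(lam * (g11 - g10))
  e0 <- g00 + (g01 - g00) * plogis(lam * (g01 - g00))
  tm <- crf_terms(lambda, fg, feats)
  p1 <- tm$prob1[ep]
  obs <- ifelse(fg$labels$label[ep] == 1L, e1, e0)
  expd <- p1 * e1 + (1 - p1) * e0
  grad <- as.vector(rowsum(obs - expd, ed, reorder = TRUE))
  out <- numeric(length(fg$dp_ids))
  out[sort(unique(ed))] <- grad
  out - l1 * sign(lambda)
}

#' Train the CRF by limited-memory BFGS
#'
#' Maximizes the factorized conditional log-likelihood from
#' \eqn{\lambda = 0} with [stats::optim()]'s limited-memory BFGS
#' (`"L-BFGS-B"`, history 6, projected-gradient tolerance 1e-5, at most
#' 500 iterations).
#'
#' @param fg Training [build_factor_graph()].
#' @param variant `"with_mi"` or `"without_mi"`.
#' @param mi_scores Named MI-score vector from [mi_scores_from_table()]
#'   (required by `"with_mi"`; pairs missing or `NA` fall back to the
#'   MI-free feature).
#' @param c Feature threshold, default 0.8.
#' @param l1 Optional l1 penalty weight (default 0, no regularization).
#' @param maxit,pgtol,lmm Optimizer controls.
#' @param init Optional starting weight vector (default all zero, the
#'   uniform-prediction start).
#' @return Object of class `crf_model`: `lambda` (named over the training
#'   domain pairs), `variant`, `c`, `g11` (per trained pair, so
#'   prediction needs no MI lookup), `logLik`, `converged`, `iterations`,
#'   `message`, `n_fallback`.
#' @export
train_crf <- function(fg, variant = c("with_mi", "without_mi"),
                      mi_scores = NULL, c = 0.8, l1 = 0,
                      maxit = 500L, pgtol = 1e-5, lmm = 6L, init = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(fg, "factor_graph"))
  if (is.null(init)) init <- numeric(length(fg$dp_ids))
  stopifnot(length(init) == length(fg$dp_ids))
  feats <- crf_features(fg$dp_ids, variant, mi_scores, c)
  fn <- function(par) {
    v <- -crf_log_likelihood(par, fg, feats, l1)
    if (!is.finite(v))
      stop("non-finite objective at lambda = [",
           paste(signif(par[seq_len(min(5L, length(par)))], 4),
                 collapse = ", "), " ...]")
    v
  }
  gr <- function(par) -crf_gradient(par, fg, feats, l1)
  opt <- optim(init, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = pgtol, lmm = lmm))
  structure(
    list(lambda = stats::setNames(opt$par, fg$dp_ids),
         variant = variant, c = c,
         g11 = stats::setNames(feats$g11, fg$dp_ids),
         logLik = -opt$value,
         converged = opt$convergence == 0L,
         iterations = opt$counts[["function"]],
         message = if (is.null(opt$message)) "" else opt$message,
         n_fallback = feats$n_fallback),
    class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("crf_model (", x$variant, "): ", length(x$lambda),
      " domain-pair weights, logLik = ", sprintf("%.4f", x$logLik),
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Predict interaction probabilities with a trained CRF
#'
#' Returns `Pr(P_ij = 1 | M) = S_1 / Z_ij` for each requested protein
#' pair.  Domain pairs never seen in training contribute neutral
#' `lambda = 0` factors (a weight of zero makes both latent states
#' equally likely regardless of the feature, so no MI score is needed for
#' them).
#'
#' @param object A [train_crf()] model.
#' @param proteins Named composition list from [load_dataset()].
#' @param pairs Data frame with columns `protein_a`, `protein_b`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.crf_model <- function(object, proteins, pairs, ...) {
  vapply(seq_len(nrow(pairs)), function(k) {
    dps <- domain_pairs_of(proteins, pairs$protein_a[k], pairs$protein_b[k])
    lam <- object$lambda[dps]
    g11 <- object$g11[dps]
    lam[is.na(lam)] <- 0
    g11[is.na(g11)] <- 1  # irrelevant at lambda = 0, but keep finite
    pair_log_terms(unname(lam), g11 = unname(g11))$prob
  }, numeric(1L))
}
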