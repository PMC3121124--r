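# Baseline predictors built on the noisy-OR generative model of domain-
# driven interaction:  D_mn ~ Bernoulli(lambda_mn) independently, and
# proteins interact iff at least one contained domain pair interacts:
#   Pr(P_ij = 1) = 1 - prod_{mn in ij} (1 - lambda_mn).

#' Association method
#'
#' Estimates the probability that domain pair (m, n) interacts as the
#' fraction of interacting protein pairs among all labeled protein pairs
#' containing it, `lambda_mn = I_mn / N_mn`.
#'
#' @param fg A [build_factor_graph()] result.
#' @return Object of class `ddi_model` with `lambda` (named probabilities
#'   over `fg$dp_ids`), `method = "association"`.
#' @export
association <- function(fg) {
  stopifnot(inherits(fg, "factor_graph"))
  structure(list(lambda = stats::setNames(fg$I / fg$N, fg$dp_ids),
                 method = "association"),
            class = "ddi_model")
}

#' Association probabilistic method (APM) for weighted interaction data
#'
#' `lambda_mn = sum of interaction strengths rho_ij over protein pairs
#' containing (m, n), divided by N_mn`.  With binary strengths
#' (`rho in {0, 1}`) the numerator reduces to `I_mn`, so the APM is
#' exactly the association method on binary data.
#'
#' @param fg A [build_factor_graph()] result.
#' @param rho Numeric vector of interaction strengths in `[0, 1]`, one
#'   per labeled pair of `fg`; defaults to the binary labels.
#' @return A `ddi_model` with `method = "apm"`.
#' @export
apm <- function(fg, rho = fg$labels$label) {
  stopifnot(inherits(fg, "factor_graph"), length(rho) == nrow(fg$labels),
            all(rho >= 0 & rho <= 1))
  num <- as.vector(rowsum(rho[fg$edge_pair], fg$edge_dp, reorder = TRUE))
  lam <- numeric(length(fg$dp_ids))
  lam[sort(unique(fg$edge_dp))] <- num
  structure(list(lambda = stats::setNames(lam / fg$N, fg$dp_ids),
                 method = "apm"),
            class = "ddi_model")
}

# Observed-data log-likelihood of the noisy-OR observation model.
deng_loglik <- function(lambda, fg, fn, fp) {
  one_minus <- 1 - lambda[fg$edge_dp]
  h <- 1 - exp(as.vector(rowsum(log(pmax(one_minus, 1e-300)),
                                fg$edge_pair, reorder = TRUE)))
  o <- fg$labels$label
  pr_o <- ifelse(o == 1L, (1 - fn) * h + fp * (1 - h),
                 fn * h + (1 - fp) * (1 - h))
  sum(log(pmax(pr_o, 1e-300)))
}

#' Expectation-maximization estimate of domain interaction probabilities
#'
#' Maximum-likelihood estimation under the noisy-OR model with a
#' false-negative observation rate `fn` (an interacting protein pair is
#' observed as non-interacting with probability `fn`; default 0.8) and a
#' false-positive rate `fp`.  Each iteration sets
#' \deqn{\lambda_{mn}^{(t+1)} = \frac{1}{N_{mn}} \sum_{ij \ni mn}
#'   \Pr(D_{mn} = 1 \mid O_{ij} = o_{ij}, \lambda^{(t)}),}
#' the per-pair posterior marginalizing the other domain pairs of the
#' same protein pair through the product form of the noisy-OR.  The
#' association estimate is the initial value.
#'
#' @param fg A [build_factor_graph()] result; observed labels are taken
#'   from it.
#' @param fn False-negative rate in `[0, 1)`, default 0.8.
#' @param fp False-positive rate in `[0, 1)`, default 1e-4 (a strictly
#'   zero `fp` makes an observed interaction with all-zero lambdas
#'   impossible; the small default avoids the degeneracy).
#' @param max_iter Maximum EM iterations, default 200.
#' @param tol Stop when the largest absolute lambda change falls below
#'   this, default 1e-6.
#' @param lambda_init Optional initial probabilities (defaults to the
#'   association solution).
#' @return A `ddi_model` with `lambda`, `method = "em"`, `fn`, `fp`,
#'   `iterations`, `converged` and the observed-data `logLik` trace.
#' @export
em_train <- function(fg, fn = 0.8, fp = 1e-4, max_iter = 200L, tol = 1e-6,
                     lambda_init = NULL) {
  stopifnot(inherits(fg, "factor_graph"),
            fn >= 0, fn < 1, fp >= 0, fp < 1)
  lambda <- if (is.null(lambda_init)) association(fg)$lambda
            else stats::setNames(as.numeric(lambda_init), fg$dp_ids)
  if (any(lambda < 0 | lambda > 1)) {
    warning("initial lambda outside [0,1]; clamping")
    lambda <- pmin(pmax(lambda, 1e-12), 1 - 1e-12)
  }
  o <- fg$labels$label
  ll_trace <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    one_minus <- 1 - lambda[fg$edge_dp]
    h <- 1 - exp(as.vector(rowsum(log(pmax(one_minus, 1e-300)),
                                  fg$edge_pair, reorder = TRUE)))
    pr_o <- ifelse(o == 1L, (1 - fn) * h + fp * (1 - h),
                   fn * h + (1 - fp) * (1 - h))
    # Pr(O = o | D_mn = 1): D_mn = 1 forces P_ij = 1
    po_d1 <- ifelse(o == 1L, 1 - fn, fn)
    post <- lambda[fg$edge_dp] * po_d1[fg$edge_pair] /
      pmax(pr_o[fg$edge_pair], 1e-300)
    new_lambda <- as.vector(rowsum(post, fg$edge_dp, reorder = TRUE)) / fg$N
    if (any(new_lambda < -1e-12 | new_lambda > 1 + 1e-12))
      warning("EM lambda escaped [0,1]; clamping")
    new_lambda <- pmin(pmax(new_lambda, 0), 1)
    delta <- max(abs(new_lambda - lambda))
    lambda <- stats::setNames(new_lambda, fg$dp_ids)
    ll_trace <- c(ll_trace, deng_loglik(lambda, fg, fn, fp))
    iterations <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(lambda = lambda, method = "em", fn = fn, fp = fp,
                 iterations = iterations, converged = converged,
                 logLik = ll_trace),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("ddi_model (", x$method, "): ", length(x$lambda),
      " domain-pair probabilities", sep = "")
  if (x$method == "em")
    cat(sprintf(", fn = %.3g, fp = %.3g, %d iteration(s)%s",
                x$fn, x$fp, x$iterations,
                if (x$converged) "" else " (not converged)"))
  cat("\n")
  invisible(x)
}

#' Predict interaction probabilities under the noisy-OR model
#'
#' `Pr(P_ij = 1) = 1 - prod_{mn in ij} (1 - lambda_mn)`; domain pairs
#' without an estimate contribute `lambda = 0`.
#'
#' @param object A `ddi_model` (from [association()], [apm()] or
#'   [em_train()]).
#' @param proteins Named composition list from [load_dataset()].
#' @param pairs Data frame with columns `protein_a`, `protein_b`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ddi_model <- function(object, proteins, pairs, ...) {
  vapply(seq_len(nrow(pairs)), function(k) {
    dps <- domain_pairs_of(proteins, pairs$protein_a[k], pairs$protein_b[k])
    lam <- object$lambda[dps]
    lam[is.na(lam)] <- 0
    1 - prod(1 - lam)
  }, numeric(1L))
}
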