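#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney rank statistic with midrank tie handling
#' (equivalently: ties count one half), and the ROC curve by a threshold
#' sweep over the distinct scores.
#'
#' @param scores Numeric prediction scores (higher = more likely
#'   positive).
#' @param labels Binary labels (0/1), same length; both classes must be
#'   present.
#' @return List with `auc` and `curve`, a data frame of
#'   `threshold`, `fpr`, `tpr` (the sweep starts at (0, 0) with an
#'   infinite threshold and ends at (1, 1)).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(l == 1)[last_of_tie]
  fp <- cumsum(l == 0)[last_of_tie]
  curve <- data.frame(threshold = c(Inf, s[last_of_tie]),
                      fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, curve = curve)
}

#' Sample non-interacting protein pairs as negatives
#'
#' Draws unordered protein pairs uniformly at random, without
#' replacement, from the complement of the positive set over the loaded
#' proteins, as many negatives as positives (unless `n` is given).
#'
#' @param proteins Named composition list from [load_dataset()].
#' @param positives Data frame with columns `protein_a`, `protein_b`
#'   naming the known interacting pairs.
#' @param n Number of negatives; defaults to `nrow(positives)`.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param include_self Whether protein self-pairs are part of the
#'   candidate universe (default `FALSE`).
#' @return Data frame `protein_a`, `protein_b`, `label` (all 0).
#' @export
sample_negatives <- function(proteins, positives, n = NULL, seed = 1L,
                             include_self = FALSE) {
  ids <- sort(names(proteins))
  if (is.null(n)) n <- nrow(positives)
  grid <- which(upper.tri(matrix(0, length(ids), length(ids)),
                          diag = include_self),
                arr.ind = TRUE)
  a <- ids[grid[, "row"]]
  b <- ids[grid[, "col"]]
  pos_key <- paste(pmin(positives$protein_a, positives$protein_b),
                   pmax(positives$protein_a, positives$protein_b),
                   sep = "\r")
  keep <- !(paste(a, b, sep = "\r") %in% pos_key)
  a <- a[keep]; b <- b[keep]
  if (length(a) < n)
    stop("cannot sample ", n, " negatives: only ", length(a),
         " non-positive pairs exist")
  pick <- with_rng_seed(seed, sample.int(length(a), n))
  data.frame(protein_a = a[pick], protein_b = b[pick], label = 0L,
             stringsAsFactors = FALSE)
}

fit_method <- function(method, fg, mi_scores, c, fn, fp, crf_control) {
  switch(method,
    crf_mi = do.call(train_crf, c(list(fg, variant = "with_mi",
                                       mi_scores = mi_scores, c = c),
                                  crf_control)),
    crf_nomi = do.call(train_crf, c(list(fg, variant = "without_mi"),
                                    crf_control)),
    em = em_train(fg, fn = fn, fp = fp),
    assoc = association(fg),
    stop("unknown method: ", method))
}

#' Five-fold cross-validated evaluation of the predictors
#'
#' Splits the labeled protein pairs into `folds` stratified random folds,
#' trains each requested method on the training folds, and scores both
#' the training pairs and the held-out pairs.  Following the evaluation
#' protocol of the method, only test pairs containing at least one domain
#' pair with a parameter estimated from that fold's training data are
#' scored; the remainder are excluded from the test AUC.
#'
#' @param proteins Named composition list from [load_dataset()].
#' @param labels Data frame `protein_a`, `protein_b`, `label`.
#' @param mi_scores Named MI-score vector (needed when `"crf_mi"` is
#'   among the methods).
#' @param methods Any of `"crf_mi"`, `"crf_nomi"`, `"em"`, `"assoc"`.
#' @param folds Number of folds, default 5.
#' @param seed Integer seed governing the fold assignment.
#' @param c CRF feature threshold, default 0.8.
#' @param fn,fp EM observation-noise rates.
#' @param crf_control Extra arguments passed to [train_crf()].
#' @return Object of class `evaluation_run`: `fold` (per-pair fold
#'   index), `results` (data frame `fold`, `method`, `train_auc`,
#'   `test_auc`, `n_test_used`), `summary` (per-method means over the
#'   folds with defined AUC), `roc` (per-method ROC curve pooled over the
#'   held-out scores of all folds), `seed`.  A fold whose filtered test
#'   set contains a single class gets `NA` AUC and is dropped from the
#'   mean with a warning.
#' @export
cross_validate <- function(proteins, labels, mi_scores = NULL,
                           methods = c("crf_mi", "crf_nomi", "em", "assoc"),
                           folds = 5L, seed = 1L, c = 0.8,
                           fn = 0.8, fp = 1e-4, crf_control = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- nrow(labels)
  if (n < folds) stop("need at least ", folds, " labeled pairs")
  fold <- integer(n)
  with_rng_seed(derive_seed(seed, "folds"), {
    for (cls in unique(labels$label)) {
      idx <- which(labels$label == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  results <- list()
  pooled <- lapply(methods, function(m) list(scores = numeric(0),
                                             labels = integer(0)))
  names(pooled) <- methods
  for (f in seq_len(folds)) {
    train <- labels[fold != f, , drop = FALSE]
    test <- labels[fold == f, , drop = FALSE]
    fg <- build_factor_graph(proteins, train)
    trained_dps <- fg$dp_ids
    has_param <- vapply(seq_len(nrow(test)), function(k) {
      any(domain_pairs_of(proteins, test$protein_a[k], test$protein_b[k])
          %in% trained_dps)
    }, logical(1L))
    test_used <- test[has_param, , drop = FALSE]
    for (m in methods) {
      model <- fit_method(m, fg, mi_scores, c, fn, fp, crf_control)
      train_scores <- predict(model, proteins, train)
      train_auc <- roc_auc(train_scores, train$label)$auc
      test_auc <- NA_real_
      if (nrow(test_used) > 0L) {
        test_scores <- predict(model, proteins, test_used)
        if (length(unique(test_used$label)) == 2L)
          test_auc <- roc_auc(test_scores, test_used$label)$auc
        else
          warning("fold ", f, ", method ", m,
                  ": filtered test set is single-class; AUC undefined")
        pooled[[m]]$scores <- c(pooled[[m]]$scores, test_scores)
        pooled[[m]]$labels <- c(pooled[[m]]$labels, test_used$label)
      } else {
        warning("fold ", f, ": no test pair passes the trained-parameter",
                " filter")
      }
      results[[length(results) + 1L]] <-
        data.frame(fold = f, method = m, train_auc = train_auc,
                   test_auc = test_auc, n_test_used = nrow(test_used),
                   stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, results)
  summary <- do.call(rbind, lapply(methods, function(m) {
    r <- results[results$method == m, ]
    data.frame(method = m,
               train_auc = mean(r$train_auc, na.rm = TRUE),
               test_auc = mean(r$test_auc, na.rm = TRUE),
               n_folds_defined = sum(!is.na(r$test_auc)),
               stringsAsFactors = FALSE)
  }))
  roc <- lapply(pooled, function(p) {
    if (length(unique(p$labels)) == 2L) roc_auc(p$scores, p$labels)$curve
    else NULL
  })
  structure(list(fold = fold, results = results, summary = summary,
                 roc = roc, seed = seed),
            class = "evaluation_run")
}

#' @export
print.evaluation_run <- function(x, ...) {
  cat("evaluation_run (seed ", x$seed, "): ",
      max(x$results$fold), "-fold cross-validation\n\n", sep = "")
  wide <- stats::reshape(x$results[, c("fold", "method", "train_auc",
                                       "test_auc")],
                         direction = "wide", idvar = "fold",
                         timevar = "method")
  print(wide, row.names = FALSE, digits = 6)
  cat("\naverages:\n")
  print(x$summary, row.names = FALSE, digits = 6)
  invisible(x)
}
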