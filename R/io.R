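# Plain-text model and score files: a JSON header in '#'-prefixed lines
# followed by a TSV body, so the files are both machine- and eye-readable.

#' Write and read domain-pair MI score tables
#'
#' TSV with columns `domain_a`, `domain_b`, `m_mn`, `n_positions_used`,
#' `M`, `seed`.
#'
#' @param mi_table Data frame from [domain_mi_table()].
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_mi_table <- function(mi_table, path) {
  write.table(mi_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mi_table
#' @export
read_mi_table <- function(path) {
  if (!file.exists(path)) stop("MI table not found: ", path)
  read.delim(path, header = TRUE, sep = "\t",
             colClasses = c("character", "character", "numeric",
                            "integer", "integer", "numeric"))
}

#' Write a trained model (CRF or baseline) to a text file
#'
#' A JSON header block (lines starting `#`) records the method and its
#' settings; the body is a TSV of `domain_a`, `domain_b`, `lambda`.
#'
#' @param model A `crf_model` or `ddi_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "crf_model")) {
    header <- list(type = "crf", variant = model$variant, c = model$c,
                   logLik = model$logLik, converged = model$converged,
                   iterations = model$iterations,
                   n_fallback = model$n_fallback)
    extra <- data.frame(g11 = unname(model$g11))
  } else if (inherits(model, "ddi_model")) {
    header <- list(type = "ddi", method = model$method)
    if (model$method == "em")
      header <- c(header, list(fn = model$fn, fp = model$fp,
                               iterations = model$iterations,
                               converged = model$converged))
    extra <- NULL
  } else stop("not a model object")
  dp <- dp_split(names(model$lambda))
  body <- cbind(dp, data.frame(lambda = unname(model$lambda)))
  if (!is.null(extra)) body <- cbind(body, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(header, auto_unbox = TRUE,
                                          digits = NA)), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path File path.
#' @return A `crf_model` or `ddi_model` (prediction-ready; training
#'   diagnostics restored from the header).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  header <- jsonlite::fromJSON(sub("^#", "", lines[hdr_lines[1L]]))
  body <- read.delim(text = lines[-hdr_lines], header = TRUE, sep = "\t",
                     colClasses = "character")
  lambda <- stats::setNames(as.numeric(body$lambda),
                            dp_id(body$domain_a, body$domain_b))
  if (identical(header$type, "crf")) {
    structure(list(lambda = lambda, variant = header$variant,
                   c = header$c,
                   g11 = stats::setNames(as.numeric(body$g11),
                                         names(lambda)),
                   logLik = header$logLik, converged = header$converged,
                   iterations = header$iterations, message = "",
                   n_fallback = header$n_fallback),
              class = "crf_model")
  } else {
    out <- list(lambda = lambda, method = header$method)
    if (identical(header$method, "em"))
      out <- c(out, list(fn = header$fn, fp = header$fp,
                         iterations = header$iterations,
                         converged = header$converged))
    structure(out, class = "ddi_model")
  }
}

#' Write an evaluation run as a cross-validation summary table
#'
#' One TSV shaped like the per-fold AUC tables (rows: folds then the
#' average; columns: method x train/test), plus one ROC-point TSV per
#' method if `roc_prefix` is given.
#'
#' @param run An [cross_validate()] result.
#' @param path Summary TSV path.
#' @param roc_prefix Optional path prefix for `<prefix>_<method>_roc.tsv`
#'   files.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(run, path, roc_prefix = NULL) {
  methods <- unique(run$results$method)
  folds <- sort(unique(run$results$fold))
  out <- data.frame(fold = c(as.character(folds), "average"))
  for (m in methods) {
    r <- run$results[run$results$method == m, ]
    r <- r[order(r$fold), ]
    s <- run$summary[run$summary$method == m, ]
    out[[paste0(m, "_train")]] <- c(r$train_auc, s$train_auc)
    out[[paste0(m, "_test")]] <- c(r$test_auc, s$test_auc)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc_prefix)) {
    for (m in methods) {
      if (!is.null(run$roc[[m]]))
        write.table(run$roc[[m]],
                    paste0(roc_prefix, "_", m, "_roc.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
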