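#' Canonical unordered domain-pair identifier
#'
#' @param m,n Character vectors of domain ids (recycled).
#' @return Character vector `"min|max"`; the same pair in either order
#'   yields the same id.
#' @export
#' @examples
#' dp_id("D2", "D1")  # "D1|D2"
dp_id <- function(m, n) paste(pmin(m, n), pmax(m, n), sep = "|")

#' Split canonical domain-pair ids back into two columns
#' @param ids Character vector of ids from [dp_id()].
#' @return Data frame with columns `domain_a`, `domain_b`.
#' @export
dp_split <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(domain_a = vapply(parts, `[`, character(1L), 1L),
             domain_b = vapply(parts, `[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}

#' Load protein domain compositions and labeled interactions
#'
#' Reads the two tab-separated inputs of the predictor: a composition
#' table (`protein_id <TAB> domains`, the second column a comma-separated
#' list of domain ids) and an interaction table
#' (`protein_a <TAB> protein_b <TAB> label` with binary labels).  Both
#' files carry a header row.  Proteins without any domain are removed
#' (with a message) and labels touching them are dropped alongside;
#' labels on unordered pairs are deduplicated; contradictory duplicates
#' or labels naming proteins absent from the composition table are
#' errors.
#'
#' @param compositions Path to the composition TSV.
#' @param interactions Path to the interaction TSV.
#' @return List with `proteins` (named list: protein id -> character
#'   vector of domain ids, possibly with repeats) and `labels` (data
#'   frame `protein_a`, `protein_b`, `label` with `protein_a <=
#'   protein_b`).
#' @export
load_dataset <- function(compositions, interactions) {
  proteins <- load_compositions(compositions)
  labels <- load_interactions(interactions, proteins,
                              dropped = attr(proteins, "dropped"))
  list(proteins = proteins, labels = labels)
}

#' @rdname load_dataset
#' @export
load_compositions <- function(compositions) {
  if (!file.exists(compositions))
    stop("composition file not found: ", compositions)
  df <- read.delim(compositions, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (ncol(df) < 2L) stop("composition table needs 2 columns, got ", ncol(df))
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate protein ids in composition table")
  doms <- strsplit(df[[2L]], ",", fixed = TRUE)
  doms <- lapply(doms, function(d) d[nzchar(trimws(d))])
  empty <- lengths(doms) == 0L
  if (any(empty))
    message("dropped ", sum(empty), " protein(s) without any domain")
  out <- stats::setNames(lapply(doms[!empty], trimws), ids[!empty])
  attr(out, "dropped") <- ids[empty]
  out
}

#' @rdname load_dataset
#' @param proteins Composition list as returned by `load_compositions()`.
#' @param dropped Protein ids removed for having no domain; labels
#'   touching them are silently restricted away (with a message).
#' @export
load_interactions <- function(interactions, proteins, dropped = character(0)) {
  if (!file.exists(interactions))
    stop("interaction file not found: ", interactions)
  df <- read.delim(interactions, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer"))
  if (ncol(df) < 3L) stop("interaction table needs 3 columns, got ", ncol(df))
  names(df)[1:3] <- c("protein_a", "protein_b", "label")
  unknown <- setdiff(c(df$protein_a, df$protein_b),
                     c(names(proteins), dropped))
  if (length(unknown) > 0L)
    stop("interaction table names unknown protein(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  touches_dropped <- df$protein_a %in% dropped | df$protein_b %in% dropped
  if (any(touches_dropped)) {
    message("dropped ", sum(touches_dropped),
            " labeled pair(s) involving domainless protein(s)")
    df <- df[!touches_dropped, , drop = FALSE]
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(df$label, key, function(x) length(unique(x)))
  if (any(agg > 1L))
    stop("contradictory labels for pair(s): ",
         paste(head(gsub("\r", " - ", names(agg)[agg > 1L]), 5L),
               collapse = ", "))
  keep <- !duplicated(key)
  data.frame(protein_a = a[keep], protein_b = b[keep],
             label = df$label[keep], stringsAsFactors = FALSE)
}

#' Domain pairs contained in a protein pair
#'
#' The set of unordered domain-type pairs `{(m, n)}` with `m` a domain of
#' the first protein and `n` a domain of the second (orientation
#' collapsed).  Repeated domains within a protein do not multiply pairs:
#' the model has one latent interaction variable per domain-type pair.
#' A protein paired with itself yields its self domain pairs.
#'
#' @param proteins Named list from [load_dataset()].
#' @param pi,pj Protein ids.
#' @return Character vector of canonical domain-pair ids (see [dp_id()]),
#'   sorted.
#' @export
#' @examples
#' prot <- list(Pi = c("D1", "D2"), Pj = "D3")
#' domain_pairs_of(prot, "Pi", "Pj")  # "D1|D3" "D2|D3"
domain_pairs_of <- function(proteins, pi, pj) {
  di <- unique(proteins[[pi]])
  dj <- unique(proteins[[pj]])
  if (is.null(di) || is.null(dj))
    stop("unknown protein: ", if (is.null(di)) pi else pj)
  sort(unique(dp_id(rep(di, times = length(dj)),
                    rep(dj, each = length(di)))))
}

#' Build the bipartite protein-pair / domain-pair factor graph
#'
#' Each labeled protein pair is a vertex on one side; each domain pair
#' occurring in at least one labeled protein pair is a vertex on the
#' other.  An edge joins them iff the protein pair contains the domain
#' pair.  `N_mn` counts the labeled protein pairs containing domain pair
#' (m, n), `I_mn` those with label 1.
#'
#' @param proteins Named list from [load_dataset()].
#' @param labels Data frame `protein_a`, `protein_b`, `label`.
#' @return Object of class `factor_graph`: `labels`, `dp_ids` (sorted),
#'   `pair_dp` (list: per labeled pair, integer indices into `dp_ids`),
#'   `dp_pairs` (list: per domain pair, integer indices of the labeled
#'   pairs containing it), `edge_pair`, `edge_dp` (flattened edge list),
#'   `N`, `I`.
#' @export
build_factor_graph <- function(proteins, labels) {
  if (nrow(labels) == 0L) stop("no labeled protein pairs")
  dps <- mapply(domain_pairs_of, labels$protein_a, labels$protein_b,
                MoreArgs = list(proteins = proteins), SIMPLIFY = FALSE)
  dp_ids <- sort(unique(unlist(dps, use.names = FALSE)))
  pair_dp <- lapply(dps, function(d) match(d, dp_ids))
  edge_pair <- rep(seq_len(nrow(labels)), lengths(pair_dp))
  edge_dp <- unlist(pair_dp, use.names = FALSE)
  N <- tabulate(edge_dp, nbins = length(dp_ids))
  I <- tabulate(edge_dp[labels$label[edge_pair] == 1L],
                nbins = length(dp_ids))
  structure(
    list(labels = labels, dp_ids = dp_ids, pair_dp = pair_dp,
         dp_pairs = unname(split(edge_pair, factor(edge_dp,
                                                   levels = seq_along(dp_ids)))),
         edge_pair = edge_pair, edge_dp = edge_dp, N = N, I = I),
    class = "factor_graph")
}

#' @export
print.factor_graph <- function(x, ...) {
  cat("factor_graph: ", nrow(x$labels), " labeled protein pairs (",
      sum(x$labels$label), " positive), ", length(x$dp_ids),
      " domain pairs, ", length(x$edge_dp), " edges\n", sep = "")
  invisible(x)
}
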