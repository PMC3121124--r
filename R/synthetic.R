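# Seeded generator for desk-scale inputs with the statistical structure
# the predictor assumes: proteins composed of domains, interaction labels
# drawn from the noisy-OR domain model, and multi-organism domain
# alignments in which designated domain pairs carry one coevolving column
# pair of analytically known mutual information.

#' Configuration of the synthetic benchmark generator
#'
#' All sizes and rates in one validated object.  Designated "truly
#' interacting" domain pairs are drawn among pairs occurring in at least
#' `min_pair_occurrence` protein pairs so the interaction signal is
#' represented in every training fold; each receives interaction
#' probability `lambda_true` and a coevolving alignment column pair with
#' joint mutual information `target_mi` (nats).  An optional confound set
#' receives the same coevolution but zero interaction probability, to
#' probe whether the CRF can down-weight uninformative MI.
#'
#' @param n_domains,n_proteins Numbers of domain families and proteins.
#' @param domains_per_protein Integer range `c(min, max)` of domains per
#'   protein.
#' @param n_organisms,seqs_per_organism Alignment rows: each domain gets
#'   `seqs_per_organism` sequences from each of `n_organisms` organisms.
#' @param n_cols Alignment columns per domain.
#' @param gap_rate Independent per-residue gap probability.
#' @param n_true_pairs Number of designated interacting domain pairs.
#' @param lambda_true Interaction probability of each designated pair.
#' @param target_mi Joint MI (nats) of each designated pair's coevolving
#'   column pair; must be at most `log(coevo_alphabet)`.
#' @param coevo_alphabet Number of residue types used by coevolving
#'   columns (at most 20; the gap symbol never encodes signal).
#' @param fn,fp Observation noise: a true interaction is recorded as 0
#'   with probability `fn`, a true non-interaction as 1 with probability
#'   `fp`.
#' @param n_positive,n_negative Sizes of the balanced labeled sample.
#' @param n_confound_pairs,confound_mi Optional high-MI non-interacting
#'   pairs.
#' @param min_pair_occurrence Minimum protein-pair occurrence count for a
#'   domain pair to be eligible as designated/confound.
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_domains = 60L, n_proteins = 200L,
                             domains_per_protein = c(1L, 3L),
                             n_organisms = 100L, seqs_per_organism = 1L,
                             n_cols = 20L, gap_rate = 0.05,
                             n_true_pairs = 5L, lambda_true = 0.8,
                             target_mi = 1.5, coevo_alphabet = 20L,
                             fn = 0.1, fp = 0,
                             n_positive = 150L, n_negative = 150L,
                             n_confound_pairs = 0L, confound_mi = 1.5,
                             min_pair_occurrence = 50L, seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              n_proteins = as.integer(n_proteins),
              domains_per_protein = as.integer(domains_per_protein),
              n_organisms = as.integer(n_organisms),
              seqs_per_organism = as.integer(seqs_per_organism),
              n_cols = as.integer(n_cols), gap_rate = gap_rate,
              n_true_pairs = as.integer(n_true_pairs),
              lambda_true = lambda_true, target_mi = target_mi,
              coevo_alphabet = as.integer(coevo_alphabet),
              fn = fn, fp = fp,
              n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              n_confound_pairs = as.integer(n_confound_pairs),
              confound_mi = confound_mi,
              min_pair_occurrence = as.integer(min_pair_occurrence),
              seed = as.integer(seed))
  stopifnot(cfg$n_domains >= 2L, cfg$n_proteins >= 2L,
            length(cfg$domains_per_protein) == 2L,
            cfg$domains_per_protein[1L] >= 1L,
            cfg$domains_per_protein[2L] >= cfg$domains_per_protein[1L],
            cfg$domains_per_protein[2L] <= cfg$n_domains,
            cfg$n_organisms >= 1L, cfg$seqs_per_organism >= 1L,
            cfg$n_cols >= 1L, cfg$gap_rate >= 0, cfg$gap_rate < 1,
            cfg$lambda_true >= 0, cfg$lambda_true <= 1,
            cfg$coevo_alphabet >= 2L, cfg$coevo_alphabet <= 20L,
            cfg$fn >= 0, cfg$fn < 1, cfg$fp >= 0, cfg$fp < 1)
  if (cfg$target_mi > log(cfg$coevo_alphabet) + 1e-12)
    stop("target_mi exceeds log(coevo_alphabet) = ",
         signif(log(cfg$coevo_alphabet), 4))
  if (cfg$n_confound_pairs > 0L &&
      cfg$confound_mi > log(cfg$coevo_alphabet) + 1e-12)
    stop("confound_mi exceeds log(coevo_alphabet)")
  structure(cfg, class = "synthetic_config")
}

#' Mutual information of the coevolution mixture distribution
#'
#' The joint law used for coevolving column pairs over `q` symbols:
#' with weight `1 - epsilon` a symbol is drawn uniformly and copied
#' (identity permutation coupling); with weight `epsilon` the two symbols
#' are independent uniform.  Marginals are uniform for every `epsilon`;
#' the MI interpolates from `log(q)` (`epsilon = 0`) to 0
#' (`epsilon = 1`) and has the closed form used here.
#'
#' @param epsilon Mixture weight of the independent component, in
#'   `[0, 1]`.
#' @param q Alphabet size.
#' @return MI in nats.
#' @export
mixture_mi <- function(epsilon, q) {
  stopifnot(epsilon >= 0, epsilon <= 1, q >= 2)
  p_diag <- epsilon / q^2 + (1 - epsilon) / q
  p_off <- epsilon / q^2
  mi <- q * p_diag * log(p_diag * q^2)
  if (epsilon > 0) mi <- mi + (q^2 - q) * p_off * log(p_off * q^2)
  max(mi, 0)
}

#' Solve for the mixture weight achieving a target MI
#'
#' @param target_mi Desired MI in nats, in `[0, log(q)]`.
#' @param q Alphabet size.
#' @return `epsilon` such that [mixture_mi()] equals `target_mi`.
#' @export
solve_epsilon <- function(target_mi, q) {
  stopifnot(target_mi >= 0, target_mi <= log(q) + 1e-12)
  if (target_mi <= 0) return(1)
  if (target_mi >= log(q)) return(0)
  uniroot(function(e) mixture_mi(e, q) - target_mi,
          interval = c(0, 1), tol = 1e-12)$root
}

#' Generate a domain-composition network with noisy-OR interaction labels
#'
#' Assigns each protein a uniform number of distinct domains, designates
#' the truly interacting domain pairs, and draws every protein pair's
#' label: each contained designated domain pair interacts independently
#' with probability `lambda_true`, the protein pair interacts iff at
#' least one does, and the observation is flipped with rates `(fn, fp)`.
#' A balanced labeled sample (`n_positive` + `n_negative` pairs, drawn
#' uniformly) is returned.
#'
#' @param cfg A [synthetic_config()].
#' @param keep_universe Also return, under `truth$universe`, the full
#'   protein-pair table (`protein_a`, `protein_b`, `k_true` = number of
#'   designated domain pairs contained, `p_true` = pre-noise label,
#'   `observed`); off by default.
#' @return List with `proteins` (named composition list), `labels`
#'   (balanced sample data frame), and `truth` (`true_dps`,
#'   `confound_dps`, `lambda_true`).
#' @export
generate_network <- function(cfg, keep_universe = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng_seed(derive_seed(cfg$seed, "network"), {
    dom_ids <- sprintf("DOM%03d", seq_len(cfg$n_domains))
    prot_ids <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
    sizes <- sample(seq(cfg$domains_per_protein[1L],
                        cfg$domains_per_protein[2L]),
                    cfg$n_proteins, replace = TRUE)
    proteins <- stats::setNames(
      lapply(sizes, function(s) sample(dom_ids, s)), prot_ids)

    np <- cfg$n_proteins
    grid <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    pa <- prot_ids[grid[, "row"]]
    pb <- prot_ids[grid[, "col"]]
    pair_dps <- mapply(domain_pairs_of, pa, pb,
                       MoreArgs = list(proteins = proteins),
                       SIMPLIFY = FALSE)
    occ <- table(unlist(pair_dps, use.names = FALSE))
    eligible <- names(occ)[occ >= cfg$min_pair_occurrence]
    n_pick <- cfg$n_true_pairs + cfg$n_confound_pairs
    if (length(eligible) < n_pick)
      stop("only ", length(eligible), " domain pairs occur in >= ",
           cfg$min_pair_occurrence, " protein pairs; cannot designate ",
           n_pick)
    picked <- sample(eligible, n_pick)
    true_dps <- picked[seq_len(cfg$n_true_pairs)]
    confound_dps <- setdiff(picked, true_dps)

    k_true <- vapply(pair_dps, function(d) sum(d %in% true_dps),
                     integer(1L))
    p_true <- runif(length(k_true)) < 1 - (1 - cfg$lambda_true)^k_true
    flip <- runif(length(p_true))
    observed <- ifelse(p_true, flip >= cfg$fn, flip < cfg$fp)

    pos <- which(observed)
    neg <- which(!observed)
    if (length(pos) < cfg$n_positive)
      stop("only ", length(pos), " observed interacting pairs; cannot ",
           "sample ", cfg$n_positive, " positives")
    if (length(neg) < cfg$n_negative)
      stop("only ", length(neg), " observed non-interacting pairs")
    take_pos <- sample(pos, cfg$n_positive)
    take_neg <- sample(neg, cfg$n_negative)
    take <- c(take_pos, take_neg)
    labels <- data.frame(protein_a = pa[take], protein_b = pb[take],
                         label = rep(c(1L, 0L), c(cfg$n_positive,
                                                  cfg$n_negative)),
                         stringsAsFactors = FALSE)
    truth <- list(true_dps = true_dps, confound_dps = confound_dps,
                  lambda_true = cfg$lambda_true)
    if (keep_universe)
      truth$universe <- data.frame(protein_a = pa, protein_b = pb,
                                   k_true = k_true, p_true = p_true,
                                   observed = observed,
                                   stringsAsFactors = FALSE)
    list(proteins = proteins, labels = labels, truth = truth)
  })
}

#' Generate multi-organism domain alignments with injected coevolution
#'
#' Every domain gets `n_organisms * seqs_per_organism` rows; row k of
#' every domain belongs to the same organism, so organism-based pairing
#' recovers the generative coupling.  Each designated (and confound)
#' domain pair coevolves at exactly one column pair, drawn from the
#' [mixture_mi()] law with `epsilon` solved to hit the configured target
#' MI; all other columns are independent draws from per-column
#' Dirichlet(0.5) residue profiles.  Gaps are then inserted independently
#' at `gap_rate`.  Sequence names end in `_ORGxx`, matching the default
#' organism parsing.
#'
#' @param cfg A [synthetic_config()].
#' @param truth The `truth` element of [generate_network()] (designated
#'   and confound domain pairs).  Pass `truth = NULL` for alignments with
#'   no coevolving pair.
#' @return Named list of [domain_alignment()] objects, one per domain.
#' @export
generate_alignments <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dom_ids <- sprintf("DOM%03d", seq_len(cfg$n_domains))
  coevo <- character(0)
  if (!is.null(truth))
    coevo <- c(truth$true_dps, truth$confound_dps)
  mi_targets <- c(rep(cfg$target_mi, length(truth$true_dps)),
                  rep(cfg$confound_mi, length(truth$confound_dps)))
  q <- cfg$coevo_alphabet
  n_rows <- cfg$n_organisms * cfg$seqs_per_organism
  orgs <- rep(sprintf("ORG%02d", seq_len(cfg$n_organisms)),
              each = cfg$seqs_per_organism)
  reps <- rep(seq_len(cfg$seqs_per_organism), cfg$n_organisms)

  with_rng_seed(derive_seed(cfg$seed, "alignments"), {
    mats <- lapply(dom_ids, function(d)
      matrix(0L, nrow = n_rows, ncol = cfg$n_cols))
    names(mats) <- dom_ids
    next_col <- stats::setNames(rep(1L, length(dom_ids)), dom_ids)

    # coevolving column pairs first, claiming columns from the front
    for (k in seq_along(coevo)) {
      pair <- dp_split(coevo[k])
      m <- pair$domain_a; n <- pair$domain_b
      col_m <- next_col[[m]]; next_col[[m]] <- col_m + 1L
      col_n <- next_col[[n]]; next_col[[n]] <- col_n + 1L
      if (col_m > cfg$n_cols || col_n > cfg$n_cols)
        stop("domain ", if (col_m > cfg$n_cols) m else n,
             " has no free column left for coevolution; increase n_cols")
      eps <- solve_epsilon(mi_targets[k], q)
      a <- sample.int(q, n_rows, replace = TRUE)
      b <- ifelse(runif(n_rows) < eps,
                  sample.int(q, n_rows, replace = TRUE), a)
      mats[[m]][, col_m] <- a
      mats[[n]][, col_n] <- b
    }

    # independent background columns from Dirichlet(0.5) profiles
    for (d in dom_ids) {
      if (next_col[[d]] > cfg$n_cols) next
      for (col in seq(next_col[[d]], cfg$n_cols)) {
        w <- rgamma(20L, shape = 0.5)
        prof <- w / sum(w)
        mats[[d]][, col] <- sample.int(20L, n_rows, replace = TRUE,
                                       prob = prof)
      }
    }

    # gaps
    if (cfg$gap_rate > 0) {
      for (d in dom_ids) {
        g <- runif(length(mats[[d]])) < cfg$gap_rate
        mats[[d]][g] <- aa_gap_index()
      }
    }

    alns <- lapply(dom_ids, function(d) {
      ids <- sprintf("%s_r%02d_%s", d, reps, orgs)
      seqs <- stats::setNames(decode_residues(mats[[d]]), ids)
      domain_alignment(d, seqs, organisms = orgs)
    })
    stats::setNames(alns, dom_ids)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: [generate_network()] plus [generate_alignments()].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `proteins`, `labels`, `truth`, `alignments`, `cfg`.
#' @export
generate_dataset <- function(cfg) {
  net <- generate_network(cfg)
  alns <- generate_alignments(cfg, net$truth)
  c(net, list(alignments = alns, cfg = cfg))
}

#' Write a synthetic benchmark to disk in the formats the loaders read
#'
#' Stockholm alignments (one per domain), a composition TSV, an
#' interaction TSV, and a JSON sidecar recording the configuration and
#' the designated domain pairs.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (al in ds$alignments)
    write_stockholm(al, file.path(dir, paste0(al$domain_id, ".sto")))
  comp <- data.frame(
    protein_id = names(ds$proteins),
    domains = vapply(ds$proteins, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  write.table(comp, file.path(dir, "compositions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$labels, file.path(dir, "interactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(ds$cfg), truth = ds$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
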