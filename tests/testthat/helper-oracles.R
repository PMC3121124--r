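# Independent oracles used across the suite.  Each deliberately
# re-derives its quantity by the most transparent route available
# (enumeration, brute-force summation, finite differences), sharing no
# code with the implementation it checks.

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force MI: explicit double loop over all 441 cells
brute_mi <- function(f_i, f_j, f_ij) {
  total <- 0
  for (a in seq_len(21)) {
    for (b in seq_len(21)) {
      if (f_ij[a, b] > 0)
        total <- total + f_ij[a, b] * log(f_ij[a, b] / (f_i[a] * f_j[b]))
    }
  }
  total
}

# brute-force CRF: enumerate all 2^(K+1) joint states (p, d_1..d_K)
# g(s, t) supplied as length-K vectors per (s, t) cell
enum_crf <- function(lambda, g11, g01, g10, g00) {
  K <- length(lambda)
  states <- as.matrix(expand.grid(rep(list(0:1), K)))
  weight_given_p <- function(p) {
    tot <- 0
    for (r in seq_len(nrow(states))) {
      d <- states[r, ]
      g <- if (p == 1) ifelse(d == 1, g11, g10)
           else ifelse(d == 1, g01, g00)
      tot <- tot + exp(sum(lambda * g))
    }
    tot
  }
  s1 <- weight_given_p(1)
  s0 <- weight_given_p(0)
  list(log_s1 = log(s1), log_s0 = log(s0), log_z = log(s1 + s0),
       prob = s1 / (s1 + s0))
}

# central finite-difference gradient of the CRF log-likelihood
fd_gradient <- function(lambda, fg, feats, h = 1e-6) {
  vapply(seq_along(lambda), function(k) {
    up <- lambda; up[k] <- up[k] + h
    dn <- lambda; dn[k] <- dn[k] - h
    (crf_log_likelihood(up, fg, feats) -
       crf_log_likelihood(dn, fg, feats)) / (2 * h)
  }, numeric(1L))
}

# tiny alignment builder: seqs is a character vector of aligned strings,
# organisms one tag per row
toy_alignment <- function(id, seqs, organisms) {
  names(seqs) <- sprintf("%s_s%02d_%s", id, seq_along(seqs), organisms)
  domain_alignment(id, seqs, organisms = organisms)
}

# random small labeled dataset for factor-graph/CRF/baseline property
# tests: proteins with 1..3 domains, random binary labels
random_dataset <- function(n_proteins = 12L, n_domains = 6L,
                           n_pairs = 20L, seed = 1L) {
  set.seed(seed)
  doms <- sprintf("D%02d", seq_len(n_domains))
  prots <- sprintf("P%02d", seq_len(n_proteins))
  proteins <- setNames(
    lapply(seq_len(n_proteins),
           function(i) sample(doms, sample(1:3, 1))), prots)
  grid <- t(combn(prots, 2L))
  take <- sample(nrow(grid), min(n_pairs, nrow(grid)))
  labels <- data.frame(protein_a = grid[take, 1L],
                       protein_b = grid[take, 2L],
                       label = sample(0:1, length(take), replace = TRUE),
                       stringsAsFactors = FALSE)
  # ensure both classes present
  if (length(unique(labels$label)) == 1L)
    labels$label[1L] <- 1L - labels$label[1L]
  list(proteins = proteins, labels = labels)
}

# random CRF instance on K domain pairs shared by one protein pair
random_crf_instance <- function(K, seed) {
  set.seed(seed)
  list(lambda = rnorm(K, sd = 1.5),
       g11 = runif(K, 0, 1), g01 = rep(-1, K),
       g10 = rep(0, K), g00 = rep(0, K))
}

write_tsv_tmp <- function(df, dir = tempdir(), name = "tmp.tsv") {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
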