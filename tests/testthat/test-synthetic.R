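test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(target_mi = 5, coevo_alphabet = 8),
               "target_mi")
  expect_error(synthetic_config(gap_rate = 1), "gap_rate")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("mixture coupling MI closed form inverts cleanly", {
  for (q in c(4L, 8L, 20L)) {
    expect_equal(mixture_mi(0, q), log(q))
    expect_equal(mixture_mi(1, q), 0)
    for (target in c(0.3, 0.8, 1.2)) {
      if (target > log(q)) next
      eps <- solve_epsilon(target, q)
      expect_equal(mixture_mi(eps, q), target, tolerance = 1e-9)
    }
  }
  # closed form equals brute-force MI of the explicit joint table
  q <- 6L; eps <- 0.35
  joint <- matrix(eps / q^2, q, q) + diag(q) * (1 - eps) / q
  marg <- rowSums(joint)
  expect_equal(sum(joint * log(joint / outer(marg, marg))),
               mixture_mi(eps, q), tolerance = 1e-12)
})

test_that("network labels follow the noisy-OR law of the designated pairs", {
  cfg <- synthetic_config(n_domains = 8, n_proteins = 60, n_true_pairs = 2,
                          lambda_true = 0.6, fn = 0, fp = 0,
                          n_positive = 50, n_negative = 50,
                          min_pair_occurrence = 10, seed = 31)
  net <- generate_network(cfg, keep_universe = TRUE)
  u <- net$truth$universe
  for (k in 1:2) {
    sub <- u[u$k_true == k, ]
    if (nrow(sub) < 30) next
    want <- 1 - (1 - cfg$lambda_true)^k
    se <- sqrt(want * (1 - want) / nrow(sub))
    expect_lt(abs(mean(sub$p_true) - want), 3 * se + 0.02)
  }
  # pairs without designated domain pairs never interact
  expect_true(all(!u$p_true[u$k_true == 0]))
  # without observation noise, observed == true
  expect_identical(u$observed, u$p_true)
  # the balanced sample has the requested composition
  expect_equal(sum(net$labels$label), 50L)
  expect_equal(sum(1 - net$labels$label), 50L)
})

test_that("lambda_true = 1 makes every designated-pair-carrying pair positive", {
  cfg <- synthetic_config(n_domains = 8, n_proteins = 40, n_true_pairs = 1,
                          lambda_true = 1, fn = 0, fp = 0,
                          n_positive = 10, n_negative = 10,
                          min_pair_occurrence = 10, seed = 5)
  net <- generate_network(cfg, keep_universe = TRUE)
  u <- net$truth$universe
  expect_true(all(u$p_true[u$k_true >= 1]))
  # and lambda_true = 0 yields no positives at all
  cfg0 <- synthetic_config(n_domains = 8, n_proteins = 40, n_true_pairs = 1,
                           lambda_true = 0, fn = 0, fp = 0,
                           n_positive = 5, n_negative = 5,
                           min_pair_occurrence = 10, seed = 5)
  expect_error(generate_network(cfg0), "cannot")
})

test_that("generated coevolving columns hit the target MI as depth grows", {
  err <- vapply(c(50L, 200L, 1000L), function(n_org) {
    cfg <- synthetic_config(n_domains = 4, n_proteins = 12,
                            n_organisms = n_org, n_cols = 6,
                            n_true_pairs = 1, target_mi = 1.5,
                            gap_rate = 0, n_positive = 4, n_negative = 4,
                            min_pair_occurrence = 1, seed = 23)
    net <- generate_network(cfg)
    alns <- generate_alignments(cfg, net$truth)
    td <- dp_split(net$truth$true_dps)
    pa <- pair_rows(alns[[td$domain_a]], alns[[td$domain_b]])
    # the coevolving pair occupies the first free columns: (1,1) for two
    # domains, (1,2) when the designated pair is a self pair
    j <- if (td$domain_a == td$domain_b) 2L else 1L
    f_ij <- joint_frequencies(pa, 1, j, eta = 0)
    mi <- mi_position_pair(column_frequencies(pa, "a", 1, eta = 0),
                           column_frequencies(pa, "b", j, eta = 0),
                           f_ij)
    # Miller-Madow correction for the O(1/M) plug-in bias
    k_ij <- sum(f_ij > 0)
    k_i <- sum(rowSums(f_ij) > 0)
    k_j <- sum(colSums(f_ij) > 0)
    mi_mm <- mi - (k_ij - k_i - k_j + 1) / (2 * pa$M)
    abs(mi_mm - 1.5)
  }, numeric(1))
  # residual bias of the plug-in estimator over a 400-cell support decays
  # slowly; require monotone convergence and a small terminal error
  expect_lt(err[3], 0.15)
  expect_lt(err[3], err[2])
  expect_lt(err[2], err[1])
  # perfect coupling, no gaps, deep alignment: MI approaches log(q)
  cfgp <- synthetic_config(n_domains = 4, n_proteins = 12,
                           n_organisms = 2000L, n_cols = 4,
                           n_true_pairs = 1, target_mi = log(20),
                           coevo_alphabet = 20, gap_rate = 0,
                           n_positive = 4, n_negative = 4,
                           min_pair_occurrence = 1, seed = 29)
  netp <- generate_network(cfgp)
  alnp <- generate_alignments(cfgp, netp$truth)
  tdp <- dp_split(netp$truth$true_dps)
  pap <- pair_rows(alnp[[tdp$domain_a]], alnp[[tdp$domain_b]])
  jp <- if (tdp$domain_a == tdp$domain_b) 2L else 1L
  mip <- mi_position_pair(column_frequencies(pap, "a", 1, eta = 0),
                          column_frequencies(pap, "b", jp, eta = 0),
                          joint_frequencies(pap, 1, jp, eta = 0))
  expect_equal(mip, log(20), tolerance = 0.05)
})

test_that("heavy gapping drives the MI-unavailable path", {
  cfg <- synthetic_config(n_domains = 4, n_proteins = 12, n_organisms = 30,
                          n_cols = 6, n_true_pairs = 1, gap_rate = 0.5,
                          n_positive = 4, n_negative = 4,
                          min_pair_occurrence = 1, seed = 41)
  net <- generate_network(cfg)
  alns <- generate_alignments(cfg, net$truth)
  s <- compute_domain_mi(alns[[1]], alns[[2]], seed = 1)
  expect_false(s$available)
  # and the CRF feature falls back to the MI-free value for such pairs
  feats <- domcrf:::crf_features("DOM001|DOM002", "with_mi",
                                 c("DOM001|DOM002" = NA_real_))
  expect_equal(feats$g11, 1)
  expect_equal(feats$n_fallback, 1L)
})

test_that("the generator is deterministic and writes loadable files", {
  cfg <- synthetic_config(n_domains = 6, n_proteins = 15, n_organisms = 10,
                          n_cols = 6, n_true_pairs = 1, n_positive = 4,
                          n_negative = 4, min_pair_occurrence = 4,
                          seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$alignments$DOM001$seqs, d2$alignments$DOM001$seqs)

  dir <- file.path(tempdir(), "synth_out")
  write_synthetic_dataset(d1, dir)
  ds <- load_dataset(file.path(dir, "compositions.tsv"),
                     file.path(dir, "interactions.tsv"))
  expect_equal(length(ds$proteins), length(d1$proteins))
  expect_equal(nrow(ds$labels), nrow(d1$labels))
  al <- read_alignment(file.path(dir, "DOM001.sto"))
  expect_identical(al$mat, d1$alignments$DOM001$mat)
  expect_identical(al$organisms, d1$alignments$DOM001$organisms)
})
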