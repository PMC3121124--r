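test_that("residue encoding normalizes Stockholm conventions and odd codes", {
  m <- encode_residues(c("AC-d.", "acWe-"))
  expect_identical(dim(m), c(2L, 5L))
  expect_identical(m[1, ], match(c("A", "C", "-", "D", "-"), aa_alphabet()))
  # X and U are not in the 21-letter alphabet -> gap, with a warning
  expect_warning(m2 <- encode_residues("AXU"), "non-standard")
  expect_identical(m2[1, 2:3], rep(aa_gap_index(), 2L))
  expect_error(encode_residues(c("AC", "ACD")), "differing lengths")
})

test_that("alignment reader parses the packaged Stockholm example", {
  path <- system.file("extdata", "example_DOMA.sto", package = "domcrf")
  al <- read_alignment(path)
  expect_s3_class(al, "domain_alignment")
  expect_equal(al$n_rows, 5L)
  expect_equal(al$n_cols, 8L)
  expect_setequal(unique(al$organisms),
                  c("HUMAN", "MOUSE", "YEAST", "ECOLI"))
  # '.' and lowercase normalized
  expect_equal(unname(al$mat[5, 3]), aa_gap_index())
})

test_that("Stockholm writer round-trips through the reader", {
  al <- toy_alignment("DomX", c("ACDE", "AC-E", "GHKL"),
                      c("HUMAN", "MOUSE", "YEAST"))
  path <- tempfile(fileext = ".sto")
  write_stockholm(al, path)
  back <- read_alignment(path, domain_id = "DomX")
  expect_identical(back$mat, al$mat)
  expect_identical(back$organisms, al$organisms)
})

test_that("rows pair greedily by organism in file order", {
  a <- toy_alignment("Da", c("AA", "CC", "DD"), c("X", "Y", "Z"))
  b <- toy_alignment("Db", c("EE", "FF", "GG"), c("Y", "Z", "W"))
  pa <- pair_rows(a, b)
  expect_equal(pa$M, 2L)
  expect_equal(pa$idx_a, c(2L, 3L))  # a's X row dropped
  expect_equal(pa$idx_b, c(1L, 2L))  # b's W row dropped
  expect_equal(pa$organisms, c("Y", "Z"))

  # self-pairing: every row pairs with itself
  ps <- pair_rows(a, a)
  expect_equal(ps$M, 3L)
  expect_equal(ps$idx_a, ps$idx_b)

  # 2 rows in a, 3 in b for one organism -> exactly 2 pairs, file order
  a2 <- toy_alignment("Da", c("AA", "CC"), c("X", "X"))
  b2 <- toy_alignment("Db", c("EE", "FF", "GG"), c("X", "X", "X"))
  p2 <- pair_rows(a2, b2)
  expect_equal(p2$M, 2L)
  expect_equal(p2$idx_b, c(1L, 2L))
})

test_that("column frequencies follow the count-based pseudocount", {
  a <- toy_alignment("Da", rep("A", 10), sprintf("O%d", 1:10))
  pa <- pair_rows(a, a)
  f0 <- column_frequencies(pa, "a", 1, eta = 0)
  expect_equal(unname(f0["A"]), 1)
  expect_equal(sum(f0), 1)
  f1 <- column_frequencies(pa, "a", 1, eta = 1)
  expect_equal(unname(f1["A"]), (10 + 1 / 21) / 11)
  expect_equal(unname(f1["C"]), (1 / 21) / 11)
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  expect_true(all(f1 > 0))
  # default pseudocount weight is 1
  expect_identical(formals(column_frequencies)$eta, 1)
})

test_that("joint frequencies follow the count-based pseudocount", {
  seqs_a <- c("A", "A", "C", "C")
  seqs_b <- c("A", "C", "A", "C")
  a <- toy_alignment("Da", seqs_a, sprintf("O%d", 1:4))
  b <- toy_alignment("Db", seqs_b, sprintf("O%d", 1:4))
  pa <- pair_rows(a, b)
  f0 <- joint_frequencies(pa, 1, 1, eta = 0)
  expect_equal(unname(f0["A", "A"]), 0.25)
  expect_equal(unname(f0["C", "C"]), 0.25)
  expect_equal(sum(f0), 1)
  f1 <- joint_frequencies(pa, 1, 1, eta = 1)
  expect_equal(unname(f1["A", "A"]), (1 + 1 / 441) / 5)
  expect_equal(unname(f1["D", "E"]), (1 / 441) / 5)
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  # perfectly correlated columns at eta = 0
  pc <- pair_rows(a, a)
  fpc <- joint_frequencies(pc, 1, 1, eta = 0)
  expect_equal(unname(fpc["A", "A"]), 0.5)
  expect_equal(unname(fpc["A", "C"]), 0)
})

test_that("column-pair MI matches closed forms and the brute-force sum", {
  # product-form joint -> 0
  f_i <- rep(1 / 21, 21)
  f_j <- c(rep(1 / 42, 20), 11 / 21)
  expect_equal(mi_position_pair(f_i, f_j, outer(f_i, f_j)), 0,
               tolerance = 1e-12)
  # uniform marginals with perfect (identity) coupling -> log 21
  f_diag <- diag(21) / 21
  expect_equal(mi_position_pair(f_i, f_i, f_diag), log(21),
               tolerance = 1e-12)
  # the independent 4-row toy -> 0
  f2 <- rep(0, 21); f2[1:2] <- 0.5
  j2 <- matrix(0, 21, 21); j2[1:2, 1:2] <- 0.25
  expect_equal(mi_position_pair(f2, f2, j2), 0)
  # negative frequencies rejected
  expect_error(mi_position_pair(-f_i, f_i, f_diag), "negative")
})

test_that("MI agrees with the 441-cell brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- matrix(rpois(441, 0.7), 21, 21)
    M <- sum(counts)
    if (M == 0) next
    eta <- sample(c(0.25, 0.5, 1, 2), 1)
    f_ij <- (counts + eta / 441) / (M + eta)
    f_i <- (rowSums(counts) + eta / 21) / (M + eta)
    f_j <- (colSums(counts) + eta / 21) / (M + eta)
    expect_equal(mi_position_pair(f_i, f_j, f_ij),
                 brute_mi(f_i, f_j, f_ij), tolerance = 1e-10)
  }
})

test_that("MI is within [0, log 21] and shrinks as the pseudocount grows", {
  set.seed(11)
  for (rep in 1:10) {
    counts <- matrix(rpois(441, 0.4), 21, 21)
    M <- sum(counts)
    if (M == 0) next
    mis <- vapply(c(0, 0.5 * M, 1 * M, 2 * M), function(eta) {
      f_ij <- (counts + eta / 441) / (M + eta)
      f_i <- (rowSums(counts) + eta / 21) / (M + eta)
      f_j <- (colSums(counts) + eta / 21) / (M + eta)
      mi_position_pair(f_i, f_j, f_ij)
    }, numeric(1))
    expect_true(all(mis >= 0 & mis <= log(21) + 1e-12))
    expect_true(all(diff(mis) <= 1e-10))
  }
})

test_that("shuffling a constant column is a no-op: corrected MI is zero", {
  a <- toy_alignment("Da", c("AC", "CA", "AA", "CC", "AC"),
                     sprintf("O%d", 1:5))
  b <- toy_alignment("Db", rep("EE", 5), sprintf("O%d", 1:5))
  pa <- pair_rows(a, b)
  f_i <- column_frequencies(pa, "a", 1)
  f_j <- column_frequencies(pa, "b", 1)
  raw <- mi_position_pair(f_i, f_j, joint_frequencies(pa, 1, 1))
  null <- shuffle_null(pa, 1, 1, n_shuffles = 10, seed = 1)
  expect_equal(null, raw, tolerance = 1e-12)
})

test_that("Monte-Carlo shuffle null converges to the permutation average", {
  a <- toy_alignment("Da", c("A", "C", "D"), c("O1", "O2", "O3"))
  b <- toy_alignment("Db", c("E", "F", "E"), c("O1", "O2", "O3"))
  pa <- pair_rows(a, b)
  f_i <- column_frequencies(pa, "a", 1)
  f_j <- column_frequencies(pa, "b", 1)
  # exact average over all 3! = 6 permutations
  per_perm <- vapply(all_permutations(3L), function(p) {
    counts <- table(factor(pa$a_mat[, 1], levels = 1:21),
                    factor(pa$b_mat[p, 1], levels = 1:21))
    f <- (counts + 1 / 441) / 4
    mi_position_pair(f_i, f_j, as.matrix(f))
  }, numeric(1))
  exact <- mean(per_perm)
  se <- sd(per_perm) / sqrt(400)
  mc <- shuffle_null(pa, 1, 1, n_shuffles = 400, seed = 5)
  expect_lt(abs(mc - exact), 3 * se + 1e-12)
  # deterministic under a fixed seed
  expect_identical(mc, shuffle_null(pa, 1, 1, n_shuffles = 400, seed = 5))
  expect_error(shuffle_null(pair_rows(toy_alignment("Dx", "A", "O1"),
                                      toy_alignment("Dy", "C", "O1")),
                            1, 1), "M < 2")
})

test_that("gap masking uses a strict threshold over paired rows", {
  seqs <- c(rep("A-", 3), rep("AA", 7))  # col 2: 3 gaps of 10
  a <- toy_alignment("Da", seqs, sprintf("O%d", 1:10))
  pa <- pair_rows(a, a)
  expect_identical(gap_mask(pa, "a", 0.2), c(FALSE, TRUE))   # 0.3 > 0.2
  seqs2 <- c(rep("A-", 2), rep("AA", 8))  # col 2: exactly 20% gaps
  pa2 <- pair_rows(toy_alignment("Da", seqs2, sprintf("O%d", 1:10)),
                   toy_alignment("Da", seqs2, sprintf("O%d", 1:10)))
  expect_identical(gap_mask(pa2, "a", 0.2), c(FALSE, FALSE))
  expect_identical(gap_mask(pa, "a", 1), c(FALSE, FALSE))
})

test_that("domain MI score is symmetric, seeded, and matches the R path", {
  set.seed(21)
  orgs <- sprintf("O%02d", 1:12)
  sym <- sample(c("A", "C", "D", "E"), 12, TRUE)
  mk <- function(id, first) {
    bg <- replicate(12, paste0(sample(c("F", "G", "H"), 3, TRUE),
                               collapse = ""))
    toy_alignment(id, paste0(first, bg), orgs)
  }
  a <- mk("DomA", sym)
  b <- mk("DomB", sym)
  s_ab <- compute_domain_mi(a, b, n_shuffles = 50, seed = 9,
                            keep_matrices = TRUE)
  s_ba <- compute_domain_mi(b, a, n_shuffles = 50, seed = 9)
  expect_identical(s_ab$m_mn, s_ba$m_mn)
  expect_identical(s_ab$m_mn,
                   compute_domain_mi(a, b, n_shuffles = 50, seed = 9)$m_mn)

  # C++ core agrees with the R-level frequency/MI path, raw and null-free
  pa <- pair_rows(a, b)
  for (i in c(1, 3)) for (j in c(1, 4)) {
    expect_equal(s_ab$mi[i, j],
                 mi_position_pair(column_frequencies(pa, "a", i),
                                  column_frequencies(pa, "b", j),
                                  joint_frequencies(pa, i, j)),
                 tolerance = 1e-12)
  }
  # the engineered coevolving column pair carries the max signal
  best <- which(s_ab$corrected == max(s_ab$corrected), arr.ind = TRUE)
  expect_equal(unname(best[1, ]), c(1L, 1L))
})

test_that("degenerate inputs yield an unavailable MI score", {
  # no shared organisms -> M = 0
  a <- toy_alignment("Da", c("AC", "DE"), c("X", "Y"))
  b <- toy_alignment("Db", c("FG", "HK"), c("W", "V"))
  s <- compute_domain_mi(a, b, seed = 1)
  expect_false(s$available)
  expect_true(is.na(s$m_mn))
  # everything gapped -> all columns masked
  g <- toy_alignment("Dg", c("--", "--", "A-"), c("X", "Y", "Z"))
  s2 <- compute_domain_mi(g, g, seed = 1)
  expect_false(s2$available)
  # constant single-column self pair: only the diagonal exists -> unavailable
  con <- toy_alignment("Dc", c("A", "A", "A"), c("X", "Y", "Z"))
  s3 <- compute_domain_mi(con, con, seed = 1)
  expect_false(s3$available)
  # constant single-column pair of distinct domains: corrected MI 0
  c1 <- toy_alignment("Dc1", c("A", "A", "A"), c("X", "Y", "Z"))
  c2 <- toy_alignment("Dc2", c("C", "C", "C"), c("X", "Y", "Z"))
  s4 <- compute_domain_mi(c1, c2, n_shuffles = 10, seed = 1)
  expect_true(s4$available)
  expect_equal(s4$m_mn, 0)
})

test_that("the MI table is order-independent and feeds the histogram", {
  set.seed(3)
  orgs <- sprintf("O%02d", 1:10)
  alns <- setNames(lapply(c("DomA", "DomB", "DomC"), function(id) {
    toy_alignment(id, replicate(10, paste0(
      sample(c("A", "C", "D", "E"), 4, TRUE), collapse = "")), orgs)
  }), c("DomA", "DomB", "DomC"))
  tab <- domain_mi_table(alns, n_shuffles = 30, seed = 4)
  expect_equal(nrow(tab), 6L)  # 3 choose 2 + 3 self pairs
  one <- compute_domain_mi(alns$DomB, alns$DomC, n_shuffles = 30, seed = 4)
  row <- tab[tab$domain_a == "DomB" & tab$domain_b == "DomC", ]
  expect_identical(row$m_mn, one$m_mn)
  h <- mi_histogram(tab, binwidth = 0.05)
  expect_equal(sum(h$count), sum(!is.na(tab$m_mn)))
  expect_true(all(h$bin_hi > h$bin_lo))
})
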