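test_that("the coverage filter keeps columns by informative fraction", {
  msa <- c("ACDE", "ACDE", "ACDE")
  expect_equal(coverage_filter(msa), 1:4)

  # a 20-sequence column with 2 gaps has coverage 0.90 < 0.95
  col_ok <- rep("A", 20)
  col_gap <- c(rep("A", 18), "-", "-")
  msa2 <- paste0(col_ok, col_gap)
  expect_equal(coverage_filter(msa2, 0.95), 1L)
  expect_equal(coverage_filter(msa2, 0.90), 1:2)

  expect_error(coverage_filter(c("--", "--"), 0.95), "no columns")
  expect_error(coverage_filter(c("A", "AA")), "ragged")

  # brute-force per-column counting on random gapped alignments
  set.seed(51)
  for (rep in 1:5) {
    mat <- matrix(sample(c(AA, "-", "X"), 12 * 30, replace = TRUE,
                         prob = c(rep(1, 20), 3, 1)), nrow = 12)
    msa3 <- apply(mat, 1, paste, collapse = "")
    naive <- which(vapply(seq_len(30), function(j) {
      mean(mat[, j] %in% AA) >= 0.75
    }, logical(1)))
    if (length(naive) == 0) next
    expect_equal(coverage_filter(msa3, 0.75), naive)
  }
})

test_that("the relative rate test counts lineage-specific changes", {
  r0 <- relative_rate_test("ACDE", "ACDE", "ACDE")
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # construct m_a = 8, m_b = 2 explicitly
  anc <- strrep("A", 50)
  a <- paste0(strrep("C", 8), substr(anc, 9, 50))          # 8 unique to a
  b <- paste0(substr(anc, 1, 48), "DD")                    # 2 unique to b
  r <- relative_rate_test(a, b, anc)
  expect_equal(r$m_a, 8L)
  expect_equal(r$m_b, 2L)
  expect_equal(r$chi2, 3.6)  # (8 - 2)^2 / 10
  expect_equal(r$p, pchisq(3.6, 1, lower.tail = FALSE))

  # antisymmetry: swapping the lineages swaps the counts
  rs <- relative_rate_test(b, a, anc)
  expect_equal(rs$m_a, r$m_b)
  expect_equal(rs$m_b, r$m_a)
  expect_equal(rs$chi2, r$chi2)
  expect_equal(rs$p, r$p)

  # gapped and ambiguous sites are eliminated first
  rg <- relative_rate_test("AC-E", "ACDX", "ACDE")
  expect_equal(rg$n_sites_used, 2L)

  expect_error(relative_rate_test("AC", "ACD", "ACD"), "length")
})

test_that("chi-square upper tails match the printed test statistics", {
  expect_equal(chi2_upper_tail(0), 1)
  expect_equal(chi2_upper_tail(3.8415), 0.05, tolerance = 1e-4)
  # erfc identity for 1 df at an arbitrary point
  x <- 2.7
  expect_equal(chi2_upper_tail(x),
               2 * pnorm(sqrt(x), lower.tail = FALSE), tolerance = 1e-12)
  expect_error(chi2_upper_tail(-1), "non-negative")
})

test_that("Tajima's D matches a step-by-step recomputation on a toy case", {
  # n = 4, hand-built alignment with S = 3
  msa <- c("AAAAAAAAAA",
           "CAAAAAAAAA",
           "CCAAAAAAAA",
           "CCCAAAAAAA")
  res <- tajima_D(msa)
  expect_equal(res$S, 3L)

  # independent spreadsheet-style recomputation
  diffs <- c(1, 2, 3, 1, 2, 1)  # all 6 pairs
  pi <- mean(diffs)
  co <- tajima_coeffs_oracle(4)
  D_expected <- (pi - 3 / co$a1) /
    sqrt(co$e1 * 3 + co$e2 * 3 * 2)
  expect_equal(res$pi, pi)
  expect_equal(res$D, D_expected, tolerance = 1e-12)
  for (nm in names(co)) {
    expect_equal(res[[nm]], co[[nm]], tolerance = 1e-12, info = nm)
  }

  expect_error(tajima_D(rep("AAAA", 4)), "no polymorphism")
  expect_error(tajima_D(c("AA", "AA", "AA")), "at least 4")
})

test_that("Tajima coefficients agree with the closed form for n = 4..30", {
  for (n in 4:30) {
    msa <- c(replicate(n - 1, "AAAAAAAAAA"), "CAAAAAAAAA")
    res <- tajima_D(msa)
    co <- tajima_coeffs_oracle(n)
    for (nm in names(co)) {
      expect_equal(res[[nm]], co[[nm]], tolerance = 1e-12,
                   info = paste("n =", n, nm))
    }
  }
})

test_that("D is negative under singleton excess and positive when balanced", {
  set.seed(61)
  n <- 12; L <- 120
  base <- random_seq(L)
  # singleton-dominated: each variant appears in exactly one sequence
  singleton <- vapply(seq_len(n), function(i) {
    chars <- strsplit(base, "")[[1]]
    idx <- ((i - 1) * 8 + 1):((i - 1) * 8 + 6)
    chars[idx] <- vapply(chars[idx], function(ch) {
      sample(setdiff(AA, ch), 1)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1))
  expect_lt(tajima_D(singleton)$D, 0)

  # balanced: two haplotypes at intermediate frequency
  alt <- strsplit(base, "")[[1]]
  idx <- 1:30
  alt[idx] <- vapply(alt[idx], function(ch) sample(setdiff(AA, ch), 1),
                     character(1))
  balanced <- c(rep(base, n / 2), rep(paste(alt, collapse = ""), n / 2))
  expect_gt(tajima_D(balanced)$D, 0)
})

test_that("evolution results serialize with all coefficients exposed", {
  msa <- c("AAAAAAAAAA", "CAAAAAAAAA", "CCAAAAAAAA", "CCCAAAAAAA")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_evolution_tsv(tajima_D(msa), f)
  got <- read.delim(f)
  expect_true(all(c("a1", "a2", "b1", "b2", "c1", "c2", "e1", "e2",
                    "S", "pi", "D") %in% names(got)))
})
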