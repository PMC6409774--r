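test_that("profile construction follows the column and pseudocount rules", {
  # identical ungapped sequences, no pseudocount: deterministic emissions
  h <- build_profile(c("MTEYK", "MTEYK", "MTEYK"), pseudocount = 0)
  expect_equal(h$length, 5L)
  expect_equal(unname(h$match_emissions[1, "M"]), 1)
  expect_equal(unname(h$match_emissions[3, "E"]), 1)
  expect_equal(sum(h$match_emissions[2, ] > 0), 1L)

  # all-gap column never becomes a match state
  h2 <- build_profile(c("A-C", "A-C", "A-C"))
  expect_equal(h2$length, 2L)

  # Laplace pseudocount arithmetic on a 2-sequence toy alignment
  h3 <- build_profile(c("AC", "AD"), pseudocount = 1)
  expect_equal(unname(h3$match_emissions[1, "A"]), 3 / 22)
  expect_equal(unname(h3$match_emissions[2, "C"]), 2 / 22)
  expect_equal(unname(h3$match_emissions[2, "W"]), 1 / 22)
  expect_equal(unname(rowSums(h3$match_emissions)), c(1, 1))

  expect_error(build_profile(c("AC", "ACD")), "ragged")
  expect_error(build_profile("AC"), "at least 2")
  expect_error(build_profile(c("--", "--")), "degenerate")
})

test_that("emission and transition rows are probability distributions", {
  refs <- make_reference_set(3)
  h <- build_profile(refs$msa$MPK)
  expect_equal(unname(rowSums(h$match_emissions)),
               rep(1, h$length), tolerance = 1e-9)
  tr <- h$transitions[-h$length, ]
  expect_equal(unname(rowSums(tr[, c("MM", "MI", "MD")])),
               rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(unname(rowSums(tr[, c("IM", "II")])),
               rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(unname(rowSums(tr[, c("DM", "DD")])),
               rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("Viterbi equals exhaustive path enumeration on small models", {
  set.seed(42)
  for (rep in 1:6) {
    len <- sample(3:4, 1)
    msa <- replicate(3, random_seq(len))
    hmm <- build_profile(msa, pseudocount = 1)
    for (len in 2:5) {
      seq <- random_seq(len)
      expect_equal(viterbi_score(hmm, seq), bf_viterbi(hmm, seq),
                   tolerance = 1e-9,
                   info = paste("model", rep, "seq", seq))
    }
  }
})

test_that("Viterbi behaves deterministically and rejects all-X input", {
  h <- build_profile(c("MTEYKLV", "MTEYKLV"))
  s1 <- viterbi_score(h, protein_record("a", "MTEYKLV"))
  s2 <- viterbi_score(h, protein_record("renamed", "MTEYKLV"))
  expect_identical(s1, s2)
  expect_error(viterbi_score(h, "XXXX"), "undefined")
  expect_error(viterbi_score(h, ""), "empty")

  # consensus of a sharp profile attains the maximal score among probes
  probes <- replicate(20, random_seq(7))
  expect_true(all(s1 >= vapply(probes, function(p) viterbi_score(h, p),
                               numeric(1))))
})

test_that("extending a matching sequence never lowers the local score", {
  refs <- make_reference_set(5)
  h <- build_profile(refs$msa$MKK)
  base <- refs$references$sequence[refs$references$family == "MKK"][1]
  prefix <- substr(base, 1, 200)
  expect_gte(viterbi_score(h, base), viterbi_score(h, prefix))
})

test_that("calibration is reproducible and fits a usable Gumbel tail", {
  refs <- make_reference_set(11)
  h <- build_profile(refs$msa$MPK)
  cal1 <- calibrate(h, n_null = 300, seed = 11)
  cal2 <- calibrate(h, n_null = 300, seed = 11)
  expect_identical(cal1$mu, cal2$mu)
  expect_identical(cal1$lambda, cal2$lambda)
  expect_gt(cal1$lambda, 0)
  expect_error(calibrate(h, n_null = 50), "at least 100")

  # Monte-Carlo check of the fitted upper tail at the 99th percentile
  cal <- calibrate(h, n_null = 1000, seed = 11)
  sm <- mapkminer:::hmm_score_matrices(h)
  null_scores <- mapkminer:::with_seed(1101, {
    vapply(seq_len(5000), function(i) {
      l <- sample(h$ref_lengths, 1)
      code <- sample.int(20L, l, replace = TRUE,
                         prob = h$ref_composition) - 1L
      mapkminer:::cpp_viterbi(code, sm$match, sm$trans)
    }, numeric(1))
  })
  q99 <- unname(quantile(null_scores, 0.99))
  empirical <- mean(null_scores > q99)
  fitted <- mapkminer:::gumbel_upper_tail(q99, cal$mu, cal$lambda)
  expect_lt(fitted / empirical, 3)
  expect_gt(fitted / empirical, 1 / 3)
})

test_that("proteome search ranks planted kinases above shuffled decoys", {
  pr <- make_proteome(n_mpk = 10, n_mkk = 0, n_kinase_decoys = 0,
                      n_random_decoys = 200, seed = 3)
  refs <- pr$references
  h <- build_profile(refs$msa$MPK)
  cal <- calibrate(h, n_null = 500, seed = 3)
  hits <- search_proteome(h, pr$proteome, cal)
  planted <- pr$truth$id[pr$truth$class == "planted_mpk"]
  expect_setequal(hits$protein_id[seq_along(planted)], planted)
  # sorted by ascending e-value, and e-value is monotone in bit score
  expect_false(is.unsorted(hits$e_value))
  expect_false(is.unsorted(rev(hits$bit_score)))

  # the 0.01 threshold separates exactly the hits at or below it
  expect_equal(hits$passes, hits$e_value <= 0.01)
  all_hits <- search_proteome(h, pr$proteome, cal, evalue_max = Inf)
  expect_true(all(all_hits$passes))
  expect_equal(nrow(all_hits), length(pr$proteome))

  # empty proteome is an empty result, not an error
  expect_equal(nrow(search_proteome(h, list(), cal)), 0L)
})

test_that("profile JSON serialization round-trips", {
  refs <- make_reference_set(9)
  h <- build_profile(refs$msa$MKK)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(h, f)
  back <- read_profile_json(f)
  expect_equal(back$length, h$length)
  expect_equal(back$match_emissions, h$match_emissions, tolerance = 1e-12)
  expect_equal(back$transitions, h$transitions, tolerance = 1e-12)
  probe <- refs$references$sequence[refs$references$family == "MKK"][2]
  expect_equal(viterbi_score(back, probe), viterbi_score(h, probe))
})
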