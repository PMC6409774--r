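test_that("pattern compilation implements the degenerate grammar", {
  m <- compile_pattern("T(D/E)Y")
  expect_equal(m$width, 3L)
  expect_equal(nrow(scan_motif("TDY", m)), 1L)
  expect_equal(nrow(scan_motif("TEY", m)), 1L)
  expect_equal(nrow(scan_motif("TAY", m)), 0L)

  expect_equal(compile_pattern("xx")$width, 2L)
  expect_equal(compile_pattern("(I/V/L)GxGx(S/F/G)GxV")$width, 9L)

  expect_error(compile_pattern("T(D/E"), "unbalanced")
  expect_error(compile_pattern("TD)Y"), "unbalanced")
  expect_error(compile_pattern("T(D/)Y"), "empty alternation")
  expect_error(compile_pattern("T()Y"), "empty alternation")
  expect_error(compile_pattern("tdy"), "lowercase")
  expect_error(compile_pattern("T(DE)Y"), "single")
})

test_that("P-loop match set equals naive enumeration over a test alphabet", {
  # exhaustive: all 9-mers over {G, S, V, A, I}
  alph <- c("G", "S", "V", "A", "I")
  grids <- do.call(expand.grid,
                   c(rep(list(alph), 9), stringsAsFactors = FALSE))
  words <- do.call(paste0, grids)
  m <- compile_pattern("(I/V/L)GxGx(S/F/G)GxV")
  # apply the compiled positional representation vectorized
  ok <- rep(TRUE, length(words))
  for (k in seq_len(9)) {
    allowed <- m$positions[[k]]
    if (is.null(allowed)) next
    ok <- ok & grids[[k]] %in% allowed
  }
  # naive oracle: regex translation
  rx <- paste0("^", pattern_to_regex("(I/V/L)GxGx(S/F/G)GxV"), "$")
  expect_equal(ok, grepl(rx, words))
  expect_gt(sum(ok), 0)
})

test_that("scanning reports overlapping hits leftmost-first", {
  h <- scan_motif("ATEYG", "T(D/E)Y")
  expect_equal(h$start, 2L)
  expect_equal(h$matched, "TEY")

  h2 <- scan_motif("TDYTDY", "T(D/E)Y")
  expect_equal(h2$start, c(1L, 4L))

  # windows containing X never match, even the wildcard-only pattern
  expect_equal(nrow(scan_motif("AXx", "xx")), 0L)
  expect_equal(nrow(scan_motif("ACX", "(A/C)C")), 1L)
})

test_that("scanning equals naive sliding-window matching on random 300-mers", {
  set.seed(5)
  patterns <- c("T(D/E)Y", "D(L/I/V)K", "GTxxYMSPER",
                "(S/T)xxxxx(S/T)", "HRD(L/I)KPxN")
  for (rep in 1:5) {
    s <- random_seq(300)
    for (p in patterns) {
      expect_equal(scan_motif(s, p)$start, regex_scan_starts(s, p),
                   info = paste(p, "rep", rep))
    }
  }
})

test_that("signature catalogs encode the published motif rules", {
  mpk <- signature_catalog("MPK")
  mkk <- signature_catalog("MKK")
  expect_error(signature_catalog("MKKK"), "unknown family")

  expect_true("GTxxYMSPER" %in% mkk$pattern)
  expect_true(mkk$mandatory[mkk$pattern == "GTxxYMSPER"])
  # the P-loop is optional: an MPK lacking it is still admissible
  expect_false(mpk$mandatory[mpk$name == "ploop"])
  expect_true(all(c("cloop", "tloop") %in% mpk$name[mpk$mandatory]))
  for (p in c(mpk$pattern, mkk$pattern)) {
    expect_s3_class(compile_pattern(p), "motif_matcher")
  }
})

test_that("evidence profiles type the T-loop and check motif order", {
  seq <- paste0(strrep("A", 20), "HRDLKPSN", strrep("G", 10), "DFGLAR",
                strrep("G", 10), "TDY", strrep("G", 10), "TRWYRAPE",
                strrep("A", 20))
  ev <- evidence_profile(seq, "MPK")
  expect_true(ev$order_ok)
  expect_equal(ev$tloop_type, "TDY")
  expect_true(ev$mandatory_ok)

  # shuffled motif order is always rejected
  set.seed(9)
  blocks <- c("HRDLKPSN", "DFGLAR", "TDY", "TRWYRAPE")
  for (rep in 1:10) {
    ord <- sample(4)
    while (identical(ord, 1:4)) ord <- sample(4)
    shuffled <- paste0(strrep("A", 10),
                       paste(blocks[ord], collapse = strrep("G", 8)),
                       strrep("A", 10))
    ev2 <- evidence_profile(shuffled, "MPK")
    expect_false(ev2$order_ok, info = paste(ord, collapse = ","))
  }
})

test_that("the MKK activation motif tolerates one mismatch", {
  base <- paste0(strrep("A", 30), "DLK", strrep("G", 20))
  ok <- evidence_profile(paste0(base, "GTHEYMSPER", strrep("A", 20)),
                         "MKK")
  expect_true(ok$mandatory_ok)

  near <- evidence_profile(paste0(base, "GTHEYMAPER", strrep("A", 20)),
                           "MKK")
  expect_true(near$mandatory_ok)
  expect_true("activation_near_match" %in% near$flags)

  # two mismatches exceed the budget
  far <- evidence_profile(paste0(base, "GTHEYMAPEK", strrep("A", 20)),
                          "MKK")
  expect_false(far$mandatory_ok)

  # budget 0 reduces to exact matching
  exact0 <- evidence_profile(paste0(base, "GTHEYMAPER", strrep("A", 20)),
                             "MKK", near_match_budget = 0L)
  expect_false(exact0$mandatory_ok)
})

test_that("T-loop typing falls back to variant and absent", {
  expect_equal(evidence_profile(paste0(strrep("A", 10), "TQY",
                                       strrep("A", 10)), "MPK")$tloop_type,
               "variant")
  expect_equal(evidence_profile(strrep("A", 30), "MPK")$tloop_type,
               "absent")
})
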