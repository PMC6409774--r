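test_that("mutation respects rate, protection and determinism", {
  s <- random_seq(1000)
  expect_identical(mutate_seq(s, 0, seed = 1), s)

  # observed substitution fraction within 3 binomial SDs of the rate
  m <- mutate_seq(s, 0.3, seed = 71)
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(frac - 0.3), sd3)

  # protected intervals are untouched even at high rates
  prot <- rbind(c(1, 50), c(900, 1000))
  mp <- mutate_seq(s, 0.9, seed = 5, protect = prot)
  expect_equal(substr(mp, 1, 50), substr(s, 1, 50))
  expect_equal(substr(mp, 900, 1000), substr(s, 900, 1000))

  expect_identical(mutate_seq(s, 0.3, seed = 71), m)
  expect_error(mutate_seq(s, 1), "rate")
})

test_that("reference sets embed the clade-diagnostic motifs", {
  refs <- make_reference_set(1)
  rtab <- refs$references
  expect_equal(sort(unique(rtab$family)), c("MKK", "MPK"))
  expect_true(all(rtab$homolog_number >= 1))

  # clade A MPK references carry the clade-A docking consensus intact
  cladeA <- rtab[rtab$family == "MPK" & rtab$clade == "A", ]
  for (s in cladeA$sequence) {
    expect_true(grepl(docking_consensus()$A, s, fixed = TRUE))
  }

  # every MPK reference has exactly one T(D/E)Y, at the designated spot,
  # with the type determined by its clade
  mpk <- rtab[rtab$family == "MPK", ]
  for (i in seq_len(nrow(mpk))) {
    hits <- scan_motif(mpk$sequence[i], "T(D/E)Y")
    expect_equal(nrow(hits), 1L, info = mpk$id[i])
    expected <- if (mpk$clade[i] %in% c("A", "B")) "TEY" else "TDY"
    expect_equal(hits$matched, expected, info = mpk$id[i])
  }

  # MKK references carry the activation motif realization
  mkk <- rtab[rtab$family == "MKK", ]
  for (s in mkk$sequence) {
    expect_equal(nrow(scan_motif(s, "GTxxYMSPER")), 1L)
  }

  # byte-identical reproducibility under a fixed seed
  refs2 <- make_reference_set(1)
  expect_identical(refs$references$sequence, refs2$references$sequence)
})

test_that("proteomes carry planted truth, ablated and shuffled decoys", {
  pr <- make_proteome(n_mpk = 6, n_mkk = 3, n_kinase_decoys = 8,
                      n_random_decoys = 20, seed = 4)
  expect_equal(nrow(pr$truth), 6 + 3 + 8 + 20)
  expect_equal(length(pr$proteome), nrow(pr$truth))
  expect_false(anyDuplicated(pr$truth$id) > 0)
  ids <- vapply(pr$proteome, `[[`, character(1), "id")
  expect_setequal(ids, pr$truth$id)

  by_id <- setNames(pr$proteome, ids)
  # kinase decoys retain a C-loop realization but never T(D/E)Y
  for (id in pr$truth$id[pr$truth$class == "kinase_decoy"]) {
    s <- by_id[[id]]$sequence
    expect_equal(nrow(scan_motif(s, "T(D/E)Y")), 0L, info = id)
    expect_gt(nrow(scan_motif(s, "D(L/I/V)K")), 0L)
  }
  # random decoys are composition-matched shuffles
  shuffled <- pr$truth$id[pr$truth$class == "random_decoy"][1]
  src <- by_id[[pr$truth$id[1]]]$sequence
  dec <- by_id[[shuffled]]$sequence
  expect_equal(sort(strsplit(dec, "")[[1]]), sort(strsplit(src, "")[[1]]))
  expect_false(dec == src)
})

test_that("gene models follow the clade-conditioned exon plan", {
  pr <- make_proteome(n_mpk = 10, n_mkk = 5, n_kinase_decoys = 0,
                      n_random_decoys = 0, seed = 6)
  models <- make_gff(pr$truth, seed = 6)
  planted <- pr$truth[pr$truth$family != "none", ]
  expect_setequal(names(models), planted$id)
  plan <- mapkminer:::default_exon_plan()
  for (i in seq_len(nrow(planted))) {
    row <- planted[i, ]
    counts <- exon_intron_counts(models[[row$id]])
    expect_equal(unname(counts["exons"]),
                 unname(plan[[row$family]][[row$clade]]),
                 info = row$id)
  }
  # MKK clade C/D are intronless by default
  cd <- planted[planted$family == "MKK" & planted$clade %in% c("C", "D"), ]
  for (id in cd$id) {
    expect_equal(unname(exon_intron_counts(models[[id]])["introns"]), 0L)
  }
  # paralog group members land on distinct chromosomes
  key <- paste(planted$family, planted$homolog_number)
  for (k in unique(key[duplicated(key)])) {
    members <- planted$id[key == k]
    chroms <- vapply(members, function(id) models[[id]]$chromosome,
                     character(1))
    expect_equal(anyDuplicated(chroms), 0L, info = k)
  }
})

test_that("expression generation recovers planted fold changes at zero noise", {
  pr <- make_proteome(n_mpk = 8, n_mkk = 4, n_kinase_decoys = 0,
                      n_random_decoys = 0, seed = 8)
  q <- make_expression(pr$truth, noise_sd = 0, seed = 8)
  fc <- log2fc(q$tpm, q$design)
  expect_equal(colnames(fc), colnames(q$planted))
  # exact up to pseudocount attenuation; tight for well-expressed genes
  ctl <- q$tpm[, "leaf_control"]
  strong <- ctl >= 100
  if (any(strong)) {
    expect_equal(fc[strong, "leaf_SA"], q$planted[strong, "leaf_SA"],
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  # planted zero everywhere stays near zero
  zero <- matrix(0, nrow = nrow(q$planted), ncol = ncol(q$planted),
                 dimnames = dimnames(q$planted))
  q0 <- make_expression(pr$truth, planted_log2fc = zero, noise_sd = 0,
                        seed = 9)
  fc0 <- log2fc(q0$tpm, q0$design)
  expect_lt(max(abs(fc0)), 0.05)

  expect_identical(make_expression(pr$truth, noise_sd = 0, seed = 8)$tpm,
                   q$tpm)
})

test_that("triplets are rate-asymmetric with the ancestor as outgroup", {
  tri <- make_triplet(500, 0.10, 0.02, seed = 3)
  expect_equal(nchar(tri), c(a = 500L, b = 500L, outgroup = 500L))
  da <- mean(strsplit(tri["a"], "")[[1]] !=
               strsplit(tri["outgroup"], "")[[1]])
  db <- mean(strsplit(tri["b"], "")[[1]] !=
               strsplit(tri["outgroup"], "")[[1]])
  expect_gt(da, db)
  expect_identical(make_triplet(500, 0.10, 0.02, seed = 3), tri)
})
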