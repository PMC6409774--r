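make_small_world <- function(seed = 2) {
  pr <- make_proteome(n_mpk = 6, n_mkk = 3, n_kinase_decoys = 6,
                      n_random_decoys = 30, seed = seed)
  list(pr = pr, refs = pr$references)
}

test_that("family calls gate HMM hits through mandatory motifs", {
  w <- make_small_world(2)
  idf <- identify_families(w$pr$proteome, w$refs$references, w$refs$msa,
                           n_null = 300, seed = 2)
  truth <- w$pr$truth
  planted <- truth$id[truth$family != "none"]
  expect_setequal(idf$protein_id, planted)
  expect_equal(idf$family,
               truth$family[match(idf$protein_id, truth$id)])
  # every accepted MPK has a typed T-loop, every accepted MKK an
  # activation hit within budget
  expect_true(all(idf$tloop_type[idf$family == "MPK"] %in%
                    c("TEY", "TDY")))
  calls <- attr(idf, "calls")
  for (cl in calls) {
    if (cl$screened_family == "MKK") {
      expect_gt(nrow(cl$evidence$hits$activation), 0)
    }
  }
})

test_that("a kinase-like decoy without T(D/E)Y is rejected and flagged", {
  w <- make_small_world(4)
  decoy_id <- w$pr$truth$id[w$pr$truth$class == "kinase_decoy"][1]
  by_id <- setNames(w$pr$proteome,
                    vapply(w$pr$proteome, `[[`, character(1), "id"))
  decoy <- by_id[[decoy_id]]
  fake_hit <- data.frame(protein_id = decoy_id, bit_score = 100,
                         e_value = 1e-30, passes = TRUE)
  call <- call_family(decoy, fake_hit, "MPK")
  expect_false(call$accepted)
  expect_true("tloop_absent" %in% call$flags)
  expect_equal(call$family, "none")

  # hit/protein mismatch is an error
  expect_error(call_family(decoy, transform(fake_hit, protein_id = "zz"),
                           "MPK"), "belongs")
})

test_that("a candidate missing only the P-loop is accepted with a flag", {
  refs <- make_reference_set(6)
  seq <- refs$references$sequence[refs$references$family == "MPK"][1]
  # ablate the P-loop window (positions 30..38 of the synthetic layout)
  broken <- paste0(substr(seq, 1, 29), strrep("A", 9), substr(seq, 39,
                                                              nchar(seq)))
  p <- protein_record("cand", broken)
  hit <- data.frame(protein_id = "cand", bit_score = 500,
                    e_value = 1e-50, passes = TRUE)
  call <- call_family(p, hit, "MPK")
  expect_true(call$accepted)
  expect_true("ploop_absent" %in% call$flags)
})

test_that("clade assignment follows the top reference hit", {
  refs <- make_reference_set(8)
  rtab <- refs$references
  # candidate identical to a reference: that clade, docking distance 0
  src <- rtab[rtab$family == "MPK" & rtab$clade == "B", ][1, ]
  p <- protein_record("q1", src$sequence)
  hit <- data.frame(protein_id = "q1", bit_score = 500, e_value = 1e-50,
                    passes = TRUE)
  call <- call_family(p, hit, "MPK")
  asg <- assign_clade(call, p, rtab)
  expect_equal(asg$clade, "B")
  expect_equal(asg$top_reference, src$id)
  expect_equal(asg$docking_distance, 0L)
  expect_true(asg$tloop_consistent)

  # a TEY carrier nearest a clade-C reference keeps clade C, flagged
  # discordant (the published clade-C members with TEY are the precedent)
  srcC <- rtab[rtab$family == "MPK" & rtab$clade == "C", ][1, ]
  seqC <- srcC$sequence
  tpos <- mapkminer:::MPK_LAYOUT$tloop
  substr(seqC, tpos, tpos + 2) <- "TEY"
  pC <- protein_record("q2", seqC)
  callC <- call_family(pC, data.frame(protein_id = "q2", bit_score = 500,
                                      e_value = 1e-50, passes = TRUE),
                       "MPK")
  asgC <- assign_clade(callC, pC, rtab)
  expect_equal(asgC$clade, "C")
  expect_false(asgC$tloop_consistent)

  expect_error(assign_clade(callC, pC,
                            rtab[rtab$family == "MKK", ]),
               "no MPK references")
})

test_that("clade recovery on diverged planted kinases is near-perfect", {
  hits_ok <- 0L; total <- 0L
  for (seed in 1:3) {
    pr <- make_proteome(n_mpk = 8, n_mkk = 4, n_kinase_decoys = 0,
                        n_random_decoys = 0, divergence = 0.15,
                        seed = seed)
    by_id <- setNames(pr$proteome,
                      vapply(pr$proteome, `[[`, character(1), "id"))
    for (i in seq_len(nrow(pr$truth))) {
      row <- pr$truth[i, ]
      p <- by_id[[row$id]]
      hit <- data.frame(protein_id = row$id, bit_score = 500,
                        e_value = 1e-50, passes = TRUE)
      call <- call_family(p, hit, row$family)
      if (!call$accepted) next
      asg <- assign_clade(call, p, pr$references$references)
      total <- total + 1L
      if (asg$clade == row$clade) hits_ok <- hits_ok + 1L
    }
  }
  expect_gte(hits_ok / total, 0.95)
})

test_that("nomenclature assigns paralog suffixes by genomic order", {
  refs <- make_reference_set(10)
  rtab <- refs$references
  mk_assignment <- function(id, family, clade, homolog) {
    structure(list(protein_id = id, family = family, clade = clade,
                   top_reference = "r", homolog_number = homolog,
                   top_score = 1, tloop_consistent = TRUE,
                   docking_distance = 0L, mkk_spacing_clade = "none"),
              class = "clade_assignment")
  }
  gm <- function(id, chrom, start) {
    gene_model(id, chrom, "+", start, start + 999,
               exons = cbind(start, start + 999))
  }
  assignments <- list(
    mk_assignment("pA", "MPK", "A", 6L),
    mk_assignment("pB", "MPK", "A", 6L),
    mk_assignment("pC", "MPK", "B", 7L)
  )
  models <- list(pA = gm("pA", "Chr11", 500), pB = gm("pB", "Chr1", 900),
                 pC = gm("pC", "Chr3", 100))
  nm <- assign_names(assignments, models, "Ha")
  named <- setNames(nm$name, nm$protein_id)
  expect_equal(unname(named["pB"]), "HaMPK6-1")  # Chr1 before Chr11
  expect_equal(unname(named["pA"]), "HaMPK6-2")
  expect_equal(unname(named["pC"]), "HaMPK7")    # singleton, no hyphen

  # stable under permutation of the input
  nm2 <- assign_names(rev(assignments), models, "Ha")
  expect_equal(setNames(nm2$name, nm2$protein_id)[names(named)], named)

  expect_error(assign_names(assignments, models[-1], "Ha"),
               "no gene model")
})

test_that("gene names parse back losslessly", {
  for (name in c("HaMPK6-2", "HaMPK7", "HaMKK23-11", "AtMKK3")) {
    p <- parse_gene_name(name)
    rebuilt <- paste0(p$species_prefix, p$family, p$homolog_number,
                      ifelse(is.na(p$paralog_index), "",
                             paste0("-", p$paralog_index)))
    expect_equal(rebuilt, name)
  }
  expect_error(parse_gene_name("MPK6"), "nomenclature")
  expect_error(parse_gene_name("HaMPKK6"), "nomenclature")
})
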