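toy_quant <- function() {
  tpm <- matrix(c(100, 300, 100, 50,
                  10, 10, 40, 10), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"),
                                c("leaf_control", "leaf_SA", "root_control",
                                  "root_SA")))
  design <- data.frame(
    sample = colnames(tpm),
    tissue = c("leaf", "leaf", "root", "root"),
    treatment = c("control", "SA", "control", "SA"),
    stringsAsFactors = FALSE
  )
  list(tpm = tpm, design = design)
}

test_that("log2 fold changes contrast each treatment with its tissue control", {
  q <- toy_quant()
  fc <- log2fc(q$tpm, q$design)
  expect_equal(dim(fc), c(2L, 2L))
  expect_equal(fc["g1", "leaf_SA"], log2(301 / 101))
  expect_equal(fc["g2", "leaf_SA"], 0)          # equal TPM, any pseudocount
  expect_equal(fc["g1", "root_SA"], log2(51 / 101))

  # antisymmetry under treatment/control swap
  swapped <- q
  swapped$design$treatment <- c("SA", "control", "SA", "control")
  fc2 <- log2fc(swapped$tpm, swapped$design)
  expect_equal(unname(fc2[, "leaf_SA"]), unname(-fc[, "leaf_SA"]))

  # missing control is a design error
  broken <- q
  broken$design$treatment[1] <- "NaCl"
  expect_error(log2fc(broken$tpm, broken$design), "control")
  expect_error(log2fc(q$tpm, q$design, pseudocount = 0))
})

test_that("standardization centers, scales and drops flat rows", {
  m <- matrix(c(1, 3,
                5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(z <- standardize(m), "zero-variance")
  expect_equal(attr(z, "dropped"), "b")
  expect_equal(unname(z["a", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(43)
  big <- matrix(rnorm(60), nrow = 10)
  rownames(big) <- paste0("g", 1:10)
  z2 <- standardize(big)
  expect_equal(unname(rowMeans(z2)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 10), tolerance = 1e-9)
})

test_that("k-means recovers planted profile archetypes deterministically", {
  set.seed(41)
  arch1 <- c(2, 2, -2, -2, 0, 0)
  arch2 <- c(-2, 0, 2, 0, -2, 2)
  m <- rbind(
    t(replicate(8, arch1 + rnorm(6, 0, 0.2))),
    t(replicate(8, arch2 + rnorm(6, 0, 0.2)))
  )
  rownames(m) <- paste0("g", 1:16)
  res <- kmeans_cluster(m, k = 2, seed = 41)
  expect_length(unique(res$labels[1:8]), 1L)
  expect_length(unique(res$labels[9:16]), 1L)
  expect_false(res$labels[1] == res$labels[16])

  res2 <- kmeans_cluster(m, k = 2, seed = 41)
  expect_identical(res$labels, res2$labels)

  one <- kmeans_cluster(m, k = 1, seed = 41)
  expect_equal(unname(one$wcss), sum(sweep(m, 2, colMeans(m))^2),
               tolerance = 1e-9)
  expect_error(kmeans_cluster(m, k = 17, seed = 1), "exceeds")
})

test_that("correlation/average-linkage clustering matches brute force", {
  m <- rbind(a = c(1, 2, 3, 4), a2 = c(2, 4, 6, 8),
             neg = c(4, 3, 2, 1), odd = c(1, -3, 7, 2))
  res <- hclust_correlation_average(m)
  # perfectly correlated rows are at distance 0 and merge first
  expect_equal(res$heights[1], 0, tolerance = 1e-12)
  expect_equal(sort(res$hclust$merge[1, ]), c(-2, -1))
  # a row and its negation sit at distance 2
  d <- 1 - cor(t(m))
  expect_equal(d["a", "neg"], 2, tolerance = 1e-12)

  set.seed(47)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    mm <- matrix(rnorm(n * 5), nrow = n)
    rownames(mm) <- paste0("r", seq_len(n))
    got <- hclust_correlation_average(mm)
    expect_equal(got$heights,
                 bf_average_linkage_heights(1 - cor(t(mm))),
                 tolerance = 1e-9, info = paste("rep", rep))
    # average linkage on these dissimilarities is monotone
    expect_false(is.unsorted(got$heights))
  }

  flat <- rbind(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(hclust_correlation_average(flat), "zero-variance.*x")
})

test_that("heatmap clipping bounds values and is idempotent", {
  m <- matrix(c(-6.1, -3, 0, 3, 5.2, 4), nrow = 2)
  clipped <- heatmap_matrix(m, z_cutoff = 4)
  expect_equal(max(clipped), 4)
  expect_equal(min(clipped), -4)
  expect_equal(clipped[clipped > -4 & clipped < 4],
               m[m > -4 & m < 4])
  expect_identical(heatmap_matrix(clipped, 4), clipped)
})

test_that("dendrograms serialize to newick", {
  m <- matrix(rnorm(20), nrow = 4,
              dimnames = list(paste0("g", 1:4), NULL))
  res <- hclust_correlation_average(m, k = 2)
  nwk <- dendrogram_newick(res)
  expect_match(nwk, "^\\(")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(m))
})

test_that("quantification tables round-trip with their design sidecar", {
  pr <- make_proteome(n_mpk = 4, n_mkk = 2, n_kinase_decoys = 0,
                      n_random_decoys = 0, seed = 3)
  q <- make_expression(pr$truth, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- withr::local_tempfile(fileext = ".tsv")
  write_quant(q, tf, df)
  back <- read_quant(tf, df)
  expect_equal(back$tpm, q$tpm, tolerance = 1e-9)
  expect_equal(back$design$tissue, q$design$tissue)
})
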