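#' Validate an expression quantification design
#'
#' A quantification set is a TPM matrix (genes x samples) plus a design
#' data frame with columns `sample`, `tissue`, `treatment`. Exactly one
#' control sample is required per tissue.
#'
#' @param tpm numeric matrix of TPM values, genes in rows, samples in
#'   columns (column names = sample names).
#' @param design data frame with columns `sample`, `tissue`, `treatment`.
#' @return invisibly, the design; errors on violations.
#' @export
validate_design <- function(tpm, design) {
  needed <- c("sample", "tissue", "treatment")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0L) {
    stop("design is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!setequal(colnames(tpm), design$sample)) {
    stop("design samples do not match TPM columns")
  }
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    stop("TPM values must be finite and non-negative")
  }
  for (tis in unique(design$tissue)) {
    nctl <- sum(design$tissue == tis & design$treatment == "control")
    if (nctl != 1L) {
      stop("tissue '", tis, "' must have exactly one control sample, ",
           "found ", nctl)
    }
  }
  invisible(design)
}

#' Per-tissue log2 fold changes versus control
#'
#' For every non-control sample, computes
#' `log2((TPM + pseudocount) / (TPM_control + pseudocount))` against the
#' control of the same tissue. With pooled (replicate-free) libraries this
#' is a descriptive contrast, not an inferential statistic.
#'
#' @inheritParams validate_design
#' @param pseudocount added to both numerator and denominator (> 0,
#'   default 1 TPM).
#' @return numeric matrix genes x contrasts; contrast columns are named
#'   `tissue_treatment`.
#' @export
log2fc <- function(tpm, design, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  validate_design(tpm, design)
  trt <- design[design$treatment != "control", , drop = FALSE]
  out <- matrix(NA_real_, nrow = nrow(tpm), ncol = nrow(trt),
                dimnames = list(rownames(tpm),
                                paste(trt$tissue, trt$treatment,
                                      sep = "_")))
  for (i in seq_len(nrow(trt))) {
    ctl_sample <- design$sample[design$tissue == trt$tissue[i] &
                                  design$treatment == "control"]
    out[, i] <- log2((tpm[, trt$sample[i]] + pseudocount) /
                       (tpm[, ctl_sample] + pseudocount))
  }
  out
}

#' Row-standardize an expression matrix
#'
#' Centers each gene row to mean 0 and scales to standard deviation 1
#' (sample SD, n-1 denominator; switch to the population convention with
#' `population = TRUE`). Zero-variance rows cannot be standardized; they
#' are dropped with a warning and listed in the `"dropped"` attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @param population use the population (n) SD convention instead of the
#'   sample (n-1) one.
#' @return standardized matrix, possibly with fewer rows; attribute
#'   `"dropped"` holds the names of removed zero-variance rows.
#' @export
standardize <- function(m, population = FALSE) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  sds <- apply(m, 1L, sd)
  if (population) sds <- sds * sqrt((ncol(m) - 1) / ncol(m))
  zero <- !is.finite(sds) | sds < .Machine$double.eps
  if (any(zero)) {
    warning("standardize: dropped ", sum(zero), " zero-variance row(s)")
  }
  kept <- m[!zero, , drop = FALSE]
  out <- (kept - rowMeans(kept)) / sds[!zero]
  attr(out, "dropped") <- rownames(m)[zero]
  out
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((m - m[rep(centers[1L], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((m - m[rep(centers[j + 1L], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' K-means clustering of expression profiles
#'
#' Runs Lloyd's algorithm (via [stats::kmeans()]) from `restarts`
#' k-means++ seedings drawn from a seeded generator and keeps the run with
#' the smallest within-cluster sum of squares. Deterministic under a fixed
#' seed. Each run's final WCSS is checked against the WCSS of its initial
#' assignment (it can never exceed it).
#'
#' @param m numeric matrix (rows = genes); `nrow(m) >= k`.
#' @param k number of clusters (default 4, the reported expression group
#'   count).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 50).
#' @return object of class `cluster_result`: list with `method = "kmeans"`,
#'   `labels` (named integer vector in 1..k), `centers`, `wcss`, `k`,
#'   `seed`.
#' @export
kmeans_cluster <- function(m, k = 4L, seed = 1L, restarts = 50L) {
  stopifnot(is.matrix(m))
  if (k > nrow(m)) stop("kmeans_cluster: k exceeds the number of rows")
  if (k < 1L) stop("kmeans_cluster: k must be positive")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(m, k)
      init_lab <- apply(
        vapply(seq_len(k),
               function(j) rowSums((m - init[rep(j, nrow(m)), ,
                                             drop = FALSE])^2),
               numeric(nrow(m))),
        1L, which.min)
      init_wcss <- sum(vapply(seq_len(k), function(j) {
        rows <- m[init_lab == j, , drop = FALSE]
        if (nrow(rows) == 0L) return(0)
        sum(sweep(rows, 2L, colMeans(rows))^2)
      }, numeric(1L)))
      fit <- suppressWarnings(
        kmeans(m, centers = init, algorithm = "Lloyd", iter.max = 100L)
      )
      if (fit$tot.withinss > init_wcss + 1e-8) {
        stop("kmeans_cluster: WCSS increased over the initial assignment")
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
        best <- fit
      }
    }
  })
  structure(list(method = "kmeans",
                 labels = setNames(best$cluster, rownames(m)),
                 centers = best$centers, wcss = best$tot.withinss,
                 k = k, seed = seed),
            class = "cluster_result")
}

#' Hierarchical clustering with correlation distance and average linkage
#'
#' Distance = 1 - Pearson correlation between gene rows; agglomeration by
#' average linkage (UPGMA on the dissimilarity, via [stats::hclust()]).
#' Zero-variance rows have undefined correlation and must be removed
#' first (the error names them).
#'
#' @param m numeric matrix with >= 2 rows and >= 2 columns.
#' @param k optional number of groups to cut into (adds `labels`).
#' @return object of class `cluster_result`: list with
#'   `method = "hclust"`, `hclust` (the merge tree), `heights`, and
#'   `labels` when `k` is given.
#' @export
hclust_correlation_average <- function(m, k = NULL) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  sds <- apply(m, 1L, sd)
  zero <- !is.finite(sds) | sds < .Machine$double.eps
  if (any(zero)) {
    stop("hclust_correlation_average: zero-variance row(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  }
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  labels <- if (!is.null(k)) setNames(cutree(hc, k = k), rownames(m))
            else NULL
  structure(list(method = "hclust", hclust = hc, heights = hc$height,
                 labels = labels, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> method=", x$method,
      if (!is.null(x$k)) paste0(" k=", x$k),
      if (!is.null(x$labels)) paste0(" (", length(x$labels), " items)"),
      "\n", sep = "")
  invisible(x)
}

#' Dendrogram as a newick string
#'
#' @param cluster a `cluster_result` from
#'   [hclust_correlation_average()].
#' @return newick string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(cluster) {
  stopifnot(identical(cluster$method, "hclust"))
  ape::write.tree(ape::as.phylo(cluster$hclust))
}

#' Clip a standardized matrix for heatmap display
#'
#' Values are clipped to `[-z_cutoff, +z_cutoff]` (default 4, the display
#' cut-off used for the expression heatmap). Idempotent.
#'
#' @param m numeric matrix (standardized values).
#' @param z_cutoff clipping bound (> 0).
#' @return clipped matrix.
#' @export
heatmap_matrix <- function(m, z_cutoff = 4) {
  stopifnot(z_cutoff > 0)
  pmin(pmax(m, -z_cutoff), z_cutoff)
}

#' Read / write a quantification table with its design sidecar
#'
#' TPM as TSV (first column = gene id) and the design as a three-column
#' TSV (`sample`, `tissue`, `treatment`).
#'
#' @param tpm_path,design_path file paths.
#' @return list with elements `tpm` (matrix) and `design` (data frame).
#' @export
read_quant <- function(tpm_path, design_path) {
  raw <- read.delim(tpm_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tpm <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(tpm) <- raw[[1L]]
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  validate_design(tpm, design)
  list(tpm = tpm, design = design)
}

#' @rdname read_quant
#' @param quant list with `tpm` and `design` (as returned by
#'   [read_quant()] or [make_expression()]).
#' @export
write_quant <- function(quant, tpm_path, design_path) {
  out <- data.frame(gene = rownames(quant$tpm), quant$tpm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, tpm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(quant$design[, c("sample", "tissue", "treatment")],
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tpm_path)
}
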