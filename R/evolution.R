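#' Site-coverage filter for an alignment
#'
#' Keeps alignment columns whose fraction of unambiguous, non-gap
#' residues is at least `min_coverage` (default 0.95, i.e. fewer than 5%
#' gaps, missing data or ambiguous letters allowed at any position).
#'
#' @param msa character vector of equal-length aligned sequences.
#' @param min_coverage minimum fraction of informative rows per column.
#' @return integer vector of surviving column indices.
#' @export
coverage_filter <- function(msa, min_coverage = 0.95) {
  widths <- unique(nchar(msa))
  if (length(widths) != 1L) stop("coverage_filter: ragged alignment")
  mat <- do.call(rbind, lapply(toupper(msa), seq_chars))
  informative <- matrix(mat %in% AA20, nrow = nrow(mat))
  keep <- which(colMeans(informative) >= min_coverage)
  if (length(keep) == 0L) {
    stop("coverage_filter: no columns survive at coverage ", min_coverage)
  }
  keep
}

#' Chi-square upper-tail probability
#'
#' `P(X > x)` for a chi-square variate; for 1 degree of freedom this is
#' `erfc(sqrt(x/2))`. Delegates to [stats::pchisq()].
#'
#' @param x observed statistic (>= 0).
#' @param df degrees of freedom (default 1).
#' @return upper-tail probability in \[0, 1\].
#' @export
chi2_upper_tail <- function(x, df = 1) {
  if (any(x < 0)) stop("chi2_upper_tail: x must be non-negative")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Relative rate test on a sequence triplet
#'
#' Compares the substitution counts unique to two ingroup lineages given
#' an outgroup: `m_a` counts sites where lineage A differs from both B
#' and the outgroup while B agrees with the outgroup; `m_b` is symmetric.
#' Under equal rates `(m_a - m_b)^2 / (m_a + m_b)` is chi-square with one
#' degree of freedom. Sites with a gap or ambiguity anywhere in the
#' triplet are eliminated before counting. With `m_a + m_b = 0` the
#' statistic is 0 and p = 1.
#'
#' @param a,b,outgroup equal-length aligned sequence strings.
#' @return object of class `triplet_rate_test`: list with `n_sites_used`,
#'   `m_a`, `m_b`, `chi2`, `p`.
#' @export
relative_rate_test <- function(a, b, outgroup) {
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  co <- seq_chars(toupper(outgroup))
  if (length(ca) != length(cb) || length(ca) != length(co)) {
    stop("relative_rate_test: sequences differ in length")
  }
  ok <- ca %in% AA20 & cb %in% AA20 & co %in% AA20
  ca <- ca[ok]; cb <- cb[ok]; co <- co[ok]
  m_a <- sum(ca != cb & ca != co & cb == co)
  m_b <- sum(cb != ca & cb != co & ca == co)
  chi2 <- if (m_a + m_b == 0L) 0 else (m_a - m_b)^2 / (m_a + m_b)
  p <- if (m_a + m_b == 0L) 1 else chi2_upper_tail(chi2, df = 1)
  structure(list(n_sites_used = sum(ok), m_a = m_a, m_b = m_b,
                 chi2 = chi2, p = p),
            class = "triplet_rate_test")
}

#' @export
print.triplet_rate_test <- function(x, ...) {
  cat("<triplet_rate_test> sites=", x$n_sites_used, " m_a=", x$m_a,
      " m_b=", x$m_b, " chi2=", signif(x$chi2, 4L),
      " p=", signif(x$p, 4L), "\n", sep = "")
  invisible(x)
}

#' Tajima's test of neutrality (D)
#'
#' Computes Tajima's D on an alignment after the site-coverage filter.
#' Over the surviving columns: S = number of segregating columns (two or
#' more observed states), pi = mean pairwise difference count over all
#' sequence pairs (pairwise deletion of non-informative cells), and the
#' standard coefficient chain
#' a1 = sum(1/i), a2 = sum(1/i^2) for i = 1..n-1,
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)),
#' c1 = b1 - 1/a1, c2 = b2 - (n+2)/(a1 n) + a2/a1^2,
#' e1 = c1/a1, e2 = c2/(a1^2 + a2),
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)).
#' Multi-state columns count once toward S and by per-pair mismatch
#' toward pi. An alignment with no polymorphism has no defined D.
#'
#' @param msa character vector (>= 4 equal-length aligned sequences).
#' @param min_coverage site-coverage threshold (default 0.95).
#' @return object of class `neutrality_result`: list with `n_sequences`,
#'   `n_sites_used`, `S`, `pi` (count scale), `pi_per_site`, coefficients
#'   `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`, and `D`.
#' @export
tajima_D <- function(msa, min_coverage = 0.95) {
  n <- length(msa)
  if (n < 4L) stop("tajima_D: need at least 4 sequences")
  keep <- coverage_filter(msa, min_coverage)
  mat <- do.call(rbind, lapply(toupper(msa), seq_chars))[, keep,
                                                         drop = FALSE]
  informative <- matrix(mat %in% AA20, nrow = n)

  S <- sum(vapply(seq_len(ncol(mat)), function(j) {
    states <- unique(mat[informative[, j], j])
    length(states) >= 2L
  }, logical(1L)))
  if (S == 0L) {
    stop("tajima_D: no polymorphism among filtered sites (D undefined)")
  }

  pairs <- utils::combn(n, 2L)
  diffs <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- informative[i, ] & informative[j, ]
    sum(mat[i, ok] != mat[j, ok])
  }, numeric(1L))
  pi <- mean(diffs)

  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  structure(list(n_sequences = n, n_sites_used = ncol(mat), S = S,
                 pi = pi, pi_per_site = pi / ncol(mat),
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = e1, e2 = e2, D = D),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat("<neutrality_result> n=", x$n_sequences, " sites=", x$n_sites_used,
      " S=", x$S, " pi=", signif(x$pi, 6L), " D=", signif(x$D, 6L),
      "\n", sep = "")
  invisible(x)
}

#' Write evolution-test results as TSV
#'
#' Exposes every coefficient column of a [tajima_D()] result, or the
#' counts and statistic of [relative_rate_test()] results.
#'
#' @param results a `neutrality_result`, or list of `triplet_rate_test`
#'   objects (optionally named).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_evolution_tsv <- function(results, path) {
  if (inherits(results, "neutrality_result")) {
    df <- as.data.frame(unclass(results))
  } else {
    results <- if (inherits(results, "triplet_rate_test")) list(results)
               else results
    df <- do.call(rbind, lapply(results, function(r) {
      as.data.frame(unclass(r))
    }))
    if (!is.null(names(results))) df <- cbind(test = names(results), df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
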