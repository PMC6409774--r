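#' Substitution scoring scheme for protein alignment
#'
#' Packages a symmetric substitution matrix together with affine gap
#' penalties. The default is BLOSUM62 (taken from Biostrings' matrix data)
#' with BLAST-like gaps: a gap of length L costs
#' `gap_open + L * gap_extend` = -(11 + L).
#'
#' @param matrix_name name of a Biostrings substitution matrix
#'   (default `"BLOSUM62"`).
#' @param gap_open gap opening penalty, <= 0 (default -11).
#' @param gap_extend per-residue gap extension penalty, <= 0 (default -1).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = -11,
                           gap_extend = -1) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  full <- get(matrix_name, envir = env)
  letters21 <- c(AA20, "X")
  S <- full[letters21, letters21]
  if (!isTRUE(all.equal(S, t(S)))) {
    stop("scoring_scheme: substitution matrix is not symmetric")
  }
  structure(list(matrix = S, matrix_name = matrix_name,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# Encode for alignment kernels: 0..19 = AA20, 20 = X.
encode_align <- function(x) {
  code <- match(seq_chars(toupper(x)), c(AA20, "X")) - 1L
  if (anyNA(code)) stop("alignment: unknown residue letter in sequence")
  code
}

seq_of <- function(protein) {
  if (inherits(protein, "protein_record")) protein$sequence
  else toupper(protein)
}

#' Optimal global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Deterministic traceback prefers the diagonal move, then the vertical
#' (gap in `b`), then the horizontal (gap in `a`).
#'
#' @param a,b [protein_record()] objects or sequence strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return object of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b`, `score` and `identity_fraction`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) {
    stop("global_align: empty input sequence")
  }
  res <- cpp_nw_affine(encode_align(sa), encode_align(sb),
                       unname(scheme$matrix), scheme$gap_open,
                       scheme$gap_extend)
  ca <- seq_chars(sa); cb <- seq_chars(sb)
  aligned_a <- ifelse(res$path_a == 0L, "-", ca[pmax(res$path_a, 1L)])
  aligned_b <- ifelse(res$path_b == 0L, "-", cb[pmax(res$path_b, 1L)])
  ident <- mean(aligned_a == aligned_b & aligned_a != "-")
  structure(list(aligned_a = paste(aligned_a, collapse = ""),
                 aligned_b = paste(aligned_b, collapse = ""),
                 score = res$score, identity_fraction = ident),
            class = "pairwise_alignment")
}

#' Best local alignment score (Smith-Waterman, affine gaps)
#'
#' @inheritParams global_align
#' @return numeric score (>= 0).
#' @export
local_score <- function(a, b, scheme = scoring_scheme()) {
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("local_score: empty input sequence")
  cpp_sw_score(encode_align(sa), encode_align(sb), unname(scheme$matrix),
               scheme$gap_open, scheme$gap_extend)
}

#' Top-scoring database hits for a query protein
#'
#' Ranks every database entry by its Smith-Waterman local alignment score
#' against the query, descending; ties keep database order. This is the
#' exact-pairwise replacement for a BLASTp top-hit search.
#'
#' @param query [protein_record()] or sequence string.
#' @param database list of [protein_record()] objects (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param k number of hits to return (default 10).
#' @return data frame with columns `id`, `score`, sorted by descending
#'   score.
#' @export
top_hits <- function(query, database, scheme = scoring_scheme(), k = 10L) {
  if (k < 1L) stop("top_hits: k must be at least 1")
  if (length(database) == 0L) stop("top_hits: empty database")
  ids <- vapply(database, `[[`, character(1L), "id")
  scores <- vapply(database, function(d) local_score(query, d, scheme),
                   numeric(1L))
  ord <- order(-scores)  # stable: ties keep database order
  out <- data.frame(id = ids[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  head(out, k)
}

#' Pairwise p-distance and Poisson correction
#'
#' `p_distance` computes the mismatch fraction over comparable columns
#' (columns where both sequences carry an unambiguous residue; gap and X
#' columns are excluded pairwise). `poisson_correct` applies the Poisson
#' multiple-hit correction d = -ln(1 - p).
#'
#' @param a,b equal-length gapped (aligned) sequence strings.
#' @return numeric distance.
#' @export
p_distance <- function(a, b) {
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb)) {
    stop("p_distance: aligned sequences differ in length")
  }
  ok <- ca %in% AA20 & cb %in% AA20
  if (!any(ok)) stop("p_distance: no comparable columns")
  mean(ca[ok] != cb[ok])
}

#' @rdname p_distance
#' @param p p-distance in \[0, 1).
#' @export
poisson_correct <- function(p) {
  if (any(p >= 1)) {
    stop("poisson_correct: p = 1 gives an infinite distance")
  }
  -log(1 - p)
}

#' Pairwise distance matrix from an alignment
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param correction `"poisson"` (default) or `"p"` (uncorrected).
#' @param saturate saturated pairs (p = 1, where the Poisson correction
#'   diverges — these arise on bootstrap resamples of distant pairs) are
#'   capped at `1 - saturate / alignment width` before correction
#'   (default 0.5); set `saturate = 0` to make saturation an error.
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as labels.
#' @export
distance_matrix <- function(msa, correction = c("poisson", "p"),
                            saturate = 0.5) {
  correction <- match.arg(correction)
  n <- length(msa)
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    stop("distance_matrix: sequences must carry unique names")
  }
  width <- nchar(msa[[1L]])
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        p <- p_distance(msa[[i]], msa[[j]])
        if (p >= 1 && saturate > 0) p <- 1 - saturate / width
        v <- if (correction == "poisson") poisson_correct(p) else p
        d[i, j] <- v; d[j, i] <- v
      }
    }
  }
  d
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm symmetric matrix with labels as dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste0(formatC(rownames(dm)[i], width = -10L),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
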