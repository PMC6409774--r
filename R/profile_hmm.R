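#' Build a profile hidden Markov model from a multiple alignment
#'
#' Constructs a Plan-7-style profile (match / insert / delete states) from a
#' rectangular gapped alignment. Columns whose gap fraction is below
#' `match_rule` become match states; emission and transition counts receive
#' a Laplace-style pseudocount and are normalized to probability
#' distributions. The background model is uniform over the 20 amino acids.
#'
#' @param msa character vector of equal-length gapped sequences (gaps `-`
#'   or `.`); at least 2 sequences.
#' @param match_rule columns with gap fraction strictly below this value
#'   become match states (default 0.5).
#' @param pseudocount Laplace pseudocount added to every emission and
#'   transition count (default 1).
#' @return an object of class `profile_hmm` with elements `length`,
#'   `match_emissions` (L x 20 probability matrix), `transitions`
#'   (L x 7 probability matrix, columns MM, MI, MD, IM, II, DM, DD),
#'   `background` (length-20 frequency vector) and `ref_lengths`
#'   (ungapped lengths of the training sequences, used by the calibrator).
#' @export
build_profile <- function(msa, match_rule = 0.5, pseudocount = 1) {
  stopifnot(is.character(msa))
  if (length(msa) < 2L) stop("build_profile: need at least 2 sequences")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) {
    stop("build_profile: ragged alignment (unequal sequence lengths)")
  }
  chars <- do.call(rbind, lapply(toupper(msa), seq_chars))
  is_gap <- matrix(chars %in% GAP_CHARS, nrow = nrow(chars))
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < match_rule)
  L <- length(match_cols)
  if (L == 0L) stop("build_profile: degenerate model (zero match columns)")
  n <- nrow(chars)

  # Match emissions: residue counts per match column (X and gaps excluded).
  emis <- matrix(pseudocount, nrow = L, ncol = 20L,
                 dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- chars[, match_cols[k]]
    tab <- table(factor(col, levels = AA20))
    emis[k, ] <- emis[k, ] + as.numeric(tab)
  }
  emis <- emis / rowSums(emis)

  # State path per sequence over match slots 1..L; insert columns are the
  # non-match columns between consecutive match columns.
  slot_of_col <- integer(ncol(chars))
  slot_of_col[match_cols] <- seq_len(L)
  # non-match column c belongs to insert slot = number of match columns
  # strictly before c (0 = before the first match state, unusable locally).
  before <- cumsum(seq_len(ncol(chars)) %in% match_cols)
  trans_counts <- matrix(0, nrow = L, ncol = 7L,
                         dimnames = list(NULL, c("MM", "MI", "MD",
                                                 "IM", "II", "DM", "DD")))
  for (s in seq_len(n)) {
    # states visited: for each column, M/D at match columns, I at others
    prev_state <- NULL  # c(type, slot)
    for (cc in seq_len(ncol(chars))) {
      if (slot_of_col[cc] > 0L) {
        type <- if (is_gap[s, cc]) "D" else "M"
        slot <- slot_of_col[cc]
      } else {
        if (is_gap[s, cc]) next  # gap in insert column: no state
        type <- "I"
        slot <- before[cc]
        if (slot == 0L || slot == L) next  # flanking inserts: local model
      }
      if (!is.null(prev_state)) {
        key <- paste0(prev_state[1L], type)
        from <- as.integer(prev_state[2L])
        # transitions are recorded at their source slot; Plan-7 forbids
        # I<->D moves, which are simply not counted
        if (key %in% colnames(trans_counts) && from >= 1L && from < L) {
          trans_counts[from, key] <- trans_counts[from, key] + 1
        }
      }
      prev_state <- c(type, slot)
    }
  }
  tp <- trans_counts + pseudocount
  # normalize per source state: M -> {MM, MI, MD}; I -> {IM, II}; D -> {DM, DD}
  tp[, c("MM", "MI", "MD")] <-
    tp[, c("MM", "MI", "MD")] / rowSums(tp[, c("MM", "MI", "MD")])
  tp[, c("IM", "II")] <- tp[, c("IM", "II")] / rowSums(tp[, c("IM", "II")])
  tp[, c("DM", "DD")] <- tp[, c("DM", "DD")] / rowSums(tp[, c("DM", "DD")])
  tp[L, ] <- NA_real_  # no transitions out of the last slot

  ungapped <- nchar(gsub("[-.]", "", msa))
  structure(
    list(length = L, match_emissions = emis, transitions = tp,
         background = setNames(rep(1 / 20, 20L), AA20),
         match_rule = match_rule, pseudocount = pseudocount,
         ref_lengths = as.integer(ungapped),
         ref_composition = emission_composition(chars, is_gap)),
    class = "profile_hmm"
  )
}

# Average residue composition of the training alignment (for the null
# sampler); falls back to uniform if the alignment is all gaps.
emission_composition <- function(chars, is_gap) {
  res <- chars[!is_gap]
  tab <- table(factor(res, levels = AA20))
  tot <- sum(tab)
  if (tot == 0L) return(setNames(rep(1 / 20, 20L), AA20))
  setNames(as.numeric(tab) / tot, AA20)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$length, " match states, pseudocount ",
      x$pseudocount, "\n", sep = "")
  invisible(x)
}

# Precompute the L x 21 log2-odds match score matrix (column 21 = X,
# scored 0 = background-neutral so ambiguous residues carry no evidence)
# and the L x 7 log2 transition matrix consumed by the C++ kernel.
hmm_score_matrices <- function(hmm) {
  ms <- log2(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
  ms <- cbind(ms, X = 0)
  tr <- log2(hmm$transitions)
  tr[is.na(tr)] <- -Inf
  list(match = ms, trans = tr)
}

#' Local Viterbi bit score of a protein against a profile HMM
#'
#' Scores the best local alignment path of the sequence through the profile
#' in log2-odds (bits) against a uniform background null. Flanking
#' unaligned residues are free; entry into any match state costs
#' `log2(1/L)`; exit after any match state is free. Ambiguity letters (X)
#' emit at background (score 0).
#'
#' @param hmm a [build_profile()] model.
#' @param protein a [protein_record()] or plain sequence string.
#' @return numeric bit score.
#' @export
viterbi_score <- function(hmm, protein) {
  stopifnot(inherits(hmm, "profile_hmm"))
  seq <- if (inherits(protein, "protein_record")) protein$sequence
         else toupper(protein)
  if (!nzchar(seq)) stop("viterbi_score: empty sequence")
  enc <- encode_aa(seq)
  if (all(is.na(enc))) {
    stop("viterbi_score: sequence contains only ambiguous residues; ",
         "score undefined")
  }
  sm <- hmm_score_matrices(hmm)
  code <- ifelse(is.na(enc), -1L, enc - 1L)
  cpp_viterbi(as.integer(code), sm$match, sm$trans)
}

#' Calibrate e-values for a profile HMM
#'
#' Fits a Gumbel (type-I extreme value) distribution to Viterbi scores of
#' background-sampled null sequences: residues drawn i.i.d. from the
#' training-set composition, lengths resampled from the training-set
#' ungapped lengths. Location/scale are estimated by the method of moments
#' and polished by maximum likelihood.
#'
#' @param hmm a [build_profile()] model.
#' @param n_null number of null sequences (>= 100; default 1000).
#' @param seed integer seed (calibration is reproducible given the seed).
#' @param length_sampler optional function(n) returning integer lengths;
#'   defaults to resampling the training lengths.
#' @return object of class `evalue_calibration` with elements `mu`,
#'   `lambda` (> 0) and `n_null`.
#' @export
calibrate <- function(hmm, n_null = 1000L, seed = 1L,
                      length_sampler = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_null < 100L) stop("calibrate: n_null must be at least 100")
  if (is.null(length_sampler)) {
    length_sampler <- function(n) sample(hmm$ref_lengths, n, replace = TRUE)
  }
  comp <- hmm$ref_composition
  sm <- hmm_score_matrices(hmm)
  scores <- with_seed(seed, {
    lens <- length_sampler(n_null)
    vapply(lens, function(l) {
      code <- sample.int(20L, l, replace = TRUE, prob = comp) - 1L
      cpp_viterbi(code, sm$match, sm$trans)
    }, numeric(1L))
  })
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-9) {
    stop("calibrate: degenerate null-score variance")
  }
  lambda0 <- pi / (s * sqrt(6))
  mu0 <- mean(scores) - 0.5772156649 / lambda0
  nll <- function(par) {
    lam <- par[2L]
    if (lam <= 0) return(Inf)
    z <- lam * (scores - par[1L])
    -sum(log(lam) - z - exp(-z))
  }
  fit <- optim(c(mu0, lambda0), nll, method = "Nelder-Mead")
  mu <- fit$par[1L]; lambda <- fit$par[2L]
  if (lambda <= 0) stop("calibrate: calibration failed (lambda <= 0)")
  structure(list(mu = mu, lambda = lambda, n_null = n_null, seed = seed),
            class = "evalue_calibration")
}

# Gumbel upper-tail probability P(S > s), numerically stable for small tails.
gumbel_upper_tail <- function(s, mu, lambda) {
  -expm1(-exp(-lambda * (s - mu)))
}

#' Screen a proteome with a calibrated profile HMM
#'
#' Scores every protein by [viterbi_score()] and converts bit scores to
#' e-values via the Gumbel calibration multiplied by the database size.
#' A hit passes when its e-value is at most `evalue_max` (default 0.01,
#' the screening threshold of the identification funnel).
#'
#' @param hmm a [build_profile()] model.
#' @param proteome list of [protein_record()] objects.
#' @param calibration an [calibrate()] result for this model.
#' @param evalue_max e-value acceptance threshold (default 0.01).
#' @return data frame of hits sorted by ascending e-value with columns
#'   `protein_id`, `bit_score`, `e_value`, `passes`.
#' @export
search_proteome <- function(hmm, proteome, calibration, evalue_max = 0.01) {
  stopifnot(inherits(hmm, "profile_hmm"),
            inherits(calibration, "evalue_calibration"))
  if (length(proteome) == 0L) {
    return(data.frame(protein_id = character(0L), bit_score = numeric(0L),
                      e_value = numeric(0L), passes = logical(0L)))
  }
  sm <- hmm_score_matrices(hmm)
  ids <- vapply(proteome, `[[`, character(1L), "id")
  scores <- vapply(proteome, function(p) {
    enc <- encode_aa(p$sequence)
    code <- ifelse(is.na(enc), -1L, enc - 1L)
    cpp_viterbi(as.integer(code), sm$match, sm$trans)
  }, numeric(1L))
  ev <- length(proteome) *
    gumbel_upper_tail(scores, calibration$mu, calibration$lambda)
  out <- data.frame(protein_id = ids, bit_score = scores, e_value = ev,
                    passes = ev <= evalue_max, stringsAsFactors = FALSE)
  out[order(out$e_value, -out$bit_score), , drop = FALSE]
}

#' Serialize / restore a profile HMM as versioned JSON
#'
#' @param hmm a [build_profile()] model.
#' @param path output (input) path.
#' @return `path` invisibly; `read_profile_json` returns the model.
#' @export
write_profile_json <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  doc <- list(format = "mapkminer-profile", version = 1L,
              length = hmm$length,
              alphabet = paste(AA20, collapse = ""),
              match_emissions = unclass(hmm$match_emissions),
              transitions = unclass(hmm$transitions),
              background = as.list(hmm$background),
              match_rule = hmm$match_rule, pseudocount = hmm$pseudocount,
              ref_lengths = hmm$ref_lengths,
              ref_composition = as.list(hmm$ref_composition))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mapkminer-profile")) {
    stop("read_profile_json: not a mapkminer profile document")
  }
  as_mat <- function(x, cols) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), nrow = doc$length,
                                         byrow = TRUE)
    dimnames(m) <- list(NULL, cols)
    m
  }
  emis <- as_mat(doc$match_emissions, AA20)
  tr <- as_mat(doc$transitions,
               c("MM", "MI", "MD", "IM", "II", "DM", "DD"))
  structure(
    list(length = doc$length, match_emissions = emis, transitions = tr,
         background = unlist(doc$background),
         match_rule = doc$match_rule, pseudocount = doc$pseudocount,
         ref_lengths = as.integer(doc$ref_lengths),
         ref_composition = unlist(doc$ref_composition)),
    class = "profile_hmm"
  )
}
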