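# Independent oracles used across the suite. Each is a deliberately
# naive computation (enumeration, regex, closed form) kept free of the
# package's own implementation path.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- profile HMM: exhaustive best local path -------------------------
# Enumerates every local state path (entry at any match state, exit after
# any match state) and returns the maximum log2-odds score.
bf_viterbi <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  enc <- match(chars, AA)
  L <- hmm$length
  emis <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  tr <- log2(hmm$transitions)
  entry <- log2(1 / L)
  n <- length(enc)
  best <- -Inf

  # state: list(type, slot); emits: M consumes a residue, I consumes a
  # residue at background (score 0), D consumes nothing.
  recurse <- function(type, slot, pos, score) {
    if (type == "M") {
      best <<- max(best, score)  # free exit after any match
    }
    if (slot > L) return(invisible())
    # possible successors
    succ <- list()
    if (type == "M") {
      if (slot < L) {
        succ <- c(succ, list(c("M", slot + 1, tr[slot, "MM"]),
                             c("I", slot, tr[slot, "MI"]),
                             c("D", slot + 1, tr[slot, "MD"])))
      }
    } else if (type == "I") {
      succ <- c(succ, list(c("M", slot + 1, tr[slot, "IM"]),
                           c("I", slot, tr[slot, "II"])))
    } else {
      if (slot < L) {
        succ <- c(succ, list(c("M", slot + 1, tr[slot, "DM"]),
                             c("D", slot + 1, tr[slot, "DD"])))
      }
    }
    for (s in succ) {
      stype <- s[1]; sslot <- as.numeric(s[2]); tcost <- as.numeric(s[3])
      if (stype == "M") {
        if (pos <= n) {
          recurse("M", sslot, pos + 1,
                  score + tcost + emis[sslot, chars[pos]])
        }
      } else if (stype == "I") {
        if (pos <= n) recurse("I", sslot, pos + 1, score + tcost)
      } else {
        recurse("D", sslot, pos, score + tcost)
      }
    }
  }
  for (j in seq_len(L)) {       # entry at any match state
    for (i in seq_len(n)) {     # starting at any residue
      recurse("M", j, i + 1, entry + emis[j, chars[i]])
    }
  }
  best
}

# --- alignment: exhaustive global alignment score --------------------
# Enumerates all global alignments; a gap run of length k costs
# gap_open + k * gap_extend.
bf_global_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1, j + 1, score + S[ca[i], cb[j]], "M")
    }
    if (i <= length(ca)) {
      cost <- if (prev == "U") gap_extend else gap_open + gap_extend
      recurse(i + 1, j, score + cost, "U")
    }
    if (j <= length(cb)) {
      cost <- if (prev == "L") gap_extend else gap_open + gap_extend
      recurse(i, j + 1, score + cost, "L")
    }
  }
  recurse(1, 1, 0, "M")
  best
}

# --- motifs: regex translation of the degenerate grammar -------------
pattern_to_regex <- function(pattern) {
  out <- ""
  i <- 1
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      while (chars[j] != ")") j <- j + 1
      alts <- setdiff(chars[(i + 1):(j - 1)], "/")
      out <- paste0(out, "[", paste(alts, collapse = ""), "]")
      i <- j + 1
    } else if (ch == "x") {
      out <- paste0(out, "[A-WY]")  # any residue but not X
      i <- i + 1
    } else {
      out <- paste0(out, ch)
      i <- i + 1
    }
  }
  out
}

# Overlapping regex match starts (1-based).
regex_scan_starts <- function(seq, pattern) {
  rx <- paste0("(?=", pattern_to_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- Tajima coefficients: independent closed-form chain --------------
tajima_coeffs_oracle <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# --- pI: fine grid search --------------------------------------------
grid_pi <- function(seq, pka = default_pka_table(), step = 1e-4) {
  grid <- seq(0, 14, by = step)
  chars <- strsplit(toupper(seq), "")[[1]]
  counts <- vapply(pka$group, function(g) {
    if (g %in% c("Nterm", "Cterm")) 1L else sum(chars == g)
  }, integer(1))
  charge <- rep(0, length(grid))
  for (k in seq_len(nrow(pka))) {
    if (counts[k] == 0L) next
    if (pka$sign[k] == "positive") {
      charge <- charge + counts[k] / (1 + 10^(grid - pka$pKa[k]))
    } else {
      charge <- charge - counts[k] / (1 + 10^(pka$pKa[k] - grid))
    }
  }
  grid[which.min(abs(charge))]
}

# --- average linkage: brute-force agglomeration ----------------------
bf_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}
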