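#' Compile a degenerate protein motif pattern
#'
#' Grammar (fixed width only): capital letters match that exact residue,
#' `x` matches any residue, and `(A/B/...)` is an alternation over single
#' residues. Examples: `"T(D/E)Y"` (the MPK activation T-loop),
#' `"GTxxYMSPER"` (the MKK activation motif).
#'
#' @param pattern pattern string.
#' @return an object of class `motif_matcher`: a list with `pattern`,
#'   `width` and `positions` (per position, the allowed residue set or
#'   `NULL` for the wildcard).
#' @export
compile_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- seq_chars(pattern)
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      alts <- character(0L)
      expecting_residue <- TRUE
      repeat {
        if (j > length(chars)) {
          stop("compile_pattern: unbalanced parentheses in '", pattern, "'")
        }
        cj <- chars[j]
        if (cj == ")") break
        if (cj == "/") {
          if (expecting_residue) {
            stop("compile_pattern: empty alternation in '", pattern, "'")
          }
          expecting_residue <- TRUE
        } else if (cj %in% LETTERS) {
          if (!expecting_residue) {
            stop("compile_pattern: alternation entries must be single ",
                 "residues in '", pattern, "'")
          }
          alts <- c(alts, cj)
          expecting_residue <- FALSE
        } else {
          stop("compile_pattern: invalid character '", cj, "' in '",
               pattern, "'")
        }
        j <- j + 1L
      }
      if (length(alts) == 0L || expecting_residue) {
        stop("compile_pattern: empty alternation in '", pattern, "'")
      }
      positions[[length(positions) + 1L]] <- alts
      i <- j + 1L
    } else if (ch == "x") {
      positions[length(positions) + 1L] <- list(NULL)  # wildcard
      i <- i + 1L
    } else if (ch %in% LETTERS) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == ")") {
      stop("compile_pattern: unbalanced parentheses in '", pattern, "'")
    } else {
      stop("compile_pattern: invalid character '", ch, "' in '",
           pattern, "' (lowercase other than x is not allowed)")
    }
  }
  structure(list(pattern = pattern, width = length(positions),
                 positions = positions),
            class = "motif_matcher")
}

# Does window (character vector of matcher width) match, allowing up to
# `budget` mismatches at non-wildcard positions? Windows containing the
# ambiguity letter X never match (conservative evidence).
window_mismatches <- function(window, matcher) {
  if (any(window == "X")) return(NA_integer_)
  mm <- 0L
  for (k in seq_len(matcher$width)) {
    allowed <- matcher$positions[[k]]
    if (is.null(allowed)) next
    if (!window[k] %in% allowed) mm <- mm + 1L
  }
  mm
}

#' Scan a protein for a motif
#'
#' Reports all (possibly overlapping) occurrences, leftmost first.
#' Positions are 1-based. Windows containing the ambiguity letter X never
#' match. `max_mismatch > 0` allows near-matches with up to that many
#' mismatches at non-wildcard positions.
#'
#' @param protein a [protein_record()] or sequence string.
#' @param pattern a pattern string or compiled [compile_pattern()] matcher.
#' @param max_mismatch mismatch budget (default 0 = exact).
#' @return data frame with columns `start` (1-based), `matched`,
#'   `mismatches`.
#' @export
scan_motif <- function(protein, pattern, max_mismatch = 0L) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence
         else toupper(protein)
  matcher <- if (inherits(pattern, "motif_matcher")) pattern
             else compile_pattern(pattern)
  chars <- seq_chars(seq)
  n <- length(chars)
  w <- matcher$width
  hits <- list()
  if (n >= w) {
    for (s in seq_len(n - w + 1L)) {
      win <- chars[s:(s + w - 1L)]
      mm <- window_mismatches(win, matcher)
      if (!is.na(mm) && mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <-
          data.frame(start = s, matched = paste(win, collapse = ""),
                     mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0L), matched = character(0L),
                      mismatches = integer(0L)))
  }
  do.call(rbind, hits)
}

#' Signature motif catalog for a kinase family
#'
#' Returns the catalog of signature motifs used to confirm HMM candidates.
#' The catalog ships as an editable TSV under `extdata`; columns are
#' `name`, `pattern`, `family`, `mandatory`, `near_match` (mismatch budget
#' applied to that motif), `fallback` (relaxed pattern accepted, with a
#' flag, when the strict one fails).
#'
#' MPK: P-loop, ATP-anchor, catalytic C-loop `HRD(L/I)KPxN` (mandatory,
#' relaxed fallback `D(L/I/V)K`), activation T-loop `T(D/E)Y` (mandatory),
#' `DFGLAR`, `TRWYRAPE`. MKK: activation `GTxxYMSPER` (mandatory with a
#' 1-mismatch tolerance), the S/T spacing motif, and the C-loop
#' `D(L/I/V)K` (mandatory).
#'
#' @param family `"MPK"` or `"MKK"`.
#' @param path optional path to an alternative catalog TSV.
#' @return data frame of motif definitions for that family.
#' @export
signature_catalog <- function(family, path = NULL) {
  if (!family %in% c("MPK", "MKK")) {
    stop("signature_catalog: unknown family '", family, "'")
  }
  if (is.null(path)) {
    path <- system.file("extdata", "signature_motifs.tsv",
                        package = "mapkminer", mustWork = TRUE)
  }
  cat <- read.delim(path, stringsAsFactors = FALSE)
  cat$mandatory <- as.logical(cat$mandatory)
  cat$fallback[is.na(cat$fallback)] <- ""
  cat[cat$family == family, , drop = FALSE]
}

#' Motif evidence profile of a candidate protein
#'
#' Scans every catalog motif of the family and derives: the T-loop type
#' (`TEY`/`TDY` from the middle residue of the first exact T(D/E)Y hit;
#' `variant` when only a TxY realization exists; `absent` otherwise),
#' whether all mandatory motifs are present (honoring per-motif near-match
#' budgets and relaxed fallbacks, which are flagged), and whether the
#' kinase-domain motif order C-loop < DFGLAR < T-loop < TRWYRAPE holds
#' over whichever of those motifs are present.
#'
#' @param protein a [protein_record()] or sequence string.
#' @param family `"MPK"` or `"MKK"`.
#' @param near_match_budget mismatch budget applied to motifs whose catalog
#'   entry declares near-match tolerance (default 1; 0 reduces to exact
#'   matching everywhere).
#' @param catalog optional catalog override (see [signature_catalog()]).
#' @return object of class `evidence_profile`: list with `protein_id`,
#'   `family`, `hits` (per-motif hit tables), `tloop_type`, `order_ok`,
#'   `mandatory_ok`, `flags`.
#' @export
evidence_profile <- function(protein, family, near_match_budget = 1L,
                             catalog = NULL) {
  if (is.null(catalog)) catalog <- signature_catalog(family)
  id <- if (inherits(protein, "protein_record")) protein$id else ""
  seq <- if (inherits(protein, "protein_record")) protein$sequence
         else toupper(protein)

  hits <- list()
  flags <- character(0L)
  mandatory_ok <- TRUE
  for (k in seq_len(nrow(catalog))) {
    entry <- catalog[k, ]
    budget <- if (entry$near_match > 0L) {
      min(entry$near_match, near_match_budget)
    } else 0L
    h <- scan_motif(seq, entry$pattern, max_mismatch = budget)
    used_fallback <- FALSE
    if (nrow(h) == 0L && nzchar(entry$fallback)) {
      h <- scan_motif(seq, entry$fallback, max_mismatch = 0L)
      if (nrow(h) == 0L && near_match_budget > 0L) {
        h <- scan_motif(seq, entry$fallback,
                        max_mismatch = near_match_budget)
      }
      used_fallback <- nrow(h) > 0L
      if (used_fallback) flags <- c(flags, paste0(entry$name, "_relaxed"))
    }
    if (nrow(h) > 0L && any(h$mismatches > 0L) && !used_fallback) {
      flags <- c(flags, paste0(entry$name, "_near_match"))
    }
    hits[[entry$name]] <- h
    if (nrow(h) == 0L) {
      flags <- c(flags, paste0(entry$name, "_absent"))
      if (entry$mandatory) mandatory_ok <- FALSE
    }
  }

  # T-loop typing (MPK); derived solely from the middle residue of the
  # first exact hit.
  tloop_type <- "absent"
  if (family == "MPK") {
    th <- hits[["tloop"]]
    if (!is.null(th) && nrow(th) > 0L) {
      mid <- substr(th$matched[1L], 2L, 2L)
      tloop_type <- if (mid == "E") "TEY" else "TDY"
    } else {
      tv <- scan_motif(seq, "TxY")
      tloop_type <- if (nrow(tv) > 0L) "variant" else "absent"
    }
  }

  # Kinase-domain motif order over the present subset.
  order_names <- if (family == "MPK") {
    c("cloop", "dfg", "tloop", "ape")
  } else {
    c("cloop", "activation")
  }
  firsts <- vapply(order_names, function(nm) {
    h <- hits[[nm]]
    if (is.null(h) || nrow(h) == 0L) NA_real_ else as.numeric(h$start[1L])
  }, numeric(1L))
  present <- firsts[!is.na(firsts)]
  order_ok <- length(present) <= 1L || !is.unsorted(present, strictly = TRUE)

  structure(
    list(protein_id = id, family = family, hits = hits,
         tloop_type = tloop_type, order_ok = order_ok,
         mandatory_ok = mandatory_ok, flags = unique(flags)),
    class = "evidence_profile"
  )
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("<evidence_profile> ", x$protein_id, " [", x$family, "] tloop=",
      x$tloop_type, " order_ok=", x$order_ok, " mandatory_ok=",
      x$mandatory_ok,
      if (length(x$flags)) paste0(" flags=", paste(x$flags, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}
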