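#' Ionizable-group pKa table
#'
#' Bjellqvist-style pKa constants for the termini and the seven ionizable
#' side chains, as used by the standard compute-pI convention. Positive
#' groups contribute `+1/(1 + 10^(pH - pKa))`, negative groups
#' `-1/(1 + 10^(pKa - pH))`. The table is an ordinary data frame and can
#' be edited and passed back in.
#'
#' @return data frame with columns `group`, `pKa`, `sign`.
#' @export
default_pka_table <- function() {
  data.frame(
    group = c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y"),
    pKa = c(7.50, 3.55, 9.00, 4.05, 4.45, 5.98, 10.00, 12.00, 10.00),
    sign = c("positive", "negative", "negative", "negative", "negative",
             "positive", "positive", "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

# Occurrence counts of each ionizable group in a sequence (termini once).
ionizable_counts <- function(seq, pka) {
  chars <- seq_chars(toupper(seq))
  counts <- vapply(pka$group, function(g) {
    if (g %in% c("Nterm", "Cterm")) 1L else sum(chars == g)
  }, integer(1L))
  setNames(counts, pka$group)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch summation over the ionizable groups: each
#' positive group contributes `1/(1 + 10^(pH - pKa))`, each negative
#' group `-1/(1 + 10^(pKa - pH))`; termini count once, side chains by
#' occurrence. Strictly decreasing in pH.
#'
#' @param seq protein sequence string.
#' @param pH pH in \[0, 14\].
#' @param pka pKa table (see [default_pka_table()]).
#' @return numeric net charge.
#' @export
net_charge <- function(seq, pH, pka = default_pka_table()) {
  stopifnot(pH >= 0, pH <= 14)
  counts <- ionizable_counts(seq, pka)
  pos <- pka$sign == "positive"
  sum(counts[pos] / (1 + 10^(pH - pka$pKa[pos]))) -
    sum(counts[!pos] / (1 + 10^(pka$pKa[!pos] - pH)))
}

#' Theoretical isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] crosses zero by bisection on
#' [0, 14]. The termini always ionize, so a crossing is guaranteed.
#'
#' @param seq protein sequence string.
#' @param pka pKa table.
#' @param tol bisection tolerance in pH units (default 1e-3).
#' @return numeric pI.
#' @export
isoelectric_point <- function(seq, pka = default_pka_table(), tol = 1e-3) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Average residue masses (Da); one water is added per chain.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.01524 Da). Sequences
#' containing X or other non-standard letters are rejected (their mass is
#' undefined).
#'
#' @param seq protein sequence string (standard residues only, non-empty).
#' @return molecular weight in Da.
#' @export
molecular_weight <- function(seq) {
  chars <- seq_chars(toupper(seq))
  if (length(chars) == 0L) stop("molecular_weight: empty sequence")
  bad <- setdiff(unique(chars), names(AVERAGE_RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop("molecular_weight: undefined composition, letter(s): ",
         paste(bad, collapse = ", "))
  }
  sum(AVERAGE_RESIDUE_MASS[chars]) + WATER_MASS
}

#' Property table for a set of proteins
#'
#' @param proteins list of [protein_record()] objects.
#' @param pka pKa table for the pI computation.
#' @return data frame with columns `protein_id`, `length`, `pI`, `Mw`
#'   (`Mw` is NA for sequences containing X).
#' @export
protein_properties <- function(proteins, pka = default_pka_table()) {
  do.call(rbind, lapply(proteins, function(p) {
    mw <- tryCatch(molecular_weight(p$sequence), error = function(e) NA_real_)
    data.frame(protein_id = p$id, length = nchar(p$sequence),
               pI = isoelectric_point(p$sequence, pka), Mw = mw,
               stringsAsFactors = FALSE)
  }))
}

#' Family-level summary statistics
#'
#' Aggregates an annotation table per family: protein-length mean (raw and
#' integer-rounded, matching the printed convention), exon-count mean and
#' range, molecular-weight mean, and pI extremes with the gene names that
#' attain them. Means include every row of the family, short outliers
#' included.
#'
#' @param table validated annotation table (see
#'   [validate_annotation_table()]).
#' @param family `"MPK"` or `"MKK"`.
#' @return object of class `family_summary` (a list).
#' @export
summarize_family <- function(table, family) {
  validate_annotation_table(table)
  rows <- table[table$family == family, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("summarize_family: no rows for family ", family)
  }
  structure(
    list(family = family, n = nrow(rows),
         mean_length = mean(rows$protein_length),
         mean_length_rounded = round(mean(rows$protein_length)),
         pI_min = min(rows$pI),
         pI_min_gene = rows$name[which.min(rows$pI)],
         pI_max = max(rows$pI),
         pI_max_gene = rows$name[which.max(rows$pI)],
         mean_Mw = mean(rows$Mw),
         mean_exons = mean(rows$exons),
         exon_min = min(rows$exons), exon_max = max(rows$exons),
         exon_min_genes = rows$name[rows$exons == min(rows$exons)],
         exon_max_genes = rows$name[rows$exons == max(rows$exons)]),
    class = "family_summary"
  )
}

#' @export
print.family_summary <- function(x, ...) {
  cat("<family_summary> ", x$family, ": n=", x$n,
      ", mean length ", round(x$mean_length, 1), " aa (",
      x$mean_length_rounded, ")",
      ", pI ", x$pI_min, " (", x$pI_min_gene, ") - ", x$pI_max,
      " (", x$pI_max_gene, ")",
      ", mean Mw ", round(x$mean_Mw, 3), " Da",
      ", mean exons ", round(x$mean_exons, 2),
      " [", x$exon_min, "-", x$exon_max, "]\n", sep = "")
  invisible(x)
}
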