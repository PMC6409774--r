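#' Protein sequence record
#'
#' A single proteome entry: identifier, free-text description, an uppercase
#' amino-acid sequence over the 20-letter alphabet (the ambiguity letter `X`
#' is tolerated and flagged), and a short species code such as `"Ha"`.
#'
#' @param id non-empty identifier, unique within a proteome.
#' @param sequence uppercase amino-acid string; no gap characters.
#' @param description free-text description.
#' @param species_code short species prefix (e.g. `"Ha"` for sunflower).
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "", species_code = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein_record: sequence must be non-empty for '", id, "'")
  }
  if (grepl("[-.]", sequence)) {
    stop("protein_record: gap characters are not allowed in '", id, "'")
  }
  bad <- setdiff(unique(seq_chars(sequence)), c(AA20, "X"))
  if (length(bad) > 0L) {
    stop("protein_record: unknown residue letter(s) ",
         paste(bad, collapse = ", "), " in '", id, "'")
  }
  structure(
    list(id = id, description = description, sequence = sequence,
         species_code = species_code,
         has_ambiguity = grepl("X", sequence, fixed = TRUE)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa",
      if (x$has_ambiguity) ", contains X", ")\n", sep = "")
  invisible(x)
}

#' Genomic gene model
#'
#' A gene locus with its exon structure. Coordinates are 1-based inclusive
#' throughout (the GFF3 convention); exon order is genomic, not
#' transcriptional, so strand does not affect exon counting.
#'
#' @param gene_id gene identifier.
#' @param chromosome chromosome (or scaffold) name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span, `start <= end`.
#' @param exons two-column matrix (start, end) of 1-based inclusive exon
#'   intervals; must be non-overlapping and contained in `[start, end]`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end, exons) {
  stopifnot(length(gene_id) == 1L, nzchar(gene_id))
  if (!strand %in% c("+", "-")) {
    stop("gene_model: unknown strand symbol '", strand, "' for ", gene_id)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("gene_model: start > end for ", gene_id)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene_model: ", gene_id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] > exons[, 2L])) {
    stop("gene_model: exon with start > end in ", gene_id)
  }
  if (any(exons[, 1L] < start | exons[, 2L] > end)) {
    stop("gene_model: exon outside the gene span of ", gene_id)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene_model: overlapping exons in ", gene_id)
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         start = start, end = end, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " ", x$chromosome, ":", x$start, "-",
      x$end, "(", x$strand, "), ", nrow(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

#' Validate an annotation table
#'
#' An annotation table is a data frame keyed by gene name with the layout of
#' the packaged sunflower table: columns `name`, `family` (MPK/MKK),
#' `chromosome`, `strand`, `start`, `end`, `protein_length`, `exons`,
#' `introns`, `localization` (M, C or `-`), `pI`, `Mw`. The structural
#' invariant `introns = exons - 1` must hold on every row.
#'
#' @param table data frame to validate.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_annotation_table <- function(table) {
  needed <- c("name", "family", "chromosome", "strand", "start", "end",
              "protein_length", "exons", "introns", "localization",
              "pI", "Mw")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(table$name)) {
    stop("annotation table has duplicated gene names")
  }
  if (!all(table$family %in% c("MPK", "MKK"))) {
    stop("annotation table family must be MPK or MKK")
  }
  if (!all(table$introns == table$exons - 1L)) {
    bad <- table$name[table$introns != table$exons - 1L]
    stop("introns != exons - 1 for: ", paste(bad, collapse = ", "))
  }
  if (!all(table$protein_length > 0L)) {
    stop("annotation table has non-positive protein lengths")
  }
  invisible(table)
}

# Convert a list of protein_record objects to a named character vector of
# sequences (names = ids).
proteome_vector <- function(proteins) {
  stopifnot(all(vapply(proteins, inherits, logical(1L), "protein_record")))
  setNames(vapply(proteins, `[[`, character(1L), "sequence"),
           vapply(proteins, `[[`, character(1L), "id"))
}
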