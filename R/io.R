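#' Read a protein FASTA file
#'
#' Wraps `Biostrings::readAAStringSet()` and returns a list of
#' [protein_record()] objects, order preserved, sequences uppercased.
#' Record identifiers must be unique.
#'
#' @param path path to a FASTA file.
#' @param species_code species prefix stored on every record.
#' @return list of `protein_record` objects.
#' @export
read_fasta <- function(path, species_code = "") {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) stop("read_fasta: empty file: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("read_fasta: malformed FASTA in ", path, ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("read_fasta: no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("read_fasta: duplicate record id(s): ", paste(dups, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  mapply(protein_record, id = ids, sequence = seqs, description = desc,
         MoreArgs = list(species_code = species_code),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' Multi-record FASTA, sequence lines wrapped at 60 columns.
#'
#' @param proteins list of [protein_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- proteome_vector(proteins)
  desc <- vapply(proteins, `[[`, character(1L), "description")
  nm <- ifelse(nzchar(desc), paste(names(seqs), desc), names(seqs))
  set <- Biostrings::AAStringSet(setNames(seqs, nm))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses GFF3 via `rtracklayer::import()` and assembles one [gene_model()]
#' per gene-kind feature, attaching exon features through their `Parent`
#' attribute. Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @param feature_kinds feature types treated as genes.
#' @return named list of `gene_model` objects (names = gene ids).
#' @export
read_gff3 <- function(path, feature_kinds = "gene") {
  if (!file.exists(path)) stop("read_gff3: no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("read_gff3: parse error in ", path, ": ",
                             conditionMessage(e))
  )
  meta <- S4Vectors::mcols(gr)
  types <- as.character(meta$type)
  is_gene <- types %in% feature_kinds
  is_exon <- types == "exon"
  gene_ids <- as.character(meta$ID[is_gene])
  if (anyDuplicated(gene_ids)) {
    stop("read_gff3: duplicated gene ID(s) in ", path)
  }
  gi <- which(is_gene)
  gene_idx <- setNames(gi, gene_ids)

  parents <- meta$Parent[is_exon]
  parent_first <- vapply(as.list(parents), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1L))
  if (anyNA(parent_first)) {
    stop("read_gff3: exon feature without a Parent attribute in ", path)
  }
  orphan <- setdiff(unique(parent_first), gene_ids)
  if (length(orphan) > 0L) {
    stop("read_gff3: exon Parent refers to absent gene(s): ",
         paste(orphan, collapse = ", "))
  }

  ex_start <- GenomicRanges::start(gr)[is_exon]
  ex_end <- GenomicRanges::end(gr)[is_exon]
  models <- lapply(gene_ids, function(id) {
    i <- gene_idx[[id]]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (!strand %in% c("+", "-")) {
      stop("read_gff3: unknown strand symbol '", strand, "' for gene ", id)
    }
    sel <- parent_first == id
    if (!any(sel)) {
      stop("read_gff3: gene ", id, " has no exon features")
    }
    gstart <- GenomicRanges::start(gr)[i]
    gend <- GenomicRanges::end(gr)[i]
    if (any(ex_start[sel] < gstart | ex_end[sel] > gend)) {
      stop("read_gff3: exon outside the span of gene ", id)
    }
    gene_model(gene_id = id,
               chromosome = as.character(GenomicRanges::seqnames(gr))[i],
               strand = strand, start = gstart, end = gend,
               exons = cbind(ex_start[sel], ex_end[sel]))
  })
  setNames(models, gene_ids)
}

#' Write gene models to GFF3
#'
#' Emits a `##gff-version 3` header, one `gene` feature per model and one
#' `exon` feature per exon interval linked through `Parent`.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "mapkminer") {
  lines <- c("##gff-version 3")
  for (m in models) {
    lines <- c(lines, paste(m$chromosome, source, "gene",
                            format(m$start, scientific = FALSE),
                            format(m$end, scientific = FALSE),
                            ".", m$strand, ".",
                            paste0("ID=", m$gene_id), sep = "\t"))
    for (k in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$chromosome, source, "exon",
                              format(m$exons[k, 1L], scientific = FALSE),
                              format(m$exons[k, 2L], scientific = FALSE),
                              ".", m$strand, ".",
                              paste0("ID=", m$gene_id, ".exon", k,
                                     ";Parent=", m$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load the packaged sunflower MPK/MKK annotation table
#'
#' Returns the transcription of the published sunflower MPK and MKK gene
#' table: 28 MPK and 8 MKK rows with proposed name, chromosome, strand,
#' coordinates, protein length, exon and intron counts, subcellular
#' localization (M = mitochondria, C = chloroplast, `-` = other),
#' isoelectric point and molecular weight.
#'
#' @return a validated annotation data frame (36 rows).
#' @export
load_sunflower_annotation <- function() {
  path <- system.file("extdata", "sunflower_mapk_annotation.tsv",
                      package = "mapkminer", mustWork = TRUE)
  read_annotation_table(path)
}

#' Read / write an annotation table
#'
#' The on-disk layout uses the published column headers
#' (`Name`, `Gene ID`, `Chr`, `Str`, `Start`, `End`, `PL`, `Exo`, `Int`,
#' `Sl`, `pI`, `Mw`); in memory the table uses descriptive lower-case
#' column names (see [validate_annotation_table()]).
#'
#' @param path TSV path.
#' @return data frame (for `read_annotation_table`); `path` invisibly
#'   (for `write_annotation_table`).
#' @export
read_annotation_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("Name", "Chr", "Str", "Start", "End", "PL", "Exo", "Int",
              "Sl", "pI", "Mw")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_annotation_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- data.frame(
    name = raw$Name,
    gene_id = if ("Gene ID" %in% names(raw)) raw[["Gene ID"]] else NA_character_,
    family = ifelse(grepl("MPK", raw$Name, fixed = TRUE), "MPK", "MKK"),
    chromosome = raw$Chr,
    strand = raw$Str,
    start = raw$Start,
    end = raw$End,
    protein_length = as.integer(raw$PL),
    exons = as.integer(raw$Exo),
    introns = as.integer(raw$Int),
    localization = raw$Sl,
    pI = as.numeric(raw$pI),
    Mw = as.numeric(raw$Mw),
    stringsAsFactors = FALSE
  )
  validate_annotation_table(tab)
  tab
}

#' @rdname read_annotation_table
#' @param table validated annotation data frame.
#' @export
write_annotation_table <- function(table, path) {
  validate_annotation_table(table)
  out <- data.frame(
    Name = table$name,
    `Gene ID` = if ("gene_id" %in% names(table)) table$gene_id else "",
    Chr = table$chromosome, Str = table$strand,
    Start = table$start, End = table$end,
    PL = table$protein_length, Exo = table$exons, Int = table$introns,
    Sl = table$localization, pI = table$pI, Mw = table$Mw,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
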