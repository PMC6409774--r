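#' Exon and intron counts of a gene model
#'
#' Structural counts only: introns = exons - 1, independent of strand.
#'
#' @param model a [gene_model()].
#' @return named integer vector `c(exons, introns)`.
#' @export
exon_intron_counts <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n <- nrow(model$exons)
  if (n < 1L) stop("exon_intron_counts: model has no exons")
  c(exons = n, introns = n - 1L)
}

#' Per-chromosome gene family distribution
#'
#' Tallies MPK and MKK genes per chromosome and lists the gene names on
#' each; also reports which chromosomes of the supplied universe carry no
#' gene of each family.
#'
#' @param table validated annotation table.
#' @param chromosomes optional character vector of all chromosomes in the
#'   genome (to report family-absent chromosomes); defaults to the
#'   chromosomes observed in the table.
#' @return object of class `chromosome_distribution`: list with `counts`
#'   (data frame chromosome / mpk_count / mkk_count / total), `genes`
#'   (named list chromosome -> gene names), `absent` (list with `MPK` and
#'   `MKK` chromosome vectors).
#' @export
chromosome_distribution <- function(table, chromosomes = NULL) {
  if (nrow(table) == 0L) {
    return(structure(list(counts = data.frame(chromosome = character(0L),
                                              mpk_count = integer(0L),
                                              mkk_count = integer(0L),
                                              total = integer(0L)),
                          genes = list(),
                          absent = list(MPK = character(0L),
                                        MKK = character(0L))),
                     class = "chromosome_distribution"))
  }
  validate_annotation_table(table)
  if (is.null(chromosomes)) chromosomes <- unique(table$chromosome)
  chromosomes <- chromosomes[order(chromosome_rank(chromosomes),
                                   chromosomes)]
  counts <- data.frame(
    chromosome = chromosomes,
    mpk_count = vapply(chromosomes, function(ch) {
      sum(table$chromosome == ch & table$family == "MPK")
    }, integer(1L)),
    mkk_count = vapply(chromosomes, function(ch) {
      sum(table$chromosome == ch & table$family == "MKK")
    }, integer(1L)),
    stringsAsFactors = FALSE
  )
  counts$total <- counts$mpk_count + counts$mkk_count
  rownames(counts) <- NULL
  genes <- lapply(setNames(chromosomes, chromosomes), function(ch) {
    table$name[table$chromosome == ch]
  })
  absent <- list(
    MPK = chromosomes[counts$mpk_count == 0L],
    MKK = chromosomes[counts$mkk_count == 0L]
  )
  structure(list(counts = counts, genes = genes, absent = absent),
            class = "chromosome_distribution")
}

#' @export
print.chromosome_distribution <- function(x, ...) {
  cat("<chromosome_distribution> over", nrow(x$counts), "chromosomes\n")
  print(x$counts)
  invisible(x)
}

#' Paralog groups and their chromosomal dispersion
#'
#' Groups genes by (family, homolog number) using the nomenclature; groups
#' with two or more members are paralog groups. A group is dispersed when
#' its members span at least two chromosomes. Same-chromosome member pairs
#' within each group are reported explicitly.
#'
#' @param table validated annotation table whose `name` column follows the
#'   nomenclature (see [parse_gene_name()]).
#' @param family restrict to one family (default both).
#' @return data frame with one row per paralog group: `family`,
#'   `homolog_number`, `n_members`, `members`, `chromosomes`, `dispersed`,
#'   `same_chromosome_pairs`.
#' @export
paralog_dispersion <- function(table, family = c("MPK", "MKK")) {
  validate_annotation_table(table)
  family <- match.arg(family, several.ok = TRUE)
  parsed <- lapply(table$name, parse_gene_name)
  tab <- data.frame(
    name = table$name,
    family = vapply(parsed, `[[`, character(1L), "family"),
    homolog_number = vapply(parsed, `[[`, integer(1L), "homolog_number"),
    chromosome = table$chromosome,
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$family %in% family, , drop = FALSE]
  key <- paste(tab$family, tab$homolog_number)
  groups <- lapply(unique(key[duplicated(key)]), function(k) {
    idx <- which(key == k)
    members <- tab$name[idx]
    chroms <- tab$chromosome[idx]
    pairs <- character(0L)
    if (length(idx) >= 2L) {
      cmb <- utils::combn(seq_along(idx), 2L)
      same <- chroms[cmb[1L, ]] == chroms[cmb[2L, ]]
      pairs <- paste(members[cmb[1L, same]], members[cmb[2L, same]],
                     sep = "/")
    }
    data.frame(family = tab$family[idx[1L]],
               homolog_number = tab$homolog_number[idx[1L]],
               n_members = length(idx),
               members = paste(members, collapse = ","),
               chromosomes = paste(chroms, collapse = ","),
               dispersed = length(unique(chroms)) >= 2L,
               same_chromosome_pairs = paste(pairs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(groups) == 0L) {
    return(data.frame(family = character(0L), homolog_number = integer(0L),
                      n_members = integer(0L), members = character(0L),
                      chromosomes = character(0L), dispersed = logical(0L),
                      same_chromosome_pairs = character(0L)))
  }
  out <- do.call(rbind, groups)
  out[order(out$family, out$homolog_number), , drop = FALSE]
}

#' Karyotype table (text rendering of the chromosome map)
#'
#' One row per gene: chromosome, start position, name, family, strand.
#' This is the tabular stand-in for a chromosome-painting figure.
#'
#' @param table validated annotation table.
#' @return data frame sorted by chromosome natural order, then position.
#' @export
karyotype_table <- function(table) {
  validate_annotation_table(table)
  pos <- pmin(table$start, table$end)
  out <- data.frame(chromosome = table$chromosome, position = pos,
                    name = table$name, family = table$family,
                    strand = table$strand, stringsAsFactors = FALSE)
  out[order(chromosome_rank(out$chromosome), out$chromosome,
            out$position), , drop = FALSE]
}
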