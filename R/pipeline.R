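#' Run the full identification and characterization pipeline
#'
#' Orchestrates the funnel end to end: profile-HMM screening and motif
#' confirmation (identify), clade assignment and orthology-based naming
#' (classify), protein properties and gene-structure summaries
#' (characterize), and, when a quantification table is supplied,
#' expression contrasts and clustering (express). Every output is written
#' as TSV (plus newick for trees) under `outdir`, and a run log records
#' every threshold and seed, so a rerun with an identical config is
#' byte-identical.
#'
#' @param config a list with elements:
#'   * `proteome`: list of [protein_record()] or a FASTA path (mandatory);
#'   * `references`: data frame (see [read_reference_set()]) or
#'     `c(fasta, labels)` paths (mandatory);
#'   * `ref_msa`: named list of per-family reference alignments
#'     (mandatory unless `references` came from [make_reference_set()],
#'     whose `msa` element is used);
#'   * `gene_models`: named list of [gene_model()] or a GFF3 path
#'     (optional; required for naming);
#'   * `quant`: list with `tpm` and `design`, or `c(tpm, design)` paths
#'     (optional);
#'   * `species_prefix` (default `"Ha"`), `evalue_max` (default 0.01),
#'     `seed` (default 1), `n_null` (default 1000),
#'     `near_match_budget` (default 1), `kmeans_k` (default 4).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (`identified`, `assignments`, `names`, `annotation`, `summaries`,
#'   `distribution`, `paralogs`, `log2fc`, `clusters`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.null(config$proteome) || is.null(config$references)) {
    stop("run_pipeline: config must name a proteome and references")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(species_prefix = "Ha", evalue_max = 0.01, seed = 1L,
              n_null = 1000L, near_match_budget = 1L, kmeans_k = 4L)
  cfg[names(config)] <- config

  proteome <- cfg$proteome
  if (is.character(proteome)) proteome <- read_fasta(proteome)
  references <- cfg$references
  ref_msa <- cfg$ref_msa
  if (is.list(references) && !is.data.frame(references) &&
      !is.null(references$references)) {
    if (is.null(ref_msa)) ref_msa <- references$msa
    references <- references$references
  } else if (is.character(references)) {
    references <- read_reference_set(references[1L], references[2L])
  }
  if (is.null(ref_msa)) {
    # ungapped reference alignments by family (equal-length references)
    ref_msa <- lapply(split(references, references$family), function(r) {
      setNames(r$sequence, r$id)
    })
  }
  gene_models <- cfg$gene_models
  if (is.character(gene_models)) gene_models <- read_gff3(gene_models)

  log_lines <- c(
    "mapkminer run log",
    paste0("evalue_max\t", cfg$evalue_max),
    paste0("near_match_budget\t", cfg$near_match_budget),
    paste0("n_null\t", cfg$n_null),
    paste0("seed\t", cfg$seed),
    paste0("kmeans_k\t", cfg$kmeans_k),
    paste0("species_prefix\t", cfg$species_prefix),
    paste0("n_proteins\t", length(proteome)),
    paste0("n_references\t", nrow(references))
  )

  # identify -----------------------------------------------------------
  identified <- identify_families(proteome, references, ref_msa,
                                  evalue_max = cfg$evalue_max,
                                  n_null = cfg$n_null, seed = cfg$seed,
                                  near_match_budget = cfg$near_match_budget)
  write.table(identified, file.path(outdir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # classify -----------------------------------------------------------
  by_id <- setNames(proteome, vapply(proteome, `[[`, character(1L), "id"))
  calls <- attr(identified, "calls")
  scheme <- scoring_scheme()
  assignments <- lapply(calls, function(cl) {
    assign_clade(cl, by_id[[cl$protein_id]], references, scheme)
  })
  assign_df <- do.call(rbind, lapply(assignments, function(a) {
    data.frame(protein_id = a$protein_id, family = a$family,
               clade = a$clade, top_reference = a$top_reference,
               homolog_number = a$homolog_number,
               tloop_consistent = a$tloop_consistent,
               docking_distance = a$docking_distance,
               mkk_spacing_clade = a$mkk_spacing_clade,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(assign_df)) {
    write.table(assign_df, file.path(outdir, "clades.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  names_df <- NULL
  annotation <- NULL
  summaries <- list()
  distribution <- NULL
  paralogs <- NULL
  if (!is.null(gene_models) && length(assignments) > 0L) {
    usable <- assignments[vapply(assignments, function(a) {
      !is.null(gene_models[[a$protein_id]])
    }, logical(1L))]
    names_df <- assign_names(usable, gene_models, cfg$species_prefix)
    write.table(names_df, file.path(outdir, "names.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    # characterize: annotation table in the published layout ------------
    props <- protein_properties(by_id[names_df$protein_id])
    annotation <- data.frame(
      name = names_df$name,
      gene_id = names_df$protein_id,
      family = names_df$family,
      chromosome = names_df$chromosome,
      strand = vapply(names_df$protein_id, function(id) {
        gene_models[[id]]$strand
      }, character(1L)),
      start = names_df$start,
      end = vapply(names_df$protein_id, function(id) {
        gene_models[[id]]$end
      }, numeric(1L)),
      protein_length = props$length,
      exons = vapply(names_df$protein_id, function(id) {
        unname(exon_intron_counts(gene_models[[id]])["exons"])
      }, integer(1L)),
      localization = "-",
      pI = round(props$pI, 2L),
      Mw = round(props$Mw, 2L),
      stringsAsFactors = FALSE
    )
    annotation$introns <- annotation$exons - 1L
    write_annotation_table(annotation, file.path(outdir, "genes.tsv"))
    for (fam in intersect(c("MPK", "MKK"), unique(annotation$family))) {
      summaries[[fam]] <- summarize_family(annotation, fam)
    }
    summary_df <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(family = s$family, n = s$n, mean_length = s$mean_length,
                 pI_min = s$pI_min, pI_max = s$pI_max,
                 mean_Mw = s$mean_Mw, mean_exons = s$mean_exons,
                 exon_min = s$exon_min, exon_max = s$exon_max,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(summary_df)) {
      write.table(summary_df, file.path(outdir, "family_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    distribution <- chromosome_distribution(annotation)
    write.table(distribution$counts,
                file.path(outdir, "chromosome_distribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    paralogs <- paralog_dispersion(annotation)
    write.table(paralogs, file.path(outdir, "paralogs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(karyotype_table(annotation),
                file.path(outdir, "karyotype.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  dock <- docking_consensus()
  write.table(data.frame(clade = names(dock),
                         consensus = unlist(dock),
                         stringsAsFactors = FALSE),
              file.path(outdir, "docking_consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # express ------------------------------------------------------------
  fc <- NULL
  clusters <- NULL
  quant <- cfg$quant
  if (!is.null(quant)) {
    if (is.character(quant)) quant <- read_quant(quant[1L], quant[2L])
    fc <- log2fc(quant$tpm, quant$design)
    write.table(data.frame(gene = rownames(fc), fc, check.names = FALSE),
                file.path(outdir, "log2fc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    z <- standardize(fc)
    if (nrow(z) >= cfg$kmeans_k) {
      km <- kmeans_cluster(z, k = cfg$kmeans_k, seed = cfg$seed)
      hc <- hclust_correlation_average(z, k = cfg$kmeans_k)
      clusters <- list(kmeans = km, hclust = hc)
      write.table(data.frame(gene = names(km$labels),
                             kmeans = unname(km$labels),
                             hclust = unname(hc$labels[names(km$labels)])),
                  file.path(outdir, "clusters.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeLines(dendrogram_newick(hc),
                 file.path(outdir, "dendrogram.nwk"))
    }
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(identified = identified, assignments = assignments,
                 names = names_df, annotation = annotation,
                 summaries = summaries, distribution = distribution,
                 paralogs = paralogs, log2fc = fc, clusters = clusters))
}
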