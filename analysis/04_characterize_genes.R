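#!/usr/bin/env Rscript

# Stage 4: gene-structure and protein-property characterization.
#
# Two parts: (a) desk statistics over the packaged sunflower MPK/MKK
# annotation table — family summaries, chromosome distribution, paralog
# dispersion and the text karyotype; (b) computed properties (pI, Mw,
# exon/intron counts) for the kinases identified in the simulation.

library(mapkminer)

outdir <- "results/characterize"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## (a) published sunflower table ------------------------------------
tab <- load_sunflower_annotation()
for (fam in c("MPK", "MKK")) {
  s <- summarize_family(tab, fam)
  print(s)
}
mpk <- summarize_family(tab, "MPK")
mkk <- summarize_family(tab, "MKK")
write.table(
  data.frame(family = c("MPK", "MKK"),
             n = c(mpk$n, mkk$n),
             mean_length = c(mpk$mean_length, mkk$mean_length),
             mean_exons = c(mpk$mean_exons, mkk$mean_exons),
             mean_Mw = c(mpk$mean_Mw, mkk$mean_Mw),
             pI_min = c(mpk$pI_min, mkk$pI_min),
             pI_max = c(mpk$pI_max, mkk$pI_max)),
  file.path(outdir, "family_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

dist <- chromosome_distribution(tab, chromosomes = paste0("Ha", 1:17))
write.table(dist$counts, file.path(outdir, "chromosome_distribution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("chromosome Ha3 carries",
    dist$counts$total[dist$counts$chromosome == "Ha3"], "genes;",
    "Ha10 carries",
    dist$counts$mkk_count[dist$counts$chromosome == "Ha10"], "MKKs\n")
cat("MPK-absent chromosomes:",
    paste(dist$absent$MPK, collapse = ", "), "\n")

paras <- paralog_dispersion(tab)
write.table(paras, file.path(outdir, "paralogs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sum(paras$dispersed[paras$family == "MPK"]),
    "MPK paralog groups span several chromosomes;",
    "same-chromosome pairs:",
    paste(paras$same_chromosome_pairs[nzchar(paras$same_chromosome_pairs)],
          collapse = ", "), "\n")
write.table(karyotype_table(tab), file.path(outdir, "karyotype.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## (b) computed properties of the simulated kinases ------------------
proteome <- read_fasta("results/simulated/proteome.fa")
truth <- read.delim("results/simulated/truth.tsv")
planted <- truth$id[truth$family != "none"]
by_id <- setNames(proteome, vapply(proteome, `[[`, character(1), "id"))
props <- protein_properties(by_id[planted])
models <- read_gff3("results/simulated/genes.gff3")
counts <- t(vapply(planted, function(id) {
  exon_intron_counts(models[[id]])
}, c(exons = 0L, introns = 0L)))
props$exons <- counts[, "exons"]
props$introns <- counts[, "introns"]
write.table(props, file.path(outdir, "simulated_properties.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("computed pI/Mw for", nrow(props), "simulated kinases; pI range",
    round(min(props$pI), 2), "-", round(max(props$pI), 2), "\n")
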