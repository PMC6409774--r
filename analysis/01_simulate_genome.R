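#!/usr/bin/env Rscript

# Stage 1: build the synthetic study system.
#
# Generates the reference kinase panel (one archetype per family and
# clade, one reference per homolog number), a proteome of 235 proteins
# (10 planted MPKs, 5 planted MKKs, 20 motif-ablated kinase decoys, 200
# shuffled decoys at divergence 0.15), clade-conditioned gene models on
# 17 chromosomes, and a pooled two-tissue expression matrix with planted
# fold changes. Everything is written as standard FASTA/GFF3/TSV under
# results/simulated/ so the later stages run purely from files.

library(mapkminer)

seed <- 1L
outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

refs <- make_reference_set(seed)
pr <- make_proteome(divergence = 0.15, seed = seed, references = refs)
models <- make_gff(pr$truth, seed = seed)
quant <- make_expression(pr$truth, seed = seed)

ref_records <- mapply(function(id, s, sp) {
  protein_record(id, s, species_code = sp)
}, refs$references$id, refs$references$sequence,
   refs$references$species_code, SIMPLIFY = FALSE)
write_fasta(unname(ref_records), file.path(outdir, "references.fa"))
write.table(refs$references[, c("id", "family", "clade",
                                "homolog_number", "species_code")],
            file.path(outdir, "reference_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_fasta(pr$proteome, file.path(outdir, "proteome.fa"))
write.table(pr$truth, file.path(outdir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gff3(models, file.path(outdir, "genes.gff3"))
write_quant(quant, file.path(outdir, "tpm.tsv"),
            file.path(outdir, "design.tsv"))
write.table(data.frame(gene = rownames(quant$planted), quant$planted,
                       check.names = FALSE),
            file.path(outdir, "planted_log2fc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("simulated", length(pr$proteome), "proteins (",
    sum(pr$truth$family == "MPK"), "MPK,",
    sum(pr$truth$family == "MKK"), "MKK planted ),",
    length(models), "gene models,",
    nrow(quant$tpm), "x", ncol(quant$tpm), "TPM matrix ->", outdir, "\n")
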