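# Synthetic genomes with planted MAPK-cascade kinases. The generators
# emulate the study conditions every pipeline stage is exercised under:
# kinase-like proteins carrying clade-specific activation-loop and docking
# motifs at tunable divergence, non-kinase decoys, multi-exon gene models
# with dispersed paralog pairs, and a pooled two-tissue by
# {control, SA, NaCl, Peg} TPM matrix with planted fold changes.

# Fixed motif layout of the synthetic archetypes (1-based start offsets).
MPK_SCAFFOLD_LEN <- 420L
MPK_LAYOUT <- list(ploop = 30L, atp_anchor = 60L, cloop = 130L,
                   dfg = 165L, tloop = 195L, ape = 225L, docking = 370L)
MKK_SCAFFOLD_LEN <- 360L
MKK_LAYOUT <- list(cloop = 120L, activation = 180L, spacing = 210L)

# Homolog numbers seeded per clade, mirroring the reference families.
MPK_CLADE_HOMOLOGS <- list(A = c(3L, 6L, 4L, 11L), B = c(1L, 2L, 7L),
                           C = c(22L, 23L), D = c(16L, 19L, 9L, 18L))
MKK_CLADE_HOMOLOGS <- list(A = c(1L, 2L, 6L), B = 3L, C = c(4L, 5L),
                           D = 9L)

random_residues <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Realize a degenerate pattern into a concrete residue string using the
# current RNG: alternations pick one residue, wildcards draw uniformly.
realize_pattern <- function(pattern) {
  matcher <- compile_pattern(pattern)
  out <- vapply(matcher$positions, function(allowed) {
    if (is.null(allowed)) sample(AA20, 1L)
    else if (length(allowed) == 1L) allowed
    else sample(allowed, 1L)
  }, character(1L))
  paste(out, collapse = "")
}

splice_at <- function(seq, start, insert) {
  paste0(substr(seq, 1L, start - 1L), insert,
         substr(seq, start + nchar(insert), nchar(seq)))
}

# Replace the middle residue of any exact T(D/E)Y occurrence that does not
# start at `keep_start` (use keep_start = -1 to scrub all), so activation
# loops appear only where planted.
scrub_tloop <- function(seq, keep_start = -1L) {
  repeat {
    hits <- scan_motif(seq, "T(D/E)Y")
    stray <- hits$start[hits$start != keep_start]
    if (length(stray) == 0L) return(seq)
    substr(seq, stray[1L] + 1L, stray[1L] + 1L) <- "N"
  }
}

# Protected intervals (two-column matrix) covering the motif layout.
layout_protect <- function(layout, widths) {
  do.call(rbind, lapply(names(layout), function(nm) {
    c(layout[[nm]], layout[[nm]] + widths[[nm]] - 1L)
  }))
}

#' Per-site substitution mutation
#'
#' Substitutes each unprotected site with probability `rate` by a
#' uniformly drawn different residue. `protect` intervals (1-based,
#' inclusive) are never touched.
#'
#' @param seq sequence string.
#' @param rate substitution probability per site, in \[0, 1).
#' @param seed optional integer seed; `NULL` uses the current RNG stream
#'   (for callers that already seeded).
#' @param protect two-column matrix or list of `c(start, end)` intervals.
#' @return mutated sequence string.
#' @export
mutate_seq <- function(seq, rate, seed = NULL, protect = NULL) {
  stopifnot(rate >= 0, rate < 1)
  run <- function() {
    chars <- seq_chars(seq)
    n <- length(chars)
    protected <- rep(FALSE, n)
    if (!is.null(protect)) {
      if (is.list(protect)) protect <- do.call(rbind, protect)
      if (length(protect) > 0L) {
        for (r in seq_len(nrow(protect))) {
          lo <- max(1L, protect[r, 1L]); hi <- min(n, protect[r, 2L])
          if (lo <= hi) protected[lo:hi] <- TRUE
        }
      }
    }
    hit <- runif(n) < rate & !protected
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Build one clade archetype for a family: random scaffold with the
# signature motifs realized at the fixed layout offsets.
build_archetype <- function(family, clade) {
  if (family == "MPK") {
    seq <- random_residues(MPK_SCAFFOLD_LEN)
    dock <- docking_consensus()[[clade]]
    tloop <- if (clade %in% c("A", "B")) "TEY" else "TDY"
    pieces <- list(
      ploop = realize_pattern("(I/V/L)GxGx(S/F/G)GxV"),
      atp_anchor = realize_pattern("VA(I/V/M)KK(I/M)xxx(F/Y)"),
      cloop = realize_pattern("HRD(L/I)KPxN"),
      dfg = "DFGLAR", tloop = tloop, ape = "TRWYRAPE",
      docking = dock
    )
    for (nm in names(pieces)) {
      seq <- splice_at(seq, MPK_LAYOUT[[nm]], pieces[[nm]])
    }
    seq <- scrub_tloop(seq, keep_start = MPK_LAYOUT$tloop)
    widths <- lapply(pieces, nchar)
    list(sequence = seq,
         protect = layout_protect(MPK_LAYOUT, widths))
  } else {
    seq <- random_residues(MKK_SCAFFOLD_LEN)
    spacing <- switch(clade,
      A = paste0(realize_pattern("SxxxxxS"), realize_pattern("TxxxxxT")),
      B = realize_pattern("SxxxxxTxxxxxT"),
      C = realize_pattern("SxxxxxTxxxxxS"),
      D = realize_pattern("SxxxxxSxxxxxT"))
    pieces <- list(
      cloop = realize_pattern("D(L/I/V)K"),
      activation = realize_pattern("GTxxYMSPER"),
      spacing = spacing
    )
    for (nm in names(pieces)) {
      seq <- splice_at(seq, MKK_LAYOUT[[nm]], pieces[[nm]])
    }
    widths <- lapply(pieces, nchar)
    list(sequence = seq,
         protect = layout_protect(MKK_LAYOUT, widths))
  }
}

#' Generate a synthetic reference kinase set
#'
#' Builds one archetype per family and clade (clade A/B MPK archetypes
#' carry the TEY activation loop, C/D carry TDY; all carry the catalytic
#' C-loop, DFGLAR and TRWYRAPE in kinase order and the clade docking
#' consensus near the C terminus; MKK archetypes carry a GTxxYMSPER
#' realization and the clade-specific S/T spacing pattern), then derives
#' one reference per homolog number by light mutation (rate 0.05) outside
#' the protected motif windows. Clade-C MPK references are labelled with
#' the soybean species code, the rest with the Arabidopsis one, mirroring
#' the composition of real reference panels.
#'
#' @param seed integer seed; a fixed seed reproduces the set exactly.
#' @param within_clade_divergence mutation rate between an archetype and
#'   its homolog references (default 0.05).
#' @return list with `references` (data frame: id, sequence, family,
#'   clade, homolog_number, species_code), `msa` (named list of per-family
#'   ungapped alignments), `protect` (per-family protected intervals).
#' @export
make_reference_set <- function(seed = 1L, within_clade_divergence = 0.05) {
  with_seed(seed, {
    refs <- list()
    msa <- list(MPK = character(0L), MKK = character(0L))
    protect <- list()
    for (family in c("MPK", "MKK")) {
      homologs <- if (family == "MPK") MPK_CLADE_HOMOLOGS
                  else MKK_CLADE_HOMOLOGS
      for (clade in names(homologs)) {
        arch <- build_archetype(family, clade)
        protect[[family]] <- arch$protect
        for (h in homologs[[clade]]) {
          sp <- if (family == "MPK" && clade == "C") "Gm" else "At"
          id <- paste0(sp, family, h)
          s <- mutate_seq(arch$sequence, within_clade_divergence,
                          protect = arch$protect)
          if (family == "MPK") {
            s <- scrub_tloop(s, keep_start = MPK_LAYOUT$tloop)
          }
          refs[[id]] <- data.frame(
            id = id, sequence = s, family = family, clade = clade,
            homolog_number = h, species_code = sp,
            stringsAsFactors = FALSE
          )
          msa[[family]] <- c(msa[[family]], setNames(s, id))
        }
      }
    }
    list(references = do.call(rbind, c(refs, list(make.row.names = FALSE))),
         msa = msa, protect = protect)
  })
}

#' Generate a synthetic proteome with planted kinases and decoys
#'
#' Planted genes are reference sequences mutated at `divergence` with
#' their motif windows protected. Kinase decoys are equally diverged
#' kinase scaffolds with the activation motif ablated (T(D/E)Y scrubbed
#' for MPK-derived decoys, GTxxYMSPER overwritten for MKK-derived ones) —
#' they retain the catalytic C-loop. Random decoys are residue shuffles of
#' planted sequences (composition-matched, structure-free). The truth
#' table records every generated record.
#'
#' @param n_mpk,n_mkk planted kinase counts per family.
#' @param n_kinase_decoys motif-ablated kinase-like decoys (alternating
#'   MPK/MKK derivation).
#' @param n_random_decoys shuffled decoys.
#' @param divergence substitution probability per unprotected site
#'   (default 0.15).
#' @param seed integer seed.
#' @param references optional [make_reference_set()] result (defaults to
#'   one generated from the same seed).
#' @return list with `proteome` (list of [protein_record()]), `truth`
#'   (data frame: id, class, family, clade, homolog_number, source_ref,
#'   length), `references`.
#' @export
make_proteome <- function(n_mpk = 10L, n_mkk = 5L, n_kinase_decoys = 20L,
                          n_random_decoys = 200L, divergence = 0.15,
                          seed = 1L, references = NULL) {
  stopifnot(n_mpk >= 0L, n_mkk >= 0L, n_kinase_decoys >= 0L,
            n_random_decoys >= 0L)
  if (is.null(references)) references <- make_reference_set(seed)
  refs <- references$references
  protect <- references$protect
  with_seed(seed + 1L, {
    records <- list()
    truth <- list()
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("HAN%04d", counter)
    }
    plant <- function(family) {
      fam_refs <- refs[refs$family == family, , drop = FALSE]
      function(i) {
        src <- fam_refs[((i - 1L) %% nrow(fam_refs)) + 1L, ]
        s <- mutate_seq(src$sequence, divergence,
                        protect = protect[[family]])
        if (family == "MPK") {
          s <- scrub_tloop(s, keep_start = MPK_LAYOUT$tloop)
        }
        id <- next_id()
        records[[id]] <<- protein_record(id, s, species_code = "Ha")
        truth[[id]] <<- data.frame(
          id = id, class = paste0("planted_", tolower(family)),
          family = family, clade = src$clade,
          homolog_number = src$homolog_number, source_ref = src$id,
          length = nchar(s), stringsAsFactors = FALSE
        )
      }
    }
    plant_mpk <- plant("MPK"); plant_mkk <- plant("MKK")
    for (i in seq_len(n_mpk)) plant_mpk(i)
    for (i in seq_len(n_mkk)) plant_mkk(i)

    for (i in seq_len(n_kinase_decoys)) {
      family <- if (i %% 2L == 1L) "MPK" else "MKK"
      fam_refs <- refs[refs$family == family, , drop = FALSE]
      src <- fam_refs[((i - 1L) %% nrow(fam_refs)) + 1L, ]
      s <- mutate_seq(src$sequence, divergence,
                      protect = protect[[family]])
      if (family == "MPK") {
        s <- scrub_tloop(s, keep_start = -1L)  # ablate the T-loop
      } else {
        # ablate the activation motif beyond any near-match tolerance
        s <- splice_at(s, MKK_LAYOUT$activation,
                       paste(rep("A", 10L), collapse = ""))
        s <- scrub_tloop(s, keep_start = -1L)
      }
      id <- next_id()
      records[[id]] <- protein_record(id, s, species_code = "Ha")
      truth[[id]] <- data.frame(
        id = id, class = "kinase_decoy", family = "none",
        clade = NA_character_, homolog_number = NA_integer_,
        source_ref = src$id, length = nchar(s), stringsAsFactors = FALSE
      )
    }

    planted_seqs <- vapply(records, `[[`, character(1L), "sequence")
    if (length(planted_seqs) == 0L) {
      planted_seqs <- refs$sequence
    }
    for (i in seq_len(n_random_decoys)) {
      src <- planted_seqs[[((i - 1L) %% length(planted_seqs)) + 1L]]
      s <- paste(sample(seq_chars(src)), collapse = "")
      id <- next_id()
      records[[id]] <- protein_record(id, s, species_code = "Ha")
      truth[[id]] <- data.frame(
        id = id, class = "random_decoy", family = "none",
        clade = NA_character_, homolog_number = NA_integer_,
        source_ref = NA_character_, length = nchar(s),
        stringsAsFactors = FALSE
      )
    }
    list(proteome = unname(records),
         truth = do.call(rbind, c(unname(truth),
                                  list(make.row.names = FALSE))),
         references = references)
  })
}

# Default exon counts per (family, clade), mirroring the published
# structural patterns: clade-B MPKs have 3 exons, MKK clades C/D are
# intronless.
default_exon_plan <- function() {
  list(MPK = c(A = 6L, B = 3L, C = 18L, D = 10L),
       MKK = c(A = 8L, B = 12L, C = 1L, D = 1L))
}

#' Generate gene models for a planted proteome
#'
#' Builds clade-conditioned multi-exon gene models on a configurable
#' number of chromosomes. Members of the same (family, homolog-number)
#' paralog group are placed on distinct chromosomes (as far as the
#' chromosome count allows), emulating dispersed paralog pairs.
#'
#' @param truth truth table from [make_proteome()].
#' @param exon_plan named list `list(MPK = c(A=..), MKK = c(..))` of exon
#'   counts per clade (default [default_exon_plan()]).
#' @param n_chromosomes chromosome count (default 17).
#' @param seed integer seed.
#' @return named list of [gene_model()] objects for every planted gene.
#' @export
make_gff <- function(truth, exon_plan = default_exon_plan(),
                     n_chromosomes = 17L, seed = 1L) {
  planted <- truth[truth$family %in% c("MPK", "MKK"), , drop = FALSE]
  stopifnot(all(unlist(exon_plan) >= 1L))
  with_seed(seed, {
    chrom_of <- character(nrow(planted))
    key <- paste(planted$family, planted$homolog_number)
    for (k in unique(key)) {
      idx <- which(key == k)
      pick <- if (length(idx) <= n_chromosomes) {
        sample.int(n_chromosomes, length(idx))
      } else {
        sample.int(n_chromosomes, length(idx), replace = TRUE)
      }
      chrom_of[idx] <- paste0("Chr", pick)
    }
    models <- lapply(seq_len(nrow(planted)), function(i) {
      row <- planted[i, ]
      n_exons <- exon_plan[[row$family]][[row$clade]]
      cds_len <- 3L * (row$length + 1L)
      cuts <- sort(sample.int(cds_len - 1L, n_exons - 1L))
      exon_lens <- diff(c(0L, cuts, cds_len))
      intron_lens <- if (n_exons > 1L) {
        sample(80:500, n_exons - 1L, replace = TRUE)
      } else integer(0L)
      start <- sample.int(1e7L, 1L) + 1e5L
      exon_starts <- integer(n_exons)
      exon_ends <- integer(n_exons)
      pos <- start
      for (e in seq_len(n_exons)) {
        exon_starts[e] <- pos
        exon_ends[e] <- pos + exon_lens[e] - 1L
        pos <- exon_ends[e] + 1L
        if (e < n_exons) pos <- pos + intron_lens[e]
      }
      gene_model(gene_id = row$id, chromosome = chrom_of[i],
                 strand = sample(c("+", "-"), 1L),
                 start = start, end = exon_ends[n_exons],
                 exons = cbind(exon_starts, exon_ends))
    })
    setNames(models, planted$id)
  })
}

#' Generate a pooled two-tissue expression matrix with planted fold
#' changes
#'
#' Emulates the pooled (replicate-free) design: two tissues (leaf, root),
#' one control and three treatments (SA, NaCl, Peg) each. Control TPM is
#' drawn log-normal (meanlog 3, sdlog 1) per gene and tissue; treatment
#' TPM equals control times `2^(planted + Normal(0, noise_sd))`.
#'
#' @param truth truth table from [make_proteome()] (planted genes only
#'   are expressed).
#' @param planted_log2fc optional genes x contrasts matrix (contrast
#'   columns `tissue_treatment`); defaults to draws from
#'   {-2, -1, 0, 1, 2}.
#' @param noise_sd biological/technical noise on the log2 scale
#'   (default 0.25).
#' @param seed integer seed.
#' @return list with `tpm` (genes x 8 samples), `design`, `planted`
#'   (the planted log2 fold-change matrix).
#' @export
make_expression <- function(truth, planted_log2fc = NULL, noise_sd = 0.25,
                            seed = 1L) {
  stopifnot(noise_sd >= 0)
  genes <- truth$id[truth$family %in% c("MPK", "MKK")]
  tissues <- c("leaf", "root")
  treatments <- c("control", "SA", "NaCl", "Peg")
  design <- expand.grid(treatment = treatments, tissue = tissues,
                        stringsAsFactors = FALSE)[, c(2L, 1L)]
  design$sample <- paste(design$tissue, design$treatment, sep = "_")
  contrasts <- paste(rep(tissues, each = 3L),
                     rep(setdiff(treatments, "control"), 2L), sep = "_")
  with_seed(seed, {
    if (is.null(planted_log2fc)) {
      planted_log2fc <- matrix(
        sample(c(-2, -1, 0, 1, 2), length(genes) * length(contrasts),
               replace = TRUE),
        nrow = length(genes), dimnames = list(genes, contrasts))
    }
    tpm <- matrix(0, nrow = length(genes), ncol = nrow(design),
                  dimnames = list(genes, design$sample))
    for (tis in tissues) {
      ctl <- rlnorm(length(genes), meanlog = 3, sdlog = 1)
      tpm[, paste0(tis, "_control")] <- ctl
      for (trt in setdiff(treatments, "control")) {
        contrast <- paste(tis, trt, sep = "_")
        noise <- rnorm(length(genes), 0, noise_sd)
        tpm[, contrast] <- ctl * 2^(planted_log2fc[, contrast] + noise)
      }
    }
    list(tpm = tpm, design = design[, c("sample", "tissue", "treatment")],
         planted = planted_log2fc)
  })
}

#' Generate a rate-asymmetric sequence triplet
#'
#' Draws a uniform ancestor, mutates two lineages at their own rates, and
#' returns the ancestor itself as the outgroup.
#'
#' @param n_sites alignment length.
#' @param rate_a,rate_b per-site substitution rates in \[0, 1).
#' @param seed integer seed.
#' @return named character vector `c(a, b, outgroup)`.
#' @export
make_triplet <- function(n_sites, rate_a, rate_b, seed = 1L) {
  stopifnot(rate_a >= 0, rate_a < 1, rate_b >= 0, rate_b < 1)
  with_seed(seed, {
    ancestor <- random_residues(n_sites)
    c(a = mutate_seq(ancestor, rate_a),
      b = mutate_seq(ancestor, rate_b),
      outgroup = ancestor)
  })
}
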