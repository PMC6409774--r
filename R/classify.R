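#' Clade-specific common-docking consensus sequences
#'
#' The four C-terminal common docking (CD) site consensi used to
#' corroborate clade assignments of MPK proteins (clade A is 16 residues,
#' B-D are 17).
#'
#' @return named list of consensus strings for clades A-D.
#' @export
docking_consensus <- function() {
  list(
    A = "KMLVFDPNKRIVEEAL",
    B = "KMLVFDPSKRISVTEAL",
    C = "SLCSWDPCKRPTAEEAL",
    D = "RLLAFDPKDRPTAEEAL"
  )
}

# MKK activation-segment serine/threonine spacing patterns per clade.
mkk_spacing_patterns <- function() {
  list(
    B = "SxxxxxTxxxxxT",
    C = "SxxxxxTxxxxxS",
    D = "SxxxxxSxxxxxT",
    A = "(S/T)xxxxx(S/T)"  # checked last: least specific
  )
}

#' Reference kinase set reader
#'
#' Reads a reference set as FASTA plus a TSV label table with columns
#' `id`, `family` (MPK/MKK), `clade` (A-D), `homolog_number`,
#' `species_code`. Every FASTA record must be labelled.
#'
#' @param fasta_path reference FASTA path.
#' @param labels_path label TSV path.
#' @return data frame with columns `id`, `sequence`, `family`, `clade`,
#'   `homolog_number`, `species_code`.
#' @export
read_reference_set <- function(fasta_path, labels_path) {
  prot <- read_fasta(fasta_path)
  labels <- read.delim(labels_path, stringsAsFactors = FALSE)
  needed <- c("id", "family", "clade", "homolog_number", "species_code")
  missing_cols <- setdiff(needed, names(labels))
  if (length(missing_cols) > 0L) {
    stop("read_reference_set: label table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  seqs <- proteome_vector(prot)
  unlabeled <- setdiff(names(seqs), labels$id)
  if (length(unlabeled) > 0L) {
    stop("read_reference_set: unlabeled reference(s): ",
         paste(unlabeled, collapse = ", "))
  }
  labels$sequence <- unname(seqs[labels$id])
  stopifnot(all(labels$homolog_number >= 1L))
  labels
}

#' Family call for a screened candidate
#'
#' Combines the HMM screening verdict with signature-motif confirmation:
#' a candidate is accepted when its HMM hit passes the e-value threshold,
#' all mandatory catalog motifs of the family are present (near-match and
#' relaxed-fallback rules per the catalog), and the kinase-domain motif
#' order holds. Missing optional motifs and relaxed matches are recorded
#' as flags, never silently dropped.
#'
#' @param protein a [protein_record()].
#' @param hit one row of a [search_proteome()] result for this protein.
#' @param family `"MPK"` or `"MKK"`.
#' @param near_match_budget mismatch budget forwarded to
#'   [evidence_profile()].
#' @return object of class `family_call`: list with `protein_id`, `family`,
#'   `hmm_evalue`, `evidence`, `accepted`, `flags`.
#' @export
call_family <- function(protein, hit, family, near_match_budget = 1L) {
  stopifnot(inherits(protein, "protein_record"))
  if (!identical(hit$protein_id, protein$id)) {
    stop("call_family: hit belongs to '", hit$protein_id,
         "', not '", protein$id, "'")
  }
  ev <- evidence_profile(protein, family,
                         near_match_budget = near_match_budget)
  flags <- ev$flags
  if (!ev$order_ok) flags <- c(flags, "order_violated")
  if (!hit$passes) flags <- c(flags, "hmm_threshold_failed")
  accepted <- isTRUE(hit$passes) && ev$mandatory_ok && ev$order_ok
  structure(
    list(protein_id = protein$id, family = if (accepted) family else "none",
         screened_family = family, hmm_evalue = hit$e_value,
         evidence = ev, accepted = accepted, flags = unique(flags)),
    class = "family_call"
  )
}

#' Assign a clade by best reference hit
#'
#' The clade of an accepted candidate is the clade of its best
#' Smith-Waterman-scoring reference of the same family (ties break by
#' reference table order). T-loop consistency records whether the observed
#' activation-loop type matches the clade convention (TEY for clades A/B,
#' TDY for C/D); discordant calls keep the top-hit clade and are flagged.
#' For MPKs the Hamming distance between the candidate's best C-terminal
#' docking window and the assigned clade's docking consensus is reported;
#' for MKKs the activation-segment spacing pattern is matched against the
#' clade-specific S/T spacing grammars.
#'
#' @param call an accepted [call_family()] result.
#' @param protein the corresponding [protein_record()].
#' @param references reference data frame (see [read_reference_set()]).
#' @param scheme a [scoring_scheme()].
#' @return object of class `clade_assignment`: list with `protein_id`,
#'   `clade`, `top_reference`, `homolog_number`, `tloop_consistent`,
#'   `docking_distance`, `mkk_spacing_clade`.
#' @export
assign_clade <- function(call, protein, references,
                         scheme = scoring_scheme()) {
  stopifnot(inherits(call, "family_call"))
  if (!call$accepted) stop("assign_clade: call was not accepted")
  fam <- call$screened_family
  refs <- references[references$family == fam, , drop = FALSE]
  if (nrow(refs) == 0L) {
    stop("assign_clade: no ", fam, " references available")
  }
  scores <- vapply(refs$sequence, function(s) {
    local_score(protein$sequence, s, scheme)
  }, numeric(1L))
  best <- which.max(scores)  # first maximum: first-in-table wins ties
  clade <- refs$clade[best]

  tloop_consistent <- TRUE
  if (fam == "MPK") {
    tt <- call$evidence$tloop_type
    tloop_consistent <- (tt == "TEY" && clade %in% c("A", "B")) ||
      (tt == "TDY" && clade %in% c("C", "D"))
  }

  docking_distance <- NA_integer_
  if (fam == "MPK") {
    docking_distance <- docking_window_distance(
      protein$sequence, docking_consensus()[[clade]]
    )
  }

  mkk_spacing_clade <- "none"
  if (fam == "MKK") {
    for (cl in names(mkk_spacing_patterns())) {
      if (nrow(scan_motif(protein$sequence,
                          mkk_spacing_patterns()[[cl]])) > 0L) {
        mkk_spacing_clade <- cl
        break
      }
    }
  }

  structure(
    list(protein_id = call$protein_id, family = fam, clade = clade,
         top_reference = refs$id[best],
         homolog_number = refs$homolog_number[best],
         top_score = scores[best],
         tloop_consistent = tloop_consistent,
         docking_distance = docking_distance,
         mkk_spacing_clade = mkk_spacing_clade),
    class = "clade_assignment"
  )
}

# Minimum Hamming distance between any window of the consensus width in
# the C-terminal region (last `tail_len` residues) and the consensus.
docking_window_distance <- function(sequence, consensus, tail_len = 60L) {
  cs <- seq_chars(consensus)
  w <- length(cs)
  chars <- seq_chars(sequence)
  n <- length(chars)
  from <- max(1L, n - tail_len + 1L)
  region <- chars[from:n]
  if (length(region) < w) return(NA_integer_)
  dists <- vapply(seq_len(length(region) - w + 1L), function(s) {
    sum(region[s:(s + w - 1L)] != cs)
  }, numeric(1L))
  as.integer(min(dists))
}

#' Orthology-based gene nomenclature
#'
#' Builds gene names as species prefix + family + homolog number, with a
#' hyphenated paralog index when two or more accepted genes share the same
#' (family, homolog number). Paralog indices follow chromosome natural
#' order, then start coordinate, so renaming is stable under input
#' permutation.
#'
#' @param assignments list of [assign_clade()] results.
#' @param gene_models named list of [gene_model()] objects keyed by
#'   protein/gene id (every assignment needs one).
#' @param species_prefix e.g. `"Ha"`.
#' @return data frame with columns `protein_id`, `name`, `species_prefix`,
#'   `family`, `clade`, `homolog_number`, `paralog_index` (NA for
#'   singletons), `chromosome`, `start`.
#' @export
assign_names <- function(assignments, gene_models, species_prefix) {
  stopifnot(length(assignments) > 0L)
  rows <- lapply(assignments, function(a) {
    gm <- gene_models[[a$protein_id]]
    if (is.null(gm)) {
      stop("assign_names: no gene model for ", a$protein_id)
    }
    data.frame(protein_id = a$protein_id, family = a$family,
               clade = a$clade, homolog_number = a$homolog_number,
               chromosome = gm$chromosome, start = gm$start,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$paralog_index <- NA_integer_
  key <- paste(tab$family, tab$homolog_number)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) >= 2L) {
      ord <- order(chromosome_rank(tab$chromosome[idx]),
                   tab$chromosome[idx], tab$start[idx])
      tab$paralog_index[idx[ord]] <- seq_along(idx)
    }
  }
  tab$species_prefix <- species_prefix
  tab$name <- paste0(species_prefix, tab$family, tab$homolog_number,
                     ifelse(is.na(tab$paralog_index), "",
                            paste0("-", tab$paralog_index)))
  tab[order(tab$family, tab$homolog_number,
            ifelse(is.na(tab$paralog_index), 0L, tab$paralog_index)),
      c("protein_id", "name", "species_prefix", "family", "clade",
        "homolog_number", "paralog_index", "chromosome", "start")]
}

# Natural order for chromosome strings: numeric suffix when present.
chromosome_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", chrom)))
  ifelse(is.na(num), Inf, num)
}

#' Parse a nomenclature gene name
#'
#' Inverse of the naming rule: splits `"HaMPK6-2"` into prefix, family,
#' homolog number and paralog index.
#'
#' @param name gene name string.
#' @return list with `species_prefix`, `family`, `homolog_number`,
#'   `paralog_index` (NA when absent).
#' @export
parse_gene_name <- function(name) {
  m <- regexec("^([A-Z][a-z]{1,3})(MPK|MKK)([0-9]+)(-([0-9]+))?$", name)
  parts <- regmatches(name, m)[[1L]]
  if (length(parts) == 0L) {
    stop("parse_gene_name: '", name, "' does not follow the nomenclature")
  }
  list(species_prefix = parts[2L], family = parts[3L],
       homolog_number = as.integer(parts[4L]),
       paralog_index = if (nzchar(parts[6L])) as.integer(parts[6L])
                       else NA_integer_)
}

#' Identify kinase families across a proteome
#'
#' Runs the full identification funnel for both families: builds one
#' profile HMM per family from the reference alignments, calibrates
#' e-values, screens the proteome, and gates every passing hit through
#' signature-motif confirmation. Proteins accepted by both family screens
#' are resolved in favor of the lower HMM e-value.
#'
#' @param proteome list of [protein_record()] objects.
#' @param references reference data frame (see [read_reference_set()]).
#' @param ref_msa named list of family alignments
#'   (`list(MPK = ..., MKK = ...)`, each a character vector).
#' @param evalue_max HMM screening threshold (default 0.01).
#' @param n_null calibration sample size (default 1000).
#' @param seed seed for the e-value calibration.
#' @param near_match_budget motif near-match budget (default 1).
#' @return data frame with one row per accepted protein: `protein_id`,
#'   `family`, `e_value`, `bit_score`, `tloop_type`, `flags`; the full
#'   per-family call lists are attached as attribute `"calls"`.
#' @export
identify_families <- function(proteome, references, ref_msa,
                              evalue_max = 0.01, n_null = 1000L,
                              seed = 1L, near_match_budget = 1L) {
  by_id <- setNames(proteome, vapply(proteome, `[[`, character(1L), "id"))
  calls <- list()
  for (fam in c("MPK", "MKK")) {
    hmm <- build_profile(ref_msa[[fam]])
    cal <- calibrate(hmm, n_null = n_null, seed = seed)
    hits <- search_proteome(hmm, proteome, cal, evalue_max = evalue_max)
    pass <- hits[hits$passes, , drop = FALSE]
    calls[[fam]] <- lapply(seq_len(nrow(pass)), function(i) {
      call_family(by_id[[pass$protein_id[i]]], pass[i, ], fam,
                  near_match_budget = near_match_budget)
    })
  }
  acc <- list()
  for (fam in c("MPK", "MKK")) {
    for (cl in calls[[fam]]) {
      if (!cl$accepted) next
      prev <- acc[[cl$protein_id]]
      if (is.null(prev) || cl$hmm_evalue < prev$hmm_evalue) {
        acc[[cl$protein_id]] <- cl
      }
    }
  }
  if (length(acc) == 0L) {
    out <- data.frame(protein_id = character(0L), family = character(0L),
                      e_value = numeric(0L), tloop_type = character(0L),
                      flags = character(0L), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(acc, function(cl) {
      data.frame(protein_id = cl$protein_id, family = cl$screened_family,
                 e_value = cl$hmm_evalue,
                 tloop_type = cl$evidence$tloop_type,
                 flags = paste(cl$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  attr(out, "calls") <- acc
  out
}
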