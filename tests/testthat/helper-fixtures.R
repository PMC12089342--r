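## Shared fixtures: small simulated transcriptomes, hand-built transcripts
## and footprint tables, and independent brute-force oracles.

library(data.table)

small_txome <- function(n_genes = 30, seed = 1, length_range = c(300, 900),
                        ...) {
  sim_transcriptome(n_genes, length_range, seed = seed, ...)
}

## simulate and assign in one step
sim_assigned <- function(txome, profile = stalling_profile(), n_reads = 5e4,
                         seed = 1, jitter_prob = 0, ...) {
  fp <- sim_footprints(txome, profile,
                       sim_config(n_reads, seed = seed,
                                  jitter_prob = jitter_prob, ...))
  res <- assign_rpfs(as_alignments(fp), annotation_of(txome))
  list(fp = fp, rpfs = res$rpfs, report = res$report)
}

## one condition/control pair and its codon shifts at the A-site offset
pair_shifts <- function(txome, dwell = NULL, n_reads = 5e4, seed = 1,
                        min_gene_count = 100) {
  cs <- cds_sequences(txome)
  cond <- sim_assigned(txome, stalling_profile(dwell), n_reads, seed)
  ctrl <- sim_assigned(txome, stalling_profile(), n_reads, seed + 1)
  list(cond = cond$rpfs, ctrl = ctrl$rpfs, cds_seqs = cs,
       shifts = compute_shifts(count_codons(cond$rpfs, cs),
                               count_codons(ctrl$rpfs, cs),
                               min_gene_count = min_gene_count))
}

## build a CDS from internal codons (ATG ... TAA appended)
cds_from_codons <- function(codons) {
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

## hand-built transcriptome from explicit CDS strings
manual_txome <- function(cds_strings, utr5 = 30L, utr3 = 30L,
                         weights = rep(1, length(cds_strings))) {
  ids <- sprintf("m%02d", seq_along(cds_strings))
  tx <- paste0(strrep("A", utr5), cds_strings, strrep("A", utr3))
  transcripts <- data.table(
    gene_id = ids, transcript_id = paste0(ids, ".t1"),
    chrom = paste0(ids, ".t1"), tx_sequence = tx, tx_length = nchar(tx),
    cds_start = as.integer(utr5), cds_length = nchar(cds_strings),
    expression_weight = weights)
  structure(list(transcripts = transcripts, utr5_length = utr5,
                 utr3_length = utr3, gc_fraction = NA_real_,
                 seed = NA_integer_),
            class = "sc_txome")
}

## hand-built assigned-footprint table
manual_rpfs <- function(gene_id, chrom, cds_start, cds_relative_5p,
                        length = 30L) {
  n <- length(cds_relative_5p)
  data.table(read_id = sprintf("r%05d", seq_len(n)), gene_id = gene_id,
             transcript_id = chrom, chrom = chrom,
             tx_pos0 = as.integer(cds_start + cds_relative_5p),
             cds_relative_5p = as.integer(cds_relative_5p),
             length = rep_len(as.integer(length), n),
             frame = as.integer(((cds_relative_5p %% 3) + 3) %% 3))
}

## hand-built alignment table (as load_alignments would return)
manual_alignments <- function(chrom, pos0, length, strand = "+",
                              secondary = FALSE, unmapped = FALSE,
                              spliced = FALSE) {
  n <- length(pos0)
  data.table(read_id = sprintf("a%05d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             pos0 = as.integer(pos0),
             ref_width = rep_len(as.integer(length), n),
             length = rep_len(as.integer(length), n),
             spliced = rep_len(spliced, n), secondary = rep_len(secondary, n),
             unmapped = rep_len(unmapped, n))
}

## ---- independent brute-force oracles -------------------------------------

## per-read assignment, straight from the filtering rules
brute_assign <- function(aln, ann, min_length = 27L, overhang = 15L) {
  retained <- list()
  counts <- c(n_unusable = 0L, n_short = 0L, n_outside_cds = 0L,
              n_ambiguous_gene = 0L, n_ambiguous_frame = 0L)
  for (i in seq_len(nrow(aln))) {
    r <- aln[i]
    if (r$secondary || r$unmapped || r$spliced) {
      counts["n_unusable"] <- counts["n_unusable"] + 1L
      next
    }
    if (r$length < min_length) {
      counts["n_short"] <- counts["n_short"] + 1L
      next
    }
    fivep <- if (r$strand == "+") r$pos0 else r$pos0 + r$ref_width - 1L
    hits <- list()
    for (j in seq_len(nrow(ann))) {
      a <- ann[j]
      if (a$chrom != r$chrom || a$strand != r$strand) next
      rel <- if (a$strand == "+") fivep - a$cds_start
             else a$cds_start + a$cds_length - 1L - fivep
      if (rel >= -overhang && rel <= a$cds_length - min_length)
        hits[[length(hits) + 1L]] <-
          list(gene = a$gene_id, tx = a$transcript_id, rel = rel,
               cds_length = a$cds_length)
    }
    if (length(hits) == 0L) {
      counts["n_outside_cds"] <- counts["n_outside_cds"] + 1L
    } else if (length(unique(vapply(hits, `[[`, "", "gene"))) > 1L) {
      counts["n_ambiguous_gene"] <- counts["n_ambiguous_gene"] + 1L
    } else if (length(unique(vapply(hits, function(h) h$rel %% 3L,
                                    0L))) > 1L) {
      counts["n_ambiguous_frame"] <- counts["n_ambiguous_frame"] + 1L
    } else {
      lens <- vapply(hits, `[[`, 0L, "cds_length")
      txs <- vapply(hits, `[[`, "", "tx")
      best <- order(-lens, txs)[1L]
      retained[[length(retained) + 1L]] <-
        data.table(read_id = r$read_id, gene_id = hits[[best]]$gene,
                   cds_relative_5p = hits[[best]]$rel)
    }
  }
  list(rpfs = if (length(retained)) rbindlist(retained) else
         data.table(read_id = character(0), gene_id = character(0),
                    cds_relative_5p = integer(0)),
       counts = counts)
}

## per-read codon counting
brute_count_codons <- function(rpfs, cds_seqs, offset = 15L,
                               in_frame_only = TRUE) {
  acc <- list()
  for (i in seq_len(nrow(rpfs))) {
    r <- rpfs[i]
    if (r$length < offset + 3L) next
    p <- r$cds_relative_5p + offset
    if (p < 0L || p + 3L > nchar(cds_seqs[[r$gene_id]])) next
    if (in_frame_only && p %% 3L != 0L) next
    cod <- substr(cds_seqs[[r$gene_id]], p + 1L, p + 3L)
    if (in_frame_only && cod %in% stop_codons()) next
    key <- paste(r$gene_id, cod)
    acc[[key]] <- (acc[[key]] %||% 0L) + 1L
  }
  out <- data.table(pair = names(acc), count = unlist(acc, use.names = FALSE))
  if (nrow(out) == 0L)
    return(data.table(gene_id = character(0), codon = character(0),
                      count = integer(0)))
  out[, c("gene_id", "codon") := tstrsplit(pair, " ")]
  setorder(out, gene_id, codon)
  out[, .(gene_id, codon, count)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## every in-frame occurrence of `codon` whose full window fits the transcript
brute_regions <- function(ann, ref_seqs, codon, flank = 30L) {
  found <- list()
  for (j in seq_len(nrow(ann))) {
    a <- ann[j]
    seqlen <- nchar(ref_seqs[[a$chrom]])
    for (p in seq(0L, a$cds_length - 3L, by = 3L)) {
      cod <- substr(ref_seqs[[a$chrom]], a$cds_start + p + 1L,
                    a$cds_start + p + 3L)
      if (cod != codon) next
      center <- a$cds_start + p
      if (center - flank >= 0L && center + flank <= seqlen - 1L)
        found[[length(found) + 1L]] <-
          data.table(chrom = a$chrom, window_start = center - flank)
    }
  }
  if (length(found) == 0L)
    return(data.table(chrom = character(0), window_start = integer(0)))
  unique(rbindlist(found))[order(chrom, window_start)]
}
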