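## Codon occupancy counting and the subsequence-shift statistic:
## per-gene codon frequencies at a fixed distance from the footprint 5' end,
## averaged over well-covered genes and compared between samples as
## (condition - control) / control.

#' Count codons at a fixed distance from footprint 5' ends
#'
#' For each assigned footprint, reads the nucleotide triplet starting
#' `offset` nt downstream of its 5' end (offset 15 targets the A site,
#' 12 the P site) and tallies counts per gene and codon. With
#' `in_frame_only = TRUE` (the default, used for the shift statistic) only
#' triplets that are in frame with the CDS are counted and stop codons are
#' dropped; with `FALSE` every triplet at that distance is counted (used to
#' build out-of-frame backgrounds).
#'
#' @param rpfs Assigned footprints from [assign_rpfs()].
#' @param cds_seqs Named character vector of CDS sequences keyed by
#'   `gene_id` (see [cds_sequences()]).
#' @param offset Distance in nt from the 5' end to the triplet (default 15).
#' @param in_frame_only Count only in-frame triplets and drop stop codons.
#' @return A `codon_freq_table`: list with `offset`, `in_frame_only`,
#'   `counts` (`data.table` `gene_id`, `codon`, `count`) and `gene_totals`
#'   (`data.table` `gene_id`, `total`). Per gene, codon counts sum to the
#'   gene total.
#' @export
count_codons <- function(rpfs, cds_seqs, offset = 15L, in_frame_only = TRUE) {
  stopifnot(offset >= 0)
  missing_genes <- setdiff(unique(rpfs$gene_id), names(cds_seqs))
  if (length(missing_genes) > 0L)
    stop("missing CDS sequence for gene(s): ",
         paste(head(missing_genes, 5L), collapse = ", "))
  d <- rpfs[, .(gene_id, cds_relative_5p, length)]
  d[, pos := cds_relative_5p + as.integer(offset)]
  cl <- nchar(cds_seqs)
  d <- d[length >= offset + 3L & pos >= 0L & pos + 3L <= cl[gene_id]]
  if (in_frame_only) d <- d[pos %% 3L == 0L]
  d[, codon := substr(cds_seqs[gene_id], pos + 1L, pos + 3L)]
  if (in_frame_only) d <- d[!(codon %in% stop_codons())]
  counts <- d[, .(count = .N), by = .(gene_id, codon)]
  setorder(counts, gene_id, codon)
  totals <- counts[, .(total = sum(count)), by = gene_id]
  structure(list(offset = as.integer(offset), in_frame_only = in_frame_only,
                 counts = counts[], gene_totals = totals[]),
            class = "codon_freq_table")
}

#' @export
print.codon_freq_table <- function(x, ...) {
  cat(sprintf("Codon frequency table: offset %d, %d genes, %d counted reads%s\n",
              x$offset, nrow(x$gene_totals), sum(x$gene_totals$total),
              if (x$in_frame_only) " (in-frame)" else " (all triplets)"))
  invisible(x)
}

#' Subsequence shift between condition and control
#'
#' Restricts to genes with at least `min_gene_count` counted footprints in
#' BOTH samples, normalizes each gene's codon counts to frequencies, averages
#' frequencies across genes (unweighted, one vote per gene, unless
#' `weighted = TRUE`), and reports the relative shift
#' `(condition - control) / control` per codon. Codons never observed in
#' either sample are omitted; codons with zero mean control frequency are
#' reported with an undefined (NA) shift and flagged.
#'
#' @param table_condition,table_control `codon_freq_table`s at the same
#'   offset.
#' @param min_gene_count Per-gene minimum count required in both samples
#'   (default 100).
#' @param weighted If `TRUE`, average gene frequencies weighted by gene
#'   totals (pooled counts) instead of unweighted.
#' @return `data.table` with one row per observed codon: `codon`,
#'   `amino_acid`, `shift`, `mean_freq_condition`, `mean_freq_control`,
#'   `n_genes_used`, `undefined`.
#' @export
compute_shifts <- function(table_condition, table_control,
                           min_gene_count = 100L, weighted = FALSE) {
  stopifnot(inherits(table_condition, "codon_freq_table"),
            inherits(table_control, "codon_freq_table"))
  if (table_condition$offset != table_control$offset)
    stop("tables computed at different offsets (",
         table_condition$offset, " vs ", table_control$offset, ")")
  g1 <- table_condition$gene_totals[total >= min_gene_count, gene_id]
  g2 <- table_control$gene_totals[total >= min_gene_count, gene_id]
  genes <- intersect(g1, g2)
  if (length(genes) == 0L)
    stop("no gene reaches min_gene_count = ", min_gene_count,
         " in both samples; lower the threshold")
  cc1 <- merge(table_condition$counts[gene_id %chin% genes],
               table_condition$gene_totals[gene_id %chin% genes],
               by = "gene_id")
  cc2 <- merge(table_control$counts[gene_id %chin% genes],
               table_control$gene_totals[gene_id %chin% genes],
               by = "gene_id")
  n_g <- length(genes)
  avg <- function(cc) {
    if (weighted) {
      tot_all <- sum(cc$total[!duplicated(cc$gene_id)])
      cc[, .(mean_freq = sum(count) / tot_all), by = codon]
    } else {
      ## absent (gene, codon) pairs contribute frequency 0, so divide the
      ## summed frequencies by the number of genes, not observed rows
      cc[, .(mean_freq = sum(count / total) / n_g), by = codon]
    }
  }
  m1 <- avg(cc1)
  m2 <- avg(cc2)
  out <- merge(m1, m2, by = "codon", all = TRUE,
               suffixes = c("_condition", "_control"))
  out[is.na(mean_freq_condition), mean_freq_condition := 0]
  out[is.na(mean_freq_control), mean_freq_control := 0]
  out[, undefined := mean_freq_control == 0]
  out[, shift := fifelse(undefined, NA_real_,
                         (mean_freq_condition - mean_freq_control) /
                           mean_freq_control)]
  out[, amino_acid := codon_to_aa(codon)]
  out[, n_genes_used := n_g]
  setcolorder(out, c("codon", "amino_acid", "shift", "mean_freq_condition",
                     "mean_freq_control", "n_genes_used", "undefined"))
  setorder(out, codon)
  out[]
}
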