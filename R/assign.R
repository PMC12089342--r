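## Footprint-to-gene assignment under the validity filters used for
## codon-occupancy analysis, plus periodicity / metagene QC.

#' Assign footprints to genes and reading frames
#'
#' Applies the validity filters used for codon-level analysis: footprints
#' shorter than `min_length` nt are removed; a footprint is retained only if
#' its 5' end lies within `[CDS_start - overhang_5p, CDS_end - min_length]`
#' of a transcript on the matching strand (the 5' overhang admits reads whose
#' A site is in the CDS while their 5' end is slightly upstream). Footprints
#' compatible with CDS of more than one gene are rejected as gene-ambiguous;
#' footprints compatible with more than one reading frame across a single
#' gene's transcripts are rejected as frame-ambiguous. Secondary, unmapped
#' and spliced alignments are never assigned.
#'
#' @param alignments Alignment `data.table` from [load_alignments()] or
#'   [as_alignments()].
#' @param annotation Annotation `data.table` from [load_annotation()] or
#'   [annotation_of()].
#' @param min_length Minimum footprint length in nt (default 27, i.e. reads
#'   longer than 26 nt).
#' @param overhang_5p Permitted 5' overhang upstream of the CDS start in nt
#'   (default 15).
#' @return A list with elements `rpfs` (a `data.table`: `read_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `tx_pos0` (5'-end position on the reference),
#'   `cds_relative_5p`, `length`, `frame`) and `report` (a `filter_report`
#'   list whose counts sum to the input count).
#' @export
assign_rpfs <- function(alignments, annotation, min_length = 27L,
                        overhang_5p = 15L) {
  stopifnot(min_length >= 1, overhang_5p >= 0)
  aln <- as.data.table(alignments)
  n_input <- nrow(aln)
  usable <- aln[!(secondary | unmapped | spliced)]
  n_unusable <- n_input - nrow(usable)
  n_short <- usable[, sum(length < min_length)]
  ok <- usable[length >= min_length]
  empty <- data.table(read_id = character(0), gene_id = character(0),
                      transcript_id = character(0), chrom = character(0),
                      tx_pos0 = integer(0), cds_relative_5p = integer(0),
                      length = integer(0), frame = integer(0))
  report <- function(n_out, n_ag, n_af, n_ret) {
    structure(list(n_input = n_input, n_unusable = n_unusable,
                   n_short = n_short, n_outside_cds = n_out,
                   n_ambiguous_gene = n_ag, n_ambiguous_frame = n_af,
                   n_retained = n_ret),
              class = "filter_report")
  }
  if (nrow(ok) == 0L)
    return(list(rpfs = empty, report = report(0L, 0L, 0L, 0L)))
  ok[, fivep0 := fifelse(strand == "+", pos0, pos0 + ref_width - 1L)]
  ok[, rid := .I]
  cand <- merge(ok, annotation, by = c("chrom", "strand"),
                allow.cartesian = TRUE, suffixes = c("", ".ann"))
  if (nrow(cand) > 0L) {
    cand[, rel := fifelse(strand == "+", fivep0 - cds_start,
                          cds_start + cds_length - 1L - fivep0)]
    cand <- cand[rel >= -overhang_5p & rel <= cds_length - min_length]
  }
  if (nrow(cand) == 0L)
    return(list(rpfs = empty, report = report(nrow(ok), 0L, 0L, 0L)))
  cand[, nmatch := .N, by = rid]
  n_outside <- nrow(ok) - uniqueN(cand$rid)
  single <- cand[nmatch == 1L]
  multi <- cand[nmatch > 1L]
  n_amb_gene <- 0L
  n_amb_frame <- 0L
  if (nrow(multi) > 0L) {
    g <- multi[, .(ngene = uniqueN(gene_id), nfrm = uniqueN(rel %% 3L)),
               by = rid]
    n_amb_gene <- g[, sum(ngene > 1L)]
    n_amb_frame <- g[, sum(ngene == 1L & nfrm > 1L)]
    keep_ids <- g[ngene == 1L & nfrm == 1L, rid]
    multi <- multi[rid %in% keep_ids][order(rid, -cds_length, transcript_id)]
    multi <- multi[!duplicated(rid)]
  }
  rep_tx <- rbind(single, multi)
  rpfs <- rep_tx[, .(read_id, gene_id, transcript_id, chrom,
                     tx_pos0 = fivep0, cds_relative_5p = rel, length,
                     frame = rel %% 3L)]
  setorder(rpfs, chrom, tx_pos0, read_id)
  list(rpfs = rpfs,
       report = report(n_outside, n_amb_gene, n_amb_frame, nrow(rpfs)))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Footprint filter report:\n")
  for (k in names(x)) cat(sprintf("  %-18s %d\n", k, x[[k]]))
  invisible(x)
}

#' Write a filter report as JSON
#' @param report A `filter_report` from [assign_rpfs()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Periodicity and start-codon metagene QC
#'
#' Elongating ribosomes leave footprints whose 5' ends fall predominantly in
#' one reading-frame phase (3-nt periodicity) and pile up near the start
#' codon. This computes per-length frame fractions and a metagene vector of
#' summed 5'-end counts at each offset in `[-30, +60]` nt around CDS starts.
#'
#' @param rpfs Assigned footprints from [assign_rpfs()].
#' @return A list: `frame_fractions` (`data.table` with `length`, `frame`,
#'   `n`, `fraction`; fractions sum to 1 within each length),
#'   `overall_frame_fractions` (length-pooled), `dominant_frame`, and
#'   `metagene` (`data.table` with `offset` in -30..60 and `count`).
#' @export
periodicity_qc <- function(rpfs) {
  if (nrow(rpfs) == 0L) stop("no retained footprints")
  ff <- rpfs[, .N, by = .(length, frame)]
  ff[, fraction := N / sum(N), by = length]
  setnames(ff, "N", "n")
  setorder(ff, length, frame)
  ov <- rpfs[, .N, by = frame]
  ov[, fraction := N / sum(N)]
  setnames(ov, "N", "n")
  setorder(ov, frame)
  offs <- -30:60
  cnt <- rpfs[cds_relative_5p >= -30L & cds_relative_5p <= 60L,
              .N, by = .(offset = cds_relative_5p)]
  metagene <- data.table(offset = offs)
  metagene <- merge(metagene, cnt, by = "offset", all.x = TRUE)
  metagene[is.na(N), N := 0L]
  setnames(metagene, "N", "count")
  list(frame_fractions = ff[], overall_frame_fractions = ov[],
       dominant_frame = ov[which.max(fraction), frame],
       metagene = metagene[])
}
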