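## Annotation and alignment input. GTF/GFF parsing goes through rtracklayer,
## BAM through Rsamtools; SAM text input is converted with Rsamtools::asBam.

#' Load CDS annotation from a GTF/GFF file
#'
#' Keeps `CDS` features, one annotation row per transcript. Transcripts whose
#' CDS length is not a multiple of 3, or whose CDS records are not contiguous
#' on one reference sequence, are dropped with a warning.
#'
#' @param gtf_path Path to a GTF/GFF file with CDS features carrying
#'   `gene_id` and `transcript_id` attributes.
#' @return Annotation `data.table` with columns `chrom`, `strand`, `gene_id`,
#'   `transcript_id`, `cds_start` (0-based), `cds_length`.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("annotation file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gtf_path)
  d <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id
  )
  ann <- d[, {
    span <- max(end) - min(start) + 1L
    len <- sum(end - start + 1L)
    list(chrom = chrom[1L], strand = strand[1L],
         gene_id = gene_id[1L],
         cds_start = min(start) - 1L, cds_length = len,
         contiguous = span == len)
  }, by = transcript_id]
  bad_gap <- ann[contiguous == FALSE]
  if (nrow(bad_gap) > 0L)
    warning("dropping ", nrow(bad_gap),
            " transcript(s) with non-contiguous CDS records: ",
            paste(head(bad_gap$transcript_id, 5L), collapse = ", "))
  ann <- ann[contiguous == TRUE]
  bad3 <- ann[cds_length %% 3L != 0L]
  if (nrow(bad3) > 0L)
    warning("dropping ", nrow(bad3),
            " transcript(s) with CDS length not a multiple of 3: ",
            paste(head(bad3$transcript_id, 5L), collapse = ", "))
  ann <- ann[cds_length %% 3L == 0L]
  ann[, contiguous := NULL]
  setcolorder(ann, c("chrom", "strand", "gene_id", "transcript_id",
                     "cds_start", "cds_length"))
  ann[]
}

## reference width consumed by a CIGAR string (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    op <- substring(parts, nchar(parts), nchar(parts))
    n <- as.integer(substring(parts, 1L, nchar(parts) - 1L))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

## aligned query width (M/I/=/X), i.e. footprint length after clipping
cigar_query_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    op <- substring(parts, nchar(parts), nchar(parts))
    n <- as.integer(substring(parts, 1L, nchar(parts) - 1L))
    sum(n[op %in% c("M", "I", "=", "X")])
  }, integer(1))
}

#' Load footprint alignments from SAM or BAM
#'
#' SAM input is converted to BAM on the fly. The 5' end is taken after soft
#' clipping (the first aligned base on the 5' side); footprint length is the
#' aligned query width. Secondary/supplementary and unmapped records are
#' flagged, and spliced (`N`-containing) alignments marked for rejection
#' downstream.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Alignment `data.table`: `read_id`, `chrom`, `strand`, `pos0`
#'   (0-based leftmost aligned position), `ref_width`, `length`, `spliced`,
#'   `secondary`, `unmapped`.
#' @export
load_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(b$pos)
  cig <- b$cigar[keep]
  data.table(
    read_id = b$qname[keep],
    chrom = as.character(b$rname[keep]),
    strand = as.character(b$strand[keep]),
    pos0 = b$pos[keep] - 1L,
    ref_width = cigar_ref_width(cig),
    length = cigar_query_width(cig),
    spliced = grepl("N", cig, fixed = TRUE),
    secondary = bitwAnd(b$flag[keep], 0x900L) != 0L,
    unmapped = bitwAnd(b$flag[keep], 0x4L) != 0L
  )
}

#' Write an assigned-footprint table as TSV
#' @param rpfs `data.table` of assigned footprints (from [assign_rpfs()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rpfs <- function(rpfs, path) {
  fwrite(rpfs, path, sep = "\t")
  invisible(path)
}

#' Read an assigned-footprint table written by [write_rpfs()]
#' @param path TSV path.
#' @return `data.table` of assigned footprints.
#' @export
read_rpfs <- function(path) {
  fread(path, sep = "\t")
}
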