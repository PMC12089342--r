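## Normalized, smoothed 5'-end density over 61-nt windows centred on
## occurrences of a query codon, and the between-sample density shift.

#' Extract 61-nt regions around in-frame occurrences of a codon
#'
#' One region per in-frame occurrence of `codon` in an annotated CDS whose
#' window (30 nt upstream through 30 nt downstream of the codon's first
#' nucleotide) lies entirely inside the reference sequence. Occurrences too
#' close to transcript ends are excluded. Regions from overlapping
#' transcripts are all retained, but regions with identical reference
#' coordinates are collapsed to one.
#'
#' @param annotation Annotation `data.table` ([load_annotation()]).
#' @param ref_seqs Named character vector of reference (transcript)
#'   sequences keyed by `chrom` (see [tx_sequences()]).
#' @param codon Sense codon (uppercase DNA triplet).
#' @param flank Flank size in nt on each side of the codon's first
#'   nucleotide (default 30, i.e. 61-nt windows).
#' @return `data.table` with columns `region_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `codon`, `window_start` (0-based),
#'   `center` (0-based position of the codon's first nucleotide).
#' @export
extract_codon_regions <- function(annotation, ref_seqs, codon, flank = 30L) {
  stopifnot(codon %in% sense_codons())
  width <- 2L * flank + 1L
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i]
    if (!a$chrom %in% names(ref_seqs))
      stop("missing reference sequence for ", a$chrom)
    seqlen <- nchar(ref_seqs[[a$chrom]])
    cds <- substr(ref_seqs[[a$chrom]], a$cds_start + 1L,
                  a$cds_start + a$cds_length)
    codons <- codon_split(cds)
    hits <- which(codons == codon)
    if (length(hits) == 0L) next
    center <- a$cds_start + 3L * (hits - 1L)
    ws <- center - flank
    keep <- ws >= 0L & (center + flank) <= seqlen - 1L
    if (!any(keep)) next
    out[[i]] <- data.table(gene_id = a$gene_id,
                           transcript_id = a$transcript_id,
                           chrom = a$chrom, codon = codon,
                           window_start = ws[keep], center = center[keep])
  }
  regions <- rbindlist(out)
  if (nrow(regions) == 0L) return(
    data.table(region_id = character(0), gene_id = character(0),
               transcript_id = character(0), chrom = character(0),
               codon = character(0), window_start = integer(0),
               center = integer(0)))
  ## collapse regions with identical reference coordinates
  regions <- regions[order(chrom, window_start, transcript_id)]
  regions <- unique(regions, by = c("chrom", "window_start"))
  regions[, region_id := sprintf("%s:%d:%s", chrom, window_start, codon)]
  setcolorder(regions, c("region_id", "gene_id", "transcript_id", "chrom",
                         "codon", "window_start", "center"))
  regions[]
}

## width-3 rectangular smoothing (height 1/3) with reflection padding at the
## window edges; reflection conserves the window mean exactly
smooth_rect3 <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  (c(x[1L], x[-n]) + x + c(x[-1L], x[n])) / 3
}

## raw 5'-end counts per region: matrix n_regions x width
region_counts <- function(rpfs, regions, width) {
  m <- matrix(0L, nrow = nrow(regions), ncol = width,
              dimnames = list(regions$region_id, NULL))
  byc <- split(seq_len(nrow(regions)), regions$chrom)
  cnt <- rpfs[, .N, by = .(chrom, tx_pos0)]
  for (ch in names(byc)) {
    sub <- cnt[chrom == ch]
    if (nrow(sub) == 0L) next
    for (ri in byc[[ch]]) {
      ws <- regions$window_start[ri]
      inw <- sub[tx_pos0 >= ws & tx_pos0 < ws + width]
      if (nrow(inw) > 0L)
        m[ri, inw$tx_pos0 - ws + 1L] <- inw$N
    }
  }
  m
}

#' Profile footprint density over codon regions in two samples
#'
#' Counts footprint 5' ends at each of the 61 window positions, jointly
#' filters to regions with at least `min_region_count` counts in BOTH
#' samples, normalizes each surviving region to mean density 1 (counts
#' divided by total/width), and smooths with a rectangular kernel of width 3
#' and height 1/3 (reflection at the window edges, which preserves the mean).
#' If fewer than `min_windows_common` regions survive while more candidates
#' exist, the count threshold is lowered stepwise (50, 40, 30, 20, 10 by
#' default) until enough regions survive or the schedule is exhausted.
#'
#' @param rpfs_condition,rpfs_control Assigned footprints of the two samples.
#' @param regions Regions from [extract_codon_regions()] (one codon).
#' @param min_region_count Joint per-region minimum count (default 50).
#' @param min_windows_common Target number of surviving regions for common
#'   codons before the threshold is lowered (default 1000).
#' @param threshold_schedule Decreasing thresholds tried when too few
#'   regions survive.
#' @return A `codon_profiles` list: `codon`, `threshold_used`, `region_id`,
#'   and per-sample `condition` / `control` lists each holding
#'   `raw_counts`, `normalized` and `smoothed` matrices (regions x 61) whose
#'   rows all have mean 1 after normalization.
#' @export
profile_regions <- function(rpfs_condition, rpfs_control, regions,
                            min_region_count = 50L,
                            min_windows_common = 1000L,
                            threshold_schedule = c(50L, 40L, 30L, 20L, 10L)) {
  if (nrow(regions) == 0L) stop("no candidate regions supplied")
  codon <- regions$codon[1L]
  width <- 2L * (regions$center[1L] - regions$window_start[1L]) + 1L
  m1 <- region_counts(rpfs_condition, regions, width)
  m2 <- region_counts(rpfs_control, regions, width)
  tot1 <- rowSums(m1)
  tot2 <- rowSums(m2)
  sched <- sort(unique(c(as.integer(min_region_count),
                         threshold_schedule[threshold_schedule <
                                              min_region_count])),
                decreasing = TRUE)
  keep <- tot1 >= sched[1L] & tot2 >= sched[1L]
  threshold_used <- sched[1L]
  for (thr in sched[-1L]) {
    if (sum(keep) >= min_windows_common || sum(keep) == nrow(regions)) break
    keep <- tot1 >= thr & tot2 >= thr
    threshold_used <- thr
  }
  if (!any(keep))
    stop("no region for codon ", codon, " reaches count ", threshold_used,
         " in both samples")
  prep <- function(m) {
    m <- m[keep, , drop = FALSE]
    norm <- m / (rowSums(m) / width)
    smooth <- t(apply(norm, 1L, smooth_rect3))
    list(raw_counts = m, normalized = norm, smoothed = smooth)
  }
  structure(list(codon = codon, threshold_used = threshold_used,
                 region_id = regions$region_id[keep],
                 condition = prep(m1), control = prep(m2)),
            class = "codon_profiles")
}

#' @export
print.codon_profiles <- function(x, ...) {
  cat(sprintf("Codon-region profiles: %s, %d regions (threshold %d)\n",
              x$codon, length(x$region_id), x$threshold_used))
  invisible(x)
}

#' Density shift between two profiled samples
#'
#' Averages the smoothed densities across regions position-wise in each
#' sample and reports the elementwise difference (condition minus control).
#'
#' @param profiles A `codon_profiles` object from [profile_regions()], or
#'   the condition member of one when `profiles_control` is also given.
#' @param profiles_control Optional control profile set (a list with
#'   `region_id` and `smoothed`); region sets must match exactly.
#' @return A list: `codon`, `mean_condition`, `mean_control`,
#'   `density_shift` (61-vectors), `n_regions_used`.
#' @export
density_shift <- function(profiles, profiles_control = NULL) {
  if (is.null(profiles_control)) {
    stopifnot(inherits(profiles, "codon_profiles"))
    cond <- profiles$condition
    ctrl <- profiles$control
    ids_cond <- ids_ctrl <- profiles$region_id
    codon <- profiles$codon
  } else {
    cond <- profiles$condition %||% profiles
    ctrl <- profiles_control$control %||% profiles_control
    ids_cond <- profiles$region_id
    ids_ctrl <- profiles_control$region_id
    codon <- profiles$codon %||% NA_character_
    if (!identical(ids_cond, ids_ctrl))
      stop("condition and control profiles cover different region sets")
  }
  mc <- colMeans(cond$smoothed)
  mk <- colMeans(ctrl$smoothed)
  list(codon = codon, mean_condition = mc, mean_control = mk,
       density_shift = mc - mk, n_regions_used = length(ids_cond))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
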