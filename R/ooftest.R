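## Significance of a codon's subsequence shift against a background of
## shifts computed from nucleotide triplets read +/- 1 nt out of frame.

#' Overlap-exclusion patterns for an out-of-frame background
#'
#' Triplets read 1 nt off the target position physically overlap the target
#' codon by two bases and would carry its signal into the background; they
#' are excluded. At the -1 offset the excluded pattern has the target's first
#' two bases as its last two (for GCA: NGC); at the +1 offset the target's
#' last two bases lead (for GCA: CAN). `N` matches any base.
#'
#' @param target_codon Sense codon under test.
#' @return `data.table` with columns `offset_side` (-1, +1) and `pattern`.
#' @export
#' @examples
#' exclusion_patterns("GCA")
exclusion_patterns <- function(target_codon) {
  stopifnot(target_codon %in% sense_codons())
  data.table(
    offset_side = c(-1L, 1L),
    pattern = c(paste0("N", substr(target_codon, 1L, 2L)),
                paste0(substr(target_codon, 2L, 3L), "N"))
  )
}

## does each triplet match an N-wildcard pattern?
matches_pattern <- function(triplets, pattern) {
  bases <- strsplit(pattern, "")[[1L]]
  hit <- rep(TRUE, length(triplets))
  for (i in 1:3) {
    if (bases[i] != "N")
      hit <- hit & substr(triplets, i, i) == bases[i]
  }
  hit
}

#' Build an out-of-frame background distribution for a codon
#'
#' Computes subsequence shifts for every nucleotide triplet read at
#' `target_offset - 1` and `target_offset + 1` nt from footprint 5' ends,
#' using the same gene-normalization machinery as the in-frame shift, then
#' removes triplets matching the overlap-exclusion patterns. Only footprints
#' whose 5' end is in frame with the target offset contribute, so the
#' background positions are genuinely out of frame.
#'
#' @param rpfs_condition,rpfs_control Assigned footprints of the two samples.
#' @param cds_seqs Named CDS sequences ([cds_sequences()]).
#' @param target_codon Sense codon under test.
#' @param target_offset In-frame offset of the signal (default 15, A site).
#' @param min_gene_count Per-gene minimum count, as in [compute_shifts()].
#' @return A `background_distribution` list: `target_codon`, `target_offset`,
#'   `background_values` (named numeric; names "<side>:<triplet>"),
#'   `excluded_patterns`, `excluded_values`, `degenerate` (TRUE when all
#'   background values are identical, e.g. condition equals control).
#' @export
build_background <- function(rpfs_condition, rpfs_control, cds_seqs,
                             target_codon, target_offset = 15L,
                             min_gene_count = 100L) {
  stopifnot(target_codon %in% sense_codons())
  pats <- exclusion_patterns(target_codon)
  phase <- target_offset %% 3L
  rc <- rpfs_condition[(cds_relative_5p + phase) %% 3L == 0L]
  rk <- rpfs_control[(cds_relative_5p + phase) %% 3L == 0L]
  vals <- list()
  excl <- list()
  for (side in c(-1L, 1L)) {
    off <- target_offset + side
    tc <- count_codons(rc, cds_seqs, offset = off, in_frame_only = FALSE)
    tk <- count_codons(rk, cds_seqs, offset = off, in_frame_only = FALSE)
    sh <- compute_shifts(tc, tk, min_gene_count = min_gene_count)
    sh <- sh[!is.na(shift)]
    pat <- pats[offset_side == side, pattern]
    drop <- matches_pattern(sh$codon, pat)
    ## sprintf (unlike paste0) keeps zero-length inputs zero-length
    vals[[as.character(side)]] <-
      setNames(sh$shift[!drop], sprintf("%d:%s", side, sh$codon[!drop]))
    excl[[as.character(side)]] <-
      setNames(sh$shift[drop], sprintf("%d:%s", side, sh$codon[drop]))
  }
  bg <- c(vals[["-1"]], vals[["1"]])
  if (length(bg) < 8L)
    stop("only ", length(bg), " background triplet shifts available ",
         "(need >= 8); increase coverage or lower min_gene_count")
  structure(list(target_codon = target_codon,
                 target_offset = as.integer(target_offset),
                 background_values = bg,
                 excluded_patterns = pats,
                 excluded_values = c(excl[["-1"]], excl[["1"]]),
                 degenerate = sd(bg) == 0),
            class = "background_distribution")
}

#' Z-test of an observed shift against an out-of-frame background
#'
#' Two-tailed Z-test: `z = (observed - mean(background)) / sd(background)`
#' (sample SD, n-1 denominator), `p = 2 * (1 - pnorm(|z|))`. Normality of
#' the background is diagnosed (not gated) with the Anderson-Darling
#' statistic, the Shapiro-Wilk p-value and Q-Q coordinates; a Shapiro-Wilk
#' p below 0.05 sets `normality_flag`.
#'
#' @param background A `background_distribution` from [build_background()].
#' @param observed_shift The in-frame shift of the target codon.
#' @return An `oof_test` list: `target_codon`, `observed_shift`,
#'   `background_n`, `background_mean`, `background_sd`, `z`, `p_two_tailed`,
#'   `anderson_darling_stat`, `shapiro_wilk_p`, `qq_points`,
#'   `normality_flag`.
#' @export
z_test <- function(background, observed_shift) {
  stopifnot(inherits(background, "background_distribution"))
  bg <- background$background_values
  s <- sd(bg)
  if (background$degenerate || s == 0)
    stop("degenerate background (zero variance); no z-test possible")
  m <- mean(bg)
  z <- (observed_shift - m) / s
  ad <- nortest::ad.test(bg)
  sw <- shapiro.test(bg)
  qq <- qqnorm(bg, plot.it = FALSE)
  structure(list(target_codon = background$target_codon,
                 observed_shift = observed_shift,
                 background_n = length(bg), background_mean = m,
                 background_sd = s, z = z,
                 p_two_tailed = 2 * (1 - pnorm(abs(z))),
                 anderson_darling_stat = unname(ad$statistic),
                 shapiro_wilk_p = sw$p.value,
                 qq_points = data.table(theoretical = qq$x, sample = qq$y),
                 normality_flag = sw$p.value < 0.05),
            class = "oof_test")
}

#' @export
print.oof_test <- function(x, ...) {
  cat(sprintf(paste0("Out-of-frame z-test for %s: observed %.4f, ",
                     "background %.4f +/- %.4f (n=%d), z = %.2f, p = %.3g%s\n"),
              x$target_codon, x$observed_shift, x$background_mean,
              x$background_sd, x$background_n, x$z, x$p_two_tailed,
              if (x$normality_flag) " [non-normal background]" else ""))
  invisible(x)
}

#' In-frame shift plus out-of-frame Z-test for one codon
#'
#' Convenience wrapper: computes the in-frame subsequence shift of
#' `target_codon` at `target_offset`, builds the out-of-frame background and
#' runs [z_test()]. Returns a degenerate-flagged result (without z) when the
#' background has zero variance.
#'
#' @inheritParams build_background
#' @return An `oof_test` list, or a list with `degenerate = TRUE` when no
#'   test is possible.
#' @export
oof_test <- function(rpfs_condition, rpfs_control, cds_seqs, target_codon,
                     target_offset = 15L, min_gene_count = 100L) {
  tc <- count_codons(rpfs_condition, cds_seqs, offset = target_offset)
  tk <- count_codons(rpfs_control, cds_seqs, offset = target_offset)
  sh <- compute_shifts(tc, tk, min_gene_count = min_gene_count)
  row <- sh[codon == target_codon]
  if (nrow(row) == 0L || is.na(row$shift))
    stop("no defined in-frame shift for ", target_codon)
  bg <- build_background(rpfs_condition, rpfs_control, cds_seqs,
                         target_codon, target_offset, min_gene_count)
  if (bg$degenerate)
    return(structure(list(target_codon = target_codon,
                          observed_shift = row$shift,
                          background_n = length(bg$background_values),
                          degenerate = TRUE),
                     class = "oof_test_degenerate"))
  z_test(bg, row$shift)
}
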