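test_that("region geometry: centered windows, ends excluded", {
  ## 90-nt CDS, no UTR: GCA at codon index 15 (nt 45) fits, index 3 (nt 9)
  ## cannot extend 30 nt upstream
  cods <- rep("AAC", 30)
  cods[1] <- "ATG"; cods[30] <- "TAA"; cods[16] <- "GCA"  # codon index 15
  cds <- paste(cods, collapse = "")
  tx <- manual_txome(cds, utr5 = 0L, utr3 = 0L)
  ann <- annotation_of(tx)
  reg <- extract_codon_regions(ann, tx_sequences(tx), "GCA")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$center, 45L)
  expect_equal(reg$window_start, 15L)

  cods2 <- rep("AAC", 30)
  cods2[1] <- "ATG"; cods2[30] <- "TAA"; cods2[4] <- "GCA"  # codon index 3
  tx2 <- manual_txome(paste(cods2, collapse = ""), utr5 = 0L, utr3 = 0L)
  reg2 <- extract_codon_regions(annotation_of(tx2), tx_sequences(tx2), "GCA")
  expect_equal(nrow(reg2), 0L)
})

test_that("identical genomic coordinates collapse; distinct overlaps are kept", {
  ## two transcripts of one gene share the reference sequence; the GCA at
  ## nt 45 is in frame for both (cds_start 0 and 6), so their windows are
  ## identical and collapse to one region
  cods <- rep("AAC", 60)
  cods[1] <- "ATG"; cods[60] <- "TAA"; cods[16] <- "GCA"; cods[26] <- "GCA"
  seqs <- setNames(paste(cods, collapse = ""), "cS")
  ann <- data.table::data.table(
    chrom = "cS", strand = "+", gene_id = "gS",
    transcript_id = c("tS1", "tS2"),
    cds_start = c(0L, 6L), cds_length = c(180L, 168L))
  reg <- extract_codon_regions(ann, seqs, "GCA")
  ## occurrences at nt 45 and 75, in frame for both transcripts: 2 unique
  ## windows after collapsing the duplicates
  expect_equal(nrow(reg), 2L)
  expect_setequal(reg$center, c(45L, 75L))
  expect_equal(anyDuplicated(reg[, .(chrom, window_start)]), 0L)
})

test_that("region extraction agrees with a brute-force transcriptome scan", {
  tx <- small_txome(8, seed = 51)
  ann <- annotation_of(tx)
  seqs <- tx_sequences(tx)
  for (cdn in c("GCA", "ACT", "TGG")) {
    fast <- extract_codon_regions(ann, seqs, cdn)[order(chrom, window_start)]
    slow <- brute_regions(ann, seqs, cdn)
    expect_equal(fast[, .(chrom, window_start)], slow)
  }
})

test_that("flat regions normalize to 1 and smoothing leaves them unchanged", {
  cods <- rep("AAC", 40)
  cods[1] <- "ATG"; cods[40] <- "TAA"; cods[21] <- "GCA"
  tx <- manual_txome(paste(cods, collapse = ""))
  ann <- annotation_of(tx)
  reg <- extract_codon_regions(ann, tx_sequences(tx), "GCA")
  expect_equal(nrow(reg), 1L)
  ## two 5'-end counts at every window position
  rel <- rep(seq(reg$window_start, reg$window_start + 60) - 30L, each = 2)
  rpfs <- manual_rpfs("m01", "m01.t1", 30L, rel)
  prof <- profile_regions(rpfs, rpfs, reg, min_region_count = 50,
                          min_windows_common = 1)
  expect_equal(as.numeric(prof$condition$normalized), rep(1, 61))
  expect_equal(as.numeric(prof$condition$smoothed), rep(1, 61))
})

test_that("a single-position spike smooths to a third of its height", {
  cods <- rep("AAC", 40)
  cods[1] <- "ATG"; cods[40] <- "TAA"; cods[21] <- "GCA"
  tx <- manual_txome(paste(cods, collapse = ""))
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  ## 61 reads all at the window center (the codon's first nucleotide)
  rpfs <- manual_rpfs("m01", "m01.t1", 30L, rep(reg$center - 30L, 61))
  prof <- profile_regions(rpfs, rpfs, reg, min_region_count = 50,
                          min_windows_common = 1)
  norm <- as.numeric(prof$condition$normalized)
  expect_equal(norm[31], 61)
  expect_equal(sum(norm != 0), 1L)
  sm <- as.numeric(prof$condition$smoothed)
  expect_equal(sm[31], 61 / 3)
  expect_equal(mean(sm), 1, tolerance = 1e-12)
})

test_that("every surviving region has normalized and smoothed mean exactly 1", {
  tx <- small_txome(20, seed = 52)
  pr <- pair_shifts(tx, dwell = c(GCA = 3), n_reads = 5e4, seed = 53,
                    min_gene_count = 50)
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  prof <- profile_regions(pr$cond, pr$ctrl, reg, min_region_count = 20,
                          min_windows_common = 10)
  for (side in c("condition", "control")) {
    expect_true(all(abs(rowMeans(prof[[side]]$normalized) - 1) < 1e-9))
    expect_true(all(abs(rowMeans(prof[[side]]$smoothed) - 1) < 1e-9))
  }
})

test_that("joint filtering is symmetric in the sample labels", {
  tx <- small_txome(20, seed = 52)
  pr <- pair_shifts(tx, dwell = c(GCA = 3), n_reads = 4e4, seed = 54,
                    min_gene_count = 50)
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  p1 <- profile_regions(pr$cond, pr$ctrl, reg, min_region_count = 20,
                        min_windows_common = 10)
  p2 <- profile_regions(pr$ctrl, pr$cond, reg, min_region_count = 20,
                        min_windows_common = 10)
  expect_setequal(p1$region_id, p2$region_id)
})

test_that("the threshold schedule lowers only when too few regions survive", {
  tx <- small_txome(20, seed = 52)
  pr <- pair_shifts(tx, dwell = NULL, n_reads = 5e3, seed = 55,
                    min_gene_count = 50)
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  strict <- profile_regions(pr$cond, pr$ctrl, reg, min_region_count = 50,
                            min_windows_common = 1000)
  expect_lt(strict$threshold_used, 50L)
  easy <- profile_regions(pr$cond, pr$ctrl, reg, min_region_count = 50,
                          min_windows_common = 1)
  expect_equal(easy$threshold_used, 50L)
})

test_that("identical samples give a zero density shift; mismatched sets abort", {
  tx <- small_txome(15, seed = 56)
  sa <- sim_assigned(tx, n_reads = 4e4, seed = 57)
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  prof <- profile_regions(sa$rpfs, sa$rpfs, reg, min_region_count = 10,
                          min_windows_common = 5)
  ds <- density_shift(prof)
  expect_equal(ds$density_shift, rep(0, 61))
  expect_equal(ds$n_regions_used, length(prof$region_id))

  other <- prof
  other$region_id <- rev(prof$region_id)
  expect_error(density_shift(prof, other), "different region sets")
})

test_that("a stalled codon shifts density at the A-site placement", {
  tx <- small_txome(40, seed = 58, length_range = c(300, 900))
  pr <- pair_shifts(tx, dwell = c(GCA = 3), n_reads = 2e5, seed = 59,
                    min_gene_count = 50)
  reg <- extract_codon_regions(annotation_of(tx), tx_sequences(tx), "GCA")
  prof <- profile_regions(pr$cond, pr$ctrl, reg, min_region_count = 20,
                          min_windows_common = 10)
  ds <- density_shift(prof)
  ## stalled ribosomes put 5' ends 15 nt upstream of the window center
  ## (position -15 = column 16); width-3 smoothing spreads the spike over
  ## columns 15-17
  expect_true(which.max(ds$density_shift) %in% 15:17)
  expect_gt(max(ds$density_shift), 0.5)
})
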