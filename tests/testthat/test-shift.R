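## helper: build a codon_freq_table by hand
manual_table <- function(counts, offset = 15L) {
  counts <- data.table::as.data.table(counts)
  totals <- counts[, .(total = sum(count)), by = gene_id]
  structure(list(offset = offset, in_frame_only = TRUE,
                 counts = counts, gene_totals = totals),
            class = "codon_freq_table")
}

test_that("codon counting indexes the CDS directly", {
  ## CDS: ATG GCA GGT GTT TCA CCA ... ; read 5' end at CDS position 0
  cds <- cds_from_codons(c("GCA", "GGT", "GTT", "TCA", "CCA", rep("AAC", 93)))
  tx <- manual_txome(cds)
  rpfs <- manual_rpfs("m01", "m01.t1", 30L, 0L)
  tab15 <- count_codons(rpfs, cds_sequences(tx), offset = 15)
  expect_equal(tab15$counts$codon, "CCA")  # the triplet at nt 15-17
  expect_equal(tab15$counts$count, 1L)
  tab12 <- count_codons(rpfs, cds_sequences(tx), offset = 12)
  expect_equal(tab12$counts$codon, "TCA")  # nt 12-14, one codon upstream
})

test_that("counting at the A-site offset reproduces the simulation truth exactly", {
  tx <- small_txome(10, seed = 21)
  sa <- sim_assigned(tx, stalling_profile(c(GGT = 4)), n_reads = 3e4, seed = 22)
  tab <- count_codons(sa$rpfs, cds_sequences(tx), offset = 15)
  truth <- merge(sa$fp, sa$rpfs[, .(read_id)], by = "read_id")
  th <- truth[, .(count = .N), by = .(gene_id, codon = a_site_codon)]
  m <- merge(tab$counts, th, by = c("gene_id", "codon"), all = TRUE)
  expect_false(anyNA(m))
  expect_equal(m$count.x, m$count.y)
})

test_that("offsets 12 and 15 count the same reads, one codon apart", {
  tx <- small_txome(10, seed = 21)
  sa <- sim_assigned(tx, n_reads = 2e4, seed = 23)
  t12 <- count_codons(sa$rpfs, cds_sequences(tx), offset = 12)
  t15 <- count_codons(sa$rpfs, cds_sequences(tx), offset = 15)
  g <- merge(t12$gene_totals, t15$gene_totals, by = "gene_id")
  expect_equal(g$total.x, g$total.y)
})

test_that("codon counting matches the brute-force oracle", {
  tx <- small_txome(6, seed = 31)
  sa <- sim_assigned(tx, n_reads = 1000, seed = 32, jitter_prob = 0.3)
  cs <- cds_sequences(tx)
  for (off in c(12L, 15L)) {
    fast <- count_codons(sa$rpfs, cs, offset = off)
    slow <- brute_count_codons(sa$rpfs, cs, offset = off)
    expect_equal(as.data.frame(fast$counts), as.data.frame(slow))
  }
})

test_that("identical samples give zero shift for every codon", {
  tx <- small_txome(10, seed = 21)
  sa <- sim_assigned(tx, n_reads = 3e4, seed = 24)
  tab <- count_codons(sa$rpfs, cds_sequences(tx))
  sh <- compute_shifts(tab, tab, min_gene_count = 50)
  expect_true(all(sh$shift == 0))
  expect_false(any(sh$undefined))
  ## normalized mean frequencies sum to 1 over counted codons
  expect_equal(sum(sh$mean_freq_condition), 1, tolerance = 1e-12)
})

test_that("two-gene hand-built example gives shift exactly 1", {
  cond <- manual_table(data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    codon = c("GCA", "AAC", "GCA", "AAC"),
    count = c(2L, 8L, 4L, 16L)))
  ctrl <- manual_table(data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    codon = c("GCA", "AAC", "GCA", "AAC"),
    count = c(1L, 9L, 2L, 18L)))
  sh <- compute_shifts(cond, ctrl, min_gene_count = 10)
  gca <- sh[codon == "GCA"]
  expect_equal(gca$mean_freq_condition, 0.2)
  expect_equal(gca$mean_freq_control, 0.1)
  expect_equal(gca$shift, 1.0)
  expect_equal(gca$n_genes_used, 2L)
})

test_that("shifts are invariant to uniform count scaling of one sample", {
  tx <- small_txome(10, seed = 21)
  pr <- pair_shifts(tx, dwell = c(GCA = 2), n_reads = 3e4, seed = 25,
                    min_gene_count = 50)
  tab_c <- count_codons(pr$cond, pr$cds_seqs)
  tab_k <- count_codons(pr$ctrl, pr$cds_seqs)
  scaled <- tab_c
  scaled$counts <- data.table::copy(tab_c$counts)[, count := count * 7L]
  scaled$gene_totals <- data.table::copy(tab_c$gene_totals)[
    , total := total * 7L]
  s1 <- compute_shifts(tab_c, tab_k, min_gene_count = 50)
  s2 <- compute_shifts(scaled, tab_k, min_gene_count = 50)
  expect_equal(s1$shift, s2$shift, tolerance = 1e-12)
})

test_that("swapping condition and control maps s to 1/(1+s) - 1", {
  tx <- small_txome(10, seed = 21)
  pr <- pair_shifts(tx, dwell = c(GCA = 3), n_reads = 3e4, seed = 26,
                    min_gene_count = 50)
  tab_c <- count_codons(pr$cond, pr$cds_seqs)
  tab_k <- count_codons(pr$ctrl, pr$cds_seqs)
  fwd <- compute_shifts(tab_c, tab_k, min_gene_count = 50)
  rev <- compute_shifts(tab_k, tab_c, min_gene_count = 50)
  m <- merge(fwd[!(undefined)], rev[!(undefined)], by = "codon")
  expect_equal(m$shift.y, 1 / (1 + m$shift.x) - 1, tolerance = 1e-10)
})

test_that("zero control frequency is flagged undefined, not dropped", {
  cond <- manual_table(data.frame(gene_id = "gA",
                                  codon = c("GCA", "AAC"),
                                  count = c(5L, 15L)))
  ctrl <- manual_table(data.frame(gene_id = "gA", codon = "AAC",
                                  count = 20L))
  sh <- compute_shifts(cond, ctrl, min_gene_count = 10)
  expect_true(sh[codon == "GCA", undefined])
  expect_true(is.na(sh[codon == "GCA", shift]))
  expect_false(sh[codon == "AAC", undefined])
})

test_that("an unreachable gene-count threshold aborts with advice", {
  cond <- manual_table(data.frame(gene_id = "gA", codon = "GCA", count = 5L))
  expect_error(compute_shifts(cond, cond, min_gene_count = 100),
               "lower the threshold")
})

test_that("mismatched offsets are refused", {
  t1 <- manual_table(data.frame(gene_id = "gA", codon = "GCA", count = 5L),
                     offset = 15L)
  t2 <- manual_table(data.frame(gene_id = "gA", codon = "GCA", count = 5L),
                     offset = 12L)
  expect_error(compute_shifts(t1, t2, min_gene_count = 1), "offsets")
})
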