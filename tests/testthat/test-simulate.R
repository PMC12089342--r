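test_that("generated transcripts satisfy the CDS invariants", {
  tx <- sim_transcriptome(20, c(90, 400), gc_fraction = 0.5, seed = 5)
  t <- tx$transcripts
  expect_equal(nrow(t), 20L)
  cds <- cds_sequences(tx)
  expect_true(all(nchar(cds) >= 90))
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% stop_codons()))
  internal_stops <- vapply(cds, function(s) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(cods[-1] %in% stop_codons())
  }, logical(1))
  expect_false(any(internal_stops))
  expect_true(all(t$expression_weight > 0))

  tx1 <- sim_transcriptome(1, c(90, 90), seed = 1)
  expect_equal(tx1$transcripts$cds_length, 90L)
})

test_that("generated CDS hit the requested GC content", {
  tx <- sim_transcriptome(50, c(300, 900), gc_fraction = 0.7, seed = 3)
  cds <- paste(cds_sequences(tx), collapse = "")
  gc <- sum(strsplit(cds, "")[[1]] %in% c("G", "C")) / nchar(cds)
  expect_lt(abs(gc - 0.7), 0.03)
})

test_that("invalid transcriptome parameters are rejected", {
  expect_error(sim_transcriptome(5, c(60, 300), seed = 1), "90")
  expect_error(sim_transcriptome(0, c(300, 400), seed = 1))
})

test_that("simulation is deterministic and conserves read count", {
  tx <- small_txome(10, seed = 2)
  cfg <- sim_config(10000, seed = 9, jitter_prob = 0.2)
  fp1 <- sim_footprints(tx, stalling_profile(), cfg)
  fp2 <- sim_footprints(tx, stalling_profile(), cfg)
  expect_identical(as.data.frame(fp1), as.data.frame(fp2))
  expect_equal(nrow(fp1), 10000L)
  fp3 <- sim_footprints(tx, stalling_profile(),
                        sim_config(10000, seed = 10, jitter_prob = 0.2))
  expect_false(identical(fp1$start0, fp3$start0))
})

test_that("with zero jitter every 5' end sits a_site_offset nt upstream of an in-frame codon", {
  tx <- small_txome(10, seed = 2)
  fp <- sim_footprints(tx, stalling_profile(), sim_config(20000, seed = 4))
  cds_start <- setNames(tx$transcripts$cds_start, tx$transcripts$chrom)
  rel <- fp$start0 - cds_start[fp$chrom]
  expect_true(all((rel + 15L) %% 3L == 0))
  expect_true(all(rel == fp$a_site_pos - 15L))
  expect_true(all(fp$length >= 20 & fp$length <= 34))
})

test_that("empirical codon occupancy matches the exhaustive probability oracle", {
  tx <- small_txome(25, seed = 6, length_range = c(300, 900))
  prof <- stalling_profile(c(GCA = 5))
  cfg <- sim_config(2e5, seed = 11)
  fp <- sim_footprints(tx, prof, cfg)

  ## independent oracle: per-position probability sum over all transcripts
  t <- tx$transcripts
  w <- t$expression_weight / sum(t$expression_weight)
  p_gca <- 0
  for (i in seq_len(nrow(t))) {
    cds <- substr(t$tx_sequence[i], t$cds_start[i] + 1,
                  t$cds_start[i] + t$cds_length[i])
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    pos <- 3L * (seq_along(cods) - 1L)
    cand <- pos >= 15L & pos <= t$cds_length[i] - (34L - 15L)
    dw <- ifelse(cand, prof[cods], 0)
    dw[is.na(dw)] <- 0
    p_gca <- p_gca + w[i] * sum(dw[cods == "GCA" & cand]) / sum(dw)
  }
  emp <- mean(fp$a_site_codon == "GCA")
  expect_lt(abs(emp - p_gca), 3 * sqrt(p_gca * (1 - p_gca) / 2e5))

  ## packaged analytic oracle agrees with the hand loop
  pr <- asite_probabilities(tx, prof, cfg)
  expect_equal(pr[pr$codon == "GCA", ]$prob, p_gca, tolerance = 1e-12)
})

test_that("FASTA/GTF output round-trips through the loaders", {
  tx <- small_txome(6, seed = 3)
  d <- withr::local_tempdir()
  write_transcriptome(tx, file.path(d, "t.fa"), file.path(d, "t.gtf"))
  ann <- load_annotation(file.path(d, "t.gtf"))
  expect_equal(as.data.frame(ann[order(transcript_id)]),
               as.data.frame(annotation_of(tx)[order(transcript_id)]))
  seqs <- Biostrings::readDNAStringSet(file.path(d, "t.fa"))
  expect_equal(setNames(as.character(seqs), names(seqs)), tx_sequences(tx))
})

test_that("SAM output is coordinate-sorted and re-loads identically", {
  tx <- small_txome(5, seed = 3)
  fp <- sim_footprints(tx, stalling_profile(), sim_config(800, seed = 4))
  d <- withr::local_tempdir()
  write_sam(fp, tx, file.path(d, "t.sam"))
  aln <- load_alignments(file.path(d, "t.sam"))
  expect_equal(nrow(aln), 800L)
  expect_equal(sort(aln$read_id), sort(fp$read_id))
  m <- merge(aln, fp, by = "read_id")
  expect_equal(m$pos0, m$start0)
  expect_equal(m$length.x, m$length.y)
  expect_true(all(aln$strand == "+"))
})
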