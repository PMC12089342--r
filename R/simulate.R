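## Synthetic transcriptome and Ribo-seq footprint simulator.
##
## Coordinates are transcript-relative, 0-based, half-open internally; each
## transcript is written as its own reference sequence ("chromosome"), so
## SAM/GTF output needs no splicing. SAM/GTF positions are 1-based per the
## standards.

## evaluate `expr` under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

## sample `n` bases with P(G or C) = gc
sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## n random sense codons at the given GC content (stop triplets resampled)
sample_sense_codons <- function(n, gc) {
  if (n == 0L) return(character(0))
  cod <- paste0(sample_bases(n, gc), sample_bases(n, gc), sample_bases(n, gc))
  bad <- which(cod %in% stop_codons())
  while (length(bad) > 0L) {
    cod[bad] <- paste0(sample_bases(length(bad), gc),
                       sample_bases(length(bad), gc),
                       sample_bases(length(bad), gc))
    bad <- bad[cod[bad] %in% stop_codons()]
  }
  cod
}

#' Generate a synthetic transcriptome with known CDS structure
#'
#' Each gene gets a single transcript consisting of a 5' UTR, a CDS (ATG
#' start, no internal stops in frame 0, stop-terminated, length a multiple of
#' 3 and at least 90 nt) and a 3' UTR. Relative abundances are drawn from a
#' log-normal distribution unless `expression_weights` is supplied.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Integer CDS length range in nt; drawn lengths are
#'   snapped down to a multiple of 3. Minimum must be >= 90.
#' @param gc_fraction Target GC content of generated sequence, in `[0, 1]`.
#' @param utr5_length,utr3_length UTR lengths in nt. The 5' UTR must be long
#'   enough to hold the footprint overhang upstream of the CDS (>= 16 nt
#'   recommended).
#' @param expression_weights Optional positive numeric vector of length
#'   `n_genes`; default log-normal(0, 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `sc_txome`: a list with element `transcripts`
#'   (a `data.table` with columns `gene_id`, `transcript_id`, `chrom`,
#'   `tx_sequence`, `tx_length`, `cds_start` (0-based), `cds_length`,
#'   `expression_weight`) plus the generation parameters.
#' @export
#' @examples
#' tx <- sim_transcriptome(5, c(300, 600), seed = 1)
#' tx$transcripts[, .(gene_id, cds_length)]
sim_transcriptome <- function(n_genes, length_range = c(300L, 1800L),
                              gc_fraction = 0.5, utr5_length = 36L,
                              utr3_length = 45L, expression_weights = NULL,
                              seed = 1L) {
  stopifnot(n_genes >= 1, length(length_range) == 2L,
            gc_fraction >= 0, gc_fraction <= 1, utr5_length >= 0,
            utr3_length >= 0)
  if (min(length_range) < 90)
    stop("length_range minimum must be >= 90 nt")
  if (!is.null(expression_weights)) {
    stopifnot(length(expression_weights) == n_genes,
              all(expression_weights > 0))
  }
  with_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n_genes,
                   replace = TRUE)
    lens <- pmax(90L, (lens %/% 3L) * 3L)
    w <- if (is.null(expression_weights)) rlnorm(n_genes, 0, 1)
         else as.numeric(expression_weights)
    tx <- vector("character", n_genes)
    cds <- vector("character", n_genes)
    for (i in seq_len(n_genes)) {
      n_internal <- lens[i] %/% 3L - 2L
      cds[i] <- paste0(
        "ATG",
        paste0(sample_sense_codons(n_internal, gc_fraction), collapse = ""),
        sample(stop_codons(), 1L)
      )
      tx[i] <- paste0(
        paste0(sample_bases(utr5_length, gc_fraction), collapse = ""),
        cds[i],
        paste0(sample_bases(utr3_length, gc_fraction), collapse = "")
      )
    }
    ids <- sprintf("g%04d", seq_len(n_genes))
    transcripts <- data.table(
      gene_id = ids,
      transcript_id = paste0(ids, ".t1"),
      chrom = paste0(ids, ".t1"),
      tx_sequence = tx,
      tx_length = nchar(tx),
      cds_start = as.integer(utr5_length),
      cds_length = lens,
      expression_weight = w
    )
    structure(list(transcripts = transcripts, utr5_length = utr5_length,
                   utr3_length = utr3_length, gc_fraction = gc_fraction,
                   seed = seed),
              class = "sc_txome")
  })
}

#' @export
print.sc_txome <- function(x, ...) {
  cat(sprintf("Synthetic transcriptome: %d genes, CDS %d-%d nt (seed %d)\n",
              nrow(x$transcripts), min(x$transcripts$cds_length),
              max(x$transcripts$cds_length), x$seed))
  invisible(x)
}

#' CDS sequences of a transcriptome
#' @param txome An `sc_txome` object.
#' @return Named character vector (names = `gene_id`) of CDS sequences.
#' @export
cds_sequences <- function(txome) {
  t <- txome$transcripts
  setNames(substr(t$tx_sequence, t$cds_start + 1L, t$cds_start + t$cds_length),
           t$gene_id)
}

#' Transcript (reference) sequences of a transcriptome
#' @param txome An `sc_txome` object.
#' @return Named character vector (names = `chrom`) of full transcript
#'   sequences.
#' @export
tx_sequences <- function(txome) {
  setNames(txome$transcripts$tx_sequence, txome$transcripts$chrom)
}

#' In-memory annotation table for a synthetic transcriptome
#'
#' Equivalent to writing the GTF with [write_transcriptome()] and re-reading
#' it with [load_annotation()].
#'
#' @param txome An `sc_txome` object.
#' @return Annotation `data.table` with columns `chrom`, `strand`, `gene_id`,
#'   `transcript_id`, `cds_start` (0-based), `cds_length`.
#' @export
annotation_of <- function(txome) {
  t <- txome$transcripts
  data.table(chrom = t$chrom, strand = "+", gene_id = t$gene_id,
             transcript_id = t$transcript_id, cds_start = t$cds_start,
             cds_length = t$cds_length)
}

#' Per-codon ribosome dwell profile
#'
#' A named vector over the 61 sense codons giving the relative dwell time of
#' the ribosomal A site on each codon (1 = baseline). Elevated dwell at a
#' codon models stalling, e.g. under shortage of the cognate aminoacyl-tRNA.
#'
#' @param multipliers Optional named numeric vector of per-codon multipliers,
#'   e.g. `c(GCA = 3, GCC = 3)`. Unnamed codons keep dwell 1. All values must
#'   be positive and names must be sense codons.
#' @return Named numeric vector over all 61 sense codons.
#' @export
#' @examples
#' p <- stalling_profile(c(GCA = 5))
#' p[c("GCA", "GCC")]
stalling_profile <- function(multipliers = NULL) {
  prof <- setNames(rep(1, 61L), sense_codons())
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers)) || any(names(multipliers) == ""))
      stop("multipliers must be a named vector of codons")
    bad <- setdiff(names(multipliers), sense_codons())
    if (length(bad) > 0L)
      stop("not sense codons: ", paste(bad, collapse = ", "))
    if (any(multipliers <= 0)) stop("dwell multipliers must be positive")
    prof[names(multipliers)] <- multipliers
  }
  prof
}

#' Default footprint read-length distribution
#'
#' Triangular over 20-34 nt with mode 30 nt, matching the size-selection
#' window of typical ribosome-profiling libraries.
#'
#' @return Named numeric probability vector (names "20".."34", sum 1).
#' @export
default_read_length_probs <- function() {
  l <- 20:34
  w <- ifelse(l <= 30, (l - 19) / 11, (35 - l) / 5)
  setNames(w / sum(w), l)
}

#' Footprint simulation configuration
#'
#' @param n_reads Number of footprints to generate.
#' @param seed Integer seed for the simulation.
#' @param read_length_probs Named probability vector over read lengths; names
#'   must be integers in 20-34 and probabilities must sum to 1.
#' @param a_site_offset Distance in nt from the footprint 5' end to the first
#'   nucleotide of the A-site codon (default 15; the P site is at 12).
#' @param jitter_prob Probability that a read's 5' end is displaced by
#'   +/- 1 nt (split evenly between the two directions), modelling imperfect
#'   nuclease trimming.
#' @param ligation_bias Optional named numeric vector: multiplicative capture
#'   bias keyed by the codon at the read's (unjittered) 5' terminus,
#'   modelling linker-ligation preference.
#' @param init_dwell Relative dwell at the start codon (default 0 = the start
#'   codon never serves as an A site). Positive values model initiation peaks
#'   for metagene QC.
#' @return An `sc_config` list.
#' @export
sim_config <- function(n_reads, seed = 1L,
                       read_length_probs = default_read_length_probs(),
                       a_site_offset = 15L, jitter_prob = 0,
                       ligation_bias = NULL, init_dwell = 0) {
  stopifnot(n_reads >= 1, a_site_offset >= 0, jitter_prob >= 0,
            jitter_prob <= 1, init_dwell >= 0)
  lens <- as.integer(names(read_length_probs))
  if (anyNA(lens) || any(lens < 20L) || any(lens > 34L))
    stop("read lengths must be integers in 20..34")
  if (abs(sum(read_length_probs) - 1) > 1e-8)
    stop("read-length probabilities must sum to 1")
  if (!is.null(ligation_bias) &&
      (is.null(names(ligation_bias)) || any(ligation_bias < 0)))
    stop("ligation_bias must be a named non-negative vector")
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 read_length_probs = read_length_probs,
                 a_site_offset = as.integer(a_site_offset),
                 jitter_prob = jitter_prob, ligation_bias = ligation_bias,
                 init_dwell = init_dwell),
            class = "sc_config")
}

## candidate A-site positions (CDS-relative nt, 0-based) and sampling weights
## for one transcript row; returns NULL if none are feasible
asite_candidates <- function(tx_sequence, cds_start, cds_length, tx_length,
                             profile, config) {
  off <- config$a_site_offset
  max_len <- max(as.integer(names(config$read_length_probs)))
  jit <- if (config$jitter_prob > 0) 1L else 0L
  cds_seq <- substr(tx_sequence, cds_start + 1L, cds_start + cds_length)
  codons <- codon_split(cds_seq)
  p <- 3L * (seq_along(codons) - 1L)
  keep <- p >= off & p <= cds_length - (max_len - off)
  w <- rep(0, length(p))
  w[keep] <- profile[codons[keep]]
  if (config$init_dwell > 0) w[1L] <- config$init_dwell
  ## the whole jittered span must fit inside the transcript
  fits <- (cds_start + p - off - jit >= 0L) &
          (cds_start + p - off + jit + max_len <= tx_length)
  w[!fits] <- 0
  if (!is.null(config$ligation_bias)) {
    fivep <- cds_start + p - off
    ok <- which(w > 0)
    term <- substr(rep(tx_sequence, length(ok)), fivep[ok] + 1L,
                   fivep[ok] + 3L)
    b <- config$ligation_bias[term]
    b[is.na(b)] <- 1
    w[ok] <- w[ok] * b
  }
  sel <- which(w > 0)
  if (length(sel) == 0L) return(NULL)
  list(pos = p[sel], codon = codons[sel], w = w[sel])
}

#' Simulate aligned ribosome footprints with known stalling structure
#'
#' For each read: a transcript is chosen proportionally to its expression
#' weight; an A-site codon is chosen within its CDS proportionally to the
#' dwell profile (uniform baseline); the 5' end is placed `a_site_offset` nt
#' upstream of the A-site codon, displaced by +/- 1 nt with probability
#' `jitter_prob`; the read length is drawn from the configured distribution.
#' A-site candidates are restricted so that every jittered read fits inside
#' its transcript, keeping the analytic occupancy probabilities exact. The
#' start codon is excluded as an A site (unless `init_dwell > 0`) and stop
#' codons never serve as A sites.
#'
#' @param txome An `sc_txome` object.
#' @param profile A [stalling_profile()] vector.
#' @param config An [sim_config()] object.
#' @return An `sc_footprints` `data.table`, one row per read, sorted by
#'   reference and position: `read_id`, `gene_id`, `chrom`, `start0`
#'   (0-based 5'-end transcript coordinate), `length`, `a_site_pos`
#'   (CDS-relative nt of the A-site codon), `a_site_codon`. This table is
#'   also the simulation truth.
#' @export
#' @examples
#' tx <- sim_transcriptome(3, c(300, 600), seed = 1)
#' fp <- sim_footprints(tx, stalling_profile(), sim_config(1000, seed = 2))
#' nrow(fp)
sim_footprints <- function(txome, profile = stalling_profile(), config) {
  stopifnot(inherits(txome, "sc_txome"), inherits(config, "sc_config"))
  t <- txome$transcripts
  if (nrow(t) == 0L) stop("empty transcriptome")
  cand <- lapply(seq_len(nrow(t)), function(i)
    asite_candidates(t$tx_sequence[i], t$cds_start[i], t$cds_length[i],
                     t$tx_length[i], profile, config))
  usable <- !vapply(cand, is.null, logical(1))
  if (!any(usable))
    stop("no feasible A-site candidates for the configured offset; ",
         "transcripts too short")
  ## flatten (gene, position) categories: P = expr weight x within-gene dwell
  gidx <- rep(which(usable),
              vapply(cand[usable], function(z) length(z$pos), integer(1)))
  pos <- unlist(lapply(cand[usable], `[[`, "pos"), use.names = FALSE)
  codn <- unlist(lapply(cand[usable], `[[`, "codon"), use.names = FALSE)
  wflat <- unlist(lapply(which(usable), function(i)
    t$expression_weight[i] * cand[[i]]$w / sum(cand[[i]]$w)),
    use.names = FALSE)
  with_seed(config$seed, {
    k <- sample.int(length(wflat), config$n_reads, replace = TRUE,
                    prob = wflat)
    lens <- as.integer(sample(names(config$read_length_probs),
                              config$n_reads, replace = TRUE,
                              prob = config$read_length_probs))
    j <- config$jitter_prob
    jit <- sample(c(-1L, 0L, 1L), config$n_reads, replace = TRUE,
                  prob = c(j / 2, 1 - j, j / 2))
    fp <- data.table(
      read_id = sprintf("read%08d", seq_len(config$n_reads)),
      gene_id = t$gene_id[gidx[k]],
      chrom = t$chrom[gidx[k]],
      start0 = t$cds_start[gidx[k]] + pos[k] - config$a_site_offset + jit,
      length = lens,
      a_site_pos = pos[k],
      a_site_codon = codn[k]
    )
    setorder(fp, chrom, start0, read_id)
    setattr(fp, "class", c("sc_footprints", class(fp)))
    setattr(fp, "config", config)
    fp[]
  })
}

#' Exact A-site codon occupancy probabilities
#'
#' Analytic counterpart of [sim_footprints()]: sums, over every feasible
#' A-site position of every transcript, the probability that a simulated read
#' decodes that position, and aggregates by codon. The empirical codon
#' occupancy of a simulation converges to these values as `n_reads` grows.
#'
#' @inheritParams sim_footprints
#' @return `data.table` with columns `codon` and `prob` (summing to 1).
#' @export
asite_probabilities <- function(txome, profile = stalling_profile(), config) {
  t <- txome$transcripts
  wtot <- 0
  acc <- new.env()
  for (i in seq_len(nrow(t))) {
    z <- asite_candidates(t$tx_sequence[i], t$cds_start[i], t$cds_length[i],
                          t$tx_length[i], profile, config)
    if (is.null(z)) next
    wtot <- wtot + t$expression_weight[i]
    pw <- t$expression_weight[i] * z$w / sum(z$w)
    for (u in seq_along(z$pos)) {
      key <- z$codon[u]
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pw[u]
    }
  }
  if (wtot == 0) stop("no feasible A-site candidates")
  out <- data.table(codon = ls(acc),
                    prob = vapply(ls(acc), function(k) acc[[k]], numeric(1)))
  out[, prob := prob / wtot]
  setorder(out, codon)
  out[]
}

#' Convert simulated footprints to an in-memory alignment table
#'
#' Produces the same table [load_alignments()] would return after writing the
#' simulation with [write_sam()] and reading it back, without touching disk.
#'
#' @param fp An `sc_footprints` table.
#' @return Alignment `data.table` (`read_id`, `chrom`, `strand`, `pos0`,
#'   `ref_width`, `length`, `spliced`, `secondary`, `unmapped`).
#' @export
as_alignments <- function(fp) {
  data.table(read_id = fp$read_id, chrom = fp$chrom, strand = "+",
             pos0 = fp$start0, ref_width = fp$length, length = fp$length,
             spliced = FALSE, secondary = FALSE, unmapped = FALSE)
}

#' Write transcript FASTA and CDS GTF for a synthetic transcriptome
#'
#' @param txome An `sc_txome` object.
#' @param fasta_path,gtf_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(txome, fasta_path, gtf_path) {
  t <- txome$transcripts
  seqs <- Biostrings::DNAStringSet(setNames(t$tx_sequence, t$chrom))
  Biostrings::writeXStringSet(seqs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(t$chrom, 2L),
    ranges = IRanges::IRanges(
      start = c(rep(1L, nrow(t)), t$cds_start + 1L),
      end = c(t$tx_length, t$cds_start + t$cds_length)),
    strand = "+",
    type = rep(c("exon", "transcript_feature"), each = nrow(t)),
    source = "stallscan",
    gene_id = rep(t$gene_id, 2L),
    transcript_id = rep(t$transcript_id, 2L))
  gr$type <- rep(c("exon", "CDS"), each = nrow(t))
  gr$phase <- rep(c(NA_integer_, 0L), each = nrow(t))
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(c(fasta_path, gtf_path))
}

#' Write simulated footprints as a coordinate-sorted SAM file
#'
#' One primary alignment per footprint (flag 0, MAPQ 255, no mismatches),
#' with the transcript as reference sequence.
#'
#' @param fp An `sc_footprints` table.
#' @param txome The `sc_txome` the footprints were simulated from.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(fp, txome, path) {
  t <- txome$transcripts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", t$chrom, t$tx_length),
               "@PG\tID:stallscan\tPN:stallscan"), con)
  ord <- fp[order(factor(chrom, levels = t$chrom), start0, read_id)]
  seq_by_chrom <- setNames(t$tx_sequence, t$chrom)
  reads <- substr(seq_by_chrom[ord$chrom], ord$start0 + 1L,
                  ord$start0 + ord$length)
  writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     ord$read_id, ord$chrom, ord$start0 + 1L, ord$length,
                     reads), con)
  invisible(path)
}

#' Write the simulation truth table
#'
#' TSV with one row per read: `read_id`, `transcript_id`, `a_site_codon`,
#' `a_site_pos` (CDS-relative nt of the A-site codon's first nucleotide).
#'
#' @param fp An `sc_footprints` table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(fp, path) {
  out <- data.table(read_id = fp$read_id, transcript_id = fp$chrom,
                    a_site_codon = fp$a_site_codon,
                    a_site_pos = fp$a_site_pos)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
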