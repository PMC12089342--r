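## End-to-end orchestration: simulate -> qc -> shift -> density -> ooftest,
## with a declarative config, per-stage outputs and a checksummed manifest.

#' Build a pipeline run configuration
#'
#' @param annotation Path to the CDS GTF.
#' @param sequences Path to the transcript FASTA.
#' @param condition,control Character vectors of SAM/BAM paths (replicates,
#'   paired by index; equal length).
#' @param labels Optional replicate labels (default `rep1`, `rep2`, ...).
#' @param offsets Codon-counting offsets in nt (default `c(12, 15)`; the
#'   amino-acid test and out-of-frame tests use the A-site offset 15 when
#'   present, otherwise the last offset).
#' @param min_gene_count Per-gene minimum count for shifts (default 100).
#' @param min_region_count Per-region minimum count for density (default 50).
#' @param min_windows_common Target region count for common codons (1000).
#' @param min_length Minimum footprint length in nt (default 27).
#' @param overhang_5p Permitted 5' overhang in nt (default 15).
#' @param density_codons Codons to profile with [profile_regions()].
#' @param oof_codons Codons to test with [oof_test()].
#' @param seed Integer seed recorded in the manifest.
#' @param out_dir Output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, sequences, condition, control,
                       labels = NULL, offsets = c(12L, 15L),
                       min_gene_count = 100L, min_region_count = 50L,
                       min_windows_common = 1000L, min_length = 27L,
                       overhang_5p = 15L, density_codons = character(0),
                       oof_codons = character(0), seed = 1L, out_dir) {
  condition <- as.character(unlist(condition))
  control <- as.character(unlist(control))
  if (length(condition) != length(control) || length(condition) < 1L)
    stop("condition and control must list the same (positive) number of ",
         "replicate alignment files")
  if (is.null(labels)) labels <- paste0("rep", seq_along(condition))
  structure(list(annotation = annotation, sequences = sequences,
                 condition = condition, control = control, labels = labels,
                 offsets = as.integer(offsets),
                 min_gene_count = as.integer(min_gene_count),
                 min_region_count = as.integer(min_region_count),
                 min_windows_common = as.integer(min_windows_common),
                 min_length = as.integer(min_length),
                 overhang_5p = as.integer(overhang_5p),
                 density_codons = density_codons, oof_codons = oof_codons,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Validate a pipeline configuration
#'
#' Checks that all referenced input paths exist and thresholds are positive;
#' called by [run_pipeline()] before any computation.
#'
#' @param config A `run_config`.
#' @return Invisibly `TRUE`, or an error naming the problem.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- c(config$annotation, config$sequences, config$condition,
             config$control)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  thr <- c(config$min_gene_count, config$min_region_count,
           config$min_windows_common, config$min_length)
  if (any(thr <= 0)) stop("thresholds must be positive")
  if (config$overhang_5p < 0) stop("overhang_5p must be non-negative")
  bad <- setdiff(c(config$density_codons, config$oof_codons), sense_codons())
  if (length(bad) > 0L)
    stop("not sense codons: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

## CDS sequences per gene from loaded annotation + reference sequences,
## using the longest-CDS transcript as each gene's representative (the same
## rule assign_rpfs uses)
cds_seqs_from <- function(annotation, ref_seqs) {
  rep_tx <- annotation[order(gene_id, -cds_length, transcript_id)][
    , .SD[1L], by = gene_id]
  setNames(substr(ref_seqs[rep_tx$chrom], rep_tx$cds_start + 1L,
                  rep_tx$cds_start + rep_tx$cds_length),
           rep_tx$gene_id)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full stalling-detection pipeline
#'
#' Executes load -> qc -> shift -> amino-acid test -> density -> out-of-frame
#' test, writing TSV/JSON outputs and a manifest with parameters and MD5
#' checksums of every output. Rerunning with an identical configuration
#' reproduces identical outputs.
#'
#' @param config A `run_config` (validated before any compute).
#' @return Invisibly, a list with the in-memory results (`reports`,
#'   `shifts`, `aa_tests`, `density`, `oof`) and the manifest path.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$out_dir, paste0(...))
  written <- character(0)
  emit <- function(x, name) {
    p <- outp(name)
    if (is.data.frame(x)) fwrite(x, p, sep = "\t")
    else jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    written <<- c(written, p)
    p
  }

  ann <- stage("load_annotation", load_annotation(config$annotation))
  ref_seqs <- stage("load_sequences", {
    s <- Biostrings::readDNAStringSet(config$sequences)
    names(s) <- sub("\\s.*$", "", names(s))
    setNames(as.character(s), names(s))
  })
  cds_seqs <- cds_seqs_from(ann, ref_seqs)

  n_rep <- length(config$condition)
  rpfs <- list(condition = vector("list", n_rep),
               control = vector("list", n_rep))
  reports <- list()
  for (i in seq_len(n_rep)) {
    for (side in c("condition", "control")) {
      path <- config[[side]][i]
      res <- stage(paste0("assign_", side, "_", config$labels[i]), {
        aln <- load_alignments(path)
        assign_rpfs(aln, ann, min_length = config$min_length,
                    overhang_5p = config$overhang_5p)
      })
      rpfs[[side]][[i]] <- res$rpfs
      reports[[paste(side, config$labels[i], sep = "_")]] <-
        unclass(res$report)
      qc <- periodicity_qc(res$rpfs)
      emit(qc$frame_fractions,
           sprintf("qc_frames_%s_%s.tsv", side, config$labels[i]))
    }
  }
  emit(reports, "filter_reports.json")

  shifts <- list()
  for (off in config$offsets) {
    for (i in seq_len(n_rep)) {
      sh <- stage(sprintf("shift_offset%d_%s", off, config$labels[i]), {
        tc <- count_codons(rpfs$condition[[i]], cds_seqs, offset = off)
        tk <- count_codons(rpfs$control[[i]], cds_seqs, offset = off)
        compute_shifts(tc, tk, min_gene_count = config$min_gene_count)
      })
      shifts[[sprintf("offset%d_%s", off, config$labels[i])]] <- sh
      emit(sh, sprintf("shift_offset%d_%s.tsv", off, config$labels[i]))
    }
  }

  test_offset <- if (15L %in% config$offsets) 15L
                 else config$offsets[length(config$offsets)]
  aa_tests <- NULL
  if (n_rep >= 2L) {
    aa_tests <- stage("test_amino_acids", {
      reps <- lapply(seq_len(n_rep), function(i)
        shifts[[sprintf("offset%d_%s", test_offset, config$labels[i])]])
      test_amino_acids(reps)
    })
    emit(aa_tests, "amino_acid_tests.tsv")
  }

  pooled_cond <- rbindlist(rpfs$condition)
  pooled_ctrl <- rbindlist(rpfs$control)

  density <- list()
  for (cdn in config$density_codons) {
    dres <- stage(paste0("density_", cdn), {
      regions <- extract_codon_regions(ann, ref_seqs, cdn)
      prof <- profile_regions(pooled_cond, pooled_ctrl, regions,
                              min_region_count = config$min_region_count,
                              min_windows_common = config$min_windows_common)
      density_shift(prof)
    })
    density[[cdn]] <- dres
    emit(data.table(position = seq_along(dres$density_shift) - 31L,
                    mean_condition = dres$mean_condition,
                    mean_control = dres$mean_control,
                    density_shift = dres$density_shift),
         sprintf("density_%s.tsv", cdn))
  }

  oof <- list()
  if (length(config$oof_codons) > 0L) {
    rows <- list()
    for (cdn in config$oof_codons) {
      res <- stage(paste0("ooftest_", cdn),
                   oof_test(pooled_cond, pooled_ctrl, cds_seqs, cdn,
                            target_offset = test_offset,
                            min_gene_count = config$min_gene_count))
      oof[[cdn]] <- res
      rows[[cdn]] <- if (inherits(res, "oof_test_degenerate"))
        data.table(codon = cdn, observed_shift = res$observed_shift,
                   background_n = res$background_n, background_mean = NA_real_,
                   background_sd = NA_real_, z = NA_real_,
                   p_two_tailed = NA_real_, shapiro_wilk_p = NA_real_,
                   degenerate = TRUE)
      else
        data.table(codon = cdn, observed_shift = res$observed_shift,
                   background_n = res$background_n,
                   background_mean = res$background_mean,
                   background_sd = res$background_sd, z = res$z,
                   p_two_tailed = res$p_two_tailed,
                   shapiro_wilk_p = res$shapiro_wilk_p, degenerate = FALSE)
    }
    emit(rbindlist(rows), "ooftests.tsv")
  }

  manifest <- list(
    parameters = unclass(config),
    inputs = as.list(tools::md5sum(c(config$annotation, config$sequences,
                                     config$condition, config$control))),
    outputs = as.list(tools::md5sum(written))
  )
  manifest_path <- outp("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(reports = reports, shifts = shifts, aa_tests = aa_tests,
                 density = density, oof = oof, manifest = manifest_path))
}

#' Simulate a two-sample experiment to disk
#'
#' Generates a transcriptome and paired condition/control footprint
#' libraries (replicates differ only in seed), writing FASTA, GTF,
#' coordinate-sorted SAM files and per-library truth tables. The returned
#' paths plug directly into [run_config()].
#'
#' @param out_dir Output directory.
#' @param n_genes,length_range,gc_fraction Transcriptome parameters
#'   ([sim_transcriptome()]).
#' @param n_reads Footprints per library.
#' @param dwell_condition,dwell_control Named dwell multipliers for the two
#'   samples ([stalling_profile()]).
#' @param replicates Number of replicate pairs.
#' @param jitter_prob 5'-end jitter probability.
#' @param seed Master seed; library seeds are derived from it.
#' @return A list of paths: `fasta`, `gtf`, `condition`, `control`,
#'   `truth_condition`, `truth_control`.
#' @export
run_simulation <- function(out_dir, n_genes = 200L,
                           length_range = c(300L, 1800L), gc_fraction = 0.5,
                           n_reads = 1e5, dwell_condition = NULL,
                           dwell_control = NULL, replicates = 1L,
                           jitter_prob = 0, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  txome <- sim_transcriptome(n_genes, length_range, gc_fraction, seed = seed)
  fasta <- file.path(out_dir, "transcriptome.fa")
  gtf <- file.path(out_dir, "annotation.gtf")
  write_transcriptome(txome, fasta, gtf)
  prof_c <- stalling_profile(dwell_condition)
  prof_k <- stalling_profile(dwell_control)
  paths <- list(fasta = fasta, gtf = gtf, condition = character(0),
                control = character(0), truth_condition = character(0),
                truth_control = character(0))
  for (i in seq_len(replicates)) {
    for (side in c("condition", "control")) {
      prof <- if (side == "condition") prof_c else prof_k
      lib_seed <- seed + 1000L * i + (side == "condition")
      fp <- sim_footprints(txome, prof,
                           sim_config(n_reads, seed = lib_seed,
                                      jitter_prob = jitter_prob))
      sam <- file.path(out_dir, sprintf("%s_rep%d.sam", side, i))
      tru <- file.path(out_dir, sprintf("truth_%s_rep%d.tsv", side, i))
      write_sam(fp, txome, sam)
      write_truth(fp, tru)
      paths[[side]] <- c(paths[[side]], sam)
      paths[[paste0("truth_", side)]] <- c(paths[[paste0("truth_", side)]],
                                           tru)
    }
  }
  paths
}
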