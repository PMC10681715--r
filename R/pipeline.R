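#' Pipeline run configuration
#'
#' Collects all stage parameters with their defaults plus the global
#' seed. Per-stage seeds are derived deterministically from the global
#' seed and the stage name (see [stage_seed()]), so stages are
#' independently reproducible. The serialized YAML form round-trips
#' byte-identically.
#'
#' @param out_dir output directory.
#' @param fasta reference FASTA path (NULL when `simulate` is TRUE).
#' @param r1,r2 pooled FASTQ paths (NULL when `simulate` is TRUE).
#' @param whitelist_file barcode whitelist path (one barcode per line,
#'   optional second column cell id); NULL to design one.
#' @param simulate if TRUE, generate the pool with [make_fixture()].
#' @param fixture_profile "tiny" or "small" (when simulating).
#' @param n_cells cells to simulate / barcodes to design.
#' @param reads_per_cell simulated read pairs per cell.
#' @param marker,read_length,insert_min,insert_max,conversion_failure,overconversion,error_rate,spike_frac,ob_fraction simulator parameters, see [pool_config()].
#' @param min_barcode_q,min_trim_len demultiplexing parameters, see
#'   [demux_config()].
#' @param max_mismatch,seed_k aligner parameters, see [build_bs_index()]
#'   and [align_pairs()].
#' @param min_sites QC threshold, see [cell_qc()].
#' @param window_bp cohort window width in bp.
#' @param seed global integer seed.
#' @param log_level "info" or "quiet".
#' @return list of class `msrrbs_config`.
#' @export
msrrbs_config <- function(out_dir,
                          fasta = NULL, r1 = NULL, r2 = NULL,
                          whitelist_file = NULL,
                          simulate = is.null(r1),
                          fixture_profile = "tiny",
                          n_cells = 4L, reads_per_cell = 2000L,
                          marker = "GGTG", read_length = 150L,
                          insert_min = 30L, insert_max = 200L,
                          conversion_failure = 0.004, overconversion = 0,
                          error_rate = 0.001, spike_frac = 0.1,
                          ob_fraction = 0.5,
                          min_barcode_q = 20, min_trim_len = 20L,
                          max_mismatch = 2L, seed_k = 20L,
                          min_sites = 500L, window_bp = 200L,
                          seed = 1L, log_level = "info") {
  cfg <- list(out_dir = out_dir, fasta = fasta, r1 = r1, r2 = r2,
              whitelist_file = whitelist_file, simulate = simulate,
              fixture_profile = fixture_profile,
              n_cells = as.integer(n_cells),
              reads_per_cell = as.integer(reads_per_cell),
              marker = marker, read_length = as.integer(read_length),
              insert_min = as.integer(insert_min),
              insert_max = as.integer(insert_max),
              conversion_failure = conversion_failure,
              overconversion = overconversion, error_rate = error_rate,
              spike_frac = spike_frac, ob_fraction = ob_fraction,
              min_barcode_q = min_barcode_q,
              min_trim_len = as.integer(min_trim_len),
              max_mismatch = as.integer(max_mismatch),
              seed_k = as.integer(seed_k),
              min_sites = as.integer(min_sites),
              window_bp = as.integer(window_bp),
              seed = as.integer(seed), log_level = log_level)
  structure(cfg, class = "msrrbs_config")
}

#' Write / read a run configuration as YAML
#' @param config `msrrbs_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(msrrbs_config, cfg)
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[msrrbs] ", ...)
}

#' Generate a bundled synthetic dataset
#'
#' Emits a reference genome, TSS table, barcode whitelist, pooled
#' paired FASTQ (with spike-in control), truth tables and the control
#' sequence into a directory. The "tiny" profile (one 60-kb
#' chromosome, 4 cells x 300 pairs) runs end-to-end in well under a
#' minute; "small" is two chromosomes, 8 cells x 1000 pairs.
#'
#' @param profile "tiny" or "small".
#' @param seed integer seed; the fixture is byte-identical given it.
#' @param dir output directory (created).
#' @param n_cells,reads_per_cell optional overrides of the profile.
#' @return list with the in-memory objects (`genome`, `catalog`,
#'   `index`, `cgis`, `profiles`, `pool`, `whitelist`, `tss`) and
#'   `paths` of everything written.
#' @export
make_fixture <- function(profile = c("tiny", "small"), seed = 1L, dir,
                         n_cells = NULL, reads_per_cell = NULL) {
  profile <- match.arg(profile)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- switch(profile,
    tiny = list(chroms = c(chr1 = 60000L), cells = 4L, pairs = 300L),
    small = list(chroms = c(chr1 = 120000L, chr2 = 80000L),
                 cells = 8L, pairs = 1000L))
  if (!is.null(n_cells)) spec$cells <- as.integer(n_cells)
  if (!is.null(reads_per_cell)) spec$pairs <- as.integer(reads_per_cell)
  genome <- random_genome(spec$chroms, gc = 0.5,
                          seed = stage_seed(seed, "genome"))
  idx <- index_cpgs(genome)
  cgis <- call_cgis(genome)
  catalog <- digest_mspi(genome)
  whitelist <- make_barcode_whitelist(spec$cells,
                                      seed = stage_seed(seed, "barcodes"))
  names(whitelist) <- sprintf("cell%02d", seq_len(spec$cells))
  profiles <- lapply(seq_len(spec$cells), function(i) {
    simulate_cell_methylome(idx, cgis,
                            seed = stage_seed(seed, paste0("methylome", i)),
                            cell_id = names(whitelist)[i])
  })
  config <- pool_config(barcodes = whitelist,
                        reads_per_cell = spec$pairs,
                        seed = stage_seed(seed, "reads"))
  pool <- simulate_reads(profiles, catalog, config, idx)
  pool <- spike_lambda(pool)
  # TSS table: one gene per ~6 kb, alternating strands
  tss <- data.table::rbindlist(lapply(names(spec$chroms), function(ch) {
    pos <- seq(3000L, spec$chroms[[ch]] - 3000L, by = 6000L)
    data.table::data.table(chrom = ch, pos = pos,
                           strand = rep(c("+", "-"), length.out = length(pos)),
                           gene_id = sprintf("%s_g%03d", ch, seq_along(pos)))
  }))
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    control = file.path(dir, "control.fa"),
    tss = file.path(dir, "tss.tsv"),
    whitelist = file.path(dir, "whitelist.tsv"),
    r1 = file.path(dir, "pool_R1.fastq.gz"),
    r2 = file.path(dir, "pool_R2.fastq.gz"),
    truth = file.path(dir, "truth.tsv"))
  write_genome_fasta(genome, paths$genome)
  write_genome_fasta(lambda_control_genome(), paths$control)
  data.table::fwrite(tss, paths$tss, sep = "\t", col.names = FALSE)
  utils::write.table(data.table::data.table(unname(whitelist), names(whitelist)),
                     paths$whitelist, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_pool_fastq(pool, file.path(dir, "pool"))
  data.table::fwrite(pool$truth, paths$truth, sep = "\t")
  list(genome = genome, catalog = catalog, index = idx, cgis = cgis,
       profiles = profiles, pool = pool, whitelist = whitelist,
       tss = tss, paths = paths)
}

read_whitelist <- function(path) {
  wl <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- wl[[1]]
  names(out) <- if (ncol(wl) >= 2) wl[[2]] else wl[[1]]
  out
}

#' Run the full msRRBS pipeline
#'
#' Executes simulate (optional) -> demultiplex/trim -> bisulfite
#' alignment in fragment space -> per-cell methylation calling -> QC,
#' conversion rate and cohort summaries, writing per-cell CGmap files,
#' report tables and a machine-readable JSON manifest that records
#' per-stage record counts and the conservation identities.
#'
#' @param config `msrrbs_config`.
#' @return the manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "msrrbs_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!config$simulate) {
    for (f in c("fasta", "r1", "r2")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("config validation: input '", f, "' missing or not found")
    }
    if (!is.null(config$whitelist_file) && !file.exists(config$whitelist_file))
      stop("config validation: whitelist file not found")
  }

  # --- stage: inputs / simulation ---
  if (config$simulate) {
    pipe_log(config, "simulating ", config$fixture_profile, " fixture")
    fx <- make_fixture(config$fixture_profile, seed = config$seed,
                       dir = file.path(out, "sim"),
                       n_cells = config$n_cells,
                       reads_per_cell = config$reads_per_cell)
    genome <- fx$genome
    reads <- fx$pool$reads
    whitelist <- fx$whitelist
    truth_rows <- nrow(fx$pool$truth)
  } else {
    genome <- read_genome_fasta(config$fasta)
    reads <- read_fastq_pair(config$r1, config$r2)
    whitelist <- if (!is.null(config$whitelist_file))
      read_whitelist(config$whitelist_file)
    else make_barcode_whitelist(config$n_cells,
                                seed = stage_seed(config$seed, "barcodes"))
    truth_rows <- NA_integer_
  }

  # --- stage: demultiplex + trim ---
  pipe_log(config, "demultiplexing ", nrow(reads), " pairs")
  dcfg <- demux_config(whitelist, marker = config$marker,
                       min_barcode_q = config$min_barcode_q,
                       min_len = config$min_trim_len)
  dm <- demux_trim(reads, dcfg)
  clean <- clean_read_count(dm$report)

  # --- stage: reference spaces ---
  control <- lambda_control_genome()
  cat_g <- select_inserts(digest_mspi(genome),
                          config$insert_min, config$insert_max)
  cat_g[, species := "genome"]
  cat_c <- select_inserts(digest_mspi(control),
                          config$insert_min, config$insert_max)
  cat_c[, species := "spikein"]
  catalog <- rbind(cat_g, cat_c)
  full_index <- index_cpgs(as_genome(c(genome, control)))
  bs <- build_bs_index(catalog, k = config$seed_k)

  # --- stage: alignment ---
  pipe_log(config, "aligning ", nrow(dm$reads), " clean pairs")
  aln <- align_pairs(dm$reads, bs, max_mismatch = config$max_mismatch)
  rates <- mapping_rate(aln, c(raw_pairs = nrow(reads), clean_pairs = clean))

  # --- stage: methylation calling ---
  pipe_log(config, "calling methylation")
  callsets <- pileup_cells(aln, dm$reads, bs, full_index)
  qc <- data.table::rbindlist(lapply(callsets, function(cs)
    as.data.frame(cell_qc(cs, min_sites = config$min_sites,
                          exclude_chrom = "lambda_control"))))
  merged <- merge_callsets(callsets)
  conv <- estimate_conversion_rate(merged)
  ctx <- context_levels(merged, exclude_chrom = "lambda_control")

  # --- stage: cohort summaries ---
  wm <- window_methylation(callsets, config$window_bp, genome)
  utils::write.table(wm, file.path(out, "window_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (cl in names(callsets)) {
    if (nrow(callsets[[cl]]$cpg) > 0)
      write_cgmap(callsets[[cl]], file.path(out, paste0(cl, ".cgmap.tsv")))
  }
  data.table::fwrite(qc, file.path(out, "cell_qc.tsv"), sep = "\t")

  cfg_path <- file.path(out, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("msrrbs")),
    r_version = R.version.string,
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    counts = list(
      input_pairs = nrow(reads), truth_rows = truth_rows,
      assigned = dm$report$assigned, unassigned = dm$report$unassigned,
      quality_filtered = dm$report$quality_filtered,
      dropped_length = dm$report$dropped_length,
      clean_pairs = clean, unique_alignments = sum(aln$status == "unique"),
      cells_detected = length(callsets)),
    conservation = list(
      demux = dm$report$assigned + dm$report$unassigned +
        dm$report$quality_filtered == nrow(reads),
      truth = is.na(truth_rows) || truth_rows == nrow(reads),
      alignments_le_clean = sum(aln$status == "unique") <= clean),
    mapping_rate = as.list(rates),
    conversion_rate = conv$rate,
    context_levels = as.list(ctx),
    qc_pass = sum(qc$pass))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!all(unlist(manifest$conservation)))
    stop("pipeline conservation identity violated; see manifest")
  invisible(manifest)
}
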