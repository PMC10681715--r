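# Shared synthetic fixtures, built once per test run and cached.
.fx_env <- new.env(parent = emptyenv())

# a small error-free pool with matching references, used by the demux,
# alignment and calling tests
fx_clean_pool <- function() {
  if (!is.null(.fx_env$clean)) return(.fx_env$clean)
  g <- random_genome(c(chr1 = 40000L), seed = 11)
  idx <- index_cpgs(g)
  cgis <- call_cgis(g)
  catalog <- digest_mspi(g)
  wl <- make_barcode_whitelist(4, seed = 5)
  names(wl) <- paste0("cell", 1:4)
  profiles <- lapply(1:4, function(i) {
    simulate_cell_methylome(idx, cgis, seed = i, cell_id = paste0("cell", i))
  })
  cfg <- pool_config(wl, reads_per_cell = 400L, error_rate = 0,
                     conversion_failure = 0, spike_frac = 0, seed = 7)
  pool <- simulate_reads(profiles, catalog, cfg, idx)
  selected <- select_inserts(catalog)
  .fx_env$clean <- list(genome = g, index = idx, cgis = cgis,
                        catalog = catalog, selected = selected,
                        whitelist = wl, profiles = profiles,
                        config = cfg, pool = pool)
  .fx_env$clean
}

# the clean pool taken through demux + trim + alignment
fx_aligned <- function() {
  if (!is.null(.fx_env$aligned)) return(.fx_env$aligned)
  fx <- fx_clean_pool()
  dm <- demux_trim(fx$pool$reads, demux_config(fx$whitelist))
  bs <- build_bs_index(fx$selected)
  aln <- align_pairs(dm$reads, bs)
  .fx_env$aligned <- c(fx, list(dm = dm, bs = bs, aln = aln))
  .fx_env$aligned
}

# map truth cell ids (profile ids) onto demux cell ids via barcode
truth_cell_of <- function(pool, whitelist, ids) {
  bc <- pool$truth$barcode[match(ids, pool$truth$read_id)]
  names(whitelist)[match(bc, whitelist)]
}

# a full default-parameter pipeline run (4 cells, spike-in control,
# conversion failure 0.004, sequencing error 0.001), sized so the
# control contributes >= 50k cytosine observations and the genome
# >= 100k non-CpG observations
fx_default_run <- function() {
  if (!is.null(.fx_env$default_run)) return(.fx_env$default_run)
  g <- random_genome(c(chr1 = 40000L), seed = 11)
  idx <- index_cpgs(g)
  cgis <- call_cgis(g)
  catalog <- digest_mspi(g)
  wl <- make_barcode_whitelist(4, seed = 5)
  names(wl) <- paste0("cell", 1:4)
  profiles <- lapply(1:4, function(i) {
    simulate_cell_methylome(idx, cgis, seed = i, cell_id = paste0("cell", i))
  })
  cfg <- pool_config(wl, reads_per_cell = 5500L, seed = 7)
  pool <- spike_lambda(simulate_reads(profiles, catalog, cfg, idx))
  dm <- demux_trim(pool$reads, demux_config(wl))
  ctrl <- lambda_control_genome()
  catg <- select_inserts(catalog)
  catg[, species := "genome"]
  catc <- select_inserts(digest_mspi(ctrl))
  catc[, species := "spikein"]
  bs <- build_bs_index(rbind(catg, catc))
  fidx <- index_cpgs(as_genome(c(g, ctrl)))
  aln <- align_pairs(dm$reads, bs)
  merged <- pileup_calls(aln, dm$reads, bs, fidx, cell_id = "merged")
  .fx_env$default_run <- list(genome = g, index = fidx, cgis = cgis,
                              whitelist = wl, profiles = profiles,
                              config = cfg, pool = pool, dm = dm, bs = bs,
                              aln = aln, merged = merged)
  .fx_env$default_run
}
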