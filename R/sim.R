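# complement lookup used in per-molecule hot loops
.base_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# greedy code over candidate words in the given order: accept a word
# when its Hamming distance to all accepted words is >= min_hamming
greedy_code <- function(cand, word_len, min_hamming, n_max = Inf) {
  m <- do.call(rbind, strsplit(cand, "", fixed = TRUE))
  accepted <- integer(0)
  for (i in seq_along(cand)) {
    if (length(accepted) > 0) {
      d <- rowSums(m[accepted, , drop = FALSE] !=
                     matrix(m[i, ], length(accepted), word_len, byrow = TRUE))
      if (min(d) < min_hamming) next
    }
    accepted <- c(accepted, i)
    if (length(accepted) >= n_max) break
  }
  cand[accepted]
}

#' Design a cell-barcode whitelist
#'
#' Builds the lexicographic greedy code (lexicode) over all barcodes of
#' the given length with no homopolymer run of 4 or more bases and
#' pairwise Hamming distance at least `min_hamming`, then draws `n`
#' barcodes from it in seeded random order. At the protocol's layout
#' (length 6, distance 3) the lexicode holds 109 barcodes, comfortably
#' covering the 96-barcode design. Deterministic given the seed;
#' requests beyond the code's capacity raise a feasibility error.
#'
#' @param n number of barcodes (the protocol designs 96).
#' @param length barcode length in bases (6 in the read layout).
#' @param min_hamming minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of `n` barcodes.
#' @export
make_barcode_whitelist <- function(n, length = 6L, min_hamming = 3L, seed = 1L) {
  stopifnot(n >= 1, length >= 1, length <= 10)
  if (n > 4^length)
    stop("infeasible barcode request: ", n,
         " barcodes cannot exist at length ", length)
  bases <- c("A", "C", "G", "T")
  words <- do.call(expand.grid, rep(list(bases), length))
  all_codes <- sort(do.call(paste0, words))
  all_codes <- all_codes[!grepl("AAAA|CCCC|GGGG|TTTT", all_codes)]
  code <- greedy_code(all_codes, length, min_hamming)
  if (n > base::length(code))
    stop("infeasible barcode request: the length-", length, " distance-",
         min_hamming, " code holds ", base::length(code),
         " barcodes, fewer than the ", n, " requested")
  local_seed(seed, sample(code, n))
}

#' Methylome archetype parameters
#'
#' An archetype describes the per-CpG methylation probability
#' distribution of a cell type: one Beta law for CpGs inside CGIs
#' (hypomethylated in mammalian cells) and one for the background
#' (hypermethylated). A length-1 numeric fixes the probability instead
#' of drawing it.
#'
#' @param cgi Beta shape pair for CGI CpGs, or a single fixed probability.
#' @param background Beta shape pair (or fixed probability) elsewhere.
#' @return list of class `methylome_archetype`.
#' @export
methylome_archetype <- function(cgi = c(1, 9), background = c(6, 2)) {
  chk <- function(x) stopifnot(is.numeric(x), length(x) %in% 1:2, all(x >= 0))
  chk(cgi); chk(background)
  structure(list(cgi = cgi, background = background),
            class = "methylome_archetype")
}

draw_archetype <- function(par, k) {
  if (length(par) == 1) rep(par, k) else stats::rbeta(k, par[1], par[2])
}

#' Simulate a per-cell methylome
#'
#' Draws a methylation probability for every CpG site in the index: CGI
#' CpGs from the archetype's low-methylation Beta, all others from the
#' background Beta. This reproduces the canonical pattern of
#' hypomethylated islands against a methylated background.
#'
#' @param index `cpg_index` from [index_cpgs()].
#' @param cgis CGI ElementSet (may be empty).
#' @param archetype [methylome_archetype()].
#' @param seed integer seed.
#' @param cell_id,species identifiers recorded in the profile.
#' @return `cell_profile`: list with `cell_id`, `species` and
#'   `prob = data.table(chrom, pos, p)`.
#' @export
simulate_cell_methylome <- function(index, cgis = NULL,
                                    archetype = methylome_archetype(),
                                    seed = 1L, cell_id = "cell1",
                                    species = "speciesA") {
  sites <- data.table::copy(index$sites)
  in_cgi <- rep(FALSE, nrow(sites))
  if (!is.null(cgis) && length(cgis) > 0) {
    gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    in_cgi <- IRanges::overlapsAny(gr, cgis, ignore.strand = TRUE)
  }
  p <- local_seed(seed, {
    out <- numeric(nrow(sites))
    out[in_cgi] <- draw_archetype(archetype$cgi, sum(in_cgi))
    out[!in_cgi] <- draw_archetype(archetype$background, sum(!in_cgi))
    out
  })
  sites[, p := p]
  structure(list(cell_id = cell_id, species = species, prob = sites),
            class = "cell_profile")
}

#' Pool (simulation) configuration
#'
#' Defaults follow the msRRBS library architecture: 4-bp marker "GGTG",
#' 6-bp cell barcode, 2x150 bp reads, 30-200 bp inserts, bisulfite
#' conversion failure 0.004 (i.e. 99.6% conversion), no over-conversion,
#' per-base sequencing error 0.001, both molecule strands sequenced
#' 50/50, and a 10% unmethylated-control spike-in fraction.
#'
#' @param barcodes barcode whitelist (distinct, equal length).
#' @param marker 4-bp marker sequence, or "NNNN" for random-marker mode.
#' @param conversion_failure probability an unmethylated C stays C.
#' @param overconversion probability a methylated C is converted to T.
#' @param read_length sequencing read length in bp.
#' @param insert_min,insert_max insert-size selection window in bp.
#' @param reads_per_cell read pairs emitted per cell.
#' @param error_rate per-base substitution error probability.
#' @param pcr_dup_rate probability a molecule is emitted twice.
#' @param spike_frac unmethylated-control pairs as a fraction of the
#'   genomic pairs in the pool.
#' @param ob_fraction fraction of molecules sequenced from the original
#'   bottom strand.
#' @param adapter_stub fixed sequencing-adapter stub appearing after the
#'   read-through barcode on short inserts.
#' @param seed integer seed for the whole pool.
#' @return list of class `pool_config`.
#' @export
pool_config <- function(barcodes,
                        marker = "GGTG",
                        conversion_failure = 0.004,
                        overconversion = 0,
                        read_length = 150L,
                        insert_min = 30L,
                        insert_max = 200L,
                        reads_per_cell = 2000L,
                        error_rate = 0.001,
                        pcr_dup_rate = 0,
                        spike_frac = 0.1,
                        ob_fraction = 0.5,
                        adapter_stub = "AGATCGGAAGAGC",
                        seed = 1L) {
  stopifnot(length(barcodes) >= 1, !anyDuplicated(barcodes),
            all(nchar(barcodes) == nchar(barcodes[1])),
            nchar(marker) == 4,
            conversion_failure >= 0, conversion_failure <= 1,
            overconversion >= 0, overconversion <= 1,
            error_rate >= 0, error_rate <= 1,
            spike_frac >= 0, ob_fraction >= 0, ob_fraction <= 1,
            insert_min > 0, insert_min <= insert_max)
  structure(list(barcodes = barcodes, marker = marker,
                 conversion_failure = conversion_failure,
                 overconversion = overconversion,
                 read_length = as.integer(read_length),
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 reads_per_cell = as.integer(reads_per_cell),
                 error_rate = error_rate, pcr_dup_rate = pcr_dup_rate,
                 spike_frac = spike_frac, ob_fraction = ob_fraction,
                 adapter_stub = adapter_stub, seed = as.integer(seed)),
            class = "pool_config")
}

#' Bisulfite-convert a sequence
#'
#' Each unmethylated C is converted to T with probability
#' `1 - conversion_failure`; each methylated C is read as C unless
#' over-converted. Non-C bases are unchanged. Uses the current RNG
#' state; wrap in a seeded context for reproducibility.
#'
#' @param sequence DNA string.
#' @param meth logical vector, one entry per C of `sequence` in order
#'   (TRUE = methylated).
#' @param conversion_failure,overconversion probabilities as in
#'   [pool_config()].
#' @return converted DNA string.
#' @export
bisulfite_convert <- function(sequence, meth, conversion_failure = 0.004,
                              overconversion = 0) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  c_idx <- which(ch == "C")
  if (length(c_idx) != length(meth))
    stop("methylation state must be given for every C (",
         length(c_idx), " Cs, ", length(meth), " states)")
  if (length(c_idx)) {
    u <- stats::runif(length(c_idx))
    to_t <- ifelse(meth, u < overconversion, u < 1 - conversion_failure)
    ch[c_idx[to_t]] <- "T"
  }
  paste(ch, collapse = "")
}

# Per-fragment simulation context: character vectors for both strands and
# cytosine tables (molecule-strand offsets, CpG flag, genome CpG position).
fragment_sim_context <- function(catalog, index) {
  cyt <- index$cytosines
  lapply(seq_len(nrow(catalog)), function(i) {
    fr <- catalog[i]
    top <- strsplit(fr$seq, "", fixed = TRUE)[[1]]
    L <- length(top)
    cy <- cyt[chrom == fr$chrom & pos >= fr$start & pos <= fr$end]
    plus <- cy[strand == "+"]
    minus <- cy[strand == "-"]
    list(
      id = fr$id, chrom = fr$chrom, start = fr$start, end = fr$end, L = L,
      top = top,
      bot = rev(chartr("ACGTN", "TGCAN", top)),
      ot = list(off = plus$pos - fr$start + 1L,
                is_cpg = plus$context == "CG",
                cpg_pos = plus$pos,
                context = plus$context),
      ob = list(off = L - (minus$pos - fr$start + 1L) + 1L,
                is_cpg = minus$context == "CG",
                cpg_pos = minus$pos - 1L,   # plus-strand C of the CpG
                context = minus$context)
    )
  })
}

# Assemble one mate string: structural prefix, converted insert, and for
# short inserts the read-through (revcomp of the 10-bp prefix) + adapter.
assemble_mate <- function(prefix, insert, readthrough, stub, read_length) {
  core <- paste0(prefix, insert)
  if (nchar(core) < read_length)
    core <- paste0(core, readthrough, stub)
  substr(core, 1L, read_length)
}

simulate_molecules <- function(cells, catalog, config, index, id_prefix,
                               is_spikein = FALSE) {
  ctx <- fragment_sim_context(catalog, index)
  nfrag <- length(ctx)
  if (nfrag == 0) stop("empty fragment catalog after size selection")
  qchar <- rawToChar(as.raw(33L + min(40L,
    if (config$error_rate > 0) round(-10 * log10(config$error_rate)) else 40L)))
  rl <- config$read_length
  pre_len <- 4L + nchar(config$barcodes[1])
  stub <- config$adapter_stub
  marker_draw <- identical(config$marker, "NNNN")

  N <- sum(vapply(cells, `[[`, 0L, "n_pairs"))
  r1 <- character(N); r2 <- character(N)
  t_cell <- character(N); t_bc <- character(N); t_frag <- character(N)
  t_chrom <- character(N); t_start <- integer(N); t_end <- integer(N)
  t_len <- integer(N); t_species <- character(N); t_strand <- character(N)
  t_nc <- integer(N); t_nm <- integer(N); t_conv <- integer(N)
  serial <- 0L
  for (cell in cells) {
    n <- cell$n_pairs
    if (n == 0) next
    frag_i <- sample.int(nfrag, n, replace = TRUE)
    ob <- stats::runif(n) < config$ob_fraction
    # per-(fragment, strand) CpG probability lookups for this cell, cached
    pmap <- new.env(parent = emptyenv())
    prob <- cell$profile$prob
    data.table::setkey(prob, chrom, pos)
    prefix_fixed <- paste0(config$marker, cell$barcode)
    rt_fixed <- revcomp(prefix_fixed)
    for (j in seq_len(n)) {
      fc <- ctx[[frag_i[j]]]
      strand <- if (ob[j]) "ob" else "ot"
      info <- fc[[strand]]
      key <- paste0(fc$id, ".", strand)
      pv <- get0(key, envir = pmap)
      if (is.null(pv)) {
        pv <- rep(0, length(info$off))
        if (any(info$is_cpg)) {
          look <- prob[data.table::data.table(chrom = fc$chrom,
                                              pos = info$cpg_pos[info$is_cpg])]
          pv[info$is_cpg] <- ifelse(is.na(look$p), 0, look$p)
        }
        assign(key, pv, envir = pmap)
      }
      nm <- length(info$off)
      meth <- if (nm) stats::runif(nm) < pv else logical(0)
      mol <- if (ob[j]) fc$bot else fc$top
      to_t <- logical(nm)
      if (nm) {
        u <- stats::runif(nm)
        to_t <- ifelse(meth, u < config$overconversion,
                       u < 1 - config$conversion_failure)
        mol[info$off[to_t]] <- "T"
      }
      conv <- paste(mol, collapse = "")
      conv_rc <- paste(.base_comp[rev(mol)], collapse = "")
      if (marker_draw) {
        marker <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                        collapse = "")
        prefix <- paste0(marker, cell$barcode)
        readthrough <- revcomp(prefix)
      } else {
        prefix <- prefix_fixed
        readthrough <- rt_fixed
      }
      serial <- serial + 1L
      r1[serial] <- assemble_mate(prefix, conv, readthrough, stub, rl)
      r2[serial] <- assemble_mate(prefix, conv_rc, readthrough, stub, rl)
      t_cell[serial] <- cell$cell_id; t_bc[serial] <- cell$barcode
      t_frag[serial] <- fc$id; t_chrom[serial] <- fc$chrom
      t_start[serial] <- fc$start; t_end[serial] <- fc$end
      t_len[serial] <- fc$L; t_species[serial] <- cell$species
      t_strand[serial] <- if (ob[j]) "OB" else "OT"
      t_nc[serial] <- nm; t_nm[serial] <- sum(meth)
      t_conv[serial] <- sum(to_t)
    }
  }
  ids <- sprintf("%s_%07d", id_prefix, seq_len(N))
  truth <- data.table::data.table(
    read_id = ids, cell_id = t_cell, barcode = t_bc, fragment_id = t_frag,
    chrom = t_chrom, start = t_start, end = t_end, insert_len = t_len,
    species = t_species, is_spikein = is_spikein, strand = t_strand,
    n_c = t_nc, n_meth = t_nm, n_converted = t_conv,
    n_retained = t_nc - t_conv)
  list(r1 = r1, r2 = r2, ids = ids, truth = truth, qchar = qchar)
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, error_rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate an msRRBS read pool
#'
#' Emits paired reads for each cell profile: an insert sampled from the
#' size-selected fragment catalog, per-molecule CpG methylation states
#' drawn from the cell's per-site probabilities (non-CpG cytosines
#' unmethylated), bisulfite conversion of the sequenced strand, the
#' structural layout \code{[marker][barcode][converted insert]} on both
#' mates with read-through into the opposite prefix and adapter stub on
#' short inserts, and per-base substitution errors. Truth rows record
#' one entry per emitted pair.
#'
#' @param profiles list of `cell_profile` objects (one per cell).
#' @param catalog size-selected fragment catalog.
#' @param config [pool_config()]; barcodes are assigned to profiles in
#'   order.
#' @param index `cpg_index` of the genome the catalog came from.
#' @param pool_id prefix for read names.
#' @return a pool: list with `reads` (`data.table(id, seq1, qual1, seq2,
#'   qual2)`), `truth` and `config`.
#' @export
simulate_reads <- function(profiles, catalog, config, index,
                           pool_id = "pool") {
  catalog <- select_inserts(catalog, config$insert_min, config$insert_max)
  if (nrow(catalog) == 0) stop("empty fragment catalog after size selection")
  if (length(profiles) > length(config$barcodes))
    stop("more profiles than barcodes in the whitelist")
  cells <- lapply(seq_along(profiles), function(i) {
    list(cell_id = profiles[[i]]$cell_id, species = profiles[[i]]$species,
         barcode = config$barcodes[i], profile = profiles[[i]],
         n_pairs = config$reads_per_cell)
  })
  out <- local_seed(config$seed, {
    sim <- simulate_molecules(cells, catalog, config, index, pool_id)
    sim$r1 <- inject_errors(sim$r1, config$error_rate)
    sim$r2 <- inject_errors(sim$r2, config$error_rate)
    sim
  })
  reads <- data.table::data.table(
    id = out$ids, seq1 = out$r1,
    qual1 = strrep(out$qchar, nchar(out$r1)),
    seq2 = out$r2, qual2 = strrep(out$qchar, nchar(out$r2)))
  list(reads = reads, truth = out$truth, config = config)
}

#' Packaged unmethylated control sequence
#'
#' A synthetic 48,502-bp random sequence standing in for an unmethylated
#' spike-in control genome (the protocol spikes unmethylated lambda
#' phage DNA). Deterministic; regenerated from a fixed seed at run time.
#'
#' @return single-chromosome genome named `lambda_control`.
#' @export
lambda_control_genome <- function() {
  random_genome(c(lambda_control = 48502L), gc = 0.5, seed = 48502L)
}

#' Append unmethylated spike-in control reads to a pool
#'
#' Control reads follow the same simulation path with every cytosine
#' unmethylated, are distributed across the pool's cells, and are
#' flagged `is_spikein` in the truth table. The number of control pairs
#' is `round(spike_frac x genomic pairs)`.
#'
#' @param pool pool from [simulate_reads()].
#' @param control_genome control genome (default
#'   [lambda_control_genome()]).
#' @return pool with control reads and truth rows appended.
#' @export
spike_lambda <- function(pool, control_genome = lambda_control_genome()) {
  config <- pool$config
  n_spike <- round(config$spike_frac * nrow(pool$reads))
  if (n_spike == 0) return(pool)
  idx <- index_cpgs(control_genome)
  catalog <- select_inserts(digest_mspi(control_genome),
                            config$insert_min, config$insert_max)
  cell_ids <- unique(pool$truth$cell_id)
  bcs <- pool$truth$barcode[match(cell_ids, pool$truth$cell_id)]
  unmeth <- list(prob = idx$sites[, .(chrom, pos, p = 0)])
  per_cell <- diff(round(seq(0, n_spike, length.out = length(cell_ids) + 1)))
  cells <- lapply(seq_along(cell_ids), function(i) {
    list(cell_id = cell_ids[i], species = "spikein", barcode = bcs[i],
         profile = unmeth, n_pairs = as.integer(per_cell[i]))
  })
  out <- local_seed(stage_seed(config$seed, "spike"), {
    sim <- simulate_molecules(cells, catalog, config, idx, "spike",
                              is_spikein = TRUE)
    sim$r1 <- inject_errors(sim$r1, config$error_rate)
    sim$r2 <- inject_errors(sim$r2, config$error_rate)
    sim
  })
  reads <- data.table::data.table(
    id = out$ids, seq1 = out$r1,
    qual1 = strrep(out$qchar, nchar(out$r1)),
    seq2 = out$r2, qual2 = strrep(out$qchar, nchar(out$r2)))
  list(reads = rbind(pool$reads, reads),
       truth = rbind(pool$truth, out$truth),
       config = config)
}

#' Simulate a two-species (barnyard) pool
#'
#' Cells are assigned a species; each cell's reads are drawn only from
#' its species' fragment catalog. Used to quantify cross-barcode
#' contamination via species-specific mapping.
#'
#' @param genome1,genome2 the two genomes (built from independent seeds,
#'   so they share no long subsequences).
#' @param cells1,cells2 number of cells of each species.
#' @param config [pool_config()] with at least `cells1 + cells2` barcodes.
#' @param archetype methylome archetype used for both species.
#' @return pool with per-read species truth.
#' @export
simulate_barnyard <- function(genome1, genome2, cells1, cells2, config,
                              archetype = methylome_archetype()) {
  sim_one <- function(genome, ncell, species, bc_offset, sub) {
    idx <- index_cpgs(genome)
    cgis <- call_cgis(genome)
    cat <- select_inserts(digest_mspi(genome), config$insert_min, config$insert_max)
    profiles <- lapply(seq_len(ncell), function(i) {
      simulate_cell_methylome(idx, cgis, archetype,
                              seed = stage_seed(config$seed, paste0(species, i)),
                              cell_id = sprintf("%s_c%02d", species, i),
                              species = species)
    })
    cfg <- config
    cfg$barcodes <- config$barcodes[bc_offset + seq_len(ncell)]
    cfg$seed <- stage_seed(config$seed, species)
    cfg$spike_frac <- 0
    simulate_reads(profiles, cat, cfg, idx, pool_id = sub)
  }
  pools <- list()
  if (cells1 > 0) pools <- c(pools, list(sim_one(genome1, cells1, "species1", 0L, "bnA")))
  if (cells2 > 0) pools <- c(pools, list(sim_one(genome2, cells2, "species2", cells1, "bnB")))
  list(reads = data.table::rbindlist(lapply(pools, `[[`, "reads")),
       truth = data.table::rbindlist(lapply(pools, `[[`, "truth")),
       config = config)
}

#' Write a pool as paired gzip FASTQ
#' @param pool pool object with a `reads` table.
#' @param prefix path prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return the two file paths, invisibly.
#' @export
write_pool_fastq <- function(pool, prefix) {
  p1 <- paste0(prefix, "_R1.fastq.gz")
  p2 <- paste0(prefix, "_R2.fastq.gz")
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = TRUE)
  }
  wr(pool$reads$seq1, pool$reads$qual1, paste0(pool$reads$id, "/1"), p1)
  wr(pool$reads$seq2, pool$reads$qual2, paste0(pool$reads$id, "/2"), p2)
  invisible(c(p1, p2))
}

#' Read paired FASTQ into a reads table
#' @param r1,r2 FASTQ paths (gzip allowed).
#' @return `data.table(id, seq1, qual1, seq2, qual2)`.
#' @export
read_fastq_pair <- function(r1, r2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    data.table::data.table(id = sub("/[12]$", "", names(x)),
                           seq = as.character(x),
                           qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1); b <- rd(r2)
  if (nrow(a) != nrow(b) || !all(a$id == b$id))
    stop("R1/R2 FASTQ files are not properly paired")
  data.table::data.table(id = a$id, seq1 = a$seq, qual1 = a$qual,
                         seq2 = b$seq, qual2 = b$qual)
}
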