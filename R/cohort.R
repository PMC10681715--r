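#' Merge methylation call sets
#'
#' Sums per-site counts across inputs; a site is present iff present in
#' at least one input. The same operation serves pseudo-bulk merging
#' (across cells) and silicon-merging (across library size windows of
#' one sample). Associative and commutative on counts.
#'
#' @param callsets list of `methylation_calls` sharing a genome and
#'   strand convention.
#' @param cell_id identifier for the merged result.
#' @return merged `methylation_calls`.
#' @export
merge_callsets <- function(callsets, cell_id = "merged") {
  stopifnot(length(callsets) >= 1)
  de <- vapply(callsets, `[[`, logical(1), "destranded")
  if (length(unique(de)) != 1)
    stop("cannot merge stranded with destranded call sets")
  byc <- if (de[1]) c("chrom", "pos") else c("chrom", "pos", "strand")
  cpg <- data.table::rbindlist(lapply(callsets, `[[`, "cpg"))
  cpg <- cpg[, .(meth = sum(meth), unmeth = sum(unmeth)), by = byc]
  noncpg <- data.table::rbindlist(lapply(callsets, `[[`, "noncpg"))
  if (nrow(noncpg))
    noncpg <- noncpg[, .(meth = sum(meth), unmeth = sum(unmeth)),
                     by = .(chrom, context)]
  methylation_calls(cpg, noncpg, cell_id = cell_id, destranded = de[1])
}

#' Element detection count and rate
#'
#' An element is detected iff at least one CpG site with at least one
#' read lies within it.
#'
#' @param callset `methylation_calls`.
#' @param elements deduplicated ElementSet.
#' @return list with `detected` and `fraction`.
#' @export
element_detection_rate <- function(callset, elements) {
  if (length(elements) == 0) stop("empty element set")
  cg <- callset$cpg[callset$cpg$meth + callset$cpg$unmeth >= 1]
  if (nrow(cg) == 0) return(list(detected = 0L, fraction = 0))
  sites <- GenomicRanges::GRanges(cg$chrom, IRanges::IRanges(cg$pos, cg$pos))
  det <- sum(IRanges::overlapsAny(elements, sites, ignore.strand = TRUE))
  list(detected = det, fraction = det / length(elements))
}

#' Saturation curve by clean-read downsampling
#'
#' For each depth, samples that many clean read pairs without
#' replacement (per replicate), re-calls methylation from the uniquely
#' aligned subset, and counts detected CpG sites and elements with at
#' least one covered CpG. The downsampling unit is the clean read pair,
#' so unmapped pairs consume depth as they do in real libraries.
#'
#' @param alignments alignment table over all clean pairs.
#' @param reads trimmed reads table.
#' @param index `bs_index`.
#' @param cpg_index genome `cpg_index`.
#' @param elements ElementSet counted at each depth.
#' @param depths increasing clean-pair depths.
#' @param replicates subsampling replicates per depth.
#' @param seed integer seed.
#' @return `data.table(depth, cpg_detected, elements_detected)` of
#'   replicate means; attribute `kind` records the element kind.
#' @export
downsample_saturation <- function(alignments, reads, index, cpg_index,
                                  elements, depths, replicates = 5L,
                                  seed = 1L) {
  total <- nrow(alignments)
  if (any(depths > total)) {
    warning("depths exceeding ", total, " clean pairs clipped")
    depths <- pmin(depths, total)
  }
  depths <- sort(unique(as.integer(depths)))
  res <- local_seed(seed, {
    rows <- lapply(depths, function(d) {
      reps <- vapply(seq_len(replicates), function(r) {
        sub <- if (d == total) alignments
        else alignments[sample.int(total, d)]
        cs <- pileup_calls(sub, reads, index, cpg_index)
        c(nrow(cs$cpg), element_detection_rate(cs, elements)$detected)
      }, numeric(2))
      data.table::data.table(depth = d,
                             cpg_detected = mean(reps[1, ]),
                             elements_detected = mean(reps[2, ]))
    })
    data.table::rbindlist(rows)
  })
  data.table::setattr(res, "kind", element_kind(elements))
  res[]
}

#' Genome-window methylation matrix
#'
#' Fixed-width windows tile each chromosome; the entry for a cell and
#' window is the coverage-weighted level (sum of methylated counts over
#' sum of total counts) across CpGs in the window, NA when no CpG is
#' covered.
#'
#' @param callsets list of `methylation_calls` (named by cell).
#' @param window_bp window width in bp (0.2 kb and 50 kb in common use).
#' @param genome genome object supplying chromosome lengths.
#' @return numeric matrix, cells x windows; column names
#'   `chrom:start-end` (1-based closed).
#' @export
window_methylation <- function(callsets, window_bp, genome) {
  stopifnot(window_bp >= 1)
  sl <- genome_lengths(as_genome(genome))
  wins <- data.table::rbindlist(lapply(names(sl), function(ch) {
    starts <- seq(1L, sl[[ch]], by = window_bp)
    data.table::data.table(chrom = ch, wstart = starts,
                           wend = pmin(starts + window_bp - 1L, sl[[ch]]))
  }))
  wins[, col := sprintf("%s:%d-%d", chrom, wstart, wend)]
  nm <- names(callsets)
  if (is.null(nm)) nm <- vapply(callsets, `[[`, character(1), "cell_id")
  mat <- matrix(NA_real_, length(callsets), nrow(wins),
                dimnames = list(nm, wins$col))
  for (i in seq_along(callsets)) {
    cg <- callsets[[i]]$cpg[chrom %in% names(sl)]
    if (nrow(cg) == 0) next
    w <- cg[, .(chrom, wstart = (pos - 1L) %/% window_bp * window_bp + 1L,
                meth, unmeth)]
    agg <- w[, .(level = sum(meth) / sum(meth + unmeth)),
             by = .(chrom, wstart)]
    idx <- match(paste(agg$chrom, agg$wstart), paste(wins$chrom, wins$wstart))
    mat[i, idx[!is.na(idx)]] <- agg$level[!is.na(idx)]
  }
  mat
}

#' Pairwise Pearson correlation of call sets
#'
#' For each pair, Pearson r over CpG sites with total coverage at least
#' `min_cov` in both members; entries with fewer than 3 shared sites are
#' NA.
#'
#' @param callsets list of at least two `methylation_calls`.
#' @param min_cov per-site coverage floor applied to both members (the
#'   bulk-comparison presets are 3, 5, 10, 15, 20).
#' @return symmetric correlation matrix.
#' @export
pairwise_correlation <- function(callsets, min_cov = 1L) {
  stopifnot(length(callsets) >= 2)
  nm <- names(callsets)
  if (is.null(nm)) nm <- vapply(callsets, `[[`, character(1), "cell_id")
  lv <- lapply(callsets, function(cs) {
    cg <- cs$cpg[cs$cpg$meth + cs$cpg$unmeth >= min_cov]
    data.table::data.table(site = paste(cg$chrom, cg$pos),
                           level = cg$meth / (cg$meth + cg$unmeth))
  })
  n <- length(callsets)
  m <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    m[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      sh <- merge(lv[[i]], lv[[j]], by = "site")
      if (nrow(sh) >= 3) {
        r <- suppressWarnings(stats::cor(sh$level.x, sh$level.y))
        m[i, j] <- m[j, i] <- r
      }
    }
  }
  m
}

#' Metagene methylation profile
#'
#' Averages methylation along gene bodies (scaled to `body_bins`) and
#' fixed-width flanks of `flank` bp up- and downstream (each split into
#' `flank_bins`), strand-aware (minus-strand genes are reversed), with
#' coverage-weighted per-bin levels across all genes.
#'
#' @param callset `methylation_calls`.
#' @param genes `GRanges` of gene bodies with strand.
#' @param flank flank width in bp.
#' @param body_bins,flank_bins bin counts.
#' @return `data.table(bin, zone, level)` with zone in
#'   upstream/body/downstream; level NA for uncovered bins.
#' @export
metagene_profile <- function(callset, genes, flank = 5000L,
                             body_bins = 40L, flank_bins = 20L) {
  if (length(genes) == 0) stop("no genes supplied")
  cg <- callset$cpg
  total_bins <- 2L * flank_bins + body_bins
  binw <- flank / flank_bins
  acc_m <- numeric(total_bins); acc_t <- numeric(total_bins)
  for (g in seq_along(genes)) {
    ch <- as.character(GenomeInfoDb::seqnames(genes)[g])
    gs <- GenomicRanges::start(genes)[g]
    ge <- GenomicRanges::end(genes)[g]
    neg <- as.character(GenomicRanges::strand(genes)[g]) == "-"
    sub <- cg[chrom == ch & pos >= gs - flank & pos <= ge + flank]
    if (nrow(sub) == 0) next
    bin <- integer(nrow(sub))
    up <- sub$pos < gs
    dn <- sub$pos > ge
    body <- !up & !dn
    bin[up] <- pmin(flank_bins, floor((sub$pos[up] - (gs - flank)) / binw) + 1L)
    bin[body] <- flank_bins +
      pmin(body_bins, floor((sub$pos[body] - gs) / (ge - gs + 1L) * body_bins) + 1L)
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins, floor((sub$pos[dn] - ge - 1L) / binw) + 1L)
    if (neg) bin <- total_bins + 1L - bin
    for (k in seq_len(nrow(sub))) {
      acc_m[bin[k]] <- acc_m[bin[k]] + sub$meth[k]
      acc_t[bin[k]] <- acc_t[bin[k]] + sub$meth[k] + sub$unmeth[k]
    }
  }
  data.table::data.table(
    bin = seq_len(total_bins),
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, body_bins, flank_bins)),
    level = ifelse(acc_t > 0, acc_m / acc_t, NA_real_))
}

#' Embed cells in two dimensions
#'
#' Windows missing in more than `max_missing` of cells are dropped and
#' remaining missing entries are imputed with the window mean (embedding
#' methods need complete input); then PCA (`prcomp`), classical MDS
#' (`cmdscale`) or tSNE (`Rtsne`) produces one 2-D coordinate per cell.
#' Deterministic given the seed.
#'
#' @param mat cells x windows matrix from [window_methylation()].
#' @param method "pca", "mds" or "tsne".
#' @param seed integer seed (used by tSNE; PCA/MDS are deterministic).
#' @param max_missing per-window missingness cutoff.
#' @return numeric matrix cells x 2.
#' @export
embed_cells <- function(mat, method = c("pca", "mds", "tsne"), seed = 1L,
                        max_missing = 0.8) {
  method <- match.arg(method)
  if (nrow(mat) < 3) stop("need at least 3 cells to embed")
  keep <- colMeans(is.na(mat)) <= max_missing
  x <- mat[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("no windows left after missingness filter")
  cm <- colMeans(x, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- cm[j]
  coords <- local_seed(seed, switch(
    method,
    pca = {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      k <- min(2L, ncol(pc$x))
      cbind(pc$x[, seq_len(k)], matrix(0, nrow(x), 2L - k))
    },
    mds = {
      d <- stats::dist(x)
      fit <- stats::cmdscale(d, k = 2)
      if (ncol(fit) < 2) fit <- cbind(fit, matrix(0, nrow(x), 2 - ncol(fit)))
      fit
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("Rtsne is required for tSNE embedding")
      perp <- max(1, min(30, floor((nrow(x) - 1) / 3)))
      Rtsne::Rtsne(x, dims = 2, perplexity = perp, check_duplicates = FALSE,
                   pca = nrow(x) > 3)$Y
    }))
  rownames(coords) <- rownames(mat)
  colnames(coords) <- c("dim1", "dim2")
  coords[, 1:2, drop = FALSE]
}
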