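#' Construct a methylation call set
#'
#' The central pipeline output: per-CpG methylated/unmethylated counts
#' for one cell (or a merged sample), plus aggregate non-CpG (CHG/CHH)
#' counts per chromosome used for conversion diagnostics.
#'
#' @param cpg `data.table(chrom, pos, meth, unmeth)` (destranded; a
#'   `strand` column is present in stranded mode). `pos` is the 1-based
#'   plus-strand C of the CG dinucleotide.
#' @param noncpg `data.table(chrom, context, meth, unmeth)` with context
#'   in CHG/CHH.
#' @param cell_id sample identifier.
#' @param destranded logical flag.
#' @return object of class `methylation_calls`.
#' @export
methylation_calls <- function(cpg, noncpg = NULL, cell_id = NA_character_,
                              destranded = TRUE) {
  cpg <- data.table::as.data.table(cpg)
  if (is.null(noncpg))
    noncpg <- data.table::data.table(chrom = character(0),
                                     context = character(0),
                                     meth = integer(0), unmeth = integer(0))
  stopifnot(all(cpg$meth >= 0), all(cpg$unmeth >= 0))
  keyc <- intersect(c("chrom", "pos", "strand"), names(cpg))
  data.table::setkeyv(cpg, keyc)
  structure(list(cell_id = cell_id, cpg = cpg,
                 noncpg = data.table::as.data.table(noncpg),
                 destranded = destranded),
            class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat("methylation_calls [", x$cell_id, "]: ", nrow(x$cpg), " CpG sites, ",
      sum(x$cpg$meth + x$cpg$unmeth), " CpG observations\n", sep = "")
  invisible(x)
}

# per-fragment cytosine lookup tables in molecule-strand coordinates
fragment_call_context <- function(index_bs, cpg_index) {
  cyt <- cpg_index$cytosines
  lapply(seq_along(index_bs$id), function(i) {
    st <- index_bs$start[i]; en <- index_bs$end[i]
    L <- index_bs$len[i]
    cy <- cyt[chrom == index_bs$chrom[i] & pos >= st & pos <= en]
    plus <- cy[strand == "+"]
    minus <- cy[strand == "-"]
    list(
      ot = list(off = plus$pos - st + 1L, context = plus$context,
                cpg_pos = plus$pos),
      ob = list(off = L - (minus$pos - st + 1L) + 1L, context = minus$context,
                cpg_pos = minus$pos - 1L))
  })
}

#' Call methylation from unique alignments
#'
#' For each uniquely aligned pair the molecule's strand sequence is
#' reconstructed from the mates; each molecule contributes at most one
#' observation per site. Where the mates overlap (most msRRBS inserts
#' are shorter than the read, so both mates see the whole molecule) a
#' base is used only when the mates agree -- discordant positions are
#' discarded as sequencing error, which suppresses miscall inflation of
#' methylation levels quadratically. At every reference cytosine of the
#' sequenced strand, read C counts as methylated and read T as
#' unmethylated (other bases are ignored). CpG
#' observations from original-bottom molecules are merged onto the
#' plus-strand C of the CG dinucleotide unless `destrand = FALSE`;
#' non-CpG cytosines accumulate into per-chromosome CHG/CHH totals.
#'
#' @param alignments alignment table (only `unique` rows are used).
#' @param reads trimmed reads table the alignments refer to.
#' @param index the `bs_index` used for alignment.
#' @param cpg_index `cpg_index` of the same genome.
#' @param destrand merge strands at CpG sites (default TRUE).
#' @param dedup collapse read pairs with identical (fragment, strand,
#'   cell) to one observation.
#' @param cell_id identifier stored in the result.
#' @return `methylation_calls`.
#' @export
pileup_calls <- function(alignments, reads, index, cpg_index,
                         destrand = TRUE, dedup = FALSE,
                         cell_id = NA_character_) {
  u <- alignments[alignments$status == "unique"]
  bad <- !(u$fragment_id %in% index$id)
  if (any(bad)) stop("alignment references unknown fragment: ",
                     u$fragment_id[which(bad)[1]])
  if (dedup && nrow(u))
    u <- u[!duplicated(paste(u$cell_id, u$fragment_id, u$strand, u$offset))]
  ctx <- fragment_call_context(index, cpg_index)
  m <- match(u$id, reads$id)
  s1 <- reads$seq1[m]; s2 <- reads$seq2[m]
  fi <- match(u$fragment_id, index$id)
  u_strand <- u$strand
  frag_chrom <- index$chrom[fi]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  acc_chrom <- vector("list", nrow(u)); acc_pos <- vector("list", nrow(u))
  acc_ctx <- vector("list", nrow(u)); acc_meth <- vector("list", nrow(u))
  acc_strand <- vector("list", nrow(u))
  for (j in seq_len(nrow(u))) {
    L <- index$len[fi[j]]
    strand <- if (u_strand[j] == "OT") "ot" else "ob"
    info <- ctx[[fi[j]]][[strand]]
    if (length(info$off) == 0) next
    ch1 <- strsplit(s1[j], "", fixed = TRUE)[[1]]
    ch2rc <- unname(comp[rev(strsplit(s2[j], "", fixed = TRUE)[[1]])])
    l1 <- length(ch1); l2 <- length(ch2rc)
    obs1 <- rep(NA_character_, L); obs2 <- rep(NA_character_, L)
    if (l1) obs1[1L:l1] <- ch1
    if (l2) obs2[(L - l2 + 1L):L] <- ch2rc
    obs <- ifelse(is.na(obs1), obs2, obs1)
    obs[!is.na(obs1) & !is.na(obs2) & obs1 != obs2] <- NA  # mate consensus
    b <- obs[info$off]
    keep <- !is.na(b) & (b == "C" | b == "T")
    if (!any(keep)) next
    acc_chrom[[j]] <- rep(frag_chrom[j], sum(keep))
    acc_pos[[j]] <- info$cpg_pos[keep]
    acc_ctx[[j]] <- info$context[keep]
    acc_meth[[j]] <- b[keep] == "C"
    acc_strand[[j]] <- rep(if (strand == "ot") "+" else "-", sum(keep))
  }
  ob <- data.table::data.table(
    chrom = unlist(acc_chrom), pos = unlist(acc_pos),
    context = unlist(acc_ctx), meth = unlist(acc_meth),
    strand = unlist(acc_strand))
  if (nrow(ob) == 0)
    return(methylation_calls(
      data.table::data.table(chrom = character(0), pos = integer(0),
                             meth = integer(0), unmeth = integer(0)),
      cell_id = cell_id, destranded = destrand))
  cg <- ob[context == "CG"]
  byc <- if (destrand) c("chrom", "pos") else c("chrom", "pos", "strand")
  cpg <- cg[, .(meth = sum(meth), unmeth = sum(!meth)), by = byc]
  noncpg <- ob[context != "CG",
               .(meth = sum(meth), unmeth = sum(!meth)),
               by = .(chrom, context)]
  methylation_calls(cpg, noncpg, cell_id = cell_id, destranded = destrand)
}

#' Per-cell methylation calling
#'
#' Splits alignments by `cell_id` and runs [pileup_calls()] per cell.
#'
#' @inheritParams pileup_calls
#' @return named list of `methylation_calls`, one per cell.
#' @export
pileup_cells <- function(alignments, reads, index, cpg_index,
                         destrand = TRUE, dedup = FALSE) {
  cells <- sort(unique(stats::na.omit(alignments$cell_id)))
  out <- lapply(cells, function(cl) {
    pileup_calls(alignments[alignments$cell_id == cl], reads, index,
                 cpg_index, destrand = destrand, dedup = dedup,
                 cell_id = cl)
  })
  stats::setNames(out, cells)
}

#' Estimate the bisulfite conversion rate from the spike-in control
#'
#' The control is fully unmethylated, so every cytosine observation on
#' it (all contexts) should read T; the conversion rate is
#' converted / (converted + retained).
#'
#' @param callset `methylation_calls` covering the control chromosome.
#' @param control_chrom chromosome name of the control sequence.
#' @return list with `rate`, `converted`, `retained`, `n`.
#' @export
estimate_conversion_rate <- function(callset, control_chrom = "lambda_control") {
  cg <- callset$cpg[chrom == control_chrom]
  nc <- callset$noncpg[chrom == control_chrom]
  retained <- sum(cg$meth) + sum(nc$meth)
  converted <- sum(cg$unmeth) + sum(nc$unmeth)
  n <- retained + converted
  if (n == 0) {
    warning("no spike-in cytosine observations; conversion rate missing")
    return(list(rate = NA_real_, converted = 0L, retained = 0L, n = 0L))
  }
  list(rate = converted / n, converted = converted, retained = retained, n = n)
}

#' Aggregate methylation level per cytosine context
#'
#' @param callset `methylation_calls`.
#' @param exclude_chrom chromosomes excluded from the summary (e.g. the
#'   spike-in control).
#' @return named numeric: `CpG`, `CHG`, `CHH` levels (NA when a context
#'   has no observations).
#' @export
context_levels <- function(callset, exclude_chrom = character(0)) {
  cg <- callset$cpg[!chrom %in% exclude_chrom]
  nc <- callset$noncpg[!chrom %in% exclude_chrom]
  lvl <- function(m, t) if (t > 0) m / t else NA_real_
  chg <- nc[context == "CHG"]; chh <- nc[context == "CHH"]
  c(CpG = lvl(sum(cg$meth), sum(cg$meth + cg$unmeth)),
    CHG = lvl(sum(chg$meth), sum(chg$meth + chg$unmeth)),
    CHH = lvl(sum(chh$meth), sum(chh$meth + chh$unmeth)))
}

#' Per-cell quality control
#'
#' A cell passes iff at least `min_sites` CpG sites were detected
#' (inclusive threshold; the full-scale default is the 0.2 M sites rule,
#' overridable for desk-scale genomes).
#'
#' @param callset `methylation_calls`.
#' @param min_sites detection threshold.
#' @param exclude_chrom chromosomes excluded from the site count.
#' @return list with `cell_id`, `detected_sites`, `mean_coverage`,
#'   `pass`.
#' @export
cell_qc <- function(callset, min_sites = 200000L,
                    exclude_chrom = character(0)) {
  cg <- callset$cpg[!chrom %in% exclude_chrom]
  det <- nrow(cg)
  list(cell_id = callset$cell_id, detected_sites = det,
       mean_coverage = if (det > 0) mean(cg$meth + cg$unmeth) else 0,
       pass = det >= min_sites)
}

#' Write CpG calls in CGmap-style text
#'
#' Columns: chrom, plus-strand nucleotide, 1-based position, context,
#' dinucleotide sub-context, methylation level, methylated count, total
#' count.
#'
#' @param callset destranded `methylation_calls` (non-empty).
#' @param path output path.
#' @export
write_cgmap <- function(callset, path) {
  if (nrow(callset$cpg) == 0) stop("empty call set")
  cg <- callset$cpg
  total <- cg$meth + cg$unmeth
  dt <- data.table::data.table(
    chrom = cg$chrom, nuc = "C", pos = cg$pos, context = "CG",
    sub_context = "CG", level = cg$meth / total,
    meth = cg$meth, total = total)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a CGmap-style file back into a call set
#' @param path CGmap path written by [write_cgmap()].
#' @param cell_id identifier for the result.
#' @return `methylation_calls` (CpG table only).
#' @export
read_cgmap <- function(path, cell_id = NA_character_) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "nuc", "pos", "context",
                                        "sub_context", "level", "meth", "total"))
  methylation_calls(
    data.table::data.table(chrom = dt$chrom, pos = dt$pos,
                           meth = dt$meth, unmeth = dt$total - dt$meth),
    cell_id = cell_id)
}

#' Write CpG levels as bedGraph
#'
#' 0-based half-open intervals with the methylation level scaled to
#' percent.
#'
#' @param callset destranded `methylation_calls` (non-empty).
#' @param path output path.
#' @export
write_bedgraph <- function(callset, path) {
  if (nrow(callset$cpg) == 0) stop("empty call set")
  cg <- callset$cpg
  dt <- data.table::data.table(
    chrom = cg$chrom, start = cg$pos - 1L, end = cg$pos,
    value = 100 * cg$meth / (cg$meth + cg$unmeth))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph of CpG levels
#' @param path bedGraph path.
#' @return `data.table(chrom, pos, level)` with 1-based positions and
#'   levels on the 0-1 scale.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  data.table::data.table(chrom = dt$chrom, pos = dt$end,
                         level = dt$value / 100)
}
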