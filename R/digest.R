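#' In-silico MspI digestion
#'
#' MspI recognizes CCGG and cuts C^CGG, leaving 5'-CG overhangs; it is
#' insensitive to CpG methylation, which is what makes it the canonical
#' RRBS enzyme. The digest places a cut after the first C of every CCGG
#' occurrence, so fragments tile each chromosome without gaps or overlaps.
#'
#' @param genome genome object (see [as_genome()]).
#' @return a `data.table` fragment catalog with columns `id`, `chrom`,
#'   `start`, `end` (1-based closed), `length`, `seq`, `has_n`; attribute
#'   `digest_enzyme` is `"MspI"`.
#' @export
digest_mspi <- function(genome) {
  genome <- as_genome(genome)
  if (length(genome) == 0) stop("empty genome")
  pieces <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L == 0) {
      warning("chromosome ", chrom, " is empty; skipped")
      return(NULL)
    }
    occ <- gregexpr("CCGG", s, fixed = TRUE)[[1]]
    cuts <- if (occ[1] == -1L) integer(0) else as.integer(occ)  # cut after this C
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    keep <- starts <= ends
    data.table::data.table(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  frags <- data.table::rbindlist(pieces)
  if (nrow(frags) == 0) stop("no fragments produced")
  frags[, `:=`(
    id = sprintf("%s_f%05d", chrom, seq_len(.N)),
    seq = substring(genome[chrom], start, end)
  ), by = chrom]
  frags[, length := end - start + 1L]
  frags[, has_n := grepl("N", seq, fixed = TRUE)]
  data.table::setcolorder(frags, c("id", "chrom", "start", "end", "length", "seq", "has_n"))
  data.table::setattr(frags, "digest_enzyme", "MspI")
  frags[]
}

#' Size-select fragments
#'
#' Retains fragments whose length falls inside the insert window. The
#' protocol's library-size windows map to insert windows 30-200 bp
#' (default), 30-400 bp and 30-600 bp.
#'
#' @param catalog fragment catalog from [digest_mspi()].
#' @param min_len,max_len inclusive insert length bounds in bp.
#' @return filtered catalog, order preserved.
#' @export
select_inserts <- function(catalog, min_len = 30L, max_len = 200L) {
  if (!(min_len > 0 && min_len <= max_len))
    stop("invalid insert window: need 0 < min_len <= max_len")
  out <- catalog[catalog$length >= min_len & catalog$length <= max_len]
  data.table::setattr(out, "digest_enzyme", attr(catalog, "digest_enzyme"))
  out[]
}

#' Fragment catalog as GRanges
#' @param catalog fragment catalog.
#' @param genome optional genome supplying seqlengths.
#' @return `GRanges` with fragment ids as names.
#' @export
fragments_granges <- function(catalog, genome = NULL) {
  gr <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(catalog$start, catalog$end)
  )
  names(gr) <- catalog$id
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <- genome_lengths(genome)[GenomeInfoDb::seqlevels(gr)]
  gr
}
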