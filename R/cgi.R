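#' Call CpG islands
#'
#' Implements the classical Gardiner-Garden-style scan for the CGI
#' definition used throughout: a region of at least `min_len` bp with GC
#' content >= `min_gc` and an observed/expected CpG ratio >= `min_oe`,
#' where expected = (#C x #G) / length. The scanner slides a `min_len`-bp
#' window with step 1, merges overlapping qualifying windows, and then
#' re-validates each merged region against the three criteria (greedily
#' trimming single bases from the ends while a merged region fails).
#' N bases count as neither C nor G.
#'
#' @param genome genome object.
#' @param min_len minimum CGI length in bp (also the scan window width).
#' @param min_gc minimum GC fraction.
#' @param min_oe minimum observed/expected CpG ratio.
#' @return ElementSet: a `GRanges` (kind "CGI") sorted by position.
#' @export
call_cgis <- function(genome, min_len = 200L, min_gc = 0.50, min_oe = 0.6) {
  genome <- as_genome(genome)
  stopifnot(min_len >= 1, min_gc > 0, min_gc <= 1, min_oe > 0)
  w <- as.integer(min_len)
  hits <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < w) return(NULL)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- ch == "C"
    isG <- ch == "G"
    isCG <- isC & c(isG[-1], FALSE)
    cumC <- c(0, cumsum(isC))
    cumG <- c(0, cumsum(isG))
    cumCG <- c(0, cumsum(isCG))
    starts <- seq_len(L - w + 1L)
    nC <- cumC[starts + w] - cumC[starts]
    nG <- cumG[starts + w] - cumG[starts]
    nCG <- cumCG[starts + w - 1L] - cumCG[starts]  # CG start must fit in window
    gc_ok <- (nC + nG) / w >= min_gc
    oe <- ifelse(nC * nG > 0, nCG * w / (nC * nG), 0)
    ok <- gc_ok & oe >= min_oe
    if (!any(ok)) return(NULL)
    qs <- starts[ok]
    # union of overlapping qualifying windows
    brk <- c(TRUE, qs[-1] > qs[-length(qs)] + w - 1L)
    grp <- cumsum(brk)
    regs <- lapply(split(qs, grp), function(v) c(min(v), max(v) + w - 1L))
    crit <- function(a, b) {
      len <- b - a + 1L
      nc <- cumC[b + 1L] - cumC[a]
      ng <- cumG[b + 1L] - cumG[a]
      ncg <- cumCG[b] - cumCG[a]
      gc <- (nc + ng) / len
      oe2 <- if (nc * ng > 0) ncg * len / (nc * ng) else 0
      c(gc = gc, oe = oe2, margin = min(gc - min_gc, oe2 - min_oe))
    }
    out <- lapply(regs, function(r) {
      a <- r[1]; b <- r[2]
      cc <- crit(a, b)
      while (cc[["margin"]] < 0 && b - a + 1L > w) {
        left <- crit(a + 1L, b)
        right <- crit(a, b - 1L)
        if (left[["margin"]] >= right[["margin"]]) { a <- a + 1L; cc <- left }
        else { b <- b - 1L; cc <- right }
      }
      if (cc[["margin"]] < 0) return(NULL)
      c(a, b)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) return(NULL)
    m <- do.call(rbind, out)
    data.table::data.table(chrom = chrom, start = m[, 1], end = m[, 2])
  })
  dt <- data.table::rbindlist(hits)
  if (nrow(dt) == 0)
    return(element_set(GenomicRanges::GRanges(seqlengths = genome_lengths(genome)),
                       kind = "CGI"))
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  GenomeInfoDb::seqlengths(gr) <- genome_lengths(genome)[GenomeInfoDb::seqlevels(gr)]
  element_set(gr, kind = "CGI")
}
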