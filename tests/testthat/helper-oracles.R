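# Independent oracles used to verify the implementation. These are kept
# deliberately naive (per-base loops, exhaustive enumeration) and share
# no code with the package internals.

# brute-force MspI digestion: test every position for CCGG by direct
# substring comparison (no regex machinery), cut after the first C,
# return fragment substrings
oracle_digest <- function(s) {
  L <- nchar(s)
  cuts <- if (L >= 4) {
    starts <- seq_len(L - 3L)
    which(substring(s, starts, starts + 3L) == "CCGG")
  } else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  mapply(function(a, b) substring(s, a, b), starts, ends)
}

# per-base painter for shore/shelf derivation with precedence
# CGI > shore > shelf; cgi is a data.frame(start, end) 1-based closed
oracle_paint <- function(chrom_len, cgi, flank = 2000L) {
  lab <- rep("none", chrom_len)
  for (k in seq_len(nrow(cgi))) {
    a <- max(1L, cgi$start[k] - 2L * flank); b <- min(chrom_len, cgi$end[k] + 2L * flank)
    lab[a:b][lab[a:b] == "none"] <- "shelf"
  }
  for (k in seq_len(nrow(cgi))) {
    a <- max(1L, cgi$start[k] - flank); b <- min(chrom_len, cgi$end[k] + flank)
    lab[a:b][lab[a:b] != "cgi"] <- "shore"
  }
  for (k in seq_len(nrow(cgi))) lab[cgi$start[k]:cgi$end[k]] <- "cgi"
  lab
}

granges_to_label <- function(chrom_len, grs, label, lab = rep("none", chrom_len)) {
  for (k in seq_along(grs)) {
    lab[GenomicRanges::start(grs)[k]:GenomicRanges::end(grs)[k]] <- label
  }
  lab
}

# brute-force context of every cytosine on both strands
oracle_contexts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  at <- function(i) if (i >= 1 && i <= L) ch[i] else "N"
  out <- list()
  for (i in seq_len(L)) {
    if (ch[i] == "C") {
      ctx <- if (at(i + 1) == "G") "CG" else if (at(i + 2) == "G") "CHG" else "CHH"
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "+", context = ctx)
    }
    if (ch[i] == "G") {
      ctx <- if (at(i - 1) == "C") "CG" else if (at(i - 2) == "C") "CHG" else "CHH"
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "-", context = ctx)
    }
  }
  do.call(rbind, out)
}

# exhaustive two-sided Mann-Whitney p-value by pair counting over all
# group assignments (independent of the rank-based implementation)
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  ustat <- function(a, b) {
    s <- 0
    for (xi in a) for (yi in b) s <- s + (xi > yi) + 0.5 * (xi == yi)
    s
  }
  u_obs <- ustat(x, y)
  cmb <- utils::combn(N, n)
  us <- apply(cmb, 2, function(ix) ustat(pooled[ix], pooled[-ix]))
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# naive string assembly of an error-free msRRBS read pair from a
# fragment whose CpG cytosines are fully methylated (non-CpG converted)
oracle_read_pair <- function(frag_seq, marker, barcode, read_length = 150L,
                             adapter = "AGATCGGAAGAGC") {
  ch <- strsplit(frag_seq, "", fixed = TRUE)[[1]]
  conv <- ch
  for (i in seq_along(ch)) {
    if (ch[i] == "C" && !(i < length(ch) && ch[i + 1] == "G")) conv[i] <- "T"
  }
  conv <- paste(conv, collapse = "")
  rc <- function(s) paste(rev(chartr("ACGT", "TGCA",
                                     strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
  prefix <- paste0(marker, barcode)
  rt <- rc(prefix)
  r1 <- substr(paste0(prefix, conv, rt, adapter), 1, read_length)
  r2 <- substr(paste0(prefix, rc(conv), rt, adapter), 1, read_length)
  c(r1, r2)
}
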