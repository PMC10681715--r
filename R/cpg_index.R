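#' Index CpG sites and cytosine contexts
#'
#' Lists all plus-strand CG dinucleotide positions (1-based position of
#' the C) and assigns every cytosine on both strands its standard
#' three-base context: CG, CHG or CHH (H = A, C or T; N and positions
#' running off the chromosome end count as H). Minus-strand cytosines are
#' reported at the plus-strand coordinate of the complementary G.
#'
#' @param genome genome object.
#' @return object of class `cpg_index`: a list with
#'   * `sites`: `data.table(chrom, pos)` of plus-strand CpG C positions;
#'   * `cytosines`: `data.table(chrom, pos, strand, context)` over all
#'     cytosines of both strands.
#' @export
index_cpgs <- function(genome) {
  genome <- as_genome(genome)
  per_chrom <- lapply(names(genome), function(chrom) {
    ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(ch)
    at <- function(i) ifelse(i >= 1 & i <= L, ch[pmax(pmin(i, L), 1L)], "N")
    cpos <- which(ch == "C")
    gpos <- which(ch == "G")
    ctx_plus <- if (length(cpos)) {
      n1 <- at(cpos + 1L); n2 <- at(cpos + 2L)
      ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    } else character(0)
    ctx_minus <- if (length(gpos)) {
      p1 <- at(gpos - 1L); p2 <- at(gpos - 2L)
      ifelse(p1 == "C", "CG", ifelse(p2 == "C", "CHG", "CHH"))
    } else character(0)
    list(
      sites = data.table::data.table(
        chrom = chrom, pos = cpos[ctx_plus == "CG"]),
      cytosines = data.table::data.table(
        chrom = chrom,
        pos = c(cpos, gpos),
        strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
        context = c(ctx_plus, ctx_minus))
    )
  })
  idx <- list(
    sites = data.table::rbindlist(lapply(per_chrom, `[[`, "sites")),
    cytosines = data.table::rbindlist(lapply(per_chrom, `[[`, "cytosines"))
  )
  data.table::setkey(idx$sites, chrom, pos)
  data.table::setkey(idx$cytosines, chrom, pos, strand)
  class(idx) <- "cpg_index"
  idx
}

#' @export
print.cpg_index <- function(x, ...) {
  cat("cpg_index:", nrow(x$sites), "CpG sites,",
      nrow(x$cytosines), "cytosines on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}
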