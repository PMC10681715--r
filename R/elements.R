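#' Construct an ElementSet
#'
#' An ElementSet is a sorted `GRanges` carrying its element kind
#' ("CGI", "shore", "shelf", "promoter", "gene", "exon", "transcript",
#' "CTCF", "enhancer" or "window") and provenance in `metadata()`.
#'
#' @param gr a `GRanges`.
#' @param kind element kind.
#' @param source "derived" (computed here) or "loaded" (read from file).
#' @return sorted `GRanges` with `metadata(gr)$kind` and `$source` set.
#' @export
element_set <- function(gr, kind, source = "derived") {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$kind <- kind
  S4Vectors::metadata(gr)$source <- source
  gr
}

#' Kind of an ElementSet
#' @param es ElementSet.
#' @return character scalar.
#' @export
element_kind <- function(es) S4Vectors::metadata(es)$kind

#' Derive CGI shores and shelves
#'
#' Shores are the 2000-bp flanks on both sides of each CGI minus any CGI
#' bases; shelves the next 2000 bp outward minus CGI and shore bases
#' (per-base precedence CGI > shore > shelf), clipped to chromosome
#' bounds.
#'
#' @param cgis ElementSet of kind "CGI" with seqlengths set.
#' @param genome genome object (for chromosome lengths).
#' @param flank_bp flank width in bp (2000 in the protocol definition).
#' @return list with ElementSets `shores` and `shelves`.
#' @export
derive_shores_shelves <- function(cgis, genome, flank_bp = 2000L) {
  if (!identical(element_kind(cgis), "CGI")) stop("input must be a CGI ElementSet")
  sl <- genome_lengths(as_genome(genome))
  gr <- GenomicRanges::granges(cgis)
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  cgi_r <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  # flank expansion may poke past chromosome ends before trim()
  ring1 <- GenomicRanges::trim(suppressWarnings(cgi_r + flank_bp))
  ring2 <- GenomicRanges::trim(suppressWarnings(cgi_r + 2L * flank_bp))
  shores <- GenomicRanges::setdiff(ring1, cgi_r, ignore.strand = TRUE)
  shelves <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(ring2, ring1, ignore.strand = TRUE),
    cgi_r, ignore.strand = TRUE)
  list(shores = element_set(shores, "shore"),
       shelves = element_set(shelves, "shelf"))
}

#' Derive promoters from a TSS table
#'
#' A promoter is the strand-aware window of 1500 bp upstream and 500 bp
#' downstream of a transcription start site, clipped to the chromosome.
#' Positions are 1-based. Whether the promoter overlaps a CGI is recorded
#' as the logical column `contains_cgi` (the definition's "containing
#' CGIs" clause is an attribute, not a filter). Duplicate coordinates are
#' removed with [dedupe_elements()].
#'
#' @param tss_table data.frame with columns `chrom`, `pos` (1-based TSS),
#'   `strand` ("+"/"-") and `gene_id`.
#' @param genome genome object.
#' @param cgis optional CGI ElementSet used to fill `contains_cgi`.
#' @param upstream,downstream promoter extent in bp.
#' @return ElementSet of kind "promoter".
#' @export
derive_promoters <- function(tss_table, genome, cgis = NULL,
                             upstream = 1500L, downstream = 500L) {
  sl <- genome_lengths(as_genome(genome))
  tss <- data.table::as.data.table(tss_table)
  known <- tss$chrom %in% names(sl)
  if (!all(known)) {
    warning(sum(!known), " TSS record(s) on unknown chromosomes skipped")
    tss <- tss[known]
  }
  if (nrow(tss) == 0) stop("no usable TSS records")
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream)
  end <- ifelse(plus, tss$pos + downstream - 1L, tss$pos + upstream - 1L)
  start <- pmax(start, 1L)
  end <- pmin(end, sl[tss$chrom])
  gr <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(start, end),
                               strand = ifelse(plus, "+", "-"),
                               gene_id = tss$gene_id)
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  if (!is.null(cgis)) {
    S4Vectors::mcols(gr)$contains_cgi <-
      IRanges::overlapsAny(gr, cgis, ignore.strand = TRUE)
  }
  dedupe_elements(element_set(gr, "promoter"))
}

#' Remove elements with identical genomic coordinates
#'
#' Exactly one interval is retained per distinct (chrom, start, end);
#' strand is ignored for the identity, matching the coordinate-only
#' dedup rule. Order (after sorting) is stable: the first occurrence
#' wins.
#'
#' @param elements ElementSet.
#' @return deduplicated ElementSet (same kind).
#' @export
dedupe_elements <- function(elements) {
  key <- paste(GenomeInfoDb::seqnames(elements),
               GenomicRanges::start(elements),
               GenomicRanges::end(elements))
  out <- elements[!duplicated(key)]
  element_set(out, element_kind(elements), S4Vectors::metadata(elements)$source)
}

#' Write an ElementSet as BED6
#' @param elements ElementSet.
#' @param path output BED path (coordinates converted to 0-based half-open).
#' @export
write_elements_bed <- function(elements, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED output")
  gr <- elements
  if (is.null(names(gr)) && !is.null(S4Vectors::mcols(gr)$gene_id))
    names(gr) <- S4Vectors::mcols(gr)$gene_id
  S4Vectors::mcols(gr) <- NULL
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read an ElementSet from BED
#' @param path BED file path.
#' @param kind element kind to assign.
#' @return ElementSet with `source = "loaded"`.
#' @export
read_elements_bed <- function(path, kind) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED input")
  element_set(rtracklayer::import.bed(path), kind, source = "loaded")
}

#' Read a TSS table from TSV
#' @param path TSV with columns chrom, pos, strand, gene_id.
#' @return data.table.
#' @export
read_tss_table <- function(path) {
  data.table::fread(path, col.names = c("chrom", "pos", "strand", "gene_id"),
                    colClasses = list(character = c(1, 3, 4), integer = 2))
}
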