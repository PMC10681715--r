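# msRRBS reads start at MspI cut sites by construction, so the mapping
# space is the size-selected fragment catalog, not the whole genome:
# read 1 anchors at one fragment end, read 2 at the other. This is the
# central desk-scale simplification of the aligner.

ct_convert <- function(x) chartr("C", "T", x)
ga_convert <- function(x) chartr("G", "A", x)

# bisulfite-aware mismatch count between equal-length ref and read;
# ref `free_ref` observed as `free_read` is not a mismatch (both given
# as single raw bytes).
bs_mismatches <- function(ref, read, free_ref, free_read) {
  ra <- charToRaw(ref); rb <- charToRaw(read)
  if (length(ra) != length(rb)) return(Inf)
  d <- ra != rb
  free <- ra == free_ref & rb == free_read
  sum(d & !free)
}

#' Build a bisulfite alignment index over a fragment catalog
#'
#' For each fragment two fully converted reference entries are kept: the
#' C-to-T converted top strand (for original-top molecules) and the
#' C-to-T converted bottom strand (equivalently the reverse complement
#' of the G-to-A converted top strand, for original-bottom molecules),
#' with an exact-match seed table over the first `k` converted bases.
#' Fragments shorter than `k` are indexed whole.
#'
#' @param catalog size-selected fragment catalog; an optional `species`
#'   column labels fragments for barnyard analysis.
#' @param k seed length in bp.
#' @return object of class `bs_index`.
#' @export
build_bs_index <- function(catalog, k = 20L) {
  if (nrow(catalog) == 0) stop("empty fragment catalog")
  species <- if ("species" %in% names(catalog)) catalog$species
  else rep("genome", nrow(catalog))
  kl <- pmin(k, catalog$length)
  top_ct <- ct_convert(catalog$seq)
  bot_ct <- revcomp(ga_convert(catalog$seq))
  tab <- data.table::data.table(
    kmer = c(substr(top_ct, 1L, kl), substr(bot_ct, 1L, kl)),
    frag_idx = rep(seq_len(nrow(catalog)), 2L),
    strand = rep(c("OT", "OB"), each = nrow(catalog)))
  data.table::setkey(tab, kmer)
  structure(list(table = tab, seq = catalog$seq, len = catalog$length,
                 id = catalog$id, chrom = catalog$chrom,
                 start = catalog$start, end = catalog$end,
                 species = species, k = as.integer(k)),
            class = "bs_index")
}

# verify one candidate placement; s1rc/s2rc are precomputed reverse
# complements of the mates. Returns c(m1, m2) or NULL if the geometry
# is impossible.
verify_candidate <- function(s1, s2, s1rc, s2rc, frag, L, strand) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 > L || l2 > L) return(NULL)
  if (strand == "OT") {
    m1 <- bs_mismatches(substr(frag, 1L, l1), s1, .raw_C, .raw_T)
    m2 <- bs_mismatches(substr(frag, L - l2 + 1L, L), s2rc, .raw_C, .raw_T)
  } else {
    m1 <- bs_mismatches(substr(frag, L - l1 + 1L, L), s1rc, .raw_G, .raw_A)
    m2 <- bs_mismatches(substr(frag, 1L, l2), s2, .raw_G, .raw_A)
  }
  c(m1, m2)
}

.raw_A <- charToRaw("A")
.raw_C <- charToRaw("C")
.raw_G <- charToRaw("G")
.raw_T <- charToRaw("T")

#' Align trimmed read pairs in fragment space
#'
#' Read 1 is C-to-T converted and looked up in the seed table over both
#' strand references; candidates are then fully verified with
#' bisulfite-aware mismatch counting (reference C read as T on the
#' converted strand is free). A pair is `unique` when a single placement
#' has strictly fewer total mismatches than any other, `ambiguous` on a
#' tie, `unmapped` when no placement keeps both mates within
#' `max_mismatch`.
#'
#' @param reads trimmed reads table (`id, seq1, seq2`, optionally
#'   `cell_id`).
#' @param index `bs_index`.
#' @param max_mismatch per-mate mismatch cap.
#' @param exhaustive if TRUE, skip the seed table and verify every
#'   fragment on both strands (brute-force oracle mode).
#' @return `data.table(id, cell_id, status, fragment_id, chrom, start,
#'   end, species, strand, offset, mismatches)`; `offset` is the 0-based
#'   offset of read 1's leftmost base within the fragment (top-strand
#'   frame).
#' @export
align_pairs <- function(reads, index, max_mismatch = 2L, exhaustive = FALSE) {
  n <- nrow(reads)
  cell <- if ("cell_id" %in% names(reads)) reads$cell_id else rep(NA_character_, n)
  res <- data.table::data.table(
    id = reads$id, cell_id = cell, status = rep("unmapped", n),
    fragment_id = NA_character_, chrom = NA_character_,
    start = NA_integer_, end = NA_integer_, species = NA_character_,
    strand = NA_character_, offset = NA_integer_, mismatches = NA_integer_)
  if (n == 0) return(res)
  all_cand <- if (exhaustive) {
    nf <- length(index$seq)
    data.table::data.table(read = rep(seq_len(n), each = 2L * nf),
                           frag_idx = rep(rep(seq_len(nf), 2L), n),
                           strand = rep(rep(c("OT", "OB"), each = nf), n))
  } else {
    kl <- pmin(index$k, nchar(reads$seq1))
    keys <- substr(ct_convert(reads$seq1), 1L, kl)
    lut <- data.table::data.table(kmer = keys, read = seq_len(n))
    merged <- index$table[lut, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    merged[, .(read, frag_idx, strand)]
  }
  if (nrow(all_cand) == 0) return(res)
  cand_read <- all_cand$read
  cand_frag <- all_cand$frag_idx
  cand_strand <- all_cand$strand
  by_read <- split(seq_along(cand_read), cand_read)
  for (rn in names(by_read)) {
    r <- as.integer(rn)
    ci <- by_read[[rn]]
    s1 <- reads$seq1[r]; s2 <- reads$seq2[r]
    s1rc <- revcomp_chr(s1); s2rc <- revcomp_chr(s2)
    scores <- vapply(ci, function(i) {
      fi <- cand_frag[i]
      mm <- verify_candidate(s1, s2, s1rc, s2rc, index$seq[fi],
                             index$len[fi], cand_strand[i])
      if (is.null(mm) || mm[1] > max_mismatch || mm[2] > max_mismatch)
        return(NA_real_)
      mm[1] + mm[2]
    }, numeric(1))
    valid <- which(!is.na(scores))
    if (length(valid) == 0) next
    best <- min(scores[valid])
    hits <- ci[valid[scores[valid] == best]]
    # identical placements reached twice count once
    hk <- paste(cand_frag[hits], cand_strand[hits])
    hits <- hits[!duplicated(hk)]
    if (length(hits) > 1) {
      data.table::set(res, r, "status", "ambiguous")
      next
    }
    i <- hits[1]; fi <- cand_frag[i]
    off <- if (cand_strand[i] == "OT") 0L
    else index$len[fi] - nchar(s1)
    data.table::set(res, r, c("status", "fragment_id", "chrom", "start",
                              "end", "species", "strand", "offset",
                              "mismatches"),
                    list("unique", index$id[fi], index$chrom[fi],
                         index$start[fi], index$end[fi], index$species[fi],
                         cand_strand[i], off, as.integer(best)))
  }
  res
}

#' Unique mapping rate
#'
#' @param alignments alignment table from [align_pairs()].
#' @param denominators named counts, e.g.
#'   `c(raw_pairs = ..., clean_pairs = ...)`.
#' @return named numeric vector of unique-alignment fractions; `NA`
#'   where a denominator is zero.
#' @export
mapping_rate <- function(alignments, denominators) {
  u <- sum(alignments$status == "unique")
  out <- ifelse(denominators > 0, u / denominators, NA_real_)
  names(out) <- names(denominators)
  out
}

#' Per-cell species assignment from a two-species index
#'
#' Fractions of unique alignments landing in each species, per cell.
#' Reads compatible with both species tie in the combined index and are
#' already excluded as ambiguous.
#'
#' @param alignments alignment table with `cell_id` and `species` from a
#'   combined two-species index.
#' @return `data.table(cell_id, n_unique, frac_<species>...)`; cells with
#'   zero unique alignments are flagged with NA fractions.
#' @export
species_assign <- function(alignments) {
  sp <- sort(unique(stats::na.omit(alignments$species)))
  cells <- unique(alignments$cell_id)
  rows <- lapply(cells, function(cl) {
    a <- alignments[alignments$cell_id == cl & alignments$status == "unique"]
    n <- nrow(a)
    fr <- if (n == 0) rep(NA_real_, length(sp))
    else vapply(sp, function(s) mean(a$species == s), numeric(1))
    out <- data.table::data.table(cell_id = cl, n_unique = n)
    for (i in seq_along(sp)) out[[paste0("frac_", sp[i])]] <- fr[i]
    out
  })
  data.table::rbindlist(rows)
}

#' Write alignments as SAM
#'
#' Minimal SAM output with fragment ids as reference names and
#' proper-pair flags set for unique alignments.
#'
#' @param alignments alignment table.
#' @param reads the trimmed reads that were aligned.
#' @param index the `bs_index` used.
#' @param path output SAM path.
#' @export
write_alignments_sam <- function(alignments, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index$id, index$len), con)
  u <- alignments[alignments$status == "unique"]
  if (nrow(u)) {
    m <- match(u$id, reads$id)
    l1 <- nchar(reads$seq1[m]); l2 <- nchar(reads$seq2[m])
    p1 <- u$offset + 1L
    p2 <- ifelse(u$strand == "OT",
                 index$len[match(u$fragment_id, index$id)] - l2 + 1L, 1L)
    flag1 <- ifelse(u$strand == "OT", 99L, 83L)
    flag2 <- ifelse(u$strand == "OT", 147L, 163L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t0\t%s\t*",
                       u$id, flag1, u$fragment_id, p1, l1, p2, reads$seq1[m]), con)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t0\t%s\t*",
                       u$id, flag2, u$fragment_id, p2, l2, p1, reads$seq2[m]), con)
  }
  invisible(path)
}
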