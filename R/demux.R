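#' Demultiplexing configuration
#'
#' @param whitelist character vector of 6-bp barcodes; names, if present,
#'   are used as cell ids (otherwise the barcode is the cell id).
#' @param marker fixed 4-bp marker required at read start, or "NNNN" to
#'   skip marker checking (random-marker mode).
#' @param min_barcode_q minimum mean Phred quality over the 6 barcode
#'   bases; below it the whole pair is removed.
#' @param min_len minimum retained mate length after trimming.
#' @param adapter_stub adapter sequence scanned for at the 3' end.
#' @return list of class `demux_config`.
#' @export
demux_config <- function(whitelist, marker = "GGTG", min_barcode_q = 20,
                         min_len = 20L, adapter_stub = "AGATCGGAAGAGC") {
  stopifnot(length(whitelist) >= 1, !anyDuplicated(whitelist),
            all(nchar(whitelist) == 6), nchar(marker) == 4)
  if (is.null(names(whitelist)))
    names(whitelist) <- unname(whitelist)
  structure(list(whitelist = whitelist, marker = marker,
                 min_barcode_q = min_barcode_q, min_len = as.integer(min_len),
                 adapter_stub = adapter_stub),
            class = "demux_config")
}

# mean Phred over barcode bases (positions 5..10), vectorized
barcode_mean_q <- function(qual) {
  qs <- substr(qual, 5L, 10L)
  if (length(qs) == 0) return(numeric(0))
  ints <- utf8ToInt(paste(qs, collapse = "")) - 33L
  colMeans(matrix(ints, nrow = 6L))
}

#' Demultiplex a read pool by cell barcode
#'
#' Bases 1-4 of each mate must equal the marker (fixed mode; skipped in
#' "NNNN" mode); bases 5-10 are the barcode. A pair is assigned iff both
#' mates carry the same whitelisted barcode with an exact match (no
#' mismatches allowed). If the mean barcode quality of either mate is
#' below the threshold, the whole pair is removed and counted as
#' quality-filtered, not unassigned.
#'
#' @param reads reads table (`id, seq1, qual1, seq2, qual2`), e.g. from
#'   [simulate_reads()] or [read_fastq_pair()].
#' @param config [demux_config()].
#' @return list with `assigned` (reads plus `barcode`, `cell_id`),
#'   `unassigned` and a `report` satisfying
#'   assigned + unassigned + quality_filtered = total.
#' @export
demultiplex <- function(reads, config) {
  bad_len <- nchar(reads$seq1) != nchar(reads$qual1) |
    nchar(reads$seq2) != nchar(reads$qual2)
  if (any(bad_len))
    stop("malformed FASTQ record (sequence/quality length mismatch): ",
         reads$id[which(bad_len)[1]])
  short <- nchar(reads$seq1) < 10 | nchar(reads$seq2) < 10
  if (any(short))
    stop("reads shorter than the 10-bp structural prefix: ",
         reads$id[which(short)[1]])
  qok <- barcode_mean_q(reads$qual1) >= config$min_barcode_q &
    barcode_mean_q(reads$qual2) >= config$min_barcode_q
  marker_ok <- if (identical(config$marker, "NNNN")) rep(TRUE, nrow(reads))
  else substr(reads$seq1, 1, 4) == config$marker &
    substr(reads$seq2, 1, 4) == config$marker
  bc1 <- substr(reads$seq1, 5, 10)
  bc2 <- substr(reads$seq2, 5, 10)
  hit <- match(bc1, config$whitelist)
  assigned_ok <- marker_ok & !is.na(hit) & bc1 == bc2
  assigned <- reads[qok & assigned_ok]
  assigned[, barcode := substr(seq1, 5, 10)]
  assigned[, cell_id := names(config$whitelist)[match(barcode, config$whitelist)]]
  per_cell <- assigned[, .(n_pairs = .N), by = .(cell_id, barcode)]
  report <- list(
    total = nrow(reads),
    quality_filtered = sum(!qok),
    assigned = sum(qok & assigned_ok),
    unassigned = sum(qok & !assigned_ok),
    dropped_length = 0L,
    per_cell = per_cell)
  list(assigned = assigned, unassigned = reads[qok & !assigned_ok],
       report = report)
}

# 1-based position of the earliest cut point for a pattern allowing up
# to one substitution for full-length occurrences, plus exact 3'-end
# partial occurrences with overlap >= min_overlap. NA when absent.
pattern_cut_pos <- function(seqs, pattern, max_mm = 1L, min_overlap = 4L) {
  m <- nchar(pattern)
  pos <- rep(NA_integer_, length(seqs))
  hit <- regexpr(pattern, seqs, fixed = TRUE)
  pos[hit > 0] <- hit[hit > 0]
  if (max_mm >= 1L && m >= 2L) {
    alts <- vapply(seq_len(m), function(i) {
      p <- pattern; substr(p, i, i) <- "."; p
    }, character(1))
    rx <- paste0("(", paste(alts, collapse = "|"), ")")
    hit2 <- regexpr(rx, seqs)
    better <- hit2 > 0 & (is.na(pos) | hit2 < pos)
    pos[better] <- hit2[better]
  }
  lens <- nchar(seqs)
  kmax <- min(m - 1L, if (length(lens)) max(lens) else 0L)
  for (k in (if (kmax >= min_overlap) seq(kmax, min_overlap, by = -1L) else integer(0))) {
    pref <- substr(pattern, 1L, k)
    cand <- lens >= k & substr(seqs, lens - k + 1L, lens) == pref
    p2 <- lens - k + 1L
    better <- cand & (is.na(pos) | p2 < pos)
    pos[better] <- p2[better]
  }
  pos
}

#' Trim structural bases and 3' read-through
#'
#' Removes the 10 leading structural bases (marker + barcode) from each
#' mate, then scans each mate's 3' side for the earliest occurrence of
#' the read-through sequence (reverse complement of the cell's 10-bp
#' prefix; one substitution tolerated for full-length hits) or the
#' adapter stub, removing everything from that occurrence onward. Pairs
#' where either mate falls below `min_len` are dropped and counted.
#'
#' @param assigned assigned reads table from [demultiplex()].
#' @param config [demux_config()].
#' @return list with `reads` (trimmed pairs) and `dropped` (count).
#' @export
trim_reads <- function(assigned, config) {
  reads <- data.table::copy(assigned)
  reads[, `:=`(seq1 = substring(seq1, 11L), qual1 = substring(qual1, 11L),
               seq2 = substring(seq2, 11L), qual2 = substring(qual2, 11L))]
  fixed_marker <- !identical(config$marker, "NNNN")
  for (bc in unique(reads$barcode)) {
    idx <- which(reads$barcode == bc)
    pattern <- if (fixed_marker) revcomp(paste0(config$marker, bc))
    else revcomp(bc)
    for (mate in c("1", "2")) {
      scol <- paste0("seq", mate); qcol <- paste0("qual", mate)
      s <- reads[[scol]][idx]
      cut <- pattern_cut_pos(s, pattern,
                             max_mm = if (fixed_marker) 1L else 0L)
      cut_a <- pattern_cut_pos(s, config$adapter_stub)
      cut <- pmin(cut, cut_a, na.rm = TRUE)
      keep_to <- ifelse(is.na(cut), nchar(s), cut - 1L)
      data.table::set(reads, idx, scol, substr(s, 1L, keep_to))
      data.table::set(reads, idx, qcol,
                      substr(reads[[qcol]][idx], 1L, keep_to))
    }
  }
  ok <- nchar(reads$seq1) >= config$min_len & nchar(reads$seq2) >= config$min_len
  list(reads = reads[ok], dropped = sum(!ok))
}

#' Clean read-pair count
#'
#' Clean pairs = assigned pairs minus pairs dropped for length during
#' trimming; the denominator for detection-rate and saturation metrics.
#'
#' @param report demultiplexing report (with `dropped_length` updated
#'   after trimming).
#' @return integer count.
#' @export
clean_read_count <- function(report) {
  as.integer(report$assigned - report$dropped_length)
}

#' Demultiplex and trim in one step
#' @param reads pooled reads table.
#' @param config [demux_config()].
#' @return list with clean `reads`, `unassigned` and the final `report`.
#' @export
demux_trim <- function(reads, config) {
  dm <- demultiplex(reads, config)
  tr <- trim_reads(dm$assigned, config)
  dm$report$dropped_length <- tr$dropped
  list(reads = tr$reads, unassigned = dm$unassigned, report = dm$report)
}
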