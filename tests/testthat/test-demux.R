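# build a minimal hand-rolled pair with controllable prefix and quality
mk_pair <- function(bc1, bc2 = bc1, marker = "GGTG", q = 30, insert = 40) {
  body <- strrep("ATGA", ceiling(insert / 4))
  s1 <- paste0(marker, bc1, substr(body, 1, insert))
  s2 <- paste0(marker, bc2, substr(body, 1, insert))
  qc <- rawToChar(as.raw(33L + q))
  data.table::data.table(id = "p1", seq1 = s1, qual1 = strrep(qc, nchar(s1)),
                         seq2 = s2, qual2 = strrep(qc, nchar(s2)))
}

test_that("pairs are assigned on exact whitelisted barcodes only", {
  wl <- c(cellA = "ACACTG", cellB = "TGTGAC")
  cfg <- demux_config(wl)
  dm <- demultiplex(mk_pair("ACACTG"), cfg)
  expect_identical(dm$report$assigned, 1L)
  expect_identical(dm$assigned$cell_id, "cellA")

  # one mismatch to the nearest whitelist entry: unassigned
  dm2 <- demultiplex(mk_pair("ACACTA"), cfg)
  expect_identical(dm2$report$assigned, 0L)
  expect_identical(dm2$report$unassigned, 1L)

  # mates disagreeing on the barcode: unassigned
  dm3 <- demultiplex(mk_pair("ACACTG", "TGTGAC"), cfg)
  expect_identical(dm3$report$unassigned, 1L)

  # wrong marker: unassigned in fixed mode, assigned in NNNN mode
  dm4 <- demultiplex(mk_pair("ACACTG", marker = "TTTT"), cfg)
  expect_identical(dm4$report$unassigned, 1L)
  dm5 <- demultiplex(mk_pair("ACACTG", marker = "TTTT"),
                     demux_config(wl, marker = "NNNN"))
  expect_identical(dm5$report$assigned, 1L)
})

test_that("pairs with low mean barcode quality are removed, not unassigned", {
  wl <- c(cellA = "ACACTG")
  cfg <- demux_config(wl, min_barcode_q = 20)
  dm <- demultiplex(mk_pair("ACACTG", q = 19), cfg)
  expect_identical(dm$report$quality_filtered, 1L)
  expect_identical(dm$report$assigned, 0L)
  expect_identical(dm$report$unassigned, 0L)
  # Q20 exactly passes (threshold is "lower than Q20")
  dm2 <- demultiplex(mk_pair("ACACTG", q = 20), cfg)
  expect_identical(dm2$report$assigned, 1L)
  # quality filter outranks whitelist membership in the accounting
  dm3 <- demultiplex(mk_pair("NNNNNN", q = 10), cfg)
  expect_identical(dm3$report$quality_filtered, 1L)
})

test_that("malformed records are rejected with the record named", {
  wl <- c(cellA = "ACACTG")
  bad <- mk_pair("ACACTG")
  bad$qual1 <- substr(bad$qual1, 1, 5)
  expect_error(demultiplex(bad, demux_config(wl)), "p1")
})

test_that("demultiplexing accounting is conserved and error-free pools round-trip", {
  fx <- fx_clean_pool()
  dm <- demultiplex(fx$pool$reads, demux_config(fx$whitelist))
  rep <- dm$report
  expect_identical(rep$assigned + rep$unassigned + rep$quality_filtered,
                   rep$total)
  expect_identical(rep$assigned, nrow(fx$pool$reads))
  expect_identical(rep$unassigned, 0L)
  want <- truth_cell_of(fx$pool, fx$whitelist, dm$assigned$id)
  expect_identical(dm$assigned$cell_id, want)
})

test_that("single-base barcode errors never cause mis-assignment", {
  # whitelist min Hamming distance >= 3; inject one substitution into
  # the read-1 barcode of every pair: pairs may drop out (mate
  # disagreement) but must never switch cell
  fx <- fx_clean_pool()
  reads <- data.table::copy(fx$pool$reads)
  set.seed(31)
  pos <- sample(5:10, nrow(reads), replace = TRUE)
  for (i in seq_len(nrow(reads))) {
    old <- substr(reads$seq1[i], pos[i], pos[i])
    substr(reads$seq1[i], pos[i], pos[i]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  dm <- demultiplex(reads, demux_config(fx$whitelist))
  expect_identical(dm$report$assigned, 0L)  # mates always disagree now
  # corrupt both mates identically: either unassigned or (if the error
  # lands on another whitelist word, impossible at distance >= 3) never
  # the wrong cell
  reads2 <- data.table::copy(fx$pool$reads)
  for (i in seq_len(nrow(reads2))) {
    old <- substr(reads2$seq1[i], pos[i], pos[i])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(reads2$seq1[i], pos[i], pos[i]) <- new
    substr(reads2$seq2[i], pos[i], pos[i]) <- new
  }
  dm2 <- demultiplex(reads2, demux_config(fx$whitelist))
  expect_identical(dm2$report$assigned, 0L)
  expect_identical(dm2$report$unassigned, nrow(reads2))
})

test_that("trimming removes the structural prefix and 3' read-through exactly", {
  fx <- fx_clean_pool()
  dm <- demultiplex(fx$pool$reads, demux_config(fx$whitelist))
  tr <- trim_reads(dm$assigned, demux_config(fx$whitelist))
  m <- match(tr$reads$id, fx$pool$truth$read_id)
  len <- fx$pool$truth$insert_len[m]
  # inserts short enough for the full read-through: trimmed to the
  # insert, bar rare chance matches of the fuzzy 10-mer inside the
  # (A/T-rich) converted insert; never trimmed too little
  short <- len <= 140
  expect_gt(mean(nchar(tr$reads$seq1[short]) == len[short]), 0.99)
  expect_gt(mean(nchar(tr$reads$seq2[short]) == len[short]), 0.99)
  expect_true(all(nchar(tr$reads$seq1[short]) <= len[short]))
  expect_true(all(nchar(tr$reads$seq2[short]) <= len[short]))
  # long inserts (no read-through): only the 10 leading bases removed,
  # except for occasional chance 3'-overlap matches of the adapter /
  # read-through prefix, which can shave at most 9 further bases
  long <- len > 140
  if (any(long)) {
    expect_gt(mean(nchar(tr$reads$seq1[long]) == 140L), 0.95)
    expect_true(all(nchar(tr$reads$seq1[long]) >= 131L))
  }
  # quality strings track the sequence trimming
  expect_identical(nchar(tr$reads$qual1), nchar(tr$reads$seq1))
  # trimmed mates equal the converted insert prefix: verify against the
  # aligned fragment sequence downstream (round trip is in test-align)
})

test_that("pairs falling below the minimum retained length are dropped", {
  wl <- c(cellA = "ACACTG")
  cfg <- demux_config(wl, min_len = 20L)
  pr <- mk_pair("ACACTG", insert = 5)
  # append the read-through so trimming cuts down to the 5-bp insert
  rt <- revcomp(paste0("GGTG", "ACACTG"))
  pr$seq1 <- paste0(substr(pr$seq1, 1, 15), rt)
  pr$seq2 <- paste0(substr(pr$seq2, 1, 15), rt)
  pr$qual1 <- strrep("?", nchar(pr$seq1))
  pr$qual2 <- strrep("?", nchar(pr$seq2))
  dm <- demultiplex(pr, cfg)
  tr <- trim_reads(dm$assigned, cfg)
  expect_identical(tr$dropped, 1L)
  expect_identical(nrow(tr$reads), 0L)
  # clean read accounting
  report <- dm$report
  report$dropped_length <- tr$dropped
  expect_identical(clean_read_count(report), 0L)
  expect_identical(clean_read_count(list(assigned = 100, dropped_length = 7)), 93L)
  expect_identical(clean_read_count(list(assigned = 0, dropped_length = 0)), 0L)
})

test_that("trimming tolerates one substitution in the read-through", {
  fx <- fx_clean_pool()
  dm <- demultiplex(fx$pool$reads, demux_config(fx$whitelist))
  one <- dm$assigned[1]
  m <- match(one$id, fx$pool$truth$read_id)
  len <- fx$pool$truth$insert_len[m]
  skip_if(len > 130, "sampled insert too long for a full read-through")
  # corrupt one base inside the read-through of mate 1
  p <- 10L + len + 3L
  old <- substr(one$seq1, p, p)
  substr(one$seq1, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  tr <- trim_reads(one, demux_config(fx$whitelist))
  expect_identical(nchar(tr$reads$seq1), len)
})
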