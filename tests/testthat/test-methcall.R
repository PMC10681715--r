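# hand-built two-fragment reference for constructed pileups
mk_ref <- function() {
  # chr1: single fragment with one CpG at pos 3 (C) / 4 (G)
  cat <- data.table::data.table(id = "f1", chrom = "chr1", start = 1L,
                                end = 8L, length = 8L, seq = "ATCGATTA",
                                has_n = FALSE)
  idx <- index_cpgs(as_genome(c(chr1 = "ATCGATTA")))
  bs <- build_bs_index(cat, k = 4L)
  list(cat = cat, idx = idx, bs = bs)
}

mk_aln <- function(n, strand = "OT") {
  data.table::data.table(
    id = paste0("r", seq_len(n)), cell_id = "c1", status = "unique",
    fragment_id = "f1", chrom = "chr1", start = 1L, end = 8L,
    species = "genome", strand = strand, offset = 0L, mismatches = 0L)
}

test_that("pileup counts methylated C and converted T per covered site", {
  ref <- mk_ref()
  # 3 molecules read C at the CpG, 1 reads T; non-CpG C absent here
  reads <- data.table::data.table(
    id = paste0("r", 1:4),
    seq1 = c("ATCGATTA", "ATCGATTA", "ATCGATTA", "ATTGATTA"),
    seq2 = revcomp(c("ATCGATTA", "ATCGATTA", "ATCGATTA", "ATTGATTA")))
  cs <- pileup_calls(mk_aln(4), reads, ref$bs, ref$idx, cell_id = "c1")
  expect_identical(nrow(cs$cpg), 1L)
  expect_identical(cs$cpg$pos, 3L)
  expect_identical(cs$cpg$meth, 3L)
  expect_identical(cs$cpg$unmeth, 1L)
  # uncovered sites are absent
  expect_false(any(cs$cpg$pos == 99))
})

test_that("OT and OB observations merge onto the plus-strand C when destranded", {
  ref <- mk_ref()
  # one OT molecule reporting methylated C at pos 3; one OB molecule
  # reporting methylation at the paired G (pos 4): bottom-strand read
  # keeps C at the complementary position
  ot_reads <- data.table::data.table(id = "r1", seq1 = "ATCGATTA",
                                     seq2 = revcomp("ATCGATTA"))
  ob_mol <- revcomp("ATCGATTA")  # unconverted bottom strand
  ob_reads <- data.table::data.table(id = "r1", seq1 = ob_mol,
                                     seq2 = revcomp(ob_mol))
  cs_ot <- pileup_calls(mk_aln(1, "OT"), ot_reads, ref$bs, ref$idx)
  cs_ob <- pileup_calls(mk_aln(1, "OB"), ob_reads, ref$bs, ref$idx)
  both <- merge_callsets(list(cs_ot, cs_ob))
  expect_identical(both$cpg$pos, 3L)
  expect_identical(both$cpg$meth, 2L)
  expect_identical(both$cpg$unmeth, 0L)

  # stranded mode keeps the two strands apart; summing reproduces the
  # destranded merge exactly
  s_ot <- pileup_calls(mk_aln(1, "OT"), ot_reads, ref$bs, ref$idx,
                       destrand = FALSE)
  s_ob <- pileup_calls(mk_aln(1, "OB"), ob_reads, ref$bs, ref$idx,
                       destrand = FALSE)
  expect_identical(s_ot$cpg$strand, "+")
  expect_identical(s_ob$cpg$strand, "-")
  expect_identical(s_ot$cpg$meth + s_ob$cpg$meth, both$cpg$meth)
})

test_that("destranding equals summing per-strand counts on real pools", {
  fx <- fx_aligned()
  de <- pileup_calls(fx$aln, fx$dm$reads, fx$bs, fx$index)
  st <- pileup_calls(fx$aln, fx$dm$reads, fx$bs, fx$index, destrand = FALSE)
  resum <- st$cpg[, .(meth = sum(meth), unmeth = sum(unmeth)),
                  by = .(chrom, pos)]
  data.table::setkey(resum, chrom, pos)
  expect_identical(resum, de$cpg)
})

test_that("per-site totals equal truth molecule coverage on clean pools", {
  fx <- fx_aligned()
  cs <- pileup_calls(fx$aln, fx$dm$reads, fx$bs, fx$index)
  tr <- fx$pool$truth
  # molecules covering a site: fragment contains the site; short inserts
  # are fully read, so every molecule of that fragment observes it
  sel <- fx$selected[fx$selected$length <= 140]
  for (k in c(1, 50, 100)) {
    s <- cs$cpg[k]
    frs <- sel[chrom == s$chrom & start <= s$pos & end >= s$pos]
    if (nrow(frs) == 0) next
    want <- sum(tr$fragment_id %in% frs$id)
    expect_identical(s$meth + s$unmeth, as.integer(want))
  }
})

test_that("site levels converge to the cell's true probabilities", {
  fx <- fx_aligned()
  cells <- pileup_cells(fx$aln, fx$dm$reads, fx$bs, fx$index)
  expect_named(cells, paste0("cell", 1:4))
  # the 3 SD envelope is a normal approximation: at small p the
  # binomial upper tail exceeds it for ~1% of sites, so near-total
  # rather than total compliance is the correct expectation
  within <- total <- 0
  for (i in 1:4) {
    cs <- cells[[i]]
    truth_p <- fx$profiles[[i]]$prob
    cg <- merge(cs$cpg, truth_p, by = c("chrom", "pos"))
    n <- cg$meth + cg$unmeth
    deep <- n >= 10
    if (!any(deep)) next
    err <- abs(cg$meth / n - cg$p)
    bound <- pmax(3 * sqrt(cg$p * (1 - cg$p) / n), 2 / n)
    within <- within + sum(err[deep] <= bound[deep] + 1e-9)
    total <- total + sum(deep)
  }
  expect_gt(total, 100)
  expect_gte(within / total, 0.98)
})

test_that("conversion rate is estimated from spike-in cytosines of all contexts", {
  cs <- methylation_calls(
    data.table::data.table(chrom = "lambda_control", pos = 10L,
                           meth = 4L, unmeth = 496L),
    data.table::data.table(chrom = "lambda_control",
                           context = c("CHG", "CHH"),
                           meth = c(0L, 0L), unmeth = c(200L, 300L)))
  est <- estimate_conversion_rate(cs)
  expect_equal(est$rate, 996 / 1000)
  expect_identical(est$n, 1000L)
  all_conv <- methylation_calls(
    data.table::data.table(chrom = "lambda_control", pos = 10L,
                           meth = 0L, unmeth = 100L))
  expect_equal(estimate_conversion_rate(all_conv)$rate, 1.0)
  none <- methylation_calls(
    data.table::data.table(chrom = "chr1", pos = 1L, meth = 1L, unmeth = 0L))
  expect_warning(est0 <- estimate_conversion_rate(none), "no spike-in")
  expect_true(is.na(est0$rate))
})

test_that("conversion-failure settings are recovered within 3 binomial SD", {
  fx <- fx_clean_pool()
  for (f in c(0, 0.004, 0.02)) {
    cfg <- fx$config
    cfg$conversion_failure <- f
    cfg$spike_frac <- 0.5
    cfg$seed <- 1000L + round(1000 * f)
    pool <- spike_lambda(simulate_reads(fx$profiles, fx$catalog, cfg, fx$index))
    dm <- demux_trim(pool$reads, demux_config(fx$whitelist))
    ctrl <- lambda_control_genome()
    catc <- select_inserts(digest_mspi(ctrl))
    catc[, species := "spikein"]
    catg <- data.table::copy(fx$selected)[, species := "genome"]
    bs <- build_bs_index(rbind(catg, catc))
    fidx <- index_cpgs(as_genome(c(fx$genome, ctrl)))
    aln <- align_pairs(dm$reads, bs)
    cs <- pileup_calls(aln, dm$reads, bs, fidx)
    est <- estimate_conversion_rate(cs)
    expect_gt(est$n, 10000)
    tol <- 3 * sqrt(max(f * (1 - f), 1e-6) / est$n)
    expect_lt(abs(est$rate - (1 - f)), max(tol, 5e-4))
  }
})

test_that("context levels aggregate counts within each context", {
  cs <- methylation_calls(
    data.table::data.table(chrom = "chr1", pos = c(2L, 8L),
                           meth = c(3L, 0L), unmeth = c(1L, 4L)),
    data.table::data.table(chrom = "chr1", context = c("CHG", "CHH"),
                           meth = c(4L, 0L), unmeth = c(996L, 250L)))
  lv <- context_levels(cs)
  expect_equal(unname(lv["CpG"]), 3 / 8)
  expect_equal(unname(lv["CHG"]), 0.004)
  expect_equal(unname(lv["CHH"]), 0)
  empty <- methylation_calls(
    data.table::data.table(chrom = character(0), pos = integer(0),
                           meth = integer(0), unmeth = integer(0)))
  expect_true(all(is.na(context_levels(empty))))
})

test_that("cell QC applies the inclusive detected-sites threshold", {
  mk <- function(n) methylation_calls(
    data.table::data.table(chrom = "chr1", pos = seq_len(n),
                           meth = 1L, unmeth = 0L), cell_id = "c")
  expect_true(cell_qc(mk(250), min_sites = 200L)$pass)
  expect_false(cell_qc(mk(100), min_sites = 200L)$pass)
  expect_true(cell_qc(mk(200), min_sites = 200L)$pass)
  expect_identical(cell_qc(mk(200), min_sites = 200L)$detected_sites, 200L)
})

test_that("CGmap output is 1-based and round-trips counts exactly", {
  cs <- methylation_calls(
    data.table::data.table(chrom = "chr1", pos = 2L, meth = 3L, unmeth = 1L),
    cell_id = "c1")
  path <- tempfile(fileext = ".tsv")
  write_cgmap(cs, path)
  line <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_identical(line[3], "2")        # 1-based position
  expect_identical(line[6], "0.75")     # level
  expect_identical(line[7:8], c("3", "4"))
  empty <- methylation_calls(
    data.table::data.table(chrom = character(0), pos = integer(0),
                           meth = integer(0), unmeth = integer(0)))
  expect_error(write_cgmap(empty, path), "empty")

  # random call sets round-trip bit-exactly
  set.seed(17)
  for (i in 1:20) {
    n <- sample(1:80, 1)
    cs2 <- methylation_calls(data.table::data.table(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      pos = sample.int(10000, n),
      meth = as.integer(rpois(n, 2)),
      unmeth = as.integer(rpois(n, 2) + 1)), cell_id = "x")
    p2 <- tempfile(fileext = ".tsv")
    write_cgmap(cs2, p2)
    back <- read_cgmap(p2, cell_id = "x")
    expect_identical(back$cpg, cs2$cpg)
  }
})

test_that("bedGraph output is 0-based half-open with percent levels", {
  cs <- methylation_calls(
    data.table::data.table(chrom = "chr1", pos = 2L, meth = 3L, unmeth = 1L))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(cs, path)
  line <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_identical(line[2:3], c("1", "2"))
  expect_identical(line[4], "75")
  back <- read_bedgraph(path)
  expect_identical(back$pos, 2L)
  expect_equal(back$level, 0.75)
})

test_that("duplicate collapse removes repeated (fragment, strand, cell) pairs", {
  ref <- mk_ref()
  reads <- data.table::data.table(
    id = paste0("r", 1:3),
    seq1 = rep("ATCGATTA", 3), seq2 = revcomp(rep("ATCGATTA", 3)))
  cs <- pileup_calls(mk_aln(3), reads, ref$bs, ref$idx, dedup = TRUE)
  expect_identical(cs$cpg$meth + cs$cpg$unmeth, 1L)
})
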