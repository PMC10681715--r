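mk_cs <- function(pos, meth, unmeth, chrom = "chr1", id = "c") {
  methylation_calls(data.table::data.table(
    chrom = chrom, pos = as.integer(pos), meth = as.integer(meth),
    unmeth = as.integer(unmeth)), cell_id = id)
}

test_that("merging call sets sums counts and is associative and commutative", {
  a <- mk_cs(c(10, 50), c(3, 1), c(1, 0), id = "a")
  b <- mk_cs(c(50, 99), c(1, 0), c(1, 3), id = "b")
  c3 <- mk_cs(120, 2, 2, id = "c3")
  m1 <- merge_callsets(list(a))
  expect_identical(m1$cpg, a$cpg)
  ab <- merge_callsets(list(a, b))
  expect_identical(ab$cpg[pos == 50]$meth, 2L)
  expect_identical(ab$cpg[pos == 50]$unmeth, 1L)
  expect_identical(nrow(ab$cpg), 3L)  # union of sites
  # commutative and associative on counts
  ba <- merge_callsets(list(b, a))
  expect_identical(ab$cpg, ba$cpg)
  left <- merge_callsets(list(merge_callsets(list(a, b)), c3))
  right <- merge_callsets(list(a, merge_callsets(list(b, c3))))
  expect_identical(left$cpg, right$cpg)
  # stranded/destranded mixing is refused
  s <- methylation_calls(data.table::data.table(
    chrom = "chr1", pos = 1L, strand = "+", meth = 1L, unmeth = 0L),
    destranded = FALSE)
  expect_error(merge_callsets(list(a, s)), "stranded")
})

test_that("element detection requires one covered CpG inside the element", {
  cs <- mk_cs(c(150, 950), c(1, 0), c(0, 1))
  els <- element_set(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 900, 2000), c(200, 1000, 2100))), "CGI")
  det <- element_detection_rate(cs, els)
  expect_identical(det$detected, 2L)
  expect_equal(det$fraction, 2 / 3)
  all_cov <- element_detection_rate(cs, els[1:2])
  expect_equal(all_cov$fraction, 1.0)
  none <- element_detection_rate(mk_cs(5000, 1, 0), els)
  expect_equal(none$fraction, 0)
  expect_error(element_detection_rate(cs, els[0]), "empty")
  # a single covered CpG suffices
  one <- element_detection_rate(mk_cs(150, 0, 1), els)
  expect_identical(one$detected, 1L)
})

test_that("window levels are coverage-weighted and NA when uncovered", {
  g <- as_genome(c(chr1 = strrep("A", 300)))
  a <- mk_cs(c(10, 50), c(3, 1), c(1, 0), id = "a")   # window 1: 4/5
  b <- mk_cs(c(20, 80), c(1, 0), c(0, 3), id = "b")   # window 1: (1+0)/(1+3)
  wm <- window_methylation(list(a = a, b = b), 100L, g)
  expect_identical(dim(wm), c(2L, 3L))
  expect_equal(wm["a", 1], 4 / 5)
  expect_equal(wm["b", 1], 1 / 4)   # coverage-weighted, not mean of levels
  expect_true(all(is.na(wm[, 2:3])))
  # single site (3,1) -> 0.75
  w1 <- window_methylation(list(x = mk_cs(10, 3, 1)), 100L, g)
  expect_equal(w1["x", 1], 0.75)
})

test_that("window levels of a merged call set equal count-weighted member levels", {
  fx <- fx_aligned()
  cells <- pileup_cells(fx$aln, fx$dm$reads, fx$bs, fx$index)
  merged <- merge_callsets(cells)
  wm_all <- window_methylation(c(cells, list(merged = merged)), 200L,
                               fx$genome)
  # recompute the merged row from member counts
  for (w in which(!is.na(wm_all["merged", ]))[1:25]) {
    col <- colnames(wm_all)[w]
    parts <- strsplit(sub("^.*:", "", col), "-")[[1]]
    lo <- as.integer(parts[1]); hi <- as.integer(parts[2])
    tot <- meth <- 0
    for (cs in cells) {
      sub <- cs$cpg[chrom == "chr1" & pos >= lo & pos <= hi]
      meth <- meth + sum(sub$meth); tot <- tot + sum(sub$meth + sub$unmeth)
    }
    expect_equal(unname(wm_all["merged", w]), meth / tot)
  }
})

test_that("pairwise correlation honours coverage floors and shared-site minima", {
  a <- mk_cs(1:10, c(0, 10, 0, 10, 0, 10, 0, 10, 0, 10),
             c(10, 0, 10, 0, 10, 0, 10, 0, 10, 0), id = "a")
  anti <- mk_cs(1:10, c(10, 0, 10, 0, 10, 0, 10, 0, 10, 0),
                c(0, 10, 0, 10, 0, 10, 0, 10, 0, 10), id = "anti")
  m <- pairwise_correlation(list(a = a, anti = anti))
  expect_equal(m["a", "a"], 1.0)
  expect_equal(m["a", "anti"], -1.0)
  # identical profiles correlate perfectly
  m2 <- pairwise_correlation(list(a = a, b = a))
  expect_equal(m2["a", "b"], 1.0)
  # fewer than 3 shared sites -> NA
  short <- mk_cs(1:2, c(1, 0), c(0, 1), id = "s")
  m3 <- pairwise_correlation(list(a = a, s = short))
  expect_true(is.na(m3["a", "s"]))
  # coverage floor excludes thin sites
  thin <- mk_cs(1:10, rep(1, 10), rep(0, 10), id = "t")
  m4 <- pairwise_correlation(list(a = a, t = thin), min_cov = 5)
  expect_true(is.na(m4["a", "t"]))
})

test_that("metagene profiles are strand-aware and coverage-weighted", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000),
                                  strand = "+")
  # uniform 0.5 methylation everywhere: flat profile
  pos <- seq(1, 9000, by = 50)
  cs <- mk_cs(pos, rep(1, length(pos)), rep(1, length(pos)))
  pr <- metagene_profile(cs, genes, flank = 2000L, body_bins = 10L,
                         flank_bins = 5L)
  expect_identical(nrow(pr), 20L)
  expect_true(all(abs(pr$level - 0.5) < 1e-12, na.rm = TRUE))
  expect_identical(pr$zone, rep(c("upstream", "body", "downstream"),
                                c(5L, 10L, 5L)))

  # methylation only downstream of the TSS of a minus-strand gene:
  # after orientation the signal sits on the body side
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000),
                               strand = "-")
  # minus-strand TSS is at 4000; "downstream of TSS" = inside the body
  body_pos <- seq(2101, 3900, by = 100)
  cs2 <- mk_cs(c(body_pos, seq(4100, 5900, by = 100)),
               c(rep(1, length(body_pos)), rep(0, 19)),
               c(rep(0, length(body_pos)), rep(1, 19)))
  pr2 <- metagene_profile(cs2, gm, flank = 2000L, body_bins = 10L,
                          flank_bins = 5L)
  expect_true(all(pr2$level[pr2$zone == "body"] == 1, na.rm = TRUE))
  expect_true(all(pr2$level[pr2$zone == "upstream"] == 0, na.rm = TRUE))

  # a single covered site yields exactly one non-missing bin
  single <- metagene_profile(mk_cs(3000, 1, 0), genes, flank = 2000L,
                             body_bins = 10L, flank_bins = 5L)
  expect_identical(sum(!is.na(single$level)), 1L)
  expect_error(metagene_profile(cs, genes[0]), "no genes")
})

test_that("embeddings separate archetypes, are seeded, and collapse identical cells", {
  g <- random_genome(c(chr1 = 60000L), seed = 15)
  idx <- index_cpgs(g)
  cgis <- call_cgis(g)
  hypo <- methylome_archetype(cgi = 0.05, background = 0.2)
  hyper <- methylome_archetype(cgi = 0.1, background = 0.9)
  mk <- function(arch, tag, i) {
    simulate_callset(simulate_cell_methylome(idx, cgis, arch,
                                             seed = 400 + i,
                                             cell_id = paste0(tag, i)),
                     mean_cov = 6, seed = 500 + i)
  }
  cells <- c(lapply(1:8, function(i) mk(hypo, "lo", i)),
             lapply(1:8, function(i) mk(hyper, "hi", i + 8)))
  names(cells) <- vapply(cells, `[[`, "", "cell_id")
  wm <- window_methylation(cells, 200L, g)
  for (method in c("pca", "mds", "tsne")) {
    if (method == "tsne") skip_if_not_installed("Rtsne")
    xy <- embed_cells(wm, method, seed = 3)
    expect_identical(dim(xy), c(16L, 2L))
    km <- local({ set.seed(1); stats::kmeans(xy, 2) })
    truth <- rep(1:2, each = 8)
    agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
    expect_identical(agree, 1)  # adjusted Rand = 1 at perfect agreement
    expect_identical(embed_cells(wm, method, seed = 3), xy)
  }
  # all-identical cells embed at (numerically) zero spread
  same <- wm[rep(1, 6), ]
  rownames(same) <- paste0("s", 1:6)
  xy0 <- embed_cells(same, "pca", seed = 1)
  expect_lt(max(dist(xy0)), 1e-8)
  expect_error(embed_cells(wm[1:2, ], "pca"), "3 cells")
})

test_that("pseudo-bulk agrees with truth better than single cells with each other", {
  fx <- fx_aligned()
  cells <- pileup_cells(fx$aln, fx$dm$reads, fx$bs, fx$index)
  pc <- pairwise_correlation(cells, min_cov = 1)
  mean_cell_r <- mean(pc[upper.tri(pc)], na.rm = TRUE)
  merged <- merge_callsets(cells)
  truth_mean <- data.table::rbindlist(
    lapply(fx$profiles, function(p) p$prob))[, .(p = mean(p)),
                                             by = .(chrom, pos)]
  cmp <- merge(merged$cpg, truth_mean, by = c("chrom", "pos"))
  pb_r <- stats::cor(cmp$meth / (cmp$meth + cmp$unmeth), cmp$p)
  expect_lt(mean_cell_r, pb_r)
})

test_that("saturation curves are monotone and exact at full depth", {
  fx <- fx_aligned()
  full <- pileup_calls(fx$aln, fx$dm$reads, fx$bs, fx$index)
  els <- fx$cgis
  skip_if(length(els) == 0, "no CGIs on this fixture genome")
  total <- nrow(fx$aln)
  depths <- c(0L, 100L, 400L, 800L, total)
  sat <- downsample_saturation(fx$aln, fx$dm$reads, fx$bs, fx$index,
                               els, depths, replicates = 3L, seed = 5)
  expect_identical(sat$depth, depths)
  expect_identical(sat$cpg_detected[1], 0)
  expect_true(all(diff(sat$cpg_detected) >= 0))
  expect_true(all(diff(sat$elements_detected) >= 0))
  # full depth equals exhaustive counts exactly
  expect_identical(sat$cpg_detected[length(depths)], as.numeric(nrow(full$cpg)))
  expect_identical(sat$elements_detected[length(depths)],
                   as.numeric(element_detection_rate(full, els)$detected))
  expect_warning(
    downsample_saturation(fx$aln, fx$dm$reads, fx$bs, fx$index, els,
                          c(10L, total + 50L), replicates = 1L, seed = 1),
    "clipped")
})
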