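# cached combination matrices for the exact MWU null, keyed "N.n"
.mwu_cache <- new.env(parent = emptyenv())

mwu_combinations <- function(N, n) {
  key <- paste0(N, ".", n)
  cmb <- get0(key, envir = .mwu_cache)
  if (is.null(cmb)) {
    cmb <- utils::combn(N, n)
    assign(key, cmb, envir = .mwu_cache)
  }
  cmb
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Computes the two-sided Mann-Whitney U p-value. For n + m <=
#' `exact_max` the null distribution of U (with midrank tie handling)
#' is obtained by enumerating all choose(n+m, n) group-label
#' assignments of the observed pooled values, and the two-sided p-value
#' doubles the smaller tail (capped at 1). Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max largest n + m for which the exact enumeration is
#'   used.
#' @return list with `u` (U statistic of `x`), `p.value` and `method`.
#' @export
mwu_test <- function(x, y, exact_max = 20L) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  N <- n + m
  eps <- 1e-9
  if (N <= exact_max) {
    cmb <- mwu_combinations(N, n)
    rs <- colSums(matrix(r[cmb], nrow = n))
    u_all <- rs - n * (n + 1) / 2
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    list(u = u_obs, p.value = min(1, p), method = "exact")
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u_obs, p.value = 1, method = "normal"))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    list(u = u_obs, p.value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
  }
}

#' Test one CpG site for differential methylation
#'
#' In `mwu` mode the per-cell levels of the two groups are compared
#' with [mwu_test()]; sites with fewer than `min_cells` covered cells
#' in either group yield NULL (a missing record, not an error). In
#' `fisher` mode pooled (meth, unmeth) counts are compared with
#' Fisher's exact test.
#'
#' @param levels_a,levels_b per-cell methylation levels (mwu mode).
#' @param counts_a,counts_b length-2 pooled (meth, unmeth) counts
#'   (fisher mode).
#' @param mode "mwu" or "fisher".
#' @param min_cells minimum covered cells per group in mwu mode.
#' @return list with `p.value`, `diff` (mean A - mean B) and group
#'   sizes, or NULL when coverage is insufficient.
#' @export
test_dmc <- function(levels_a = NULL, levels_b = NULL,
                     counts_a = NULL, counts_b = NULL,
                     mode = c("mwu", "fisher"), min_cells = 3L) {
  mode <- match.arg(mode)
  if (mode == "mwu") {
    levels_a <- levels_a[!is.na(levels_a)]
    levels_b <- levels_b[!is.na(levels_b)]
    if (length(levels_a) < min_cells || length(levels_b) < min_cells)
      return(NULL)
    tt <- mwu_test(levels_a, levels_b)
    list(p.value = tt$p.value, diff = mean(levels_a) - mean(levels_b),
         n_a = length(levels_a), n_b = length(levels_b))
  } else {
    tab <- rbind(counts_a, counts_b)
    ft <- stats::fisher.test(tab)
    la <- counts_a[1] / sum(counts_a); lb <- counts_b[1] / sum(counts_b)
    list(p.value = ft$p.value, diff = la - lb,
         n_a = sum(counts_a), n_b = sum(counts_b))
  }
}

#' Differential methylation table over two cell groups
#'
#' Builds per-cell level vectors per CpG site from two groups of call
#' sets and tests each site with [test_dmc()].
#'
#' @param group_a,group_b lists of `methylation_calls`.
#' @param min_cells minimum covered cells per group at a site.
#' @param min_cov per-cell coverage needed for a site to count as
#'   covered in that cell.
#' @param mode passed to [test_dmc()] ("fisher" pools counts within
#'   each group).
#' @return `data.table(chrom, pos, p, diff, n_a, n_b)` sorted by
#'   position; sites with insufficient coverage are absent.
#' @export
dmc_table <- function(group_a, group_b, min_cells = 3L, min_cov = 1L,
                      mode = c("mwu", "fisher")) {
  mode <- match.arg(mode)
  levels_of <- function(cs) {
    cg <- cs$cpg[cs$cpg$meth + cs$cpg$unmeth >= min_cov]
    data.table::data.table(chrom = cg$chrom, pos = cg$pos,
                           meth = cg$meth, unmeth = cg$unmeth,
                           level = cg$meth / (cg$meth + cg$unmeth))
  }
  la <- data.table::rbindlist(lapply(group_a, levels_of), idcol = "cell")
  lb <- data.table::rbindlist(lapply(group_b, levels_of), idcol = "cell")
  if (mode == "mwu") {
    ca <- la[, .(na = .N, va = list(level)), by = .(chrom, pos)]
    cb <- lb[, .(nb = .N, vb = list(level)), by = .(chrom, pos)]
    sites <- merge(ca, cb, by = c("chrom", "pos"))
    sites <- sites[na >= min_cells & nb >= min_cells]
    if (nrow(sites) == 0)
      return(data.table::data.table(chrom = character(0), pos = integer(0),
                                    p = numeric(0), diff = numeric(0),
                                    n_a = integer(0), n_b = integer(0)))
    res <- lapply(seq_len(nrow(sites)), function(i) {
      test_dmc(sites$va[[i]], sites$vb[[i]], min_cells = min_cells)
    })
    out <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos,
      p = vapply(res, `[[`, numeric(1), "p.value"),
      diff = vapply(res, `[[`, numeric(1), "diff"),
      n_a = sites$na, n_b = sites$nb)
  } else {
    ca <- la[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
    cb <- lb[, .(meth = sum(meth), unmeth = sum(unmeth)), by = .(chrom, pos)]
    sites <- merge(ca, cb, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
    if (nrow(sites) == 0)
      return(data.table::data.table(chrom = character(0), pos = integer(0),
                                    p = numeric(0), diff = numeric(0),
                                    n_a = integer(0), n_b = integer(0)))
    res <- lapply(seq_len(nrow(sites)), function(i) {
      test_dmc(counts_a = c(sites$meth_a[i], sites$unmeth_a[i]),
               counts_b = c(sites$meth_b[i], sites$unmeth_b[i]),
               mode = "fisher")
    })
    out <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos,
      p = vapply(res, `[[`, numeric(1), "p.value"),
      diff = vapply(res, `[[`, numeric(1), "diff"),
      n_a = sites$meth_a + sites$unmeth_a,
      n_b = sites$meth_b + sites$unmeth_b)
  }
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Call differentially methylated regions
#'
#' Significant same-direction DMCs are chained while consecutive gaps
#' are below `merge_gap` bp (an opposite-direction significant site
#' breaks a chain); a chain becomes a DMR iff it contains at least
#' `min_cpg` sites and spans at least `min_len` bp (first to last
#' member C, inclusive). These are the single-cell DMR criteria:
#' p < 0.05, >= 3 CpGs, >= 100 bp between independent DMRs, length
#' >= 50 bp.
#'
#' @param dmc DMC table from [dmc_table()] (sorted by position).
#' @param p_threshold significance cutoff on the raw p-value (no
#'   multiple-testing correction by default; set `adjust = "BH"` for
#'   Benjamini-Hochberg).
#' @param min_cpg minimum member CpG count.
#' @param merge_gap chains break at gaps >= this many bp.
#' @param min_len minimum region span in bp.
#' @param adjust "none" (default) or "BH".
#' @return `data.table(chrom, start, end, n_cpg, mean_diff, direction,
#'   p_summary, sites)` with `sites` a list column of member positions.
#' @export
call_dmrs <- function(dmc, p_threshold = 0.05, min_cpg = 3L,
                      merge_gap = 100L, min_len = 50L,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpg = integer(0), mean_diff = numeric(0), direction = character(0),
    p_summary = numeric(0), sites = list())
  if (nrow(dmc) == 0) return(empty)
  dmc <- data.table::copy(dmc)
  data.table::setkey(dmc, chrom, pos)
  pv <- if (adjust == "BH") stats::p.adjust(dmc$p, "BH") else dmc$p
  sig <- dmc[pv < p_threshold & !is.na(pv) & diff != 0]
  if (nrow(sig) == 0) return(empty)
  sig[, direction := ifelse(diff > 0, "hyper", "hypo")]
  sig[, new_chain := c(TRUE, chrom[-1] != chrom[-.N] |
                         direction[-1] != direction[-.N] |
                         pos[-1] - pos[-.N] >= merge_gap)]
  sig[, chain := cumsum(new_chain)]
  out <- sig[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                 n_cpg = .N, mean_diff = mean(diff),
                 direction = direction[1],
                 p_summary = stats::pchisq(-2 * sum(log(pmax(p, 1e-300))),
                                           df = 2 * .N, lower.tail = FALSE),
                 sites = list(pos)),
             by = chain][, chain := NULL]
  out <- out[n_cpg >= min_cpg & end - start + 1L >= min_len]
  out[]
}

#' Annotate DMRs with overlapping element kinds
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param element_sets list of deduplicated ElementSets.
#' @return the DMR table with an `annotation` column: overlapping kinds
#'   (>= 1 bp) separated by ";", or "intergenic".
#' @export
annotate_dmrs <- function(dmrs, element_sets) {
  out <- data.table::copy(dmrs)
  if (nrow(out) == 0) { out[, annotation := character(0)]; return(out[]) }
  gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end))
  anns <- rep("", nrow(out))
  for (es in element_sets) {
    hit <- IRanges::overlapsAny(gr, es, ignore.strand = TRUE)
    anns[hit] <- paste0(anns[hit], ifelse(anns[hit] == "", "", ";"),
                        element_kind(es))
  }
  out[, annotation := ifelse(anns == "", "intergenic", anns)]
  out[]
}

#' Write DMRs as BED6+
#'
#' Name column is the direction; score is -10 log10(p) capped at 1000.
#'
#' @param dmrs (annotated) DMR table.
#' @param path output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$p_summary, 1e-100))))
  dt <- data.table::data.table(chrom = dmrs$chrom, start = dmrs$start - 1L,
                               end = dmrs$end, name = dmrs$direction,
                               score = score, strand = ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
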