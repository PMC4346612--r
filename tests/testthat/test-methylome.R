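flat_methylome <- function(n = 5000, level = 0.85, coverage = 30,
                           spacing = 100, seed = 1) {
  set.seed(seed)
  covg <- pmax(1, rpois(n, coverage))
  data.table::data.table(chrom = "1", pos = seq_len(n) * spacing,
                         fraction = rbinom(n, covg, level) / covg,
                         coverage = covg)
}

test_that("a flat methylome yields no UMRs", {
  expect_equal(nrow(call_umrs(flat_methylome())), 0)
})

test_that("a planted hypomethylated region is recovered as exactly one UMR", {
  m <- flat_methylome(seed = 2)
  # 10 CpGs over 300 bp at fractional methylation 0.05
  umr_pos <- as.integer(250000 + seq(0, 297, length.out = 10))
  set.seed(3)
  covg <- pmax(1, rpois(10, 30))
  planted <- data.table::data.table(chrom = "1", pos = umr_pos,
                                    fraction = rbinom(10, covg, 0.05) / covg,
                                    coverage = covg)
  m2 <- rbind(m[pos < 250000 | pos > 250300], planted)
  data.table::setorder(m2, chrom, pos)
  out <- call_umrs(m2)
  expect_equal(nrow(out), 1)
  expect_true(out$start >= 249000 && out$end <= 251000)
  expect_equal(out$n_cpgs, 10)
  expect_lt(out$p_value, 0.0005)
  # per-CpG binomial oracle: every planted CpG individually significant
  bg <- weighted.mean(m2$fraction, m2$coverage)
  p_each <- vapply(seq_len(10), function(i)
    sum(dbinom(0:round(planted$fraction[i] * planted$coverage[i]),
               planted$coverage[i], bg)), numeric(1))
  expect_true(all(p_each < 0.05))
})

test_that("UMR output is sorted, non-overlapping and below background", {
  sim <- simulate_genome(small_sim_config(rng_seed = 47))
  u <- call_umrs(sim$methylomes$luminal)
  expect_gt(nrow(u), 0)
  bg <- attr(u, "background")
  expect_true(all(u$mean_methylation < bg))
  expect_true(all(u$p_value < 0.0005))
  by_chrom <- split(u, u$chrom)
  for (d in by_chrom) {
    expect_false(is.unsorted(d$start))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("degenerate methylome inputs are handled as specified", {
  expect_error(call_umrs(flat_methylome(n = 100)), "1000")
  low <- flat_methylome(level = 0.3, seed = 5)
  expect_warning(call_umrs(low), "hypomethylated input")
})

test_that("MeDIP calibration filters mappability and maps quantiles monotonically", {
  set.seed(6)
  L <- 60000
  pos <- seq(1000, 50000, by = 100)
  sigv <- rep(1, L)
  sigv[pos + 1] <- seq_along(pos)          # strictly increasing CpG signal
  mapv <- rep(1, L)
  mapv[pos[5] + 1] <- 0.3                   # one low-mappability CpG
  mapv[pos[10] + 1] <- 0.75
  signal <- suppressMessages(coverage_track(list("1" = sigv), assay = "medip"))
  mp <- suppressMessages(coverage_track(list("1" = mapv),
                                        assay = "mappability",
                                        library_total = 1))
  cpgs <- data.table::data.table(chrom = "1", pos = pos)
  ref <- runif(5000)
  out <- calibrate_medip(signal, ref, mp, cpgs, signal_window = 0)
  expect_false(pos[5] %in% out$pos)         # mappability < 0.5 dropped
  expect_true(pos[10] %in% out$pos)         # 0.5 <= m < 1 kept, corrected
  # monotone: higher raw enrichment never gives a lower score
  o <- out[order(raw_enrichment)]
  expect_true(all(diff(o$score) >= 0))
  expect_true(all(out$score >= 0 & out$score <= 1))
  expect_true(all(out$class %in% c("hypomethylated", "intermediate",
                                   "hypermethylated")))
  expect_error(calibrate_medip(signal, numeric(0), mp, cpgs), "empty reference")
})

test_that("boundary profiles emit 20 bins per side and match the per-CpG oracle", {
  sim <- simulate_genome(small_sim_config(rng_seed = 53))
  meth <- sim$methylomes$luminal
  ex <- sim$genes$exons[1:40]
  feats <- data.table::data.table(
    chrom = ex$chrom, pos = ifelse(ex$strand == "-", ex$end, ex$start),
    strand = ex$strand,
    group = rep(c("g1", "g2"), length.out = nrow(ex)))
  prof <- boundary_profile(meth, feats)
  expect_equal(sort(unique(prof$bin)), c(-(10:1), 1:10))
  expect_equal(nrow(prof), 2 * 20)
  oracle <- oracle_profile(meth, feats)
  m <- merge(prof[n_cpgs > 0], oracle, by = c("group", "bin"))
  expect_equal(nrow(m), nrow(prof[n_cpgs > 0]))
  expect_equal(m$mean_methylation.x, m$mean_methylation.y, tolerance = 1e-12)
  expect_equal(m$n_cpgs.x, m$n_cpgs.y)
})

test_that("a uniform methylome yields flat profiles and a null group test", {
  m <- flat_methylome(n = 20000, spacing = 20, seed = 8)
  feats <- data.table::data.table(chrom = "1",
                                  pos = as.integer(seq(5000, 300000, by = 3000)),
                                  strand = "+",
                                  group = rep(c("a", "b"), length.out = 99))
  prof <- boundary_profile(m, feats)
  spread <- prof[, diff(range(mean_methylation))]
  expect_lt(spread, 0.1)
  tt <- boundary_group_test(m, feats)
  expect_gt(tt$p_value, 0.05)
})

test_that("planted boundary hypomethylation separates groups decisively", {
  set.seed(9)
  n_per <- 500
  pos_all <- list(); frac_all <- list()
  feats <- list()
  for (i in seq_len(2 * n_per)) {
    center <- i * 2000L
    p <- seq(center - 200L, center + 199L, by = 40L)
    expressed <- i <= n_per
    f <- if (expressed) pmax(0, 0.85 - 0.6 * exp(-abs(p - center) / 60)) else
      rep(0.85, length(p))
    f <- pmin(1, pmax(0, f + rnorm(length(p), 0, 0.05)))
    pos_all[[i]] <- p; frac_all[[i]] <- f
    feats[[i]] <- data.table::data.table(
      chrom = "1", pos = center, strand = "+",
      group = if (expressed) "expressed" else "not_expressed")
  }
  meth <- data.table::data.table(chrom = "1", pos = unlist(pos_all),
                                 fraction = unlist(frac_all), coverage = 30)
  tt <- boundary_group_test(meth, data.table::rbindlist(feats))
  expect_lt(tt$p_value, 1e-6)
})

test_that("exon signal enrichment is unity on uniform tracks and scale invariant", {
  ex <- data.table::data.table(chrom = "1",
                               start = seq(0, 9000, by = 1000),
                               end = seq(200, 9200, by = 1000),
                               group = rep(c("x", "y"), 5))
  tr <- flat_track(c("1" = 10000), 4, assay = "h3k36me3", library_total = 1e4)
  out <- exon_signal_enrichment(tr, ex)
  expect_equal(out$fold_enrichment, c(1, 1))
  tr2 <- flat_track(c("1" = 10000), 8, assay = "h3k36me3",
                    library_total = 2e4)
  expect_equal(exon_signal_enrichment(tr2, ex)$fold_enrichment,
               out$fold_enrichment)
  expect_error(exon_signal_enrichment(flat_track(c("1" = 100), 0,
                                                 library_total = 1), ex),
               "zero genome-wide signal")
})

test_that("planted H3K36me3 exon enrichment is recovered within 10%", {
  sim <- simulate_genome(small_sim_config(rng_seed = 59))
  expr_lum <- quantify(sim$rna$luminal, sim$genes,
                       manual_norm(sim$rna$luminal$library_total))
  ex <- data.table::copy(sim$genes$exons)
  on_ids <- expr_lum[type == "exon" & rpkm > 0.1, feature_id]
  ex[, group := data.table::fifelse(exon_id %in% on_ids, "expressed",
                                    "not_expressed")]
  out <- exon_signal_enrichment(sim$h3k36me3$luminal, ex)
  ratio <- out[group == "expressed", fold_enrichment] /
    out[group == "not_expressed", fold_enrichment]
  expect_equal(ratio, sim$config$h3k36me3_enrichment, tolerance = 0.1)
})
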