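retention_expr <- function(gene_rpkm = 20, intron_rpkm = 1.5,
                           intron_cov = 0.4, flank_cov = 1.0,
                           breadth = 0.95) {
  rbind(fx_row("G1", "gene", "G1", gene_rpkm),
        fx_row("G1:E1", "exon", "G1", 10, ncov = flank_cov, index = 1L),
        fx_row("G1:E2", "exon", "G1", 10, ncov = flank_cov, index = 2L),
        fx_row("G1:E3", "exon", "G1", 10, ncov = flank_cov, index = 3L),
        fx_row("G1:I1", "intron", "G1", intron_rpkm, ncov = intron_cov,
               breadth = breadth, index = 1L),
        fx_row("G1:I2", "intron", "G1", 0.1, ncov = 0.01, breadth = 0.1,
               index = 2L))
}

test_that("the four retention rules admit and reject as stated", {
  gm <- toy_gene_models()
  flags <- c(FALSE, FALSE)
  # all thresholds met
  out <- call_retained_introns(retention_expr(), gm, flags)
  expect_equal(out$intron_id, "G1:I1")
  expect_equal(out$coverage_ratio, 0.4)
  # RPKM prefilter: 0.9 <= 1
  expect_equal(nrow(call_retained_introns(
    retention_expr(intron_rpkm = 0.9), gm, flags)), 0)
  # gene-relative rule: intron 1.5 vs 5% of gene 40 = 2
  expect_equal(nrow(call_retained_introns(
    retention_expr(gene_rpkm = 40), gm, flags)), 0)
  # coverage ratio rule: 0.25 <= 0.30
  expect_equal(nrow(call_retained_introns(
    retention_expr(intron_cov = 0.25), gm, flags)), 0)
  # breadth rule
  expect_equal(nrow(call_retained_introns(
    retention_expr(breadth = 0.85), gm, flags)), 0)
  # noncoding host gene never yields a call
  gm_nc <- toy_gene_models(biotype = "noncoding")
  expect_equal(nrow(call_retained_introns(retention_expr(), gm_nc, flags)), 0)
})

test_that("the caller equals a brute-force four-rule filter on simulated data", {
  sim <- simulate_genome(small_sim_config(rng_seed = 29))
  norm <- suppressMessages(compute_normalization(sim$rna$luminal, sim$genes))
  expr <- quantify(sim$rna$luminal, sim$genes, norm)
  flags <- flag_opposite_strand_introns(sim$genes)
  calls <- suppressMessages(
    call_retained_introns(expr, sim$genes, flags, cell_type = "luminal"))
  expect_equal(sort(calls$intron_id),
               oracle_retention(expr, sim$genes, flags))
})

test_that("opposite-strand introns never appear even at saturated coverage", {
  gm <- gene_models(data.frame(
    gene_id = c("A", "A", "B"), chrom = "1",
    start = c(1000, 3000, 1800), end = c(2000, 4000, 2200),
    strand = c("+", "+", "-"), biotype = "protein_coding"))
  tr <- flat_track(c("1" = 5000), 50, library_total = 1e5)
  expr <- quantify(tr, gm, manual_norm(1e5))
  flags <- flag_opposite_strand_introns(gm)
  calls <- call_retained_introns(expr, gm, flags)
  expect_false("A:I1" %in% calls$intron_id)  # flagged despite full coverage
  # the same intron is called when the flag is withdrawn
  calls2 <- call_retained_introns(expr, gm, rep(FALSE, length(flags)))
  expect_true("A:I1" %in% calls2$intron_id)
})

test_that("the specificity partition conserves counts and classifies overlap", {
  mk <- function(ids) data.table::data.table(intron_id = ids)
  part <- specificity_partition(list(a = mk(c("i1", "i2")),
                                     b = mk(c("i2", "i3"))))
  expect_equal(part$n_total, 3)
  expect_equal(part$n_shared, 1)
  expect_equal(part$introns[intron_id == "i2", called_in], "a,b")
  expect_equal(sum(part$summary$n_specific) + part$n_shared, part$n_total)
  # disjoint call sets: all specific
  part2 <- specificity_partition(list(a = mk("i1"), b = mk("i9")))
  expect_equal(part2$frac_specific, 1)
})

test_that("the 50-nt rule classifies boundary cases of premature stops", {
  e <- function(n) paste(rep("GCT", n), collapse = "")   # alanine runs
  # stop inside the retained last intron, within 50 nt of the last
  # remaining junction: not NMD
  exons <- c(paste0("ATG", e(10)), e(20), e(20))
  intr_stop <- paste0("TAA", e(5))                       # in-frame stop
  expect_false(predict_nmd(exons, 1, intr_stop, 2))
  # early in-frame stop in a mid-CDS retained intron, far upstream of the
  # last junction: NMD
  exons2 <- c(paste0("ATG", e(10)), e(40), e(20))
  expect_true(predict_nmd(exons2, 1, intr_stop, 1))
  # no CDS annotation: indeterminate
  expect_true(is.na(predict_nmd(exons, NA, intr_stop, 1)))
  # frameshifting intron (length not multiple of 3) creating a downstream
  # stop through the shifted frame
  intr_fs <- paste0("G", e(2))                            # 7 nt
  out <- predict_nmd(exons2, 1, intr_fs, 1)
  expect_true(out %in% c(TRUE, FALSE))
})

test_that("NMD decisions equal an independent codon-walk oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  oracle_nmd <- function(exon_seqs, cds_start, intron_seq, intron_after,
                         rule_nt = 50) {
    segs <- append(as.list(exon_seqs), list(intron_seq),
                   after = intron_after)
    mrna <- paste(unlist(segs), collapse = "")
    lens <- nchar(unlist(segs))
    # junction positions: cumulative segment ends, dropping the two
    # boundaries fused by the retained intron and the transcript end
    ends <- cumsum(lens)
    keep <- setdiff(seq_along(segs), c(intron_after, intron_after + 1L,
                                       length(segs)))
    if (!length(keep)) return(FALSE)
    last_j <- max(ends[keep])
    n_codons <- (nchar(mrna) - cds_start + 1L) %/% 3L
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(mrna, cds_start, cds_start + 3L * n_codons - 1L)),
      if.fuzzy.codon = "X"))
    st <- regexpr("*", aa, fixed = TRUE)
    if (st < 0) return(FALSE)
    stop_end <- cds_start - 1 + as.integer(st) * 3
    (last_j - stop_end) > rule_nt
  }
  for (rep in 1:50) {
    n_ex <- sample(3:6, 1)
    exons <- vapply(sample(30:200, n_ex, replace = TRUE), rand_seq,
                    character(1))
    intr <- rand_seq(sample(40:300, 1))
    after <- sample(seq_len(n_ex - 1), 1)
    cds <- sample(1:20, 1)
    expect_equal(predict_nmd(exons, cds, intr, after),
                 oracle_nmd(exons, cds, intr, after),
                 info = sprintf("replicate %d", rep))
  }
})

test_that("boundary methylation deltas recover constructed peak-valley shapes", {
  # flat methylome: delta 0 at both boundaries
  pos <- seq(10, 4000, by = 10)
  flat <- data.table::data.table(chrom = "1", pos = pos, fraction = 0.8,
                                 coverage = 30)
  intr <- data.table::data.table(chrom = "1", start = 1000L, end = 3000L,
                                 strand = "+")
  d <- boundary_methylation_delta(flat, intr)
  expect_equal(d$delta_5p, 0)
  expect_equal(d$delta_3p, 0)
  # exon side at 0.9, intron side dipping to 0.3 in one bin
  m <- data.table::copy(flat)
  m[, fraction := 0.9]
  m[pos >= 1040 & pos < 1060, fraction := 0.3]  # inside the 5' intron window
  d2 <- boundary_methylation_delta(m, intr)
  expect_equal(d2$delta_5p, 0.6)
  expect_equal(d2$delta_3p, 0)
  # a window with no CpGs is excluded and counted
  sparse <- flat[pos > 1300]
  d3 <- boundary_methylation_delta(sparse, intr)
  expect_true(is.na(d3$delta_5p))
  expect_gte(attr(d3, "n_excluded"), 1)
})

test_that("retained introns show shallower boundary dips than spliced ones", {
  set.seed(91)
  n_per <- 100
  mk_cohort <- function(offset0, dip) {
    lapply(seq_len(n_per), function(i) {
      s <- offset0 + (i - 1) * 5000L
      pos <- seq(s - 300, s + 2300, by = 25)
      fr <- rep(0.85, length(pos))
      inside5 <- pos >= s & pos < s + 200
      fr[inside5] <- dip
      fr <- pmin(pmax(fr + rnorm(length(fr), 0, 0.03), 0), 1)
      list(meth = data.table::data.table(chrom = "1", pos = pos,
                                         fraction = fr, coverage = 30),
           intr = data.table::data.table(chrom = "1", start = s,
                                         end = s + 2000L, strand = "+"))
    })
  }
  # spliced introns have deep 5' valleys; retained introns shallow ones
  spliced <- mk_cohort(1000L, dip = 0.25)
  retained <- mk_cohort(600000L, dip = 0.65)
  delta_of <- function(cohort) vapply(cohort, function(x)
    boundary_methylation_delta(x$meth, x$intr)$delta_5p, numeric(1))
  d_spliced <- delta_of(spliced)
  d_retained <- delta_of(retained)
  tt <- t.test(d_retained, d_spliced, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})
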