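toy_linking_setup <- function() {
  gm <- gene_models(data.frame(
    gene_id = c("G1", "G1", "G2", "G2"), chrom = "1",
    start = c(50000, 52000, 120000, 122000),
    end = c(50500, 52500, 120500, 122500),
    strand = "+", biotype = "protein_coding"))
  de <- data.table::data.table(feature_id = "G1", gene_id = "G1",
                               direction = "up_in_A", p_value = 1e-10,
                               q_value = 1e-9, rpkm_A = 10, rpkm_B = 1,
                               count_A = 100, count_B = 10)
  list(gm = gm, de = de)
}

test_that("UMR-gene links honour the proximal and distal windows", {
  s <- toy_linking_setup()
  umrs <- data.table::data.table(
    chrom = "1", start = c(48800, 35200), end = c(49100, 35500),
    cell_type = "lum", umr_id = c("u_near", "u_far"))
  out <- link_umrs_to_genes(umrs, s$gm, s$de, "lum", "myo")
  near <- out$links[umr_id == "u_near" & gene_id == "G1"]
  # 1 kb upstream: both proximal and distal
  expect_true(any(near$distance_class == "proximal"))
  far <- out$links[umr_id == "u_far" & gene_id == "G1"]
  # ~14.6 kb away: distal only
  expect_equal(nrow(far), 1)
  expect_equal(far$distance_class, "distal")
  # every proximal link is also within the distal window by construction
  expect_true(all(out$links[distance_class == "proximal",
                            umr_id %in% out$links$umr_id]))
})

test_that("directionality fractions sum to one in every class", {
  s <- toy_linking_setup()
  umrs <- data.table::data.table(
    chrom = "1", start = c(48800, 121000, 35200), end = c(49100, 121300, 35500),
    cell_type = c("lum", "myo", "lum"),
    umr_id = c("u1", "u2", "u3"))
  out <- link_umrs_to_genes(umrs, s$gm, s$de, "lum", "myo")
  d <- out$directionality
  expect_equal(d$frac_same + d$frac_other + d$frac_not_de, rep(1, nrow(d)))
  # u1 belongs to lum and neighbours the lum-upregulated G1
  expect_equal(out$links[umr_id == "u1" & gene_id == "G1",
                         gene_direction][1], "up_in_same_type")
  # u2 belongs to myo but neighbours nothing differential (G2 is not DE)
  expect_true(all(out$links[umr_id == "u2", gene_direction] == "not_de"))
})

test_that("a fully planted construction gives directionality exactly 1", {
  cfg <- small_sim_config(n_umrs = 6, n_de_genes = 12, low_block_frac = 0,
                          rng_seed = 61)
  sim <- simulate_genome(cfg)
  run <- suppressMessages(run_pipeline(sim, stages = c("quant", "de", "umr",
                                                       "regnet")))
  d <- run$results$regnet$directionality
  expect_equal(d[class == "proximal" & denominator == "umr", frac_same], 1)
})

test_that("TF overlap asymmetry counts, flags and inverts symmetrically", {
  u_A <- data.table::data.table(chrom = "1",
                                start = seq(1000, 16000, by = 1000),
                                end = seq(1200, 16200, by = 1000))
  u_B <- data.table::data.table(chrom = "1", start = c(50000, 51000),
                                end = c(50200, 51200))
  # 16 sites inside A UMRs, 2 inside B UMRs
  tf <- list(TFX = data.table::data.table(
    chrom = "1", start = c(u_A$start + 50, u_B$start + 50),
    end = c(u_A$start + 60, u_B$start + 60)))
  chrl <- c("1" = 100000)
  out <- tf_overlap_asymmetry(u_A, u_B, tf, chrl, n_permutations = 10,
                              seed = 1)
  expect_equal(out$n_sites_in_A_umrs, 16)
  expect_equal(out$n_sites_in_B_umrs, 2)
  expect_equal(out$ratio, 8)
  expect_true(out$flagged_2x && out$flagged_8x)
  expect_false(out$pseudocount_used)
  # antisymmetry: swapping the sets inverts the ratio exactly
  rev <- tf_overlap_asymmetry(u_B, u_A, tf, chrl, n_permutations = 10,
                              seed = 1)
  expect_equal(rev$ratio, 1 / out$ratio)
  # identical sets: ratio 1, nothing flagged
  same <- tf_overlap_asymmetry(u_A, u_A, tf, chrl, n_permutations = 10,
                               seed = 1)
  expect_equal(same$ratio, 1)
  expect_false(same$flagged_2x)
  # zero-count side engages the pseudocount
  tf0 <- list(TFZ = data.table::data.table(chrom = "1", start = 50050,
                                           end = 50060))
  z <- tf_overlap_asymmetry(u_A, u_B, tf0, chrl, n_permutations = 10,
                            seed = 1)
  expect_true(z$pseudocount_used)
  expect_equal(z$ratio, (0 + 1) / (1 + 1))
})

test_that("permutation expectation matches the analytic tiling probability", {
  # TF sites of width 200 every 1000 bp tile 20% of the chromosome; for
  # width-1 query intervals the analytic overlap probability is 0.20
  sites <- data.table::data.table(chrom = "1",
                                  start = seq(0, 999000, by = 1000),
                                  end = seq(200, 999200, by = 1000))
  umrs <- data.table::data.table(chrom = "1",
                                 start = seq(5000, 104000, by = 1000),
                                 end = seq(5001, 104001, by = 1000))
  out <- tf_overlap_asymmetry(umrs, umrs, list(TF = sites),
                              c("1" = 1e6), n_permutations = 1000, seed = 3)
  expect_equal(out$expected_by_chance, 0.20, tolerance = 0.02)
})

test_that("cell-type-specific UMR splitting drops shared regions", {
  a <- data.table::data.table(chrom = "1", start = c(100, 5000),
                              end = c(400, 5400))
  b <- data.table::data.table(chrom = "1", start = c(300, 9000),
                              end = c(600, 9300))
  sp <- specific_umrs(a, b)
  expect_equal(sp$A$start, 5000)
  expect_equal(sp$B$start, 9000)
})

test_that("SNP overlap uses half-open containment", {
  umrs <- data.table::data.table(chrom = "1", start = 1000, end = 1300,
                                 umr_id = "u1")
  snps <- data.table::data.table(chrom = "1", pos = c(1000, 1299, 1300, 999),
                                 name = c("at_start", "inside", "at_end",
                                          "before"))
  out <- snp_overlap(umrs, snps)
  expect_setequal(out$snp, c("at_start", "inside"))

  # k planted SNPs inside UMRs among m total are all and only those reported
  set.seed(71)
  u2 <- data.table::data.table(chrom = "1",
                               start = seq(10000, 90000, by = 10000),
                               end = seq(10300, 90300, by = 10000))
  pos <- sample(1:100000, 400)
  s2 <- data.table::data.table(chrom = "1", pos = pos,
                               name = sprintf("rs%03d", seq_along(pos)))
  inside <- vapply(pos, function(p)
    any(p >= u2$start & p < u2$end), logical(1))
  out2 <- snp_overlap(u2, s2)
  expect_setequal(out2$snp, s2$name[inside])
})
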