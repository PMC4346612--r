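#' Read a per-CpG methylome table
#'
#' Tab-separated columns chrom, pos (0-based position of the C on the +
#' strand; symmetric CG calls should be folded onto the + strand C upstream),
#' fraction (fractional methylation in `[0, 1]`), coverage (reads, `>= 1`).
#' Positions must be strictly increasing per chromosome.
#'
#' @param path TSV file (gzip transparent)
#' @return data.table with the four columns, class `methylome_track`
#' @export
read_methylome <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  .chk(all(c("chrom", "pos", "fraction", "coverage") %in% names(dt)),
       "methylome needs chrom, pos, fraction, coverage columns")
  dt[, chrom := norm_chrom(chrom)]
  .chk(all(dt$fraction >= 0 & dt$fraction <= 1), "fraction outside [0, 1]")
  .chk(all(dt$coverage >= 1), "coverage must be >= 1 for retained records")
  inc <- dt[, all(diff(pos) > 0), by = chrom]$V1
  .chk(all(inc), "CpG positions must be strictly increasing per chromosome")
  dt[]
}

#' Write a per-CpG methylome table
#'
#' @param meth per-CpG data.table (extra columns are dropped)
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_methylome <- function(meth, path) {
  m <- data.table::as.data.table(meth)[, .(chrom, pos, fraction, coverage)]
  data.table::setorder(m, chrom, pos)
  data.table::fwrite(m, path, sep = "\t")
  invisible(path)
}

#' Detect unmethylated regions (UMRs) from a WGBS methylome
#'
#' The background methylation level is the genome-wide coverage-weighted mean
#' fraction. Each CpG is tested for hypomethylation with a lower-tail
#' binomial test of its methylated read count against the background rate;
#' significant CpGs — per-CpG p below `cpg_alpha` and observed fraction at or
#' below `max_fraction`, the absolute hypomethylation ceiling that makes the
#' call "unmethylated" rather than merely "below background" — lying within
#' `merge_gap` bp of each other are merged into candidate regions; each
#' region's p-value is the Fisher combination of its CpG p-values, and
#' regions are kept when the combined p is below `p_cutoff` and the region
#' holds at least `min_cpgs` significant CpGs.
#'
#' @param meth per-CpG data.table (chrom, pos, fraction, coverage)
#' @param p_cutoff region-level p-value cutoff (0.0005)
#' @param min_cpgs minimal significant CpGs per region
#' @param merge_gap maximal gap (bp) between significant CpGs in one region
#' @param cpg_alpha per-CpG significance level for seeding regions
#' @param max_fraction absolute per-CpG methylation ceiling for a seed CpG
#' @param background override the estimated background methylation
#' @return data.table of regions (chrom, start, end, n_cpgs,
#'   mean_methylation, p_value), sorted and non-overlapping, class
#'   `umr_set`, with the background level in attribute `background`
#' @export
call_umrs <- function(meth, p_cutoff = 0.0005, min_cpgs = 4,
                      merge_gap = 500, cpg_alpha = 0.05,
                      max_fraction = 0.25, background = NULL) {
  meth <- data.table::as.data.table(meth)
  .chk(nrow(meth) >= 1000,
       "need >= 1000 CpGs to estimate the background methylation")
  bg <- background %||% weighted.mean(meth$fraction, meth$coverage)
  if (bg < 0.5)
    warning("globally hypomethylated input (background < 0.5); test still runs")
  m <- data.table::copy(meth)
  m[, mreads := round(fraction * coverage)]
  m[, p_cpg := pbinom(mreads, coverage, bg)]
  sig <- m[p_cpg < cpg_alpha & fraction <= max_fraction & fraction < bg]
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpgs = integer(0), mean_methylation = numeric(0), p_value = numeric(0))
  if (!nrow(sig)) {
    data.table::setattr(empty, "background", bg)
    data.table::setattr(empty, "class", c("umr_set", class(empty)))
    return(empty[])
  }
  data.table::setorder(sig, chrom, pos)
  sig[, new_block := c(TRUE, diff(pos) > merge_gap), by = chrom]
  sig[, block := cumsum(new_block)]
  reg <- sig[, .(chrom = chrom[1], start = min(pos), end = max(pos) + 1L,
                 n_cpgs = .N, mean_methylation = mean(fraction),
                 fisher = -2 * sum(log(pmax(p_cpg, 1e-300)))),
             by = block]
  reg[, p_value := pchisq(fisher, df = 2 * n_cpgs, lower.tail = FALSE)]
  out <- reg[p_value < p_cutoff & n_cpgs >= min_cpgs,
             .(chrom, start, end, n_cpgs, mean_methylation, p_value)]
  stopifnot(all(out$mean_methylation < bg))
  data.table::setorder(out, chrom, start)
  data.table::setattr(out, "background", bg)
  data.table::setattr(out, "class", c("umr_set", class(out)))
  out[]
}

#' Calibrate MeDIP enrichment to absolute methylation scores
#'
#' Per-CpG raw enrichment is the MeDIP signal at the CpG divided by the
#' CpG-free background (mean signal over all bases at least `bg_distance` bp
#' away from any CpG). CpGs with mappability below 0.5 are excluded; for
#' mappability in `[0.5, 1)` the signal is corrected by division. Raw
#' enrichments are then quantile-mapped onto a reference WGBS
#' fractional-methylation sample, yielding a score in `[0, 1]` whose
#' distribution matches the reference; scores are classed hypomethylated
#' (`< 0.35`), hypermethylated (`> 0.8`) or intermediate.
#'
#' @param signal a [coverage_track()] of MeDIP depth
#' @param reference numeric vector of WGBS fractional methylation values
#'   (the reference distribution)
#' @param mappability a [coverage_track()] with values in `[0, 1]`
#' @param cpgs data.table of CpG positions (chrom, pos)
#' @param min_mappability exclusion threshold (0.5)
#' @param bg_distance minimal distance from a CpG for background bases (bp)
#' @param signal_window width (bp) of the window centred on the CpG over
#'   which the MeDIP fragment pileup is averaged to give the CpG's signal
#' @param hypo,hyper class boundaries (0.35 / 0.8)
#' @return data.table: chrom, pos, raw_enrichment, score, class, mappability
#' @export
calibrate_medip <- function(signal, reference, mappability, cpgs,
                            min_mappability = 0.5, bg_distance = 500,
                            signal_window = 100, hypo = 0.35, hyper = 0.8) {
  .chk(length(reference) > 0, "empty reference distribution")
  cpgs <- data.table::as.data.table(cpgs)
  cpgs[, chrom := norm_chrom(chrom)]
  # background: mean signal over bases >= bg_distance from any CpG
  bg_sum <- 0; bg_len <- 0
  for (ch in names(signal$cov)) {
    L <- length(signal$cov[[ch]])
    p <- cpgs[chrom == ch, pos]
    if (length(p)) {
      near <- IRanges::reduce(IRanges::IRanges(pmax(p + 1L - bg_distance, 1L),
                                               pmin(p + 1L + bg_distance, L)))
      far <- IRanges::gaps(near, start = 1L, end = L)
    } else {
      far <- IRanges::IRanges(1L, L)
    }
    if (length(far)) {
      s0 <- IRanges::start(far) - 1L
      e0 <- IRanges::end(far)
      bg_sum <- bg_sum + sum(interval_sums(signal, rep(ch, length(far)), s0, e0))
      bg_len <- bg_len + sum(e0 - s0)
    }
  }
  if (bg_len == 0 || bg_sum == 0)
    stop("zero background: no CpG-free bases or no background signal",
         call. = FALSE)
  bg <- bg_sum / bg_len
  out <- data.table::copy(cpgs)
  half <- as.integer(signal_window %/% 2)
  out[, sig := interval_sums(signal, chrom, pos - half, pos + half + 1L) /
        (2L * half + 1L)]
  out[, mappability := interval_sums(mappability, chrom, pos, pos + 1L)]
  out <- out[mappability >= min_mappability]
  out[, sig := sig / pmin(mappability, 1)]
  out[, raw_enrichment := sig / bg]
  n <- nrow(out)
  .chk(n > 0, "no CpGs left after the mappability filter")
  p <- (rank(out$raw_enrichment, ties.method = "average") - 0.5) / n
  out[, score := quantile(reference, probs = p, names = FALSE, type = 7)]
  out[, class := data.table::fcase(score < hypo, "hypomethylated",
                                   score > hyper, "hypermethylated",
                                   default = "intermediate")]
  out[, sig := NULL]
  out[]
}

#' Binned methylation metaprofile around feature boundaries
#'
#' For each boundary (e.g. exon junction) methylation is averaged per
#' `bin`-bp bin over `window` bp on each side, strand-oriented 5'-to-3':
#' bins -window/bin .. -1 are 5' of the boundary, bins 1 .. window/bin are
#' 3' of it. The per-group bin mean averages over all CpGs falling in that
#' bin across the group's features; the CpG count per bin is also reported.
#'
#' @param meth per-CpG data.table (chrom, pos, fraction)
#' @param features data.table with chrom, pos (0-based boundary), strand,
#'   group
#' @param window,bin profile extent and bin width (bp; defaults 200 / 20)
#' @return data.table: group, bin (signed index), mean_methylation,
#'   mean_cpgs (CpGs per feature per bin), n_cpgs, n_features
#' @export
boundary_profile <- function(meth, features, window = 200, bin = 20) {
  meth <- data.table::as.data.table(meth)
  ft <- data.table::as.data.table(features)
  .chk(all(c("chrom", "pos", "strand", "group") %in% names(ft)),
       "features need chrom, pos, strand, group")
  nb <- window %/% bin
  ft[, fid := .I]
  win <- ft[, .(fid, chrom, group, strand,
                wstart = pos - window, wend = pos + window, center = pos)]
  data.table::setkey(win, chrom, wstart, wend)
  mm <- meth[, .(chrom, pstart = pos, pend = pos, fraction)]
  ov <- data.table::foverlaps(mm, win,
                              by.x = c("chrom", "pstart", "pend"),
                              type = "within", nomatch = NULL)
  if (!nrow(ov))
    return(data.table::data.table(group = character(0), bin = integer(0),
                                  mean_methylation = numeric(0),
                                  mean_cpgs = numeric(0), n_cpgs = integer(0),
                                  n_features = integer(0)))
  ov[, off := pstart - center]
  ov[strand == "-", off := -off - 1L]
  ov <- ov[off >= -window & off < window]
  ov[, bin_idx := data.table::fifelse(off < 0, -((-off - 1L) %/% bin) - 1L,
                                      off %/% bin + 1L)]
  nfeat <- ft[, .(n_features = .N), by = group]
  prof <- ov[, .(mean_methylation = mean(fraction), n_cpgs = .N),
             by = .(group, bin = bin_idx)]
  prof <- merge(prof, nfeat, by = "group")
  prof[, mean_cpgs := n_cpgs / n_features]
  grid <- data.table::CJ(group = nfeat$group, bin = c(-(nb:1), 1:nb))
  prof <- merge(grid, prof, by = c("group", "bin"), all.x = TRUE)
  prof[is.na(n_cpgs), `:=`(n_cpgs = 0L, mean_cpgs = 0)]
  prof <- merge(prof[, -"n_features"], nfeat, by = "group")
  data.table::setorder(prof, group, bin)
  prof[]
}

#' Welch t-test of boundary methylation between feature groups
#'
#' Each feature is summarized by its mean CpG methylation across the
#' boundary window; groups are compared pairwise with a two-sided Welch
#' (unequal-variance) t-test.
#'
#' @inheritParams boundary_profile
#' @return data.table of pairwise tests: group_a, group_b, p_value,
#'   mean_a, mean_b
#' @export
boundary_group_test <- function(meth, features, window = 200, bin = 20) {
  meth <- data.table::as.data.table(meth)
  ft <- data.table::as.data.table(features)
  ft[, fid := .I]
  win <- ft[, .(fid, chrom, group, wstart = pos - window, wend = pos + window)]
  data.table::setkey(win, chrom, wstart, wend)
  mm <- meth[, .(chrom, pstart = pos, pend = pos, fraction)]
  ov <- data.table::foverlaps(mm, win,
                              by.x = c("chrom", "pstart", "pend"),
                              type = "within", nomatch = NULL)
  per_feat <- ov[, .(m = mean(fraction), group = group[1]), by = fid]
  gs <- split(per_feat$m, per_feat$group)
  gn <- names(gs)
  rows <- list()
  for (i in seq_along(gn)) for (j in seq_along(gn)) if (i < j) {
    a <- gs[[i]]; b <- gs[[j]]
    p <- if (length(a) >= 2 && length(b) >= 2)
      t.test(a, b, var.equal = FALSE)$p.value else NA_real_
    rows[[length(rows) + 1L]] <- data.table::data.table(
      group_a = gn[i], group_b = gn[j], p_value = p,
      mean_a = mean(a), mean_b = mean(b))
  }
  data.table::rbindlist(rows)
}

#' Fold enrichment of a signal track within exon groups
#'
#' Per group, the mean over exons of (mean per-base signal in the exon)
#' divided by the genome-wide mean signal — e.g. H3K36me3 enrichment over
#' expressed versus silent exons.
#'
#' @param track a [coverage_track()] (e.g. H3K36me3)
#' @param exons data.table with chrom, start, end, group
#' @return data.table: group, fold_enrichment, n
#' @export
exon_signal_enrichment <- function(track, exons) {
  ex <- data.table::copy(data.table::as.data.table(exons))
  gmean <- genome_mean_signal(track)
  if (gmean == 0) stop("zero genome-wide signal", call. = FALSE)
  ex[, mean_signal := interval_sums(track, chrom, start, end) / (end - start)]
  out <- ex[, .(fold_enrichment = mean(mean_signal) / gmean, n = .N),
            by = group]
  data.table::setorder(out, group)
  out[]
}

#' Write UMRs as BED6 plus a statistics TSV
#'
#' @param umrs a [call_umrs()] result
#' @param bed_path,tsv_path output paths (either may be `NULL`)
#' @param cell_type label written into the BED name column
#' @return invisibly, the paths written
#' @export
write_umrs <- function(umrs, bed_path = NULL, tsv_path = NULL,
                       cell_type = "umr") {
  u <- data.table::as.data.table(umrs)
  if (!is.null(bed_path)) {
    u2 <- data.table::copy(u)
    u2[, name := sprintf("%s_%d", cell_type, .I)]
    write_bed(u2[, .(chrom, start, end, name, score = 0, strand = ".")],
              bed_path)
  }
  if (!is.null(tsv_path)) data.table::fwrite(u, tsv_path, sep = "\t")
  invisible(c(bed_path, tsv_path))
}
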