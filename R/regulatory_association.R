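#' Link UMRs to genes and summarize regulatory directionality
#'
#' Each UMR is linked to every gene whose TSS window it overlaps: proximal
#' links use TSS +/- 2 kb, distal links TSS +/- 20 kb (every proximal link is
#' also distal). The directionality summary asks, for cell-type-specific
#' UMRs, whether the nearest linked differentially expressed gene is
#' upregulated in the UMR's own cell type. Because the text leaves the
#' denominator ambiguous, fractions are reported both per UMR (nearest DE
#' gene) and per UMR-gene pair.
#'
#' @param umrs data.table of UMRs with chrom, start, end, cell_type and
#'   optionally umr_id
#' @param gm a [gene_models()] object (TSS anchors)
#' @param de_genes gene-level [de_call()] result for the pair `type_A` vs
#'   `type_B`
#' @param type_A,type_B cell-type labels mapped to directions `up_in_A` /
#'   `up_in_B`
#' @param proximal_bp,distal_bp window half-widths (2 kb / 20 kb)
#' @return list with `links` (umr_id, gene_id, distance_class, distance,
#'   gene_direction) and `directionality` (per class and denominator, the
#'   fractions up in the same type, the other type, or not DE)
#' @export
link_umrs_to_genes <- function(umrs, gm, de_genes, type_A, type_B,
                               proximal_bp = 2000, distal_bp = 20000) {
  u <- data.table::copy(data.table::as.data.table(umrs))
  if (!"umr_id" %in% names(u)) u[, umr_id := sprintf("umr%d", .I)]
  g <- gm$genes
  up_type <- setNames(ifelse(de_genes$direction == "up_in_A", type_A, type_B),
                      de_genes$feature_id)
  win <- g[, .(gene_id, chrom, tss,
               wstart = tss - distal_bp, wend = tss + distal_bp)]
  data.table::setkey(win, chrom, wstart, wend)
  uu <- u[, .(umr_id, chrom, ustart = start, uend = end - 1L, cell_type)]
  ov <- data.table::foverlaps(uu, win,
                              by.x = c("chrom", "ustart", "uend"),
                              type = "any", nomatch = NULL)
  links <- ov[, .(umr_id, gene_id, cell_type, tss,
                  midpoint = (ustart + uend + 1) / 2, ustart, uend)]
  links[, distance := abs(midpoint - tss)]
  links[, proximal := ustart <= tss + proximal_bp & uend >= tss - proximal_bp]
  links[, gene_direction := data.table::fcase(
    !gene_id %in% names(up_type), "not_de",
    up_type[gene_id] == cell_type, "up_in_same_type",
    default = "up_in_other_type")]
  links[, distance_class := data.table::fifelse(proximal, "proximal", "distal")]
  if (nrow(links))
    stopifnot(links[proximal == TRUE,
                    all(distance <= distal_bp + (uend - ustart + 1))])

  frac_tab <- function(cls) {
    sub <- if (cls == "proximal") links[proximal == TRUE] else links
    if (!nrow(sub))
      return(data.table::data.table(
        class = cls, denominator = c("umr", "pair"),
        frac_same = NA_real_, frac_other = NA_real_, frac_not_de = NA_real_,
        n = 0L))
    # per-UMR: nearest linked DE gene decides; UMRs with no DE link -> not_de
    per_umr <- sub[order(distance)][, .(
      dir = { d <- gene_direction[gene_direction != "not_de"]
              if (length(d)) d[1] else "not_de" }), by = umr_id]
    pu <- data.table::data.table(
      class = cls, denominator = "umr",
      frac_same = mean(per_umr$dir == "up_in_same_type"),
      frac_other = mean(per_umr$dir == "up_in_other_type"),
      frac_not_de = mean(per_umr$dir == "not_de"),
      n = nrow(per_umr))
    pp <- data.table::data.table(
      class = cls, denominator = "pair",
      frac_same = mean(sub$gene_direction == "up_in_same_type"),
      frac_other = mean(sub$gene_direction == "up_in_other_type"),
      frac_not_de = mean(sub$gene_direction == "not_de"),
      n = nrow(sub))
    rbind(pu, pp)
  }
  direc <- rbind(frac_tab("proximal"), frac_tab("distal"))
  out_links <- links[, .(umr_id, gene_id, cell_type, distance_class,
                         distance, gene_direction)]
  data.table::setorder(out_links, umr_id, distance)
  list(links = out_links[], directionality = direc[])
}

#' Split two UMR sets into cell-type-specific subsets
#'
#' A UMR is specific to its cell type when it overlaps (by >= 1 bp) no UMR of
#' the other set; regions detected in both cell types (e.g. constitutively
#' unmethylated domains) are dropped from both.
#'
#' @param umrs_A,umrs_B data.tables of UMR intervals (chrom, start, end)
#' @return list with `A` and `B`, the specific subsets
#' @export
specific_umrs <- function(umrs_A, umrs_B) {
  ua <- data.table::as.data.table(umrs_A)
  ub <- data.table::as.data.table(umrs_B)
  ov <- function(x, y) {
    if (!nrow(x) || !nrow(y)) return(rep(FALSE, nrow(x)))
    gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
    gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
    GenomicRanges::countOverlaps(gx, gy, minoverlap = 1L) > 0
  }
  list(A = ua[!ov(ua, ub)], B = ub[!ov(ub, ua)])
}

.count_site_overlaps <- function(sites, regions) {
  if (!nrow(sites) || !nrow(regions)) return(0L)
  sr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$start + 1L, sites$end))
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  sum(GenomicRanges::countOverlaps(sr, rr, minoverlap = 1L) > 0)
}

#' Transcription-factor binding asymmetry between two UMR sets
#'
#' Per TF, counts binding sites overlapping (>= 1 bp) each of two UMR sets
#' and reports the A/B ratio (with a +1 pseudocount on both counts when
#' either is zero) plus the overlap fraction expected by chance from
#' `n_permutations` uniform placements of UMR-length intervals on their own
#' chromosomes. TFs are flagged at ratio >= 2 and >= 8.
#'
#' @param umrs_A,umrs_B data.tables of UMR intervals (chrom, start, end)
#' @param tf_sites named list of per-TF site tables (chrom, start, end)
#' @param chrom_lengths named vector of chromosome lengths
#' @param n_permutations permutations for the chance expectation
#' @param seed RNG seed for the permutations
#' @return data.table: tf, n_sites_in_A_umrs, n_sites_in_B_umrs, ratio,
#'   pseudocount_used, expected_by_chance, observed_frac_A, observed_frac_B,
#'   flagged_2x, flagged_8x
#' @export
tf_overlap_asymmetry <- function(umrs_A, umrs_B, tf_sites,
                                 chrom_lengths, n_permutations = 1000,
                                 seed = 1) {
  .chk(is.list(tf_sites) && !is.null(names(tf_sites)), "tf_sites must be named")
  ua <- data.table::as.data.table(umrs_A)
  ub <- data.table::as.data.table(umrs_B)
  pool <- rbind(ua[, .(chrom, start, end)], ub[, .(chrom, start, end)])
  pool[, width := end - start]
  set.seed(seed)
  # pre-draw permuted placements of the pooled UMR intervals
  perms <- vector("list", n_permutations)
  for (k in seq_len(n_permutations)) {
    L <- unname(chrom_lengths[pool$chrom])
    s <- floor(runif(nrow(pool)) * (L - pool$width))
    perms[[k]] <- data.table::data.table(chrom = pool$chrom, start = s,
                                         end = s + pool$width)
  }
  frac_overlap <- function(regions, sr) {
    if (!nrow(regions)) return(NA_real_)
    rr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
    mean(GenomicRanges::countOverlaps(rr, sr, minoverlap = 1L) > 0)
  }
  rows <- list()
  for (tf in names(tf_sites)) {
    st <- data.table::as.data.table(tf_sites[[tf]])
    if (!nrow(st)) { warning(sprintf("TF %s has no sites; skipped", tf)); next }
    n_A <- .count_site_overlaps(st, ua)
    n_B <- .count_site_overlaps(st, ub)
    pseudo <- (n_A == 0 || n_B == 0)
    ratio <- if (pseudo) (n_A + 1) / (n_B + 1) else n_A / n_B
    sr <- GenomicRanges::GRanges(st$chrom,
                                 IRanges::IRanges(st$start + 1L, st$end))
    exp_frac <- mean(vapply(perms, frac_overlap, numeric(1), sr = sr))
    rows[[tf]] <- data.table::data.table(
      tf = tf, n_sites_in_A_umrs = n_A, n_sites_in_B_umrs = n_B,
      ratio = ratio, pseudocount_used = pseudo,
      expected_by_chance = exp_frac,
      observed_frac_A = frac_overlap(ua, sr),
      observed_frac_B = frac_overlap(ub, sr),
      flagged_2x = ratio >= 2, flagged_8x = ratio >= 8)
  }
  data.table::rbindlist(rows)
}

#' SNPs falling inside UMRs
#'
#' Half-open containment: a SNP at a UMR's start position overlaps, one at
#' its end position does not.
#'
#' @param umrs data.table of UMR intervals with optional umr_id
#' @param snps data.table with chrom, pos and optionally name
#' @return data.table with one row per (SNP, UMR) pair
#' @export
snp_overlap <- function(umrs, snps) {
  u <- data.table::copy(data.table::as.data.table(umrs))
  if (!"umr_id" %in% names(u)) u[, umr_id := sprintf("umr%d", .I)]
  s <- data.table::copy(data.table::as.data.table(snps))
  if (!"name" %in% names(s)) s[, name := sprintf("snp%d", .I)]
  uu <- u[, .(umr_id, chrom, ustart = start, uend = end - 1L)]
  data.table::setkey(uu, chrom, ustart, uend)
  ss <- s[, .(name, chrom, pstart = pos, pend = pos)]
  ov <- data.table::foverlaps(ss, uu, by.x = c("chrom", "pstart", "pend"),
                              type = "within", nomatch = NULL)
  out <- ov[, .(snp = name, chrom, pos = pstart, umr_id)]
  data.table::setorder(out, chrom, pos)
  out[]
}
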