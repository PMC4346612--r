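.binom_two_sided <- function(a, n, pr) {
  # doubled-tail two-sided binomial p-value; symmetric under (a, pr) ->
  # (n - a, 1 - pr), so swapping the two libraries preserves p exactly
  lo <- pbinom(a, n, pr)
  hi <- pbinom(a - 1, n, pr, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' Differential expression between two libraries
#'
#' Per-feature two-library count test: the feature's reads in sample A are
#' tested against a binomial with the two library totals as weights
#' (two-sided, doubled tail), with Benjamini-Hochberg correction across all
#' tested features. Calls are retained when `q <= fdr`, the larger RPKM
#' exceeds `min_rpkm` and the larger read count exceeds `min_reads`
#' (defaults 0.015 / 0.005 / 25).
#'
#' @param expr_A,expr_B [quantify()] results for the two samples (same
#'   annotation)
#' @param total_A,total_B library totals (included reads), e.g.
#'   `norm$total_included_reads`
#' @param level `"gene"` or `"exon"`
#' @param fdr BH FDR cutoff
#' @param min_rpkm minimal RPKM of the larger sample
#' @param min_reads minimal read count of the larger sample
#' @return data.table of calls: feature_id, direction (`up_in_A` /
#'   `up_in_B`), p_value, q_value, rpkm_A, rpkm_B, count_A, count_B; the
#'   number of features tested is in attribute `n_tested`
#' @export
de_call <- function(expr_A, expr_B, total_A, total_B,
                    level = c("gene", "exon"), fdr = 0.015,
                    min_rpkm = 0.005, min_reads = 25) {
  level <- match.arg(level)
  a <- data.table::as.data.table(expr_A)[type == level]
  b <- data.table::as.data.table(expr_B)[type == level]
  .chk(nrow(a) == nrow(b) && all(sort(a$feature_id) == sort(b$feature_id)),
       "mismatched annotations between the two samples")
  m <- merge(a[, .(feature_id, gene_id, rpkm_A = rpkm, count_A = read_count)],
             b[, .(feature_id, rpkm_B = rpkm, count_B = read_count)],
             by = "feature_id")
  m[, `:=`(ca = round(count_A), cb = round(count_B))]
  tested <- m[ca + cb > 0]
  pr <- total_A / (total_A + total_B)
  tested[, p_value := .binom_two_sided(ca, ca + cb, pr)]
  tested[, q_value := p.adjust(p_value, "BH")]
  calls <- tested[q_value <= fdr & pmax(rpkm_A, rpkm_B) > min_rpkm &
                    pmax(count_A, count_B) > min_reads]
  calls[, direction := ifelse(rpkm_A > rpkm_B, "up_in_A", "up_in_B")]
  out <- calls[, .(feature_id, gene_id, direction, p_value, q_value,
                   rpkm_A, rpkm_B, count_A, count_B)]
  data.table::setattr(out, "n_tested", nrow(tested))
  out[]
}

#' Cell-type-specific isoform (cassette exon) calls
#'
#' A differentially expressed exon qualifies when it is expressed in only one
#' of the two samples, operationalized gene-relatively: exon RPKM at least
#' 10% of gene RPKM on the expressed side and at most 1% on the silent side;
#' exons in the 1-10% band on either side are discarded as likely false
#' positives. Genes that are themselves differentially expressed are removed.
#'
#' @param expr_A,expr_B [quantify()] results for the two samples
#' @param de_exons exon-level [de_call()] result
#' @param de_genes gene-level [de_call()] result
#' @param expressed_min,silent_max the gene-relative bands (0.10 / 0.01)
#' @return data.table: gene_id, exon_id, expressed_in (`A`/`B`), exon_rel_A,
#'   exon_rel_B, junction_supported (NA until [junction_support()])
#' @export
isoform_call <- function(expr_A, expr_B, de_exons, de_genes,
                         expressed_min = 0.10, silent_max = 0.01) {
  ga <- data.table::as.data.table(expr_A)[type == "gene",
                                          .(gene_id, grpkm_A = rpkm)]
  gb <- data.table::as.data.table(expr_B)[type == "gene",
                                          .(gene_id, grpkm_B = rpkm)]
  ea <- data.table::as.data.table(expr_A)[type == "exon",
                                          .(feature_id, erpkm_A = rpkm)]
  eb <- data.table::as.data.table(expr_B)[type == "exon",
                                          .(feature_id, erpkm_B = rpkm)]
  x <- merge(de_exons[, .(feature_id, gene_id)], ea, by = "feature_id")
  x <- merge(x, eb, by = "feature_id")
  x <- merge(x, ga, by = "gene_id")
  x <- merge(x, gb, by = "gene_id")
  dead <- x[grpkm_A == 0 & grpkm_B == 0]
  if (nrow(dead))
    warning(sprintf("%d exon(s) skipped: gene RPKM zero in both samples",
                    nrow(dead)))
  x <- x[grpkm_A > 0 | grpkm_B > 0]
  x[, rel_A := ifelse(grpkm_A > 0, erpkm_A / grpkm_A, 0)]
  x[, rel_B := ifelse(grpkm_B > 0, erpkm_B / grpkm_B, 0)]
  x[, expressed_in := data.table::fcase(
    rel_A >= expressed_min & rel_B <= silent_max, "A",
    rel_B >= expressed_min & rel_A <= silent_max, "B",
    default = NA_character_)]
  x <- x[!is.na(expressed_in) & !gene_id %in% de_genes$feature_id]
  out <- x[, .(gene_id, exon_id = feature_id, expressed_in,
               exon_rel_A = rel_A, exon_rel_B = rel_B,
               junction_supported = NA)]
  data.table::setorder(out, gene_id, exon_id)
  out[]
}

#' Annotate isoform calls with exon-junction support
#'
#' A call is junction-supported when at least one junction touching its exon
#' has RPKM above `threshold` in the expressed sample and below it in the
#' silent sample.
#'
#' @param calls an [isoform_call()] result
#' @param junc_A,junc_B [junction_rpkm()] results per sample, with `exon_id`
#' @param threshold asymmetric-support RPKM threshold (0.1)
#' @return `calls` with `junction_supported` filled and a `no_junction` flag
#' @export
junction_support <- function(calls, junc_A, junc_B, threshold = 0.1) {
  calls <- data.table::copy(data.table::as.data.table(calls))
  ja <- data.table::as.data.table(junc_A)[, .(junction_id, exon_id, rpkm_A = rpkm)]
  jb <- data.table::as.data.table(junc_B)[, .(junction_id, rpkm_B = rpkm)]
  j <- merge(ja, jb, by = "junction_id")
  supp <- j[, .(sup_A = any(rpkm_A > threshold & rpkm_B < threshold),
                sup_B = any(rpkm_B > threshold & rpkm_A < threshold)),
            by = exon_id]
  calls <- merge(calls, supp, by.x = "exon_id", by.y = "exon_id",
                 all.x = TRUE, sort = FALSE)
  calls[, no_junction := is.na(sup_A)]
  calls[, junction_supported := data.table::fifelse(
    no_junction, FALSE,
    data.table::fifelse(expressed_in == "A", sup_A, sup_B))]
  calls[, c("sup_A", "sup_B") := NULL]
  data.table::setcolorder(calls, c("gene_id", "exon_id"))
  calls[]
}

#' Hypergeometric overlap significance for two feature sets
#'
#' Upper-tail probability of observing at least the given overlap between
#' two sets drawn from a common universe.
#'
#' @param n_A,n_B set sizes
#' @param overlap observed overlap
#' @param universe universe size
#' @return upper-tail hypergeometric p-value, `P[X >= overlap]`
#' @export
overlap_significance <- function(n_A, n_B, overlap, universe) {
  .chk(overlap <= min(n_A, n_B) && n_A <= universe && n_B <= universe &&
         overlap >= 0, "inconsistent set sizes")
  phyper(overlap - 1, n_A, universe - n_A, n_B, lower.tail = FALSE)
}
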