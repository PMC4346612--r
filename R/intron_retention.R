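#' Call retained introns from expression features
#'
#' An intron of a protein-coding gene is called retained when it passes all
#' four rules: intron RPKM above `min_intron_rpkm` (expression prefilter),
#' intron RPKM above `gene_frac` of the gene RPKM, intron normalized coverage
#' above `cov_ratio` of the flanking merged exons' normalized coverage
#' (arithmetic mean of the two flanks by default; at gene ends the single
#' available flank is used and logged), and at least `min_breadth` of the
#' intron covered by one read or more. Introns overlapping exons on the
#' opposite strand are excluded before testing.
#'
#' @param expr a [quantify()] result for one sample
#' @param gm the [gene_models()] used for quantification
#' @param opposite_flags logical vector from
#'   [flag_opposite_strand_introns()]; `NULL` to compute it here
#' @param min_intron_rpkm,gene_frac,cov_ratio,min_breadth the four thresholds
#'   (defaults 1 / 0.05 / 0.30 / 0.90)
#' @param cov_ratio_mode `"mean"` compares against the mean of the two
#'   flanks; `"both"` requires the ratio against each flank individually
#' @param cell_type label recorded on the calls
#' @return data.table of calls: gene_id, intron_id, chrom, start, end,
#'   intron_rpkm, gene_rpkm, coverage_ratio, breadth, cell_type
#' @export
call_retained_introns <- function(expr, gm, opposite_flags = NULL,
                                  min_intron_rpkm = 1, gene_frac = 0.05,
                                  cov_ratio = 0.30, min_breadth = 0.90,
                                  cov_ratio_mode = c("mean", "both"),
                                  cell_type = NA_character_) {
  cov_ratio_mode <- match.arg(cov_ratio_mode)
  expr <- data.table::as.data.table(expr)
  if (is.null(opposite_flags)) opposite_flags <- flag_opposite_strand_introns(gm)
  intr <- data.table::copy(gm$introns)
  .chk(length(opposite_flags) == nrow(intr),
       "opposite_flags must be parallel to gm$introns")
  intr[, opposite := opposite_flags]

  ie <- expr[type == "intron",
             .(intron_id = feature_id, gene_id, intron_rpkm = rpkm,
               intron_cov = normalized_coverage, breadth,
               intron_index = feature_index)]
  ge <- expr[type == "gene", .(gene_id, gene_rpkm = rpkm)]
  ee <- expr[type == "exon", .(gene_id, exon_index = feature_index,
                               exon_cov = normalized_coverage)]
  x <- merge(ie, ge, by = "gene_id")
  x <- merge(x, gm$genes[, .(gene_id, biotype)], by = "gene_id")
  x <- merge(x, intr[, .(intron_id, opposite)], by = "intron_id")

  left <- ee[, .(gene_id, intron_index = exon_index, left_cov = exon_cov)]
  right <- ee[, .(gene_id, intron_index = exon_index - 1L,
                  right_cov = exon_cov)]
  x <- merge(x, left, by = c("gene_id", "intron_index"), all.x = TRUE)
  x <- merge(x, right, by = c("gene_id", "intron_index"), all.x = TRUE)
  single_flank <- sum(is.na(x$left_cov) | is.na(x$right_cov))
  if (single_flank > 0)
    message(sprintf("%d intron(s) evaluated with a single flanking exon",
                    single_flank))
  x[, flank_mean := rowMeans(cbind(left_cov, right_cov), na.rm = TRUE)]
  if (cov_ratio_mode == "mean") {
    x[, coverage_ratio := ifelse(flank_mean > 0, intron_cov / flank_mean, Inf)]
    x[, pass_ratio := coverage_ratio > cov_ratio]
  } else {
    x[, coverage_ratio := ifelse(flank_mean > 0, intron_cov / flank_mean, Inf)]
    x[, pass_ratio := (is.na(left_cov) | intron_cov > cov_ratio * left_cov) &
          (is.na(right_cov) | intron_cov > cov_ratio * right_cov)]
  }
  calls <- x[biotype == "protein_coding" & opposite == FALSE &
               intron_rpkm > min_intron_rpkm &
               intron_rpkm > gene_frac * gene_rpkm &
               pass_ratio == TRUE & breadth >= min_breadth]
  # assert the four invariants on emission
  stopifnot(all(calls$intron_rpkm > min_intron_rpkm),
            all(calls$intron_rpkm > gene_frac * calls$gene_rpkm),
            all(calls$breadth >= min_breadth))
  out <- merge(calls, gm$introns[, .(intron_id, chrom, start, end)],
               by = "intron_id")
  out <- out[, .(gene_id, intron_id, intron_index, chrom, start, end,
                 intron_rpkm, gene_rpkm, coverage_ratio, breadth,
                 cell_type = cell_type)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Partition retention calls into shared and cell-type-specific sets
#'
#' @param call_list named list of [call_retained_introns()] results, one per
#'   cell type (identical thresholds)
#' @return list with `introns` (per-intron membership: called_in, n_types,
#'   specific) and `summary` (per-type specific counts plus the shared count)
#' @export
specificity_partition <- function(call_list) {
  .chk(length(call_list) >= 2 && !is.null(names(call_list)),
       "need a named list of calls for >= 2 cell types")
  long <- data.table::rbindlist(lapply(names(call_list), function(ct)
    data.table::data.table(intron_id = call_list[[ct]]$intron_id,
                           cell_type = ct)))
  per <- long[, .(called_in = paste(sort(cell_type), collapse = ","),
                  n_types = data.table::uniqueN(cell_type)), by = intron_id]
  per[, specific := n_types == 1L]
  summ <- long[intron_id %in% per[specific == TRUE, intron_id],
               .(n_specific = .N), by = cell_type]
  missing_ct <- setdiff(names(call_list), summ$cell_type)
  if (length(missing_ct))
    summ <- rbind(summ, data.table::data.table(cell_type = missing_ct,
                                               n_specific = 0L))
  list(introns = per[], summary = summ[order(cell_type)],
       n_shared = sum(!per$specific), n_total = nrow(per),
       frac_specific = if (nrow(per)) mean(per$specific) else NA_real_)
}

.find_stop <- function(seq, from) {
  # position (1-based, first base) of the first in-frame stop codon at or
  # after `from`, or NA
  n <- nchar(seq)
  if (from + 2 > n) return(NA_integer_)
  starts <- seq.int(from, n - 2, by = 3)
  codons <- substring(seq, starts, starts + 2)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (!length(hit)) NA_integer_ else starts[hit[1]]
}

#' Predict nonsense-mediated decay of a retained-intron transcript
#'
#' Applies the 50-nt rule: the transcript is predicted to undergo NMD when
#' translation of the retained-intron mRNA terminates at a stop codon more
#' than `rule_nt` nucleotides upstream of the last remaining exon-exon
#' junction. Retaining intron i removes the junction between exons i and
#' i + 1; the other junctions stay.
#'
#' @param exon_seqs character vector of exon sequences in transcript
#'   (5'-to-3') order, already strand-resolved
#' @param cds_start 1-based position of the first CDS base within the spliced
#'   mRNA, or `NA` when no CDS is annotated
#' @param intron_seq sequence of the retained intron
#' @param intron_after index of the exon after which the intron sits
#' @param rule_nt the junction-distance rule (50 nt)
#' @return `TRUE`/`FALSE`, or `NA` when no CDS is available (indeterminate,
#'   excluded from NMD rates)
#' @export
predict_nmd <- function(exon_seqs, cds_start, intron_seq, intron_after,
                        rule_nt = 50) {
  if (is.na(cds_start)) return(NA)
  n_ex <- length(exon_seqs)
  .chk(intron_after >= 1 && intron_after < n_ex,
       "intron_after must name an internal junction")
  segs <- append(as.list(exon_seqs), list(intron_seq), after = intron_after)
  # exon indices in the new transcript: 1..intron_after, intron,
  # intron_after+2 .. n_ex+1; junctions survive at the 3' end of every
  # original exon except exon `intron_after` (fused to the intron) and the
  # last exon
  seg_len <- nchar(unlist(segs))
  seg_end <- cumsum(seg_len)
  orig_exon_pos <- seq_len(n_ex + 1L)[-(intron_after + 1L)]  # segment index per exon
  junction_exons <- setdiff(seq_len(n_ex - 1L), intron_after)
  junction_pos <- seg_end[orig_exon_pos[junction_exons]]
  mrna <- toupper(paste(unlist(segs), collapse = ""))
  if (!length(junction_pos)) return(FALSE)
  last_junction <- max(junction_pos)
  stop_start <- .find_stop(mrna, cds_start)
  if (is.na(stop_start)) return(FALSE)
  stop_end <- stop_start + 2L
  (last_junction - stop_end) > rule_nt
}

#' Methylation peak-minus-valley statistic at intron boundaries
#'
#' For each intron boundary (strand-oriented 5' and 3'), CpG methylation is
#' averaged in `bin`-bp bins over `window` bp on the exon side and the intron
#' side; the statistic is the maximum over exon-side bins minus the minimum
#' over intron-side bins. Boundaries whose windows contain no CpG are `NA`
#' and counted in attribute `n_excluded`.
#'
#' @param methylome per-CpG data.table (chrom, pos, fraction)
#' @param introns data.table with chrom, start, end, strand (0-based
#'   half-open) and optionally intron_id
#' @param window,bin window and bin sizes in bp (defaults 200 / 20)
#' @return data.table with per-intron `delta_5p`, `delta_3p`
#' @export
boundary_methylation_delta <- function(methylome, introns, window = 200,
                                       bin = 20) {
  meth <- data.table::as.data.table(methylome)
  intr <- data.table::as.data.table(introns)
  if (!"intron_id" %in% names(intr))
    intr[, intron_id := sprintf("intron%d", .I)]
  side_delta <- function(ch, boundary, exon_dir) {
    # exon_dir +1: exon side is [boundary, boundary+window); -1: the mirror
    m <- meth[chrom == ch]
    bin_mean <- function(lo, hi) {
      mm <- m[pos >= lo & pos < hi]
      if (!nrow(mm)) return(rep(NA_real_, window %/% bin))
      b <- pmin((mm$pos - lo) %/% bin + 1L, window %/% bin)
      v <- rep(NA_real_, window %/% bin)
      agg <- tapply(mm$fraction, b, mean)
      v[as.integer(names(agg))] <- agg
      v
    }
    if (exon_dir > 0) {
      exon_bins <- bin_mean(boundary, boundary + window)
      intr_bins <- bin_mean(boundary - window, boundary)
    } else {
      exon_bins <- bin_mean(boundary - window, boundary)
      intr_bins <- bin_mean(boundary, boundary + window)
    }
    if (all(is.na(exon_bins)) || all(is.na(intr_bins))) return(NA_real_)
    max(exon_bins, na.rm = TRUE) - min(intr_bins, na.rm = TRUE)
  }
  res <- lapply(seq_len(nrow(intr)), function(i) {
    ch <- intr$chrom[i]; s <- intr$start[i]; e <- intr$end[i]
    if (intr$strand[i] == "-") {
      # 5' intron boundary at `end`: exon side right of it
      d5 <- side_delta(ch, e, +1)
      d3 <- side_delta(ch, s, -1)
    } else {
      d5 <- side_delta(ch, s, -1)
      d3 <- side_delta(ch, e, +1)
    }
    c(d5, d3)
  })
  out <- data.table::data.table(
    intron_id = intr$intron_id,
    delta_5p = vapply(res, `[`, numeric(1), 1),
    delta_3p = vapply(res, `[`, numeric(1), 2))
  data.table::setattr(out, "n_excluded",
                      sum(is.na(out$delta_5p)) + sum(is.na(out$delta_3p)))
  out[]
}
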