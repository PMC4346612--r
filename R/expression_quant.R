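#' Exclusion-based RPKM normalization factor
#'
#' The library normalizer is the total number of reads in coding exons after
#' excluding (i) reads on the mitochondrial chromosome, (ii) reads in genes
#' coding for ribosomal proteins, and (iii) reads in the top 0.5% expressed
#' exons (ranked by provisional RPKM; ties broken by coordinate for
#' determinism). Reads per feature are estimated from per-base coverage sums
#' divided by the read length, keeping the pipeline alignment-free.
#'
#' @param track a [coverage_track()] of RNA-seq depth
#' @param gm a [gene_models()] object from the same genome
#' @param mito_chrom mitochondrial chromosome name (reads there are excluded)
#' @param ribosomal_gene_ids gene ids of ribosomal-protein genes to exclude
#' @param read_length read length (bp) used to convert coverage to reads
#' @param top_exon_fraction fraction of top-expressed exons to exclude
#' @return an object of class `normalization_factor` with
#'   `total_included_reads`, the excluded read counts and the set of
#'   excluded exon ids
#' @export
compute_normalization <- function(track, gm, mito_chrom = "MT",
                                  ribosomal_gene_ids = character(0),
                                  read_length = 75,
                                  top_exon_fraction = 0.005) {
  coding <- gm$genes[biotype == "protein_coding", gene_id]
  ex <- gm$exons[gene_id %in% coding]
  .chk(nrow(ex) > 0, "no coding exons in annotation")
  counts <- interval_sums(track, ex$chrom, ex$start, ex$end) / read_length
  mito_chrom <- norm_chrom(mito_chrom)
  is_mito <- ex$chrom == mito_chrom
  is_ribo <- ex$gene_id %in% ribosomal_gene_ids
  excluded_mito <- sum(counts[is_mito])
  excluded_ribo <- sum(counts[is_ribo & !is_mito])
  keep <- !is_mito & !is_ribo
  t0 <- sum(counts[keep])
  if (t0 <= 0) stop("empty library", call. = FALSE)
  ek <- ex[keep]
  ck <- counts[keep]
  prov_rpkm <- ck / ((ek$end - ek$start) / 1e3) / (t0 / 1e6)
  ord <- order(-prov_rpkm, ek$chrom, ek$start)
  n_top <- ceiling(top_exon_fraction * nrow(ek))
  top_idx <- ord[seq_len(n_top)]
  excluded_top <- sum(ck[top_idx])
  total <- t0 - excluded_top
  if (total <= 0) stop("empty library", call. = FALSE)
  structure(list(total_included_reads = total,
                 excluded_mito_reads = excluded_mito,
                 excluded_ribosomal_reads = excluded_ribo,
                 excluded_top_exon_reads = excluded_top,
                 excluded_top_exon_ids = ek$exon_id[top_idx],
                 top_exon_fraction = top_exon_fraction,
                 read_length = read_length),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat(sprintf(paste0("normalization_factor: %.0f included reads ",
                     "(excluded: %.0f mito, %.0f ribosomal, %.0f top-%.2g%% exons)\n"),
              x$total_included_reads, x$excluded_mito_reads,
              x$excluded_ribosomal_reads, x$excluded_top_exon_reads,
              100 * x$top_exon_fraction))
  invisible(x)
}

.feature_expr <- function(track, dt, id, type, gene_id, total, read_length) {
  len <- dt$end - dt$start
  .chk(all(len > 0), "zero-length feature")
  covsum <- interval_sums(track, dt$chrom, dt$start, dt$end)
  breadth <- interval_breadth(track, dt$chrom, dt$start, dt$end)
  read_count <- covsum / read_length
  data.table::data.table(
    feature_id = id, type = type, gene_id = gene_id,
    chrom = dt$chrom, start = dt$start, end = dt$end, strand = dt$strand,
    length = len, read_count = read_count,
    rpkm = read_count / (len / 1e3) / (total / 1e6),
    normalized_coverage = (covsum / len) / (total / 1e6),
    breadth = breadth)
}

#' Quantify genes, exons and introns as modified RPKM
#'
#' Gene RPKM uses the total reads over all merged exons normalized by total
#' exonic length; exon and intron RPKM are computed over their own lengths
#' with the same library normalizer. `normalized_coverage` is mean per-base
#' depth divided by (included reads / 1e6); `breadth` is the fraction of
#' feature bases covered by at least one read.
#'
#' @param track a [coverage_track()]
#' @param gm a [gene_models()] object
#' @param norm a [compute_normalization()] result from the same track
#' @return a data.table of per-feature expression (types `gene`, `exon`,
#'   `intron`), class `feature_expression`
#' @export
quantify <- function(track, gm, norm) {
  total <- norm$total_included_reads
  rl <- norm$read_length
  ex <- .feature_expr(track, gm$exons, gm$exons$exon_id, "exon",
                      gm$exons$gene_id, total, rl)
  ex[, exon_index := gm$exons$exon_index]
  # gene read count = sum over merged exons (bookkeeping conserved exactly)
  gsum <- ex[, .(read_count = sum(read_count),
                 covered = sum(breadth * length)), by = gene_id]
  g <- merge(gm$genes, gsum, by = "gene_id", sort = FALSE)
  gdt <- data.table::data.table(
    feature_id = g$gene_id, type = "gene", gene_id = g$gene_id,
    chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
    length = g$exonic_length, read_count = g$read_count,
    rpkm = g$read_count / (g$exonic_length / 1e3) / (total / 1e6),
    normalized_coverage = (g$read_count * rl / g$exonic_length) / (total / 1e6),
    breadth = g$covered / g$exonic_length, exon_index = NA_integer_)
  idt <- if (nrow(gm$introns))
    cbind(.feature_expr(track, gm$introns, gm$introns$intron_id, "intron",
                        gm$introns$gene_id, total, rl),
          exon_index = gm$introns$intron_index)
  else NULL
  out <- data.table::rbindlist(list(gdt, ex, idt), use.names = TRUE)
  data.table::setnames(out, "exon_index", "feature_index")
  data.table::setattr(out, "class",
                      c("feature_expression", class(out)))
  out[]
}

#' Junction RPKM over a fixed effective length
#'
#' Exon-junction read counts are an input table (the package does not
#' realign reads); each junction's RPKM is computed over a configurable
#' effective length, by default the read length.
#'
#' @param junctions data.table with `junction_id`, `count` and optionally
#'   `exon_id`, `gene_id`
#' @param norm a [compute_normalization()] result
#' @param effective_length effective junction length in bp
#' @return data.table with junction RPKM
#' @export
junction_rpkm <- function(junctions, norm, effective_length = norm$read_length) {
  j <- data.table::as.data.table(junctions)
  .chk(all(c("junction_id", "count") %in% names(j)),
       "junction table needs junction_id and count")
  if (any(j$count < 0)) stop("negative junction count", call. = FALSE)
  j <- data.table::copy(j)
  j[, rpkm := count / (effective_length / 1e3) /
        (norm$total_included_reads / 1e6)]
  j[]
}

#' Write a feature-expression table as TSV
#'
#' @param expr a [quantify()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  data.table::fwrite(data.table::as.data.table(expr), path, sep = "\t")
  invisible(path)
}
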