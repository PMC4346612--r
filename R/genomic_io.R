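#' Gene models: merged exons, introns, TSS
#'
#' A `gene_models` object is the coordinate frame for all quantification:
#' per gene the union of all annotated transcript exons ("merged exons"),
#' the introns tiling the gaps between them, the strand-aware TSS and the
#' total exonic length. All coordinates are 0-based half-open.
#'
#' @param exons data.table/data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open exon intervals; overlapping
#'   exons of different transcripts are allowed and will be merged) and
#'   optionally `biotype` (`protein_coding` or `noncoding`)
#' @return an object of class `gene_models` with components `genes`,
#'   `exons` (merged) and `introns`, each a data.table
#' @export
gene_models <- function(exons) {
  ex <- data.table::as.data.table(exons)
  .chk(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(ex)),
       "exons need gene_id, chrom, start, end, strand columns")
  if (!"biotype" %in% names(ex)) ex[, biotype := "protein_coding"]
  ex[, chrom := norm_chrom(chrom)]
  .chk(all(ex$start < ex$end), "exon intervals must satisfy start < end")
  .chk(all(ex$strand %in% c("+", "-", ".")), "strand must be one of + - .")
  multi <- ex[, .(n_chrom = data.table::uniqueN(chrom),
                  n_strand = data.table::uniqueN(strand)), by = gene_id]
  bad <- multi[n_chrom > 1 | n_strand > 1, gene_id]
  if (length(bad))
    stop(sprintf("gene(s) spanning multiple chromosomes or strands rejected: %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)

  gr <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end),
                               strand = ex$strand)
  merged <- GenomicRanges::reduce(S4Vectors::split(gr, ex$gene_id))
  md <- data.table::as.data.table(merged)
  data.table::setnames(md, "group_name", "gene_id")
  md <- md[, .(gene_id, chrom = norm_chrom(as.character(seqnames)),
               start = start - 1L, end = end,
               strand = as.character(strand))]
  data.table::setorder(md, gene_id, chrom, start)
  md[, exon_index := seq_len(.N), by = gene_id]
  md[, exon_id := paste0(gene_id, ":E", exon_index)]

  bio <- unique(ex[, .(gene_id, biotype)])
  .chk(!anyDuplicated(bio$gene_id), "inconsistent biotype within a gene")

  genes <- md[, .(chrom = chrom[1], strand = strand[1],
                  start = min(start), end = max(end),
                  exonic_length = sum(end - start), n_exons = .N), by = gene_id]
  genes <- merge(genes, bio, by = "gene_id", sort = FALSE)
  genes[, tss := ifelse(strand == "-", end, start)]
  .chk(all(genes$exonic_length > 0), "zero exonic length")

  introns <- md[, {
    if (.N > 1)
      list(chrom = chrom[-1], start = end[-.N], end = start[-1],
           strand = strand[-1], intron_index = seq_len(.N - 1))
    else
      list(chrom = character(0), start = integer(0), end = integer(0),
           strand = character(0), intron_index = integer(0))
  }, by = gene_id]
  if (nrow(introns)) introns[, intron_id := paste0(gene_id, ":I", intron_index)]
  else introns[, intron_id := character(0)]

  data.table::setorder(genes, chrom, start)
  structure(list(genes = genes[], exons = md[], introns = introns[]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d protein_coding), %d merged exons, %d introns\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

.validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#") || !nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop(sprintf("GTF parse error at line %d of %s", i, path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read gene models from a GTF annotation
#'
#' Uses the Ensembl GTF dialect (1-based closed coordinates, `gene_id` /
#' `gene_biotype` attributes); exon records of all transcripts of a gene are
#' merged into disjoint intervals. Genes without exon records are skipped
#' with a warning.
#'
#' @param path GTF file (gzip transparent)
#' @return a [gene_models()] object
#' @export
read_gtf <- function(path) {
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  dt <- data.table::as.data.table(gr)
  ex <- dt[type == "exon"]
  n_dropped <- length(setdiff(dt$gene_id, ex$gene_id))
  if (n_dropped > 0)
    warning(sprintf("%d gene(s) without exon records skipped", n_dropped))
  .chk(nrow(ex) > 0, "no exon records in %s", path)
  bt <- if ("gene_biotype" %in% names(ex)) ex$gene_biotype else "protein_coding"
  gene_models(data.table::data.table(
    gene_id = ex$gene_id, chrom = as.character(ex$seqnames),
    start = ex$start - 1L, end = ex$end, strand = as.character(ex$strand),
    biotype = ifelse(bt == "protein_coding", "protein_coding", "noncoding")))
}

#' Write gene models as an Ensembl-dialect GTF
#'
#' Each gene is emitted as one gene record plus exon records of its merged
#' exon structure (a single synthetic transcript), converting the internal
#' 0-based half-open coordinates back to 1-based closed.
#'
#' @param gm a [gene_models()] object
#' @param path output file
#' @param use_chr_prefix prepend `"chr"` to chromosome names
#' @return `path`, invisibly
#' @export
write_gtf <- function(gm, path, use_chr_prefix = FALSE) {
  g <- gm$genes
  e <- merge(gm$exons, g[, .(gene_id, biotype)], by = "gene_id", sort = FALSE)
  attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
  gl <- data.table::data.table(
    chrom = .restore_chrom(g$chrom, use_chr_prefix), src = "epicell",
    type = "gene", start = g$start + 1L, end = g$end, score = ".",
    strand = g$strand, frame = ".", attr = attr_g, ord = g$start)
  attr_e <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s"; exon_number "%d";',
                    e$gene_id, e$gene_id, e$biotype, e$exon_index)
  el <- data.table::data.table(
    chrom = .restore_chrom(e$chrom, use_chr_prefix), src = "epicell",
    type = "exon", start = e$start + 1L, end = e$end, score = ".",
    strand = e$strand, frame = ".", attr = attr_e, ord = e$start)
  out <- rbind(gl, el)
  data.table::setorder(out, chrom, ord, type)
  out[, ord := NULL]
  writeLines(c("#!genome-build synthetic",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Flag introns overlapping exons on the opposite strand
#'
#' An intron is flagged when at least 1 bp of it overlaps a merged exon of
#' any gene annotated on the opposite strand; such introns are excluded from
#' intron-retention analysis (coverage there is ambiguous between the two
#' strands in non-strand-specific libraries).
#'
#' @param gm a [gene_models()] object
#' @return logical vector parallel to `gm$introns` rows
#' @export
flag_opposite_strand_introns <- function(gm) {
  intr <- gm$introns
  if (!nrow(intr)) return(logical(0))
  ex <- gm$exons
  ir <- GenomicRanges::GRanges(intr$chrom,
                               IRanges::IRanges(intr$start + 1L, intr$end))
  flagged <- logical(nrow(intr))
  for (s in c("+", "-")) {
    opp <- ex[strand == (if (s == "+") "-" else "+")]
    idx <- which(intr$strand == s)
    if (!length(idx) || !nrow(opp)) next
    er <- GenomicRanges::GRanges(opp$chrom,
                                 IRanges::IRanges(opp$start + 1L, opp$end))
    ov <- GenomicRanges::countOverlaps(ir[idx], er, minoverlap = 1L)
    flagged[idx] <- ov > 0
  }
  flagged
}

#' Read a BED file (3-6 columns) of intervals
#'
#' @param path BED file; 0-based half-open as per the BED convention
#' @return data.table with columns chrom, start, end and, when present,
#'   name, score, strand
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6)), cols[seq_len(min(ncol(dt), 6))])
  dt[, chrom := norm_chrom(chrom)]
  .chk(all(dt$start < dt$end), "BED intervals must satisfy start < end")
  dt[]
}

#' Write intervals as BED6
#'
#' @param dt data.table with chrom, start, end and optional name, score, strand
#' @param path output file
#' @param use_chr_prefix prepend `"chr"` to chromosome names
#' @return `path`, invisibly
#' @export
write_bed <- function(dt, path, use_chr_prefix = FALSE) {
  dt <- data.table::as.data.table(dt)
  if (!"name" %in% names(dt)) dt[, name := "."]
  if (!"score" %in% names(dt)) dt[, score := 0]
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  out <- dt[, .(chrom = .restore_chrom(norm_chrom(chrom), use_chr_prefix),
                start, end, name, score, strand)]
  data.table::setorder(out, chrom, start, end)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
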