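# Independent brute-force oracles, deliberately written as naive base-R
# loops so they share no code path with the package implementations.

# quadratic all-pairs interval scan for opposite-strand exon overlap
oracle_opposite_flags <- function(gm) {
  intr <- as.data.frame(gm$introns)
  ex <- as.data.frame(gm$exons)
  out <- logical(nrow(intr))
  for (i in seq_len(nrow(intr))) {
    for (j in seq_len(nrow(ex))) {
      if (ex$chrom[j] == intr$chrom[i] && ex$strand[j] != intr$strand[i] &&
          ex$start[j] < intr$end[i] && ex$end[j] > intr$start[i]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# naive four-rule retention filter over a feature-expression table
oracle_retention <- function(expr, gm, flags, min_rpkm = 1, frac = 0.05,
                             ratio = 0.30, breadth_min = 0.90) {
  expr <- as.data.frame(expr)
  intr <- as.data.frame(gm$introns)
  genes <- as.data.frame(gm$genes)
  hits <- character(0)
  for (i in seq_len(nrow(intr))) {
    if (flags[i]) next
    g <- intr$gene_id[i]
    if (genes$biotype[genes$gene_id == g] != "protein_coding") next
    iid <- intr$intron_id[i]
    ie <- expr[expr$type == "intron" & expr$feature_id == iid, ]
    ge <- expr[expr$type == "gene" & expr$feature_id == g, ]
    ii <- intr$intron_index[i]
    fl <- expr[expr$type == "exon" & expr$gene_id == g &
                 expr$feature_index %in% c(ii, ii + 1L), ]
    fm <- mean(fl$normalized_coverage)
    cr <- if (fm > 0) ie$normalized_coverage / fm else Inf
    if (ie$rpkm > min_rpkm && ie$rpkm > frac * ge$rpkm && cr > ratio &&
        ie$breadth >= breadth_min)
      hits <- c(hits, iid)
  }
  sort(hits)
}

# naive gene-relative band filter for isoform calls
oracle_isoform <- function(expr_A, expr_B, de_exon_ids, de_gene_ids,
                           expressed_min = 0.10, silent_max = 0.01) {
  ea <- as.data.frame(expr_A); eb <- as.data.frame(expr_B)
  hits <- character(0)
  for (eid in de_exon_ids) {
    ra <- ea[ea$type == "exon" & ea$feature_id == eid, ]
    g <- ra$gene_id
    if (g %in% de_gene_ids) next
    ga <- ea[ea$type == "gene" & ea$feature_id == g, "rpkm"]
    gb <- eb[eb$type == "gene" & eb$feature_id == g, "rpkm"]
    if (ga == 0 && gb == 0) next
    rel_a <- if (ga > 0) ra$rpkm / ga else 0
    rel_b0 <- eb[eb$type == "exon" & eb$feature_id == eid, "rpkm"]
    rel_b <- if (gb > 0) rel_b0 / gb else 0
    if ((rel_a >= expressed_min && rel_b <= silent_max) ||
        (rel_b >= expressed_min && rel_a <= silent_max))
      hits <- c(hits, eid)
  }
  sort(hits)
}

# exhaustive hypergeometric upper tail by direct combinatorial sum
oracle_hyper <- function(n_A, n_B, overlap, universe) {
  ks <- overlap:min(n_A, n_B)
  sum(choose(n_A, ks) * choose(universe - n_A, n_B - ks)) /
    choose(universe, n_B)
}

# entropy through natural logs, element by element
oracle_entropy <- function(E) {
  tot <- sum(E)
  if (tot == 0) return(NA_real_)
  h <- 0
  for (e in E) {
    f <- e / tot
    if (f > 0) h <- h - f * log(f) / log(2)
  }
  h
}

# per-CpG brute-force boundary profile with the package's bin convention
oracle_profile <- function(meth, features, window = 200, bin = 20) {
  meth <- as.data.frame(meth); ft <- as.data.frame(features)
  nb <- window %/% bin
  acc <- list()
  for (i in seq_len(nrow(ft))) {
    m <- meth[meth$chrom == ft$chrom[i], ]
    m <- m[abs(m$pos - ft$pos[i]) <= window + 1L, ]
    for (j in seq_len(nrow(m))) {
      off <- m$pos[j] - ft$pos[i]
      if (ft$strand[i] == "-") off <- -off - 1L
      if (off < -window || off >= window) next
      b <- if (off < 0) -((-off - 1L) %/% bin) - 1L else off %/% bin + 1L
      key <- paste(ft$group[i], b)
      acc[[key]] <- c(acc[[key]], m$fraction[j])
    }
  }
  out <- data.frame(do.call(rbind, strsplit(names(acc), " ")),
                    stringsAsFactors = FALSE)
  names(out) <- c("group", "bin")
  out$bin <- as.integer(out$bin)
  out$mean_methylation <- vapply(acc, mean, numeric(1))
  out$n_cpgs <- vapply(acc, length, numeric(1))
  out[order(out$group, out$bin), ]
}

# small quick simulation for unit tests
small_sim_config <- function(...) {
  defaults <- list(n_genes = 40, n_chroms = 1, chrom_length = 6e5,
                   cell_types = c("luminal", "myoepithelial"),
                   n_de_genes = 8, n_cassette_exons = 6,
                   n_retained_introns = 8, n_antisense_pairs = 4, n_umrs = 8)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# constant-depth coverage track over explicit chromosome lengths
flat_track <- function(lens, value, assay = "rnaseq", library_total = NULL) {
  suppressMessages(coverage_track(
    lapply(lens, function(L) rep(value, L)), assay = assay,
    library_total = library_total))
}

# hand-built normalization factor for formula tests
manual_norm <- function(total, read_length = 75) {
  structure(list(total_included_reads = total, read_length = read_length),
            class = "normalization_factor")
}

# three-exon single-gene models used by the retention unit tests
toy_gene_models <- function(biotype = "protein_coding") {
  gene_models(data.frame(
    gene_id = "G1", chrom = "1",
    start = c(1000, 2000, 3000), end = c(1500, 2500, 3500),
    strand = "+", biotype = biotype))
}

# fabricate a feature-expression table row
fx_row <- function(id, type, gene, rpkm, ncov = rpkm, breadth = 1,
                   index = NA_integer_, count = rpkm) {
  data.table::data.table(feature_id = id, type = type, gene_id = gene,
                         chrom = "1", start = 0L, end = 100L, strand = "+",
                         length = 100L, read_count = count, rpkm = rpkm,
                         normalized_coverage = ncov, breadth = breadth,
                         feature_index = index)
}
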