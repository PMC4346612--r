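#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions emulated by [simulate_genome()]: gene models
#' with exons/introns on a small multi-chromosome genome, cell-type-specific
#' expression with planted differential genes, cassette exons and retained
#' introns, bimodal CpG methylation with planted unmethylated regions (UMRs),
#' and H3K36me3 enrichment over expressed exons. Defaults are desk-scale
#' (200 genes, two 2-Mb chromosomes, three cell types) so the full pipeline
#' runs in well under a minute.
#'
#' @param n_genes number of host genes (antisense decoys are extra)
#' @param n_chroms,chrom_length genome shape (bp)
#' @param cell_types cell-type labels; the first two form the comparison pair
#' @param exons_per_gene,exon_length,intron_length `c(min, max)` ranges (bp)
#' @param frac_noncoding fraction of genes labelled noncoding
#' @param frac_expressed fraction of genes with nonzero expression
#' @param depth_meanlog,depth_sdlog log-normal parameters of the per-gene mean
#'   exonic read depth (reads per base)
#' @param n_de_genes,de_fold planted differential genes between the first two
#'   cell types and their fold change
#' @param n_cassette_exons planted cell-type-specific cassette exons
#' @param n_retained_introns,retention_fraction planted retained introns and
#'   the intron/exon coverage fraction they receive in the target cell type
#' @param intron_noise_fraction baseline intronic coverage as a fraction of
#'   exonic depth (pre-mRNA background)
#' @param n_antisense_pairs antisense single-exon genes planted inside introns
#'   (ground truth for the opposite-strand exclusion)
#' @param methylation_background mean methylation of the high (methylated)
#'   mode
#' @param methylation_concentration Beta concentration of the per-CpG jitter
#'   around its region's methylation level
#' @param block_length `c(min, max)` length (bp) of the homogeneous
#'   methylation blocks tiling the genome
#' @param block_level_concentration Beta concentration of the per-block
#'   methylation level around its mode mean
#' @param low_block_frac,low_block_mean fraction and mean methylation of
#'   constitutively hypomethylated blocks (the low mode of the bimodal
#'   methylome, present in every cell type)
#' @param cpg_density background CpGs per 100 bp (jittered-grid placement)
#' @param cpg_coverage mean reads per CpG (Poisson)
#' @param n_umrs,umr_width,umr_n_cpgs,umr_target_methylation planted UMRs
#' @param umr_near_tss_bp distance from a planted UMR edge to the TSS of its
#'   associated differential gene
#' @param h3k36me3_background,h3k36me3_enrichment per-base Poisson rate
#'   genome-wide and the fold enrichment over expressed exons
#' @param read_length nominal read length (bp) used to convert coverage sums
#'   into read counts
#' @param rng_seed integer seed; fixed seed gives byte-identical output
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_genes = 200, n_chroms = 2, chrom_length = 2e6,
                       cell_types = c("luminal", "myoepithelial", "progenitor"),
                       exons_per_gene = c(4, 8),
                       exon_length = c(100, 300),
                       intron_length = c(500, 2000),
                       frac_noncoding = 0.1,
                       frac_expressed = 0.9,
                       depth_meanlog = log(30), depth_sdlog = 0.4,
                       n_de_genes = 40, de_fold = 4,
                       n_cassette_exons = 30,
                       n_retained_introns = 50, retention_fraction = 0.5,
                       intron_noise_fraction = 0.01,
                       n_antisense_pairs = 10,
                       methylation_background = 0.85,
                       methylation_concentration = 100,
                       block_length = c(500, 3000),
                       block_level_concentration = 10,
                       low_block_frac = 0.2, low_block_mean = 0.1,
                       cpg_density = 1.0,
                       cpg_coverage = 30,
                       n_umrs = 50, umr_width = 300, umr_n_cpgs = 10,
                       umr_target_methylation = 0.05,
                       umr_near_tss_bp = 500,
                       h3k36me3_background = 1, h3k36me3_enrichment = 5,
                       read_length = 75,
                       rng_seed = 42) {
  cfg <- as.list(environment())
  .chk(retention_fraction >= 0 && retention_fraction <= 1,
       "retention_fraction must lie in [0, 1]")
  .chk(length(cell_types) >= 2, "need at least two cell types")
  .chk(n_chroms >= 1 && chrom_length > 1e4, "genome too small")
  structure(cfg, class = "sim_config")
}

.runif_int <- function(n, lo, hi) as.integer(lo + floor(runif(n) * (hi - lo + 1)))

# Lay out gene structures sequentially along chromosomes.
.sim_layout <- function(cfg) {
  chroms <- paste0("sim", seq_len(cfg$n_chroms))
  cursor <- setNames(rep(10000L, cfg$n_chroms), chroms)
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    ch <- chroms[((g - 1L) %% cfg$n_chroms) + 1L]
    n_ex <- .runif_int(1, cfg$exons_per_gene[1], cfg$exons_per_gene[2])
    ex_len <- .runif_int(n_ex, cfg$exon_length[1], cfg$exon_length[2])
    in_len <- if (n_ex > 1)
      .runif_int(n_ex - 1, cfg$intron_length[1], cfg$intron_length[2])
    else integer(0)
    strand <- if (runif(1) < 0.5) "+" else "-"
    start <- cursor[[ch]]
    starts <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    cursor[[ch]] <- ends[n_ex] + .runif_int(1, 3000, 8000)
    rows[[g]] <- data.table::data.table(
      gene_id = sprintf("G%04d", g), chrom = ch,
      start = starts, end = ends, strand = strand)
  }
  if (any(cursor > cfg$chrom_length))
    stop("infeasible config: genes do not fit on the chromosomes; ",
         "increase chrom_length or reduce n_genes", call. = FALSE)
  ex <- data.table::rbindlist(rows)
  nc <- sample(unique(ex$gene_id),
               round(cfg$frac_noncoding * cfg$n_genes))
  ex[, biotype := ifelse(gene_id %in% nc, "noncoding", "protein_coding")]
  ex
}

#' Simulate a genome with planted ground truth
#'
#' Generates gene models, per-cell-type RNA-seq and H3K36me3 coverage tracks,
#' per-cell-type WGBS methylomes and truth tables listing every planted event.
#' Exonic RNA coverage is per-base Poisson around the gene's target depth;
#' a planted retained intron receives `retention_fraction` of the flanking
#' exonic depth across its whole length in its target cell type; a planted
#' cassette exon receives full depth in the target cell type and none
#' elsewhere (the remaining exons are scaled up so the host gene's total read
#' count is conserved and the gene itself stays non-differential); CpG
#' methylation is Beta-concentrated near the background mean except inside
#' planted UMRs.
#'
#' @param config a [sim_config()]
#' @return a list of class `sim_genome` with components `genes`
#'   ([gene_models()]), `rna`, `h3k36me3` (named lists of [coverage_track()]
#'   per cell type), `methylomes` (named list of per-CpG data.tables),
#'   `junctions` (simulated exon-junction read counts), `truth` (list of
#'   truth tables), `chrom_lengths`, and `config`
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$rng_seed)
  cts <- cfg$cell_types
  ctA <- cts[1]; ctB <- cts[2]
  chroms <- paste0("sim", seq_len(cfg$n_chroms))
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  ex <- .sim_layout(cfg)

  ## --- antisense decoy genes inside introns -------------------------------
  host <- ex[, .(n_ex = .N, strand = strand[1], biotype = biotype[1]),
             by = gene_id][n_ex >= 2]
  as_rows <- list()
  truth_antisense <- data.table::data.table(gene_id = character(0),
                                            intron_index = integer(0))
  n_as <- min(cfg$n_antisense_pairs, nrow(host))
  if (n_as > 0) {
    hosts <- sample(host$gene_id, n_as)
    for (k in seq_along(hosts)) {
      he <- ex[gene_id == hosts[k]][order(start)]
      ii <- .runif_int(1, 1, nrow(he) - 1)          # intron index
      istart <- he$end[ii]; iend <- he$start[ii + 1]
      w <- min(200L, iend - istart - 40L)
      if (w < 50) next
      s0 <- istart + 20L
      as_rows[[length(as_rows) + 1L]] <- data.table::data.table(
        gene_id = sprintf("AS%03d", k), chrom = he$chrom[1],
        start = s0, end = s0 + w,
        strand = if (he$strand[1] == "+") "-" else "+",
        biotype = "noncoding")
      truth_antisense <- rbind(truth_antisense,
        data.table::data.table(gene_id = hosts[k], intron_index = ii))
    }
  }
  ex_all <- rbind(ex, data.table::rbindlist(as_rows))
  gm <- gene_models(ex_all)

  ## --- expression design --------------------------------------------------
  genes <- gm$genes
  gid <- genes$gene_id
  is_host <- !startsWith(gid, "AS")
  expressed <- is_host & (runif(length(gid)) < cfg$frac_expressed)
  base_depth <- ifelse(expressed, rlnorm(length(gid), cfg$depth_meanlog,
                                         cfg$depth_sdlog), 0)
  names(base_depth) <- gid

  pool <- gid[expressed & genes$biotype == "protein_coding"]
  n_de <- min(cfg$n_de_genes, floor(length(pool) / 3))
  de_genes <- if (n_de > 0) sample(pool, n_de) else character(0)
  pool2 <- setdiff(pool, de_genes)
  cass_ok <- intersect(pool2, genes[n_exons >= 4, gene_id])
  n_cass <- min(cfg$n_cassette_exons, length(cass_ok))
  cass_genes <- if (n_cass > 0) sample(cass_ok, n_cass) else character(0)
  pool3 <- setdiff(pool2, cass_genes)
  ri_ok <- intersect(pool3, genes[n_exons >= 2, gene_id])
  n_ri <- min(cfg$n_retained_introns, length(ri_ok))
  ri_genes <- if (n_ri > 0) sample(ri_ok, n_ri) else character(0)

  truth_de <- data.table::data.table(
    gene_id = de_genes,
    up_in = rep(c(ctA, ctB), length.out = length(de_genes)))
  truth_cass <- data.table::data.table(
    gene_id = cass_genes,
    exon_index = vapply(cass_genes, function(g)
      .runif_int(1, 2, genes[gene_id == g, n_exons] - 1L), integer(1)),
    cell_type = rep(c(ctA, ctB), length.out = length(cass_genes)))
  if (nrow(truth_cass))
    truth_cass[, exon_id := paste0(gene_id, ":E", exon_index)]
  truth_ri <- data.table::data.table(
    gene_id = ri_genes,
    intron_index = vapply(ri_genes, function(g)
      .runif_int(1, 1, genes[gene_id == g, n_exons] - 1L), integer(1)),
    cell_type = rep(c(ctA, ctB), length.out = length(ri_genes)),
    retention_fraction = cfg$retention_fraction)
  if (nrow(truth_ri))
    truth_ri[, intron_id := paste0(gene_id, ":I", intron_index)]

  ## --- RNA and H3K36me3 coverage per cell type ----------------------------
  exn <- gm$exons; intr <- gm$introns
  el <- genes$exonic_length; names(el) <- gid
  rna <- list(); k36 <- list()
  for (ct in cts) {
    depth <- base_depth
    if (nrow(truth_de)) {
      up_here <- truth_de[up_in == ct, gene_id]
      up_elsewhere <- truth_de[up_in != ct & up_in %in% c(ctA, ctB), gene_id]
      depth[up_here] <- depth[up_here] * cfg$de_fold
      if (!ct %in% c(ctA, ctB)) depth[truth_de$gene_id] <- base_depth[truth_de$gene_id]
    }
    cov <- lapply(chrom_lengths, function(L) numeric(L))
    for (j in seq_len(nrow(exn))) {
      g <- exn$gene_id[j]; d <- depth[[g]]
      if (d <= 0) next
      lam <- d
      if (nrow(truth_cass) && g %in% truth_cass$gene_id) {
        tc <- truth_cass[gene_id == g]
        le <- exn[gene_id == g & exon_index == tc$exon_index, end - start]
        if (tc$cell_type != ct) {
          if (exn$exon_index[j] == tc$exon_index) lam <- 0
          else lam <- d * el[[g]] / (el[[g]] - le)   # conserve gene count
        }
      }
      if (lam <= 0) next
      idx <- (exn$start[j] + 1L):exn$end[j]
      ch <- exn$chrom[j]
      cov[[ch]][idx] <- cov[[ch]][idx] + rpois(length(idx), lam)
    }
    for (j in seq_len(nrow(intr))) {
      g <- intr$gene_id[j]; d <- depth[[g]]
      if (d <= 0) next
      lam <- d * cfg$intron_noise_fraction
      if (nrow(truth_ri) && g %in% truth_ri$gene_id) {
        tr <- truth_ri[gene_id == g]
        if (tr$cell_type == ct && intr$intron_index[j] == tr$intron_index)
          lam <- d * tr$retention_fraction
      }
      if (lam <= 0) next
      idx <- (intr$start[j] + 1L):intr$end[j]
      ch <- intr$chrom[j]
      cov[[ch]][idx] <- cov[[ch]][idx] + rpois(length(idx), lam)
    }
    rna[[ct]] <- suppressMessages(
      coverage_track(cov, assay = "rnaseq", read_length = cfg$read_length))

    kcov <- lapply(chrom_lengths, function(L)
      as.numeric(rpois(L, cfg$h3k36me3_background)))
    extra <- cfg$h3k36me3_background * (cfg$h3k36me3_enrichment - 1)
    for (j in seq_len(nrow(exn))) {
      g <- exn$gene_id[j]
      if (depth[[g]] <= 0) next
      # silenced cassette exons carry no transcription-coupled mark
      if (nrow(truth_cass) && g %in% truth_cass$gene_id) {
        tc <- truth_cass[gene_id == g]
        if (tc$cell_type != ct && exn$exon_index[j] == tc$exon_index) next
      }
      idx <- (exn$start[j] + 1L):exn$end[j]
      ch <- exn$chrom[j]
      kcov[[ch]][idx] <- kcov[[ch]][idx] + rpois(length(idx), extra)
    }
    k36[[ct]] <- suppressMessages(
      coverage_track(kcov, assay = "h3k36me3", read_length = cfg$read_length))
  }

  ## --- planted UMRs -------------------------------------------------------
  umr_rows <- list()
  if (cfg$n_umrs > 0) {
    near <- cfg$umr_near_tss_bp; w <- cfg$umr_width
    cand <- if (nrow(truth_de)) truth_de else
      data.table::data.table(gene_id = character(0), up_in = character(0))
    gi <- data.table::copy(genes); data.table::setkey(gi, gene_id)
    taken <- data.table::data.table(chrom = character(0), start = integer(0),
                                    end = integer(0))
    add_umr <- function(ch, s, e, ct) {
      if (s < 1000 || e > chrom_lengths[[ch]] - 1000) return(FALSE)
      clash <- taken[chrom == ch & start < e + 2000 & end > s - 2000]
      if (nrow(clash)) return(FALSE)
      taken <<- rbind(taken, data.table::data.table(chrom = ch, start = s, end = e))
      umr_rows[[length(umr_rows) + 1L]] <<- data.table::data.table(
        chrom = ch, start = s, end = e, cell_type = ct)
      TRUE
    }
    i <- 1L
    while (length(umr_rows) < cfg$n_umrs && i <= nrow(cand)) {
      g <- gi[cand$gene_id[i]]
      if (g$strand == "+") { e <- g$tss - near; s <- e - w }
      else { s <- g$tss + near; e <- s + w }
      add_umr(g$chrom, s, e, cand$up_in[i])
      i <- i + 1L
    }
    # remaining UMRs go into intergenic gaps
    spans <- genes[is_host][order(chrom, start)]
    gaps <- spans[, {
      s <- end[-.N] + 1000L; e <- start[-1] - 1000L
      list(gs = s, ge = e)
    }, by = chrom][ge - gs > w + 200]
    j <- 1L
    while (length(umr_rows) < cfg$n_umrs && j <= nrow(gaps)) {
      mid <- floor((gaps$gs[j] + gaps$ge[j]) / 2)
      add_umr(gaps$chrom[j], mid - floor(w / 2), mid - floor(w / 2) + w,
              cts[((j - 1L) %% 2L) + 1L])
      j <- j + 1L
    }
  }
  truth_umr <- if (length(umr_rows)) data.table::rbindlist(umr_rows) else
    data.table::data.table(chrom = character(0), start = integer(0),
                           end = integer(0), cell_type = character(0))
  if (nrow(truth_umr)) {
    truth_umr[, `:=`(target_methylation = cfg$umr_target_methylation,
                     n_cpgs = cfg$umr_n_cpgs,
                     umr_id = sprintf("trueUMR%03d", seq_len(.N)))]
  }

  ## --- methylomes: bimodal, block-structured landscape --------------------
  # jittered-grid CpG placement; homogeneous methylation blocks with a
  # bimodal level distribution (constitutive low blocks in every cell type),
  # planted UMRs hypomethylated only in their target cell type
  cpg_pos <- list(); block_tab <- list()
  step <- max(2L, as.integer(round(100 / cfg$cpg_density)))
  cb <- cfg$block_level_concentration
  for (ch in chroms) {
    L <- as.integer(chrom_lengths[[ch]])
    grid <- seq.int(1000L, L - 1000L, by = step)
    p <- grid + .runif_int(length(grid), -25L, 25L)
    p <- sort(unique(p))
    p <- p[c(TRUE, diff(p) >= 2)]
    tu <- truth_umr[chrom == ch]
    if (nrow(tu)) {
      inside <- rep(FALSE, length(p))
      for (r in seq_len(nrow(tu)))
        inside <- inside | (p >= tu$start[r] & p < tu$end[r])
      p <- p[!inside]
      planted <- unlist(lapply(seq_len(nrow(tu)), function(r)
        tu$start[r] + round(seq(0, tu$end[r] - tu$start[r] - 2,
                                length.out = cfg$umr_n_cpgs))))
      p <- sort(unique(c(p, as.integer(planted))))
    }
    cpg_pos[[ch]] <- p
    # block boundaries and levels
    n_max <- ceiling(L / cfg$block_length[1]) + 1L
    lens <- .runif_int(n_max, cfg$block_length[1], cfg$block_length[2])
    ends <- cumsum(as.numeric(lens))
    nb <- which(ends >= L)[1]
    ends <- pmin(ends[seq_len(nb)], L)
    starts <- c(0, ends[-nb])
    low <- runif(nb) < cfg$low_block_frac
    lev <- ifelse(low,
                  rbeta(nb, cfg$low_block_mean * cb,
                        (1 - cfg$low_block_mean) * cb),
                  rbeta(nb, cfg$methylation_background * cb,
                        (1 - cfg$methylation_background) * cb))
    # keep planted-UMR neighbourhoods on the high mode so cell-type
    # specificity of planted UMRs is unambiguous
    if (nrow(tu)) {
      for (r in seq_len(nrow(tu))) {
        hit <- which(starts < tu$end[r] + 1000 & ends > tu$start[r] - 1000)
        redo <- hit[low[hit]]
        if (length(redo)) {
          low[redo] <- FALSE
          lev[redo] <- rbeta(length(redo), cfg$methylation_background * cb,
                             (1 - cfg$methylation_background) * cb)
        }
      }
    }
    block_tab[[ch]] <- data.table::data.table(
      chrom = ch, start = as.integer(starts), end = as.integer(ends),
      level = lev, low = low)
  }
  blocks <- data.table::rbindlist(block_tab)
  truth_low_blocks <- blocks[low == TRUE,
                             .(chrom, start, end, level)]
  conc <- cfg$methylation_concentration
  methylomes <- list()
  for (ct in cts) {
    rows <- list()
    for (ch in chroms) {
      p <- cpg_pos[[ch]]
      bt <- block_tab[[ch]]
      mu <- bt$level[findInterval(p, bt$start)]
      tu <- truth_umr[chrom == ch & cell_type == ct]
      for (r in seq_len(nrow(tu)))
        mu[p >= tu$start[r] & p < tu$end[r]] <- cfg$umr_target_methylation
      true_m <- rbeta(length(p), mu * conc, (1 - mu) * conc)
      covg <- rpois(length(p), cfg$cpg_coverage)
      keep <- covg >= 1
      obs <- rbinom(sum(keep), covg[keep], true_m[keep]) / covg[keep]
      rows[[ch]] <- data.table::data.table(
        chrom = ch, pos = p[keep], fraction = obs, coverage = covg[keep],
        true_methylation = true_m[keep])
    }
    methylomes[[ct]] <- data.table::rbindlist(rows)
  }

  ## --- junction read counts for cassette exons ----------------------------
  jrows <- list()
  for (i in seq_len(nrow(truth_cass))) {
    g <- truth_cass$gene_id[i]; ei <- truth_cass$exon_index[i]
    tgt <- truth_cass$cell_type[i]
    for (side in c("L", "R")) {
      jid <- sprintf("%s:J%d%s", g, ei, side)
      for (ct in cts) {
        cnt <- if (ct == tgt) max(1L, round(base_depth[[g]] / 2)) else 0L
        jrows[[length(jrows) + 1L]] <- data.table::data.table(
          junction_id = jid, gene_id = g,
          exon_id = paste0(g, ":E", ei), cell_type = ct, count = cnt)
      }
    }
  }
  junctions <- if (length(jrows)) data.table::rbindlist(jrows) else
    data.table::data.table(junction_id = character(0), gene_id = character(0),
                           exon_id = character(0), cell_type = character(0),
                           count = integer(0))

  structure(list(
    genes = gm, rna = rna, h3k36me3 = k36, methylomes = methylomes,
    junctions = junctions,
    truth = list(de_genes = truth_de, cassette_exons = truth_cass,
                 retained_introns = truth_ri, umrs = truth_umr,
                 low_blocks = truth_low_blocks,
                 antisense_introns = truth_antisense,
                 base_depth = data.table::data.table(gene_id = gid,
                                                     depth = base_depth[gid])),
    chrom_lengths = chrom_lengths, config = cfg), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(paste0("sim_genome: %d genes on %d chromosome(s), %d cell types; ",
                     "planted: %d DE genes, %d cassette exons, %d retained introns, %d UMRs\n"),
              sum(!startsWith(x$genes$genes$gene_id, "AS")),
              length(x$chrom_lengths), length(x$rna),
              nrow(x$truth$de_genes), nrow(x$truth$cassette_exons),
              nrow(x$truth$retained_introns), nrow(x$truth$umrs)))
  invisible(x)
}

#' Simulate a MeDIP-seq experiment from a methylome
#'
#' MeDIP enrichment at each base is the fragment-smoothed (Gaussian kernel,
#' `fragment_sd`) sum of nearby CpG methylation scaled by sequencing depth,
#' plus a CpG-free background rate, with per-base Poisson noise. A companion
#' mappability track carries planted low-mappability patches.
#'
#' @param methylome per-CpG data.table (chrom, pos, fraction, coverage)
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param fragment_sd Gaussian smoothing bandwidth (bp), the sonicated
#'   fragment scale
#' @param depth expected reads contributed by a fully methylated CpG
#' @param bg_fraction CpG-free background rate as a fraction of `depth`
#' @param n_low_patches,patch_width low-mappability patches per chromosome
#' @param seed RNG seed for the noise
#' @return list with `signal` and `mappability` [coverage_track()]s
#' @export
simulate_medip <- function(methylome, chrom_lengths, fragment_sd = 150,
                           depth = 30, bg_fraction = 0.1,
                           n_low_patches = 4, patch_width = 2000, seed = 1) {
  set.seed(seed)
  meth <- data.table::as.data.table(methylome)
  half <- ceiling(3 * fragment_sd)
  kern <- exp(-((-half):half)^2 / (2 * fragment_sd^2))
  sig <- list(); mapp <- list()
  for (ch in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[ch]])
    spikes <- numeric(L)
    m <- meth[chrom == ch]
    if (nrow(m)) spikes[m$pos + 1L] <- depth * m$fraction
    lam <- rep(bg_fraction * depth, L)
    if (nrow(m)) {
      sm <- stats::convolve(spikes, rev(kern), type = "open")
      lam <- lam + sm[(half + 1):(half + L)]
    }
    sig[[ch]] <- as.numeric(rpois(L, pmax(lam, 0)))
    mp <- rep(1, L)
    if (n_low_patches > 0) {
      at <- floor(seq(L * 0.1, L * 0.9, length.out = n_low_patches))
      lev <- rep(c(0.3, 0.75), length.out = n_low_patches)
      for (k in seq_along(at)) {
        idx <- at[k]:(min(L, at[k] + patch_width - 1L))
        mp[idx] <- lev[k]
      }
    }
    mapp[[ch]] <- mp
  }
  list(signal = suppressMessages(coverage_track(sig, assay = "medip")),
       mappability = suppressMessages(
         coverage_track(mapp, assay = "mappability", library_total = 1)))
}

#' Write a simulated genome to disk in standard formats
#'
#' Emits the annotation as GTF, RNA and H3K36me3 tracks as bedGraph,
#' methylomes as CpG TSVs, truth tables as BED/TSV and the configuration as
#' JSON. Everything re-parses through the package's readers.
#'
#' @param sim a [simulate_genome()] result
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$genes, file.path(dir, "annotation.gtf"))
  for (ct in names(sim$rna)) {
    write_coverage(sim$rna[[ct]], file.path(dir, sprintf("rna_%s.bedGraph", ct)))
    write_coverage(sim$h3k36me3[[ct]],
                   file.path(dir, sprintf("h3k36me3_%s.bedGraph", ct)))
    write_methylome(sim$methylomes[[ct]],
                    file.path(dir, sprintf("wgbs_%s.tsv", ct)))
  }
  tr <- sim$truth
  if (nrow(tr$umrs))
    write_bed(tr$umrs[, .(chrom, start, end, name = umr_id, score = 0,
                          strand = ".")],
              file.path(dir, "truth_umrs.bed"))
  data.table::fwrite(tr$de_genes, file.path(dir, "truth_de_genes.tsv"), sep = "\t")
  data.table::fwrite(tr$cassette_exons, file.path(dir, "truth_cassette_exons.tsv"),
                     sep = "\t")
  data.table::fwrite(tr$retained_introns,
                     file.path(dir, "truth_retained_introns.tsv"), sep = "\t")
  data.table::fwrite(sim$junctions, file.path(dir, "junctions.tsv"), sep = "\t")
  cfg <- sim$config
  jsonlite::write_json(cfg[setdiff(names(cfg), character(0))],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
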