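#' Default pipeline thresholds
#'
#' All stage thresholds in one inspectable place. Defaults are the study
#' values: DE FDR 0.015 with minimal RPKM 0.005 and minimal read count 25;
#' isoform bands 10% / 1% of gene RPKM; intron-retention rules RPKM > 1,
#' > 5% of gene RPKM, coverage ratio > 0.30, breadth >= 0.90; UMR region
#' p < 0.0005; MeDIP classes at 0.35 / 0.8; proximal/distal TSS windows
#' 2 kb / 20 kb; boundary profiles 200 bp in 20-bp bins.
#'
#' @return named list of thresholds
#' @export
pipeline_defaults <- function() {
  list(fdr = 0.015, min_rpkm = 0.005, min_reads = 25,
       isoform_expressed_min = 0.10, isoform_silent_max = 0.01,
       junction_rpkm_threshold = 0.1,
       min_intron_rpkm = 1, gene_frac = 0.05, cov_ratio = 0.30,
       min_breadth = 0.90, cov_ratio_mode = "mean",
       umr_p = 0.0005, umr_min_cpgs = 4, umr_merge_gap = 500,
       umr_cpg_alpha = 0.05, umr_max_fraction = 0.25,
       medip_hypo = 0.35, medip_hyper = 0.8, medip_min_mappability = 0.5,
       proximal_bp = 2000, distal_bp = 20000,
       profile_window = 200, profile_bin = 20,
       entropy_h_max = 1, entropy_expr_min = 1, entropy_slope = 0.25,
       read_length = 75, top_exon_fraction = 0.005,
       mito_chrom = "MT", n_permutations = 1000)
}

.stage_counts <- function(results) {
  cnt <- function(x) if (is.null(x)) 0L else if (is.data.frame(x)) nrow(x)
    else if (is.list(x)) sum(vapply(x, cnt, integer(1))) else length(x)
  vapply(results, cnt, integer(1))
}

#' Run the full analysis pipeline on a (simulated) data bundle
#'
#' Executes the stages in dependency order on the first two cell types:
#' normalization and quantification per cell type; gene- and exon-level
#' differential expression; isoform (cassette exon) calls with junction
#' support; intron retention per cell type with the cell-type-specificity
#' partition; entropy scores and the 2-D specificity threshold on the gene
#' RPKM matrix over all cell types; UMR detection per cell type; UMR-gene
#' links with the directionality summary; and the exon-boundary methylation
#' profile. Returns the result bundle plus a provenance manifest (config
#' hash, package version, per-stage row counts).
#'
#' @param sim a [simulate_genome()] bundle (or `NULL` to simulate `config`)
#' @param config a [sim_config()], used when `sim` is `NULL`
#' @param params threshold list, see [pipeline_defaults()]
#' @param stages character vector of stages to run (subset of the default);
#'   methylome-dependent stages are skipped with a notice when no methylome
#'   is present
#' @return list of class `pipeline_run` with `results`, `manifest`, `sim`
#' @export
run_pipeline <- function(sim = NULL, config = sim_config(),
                         params = pipeline_defaults(),
                         stages = c("quant", "de", "isoform", "retention",
                                    "entropy", "umr", "regnet", "profile")) {
  if (is.null(sim)) sim <- simulate_genome(config)
  cts <- names(sim$rna)
  ctA <- cts[1]; ctB <- cts[2]
  gm <- sim$genes
  res <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  have_meth <- length(sim$methylomes) > 0

  if ("quant" %in% stages) {
    res$norm <- run_stage("quant", function()
      lapply(sim$rna, compute_normalization, gm = gm,
             mito_chrom = params$mito_chrom,
             read_length = params$read_length,
             top_exon_fraction = params$top_exon_fraction))
    res$expr <- run_stage("quant", function()
      lapply(cts, function(ct) quantify(sim$rna[[ct]], gm, res$norm[[ct]])))
    names(res$expr) <- cts
  }
  if ("de" %in% stages) {
    res$de_genes <- run_stage("de", function()
      de_call(res$expr[[ctA]], res$expr[[ctB]],
              res$norm[[ctA]]$total_included_reads,
              res$norm[[ctB]]$total_included_reads, "gene",
              fdr = params$fdr, min_rpkm = params$min_rpkm,
              min_reads = params$min_reads))
    res$de_exons <- run_stage("de", function()
      de_call(res$expr[[ctA]], res$expr[[ctB]],
              res$norm[[ctA]]$total_included_reads,
              res$norm[[ctB]]$total_included_reads, "exon",
              fdr = params$fdr, min_rpkm = params$min_rpkm,
              min_reads = params$min_reads))
  }
  if ("isoform" %in% stages) {
    res$isoforms <- run_stage("isoform", function() {
      calls <- isoform_call(res$expr[[ctA]], res$expr[[ctB]],
                            res$de_exons, res$de_genes,
                            expressed_min = params$isoform_expressed_min,
                            silent_max = params$isoform_silent_max)
      if (nrow(sim$junctions)) {
        ja <- junction_rpkm(sim$junctions[cell_type == ctA], res$norm[[ctA]])
        jb <- junction_rpkm(sim$junctions[cell_type == ctB], res$norm[[ctB]])
        calls <- junction_support(calls, ja, jb,
                                  threshold = params$junction_rpkm_threshold)
      }
      calls
    })
  }
  if ("retention" %in% stages) {
    flags <- flag_opposite_strand_introns(gm)
    res$retention <- run_stage("retention", function() {
      out <- lapply(cts, function(ct)
        call_retained_introns(res$expr[[ct]], gm, flags,
                              min_intron_rpkm = params$min_intron_rpkm,
                              gene_frac = params$gene_frac,
                              cov_ratio = params$cov_ratio,
                              min_breadth = params$min_breadth,
                              cov_ratio_mode = params$cov_ratio_mode,
                              cell_type = ct))
      names(out) <- cts
      out
    })
    res$retention_partition <- specificity_partition(res$retention)
  }
  if ("entropy" %in% stages) {
    res$entropy <- run_stage("entropy", function() {
      gene_ids <- data.table::as.data.table(res$expr[[ctA]])[type == "gene",
                                                             feature_id]
      mat <- sapply(cts, function(ct) {
        e <- data.table::as.data.table(res$expr[[ct]])[type == "gene"]
        e[match(gene_ids, feature_id), rpkm]
      })
      rownames(mat) <- gene_ids
      es <- entropy_scores(mat)
      list(scores = es,
           specific = specificity_threshold(
             es, h_max = params$entropy_h_max,
             expr_min = params$entropy_expr_min,
             slope = params$entropy_slope))
    })
  }
  if ("umr" %in% stages) {
    if (!have_meth) {
      message("no methylome supplied; UMR/regnet/profile stages skipped")
    } else {
      res$umrs <- run_stage("umr", function() {
        out <- lapply(sim$methylomes, call_umrs,
                      p_cutoff = params$umr_p,
                      min_cpgs = params$umr_min_cpgs,
                      merge_gap = params$umr_merge_gap,
                      cpg_alpha = params$umr_cpg_alpha,
                      max_fraction = params$umr_max_fraction)
        out
      })
    }
  }
  if ("regnet" %in% stages && have_meth && !is.null(res$umrs)) {
    res$regnet <- run_stage("regnet", function() {
      spec <- specific_umrs(res$umrs[[ctA]], res$umrs[[ctB]])
      uA <- data.table::copy(data.table::as.data.table(spec$A))[, cell_type := ctA]
      uB <- data.table::copy(data.table::as.data.table(spec$B))[, cell_type := ctB]
      u <- rbind(uA, uB)
      u[, umr_id := sprintf("%s_%d", cell_type, seq_len(.N)), by = cell_type]
      link_umrs_to_genes(u, gm, res$de_genes, ctA, ctB,
                         proximal_bp = params$proximal_bp,
                         distal_bp = params$distal_bp)
    })
  }
  if ("profile" %in% stages && have_meth) {
    res$boundary_profile <- run_stage("profile", function() {
      ex <- gm$exons
      expressed <- lapply(c(ctA, ctB), function(ct) {
        e <- data.table::as.data.table(res$expr[[ct]])[type == "exon"]
        e[rpkm > 0.1, feature_id]
      })
      grp <- data.table::fcase(
        ex$exon_id %in% expressed[[1]] & ex$exon_id %in% expressed[[2]],
        "expressed_both",
        ex$exon_id %in% expressed[[1]], paste0(ctA, "_specific"),
        ex$exon_id %in% expressed[[2]], paste0(ctB, "_specific"),
        default = "not_expressed")
      # 5' exon boundary junctions, strand-oriented
      feats <- data.table::data.table(
        chrom = ex$chrom,
        pos = ifelse(ex$strand == "-", ex$end, ex$start),
        strand = ex$strand, group = grp)
      boundary_profile(sim$methylomes[[ctA]], feats,
                       window = params$profile_window,
                       bin = params$profile_bin)
    })
  }

  cfg_json <- jsonlite::toJSON(sim$config[order(names(sim$config))],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("epicell")),
    config_hash = unname(tools::md5sum(tmp)),
    rng_seed = sim$config$rng_seed,
    stage_rows = as.list(.stage_counts(res)))
  unlink(tmp)
  structure(list(results = res, manifest = manifest, sim = sim),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (seed", x$manifest$rng_seed, ")\n")
  for (nm in names(x$manifest$stage_rows))
    cat(sprintf("  %-20s %d rows\n", nm, x$manifest$stage_rows[[nm]]))
  invisible(x)
}

#' Write the main pipeline outputs as TSV files
#'
#' @param run a [run_pipeline()] result
#' @param dir output directory (created if absent)
#' @return named vector of row counts per written table
#' @export
write_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- run$results
  counts <- c()
  wr <- function(x, name) {
    if (is.null(x)) return()
    data.table::fwrite(data.table::as.data.table(x),
                       file.path(dir, paste0(name, ".tsv")), sep = "\t")
    counts[[name]] <<- nrow(x)
  }
  wr(res$de_genes, "de_genes")
  wr(res$de_exons, "de_exons")
  wr(res$isoforms, "isoforms")
  for (ct in names(res$retention)) wr(res$retention[[ct]],
                                      paste0("retention_", ct))
  for (ct in names(res$umrs)) wr(res$umrs[[ct]], paste0("umrs_", ct))
  if (!is.null(res$regnet)) {
    wr(res$regnet$links, "umr_gene_links")
    wr(res$regnet$directionality, "directionality")
  }
  wr(res$boundary_profile, "boundary_profile")
  if (!is.null(res$entropy)) wr(res$entropy$specific, "specific_features")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  counts
}
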