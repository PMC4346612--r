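#' @import data.table
#' @importFrom stats pbinom pchisq phyper p.adjust quantile rbinom rlnorm
#'   rpois runif rbeta setNames weighted.mean dist hclust cutree t.test
#'   cor dnorm sd median complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.chk <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Strip a UCSC-style "chr" prefix from chromosome names
#'
#' Chromosome names are normalized to the Ensembl dialect (no prefix)
#' internally; writers can restore the prefix.
#'
#' @param x character vector of chromosome names
#' @return character vector without the "chr" prefix
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

.restore_chrom <- function(x, use_chr_prefix = FALSE) {
  if (use_chr_prefix) paste0("chr", x) else x
}

# deterministic child seed from a parent seed and a stream label
.child_seed <- function(seed, stream) {
  (as.integer(seed) * 1000003L + sum(utf8ToInt(stream)) * 7919L) %% 2147483647L
}
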