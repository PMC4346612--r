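#' Entropy-based cell-type specificity scores
#'
#' For each feature (gene, miRNA, lincRNA, ...) with expression `E_i` across
#' `N` cell types, the expression fractions are `F_i = E_i / sum(E)`, the
#' entropy is `H = -sum(F_i * log2(F_i))` (with `0 * log2(0) := 0`) and the
#' per-type specificity is `Q_i = H - log2(F_i)`. `H ~ 0` marks expression
#' confined to one cell type; `H ~ log2(N)` marks uniform expression.
#' Features with zero total expression get `H = NA` and are excluded
#' downstream. `Q_i` is `Inf` where `F_i = 0` ("not expressed in this type").
#'
#' @param mat numeric matrix, features x cell types, non-negative, with
#'   row and column names
#' @return an object of class `entropy_scores`: `scores` (data.table with
#'   feature_id, H, max_expr, top_type), `F` and `Q` matrices
#' @export
entropy_scores <- function(mat) {
  mat <- as.matrix(mat)
  .chk(ncol(mat) >= 2, "need at least two cell types")
  if (any(mat < 0)) stop("negative expression value", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%d", seq_len(nrow(mat)))
  tot <- rowSums(mat)
  Fm <- mat / ifelse(tot > 0, tot, NA_real_)
  Hterm <- ifelse(Fm > 0, Fm * log2(Fm), 0)
  H <- -rowSums(Hterm)
  Q <- H - log2(Fm)             # Inf where F == 0
  max_expr <- apply(mat, 1, max)
  top <- colnames(mat)[max.col(mat, ties.method = "first")]
  scores <- data.table::data.table(
    feature_id = rownames(mat), H = H, max_expr = max_expr,
    top_type = ifelse(tot > 0, top, NA_character_))
  structure(list(scores = scores[], F = Fm, Q = Q, n_types = ncol(mat),
                 cell_types = colnames(mat)),
            class = "entropy_scores")
}

#' @export
print.entropy_scores <- function(x, ...) {
  cat(sprintf("entropy_scores: %d features x %d cell types; H in [0, %.3f]\n",
              nrow(x$scores), x$n_types, log2(x$n_types)))
  invisible(x)
}

#' Two-dimensional specificity threshold in (H, max expression)
#'
#' A feature is called cell-type-specific when its maximal expression reaches
#' `expr_min` and its entropy satisfies
#' `H <= h_max + slope * log10(max_expr / expr_min)` — a linear-in-log
#' relaxation encoding that highly expressed features may be allowed a
#' higher entropy. With `slope = 0` this is a rectangular gate. Each passing
#' feature is assigned to its highest-expressing cell type.
#'
#' @param es an [entropy_scores()] object
#' @param h_max entropy cutoff at `max_expr = expr_min` (bits)
#' @param expr_min minimal maximal expression (RPKM / RPM)
#' @param slope extra entropy allowed per decade of expression
#'   (bits / log10 unit)
#' @return data.table of specific features: feature_id, cell_type, H,
#'   max_expr
#' @export
specificity_threshold <- function(es, h_max = 1, expr_min = 1, slope = 0.25) {
  s <- es$scores
  pass <- !is.na(s$H) & s$max_expr >= expr_min &
    s$H <= h_max + slope * log10(s$max_expr / expr_min)
  out <- s[pass, .(feature_id, cell_type = top_type, H, max_expr)]
  data.table::setorder(out, cell_type, -max_expr)
  out[]
}

#' Hierarchically cluster Q profiles of specific features
#'
#' Average-linkage clustering on the Euclidean distance of Q row-vectors,
#' with infinite Q (zero expression fraction) clipped to one bit above the
#' largest finite Q so "absent" renders as the heatmap maximum. Leaf order
#' is deterministic for a fixed input order, and cluster memberships are
#' invariant under row permutation.
#'
#' @param es an [entropy_scores()] object
#' @param features feature ids to cluster (e.g. from
#'   [specificity_threshold()]); defaults to all features with finite H
#' @param clip value replacing infinite Q; `NULL` for max finite + 1
#' @return list with `order` (feature ids in dendrogram order), `hclust`,
#'   and the clipped `Q` matrix
#' @export
cluster_Q <- function(es, features = NULL, clip = NULL) {
  Q <- es$Q
  if (is.null(features))
    features <- rownames(Q)[is.finite(rowSums(es$F)) & !is.na(es$scores$H)]
  .chk(all(features %in% rownames(Q)), "unknown feature id(s)")
  Q <- Q[features, , drop = FALSE]
  if (nrow(Q) == 1)
    return(list(order = rownames(Q), hclust = NULL, Q = Q))
  fin <- Q[is.finite(Q)]
  clip <- clip %||% (if (length(fin)) max(fin) + 1 else 1)
  Q[!is.finite(Q)] <- clip
  hc <- hclust(dist(Q), method = "average")
  list(order = rownames(Q)[hc$order], hclust = hc, Q = Q)
}
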