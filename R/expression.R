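# Expression tiering and tissue-induction flagging over a probeset-by-tissue
# abundance matrix with a gene<->probeset map.

#' Read an expression matrix and gene map
#'
#' @param matrix_path TSV: first column `probeset`, remaining columns one per
#'   tissue, non-negative abundances.
#' @param map_path TSV with columns `gene_id`, `probeset`.
#' @return list with `matrix` (numeric matrix, probesets x tissues) and `map`.
#' @export
read_expression <- function(matrix_path, map_path) {
  df <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "probeset") stop("first column must be 'probeset'")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$probeset
  if (any(mat < 0)) stop("negative abundance values")
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "probeset") %in% names(map))) {
    stop("gene map must have columns gene_id, probeset")
  }
  list(matrix = mat, map = map)
}

#' Collapse a probeset matrix to gene level
#'
#' Genes with several probesets get the mean abundance per tissue.
#'
#' @param mat probeset x tissue matrix.
#' @param map data.frame `gene_id`, `probeset`.
#' @return gene x tissue matrix, rows ordered by gene id.
#' @export
collapse_to_genes <- function(mat, map) {
  map <- map[map$probeset %in% rownames(mat), , drop = FALSE]
  genes <- sort(unique(map$gene_id))
  out <- t(vapply(genes, function(g) {
    ps <- map$probeset[map$gene_id == g]
    colMeans(mat[ps, , drop = FALSE])
  }, numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  out
}

#' Log2-transform an abundance matrix
#'
#' @param mat non-negative matrix.
#' @param pseudocount added before taking log2 (default 1, so 0 maps to 0).
#' @return `log2(mat + pseudocount)`.
#' @export
log2_matrix <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("negative values in expression matrix")
  log2(mat + pseudocount)
}

#' Tier genes by mean log2 abundance
#'
#' Genes are ranked by their mean log2 abundance (ties broken by gene id) and
#' split into `k` tiers of near-equal size (quantile cuts; when sizes cannot
#' be equal, lower tiers receive the extra genes). Tier labels run from
#' `"low"` to `"high"` (`"tier2"`... for k > 3).
#'
#' @param mat gene x tissue abundance matrix (linear scale).
#' @param k number of tiers (default 3).
#' @param pseudocount passed to [log2_matrix()].
#' @return data.frame `gene_id`, `mean_log2`, `tier`, ordered by gene id;
#'   `attr(, "cuts")` holds the boundary mean-log2 values.
#' @export
abundance_tiers <- function(mat, k = 3L, pseudocount = 1) {
  if (k < 2L) stop("k must be >= 2")
  if (nrow(mat) < k) stop("need at least k genes")
  means <- rowMeans(log2_matrix(mat, pseudocount))
  ids <- rownames(mat)
  ord <- order(means, ids)
  n <- length(means)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  labels <- if (k == 3L) c("low", "medium", "high") else
    c("low", paste0("tier", seq_len(k - 2L) + 1L), "high")
  tier <- rep(labels, times = sizes)
  out <- data.frame(gene_id = ids[ord], mean_log2 = means[ord], tier = tier,
                    stringsAsFactors = FALSE)
  cuts <- vapply(cumsum(sizes)[-k], function(i) out$mean_log2[i], numeric(1))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cuts") <- cuts
  out
}

#' Flag genes induced in a target tissue set
#'
#' The induction score is the mean abundance over the target tissues divided
#' by the mean over all other tissues (bounded below by `floor` plus a small
#' epsilon); genes with score >= `fold` are flagged. The score is invariant
#' under rescaling the whole matrix.
#'
#' @param mat gene x tissue abundance matrix (linear scale).
#' @param target_tissues tissue column names defining the induction target.
#' @param fold flagging threshold (default 2).
#' @param floor lower bound for the non-target mean (default 0).
#' @return data.frame `gene_id`, `score`, `flagged`, sorted by descending
#'   score (ties by gene id).
#' @export
tissue_induction <- function(mat, target_tissues, fold = 2, floor = 0) {
  unknown <- setdiff(target_tissues, colnames(mat))
  if (length(unknown) > 0L) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  other <- setdiff(colnames(mat), target_tissues)
  if (length(other) == 0L) stop("no non-target tissues left")
  eps <- 1e-9
  tgt <- rowMeans(mat[, target_tissues, drop = FALSE])
  bg <- pmax(rowMeans(mat[, other, drop = FALSE]), floor + eps)
  score <- tgt / bg
  out <- data.frame(gene_id = rownames(mat), score = score,
                    flagged = score >= fold, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
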