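# Chromosomal distribution and local-duplication calling. Family genes lying
# within a bounded window of adjacent gene models on one chromosome are
# chained into duplication clusters; whole-genome-duplication (WGD) pairs are
# ingested from an externally computed list, never detected here.

#' Find local gene-duplication clusters of a gene family
#'
#' Family genes on the same chromosome whose consecutive members are at most
#' `window` apart in gene-model rank are chained transitively; maximal chains
#' of size >= 2 are reported. A cluster may therefore span more than `window`
#' ranks end to end.
#'
#' @param index gene-order index from [read_gene_order()] /
#'   [build_gene_order()].
#' @param family_ids character vector of family gene ids; every id must be
#'   present in the index.
#' @param window maximal rank distance between consecutive family members
#'   (default 100 adjacent gene models).
#' @return data.frame, one row per cluster, sorted by chromosome then rank:
#'   `cluster_id`, `chromosome`, `rank_min`, `rank_max`, `size`, `members`
#'   (ids joined by `;`, in rank order).
#' @export
find_local_duplications <- function(index, family_ids, window = 100L) {
  missing <- setdiff(family_ids, index$gene_id)
  if (length(missing) > 0L) {
    stop("family ids missing from gene order: ", paste(missing, collapse = ", "))
  }
  fam <- index[index$gene_id %in% family_ids, , drop = FALSE]
  fam <- fam[order(fam$chromosome, fam$rank), , drop = FALSE]
  out <- data.frame(cluster_id = integer(), chromosome = character(),
                    rank_min = integer(), rank_max = integer(),
                    size = integer(), members = character(),
                    stringsAsFactors = FALSE)
  for (chrom in unique(fam$chromosome)) {
    fc <- fam[fam$chromosome == chrom, , drop = FALSE]
    if (nrow(fc) < 2L) next
    gap_ok <- diff(fc$rank) <= window
    runs <- rle(gap_ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      sel <- starts[k]:(ends[k] + 1L)
      out <- rbind(out, data.frame(
        cluster_id = nrow(out) + 1L, chromosome = chrom,
        rank_min = min(fc$rank[sel]), rank_max = max(fc$rank[sel]),
        size = length(sel),
        members = paste(fc$gene_id[sel], collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-chromosome distribution of a gene family
#'
#' @param index gene-order index.
#' @param family_ids family gene ids (must be present in the index).
#' @return list: `counts` (`chromosome`, `n`, `fraction`) and `coords`
#'   (`chromosome`, `start`, `gene_id`, for plotting), both deterministic.
#' @export
chromosome_distribution <- function(index, family_ids) {
  missing <- setdiff(family_ids, index$gene_id)
  if (length(missing) > 0L) {
    stop("family ids missing from gene order: ", paste(missing, collapse = ", "))
  }
  fam <- index[index$gene_id %in% family_ids, , drop = FALSE]
  chroms <- sort(unique(index$chromosome))
  counts <- data.frame(
    chromosome = chroms,
    n = vapply(chroms, function(ch) sum(fam$chromosome == ch), integer(1)),
    stringsAsFactors = FALSE)
  counts$fraction <- if (length(family_ids)) counts$n / length(family_ids) else 0
  rownames(counts) <- NULL
  coords <- fam[order(fam$chromosome, fam$start, fam$gene_id),
                c("chromosome", "start", "gene_id")]
  rownames(coords) <- NULL
  list(counts = counts, coords = coords)
}

#' Load externally computed WGD gene pairs
#'
#' Reads a two-column TSV of paralog pairs (optional third column `source`),
#' filters them to family membership, and — when annotations are supplied —
#' reports motif-architecture concordance (equality of the per-protein finger
#' type strings) for each retained pair.
#'
#' @param path TSV with columns `gene_a`, `gene_b` (optional `source`); a
#'   header row is expected.
#' @param family_ids family gene ids.
#' @param annotations optional annotation data.frame from [annotate_family()].
#' @return data.frame `gene_a`, `gene_b`, `source`, and `concordant` when
#'   annotations are given. Pairs with a non-family member are dropped with a
#'   warning; malformed rows are rejected with a warning.
#' @export
load_wgd_pairs <- function(path, family_ids, annotations = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("WGD pair file must have columns gene_a, gene_b")
  }
  if (is.null(df$source)) df$source <- "external"
  bad <- is.na(df$gene_a) | is.na(df$gene_b) | df$gene_a == "" |
    df$gene_b == "" | df$gene_a == df$gene_b
  if (any(bad)) {
    warning(sprintf("rejected %d malformed WGD pair row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  in_family <- df$gene_a %in% family_ids & df$gene_b %in% family_ids
  if (any(!in_family)) {
    warning(sprintf("dropped %d WGD pair(s) with non-family members",
                    sum(!in_family)))
    df <- df[in_family, , drop = FALSE]
  }
  df <- df[, c("gene_a", "gene_b", "source"), drop = FALSE]
  if (!is.null(annotations) && nrow(df) > 0L) {
    ts <- stats::setNames(annotations$type_string, annotations$protein_id)
    df$concordant <- !is.na(ts[df$gene_a]) & !is.na(ts[df$gene_b]) &
      ts[df$gene_a] == ts[df$gene_b]
  }
  rownames(df) <- NULL
  df
}
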