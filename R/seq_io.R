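#' Read a protein FASTA into a proteome table
#'
#' Loads an amino-acid FASTA, normalizes sequences (uppercase, trailing stop
#' codon `*` stripped) and optionally collapses splice variants to one record
#' per gene. Variant identifiers are recognized as a trailing `.n` suffix on
#' the record id (configurable via `variant_regex`).
#'
#' @param path path to a protein FASTA file.
#' @param variant_policy `"longest_per_gene"` (default) keeps, for each gene,
#'   the longest variant (ties broken by the lexicographically smallest
#'   variant id) and sets the record `id` to the gene id; `"all"` keeps every
#'   record.
#' @param variant_regex regular expression matched against the end of the
#'   record id to strip the splice-variant suffix.
#' @return a `data.frame` with columns `id`, `variant_id`, `gene_id`,
#'   `description`, `sequence`. `id` is unique.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1.1 demo", "MKV", ">g1.2 demo", "MK"), fa)
#' read_proteome(fa)  # one record, the longer variant g1.1
#' @export
read_proteome <- function(path,
                          variant_policy = c("longest_per_gene", "all"),
                          variant_regex = "\\.[0-9]+$") {
  variant_policy <- match.arg(variant_policy)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("not a parseable FASTA file: ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(aa)
  if (any(headers == "" | is.na(headers))) stop("FASTA headers must be non-empty")
  if (anyDuplicated(headers)) stop("duplicate identical FASTA headers")
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence after normalization")
  gene_id <- sub(variant_regex, "", ids)
  out <- data.frame(id = ids, variant_id = ids, gene_id = gene_id,
                    description = desc, sequence = seqs,
                    stringsAsFactors = FALSE)
  if (variant_policy == "longest_per_gene") {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$gene_id), function(i) {
      len <- nchar(out$sequence[i])
      i <- i[len == max(len)]
      i[order(out$variant_id[i])][1L]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    out$id <- out$gene_id
  }
  if (anyDuplicated(out$id)) stop("record ids not unique after variant collapsing")
  rownames(out) <- NULL
  out
}

#' Collapse splice variants of an in-memory proteome
#'
#' Same policy as [read_proteome()] with `longest_per_gene`: keeps, per gene,
#' the longest variant (ties by smallest variant id) and sets `id` to the
#' gene id.
#'
#' @param proteome proteome data.frame with `id`, `sequence` (a `gene_id`
#'   column is derived from `variant_regex` if absent).
#' @param variant_regex suffix pattern identifying splice variants.
#' @return collapsed proteome data.frame.
#' @export
collapse_variants <- function(proteome, variant_regex = "\\.[0-9]+$") {
  if (is.null(proteome$gene_id)) {
    proteome$gene_id <- sub(variant_regex, "", proteome$id)
  }
  keep <- unlist(lapply(split(seq_len(nrow(proteome)), proteome$gene_id),
                        function(i) {
    len <- nchar(proteome$sequence[i])
    i <- i[len == max(len)]
    i[order(proteome$id[i])][1L]
  }), use.names = FALSE)
  out <- proteome[sort(keep), , drop = FALSE]
  out$id <- out$gene_id
  rownames(out) <- NULL
  out
}

#' Write a proteome table to FASTA
#'
#' @param proteome data.frame as returned by [read_proteome()] or
#'   [generate_proteome()] (columns `id`, `sequence`, optional `description`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  hdr <- proteome$id
  if (!is.null(proteome$description)) {
    has <- nzchar(proteome$description)
    hdr[has] <- paste(proteome$id[has], proteome$description[has])
  }
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, hdr))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read gene order from a gene-model table or GFF3
#'
#' Builds a per-chromosome rank index: genes are ordered by ascending start
#' coordinate (ties broken by gene id) and given consecutive 0-based ranks
#' within each chromosome. TSV input needs columns `gene_id`, `chromosome`,
#' `start` (optional `end`, `strand`); GFF3 input (read via rtracklayer) uses
#' rows of type `gene` with the `ID` attribute.
#'
#' @param path TSV or `.gff`/`.gff3` file of gene models.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `rank`;
#'   rows with missing coordinates are rejected and counted in
#'   `attr(, "n_rejected")` with a warning.
#' @export
read_gene_order <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "gene"]
    id <- S4Vectors::mcols(gr)$ID
    if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
    df <- data.frame(gene_id = as.character(id),
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chromosome", "start")
    if (!all(need %in% names(df))) {
      stop("gene-order TSV must have columns: ", paste(need, collapse = ", "))
    }
    df <- df[, intersect(c(need, "end", "strand"), names(df)), drop = FALSE]
  }
  build_gene_order(df)
}

#' Build a gene-order index from an in-memory table
#'
#' @param df data.frame with `gene_id`, `chromosome`, `start`.
#' @return see [read_gene_order()].
#' @export
build_gene_order <- function(df) {
  bad <- is.na(df$start) | is.na(df$chromosome) | is.na(df$gene_id) |
    df$gene_id == ""
  n_rejected <- sum(bad)
  if (n_rejected > 0L) {
    warning(sprintf("rejected %d gene-model row(s) with missing fields", n_rejected))
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  df$rank <- as.integer(stats::ave(df$start, df$chromosome,
                                   FUN = function(x) seq_along(x) - 1L))
  rownames(df) <- NULL
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in gene order")
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Export per-protein annotations and motif/EAR features
#'
#' Writes `annotations.tsv` (one row per protein: id, finger count, type
#' string, EAR count, class labels) and `features.gff3` (one row per motif or
#' EAR site, GFF3-style with 1-based inclusive protein coordinates). Row order
#' is deterministic: id, then start.
#'
#' @param annotations data.frame from [annotate_family()].
#' @param motifs motif data.frame (0-based half-open coordinates).
#' @param ears EAR data.frame (0-based half-open coordinates).
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_annotations <- function(annotations, motifs, ears, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann_path <- file.path(dir, "annotations.tsv")
  feat_path <- file.path(dir, "features.gff3")

  ann <- annotations[order(annotations$protein_id), , drop = FALSE]
  write_tsv_stable(ann, ann_path)

  feat <- rbind(
    if (nrow(motifs)) data.frame(
      seqid = motifs$protein_id, source = "zfpkit", type = "zinc_finger_C2H2",
      start = motifs$start + 1L, end = motifs$end, score = ".", strand = ".",
      phase = ".",
      attributes = sprintf("mtype=%s;subgroup=%s;cys_gap=%d;his_gap=%d",
                           motifs$mtype, ifelse(motifs$subgroup == "", ".",
                                                motifs$subgroup),
                           motifs$cys_gap, motifs$his_gap),
      stringsAsFactors = FALSE) else NULL,
    if (nrow(ears)) data.frame(
      seqid = ears$protein_id, source = "zfpkit", type = "EAR_motif",
      start = ears$start + 1L, end = ears$end, score = ".", strand = ".",
      phase = ".",
      attributes = sprintf("pattern=%s;matched=%s", ears$pattern_id, ears$matched),
      stringsAsFactors = FALSE) else NULL)
  if (is.null(feat)) {
    feat <- data.frame(seqid = character(), source = character(),
                       type = character(), start = integer(), end = integer(),
                       score = character(), strand = character(),
                       phase = character(), attributes = character(),
                       stringsAsFactors = FALSE)
  }
  feat <- feat[order(feat$seqid, feat$start, feat$type), , drop = FALSE]
  con <- file(feat_path, "wb")
  writeLines("##gff-version 3", con)
  writeLines(paste(feat$seqid, feat$source, feat$type, feat$start, feat$end,
                   feat$score, feat$strand, feat$phase, feat$attributes,
                   sep = "\t"), con)
  close(con)
  invisible(c(annotations = ann_path, features = feat_path))
}

#' Re-read a feature file written by [write_annotations()]
#'
#' Returns motif and EAR coordinates converted back to the internal 0-based
#' half-open convention, for round-trip checks and downstream reuse.
#'
#' @param path `features.gff3` path.
#' @return data.frame with `protein_id`, `type`, `start`, `end`, `attributes`.
#' @export
read_motif_features <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), type = character(),
                      start = integer(), end = integer(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(protein_id = vapply(parts, `[[`, "", 1L),
             type = vapply(parts, `[[`, "", 3L),
             start = as.integer(vapply(parts, `[[`, "", 4L)) - 1L,
             end = as.integer(vapply(parts, `[[`, "", 5L)),
             attributes = vapply(parts, `[[`, "", 9L),
             stringsAsFactors = FALSE)
}
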