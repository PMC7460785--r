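# The C2H2 zinc finger is scanned with two fixed-geometry patterns,
#   X2-C-X2-C-X12-H-X{3,5}-H  and  X2-C-X4-C-X12-H-X{3,5}-H,
# i.e. regexes ".{2}C.{2}C.{12}H.{3,5}H" / ".{2}C.{4}C.{12}H.{3,5}H".
# Published mode mirrors default regex-engine semantics (leftmost,
# non-overlapping, greedy inter-His gap) per pattern, then merges the two
# pattern sets, preferring the canonical C-X2-C geometry on overlap.
# Exhaustive mode enumerates every matching window for oracle use.

c2h2_pattern <- function(cys_gap, his_gap = NULL) {
  if (is.null(his_gap)) sprintf(".{2}C.{%d}C.{12}H.{3,5}H", cys_gap)
  else sprintf(".{2}C.{%d}C.{12}H.{%d}H", cys_gap, his_gap)
}

motif_row <- function(protein_id, seq, start0, cys_gap, his_gap) {
  len <- 18L + cys_gap + his_gap
  h1 <- start0 + 16L + cys_gap        # 0-based offset of the first His
  data.frame(protein_id = protein_id,
             start = start0, end = start0 + len,
             sequence = substr(seq, start0 + 1L, start0 + len),
             cys_gap = cys_gap, his_gap = his_gap,
             core6 = substr(seq, h1 - 4L, h1 + 1L),
             inter_his = substr(seq, h1 + 2L, h1 + 1L + his_gap),
             mtype = "unassigned", subgroup = "",
             stringsAsFactors = FALSE)
}

scan_c2h2_one <- function(protein_id, seq, mode) {
  res <- list()
  if (mode == "published") {
    for (cg in c(2L, 4L)) {
      m <- gregexpr(c2h2_pattern(cg), seq, perl = TRUE)[[1]]
      if (m[1L] == -1L) next
      starts0 <- as.integer(m) - 1L
      lens <- attr(m, "match.length")
      for (k in seq_along(starts0)) {
        res[[length(res) + 1L]] <-
          motif_row(protein_id, seq, starts0[k], cg, lens[k] - 18L - cg)
      }
    }
    if (length(res) == 0L) return(empty_motif_df())
    out <- do.call(rbind, res)
    # cross-pattern overlap: drop the C-X4-C call where it overlaps a C-X2-C call
    if (any(out$cys_gap == 2L) && any(out$cys_gap == 4L)) {
      g2 <- out[out$cys_gap == 2L, , drop = FALSE]
      keep4 <- vapply(which(out$cys_gap == 4L), function(i) {
        !any(out$start[i] < g2$end & g2$start < out$end[i])
      }, logical(1))
      out <- rbind(g2, out[out$cys_gap == 4L, , drop = FALSE][keep4, , drop = FALSE])
    }
  } else {
    # exhaustive: every window satisfying either pattern, overlaps allowed
    n <- nchar(seq)
    for (cg in c(2L, 4L)) for (hg in c(3L, 4L, 5L)) {
      len <- 18L + cg + hg
      if (n < len) next
      pat <- sprintf("(?=(%s))", c2h2_pattern(cg, hg))
      m <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (m[1L] == -1L) next
      for (s0 in as.integer(m) - 1L) {
        res[[length(res) + 1L]] <- motif_row(protein_id, seq, s0, cg, hg)
      }
    }
    if (length(res) == 0L) return(empty_motif_df())
    out <- do.call(rbind, res)
  }
  out <- out[order(out$start, out$cys_gap, out$his_gap), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan protein sequences for C2H2 zinc finger motifs
#'
#' @param proteome a proteome data.frame (columns `id`, `sequence`) or a
#'   single-row record.
#' @param mode `"published"` — per pattern, leftmost non-overlapping matches
#'   with a greedy inter-His gap; the two pattern sets are merged and, where a
#'   `cys_gap = 2` and a `cys_gap = 4` call overlap, the `cys_gap = 2` call is
#'   kept. `"exhaustive"` — every window satisfying either pattern (overlaps
#'   allowed), intended as an oracle superset.
#' @return motif data.frame: `protein_id`, `start`, `end` (0-based half-open
#'   protein coordinates), `sequence`, `cys_gap`, `his_gap`, `core6` (the six
#'   residues ending at the first His), `inter_his` (residues between the two
#'   His), `mtype = "unassigned"`, `subgroup = ""`.
#' @examples
#' p <- data.frame(id = "demo", sequence = "MAAYKCPDCGASFSRSQALGGHQNAHRRAA")
#' scan_c2h2(p)
#' @export
scan_c2h2 <- function(proteome, mode = c("published", "exhaustive")) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(proteome)), function(i) {
    scan_c2h2_one(proteome$id[i], proteome$sequence[i], mode)
  })
  out <- do.call(rbind, c(list(empty_motif_df()), out))
  rownames(out) <- NULL
  out
}

#' Scan protein sequences for EAR repression motifs
#'
#' Default patterns are the two canonical EAR classes, `LxLxL` and `DLNxxP`
#' (`L`/`D`/`N`/`P` positions exact, `x` any residue). Each pattern is scanned
#' independently (leftmost, non-overlapping); results are merged and sorted by
#' start.
#'
#' @param proteome proteome data.frame (columns `id`, `sequence`).
#' @param patterns named character vector of regex patterns.
#' @return data.frame: `protein_id`, `start`, `end` (0-based half-open),
#'   `pattern_id`, `matched`.
#' @examples
#' scan_ear(data.frame(id = "p", sequence = "AADLNTTPAAGLKLHLK"))
#' @export
scan_ear <- function(proteome, patterns = c(LxLxL = "L.L.L", DLNxxP = "DLN..P")) {
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    seq <- proteome$sequence[i]
    for (pid in names(patterns)) {
      m <- gregexpr(patterns[[pid]], seq, perl = TRUE)[[1]]
      if (m[1L] == -1L) next
      starts0 <- as.integer(m) - 1L
      lens <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = proteome$id[i], start = starts0, end = starts0 + lens,
        pattern_id = pid,
        matched = substring(seq, starts0 + 1L, starts0 + lens),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(empty_ear_df()), rows))
  out <- out[order(out$protein_id, out$start, out$pattern_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply an external confirmation keep/drop list to motif calls
#'
#' The confirmation scan itself (PROSITE/PFAM-style profile matching) is an
#' external step; this ingests its verdicts. Proteins marked `drop` are
#' removed; ids in the list that are absent from the calls produce a warning
#' and are ignored. With no list the calls pass through unchanged.
#'
#' @param motifs motif data.frame from [scan_c2h2()].
#' @param keep_drop `NULL`, or a data.frame with columns `id` and `decision`
#'   (`"keep"`/`"drop"`).
#' @return filtered motif data.frame; the number of dropped proteins is
#'   reported via `message()` and in `attr(, "n_dropped")`.
#' @export
attach_confirmation <- function(motifs, keep_drop = NULL) {
  if (is.null(keep_drop)) {
    attr(motifs, "n_dropped") <- 0L
    return(motifs)
  }
  stopifnot(all(c("id", "decision") %in% names(keep_drop)))
  unknown <- setdiff(keep_drop$id, motifs$protein_id)
  if (length(unknown) > 0L) {
    warning(sprintf("%d keep/drop id(s) not among motif calls; ignored",
                    length(unknown)))
  }
  drop_ids <- keep_drop$id[keep_drop$decision == "drop"]
  drop_ids <- intersect(drop_ids, motifs$protein_id)
  out <- motifs[!(motifs$protein_id %in% drop_ids), , drop = FALSE]
  message(sprintf("confirmation filter dropped %d protein(s)", length(drop_ids)))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(drop_ids)
  out
}
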