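# Per-protein aggregation: finger-count classes, tandem arrays (maximal runs
# of fingers whose inter-motif linkers are shorter than a threshold; the
# operational rule is linker < 11 residues), and EAR-arrangement classes for
# single-finger proteins.

#' Call tandem arrays among the motifs of one protein
#'
#' The linker is the number of residues strictly between two consecutive
#' motifs (next start minus previous end in 0-based half-open coordinates).
#' Maximal runs in which every consecutive linker is `< threshold` and that
#' contain at least two motifs are reported.
#'
#' @param motifs motif data.frame for a single protein, sorted by start,
#'   non-overlapping (overlap is a scanner-contract violation and errors).
#' @param threshold linker threshold (default 11: arrays are fingers linked
#'   by fewer than 11 residues).
#' @return data.frame with one row per array: `array_id`, `first`, `last`
#'   (member indices into `motifs`), `size`, `linkers` (comma-joined).
#' @export
call_tandem_arrays <- function(motifs, threshold = 11L) {
  empty <- data.frame(array_id = integer(), first = integer(), last = integer(),
                      size = integer(), linkers = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(motifs)
  if (n < 2L) return(empty)
  if (is.unsorted(motifs$start)) motifs <- motifs[order(motifs$start), , drop = FALSE]
  linkers <- motifs$start[-1L] - motifs$end[-n]
  if (any(linkers < 0L)) stop("overlapping motifs: scanner contract violated")
  tandem <- linkers < threshold
  runs <- rle(tandem)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- empty
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    first <- starts[k]; last <- ends[k] + 1L   # linker i joins motifs i, i+1
    out <- rbind(out, data.frame(
      array_id = nrow(out) + 1L, first = first, last = last,
      size = last - first + 1L,
      linkers = paste(linkers[starts[k]:ends[k]], collapse = ","),
      stringsAsFactors = FALSE))
  }
  out
}

count_class_label <- function(n) {
  lab <- c(`1` = "single", `2` = "two", `3` = "three", `4` = "four",
           `5` = "five", `6` = "six", `9` = "nine")
  key <- as.character(n)
  if (key %in% names(lab)) unname(lab[key]) else sprintf("other-%d", n)
}

midpoint <- function(start, end) (start + end) / 2

arrangement_label <- function(n_motifs, motifs, ears) {
  if (nrow(ears) == 0L) return("not_applicable")
  fm <- midpoint(motifs$start, motifs$end)
  em <- midpoint(ears$start, ears$end)
  if (n_motifs == 1L) {
    if (nrow(ears) == 1L) {
      return(if (em > fm) "C2H2_then_EAR" else "EAR_then_C2H2")
    }
    if (nrow(ears) == 2L) {
      if (min(em) < fm && fm < max(em)) return("C2H2_between_EARs")
      return("EARs_flanking_other")
    }
    return("mixed")
  }
  # multi-finger: only all-one-side layouts get a directional label
  if (all(sapply(em, function(e) all(e > fm)))) return("C2H2_then_EAR")
  if (all(sapply(em, function(e) all(e < fm)))) return("EAR_then_C2H2")
  "not_applicable"
}

#' Classify the motif/EAR architecture of one protein
#'
#' @param protein_id protein identifier.
#' @param motifs motif rows for this protein.
#' @param ears EAR rows for this protein.
#' @param tandem_threshold linker threshold for [call_tandem_arrays()].
#' @return one-row data.frame: `protein_id`, `n_motifs`, `count_class`,
#'   `n_ears`, `ear_class` (`no_EAR` / `one_EAR` / `multi_EAR`),
#'   `array_class` (`single_finger` / `has_tandem` / `no_tandem`),
#'   `arrangement`, `type_string` (finger types joined by `-`),
#'   `ear_in_finger` (an EAR overlapping a finger, reported as a flag, not an
#'   arrangement class), `n_arrays`. The tandem-array table is attached as
#'   `attr(, "arrays")`.
#' @export
classify_architecture <- function(protein_id, motifs, ears,
                                  tandem_threshold = 11L) {
  motifs <- motifs[order(motifs$start), , drop = FALSE]
  ears <- ears[order(ears$start), , drop = FALSE]
  n <- nrow(motifs)
  arrays <- call_tandem_arrays(motifs, tandem_threshold)
  ear_class <- if (nrow(ears) == 0L) "no_EAR" else if (nrow(ears) == 1L) "one_EAR" else "multi_EAR"
  array_class <- if (n <= 1L) "single_finger" else if (nrow(arrays) > 0L) "has_tandem" else "no_tandem"
  overlap <- FALSE
  if (n > 0L && nrow(ears) > 0L) {
    for (i in seq_len(nrow(ears))) {
      overlap <- overlap || any(ears$start[i] < motifs$end & motifs$start < ears$end[i])
    }
  }
  out <- data.frame(
    protein_id = protein_id, n_motifs = n,
    count_class = count_class_label(n), n_ears = nrow(ears),
    ear_class = ear_class, array_class = array_class,
    arrangement = if (n == 0L) "not_applicable" else arrangement_label(n, motifs, ears),
    type_string = paste(motifs$mtype, collapse = "-"),
    ear_in_finger = overlap, n_arrays = nrow(arrays),
    stringsAsFactors = FALSE)
  attr(out, "arrays") <- arrays
  out
}

#' Annotate every protein that carries at least one motif
#'
#' @param motifs typed motif data.frame (all proteins).
#' @param ears EAR data.frame (all proteins).
#' @param tandem_threshold linker threshold.
#' @return list with `annotations` (one row per protein, ordered by id) and
#'   `arrays` (long table: `protein_id`, `array_id`, `first`, `last`, `size`,
#'   `linkers`).
#' @export
annotate_family <- function(motifs, ears, tandem_threshold = 11L) {
  ids <- sort(unique(motifs$protein_id))
  ann <- list(); arr <- list()
  for (id in ids) {
    a <- classify_architecture(id,
                               motifs[motifs$protein_id == id, , drop = FALSE],
                               ears[ears$protein_id == id, , drop = FALSE],
                               tandem_threshold)
    ann[[length(ann) + 1L]] <- a
    ar <- attr(a, "arrays")
    if (nrow(ar) > 0L) {
      ar <- cbind(protein_id = id, ar, stringsAsFactors = FALSE)
      arr[[length(arr) + 1L]] <- ar
    }
  }
  annotations <- do.call(rbind, c(list(
    data.frame(protein_id = character(), n_motifs = integer(),
               count_class = character(), n_ears = integer(),
               ear_class = character(), array_class = character(),
               arrangement = character(), type_string = character(),
               ear_in_finger = logical(), n_arrays = integer(),
               stringsAsFactors = FALSE)), ann))
  arrays <- if (length(arr)) do.call(rbind, arr) else
    data.frame(protein_id = character(), array_id = integer(),
               first = integer(), last = integer(), size = integer(),
               linkers = character(), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  rownames(arrays) <- NULL
  list(annotations = annotations, arrays = arrays)
}

#' Summarize a family of annotated ZFPs
#'
#' @param annotations annotation data.frame from [annotate_family()].
#' @return list: `count_class` table (with `n`), `fraction_single`,
#'   `single_ear` (EAR classes within single-finger proteins), `multi_tandem`
#'   (tandem vs non-tandem within multi-finger proteins).
#' @export
family_summary <- function(annotations) {
  classes <- c("single", "two", "three", "four", "five", "six", "nine")
  classes <- c(classes, sort(setdiff(unique(annotations$count_class), classes)))
  count_class <- data.frame(
    count_class = classes,
    n = vapply(classes, function(cl) sum(annotations$count_class == cl),
               integer(1)),
    stringsAsFactors = FALSE)
  rownames(count_class) <- NULL
  singles <- annotations[annotations$count_class == "single", , drop = FALSE]
  single_ear <- data.frame(
    ear_class = c("no_EAR", "one_EAR", "multi_EAR"),
    n = vapply(c("no_EAR", "one_EAR", "multi_EAR"),
               function(cl) sum(singles$ear_class == cl), integer(1)),
    stringsAsFactors = FALSE)
  rownames(single_ear) <- NULL
  multi <- annotations[annotations$n_motifs > 1L, , drop = FALSE]
  multi_tandem <- data.frame(
    array_class = c("has_tandem", "no_tandem"),
    n = vapply(c("has_tandem", "no_tandem"),
               function(cl) sum(multi$array_class == cl), integer(1)),
    stringsAsFactors = FALSE)
  rownames(multi_tandem) <- NULL
  list(count_class = count_class,
       fraction_single = if (nrow(annotations)) nrow(singles) / nrow(annotations) else 0,
       single_ear = single_ear, multi_tandem = multi_tandem)
}

#' Produce a deterministic diagram layout for one protein
#'
#' Returns the rectangles a motif-architecture figure would draw: one row per
#' feature with protein coordinates and the drawing convention (C2H2 black,
#' EAR red) recorded in the metadata attribute.
#'
#' @param protein_id protein identifier.
#' @param protein_length protein length (residues).
#' @param motifs,ears feature rows for this protein.
#' @return data.frame `feature`, `start`, `end`, `color`, ordered by start
#'   then feature; `attr(, "metadata")` holds `protein_id`, `protein_length`
#'   and the color convention.
#' @export
render_architecture <- function(protein_id, protein_length, motifs, ears) {
  feats <- rbind(
    if (nrow(motifs)) data.frame(feature = "C2H2", start = motifs$start,
                                 end = motifs$end, color = "black",
                                 stringsAsFactors = FALSE) else NULL,
    if (nrow(ears)) data.frame(feature = "EAR", start = ears$start,
                               end = ears$end, color = "red",
                               stringsAsFactors = FALSE) else NULL)
  if (is.null(feats)) {
    feats <- data.frame(feature = character(), start = integer(),
                        end = integer(), color = character(),
                        stringsAsFactors = FALSE)
  }
  feats <- feats[order(feats$start, feats$feature), , drop = FALSE]
  rownames(feats) <- NULL
  attr(feats, "metadata") <- list(protein_id = protein_id,
                                  protein_length = protein_length,
                                  convention = c(C2H2 = "black", EAR = "red"))
  feats
}
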