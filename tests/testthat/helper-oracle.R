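# Independent character-by-character validator and brute-force window
# enumerator for the C2H2 pattern, used as oracles against the scanner.

oracle_is_c2h2 <- function(seq, s0, cys_gap, his_gap) {
  len <- 18L + cys_gap + his_gap
  if (s0 + len > nchar(seq)) return(FALSE)
  ch <- strsplit(substr(seq, s0 + 1L, s0 + len), "")[[1]]
  ch[3L] == "C" &&
    ch[4L + cys_gap] == "C" &&
    ch[17L + cys_gap] == "H" &&
    ch[18L + cys_gap + his_gap] == "H"
}

# Enumerate every window satisfying either pattern (any start, cys gap 2/4,
# His gap 3-5), by brute force.
oracle_find_all <- function(seq) {
  hits <- list()
  for (s0 in 0:(nchar(seq) - 1L)) {
    for (cg in c(2L, 4L)) for (hg in c(3L, 4L, 5L)) {
      if (oracle_is_c2h2(seq, s0, cg, hg)) {
        hits[[length(hits) + 1L]] <-
          data.frame(start = s0, end = s0 + 18L + cg + hg,
                     cys_gap = cg, his_gap = hg)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      cys_gap = integer(), his_gap = integer()))
  }
  do.call(rbind, hits)
}

random_aa_seq <- function(n, alphabet = c("A", "C", "D", "E", "G", "H", "K",
                                          "L", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Build a 23-mer motif test row without going through the scanner.
mk_motif <- function(core6 = "QALGGH", inter = "QNA", his_gap = 3L,
                     sequence = NULL, protein_id = "p1", start = 0L) {
  if (is.null(sequence)) {
    stopifnot(nchar(core6) == 6L, substr(core6, 6, 6) == "H")
    sequence <- paste0("AK", "C", "PE", "C", "GASFSRS",
                       substr(core6, 1, 5), "H", inter, "H")
  }
  data.frame(protein_id = protein_id, start = start,
             end = start + nchar(sequence), sequence = sequence,
             cys_gap = 2L, his_gap = his_gap, core6 = core6,
             inter_his = inter, mtype = "unassigned", subgroup = "",
             stringsAsFactors = FALSE)
}

# Cached study-scale fixture shared across test files.
.fixture_env <- new.env(parent = emptyenv())
study_fixture <- function(seed = 7L) {
  key <- paste0("seed", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- synthetic_spec(seed = seed)
    pr <- generate_proteome(spec)
    prot <- collapse_variants(pr$proteome)
    candidates <- scan_c2h2(prot)
    confirmed <- suppressMessages(attach_confirmation(candidates, pr$truth$keep_drop))
    motifs <- rbind(confirmed, scan_c2h2(pr$appended))
    cls <- classify_all(motifs)
    family <- rbind(
      prot[prot$id %in% motifs$protein_id,
           c("id", "gene_id", "description", "sequence")],
      pr$appended[, c("id", "gene_id", "description", "sequence")])
    ears <- scan_ear(family)
    ann <- annotate_family(cls$motifs, ears)
    .fixture_env[[key]] <- list(spec = spec, pr = pr, proteome = prot,
                                candidates = candidates, motifs = cls$motifs,
                                cls = cls, family = family, ears = ears,
                                ann = ann)
  }
  .fixture_env[[key]]
}
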