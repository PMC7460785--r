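# Synthetic proteomes, gene orders and expression matrices with planted,
# labelled ground truth. The default ("study-scale") plan mirrors the family
# structure reported for the M. truncatula C2H2 ZFP family: 272 scan
# candidates of which 55 are marked for confirmation-drop, leaving 217
# proteins carrying 328 fingers, plus a nine-finger TFIIIA-like record
# appended after confirmation (218 proteins / 337 fingers); finger types
# 93 Q (Q1..Q6 = 28/22/12/10/10/11), 57 QM, 19 IDD, 41 Z (8 subgroups),
# 127 C; finger-count classes 151/38/16/9/1/2/1; 15 tandem-array proteins;
# 46 local-duplication clusters over 8 chromosomes (59 family genes on
# chromosome 1); 119 genes with expression probesets, 14 nodule-induced.
#
# Flanks and linkers are drawn from an alphabet excluding C and H (so planted
# fingers are the only scanner matches) and additionally excluding L (so
# planted EAR sites are the only LxLxL/DLNxxP matches).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
CLEAN_ALPHABET <- setdiff(AA20, c("C", "H", "L"))

Q_INTERHIS <- list(Q1 = "QNA", Q2 = c("KAS", "RAS"), Q3 = c("MRR", "MRK"),
                   Q4 = c("MNI", "MNV"), Q5 = c("KRC", "KRS"))

# Nine QM core signatures: "QALGG" modified at 1-2 of the five pre-His
# positions (no C/H introduced).
QM_CORES <- c("RALGG", "QGLGG", "QAMGG", "QALSG", "QALGA",
              "RGLGG", "KALGA", "QTLSG", "QAVGA")

qm_truth_label <- function(core5) {
  ref <- strsplit("QALGG", "")[[1]]
  got <- strsplit(core5, "")[[1]]
  mism <- which(got != ref)
  paste(sprintf("P%d:%s", mism, got[mism]), collapse = ",")
}

sample_c_core <- function(alphabet, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    core5 <- random_residues(5L, alphabet)
    if (hamming(core5, "QALGG") >= 3L) return(core5)
  }
  stop("could not sample a C-type core distinct from the Q/QM rules")
}

sample_q6_interhis <- function(alphabet, max_tries = 100L) {
  banned <- unlist(Q_INTERHIS, use.names = FALSE)
  for (i in seq_len(max_tries)) {
    tri <- random_residues(3L, alphabet)
    if (!(tri %in% c(banned, "QNA"))) return(tri)
  }
  stop("could not sample a non-consensus inter-His triplet")
}

make_ear_seq <- function(pattern, alphabet) {
  xs <- setdiff(alphabet, c("L", "D", "N", "P"))
  if (pattern == "LxLxL") {
    paste0("L", sample(xs, 1), "L", sample(xs, 1), "L")
  } else if (pattern == "DLNxxP") {
    paste0("DLN", sample(xs, 1), sample(xs, 1), "P")
  } else stop("unknown EAR pattern: ", pattern)
}

# Build one finger per its plan entry. Returns the sequence, geometry, true
# type/subgroup labels and (for the TRM1-like case) the offset of an EAR
# embedded in the X12 segment.
make_finger <- function(f, alphabet, z_templates, idd_refs) {
  cg <- f$cys_gap %||% 2L
  hg <- f$his_gap %||% 3L
  embedded_ear <- NULL
  if (f$mtype == "IDD") {
    seq <- idd_refs[[sample(length(idd_refs), 1)]]
    cg <- 2L; hg <- 3L
    sub <- ""
  } else if (f$mtype == "Z") {
    tpl <- z_templates[[f$subgroup]]
    cg <- 2L; hg <- 3L
    chars <- strsplit(tpl, "")[[1]]
    if (sample(0:1, 1) == 1L) {
      mutable <- c(1, 2, 4, 5, 7:13, 20:22)   # keep C/H scaffold and core5
      p <- sample(mutable, 1)
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
    }
    seq <- paste(chars, collapse = "")
    sub <- f$subgroup
  } else {
    core5 <- switch(f$mtype,
                    Q = "QALGG",
                    QM = f$core5 %||% QM_CORES[[1]],
                    C = sample_c_core(alphabet))
    inter <- if (f$mtype == "Q") {
      if (!is.null(f$subgroup) && f$subgroup %in% names(Q_INTERHIS)) {
        hg <- 3L
        sample(Q_INTERHIS[[f$subgroup]], 1)
      } else if (hg == 3L) sample_q6_interhis(alphabet) else
        random_residues(hg, alphabet)
    } else random_residues(hg, alphabet)
    x12head <- if (isTRUE(f$embed_ear)) {
      embedded_ear <- list(pattern = "LxLxL", offset = 4L + cg, matched = "LKLHL")
      paste0("LKLHLK", random_residues(1L, alphabet))
    } else random_residues(7L, alphabet)
    seq <- paste0(random_residues(2L, alphabet), "C",
                  random_residues(cg, alphabet), "C",
                  x12head, core5, "H", inter, "H")
    sub <- switch(f$mtype,
                  Q = f$subgroup %||% "Q6",
                  QM = qm_truth_label(core5),
                  C = "")
  }
  list(seq = seq, cys_gap = cg, his_gap = hg,
       mtype = f$mtype, subgroup = sub, embedded_ear = embedded_ear)
}

make_z_templates <- function(labels, alphabet) {
  templates <- list()
  cores <- character()
  for (lab in labels) {
    repeat {
      core5 <- sample_c_core(alphabet)
      if (!(core5 %in% cores)) break
    }
    cores <- c(cores, core5)
    templates[[lab]] <- paste0(random_residues(2L, alphabet), "C",
                               random_residues(2L, alphabet), "C",
                               random_residues(7L, alphabet), core5, "H",
                               random_residues(3L, alphabet), "H")
  }
  templates
}

protein_plan <- function(id, fingers, linkers = integer(), ears = list(),
                         appended = FALSE) {
  list(id = id, fingers = fingers, linkers = as.integer(linkers),
       ears = ears, appended = appended)
}

finger_plan <- function(mtype, subgroup = NULL, cys_gap = 2L, his_gap = 3L,
                        core5 = NULL, embed_ear = FALSE) {
  list(mtype = mtype, subgroup = subgroup, cys_gap = as.integer(cys_gap),
       his_gap = as.integer(his_gap), core5 = core5, embed_ear = embed_ear)
}

ear_plan <- function(pattern = "LxLxL", where = c("downstream", "upstream")) {
  list(pattern = pattern, where = match.arg(where))
}

#' Build a family plan of independent single-finger proteins
#'
#' Convenience for small fixtures: each row of `motif_plan` contributes
#' `count` single-finger proteins of the given type/subgroup/geometry.
#'
#' @param motif_plan data.frame with columns `mtype`, `subgroup`, `cys_gap`,
#'   `his_gap`, `count` (missing columns take defaults).
#' @param id_prefix protein id prefix.
#' @return a family plan list for [synthetic_spec()].
#' @export
simple_family_plan <- function(motif_plan, id_prefix = "SYN") {
  plan <- list()
  for (r in seq_len(nrow(motif_plan))) {
    sub_r <- if (!is.null(motif_plan$subgroup) && !is.na(motif_plan$subgroup[r]))
      motif_plan$subgroup[r] else NULL
    for (k in seq_len(motif_plan$count[r])) {
      plan[[length(plan) + 1L]] <- protein_plan(
        sprintf("%s%04d", id_prefix, length(plan) + 1L),
        list(finger_plan(motif_plan$mtype[r],
                         subgroup = sub_r,
                         cys_gap = if (!is.null(motif_plan$cys_gap))
                           motif_plan$cys_gap[r] else 2L,
                         his_gap = if (!is.null(motif_plan$his_gap))
                           motif_plan$his_gap[r] else 3L)))
    }
  }
  plan
}

#' The study-scale family plan
#'
#' 217 main proteins plus an appended nine-finger TFIIIA-like record,
#' reproducing the finger-count, type/subgroup, EAR-arrangement and
#' tandem-array composition described at the top of this file.
#'
#' @return family plan list.
#' @export
study_family_plan <- function() with_seed(1042L, {
  plan <- list()
  szp <- function(i) sprintf("SZP%04d", i)
  idx <- 0L

  # ---- per-type subgroup quota iterators over single-finger proteins ----
  q_single_subs <- rep(c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6"),
                       times = c(8, 10, 6, 6, 10, 9))
  q_ptr <- 0L
  next_q_sub <- function() { q_ptr <<- q_ptr + 1L; q_single_subs[q_ptr] }
  qm_single_cores <- rep(QM_CORES, times = c(5, 4, 4, 4, 4, 3, 3, 3, 3))
  qm_ptr <- 0L
  next_qm_core <- function() { qm_ptr <<- qm_ptr + 1L; qm_single_cores[qm_ptr] }
  z_single_subs <- c("Zs1", "Zs2", "Zs3", "Zs4", "Zs4", "Zs5", "Zs6",
                     "Zs8", "Zs8")
  z_ptr <- 0L
  next_z_sub <- function() { z_ptr <<- z_ptr + 1L; z_single_subs[z_ptr] }
  q6_geom <- list(c(2L, 3L), c(2L, 4L), c(4L, 3L), c(2L, 5L))
  q6_ptr <- 0L
  q_finger <- function() {
    sub <- next_q_sub()
    if (sub == "Q6") {
      q6_ptr <<- q6_ptr + 1L
      g <- q6_geom[[(q6_ptr - 1L) %% length(q6_geom) + 1L]]
      finger_plan("Q", subgroup = "Q6", cys_gap = g[1], his_gap = g[2])
    } else finger_plan("Q", subgroup = sub)
  }
  ear_pat <- function(i) if (i %% 5L == 0L) "DLNxxP" else "LxLxL"

  add <- function(fingers, linkers = integer(), ears = list()) {
    idx <<- idx + 1L
    plan[[length(plan) + 1L]] <<- protein_plan(szp(idx), fingers, linkers, ears)
  }

  # ---- 151 single-finger proteins ----
  for (i in 1:15) add(list(finger_plan("IDD")))                       # no EAR
  for (i in 1:30) add(list(finger_plan("C", cys_gap = c(2, 4)[i %% 2 + 1],
                                       his_gap = c(3, 4, 5)[i %% 3 + 1])))
  for (i in 1:17) add(list(finger_plan("QM", core5 = next_qm_core())))
  for (i in 1:9)  add(list(finger_plan("Z", subgroup = next_z_sub())))
  for (i in 1:3)  add(list(q_finger()))
  for (i in 1:59)                                                     # C2H2 then EAR
    add(list(if (i <= 40) q_finger()
             else if (i <= 50) finger_plan("QM", core5 = next_qm_core())
             else finger_plan("C")),
        ears = list(ear_plan(ear_pat(i), "downstream")))
  add(list(q_finger()), ears = list(ear_plan("LxLxL", "upstream")))   # JAG-like
  for (i in 1:9)                                                      # finger between EARs
    add(list(if (i <= 5) q_finger() else finger_plan("QM", core5 = next_qm_core())),
        ears = list(ear_plan("LxLxL", "upstream"),
                    ear_plan(ear_pat(i), "downstream")))
  for (i in 1:7)                                                      # both EARs one side
    add(list(if (i <= 5) finger_plan("C") else finger_plan("QM", core5 = next_qm_core())),
        ears = list(ear_plan("LxLxL", "downstream"),
                    ear_plan(ear_pat(i), "downstream")))
  add(list(finger_plan("C")),                                         # three EARs
      ears = list(ear_plan("LxLxL", "upstream"),
                  ear_plan("LxLxL", "downstream"),
                  ear_plan("DLNxxP", "downstream")))

  # ---- 38 two-finger proteins ----
  qq_subs <- rep(c("Q1", "Q2", "Q3", "Q4", "Q6"), times = c(10, 6, 3, 2, 1))
  for (s in qq_subs) {
    if (s == "Q6") {
      add(list(finger_plan("Q", "Q6", his_gap = 4L),
               finger_plan("Q", "Q6", his_gap = 5L)),
          linkers = sample(20:80, 1))
    } else {
      add(list(finger_plan("Q", s), finger_plan("Q", s)),
          linkers = sample(20:80, 1))
    }
  }
  qm2_cores <- rep(QM_CORES[1:4], times = c(4, 3, 3, 2))
  for (cr in qm2_cores) {
    add(list(finger_plan("QM", core5 = cr), finger_plan("QM", core5 = cr)),
        linkers = sample(20:80, 1))
  }
  zz_subs <- c("Zs1", "Zs1", "Zs1", "Zs2")
  zz_linkers <- c(0L, 5L, 10L, 45L)   # first three are tandem arrays
  for (k in seq_along(zz_subs)) {
    add(list(finger_plan("Z", subgroup = zz_subs[k]),
             finger_plan("Z", subgroup = zz_subs[k])),
        linkers = zz_linkers[k])
  }

  # ---- 16 three-finger proteins ----
  zzc_subs <- rep(c("Zs1", "Zs2", "Zs3", "Zs4", "Zs5", "Zs6", "Zs7"),
                  times = c(4, 2, 2, 1, 1, 1, 1))
  zzc_linkers <- list(c(10L, 10L), c(9L, 40L))   # one full array, one partial
  for (k in seq_along(zzc_subs)) {
    lk <- if (k <= 2L) zzc_linkers[[k]] else sample(15:60, 2)
    add(list(finger_plan("Z", subgroup = zzc_subs[k]),
             finger_plan("Z", subgroup = zzc_subs[k]),
             finger_plan("C")),
        linkers = lk)
  }
  for (k in 1:4) {
    add(list(finger_plan("IDD"), finger_plan("C"), finger_plan("C")),
        linkers = sample(15:60, 2))
  }

  # ---- 9 four-finger proteins (all C fingers) ----
  four_linkers <- list(c(10L, 9L, 65L), c(10L, 9L, 65L), c(10L, 9L, 65L),
                       c(5L, 5L, 5L), c(0L, 0L, 0L), c(8L, 3L, 50L),
                       c(20L, 35L, 18L), c(25L, 12L, 40L), c(30L, 30L, 30L))
  for (lk in four_linkers) {
    add(replicate(4, finger_plan("C"), simplify = FALSE), linkers = lk)
  }

  # ---- TRM1-like: five fingers, 4-finger tandem array, EAR inside finger 5
  plan[[length(plan) + 1L]] <- protein_plan(
    "TRM1_like",
    c(replicate(4, finger_plan("C"), simplify = FALSE),
      list(finger_plan("C", embed_ear = TRUE))),
    linkers = c(10L, 9L, 10L, 65L))

  # ---- two six-finger proteins (tandem) ----
  add(replicate(6, finger_plan("C"), simplify = FALSE),
      linkers = c(3L, 3L, 3L, 3L, 3L))
  add(replicate(6, finger_plan("C"), simplify = FALSE),
      linkers = c(0L, 5L, 9L, 2L, 7L))

  # ---- TFIIIA-like: nine fingers, appended after confirmation ----
  plan[[length(plan) + 1L]] <- protein_plan(
    "TFIIIA_like", replicate(9, finger_plan("C"), simplify = FALSE),
    linkers = c(40L, 7L, 7L, 25L, 3L, 3L, 3L, 3L), appended = TRUE)

  plan
})

#' The study-scale gene-order plan
#'
#' 218 family genes over 8 chromosomes (59/20/25/35/26/3/36/14) with 46
#' planted local-duplication clusters (38 of size 2, four of size 3, two of
#' size 4, one of 5, one of 6).
#'
#' @return gene-order plan list for [synthetic_spec()].
#' @export
study_gene_order_plan <- function() {
  list(window = 100L,
       chrom_plan = list(
         chr1 = list(n = 59, clusters = c(6, 5, 4, 4, 3, 3, 2, 2, 2, 2, 2, 2)),
         chr2 = list(n = 20, clusters = c(2, 2)),
         chr3 = list(n = 25, clusters = c(3, 2, 2, 2, 2)),
         chr4 = list(n = 35, clusters = c(2, 2, 2, 2, 2, 2, 2)),
         chr5 = list(n = 26, clusters = c(2, 2, 2, 2, 2, 2)),
         chr6 = list(n = 3,  clusters = numeric()),
         chr7 = list(n = 36, clusters = c(3, 2, 2, 2, 2, 2, 2, 2, 2)),
         chr8 = list(n = 14, clusters = c(2, 2, 2, 2, 2))))
}

#' The study-scale expression plan
#'
#' 119 family genes with probesets across ten tissues, tier means separated
#' by 4 log2 units, and 14 nodule-induced genes (nine single-finger, two
#' two-finger, two three-finger, one four-finger; the strongest an
#' RSD-like single-finger EAR protein at fold 64).
#'
#' @return expression plan list for [synthetic_spec()].
#' @export
study_expression_plan <- function() {
  genes <- c(sprintf("SZP%04d", 1:100), sprintf("SZP%04d", 152:159),
             sprintf("SZP%04d", 190:195), sprintf("SZP%04d", 206:208),
             "TRM1_like", "TFIIIA_like")
  induced <- data.frame(
    gene_id = c("SZP0075", sprintf("SZP%04d", c(3, 12, 24, 33, 47, 58, 76, 90)),
                "SZP0152", "SZP0153", "SZP0190", "SZP0191", "SZP0206"),
    fold = c(64, 16, 8, 16, 8, 16, 8, 16, 8, 16, 8, 16, 8, 8),
    stringsAsFactors = FALSE)
  list(tissues = c("root", "stem", "leaf", "petiole", "flower", "pod",
                   "seed", "seed_coat", "shoot_bud", "nodule"),
       genes = genes,
       tier_log2_means = c(low = 2, medium = 6, high = 10),
       log2_sd = 0.2,
       target_tissues = "nodule",
       induced = induced)
}

#' Construct a synthetic-data specification
#'
#' The defaults are the study-scale conditions (see [study_family_plan()],
#' [study_gene_order_plan()], [study_expression_plan()]); every component can
#' be replaced for smaller fixtures. The seed fully determines all outputs.
#'
#' @param seed integer seed driving all randomness.
#' @param family_plan list of protein plans.
#' @param n_decoy_proteins motif-free decoy proteins added to the proteome.
#' @param n_false_candidates decoy candidates carrying one C-like finger that
#'   the confirmation keep/drop list marks `drop`.
#' @param n_variant_genes number of leading family genes emitted with an
#'   additional (shorter) splice-variant record.
#' @param alphabet flank/linker residue alphabet; the default excludes C and
#'   H (no spurious finger matches) and L (no spurious EAR matches).
#' @param decoy_len length bounds for decoy proteins.
#' @param gene_order_plan chromosome layout plan (`window`, `chrom_plan`).
#' @param expression_plan expression plan, or `NULL`.
#' @return object of class `zfp_synth_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           family_plan = study_family_plan(),
                           n_decoy_proteins = 300L,
                           n_false_candidates = 55L,
                           n_variant_genes = 20L,
                           alphabet = CLEAN_ALPHABET,
                           decoy_len = c(80L, 300L),
                           gene_order_plan = study_gene_order_plan(),
                           expression_plan = study_expression_plan()) {
  spec <- list(seed = as.integer(seed), family_plan = family_plan,
               n_decoy_proteins = as.integer(n_decoy_proteins),
               n_false_candidates = as.integer(n_false_candidates),
               n_variant_genes = as.integer(n_variant_genes),
               alphabet = alphabet, decoy_len = as.integer(decoy_len),
               flank_len = c(15L, 60L), ear_gap = c(10L, 60L),
               cflank_len = c(5L, 30L),
               gene_order_plan = gene_order_plan,
               expression_plan = expression_plan)
  class(spec) <- "zfp_synth_spec"
  spec
}

#' Generate a synthetic proteome with planted ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with:
#'   `proteome` — all main records (family primary variants, splice-variant
#'   copies, false candidates, decoys);
#'   `appended` — records flagged `appended` in the plan (e.g. the
#'   TFIIIA-like protein), kept out of the main proteome;
#'   `truth` — list of `motifs`, `ears` (planted coordinates and labels on
#'   the primary variants, 0-based half-open), `proteins` (per-protein plan
#'   summary), and `keep_drop` (confirmation verdicts for every candidate).
#' @export
generate_proteome <- function(spec) {
  with_seed(spec$seed, {
    z_labels <- unique(unlist(lapply(spec$family_plan, function(pp)
      vapply(pp$fingers, function(f)
        if (f$mtype == "Z") f$subgroup %||% "Zs1" else NA_character_,
        character(1)))))
    z_labels <- z_labels[!is.na(z_labels)]
    z_templates <- make_z_templates(z_labels, spec$alphabet)
    idd_refs <- unname(idd_reference_motifs())

    records <- list(); motifs <- list(); ears <- list(); prot_rows <- list()
    appended <- list()

    for (pp in spec$family_plan) {
      cursor <- 0L
      parts <- character()
      addseq <- function(s) {
        parts[[length(parts) + 1L]] <<- s
        cursor <<- cursor + nchar(s)
      }
      up <- Filter(function(e) e$where == "upstream", pp$ears)
      down <- Filter(function(e) e$where == "downstream", pp$ears)
      p_ears <- list(); p_motifs <- list()
      addseq(random_residues(sample(spec$flank_len[1]:spec$flank_len[2], 1),
                             spec$alphabet))
      for (e in up) {
        es <- make_ear_seq(e$pattern, spec$alphabet)
        p_ears[[length(p_ears) + 1L]] <- data.frame(
          protein_id = pp$id, start = cursor, end = cursor + nchar(es),
          pattern_id = e$pattern, matched = es, stringsAsFactors = FALSE)
        addseq(es)
        addseq(random_residues(sample(spec$ear_gap[1]:spec$ear_gap[2], 1),
                               spec$alphabet))
      }
      for (k in seq_along(pp$fingers)) {
        fg <- make_finger(pp$fingers[[k]], spec$alphabet, z_templates, idd_refs)
        h1 <- cursor + 16L + fg$cys_gap
        p_motifs[[length(p_motifs) + 1L]] <- data.frame(
          protein_id = pp$id, start = cursor, end = cursor + nchar(fg$seq),
          sequence = fg$seq, cys_gap = fg$cys_gap, his_gap = fg$his_gap,
          core6 = substr(fg$seq, 17L + fg$cys_gap - 5L, 17L + fg$cys_gap),
          inter_his = substr(fg$seq, 18L + fg$cys_gap,
                             17L + fg$cys_gap + fg$his_gap),
          mtype = fg$mtype, subgroup = fg$subgroup, stringsAsFactors = FALSE)
        if (!is.null(fg$embedded_ear)) {
          ee <- fg$embedded_ear
          p_ears[[length(p_ears) + 1L]] <- data.frame(
            protein_id = pp$id, start = cursor + ee$offset,
            end = cursor + ee$offset + nchar(ee$matched),
            pattern_id = ee$pattern, matched = ee$matched,
            stringsAsFactors = FALSE)
        }
        addseq(fg$seq)
        if (k < length(pp$fingers)) {
          addseq(random_residues(pp$linkers[k], spec$alphabet))
        }
      }
      for (e in down) {
        addseq(random_residues(sample(spec$ear_gap[1]:spec$ear_gap[2], 1),
                               spec$alphabet))
        es <- make_ear_seq(e$pattern, spec$alphabet)
        p_ears[[length(p_ears) + 1L]] <- data.frame(
          protein_id = pp$id, start = cursor, end = cursor + nchar(es),
          pattern_id = e$pattern, matched = es, stringsAsFactors = FALSE)
        addseq(es)
      }
      addseq(random_residues(sample(spec$cflank_len[1]:spec$cflank_len[2], 1),
                             spec$alphabet))
      seq <- paste(parts, collapse = "")
      rec <- data.frame(id = pp$id, gene_id = pp$id,
                        description = "synthetic ZFP", sequence = seq,
                        stringsAsFactors = FALSE)
      if (isTRUE(pp$appended)) appended[[length(appended) + 1L]] <- rec
      else records[[length(records) + 1L]] <- rec
      motifs <- c(motifs, p_motifs)
      ears <- c(ears, p_ears)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = pp$id, n_fingers = length(pp$fingers),
        n_ears = length(p_ears),
        appended = isTRUE(pp$appended), stringsAsFactors = FALSE)
    }

    # splice variants: a shorter second transcript for the first genes
    variants <- list()
    nvar <- min(spec$n_variant_genes, length(records))
    if (nvar > 0L) {
      for (i in seq_len(nvar)) {
        full <- records[[i]]
        v1 <- full; v1$id <- paste0(full$gene_id, ".1")
        v2 <- full; v2$id <- paste0(full$gene_id, ".2")
        v2$sequence <- substr(full$sequence, 1L, nchar(full$sequence) - 3L)
        records[[i]] <- v1
        variants[[length(variants) + 1L]] <- v2
      }
    }

    # false candidates: one C-like finger each; confirmation marks them drop
    false_ids <- character()
    if (spec$n_false_candidates > 0L) {
      for (i in seq_len(spec$n_false_candidates)) {
        id <- sprintf("FLS%04d", i)
        false_ids <- c(false_ids, id)
        fg <- make_finger(finger_plan("C", cys_gap = c(2L, 4L)[i %% 2 + 1],
                                      his_gap = c(3L, 4L, 5L)[i %% 3 + 1]),
                          spec$alphabet, z_templates, idd_refs)
        seq <- paste0(random_residues(sample(20:60, 1), spec$alphabet), fg$seq,
                      random_residues(sample(20:60, 1), spec$alphabet))
        records[[length(records) + 1L]] <- data.frame(
          id = id, gene_id = id, description = "synthetic false candidate",
          sequence = seq, stringsAsFactors = FALSE)
      }
    }

    # motif-free decoys
    if (spec$n_decoy_proteins > 0L) {
      for (i in seq_len(spec$n_decoy_proteins)) {
        records[[length(records) + 1L]] <- data.frame(
          id = sprintf("DEC%04d", i), gene_id = sprintf("DEC%04d", i),
          description = "synthetic decoy",
          sequence = random_residues(sample(spec$decoy_len[1]:spec$decoy_len[2], 1),
                                     spec$alphabet),
          stringsAsFactors = FALSE)
      }
    }

    proteome <- do.call(rbind, c(list(data.frame(
      id = character(), gene_id = character(), description = character(),
      sequence = character(), stringsAsFactors = FALSE)), records, variants))
    rownames(proteome) <- NULL
    truth_motifs <- do.call(rbind, c(list(empty_motif_df()), motifs))
    truth_ears <- do.call(rbind, c(list(empty_ear_df()), ears))
    proteins <- do.call(rbind, c(list(data.frame(
      protein_id = character(), n_fingers = integer(), n_ears = integer(),
      appended = logical(), stringsAsFactors = FALSE)), prot_rows))
    family_ids <- proteins$protein_id
    keep_drop <- data.frame(
      id = c(setdiff(family_ids[!proteins$appended], character()), false_ids),
      decision = c(rep("keep", sum(!proteins$appended)),
                   rep("drop", length(false_ids))),
      stringsAsFactors = FALSE)
    list(proteome = proteome,
         appended = if (length(appended)) do.call(rbind, appended) else NULL,
         truth = list(motifs = truth_motifs, ears = truth_ears,
                      proteins = proteins, keep_drop = keep_drop,
                      family_ids = family_ids))
  })
}

#' Generate a synthetic gene order with planted duplication clusters
#'
#' Chromosomes are laid out as alternating family units (planted clusters or
#' singleton family genes) separated by more than `window` decoy gene models,
#' so that exactly the planted clusters are recoverable. Cluster members are
#' 1-3 gene models apart.
#'
#' @param spec a [synthetic_spec()]; `spec$gene_order_plan$chrom_plan` must
#'   allocate exactly the family ids produced by [generate_proteome()].
#' @param family_ids family gene ids in plan order.
#' @return list with `index` (gene-order data.frame incl. decoy gene models),
#'   `truth_clusters` (chromosome, size, members in the
#'   [find_local_duplications()] member format) and `window`.
#' @export
generate_gene_order <- function(spec, family_ids) {
  gp <- spec$gene_order_plan
  n_planned <- sum(vapply(gp$chrom_plan, function(x) x$n, numeric(1)))
  if (n_planned != length(family_ids)) {
    stop(sprintf("gene-order plan allocates %d genes but family has %d",
                 n_planned, length(family_ids)))
  }
  with_seed(spec$seed + 1L, {
    rows <- list(); truth <- list()
    fam_ptr <- 0L
    take_fam <- function(n) {
      ids <- family_ids[(fam_ptr + 1L):(fam_ptr + n)]
      fam_ptr <<- fam_ptr + n
      ids
    }
    decoy_i <- 0L
    for (chrom in names(gp$chrom_plan)) {
      cp <- gp$chrom_plan[[chrom]]
      n_clustered <- sum(cp$clusters)
      n_single <- cp$n - n_clustered
      if (n_single < 0L) stop("cluster plan exceeds chromosome allocation")
      units <- c(lapply(cp$clusters, function(s) take_fam(s)),
                 as.list(if (n_single > 0L) take_fam(n_single) else character()))
      genes <- character()
      add_decoys <- function(k) {
        ids <- sprintf("GM%s_%05d", sub("chr", "", chrom), decoy_i + seq_len(k))
        decoy_i <<- decoy_i + k
        genes <<- c(genes, ids)
      }
      add_decoys(sample(5:30, 1))
      for (u in units) {
        if (length(u) > 1L) {
          truth[[length(truth) + 1L]] <- data.frame(
            chromosome = chrom, size = length(u),
            members = paste(u, collapse = ";"), stringsAsFactors = FALSE)
          for (k in seq_along(u)) {
            genes <- c(genes, u[k])
            if (k < length(u)) add_decoys(sample(0:2, 1))
          }
        } else {
          genes <- c(genes, u)
        }
        add_decoys(gp$window + sample(1:20, 1))
      }
      start <- cumsum(sample(1000:10000, length(genes), replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes, chromosome = chrom, start = start,
        stringsAsFactors = FALSE)
    }
    index <- build_gene_order(do.call(rbind, rows))
    truth_clusters <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chromosome = character(), size = integer(),
                 members = character(), stringsAsFactors = FALSE)
    list(index = index, truth_clusters = truth_clusters, window = gp$window)
  })
}

#' Generate a synthetic expression matrix with planted tiers and inductions
#'
#' Abundances are drawn per gene and tissue as `2^(tier mean + N(0, sd))`;
#' induced genes have their target-tissue columns multiplied by the planted
#' fold. Tier means are well separated by default (4 log2 units), so tertile
#' tiering recovers the planted labels.
#'
#' @param spec a [synthetic_spec()] with a non-NULL `expression_plan`.
#' @return list with `matrix` (probeset x tissue), `map` (gene<->probeset),
#'   `truth_tiers` (gene_id, tier) and `truth_induced` (gene_id, fold).
#' @export
generate_expression <- function(spec) {
  ep <- spec$expression_plan
  if (is.null(ep)) stop("spec has no expression plan")
  with_seed(spec$seed + 2L, {
    genes <- ep$genes
    tiers <- names(ep$tier_log2_means)[(seq_along(genes) - 1L) %%
                                         length(ep$tier_log2_means) + 1L]
    mat <- t(vapply(seq_along(genes), function(i) {
      2^(ep$tier_log2_means[[tiers[i]]] +
           stats::rnorm(length(ep$tissues), 0, ep$log2_sd))
    }, numeric(length(ep$tissues))))
    colnames(mat) <- ep$tissues
    for (r in seq_len(nrow(ep$induced))) {
      i <- match(ep$induced$gene_id[r], genes)
      if (is.na(i)) stop("induced gene not in expression gene set: ",
                         ep$induced$gene_id[r])
      mat[i, ep$target_tissues] <- mat[i, ep$target_tissues] * ep$induced$fold[r]
    }
    probesets <- sprintf("PS%04d_at", seq_along(genes))
    rownames(mat) <- probesets
    list(matrix = mat,
         map = data.frame(gene_id = genes, probeset = probesets,
                          stringsAsFactors = FALSE),
         truth_tiers = data.frame(gene_id = genes, tier = tiers,
                                  stringsAsFactors = FALSE),
         truth_induced = ep$induced)
  })
}
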