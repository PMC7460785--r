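# Five major C2H2 types, assigned with precedence Q -> QM -> IDD -> Z -> C:
#   Q   : core6 (six residues ending at the first His) exactly "QALGGH";
#         subgroups Q1-Q5 from the three inter-His residues, Q6 otherwise.
#   QM  : core modified at 1..qm_max_mismatch of the five pre-His positions.
#   IDD : highly conserved 23-mer starting with Phe; >= idd_min_matches
#         positions agree with a packaged per-position profile.
#   Z   : conserved core outside Q/QM/IDD — matched against a configured
#         core table, or (fallback) deterministic single-linkage clusters of
#         the remaining motifs at >= z_cluster_min_identity.
#   C   : residual class, no conserved core.

#' Packaged IDD reference zinc fingers
#'
#' Returns the 23-mer reference set used to build the default IDD profile.
#' These are synthetic stand-in fingers (see
#' `inst/extdata/idd_reference_synthetic.fasta`) with the structural
#' hallmarks of IDD-type C2H2 motifs: length 23 (C-X2-C geometry, 3-residue
#' inter-His gap), phenylalanine at position 1, and at least 16 of 23
#' positions invariant across the set.
#'
#' @return named character vector of 23-mers.
#' @export
idd_reference_motifs <- function() {
  path <- system.file("extdata", "idd_reference_synthetic.fasta",
                      package = "zfpkit", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' Build a per-position consensus profile from aligned motifs
#'
#' @param motifs character vector of >= 2 equal-length motif strings.
#' @return data.frame with one row per position: `position` (1-based),
#'   `residue` (majority residue; ties broken alphabetically), `freq`
#'   (majority frequency), `invariant` (`freq == 1`).
#' @examples
#' build_idd_profile(c("FAC", "FAC", "FTC"))
#' @export
build_idd_profile <- function(motifs) {
  if (length(motifs) < 2L) stop("need >= 2 reference motifs")
  lens <- nchar(motifs)
  if (length(unique(lens)) != 1L) stop("reference motifs have mixed lengths")
  mat <- do.call(rbind, strsplit(motifs, ""))
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    tab <- tab[order(-tab, names(tab))]
    data.frame(position = j, residue = names(tab)[1L],
               freq = as.numeric(tab[1L]) / nrow(mat),
               invariant = as.numeric(tab[1L]) == nrow(mat),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default classifier rule set
#'
#' @param idd_reference optional character vector of aligned 23-mers used to
#'   build the IDD profile; defaults to the packaged reference set.
#' @return a list of rules consumed by [classify_motif()] / [classify_all()]:
#'   `q_core`, `q_subgroups` (Q1 `QNA`; Q2 `KAS`/`RAS`; Q3 `MRR`/`MRK`;
#'   Q4 `MNI`/`MNV`; Q5 `KRC`/`KRS`), `qm_max_mismatch` (2), `idd_profile`,
#'   `idd_min_matches` (16), `idd_require_first_f` (TRUE),
#'   `z_subgroup_cores` (NULL: fallback clustering), `z_cluster_min_size` (2),
#'   `z_cluster_min_identity` (0.60).
#' @export
default_classifier_rules <- function(idd_reference = idd_reference_motifs()) {
  rules <- list(
    q_core = "QALGGH",
    q_subgroups = list(Q1 = "QNA", Q2 = c("KAS", "RAS"),
                       Q3 = c("MRR", "MRK"), Q4 = c("MNI", "MNV"),
                       Q5 = c("KRC", "KRS")),
    qm_max_mismatch = 2L,
    idd_profile = build_idd_profile(idd_reference),
    idd_min_matches = 16L,
    idd_require_first_f = TRUE,
    z_subgroup_cores = NULL,
    z_cluster_min_size = 2L,
    z_cluster_min_identity = 0.60)
  validate_rules(rules)
  rules
}

validate_rules <- function(rules) {
  stopifnot(rules$qm_max_mismatch >= 1L,
            rules$idd_min_matches > 0L, rules$idd_min_matches <= 23L)
  labels <- unlist(rules$q_subgroups, use.names = FALSE)
  if (anyDuplicated(labels)) stop("q_subgroups inter-His tables overlap")
  invisible(rules)
}

#' Load classifier rules from a YAML config
#'
#' Reads a `classify:` section (scalar overrides such as `qm_max_mismatch`,
#' `idd_min_matches`, `z_cluster_min_identity`, plus optional `q_subgroups`
#' and `z_subgroup_cores` tables) and merges it over
#' [default_classifier_rules()]. A `scan:` section with `ear_patterns` is
#' returned in `attr(, "ear_patterns")`.
#'
#' @param path YAML file.
#' @return rules list.
#' @export
load_classifier_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- default_classifier_rules()
  cl <- cfg$classify %||% list()
  for (key in c("q_core", "qm_max_mismatch", "idd_min_matches",
                "idd_require_first_f", "z_cluster_min_size",
                "z_cluster_min_identity")) {
    if (!is.null(cl[[key]])) rules[[key]] <- cl[[key]]
  }
  if (!is.null(cl$q_subgroups)) rules$q_subgroups <- lapply(cl$q_subgroups, unlist)
  if (!is.null(cl$z_subgroup_cores)) {
    rules$z_subgroup_cores <- lapply(cl$z_subgroup_cores, unlist)
  }
  rules$qm_max_mismatch <- as.integer(rules$qm_max_mismatch)
  rules$idd_min_matches <- as.integer(rules$idd_min_matches)
  validate_rules(rules)
  if (!is.null(cfg$scan$ear_patterns)) {
    attr(rules, "ear_patterns") <- unlist(cfg$scan$ear_patterns)
  }
  rules
}

idd_profile_matches <- function(sequence, profile) {
  if (nchar(sequence) != nrow(profile)) return(0L)
  sum(strsplit(sequence, "")[[1]] == profile$residue)
}

classify_one <- function(core6, inter_his, his_gap, sequence, rules) {
  if (nchar(sequence) < 23L) stop("motif shorter than 23 residues: scanner contract violated")
  # Q
  if (core6 == rules$q_core) {
    sub <- "Q6"
    if (his_gap == 3L) {
      for (lab in names(rules$q_subgroups)) {
        if (inter_his %in% rules$q_subgroups[[lab]]) { sub <- lab; break }
      }
    }
    return(c("Q", sub))
  }
  # QM: Hamming distance on the five pre-His core positions
  d <- hamming(substr(core6, 1L, 5L), substr(rules$q_core, 1L, 5L))
  if (d >= 1L && d <= rules$qm_max_mismatch) {
    mism <- which(strsplit(substr(core6, 1L, 5L), "")[[1]] !=
                    strsplit(substr(rules$q_core, 1L, 5L), "")[[1]])
    sub <- paste(sprintf("P%d:%s", mism, substring(core6, mism, mism)),
                 collapse = ",")
    return(c("QM", sub))
  }
  # IDD: aligned 23-mer against the packaged profile
  if (nchar(sequence) == nrow(rules$idd_profile) &&
      (!rules$idd_require_first_f || substr(sequence, 1L, 1L) == "F") &&
      idd_profile_matches(sequence, rules$idd_profile) >= rules$idd_min_matches) {
    return(c("IDD", ""))
  }
  # Z via configured core table (fallback clustering lives in classify_all)
  if (!is.null(rules$z_subgroup_cores)) {
    for (lab in names(rules$z_subgroup_cores)) {
      if (core6 %in% rules$z_subgroup_cores[[lab]]) return(c("Z", lab))
    }
  }
  c("C", "")
}

#' Classify a single C2H2 motif
#'
#' @param motif one-row motif data.frame (needs `core6`, `inter_his`,
#'   `his_gap`, `sequence`).
#' @param rules rule list from [default_classifier_rules()].
#' @return the motif row with `mtype` and `subgroup` set. Without a
#'   `z_subgroup_cores` table this function never returns type Z (the
#'   clustering fallback needs the full motif set; use [classify_all()]).
#' @export
classify_motif <- function(motif, rules = default_classifier_rules()) {
  ts <- classify_one(motif$core6, motif$inter_his, motif$his_gap,
                     motif$sequence, rules)
  motif$mtype <- ts[1L]
  motif$subgroup <- ts[2L]
  motif
}

# Deterministic single-linkage clustering on pairwise string identity.
# Returns integer component labels for the given sequences.
single_linkage_components <- function(seqs, min_identity) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (string_identity(seqs[i], seqs[j]) >= min_identity) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Classify all motifs and summarize type/subgroup counts
#'
#' Applies the per-motif rules, then — when no Z core table is configured —
#' resolves the Z type by deterministic single-linkage clustering of the
#' still-unassigned motifs on pairwise identity of the full motif string.
#' Clusters of size >= `z_cluster_min_size` become Z subgroups, labelled
#' `Z1`, `Z2`, ... in order of their smallest member protein id; everything
#' else is type C.
#'
#' @param motifs motif data.frame from [scan_c2h2()].
#' @param rules rule list.
#' @return list with `motifs` (typed), `type_summary` (`mtype`, `n_motifs`,
#'   `n_genes`) and `subgroup_summary` (`mtype`, `subgroup`, `n_motifs`).
#' @export
classify_all <- function(motifs, rules = default_classifier_rules()) {
  validate_rules(rules)
  if (nrow(motifs) > 0L) {
    for (i in seq_len(nrow(motifs))) {
      ts <- classify_one(motifs$core6[i], motifs$inter_his[i],
                         motifs$his_gap[i], motifs$sequence[i], rules)
      motifs$mtype[i] <- ts[1L]
      motifs$subgroup[i] <- ts[2L]
    }
    if (is.null(rules$z_subgroup_cores)) {
      idx <- which(motifs$mtype == "C")
      if (length(idx) > 1L) {
        comp <- single_linkage_components(motifs$sequence[idx],
                                          rules$z_cluster_min_identity)
        sizes <- table(comp)
        big <- names(sizes)[sizes >= rules$z_cluster_min_size]
        if (length(big) > 0L) {
          first_id <- vapply(big, function(cc) {
            sel <- idx[comp == as.integer(cc)]
            min(paste(motifs$protein_id[sel], sprintf("%09d", motifs$start[sel])))
          }, character(1))
          big <- big[order(first_id)]
          for (k in seq_along(big)) {
            sel <- idx[comp == as.integer(big[k])]
            motifs$mtype[sel] <- "Z"
            motifs$subgroup[sel] <- sprintf("Z%d", k)
          }
        }
      }
    }
  }
  types <- c("Q", "QM", "IDD", "Z", "C")
  type_summary <- data.frame(
    mtype = types,
    n_motifs = vapply(types, function(t) sum(motifs$mtype == t), integer(1)),
    n_genes = vapply(types, function(t)
      length(unique(motifs$protein_id[motifs$mtype == t])), integer(1)),
    stringsAsFactors = FALSE)
  rownames(type_summary) <- NULL
  sg <- motifs[motifs$subgroup != "", c("mtype", "subgroup")]
  subgroup_summary <- if (nrow(sg)) {
    agg <- stats::aggregate(list(n_motifs = rep(1L, nrow(sg))),
                            by = list(mtype = sg$mtype, subgroup = sg$subgroup),
                            FUN = sum)
    agg[order(agg$mtype, agg$subgroup), , drop = FALSE]
  } else {
    data.frame(mtype = character(), subgroup = character(),
               n_motifs = integer(), stringsAsFactors = FALSE)
  }
  rownames(subgroup_summary) <- NULL
  list(motifs = motifs, type_summary = type_summary,
       subgroup_summary = subgroup_summary)
}
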