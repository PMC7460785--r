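# End-to-end orchestration: scan -> confirmation filter -> classify ->
# annotate -> genome context -> physchem -> expression, with per-stage TSV
# outputs and a JSON run manifest. Stages whose inputs are absent are
# skipped and noted in the manifest.

#' Build a pipeline configuration
#'
#' @param proteome path to the proteome FASTA (required).
#' @param gene_order optional gene-model TSV/GFF3 path.
#' @param expression,expression_map optional expression matrix / gene-map
#'   TSV paths.
#' @param keep_drop optional confirmation keep/drop TSV (columns `id`,
#'   `decision`).
#' @param wgd_pairs optional WGD pair TSV.
#' @param rules optional classifier-rules YAML (see
#'   [load_classifier_rules()]).
#' @param out_dir output directory.
#' @param mode scan mode (`"published"` or `"exhaustive"`).
#' @param variant_policy splice-variant policy for [read_proteome()].
#' @param tandem_threshold,dup_window,induction_fold,induction_tissues,tiers_k
#'   stage thresholds.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return config list of class `zfp_config`.
#' @export
pipeline_config <- function(proteome, gene_order = NULL, expression = NULL,
                            expression_map = NULL, keep_drop = NULL,
                            wgd_pairs = NULL, rules = NULL,
                            out_dir = "zfpkit_out",
                            mode = "published",
                            variant_policy = "longest_per_gene",
                            tandem_threshold = 11L, dup_window = 100L,
                            induction_fold = 2, induction_tissues = "nodule",
                            tiers_k = 3L, seed = 1L) {
  stopifnot(tandem_threshold > 0L, dup_window > 0L, induction_fold > 0,
            tiers_k >= 2L)
  cfg <- list(proteome = proteome, gene_order = gene_order,
              expression = expression, expression_map = expression_map,
              keep_drop = keep_drop, wgd_pairs = wgd_pairs, rules = rules,
              out_dir = out_dir, mode = mode,
              variant_policy = variant_policy,
              tandem_threshold = as.integer(tandem_threshold),
              dup_window = as.integer(dup_window),
              induction_fold = induction_fold,
              induction_tissues = induction_tissues,
              tiers_k = as.integer(tiers_k), seed = as.integer(seed))
  class(cfg) <- "zfp_config"
  cfg
}

#' Run the full ZFP identification pipeline
#'
#' @param config a [pipeline_config()].
#' @param append_proteins optional data.frame of extra protein records (e.g.
#'   a manually sequenced gene absent from the annotation) appended to the
#'   family *after* the confirmation filter, mirroring how a missed gene is
#'   rescued from an independent source.
#' @return list with all stage results (`proteome`, `motifs`, `ears`,
#'   `classified`, `annotation`, `genome`, `physchem`, `expression`,
#'   `manifest`), invisibly; outputs are written under `config$out_dir`.
#' @export
run_pipeline <- function(config, append_proteins = NULL) {
  stopifnot(inherits(config, "zfp_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("zfpkit")),
                   seed = config$seed,
                   thresholds = list(tandem = config$tandem_threshold,
                                     dup_window = config$dup_window,
                                     induction_fold = config$induction_fold,
                                     tiers_k = config$tiers_k),
                   skipped = character())

  rules <- if (!is.null(config$rules)) load_classifier_rules(config$rules)
           else default_classifier_rules()
  ear_patterns <- attr(rules, "ear_patterns") %||%
    c(LxLxL = "L.L.L", DLNxxP = "DLN..P")

  proteome <- read_proteome(config$proteome, config$variant_policy)
  manifest$n_proteins_scanned <- nrow(proteome)

  motifs <- scan_c2h2(proteome, config$mode)
  manifest$n_candidate_proteins <- length(unique(motifs$protein_id))
  manifest$n_candidate_motifs <- nrow(motifs)

  keep_drop <- if (!is.null(config$keep_drop))
    utils::read.delim(config$keep_drop, stringsAsFactors = FALSE) else NULL
  motifs <- attach_confirmation(motifs, keep_drop)
  manifest$n_dropped_by_confirmation <- attr(motifs, "n_dropped")

  if (!is.null(append_proteins)) {
    proteome <- rbind(proteome[, c("id", "gene_id", "description", "sequence")],
                      append_proteins[, c("id", "gene_id", "description",
                                          "sequence")])
    motifs <- rbind(motifs, scan_c2h2(append_proteins, config$mode))
  }

  family_ids <- sort(unique(motifs$protein_id))
  family <- proteome[proteome$id %in% family_ids, , drop = FALSE]
  ears <- scan_ear(family, ear_patterns)

  cls <- classify_all(motifs, rules)
  ann <- annotate_family(cls$motifs, ears, config$tandem_threshold)
  manifest$n_family_proteins <- length(family_ids)
  manifest$n_family_motifs <- nrow(cls$motifs)
  manifest$type_counts <- stats::setNames(as.list(cls$type_summary$n_motifs),
                                          cls$type_summary$mtype)
  fs <- family_summary(ann$annotations)
  manifest$count_class <- stats::setNames(as.list(fs$count_class$n),
                                          fs$count_class$count_class)
  manifest$fraction_single <- fs$fraction_single
  manifest$n_tandem_proteins <- sum(ann$annotations$array_class == "has_tandem")

  write_annotations(ann$annotations, cls$motifs, ears, config$out_dir)
  write_tsv_stable(cls$type_summary,
                   file.path(config$out_dir, "type_summary.tsv"))
  write_tsv_stable(cls$subgroup_summary,
                   file.path(config$out_dir, "subgroup_summary.tsv"))

  genome <- NULL
  if (!is.null(config$gene_order)) {
    index <- read_gene_order(config$gene_order)
    present <- intersect(family_ids, index$gene_id)
    dist <- chromosome_distribution(index, present)
    dups <- find_local_duplications(index, present, config$dup_window)
    wgd <- if (!is.null(config$wgd_pairs))
      load_wgd_pairs(config$wgd_pairs, present, ann$annotations) else NULL
    genome <- list(distribution = dist, duplications = dups, wgd = wgd)
    manifest$n_duplication_clusters <- nrow(dups)
    manifest$chromosome_counts <- stats::setNames(as.list(dist$counts$n),
                                                  dist$counts$chromosome)
    write_tsv_stable(dist$counts,
                     file.path(config$out_dir, "chromosome_distribution.tsv"))
    write_tsv_stable(dist$coords,
                     file.path(config$out_dir, "plot_coordinates.tsv"))
    write_tsv_stable(dups, file.path(config$out_dir, "local_duplications.tsv"))
    if (!is.null(wgd)) {
      write_tsv_stable(wgd, file.path(config$out_dir, "wgd_pairs.tsv"))
    }
  } else {
    manifest$skipped <- c(manifest$skipped, "genome_context")
  }

  pc <- physchem_profile(family)
  write_tsv_stable(pc, file.path(config$out_dir, "physchem.tsv"))
  manifest$pi_range <- range(pc$pi)
  manifest$mw_kda_range <- range(pc$mw_kda)

  expression <- NULL
  if (!is.null(config$expression) && !is.null(config$expression_map)) {
    ex <- read_expression(config$expression, config$expression_map)
    gmat <- collapse_to_genes(ex$matrix, ex$map)
    tiers <- abundance_tiers(gmat, config$tiers_k)
    induction <- tissue_induction(gmat, config$induction_tissues,
                                  config$induction_fold)
    expression <- list(matrix = gmat, tiers = tiers, induction = induction)
    manifest$n_expression_genes <- nrow(gmat)
    manifest$n_induced <- sum(induction$flagged)
    write_tsv_stable(tiers, file.path(config$out_dir, "expression_tiers.tsv"))
    write_tsv_stable(induction, file.path(config$out_dir, "tissue_induction.tsv"))
  } else {
    manifest$skipped <- c(manifest$skipped, "expression")
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(proteome = proteome, motifs = cls$motifs, ears = ears,
                 classified = cls, annotation = ann, genome = genome,
                 physchem = pc, expression = expression, manifest = manifest))
}
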