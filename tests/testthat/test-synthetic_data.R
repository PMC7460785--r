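test_that("generation is fully determined by the seed", {
  spec <- synthetic_spec(
    seed = 61,
    family_plan = simple_family_plan(data.frame(mtype = c("Q", "C"),
                                                subgroup = c("Q3", NA),
                                                count = c(4L, 4L))),
    n_decoy_proteins = 10L, n_false_candidates = 3L, n_variant_genes = 2L,
    gene_order_plan = list(window = 50L, chrom_plan = list(
      chr1 = list(n = 8, clusters = c(2)))),
    expression_plan = list(tissues = c("root", "leaf", "nodule"),
                           genes = sprintf("SYN%04d", 1:6),
                           tier_log2_means = c(low = 2, medium = 6, high = 10),
                           log2_sd = 0.2, target_tissues = "nodule",
                           induced = data.frame(gene_id = "SYN0002", fold = 8)))
  a <- generate_proteome(spec); b <- generate_proteome(spec)
  expect_identical(a, b)
  ga <- generate_gene_order(spec, a$truth$family_ids)
  gb <- generate_gene_order(spec, b$truth$family_ids)
  expect_identical(ga, gb)
  ea <- generate_expression(spec); eb <- generate_expression(spec)
  expect_identical(ea, eb)
  # a different seed changes the sequences
  c2 <- generate_proteome(synthetic_spec(
    seed = 62, family_plan = spec$family_plan, n_decoy_proteins = 10L,
    n_false_candidates = 3L, n_variant_genes = 2L,
    gene_order_plan = NULL, expression_plan = NULL))
  expect_false(identical(a$proteome$sequence, c2$proteome$sequence))
})

test_that("decoy-only proteomes contain no scanner or EAR matches", {
  pr <- generate_proteome(synthetic_spec(
    seed = 63, family_plan = list(), n_decoy_proteins = 10L,
    n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = NULL, expression_plan = NULL))
  expect_equal(nrow(pr$proteome), 10L)
  expect_equal(nrow(scan_c2h2(pr$proteome)), 0L)
  expect_equal(nrow(scan_ear(pr$proteome)), 0L)
})

test_that("every planted motif satisfies its pattern and classification rule", {
  fx <- study_fixture()
  truth <- fx$pr$truth$motifs
  seqs <- c(setNames(fx$proteome$sequence, fx$proteome$id),
            setNames(fx$pr$appended$sequence, fx$pr$appended$id))
  for (i in seq_len(nrow(truth))) {
    expect_true(oracle_is_c2h2(seqs[[truth$protein_id[i]]], truth$start[i],
                               truth$cys_gap[i], truth$his_gap[i]))
  }
  # scan on the full study proteome recovers exactly the planted coordinates
  got <- fx$motifs[order(fx$motifs$protein_id, fx$motifs$start), ]
  tr_fam <- truth[order(truth$protein_id, truth$start), ]
  expect_equal(got$protein_id, tr_fam$protein_id)
  expect_equal(got$start, tr_fam$start)
  expect_equal(got$end, tr_fam$end)
  # and classification reproduces the planted types motif-by-motif
  expect_equal(got$mtype, tr_fam$mtype)
})

test_that("planted EAR sites are the only EAR matches on clean data", {
  fx <- study_fixture()
  got <- fx$ears[order(fx$ears$protein_id, fx$ears$start), ]
  tr <- fx$pr$truth$ears
  # truth records whole planted sites; LxLxL matches are their 5-mer prefix
  tr$end <- ifelse(tr$pattern_id == "LxLxL", tr$start + 5L, tr$end)
  tr$matched <- substr(tr$matched, 1L, tr$end - tr$start)
  tr <- tr[order(tr$protein_id, tr$start), ]
  rownames(got) <- rownames(tr) <- NULL
  expect_equal(got$protein_id, tr$protein_id)
  expect_equal(got$start, tr$start)
  expect_equal(got$pattern_id, tr$pattern_id)
})

test_that("gene-order plans must cover the family exactly", {
  spec <- synthetic_spec(
    seed = 64, family_plan = simple_family_plan(data.frame(mtype = "C", count = 5L)),
    n_decoy_proteins = 0L, n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = list(window = 100L, chrom_plan = list(
      chr1 = list(n = 4, clusters = numeric()))),
    expression_plan = NULL)
  pr <- generate_proteome(spec)
  expect_error(generate_gene_order(spec, pr$truth$family_ids), "allocates")
})

test_that("no planted clusters means no recovered clusters", {
  spec <- synthetic_spec(
    seed = 65, family_plan = simple_family_plan(data.frame(mtype = "C", count = 6L)),
    n_decoy_proteins = 0L, n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = list(window = 100L, chrom_plan = list(
      chr1 = list(n = 6, clusters = numeric()))),
    expression_plan = NULL)
  pr <- generate_proteome(spec)
  go <- generate_gene_order(spec, pr$truth$family_ids)
  expect_equal(nrow(go$truth_clusters), 0L)
  expect_equal(nrow(find_local_duplications(go$index, pr$truth$family_ids,
                                            go$window)), 0L)
})

test_that("expression generation rejects induced genes outside the gene set", {
  spec <- synthetic_spec(
    seed = 66, family_plan = simple_family_plan(data.frame(mtype = "C", count = 3L)),
    n_decoy_proteins = 0L, n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = NULL,
    expression_plan = list(tissues = c("root", "nodule"),
                           genes = sprintf("SYN%04d", 1:3),
                           tier_log2_means = c(low = 2, high = 8),
                           log2_sd = 0.2, target_tissues = "nodule",
                           induced = data.frame(gene_id = "MISSING", fold = 8)))
  expect_error(generate_expression(spec), "not in expression gene set")
})
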