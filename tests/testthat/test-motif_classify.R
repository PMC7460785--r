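test_that("Q typing and inter-His subgrouping follow the consensus tables", {
  expect_equal(unlist(classify_motif(mk_motif("QALGGH", "QNA"))[c("mtype", "subgroup")]),
               c(mtype = "Q", subgroup = "Q1"))
  expect_equal(classify_motif(mk_motif("QALGGH", "RAS"))$subgroup, "Q2")
  expect_equal(classify_motif(mk_motif("QALGGH", "KAS"))$subgroup, "Q2")
  expect_equal(classify_motif(mk_motif("QALGGH", "MRK"))$subgroup, "Q3")
  expect_equal(classify_motif(mk_motif("QALGGH", "MNV"))$subgroup, "Q4")
  expect_equal(classify_motif(mk_motif("QALGGH", "KRC"))$subgroup, "Q5")
  # no consensus between the histidines -> Q6
  expect_equal(classify_motif(mk_motif("QALGGH", "TTT"))$subgroup, "Q6")
  # subgroups are only defined for a 3-residue inter-His gap
  m4 <- mk_motif("QALGGH", "QNAA", his_gap = 4L)
  expect_equal(classify_motif(m4)$subgroup, "Q6")
})

test_that("QM typing uses Hamming distance 1-2 on the five pre-His positions", {
  r <- classify_motif(mk_motif("RALGGH", "QNA"))
  expect_equal(r$mtype, "QM")
  expect_equal(r$subgroup, "P1:R")
  expect_equal(classify_motif(mk_motif("QGLGGH", "TTT"))$mtype, "QM")
  r2 <- classify_motif(mk_motif("RGLGGH", "TTT"))
  expect_equal(r2$mtype, "QM")
  expect_equal(r2$subgroup, "P1:R,P2:G")
  # three mismatches is beyond QM
  expect_equal(classify_motif(mk_motif("RGAGGH", "TTT"))$mtype, "C")
  # a motif is never both Q and QM
  expect_equal(classify_motif(mk_motif("QALGGH", "TTT"))$mtype, "Q")
})

test_that("IDD typing requires the leading Phe and the profile match", {
  refs <- idd_reference_motifs()
  seq <- unname(refs[1])
  m <- mk_motif(core6 = substr(seq, 13, 18), inter = substr(seq, 20, 22),
                sequence = seq)
  expect_equal(classify_motif(m)$mtype, "IDD")
  # replacing the leading F fails the requirement
  seq2 <- paste0("A", substr(seq, 2, 23))
  m2 <- mk_motif(core6 = substr(seq2, 13, 18), inter = substr(seq2, 20, 22),
                 sequence = seq2)
  expect_equal(classify_motif(m2)$mtype, "C")
  # all packaged references classify as IDD
  for (s in refs) {
    mi <- mk_motif(core6 = substr(s, 13, 18), inter = substr(s, 20, 22),
                   sequence = s)
    expect_equal(classify_motif(mi)$mtype, "IDD")
  }
})

test_that("motifs shorter than the minimal finger are rejected", {
  m <- mk_motif()
  m$sequence <- substr(m$sequence, 1, 20)
  expect_error(classify_motif(m), "shorter than 23")
})

test_that("build_idd_profile reports consensus, frequency, invariance", {
  p <- build_idd_profile(rep("FACDE", 3))
  expect_true(all(p$invariant))
  expect_equal(p$residue, c("F", "A", "C", "D", "E"))
  p2 <- build_idd_profile(c("FACDE", "FACDQ"))
  expect_equal(sum(p2$invariant), 4L)
  expect_equal(p2$freq[5], 0.5)
  expect_error(build_idd_profile(c("FACDE", "FACD")), "mixed lengths")
  expect_error(build_idd_profile("FACDE"), ">= 2")
})

test_that("Q labels depend only on core6 and inter_his", {
  m <- mk_motif("QALGGH", "QNA")
  base <- classify_motif(m)
  # permute residues outside core6/inter_his
  m2 <- m
  m2$sequence <- paste0("KA", "C", "EP", "C", "SRSFSAG",
                        "QALGG", "H", "QNA", "H")
  out <- classify_motif(m2)
  expect_equal(out$mtype, base$mtype)
  expect_equal(out$subgroup, base$subgroup)
})

test_that("classification partitions the motif set and conserves counts", {
  fx <- study_fixture()
  cls <- fx$cls
  expect_true(all(cls$motifs$mtype %in% c("Q", "QM", "IDD", "Z", "C")))
  expect_equal(sum(cls$type_summary$n_motifs), nrow(cls$motifs))
  # subgroup counts within a type sum to the type count (Q and Z fully
  # subgrouped; QM subgrouped by mismatch signature)
  for (t in c("Q", "Z")) {
    expect_equal(sum(cls$subgroup_summary$n_motifs[cls$subgroup_summary$mtype == t]),
                 cls$type_summary$n_motifs[cls$type_summary$mtype == t])
  }
  # empty input gives an all-zero summary
  cls0 <- classify_all(fx$motifs[0, ])
  expect_equal(sum(cls0$type_summary$n_motifs), 0L)
})

test_that("planted type and subgroup counts are reproduced exactly", {
  plan <- simple_family_plan(data.frame(
    mtype = c("Q", "QM", "C"), subgroup = c("Q1", NA, NA),
    count = c(10L, 5L, 3L)))
  pr <- generate_proteome(synthetic_spec(
    seed = 9, family_plan = plan, n_decoy_proteins = 10L,
    n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = NULL, expression_plan = NULL))
  cls <- classify_all(scan_c2h2(pr$proteome))
  got <- setNames(cls$type_summary$n_motifs, cls$type_summary$mtype)
  expect_equal(got[["Q"]], 10L)
  expect_equal(got[["QM"]], 5L)
  expect_equal(got[["C"]], 3L)
  expect_equal(got[["Z"]], 0L)
  q1 <- cls$subgroup_summary
  expect_equal(q1$n_motifs[q1$subgroup == "Q1"], 10L)
})

test_that("Z fallback clustering recovers planted subgroup sizes deterministically", {
  plan <- simple_family_plan(data.frame(
    mtype = "Z", subgroup = c("Zs1", "Zs2", "Zs3"), count = c(5L, 3L, 2L)))
  pr <- generate_proteome(synthetic_spec(
    seed = 13, family_plan = plan, n_decoy_proteins = 0L,
    n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = NULL, expression_plan = NULL))
  cls <- classify_all(scan_c2h2(pr$proteome))
  expect_equal(cls$type_summary$n_motifs[cls$type_summary$mtype == "Z"], 10L)
  zs <- cls$subgroup_summary[cls$subgroup_summary$mtype == "Z", ]
  expect_equal(sort(zs$n_motifs), c(2L, 3L, 5L))
  # deterministic on reruns
  cls2 <- classify_all(scan_c2h2(pr$proteome))
  expect_identical(cls$motifs$subgroup, cls2$motifs$subgroup)
})

test_that("a configured Z core table takes the primary path", {
  rules <- default_classifier_rules()
  rules$z_subgroup_cores <- list(ZA = "MNPQRH")
  m <- classify_motif(mk_motif("MNPQRH", "TTT"), rules)
  expect_equal(m$mtype, "Z")
  expect_equal(m$subgroup, "ZA")
})

test_that("rules survive YAML serialization with identical classification", {
  fx <- study_fixture()
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(classify = list(qm_max_mismatch = 2L,
                                        idd_min_matches = 16L,
                                        z_cluster_min_identity = 0.60)), yml)
  rules <- load_classifier_rules(yml)
  a <- classify_all(fx$motifs, default_classifier_rules())
  b <- classify_all(fx$motifs, rules)
  expect_identical(a$motifs$mtype, b$motifs$mtype)
  expect_identical(a$motifs$subgroup, b$motifs$subgroup)
})
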