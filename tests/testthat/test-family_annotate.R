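# Minimal motif/EAR rows for architecture tests (only coordinates matter).
mk_span <- function(id, starts, len = 23L, mtype = "C") {
  data.frame(protein_id = id, start = starts, end = starts + len,
             sequence = strrep("A", len), cys_gap = 2L, his_gap = 3L,
             core6 = "AAAAAH", inter_his = "AAA", mtype = mtype,
             subgroup = "", stringsAsFactors = FALSE)
}
mk_ear <- function(id, starts) {
  data.frame(protein_id = rep(id, length(starts)), start = starts,
             end = starts + 5L, pattern_id = rep("LxLxL", length(starts)),
             matched = rep("LALAL", length(starts)), stringsAsFactors = FALSE)
}

test_that("tandem arrays are maximal runs of linkers under the threshold", {
  # zero-residue linker joins two fingers
  a <- call_tandem_arrays(mk_span("p", c(0L, 23L)))
  expect_equal(a$size, 2L)
  expect_equal(a$linkers, "0")
  # linkers 10,10 give one array of three
  b <- call_tandem_arrays(mk_span("p", c(0L, 33L, 66L)))
  expect_equal(b$size, 3L)
  expect_equal(b$linkers, "10,10")
  # linkers 10,9,65: array of three, fourth finger isolated
  d <- call_tandem_arrays(mk_span("p", c(0L, 33L, 65L, 153L)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$size, 3L)
  expect_equal(d$last, 3L)
  # a single motif forms no array; linker 11 is not tandem (strict < 11)
  expect_equal(nrow(call_tandem_arrays(mk_span("p", 0L))), 0L)
  expect_equal(nrow(call_tandem_arrays(mk_span("p", c(0L, 34L)))), 0L)
  expect_equal(nrow(call_tandem_arrays(mk_span("p", c(0L, 33L)))), 1L)
  expect_error(call_tandem_arrays(mk_span("p", c(0L, 10L))), "overlap")
})

test_that("lowering the linker threshold never enlarges arrays", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    linkers <- sample(0:30, n - 1, replace = TRUE)
    starts <- cumsum(c(0L, linkers + 23L))
    m <- mk_span("p", starts)
    member_size <- function(th) {
      arr <- call_tandem_arrays(m, th)
      sz <- rep(1L, n)
      for (r in seq_len(nrow(arr))) sz[arr$first[r]:arr$last[r]] <- arr$size[r]
      sz
    }
    for (pair in list(c(5L, 11L), c(11L, 25L))) {
      expect_true(all(member_size(pair[1]) <= member_size(pair[2])))
    }
  }
})

test_that("EAR arrangements classify from coordinate order", {
  # finger at the N-terminus, EAR at the C-terminus (PALM1/RSD layout)
  a <- classify_architecture("p", mk_span("p", 10L), mk_ear("p", 200L))
  expect_equal(a$arrangement, "C2H2_then_EAR")
  expect_equal(a$ear_class, "one_EAR")
  # EAR upstream of the finger (JAG layout)
  b <- classify_architecture("p", mk_span("p", 100L), mk_ear("p", 10L))
  expect_equal(b$arrangement, "EAR_then_C2H2")
  # finger between two EARs
  d <- classify_architecture("p", mk_span("p", 100L), mk_ear("p", c(10L, 200L)))
  expect_equal(d$arrangement, "C2H2_between_EARs")
  expect_equal(d$ear_class, "multi_EAR")
  # two EARs on the same side
  e <- classify_architecture("p", mk_span("p", 10L), mk_ear("p", c(100L, 200L)))
  expect_equal(e$arrangement, "EARs_flanking_other")
  # no EAR
  f <- classify_architecture("p", mk_span("p", 10L), mk_ear("p", integer(0)))
  expect_equal(f$ear_class, "no_EAR")
  expect_equal(f$arrangement, "not_applicable")
  expect_equal(f$array_class, "single_finger")
  # multi-finger with interleaved EAR gets no directional label
  g <- classify_architecture("p", mk_span("p", c(0L, 100L)), mk_ear("p", 50L))
  expect_equal(g$arrangement, "not_applicable")
  # multi-finger with all EARs downstream keeps the directional label
  h <- classify_architecture("p", mk_span("p", c(0L, 50L)), mk_ear("p", 200L))
  expect_equal(h$arrangement, "C2H2_then_EAR")
  # an EAR inside a finger is flagged, not an arrangement class
  i <- classify_architecture("p", mk_span("p", 10L), mk_ear("p", 15L))
  expect_true(i$ear_in_finger)
})

test_that("family summary counts partition the family", {
  plan <- c(simple_family_plan(data.frame(mtype = "C", count = 7L), "SGL"),
            list())
  # add 3 two-finger proteins
  for (k in 1:3) {
    plan[[length(plan) + 1L]] <- zfpkit:::protein_plan(
      sprintf("DBL%04d", k),
      list(zfpkit:::finger_plan("C"), zfpkit:::finger_plan("C")),
      linkers = 30L)
  }
  pr <- generate_proteome(synthetic_spec(
    seed = 17, family_plan = plan, n_decoy_proteins = 0L,
    n_false_candidates = 0L, n_variant_genes = 0L,
    gene_order_plan = NULL, expression_plan = NULL))
  motifs <- classify_all(scan_c2h2(pr$proteome))$motifs
  ann <- annotate_family(motifs, scan_ear(pr$proteome))
  fs <- family_summary(ann$annotations)
  expect_equal(fs$count_class$n[fs$count_class$count_class == "single"], 7L)
  expect_equal(fs$count_class$n[fs$count_class$count_class == "two"], 3L)
  expect_equal(fs$fraction_single, 0.7)
  expect_equal(sum(fs$count_class$n), nrow(ann$annotations))
  # empty input gives zeros
  fs0 <- family_summary(ann$annotations[0, ])
  expect_equal(sum(fs0$count_class$n), 0L)
  expect_equal(fs0$fraction_single, 0)
})

test_that("study-scale architecture classes match the planted family", {
  fx <- study_fixture()
  fs <- family_summary(fx$ann$annotations)
  cc <- setNames(fs$count_class$n, fs$count_class$count_class)
  expect_equal(cc[c("single", "two", "three", "four", "five", "six", "nine")],
               c(single = 151L, two = 38L, three = 16L, four = 9L,
                 five = 1L, six = 2L, nine = 1L))
  se <- setNames(fs$single_ear$n, fs$single_ear$ear_class)
  expect_equal(se, c(no_EAR = 74L, one_EAR = 60L, multi_EAR = 17L))
  mt <- setNames(fs$multi_tandem$n, fs$multi_tandem$array_class)
  expect_equal(mt, c(has_tandem = 15L, no_tandem = 52L))
  # TRM1-like protein: 4-finger array plus isolated fifth finger, EAR inside it
  trm <- fx$ann$annotations[fx$ann$annotations$protein_id == "TRM1_like", ]
  expect_equal(trm$n_motifs, 5L)
  expect_true(trm$ear_in_finger)
  arr <- fx$ann$arrays[fx$ann$arrays$protein_id == "TRM1_like", ]
  expect_equal(arr$size, 4L)
  # TFIIIA-like protein: fingers 2-4 and 5-9 form two arrays
  tf <- fx$ann$arrays[fx$ann$arrays$protein_id == "TFIIIA_like", ]
  expect_equal(sort(tf$size), c(3L, 5L))
})

test_that("architecture rendering is deterministic and complete", {
  motifs <- mk_span("p", 10L)
  ears <- mk_ear("p", 60L)
  r1 <- render_architecture("p", 100L, motifs, ears)
  r2 <- render_architecture("p", 100L, motifs, ears)
  expect_identical(r1, r2)
  expect_equal(r1$feature, c("C2H2", "EAR"))
  expect_equal(r1$color, c("black", "red"))
  expect_equal(attr(r1, "metadata")$protein_length, 100L)
})
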