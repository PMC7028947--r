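test_that("putative-germline filter removes only annotated high-frequency variants", {
  v <- make_variants(
    make_variant(population_af = 0.05),      # common -> removed
    make_variant(population_af = 0.0005),    # rare -> kept
    make_variant(population_af = NA_real_),  # unannotated -> kept
    make_variant(population_af = 0.001))     # boundary: <= threshold kept
  out <- filter_putative_germline(v)
  expect_equal(nrow(out), 3)
  expect_equal(out$population_af, c(0.0005, NA, 0.001))
})

test_that("germline filter is idempotent and yields a subset, preserving order", {
  set.seed(11)
  for (i in 1:20) {
    af <- sample(c(NA, runif(1, 0, 0.01)), 30, replace = TRUE)
    v <- do.call(rbind, lapply(af, function(a) make_variant(population_af = a)))
    v$tag <- seq_len(nrow(v))
    once <- filter_putative_germline(v)
    expect_identical(filter_putative_germline(once), once)
    expect_true(all(once$tag %in% v$tag))
    expect_false(is.unsorted(once$tag))
  }
})

test_that("loss-of-function and deleteriousness rules follow the triage criteria", {
  expect_true(is_loss_of_function("nonsense"))
  expect_true(is_loss_of_function("frameshift_indel"))
  expect_true(is_loss_of_function("splice_site"))
  expect_false(is_loss_of_function("missense"))
  expect_false(is_loss_of_function("inframe_indel"))

  # LoF deleterious regardless of annotations
  expect_true(is_deleterious("frameshift_indel"))
  # missense: SIFT and/or PolyPhen, inclusive OR
  expect_true(is_deleterious("missense", "damaging", "benign"))
  expect_true(is_deleterious("missense", "tolerated", "probably_damaging"))
  expect_false(is_deleterious("missense", "tolerated", "possibly_damaging"))
  expect_false(is_deleterious("synonymous", "damaging", "probably_damaging"))
  # every LoF variant is deleterious (implication property)
  for (cons in c("nonsense", "frameshift_indel", "splice_site"))
    expect_true(is_deleterious(cons, "tolerated", "benign"))
})

test_that("inclusive and restrictive DDR criteria apply gene and evidence rules", {
  ann <- default_gene_annotation()
  hr_missense <- make_variant(gene = "BRCA1", polyphen_call = "probably_damaging")
  expect_true(ddr_alteration_inclusive(hr_missense, ann))
  expect_false(ddr_alteration_inclusive(make_variant(gene = "ERBB3", consequence = "nonsense"), ann))
  expect_false(ddr_alteration_inclusive(make_variant(gene = "BRCA1", consequence = "synonymous"), ann))

  # restrictive: catalogue evidence thresholds
  expect_true(ddr_alteration_restrictive(make_variant(gene = "MSH6", cosmic_count = 5L), ann))
  expect_false(ddr_alteration_restrictive(make_variant(gene = "MSH6", cosmic_count = 4L), ann))
  expect_true(ddr_alteration_restrictive(make_variant(gene = "MSH6", in_oncokb = TRUE), ann))
  expect_true(ddr_alteration_restrictive(
    make_variant(gene = "ERCC2", in_helicase_domain = TRUE), ann))
  expect_false(ddr_alteration_restrictive(
    make_variant(gene = "BRCA1", in_helicase_domain = TRUE), ann))

  # non-implication in both directions:
  # inclusive-only: SIFT-damaging missense with no catalogue evidence
  incl_only <- make_variant(gene = "BRCA1", sift_call = "damaging")
  expect_true(ddr_alteration_inclusive(incl_only, ann))
  expect_false(ddr_alteration_restrictive(incl_only, ann))
  # restrictive-only: catalogued missense that SIFT/PolyPhen call benign
  restr_only <- make_variant(gene = "BRCA1", sift_call = "tolerated",
                             polyphen_call = "benign", cosmic_count = 12L)
  expect_true(ddr_alteration_restrictive(restr_only, ann))
  expect_false(ddr_alteration_inclusive(restr_only, ann))

  expect_error(ddr_alteration_inclusive(make_variant(gene = "NOSUCHGENE"), ann),
               "NOSUCHGENE")
})

test_that("snv_count counts exonic non-synonymous variants", {
  expect_equal(snv_count(make_variant()[0, ]), 0L)
  v <- make_variants(make_variant(), make_variant(),
                     make_variant(consequence = "synonymous"),
                     make_variant(consequence = "frameshift_indel"))
  expect_equal(snv_count(v), 3)
  v10 <- do.call(rbind, replicate(10, make_variant(), simplify = FALSE))
  expect_equal(snv_count(v10), 10)
  mixed <- rbind(make_variant(patient_id = "P1"), make_variant(patient_id = "P2"))
  expect_error(snv_count(mixed), "single patient")
})

test_that("snv_count is additive and matches a brute-force whitelist count", {
  set.seed(42)
  classes <- c("missense", "nonsense", "frameshift_indel", "inframe_indel",
               "splice_site", "synonymous", "other")
  cons <- sample(classes, 1000, replace = TRUE)
  v <- do.call(rbind, lapply(cons, function(cl) make_variant(consequence = cl)))
  # independently coded whitelist
  brute <- 0L
  for (cl in cons)
    if (cl %in% c("missense", "nonsense", "frameshift_indel",
                  "inframe_indel", "splice_site")) brute <- brute + 1L
  expect_equal(snv_count(v), brute)
  # additivity over a disjoint split
  cut <- 400
  expect_equal(snv_count(v[1:cut, ]) + snv_count(v[(cut + 1):1000, ]),
               snv_count(v))
})

test_that("pathway flags reflect qualifying variants per DDR pathway", {
  ann <- default_gene_annotation()
  f <- pathway_flags(make_variant(gene = "BRCA1", sift_call = "damaging"), ann)
  expect_true(f[["HR"]]); expect_false(f[["NER"]]); expect_true(f[["any_ddr"]])
  f0 <- pathway_flags(make_variant()[0, ], ann)
  expect_false(any(f0))
  f2 <- pathway_flags(make_variant(gene = "ERCC2", consequence = "nonsense"), ann,
                      mode = "restrictive")
  expect_true(f2[["NER"]]); expect_false(f2[["HR"]])
})

test_that("gene whitelist restricts variants before counting", {
  v <- make_variants(make_variant(gene = "TP53"), make_variant(gene = "BRCA1"))
  expect_equal(nrow(apply_gene_whitelist(v, c("TP53"))), 1)
  expect_identical(apply_gene_whitelist(v, NULL), v)
})
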