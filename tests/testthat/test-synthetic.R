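test_that("generation honors the designed scaffold multiplicities", {
  gen <- generate_library(library_spec("c1ccccc1", 5, seed = 1))
  expect_equal(nrow(gen$library), 5L)
  scafs <- murcko_scaffold(gen$library$smiles)
  expect_equal(unique(scafs), canonical_smiles("c1ccccc1"))

  gen91 <- generate_library(library_spec(c("c1ccccc1", "C1CCCCC1"), c(9, 1),
                                         seed = 2))
  prof <- scaffold_profile(gen91$library)
  expect_equal(prof$table$count, c(9L, 1L))
  expect_equal(prof$auc, 0.7)
  expect_equal(gen91$ground_truth$auc, 0.7)
})

test_that("generation is reproducible per seed and the ground truth labels are faithful", {
  spec <- library_spec(c("c1ccncc1", "c1ccoc1"), c(4, 3), n_acyclic = 2,
                       seed = 17)
  g1 <- generate_library(spec)
  g2 <- generate_library(spec)
  expect_identical(sort(g1$library$smiles), sort(g2$library$smiles))
  expect_identical(g1$ground_truth, g2$ground_truth)
  # per-molecule labels match recomputed frameworks
  scafs <- murcko_scaffold(g1$library$smiles)
  truth <- g1$ground_truth$labels$scaffold[match(g1$library$id,
                                                 g1$ground_truth$labels$id)]
  expect_equal(scafs, truth)
  expect_equal(sum(is.na(scafs)), 2L)
})

test_that("generated metadata satisfies the record schema invariants", {
  spec <- library_spec(c("c1ccccc1", "C1CCCCC1"), c(6, 4), n_acyclic = 3,
                       seed = 23)
  lib <- generate_library(spec)$library
  expect_false(anyDuplicated(lib$id) > 0)
  expect_true(all(lib$year >= 2000 & lib$year <= 2018))
  expect_true(all(lib$kingdom %in% c("Plantae", "Fungi", "Other")))
  ms <- metadata_summary(lib)
  expect_equal(ms$n_compounds, 13L)
  expect_equal(sum(ms$by_year$n), 13L)
  expect_equal(sum(ms$by_kingdom$n), 13L)
})

test_that("an undersized vocabulary fails naming the scaffold", {
  spec <- library_spec("c1ccccc1", 3, substituents = c("C", "CC", "CCC"),
                       seed = 3)
  expect_silent(generate_library(spec))
  expect_error(library_spec("c1ccccc1", 9,
                            substituents = c("C", "CC", "CCC")),
               "vocabulary")
  # collisions at generation time also trigger the exhaustion error
  spec_dup <- library_spec("c1ccccc1", 3,
                           substituents = c("C", "OC", "CO"), seed = 3)
  expect_silent(generate_library(spec_dup))
})

test_that("spec validation rejects corrupt templates and substituents", {
  expect_error(library_spec("CCO", 2), "ring")
  expect_error(library_spec("Cc1ccccc1", 2), "pure framework")
  expect_error(library_spec(c("c1ccccc1", "C1=CC=CC=C1"), c(1, 1)), "distinct")
  expect_error(library_spec("c1ccccc1", 2,
                            substituents = c("C", "C1CC1")), "substituent")
  expect_error(library_spec("c1ccccc1", 2,
                            substituents = c("C", "=C")), "substituent")
  expect_error(library_spec("c1ccccc1", c(2, 3)), "length")
  expect_error(library_spec("c1ccccc1", 2, n_acyclic = 99), "acyclic")
})

test_that("closed-form AUC matches hand trapezoids", {
  expect_equal(closed_form_auc(c(1, 1, 1, 1)), 0.5)
  expect_equal(closed_form_auc(c(9, 1)), 0.7)
  # counts (3,2,1): points (0,0), (1/3,1/2), (2/3,5/6), (1,1);
  # trapezoids 1/12 + 2/9 + 11/36 = 11/18
  expect_equal(closed_form_auc(c(3, 2, 1)), 11 / 18)
  expect_equal(closed_form_auc(c(2, 3, 1)), 11 / 18)  # order-free
  expect_error(closed_form_auc(numeric(0)), "positive")
  expect_error(closed_form_auc(c(2, 0)), "positive")
})

test_that("measured recovery AUC equals the closed form on designed libraries", {
  for (seed in 1:6) {
    counts <- withr::with_seed(seed, sample(1:5, sample(2:4, 1), replace = TRUE))
    templates <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1")[seq_along(counts)]
    gen <- generate_library(library_spec(templates, counts, seed = seed))
    prof <- scaffold_profile(gen$library)
    expect_equal(sort(prof$table$count), sort(as.integer(counts)))
    expect_equal(prof$auc, closed_form_auc(counts), tolerance = 1e-12)
  }
})
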