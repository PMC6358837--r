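scaled_tab <- function(m) {
  colnames(m) <- c("MW", "SlogP", "TPSA", "RB", "HBD", "HBA")
  tibble::as_tibble(m)
}

test_that("property diversity is the stated pairwise-distance statistic", {
  same <- scaled_tab(matrix(0.3, nrow = 4, ncol = 6))
  expect_equal(as.numeric(property_diversity(same)), 0)

  two <- scaled_tab(rbind(rep(0, 6), c(1, rep(0, 5))))
  expect_equal(as.numeric(property_diversity(two)), 1)

  corners <- scaled_tab(rbind(rep(0, 6), c(1, rep(0, 5)), c(0, 1, rep(0, 4))))
  # pair distances {1, 1, sqrt(2)}
  expect_equal(as.numeric(property_diversity(corners, "mean")),
               (2 + sqrt(2)) / 3)
  expect_equal(as.numeric(property_diversity(corners, "median")), 1)
  expect_error(property_diversity(corners[1, ]), "two")
})

test_that("CD points bundle the component statistics unchanged", {
  gen <- generate_library(library_spec(c("c1ccccc1", "C1CCCCC1"), c(9, 1),
                                       seed = 21))
  cd <- cd_table(list(designed = gen$library), seed = 2)
  expect_equal(cd$scaffold_auc, 0.7)
  expect_equal(cd$n_compounds, 10L)
  fp <- maccs_fingerprints(gen$library)
  expect_equal(cd$median_tanimoto, similarity_stats(fp)$median)
})

test_that("a library of identical molecules is maximally non-diverse", {
  lib <- make_library(rep("Cc1ccccc1", 5))
  suppressWarnings(cd <- cd_table(list(mono = lib), seed = 1))
  expect_equal(cd$median_tanimoto, 1.0)
  expect_equal(cd$scaffold_auc, 0.5)  # degenerate single-scaffold curve
  expect_equal(cd$property_diversity, 0)
})

test_that("the more scaffold-redundant of two libraries has strictly higher AUC", {
  redundant <- generate_library(library_spec(
    c("c1ccccc1", "C1CCCCC1", "c1ccncc1"), c(8, 1, 1), seed = 31))$library
  diverse <- generate_library(library_spec(
    c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1", "C1CCNC1"),
    c(2, 2, 2, 2, 2), seed = 32))$library
  cd <- cd_table(list(redundant = redundant, diverse = diverse), seed = 3)
  expect_gt(cd$scaffold_auc[cd$library == "redundant"],
            cd$scaffold_auc[cd$library == "diverse"])
})

test_that("CD statistics are invariant to record order and stable under duplicating every molecule", {
  gen <- generate_library(library_spec(c("c1ccccc1", "c1ccoc1"), c(4, 2),
                                       seed = 41))
  lib <- gen$library
  shuffled <- lib[withr::with_seed(5, sample(nrow(lib))), ]
  cd1 <- cd_table(list(x = lib), seed = 7)
  cd2 <- cd_table(list(x = shuffled), seed = 7)
  expect_equal(as.data.frame(cd1), as.data.frame(cd2))

  # duplicating every molecule scales the scaffold counts uniformly, so
  # the recovery curve and AUC are exactly unchanged; the pairwise
  # fingerprint and property statistics gain one identity pair per
  # molecule (a O(1/n) fraction), so they are unchanged up to that
  # contribution
  big <- generate_library(library_spec(
    c("c1ccccc1", "c1ccoc1", "c1ccncc1"), c(12, 10, 8), seed = 42))$library
  doubled <- big
  doubled$id <- paste0(doubled$id, "b")
  both <- dplyr::bind_rows(big, doubled)
  cdb <- cd_table(list(x = big), seed = 7)
  cd3 <- cd_table(list(x = both), seed = 7)
  expect_equal(cd3$scaffold_auc, cdb$scaffold_auc)
  expect_equal(cd3$n_compounds, 2L * cdb$n_compounds)
  expect_equal(cd3$median_tanimoto, cdb$median_tanimoto, tolerance = 0.05)
  expect_equal(cd3$property_diversity, cdb$property_diversity,
               tolerance = 2 / nrow(big))
})

test_that("quadrant classification uses median thresholds and flags the single-point case", {
  pts <- tibble::tibble(
    library = c("a", "b"),
    median_tanimoto = c(0.3, 0.7),
    scaffold_auc = c(0.55, 0.9),
    property_diversity = c(0.8, 0.4),
    n_compounds = c(100L, 50L))
  cdd <- cd_plot_data(pts)
  expect_equal(cdd$points$quadrant,
               c("diverse: fingerprints & scaffolds", "low diversity: both"))
  expect_equal(cdd$color_bounds, c(0.4, 0.8))
  expect_s3_class(autoplot(cdd), "ggplot")

  expect_warning(single <- cd_plot_data(pts[1, ]), "thresholds")
  expect_true(is.na(single$points$quadrant))

  fixed <- cd_plot_data(pts, x_threshold = 0.2, y_threshold = 0.5)
  expect_equal(fixed$points$quadrant, rep("low diversity: both", 2))
})
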