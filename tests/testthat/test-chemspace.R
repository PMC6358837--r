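test_that("subsampling is uniform-without-replacement with floor rounding", {
  lib <- make_library(rep("CCO", 10), ids = sprintf("x%02d", 1:10))
  expect_equal(subsample_library(lib, fraction = 1, seed = 1), lib)
  one_a <- subsample_library(lib, count = 1, seed = 7)
  one_b <- subsample_library(lib, count = 1, seed = 7)
  expect_identical(one_a$id, one_b$id)
  # the fractional request is floored: 40% of 2214 rows keeps 885
  big <- tibble::tibble(id = as.character(seq_len(2214)))
  expect_equal(nrow(subsample_library(big, fraction = 0.4, seed = 3)), 885L)
  expect_error(subsample_library(lib, count = 11, seed = 1), "11")
  expect_error(subsample_library(lib, fraction = 0.5, count = 2, seed = 1),
               "exactly one")
})

test_that("min-max scaling maps to [0,1], is idempotent and monotone", {
  tab <- tibble::tibble(id = as.character(1:3), MW = c(0, 5, 10),
                        SlogP = c(-2, 0, 2), TPSA = c(7, 7, 7),
                        RB = c(1, 3, 2), HBD = c(0, 1, 2), HBA = c(2, 4, 6))
  sc <- scale_properties(tab)
  expect_equal(sc$MW, c(0, 0.5, 1))
  expect_equal(sc$TPSA, c(0.5, 0.5, 0.5))  # constant column rule
  expect_true(all(as.matrix(sc[, property_cols()]) >= 0 &
                    as.matrix(sc[, property_cols()]) <= 1))
  # re-scaling scaled data changes nothing
  sc2 <- scale_properties(sc)
  expect_equal(as.data.frame(sc2), as.data.frame(sc), ignore_attr = TRUE)
  # order within a column is preserved
  expect_equal(order(sc$RB), order(tab$RB))
  # recorded bounds reproduce the table from raw values
  b <- attr(sc, "bounds")
  mwb <- b[b$property == "MW", ]
  expect_equal((tab$MW - mwb$min) / (mwb$max - mwb$min), sc$MW)
})

test_that("union scope shares bounds across libraries, per-library scope does not", {
  tab <- tibble::tibble(
    library = rep(c("A", "B"), each = 2), id = as.character(1:4),
    MW = c(0, 10, 10, 30), SlogP = 1:4, TPSA = 1:4, RB = 1:4,
    HBD = 1:4, HBA = 1:4)
  un <- scale_properties(tab, scope = "union")
  expect_equal(un$MW, c(0, 1 / 3, 1 / 3, 1))
  per <- scale_properties(tab, scope = "per_library")
  expect_equal(per$MW, c(0, 1, 0, 1))
})

test_that("PCA satisfies its spectral contracts", {
  # collinear data: one component carries all variance
  tab <- tibble::tibble(a = c(0, 1, 2, 3), b = c(0, 2, 4, 6))
  fit <- chem_pca(tab, k = 2, columns = c("a", "b"))
  expect_equal(fit$var_explained[1], 1, tolerance = 1e-12)
  # 4-point square: isotropic, 50/50 split
  sq <- tibble::tibble(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  fit_sq <- chem_pca(sq, k = 2, columns = c("a", "b"))
  expect_equal(fit_sq$var_explained, c(0.5, 0.5))

  lib <- make_library(battery_smiles())
  sc <- scale_properties(compute_properties(lib))
  full <- chem_pca(sc, k = 6)
  expect_equal(sum(full$var_explained), 1)
  expect_true(all(diff(full$var_explained) <= 1e-12))
  expect_equal(crossprod(full$loadings), diag(6), ignore_attr = TRUE)
  # reconstruction from all components returns the centered data
  x <- as.matrix(sc[, property_cols()])
  xc <- scale(x, center = TRUE, scale = FALSE)
  recon <- as.matrix(full$scores[, paste0("PC", 1:6)]) %*% t(full$loadings)
  expect_lt(max(abs(recon - xc)), 1e-8)
  # the sign convention makes each component's dominant loading positive
  for (j in 1:6) {
    expect_gt(full$loadings[which.max(abs(full$loadings[, j])), j], 0)
  }
  expect_error(chem_pca(sc, k = 7), "exceeds")
})

test_that("t-SNE keeps its cardinality, determinism and duplicate contracts", {
  gen <- generate_library(library_spec(
    c("c1ccccc1", "C1CCCCC1", "c1ccncc1"), c(25, 25, 25), seed = 5))
  fp <- maccs_fingerprints(gen$library)
  emb <- chem_tsne(fp, perplexity = 8, seed = 2, n_iter = 260)
  expect_equal(nrow(emb$coords), nrow(fp))
  emb2 <- chem_tsne(fp, perplexity = 8, seed = 2, n_iter = 260)
  expect_identical(emb$coords, emb2$coords)
  expect_error(chem_tsne(fp[1:10, ], perplexity = 8, seed = 1), "at least")

  # duplicate fingerprint rows end up closer than the 1st percentile of
  # all pairwise embedded distances once the optimization has converged
  # (a battery of structurally distinct molecules, so the only exact
  # fingerprint duplicate is the planted one)
  fp_bat <- maccs_fingerprints(make_library(battery_smiles()))
  fp_dup <- rbind(fp_bat, fp_bat[1, , drop = FALSE])
  rownames(fp_dup)[nrow(fp_dup)] <- "DUP"
  emb_d <- chem_tsne(fp_dup, perplexity = 6, seed = 2, n_iter = 1000)
  xy <- as.matrix(emb_d$coords[, c("TSNE1", "TSNE2")])
  d_all <- dist(xy)
  d_dup <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
  expect_lte(d_dup, quantile(d_all, 0.01))
})

test_that("tanimoto-metric embedding runs and reports its objective", {
  gen <- generate_library(library_spec(
    c("c1ccccc1", "c1ccoc1"), c(20, 20), seed = 6))
  fp <- maccs_fingerprints(gen$library)
  emb <- chem_tsne(fp, perplexity = 6, seed = 3, n_iter = 260,
                   metric = "tanimoto")
  expect_equal(emb$metric, "tanimoto")
  expect_true(is.finite(emb$final_cost))
  expect_equal(emb$final_cost, tail(emb$itercosts, 1))
})

test_that("neighbor reports rank by embedded distance with fingerprint checks", {
  coords <- tibble::tibble(
    library = c(rep("ref", 4), "query"),
    id = c("r1", "r2", "r3", "r4", "q1"),
    X = c(0, 1, 5, 9, 0), Y = c(0, 0, 0, 0, 0))
  out <- neighbor_report(coords, "q1", reference = "ref", k = 2)
  expect_equal(out$ref_id, c("r1", "r2"))
  expect_equal(out$distance, c(0, 1))
  # k larger than the reference returns everything, ordered
  all_out <- neighbor_report(coords, "q1", reference = "ref", k = 99)
  expect_equal(all_out$ref_id, c("r1", "r2", "r3", "r4"))
  expect_error(neighbor_report(coords, "nope", reference = "ref"), "unknown")
})

test_that("on a two-cluster synthetic library every query's top neighbor is its own cluster", {
  gen <- generate_library(library_spec(
    c("c1ccc2ccccc2c1", "C1CCOC1"), c(20, 20), seed = 9))
  truth <- gen$ground_truth$labels
  fp <- maccs_fingerprints(gen$library)
  emb <- chem_tsne(fp, perplexity = 6, seed = 4, n_iter = 400,
                   groups = rep("ref", nrow(fp)))
  queries <- truth$id[c(1, 2, 21, 22)]
  out <- neighbor_report(emb, queries, reference = "ref", k = 2)
  # rank 1 is the query itself (distance 0); rank 2 is the true neighbor
  nearest <- out[out$rank == 2, ]
  own <- truth$scaffold[match(queries, truth$id)]
  got <- truth$scaffold[match(nearest$ref_id, truth$id)]
  expect_equal(got, own)
})
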