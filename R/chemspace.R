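#' Seeded uniform subsample of a library
#'
#' Uniform random sample without replacement, reproducible for a given
#' seed (R's default generator). A fractional request is rounded down
#' (`floor(fraction * n)`). Original row order is preserved among the
#' retained records.
#'
#' @param data A library tibble (any data frame).
#' @param fraction Fraction of rows to keep, in (0, 1]. Exactly one of
#'   `fraction` and `count` must be given.
#' @param count Number of rows to keep.
#' @param seed Integer seed.
#' @return The sub-library tibble.
#' @export
subsample_library <- function(data, fraction = NULL, count = NULL, seed = 42L) {
  df <- as_tibble(data)
  n <- nrow(df)
  if (is.null(fraction) == is.null(count)) {
    abort("give exactly one of `fraction` or `count`")
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
    count <- floor(fraction * n)
  }
  if (count > n) abort(sprintf("requested %d records from a library of %d", count, n))
  idx <- withr::with_seed(seed, sort(sample.int(n, count)))
  out <- df[idx, , drop = FALSE]
  attr(out, "library_name") <- attr(data, "library_name")
  out
}

#' Min-max scale property tables
#'
#' Linear transformation of each property column to \[0, 1\] using the
#' column minimum and maximum. With `scope = "union"` (the default, and
#' the right choice when several libraries are compared in one chemical
#' space) one shared min/max per column is computed over all rows; with
#' `scope = "per_library"` each library is scaled against its own
#' bounds, which makes values incomparable across libraries. A constant
#' column maps to 0.5 everywhere.
#'
#' @param properties A property table ([compute_properties()]), possibly
#'   row-bound across libraries with a `library` column.
#' @param columns Property columns to scale.
#' @param scope `"union"` or `"per_library"`.
#' @return The table with scaled property columns; scaling bounds are
#'   recorded in the `bounds` attribute (tibble: property, min, max, and
#'   library for per-library scope).
#' @export
scale_properties <- function(properties, columns = property_names,
                             scope = c("union", "per_library")) {
  scope <- match.arg(scope)
  df <- as_tibble(properties)
  if (nrow(df) == 0L) abort("cannot scale an empty property table")
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing property column(s): ", paste(missing_cols, collapse = ", ")))
  }
  scale_block <- function(block) {
    bounds <- map(columns, function(col) {
      x <- block[[col]]
      lo <- min(x)
      hi <- max(x)
      block[[col]] <<- if (hi > lo) (x - lo) / (hi - lo) else rep(0.5, length(x))
      tibble(property = col, min = lo, max = hi)
    })
    list(block = block, bounds = bind_rows(bounds))
  }
  if (scope == "union" || !"library" %in% names(df)) {
    res <- scale_block(df)
    out <- res$block
    bounds <- res$bounds
  } else {
    parts <- imap(split(df, df$library), function(part, lib) {
      r <- scale_block(part)
      r$bounds$library <- lib
      r
    })
    out <- bind_rows(map(parts, "block"))
    bounds <- bind_rows(map(parts, "bounds"))
  }
  attr(out, "bounds") <- bounds
  attr(out, "scope") <- scope
  out
}

#' PCA of scaled properties
#'
#' Principal component analysis of the (min-max scaled) property matrix:
#' components are the eigenvectors of the column-centered covariance,
#' ordered by decreasing eigenvalue; scores are the centered data
#' projected on them. The sign of each component is fixed so that its
#' largest-magnitude loading is positive. Explained-variance fractions
#' are reported for all components and sum to 1.
#'
#' @param scaled A scaled property table ([scale_properties()]).
#' @param k Number of components to keep in the scores (`k <=` number of
#'   property columns).
#' @param columns Property columns.
#' @return An object of class `chem_pca`: `scores` (tibble with
#'   `library`/`id` if present and `PC1..PCk`), `loadings` (full matrix,
#'   columns orthonormal), `var_explained` (all components), `center`,
#'   `k`.
#' @export
chem_pca <- function(scaled, k = 2, columns = NULL) {
  df <- as_tibble(scaled)
  columns <- columns %||% intersect(property_names, names(df))
  if (length(columns) == 0L) columns <- names(df)[vapply(df, is.numeric, logical(1))]
  if (k > length(columns)) {
    abort(sprintf("`k` (%d) exceeds the number of property columns (%d)",
                  k, length(columns)))
  }
  x <- as.matrix(df[, columns])
  if (nrow(x) < 2L) abort("PCA needs at least two rows")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  load <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varfrac <- fit$sdev^2 / sum(fit$sdev^2)
  sc <- as_tibble(scores[, seq_len(k), drop = FALSE])
  for (col in intersect(c("library", "id"), names(df))) {
    sc[[col]] <- df[[col]]
  }
  sc <- select(sc, any_of(c("library", "id")), everything())
  out <- list(scores = sc, loadings = load, var_explained = varfrac,
              center = fit$center, k = k, columns = columns)
  class(out) <- "chem_pca"
  out
}

#' @export
print.chem_pca <- function(x, ...) {
  cat(sprintf("PCA of %d rows x %d properties; variance explained: %s\n",
              nrow(x$scores), length(x$columns),
              paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                            100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' @rdname chem_pca
#' @param x,object A `chem_pca` object.
#' @param ... Unused.
#' @export
tidy.chem_pca <- function(x, ...) x$scores

#' @rdname chem_pca
#' @export
glance.chem_pca <- function(x, ...) {
  tibble(n = nrow(x$scores), k = x$k,
         var_pc1 = x$var_explained[1],
         var_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
         var_cum_k = sum(x$var_explained[seq_len(x$k)]))
}

#' @rdname chem_pca
#' @export
autoplot.chem_pca <- function(object, ...) {
  df <- object$scores
  has_lib <- "library" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "Property-based chemical space (PCA)"
    ) +
    ggplot2::theme_bw()
  if (has_lib) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$library),
                            alpha = 0.7, size = 1.5)
  } else {
    p + ggplot2::geom_point(alpha = 0.7, size = 1.5)
  }
}

#' t-SNE embedding of fingerprints
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of a
#' fingerprint matrix, via the Rtsne implementation. Bit vectors are
#' either treated as 0/1 coordinates under the Euclidean metric
#' (`metric = "binary"`) or converted to a precomputed 1 - Tanimoto
#' distance matrix (`metric = "tanimoto"`). Stochastic but reproducible
#' for a fixed seed; the objective (KL divergence) is recorded at the
#' optimizer's checkpoints.
#'
#' @param fps Fingerprint matrix ([maccs_fingerprints()]), or any
#'   numeric matrix with one row per molecule.
#' @param perplexity t-SNE perplexity (needs at least `3 * perplexity + 1`
#'   rows).
#' @param seed Integer seed.
#' @param n_iter Optimization iterations.
#' @param metric `"binary"` or `"tanimoto"`.
#' @param groups Optional per-row library labels carried into the
#'   coordinates.
#' @return An object of class `chem_tsne`: `coords` (tibble with `id`,
#'   optional `library`, `TSNE1`, `TSNE2`), `perplexity`, `seed`,
#'   `n_iter`, `metric`, `itercosts`, `final_cost`.
#' @export
chem_tsne <- function(fps, perplexity = 30, seed = 42L, n_iter = 1000,
                      metric = c("binary", "tanimoto"), groups = NULL) {
  metric <- match.arg(metric)
  m <- unclass(fps)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n < 3 * perplexity + 1) {
    abort(sprintf("t-SNE with perplexity %g needs at least %d rows (got %d)",
                  perplexity, ceiling(3 * perplexity + 1), n))
  }
  fit <- withr::with_seed(seed, {
    if (metric == "tanimoto") {
      d <- 1 - tanimoto_matrix(m)
      Rtsne::Rtsne(stats::as.dist(d), dims = 2, perplexity = perplexity,
                   max_iter = n_iter, is_distance = TRUE, pca = FALSE)
    } else {
      Rtsne::Rtsne(m, dims = 2, perplexity = perplexity, max_iter = n_iter,
                   pca = FALSE, check_duplicates = FALSE)
    }
  })
  ids <- rownames(fps) %||% sprintf("CPD%04d", seq_len(n))
  coords <- tibble(id = ids, TSNE1 = fit$Y[, 1], TSNE2 = fit$Y[, 2])
  if (!is.null(groups)) {
    coords$library <- groups
    coords <- select(coords, "library", everything())
  }
  out <- list(coords = coords, perplexity = perplexity, seed = seed,
              n_iter = n_iter, metric = metric,
              itercosts = as.numeric(fit$itercosts),
              final_cost = as.numeric(tail(fit$itercosts, 1)))
  class(out) <- "chem_tsne"
  out
}

#' @export
print.chem_tsne <- function(x, ...) {
  cat(sprintf(
    "t-SNE embedding of %d molecules (perplexity %g, %d iterations, %s metric, seed %s)\n  final KL divergence %.4f\n",
    nrow(x$coords), x$perplexity, x$n_iter, x$metric, x$seed, x$final_cost))
  invisible(x)
}

#' @rdname chem_tsne
#' @param x,object A `chem_tsne` object.
#' @param ... Unused.
#' @export
tidy.chem_tsne <- function(x, ...) x$coords

#' @rdname chem_tsne
#' @export
glance.chem_tsne <- function(x, ...) {
  tibble(n = nrow(x$coords), perplexity = x$perplexity, n_iter = x$n_iter,
         metric = x$metric, seed = x$seed, final_cost = x$final_cost)
}

#' @rdname chem_tsne
#' @export
autoplot.chem_tsne <- function(object, ...) {
  df <- object$coords
  has_lib <- "library" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$TSNE1, .data$TSNE2)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2",
                  title = "Fingerprint-based chemical space (t-SNE)") +
    ggplot2::theme_bw()
  if (has_lib) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$library),
                            alpha = 0.7, size = 1.5)
  } else {
    p + ggplot2::geom_point(alpha = 0.7, size = 1.5)
  }
}

#' Nearest reference compounds in an embedding
#'
#' For each query record, the `k` nearest records of a reference library
#' by Euclidean distance in the embedded space, with the Tanimoto
#' similarity in the original fingerprint space attached when
#' fingerprints are supplied.
#'
#' @param embedding A `chem_tsne` or `chem_pca` object, or a coordinate
#'   tibble with `id`, a `library` column and two coordinate columns.
#' @param query_ids Ids of the query compounds.
#' @param reference Library label of the reference set.
#' @param k Neighbors per query; capped at the reference size (all
#'   references returned, ordered, when larger).
#' @param fingerprints Optional fingerprint matrix covering both
#'   libraries (rownames = ids).
#' @return A tibble with `query_id`, `rank`, `ref_id`, `distance` and
#'   (optionally) `tanimoto`.
#' @export
neighbor_report <- function(embedding, query_ids, reference, k = 3,
                            fingerprints = NULL) {
  coords <- if (inherits(embedding, c("chem_tsne", "chem_pca"))) {
    if (inherits(embedding, "chem_tsne")) embedding$coords else embedding$scores
  } else {
    as_tibble(embedding)
  }
  if (!"library" %in% names(coords)) {
    abort("embedding coordinates need a `library` column")
  }
  dims <- setdiff(names(coords)[vapply(coords, is.numeric, logical(1))],
                  c("library", "id"))[1:2]
  unknown <- setdiff(query_ids, coords$id)
  if (length(unknown)) {
    abort(paste0("unknown query id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  ref <- filter(coords, .data$library == reference)
  if (nrow(ref) == 0L) abort(paste0("no records in reference library: ", reference))
  k <- min(k, nrow(ref))
  refm <- as.matrix(ref[, dims])
  out <- map(query_ids, function(q) {
    qv <- as.numeric(coords[match(q, coords$id), dims])
    d <- sqrt(rowSums(sweep(refm, 2, qv)^2))
    ord <- order(d)[seq_len(k)]
    tibble(query_id = q, rank = seq_len(k), ref_id = ref$id[ord],
           distance = d[ord])
  })
  out <- bind_rows(out)
  if (!is.null(fingerprints)) {
    fp <- unclass(fingerprints)
    out$tanimoto <- map2_dbl(out$query_id, out$ref_id, function(a, b) {
      suppressWarnings(tanimoto(fp[a, ], fp[b, ]))
    })
  }
  out
}

#' @importFrom purrr map2_dbl
#' @importFrom utils tail
NULL
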