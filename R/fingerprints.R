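#' 166-bit structural-key fingerprints
#'
#' Computes the 166-key structural fingerprint (MACCS dictionary, as
#' implemented by the OpenBabel engine; key numbering follows the
#' published 1..166 dictionary) for every record. Deterministic for a
#' given canonical structure.
#'
#' @param data A library tibble with `smiles` (and optionally `id`)
#'   columns, or a character vector of SMILES.
#' @return An integer 0/1 matrix of class `maccs_fp` with one row per
#'   record (rownames = ids) and exactly 166 columns, with the library
#'   label in the `library_name` attribute and the engine recorded in
#'   `engine`.
#' @export
maccs_fingerprints <- function(data) {
  if (is.character(data)) {
    data <- tibble(id = sprintf("CPD%04d", seq_along(data)), smiles = data)
  }
  df <- as_tibble(data)
  if (!"smiles" %in% names(df)) abort("`data` needs a `smiles` column")
  if (!"id" %in% names(df)) df$id <- sprintf("CPD%04d", seq_len(nrow(df)))
  can <- canonical_smiles(df$smiles)
  if (anyNA(can)) {
    abort(paste0("invalid structure(s) for record id(s): ",
                 paste(head(df$id[is.na(can)], 5), collapse = ", ")))
  }
  m <- ob_maccs(can)
  rownames(m) <- df$id
  structure(m, class = c("maccs_fp", class(m)),
            library_name = attr(data, "library_name"),
            engine = "OpenBabel MACCS (166 structural keys)")
}

#' Tanimoto similarity of two bit vectors
#'
#' `T = c / (a + b - c)` with `a`, `b` the on-bit counts and `c` the
#' shared on-bits. By convention two all-zero vectors are identical
#' (`T = 1`), with a warning.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("fingerprint length mismatch: %d vs %d", length(a), length(b)))
  }
  a <- as.logical(a)
  b <- as.logical(b)
  denom <- sum(a) + sum(b) - sum(a & b)
  if (denom == 0) {
    warn("both fingerprints are all-zero; Tanimoto defined as 1")
    return(1)
  }
  sum(a & b) / denom
}

# Full m x m Tanimoto matrix from a 0/1 matrix (rows = molecules).
tanimoto_matrix <- function(fps) {
  m <- unclass(fps)
  storage.mode(m) <- "double"
  common <- tcrossprod(m)
  on <- rowSums(m)
  denom <- outer(on, on, "+") - common
  zero <- denom == 0
  if (any(zero)) {
    warn("all-zero fingerprint pair(s); Tanimoto defined as 1")
    denom[zero] <- 1
    common[zero] <- 1
  }
  common / denom
}

# Tanimoto for index pairs (i, j) into fps, vectorized.
tanimoto_pairs <- function(fps, i, j) {
  m <- unclass(fps)
  storage.mode(m) <- "double"
  common <- rowSums(m[i, , drop = FALSE] * m[j, , drop = FALSE])
  denom <- rowSums(m[i, , drop = FALSE]) + rowSums(m[j, , drop = FALSE]) - common
  zero <- denom == 0
  if (any(zero)) {
    warn("all-zero fingerprint pair(s); Tanimoto defined as 1")
    denom[zero] <- 1
    common[zero] <- 1
  }
  common / denom
}

#' Pairwise Tanimoto similarity statistics
#'
#' Summary of the distribution of pairwise Tanimoto similarities of a
#' fingerprint set: the library-diversity statistic used on the x-axis
#' of Consensus Diversity plots is the median (lower median = larger
#' fingerprint-based diversity; the median is used directly, never
#' inverted). All unordered pairs are enumerated when their number is at
#' most `max_pairs`; larger sets are summarized from a uniform seeded
#' random sample of pairs and flagged `sampled`.
#'
#' @param fps A fingerprint matrix ([maccs_fingerprints()]).
#' @param max_pairs Exhaustive-enumeration cap (default 2e6 pairs).
#' @param seed Seed for pair sampling (required when sampling kicks in).
#' @return A list of class `similarity_stats`: `n_molecules`, `n_pairs`,
#'   `median`, `mean`, `min`, `max`, `sampled`, `seed`, and `histogram`
#'   (tibble of bin edges and counts).
#' @export
similarity_stats <- function(fps, max_pairs = 2e6, seed = NULL) {
  m <- nrow(fps)
  if (is.null(m) || m < 2L) {
    abort("similarity statistics need at least two molecules")
  }
  n_total <- m * (m - 1) / 2
  sampled <- n_total > max_pairs
  if (sampled) {
    if (is.null(seed)) abort("`seed` is required when pairs are sampled")
    sims <- withr::with_seed(seed, {
      ks <- sample(n_total, max_pairs)
      ij <- pair_index(ks, m)
      tanimoto_pairs(fps, ij[, 1L], ij[, 2L])
    })
  } else {
    tm <- tanimoto_matrix(fps)
    sims <- tm[lower.tri(tm)]
  }
  edges <- seq(0, 1, by = 0.05)
  hist_counts <- tabulate(pmin(findInterval(sims, edges,
                                            rightmost.closed = TRUE), 20L),
                          nbins = 20L)
  out <- list(
    n_molecules = m,
    n_pairs = length(sims),
    median = median(sims),
    mean = mean(sims),
    min = min(sims),
    max = max(sims),
    sampled = sampled,
    seed = if (sampled) seed else NA_integer_,
    histogram = tibble(lower = edges[-21L], upper = edges[-1L],
                       count = hist_counts)
  )
  class(out) <- "similarity_stats"
  out
}

# Map linear pair indices 1..m(m-1)/2 to (i, j), i < j, enumerating
# pairs in column order (1,2), (1,3), (2,3), (1,4), ...
pair_index <- function(k, m) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  # guard against sqrt() rounding at triangular-number boundaries
  over <- i < 1
  j[over] <- j[over] - 1
  i[over] <- k[over] - (j[over] - 1) * (j[over] - 2) / 2
  under <- i > j - 1
  j[under] <- j[under] + 1
  i[under] <- k[under] - (j[under] - 1) * (j[under] - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' @export
print.similarity_stats <- function(x, ...) {
  cat(sprintf(
    "Pairwise Tanimoto over %d molecules (%d pairs%s)\n  median %.4f  mean %.4f  range [%.4f, %.4f]\n",
    x$n_molecules, x$n_pairs, if (x$sampled) ", sampled" else "",
    x$median, x$mean, x$min, x$max))
  invisible(x)
}

#' @rdname similarity_stats
#' @param x A `similarity_stats` object.
#' @param ... Unused.
#' @export
glance.similarity_stats <- function(x, ...) {
  tibble(n_molecules = x$n_molecules, n_pairs = x$n_pairs,
         median = x$median, mean = x$mean, min = x$min, max = x$max,
         sampled = x$sampled)
}

#' @rdname similarity_stats
#' @export
tidy.similarity_stats <- function(x, ...) x$histogram
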