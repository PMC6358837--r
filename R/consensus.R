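#' Whole-property diversity of one library
#'
#' The mean (or median) of all pairwise Euclidean distances between a
#' library's scaled property vectors. The table must have been scaled
#' with union scope across every library being compared for the values
#' to be comparable. Exhaustive up to `max_pairs` pairs, then a seeded
#' uniform pair sample (flagged in the `sampled` attribute).
#'
#' @param scaled Scaled property rows of one library
#'   ([scale_properties()]).
#' @param statistic `"mean"` (default) or `"median"`.
#' @param columns Property columns.
#' @param max_pairs Exhaustive-enumeration cap.
#' @param seed Seed for pair sampling.
#' @return The distance statistic (non-negative double) with attributes
#'   `n_pairs`, `statistic`, `sampled`.
#' @export
property_diversity <- function(scaled, statistic = c("mean", "median"),
                               columns = property_names, max_pairs = 2e6,
                               seed = NULL) {
  statistic <- match.arg(statistic)
  df <- as_tibble(scaled)
  columns <- intersect(columns, names(df))
  x <- as.matrix(df[, columns])
  n <- nrow(x)
  if (n < 2L) abort("property diversity needs at least two rows")
  n_total <- n * (n - 1) / 2
  sampled <- n_total > max_pairs
  if (sampled) {
    if (is.null(seed)) abort("`seed` is required when pairs are sampled")
    d <- withr::with_seed(seed, {
      ks <- sample(n_total, max_pairs)
      ij <- pair_index(ks, n)
      sqrt(rowSums((x[ij[, 1L], , drop = FALSE] - x[ij[, 2L], , drop = FALSE])^2))
    })
  } else {
    d <- as.numeric(dist(x))
  }
  val <- if (statistic == "mean") mean(d) else median(d)
  structure(val, n_pairs = length(d), statistic = statistic, sampled = sampled)
}

#' Consensus Diversity table
#'
#' Assembles, for each library, the four statistics of a Consensus
#' Diversity (CD) plot: the median pairwise Tanimoto similarity of the
#' 166-bit structural-key fingerprints (x-axis; lower = more diverse),
#' the area under the cyclic-system scaffold recovery curve (y-axis;
#' lower = more diverse), the whole-property diversity (pairwise
#' Euclidean distance of the six properties scaled over the union of all
#' compared libraries; colour, lighter = more diverse) and the library
#' size (point size). The statistics are bundled as computed, with no
#' re-scaling.
#'
#' @param libraries A named list of library tibbles (curated), or a
#'   single tibble with a `library` column.
#' @param statistic Statistic for property diversity (`"mean"` or
#'   `"median"`).
#' @param max_pairs Pair cap shared by the Tanimoto and property-distance
#'   computations.
#' @param seed Seed used when any pairwise computation must sample.
#' @return A tibble of class `cd_table` with columns `library`,
#'   `median_tanimoto`, `scaffold_auc`, `property_diversity`,
#'   `n_compounds`.
#' @export
cd_table <- function(libraries, statistic = c("mean", "median"),
                     max_pairs = 2e6, seed = 42L) {
  statistic <- match.arg(statistic)
  libs <- normalize_library_list(libraries)
  props <- imap(libs, function(lib, nm) {
    p <- compute_properties(lib)
    p$library <- nm
    p
  })
  scaled <- scale_properties(bind_rows(props), scope = "union")
  rows <- imap(libs, function(lib, nm) {
    fps <- maccs_fingerprints(lib)
    sim <- similarity_stats(fps, max_pairs = max_pairs, seed = seed)
    prof <- scaffold_profile(lib, name = nm)
    pd <- property_diversity(filter(scaled, .data$library == nm),
                             statistic = statistic, max_pairs = max_pairs,
                             seed = seed)
    tibble(
      library = nm,
      median_tanimoto = sim$median,
      scaffold_auc = prof$auc,
      property_diversity = as.numeric(pd),
      n_compounds = nrow(lib)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("cd_table", class(out))
  attr(out, "statistic") <- statistic
  out
}

normalize_library_list <- function(libraries) {
  if (is.data.frame(libraries)) {
    if ("library" %in% names(libraries)) {
      return(split(as_tibble(libraries), libraries$library))
    }
    nm <- attr(libraries, "library_name") %||% "library"
    return(setNames(list(as_tibble(libraries)), nm))
  }
  if (!is.list(libraries) || is.null(names(libraries)) ||
      any(!nzchar(names(libraries)))) {
    abort("`libraries` must be a named list of library tibbles")
  }
  if (anyDuplicated(names(libraries))) abort("duplicated library labels")
  libraries
}

#' Classify CD points into quadrants
#'
#' Attaches the reference lines and quadrant labels of a CD plot.
#' Thresholds default to the median of each axis across the compared
#' libraries; with fewer than two points no thresholds can be derived
#' and the quadrant is undefined (with a warning).
#'
#' @param points A `cd_table`.
#' @param x_threshold,y_threshold Optional fixed reference lines for the
#'   median-Tanimoto (x) and scaffold-AUC (y) axes.
#' @return A list of class `cd_plot_data`: `points` (with a `quadrant`
#'   column), `x_threshold`, `y_threshold`, `color_bounds`,
#'   `size_bounds`.
#' @export
cd_plot_data <- function(points, x_threshold = NULL, y_threshold = NULL) {
  df <- as_tibble(points)
  need <- c("library", "median_tanimoto", "scaffold_auc",
            "property_diversity", "n_compounds")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing CD column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) < 2L && (is.null(x_threshold) || is.null(y_threshold))) {
    warn("fewer than two libraries: no thresholds derivable, quadrant undefined")
    df$quadrant <- NA_character_
    tx <- x_threshold %||% NA_real_
    ty <- y_threshold %||% NA_real_
  } else {
    tx <- x_threshold %||% median(df$median_tanimoto)
    ty <- y_threshold %||% median(df$scaffold_auc)
    df$quadrant <- dplyr::case_when(
      df$median_tanimoto <= tx & df$scaffold_auc <= ty ~ "diverse: fingerprints & scaffolds",
      df$median_tanimoto <= tx & df$scaffold_auc > ty ~ "diverse: fingerprints only",
      df$median_tanimoto > tx & df$scaffold_auc <= ty ~ "diverse: scaffolds only",
      TRUE ~ "low diversity: both"
    )
  }
  out <- list(points = df, x_threshold = tx, y_threshold = ty,
              color_bounds = range(df$property_diversity),
              size_bounds = range(df$n_compounds))
  class(out) <- "cd_plot_data"
  out
}

#' @export
print.cd_plot_data <- function(x, ...) {
  cat(sprintf("CD plot data: %d libraries (x threshold %.3f, y threshold %.3f)\n",
              nrow(x$points), x$x_threshold, x$y_threshold))
  print(x$points)
  invisible(x)
}

#' @rdname cd_plot_data
#' @param x A `cd_plot_data` object.
#' @param ... Unused.
#' @export
tidy.cd_plot_data <- function(x, ...) x$points

#' @rdname cd_plot_data
#' @param object A `cd_plot_data` (or `cd_table`) object.
#' @export
autoplot.cd_plot_data <- function(object, ...) {
  df <- object$points
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$median_tanimoto,
                                        .data$scaffold_auc))
  if (is.finite(object$x_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$x_threshold,
                                 linetype = "dashed", colour = "grey50")
  }
  if (is.finite(object$y_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$y_threshold,
                                 linetype = "dashed", colour = "grey50")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_compounds,
                                     fill = .data$property_diversity),
                        shape = 21, colour = "grey20", alpha = 0.9) +
    ggplot2::geom_text(ggplot2::aes(label = .data$library),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_fill_gradient(low = "#08306b", high = "#9ecae1",
                                 limits = object$color_bounds) +
    ggplot2::labs(
      x = "median Tanimoto similarity (166-bit keys; lower = more diverse)",
      y = "scaffold recovery AUC (lower = more diverse)",
      size = "compounds", fill = "property\ndiversity",
      title = "Consensus Diversity plot"
    ) +
    ggplot2::theme_bw()
}

#' @rdname cd_plot_data
#' @export
autoplot.cd_table <- function(object, ...) {
  autoplot(cd_plot_data(object), ...)
}
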