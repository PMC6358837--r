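#' Bemis-Murcko molecular framework
#'
#' Strips every acyclic terminal substituent, keeping all ring systems,
#' the linkers connecting them, and atoms attached to that core by a
#' double or triple bond (the common framework convention: exocyclic
#' carbonyls survive, whole acyl side chains do not). Atom types and
#' bond orders are retained; E/Z bond stereo is not carried into the
#' scaffold. Acyclic molecules have no framework and give `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES; `NA` for
#'   acyclic or unparseable inputs.
#' @export
murcko_scaffold <- function(smiles) {
  can <- canonical_smiles(smiles)
  out <- rep(NA_character_, length(smiles))
  ringed <- which(!is.na(can) & smiles_has_ring(can))
  if (!length(ringed)) return(out)
  sd <- ob_sdfset(can[ringed])
  tags <- npp_tags(length(ringed))
  molfiles <- character(length(ringed))
  has_frame <- logical(length(ringed))
  for (j in seq_along(ringed)) {
    i <- sd$idx[j]
    if (is.na(i)) next
    g <- sdf_graph(sd$sdfset[[i]])
    keep <- framework_atoms(g)
    if (is.null(keep)) next
    molfiles[j] <- framework_molfile(g, keep, tags[j])
    has_frame[j] <- TRUE
  }
  if (!any(has_frame)) return(out)
  smi <- ob_molfile_to_smiles(molfiles[has_frame])
  hit <- match(tags[has_frame], names(smi))
  out[ringed[has_frame]] <- ifelse(is.na(hit), NA_character_,
                                   unname(smi[hit]))
  out
}

#' Scaffold frequency profile of a library
#'
#' Extracts the Bemis-Murcko framework of every compound, ranks
#' scaffolds by frequency (ties broken by lexicographic order of the
#' canonical scaffold SMILES, so the ranking is deterministic), and
#' attaches the cyclic-system recovery curve and its AUC. Acyclic
#' molecules carry no cyclic system: they are excluded from the scaffold
#' table and counted in `n_acyclic`.
#'
#' @param data A (curated) library tibble with `smiles` (and optionally
#'   `id`) columns, or a character vector of SMILES.
#' @param name Library label.
#' @return An object of class `scaffold_profile` with fields
#'   `library_name`, `table` (tibble: rank, scaffold, count, pct),
#'   `n_compounds`, `n_scaffolds`, `n_acyclic`, `curve` (tibble: x, y)
#'   and `auc`.
#' @export
scaffold_profile <- function(data, name = NULL) {
  if (is.character(data)) data <- tibble(smiles = data)
  df <- as_tibble(data)
  if (!"smiles" %in% names(df)) abort("`data` needs a `smiles` column")
  if (nrow(df) == 0L) abort("cannot profile an empty library")
  name <- name %||% attr(data, "library_name") %||% "library"
  scaf <- murcko_scaffold(df$smiles)
  if (any(is.na(canonical_smiles(df$smiles)))) {
    abort("library contains unparseable structures; curate it first")
  }
  tab <- tibble(scaffold = scaf[!is.na(scaf)]) |>
    count(.data$scaffold, name = "count") |>
    arrange(desc(.data$count), .data$scaffold) |>
    mutate(rank = row_number(), pct = .data$count / nrow(df)) |>
    select("rank", "scaffold", "count", "pct")
  if (nrow(tab) == 0L) abort("library has no cyclic system: no scaffolds to profile")
  curve <- recovery_curve(tab$count)
  out <- list(
    library_name = name,
    table = tab,
    n_compounds = nrow(df),
    n_scaffolds = nrow(tab),
    n_acyclic = sum(is.na(scaf)),
    curve = curve,
    auc = recovery_auc(curve, warn_degenerate = FALSE)
  )
  class(out) <- "scaffold_profile"
  out
}

#' Cyclic-system recovery curve
#'
#' For scaffold counts sorted in decreasing order, the curve through the
#' points (i/n, C_i/N') for i = 1..n, with C_i the cumulative count of
#' the i most frequent scaffolds and N' the number of scaffold-bearing
#' compounds, prepended with (0, 0). The curve is non-decreasing and
#' concave; it is the diagonal exactly when all counts are equal.
#'
#' @param counts Positive scaffold frequencies (any order).
#' @return A tibble with columns `x` (cumulative fraction of scaffolds)
#'   and `y` (cumulative fraction of compounds).
#' @export
recovery_curve <- function(counts) {
  if (inherits(counts, "scaffold_profile")) counts <- counts$table$count
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts <= 0)) {
    abort("`counts` must be a non-empty vector of positive frequencies")
  }
  counts <- sort(counts, decreasing = TRUE)
  n <- length(counts)
  tibble(x = c(0, seq_len(n) / n),
         y = c(0, cumsum(counts) / sum(counts)))
}

#' Area under a recovery curve
#'
#' Trapezoidal area under the cyclic-system recovery curve. Ranges from
#' 0.5 (all scaffold counts equal: maximal scaffold diversity) to 1
#' (one scaffold dominates); lower values indicate higher scaffold
#' diversity.
#'
#' @param curve A curve tibble from [recovery_curve()] (or a
#'   `scaffold_profile`).
#' @param warn_degenerate Warn when the curve has a single scaffold
#'   (two points), where the AUC is the uninformative 0.5.
#' @return The AUC, a number in \[0.5, 1\].
#' @export
recovery_auc <- function(curve, warn_degenerate = TRUE) {
  if (inherits(curve, "scaffold_profile")) curve <- curve$curve
  x <- curve$x
  y <- curve$y
  if (length(x) < 2L) abort("a recovery curve needs at least two points")
  if (length(x) == 2L && warn_degenerate) {
    warn("single-scaffold profile: recovery curve is degenerate and its AUC (0.5) is uninformative")
  }
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Fraction of compounds covered by the top n scaffolds
#'
#' Cumulative count of the `n` most frequent scaffolds divided by the
#' total number of compounds in the library, acyclic molecules included
#' in the denominator.
#'
#' @param profile A `scaffold_profile`.
#' @param n Number of top scaffolds, between 1 and `n_scaffolds`.
#' @return A fraction in (0, 1].
#' @export
top_n_coverage <- function(profile, n) {
  stopifnot(inherits(profile, "scaffold_profile"))
  if (n < 1L || n > profile$n_scaffolds) {
    abort(sprintf("`n` must be between 1 and n_scaffolds (%d)",
                  profile$n_scaffolds))
  }
  sum(profile$table$count[seq_len(n)]) / profile$n_compounds
}

#' @export
print.scaffold_profile <- function(x, ...) {
  cat("Scaffold profile of", x$library_name, "\n")
  cat(sprintf("  %d compounds, %d scaffolds, %d acyclic; recovery AUC %.4f\n",
              x$n_compounds, x$n_scaffolds, x$n_acyclic, x$auc))
  print(head(x$table, 10))
  invisible(x)
}

#' @rdname scaffold_profile
#' @param x A `scaffold_profile`.
#' @param ... Unused.
#' @export
tidy.scaffold_profile <- function(x, ...) x$table

#' @rdname scaffold_profile
#' @export
glance.scaffold_profile <- function(x, ...) {
  tibble(library = x$library_name, n_compounds = x$n_compounds,
         n_scaffolds = x$n_scaffolds, n_acyclic = x$n_acyclic,
         auc = x$auc)
}

#' @rdname scaffold_profile
#' @param object A `scaffold_profile`.
#' @export
autoplot.scaffold_profile <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "fraction of scaffolds (ranked by frequency)",
      y = "fraction of compounds recovered",
      title = sprintf("Cyclic-system recovery curve: %s (AUC %.3f)",
                      object$library_name, object$auc)
    ) +
    ggplot2::theme_bw()
}
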