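#' Write a plot to SVG
#'
#' @param plot A ggplot object.
#' @param path Output file (.svg).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
write_plot <- function(plot, path, width = 7, height = 5) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Run configuration for a multi-library profiling run
#'
#' @param libraries A data frame (or list coercible to one) with columns
#'   `path`, `label` and optionally `format`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in, and used by, every stochastic
#'   stage.
#' @param stages Character subset of
#'   `c("properties", "scaffolds", "fingerprints", "chemspace", "cd")`.
#' @param tsne Run the t-SNE embedding inside the chemspace stage
#'   (needs enough compounds for the chosen perplexity).
#' @param perplexity t-SNE perplexity.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(libraries, out_dir, seed = 42L,
                       stages = c("properties", "scaffolds",
                                  "fingerprints", "chemspace", "cd"),
                       tsne = FALSE, perplexity = 30) {
  libs <- as_tibble(libraries)
  if (!all(c("path", "label") %in% names(libs))) {
    abort("`libraries` needs `path` and `label` columns")
  }
  if (!"format" %in% names(libs)) libs$format <- "auto"
  if (anyDuplicated(libs$label)) {
    abort(paste0("duplicated library label(s): ",
                 paste(unique(libs$label[duplicated(libs$label)]), collapse = ", ")))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(libraries = libs, out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, tsne = tsne, perplexity = perplexity),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields `libraries` (list of `path`,
#'   `label`, optional `format`), `out_dir`, `seed`, `stages`, `tsne`,
#'   `perplexity`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  libs <- bind_rows(lapply(y$libraries, as_tibble))
  args <- list(libraries = libs, out_dir = y$out_dir %||% ".")
  for (field in c("seed", "stages", "tsne", "perplexity")) {
    if (!is.null(y[[field]])) args[[field]] <- y[[field]]
  }
  do.call(run_config, args)
}

stage_msg <- function(fmt, ...) {
  message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
}

#' Profile one or more libraries end to end
#'
#' Reads and curates every configured library, runs the requested
#' stages, and writes per-stage CSV/JSON/SVG artifacts plus a Markdown
#' summary stitching them together. Every artifact records the seed and
#' the engine/decision metadata that produced it; re-running with the
#' same configuration reproduces all outputs (stochastic stages
#' seed-for-seed).
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the curated libraries, the per-stage
#'   results and the paths written.
#' @export
run_profile <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add_path <- function(p) paths[[length(paths) + 1L]] <<- p

  meta <- list(
    seed = config$seed,
    engines = as.list(property_engine_metadata()),
    fingerprints = "OpenBabel MACCS (166 structural keys)",
    property_scaling = "min-max, union scope across compared libraries",
    property_diversity_statistic = "mean pairwise Euclidean distance",
    duplicate_definition = "canonical parent SMILES, stereochemistry included"
  )
  jsonlite::write_json(meta, file.path(out, "run-metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  add_path(file.path(out, "run-metadata.json"))

  stage_msg("curating %d libraries", nrow(config$libraries))
  libs <- list()
  for (i in seq_len(nrow(config$libraries))) {
    row <- config$libraries[i, ]
    raw <- read_library(row$path, format = row$format, name = row$label)
    lib <- curate_library(raw, name = row$label)
    libs[[row$label]] <- lib
    write_library(lib, file.path(out, paste0(row$label, "-curated.csv")), "csv")
    jsonlite::write_json(unclass(curation_report(lib)),
                         file.path(out, paste0(row$label, "-curation.json")),
                         auto_unbox = TRUE, pretty = TRUE)
    add_path(file.path(out, paste0(row$label, "-curated.csv")))
  }

  results <- list(libraries = libs)
  props_all <- NULL
  if (any(c("properties", "chemspace", "cd") %in% config$stages)) {
    stage_msg("computing property tables")
    props_all <- bind_rows(imap(libs, function(lib, nm) {
      p <- compute_properties(lib)
      p$library <- nm
      p
    }))
  }

  if ("properties" %in% config$stages) {
    readr::write_csv(props_all, file.path(out, "properties.csv"))
    summ <- summarize_properties(props_all)
    readr::write_csv(select(as_tibble(summ), -"outliers"),
                     file.path(out, "property-summary.csv"))
    jsonlite::write_json(select(as_tibble(summ), -"outliers"),
                         file.path(out, "property-summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_plot(autoplot(summ), file.path(out, "property-boxplots.svg"),
               width = 9, height = 6)
    results$property_summary <- summ
    add_path(file.path(out, "properties.csv"))
  }

  if ("scaffolds" %in% config$stages) {
    stage_msg("scaffold analysis")
    profs <- imap(libs, function(lib, nm) scaffold_profile(lib, name = nm))
    readr::write_csv(bind_rows(map(profs, tidy), .id = "library"),
                     file.path(out, "scaffolds.csv"))
    jsonlite::write_json(
      map(profs, function(p) list(auc = p$auc, curve = p$curve,
                                  n_scaffolds = p$n_scaffolds,
                                  n_acyclic = p$n_acyclic)),
      file.path(out, "scaffold-curves.json"), auto_unbox = TRUE, digits = NA)
    for (nm in names(profs)) {
      write_plot(autoplot(profs[[nm]]),
                 file.path(out, paste0(nm, "-recovery-curve.svg")))
    }
    results$scaffold_profiles <- profs
    add_path(file.path(out, "scaffolds.csv"))
  }

  fps_all <- NULL
  if (any(c("fingerprints", "chemspace", "cd") %in% config$stages)) {
    stage_msg("fingerprints")
    fps_all <- imap(libs, function(lib, nm) maccs_fingerprints(lib))
  }

  if ("fingerprints" %in% config$stages) {
    stats <- imap(fps_all, function(fp, nm) {
      glance(similarity_stats(fp, seed = config$seed))
    })
    jsonlite::write_json(bind_rows(stats, .id = "library"),
                         file.path(out, "fingerprint-diversity.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$fingerprint_stats <- stats
    add_path(file.path(out, "fingerprint-diversity.json"))
  }

  if ("chemspace" %in% config$stages) {
    stage_msg("chemical-space embedding")
    scaled <- scale_properties(props_all, scope = "union")
    pca <- chem_pca(scaled, k = 2)
    readr::write_csv(tidy(pca), file.path(out, "pca-coordinates.csv"))
    jsonlite::write_json(
      list(loadings = as.data.frame(pca$loadings),
           var_explained = pca$var_explained),
      file.path(out, "pca-loadings.json"), auto_unbox = TRUE, digits = NA)
    write_plot(autoplot(pca), file.path(out, "pca.svg"))
    results$pca <- pca
    if (isTRUE(config$tsne)) {
      fpm <- do.call(rbind, map(fps_all, unclass))
      groups <- rep(names(fps_all), vapply(fps_all, nrow, integer(1)))
      ts <- chem_tsne(fpm, perplexity = config$perplexity,
                      seed = config$seed, groups = groups)
      readr::write_csv(tidy(ts), file.path(out, "tsne-coordinates.csv"))
      write_plot(autoplot(ts), file.path(out, "tsne.svg"))
      results$tsne <- ts
    }
    add_path(file.path(out, "pca-coordinates.csv"))
  }

  if ("cd" %in% config$stages) {
    stage_msg("consensus diversity")
    cd <- cd_table(libs, seed = config$seed)
    cdd <- cd_plot_data(cd)
    readr::write_csv(tidy(cdd), file.path(out, "cd-points.csv"))
    jsonlite::write_json(tidy(cdd), file.path(out, "cd-points.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_plot(autoplot(cdd), file.path(out, "cd-plot.svg"))
    results$cd <- cdd
    add_path(file.path(out, "cd-points.csv"))
  }

  write_report_md(config, libs, results, out)
  add_path(file.path(out, "report.md"))
  stage_msg("done: %s", out)
  invisible(c(results, list(paths = paths)))
}

write_report_md <- function(config, libs, results, out) {
  lines <- c(
    "# Library profiling report", "",
    sprintf("Seed: %d. Stages: %s.", config$seed,
            paste(config$stages, collapse = ", ")),
    "", "## Libraries", "",
    "| library | input | invalid | salts stripped | neutralized | duplicates | curated |",
    "|---|---|---|---|---|---|---|")
  for (nm in names(libs)) {
    r <- curation_report(libs[[nm]])
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d | %d | %d |", nm,
                              r$n_input, r$n_invalid, r$n_salts_stripped,
                              r$n_neutralized, r$n_duplicates_removed,
                              r$n_output))
  }
  if (!is.null(results$scaffold_profiles)) {
    lines <- c(lines, "", "## Scaffold diversity", "",
               "| library | scaffolds | acyclic | recovery AUC |", "|---|---|---|---|")
    for (nm in names(results$scaffold_profiles)) {
      p <- results$scaffold_profiles[[nm]]
      lines <- c(lines, sprintf("| %s | %d | %d | %.4f |", nm,
                                p$n_scaffolds, p$n_acyclic, p$auc))
    }
  }
  if (!is.null(results$cd)) {
    pts <- results$cd$points
    lines <- c(lines, "", "## Consensus Diversity", "",
               "| library | median Tanimoto | scaffold AUC | property diversity | n | quadrant |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.4f | %.4f | %.4f | %d | %s |",
                       pts$library, pts$median_tanimoto, pts$scaffold_auc,
                       pts$property_diversity, pts$n_compounds, pts$quadrant))
  }
  lines <- c(lines, "", "## Decisions in force", "",
             paste0("- ", property_engine_metadata()["descriptors"]),
             paste0("- ", property_engine_metadata()["RB"]),
             "- Fingerprints: OpenBabel MACCS (166 structural keys); Tanimoto; all-zero pair convention T = 1",
             "- Property scaling: min-max over the union of compared libraries; property diversity: mean pairwise Euclidean distance",
             "- Duplicates: canonical parent SMILES, stereochemistry included",
             sprintf("- Seed: %d (recorded in run-metadata.json)", config$seed))
  readr::write_lines(lines, file.path(out, "report.md"))
}
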