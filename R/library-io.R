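#' @name library-io
#' @title Reading and writing compound libraries
#'
#' @description A compound library is a tibble with one row per compound
#' and the record schema `id`, `name`, `smiles`, `journal`, `doi`,
#' `year`, `kingdom`, `genus`, `species`, `location`, `activity`, plus a
#' logical `valid` column flagging records whose structure could not be
#' parsed. Only `id` and `smiles` are required on input; missing metadata
#' columns are filled with `NA`.
NULL

library_schema <- c("id", "name", "smiles", "journal", "doi", "year",
                    "kingdom", "genus", "species", "location", "activity")

empty_library <- function(name = NULL) {
  out <- tibble(
    id = character(), name = character(), smiles = character(),
    journal = character(), doi = character(), year = integer(),
    kingdom = character(), genus = character(), species = character(),
    location = character(), activity = character(), valid = logical()
  )
  attr(out, "library_name") <- name
  out
}

complete_schema <- function(df) {
  for (col in library_schema) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "year") NA_integer_ else NA_character_
    }
  }
  df$year <- suppressWarnings(as.integer(df$year))
  for (col in setdiff(library_schema, "year")) df[[col]] <- as.character(df[[col]])
  df[, c(library_schema, intersect("valid", names(df))), drop = FALSE]
}

validate_records <- function(df, year_range = NULL) {
  if (nrow(df) == 0L) return(df)
  if (any(is.na(df$id) | !nzchar(df$id))) {
    abort("every record needs a non-empty id")
  }
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    abort(paste0("duplicated record ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(year_range) && any(!is.na(df$year))) {
    bad <- !is.na(df$year) & (df$year < year_range[1] | df$year > year_range[2])
    if (any(bad)) {
      warn(sprintf("%d record(s) with year outside [%d, %d]; year set to NA",
                   sum(bad), year_range[1], year_range[2]))
      df$year[bad] <- NA_integer_
    }
  }
  df
}

#' Read a compound library
#'
#' Parses a library from CSV (one schema column per field), a SMILES list
#' (one molecule per line, optionally followed by whitespace and an id),
#' or SDF (data fields mapped to schema fields). Structures that cannot
#' be parsed are retained and flagged `valid = FALSE`, never silently
#' dropped. Input order is preserved.
#'
#' @param path File to read.
#' @param format `"csv"`, `"smiles"`, `"sdf"`, or `"auto"` to infer from
#'   the file extension.
#' @param schema Named character vector mapping schema fields to column
#'   (or SDF data-field) names in the file, e.g.
#'   `c(smiles = "SMILES", id = "ID")`. Unmapped fields use their own
#'   names.
#' @param name Library label stored in the `library_name` attribute;
#'   defaults to the file base name.
#' @param year_range Optional `c(min, max)`; years outside it are set to
#'   `NA` with a warning.
#' @return A tibble in the library schema with a `valid` column.
#' @export
read_library <- function(path, format = c("auto", "csv", "smiles", "sdf"),
                         schema = NULL, name = NULL, year_range = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read library file: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", smi = "smiles", smiles = "smiles",
                     txt = "smiles", sdf = "sdf", mol = "sdf",
                     abort(paste0("cannot infer format from extension of ", path)))
  }
  name <- name %||% tools::file_path_sans_ext(basename(path))
  df <- switch(format,
               csv = read_library_csv(path, schema),
               smiles = read_library_smiles(path),
               sdf = read_library_sdf(path, schema))
  if (nrow(df) == 0L) return(empty_library(name))
  df <- complete_schema(df)
  if (!"valid" %in% names(df)) {
    df$valid <- !is.na(canonical_smiles(df$smiles))
  }
  df <- validate_records(df, year_range)
  out <- as_tibble(df)
  attr(out, "library_name") <- name
  out
}

read_library_csv <- function(path, schema) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L && ncol(raw) == 0L) return(raw)
  cols <- setNames(library_schema, library_schema)
  if (!is.null(schema)) cols[names(schema)] <- schema
  if (!cols[["smiles"]] %in% names(raw)) {
    abort(paste0("schema error: CSV is missing the SMILES column '",
                 cols[["smiles"]], "'"))
  }
  df <- tibble(.rows = nrow(raw))
  for (field in library_schema) {
    src <- cols[[field]]
    df[[field]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  if (all(is.na(df$id))) df$id <- sprintf("CPD%04d", seq_len(nrow(df)))
  df
}

read_library_smiles <- function(path) {
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(tibble(id = character(), smiles = character()))
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  id <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
               character(1))
  if (all(is.na(id))) id <- sprintf("CPD%04d", seq_along(smiles))
  tibble(id = id, smiles = smiles)
}

read_library_sdf <- function(path, schema) {
  txt <- readr::read_file(path)
  recs <- strsplit(txt, "\\$\\$\\$\\$\r?\n?")[[1]]
  recs <- recs[grepl("M  END", recs, fixed = TRUE)]
  if (!length(recs)) return(tibble(id = character(), smiles = character()))
  tags <- npp_tags(length(recs))
  retitled <- vapply(seq_along(recs), function(i) {
    sub("^[^\n]*", tags[i], recs[i])
  }, character(1))
  smi <- ob_molfile_to_smiles(paste0(retitled, "\n$$$$"))
  con <- textConnection(txt)
  on.exit(close(con))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con)))
  fields <- ChemmineR::datablock(sdfset)
  cols <- setNames(library_schema, library_schema)
  if (!is.null(schema)) cols[names(schema)] <- schema
  df <- tibble(.rows = length(recs))
  for (field in library_schema) {
    df[[field]] <- vapply(seq_along(recs), function(i) {
      fb <- fields[[i]]
      if (cols[[field]] %in% names(fb)) fb[[cols[[field]]]] else NA_character_
    }, character(1))
  }
  hit <- match(tags, names(smi))
  df$smiles <- ifelse(is.na(hit), NA_character_, unname(smi[hit]))
  df$valid <- !is.na(df$smiles)
  if (all(is.na(df$id))) {
    titles <- vapply(recs, function(r) trimws(sub("\n.*$", "", r)), character(1))
    df$id <- ifelse(nzchar(titles), titles, sprintf("CPD%04d", seq_along(recs)))
  }
  df
}

#' Write a compound library
#'
#' Round-trip safe with [read_library()]: structures and schema fields
#' survive a write/read cycle. Missing values become empty cells (CSV) or
#' omitted data fields (SDF), never the string `"NA"`.
#'
#' @param library A library tibble (schema of [read_library()]).
#' @param path Output file.
#' @param format `"csv"`, `"smiles"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("csv", "smiles", "sdf")) {
  format <- match.arg(format)
  df <- complete_schema(as_tibble(library))
  if (format == "csv") {
    readr::write_csv(df[, library_schema], path, na = "")
  } else if (format == "smiles") {
    readr::write_lines(paste(df$smiles, df$id), path)
  } else {
    if (nrow(df) == 0L) {
      readr::write_file("", path)
    } else {
      sdfstr <- ChemmineOB::convertFormat(
        "SMI", "SDF", source = paste0(paste(df$smiles, df$id), "\n", collapse = ""))
    recs <- strsplit(sdfstr, "\\$\\$\\$\\$\n?")[[1]]
      recs <- recs[grepl("M  END", recs, fixed = TRUE)]
      if (length(recs) != nrow(df)) {
        abort("SDF export failed: library contains unparseable structures")
      }
      out <- vapply(seq_along(recs), function(i) {
        meta <- df[i, setdiff(library_schema, "id")]
        keepcol <- !vapply(meta, is.na, logical(1))
        fields <- paste0("> <", names(meta)[keepcol], ">\n",
                         unlist(meta[keepcol]), "\n", collapse = "\n")
        paste0(sub("\n+$", "\n", recs[i]), fields, "\n$$$$")
      }, character(1))
      readr::write_lines(out, path)
    }
  }
  invisible(path)
}

#' Summarize library metadata
#'
#' Counts compounds by publication year and by kingdom, and the number of
#' distinct genera per kingdom (case-insensitive, whitespace-trimmed).
#' Missing metadata is grouped under `"unknown"`. Kingdom counts always
#' include the three schema levels (Plantae, Fungi, Other), zero-filled.
#'
#' @param library A library tibble.
#' @return A list of class `library_metadata` with tibbles `by_year`,
#'   `by_kingdom` and `genera_per_kingdom`, plus `n_compounds`.
#' @export
metadata_summary <- function(library) {
  df <- as_tibble(library)
  year_chr <- ifelse(is.na(df$year), "unknown", as.character(df$year))
  by_year <- df |>
    mutate(year = year_chr) |>
    count(.data$year, name = "n") |>
    arrange(.data$year)
  kingdom_levels <- c("Plantae", "Fungi", "Other")
  kd <- ifelse(is.na(df$kingdom) | !nzchar(trimws(df$kingdom)),
               "unknown", trimws(df$kingdom))
  kd <- ifelse(kd %in% c(kingdom_levels, "unknown"), kd, "Other")
  by_kingdom <- tibble(kingdom = kd) |>
    count(.data$kingdom, name = "n")
  for (lev in kingdom_levels) {
    if (!lev %in% by_kingdom$kingdom) {
      by_kingdom <- bind_rows(by_kingdom, tibble(kingdom = lev, n = 0L))
    }
  }
  by_kingdom <- by_kingdom |>
    mutate(kingdom = factor(.data$kingdom, levels = c(kingdom_levels, "unknown"))) |>
    arrange(.data$kingdom) |>
    mutate(kingdom = as.character(.data$kingdom))
  genus_norm <- tolower(trimws(ifelse(is.na(df$genus), "unknown", df$genus)))
  genera <- tibble(kingdom = kd, genus = genus_norm) |>
    filter(.data$genus != "unknown") |>
    distinct() |>
    count(.data$kingdom, name = "n_genera")
  out <- list(n_compounds = nrow(df), by_year = by_year,
              by_kingdom = by_kingdom, genera_per_kingdom = genera)
  class(out) <- "library_metadata"
  out
}

#' @export
print.library_metadata <- function(x, ...) {
  cat("Library metadata:", x$n_compounds, "compounds\n")
  cat("By kingdom:\n")
  print(x$by_kingdom, n = Inf)
  cat("Distinct genera per kingdom:\n")
  print(x$genera_per_kingdom, n = Inf)
  cat("Years:", nrow(x$by_year), "distinct values\n")
  invisible(x)
}
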