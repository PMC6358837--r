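#' Compute the six physicochemical properties
#'
#' For every structure: molecular weight (MW, g/mol, average atomic
#' masses), calculated octanol/water partition coefficient (SlogP,
#' Wildman-Crippen atom contributions), topological polar surface area
#' (TPSA, Angstrom^2, Ertl), rotatable-bond count (RB: single, non-ring
#' bonds between two non-terminal heavy atoms, excluding amide C-N),
#' H-bond donor count (HBD: O-H and N-H donors) and H-bond acceptor
#' count (HBA: pattern-based N/O acceptors excluding pyrrole-type N;
#' amide N is counted). MW, SlogP, TPSA, HBD and HBA come from the
#' OpenBabel descriptor engine; RB is computed on the molecular graph.
#' The definitions in force are recorded in the result's `engine`
#' attribute.
#'
#' Deterministic: identical canonical structures give identical vectors,
#' whatever SMILES spelling they arrive in.
#'
#' @param data A library tibble with a `smiles` column (and optionally
#'   `id`), or a character vector of SMILES.
#' @return A tibble with columns `id`, `MW`, `SlogP`, `TPSA`, `RB`,
#'   `HBD`, `HBA`, one row per input record, in input order.
#' @export
compute_properties <- function(data) {
  if (is.character(data)) {
    data <- tibble(id = sprintf("CPD%04d", seq_along(data)), smiles = data)
  }
  df <- as_tibble(data)
  if (!"smiles" %in% names(df)) abort("`data` needs a `smiles` column")
  if (!"id" %in% names(df)) df$id <- sprintf("CPD%04d", seq_len(nrow(df)))
  if (nrow(df) == 0L) {
    return(tibble(id = character(), MW = double(), SlogP = double(),
                  TPSA = double(), RB = integer(), HBD = integer(),
                  HBA = integer()))
  }
  can <- canonical_smiles(df$smiles)
  if (anyNA(can)) {
    abort(paste0("invalid structure(s) for record id(s): ",
                 paste(head(df$id[is.na(can)], 5), collapse = ", ")))
  }
  props <- ob_properties(can)
  heavy <- heavy_atom_count(props$formula)
  rb <- integer(nrow(df))
  needs_graph <- heavy >= 4L
  if (any(needs_graph)) {
    sd <- ob_sdfset(can[needs_graph])
    rb[needs_graph] <- vapply(sd$idx, function(i) {
      rotatable_bond_count(sdf_graph(sd$sdfset[[i]]))
    }, integer(1))
  }
  out <- tibble(
    id = df$id,
    MW = props$MW,
    SlogP = props$logP,
    TPSA = props$TPSA,
    RB = rb,
    HBD = as.integer(props$HBD),
    HBA = as.integer(props$HBA2)
  )
  attr(out, "engine") <- property_engine_metadata()
  out
}

property_engine_metadata <- function() {
  c(descriptors = "OpenBabel 3.1 (MW: average atomic masses; SlogP: Wildman-Crippen; TPSA: Ertl; HBD: O-H/N-H donors; HBA: pattern-based N/O excluding pyrrole-type N, amide N counted)",
    RB = "npprofiler graph rule: single non-ring bonds between non-terminal heavy atoms, amide C-N excluded")
}

property_names <- c("MW", "SlogP", "TPSA", "RB", "HBD", "HBA")

#' Box-plot summary of one numeric column
#'
#' Mean, median, standard deviation, quartiles (midpoint-interpolation
#' rule, `quantile(type = 5)`, so `c(1, 2, 3, 4)` gives Q1 = 1.5 and
#' Q3 = 3.5), Tukey whiskers clipped to the data (the most extreme
#' observations within `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`) and the
#' outliers beyond them.
#'
#' @param values Numeric vector with at least one finite value.
#' @return One-row tibble with `n`, `min`, `q1`, `median`, `mean`, `q3`,
#'   `max`, `sd`, `whisker_lo`, `whisker_hi`, `n_outliers` and a list
#'   column `outliers`.
#' @export
box_summary <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) abort("box_summary() needs at least one finite value")
  q <- quantile(x, c(0.25, 0.75), type = 5, names = FALSE)
  iqr <- q[2] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[2] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  tibble(
    n = length(x),
    min = min(x),
    q1 = q[1],
    median = median(x),
    mean = mean(x),
    q3 = q[2],
    max = max(x),
    sd = if (length(x) > 1L) sd(x) else 0,
    whisker_lo = min(x[inside]),
    whisker_hi = max(x[inside]),
    n_outliers = sum(!inside),
    outliers = list(x[!inside])
  )
}

#' Summarize a property table
#'
#' Applies [box_summary()] to each of the six properties (or any numeric
#' columns requested).
#'
#' @param properties A property table from [compute_properties()];
#'   optionally with a `library` column, in which case summaries are per
#'   library.
#' @param columns Columns to summarize.
#' @return A tibble of class `property_summary`, one row per (library,)
#'   property.
#' @export
summarize_properties <- function(properties, columns = property_names) {
  df <- as_tibble(properties)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing property column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  grouped <- "library" %in% names(df)
  split_by <- if (grouped) split(df, df$library) else list(df)
  out <- imap(split_by, function(part, lib) {
    res <- map(columns, function(col) {
      s <- box_summary(part[[col]])
      s$property <- col
      s
    })
    res <- bind_rows(res)
    if (grouped) res$library <- lib
    res
  })
  out <- bind_rows(out) |>
    select(any_of(c("library", "property")), everything())
  class(out) <- c("property_summary", class(out))
  out
}

#' @importFrom dplyr any_of
#' @export
autoplot.property_summary <- function(object, ...) {
  df <- as_tibble(object)
  out_df <- df |>
    select(any_of(c("library", "property")), "outliers") |>
    tidyr::unnest("outliers")
  if (!"library" %in% names(df)) {
    df$library <- "library"
    out_df$library <- "library"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$library)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", fill = "grey85"
    ) +
    ggplot2::geom_point(data = out_df, ggplot2::aes(y = .data$outliers),
                        shape = 8, colour = "red", size = 1.2) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Physicochemical property distributions") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
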