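#' Curation policy
#'
#' Options controlling [curate_library()]. The defaults implement the
#' usual "wash": keep the largest organic fragment of multi-fragment
#' records (salt stripping), neutralize charges where a neutral valid
#' valence exists (anionic acids are protonated, protonated amines
#' deprotonated; permanent charges such as quaternary ammonium are
#' retained), and remove exact canonical duplicates, stereochemistry
#' included, keeping the first occurrence.
#'
#' @param strip_salts Reduce multi-fragment structures to the largest
#'   organic fragment (most heavy atoms among carbon-containing
#'   fragments; ties broken by total atom count, then lexicographically
#'   smallest canonical SMILES).
#' @param neutralize Apply the neutralization rules.
#' @param deduplicate Remove records with identical canonical parent
#'   structures.
#' @return A list of class `curation_policy`.
#' @export
curation_policy <- function(strip_salts = TRUE, neutralize = TRUE,
                            deduplicate = TRUE) {
  structure(list(strip_salts = strip_salts, neutralize = neutralize,
                 deduplicate = deduplicate),
            class = "curation_policy")
}

#' Curate a compound library
#'
#' Standardizes structures and removes duplicates, producing a curated
#' library whose `smiles` column holds canonical parent structures. The
#' operation is idempotent: curating an already-curated library changes
#' nothing and reports zero removals. Records whose structure cannot be
#' parsed, and records with no organic fragment (salt-only entries), are
#' counted as invalid and excluded, so that always
#' `n_output = n_input - n_invalid - n_duplicates_removed`.
#'
#' @param records A library tibble (see [read_library()]).
#' @param policy A [curation_policy()].
#' @param name Library label; defaults to the input's `library_name`
#'   attribute.
#' @return A tibble of class `curated_library` with attributes `report`
#'   (a `curation_report`) and `provenance` (tibble of per-record
#'   curation actions).
#' @export
curate_library <- function(records, policy = curation_policy(), name = NULL) {
  df <- complete_schema(as_tibble(records))
  df <- validate_records(df)
  name <- name %||% attr(records, "library_name") %||% "library"
  n_input <- nrow(df)
  prov <- list()
  log_action <- function(ids, action) {
    if (length(ids)) prov[[length(prov) + 1L]] <<- tibble(id = ids, action = action)
  }

  can <- canonical_smiles(df$smiles)
  invalid <- is.na(can)
  log_action(df$id[invalid], "invalid structure")

  parent <- can
  n_salts <- 0L
  if (policy$strip_salts && any(!invalid)) {
    stripped <- strip_to_parent(parent[!invalid])
    no_organic <- is.na(stripped$parent)
    changed <- !no_organic & stripped$stripped
    log_action(df$id[!invalid][changed], "salt stripped")
    log_action(df$id[!invalid][no_organic], "removed: no organic fragment")
    n_salts <- sum(changed)
    parent[!invalid] <- stripped$parent
    invalid <- is.na(parent)
  }

  n_neutralized <- 0L
  if (any(!invalid)) {
    final <- canonical_smiles(parent[!invalid], neutralize = policy$neutralize)
    if (anyNA(final)) abort("internal error: canonical parent failed to re-parse")
    if (policy$neutralize) {
      changed <- final != parent[!invalid]
      n_neutralized <- sum(changed)
      log_action(df$id[!invalid][changed], "neutralized")
    }
    parent[!invalid] <- final
  }

  keep <- !invalid
  n_dup <- 0L
  if (policy$deduplicate) {
    dup <- keep & duplicated(ifelse(keep, parent, NA_character_), incomparables = NA)
    n_dup <- sum(dup)
    if (n_dup) {
      first_of <- function(s) df$id[which(keep & !dup & parent == s)][1L]
      log_action(df$id[dup],
                 paste0("duplicate of ", vapply(parent[dup], first_of, character(1))))
      keep <- keep & !dup
    }
  }

  out <- df[keep, , drop = FALSE]
  out$smiles <- parent[keep]
  out$valid <- NULL
  report <- structure(list(
    n_input = n_input,
    n_invalid = sum(invalid),
    n_salts_stripped = n_salts,
    n_neutralized = n_neutralized,
    n_duplicates_removed = n_dup,
    n_output = nrow(out)
  ), class = "curation_report")
  stopifnot(report$n_output == report$n_input - report$n_invalid -
              report$n_duplicates_removed)
  out <- as_tibble(out)
  class(out) <- c("curated_library", class(out))
  attr(out, "library_name") <- name
  attr(out, "report") <- report
  attr(out, "provenance") <- if (length(prov)) bind_rows(prov) else
    tibble(id = character(), action = character())
  out
}

# Largest-organic-fragment selection on canonical SMILES. Returns the
# chosen fragment (NA when no fragment contains carbon) and whether
# anything was removed.
strip_to_parent <- function(can) {
  frag_lists <- strsplit(can, ".", fixed = TRUE)
  multi <- lengths(frag_lists) > 1L
  parent <- can
  if (any(multi)) {
    parent[multi] <- vapply(frag_lists[multi], pick_parent_fragment, character(1))
  }
  list(parent = parent, stripped = multi)
}

pick_parent_fragment <- function(frags) {
  frags <- canonical_smiles(frags)
  if (anyNA(frags)) return(NA_character_)
  props <- ob_properties(frags)
  counts <- lapply(props$formula, parse_formula)
  heavy <- vapply(counts, function(ct) sum(ct[names(ct) != "H"]), numeric(1))
  total <- vapply(counts, sum, numeric(1))
  organic <- vapply(counts, function(ct) "C" %in% names(ct), logical(1))
  if (!any(organic)) return(NA_character_)
  ord <- order(!organic, -heavy, -total, frags)
  frags[ord[1L]]
}

#' Extract the curation report
#'
#' @param x A `curated_library`.
#' @return The `curation_report` stored on the library.
#' @export
curation_report <- function(x) {
  rep <- attr(x, "report")
  if (is.null(rep)) abort("not a curated library: no curation report attached")
  rep
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input records        %6d\n", x$n_input))
  cat(sprintf("  invalid / inorganic  %6d\n", x$n_invalid))
  cat(sprintf("  salts stripped       %6d\n", x$n_salts_stripped))
  cat(sprintf("  neutralized          %6d\n", x$n_neutralized))
  cat(sprintf("  duplicates removed   %6d\n", x$n_duplicates_removed))
  cat(sprintf("  curated output       %6d\n", x$n_output))
  invisible(x)
}

#' @rdname curation_report
#' @param x A `curated_library`.
#' @param ... Unused.
#' @export
glance.curated_library <- function(x, ...) {
  as_tibble(unclass(curation_report(x)))
}
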