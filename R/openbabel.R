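# Internal bridge to the OpenBabel backend (ChemmineOB / ChemmineR).
#
# Every batch conversion tags molecules with a synthetic title so that
# entries the toolkit drops (unparseable SMILES) can be re-aligned with
# their inputs; callers receive NA at those positions. All functions here
# are vectorized over molecules and make a constant number of backend
# calls per batch.

npp_tags <- function(n) sprintf("npp%07d", seq_len(n))

ob_neutralize_opts <- function() {
  data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE)
}

# Parse "SMILES\ttitle" lines returned by convertFormat into a named
# character vector (names = titles).
ob_parse_smiles_lines <- function(txt) {
  lines <- strsplit(txt %||% "", "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1L)
  ttl <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else "",
                character(1))
  setNames(smi, ttl)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the backend's canonical form, optionally applying
#' the charge-neutralization operation (protonate anions, deprotonate
#' protonated amines; permanent charges such as quaternary ammonium are
#' retained). Unparseable inputs yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param neutralize Apply the neutralization operation before
#'   canonicalizing.
#' @return Character vector of canonical SMILES, `NA` where the input
#'   could not be parsed.
#' @export
canonical_smiles <- function(smiles, neutralize = FALSE) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  s <- trimws(as.character(smiles))
  ok <- !is.na(s) & nzchar(s) & !grepl("[[:space:]]", s)
  if (!any(ok)) return(out)
  tags <- npp_tags(n)
  src <- paste0(paste(s[ok], tags[ok]), "\n", collapse = "")
  res <- if (neutralize) {
    ChemmineOB::convertFormat("SMI", "CAN", source = src,
                              options = ob_neutralize_opts())
  } else {
    ChemmineOB::convertFormat("SMI", "CAN", source = src)
  }
  got <- ob_parse_smiles_lines(res)
  hit <- match(tags, names(got))
  out[!is.na(hit)] <- unname(got[stats::na.omit(hit)])
  out
}

# SMILES batch -> ChemmineR SDFset plus a per-input index into the set
# (NA where conversion failed). Inputs are expected to be valid SMILES.
ob_sdfset <- function(smiles) {
  n <- length(smiles)
  tags <- npp_tags(n)
  s <- trimws(as.character(smiles))
  src <- paste0(paste(s, tags), "\n", collapse = "")
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", source = src)
  con <- textConnection(sdfstr)
  on.exit(close(con))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con)))
  list(sdfset = sdfset, idx = match(tags, ChemmineR::sdfid(sdfset)))
}

# Batch molecular properties from the backend engine. `smiles` must all be
# valid; rows come back aligned with the input.
ob_properties <- function(smiles) {
  n <- length(smiles)
  tags <- npp_tags(n)
  src <- paste0(paste(trimws(smiles), tags), "\n", collapse = "")
  res <- ChemmineOB::forEachMol("SMILES", src,
                                function(m) ChemmineOB::prop_OB(m))
  df <- dplyr::bind_rows(res)
  df$title <- trimws(df$title)
  hit <- match(tags, df$title)
  if (anyNA(hit)) {
    abort("descriptor engine dropped one or more structures; inputs must be valid SMILES")
  }
  df[hit, , drop = FALSE]
}

# Batch 166-bit structural keys (MACCS dictionary as implemented by
# OpenBabel; key numbering matches the published 1..166 dictionary).
ob_maccs <- function(smiles) {
  n <- length(smiles)
  src <- paste0(paste(trimws(smiles), npp_tags(n)), "\n", collapse = "")
  res <- ChemmineOB::forEachMol("SMILES", src, function(m) {
    ChemmineOB::fingerprint_OB(list(m), "MACCS")
  })
  if (length(res) != n) {
    abort("fingerprint engine dropped one or more structures; inputs must be valid SMILES")
  }
  m <- do.call(rbind, res)[, seq_len(166L), drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# Concatenated V2000 molfiles -> canonical SMILES, aligned by the molfile
# title line (a npp_tags() tag set by the caller).
ob_molfile_to_smiles <- function(molfiles) {
  src <- paste0(paste(molfiles, collapse = "\n"), "\n")
  res <- ChemmineOB::convertFormat("SDF", "CAN", source = src)
  ob_parse_smiles_lines(res)
}

# Chemical formula string (e.g. "C7H6O2") -> named counts per element.
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

heavy_atom_count <- function(formula) {
  vapply(formula, function(f) {
    ct <- parse_formula(f)
    sum(ct[names(ct) != "H"])
  }, integer(1), USE.NAMES = FALSE)
}

contains_carbon <- function(formula) {
  vapply(formula, function(f) "C" %in% names(parse_formula(f)),
         logical(1), USE.NAMES = FALSE)
}
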