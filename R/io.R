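#' @title Species and mimicry-record tables
#' @description
#' The package works with two tidy tables.
#'
#' The **species table** has one row per corvid species:
#' \describe{
#'   \item{species}{standardized binomial name.}
#'   \item{genus}{genus the species belongs to.}
#'   \item{lit_count}{secondary-source evidence: entries in the corvid
#'     literature database plus one Birds of the World account, so always
#'     at least 1.}
#'   \item{xc_count}{primary-source evidence: number of xeno-canto audio
#'     recordings, possibly 0.}
#'   \item{detected_lit, detected_xc}{whether mimicry has been reported in
#'     that source.}
#'   \item{body_mass_g, repertoire_size, breeding_system, habitat,
#'     trophic_niche}{optional covariates; missing values are empty cells.}
#' }
#'
#' The **records table** has one row per individual mimicry observation:
#' \describe{
#'   \item{species}{must match a species-table row.}
#'   \item{source}{`"xeno_canto"` or `"literature"`.}
#'   \item{reliability}{rater confidence `"high"`, `"moderate"` or `"low"`;
#'     present if and only if the source is xeno-canto.}
#'   \item{bird_seen}{`"yes"`, `"no"` or `"unknown"` (xeno-canto only).}
#'   \item{mimicked_sound}{free-text label of the mimicked model sound.}
#'   \item{duration_s, date, lat, lon}{optional recording metadata.}
#' }
#' @name corvmimic-data
NULL

SPECIES_COLS <- c("species", "genus", "lit_count", "xc_count",
                  "detected_lit", "detected_xc", "body_mass_g",
                  "repertoire_size", "breeding_system", "habitat",
                  "trophic_niche")
RECORD_COLS <- c("species", "source", "reliability", "bird_seen",
                 "mimicked_sound", "duration_s", "date", "lat", "lon")

BREEDING_LEVELS <- c("cooperative", "groups", "territorial_pairs")
TROPHIC_LEVELS <- c("frugivore", "granivore", "invertivore", "omnivore")
RELIABILITY_LEVELS <- c("high", "moderate", "low")
SEEN_LEVELS <- c("yes", "no", "unknown")
SOURCE_LEVELS <- c("xeno_canto", "literature")

# case-insensitive, whitespace-normalized key used for species matching
norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

species_col_types <- function() {
  readr::cols(
    species = readr::col_character(),
    genus = readr::col_character(),
    lit_count = readr::col_integer(),
    xc_count = readr::col_integer(),
    detected_lit = readr::col_logical(),
    detected_xc = readr::col_logical(),
    body_mass_g = readr::col_double(),
    repertoire_size = readr::col_integer(),
    breeding_system = readr::col_character(),
    habitat = readr::col_character(),
    trophic_niche = readr::col_character()
  )
}

record_col_types <- function() {
  readr::cols(
    species = readr::col_character(),
    source = readr::col_character(),
    reliability = readr::col_character(),
    bird_seen = readr::col_character(),
    mimicked_sound = readr::col_character(),
    duration_s = readr::col_double(),
    date = readr::col_character(),
    lat = readr::col_double(),
    lon = readr::col_double()
  )
}

#' Read a species/records dataset from CSV
#'
#' Reads the species table and (optionally) the per-observation mimicry
#' records table, validating both against the schema described in
#' [corvmimic-data]. Missing values must be empty cells; the literal string
#' `"NA"` is kept as text so species or labels named "NA" are never
#' silently lost.
#'
#' @param species_path path to the species CSV.
#' @param records_path optional path to the records CSV.
#' @param schema_strict if `TRUE` (default), cross-table invariants are
#'   enforced as errors: every record species must exist in the species
#'   table, and a species flagged `detected_xc` must have at least one
#'   xeno-canto record when a records table is supplied.
#' @return a list with tibbles `species` and `records` (the latter empty,
#'   with the right columns, when `records_path` is `NULL`).
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
read_dataset <- function(species_path, records_path = NULL,
                         schema_strict = TRUE) {
  if (!file.exists(species_path)) {
    abort(sprintf("Species file not found: %s", species_path))
  }
  species <- readr::read_csv(species_path, col_types = species_col_types(),
                             na = "", comment = "#", progress = FALSE)
  if (is.null(records_path)) {
    records <- empty_records()
  } else {
    if (!file.exists(records_path)) {
      abort(sprintf("Records file not found: %s", records_path))
    }
    records <- readr::read_csv(records_path, col_types = record_col_types(),
                               na = "", comment = "#", progress = FALSE)
  }
  validate_dataset(species, records, strict = schema_strict)
  list(species = species, records = records)
}

empty_records <- function() {
  tibble::tibble(species = character(), source = character(),
                 reliability = character(), bird_seen = character(),
                 mimicked_sound = character(), duration_s = double(),
                 date = character(), lat = double(), lon = double())
}

#' Validate a species/records dataset
#'
#' Checks the schema invariants: column presence, count ranges
#' (`lit_count >= 1`, `xc_count >= 0`), label vocabularies, the
#' reliability-iff-xeno-canto rule, referential integrity of record species,
#' and (strict mode) that xeno-canto detections are backed by at least one
#' record.
#'
#' @inheritParams read_dataset
#' @param species,records tibbles as described in [corvmimic-data].
#' @param strict enforce cross-table invariants.
#' @return invisibly, the validated species tibble.
#' @export
validate_dataset <- function(species, records = NULL, strict = TRUE) {
  missing_cols <- setdiff(SPECIES_COLS, names(species))
  if (length(missing_cols)) {
    abort(paste0("Species table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(species$species) || anyNA(species$genus)) {
    abort("`species` and `genus` must be non-missing.")
  }
  if (anyDuplicated(norm_name(species$species))) {
    abort("Duplicated species names in the species table.")
  }
  assert_count(species$lit_count, "lit_count", min = 1)
  assert_count(species$xc_count, "xc_count", min = 0)
  if (!is.logical(species$detected_lit) || !is.logical(species$detected_xc) ||
      anyNA(species$detected_lit) || anyNA(species$detected_xc)) {
    abort("`detected_lit` and `detected_xc` must be non-missing logicals.")
  }
  if (any(species$detected_xc & species$xc_count == 0)) {
    abort("Species detected on xeno-canto must have xc_count >= 1.")
  }
  check_levels(species$breeding_system, BREEDING_LEVELS, "breeding_system")
  check_levels(species$trophic_niche, TROPHIC_LEVELS, "trophic_niche")

  if (!is.null(records) && nrow(records)) {
    missing_cols <- setdiff(RECORD_COLS, names(records))
    if (length(missing_cols)) {
      abort(paste0("Records table is missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    check_levels(records$source, SOURCE_LEVELS, "source", allow_na = FALSE)
    check_levels(records$reliability, RELIABILITY_LEVELS, "reliability")
    check_levels(records$bird_seen, SEEN_LEVELS, "bird_seen")
    is_xc <- records$source == "xeno_canto"
    if (any(is_xc & is.na(records$reliability))) {
      abort("Every xeno-canto record needs a reliability label.")
    }
    if (any(!is_xc & !is.na(records$reliability))) {
      abort("`reliability` applies to xeno-canto records only.")
    }
    orphans <- setdiff(norm_name(records$species), norm_name(species$species))
    if (strict && length(orphans)) {
      abort(paste0("Records refer to species absent from the species table: ",
                   paste(head(orphans, 5), collapse = ", ")))
    }
    if (strict) {
      with_rec <- unique(norm_name(records$species[is_xc]))
      unsupported <- species$detected_xc &
        !(norm_name(species$species) %in% with_rec)
      if (any(unsupported)) {
        abort(paste0("detected_xc is TRUE without any xeno-canto record for: ",
                     paste(head(species$species[unsupported], 5),
                           collapse = ", ")))
      }
    }
  }
  invisible(species)
}

check_levels <- function(x, levels, name, allow_na = TRUE) {
  bad <- !is.na(x) & !(x %in% levels)
  if (allow_na) {
    if (any(bad)) {
      abort(sprintf("Unknown %s label(s): %s", name,
                    paste(unique(x[bad]), collapse = ", ")))
    }
  } else if (anyNA(x) || any(bad)) {
    abort(sprintf("`%s` must be one of: %s", name,
                  paste(levels, collapse = ", ")))
  }
  invisible(x)
}

#' Write a species/records dataset to CSV
#'
#' Serializes the two tables so that [read_dataset()] recovers them exactly:
#' UTF-8, comma-delimited, header row, missing values as empty cells (never
#' the string `"NA"`).
#'
#' @inheritParams validate_dataset
#' @param species_path,records_path output file paths; the records file is
#'   only written when `records_path` is non-`NULL`.
#' @return invisibly, `species_path`.
#' @export
write_dataset <- function(species, records = NULL, species_path,
                          records_path = NULL) {
  validate_dataset(species, records, strict = FALSE)
  readr::write_csv(species[SPECIES_COLS], species_path, na = "")
  if (!is.null(records_path)) {
    rec <- if (is.null(records)) empty_records() else records
    readr::write_csv(rec[RECORD_COLS], records_path, na = "")
  }
  invisible(species_path)
}

#' Read a phylogenetic tree for downstream joins
#'
#' Convenience pass-through to `ape::read.tree()` for users who want to join
#' model output onto a corvid phylogeny (e.g. one exported from Open Tree of
#' Life). No branch-length or ultrametricity requirements are imposed; the
#' package itself does not use the tree.
#'
#' @param path a Newick file.
#' @return an `ape::phylo` object.
#' @export
read_corvid_tree <- function(path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Package 'ape' is required to read trees.")
  }
  ape::read.tree(path)
}
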