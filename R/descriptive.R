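#' Cross-tabulate mimicry detection by source
#'
#' One row per detection category — neither source, literature only,
#' xeno-canto only, or both — with the number of species and the mean
#' evidence count per source in each cell. The margins reconcile exactly
#' with the detection flags: `lit_only + both` equals the number of species
#' detected in the literature, and `xc_only + both` those detected on
#' xeno-canto.
#'
#' @inheritParams validate_dataset
#' @return tibble with columns `cell`, `n_species`, `mean_lit_count`,
#'   `mean_xc_count`.
#' @export
cross_table <- function(species) {
  validate_dataset(species, strict = FALSE)
  cells <- c("none", "lit_only", "xc_only", "both")
  species |>
    dplyr::mutate(cell = dplyr::case_when(
      .data$detected_lit & .data$detected_xc ~ "both",
      .data$detected_lit ~ "lit_only",
      .data$detected_xc ~ "xc_only",
      TRUE ~ "none")) |>
    dplyr::mutate(cell = factor(.data$cell, levels = cells)) |>
    dplyr::group_by(.data$cell, .drop = FALSE) |>
    dplyr::summarise(n_species = dplyr::n(),
                     mean_lit_count = mean(.data$lit_count),
                     mean_xc_count = mean(.data$xc_count),
                     .groups = "drop") |>
    dplyr::mutate(cell = as.character(.data$cell))
}

#' Summarize the rated mimicry records
#'
#' Tallies the reliability-rated (xeno-canto) mimicry records: overall
#' count, counts per reliability class and per bird-seen status. Both
#' categorizations partition the same records, so each set of counts sums
#' to the total. Literature reports are tallied separately in
#' `n_literature_records`.
#'
#' @inheritParams validate_dataset
#' @return one-row tibble: `n_records`, `n_high`, `n_moderate`, `n_low`,
#'   `n_seen_yes`, `n_seen_no`, `n_seen_unknown`, `n_literature_records`.
#' @export
record_summary <- function(records) {
  xc <- dplyr::filter(records, .data$source == "xeno_canto")
  seen <- ifelse(is.na(xc$bird_seen), "unknown", xc$bird_seen)
  tibble::tibble(
    n_records = nrow(xc),
    n_high = sum(xc$reliability == "high"),
    n_moderate = sum(xc$reliability == "moderate"),
    n_low = sum(xc$reliability == "low"),
    n_seen_yes = sum(seen == "yes"),
    n_seen_no = sum(seen == "no"),
    n_seen_unknown = sum(seen == "unknown"),
    n_literature_records = sum(records$source == "literature"))
}

#' Distinct mimicked sound types per mimic species
#'
#' Counts the distinct mimicked-sound labels per species (labels are
#' compared case-insensitively after trimming whitespace; no semantic
#' merging is attempted) and summarizes their distribution across mimic
#' species. Both the sample (n-1 denominator) and population (n) standard
#' deviations are reported, since published summaries do not always state
#' the convention.
#'
#' @inheritParams validate_dataset
#' @param species optional species table; required when
#'   `mimic_species_only = FALSE`.
#' @param mimic_species_only restrict to species with at least one record
#'   (default); with `FALSE`, species without any record enter with a
#'   count of 0.
#' @return one-row tibble: `n_species`, `min`, `max`, `mean`, `sd_sample`,
#'   `sd_population`, with the per-species counts attached as attribute
#'   `"per_species"`.
#' @export
sound_type_stats <- function(records, species = NULL,
                             mimic_species_only = TRUE) {
  rec <- dplyr::filter(records, !is.na(.data$mimicked_sound))
  if (!nrow(rec)) abort("No mimicry records with sound labels.")
  per <- rec |>
    dplyr::mutate(label = tolower(trimws(.data$mimicked_sound))) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_sounds = dplyr::n_distinct(.data$label),
                     .groups = "drop")
  if (!mimic_species_only) {
    if (is.null(species)) {
      abort("`species` is required when mimic_species_only = FALSE.")
    }
    missing <- setdiff(norm_name(species$species), norm_name(per$species))
    extra <- species$species[norm_name(species$species) %in% missing]
    per <- dplyr::bind_rows(per, tibble::tibble(species = extra,
                                                n_sounds = 0L))
  }
  x <- per$n_sounds
  out <- tibble::tibble(
    n_species = nrow(per), min = min(x), max = max(x), mean = mean(x),
    sd_sample = sd(x), sd_population = sqrt(mean((x - mean(x))^2)))
  attr(out, "per_species") <- per
  out
}
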