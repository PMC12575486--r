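#' Reliability-based false-positive scenario
#'
#' The recordings behind each xeno-canto detection carry a rater-assigned
#' reliability (`high`, `moderate`, `low`). Sensitivity refits recode
#' detections whose support does not survive a conservative rule:
#' \describe{
#'   \item{baseline}{every record counts; the dataset is unchanged.}
#'   \item{all_low_false}{low-reliability records are treated as false, so
#'     a species detected only through low-reliability records becomes
#'     undetected.}
#'   \item{only_high_true}{only high-reliability records count as true
#'     detections.}
#' }
#'
#' @param rule one of `"baseline"`, `"all_low_false"`, `"only_high_true"`.
#' @param name optional scenario label (defaults to the rule).
#' @param description optional free text.
#' @return a `sensitivity_scenario` object.
#' @export
sensitivity_scenario <- function(rule = c("baseline", "all_low_false",
                                          "only_high_true"),
                                 name = NULL, description = NULL) {
  rule <- match.arg(rule)
  structure(list(rule = rule, name = name %||% rule,
                 description = description %||% ""),
            class = "sensitivity_scenario")
}

surviving_reliability <- function(rule) {
  switch(rule,
         baseline = RELIABILITY_LEVELS,
         all_low_false = c("high", "moderate"),
         only_high_true = "high",
         abort(sprintf("Unknown scenario rule: %s", rule)))
}

#' Recode detections under a reliability scenario
#'
#' Returns a copy of the species table in which `detected_xc` is `TRUE`
#' only for species with at least one xeno-canto record surviving the
#' scenario rule. Literature detections are untouched. By default evidence
#' counts are also untouched: a discounted record is still a recording
#' someone made, so it keeps contributing to the species' evidence; set
#' `drop_discounted_evidence = TRUE` to also subtract discounted records
#' from `xc_count`.
#'
#' @inheritParams validate_dataset
#' @param scenario a [sensitivity_scenario()].
#' @param drop_discounted_evidence also remove discounted records from the
#'   evidence count (default `FALSE`).
#' @return the recoded species tibble.
#' @export
apply_reliability_rule <- function(species, records, scenario,
                                   drop_discounted_evidence = FALSE) {
  stopifnot(inherits(scenario, "sensitivity_scenario"))
  if (scenario$rule == "baseline" && !drop_discounted_evidence) {
    return(species)
  }
  keep <- surviving_reliability(scenario$rule)
  xc <- dplyr::filter(records, .data$source == "xeno_canto")
  if (nrow(xc) && anyNA(xc$reliability)) {
    abort("Every xeno-canto record needs a reliability label.")
  }
  surv <- dplyr::filter(xc, .data$reliability %in% keep)
  key <- norm_name(species$species)
  out <- species
  out$detected_xc <- key %in% norm_name(surv$species)
  if (drop_discounted_evidence) {
    dropped <- table(norm_name(xc$species[!(xc$reliability %in% keep)]))
    n_drop <- as.integer(dropped[key])
    n_drop[is.na(n_drop)] <- 0L
    out$xc_count <- pmax(0L, out$xc_count - n_drop)
    out$detected_xc <- out$detected_xc & out$xc_count > 0
  }
  out
}

#' Refit the model under each false-positive scenario
#'
#' Applies each reliability rule, refits [fit_occurrence()] on the recoded
#' dataset (same priors, same seed), and tabulates the posterior of the
#' occurrence probability `q` per scenario. Because rules can only flip
#' detections from `TRUE` to `FALSE`, the conservative posteriors should
#' sit at or below the baseline, up to Monte-Carlo error.
#'
#' @inheritParams fit_occurrence
#' @inheritParams apply_reliability_rule
#' @param scenarios list of [sensitivity_scenario()] objects; default all
#'   three rules.
#' @return tibble sorted by scenario name: `scenario`, `rule`,
#'   `n_detected_xc`, `mean`, `sd`, `hpdi_low`, `hpdi_high`.
#' @export
sensitivity_sweep <- function(species, records,
                              scenarios = list(
                                sensitivity_scenario("baseline"),
                                sensitivity_scenario("all_low_false"),
                                sensitivity_scenario("only_high_true")),
                              use_lit = TRUE, use_xc = TRUE,
                              priors = prior_config(), mcmc = mcmc_config()) {
  rows <- purrr::map_dfr(scenarios, function(sc) {
    recoded <- apply_reliability_rule(species, records, sc)
    fit <- fit_occurrence(recoded, use_lit = use_lit, use_xc = use_xc,
                          priors = priors, mcmc = mcmc)
    s <- dplyr::filter(fit$summary, .data$parameter == "q")
    tibble::tibble(scenario = sc$name, rule = sc$rule,
                   n_detected_xc = sum(recoded$detected_xc),
                   mean = s$mean, sd = s$sd,
                   hpdi_low = s$hpdi_low, hpdi_high = s$hpdi_high)
  })
  dplyr::arrange(rows, .data$scenario)
}

#' Scale-up parameter-recovery simulation
#'
#' Checks that the model recovers a known occurrence probability when the
#' empirical parameter estimates and evidence distribution are supplied as
#' simulation inputs at a (possibly much larger) number of species. For
#' each replicate, evidence pairs are drawn from `evidence_distribution`,
#' latent mimic states and detections are simulated from `params`, and the
#' model is refit under each source condition; the report aggregates the
#' error of the posterior mean and the coverage of the 89% HPDI.
#'
#' @param params an [evidence_params()] object, e.g. posterior means from
#'   the empirical fit — its `q` is the true value to recover.
#' @param evidence_distribution an object from
#'   [fit_evidence_distribution()].
#' @param n_species species per simulated dataset (>= 10).
#' @param n_replicates simulated datasets per condition.
#' @param seed integer seed for the whole simulation.
#' @param conditions subset of `c("literature_only", "xeno_canto_only",
#'   "both")`.
#' @param mcmc an [mcmc_config()] used for the refits (its seed is
#'   overridden per replicate).
#' @return tibble with one row per condition: `condition`, `n_species`,
#'   `n_replicates`, `coverage` (share of replicates whose 89% HPDI covers
#'   the true `q`), `mae` (mean absolute error of the posterior mean),
#'   `bias`. Per-replicate results are attached as attribute
#'   `"replicates"`.
#' @export
scale_up_recovery <- function(params, evidence_distribution, n_species,
                              n_replicates = 20, seed = 1,
                              conditions = c("literature_only",
                                             "xeno_canto_only", "both"),
                              mcmc = mcmc_config(chains = 3, iter = 2500,
                                                 warmup = 2000)) {
  stopifnot(inherits(params, "evidence_params"), n_species >= 10,
            n_replicates >= 1)
  conditions <- match.arg(conditions, several.ok = TRUE)
  sel <- list(literature_only = c(TRUE, FALSE),
              xeno_canto_only = c(FALSE, TRUE),
              both = c(TRUE, TRUE))
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    rep_seed <- (seed * 1000L + r) %% .Machine$integer.max
    set.seed(rep_seed)
    ev <- draw_evidence(evidence_distribution, n_species)
    z <- rbinom(n_species, 1, params$q) == 1
    det_lit <- z & (runif(n_species) <
                      detection_probability(params$d_lit, ev$e_lit))
    det_xc <- z & (runif(n_species) <
                     detection_probability(params$d_xc, ev$e_xc))
    species <- tibble::tibble(
      species = sprintf("sim sp%04d", seq_len(n_species)),
      genus = "sim", lit_count = ev$e_lit, xc_count = ev$e_xc,
      detected_lit = det_lit, detected_xc = det_xc,
      body_mass_g = NA_real_, repertoire_size = NA_integer_,
      breeding_system = NA_character_, habitat = NA_character_,
      trophic_niche = NA_character_)
    purrr::map_dfr(conditions, function(cond) {
      s <- sel[[cond]]
      m <- mcmc
      m$seed <- rep_seed
      # a hard replicate occasionally needs a longer adaptation phase;
      # retry with doubled warmup/draws before giving up
      fit <- NULL
      for (attempt in 1:3) {
        fit <- tryCatch(
          suppressWarnings(
            fit_occurrence(species, use_lit = s[1], use_xc = s[2],
                           priors = prior_config(), mcmc = m)),
          error = function(e) {
            if (attempt < 3 && grepl("converge", conditionMessage(e))) {
              NULL
            } else {
              abort(conditionMessage(e))
            }
          })
        if (!is.null(fit)) break
        m$warmup <- m$warmup * 2L
        m$iter <- m$iter * 2L
        m$seed <- m$seed + 1L
      }
      qs <- dplyr::filter(fit$summary, .data$parameter == "q")
      tibble::tibble(replicate = r, condition = cond,
                     q_true = params$q, q_mean = qs$mean,
                     hpdi_low = qs$hpdi_low, hpdi_high = qs$hpdi_high,
                     covered = qs$hpdi_low <= params$q &
                       params$q <= qs$hpdi_high,
                     error = qs$mean - params$q)
    })
  })
  report <- reps |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_species = n_species, n_replicates = n_replicates,
                     coverage = mean(.data$covered),
                     mae = mean(abs(.data$error)),
                     bias = mean(.data$error), .groups = "drop")
  attr(report, "replicates") <- reps
  report
}

#' Prior-sensitivity sweep
#'
#' Refits the model under a grid of prior settings and reports how much the
#' posterior mean of `q` moves.
#'
#' @inheritParams fit_occurrence
#' @param prior_grid a named list of [prior_config()] objects (>= 2).
#' @return tibble: `prior`, `q_mean`, `q_sd`, `hpdi_low`, `hpdi_high`, with
#'   the maximum pairwise difference of posterior means as attribute
#'   `"max_diff"`.
#' @export
prior_sensitivity <- function(species, prior_grid, use_lit = TRUE,
                              use_xc = TRUE, mcmc = mcmc_config()) {
  if (nrow(species) == 0) abort("Empty dataset.")
  stopifnot(is.list(prior_grid), length(prior_grid) >= 2)
  if (is.null(names(prior_grid))) {
    names(prior_grid) <- paste0("prior_", seq_along(prior_grid))
  }
  rows <- purrr::map_dfr(names(prior_grid), function(nm) {
    fit <- fit_occurrence(species, use_lit = use_lit, use_xc = use_xc,
                          priors = prior_grid[[nm]], mcmc = mcmc)
    s <- dplyr::filter(fit$summary, .data$parameter == "q")
    tibble::tibble(prior = nm, q_mean = s$mean, q_sd = s$sd,
                   hpdi_low = s$hpdi_low, hpdi_high = s$hpdi_high)
  })
  attr(rows, "max_diff") <- max(stats::dist(rows$q_mean))
  rows
}
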