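#' Evidence-model parameters
#'
#' Bundle of the corvid-wide occurrence probability and the per-unit
#' detection probabilities of the two evidence sources.
#'
#' @param q probability that a randomly chosen corvid species is a mimic
#'   (the corvid-wide intercept), in (0, 1).
#' @param d_lit probability that a single literature-database entry reveals
#'   mimicry in a true mimic, in (0, 1).
#' @param d_xc probability that a single xeno-canto recording reveals
#'   mimicry in a true mimic, in (0, 1).
#' @param fp_low,fp_mod optional per-record false-positive probabilities for
#'   low/moderate-reliability records; `NULL` (the baseline model) means a
#'   non-mimic is never detected.
#' @return an object of class `evidence_params`.
#' @export
#' @examples
#' evidence_params(q = 0.8, d_lit = 0.05, d_xc = 0.003)
evidence_params <- function(q, d_lit, d_xc, fp_low = NULL, fp_mod = NULL) {
  assert_probability(q, "q")
  assert_probability(d_lit, "d_lit")
  assert_probability(d_xc, "d_xc")
  if (!is.null(fp_low)) assert_probability(fp_low, "fp_low", open = FALSE)
  if (!is.null(fp_mod)) assert_probability(fp_mod, "fp_mod", open = FALSE)
  structure(list(q = q, d_lit = d_lit, d_xc = d_xc,
                 fp_low = fp_low, fp_mod = fp_mod),
            class = "evidence_params")
}

#' @export
print.evidence_params <- function(x, ...) {
  cat(sprintf("Evidence-model parameters: q = %.4f, d_lit = %.5f, d_xc = %.5f\n",
              x$q, x$d_lit, x$d_xc))
  invisible(x)
}

#' Per-species probability of detection given evidence
#'
#' Each evidence unit (a literature entry or a recording) independently
#' reveals mimicry in a true mimic with probability `d`, so with `e` units
#' the species is detected at least once with probability
#' \eqn{1 - (1 - d)^e}. Zero evidence gives zero detection probability; the
#' function is strictly increasing in both `d` and `e`.
#'
#' @param d per-unit detection probability, in (0, 1). Vectorized.
#' @param e number of evidence units, a non-negative integer. Vectorized.
#' @return detection probability.
#' @export
#' @examples
#' detection_probability(0.1, 10)  # 1 - 0.9^10
detection_probability <- function(d, e) {
  assert_probability(d, "d")
  assert_count(e, "e", min = 0)
  -expm1(log_surv(d, e))
}

#' Log-likelihood of the observed detection pattern, per species
#'
#' Marginalizes the latent mimic status: a species is a mimic with
#' probability `q`; a mimic with `e_s` units of evidence from source `s` is
#' detected there with probability \eqn{1-(1-d_s)^{e_s}}; a non-mimic is
#' never detected (baseline model). The contribution of one species is
#' \deqn{\log\left[q \prod_s f_s + (1-q)\, [\text{no detections}]\right]}
#' where \eqn{f_s} is the Bernoulli likelihood of the observed detection
#' flag for source `s`. Sources excluded by the selection are ignored, so a
#' species with all its evidence deselected contributes exactly 0.
#'
#' @param params an [evidence_params()] object.
#' @param species species tibble (see [corvmimic-data]); only the evidence
#'   counts and detection flags are used.
#' @param use_lit,use_xc which evidence sources to condition on; at least
#'   one must be `TRUE`.
#' @return numeric vector of per-species log-likelihood contributions.
#' @export
species_loglik <- function(params, species, use_lit = TRUE, use_xc = TRUE) {
  stopifnot(inherits(params, "evidence_params"))
  if (!use_lit && !use_xc) abort("At least one source must be selected.")
  if (use_lit && any(species$detected_lit & species$lit_count == 0)) {
    abort("Inconsistent data: literature detection without literature evidence.")
  }
  if (use_xc && any(species$detected_xc & species$xc_count == 0)) {
    abort("Inconsistent data: xeno-canto detection without recordings.")
  }
  loglik_terms(species, use_lit, use_xc,
               q = params$q, d_lit = params$d_lit, d_xc = params$d_xc)
}

# Core vectorized likelihood; scalar q/d's, vector data columns.
loglik_terms <- function(species, use_lit, use_xc, q, d_lit, d_xc) {
  s <- nrow(species)
  log_f_mimic <- numeric(s)
  any_det <- rep(FALSE, s)
  if (use_lit) {
    ls <- log_surv(d_lit, species$lit_count)       # log P(miss all | mimic)
    log_f_mimic <- log_f_mimic +
      ifelse(species$detected_lit, log(-expm1(ls)), ls)
    any_det <- any_det | species$detected_lit
  }
  if (use_xc) {
    ls <- log_surv(d_xc, species$xc_count)
    log_f_mimic <- log_f_mimic +
      ifelse(species$detected_xc, log(-expm1(ls)), ls)
    any_det <- any_det | species$detected_xc
  }
  # detected: only the mimic branch survives; undetected: mix with (1-q)
  ifelse(any_det,
         log(q) + log_f_mimic,
         log(q * exp(log_f_mimic) + (1 - q)))
}
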