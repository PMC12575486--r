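#' Posterior probability that an undetected species is a mimic
#'
#' For a species never detected as a mimic, Bayes' rule over the latent
#' mimic status gives
#' \deqn{P(\text{mimic} \mid \text{no detection}) =
#'   \frac{q\,(1-d_{lit})^{e_{lit}}(1-d_{xc})^{e_{xc}}}
#'        {q\,(1-d_{lit})^{e_{lit}}(1-d_{xc})^{e_{xc}} + (1-q)}.}
#' With no evidence at all this is just `q` — the corvid-wide intercept is
#' the best guess for an unstudied species — and it declines strictly as
#' undetected evidence accumulates. A detected species is a known mimic, so
#' the function returns 1.
#'
#' @inheritParams species_loglik
#' @param e_lit,e_xc evidence counts (literature entries, recordings).
#'   Vectorized.
#' @param detected logical; has mimicry been detected in any source?
#' @return probability of being a mimic.
#' @export
#' @examples
#' p <- evidence_params(q = 0.5, d_lit = 0.1, d_xc = 0.01)
#' p_hidden(p, e_lit = 10, e_xc = 0, detected = FALSE)
p_hidden <- function(params, e_lit, e_xc, detected = FALSE) {
  stopifnot(inherits(params, "evidence_params"))
  assert_count(e_lit, "e_lit", 0)
  assert_count(e_xc, "e_xc", 0)
  surv <- exp(log_surv(params$d_lit, e_lit) + log_surv(params$d_xc, e_xc))
  out <- params$q * surv / (params$q * surv + (1 - params$q))
  out[rep_len(detected, length(out))] <- 1
  out
}

#' Composite evidence score in literature-entry units
#'
#' Converts a species' combined evidence into the single number of
#' literature-database entries that would carry the same information about
#' a non-detection: the count `c` such that
#' \eqn{(1-d_{lit})^{c} = (1-d_{lit})^{e_{lit}}(1-d_{xc})^{e_{xc}}}, i.e.
#' \deqn{c = e_{lit} + e_{xc}\,\frac{\log(1-d_{xc})}{\log(1-d_{lit})}.}
#' Two undetected species with equal composite score have identical hidden
#' mimicry probabilities for any parameter values — the score is the
#' sufficient statistic of the no-detection likelihood.
#'
#' @inheritParams p_hidden
#' @return composite score (equivalent literature entries), `>= 0`.
#' @export
composite_evidence <- function(params, e_lit, e_xc) {
  stopifnot(inherits(params, "evidence_params"))
  assert_count(e_lit, "e_lit", 0)
  assert_count(e_xc, "e_xc", 0)
  e_lit + e_xc * log1p(-params$d_xc) / log1p(-params$d_lit)
}

#' Per-species hidden-mimicry table
#'
#' Computes each species' probability of being a mimic, integrated over the
#' posterior draws of a fitted model: the closed-form [p_hidden()] is
#' evaluated at every draw and averaged, with an 89% HPDI over draws (a
#' plug-in evaluation at the posterior means is available for speed).
#' Composite scores are evaluated at the posterior-mean detection rates.
#' Detected species are retained with probability 1 so the table covers the
#' whole dataset.
#'
#' @inheritParams fit_occurrence
#' @param fit a `mimic_fit` from [fit_occurrence()] with both sources
#'   active, or any object whose draws contain `q`, `d_lit` and `d_xc`.
#' @param method `"draws"` (default, posterior-integrated) or `"plugin"`
#'   (evaluate once at posterior means).
#' @return tibble: `species`, `genus`, `e_lit`, `e_xc`, `detected`,
#'   `composite_score`, `p_hidden_mean`, `p_hidden_low`, `p_hidden_high`.
#' @export
hidden_table <- function(species, fit, method = c("draws", "plugin")) {
  method <- match.arg(method)
  # model-level check only: evidence counts may legitimately be zero here
  assert_count(species$lit_count, "lit_count", min = 0)
  assert_count(species$xc_count, "xc_count", min = 0)
  draws <- if (inherits(fit, "mimic_fit")) fit$draws else tibble::as_tibble(fit)
  needed <- c("q", "d_lit", "d_xc")
  if (!all(needed %in% names(draws))) {
    abort("`fit` must provide posterior draws of q, d_lit and d_xc.")
  }
  hp <- if (inherits(fit, "mimic_fit")) fit$mcmc$hpdi_prob else 0.89
  detected <- species$detected_lit | species$detected_xc
  mean_params <- evidence_params(q = mean(draws$q),
                                 d_lit = mean(draws$d_lit),
                                 d_xc = mean(draws$d_xc))
  score <- composite_evidence(mean_params, species$lit_count,
                              species$xc_count)
  if (method == "plugin" || nrow(draws) == 1) {
    pars1 <- evidence_params(draws$q[1], draws$d_lit[1], draws$d_xc[1])
    use <- if (method == "plugin") mean_params else pars1
    pm <- p_hidden(use, species$lit_count, species$xc_count, detected)
    lo <- hi <- pm
  } else {
    # draws x species matrix of the closed form
    surv <- exp(outer(log1p(-draws$d_lit), species$lit_count) +
                outer(log1p(-draws$d_xc), species$xc_count))
    num <- draws$q * surv
    mat <- num / (num + (1 - draws$q))
    mat[, detected] <- 1
    pm <- colMeans(mat)
    ints <- apply(mat, 2, hpdi, prob = hp)
    lo <- ints["low", ]
    hi <- ints["high", ]
  }
  out <- tibble::tibble(genus = species[["genus"]],
                        e_lit = species[["lit_count"]],
                        e_xc = species[["xc_count"]],
                        detected = detected, composite_score = score,
                        p_hidden_mean = pm, p_hidden_low = lo,
                        p_hidden_high = hi)
  dplyr::bind_cols(tibble::tibble(species = species[["species"]]), out)
}

#' Rank undetected species by hidden-mimicry probability
#'
#' Returns the `k` undetected species most and least likely to be hidden
#' mimics. Ties are broken alphabetically by species name so output is
#' deterministic; when every candidate is tied (e.g. all species have zero
#' evidence) the result carries attribute `all_tied = TRUE`.
#'
#' @param hidden a tibble from [hidden_table()].
#' @param k list length per direction.
#' @return list with tibbles `top` (descending probability) and `bottom`
#'   (ascending).
#' @export
rank_species <- function(hidden, k = 10) {
  stopifnot(nrow(hidden) > 0, k >= 1)
  und <- dplyr::filter(hidden, !.data$detected)
  if (k > nrow(und)) {
    abort(sprintf("k = %d exceeds the %d undetected species.", k, nrow(und)))
  }
  top <- dplyr::arrange(und, dplyr::desc(.data$p_hidden_mean), .data$species)
  bottom <- dplyr::arrange(und, .data$p_hidden_mean, .data$species)
  out <- list(top = head(top, k), bottom = head(bottom, k))
  attr(out, "all_tied") <- length(unique(und$p_hidden_mean)) == 1
  out
}

#' Plot hidden-mimicry probability against composite evidence
#'
#' @param hidden a tibble from [hidden_table()].
#' @return a ggplot of per-species posterior mimicry probability (with 89%
#'   HPDI) against the composite evidence score, log-scaled.
#' @export
plot_hidden <- function(hidden) {
  ggplot2::ggplot(dplyr::filter(hidden, !.data$detected),
                  ggplot2::aes(x = .data$composite_score,
                               y = .data$p_hidden_mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p_hidden_low,
                                         ymax = .data$p_hidden_high),
                            colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "composite evidence score (literature-entry units)",
                  y = "P(hidden mimic)") +
    ggplot2::theme_minimal()
}
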