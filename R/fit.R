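#' Prior configuration for the evidence model
#'
#' Independent Beta priors. Defaults: a flat Beta(1, 1) on the corvid-wide
#' occurrence probability `q`, and Beta(1, 9) on each per-unit detection
#' probability — weakly favouring small values, since a single literature
#' entry or recording only rarely documents mimicry.
#'
#' @param q,d_lit,d_xc length-2 numeric vectors of Beta shape parameters.
#' @return a `prior_config` object.
#' @export
prior_config <- function(q = c(1, 1), d_lit = c(1, 9), d_xc = c(1, 9)) {
  for (s in list(q, d_lit, d_xc)) {
    stopifnot(is.numeric(s), length(s) == 2, all(s > 0))
  }
  structure(list(q = q, d_lit = d_lit, d_xc = d_xc), class = "prior_config")
}

#' MCMC settings
#'
#' @param chains number of independent chains (default 4).
#' @param iter post-warmup draws per chain (default 2500).
#' @param warmup adaptation iterations per chain, discarded (default 2000).
#' @param seed integer seed; fixing it makes runs bit-reproducible.
#' @param hpdi_prob interval mass for posterior summaries (default 0.89).
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(chains = 4, iter = 2500, warmup = 2000, seed = 1,
                        hpdi_prob = 0.89) {
  stopifnot(chains >= 1, iter >= 100, warmup >= 100,
            hpdi_prob > 0, hpdi_prob < 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 hpdi_prob = hpdi_prob),
            class = "mcmc_config")
}

# parameters active under a source selection
active_params <- function(use_lit, use_xc) {
  c("q", if (use_lit) "d_lit", if (use_xc) "d_xc")
}

# log posterior density on the unconstrained (logit) scale, including the
# Beta log-priors and the logit Jacobian
make_log_post <- function(species, use_lit, use_xc, priors) {
  pars <- active_params(use_lit, use_xc)
  shapes <- priors[pars]
  function(theta) {
    p <- inv_logit(theta)
    if (any(p <= 0) || any(p >= 1)) return(-Inf)
    names(p) <- pars
    ll <- sum(loglik_terms(species, use_lit, use_xc,
                           q = p[["q"]],
                           d_lit = if (use_lit) p[["d_lit"]] else 0.5,
                           d_xc = if (use_xc) p[["d_xc"]] else 0.5))
    lp <- sum(vapply(pars, function(nm) {
      dbeta(p[[nm]], shapes[[nm]][1], shapes[[nm]][2], log = TRUE) +
        log(p[[nm]]) + log1p(-p[[nm]])   # Jacobian of logit
    }, numeric(1)))
    ll + lp
  }
}

# Adaptive random-walk Metropolis on the unconstrained scale. The proposal
# covariance is adapted from the chain history during warmup only; sampling
# then proceeds with a fixed kernel.
run_chain <- function(log_post, init, iter, warmup) {
  d <- length(init)
  total <- warmup + iter
  out <- matrix(NA_real_, total, d)
  theta <- init
  lp <- log_post(theta)
  if (!is.finite(lp)) abort("Initial value has zero posterior density.")
  scale <- 2.38 / sqrt(d)
  chol_prop <- diag(d)
  n_acc <- 0
  for (t in seq_len(total)) {
    prop <- theta + scale * drop(rnorm(d) %*% chol_prop)
    lp_prop <- log_post(prop)
    accepted <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
    if (accepted) {
      theta <- prop
      lp <- lp_prop
      n_acc <- n_acc + 1
    }
    out[t, ] <- theta
    if (t <= warmup) {
      # Robbins-Monro scale adaptation toward ~30% acceptance
      scale <- scale * exp((as.numeric(accepted) - 0.3) / sqrt(t))
      if (t >= 200 && t %% 100 == 0) {
        hist <- out[max(1, t - 499):t, , drop = FALSE]
        cov_hat <- stats::cov(hist) + diag(1e-6, d)
        chol_prop <- chol(cov_hat)
      }
    }
  }
  list(draws = out[(warmup + 1):total, , drop = FALSE],
       accept_rate = n_acc / total)
}

#' Fit the Bayesian evidence-accumulation model
#'
#' Samples the joint posterior of the corvid-wide occurrence probability `q`
#' and the per-unit detection probabilities of the selected sources, given
#' each species' evidence counts and detection flags. The latent per-species
#' mimic status is marginalized analytically, leaving a 2- or 3-parameter
#' posterior explored by adaptive random-walk Metropolis on the logit scale.
#'
#' @inheritParams species_loglik
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_config()]; the seed makes the fit reproducible.
#' @return a `mimic_fit` object: posterior draws, summaries (mean, sd, 89%
#'   HPDI, effective sample size, split-Rhat), and the settings used.
#'   Access draws with [posterior_draws()], summaries with [tidy()].
#' @export
#' @examples
#' dat <- generate_corvid_data(synth_config(n_species = 40, seed = 7))
#' fit <- fit_occurrence(dat$species, mcmc = mcmc_config(chains = 2,
#'                                                       iter = 500,
#'                                                       warmup = 300))
#' tidy(fit)
fit_occurrence <- function(species, use_lit = TRUE, use_xc = TRUE,
                           priors = prior_config(), mcmc = mcmc_config()) {
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))
  if (!use_lit && !use_xc) abort("At least one source must be selected.")
  if (nrow(species) < 2) abort("Need at least 2 species to fit.")
  validate_dataset(species, strict = FALSE)
  detected <- (use_lit & species$detected_lit) | (use_xc & species$detected_xc)
  if (all(detected) || !any(detected)) {
    warn(paste("All species share the same detection status under this",
               "selection; the posterior will be prior-dominated."))
  }
  pars <- active_params(use_lit, use_xc)
  log_post <- make_log_post(species, use_lit, use_xc, priors)

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    init <- logit(vapply(pars, function(nm) {
      rbeta(1, priors[[nm]][1] + 1, priors[[nm]][2] + 1)
    }, numeric(1)))
    chains[[ch]] <- run_chain(log_post, init, mcmc$iter, mcmc$warmup)
  }
  draw_mats <- lapply(chains, function(x) inv_logit(x$draws))

  summary <- purrr::map_dfr(seq_along(pars), function(j) {
    per_chain <- vapply(draw_mats, function(m) m[, j], numeric(mcmc$iter))
    pooled <- as.vector(per_chain)
    h <- hpdi(pooled, mcmc$hpdi_prob)
    tibble::tibble(parameter = pars[j], mean = mean(pooled),
                   sd = sd(pooled), hpdi_low = h[["low"]],
                   hpdi_high = h[["high"]],
                   ess = ess_multi(per_chain),
                   rhat = if (mcmc$chains > 1) split_rhat(per_chain)
                          else split_rhat(matrix(pooled, ncol = 1)))
  })
  if (any(summary$rhat > 1.1)) {
    abort(paste0("Chains did not converge (max split-Rhat = ",
                 sprintf("%.3f", max(summary$rhat)),
                 ", min ESS = ", sprintf("%.0f", min(summary$ess)),
                 "); increase iterations or warmup."))
  }
  if (any(summary$rhat > 1.01)) {
    warn(sprintf("Split-Rhat above 1.01 for: %s",
                 paste(summary$parameter[summary$rhat > 1.01],
                       collapse = ", ")))
  }
  draws <- purrr::map_dfr(seq_along(draw_mats), function(ch) {
    m <- draw_mats[[ch]]
    colnames(m) <- pars
    dplyr::bind_cols(tibble::tibble(.chain = ch, .iter = seq_len(nrow(m))),
                     tibble::as_tibble(m))
  })
  structure(list(draws = draws, summary = summary,
                 selection = list(use_lit = use_lit, use_xc = use_xc),
                 priors = priors, mcmc = mcmc,
                 n_species = nrow(species),
                 accept_rates = vapply(chains, `[[`, numeric(1),
                                       "accept_rate")),
            class = "mimic_fit")
}

#' Posterior draws of a fitted model
#'
#' @param fit a `mimic_fit`.
#' @return tibble with columns `.chain`, `.iter` and one column per
#'   parameter, on the probability scale.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "mimic_fit"))
  fit$draws
}

#' @export
print.mimic_fit <- function(x, ...) {
  sel <- c("literature"[x$selection$use_lit],
           "xeno-canto"[x$selection$use_xc])
  cat(sprintf("Evidence-accumulation fit: %d species, sources: %s\n",
              x$n_species, paste(sel, collapse = " + ")))
  cat(sprintf("%d chains x %d draws (warmup %d), seed %d\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup, x$mcmc$seed))
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_occurrence
#' @param x a `mimic_fit`.
#' @param ... unused.
#' @export
tidy.mimic_fit <- function(x, ...) x$summary

#' @rdname fit_occurrence
#' @export
glance.mimic_fit <- function(x, ...) {
  tibble::tibble(n_species = x$n_species, chains = x$mcmc$chains,
                 draws = x$mcmc$chains * x$mcmc$iter,
                 max_rhat = max(x$summary$rhat),
                 min_ess = min(x$summary$ess),
                 mean_accept = mean(x$accept_rates))
}

#' @rdname fit_occurrence
#' @param object a `mimic_fit`.
#' @export
autoplot.mimic_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, -c(".chain", ".iter"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "posterior value", y = "density") +
    ggplot2::theme_minimal()
}

#' Deterministic grid-integration posterior (oracle)
#'
#' Integrates the same posterior as [fit_occurrence()] over a regular
#' mid-point grid on each active parameter, with no Monte-Carlo error. Used
#' to validate the sampler on small datasets; cost grows as
#' `n_grid^3` with both sources active, so keep datasets small.
#'
#' @inheritParams fit_occurrence
#' @param n_grid grid points per parameter (default 200).
#' @return tibble with columns `parameter`, `mean`, `sd`.
#' @export
grid_posterior <- function(species, use_lit = TRUE, use_xc = TRUE,
                           priors = prior_config(), n_grid = 200) {
  if (!use_lit && !use_xc) abort("At least one source must be selected.")
  validate_dataset(species, strict = FALSE)
  g <- (seq_len(n_grid) - 0.5) / n_grid
  lg1m <- log1p(-g)
  det <- (use_lit & species$detected_lit) | (use_xc & species$detected_xc)

  # per-source log f(mimic) profiles over the grid:
  # detected species separate additively; undetected species do not.
  src_prof <- function(e, hit) {
    # matrix grid x species of log f_s(flag | mimic, e)
    surv <- outer(lg1m, e)               # e * log(1-d)
    out <- ifelse(matrix(hit, n_grid, length(hit), byrow = TRUE),
                  log(-expm1(surv)), surv)
    dim(out) <- dim(surv)
    out
  }
  A_lit <- if (use_lit) src_prof(species$lit_count, species$detected_lit)
  A_xc <- if (use_xc) src_prof(species$xc_count, species$detected_xc)

  det_lit <- if (use_lit) rowSums(A_lit[, det, drop = FALSE]) else 0
  det_xc <- if (use_xc) rowSums(A_xc[, det, drop = FALSE]) else 0
  und_lit <- if (use_lit) A_lit[, !det, drop = FALSE] else NULL
  und_xc <- if (use_xc) A_xc[, !det, drop = FALSE] else NULL
  n_det <- sum(det)
  n_und <- sum(!det)

  lp_prior <- function(nm) dbeta(g, priors[[nm]][1], priors[[nm]][2],
                                 log = TRUE)
  pq <- lp_prior("q")

  if (use_lit && use_xc) {
    # full log-posterior array over (q, d_lit, d_xc); the undetected
    # species couple the two detection grids, so each q slice is built
    # from the outer sum of their per-source survival profiles
    base <- outer(det_lit + lp_prior("d_lit"), det_xc + lp_prior("d_xc"), "+")
    und_ms <- if (n_und > 0) {
      lapply(seq_len(n_und), function(s) outer(und_lit[, s], und_xc[, s], "+"))
    } else list()
    lp <- array(NA_real_, c(n_grid, n_grid, n_grid))
    for (i in seq_len(n_grid)) {
      q <- g[i]
      slice <- base + n_det * log(q) + pq[i]
      for (m in und_ms) slice <- slice + log(q * exp(m) + (1 - q))
      lp[i, , ] <- slice
    }
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    wq <- rowSums(matrix(w, n_grid))
    wl <- apply(w, 2, sum)
    wx <- apply(w, 3, sum)
    means <- c(sum(wq * g), sum(wl * g), sum(wx * g))
    res <- tibble::tibble(
      parameter = c("q", "d_lit", "d_xc"),
      mean = means,
      sd = sqrt(c(sum(wq * g^2), sum(wl * g^2), sum(wx * g^2)) - means^2))
    return(res)
  }

  # single source: dense 2-D grid
  A <- if (use_lit) A_lit else A_xc
  det_prof <- if (use_lit) det_lit else det_xc
  und <- A[, !det, drop = FALSE]
  pd <- lp_prior(if (use_lit) "d_lit" else "d_xc")
  lp <- matrix(0, n_grid, n_grid)        # q x d
  for (i in seq_len(n_grid)) {
    q <- g[i]
    row <- n_det * log(q) + det_prof + pd + pq[i]
    if (n_und > 0) row <- row + colSums(log(q * exp(t(und)) + (1 - q)))
    lp[i, ] <- row
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  wq <- rowSums(w)
  wd <- colSums(w)
  tibble::tibble(
    parameter = c("q", if (use_lit) "d_lit" else "d_xc"),
    mean = c(sum(wq * g), sum(wd * g)),
    sd = sqrt(c(sum(wq * g^2) - sum(wq * g)^2,
                sum(wd * g^2) - sum(wd * g)^2)))
}

#' Posterior of occurrence under each evidence condition
#'
#' Fits the model conditioning on secondary sources only (literature),
#' primary sources only (xeno-canto recordings), and both combined, and
#' stacks the posterior of `q` for each condition next to its prior. With
#' more evidence the interval should not widen: if the combined-source 89%
#' HPDI is wider than a single-source one, a warning flags it.
#'
#' @inheritParams fit_occurrence
#' @return tibble with one row per condition (`prior`, `literature_only`,
#'   `xeno_canto_only`, `both`) and columns `mean`, `sd`, `hpdi_low`,
#'   `hpdi_high`, `hpdi_width`. The fitted `mimic_fit` objects are attached
#'   as attribute `"fits"`.
#' @export
posterior_by_source <- function(species, priors = prior_config(),
                                mcmc = mcmc_config()) {
  conds <- list(literature_only = c(TRUE, FALSE),
                xeno_canto_only = c(FALSE, TRUE),
                both = c(TRUE, TRUE))
  fits <- purrr::map(conds, function(s) {
    fit_occurrence(species, use_lit = s[1], use_xc = s[2],
                   priors = priors, mcmc = mcmc)
  })
  set.seed(mcmc$seed)
  prior_draws <- rbeta(mcmc$chains * mcmc$iter, priors$q[1], priors$q[2])
  ph <- hpdi(prior_draws, mcmc$hpdi_prob)
  rows <- dplyr::bind_rows(
    tibble::tibble(condition = "prior", mean = mean(prior_draws),
                   sd = sd(prior_draws), hpdi_low = ph[["low"]],
                   hpdi_high = ph[["high"]]),
    purrr::map_dfr(names(fits), function(nm) {
      s <- dplyr::filter(fits[[nm]]$summary, .data$parameter == "q")
      tibble::tibble(condition = nm, mean = s$mean, sd = s$sd,
                     hpdi_low = s$hpdi_low, hpdi_high = s$hpdi_high)
    }))
  rows$hpdi_width <- rows$hpdi_high - rows$hpdi_low
  w <- setNames(rows$hpdi_width, rows$condition)
  if (w[["both"]] > w[["literature_only"]] + 1e-9 ||
      w[["both"]] > w[["xeno_canto_only"]] + 1e-9) {
    warn("Combined-source HPDI is wider than a single-source HPDI.")
  }
  attr(rows, "fits") <- fits
  rows
}

#' Plot prior and posteriors of occurrence by evidence condition
#'
#' @param by_source output of [posterior_by_source()].
#' @return a ggplot: point estimates with 89% HPDI bars per condition.
#' @export
plot_occurrence <- function(by_source) {
  by_source$condition <- factor(by_source$condition,
                                levels = c("prior", "literature_only",
                                           "xeno_canto_only", "both"))
  ggplot2::ggplot(by_source,
                  ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hpdi_low,
                                          ymax = .data$hpdi_high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "occurrence of mimicry (q)") +
    ggplot2::theme_minimal()
}
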