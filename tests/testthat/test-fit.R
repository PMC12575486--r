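test_that("hpdi returns the shortest interval with the requested mass", {
  set.seed(9)
  x <- rbeta(5000, 2, 8)
  h <- hpdi(x, 0.89)
  inside <- mean(x >= h[["low"]] & x <= h[["high"]])
  expect_gte(inside, 0.89)
  # brute-force minimal window over sorted draws
  xs <- sort(x)
  m <- ceiling(0.89 * length(xs))
  widths <- xs[(m + 1):length(xs)] - xs[1:(length(xs) - m)]
  expect_equal(h[["high"]] - h[["low"]], min(widths))
  # skewed sample: HPDI sits left of the equal-tail interval
  expect_lt(h[["high"]], quantile(x, 0.945))
})

test_that("fits are bit-reproducible for a fixed seed and differ across seeds", {
  dat <- generate_corvid_data(synth_config(n_species = 30, seed = 11))
  f1 <- suppressWarnings(fit_occurrence(dat$species, mcmc = light_mcmc(7)))
  f2 <- suppressWarnings(fit_occurrence(dat$species, mcmc = light_mcmc(7)))
  f3 <- suppressWarnings(fit_occurrence(dat$species, mcmc = light_mcmc(8)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("degenerate inputs error or warn as appropriate", {
  dat <- generate_corvid_data(synth_config(n_species = 20, seed = 3))
  expect_error(fit_occurrence(dat$species[0, ]), "at least 2")
  expect_error(fit_occurrence(dat$species, use_lit = FALSE,
                              use_xc = FALSE), "At least one source")
  none <- dat$species
  none$detected_lit <- FALSE
  none$detected_xc <- FALSE
  w <- capture_warnings(fit_occurrence(none, mcmc = light_mcmc()))
  expect_true(any(grepl("prior-dominated", w)))
})

test_that("universal detection pushes occurrence above the prior mean, more so with size", {
  mk <- function(n) toy_species(rep(200L, n), rep(500L, n), TRUE, TRUE)
  q20 <- suppressWarnings(
    fit_occurrence(mk(20), mcmc = light_mcmc(2)))$summary$mean[1]
  q80 <- suppressWarnings(
    fit_occurrence(mk(80), mcmc = light_mcmc(2)))$summary$mean[1]
  expect_gt(q20, 0.5)   # prior mean under Beta(1, 1)
  expect_gt(q80, q20)
})

test_that("MCMC matches the deterministic grid oracle, single source", {
  dat <- generate_corvid_data(synth_config(n_species = 10, seed = 21))
  g <- grid_posterior(dat$species, use_xc = FALSE, n_grid = 200)
  f <- suppressWarnings(
    fit_occurrence(dat$species, use_xc = FALSE,
                   mcmc = mcmc_config(seed = 13)))
  expect_lt(abs(g$mean[g$parameter == "q"] -
                  f$summary$mean[f$summary$parameter == "q"]), 0.02)
  expect_lt(abs(g$mean[g$parameter == "d_lit"] -
                  f$summary$mean[f$summary$parameter == "d_lit"]), 0.02)
})

test_that("a source without evidence leaves its posterior at the prior", {
  # species detected in the literature but with no xeno-canto recordings
  # at all: the xc-only condition carries zero information about q
  set.seed(4)
  sp <- toy_species(sample(5:60, 24, TRUE), 0L,
                    detected_lit = runif(24) < 0.5, detected_xc = FALSE)
  out <- suppressWarnings(posterior_by_source(sp, mcmc = light_mcmc(3)))
  expect_equal(out$condition,
               c("prior", "literature_only", "xeno_canto_only", "both"))
  prior_mean <- out$mean[out$condition == "prior"]
  xc_mean <- out$mean[out$condition == "xeno_canto_only"]
  expect_lt(abs(xc_mean - prior_mean), 0.1)
})

test_that("tidy, glance and autoplot expose the fit", {
  dat <- generate_corvid_data(synth_config(n_species = 25, seed = 6))
  fit <- suppressWarnings(fit_occurrence(dat$species, mcmc = light_mcmc()))
  td <- tidy(fit)
  expect_named(td, c("parameter", "mean", "sd", "hpdi_low", "hpdi_high",
                     "ess", "rhat"))
  expect_setequal(td$parameter, c("q", "d_lit", "d_xc"))
  expect_true(all(td$hpdi_low <= td$mean & td$mean <= td$hpdi_high))
  gl <- glance(fit)
  expect_equal(gl$n_species, 25)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_occurrence(
    suppressWarnings(posterior_by_source(dat$species,
                                         mcmc = light_mcmc()))), "ggplot")
})
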