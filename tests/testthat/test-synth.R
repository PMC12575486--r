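test_that("generation is reproducible from the seed", {
  cfg <- synth_config(n_species = 50, seed = 77, fp_rate_low = 0.001)
  a <- generate_corvid_data(cfg)
  b <- generate_corvid_data(cfg)
  expect_identical(a, b)
  c <- generate_corvid_data(synth_config(n_species = 50, seed = 78,
                                         fp_rate_low = 0.001))
  expect_false(identical(a$species, c$species))
})

test_that("the saturated limit detects essentially every species", {
  cfg <- synth_config(
    n_species = 200, true_q = 0.999, true_d_lit = 0.5, true_d_xc = 0.5,
    lit_count_dist = count_resample(rep(50L, 10), min = 1),
    xc_count_dist = count_resample(rep(50L, 10)), rho = 0, seed = 5)
  dat <- generate_corvid_data(cfg)
  detected <- dat$species$detected_lit | dat$species$detected_xc
  expect_gt(mean(detected), 0.98)
})

test_that("latent mimicry frequency concentrates at true_q", {
  cfg <- synth_config(n_species = 10000, true_q = 0.8, seed = 12)
  dat <- generate_corvid_data(cfg)
  # 3-sigma binomial band around 0.8
  expect_lt(abs(mean(dat$truth$z) - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
})

test_that("generated counts match the configured moments within 3 SE", {
  n <- 4000
  mu <- 153; size <- 0.181
  cfg <- synth_config(n_species = n, true_q = 0.82, rho = 0, seed = 99,
                      xc_count_dist = count_nbinom(mu, size))
  dat <- generate_corvid_data(cfg)
  se <- sqrt((mu + mu^2 / size) / n)
  expect_lt(abs(mean(dat$species$xc_count) - mu), 3 * se)
  # literature support floor
  expect_gte(min(dat$species$lit_count), 1)
})

test_that("copula mode induces rank correlation between the two counts", {
  base <- synth_config(n_species = 3000, seed = 8, rho = 0)
  dep <- synth_config(n_species = 3000, seed = 8, rho = 0.7)
  r0 <- cor(generate_corvid_data(base)$species[, c("lit_count", "xc_count")],
            method = "spearman")[1, 2]
  r7 <- cor(generate_corvid_data(dep)$species[, c("lit_count", "xc_count")],
            method = "spearman")[1, 2]
  expect_lt(abs(r0), 0.1)
  expect_gt(r7, 0.5)
})

test_that("false positives create low-reliability records on non-mimics", {
  cfg <- synth_config(n_species = 300, true_q = 0.3, fp_rate_low = 0.01,
                      seed = 31)
  dat <- generate_corvid_data(cfg)
  non_mimics <- dat$truth$species[!dat$truth$z]
  fp_detected <- dat$species$detected_xc &
    dat$species$species %in% non_mimics
  expect_gt(sum(fp_detected), 0)
  fp_rec <- dat$records[dat$records$species %in% non_mimics &
                          dat$records$source == "xeno_canto", ]
  expect_true(all(fp_rec$reliability == "low"))
})

test_that("evidence-distribution fits match sample moments", {
  sp <- corvid_example()$species
  fit <- fit_evidence_distribution(sp, method = "nbinom")
  expect_equal(unname(fit$moments$xc["mean"]), mean(sp$xc_count))
  # method of moments: implied NB variance equals the sample variance
  implied_var <- function(d) (d$mu - d$min) + (d$mu - d$min)^2 / d$size
  expect_equal(implied_var(fit$xc), var(sp$xc_count), tolerance = 1e-8)
  expect_equal(fit$xc$mu, mean(sp$xc_count))

  # published-scale check: mean 153, SD 360 gives a dispersion near 0.18
  expect_lt(abs(fit$xc$size - 153^2 / (360^2 - 153)), 0.02)

  # resampler support: every drawn pair occurs in the data
  rs <- fit_evidence_distribution(sp, method = "resample")
  set.seed(2)
  drawn <- draw_evidence(rs, 500)
  key <- paste(sp$lit_count, sp$xc_count)
  expect_true(all(paste(drawn$e_lit, drawn$e_xc) %in% key))

  # degenerate input reproduces the constant
  const <- toy_species(rep(4L, 6), rep(9L, 6), FALSE, FALSE)
  rs2 <- fit_evidence_distribution(const, method = "resample")
  d2 <- draw_evidence(rs2, 50)
  expect_true(all(d2$e_lit == 4L & d2$e_xc == 9L))

  # underdispersed counts fall back to Poisson with a warning per source
  w <- capture_warnings(fit_evidence_distribution(const, method = "nbinom"))
  expect_true(all(grepl("Poisson", w)) && length(w) == 2)

  expect_error(fit_evidence_distribution(const[1:3, ]), "at least 5")
})

test_that("refitting generated data recovers the generating parameters", {
  cfg <- synth_config(n_species = 400, true_q = 0.82, true_d_lit = 0.05,
                      true_d_xc = 0.003, seed = 55)
  dat <- generate_corvid_data(cfg)
  fit <- suppressWarnings(
    fit_occurrence(dat$species, mcmc = mcmc_config(chains = 2, seed = 55)))
  s <- fit$summary
  for (par in c("q", "d_lit", "d_xc")) {
    truth <- switch(par, q = 0.82, d_lit = 0.05, d_xc = 0.003)
    row <- s[s$parameter == par, ]
    expect_lt(abs(row$mean - truth), 4 * row$sd)
  }
})
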