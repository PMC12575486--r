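test_that("reliability rules recode detections as specified", {
  dat <- corvid_example()
  sp <- dat$species
  rec <- dat$records

  # baseline is the identity
  expect_identical(apply_reliability_rule(sp, rec,
                                          sensitivity_scenario("baseline")),
                   sp)

  # species with only low-reliability records flip under all_low_false
  low_only <- rec |>
    dplyr::filter(source == "xeno_canto") |>
    dplyr::group_by(species) |>
    dplyr::summarise(low_only = all(reliability == "low")) |>
    dplyr::filter(low_only)
  expect_equal(nrow(low_only), 3)   # three such species, as in the dataset
  recoded <- apply_reliability_rule(sp, rec,
                                    sensitivity_scenario("all_low_false"))
  expect_false(any(recoded$detected_xc[sp$species %in% low_only$species]))

  # a species holding high records stays detected under only_high_true
  strict <- apply_reliability_rule(sp, rec,
                                   sensitivity_scenario("only_high_true"))
  has_high <- unique(rec$species[rec$reliability %in% "high"])
  expect_true(all(strict$detected_xc[sp$species %in% has_high]))

  # moderate counts as true under all_low_false, false under only_high_true
  sp1 <- toy_species(1, 5, FALSE, TRUE)
  rec1 <- tibble::tibble(species = sp1$species, source = "xeno_canto",
                         reliability = "moderate", bird_seen = "yes",
                         mimicked_sound = "bell", duration_s = 10,
                         date = NA_character_, lat = NA_real_,
                         lon = NA_real_)
  expect_true(apply_reliability_rule(
    sp1, rec1, sensitivity_scenario("all_low_false"))$detected_xc)
  expect_false(apply_reliability_rule(
    sp1, rec1, sensitivity_scenario("only_high_true"))$detected_xc)

  # unknown rule objects are rejected
  bogus <- structure(list(rule = "flip_everything", name = "x",
                          description = ""),
                     class = "sensitivity_scenario")
  expect_error(apply_reliability_rule(sp, rec, bogus), "Unknown scenario")

  # rules are monotone: they only ever un-detect
  for (rule in c("all_low_false", "only_high_true")) {
    out <- apply_reliability_rule(sp, rec, sensitivity_scenario(rule))
    expect_true(all(sp$detected_xc[out$detected_xc]))
    expect_identical(out$detected_lit, sp$detected_lit)
    expect_identical(out$xc_count, sp$xc_count)
  }
})

test_that("discounted records can optionally be removed as evidence", {
  sp1 <- toy_species(1, 10, FALSE, TRUE)
  rec1 <- tibble::tibble(species = sp1$species, source = "xeno_canto",
                         reliability = c("low", "low", "high"),
                         bird_seen = "yes", mimicked_sound = "bell",
                         duration_s = 10, date = NA_character_,
                         lat = NA_real_, lon = NA_real_)
  out <- apply_reliability_rule(sp1, rec1,
                                sensitivity_scenario("all_low_false"),
                                drop_discounted_evidence = TRUE)
  expect_equal(out$xc_count, 8L)
  expect_true(out$detected_xc)   # the high record remains
})

test_that("scenarios are no-ops when no low or moderate records exist", {
  cfg <- synth_config(n_species = 60, seed = 17,
                      reliability_mix = c(high = 1, moderate = 0, low = 0))
  dat <- generate_corvid_data(cfg)
  sweep <- suppressWarnings(
    sensitivity_sweep(dat$species, dat$records, mcmc = light_mcmc(5)))
  expect_equal(nrow(sweep), 3)
  expect_equal(sweep$mean[sweep$rule == "all_low_false"],
               sweep$mean[sweep$rule == "baseline"])
  expect_equal(sweep$mean[sweep$rule == "only_high_true"],
               sweep$mean[sweep$rule == "baseline"])
})

test_that("all-low detections collapse to near-prior under all_low_false", {
  cfg <- synth_config(n_species = 60, seed = 23,
                      reliability_mix = c(high = 0, moderate = 0, low = 1))
  dat <- generate_corvid_data(cfg)
  # keep only xc detections so the rule wipes out every detection
  sp <- dat$species
  sp$detected_lit <- FALSE
  sweep <- suppressWarnings(
    sensitivity_sweep(sp, dat$records, mcmc = light_mcmc(5)))
  base <- sweep$mean[sweep$rule == "baseline"]
  conservative <- sweep$mean[sweep$rule == "all_low_false"]
  expect_lt(conservative, base)
  expect_equal(sweep$n_detected_xc[sweep$rule == "all_low_false"], 0)
})

test_that("prior sensitivity reports the spread across prior settings", {
  expect_error(prior_sensitivity(corvid_example()$species[0, ],
                                 list(prior_config(), prior_config())),
               "Empty dataset")
  # strongly informative prior dominates a tiny, uninformative dataset
  sp <- toy_species(c(1, 1, 1), c(0, 0, 0), FALSE, FALSE)
  grid <- list(flat = prior_config(),
               strong = prior_config(q = c(90, 10)))
  out <- suppressWarnings(
    prior_sensitivity(sp, grid, mcmc = light_mcmc(2)))
  strong_mean <- out$q_mean[out$prior == "strong"]
  expect_lt(abs(strong_mean - 0.9), 0.05)
  # grid oracle agrees under the same strong prior
  g <- grid_posterior(sp, priors = grid$strong, n_grid = 150)
  expect_lt(abs(strong_mean - g$mean[g$parameter == "q"]), 0.03)
  expect_gt(attr(out, "max_diff"), 0)
})

test_that("scale-up recovery reports coverage and error per condition", {
  p <- evidence_params(q = 0.8, d_lit = 0.05, d_xc = 0.004)
  dist <- fit_evidence_distribution(corvid_example()$species)
  rep <- scale_up_recovery(p, dist, n_species = 60, n_replicates = 3,
                           seed = 2, conditions = "both",
                           mcmc = light_mcmc())
  expect_named(rep, c("condition", "n_species", "n_replicates", "coverage",
                      "mae", "bias"))
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 1))
  expect_equal(nrow(attr(rep, "replicates")), 3)

  # information-poor limit: minuscule detection rates and almost no
  # evidence leave the posterior near the flat prior, with wide intervals
  weak <- evidence_params(q = 0.8, d_lit = 1e-5, d_xc = 1e-6)
  thin <- fit_evidence_distribution(toy_species(rep(1L, 6), rep(0L, 6),
                                                FALSE, FALSE))
  rep2 <- scale_up_recovery(weak, thin, n_species = 10, n_replicates = 2,
                            seed = 3, conditions = "both",
                            mcmc = light_mcmc())
  r2 <- attr(rep2, "replicates")
  expect_true(all(r2$hpdi_high - r2$hpdi_low > 0.5))
  expect_true(all(abs(r2$q_mean - 0.5) < 0.25))
})
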