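test_that("hidden-mimicry probability obeys its closed-form identities", {
  p <- evidence_params(q = 0.37, d_lit = 0.1, d_xc = 0.02)
  # no evidence: best guess is the corvid-wide intercept
  expect_equal(p_hidden(p, 0, 0), 0.37)
  # detected species are mimics
  expect_equal(p_hidden(p, 5, 5, detected = TRUE), 1)
  # worked closed form
  p2 <- evidence_params(q = 0.5, d_lit = 0.1, d_xc = 0.5)
  expect_equal(p_hidden(p2, 10, 0), 0.9^10 / (0.9^10 + 1))
  # Bayes-rule enumeration oracle
  set.seed(14)
  for (i in 1:20) {
    q <- runif(1, 0.05, 0.95)
    dl <- runif(1, 0.01, 0.5)
    dx <- runif(1, 0.001, 0.2)
    el <- sample(0:100, 1)
    ex <- sample(0:500, 1)
    expect_equal(p_hidden(evidence_params(q, dl, dx), el, ex),
                 enum_p_hidden(q, dl, dx, el, ex), tolerance = 1e-12)
  }
})

test_that("hidden probability declines strictly in each evidence count", {
  p <- evidence_params(q = 0.8, d_lit = 0.05, d_xc = 0.005)
  expect_true(all(diff(p_hidden(p, 0:200, 0)) < 0))
  expect_true(all(diff(p_hidden(p, 0, 0:2000)) < 0))
  expect_lt(p_hidden(p, 500, 5000), 1e-6)  # e -> Inf limit
})

test_that("composite score converts evidence to literature-entry units", {
  p <- evidence_params(q = 0.5, d_lit = 0.2, d_xc = 0.05)
  expect_equal(composite_evidence(p, 5, 0), 5)
  p_eq <- evidence_params(q = 0.5, d_lit = 0.2, d_xc = 0.2)
  expect_equal(composite_evidence(p_eq, 0, 10), 10)
  expect_equal(composite_evidence(p, 0, 4), 4 * log(0.95) / log(0.8))
  # survival matching: the score's survival equals the joint survival
  sc <- composite_evidence(p, 3, 7)
  expect_equal((1 - 0.2)^sc, (1 - 0.2)^3 * (1 - 0.05)^7)
})

test_that("equal composite score implies equal hidden probability", {
  set.seed(31)
  for (i in 1:20) {
    d_lit <- runif(1, 0.05, 0.5)
    k <- sample(2:6, 1)
    d_xc <- 1 - (1 - d_lit)^k   # one xc unit worth exactly k lit units
    m <- sample(1:20, 1)
    q <- runif(1, 0.1, 0.9)
    p <- evidence_params(q, d_lit, d_xc)
    expect_equal(composite_evidence(p, k * m, 0),
                 composite_evidence(p, 0, m), tolerance = 1e-9)
    expect_equal(p_hidden(p, k * m, 0), p_hidden(p, 0, m),
                 tolerance = 1e-12)
  }
})

test_that("hidden table integrates the closed form over posterior draws", {
  sp <- toy_species(c(1, 10, 200), c(0, 50, 1000), FALSE,
                    c(FALSE, FALSE, TRUE))
  sp$lit_count[1] <- 0L

  # two-draw posterior, zero-evidence species averages the draws of q
  draws <- tibble::tibble(q = c(0.4, 0.6), d_lit = c(0.1, 0.1),
                          d_xc = c(0.01, 0.01))
  tbl <- hidden_table(sp, draws)
  expect_equal(tbl$p_hidden_mean[1], 0.5)
  # detected species fixed at 1
  expect_equal(tbl$p_hidden_mean[3], 1)

  # single-draw posterior degenerates to the plug-in value
  one <- draws[1, ]
  t1 <- hidden_table(sp, one)
  plug <- p_hidden(evidence_params(0.4, 0.1, 0.01), sp$lit_count,
                   sp$xc_count, sp$detected_lit | sp$detected_xc)
  expect_equal(t1$p_hidden_mean, plug)

  expect_error(hidden_table(sp, tibble::tibble(q = 0.5)), "draws")
})

test_that("species with the most evidence has the smallest hidden probability", {
  dat <- generate_corvid_data(synth_config(n_species = 60, seed = 9))
  fit <- suppressWarnings(fit_occurrence(dat$species, mcmc = light_mcmc()))
  tbl <- hidden_table(dat$species, fit)
  und <- dplyr::filter(tbl, !detected)
  best_doc <- which.max(und$composite_score)
  expect_equal(which.min(und$p_hidden_mean), best_doc)
  expect_s3_class(plot_hidden(tbl), "ggplot")
})

test_that("ranking is deterministic with alphabetical tie-breaks", {
  tbl <- tibble::tibble(
    species = c("c sp", "a sp", "b sp", "d sp"),
    genus = "g", e_lit = 1L, e_xc = 0L,
    detected = c(FALSE, FALSE, FALSE, TRUE),
    composite_score = 1, p_hidden_mean = c(0.5, 0.1, 0.8, 1),
    p_hidden_low = 0, p_hidden_high = 1)
  rk <- rank_species(tbl, k = 1)
  expect_equal(rk$top$species, "b sp")
  expect_equal(rk$bottom$species, "a sp")
  expect_false(attr(rk, "all_tied"))
  expect_error(rank_species(tbl, k = 5), "exceeds")

  tied <- dplyr::mutate(tbl, p_hidden_mean = c(0.3, 0.3, 0.3, 1))
  rk2 <- rank_species(tied, k = 3)
  expect_true(attr(rk2, "all_tied"))
  expect_equal(rk2$bottom$species, c("a sp", "b sp", "c sp"))
})
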