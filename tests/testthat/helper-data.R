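# Minimal species tibble for likelihood-level tests; counts need not obey
# the schema floor (lit_count >= 1) because these rows never pass through
# read_dataset().
toy_species <- function(lit_count, xc_count, detected_lit, detected_xc,
                        genus = "Corvus") {
  n <- max(length(lit_count), length(xc_count))
  tibble::tibble(
    species = sprintf("Corvus toy%02d", seq_len(n)),
    genus = genus,
    lit_count = as.integer(rep_len(lit_count, n)),
    xc_count = as.integer(rep_len(xc_count, n)),
    detected_lit = rep_len(detected_lit, n),
    detected_xc = rep_len(detected_xc, n),
    body_mass_g = NA_real_, repertoire_size = NA_integer_,
    breeding_system = NA_character_, habitat = NA_character_,
    trophic_niche = NA_character_)
}

# Brute-force likelihood by explicit enumeration of the latent mimic
# status; the independent oracle for species_loglik and p_hidden.
enum_loglik <- function(q, d_lit, d_xc, e_lit, e_xc, det_lit, det_xc,
                        use_lit = TRUE, use_xc = TRUE) {
  lik_given_z <- function(z) {
    f <- 1
    if (use_lit) {
      p <- if (z) 1 - (1 - d_lit)^e_lit else 0
      f <- f * if (det_lit) p else 1 - p
    }
    if (use_xc) {
      p <- if (z) 1 - (1 - d_xc)^e_xc else 0
      f <- f * if (det_xc) p else 1 - p
    }
    f
  }
  log(q * lik_given_z(TRUE) + (1 - q) * lik_given_z(FALSE))
}

enum_p_hidden <- function(q, d_lit, d_xc, e_lit, e_xc) {
  joint_mimic <- q * (1 - d_lit)^e_lit * (1 - d_xc)^e_xc
  joint_non <- (1 - q) * 1
  joint_mimic / (joint_mimic + joint_non)
}

light_mcmc <- function(seed = 1) {
  mcmc_config(chains = 2, iter = 800, warmup = 600, seed = seed)
}
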