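test_that("chirp spec validation names the offending field", {
  expect_error(chirp_spec(f_start = -5), "f_start")
  expect_error(chirp_spec(f_end = 50), "f_end")
  expect_error(chirp_spec(f_end = 3000), "f_end")   # beyond Nyquist
  expect_error(chirp_spec(duration = 0), "duration")
  expect_error(chirp_spec(amplitude = 1.5), "amplitude")
})

test_that("chirp sweeps linearly from 100 to 1000 Hz over 56000 samples", {
  spec <- default_chirp()
  expect_equal(chirp_frequency(spec, 0), 100)
  expect_equal(chirp_frequency(spec, 7), 550)
  expect_equal(chirp_frequency(spec, 14), 1000)
  rec <- clean_chirp_rec()
  expect_length(rec$samples, 56000)
  expect_true(all(abs(rec$samples) <= spec$amplitude + 1e-12))
  # instantaneous frequency from the analytic phase: zero-crossing spacing
  # near t = 7 s should correspond to ~550 Hz
  mid <- rec$samples[27500:28500]
  zc <- which(diff(sign(mid)) != 0)
  f_est <- 4000 / (2 * mean(diff(zc)))
  expect_lt(abs(f_est - chirp_frequency(spec, (27500 + 28000) / 2 / 4000)), 10)
})

test_that("flat transmission profiles scale amplitude exactly", {
  rec <- clean_chirp_rec()
  out0 <- apply_transmission(rec, flat_profile(0))
  expect_lt(max(abs(out0$samples - rec$samples)), 1e-6)
  out20 <- apply_transmission(rec, flat_profile(20))
  expect_equal(rms(out20$samples) / rms(rec$samples), 0.1, tolerance = 0.01)
})

test_that("frequency-dependent attenuation matches the narrowband oracle", {
  # sloped profile; oracle = direct RMS ratio of an isolated pure tone
  prof <- transmission_profile(c(100, 1000), c(3, 18))
  for (f in c(200, 400, 700, 900)) {
    tone <- recording(0.5 * sin(2 * pi * f * (0:15999) / 4000), 4000)
    out <- apply_transmission(tone, prof)
    expected_db <- stats::approx(prof$frequencies, prof$attenuation_db, f)$y
    measured_db <- -20 * log10(rms(out$samples) / rms(tone$samples))
    expect_lt(abs(measured_db - expected_db), 0.1)
  }
  # and through the STFT band-tracking pipeline, across the whole sweep
  rec <- clean_chirp_rec()
  p_in <- intensity_profile(rec)
  p_out <- intensity_profile(apply_transmission(rec, prof))
  mid <- p_in$chirp_freqs >= 150 & p_in$chirp_freqs <= 950
  expected <- stats::approx(prof$frequencies, prof$attenuation_db,
                            p_in$chirp_freqs[mid])$y
  measured <- (p_in$intensity_db - p_out$intensity_db)[mid]
  expect_lt(max(abs(measured - expected)), 1)
})

test_that("transmission profile enforces its invariants", {
  expect_error(transmission_profile(c(100, 1000), c(-1, 3)), ">= 0")
  expect_error(transmission_profile(c(100, 1000), c(Inf, 3)), "finite")
  expect_error(apply_transmission(clean_chirp_rec(),
                                  transmission_profile(c(200, 800), c(1, 1))),
               "does not cover")
})

test_that("ACS profiles stay >= 5 dB above baseline with band-average in range", {
  set.seed(1)
  for (i in 1:20) {
    base <- healthy_profile(gain_offset_db = rnorm(1, 0, 2))
    extra_mean <- runif(1, 12, 16)
    acs <- acs_profile(base, extra_mean)
    extra <- acs$attenuation_db - base$attenuation_db
    expect_true(all(extra >= 5))
    expect_gte(mean(extra), 10)
    expect_lte(mean(extra), 16)
    expect_identical(acs$class_tag, "ACS_LIKE")
  }
})

test_that("noise addition honors its RMS, off switch, and determinism", {
  silence <- recording(numeric(8000), 4000)
  n <- add_noise(silence, -40, seed = 5, ref_amplitude = 0.5)
  expect_equal(rms(n$samples), 0.5 * 10^(-40 / 20), tolerance = 0.05)
  expect_identical(add_noise(clean_chirp_rec(), -Inf)$samples,
                   clean_chirp_rec()$samples)
  a <- add_noise(clean_chirp_rec(), -40, seed = 9)
  b <- add_noise(clean_chirp_rec(), -40, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_error(add_noise(clean_chirp_rec(), 10), "noise_db")
})

test_that("default cohort has 133 healthy and 12 ACS observations", {
  meta <- default_cohort()$metadata
  counts <- table(meta$true_label)
  expect_equal(unname(counts[["healthy"]]), 133)
  expect_equal(unname(counts[["acs"]]), 12)
  expect_equal(nrow(meta), 145)
  expect_true(all(meta$location %in% POSTERIOR_LOCATIONS))
  # ACS observations sit at the configured affected (basal) sites
  expect_true(all(meta$location[meta$true_label == "acs"] %in% c("PBL", "PBR")))
  expect_true(all(is.na(meta$mean_extra_db[meta$true_label == "healthy"])))
  acs_extra <- meta$mean_extra_db[meta$true_label == "acs"]
  expect_true(all(acs_extra >= 12 & acs_extra <= 16))
})

test_that("cohort generation is deterministic and respects n_acs = 0", {
  cfg <- cohort_config(n_healthy = 8, n_acs = 3, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  for (i in seq_along(a$recordings)) {
    expect_identical(a$recordings[[i]]$samples, b$recordings[[i]]$samples)
  }
  only_h <- generate_cohort(cohort_config(n_healthy = 7, n_acs = 0))
  expect_true(all(only_h$metadata$true_label == "healthy"))
  expect_error(generate_cohort(cohort_config(n_healthy = 0, n_acs = 0)),
               "empty cohort")
})

test_that("injected group attenuation is recovered within 1 dB by the pipeline", {
  # parameter recovery: generator separation -> spectral-analysis difference
  coh <- small_cohort()
  labs <- coh$metadata$true_label
  profiles <- lapply(coh$recordings, intensity_profile)
  d <- group_difference(group_average_curve(profiles[labs == "healthy"]),
                        group_average_curve(profiles[labs == "acs"]))
  injected <- mean(coh$metadata$mean_extra_db[labs == "acs"])
  expect_lt(abs(d$mean_db - injected), 1)
  expect_gt(d$min_db, 5 - 1)  # floor minus subject-variability allowance
})
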