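test_that("weighted averaging reproduces the hand-worked two-recording case", {
  # constant PSDs 3 and 7 at distances 1 mm and 3 mm:
  # (3*1 + 7/3) / (1 + 1/3) = 16/4 = 4 at every bin
  got <- oracle_weighted_mean(list(rep(3, 100), rep(7, 100)), c(1, 3))
  expect_equal(got, rep(4, 100))

  # the same computation through the package, on a crafted two-channel survey
  geom <- lead_geometry("unit", contact_height = 0.75, inter_level_gap = 0.25,
                        lead_diameter = 1.27)
  # level spacing 1 mm: contact "0" sits 1 mm from virtual "1", 3 mm from "3"
  expect_equal(contact_distance(geom, "0", "1"), 1)
  expect_equal(contact_distance(geom, "0", "3"), 3)
  t <- seq(0, 20, by = 1 / 250)
  set.seed(1)
  x1 <- rnorm(length(t))
  x2 <- rnorm(length(t))
  survey <- new_hemisphere_survey(list("0-1" = x1, "0-3" = x2), fs = 250,
                                  geometry = geom)
  suppressWarnings({
    spectra <- survey_spectra(survey)
    w <- weighted_monopolar_spectrum("0", survey, spectra)
  })
  want <- oracle_weighted_mean(list(spectra[["0-1"]]$power,
                                    spectra[["0-3"]]$power), c(1, 3))
  expect_equal(w$power, want, tolerance = 1e-12)
  expect_equal(attr(w, "n_contributing"), 2L)
})

test_that("weighted monopolar spectra match the brute-force oracle", {
  sim <- quick_sim("1C", snr = 2, seed = 3)
  spectra <- survey_spectra(sim$survey)
  geom <- sim$survey$geometry
  for (ct in monopolar_configs()) {
    got <- weighted_monopolar_spectrum(ct, sim$survey, spectra)
    contrib <- attr(got, "weights")
    want <- oracle_weighted_mean(lapply(contrib$label,
                                        function(l) spectra[[l]]$power),
                                 contrib$distance)
    expect_equal(got$power, want, tolerance = 1e-12)
  }
})

test_that("equal distances reduce to the arithmetic mean; n = 1 is identity", {
  p1 <- runif(100)
  p2 <- runif(100)
  expect_equal(oracle_weighted_mean(list(p1, p2), c(2, 2)), (p1 + p2) / 2)
  expect_equal(oracle_weighted_mean(list(p1), 5), p1)
})

test_that("increasing a recording's distance strictly lowers its influence", {
  # two constant spectra; the second carries the distinctive power
  f <- function(d2) oracle_weighted_mean(list(rep(1, 3), rep(10, 3)),
                                         c(1, d2))[1]
  vals <- vapply(c(1, 2, 4, 8), f, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("a contact absent from every recording is a no-data error", {
  geom <- lead_geometry()
  survey <- new_hemisphere_survey(list("0-1" = rnorm(1000)), fs = 250,
                                  geometry = geom)
  spectra <- suppressWarnings(survey_spectra(survey))
  expect_error(weighted_monopolar_spectrum("2B", survey, spectra),
               "no recording")
})

test_that("strategy selection prefers low-beta and reports consensus", {
  mk <- function(bump_freq, height) {
    synth_spectrum(offset = 1, exponent = 1.5, bump_freq = bump_freq,
                   bump_height = height)
  }
  # no qualifying peak anywhere -> low_beta
  flatset <- lapply(1:10, function(i) synth_spectrum(offset = 1,
                                                     exponent = 1.5))
  names(flatset) <- monopolar_configs()
  st <- choose_strategy(flatset)
  expect_identical(st$mode, "low_beta")
  expect_true(is.na(st$peak_freq))

  # single candidate at 19 Hz
  one <- flatset
  one[["2B"]] <- mk(19, 0.8)
  st1 <- choose_strategy(one)
  expect_identical(st1$mode, "peak")
  expect_equal(st1$peak_freq, 19)

  # candidates at 17 and 28 Hz -> low beta preferred even if less prominent
  two <- flatset
  two[["1A"]] <- mk(17, 0.6)
  two[["2B"]] <- mk(28, 1.2)
  st2 <- choose_strategy(two)
  expect_identical(st2$mode, "peak")
  expect_equal(st2$peak_freq, 17)
  expect_true(st2$qc$consensus_disagreement)  # spread > 3 Hz
})

test_that("activity scoring matches the hand-worked indicator case", {
  flat <- new_spectrum(1:100, replace(rep(0, 100), 18, 5), "flattened")
  st <- list(mode = "peak", peak_freq = 18)
  # mean over the 5-bin window 16-20 = h/5; normalizer = total positive = h
  expect_equal(as.numeric(score_activity(flat, st)), 1 / 5)
  # scale invariance
  flat2 <- new_spectrum(1:100, replace(rep(0, 100), 18, 500), "flattened")
  expect_equal(as.numeric(score_activity(flat2, st)),
               as.numeric(score_activity(flat, st)))
  # all-zero flattened spectrum scores 0 with a QC flag
  z <- new_spectrum(1:100, rep(0, 100), "flattened")
  s0 <- score_activity(z, st)
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "qc_degenerate"))
})

test_that("level ranking follows activity with rank 4 = best", {
  flats <- list()
  acts <- c("0" = 0.1, "1" = 0.4, "2" = 0.2, "3" = 0.3)
  for (id in names(acts)) {
    flats[[id]] <- new_spectrum(1:100, replace(rep(0, 100), 15, acts[[id]]),
                                "flattened")
  }
  st <- list(mode = "low_beta", peak_freq = NA)
  # indicator at 15 Hz: score = (a/8)/a = 1/8 for all -> use distinct
  # denominators instead: put extra positive power outside the band
  for (id in names(acts)) {
    flats[[id]]$power[50] <- 1 - acts[[id]]  # total positive power = 1
  }
  lv <- rank_levels(flats, st)
  expect_equal(lv$level_ranks, c("0" = 1L, "1" = 4L, "2" = 2L, "3" = 3L))
  expect_identical(lv$best_level, 1L)
  expect_false(lv$qc$tie)
})

test_that("ties rank deterministically toward ventral / alphabetical", {
  z <- new_spectrum(1:100, rep(0, 100), "flattened")
  flats <- list("0" = z, "1" = z, "2" = z, "3" = z,
                "1A" = z, "1B" = z, "1C" = z, "2A" = z, "2B" = z, "2C" = z)
  st <- list(mode = "low_beta", peak_freq = NA)
  lv <- rank_levels(flats, st)
  expect_true(lv$qc$tie)
  expect_identical(lv$best_level, 0L)  # most ventral wins the tie
  dc <- select_directional(flats, st, lv$best_level)
  expect_identical(dc$directional_level_used, 1L)  # fallback 0 -> 1
  expect_identical(dc$best_contact, "1A")          # alphabetical tie-break
  expect_true(dc$qc$tie)
})

test_that("directional fallback maps rings to neighbors, levels to self", {
  z <- new_spectrum(1:100, rep(0, 100), "flattened")
  flats <- list("1A" = z, "1B" = z, "1C" = z, "2A" = z, "2B" = z, "2C" = z)
  st <- list(mode = "low_beta", peak_freq = NA)
  expect_identical(select_directional(flats, st, 0L)$directional_level_used,
                   1L)
  expect_identical(select_directional(flats, st, 3L)$directional_level_used,
                   2L)
  expect_identical(select_directional(flats, st, 1L)$directional_level_used,
                   1L)
  expect_identical(select_directional(flats, st, 2L)$directional_level_used,
                   2L)
})

test_that("segment ranking orders activities with rank 3 = best", {
  st <- list(mode = "low_beta", peak_freq = NA)
  flats <- list()
  acts <- c("1A" = 0.5, "1B" = 0.3, "1C" = 0.1)
  for (id in names(acts)) {
    p <- rep(0, 100)
    p[15] <- acts[[id]]
    p[50] <- 1 - acts[[id]]
    flats[[id]] <- new_spectrum(1:100, p, "flattened")
  }
  dc <- select_directional(flats, st, 1L)
  expect_equal(dc$contact_ranks, c("1A" = 3L, "1B" = 2L, "1C" = 1L))
  expect_identical(dc$best_contact, "1A")
})

test_that("run_detec output is internally consistent", {
  sim <- quick_sim("2A", snr = 4, seed = 9)
  res <- run_detec(sim$survey)
  expect_s3_class(res, "detec_selection")
  expect_setequal(res$level_ranks, 1:4)
  expect_setequal(res$contact_ranks, 1:3)
  expect_identical(
    res$best_level,
    as.integer(names(res$level_activity)[which.max(res$level_activity)]))
  expect_identical(
    res$best_contact,
    names(res$contact_activity)[which.max(res$contact_activity)])
  expect_true(res$directional_level_used %in% 1:2)
  expect_identical(res$best_level, 2L)
  expect_identical(res$best_contact, "2A")
})

test_that("run_detec on an all-zero survey degrades gracefully", {
  survey <- uniform_survey(numeric(5000))
  res <- run_detec(survey)
  expect_identical(res$strategy$mode, "low_beta")
  expect_true(all(res$level_activity == 0))
  expect_true(all(res$contact_activity == 0))
  expect_true(res$qc$level_tie)
  expect_true(res$qc$contact_tie)
  expect_length(res$qc$degenerate_configs, 10L)
})

test_that("run_detec is invariant to channel order", {
  sim <- quick_sim("1B", snr = 2, seed = 13)
  res1 <- run_detec(sim$survey)
  shuffled <- sim$survey
  set.seed(99)
  shuffled$recordings <- shuffled$recordings[sample(montage_pairs())]
  res2 <- run_detec(shuffled)
  expect_equal(res1$level_activity, res2$level_activity)
  expect_equal(res1$contact_activity, res2$contact_activity)
  expect_identical(res1$best_level, res2$best_level)
  expect_identical(res1$best_contact, res2$best_contact)
  expect_identical(res1$strategy$mode, res2$strategy$mode)
})

test_that("unknown config fields are rejected", {
  expect_error(detec_config(nonsense = 1), "unknown configuration")
})

test_that("bipolar screening is available as a strategy variant", {
  sim <- quick_sim("2B", snr = 4, seed = 17)
  res_m <- run_detec(sim$survey)
  res_b <- run_detec(sim$survey, detec_config(screen = "bipolar"))
  expect_s3_class(res_b, "detec_selection")
  expect_true(res_b$strategy$mode %in% c("peak", "low_beta"))
  expect_setequal(res_b$level_ranks, 1:4)
  # with a strong planted source both readings find a peak
  expect_identical(res_m$strategy$mode, "peak")
  expect_identical(res_b$strategy$mode, "peak")
})
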