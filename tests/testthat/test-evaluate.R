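test_that("spearman_rank matches the brute-force oracle with and without ties", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) {  # inject ties
      x <- round(x)
      y <- round(y * 2) / 2
    }
    if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) next
    got <- spearman_rank(x, y)
    expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("perfect and reversed monotone pairs give rho of +1 and -1", {
  x <- c(0.3, 1.2, 5, 9)
  expect_equal(spearman_rank(x, x^3)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)
})

test_that("the n = 4 worked example has rho 0.6 with exact enumeration p", {
  x <- 1:4
  y <- c(2, 1, 4, 3)
  got <- spearman_rank(x, y)
  expect_equal(got$rho, 0.6, tolerance = 1e-12)
  expect_identical(got$method, "exact")
  expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  expect_equal(got$p, 10 / 24, tolerance = 1e-12)  # enumeration of 4! orders
})

test_that("exact p switches to the t approximation for n > 9", {
  set.seed(3)
  x <- rnorm(12)
  y <- x + rnorm(12)
  got <- spearman_rank(x, y)
  expect_identical(got$method, "t-approximation")
  # against the standard reference implementation
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
  expect_error(spearman_rank(1:4, 1:3), "equal length")
  expect_error(spearman_rank(rep(1, 4), 1:4), "zero variance")
})

# A small synthetic cohort: selections from simulation, clinical scores
# generated as a noisy monotone function of contact-to-source distance.
make_cohort <- function(n_hemi = 4, seed = 100, noise_sd = 0) {
  set.seed(seed)
  targets <- rep(all_segments, length.out = n_hemi)
  sels <- list()
  clin <- list()
  for (i in seq_len(n_hemi)) {
    hemi <- paste0("H", i)
    pos <- source_near_segment(default_geom, targets[i])
    sim <- simulate_survey(source_model(pos), noise_model(), default_geom,
                           snr = 4, seed = seed + i, hemisphere = hemi)
    res <- run_detec(sim$survey)
    sels[[hemi]] <- res
    d <- vapply(monopolar_configs(), function(id) {
      sqrt(sum((contact_center(default_geom, id) - pos)^2))
    }, numeric(1))
    clin[[hemi]] <- data.frame(hemisphere = hemi,
                               contact_id = names(d),
                               efficacy = 10 - d + rnorm(length(d),
                                                         sd = noise_sd))
  }
  list(selections = sels, clinical = do.call(rbind, clin))
}

test_that("match rates are 1 when clinical scores follow the ground truth", {
  cohort <- make_cohort(n_hemi = 4, seed = 100, noise_sd = 0)
  mr <- match_rates(cohort$selections, cohort$clinical)
  expect_equal(mr$level_match, 1.0)
  expect_equal(mr$contact_match, 1.0)
  expect_equal(mr$level_top2, 1.0)
  expect_identical(mr$n, 4L)
  expect_length(mr$excluded, 0L)
})

test_that("hemispheres without clinical data are excluded with a warning", {
  cohort <- make_cohort(n_hemi = 3, seed = 200)
  clin <- cohort$clinical[cohort$clinical$hemisphere != "H2", ]
  expect_warning(mr <- match_rates(cohort$selections, clin), "H2")
  expect_identical(mr$n, 2L)
  expect_identical(mr$excluded, "H2")
})

test_that("empty overlap between selections and clinical data errors", {
  cohort <- make_cohort(n_hemi = 2, seed = 300)
  clin <- cohort$clinical
  clin$hemisphere <- paste0("X", clin$hemisphere)
  expect_error(match_rates(cohort$selections, clin), "no hemisphere")
})

test_that("match rates are invariant to hemisphere ordering", {
  cohort <- make_cohort(n_hemi = 4, seed = 400, noise_sd = 0.5)
  mr1 <- match_rates(cohort$selections, cohort$clinical)
  mr2 <- match_rates(rev(cohort$selections), cohort$clinical)
  expect_equal(mr1$level_match, mr2$level_match)
  expect_equal(mr1$contact_match, mr2$contact_match)
  expect_true(all(c(mr1$level_match, mr1$level_top2, mr1$contact_match) >= 0))
  expect_true(all(c(mr1$level_match, mr1$level_top2, mr1$contact_match) <= 1))
})

test_that("z-scored activity has mean 0 and sd 1 per hemisphere", {
  set.seed(5)
  act <- data.frame(hemisphere = rep(c("A", "B"), each = 8),
                    contact_id = rep(lead_contacts(), 2),
                    activity = rnorm(16))
  coords <- data.frame(hemisphere = rep(c("A", "B"), each = 8),
                       contact_id = rep(lead_contacts(), 2),
                       x = rnorm(16, -12), y = rnorm(16, -12),
                       z = rnorm(16, -6), side = "left")
  ss <- sweetspot_distance_analysis(act, coords)
  for (h in c("A", "B")) {
    z <- ss$table$activity_z[ss$table$hemisphere == h]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  }
})

test_that("a contact at the sweet spot has distance 0; x is mirrored", {
  spot <- c(-12.5, -12.72, -5.38)  # anatomical center of gravity
  act <- data.frame(hemisphere = "A", contact_id = c("0", "1A", "2A"),
                    activity = c(1, 2, 3))
  coords <- data.frame(hemisphere = "A", contact_id = c("0", "1A", "2A"),
                       x = c(-12.5, -10, 12.5),
                       y = c(-12.72, -10, -12.72),
                       z = c(-5.38, -4, -5.38),
                       side = c("left", "left", "right"))
  ss <- sweetspot_distance_analysis(act, coords, spot)
  tab <- ss$table
  expect_equal(tab$distance[tab$contact_id == "0"], 0)
  # right-side contact mirrored onto the left: also lands on the spot
  expect_equal(tab$distance[tab$contact_id == "2A"], 0)
})

test_that("constant activity or too few contacts are errors", {
  act <- data.frame(hemisphere = "A", contact_id = c("0", "1A", "2A"),
                    activity = c(1, 1, 1))
  coords <- data.frame(hemisphere = "A", contact_id = c("0", "1A", "2A"),
                       x = -(10:12), y = -(10:12), z = -(4:6), side = "left")
  expect_error(sweetspot_distance_analysis(act, coords), "constant")
  act2 <- act[1:2, ]
  act2$activity <- c(1, 2)
  expect_error(sweetspot_distance_analysis(act2, coords[1:2, ]),
               "insufficient")
})

test_that("activity tracking negative distance recovers a negative r", {
  signs <- vapply(1:25, function(seed) {
    set.seed(seed)
    n <- 16
    coords <- data.frame(hemisphere = "A",
                         contact_id = as.character(seq_len(n)),
                         x = rnorm(n, -12, 2), y = rnorm(n, -12, 2),
                         z = rnorm(n, -6, 2), side = "left")
    spot <- c(-12.5, -12.72, -5.38)
    d <- sqrt((coords$x - spot[1])^2 + (coords$y - spot[2])^2 +
                (coords$z - spot[3])^2)
    act <- data.frame(hemisphere = "A",
                      contact_id = coords$contact_id,
                      activity = -d + rnorm(n, sd = 0.5))
    sign(sweetspot_distance_analysis(act, coords, spot)$r)
  }, numeric(1))
  expect_gte(mean(signs == -1), 0.95)
})

test_that("the tidy selection table carries one row per configuration", {
  cohort <- make_cohort(n_hemi = 2, seed = 500)
  tab <- selection_table(cohort$selections)
  expect_identical(nrow(tab), 2L * 7L)  # 4 levels + 3 segments per hemisphere
  expect_setequal(unique(tab$role), c("level", "segment"))
  expect_true(all(tab$rank[tab$role == "level"] %in% 1:4))
  expect_true(all(tab$rank[tab$role == "segment"] %in% 1:3))
})
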