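test_that("detection-vs-day curves reduce correctly on degenerate draws", {
  # all-zero coefficients: p = 0.5 at every lag
  d0 <- fake_draws(draw_matrix(50, sigma_alpha = 1e-12))
  cv <- species_detection_vs_day(d0, "sp1", proportion = 0.5)
  expect_equal(cv$mean, rep(0.5, 4), tolerance = 1e-9)
  expect_equal(cv$lag_day, 0:3)

  # hand-built 3-draw posterior, alpha forced to zero
  m <- draw_matrix(3, beta0 = c(-1, 0, 1), beta2 = c(2, 1, 0))
  d3 <- fake_draws(m)
  cv3 <- species_detection_vs_day(d3, "sp1", proportion = 0.5,
                                  marginalize_alpha = FALSE)
  by_hand <- mean(plogis(c(-1, 0, 1) + c(2, 1, 0) * 0.5))
  expect_equal(cv3$mean[cv3$lag_day == 1], by_hand)
  expect_equal(cv3$mean[cv3$lag_day == 3],
               mean(plogis(c(-1, 0, 1))))  # slope family is zero

  # unchanged on recomputation (alpha marginalization is seeded)
  cva <- species_detection_vs_day(d0, "sp1", proportion = 0.3)
  cvb <- species_detection_vs_day(d0, "sp1", proportion = 0.3)
  expect_identical(cva, cvb)

  expect_error(species_detection_vs_day(d0, "nope", 0.5), "unknown species")
  expect_error(species_detection_vs_day(d0, "sp1", 1.5), "proportion")
})

test_that("per-draw detection is monotone in proportion for positive slopes", {
  set.seed(4)
  m <- draw_matrix(200, beta0 = rnorm(200), beta1 = abs(rnorm(200)) + 0.1)
  d <- fake_draws(m)
  grid <- seq(0, 1, by = 0.25)
  curves <- vapply(grid, function(pr)
    species_detection_vs_day(d, "sp1", pr,
                             marginalize_alpha = FALSE)$mean[1], numeric(1))
  expect_true(all(diff(curves) > 0))
})

test_that("meal-proportion inversion solves the logit analytically", {
  # beta0 = 0, slope = 4, target 0.5: logit(0.5) = 0 -> proportion 0
  d1 <- fake_draws(draw_matrix(10, beta0 = 0, beta2 = 4))
  r1 <- proportion_for_target_probability(d1, "sp1", lag_day = 1,
                                          target_p = 0.5)
  expect_equal(r1$median, 0)

  # beta0 = -2, slope = 4 -> proportion 0.5
  d2 <- fake_draws(draw_matrix(10, beta0 = -2, beta2 = 4))
  r2 <- proportion_for_target_probability(d2, "sp1", lag_day = 1,
                                          target_p = 0.5)
  expect_equal(r2$median, 0.5)
  expect_equal(r2$grams, 0.5 * 1750)

  # species-averaged route reads the hyper-means
  r3 <- proportion_for_target_probability(d2, species = NULL, lag_day = 1,
                                          target_p = 0.5)
  expect_equal(r3$median, 0.5)

  # forward-inverse round trip is exact per draw
  set.seed(9)
  m <- draw_matrix(100, beta0 = rnorm(100), beta2 = runif(100, 0.5, 3))
  d <- fake_draws(m)
  inv <- proportion_for_target_probability(d, "sp1", lag_day = 1,
                                           target_p = 0.73)
  prop <- (qlogis(0.73) - m[, "beta0[sp1]"]) / m[, "beta2[sp1]"]
  p_fwd <- plogis(m[, "beta0[sp1]"] + m[, "beta2[sp1]"] * prop)
  expect_equal(p_fwd, rep(0.73, 100), tolerance = 1e-12)
  expect_equal(inv$median, unname(quantile(prop, 0.5, type = 7)))

  # all-zero slopes are excluded; nothing left is an error
  dz <- fake_draws(draw_matrix(10, beta2 = 0))
  expect_error(proportion_for_target_probability(dz, "sp1", lag_day = 1,
                                                 target_p = 0.5),
               "slope")
  expect_error(proportion_for_target_probability(d2, "sp1",
                                                 target_p = 1.1),
               "target_p")
})

test_that("spike-diet windows are read off the detection matrix", {
  sched <- data.frame(date = as.Date("2017-11-04"), individual_id = "B",
                      species = "Coturnix coturnix", proportion = 0.4)
  sched <- rbind(sched,
                 data.frame(date = as.Date("2017-11-01") + 0:9,
                            individual_id = "B", species = "Gallus gallus",
                            proportion = 0.6))
  mk_matrix <- function(days_detected) {
    data.frame(scat_id = paste0("B", days_detected),
               subsample_id = paste0("B", days_detected, "_d0"),
               individual_id = "B",
               defecation_date = as.Date("2017-11-04") + days_detected,
               degradation_day = 0L, species = "Coturnix coturnix",
               detected = 1L)
  }

  # detections on days 1-3 after feeding: 72 h maximum, 8-22 h minimum
  w <- spike_diet_window(mk_matrix(1:3), sched, "Coturnix coturnix")
  expect_equal(w$max_hours, 72)
  expect_equal(w$min_hours_bound, c(8, 22))

  # detection only on day +1: 24-48 h bracket at day resolution
  w1 <- spike_diet_window(mk_matrix(1), sched, "Coturnix coturnix")
  expect_equal(w1$max_days, 1)
  expect_equal(w1$max_hours, 24)

  # never detected: distinct condition class
  none <- mk_matrix(1)
  none$detected <- 0L
  expect_error(spike_diet_window(none, sched, "Coturnix coturnix"),
               class = "spike_never_detected")

  # fed twice: window undefined
  twice <- rbind(sched,
                 data.frame(date = as.Date("2017-11-09"),
                            individual_id = "B",
                            species = "Coturnix coturnix",
                            proportion = 0.2))
  expect_error(spike_diet_window(mk_matrix(1:3), twice,
                                 "Coturnix coturnix"),
               "more than once")
})

test_that("the bundled schedule supports the quail spike computation", {
  sched <- cheetah_feeding_schedule("corrected")
  fed <- sched[sched$species == "Coturnix coturnix", ]
  expect_equal(nrow(fed), 1L)  # fed exactly once, to one individual
  expect_equal(fed$individual_id, "Innis")
  # detections in fresh scats up to 3 days later -> the 72 h window
  mat <- data.frame(scat_id = "I1", subsample_id = "I1_d0",
                    individual_id = "Innis",
                    defecation_date = fed$date + 3, degradation_day = 0L,
                    species = "Coturnix coturnix", detected = 1L)
  w <- spike_diet_window(mat, sched, "Coturnix coturnix")
  expect_equal(w$max_hours, 72)
})

test_that("coefficient forest is a numerical summary of the draws", {
  set.seed(8)
  sym <- matrix(rnorm(20000), ncol = 1, dimnames = list(NULL, "b"))
  cf <- coefficient_forest(fake_draws(sym))
  expect_lt(abs(cf$mean - cf$q50), 0.05)  # symmetric draws: mean ~ median
  expect_true(all(cf$q2.5 <= cf$q25 & cf$q25 <= cf$q50 &
                    cf$q50 <= cf$q75 & cf$q75 <= cf$q97.5))

  const <- matrix(2, nrow = 50, ncol = 1, dimnames = list(NULL, "b"))
  cfc <- coefficient_forest(fake_draws(const))
  expect_equal(cfc$q2.5, cfc$q97.5)  # zero-width intervals
  expect_equal(cfc$mean, 2)
})
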