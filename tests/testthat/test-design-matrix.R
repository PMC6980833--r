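test_that("lag covariates come from the bundled trial schedule", {
  sched <- cheetah_feeding_schedule("corrected")
  # one fresh scat from Jura on 7 Nov 2017
  mat <- data.frame(scat_id = "J1", subsample_id = "J1_d0",
                    individual_id = "Jura",
                    defecation_date = as.Date("2017-11-07"),
                    degradation_day = 0L,
                    species = c("Cervus spp", "Gallus gallus",
                                "Equus caballus"),
                    detected = c(1L, 1L, 0L))
  inp <- build_model_input(mat, sched)
  d <- inp$data
  # deer made up 0.82 of Jura's ration that day
  expect_equal(d$pr0[d$species == "Cervus spp"], 0.82)
  expect_equal(d$pr1[d$species == "Cervus spp"], 0.82)  # and the day before
  # horse was never fed to Jura in the window -> all lags zero
  horse <- d[d$species == "Equus caballus", c("pr0", "pr1", "pr2", "pr3")]
  expect_true(all(horse == 0))
  expect_equal(d$individual, rep(0L, 3))  # single individual -> reference 0
})

test_that("verbatim and corrected schedule variants differ as documented", {
  v <- cheetah_feeding_schedule("verbatim")
  c <- cheetah_feeding_schedule("corrected")
  expect_equal(nrow(v), nrow(c))
  changed <- which(v$proportion != c$proportion)
  expect_length(changed, 4L)
  expect_true(all(v$proportion[changed] == 0.6))
  expect_true(all(c$proportion[changed] == 0.06))
  # the corrected variant is the one whose daily menus sum to 1
  sums <- daily_proportion_sums(c)
  expect_true(all(abs(sums$proportion - 1) < 0.02))
  expect_false(all(abs(daily_proportion_sums(v)$proportion - 1) < 0.02))
})

test_that("model input equals the covariates the generator used", {
  s <- study_synthetic(seed = 51)
  det <- s$detections
  inp <- build_model_input(det, s$schedule)
  ord <- order(det$scat_id, det$degradation_day, det$species)
  gen <- det[ord, ]
  expect_equal(inp$data$pr0, gen$pr0)
  expect_equal(inp$data$pr1, gen$pr1)
  expect_equal(inp$data$pr2, gen$pr2)
  expect_equal(inp$data$pr3, gen$pr3)
  expect_equal(inp$data$y, gen$detected)
  expect_equal(inp$n_scats, 26L)
  expect_equal(inp$n_species, 5L)

  # order independence / idempotence: shuffled input gives identical output
  set.seed(1)
  shuffled <- det[sample(nrow(det)), ]
  inp2 <- build_model_input(shuffled, s$schedule)
  expect_identical(inp$data, inp2$data)

  # unknown species is an error naming the offender
  bad <- det
  bad$species[1] <- "Vulpes vulpes"
  expect_error(build_model_input(bad, s$schedule), "Vulpes vulpes")

  # scats without full schedule coverage are dropped with a warning
  trimmed <- s$schedule[s$schedule$date > min(s$schedule$date), ]
  expect_warning(build_model_input(det, trimmed), "dropped")
})

test_that("pr0 column sums match the schedule per scat-day", {
  s <- study_synthetic(seed = 61)
  inp <- build_model_input(s$detections, s$schedule)
  d <- inp$data[inp$data$degradation_day == 0, ]
  sums <- tapply(d$pr0, d$scat_id, sum)
  sched <- s$schedule
  for (scat in names(sums)) {
    row <- d[d$scat_id == scat, ][1, ]
    date <- s$detections$defecation_date[s$detections$scat_id == scat][1]
    ind <- s$detections$individual_id[s$detections$scat_id == scat][1]
    fed <- sched[sched$date == date & sched$individual_id == ind &
                   sched$species %in% inp$species, ]
    expect_equal(unname(sums[scat]), sum(fed$proportion), tolerance = 1e-9)
  }
})

test_that("meal-size curve pools detections by fed proportion", {
  rows <- data.frame(y = c(1, 1, 1, 1), species = "sp1",
                     scat_id = c("a", "a", "b", "b"),
                     pr0 = c(0.1, 0.4, 0.6, 0.9), pr1 = 0, pr2 = 0,
                     pr3 = 0, degradation_day = 0, individual = 0)
  inp <- model_input_from_rows(rows)
  curve <- empirical_meal_size_curve(inp, n_bins = 2)
  expect_equal(curve$fraction_detected, c(1, 1))
  expect_equal(curve$n, c(2L, 2L))

  rows$y <- c(1, 0, 1, 0)
  one <- empirical_meal_size_curve(model_input_from_rows(rows), n_bins = 1)
  expect_equal(one$fraction_detected, 0.5)

  # synthetic data with a positive meal-size slope yields an increasing
  # trend across well-populated bins
  sched <- tiny_schedule(seed = 71)
  params <- true_parameters(five_species, beta0 = -2, beta1 = 5)
  det <- simulate_detections(sched, params, as.Date("2017-11-03") + 3:15,
                             0:9, seed = 72)
  curve <- empirical_meal_size_curve(build_model_input(det, sched),
                                     n_bins = 4)
  good <- curve[curve$n >= 50, ]
  fit <- stats::coef(stats::lm(fraction_detected ~ bin_mid, data = good))
  expect_gt(fit[["bin_mid"]], 0)
})
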