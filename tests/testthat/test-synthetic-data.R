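test_that("feeding schedule generator respects the simplex and the seed", {
  # one species, one day: the simplex has a single vertex
  one <- generate_feeding_schedule(1, "A", "deer", 1, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_equal(one$proportion, 1.0)

  # seed determinism
  a <- generate_feeding_schedule(17, c("A", "B"), c(five_species, "sp6"),
                                 3, seed = 7)
  b <- generate_feeding_schedule(17, c("A", "B"), c(five_species, "sp6"),
                                 3, seed = 7)
  expect_identical(a, b)

  # proportions per (day, individual) sum to 1
  big <- generate_feeding_schedule(100, c("A", "B"), five_species, 4,
                                   seed = 5)
  sums <- daily_proportion_sums(big)
  expect_true(all(abs(sums$proportion - 1) < 1e-9))
  expect_equal(nrow(sums), 200L)

  expect_error(generate_feeding_schedule(5, "A", character(0), 1, seed = 1),
               "non-empty")
  expect_error(generate_feeding_schedule(5, "A", five_species, 9, seed = 1),
               "max_species_per_day")
})

test_that("simulated detections follow the logit model", {
  sched <- tiny_schedule(seed = 2)
  days <- as.Date("2017-11-03") + 3:6

  sat <- true_parameters(five_species, beta0 = 20)
  det1 <- simulate_detections(sched, sat, days, c(0, 3), seed = 1)
  expect_true(all(det1$detected == 1L))
  expect_true(all(det1$true_p > 0.999))

  never <- true_parameters(five_species, beta0 = -20)
  det0 <- simulate_detections(sched, never, days, c(0, 3), seed = 1)
  expect_true(all(det0$detected == 0L))

  # coin-flip model: empirical frequency 0.5 within binomial tolerance
  fair <- true_parameters(five_species, beta0 = 0)
  sched_l <- generate_feeding_schedule(260, c("A", "B"), five_species, 3,
                                       seed = 4)
  det <- simulate_detections(sched_l, fair,
                             as.Date("2017-11-03") + 3:259, c(0, 3, 5, 12),
                             seed = 9)
  expect_gt(nrow(det), 10000)
  expect_lt(abs(mean(det$detected) - 0.5), 0.02)

  expect_error(simulate_detections(sched, fair, days, c(-1, 3), seed = 1),
               ">= 0")
  # scats without a full 3-day feeding history are skipped
  expect_message(
    early <- simulate_detections(sched, fair,
                                 as.Date("2017-11-03") + c(1, 5), c(0),
                                 seed = 1),
    "skipped")
  expect_true(all(early$defecation_date == as.Date("2017-11-08")))
})

test_that("detection frequencies match true probabilities over replicates", {
  sched <- tiny_schedule(seed = 6)
  params <- true_parameters(five_species, beta0 = c(-1, 0, 0.5, 1, 2),
                            beta1 = 2, beta5 = -0.1)
  det <- simulate_detections(sched, params, as.Date("2017-11-03") + 3:15,
                             0:29, seed = 13)
  # group rows sharing identical true p; binomial envelope per group
  grp <- split(det, round(det$true_p, 10))
  big <- grp[vapply(grp, nrow, integer(1)) >= 50]
  for (g in big) {
    p <- g$true_p[1]; n <- nrow(g)
    expect_lt(abs(mean(g$detected) - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("simulated read tables split depth between consumer and prey", {
  s <- study_synthetic(seed = 21)
  det <- s$detections[s$detections$degradation_day <= 3, ]

  # consumer-degenerate split leaves prey with ~no reads
  rt <- simulate_read_table(det, consumer_fraction = 1 - 1e-9,
                            mean_depth = 1000, seed = 2)
  prey <- rt$reads[rt$reads$taxon != "Acinonyx jubatus", ]
  expect_true(sum(prey$read_count) <= 2)

  # zero contamination -> empty control table
  expect_equal(nrow(rt$controls), 0L)
  rt2 <- simulate_read_table(det, control_contamination_rate = 0.5,
                             mean_depth = 1000, seed = 3)
  expect_gt(nrow(rt2$controls), 0L)

  # pooled consumer share concentrates at consumer_fraction; subsamples
  # with no detected prey put their whole depth on the consumer, so pool
  # over the prey-bearing ones
  rt3 <- simulate_read_table(s$detections, consumer_fraction = 0.54,
                             mean_depth = 10000, seed = 4)
  has_prey <- unique(rt3$reads$subsample_id[rt3$reads$taxon !=
                                              "Acinonyx jubatus"])
  rr <- rt3$reads[rt3$reads$subsample_id %in% has_prey, ]
  share <- sum(rr$read_count[rr$taxon == "Acinonyx jubatus"]) /
    sum(rr$read_count)
  expect_lt(abs(share - 0.54), 0.02)
  expect_gt(length(unique(rt3$subsamples$subsample_id)), 200)

  # deterministic under seed
  rt4 <- simulate_read_table(s$detections, consumer_fraction = 0.54,
                             mean_depth = 10000, seed = 4)
  expect_identical(rt3, rt4)

  expect_error(simulate_read_table(det[0, ], seed = 1), "empty")
  expect_error(simulate_read_table(det, consumer_fraction = 1, seed = 1),
               "consumer_fraction")
})
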