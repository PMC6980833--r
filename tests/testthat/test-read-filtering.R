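rt <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(subsample_id = r[[1]], taxon = r[[2]],
               read_count = as.integer(r[[3]]),
               sequence_length = as.integer(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("length/abundance filter keeps boundary rows and drops the rest", {
  tab <- rt(list("s1", "a", 5, 100), list("s1", "b", 12, 100),
            list("s1", "c", 50, 70))
  out <- filter_reads(tab)
  expect_equal(out$taxon, "b")

  # exact boundaries are retained: count == 10, length == 80
  edge <- rt(list("s1", "a", 10, 80), list("s1", "b", 9, 80),
             list("s1", "c", 10, 79))
  expect_equal(filter_reads(edge)$taxon, "a")

  # all rows failing is an empty table, not an error
  none <- filter_reads(rt(list("s1", "a", 1, 10)))
  expect_equal(nrow(none), 0L)

  expect_error(filter_reads(tab, min_length = -1), "non-negative")
})

test_that("taxon reassignment collapses ranks, merges and reports drops", {
  targets <- c("Oryctolagus cuniculus", "Cervus spp")
  tab <- rt(list("sub1", "Leporidae", 40, 100),
            list("sub1", "Cervidae", 10, 100),
            list("sub1", "Cervus spp", 30, 98),
            list("sub1", "Homo sapiens", 500, 100))
  out <- reassign_taxa(tab, target_species = targets)
  expect_setequal(out$taxon, targets)
  expect_equal(out$read_count[out$taxon == "Oryctolagus cuniculus"], 40L)
  # family + species rows merge with summed counts
  expect_equal(out$read_count[out$taxon == "Cervus spp"], 40L)
  excl <- attr(out, "exclusions")
  expect_equal(excl$n_rows_dropped, 1L)
  expect_equal(excl$n_reads_dropped, 500L)
  # read conservation up to the reported drop
  expect_equal(sum(out$read_count) + excl$n_reads_dropped,
               sum(tab$read_count))

  expect_error(
    reassign_taxa(tab, mapping = data.frame(pattern = "Leporidae",
                                            target = "Lepus europaeus"),
                  target_species = targets),
    "not in `target_species`")
})

test_that("presence calls follow the control rule and are monotone", {
  targets <- "Cervus spp"
  mk <- function(sample_n, control_n) {
    tab <- rt(list("s1", "Cervus spp", sample_n, 100))
    tab$control_id <- "c1"
    ctr <- data.frame(control_id = "c1", taxon = "Cervus spp",
                      read_count = as.integer(control_n))
    call_presence(tab[tab$read_count > 0, , drop = FALSE],
                  ctr[ctr$read_count > 0, , drop = FALSE],
                  target_species = targets,
                  control_map = c(s1 = "c1"),
                  subsample_info = data.frame(subsample_id = "s1",
                                              control_id = "c1"))$detected
  }
  expect_equal(mk(50, 0), 1L)
  expect_equal(mk(50, 9), 1L)   # control just below the threshold
  expect_equal(mk(50, 10), 0L)  # control at the threshold vetoes
  expect_equal(mk(0, 0), 0L)

  # monotonicity over a grid: raising the sample count never flips 1 -> 0,
  # raising the control count never flips 0 -> 1
  grid <- expand.grid(s = c(0, 1, 5, 50), c = c(0, 5, 9, 10, 30))
  det <- mapply(mk, grid$s, grid$c)
  for (cc in unique(grid$c))
    expect_true(all(diff(det[grid$c == cc][order(grid$s[grid$c == cc])]) >= 0))
  for (ss in unique(grid$s))
    expect_true(all(diff(det[grid$s == ss][order(grid$c[grid$s == ss])]) <= 0))
})

test_that("presence matrix is dense, excludes the consumer, resolves controls", {
  targets <- c("Cervus spp", "Coturnix coturnix")
  tab <- rt(list("s1", "Cervus spp", 50, 100),
            list("s1", "Acinonyx jubatus", 900, 100),
            list("s2", "Coturnix coturnix", 20, 100))
  ctr <- data.frame(control_id = "batch", taxon = "Cervus spp",
                    read_count = 3L)
  out <- call_presence(tab, ctr, target_species = targets)  # shared batch
  expect_equal(nrow(out), 4L)  # 2 subsamples x 2 species, explicit 0/1
  expect_false("Acinonyx jubatus" %in% out$species)
  expect_equal(out$detected[out$subsample_id == "s1" &
                              out$species == "Cervus spp"], 1L)
  expect_equal(out$detected[out$subsample_id == "s2" &
                              out$species == "Cervus spp"], 0L)

  two_ctrl <- rbind(ctr, data.frame(control_id = "batch2",
                                    taxon = "Cervus spp", read_count = 0L))
  expect_error(call_presence(tab, two_ctrl, target_species = targets),
               "no mappable negative control for subsample 's1'")
})

test_that("burn-in scats and excluded species are removed", {
  s <- study_synthetic(seed = 31)
  det <- s$detections
  first_day <- min(s$schedule$date)

  out <- exclude_burnin_scats(det, s$schedule, burnin_days = 5,
                              excluded_species = "sp5")
  expect_true(all(as.Date(out$defecation_date) >= first_day + 5))
  expect_false("sp5" %in% out$species)
  excl <- attr(out, "exclusions")
  expect_equal(excl$n_burnin_rows +
                 excl$n_excluded_species_rows + nrow(out), nrow(det))

  # day-2 scat rows are all removed under the default 3-day rule
  fake <- det
  fake$defecation_date <- first_day + 1
  expect_warning(res <- exclude_burnin_scats(fake, s$schedule,
                                             excluded_species = character(0)),
                 "all detection rows removed")
  expect_equal(nrow(res), 0L)

  # identity transform when disabled
  same <- exclude_burnin_scats(det, s$schedule, burnin_days = 0,
                               excluded_species = character(0))
  expect_equal(nrow(same), nrow(det))
})

test_that("read tables round-trip to the generating detection matrix", {
  s <- study_synthetic(seed = 41)
  det <- s$detections[s$detections$degradation_day %in% c(0, 3, 5), ]
  rt <- simulate_read_table(det, consumer_fraction = 0.5,
                            mean_depth = 50000,
                            control_contamination_rate = 0, seed = 8)
  # fixture satisfies the recovery preconditions at this depth
  prey <- rt$reads[rt$reads$taxon != "Acinonyx jubatus", ]
  expect_true(all(prey$read_count >= 10))
  expect_true(all(rt$reads$sequence_length >= 80))

  filtered <- filter_reads(rt$reads)
  species <- sort(unique(det$species))
  reassigned <- reassign_taxa(filtered, target_species = species)
  called <- call_presence(reassigned, rt$controls,
                          target_species = species,
                          subsample_info = rt$subsamples)

  truth <- det[order(det$subsample_id, det$species),
               c("subsample_id", "species", "detected")]
  got <- called[order(called$subsample_id, called$species),
                c("subsample_id", "species", "detected")]
  rownames(truth) <- rownames(got) <- NULL
  expect_equal(got, truth)
})
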