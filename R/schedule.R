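#' Generate a synthetic feeding schedule
#'
#' Emulates the structure of a captive feeding trial: each individual is fed
#' once per day a bowl containing one to `max_species_per_day` prey species,
#' with the daily proportions of each species drawn from a flat Dirichlet on
#' the simplex (so they always sum to 1).
#'
#' @param n_days Number of trial days (>= 1).
#' @param individuals Character vector of individual labels.
#' @param species Character vector of prey species labels (non-empty).
#' @param max_species_per_day Maximum number of distinct prey species offered
#'   to one individual on one day; between 1 and `length(species)`.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param start_date First trial day (`Date` or string).
#' @return A `data.frame` of feeding events with columns `date`,
#'   `individual_id`, `species`, `proportion`. Proportions for each
#'   (date, individual) sum to 1.
#' @examples
#' sched <- generate_feeding_schedule(5, c("A", "B"), c("deer", "quail"), 2, seed = 1)
#' @export
generate_feeding_schedule <- function(n_days, individuals, species,
                                      max_species_per_day, seed,
                                      start_date = as.Date("2017-11-03")) {
  if (length(species) == 0L)
    stop("`species` must be a non-empty character vector", call. = FALSE)
  if (n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  if (max_species_per_day < 1L || max_species_per_day > length(species))
    stop("`max_species_per_day` must be between 1 and length(species)",
         call. = FALSE)
  if (length(individuals) == 0L)
    stop("`individuals` must be non-empty", call. = FALSE)
  start_date <- as.Date(start_date)

  set.seed(as.integer(seed))
  out <- vector("list", n_days * length(individuals))
  idx <- 0L
  for (d in seq_len(n_days)) {
    day <- start_date + (d - 1L)
    for (ind in individuals) {
      k <- if (max_species_per_day == 1L) 1L else
        sample.int(max_species_per_day, 1L)
      sp <- if (length(species) == 1L) species else sample(species, k)
      # flat Dirichlet via normalized Gamma(1) draws
      w <- stats::rgamma(k, shape = 1)
      p <- w / sum(w)
      idx <- idx + 1L
      out[[idx]] <- data.frame(date = rep(day, k),
                               individual_id = rep(ind, k),
                               species = sp,
                               proportion = p,
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled captive cheetah feeding schedule
#'
#' The feeding schedule of the two captive cheetahs (Jura and Innis) over the
#' November 2017 trial, shipped as plain CSV. The `"verbatim"` variant keeps
#' the proportions exactly as printed, including three daily menus whose
#' proportions cannot sum to 1 because a `0.6` is evidently a misprint of
#' `0.06` (8 Nov Innis rabbit, 8 Nov Jura chicken and rabbit, 9 Nov Innis
#' rabbit). The `"corrected"` variant applies exactly that reading — the only
#' one under which every daily menu sums to 1 — and changes nothing else.
#'
#' @param variant `"corrected"` (default) or `"verbatim"`.
#' @return A feeding-event `data.frame` (`date`, `individual_id`, `species`,
#'   `proportion`).
#' @export
cheetah_feeding_schedule <- function(variant = c("corrected", "verbatim")) {
  variant <- match.arg(variant)
  path <- system.file("extdata",
                      paste0("cheetah_feeding_", variant, ".csv"),
                      package = "scatdetect", mustWork = TRUE)
  read_feeding_schedule(path)
}

#' Total fed proportion per (date, individual)
#'
#' Convenience check that a schedule's daily menus sum to 1.
#'
#' @param schedule Feeding-event `data.frame`.
#' @return A `data.frame` with `date`, `individual_id`, `proportion` (the
#'   day's sum).
#' @export
daily_proportion_sums <- function(schedule) {
  stats::aggregate(proportion ~ date + individual_id, data = schedule, FUN = sum)
}
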