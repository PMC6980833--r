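# pull a named column from the pooled draw matrix, with a clear error
draw_column <- function(m, name) {
  if (!name %in% colnames(m))
    stop("parameter '", name, "' was not monitored", call. = FALSE)
  m[, name]
}

#' Posterior detection probability of one species versus feeding lag
#'
#' For each feeding lag d in 0..3, computes the posterior distribution of
#' the detection probability
#' `logit^-1(beta0_s + beta(d+1)_s * proportion + beta5 * degradation_day +
#' beta6 * individual + alpha)` where the scat random effect alpha is, by
#' default, marginalized by drawing a fresh alpha ~ N(0, sigma_alpha) for
#' every posterior draw (a new, typical scat rather than one of the trial's
#' scats). Defaults condition on a fresh scat (degradation day 0) and the
#' reference individual.
#'
#' @param draws A `posterior_draws` object.
#' @param species Modelled species label.
#' @param proportion Proportion of the daily diet fed, in [0, 1].
#' @param degradation_day Conditioning degradation day (default 0).
#' @param individual Conditioning individual indicator (default 0).
#' @param marginalize_alpha Draw a fresh scat effect per posterior draw
#'   (default `TRUE`); `FALSE` sets alpha = 0 (a median scat).
#' @param alpha_seed Seed for the alpha marginalization draws (documented
#'   source of randomness; fixed default makes repeated calls identical).
#' @return A `data.frame` of class `"detection_curve"` with one row per lag:
#'   posterior `mean`, `sd`, and 2.5/25/50/75/97.5% quantiles of p.
#' @export
species_detection_vs_day <- function(draws, species, proportion,
                                     degradation_day = 0, individual = 0,
                                     marginalize_alpha = TRUE,
                                     alpha_seed = 1L) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!species %in% draws$species)
    stop("unknown species '", species, "'; modelled species: ",
         paste(draws$species, collapse = ", "), call. = FALSE)
  if (proportion < 0 || proportion > 1)
    stop("`proportion` must be in [0, 1]", call. = FALSE)
  m <- as_draws_matrix(draws)
  b0 <- draw_column(m, sprintf("beta0[%s]", species))
  b5 <- draw_column(m, "beta5")
  b6 <- draw_column(m, "beta6")
  alpha <- if (marginalize_alpha && draws$random_effect) {
    sa <- draw_column(m, "sigma_alpha")
    set.seed(as.integer(alpha_seed))
    stats::rnorm(length(sa), 0, sa)
  } else 0

  rows <- lapply(0:3, function(lag) {
    slope <- draw_column(m, sprintf("beta%d[%s]", lag + 1L, species))
    p <- stats::plogis(b0 + slope * proportion + b5 * degradation_day +
                         b6 * individual + alpha)
    q <- stats::quantile(p, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
    data.frame(lag_day = lag, mean = mean(p), sd = stats::sd(p),
               q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
               q97.5 = q[5])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "conditioning") <- list(species = species,
                                    proportion = proportion,
                                    degradation_day = degradation_day,
                                    individual = individual,
                                    marginalize_alpha = marginalize_alpha)
  class(out) <- c("detection_curve", class(out))
  out
}

#' Meal proportion required for a target detection probability
#'
#' Inverts the detection model per posterior draw: the proportion solving
#' `logit(target_p) = beta0 + slope * proportion + beta5 * degradation_day
#' + beta6 * individual` on the chosen lag day, i.e.
#' `proportion = (logit(target_p) - other_terms) / slope`. Draws whose
#' slope magnitude is below `slope_tol` are excluded and counted. With
#' `species = NULL` the species-averaged (hyper-mean) coefficients are
#' used. The grams equivalent uses a configurable daily intake.
#'
#' @param draws A `posterior_draws` object.
#' @param species Species label, or `NULL` for the species-averaged
#'   (hyper-mean) coefficients.
#' @param lag_day Feeding lag day whose slope is inverted (0..3; default 1,
#'   the lag with the strongest detection signal).
#' @param target_p Target detection probability in (0, 1).
#' @param degradation_day,individual Conditioning covariate values
#'   (defaults 0; the scat effect is set to 0).
#' @param slope_tol Draws with `|slope| < slope_tol` are excluded.
#' @param daily_intake_g Daily food intake in grams used for the grams
#'   equivalent (default the mean of the two trial animals' rations,
#'   1700 g and 1800 g).
#' @return A list of class `"proportion_requirement"`: posterior `median`,
#'   `mean`, `q2.5`, `q97.5` of the required proportion, the fraction of
#'   draws falling outside [0, 1] (`frac_outside_unit`), the number of
#'   excluded near-zero-slope draws, and `grams` (median proportion times
#'   daily intake).
#' @export
proportion_for_target_probability <- function(draws, species = NULL,
                                              lag_day = 1L, target_p,
                                              degradation_day = 0,
                                              individual = 0,
                                              slope_tol = 1e-8,
                                              daily_intake_g = 1750) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (target_p <= 0 || target_p >= 1)
    stop("`target_p` must be in (0, 1)", call. = FALSE)
  if (!lag_day %in% 0:3) stop("`lag_day` must be in 0..3", call. = FALSE)
  m <- as_draws_matrix(draws)
  if (is.null(species)) {
    if (!draws$hierarchical)
      stop("species-averaged inversion needs a hierarchical fit",
           call. = FALSE)
    b0 <- draw_column(m, "mu_beta0")
    slope <- draw_column(m, sprintf("mu_beta%d", lag_day + 1L))
  } else {
    if (!species %in% draws$species)
      stop("unknown species '", species, "'", call. = FALSE)
    b0 <- draw_column(m, sprintf("beta0[%s]", species))
    slope <- draw_column(m, sprintf("beta%d[%s]", lag_day + 1L, species))
  }
  b5 <- draw_column(m, "beta5")
  b6 <- draw_column(m, "beta6")
  other <- b0 + b5 * degradation_day + b6 * individual
  keep <- abs(slope) >= slope_tol
  if (!any(keep))
    stop("all draws have |slope| below `slope_tol`; required proportion ",
         "undefined", call. = FALSE)
  prop <- (stats::qlogis(target_p) - other[keep]) / slope[keep]
  q <- stats::quantile(prop, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
  structure(list(median = unname(q[3]), mean = mean(prop),
                 q2.5 = unname(q[1]), q25 = unname(q[2]),
                 q75 = unname(q[4]), q97.5 = unname(q[5]),
                 frac_outside_unit = mean(prop < 0 | prop > 1),
                 n_excluded = sum(!keep),
                 n_draws = sum(keep),
                 grams = unname(q[3]) * daily_intake_g,
                 target_p = target_p, lag_day = lag_day,
                 species = if (is.null(species)) "(species-averaged)"
                           else species),
            class = "proportion_requirement")
}

#' @export
print.proportion_requirement <- function(x, ...) {
  cat(sprintf(
    "Proportion of daily diet for %.0f%% detection (%s, lag day %d):\n",
    100 * x$target_p, x$species, x$lag_day))
  cat(sprintf("  median %.3f (95%% CrI %.3f to %.3f); ~%.0f g of daily intake\n",
              x$median, x$q2.5, x$q97.5, x$grams))
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, "near-zero-slope draws excluded\n")
  invisible(x)
}

#' Detection window of a spike diet
#'
#' A spike diet is a prey item fed exactly once; the interval between that
#' feeding and the last scat in which the item is detected bounds the gut
#' transit time. Only fresh subsamples (degradation day 0) count: the item
#' must have been present when the scat was deposited. `max_hours` is the
#' latest detection, at day resolution (days x 24). Because deposit times
#' of overnight scats are unknown, the minimum passage time is reported as
#' an interval: deposits can occur between `evening_hour` on the eve of
#' collection and `collection_hour`, and feeding ends at
#' `feeding_end_hour`, giving
#' `[(d - 1) * 24 + (24 - feeding_end + evening - 24), d * 24 -
#' (feeding_end - collection)]` for first detection `d` days after feeding
#' (the trial's daily routine: fed by 11:00, scats collected around 9:00,
#' evening from 19:00 — so first detection one day later gives 8-22 h).
#'
#' @param matrix Detection matrix.
#' @param schedule Feeding-event `data.frame`.
#' @param spike_species The spike prey label; must occur exactly once in
#'   the schedule.
#' @param feeding_end_hour,collection_hour,evening_hour Daily routine hours
#'   used for the minimum-passage interval.
#' @return A list of class `"spike_window"`: `max_hours`, `max_days`,
#'   `min_hours_bound` (length-2 interval), `min_days`, `n_detections`.
#'   Raises a condition of class `"spike_never_detected"` when the spike is
#'   absent from every fresh subsample.
#' @export
spike_diet_window <- function(matrix, schedule, spike_species,
                              feeding_end_hour = 11, collection_hour = 9,
                              evening_hour = 19) {
  schedule$date <- as.Date(schedule$date)
  fed <- schedule[schedule$species == spike_species &
                    schedule$proportion > 0, , drop = FALSE]
  if (nrow(fed) == 0L)
    stop("spike species '", spike_species, "' never fed", call. = FALSE)
  if (nrow(unique(fed[, c("date", "individual_id")])) != 1L)
    stop("spike species '", spike_species,
         "' fed more than once; detection window undefined", call. = FALSE)
  feed_date <- fed$date[1]
  ind <- fed$individual_id[1]

  matrix$defecation_date <- as.Date(matrix$defecation_date)
  hits <- matrix[matrix$species == spike_species &
                   matrix$individual_id == ind &
                   matrix$degradation_day == 0 &
                   matrix$detected == 1 &
                   matrix$defecation_date >= feed_date, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop(structure(class = c("spike_never_detected", "error", "condition"),
                   list(message = paste0("spike species '", spike_species,
                                         "' never detected in a fresh subsample"),
                        call = sys.call(-1))))
  d <- as.numeric(hits$defecation_date - feed_date)
  max_days <- max(d)
  min_days <- min(d)
  min_low <- (min_days - 1) * 24 + (24 - feeding_end_hour) -
    (24 - evening_hour)
  min_high <- min_days * 24 - (feeding_end_hour - collection_hour)
  structure(list(max_hours = max_days * 24, max_days = max_days,
                 min_hours_bound = c(max(min_low, 0), min_high),
                 min_days = min_days, n_detections = nrow(hits),
                 spike_species = spike_species, feed_date = feed_date),
            class = "spike_window")
}

#' @export
print.spike_window <- function(x, ...) {
  cat(sprintf("Spike diet '%s' (fed %s): detected in %d fresh subsample(s)\n",
              x$spike_species, format(x$feed_date), x$n_detections))
  cat(sprintf("  maximum passage time: %d h (%d days at day resolution)\n",
              as.integer(x$max_hours), as.integer(x$max_days)))
  cat(sprintf("  minimum passage time: %.0f-%.0f h (deposit time unknown)\n",
              x$min_hours_bound[1], x$min_hours_bound[2]))
  invisible(x)
}

#' Forest-plot table of posterior coefficients
#'
#' Posterior mean with 50% and 95% credible intervals for every monitored
#' parameter — the numerical content of a coefficient forest plot, and a
#' superset of the headline summary.
#'
#' @param draws A `posterior_draws` object.
#' @return A `data.frame` with `parameter`, `mean`, `q2.5`, `q25`, `q50`,
#'   `q75`, `q97.5`.
#' @export
coefficient_forest <- function(draws) {
  s <- summarize_posterior(draws)
  s[, c("parameter", "mean", "q2.5", "q25", "q50", "q75", "q97.5")]
}
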