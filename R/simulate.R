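#' Construct a set of true generating parameters
#'
#' Bundles the coefficients of the Bernoulli-logit detection model used by
#' [simulate_detections()]: per-species intercepts and lag-0..lag-3 meal
#' proportion slopes, a degradation-day slope, an individual contrast, and
#' the scat random-effect SD.
#'
#' @param species Character vector of prey species labels (defines the order
#'   of all per-species vectors).
#' @param beta0,beta1,beta2,beta3,beta4 Numeric, either length 1 (recycled)
#'   or one value per species. `beta1`..`beta4` are the slopes on the
#'   proportion fed 0..3 days before defecation.
#' @param beta5 Degradation-day slope (per day of environmental exposure).
#' @param beta6 Individual contrast (second individual minus first).
#' @param sigma_alpha Scat random-effect SD (>= 0).
#' @param alpha Optional vector of per-scat random effects; if `NULL` they
#'   are drawn N(0, `sigma_alpha`) inside [simulate_detections()].
#' @return A list of class `"true_parameters"`.
#' @export
true_parameters <- function(species, beta0 = 0, beta1 = 0, beta2 = 0,
                            beta3 = 0, beta4 = 0, beta5 = 0, beta6 = 0,
                            sigma_alpha = 0, alpha = NULL) {
  S <- length(species)
  if (S == 0L) stop("`species` must be non-empty", call. = FALSE)
  if (sigma_alpha < 0) stop("`sigma_alpha` must be >= 0", call. = FALSE)
  expand <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, S)
    if (length(x) != S)
      stop(sprintf("`%s` must have length 1 or %d", nm, S), call. = FALSE)
    stats::setNames(as.numeric(x), species)
  }
  structure(list(species = species,
                 beta0 = expand(beta0, "beta0"),
                 beta1 = expand(beta1, "beta1"),
                 beta2 = expand(beta2, "beta2"),
                 beta3 = expand(beta3, "beta3"),
                 beta4 = expand(beta4, "beta4"),
                 beta5 = as.numeric(beta5),
                 beta6 = as.numeric(beta6),
                 sigma_alpha = as.numeric(sigma_alpha),
                 alpha = alpha),
            class = "true_parameters")
}

# lagged proportion fed: proportion of `species` fed to `individual` on
# `date` - lag, or 0 when not fed. `schedule` indexed by a lookup key.
schedule_lookup <- function(schedule) {
  key <- paste(schedule$individual_id, as.character(schedule$date),
               schedule$species, sep = "\r")
  stats::setNames(schedule$proportion, key)
}

lagged_proportion <- function(lookup, individual, date, species, lag) {
  key <- paste(individual, as.character(date - lag), species, sep = "\r")
  v <- unname(lookup[key])
  v[is.na(v)] <- 0
  v
}

#' Simulate Bernoulli prey detections from the logit detection model
#'
#' For each scat (one per individual per scat day), each degradation day and
#' each prey species, draws detection Y ~ Bernoulli(p) where logit(p) is the
#' linear predictor of the detection model: per-species intercept, the
#' proportions of that species fed on the defecation day and the three
#' preceding days, a degradation-day term, an individual term, and a
#' per-scat random effect. The true probability is recorded next to each
#' draw so recovery tests can compare estimates against the generating
#' process.
#'
#' Scats whose defecation date lacks feeding records for the individual on
#' the defecation day or any of the 3 preceding days are skipped with a
#' message (there is no ground truth for their lag covariates).
#'
#' @param schedule Feeding-event `data.frame` (see
#'   [generate_feeding_schedule()]).
#' @param params A [true_parameters()] object.
#' @param scat_days Vector of `Date`s on which each individual deposits one
#'   scat.
#' @param degradation_days Non-negative integer vector of days after deposit
#'   at which each scat is subsampled.
#' @param seed Integer seed.
#' @return A detection-matrix `data.frame` with columns `scat_id`,
#'   `subsample_id`, `individual_id`, `defecation_date`, `degradation_day`,
#'   `species`, `detected`, plus the generating covariates `pr0`..`pr3` and
#'   `true_p`.
#' @export
simulate_detections <- function(schedule, params, scat_days,
                                degradation_days, seed) {
  stopifnot(inherits(params, "true_parameters"))
  if (any(degradation_days < 0))
    stop("degradation days must be >= 0", call. = FALSE)
  scat_days <- as.Date(scat_days)
  schedule$date <- as.Date(schedule$date)
  degradation_days <- sort(unique(as.integer(degradation_days)))

  individuals <- sort(unique(schedule$individual_id))
  lookup <- schedule_lookup(schedule)
  fed_key <- unique(paste(schedule$individual_id,
                          as.character(schedule$date), sep = "\r"))
  species <- params$species
  S <- length(species)

  set.seed(as.integer(seed))

  # enumerate scats, skipping those without a full 4-day feeding history
  scats <- expand.grid(individual_id = individuals, date = scat_days,
                       stringsAsFactors = FALSE)
  covered <- vapply(seq_len(nrow(scats)), function(r) {
    all(paste(scats$individual_id[r],
              as.character(scats$date[r] - 0:3), sep = "\r") %in% fed_key)
  }, logical(1))
  if (any(!covered))
    message(sum(!covered), " scat(s) skipped: incomplete feeding history ",
            "on the defecation day or the 3 preceding days")
  scats <- scats[covered, , drop = FALSE]
  if (nrow(scats) == 0L)
    stop("no scat day has a complete 3-day feeding history", call. = FALSE)
  n_scat <- nrow(scats)
  scat_id <- paste0(scats$individual_id, "_", format(scats$date, "%Y%m%d"))

  alpha <- params$alpha
  if (is.null(alpha)) alpha <- stats::rnorm(n_scat, 0, params$sigma_alpha)
  if (length(alpha) != n_scat)
    stop("`alpha` must have one value per retained scat (", n_scat, ")",
         call. = FALSE)

  rows <- expand.grid(species_i = seq_len(S),
                      deg = degradation_days,
                      scat = seq_len(n_scat))
  ind01 <- as.integer(factor(scats$individual_id, levels = individuals)) - 1L
  sc <- rows$scat
  sp <- species[rows$species_i]
  pr <- sapply(0:3, function(lag)
    lagged_proportion(lookup, scats$individual_id[sc], scats$date[sc], sp, lag))
  eta <- params$beta0[sp] + params$beta1[sp] * pr[, 1] +
    params$beta2[sp] * pr[, 2] + params$beta3[sp] * pr[, 3] +
    params$beta4[sp] * pr[, 4] + params$beta5 * rows$deg +
    params$beta6 * ind01[sc] + alpha[sc]
  p <- stats::plogis(eta)
  y <- stats::rbinom(length(p), 1L, p)

  out <- data.frame(scat_id = scat_id[sc],
                    subsample_id = paste0(scat_id[sc], "_d", rows$deg),
                    individual_id = scats$individual_id[sc],
                    defecation_date = scats$date[sc],
                    degradation_day = as.integer(rows$deg),
                    species = unname(sp),
                    detected = y,
                    pr0 = unname(pr[, 1]), pr1 = unname(pr[, 2]),
                    pr2 = unname(pr[, 3]), pr3 = unname(pr[, 4]),
                    true_p = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- stats::setNames(alpha, scat_id)
  out
}

#' Simulate a taxon-assigned read table from a detection matrix
#'
#' Emulates the summarised output of an amplicon metabarcoding run on scat
#' subsamples: per subsample the total read count is Poisson(`mean_depth`),
#' the consumer taxon takes on average `consumer_fraction` of the reads
#' (about half in typical scat libraries, reflecting the defecator's own
#' epithelial cells), and the prey species detected in that subsample split
#' the remainder via a multinomial draw. Undetected prey receive zero reads.
#' Each subsample has a paired negative control whose per-taxon counts are
#' Poisson(`control_contamination_rate`). A configurable fraction of rows
#' receives a sub-80 bp sequence length so the length filter can be
#' exercised.
#'
#' @param detections Detection matrix as from [simulate_detections()].
#' @param consumer_fraction Expected fraction of reads assigned to the
#'   consumer, in (0, 1). Default 0.54.
#' @param mean_depth Mean total reads per subsample (> 0).
#' @param control_contamination_rate Expected reads per taxon in a negative
#'   control (0 switches contamination off).
#' @param seed Integer seed.
#' @param consumer Consumer taxon label.
#' @param short_read_fraction Fraction of read-table rows assigned a length
#'   below 80 bp (default 0).
#' @return A list with elements `reads` (columns `subsample_id`, `taxon`,
#'   `read_count`, `sequence_length`, `control_id`), `controls` (columns
#'   `control_id`, `taxon`, `read_count`) and `subsamples` (subsample
#'   metadata: scat, individual, defecation date, degradation day, control).
#' @export
simulate_read_table <- function(detections, consumer_fraction = 0.54,
                                mean_depth = 10000,
                                control_contamination_rate = 0,
                                seed = 1L,
                                consumer = "Acinonyx jubatus",
                                short_read_fraction = 0) {
  if (is.null(detections) || nrow(detections) == 0L)
    stop("`detections` is empty", call. = FALSE)
  if (consumer_fraction <= 0 || consumer_fraction >= 1)
    stop("`consumer_fraction` must be in (0, 1)", call. = FALSE)
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)

  set.seed(as.integer(seed))
  subs <- unique(detections[, c("subsample_id", "scat_id", "individual_id",
                                "defecation_date", "degradation_day")])
  subs <- subs[order(subs$subsample_id), , drop = FALSE]
  subs$control_id <- paste0("CTRL_", subs$subsample_id)
  rownames(subs) <- NULL
  taxa <- sort(unique(detections$species))

  reads <- vector("list", nrow(subs))
  for (r in seq_len(nrow(subs))) {
    sid <- subs$subsample_id[r]
    det <- detections[detections$subsample_id == sid &
                        detections$detected == 1L, "species"]
    total <- stats::rpois(1L, mean_depth)
    k <- length(det)
    prob <- c(consumer_fraction, rep((1 - consumer_fraction) / max(k, 1), k))
    counts <- as.integer(stats::rmultinom(1L, total, prob))
    reads[[r]] <- data.frame(subsample_id = sid,
                             taxon = c(consumer, det),
                             read_count = counts,
                             control_id = subs$control_id[r],
                             stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)

  n <- nrow(reads)
  short <- stats::runif(n) < short_read_fraction
  len <- as.integer(round(stats::rnorm(n, 100, 5)))
  len[short] <- as.integer(sample(30:79, sum(short), replace = TRUE))
  reads$sequence_length <- pmax(len, 20L)
  reads <- reads[, c("subsample_id", "taxon", "read_count",
                     "sequence_length", "control_id")]

  ctrl <- expand.grid(control_id = subs$control_id,
                      taxon = c(consumer, taxa),
                      stringsAsFactors = FALSE)
  ctrl <- ctrl[order(ctrl$control_id, ctrl$taxon), , drop = FALSE]
  ctrl$read_count <- if (control_contamination_rate > 0)
    stats::rpois(nrow(ctrl), control_contamination_rate) else 0L
  ctrl <- ctrl[ctrl$read_count > 0L, , drop = FALSE]
  rownames(ctrl) <- rownames(reads) <- NULL

  list(reads = reads, controls = ctrl, subsamples = subs)
}
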