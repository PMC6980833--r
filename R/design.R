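#' Build the detection model's input from detections and a feeding schedule
#'
#' Joins the binary detection matrix to the feeding schedule to produce, for
#' every (scat, degradation day, species) row, the lagged meal-proportion
#' covariates: `pr0` is the proportion of that species fed to the scat's
#' individual on the defecation date, `pr1`..`pr3` the proportions on the
#' 1st..3rd day before; 0 when the species was not fed that day.
#' Degradation day enters on its raw day scale and the individual as a 0/1
#' indicator (sorted label order, first label = 0). Scats whose individual
#' lacks feeding records on any of the 4 relevant days are dropped with a
#' warning. Output rows are sorted canonically (scat, degradation day,
#' species), so the construction is idempotent and independent of input row
#' order.
#'
#' @param matrix Detection matrix (`scat_id`, `individual_id`,
#'   `defecation_date`, `degradation_day`, `species`, `detected`).
#' @param schedule Feeding-event `data.frame`.
#' @return An object of class `"model_input"`: a list with `data` (the row
#'   table: `y`, `species`, `species_index`, `scat_id`, `scat_index`,
#'   `pr0`..`pr3`, `degradation_day`, `individual`), plus `species`, `scats`,
#'   `individuals`, `n_species`, `n_scats`, `n_rows`.
#' @export
build_model_input <- function(matrix, schedule) {
  schedule$date <- as.Date(schedule$date)
  matrix$defecation_date <- as.Date(matrix$defecation_date)

  unknown <- setdiff(unique(matrix$species), unique(schedule$species))
  if (length(unknown))
    stop("species in detection matrix but never in schedule: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)

  fed_key <- unique(paste(schedule$individual_id,
                          as.character(schedule$date), sep = "\r"))
  scat_tab <- unique(matrix[, c("scat_id", "individual_id",
                                "defecation_date")])
  covered <- vapply(seq_len(nrow(scat_tab)), function(r)
    all(paste(scat_tab$individual_id[r],
              as.character(scat_tab$defecation_date[r] - 0:3),
              sep = "\r") %in% fed_key), logical(1))
  if (any(!covered)) {
    warning(sum(!covered), " scat(s) dropped: feeding schedule does not ",
            "cover the defecation day and the 3 preceding days")
    matrix <- matrix[matrix$scat_id %in% scat_tab$scat_id[covered], ,
                     drop = FALSE]
  }
  if (nrow(matrix) == 0L) stop("no usable rows remain", call. = FALSE)

  species <- sort(unique(matrix$species))
  scats <- sort(unique(matrix$scat_id))
  individuals <- sort(unique(matrix$individual_id))
  if (length(individuals) > 2L)
    warning("more than two individuals; `individual` is coded 0 for '",
            individuals[1], "' and 1 otherwise")

  ord <- order(matrix$scat_id, matrix$degradation_day, matrix$species)
  m <- matrix[ord, , drop = FALSE]

  lookup <- schedule_lookup(schedule)
  pr <- sapply(0:3, function(lag)
    lagged_proportion(lookup, m$individual_id, m$defecation_date,
                      m$species, lag))

  data <- data.frame(
    y = as.integer(m$detected),
    species = m$species,
    species_index = match(m$species, species),
    scat_id = m$scat_id,
    scat_index = match(m$scat_id, scats),
    pr0 = pr[, 1], pr1 = pr[, 2], pr2 = pr[, 3], pr3 = pr[, 4],
    degradation_day = as.numeric(m$degradation_day),
    individual = as.integer(m$individual_id != individuals[1]),
    stringsAsFactors = FALSE)
  rownames(data) <- NULL

  structure(list(data = data, species = species, scats = scats,
                 individuals = individuals, n_species = length(species),
                 n_scats = length(scats), n_rows = nrow(data)),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat("Detection model input:", x$n_rows, "rows |", x$n_species,
      "species |", x$n_scats, "scats |", length(x$individuals),
      "individuals\n")
  invisible(x)
}

#' Empirical detection probability versus meal size
#'
#' Model-free view of the meal-size effect: each row's meal size is taken as
#' the largest proportion of that species fed over the defecation day and
#' the three preceding days (`max(pr0..pr3)`); rows are pooled into
#' `n_bins` equal-width bins on [0, 1] and the fraction of rows with a
#' detection is reported per bin.
#'
#' @param input A [build_model_input()] object.
#' @param n_bins Number of equal-width proportion bins (>= 1).
#' @return A `data.frame` with `bin_low`, `bin_high`, `bin_mid`,
#'   `proportion_fed` (mean within bin), `fraction_detected`, `n`.
#' @export
empirical_meal_size_curve <- function(input, n_bins = 10L) {
  stopifnot(inherits(input, "model_input"))
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  d <- input$data
  prop <- pmax(d$pr0, d$pr1, d$pr2, d$pr3)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(prop, edges), n_bins)  # prop == 1 folds into top bin
  out <- data.frame(bin = seq_len(n_bins),
                    bin_low = edges[-length(edges)],
                    bin_high = edges[-1])
  out$bin_mid <- (out$bin_low + out$bin_high) / 2
  out$proportion_fed <- as.numeric(tapply(prop, factor(bin, levels = out$bin),
                                          mean))
  out$fraction_detected <- as.numeric(tapply(d$y, factor(bin, levels = out$bin),
                                             mean))
  out$n <- as.integer(table(factor(bin, levels = out$bin)))
  out
}
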