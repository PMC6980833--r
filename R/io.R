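# --- date handling -----------------------------------------------------

# Dates arrive either ISO-8601 (YYYY-MM-DD) or in the trial's DD.MM.YYYY
# notation; auto-detected per column and normalized to Date for unambiguous
# lag arithmetic.
parse_dates <- function(x, file = "<data>", column = "date") {
  x <- trimws(as.character(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{2}\\.\\d{2}\\.\\d{4}$", x)
  bad <- !(iso | dmy) | is.na(x)
  if (any(bad))
    stop(sprintf("%s: unparseable %s at row(s) %s (expect YYYY-MM-DD or DD.MM.YYYY)",
                 file, column, paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  out[iso] <- as.Date(x[iso])
  out[dmy] <- as.Date(x[dmy], format = "%d.%m.%Y")
  if (anyNA(out))
    stop(sprintf("%s: invalid calendar %s at row(s) %s", file, column,
                 paste(utils::head(which(is.na(out)), 5), collapse = ", ")),
         call. = FALSE)
  out
}

read_csv_checked <- function(path, required, file_label = basename(path)) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", file_label,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

# --- readers ------------------------------------------------------------

#' Read a feeding schedule CSV
#'
#' Required columns: `date`, `individual_id`, `species`, `proportion`.
#' Dates may be ISO-8601 or DD.MM.YYYY (auto-detected). Proportions must
#' lie in [0, 1]; offending rows are reported by number. Unknown columns
#' are preserved as passthrough metadata.
#'
#' @param path CSV path.
#' @return A feeding-event `data.frame`.
#' @export
read_feeding_schedule <- function(path) {
  df <- read_csv_checked(path, c("date", "individual_id", "species",
                                 "proportion"))
  df$date <- parse_dates(df$date, basename(path))
  df$proportion <- as.numeric(df$proportion)
  bad <- is.na(df$proportion) | df$proportion < 0 | df$proportion > 1
  if (any(bad))
    stop(sprintf("%s: proportion outside [0, 1] at row(s) %s",
                 basename(path),
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  df
}

#' Read a taxon-assigned read table CSV
#'
#' Required columns: `subsample_id`, `taxon`, `read_count`; optional
#' `sequence_length` and `control_id`.
#'
#' @param path CSV path.
#' @return A read-table `data.frame`.
#' @export
read_read_table <- function(path) {
  df <- read_csv_checked(path, c("subsample_id", "taxon", "read_count"))
  df$read_count <- as.integer(df$read_count)
  bad <- is.na(df$read_count) | df$read_count < 0
  if (any(bad))
    stop(sprintf("%s: read_count must be a non-negative integer at row(s) %s",
                 basename(path),
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  if ("sequence_length" %in% names(df))
    df$sequence_length <- as.integer(df$sequence_length)
  df
}

#' Read a negative-control read table CSV
#'
#' Required columns: `control_id` (or `subsample_id`), `taxon`,
#' `read_count`.
#'
#' @param path CSV path.
#' @return A control read-table `data.frame`.
#' @export
read_control_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"control_id" %in% names(df) && "subsample_id" %in% names(df))
    df$control_id <- df$subsample_id
  missing <- setdiff(c("control_id", "taxon", "read_count"), names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$read_count <- as.integer(df$read_count)
  df
}

#' Read subsample metadata CSV
#'
#' Required columns: `subsample_id`, `scat_id`, `individual_id`,
#' `defecation_date`, `degradation_day`; optional `control_id`.
#'
#' @param path CSV path.
#' @return A `data.frame` of subsample metadata.
#' @export
read_subsample_info <- function(path) {
  df <- read_csv_checked(path, c("subsample_id", "scat_id", "individual_id",
                                 "defecation_date", "degradation_day"))
  df$defecation_date <- parse_dates(df$defecation_date, basename(path),
                                    "defecation_date")
  df$degradation_day <- as.integer(df$degradation_day)
  df
}

#' Read a detection matrix CSV
#'
#' Required columns: `scat_id`, `subsample_id`, `individual_id`,
#' `defecation_date`, `degradation_day`, `species`, `detected`.
#'
#' @param path CSV path.
#' @return A detection-matrix `data.frame`.
#' @export
read_detection_matrix <- function(path) {
  df <- read_csv_checked(path, c("scat_id", "subsample_id", "individual_id",
                                 "defecation_date", "degradation_day",
                                 "species", "detected"))
  df$defecation_date <- parse_dates(df$defecation_date, basename(path),
                                    "defecation_date")
  df$degradation_day <- as.integer(df$degradation_day)
  df$detected <- as.integer(df$detected)
  if (!all(df$detected %in% c(0L, 1L)))
    stop(basename(path), ": `detected` must be 0/1", call. = FALSE)
  df
}

#' Build a model input directly from a concatenated row table
#'
#' For data already in one flat table — one row per
#' (scat, degradation day, species) with the binary response and the lag
#' covariates precomputed (the shape of a concatenated feeding +
#' metabarcoding export). Required columns: `y` (or `detected`),
#' `species`, `scat_id`, `pr0`..`pr3`, `degradation_day`, `individual`.
#'
#' @param rows A `data.frame` in the flat schema above.
#' @return A `"model_input"` object.
#' @export
model_input_from_rows <- function(rows) {
  if (!"y" %in% names(rows) && "detected" %in% names(rows))
    rows$y <- rows$detected
  required <- c("y", "species", "scat_id", "pr0", "pr1", "pr2", "pr3",
                "degradation_day", "individual")
  missing <- setdiff(required, names(rows))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  species <- sort(unique(rows$species))
  scats <- sort(unique(rows$scat_id))
  ord <- order(rows$scat_id, rows$degradation_day, rows$species)
  r <- rows[ord, , drop = FALSE]
  data <- data.frame(y = as.integer(r$y), species = r$species,
                     species_index = match(r$species, species),
                     scat_id = r$scat_id,
                     scat_index = match(r$scat_id, scats),
                     pr0 = as.numeric(r$pr0), pr1 = as.numeric(r$pr1),
                     pr2 = as.numeric(r$pr2), pr3 = as.numeric(r$pr3),
                     degradation_day = as.numeric(r$degradation_day),
                     individual = as.integer(r$individual),
                     stringsAsFactors = FALSE)
  rownames(data) <- NULL
  if (!all(data$y %in% c(0L, 1L)))
    stop("`y` must be 0/1", call. = FALSE)
  individuals <- sort(unique(data$individual))
  structure(list(data = data, species = species, scats = scats,
                 individuals = as.character(individuals),
                 n_species = length(species), n_scats = length(scats),
                 n_rows = nrow(data)),
            class = "model_input")
}

# --- writers ------------------------------------------------------------

write_table_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize posterior draws to CSV plus a JSON sidecar
#'
#' Columnar CSV: `chain`, `iteration`, then one column per monitored
#' scalar. The sidecar (same path with extension `.meta.json`) records the
#' run metadata (chains, iterations, burn-in, thin, seed, species, scats,
#' model flags) needed to rebuild the `posterior_draws` object.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_posterior_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  tabs <- lapply(seq_along(draws$chains), function(j) {
    m <- draws$chains[[j]]
    cbind(data.frame(chain = j, iteration = seq_len(nrow(m))),
          as.data.frame(m, check.names = FALSE))
  })
  write_table_csv(do.call(rbind, tabs), path)
  meta <- draws[c("parameters", "n_chains", "n_iter", "n_burnin", "thin",
                  "seed", "acceptance_rates", "species", "scats",
                  "individuals", "hierarchical", "random_effect",
                  "monitor_alpha")]
  jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read posterior draws written by [write_posterior_draws()]
#'
#' @param path CSV path (the `.meta.json` sidecar must sit next to it).
#' @return A `posterior_draws` object.
#' @export
read_posterior_draws <- function(path) {
  meta_path <- sub("\\.csv$", ".meta.json", path)
  if (!file.exists(meta_path))
    stop("missing draws metadata sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  chains <- lapply(sort(unique(df$chain)), function(j) {
    m <- as.matrix(df[df$chain == j, meta$parameters, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  structure(list(chains = chains, parameters = meta$parameters,
                 n_chains = meta$n_chains, n_iter = meta$n_iter,
                 n_burnin = meta$n_burnin, thin = meta$thin,
                 seed = meta$seed,
                 acceptance_rates = meta$acceptance_rates,
                 species = meta$species, scats = meta$scats,
                 individuals = meta$individuals,
                 hierarchical = meta$hierarchical,
                 random_effect = meta$random_effect,
                 monitor_alpha = meta$monitor_alpha),
            class = "posterior_draws")
}
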