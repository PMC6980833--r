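#' Filter a read table on sequence length and read abundance
#'
#' Removes rows shorter than `min_length` base pairs or with read counts
#' below `min_abundance` (likely sequencing errors or chimaeras). Boundary
#' values are kept: a row with length exactly `min_length` or count exactly
#' `min_abundance` survives. Row order and counts are untouched.
#'
#' @param table Read table with at least `read_count` and `sequence_length`
#'   columns.
#' @param min_length Minimum sequence length in bp (default 80).
#' @param min_abundance Minimum read count (default 10).
#' @return The filtered read table (possibly zero rows).
#' @export
filter_reads <- function(table, min_length = 80L, min_abundance = 10L) {
  if (min_length < 0 || min_abundance < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  if (is.null(table) || nrow(table) == 0L)
    stop("`table` is empty", call. = FALSE)
  keep <- table$sequence_length >= min_length &
    table$read_count >= min_abundance
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default higher-rank to species taxon mapping
#'
#' Family-level assignments collapsed onto the trial's known species:
#' Felidae to the consumer (cheetah), Leporidae to rabbit, Equidae to horse,
#' Cervidae to deer.
#'
#' @return A `data.frame` with columns `pattern`, `target`, `rank`.
#' @export
default_taxon_mapping <- function() {
  data.frame(
    pattern = c("Felidae", "Leporidae", "Equidae", "Cervidae"),
    target  = c("Acinonyx jubatus", "Oryctolagus cuniculus",
                "Equus caballus", "Cervus spp"),
    rank    = c("family", "family", "family", "family"),
    stringsAsFactors = FALSE)
}

#' Collapse higher-rank taxon assignments onto the target species list
#'
#' Applies a many-to-one mapping (e.g. Leporidae to *Oryctolagus
#' cuniculus*), sums read counts of rows that land on the same
#' (subsample, species) pair, and drops rows whose taxon is neither a target
#' species nor the consumer after mapping (non-target or unassigned
#' sequences). Dropped rows and reads are tallied in the `"exclusions"`
#' attribute of the result.
#'
#' @param table Read table (`subsample_id`, `taxon`, `read_count`, ...).
#' @param mapping Mapping `data.frame` with columns `pattern`, `target`.
#'   When omitted, [default_taxon_mapping()] is used with rows irrelevant
#'   to `target_species` discarded; an explicitly supplied mapping whose
#'   target is not a modelled species is a configuration error.
#' @param target_species Character vector of modelled prey species.
#' @param consumer Consumer taxon label, retained for read-share reporting.
#' @return Read table with species-level taxa; merged rows keep the maximum
#'   `sequence_length` of their parents (length filtering happens upstream).
#' @export
reassign_taxa <- function(table, mapping = default_taxon_mapping(),
                          target_species, consumer = "Acinonyx jubatus") {
  if (is.null(table) || nrow(table) == 0L)
    stop("`table` is empty", call. = FALSE)
  if (missing(mapping)) {
    mapping <- mapping[mapping$target %in% c(target_species, consumer), ,
                       drop = FALSE]
  } else {
    bad <- setdiff(mapping$target, c(target_species, consumer))
    if (length(bad))
      stop("mapping target(s) not in `target_species`: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  taxon <- table$taxon
  hit <- match(taxon, mapping$pattern)
  taxon[!is.na(hit)] <- mapping$target[hit[!is.na(hit)]]
  table$taxon <- taxon

  keep <- taxon %in% c(target_species, consumer)
  dropped <- table[!keep, , drop = FALSE]
  kept <- table[keep, , drop = FALSE]

  # merge rows mapping onto the same (subsample, species)
  key <- paste(kept$subsample_id, kept$taxon, sep = "\r")
  counts <- rowsum(kept$read_count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- kept[first, , drop = FALSE]
  out$read_count <- as.integer(counts[match(paste(out$subsample_id,
                                                  out$taxon, sep = "\r"),
                                            rownames(counts))])
  if ("sequence_length" %in% names(kept)) {
    lens <- tapply(kept$sequence_length, key, max)
    out$sequence_length <- as.integer(lens[paste(out$subsample_id, out$taxon,
                                                 sep = "\r")])
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    n_rows_dropped = nrow(dropped),
    n_reads_dropped = sum(dropped$read_count),
    dropped_taxa = sort(table(dropped$taxon), decreasing = TRUE))
  out
}

#' Call prey presence/absence against negative controls
#'
#' A prey species is called present in a subsample when it has at least one
#' read there and its matched negative control carries fewer than
#' `control_max` reads of that species (a species absent from the control is
#' treated as count 0). The consumer is never emitted as a prey row. Every
#' (subsample, target species) pair appears in the output with an explicit
#' 0/1 call.
#'
#' Controls are resolved per subsample via, in order: a `control_id` column
#' in `table`, the `control_map` argument (named vector subsample -> control),
#' or — when `controls` contains a single control — that shared batch
#' control. A subsample with no resolvable control is an error.
#'
#' @param table Species-level read table (after [filter_reads()] and
#'   [reassign_taxa()]).
#' @param controls Control read table (`control_id` or `subsample_id`,
#'   `taxon`, `read_count`).
#' @param control_max Control read threshold; control counts `>= control_max`
#'   veto the detection (default 10).
#' @param target_species Modelled prey species.
#' @param consumer Consumer taxon label.
#' @param control_map Optional named character vector mapping subsample ids
#'   to control ids.
#' @param subsample_info Optional metadata `data.frame` (`subsample_id`,
#'   `scat_id`, `individual_id`, `defecation_date`, `degradation_day`)
#'   joined onto the output.
#' @return Detection matrix `data.frame` with one row per
#'   (subsample, species) and a 0/1 `detected` column.
#' @export
call_presence <- function(table, controls, control_max = 10L,
                          target_species, consumer = "Acinonyx jubatus",
                          control_map = NULL, subsample_info = NULL) {
  if (control_max < 0) stop("`control_max` must be >= 0", call. = FALSE)
  subsamples <- sort(unique(c(table$subsample_id,
                              if (!is.null(subsample_info))
                                subsample_info$subsample_id)))
  ctrl_ids <- if ("control_id" %in% names(controls)) controls$control_id
              else controls$subsample_id

  resolve <- function(sid) {
    if ("control_id" %in% names(table)) {
      cid <- table$control_id[match(sid, table$subsample_id)]
      if (!is.na(cid)) return(cid)
    }
    if (!is.null(subsample_info) && "control_id" %in% names(subsample_info)) {
      cid <- subsample_info$control_id[match(sid, subsample_info$subsample_id)]
      if (!is.na(cid)) return(cid)
    }
    if (!is.null(control_map) && sid %in% names(control_map))
      return(unname(control_map[sid]))
    u <- unique(ctrl_ids)
    if (length(u) == 1L) return(u)  # shared batch control
    stop("no mappable negative control for subsample '", sid, "'",
         call. = FALSE)
  }
  cid <- vapply(subsamples, resolve, character(1))

  sample_count <- function(sid, sp) {
    i <- table$subsample_id == sid & table$taxon == sp
    if (any(i)) sum(table$read_count[i]) else 0L
  }
  control_count <- function(c_id, sp) {
    i <- ctrl_ids == c_id & controls$taxon == sp
    if (any(i)) sum(controls$read_count[i]) else 0L
  }

  grid <- expand.grid(subsample_id = subsamples, species = target_species,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subsample_id, grid$species), , drop = FALSE]
  n_s <- vapply(seq_len(nrow(grid)), function(r)
    sample_count(grid$subsample_id[r], grid$species[r]), numeric(1))
  n_c <- vapply(seq_len(nrow(grid)), function(r)
    control_count(cid[grid$subsample_id[r]], grid$species[r]), numeric(1))
  grid$detected <- as.integer(n_s >= 1 & n_c < control_max)

  if (!is.null(subsample_info)) {
    meta_cols <- intersect(c("scat_id", "individual_id", "defecation_date",
                             "degradation_day"), names(subsample_info))
    m <- match(grid$subsample_id, subsample_info$subsample_id)
    for (col in meta_cols) grid[[col]] <- subsample_info[[col]][m]
    cols <- intersect(c("scat_id", "subsample_id", "individual_id",
                        "defecation_date", "degradation_day", "species",
                        "detected"), names(grid))
    grid <- grid[, cols, drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

#' Drop burn-in scats and excluded species from a detection matrix
#'
#' Scats deposited within the first `burnin_days` days of each individual's
#' feeding trial are removed: what the animal ate before the trial is
#' unknown, so their lag covariates cannot be built. Species in
#' `excluded_species` (by default turkey, fed only inside that window) are
#' removed everywhere.
#'
#' @param matrix Detection matrix with `defecation_date` and
#'   `individual_id`.
#' @param schedule Feeding-event `data.frame`; defines each individual's
#'   first feeding date.
#' @param burnin_days Number of leading trial days to drop (default 3;
#'   0 disables).
#' @param excluded_species Species removed outright.
#' @return The reduced detection matrix, with dropped-row tallies in the
#'   `"exclusions"` attribute.
#' @export
exclude_burnin_scats <- function(matrix, schedule, burnin_days = 3L,
                                 excluded_species = "Meleagris gallopavo") {
  schedule$date <- as.Date(schedule$date)
  first_day <- tapply(schedule$date, schedule$individual_id, min)
  offset <- as.numeric(as.Date(matrix$defecation_date)) -
    as.numeric(first_day[matrix$individual_id])
  in_burnin <- !is.na(offset) & offset < burnin_days
  excluded <- matrix$species %in% excluded_species
  out <- matrix[!in_burnin & !excluded, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("all detection rows removed by burn-in/species exclusion")
  attr(out, "exclusions") <- list(n_burnin_rows = sum(in_burnin),
                                  n_excluded_species_rows = sum(excluded &
                                                                  !in_burnin))
  out
}
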