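#' Load flower-visitation records
#'
#' @param path CSV with columns `species`, `plant_individual`, `n_flowers`,
#'   `observation_hours` (hours per flower), `group`, `visits` (or a
#'   data.frame). One row per (plant individual, pollinator group).
#' @return Validated visitation data.frame.
#' @export
load_visitation <- function(path) {
  d <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  need <- c("species", "plant_individual", "n_flowers", "observation_hours",
            "group", "visits")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(d$n_flowers < 1)) stop("n_flowers must be >= 1", call. = FALSE)
  if (any(d$observation_hours <= 0)) stop("observation_hours must be > 0", call. = FALSE)
  if (any(d$visits < 0)) stop("negative visit count", call. = FALSE)
  d[need]
}

#' Visitation frequency of one pollinator group
#'
#' VF = total visits by the group divided by the total observation effort in
#' flower-hours, i.e. the sum over observed flowers of their observation time.
#'
#' @param visits Visit counts per record.
#' @param n_flowers Observed flowers per record.
#' @param observation_hours Observation time per flower for the record.
#' @return Visits per flower-hour.
#' @export
#' @examples
#' visitation_frequency(10, 2, 24)  # 10 visits over 48 flower-hours
visitation_frequency <- function(visits, n_flowers, observation_hours) {
  effort <- sum(n_flowers * observation_hours)
  if (effort <= 0) stop("zero observation effort", call. = FALSE)
  sum(visits) / effort
}

#' Per-species visitation-frequency table
#'
#' Observation effort is a property of the plant, not of the visitor group:
#' flower-hours are summed over the distinct `(species, plant_individual)`
#' observation units, and each group's visits are divided by that common
#' species-level effort.
#'
#' @param records Visitation records from [load_visitation()].
#' @return Data.frame: one row per species, one `vf_<group>` column per group.
#' @export
visitation_table <- function(records) {
  records <- load_visitation(records)
  units <- !duplicated(records[, c("species", "plant_individual")])
  effort <- tapply(records$n_flowers[units] * records$observation_hours[units],
                   records$species[units], sum)
  groups <- sort(unique(records$group))
  species <- sort(unique(records$species))
  vf <- sapply(groups, function(g) {
    v <- tapply(records$visits[records$group == g],
                records$species[records$group == g], sum)
    out <- stats::setNames(numeric(length(species)), species)
    out[names(v)] <- v
    out / as.numeric(effort[species])
  })
  vf <- matrix(vf, nrow = length(species),
               dimnames = list(NULL, paste0("vf_", groups)))
  data.frame(species = species, vf, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Primary pollinator group from visitation frequencies
#'
#' The primary group maximizes VF. Exact ties are broken lexicographically and
#' flagged; a species with all-zero VF is unassigned.
#'
#' @param vf Named numeric vector of visitation frequencies by group.
#' @return List: `group` (label or `NA`), `tie` (logical), `unassigned`.
#' @export
#' @examples
#' assign_primary_group(c(bees = 0.5, birds = 0.1))
assign_primary_group <- function(vf) {
  if (length(vf) == 0) stop("empty visitation-frequency mapping", call. = FALSE)
  if (any(vf < 0)) stop("negative visitation frequency", call. = FALSE)
  if (all(vf == 0)) return(list(group = NA_character_, tie = FALSE, unassigned = TRUE))
  top <- names(vf)[vf == max(vf)]
  list(group = sort(top)[1], tie = length(top) > 1, unassigned = FALSE)
}

#' Assign every species its primary pollinator group
#'
#' @param records Visitation records, or a VF table from [visitation_table()].
#' @return Assignment data.frame: `species`, `vf_*` columns, `primary_group`,
#'   `tie`, `excluded` (all `FALSE`; see [exclude_rare_groups()]).
#' @export
assign_pollinators <- function(records) {
  vf <- if (any(startsWith(names(records), "vf_"))) records else visitation_table(records)
  vfm <- as.matrix(vf[, startsWith(names(vf), "vf_"), drop = FALSE])
  colnames(vfm) <- sub("^vf_", "", colnames(vfm))
  ass <- apply(vfm, 1, function(r) assign_primary_group(r))
  vf$primary_group <- vapply(ass, `[[`, character(1), "group")
  vf$tie <- vapply(ass, `[[`, logical(1), "tie")
  vf$excluded <- FALSE
  vf
}

#' Exclude pollinator groups with few affiliated plant species
#'
#' Groups that are the primary visitor of fewer than `min_species` species
#' are removed from the analyzed set; their species are flagged `excluded`
#' (as are unassigned species).
#'
#' @param assignments Assignment table from [assign_pollinators()].
#' @param min_species Minimum species per retained group (default 5).
#' @return The table with `excluded` updated.
#' @export
exclude_rare_groups <- function(assignments, min_species = 5) {
  stopifnot(min_species >= 1)
  counts <- table(assignments$primary_group)
  rare <- names(counts)[counts < min_species]
  assignments$excluded <- is.na(assignments$primary_group) |
    assignments$primary_group %in% rare
  assignments
}

#' Load a per-species primary-pollinator assignment table
#'
#' For data sets where the group affiliations are supplied directly rather
#' than derived from visitation records. The packaged
#' `synthetic_pollinator_assignments.csv` is a constructed stand-in (the
#' survey's species-by-species affiliations are not published as data);
#' it matches the published group structure but not necessarily the true
#' per-species labels.
#'
#' @param path CSV with columns `species`, `primary_group` (or a data.frame).
#' @return Assignment data.frame with `excluded = FALSE` flags.
#' @export
load_assignments <- function(path) {
  d <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  need <- c("species", "primary_group")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$species)) stop("duplicate species", call. = FALSE)
  d$tie <- if ("tie" %in% names(d)) d$tie else FALSE
  d$excluded <- if ("excluded" %in% names(d)) d$excluded else FALSE
  d
}
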