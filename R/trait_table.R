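#' Locate a packaged example data file
#'
#' The package ships the Mount Cameroon nectar survey as plain-text fixtures:
#' `mt_cameroon_nectar.csv` (per-species sample counts, sugar proportions and
#' 24 h sugar amounts), `mt_cameroon_taxonomy.csv` (species/genus/family), and
#' `synthetic_pollinator_assignments.csv` (a constructed stand-in for the
#' per-species primary-pollinator table, see [load_assignments()]).
#'
#' @param file File name within `inst/extdata`; `NULL` lists available files.
#' @return Full path to the file.
#' @export
#' @examples
#' nectar_example()
#' head(read.csv(nectar_example("mt_cameroon_nectar.csv")))
nectar_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nectarphylo")))
  }
  path <- system.file("extdata", file, package = "nectarphylo")
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; summary tables here follow the
#' conventional half-up rule (e.g. 30.5% prints as 31%).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

prop_cols <- c("sucrose", "glucose", "fructose")

#' Load a nectar trait table
#'
#' Reads either sample-level data (columns `species`, `sucrose_ug`,
#' `glucose_ug`, `fructose_ug`, optional `concentration_pct`; one row per
#' nectar sample) or a species-level summary table (columns `species`,
#' `n_samples`, `sucrose_pct`, `glucose_pct`, `fructose_pct`, optional
#' `*_sd` and `amount_ug`/`amount_sd`; one row per species, percentages as
#' printed). Species-level input is converted directly to profiles; sample
#' rows must be passed through [summarize_species()].
#'
#' Species-level percentages are kept exactly as given (not renormalized);
#' the deviation of each row's percentage sum from 100 is recorded in the
#' `prop_sum_error` column of the resulting profiles.
#'
#' @param path CSV file path (or a data.frame already in one of the schemas).
#' @param mode `"auto"` (default), `"samples"`, or `"species"`.
#' @return For `mode = "samples"` a `nectar_samples` data.frame; for
#'   `mode = "species"` a `nectar_profiles` data.frame (see
#'   [summarize_species()] for columns).
#' @export
#' @examples
#' prof <- load_trait_table(nectar_example("mt_cameroon_nectar.csv"))
#' nrow(prof)
load_trait_table <- function(path, mode = c("auto", "samples", "species")) {
  mode <- match.arg(mode)
  d <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  sample_cols <- c("species", "sucrose_ug", "glucose_ug", "fructose_ug")
  species_cols <- c("species", "n_samples", "sucrose_pct", "glucose_pct", "fructose_pct")
  if (mode == "auto") {
    mode <- if (all(sample_cols %in% names(d))) "samples"
      else if (all(species_cols %in% names(d))) "species"
      else stop("columns match neither the sample-level nor the species-level schema",
                call. = FALSE)
  }
  if (mode == "samples") {
    miss <- setdiff(sample_cols, names(d))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    mass <- as.matrix(d[, c("sucrose_ug", "glucose_ug", "fructose_ug")])
    if (anyNA(mass)) stop("missing sugar mass", call. = FALSE)
    if (any(mass < 0)) stop("negative sugar mass", call. = FALSE)
    if (any(rowSums(mass) == 0)) stop("sample with zero total sugar mass", call. = FALSE)
    out <- d
    class(out) <- c("nectar_samples", "data.frame")
    return(out)
  }
  miss <- setdiff(species_cols, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$species)) stop("duplicate species in species-level table", call. = FALSE)
  pct <- as.matrix(d[, c("sucrose_pct", "glucose_pct", "fructose_pct")])
  if (any(pct < 0) || anyNA(pct)) stop("invalid percentage", call. = FALSE)
  if (any(d$n_samples < 1)) stop("n_samples must be >= 1", call. = FALSE)
  prof <- data.frame(
    species = d$species,
    n_samples = as.integer(d$n_samples),
    prop_sucrose = d$sucrose_pct / 100,
    prop_glucose = d$glucose_pct / 100,
    prop_fructose = d$fructose_pct / 100,
    sd_sucrose = if ("sucrose_sd" %in% names(d)) d$sucrose_sd / 100 else NA_real_,
    sd_glucose = if ("glucose_sd" %in% names(d)) d$glucose_sd / 100 else NA_real_,
    sd_fructose = if ("fructose_sd" %in% names(d)) d$fructose_sd / 100 else NA_real_,
    mean_amount = if ("amount_ug" %in% names(d)) d$amount_ug else NA_real_,
    sd_amount = if ("amount_sd" %in% names(d)) d$amount_sd else NA_real_,
    stringsAsFactors = FALSE
  )
  prof$amount_sucrose <- prof$mean_amount * prof$prop_sucrose
  prof$amount_glucose <- prof$mean_amount * prof$prop_glucose
  prof$amount_fructose <- prof$mean_amount * prof$prop_fructose
  hex <- prof$prop_glucose + prof$prop_fructose
  prof$sucrose_hexose_ratio <- ifelse(hex > 0, prof$prop_sucrose / hex, NA_real_)
  prof$ratio_approximate <- TRUE   # computed from species means, not per sample
  prof$prop_sum_error <- rowSums(pct) / 100 - 1
  class(prof) <- c("nectar_profiles", "data.frame")
  prof
}

#' Load a species taxonomy table
#'
#' @param path CSV with columns `species`, `genus`, `family` (or a data.frame).
#' @return Validated taxonomy data.frame.
#' @export
load_taxonomy <- function(path) {
  d <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  need <- c("species", "genus", "family")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$species)) stop("duplicate species in taxonomy", call. = FALSE)
  if (any(!nzchar(d$family))) stop("empty family name", call. = FALSE)
  d[need]
}

#' Per-sample sugar proportions
#'
#' Converts sugar masses of one or more nectar samples into proportions of
#' the total sugar mass.
#'
#' @param sucrose,glucose,fructose Sugar masses (ug); vectors of equal length.
#' @return Matrix with columns `sucrose`, `glucose`, `fructose`; rows sum to 1.
#' @export
#' @examples
#' sample_proportions(93, 3.7, 3.3)
sample_proportions <- function(sucrose, glucose, fructose) {
  m <- cbind(sucrose = sucrose, glucose = glucose, fructose = fructose)
  if (any(m < 0)) stop("negative sugar mass", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero total sugar mass", call. = FALSE)
  m / tot
}

#' Summarize nectar samples into species profiles
#'
#' For each species: the unweighted mean (and sample SD) of per-sample sugar
#' proportions, the mean total sugar amount and per-sugar amounts, and the
#' sucrose/hexose ratio averaged over samples (samples with no hexoses are
#' excluded from the ratio mean and counted in `n_ratio_undefined`).
#'
#' @param samples A `nectar_samples` table from [load_trait_table()].
#' @return A `nectar_profiles` data.frame, one row per species, with columns
#'   `species`, `n_samples`, `prop_*`, `sd_*`, `mean_amount`, `sd_amount`,
#'   `amount_*` (per-sugar ug/flower/24 h), `sucrose_hexose_ratio`,
#'   `ratio_approximate` (FALSE here: sample-level averaging),
#'   `prop_sum_error` (0 here).
#' @export
summarize_species <- function(samples) {
  stopifnot(is.data.frame(samples))
  sp <- unique(samples$species)
  rows <- lapply(sp, function(s) {
    d <- samples[samples$species == s, , drop = FALSE]
    p <- sample_proportions(d$sucrose_ug, d$glucose_ug, d$fructose_ug)
    tot <- d$sucrose_ug + d$glucose_ug + d$fructose_ug
    hex <- d$glucose_ug + d$fructose_ug
    r <- ifelse(hex > 0, d$sucrose_ug / hex, NA_real_)
    data.frame(
      species = s, n_samples = nrow(d),
      prop_sucrose = mean(p[, 1]), prop_glucose = mean(p[, 2]),
      prop_fructose = mean(p[, 3]),
      sd_sucrose = stats::sd(p[, 1]), sd_glucose = stats::sd(p[, 2]),
      sd_fructose = stats::sd(p[, 3]),
      mean_amount = mean(tot), sd_amount = stats::sd(tot),
      amount_sucrose = mean(d$sucrose_ug), amount_glucose = mean(d$glucose_ug),
      amount_fructose = mean(d$fructose_ug),
      sucrose_hexose_ratio = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE),
      n_ratio_undefined = sum(is.na(r)),
      ratio_approximate = FALSE, prop_sum_error = 0,
      stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, rows)
  rownames(prof) <- NULL
  class(prof) <- c("nectar_profiles", "data.frame")
  prof
}

#' Keep species with at least `min_n` nectar samples
#'
#' @param profiles A `nectar_profiles` data.frame.
#' @param min_n Minimum sample count (default 3, the survey's inclusion rule).
#' @return Filtered profiles.
#' @export
filter_min_samples <- function(profiles, min_n = 3) {
  stopifnot(min_n >= 1)
  profiles[profiles$n_samples >= min_n, , drop = FALSE]
}

#' Dataset-level nectar summary
#'
#' Species are weighted equally (not by sample count): means and SDs are taken
#' over species mean proportions and amounts.
#'
#' @param profiles A `nectar_profiles` data.frame.
#' @return List with `n_species`, `total_samples`, `mean_prop` / `sd_prop`
#'   (fractions, named by sugar), `mean_amount` (per-sugar ug/flower/24 h),
#'   `mean_total_amount`, `n_ratio_gt1`, `mean_ratio`, `sd_ratio`.
#' @export
#' @examples
#' prof <- load_trait_table(nectar_example("mt_cameroon_nectar.csv"))
#' dataset_summary(prof)$total_samples
dataset_summary <- function(profiles) {
  stopifnot(nrow(profiles) >= 1)
  p <- as.matrix(profiles[, paste0("prop_", prop_cols)])
  a <- as.matrix(profiles[, paste0("amount_", prop_cols)])
  r <- profiles$sucrose_hexose_ratio
  list(
    n_species = nrow(profiles),
    total_samples = sum(profiles$n_samples),
    mean_prop = stats::setNames(colMeans(p), prop_cols),
    sd_prop = stats::setNames(apply(p, 2, stats::sd), prop_cols),
    mean_amount = stats::setNames(colMeans(a), prop_cols),
    mean_total_amount = mean(profiles$mean_amount),
    n_ratio_gt1 = sum(r > 1, na.rm = TRUE),
    mean_ratio = mean(r, na.rm = TRUE),
    sd_ratio = if (sum(!is.na(r)) > 1) stats::sd(r, na.rm = TRUE) else NA_real_
  )
}

#' Family-level mean sugar proportions
#'
#' Unweighted mean over species of species mean proportions, by family.
#'
#' @param profiles A `nectar_profiles` data.frame.
#' @param taxonomy Taxonomy from [load_taxonomy()].
#' @return Data.frame: `family`, `n_species`, `prop_sucrose`, `prop_glucose`,
#'   `prop_fructose` (fractions).
#' @export
family_summary <- function(profiles, taxonomy) {
  miss <- setdiff(profiles$species, taxonomy$species)
  if (length(miss)) {
    stop("species missing from taxonomy: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- merge(profiles, taxonomy, by = "species")
  agg <- stats::aggregate(
    m[, paste0("prop_", prop_cols)],
    by = list(family = m$family), FUN = mean
  )
  agg$n_species <- as.vector(table(m$family)[agg$family])
  agg[order(agg$family), c("family", "n_species", paste0("prop_", prop_cols))]
}
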