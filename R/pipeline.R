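#' Build the analyzed trait matrix from species profiles
#'
#' The eight standard nectar traits: the three sugar proportions, the three
#' per-sugar 24 h amounts, the sucrose/hexose ratio, and the total sugar
#' amount. Rows are named by tree tip label ([species_to_tip()]).
#'
#' @param profiles A `nectar_profiles` data.frame.
#' @return Numeric matrix, rows = species (tip labels), 8 columns.
#' @export
trait_matrix <- function(profiles) {
  m <- cbind(
    prop_sucrose = profiles$prop_sucrose,
    prop_glucose = profiles$prop_glucose,
    prop_fructose = profiles$prop_fructose,
    amount_sucrose = profiles$amount_sucrose,
    amount_glucose = profiles$amount_glucose,
    amount_fructose = profiles$amount_fructose,
    sucrose_hexose_ratio = profiles$sucrose_hexose_ratio,
    total_amount = profiles$mean_amount
  )
  rownames(m) <- species_to_tip(profiles$species)
  m
}

#' Run the full comparative analysis
#'
#' Orchestrates the stages end to end: trait summary, pollinator assignment
#' with the rare-group exclusion rule, global and local phylogenetic signal
#' for the eight standard traits, simulation-based phylogenetic
#' MANOVA/ANOVA with Games-Howell post hoc tests, and (optionally) the five
#' evolutionary models over stochastic regime maps with an AICc table.
#'
#' @param traits Path or data.frame for [load_trait_table()].
#' @param taxonomy Path or data.frame for [load_taxonomy()] (optional; needed
#'   for family summaries and the fallback tree).
#' @param tree A `phylo`/path/Newick string, or `NULL` to build the
#'   taxonomy-derived fallback tree.
#' @param assignments Path or data.frame of per-species primary groups, or
#'   `NULL` to skip group analyses; a visitation table is accepted and
#'   converted via [assign_pollinators()].
#' @param min_samples Species inclusion rule (default 3 samples).
#' @param min_group_species Rare-group exclusion rule (default 5 species).
#' @param n_perm,n_sim,n_maps Randomization / simulation sizes.
#' @param seed Integer seed covering every stochastic step.
#' @param do_signal,do_models Stage toggles.
#' @param out_dir If non-`NULL`, CSV tables and a run manifest are written.
#' @return List bundle: `profiles`, `summary`, `family_summary`,
#'   `assignments`, `tree`, `signal`, `local_moran`, `comparisons`,
#'   `model_fits`, `model_table`, `manifest`.
#' @export
run_pipeline <- function(traits, taxonomy = NULL, tree = NULL,
                         assignments = NULL, min_samples = 3,
                         min_group_species = 5, n_perm = 999, n_sim = 1000,
                         n_maps = 10, seed = 1L, do_signal = TRUE,
                         do_models = TRUE, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  profiles <- stage("trait_table", {
    p <- load_trait_table(traits)
    if (inherits(p, "nectar_samples")) p <- summarize_species(p)
    filter_min_samples(p, min_samples)
  })
  summ <- dataset_summary(profiles)
  tax <- if (!is.null(taxonomy)) stage("taxonomy", load_taxonomy(taxonomy)) else NULL
  fam <- if (!is.null(tax)) stage("family_summary", family_summary(profiles, tax)) else NULL
  phy <- stage("phylo_core", {
    t0 <- if (is.null(tree)) {
      if (is.null(tax)) stop("need a tree or a taxonomy for the fallback tree")
      taxonomy_tree(tax)
    } else read_phylogeny(tree)
    t0 <- ape::keep.tip(t0, intersect(t0$tip.label,
                                      species_to_tip(profiles$species)))
    resolve_multichotomies(t0, seed = seed)
  })
  tm <- trait_matrix(profiles)
  tm <- tm[phy$tip.label, , drop = FALSE]

  ass <- NULL
  if (!is.null(assignments)) {
    ass <- stage("pollinator_assignment", {
      a <- if (is.data.frame(assignments) &&
               all(c("species", "primary_group") %in% names(assignments))) {
        load_assignments(assignments)
      } else if (is.character(assignments) && length(assignments) == 1) {
        d <- utils::read.csv(assignments, check.names = FALSE)
        if ("primary_group" %in% names(d)) load_assignments(d) else assign_pollinators(d)
      } else {
        assign_pollinators(assignments)
      }
      exclude_rare_groups(a, min_group_species)
    })
  }

  sig <- loc <- NULL
  if (do_signal) {
    sig <- stage("signal_stats",
                 phylo_signal_table(phy, tm, n_perm = n_perm, seed = seed))
    loc <- stage("local_moran", {
      out <- lapply(colnames(tm), function(tn)
        cbind(trait = tn,
              local_moran_i(phy, stats::setNames(tm[, tn], rownames(tm)),
                            n_perm = n_perm, seed = seed)))
      do.call(rbind, out)
    })
  }

  comparisons <- model_fits <- mt <- NULL
  if (!is.null(ass)) {
    kept <- ass[!ass$excluded & species_to_tip(ass$species) %in% phy$tip.label, ]
    groups <- stats::setNames(kept$primary_group, species_to_tip(kept$species))
    gphy <- ape::keep.tip(phy, names(groups))
    gtm <- tm[gphy$tip.label, , drop = FALSE]
    comparisons <- stage("comparative_tests", list(
      proportions = phylo_manova(
        gphy, gtm[, c("prop_sucrose", "prop_glucose", "prop_fructose")],
        groups, n_sim = n_sim, seed = seed),
      amounts = phylo_manova(
        gphy, gtm[, c("amount_sucrose", "amount_glucose", "amount_fructose")],
        groups, n_sim = n_sim, seed = seed, preprocess = "none"),
      ratio = phylo_anova(gphy, gtm[, "sucrose_hexose_ratio"], groups,
                          n_sim = n_sim, seed = seed),
      total_amount = phylo_anova(gphy, gtm[, "total_amount"], groups,
                                 n_sim = n_sim, seed = seed)
    ))
    if (do_models) {
      model_fits <- stage("evo_models", {
        mk <- fit_mk(gphy, groups)
        maps <- stochastic_map(fit = mk, n_maps = n_maps, seed = seed)
        insect_map <- stats::setNames(
          ifelse(mk$states == "birds", "birds", "insects"), mk$states)
        maps2 <- lapply(maps, collapse_regimes, map = insect_map)
        fits <- lapply(colnames(gtm), function(tn) {
          x <- stats::setNames(gtm[, tn], rownames(gtm))
          list(BM1 = fit_model(gphy, x, "BM1"),
               BMS = fit_model(gphy, x, "BMS", maps),
               OU1 = fit_model(gphy, x, "OU1"),
               `OU-PG(5)` = fit_model(gphy, x, "OUPG", maps),
               `OU-PG(2)` = fit_model(gphy, x, "OUPG", maps2))
        })
        stats::setNames(fits, colnames(gtm))
      })
      mt <- model_table(model_fits)
    }
  }

  manifest <- list(
    seed = seed, min_samples = min_samples,
    min_group_species = min_group_species, n_perm = n_perm, n_sim = n_sim,
    n_maps = n_maps, n_species = summ$n_species,
    total_samples = summ$total_samples, n_tips = length(phy$tip.label),
    stages = c(signal = do_signal, models = do_models && !is.null(ass))
  )
  bundle <- list(profiles = profiles, summary = summ, family_summary = fam,
                 assignments = ass, tree = phy, signal = sig,
                 local_moran = loc, comparisons = comparisons,
                 model_fits = model_fits, model_table = mt,
                 manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(bundle$profiles, "species_profiles.csv")
  wr(bundle$family_summary, "family_summary.csv")
  wr(bundle$assignments, "pollinator_assignments.csv")
  wr(bundle$signal, "signal_table.csv")
  wr(bundle$local_moran, "local_moran.csv")
  wr(bundle$model_table, "model_aicc_table.csv")
  tabs <- render_tables(bundle)
  wr(tabs$species_summary, "table1_species_summary.csv")
  wr(tabs$signal_grid, "table2_signal_grid.csv")
  wr(tabs$aicc_grid, "table3_aicc_grid.csv")
  write_phylogeny(bundle$tree, file.path(out_dir, "analysis_tree.nwk"))
  mf <- bundle$manifest
  writeLines(paste0(names(mf), ": ",
                    vapply(mf, function(v) paste(format(v), collapse = " "),
                           character(1))),
             file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}

#' Render report-style tables from a pipeline bundle
#'
#' Produces the three report grids: a species summary (sample counts,
#' percentages and amounts), a signal-index-by-trait grid with significance
#' stars, and an AICc model-by-trait grid with the best model per trait
#' flagged.
#'
#' @param bundle Result of [run_pipeline()].
#' @return List: `species_summary`, `signal_grid`, `aicc_grid` (grids `NULL`
#'   when the corresponding stage did not run).
#' @export
render_tables <- function(bundle) {
  p <- bundle$profiles
  species_summary <- data.frame(
    species = p$species, n_samples = p$n_samples,
    sucrose_pct = round_half_up(100 * p$prop_sucrose, 1),
    glucose_pct = round_half_up(100 * p$prop_glucose, 1),
    fructose_pct = round_half_up(100 * p$prop_fructose, 1),
    amount_ug = round_half_up(p$mean_amount, 1),
    stringsAsFactors = FALSE)
  signal_grid <- NULL
  if (!is.null(bundle$signal)) {
    s <- bundle$signal
    s$cell <- paste0(formatC(s$statistic, format = "f", digits = 3),
                     ifelse(nzchar(s$stars), paste0(" ", s$stars), ""))
    signal_grid <- stats::reshape(
      s[, c("trait", "method", "cell")], idvar = "trait",
      timevar = "method", direction = "wide")
    names(signal_grid) <- sub("^cell\\.", "", names(signal_grid))
  }
  aicc_grid <- NULL
  if (!is.null(bundle$model_table)) {
    m <- bundle$model_table
    m$cell <- paste0(formatC(m$aicc, format = "f", digits = 2),
                     ifelse(m$best, " *best*", ""))
    aicc_grid <- stats::reshape(
      m[, c("trait", "model", "cell")], idvar = "model",
      timevar = "trait", direction = "wide")
    names(aicc_grid) <- sub("^cell\\.", "", names(aicc_grid))
  }
  list(species_summary = species_summary, signal_grid = signal_grid,
       aicc_grid = aicc_grid)
}
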