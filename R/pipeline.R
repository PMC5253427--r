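#' Configuration for a full pipeline run
#'
#' Bundles the inputs (a genotype table or file, or a `sim_config` to
#' generate one), the resistance surfaces and barrier sets, the behaviour
#' subgroup, stage toggles, permutation counts and seeds for one end-to-end
#' analysis. Validation is a dry run: referenced paths must exist before any
#' computation starts.
#'
#' @param genotypes a `genotype_tbl`, a path, or `NULL` when `sim` is given.
#' @param sim optional `sim_config`; when supplied, genotypes (and, for
#'   resistance-based models, the landscape) are simulated.
#' @param surfaces named list of `resistance_surface` objects or file paths
#'   (names become surface ids, e.g. `RSF`, `PRR`).
#' @param barriers named list of `barrier_set` objects or file paths; names
#'   should be barrier classes.
#' @param subgroup `"all"`, `"migratory"` or `"sedentary"` (behaviour filter
#'   applied before any distance computation; unclassified individuals only
#'   appear in `"all"`).
#' @param stages character vector of stages to run, out of
#'   `c("distances", "genetic", "relatedness", "mantel", "rcm", "distlm",
#'   "bayesass")`.
#' @param n_perm permutations for Mantel/RCM/DISTLM stages.
#' @param mcmc an `mcmc_config` for the migration stage.
#' @param seed master seed, recorded in every output header.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @export
pipeline_config <- function(genotypes = NULL, sim = NULL, surfaces = list(),
                            barriers = list(),
                            subgroup = c("all", "migratory", "sedentary"),
                            stages = c("distances", "genetic", "relatedness",
                                       "mantel", "rcm"),
                            n_perm = 999,
                            mcmc = mcmc_config(n_iter = 50000, burn_in = 10000,
                                               thin = 50, n_chains = 3),
                            seed = 1, out_dir = NULL) {
  subgroup <- match.arg(subgroup)
  known <- c("distances", "genetic", "relatedness", "mantel", "rcm",
             "distlm", "bayesass")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(genotypes) && is.null(sim)) stop("either genotypes or sim required")
  if (is.character(genotypes) && !file.exists(genotypes)) {
    stop("genotype file not found: ", genotypes)
  }
  for (s in surfaces) if (is.character(s) && !file.exists(s)) {
    stop("surface file not found: ", s)
  }
  for (b in barriers) if (is.character(b) && !file.exists(b)) {
    stop("barrier file not found: ", b)
  }
  structure(list(genotypes = genotypes, sim = sim, surfaces = surfaces,
                 barriers = barriers, subgroup = subgroup, stages = stages,
                 n_perm = n_perm, mcmc = mcmc, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full landscape-genetics pipeline
#'
#' Executes the enabled stages in dependency order on the selected behaviour
#' subgroup: genetic distances (a_r, F_ST) and relatedness; geographic,
#' least-cost and barrier distance matrices; the simple-Mantel association
#' table (predictors in the fixed row order IBD, LCP per surface, IBB per
#' barrier class, against both the genetic and the relatedness matrix);
#' reciprocal causal modelling over the distance models; optional DISTLM and
#' migration MCMC. All randomized stages derive their seeds from the master
#' seed, so a rerun with the same configuration is bit-identical. When
#' `out_dir` is set, each table is written as CSV with `# seed:` and
#' `# n_perm:` comment headers, plus a JSON run manifest.
#'
#' @param cfg a `pipeline_config`.
#' @return (invisibly) a named list of results plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  results <- list()
  skipped <- setdiff(c("distances", "genetic", "relatedness", "mantel", "rcm",
                       "distlm", "bayesass"), cfg$stages)
  surfaces <- lapply(cfg$surfaces, function(s)
    if (is.character(s)) read_resistance(s) else s)
  barriers <- lapply(cfg$barriers, function(b)
    if (is.character(b)) read_barriers(b) else b)
  if (!is.null(cfg$sim)) {
    land <- NULL
    if (cfg$sim$migration_model == "resistance_decay" || length(surfaces) == 0) {
      land <- make_landscape(cfg$sim)
      if (length(surfaces) == 0 && !is.null(land$surface)) {
        surfaces <- list(SIM = land$surface)
      }
      if (length(barriers) == 0 && !is.null(land$barriers)) {
        barriers <- list(linear_features = land$barriers)
      }
    }
    simres <- simulate_genotypes(cfg$sim,
      surface = if (!is.null(land)) land$surface else surfaces[[1]])
    g <- simres$genotypes
    results$truth <- simres$truth
  } else {
    g <- if (is.character(cfg$genotypes)) read_genotypes(cfg$genotypes) else cfg$genotypes
  }
  g_all <- g
  g <- filter_subgroup(g, cfg$subgroup)
  if (nrow(g) < 4) stop("subgroup '", cfg$subgroup, "' has fewer than 4 individuals")
  results$genotypes <- g

  dists <- list()
  if ("distances" %in% cfg$stages) {
    dists$IBD <- euclidean_matrix(g, log_transform = TRUE)
    for (sid in names(surfaces)) {
      dists[[paste0("LCP_", sid)]] <- lcp_matrix(g, surfaces[[sid]], surface_id = sid)
    }
    for (bid in names(barriers)) {
      dists[[paste0("IBB_", bid)]] <- barrier_count_matrix(g, barriers[[bid]])
    }
    results$distances <- dists
  }
  if ("genetic" %in% cfg$stages) {
    results$ar <- rousset_ar(g)
    if (length(unique(g$population_id)) >= 2) results$fst <- pairwise_fst(g)
  }
  if ("relatedness" %in% cfg$stages) {
    results$relatedness <- ml_relatedness(g)
  }
  if ("mantel" %in% cfg$stages && length(dists) > 0) {
    responses <- list()
    if (!is.null(results$ar)) responses$a_r <- results$ar
    if (!is.null(results$relatedness)) responses$relatedness <- results$relatedness$matrix
    rows <- list()
    k <- 0
    for (pred in names(dists)) for (resp in names(responses)) {
      k <- k + 1
      mt <- mantel_test(responses[[resp]], dists[[pred]], n_perm = cfg$n_perm,
                        tail = if (resp == "relatedness") "less" else "greater",
                        seed = cfg$seed + k)
      rows[[k]] <- tibble::tibble(predictor = pred, response = resp,
                                  subgroup = cfg$subgroup,
                                  r = mt$r, p.value = mt$p, n = mt$n)
    }
    results$mantel <- dplyr::bind_rows(rows)
  }
  if ("rcm" %in% cfg$stages && length(dists) >= 2 && !is.null(results$ar)) {
    results$rcm <- rcm(results$ar, dists, n_perm = cfg$n_perm,
                       seed = cfg$seed + 1000)
  }
  if ("distlm" %in% cfg$stages && !is.null(results$ar)) {
    preds <- tibble::tibble(unit = g$individual_id, longitude = g$x,
                            latitude = g$y, population = g$population_id)
    results$distlm <- distlm_marginal(results$ar, preds,
                                      groups = list(coordinates = c("longitude", "latitude")),
                                      n_perm = cfg$n_perm, seed = cfg$seed + 2000)
  }
  if ("bayesass" %in% cfg$stages) {
    mcfg <- cfg$mcmc
    mcfg$seed <- mcfg$seed %||% (cfg$seed + 3000)
    results$bayesass <- run_bayesass(g_all, mcfg)
  }

  manifest <- list(
    subgroup = cfg$subgroup, seed = cfg$seed, n_perm = cfg$n_perm,
    stages_run = intersect(cfg$stages, names_run(results)),
    stages_skipped = skipped,
    n_individuals = nrow(g),
    n_loci = length(loci(g)),
    surfaces = names(surfaces), barriers = names(barriers),
    package_version = as.character(utils::packageVersion("landgenr"))
  )
  results$manifest <- manifest

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(seed = cfg$seed, n_perm = cfg$n_perm)
    write_with_header <- function(df, file) {
      con <- file(file.path(cfg$out_dir, file), "w")
      writeLines(paste0("# ", names(hdr), ": ", hdr), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    if (!is.null(results$mantel)) write_with_header(results$mantel, "mantel_table.csv")
    if (!is.null(results$rcm)) {
      write_with_header(tidy(results$rcm), "rcm_cells.csv")
      write_with_header(results$rcm$verdicts, "rcm_verdicts.csv")
    }
    if (!is.null(results$distlm)) write_with_header(results$distlm, "distlm_table.csv")
    if (!is.null(results$bayesass)) {
      write_with_header(tidy(results$bayesass), "migration_table.csv")
    }
    if (!is.null(results$ar)) {
      write_matrix(results$ar, file.path(cfg$out_dir, "ar_matrix.csv"),
                   comments = c(seed = cfg$seed))
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}

names_run <- function(results) {
  map <- c(distances = "distances", ar = "genetic", fst = "genetic",
           relatedness = "relatedness", mantel = "mantel", rcm = "rcm",
           distlm = "distlm", bayesass = "bayesass")
  unique(unname(map[intersect(names(map), names(results))]))
}
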