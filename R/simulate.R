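#' Simulation configuration for the synthetic study generator
#'
#' Defaults emulate the sampling design the pipeline was built for: 8 local
#' populations, 207 diploid individuals genotyped at 14 microsatellite loci
#' with 5-15 alleles each, spatially limited migration over a resistance
#' landscape, and migratory / sedentary / unclassified behaviour labels in
#' the observed proportions 126 : 21 : 60. Centroids default to a ring over
#' the landscape extent; gene flow defaults to a distance-decay kernel.
#'
#' @param n_populations number of local populations.
#' @param n_individuals_per_pop sampled individuals per population (recycled).
#' @param n_loci number of codominant loci.
#' @param n_alleles_per_locus length-2 range; allele counts are drawn
#'   uniformly per locus.
#' @param n_generations forward-time generations of drift + migration.
#' @param pop_sizes simulated diploid sizes N (recycled).
#' @param migration_model `"island"`, `"distance_decay"` or
#'   `"resistance_decay"` (the latter needs a surface for centroid least-cost
#'   distances).
#' @param decay_scale e-folding scale of the migration kernel, in the units
#'   of the relevant distance.
#' @param kernel_shape stretch exponent of the dispersal kernel
#'   `exp(-(d/decay_scale)^kernel_shape)`; 1 is exponential, values below 1
#'   give the fat-tailed kernels reported for wide-ranging ungulates.
#' @param total_immigration total per-generation immigration rate per
#'   population (capped at 1/3 to stay inside the estimator prior).
#' @param true_migration_matrix optional explicit matrix `m[i, j]` = fraction
#'   of population i drawn from population j per generation (diagonal
#'   ignored; off-diagonal row sums must be <= 1/3).
#' @param migrant_sampling if `TRUE`, generations run as pure drift and
#'   migration is applied as individual-level migrant ancestry (first- or
#'   second-generation, the recent-migration model's own data-generating
#'   process) at the final sampling step; requires `true_migration_matrix`.
#' @param behaviour_fraction_migratory,behaviour_fraction_sedentary label
#'   probabilities; the remainder is unclassified.
#' @param sedentary_structured if `TRUE`, a parallel frequency track with
#'   migration scaled by `sedentary_migration_factor` generates sedentary
#'   individuals, giving them stronger spatial genetic structure.
#' @param sedentary_migration_factor see above.
#' @param dirichlet_alpha symmetric Dirichlet parameter for initial allele
#'   frequencies (independently per population and locus).
#' @param shared_initial_freqs if `TRUE`, one initial frequency vector per
#'   locus is shared by all populations (a common ancestral gene pool;
#'   differentiation then accumulates from drift after generation 0), instead
#'   of independent draws per population.
#' @param scatter_sd Gaussian scatter (metres) of individuals around their
#'   population centroid.
#' @param missing_rate per-genotype missing probability.
#' @param extent landscape edge length in metres.
#' @param grid_dim raster rows/cols for `make_landscape()`.
#' @param n_bumps,bump_amplitude,bump_width Gaussian cost bumps of the
#'   landscape generator.
#' @param wall add a high-cost vertical wall with one gap?
#' @param wall_gap_frac vertical position of the wall gap as a fraction of
#'   the landscape height from the bottom (0.5 = mid-height).
#' @param wall_cost,n_barrier_lines wall cost multiplier and number of
#'   barrier polylines emitted with the landscape.
#' @param pop_centroids optional K x 2 matrix of centroids (metres).
#' @param island_m total immigration rate under the island model.
#' @param rng_seed integer seed; identical configs give bit-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 8,
                       n_individuals_per_pop = c(rep(26, 7), 25),
                       n_loci = 14,
                       n_alleles_per_locus = c(5, 15),
                       n_generations = 100,
                       pop_sizes = 100,
                       migration_model = c("distance_decay", "island", "resistance_decay"),
                       decay_scale = 10000,
                       kernel_shape = 1,
                       total_immigration = 1 / 3,
                       true_migration_matrix = NULL,
                       migrant_sampling = FALSE,
                       behaviour_fraction_migratory = 126 / 207,
                       behaviour_fraction_sedentary = 21 / 207,
                       sedentary_structured = FALSE,
                       sedentary_migration_factor = 0.2,
                       dirichlet_alpha = 1,
                       shared_initial_freqs = FALSE,
                       scatter_sd = 1500,
                       missing_rate = 0,
                       extent = 30000,
                       grid_dim = c(50, 50),
                       n_bumps = 6, bump_amplitude = 4, bump_width = 5000,
                       wall = FALSE, wall_cost = 25, wall_gap_frac = 0.5,
                       n_barrier_lines = 0,
                       pop_centroids = NULL,
                       island_m = 0.01,
                       rng_seed = 1) {
  migration_model <- match.arg(migration_model)
  K <- n_populations
  stopifnot(K >= 1, n_loci >= 1, length(n_alleles_per_locus) == 2)
  n_ind <- rep_len(n_individuals_per_pop, K)
  N <- rep_len(pop_sizes, K)
  if (any(N < 2) || any(n_ind < 1)) stop("population sizes must be >= 2, samples >= 1")
  if (behaviour_fraction_migratory + behaviour_fraction_sedentary > 1 + 1e-12) {
    stop("behaviour fractions exceed 1")
  }
  if (is.null(pop_centroids)) {
    ang <- 2 * pi * (seq_len(K) - 1) / max(K, 1)
    pop_centroids <- cbind(extent / 2 + 0.35 * extent * cos(ang),
                           extent / 2 + 0.35 * extent * sin(ang))
  }
  pop_centroids <- as.matrix(pop_centroids)
  stopifnot(nrow(pop_centroids) == K, ncol(pop_centroids) == 2)
  if (!is.null(true_migration_matrix)) {
    tm <- as.matrix(true_migration_matrix)
    stopifnot(nrow(tm) == K, ncol(tm) == K)
    off <- rowSums(tm) - diag(tm)
    if (any(off > 1 / 3 + 1e-9)) {
      stop("off-diagonal row sums of true_migration_matrix must be <= 1/3")
    }
  }
  if (migrant_sampling && is.null(true_migration_matrix)) {
    stop("migrant_sampling requires an explicit true_migration_matrix")
  }
  total_immigration <- min(total_immigration, 1 / 3)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic resistance landscape
#'
#' A base cost of 1 plus deterministic (seeded) Gaussian cost bumps;
#' optionally a high-cost vertical wall with a single gap at mid-height, and
#' vertical barrier polylines for barrier-count analyses. With
#' `n_bumps = 0, wall = FALSE` the surface is uniform cost 1.
#'
#' @param config a `sim_config`.
#' @return list with `surface` (a `resistance_surface`) and `barriers`
#'   (a `barrier_set` or `NULL`).
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  nr <- config$grid_dim[1]; nc <- config$grid_dim[2]
  cs <- config$extent / nc
  vals <- matrix(1, nr, nc)
  if (config$n_bumps > 0) {
    cx <- stats::runif(config$n_bumps, 0, config$extent)
    cy <- stats::runif(config$n_bumps, 0, config$extent)
    amp <- stats::runif(config$n_bumps, 0.3, 1) * config$bump_amplitude
    xs <- (seq_len(nc) - 0.5) * cs
    ys <- (nr - seq_len(nr) + 0.5) * cs
    for (b in seq_len(config$n_bumps)) {
      dx2 <- outer(ys, xs, function(y, x) (x - cx[b])^2 + (y - cy[b])^2)
      vals <- vals + amp[b] * exp(-dx2 / (2 * config$bump_width^2))
    }
  }
  if (config$wall) {
    wc <- round(nc / 2)
    gap <- min(nr, max(1, round(nr * (1 - config$wall_gap_frac))))
    rows <- setdiff(seq_len(nr), gap)
    vals[rows, wc] <- vals[rows, wc] * config$wall_cost
  }
  surface <- resistance_surface(vals, cell_size = cs, origin_x = 0, origin_y = 0)
  barriers <- NULL
  if (config$n_barrier_lines > 0) {
    xs <- config$extent * seq_len(config$n_barrier_lines) /
      (config$n_barrier_lines + 1)
    feats <- lapply(xs, function(x) cbind(c(x, x), c(0, config$extent)))
    barriers <- barrier_set(feats, geometry = "polyline", class = "linear_features")
  }
  list(surface = surface, barriers = barriers)
}

#' Forward-time simulation of genotypes over the landscape
#'
#' Initial allele frequencies are drawn from a symmetric Dirichlet
#' independently per population and locus (so populations start diverged);
#' each generation, migration mixes frequencies (a gene copy in population i
#' descends from population j with probability `m[i, j]`) and drift
#' resamples `2N` gene copies multinomially. The final generation is sampled
#' into diploid individuals (Hardy-Weinberg draws within population), placed
#' by Gaussian scatter around their centroid, and labelled
#' migratory/sedentary/unclassified i.i.d.
#'
#' Under `migrant_sampling = TRUE` the generations are pure drift and the
#' configured migration matrix instead assigns each sampled individual a
#' migrant ancestry (non-migrant, or first-/second-generation migrant from
#' j with probabilities `m_ij` and `2 m_ij m_ii`), drawing its genes from the
#' corresponding source frequencies — the recent-migration estimator's own
#' data model, used for parameter-recovery experiments.
#'
#' @param config a `sim_config`.
#' @param surface optional `resistance_surface`; required when
#'   `migration_model = "resistance_decay"`.
#' @return list with `genotypes` (a `genotype_tbl`) and `truth` (list:
#'   `migration` — the per-generation migration matrix actually applied;
#'   `realized_ancestry` — sampled-individual migrant counts (migrant
#'   sampling mode); `final_freqs` tibble; `individuals` tibble).
#' @export
simulate_genotypes <- function(config, surface = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$migration_model == "resistance_decay" && is.null(surface)) {
    stop("resistance_decay migration requires a resistance surface")
  }
  set.seed(config$rng_seed)
  K <- config$n_populations
  L <- config$n_loci
  N <- rep_len(config$pop_sizes, K)
  nall <- if (config$n_alleles_per_locus[1] == config$n_alleles_per_locus[2]) {
    rep(config$n_alleles_per_locus[1], L)
  } else {
    sample(config$n_alleles_per_locus[1]:config$n_alleles_per_locus[2], L, replace = TRUE)
  }
  m <- migration_matrix_of(config, surface)
  # freqs[[pop]][[locus]] numeric vector
  rdirich <- function(n, alpha) {
    x <- stats::rgamma(n, alpha)
    if (sum(x) == 0) x[1] <- 1
    x / sum(x)
  }
  freqs <- if (isTRUE(config$shared_initial_freqs)) {
    shared <- lapply(seq_len(L), function(l) rdirich(nall[l], config$dirichlet_alpha))
    lapply(seq_len(K), function(i) shared)
  } else {
    lapply(seq_len(K), function(i)
      lapply(seq_len(L), function(l) rdirich(nall[l], config$dirichlet_alpha)))
  }
  freqs_sed <- if (config$sedentary_structured) freqs else NULL
  m_sed <- m
  if (config$sedentary_structured) {
    m_sed[row(m_sed) != col(m_sed)] <- m_sed[row(m_sed) != col(m_sed)] *
      config$sedentary_migration_factor
    diag(m_sed) <- 1 - (rowSums(m_sed) - diag(m_sed))
  }
  mig_applied <- if (config$migrant_sampling) diag(K) else m
  step <- function(fr, mm) {
    lapply(seq_len(K), function(i) {
      lapply(seq_len(L), function(l) {
        p_mix <- Reduce(`+`, lapply(seq_len(K), function(j) mm[i, j] * fr[[j]][[l]]))
        cnt <- stats::rmultinom(1, 2 * N[i], p_mix)
        as.numeric(cnt) / (2 * N[i])
      })
    })
  }
  for (gen in seq_len(config$n_generations)) {
    freqs <- step(freqs, mig_applied)
    if (config$sedentary_structured) freqs_sed <- step(freqs_sed, m_sed)
  }
  # sample individuals
  n_ind <- rep_len(config$n_individuals_per_pop, K)
  pop_of <- rep(seq_len(K), n_ind)
  n_tot <- length(pop_of)
  beh <- sample(c("migratory", "sedentary", "unclassified"), n_tot, replace = TRUE,
                prob = c(config$behaviour_fraction_migratory,
                         config$behaviour_fraction_sedentary,
                         1 - config$behaviour_fraction_migratory -
                           config$behaviour_fraction_sedentary))
  anc_src <- pop_of; anc_gen <- integer(n_tot)
  if (config$migrant_sampling) {
    tm <- as.matrix(config$true_migration_matrix)
    diag(tm) <- 0
    for (ii in seq_len(n_tot)) {
      i <- pop_of[ii]
      if (config$sedentary_structured && beh[ii] == "sedentary") next
      mii <- 1 - sum(tm[i, ])
      pr <- c(none = 1 - sum(tm[i, ] * (1 + 2 * mii)),
              stats::setNames(tm[i, ], paste0("g1_", seq_len(K))),
              stats::setNames(2 * tm[i, ] * mii, paste0("g2_", seq_len(K))))
      pick <- sample(seq_along(pr), 1, prob = pmax(pr, 0))
      if (pick > 1) {
        j <- (pick - 2) %% K + 1
        anc_src[ii] <- j
        anc_gen[ii] <- if (pick <= K + 1) 1L else 2L
      }
    }
  }
  draw_gene <- function(fr_pop, l) sample.int(nall[l], 1, prob = fr_pop[[l]])
  a1 <- matrix(NA_integer_, n_tot, L); a2 <- a1
  for (ii in seq_len(n_tot)) {
    i <- pop_of[ii]
    fr_home <- if (config$sedentary_structured && beh[ii] == "sedentary")
      freqs_sed[[i]] else freqs[[i]]
    for (l in seq_len(L)) {
      if (anc_gen[ii] == 0) {
        a1[ii, l] <- draw_gene(fr_home, l); a2[ii, l] <- draw_gene(fr_home, l)
      } else if (anc_gen[ii] == 1) {
        a1[ii, l] <- draw_gene(freqs[[anc_src[ii]]], l)
        a2[ii, l] <- draw_gene(freqs[[anc_src[ii]]], l)
      } else {
        a1[ii, l] <- draw_gene(freqs[[anc_src[ii]]], l)
        a2[ii, l] <- draw_gene(fr_home, l)
      }
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n_tot * L) < config$missing_rate, n_tot, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  xy <- config$pop_centroids[pop_of, , drop = FALSE] +
    matrix(stats::rnorm(2 * n_tot, 0, config$scatter_sd), ncol = 2)
  xy[, 1] <- pmin(pmax(xy[, 1], 1), config$extent - 1)
  xy[, 2] <- pmin(pmax(xy[, 2], 1), config$extent - 1)
  df <- tibble::tibble(
    individual_id = sprintf("ind_%03d", seq_len(n_tot)),
    population_id = sprintf("pop%d", pop_of),
    du_id = ifelse(pop_of <= ceiling(K / 2), "DU_A", "DU_B"),
    behaviour = beh, x = xy[, 1], y = xy[, 2]
  )
  locus_names <- sprintf("loc%02d", seq_len(L))
  for (l in seq_len(L)) {
    df[[paste0(locus_names[l], "_a1")]] <- a1[, l]
    df[[paste0(locus_names[l], "_a2")]] <- a2[, l]
  }
  g <- genotype_table(df, loci = locus_names)
  ff <- dplyr::bind_rows(lapply(seq_len(K), function(i)
    dplyr::bind_rows(lapply(seq_len(L), function(l)
      tibble::tibble(population = sprintf("pop%d", i), locus = locus_names[l],
                     allele = seq_len(nall[l]), freq = freqs[[i]][[l]])))))
  realized <- NULL
  if (config$migrant_sampling) {
    realized <- matrix(0, K, K)
    for (ii in seq_len(n_tot)) {
      if (anc_gen[ii] > 0) realized[pop_of[ii], anc_src[ii]] <-
          realized[pop_of[ii], anc_src[ii]] + 1
    }
    realized <- realized / n_ind
  }
  truth <- list(
    migration = mig_applied,
    configured_migration = if (!is.null(config$true_migration_matrix))
      as.matrix(config$true_migration_matrix) else m,
    realized_ancestry = realized,
    final_freqs = ff,
    individuals = tibble::tibble(individual_id = df$individual_id,
                                 source_population = sprintf("pop%d", anc_src),
                                 migrant_generation = anc_gen,
                                 behaviour = beh)
  )
  list(genotypes = g, truth = truth)
}

# per-generation migration matrix implied by the config
migration_matrix_of <- function(config, surface = NULL) {
  K <- config$n_populations
  if (!is.null(config$true_migration_matrix)) {
    m <- as.matrix(config$true_migration_matrix)
    diag(m) <- 0
  } else if (config$migration_model == "island") {
    m <- matrix(config$island_m / max(1, K - 1), K, K)
    diag(m) <- 0
  } else {
    d <- if (config$migration_model == "resistance_decay") {
      centroid_lcp(config, surface)
    } else {
      as.matrix(stats::dist(config$pop_centroids))
    }
    w <- exp(-(d / config$decay_scale)^(config$kernel_shape %||% 1))
    diag(w) <- 0
    m <- config$total_immigration * w / pmax(rowSums(w), .Machine$double.eps)
  }
  off <- rowSums(m)
  if (any(off > 1 / 3 + 1e-9) && is.null(config$true_migration_matrix) &&
      config$migration_model == "island") {
    stop("island_m exceeds the 1/3 total-immigration cap")
  }
  diag(m) <- 1 - rowSums(m)
  m
}

centroid_lcp <- function(config, surface) {
  cells <- surface_cell_of(surface, config$pop_centroids[, 1],
                           config$pop_centroids[, 2])
  gr <- surface_graph(surface)
  id <- (cells[, 2] - 1L) * surface$n_rows + cells[, 1]
  dm <- igraph::distances(gr$graph, v = match(id, gr$nodes),
                          to = match(id, gr$nodes), algorithm = "dijkstra")
  dm
}
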