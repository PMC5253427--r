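#' MCMC run plan for the recent-migration estimator
#'
#' Defaults are the full published protocol: three chains of 3,000,000
#' iterations, 1,000,000 burn-in, one sample every 2,000 iterations, and
#' proposal-window widths (deltas) for allele frequencies, inbreeding and
#' migration rate. Desk-scale analyses and the package's own tests use
#' shorter plans via these arguments.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded iterations (must be < `n_iter`).
#' @param thin sampling frequency.
#' @param n_chains independent chains, pooled for summaries.
#' @param delta_p,delta_F,delta_m random-walk proposal widths in (0, 1].
#' @param seed optional integer seed.
#' @export
mcmc_config <- function(n_iter = 3e6, burn_in = 1e6, thin = 2000, n_chains = 3,
                        delta_p = 0.1, delta_F = 0.1, delta_m = 0.05,
                        seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1)
  for (d in c(delta_p, delta_F, delta_m)) {
    if (d <= 0 || d > 1) stop("delta values must lie in (0, 1]")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 delta_p = delta_p, delta_F = delta_F, delta_m = delta_m,
                 seed = seed),
            class = "mcmc_config")
}

#' Bayesian estimation of recent directional migration rates
#'
#' Metropolis-within-Gibbs sampling of the Wilson-Rannala model: each
#' individual carries a latent migrant ancestry (non-migrant, first- or
#' second-generation migrant from each source population), population allele
#' frequencies and inbreeding coefficients are free parameters (so neither
#' Hardy-Weinberg nor migration-drift equilibrium is assumed), and the
#' migration matrix has a uniform prior over the constrained simplex with
#' total immigration per population at most 1/3. `m[i, j]` is the fraction
#' of population i made of recent migrants from population j.
#'
#' Posterior summaries pool thinned post-burn-in samples across chains:
#' means, equal-tailed 95% credible intervals, a qualitative gene-flow class
#' per entry, net emigration per population, and a split R-hat convergence
#' diagnostic on every migration entry (warning above 1.2).
#'
#' @param g a `genotype_tbl` with >= 2 populations.
#' @param cfg an `mcmc_config`.
#' @return a `bayesass_fit`: `mean`, `ci_low`, `ci_high` (K x K, receiving
#'   population in rows, source in columns), `class` (character matrix),
#'   `net_emigration` (named vector), `F_mean`, `acceptance`, `rhat`,
#'   `samples` (pooled draws, one column per m entry), `chains` (per-chain
#'   sample matrices), `populations`, `cfg`.
#' @export
run_bayesass <- function(g, cfg = mcmc_config()) {
  pops <- unique(g$population_id)
  K <- length(pops)
  if (K < 2) stop("need at least 2 populations")
  if (any(table(g$population_id) < 2)) stop("each population needs >= 2 individuals")
  L <- length(loci(g))
  geno <- matrix(-1L, nrow(g), 2 * L)
  nall <- integer(L)
  for (li in seq_len(L)) {
    al <- locus_alleles(g, loci(g)[li])
    lev <- sort(unique(c(al[, 1], al[, 2])))
    lev <- lev[!is.na(lev)]
    nall[li] <- max(length(lev), 1L)
    idx1 <- match(al[, 1], lev) - 1L
    idx2 <- match(al[, 2], lev) - 1L
    geno[, 2 * li - 1] <- ifelse(is.na(idx1), -1L, idx1)
    geno[, 2 * li] <- ifelse(is.na(idx2), -1L, idx2)
  }
  pop_idx <- match(g$population_id, pops) - 1L
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chains <- lapply(seq_len(cfg$n_chains), function(ch) {
    bayesass_chain_cpp(geno, pop_idx, K, nall, cfg$n_iter, cfg$burn_in,
                       cfg$thin, cfg$delta_p, cfg$delta_F, cfg$delta_m)
  })
  m_chains <- lapply(chains, `[[`, "m_samples")
  pooled <- do.call(rbind, m_chains)
  mean_m <- matrix(colMeans(pooled), K, K, byrow = TRUE,
                   dimnames = list(pops, pops))
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  ci_low <- matrix(qs[1, ], K, K, byrow = TRUE, dimnames = list(pops, pops))
  ci_high <- matrix(qs[2, ], K, K, byrow = TRUE, dimnames = list(pops, pops))
  cls <- matrix(NA_character_, K, K, dimnames = list(pops, pops))
  off <- which(row(cls) != col(cls), arr.ind = TRUE)
  cls[off] <- vapply(mean_m[off], classify_gene_flow, character(1))
  rhat <- apply_split_rhat(m_chains, K)
  dimnames(rhat) <- list(pops, pops)
  if (any(rhat[off] > 1.2, na.rm = TRUE)) {
    warning("chains disagree: split R-hat > 1.2 on ",
            sum(rhat[off] > 1.2, na.rm = TRUE), " migration entries")
  }
  acc <- Reduce(`+`, lapply(chains, `[[`, "acceptance")) / length(chains)
  fit <- structure(list(
    mean = mean_m, ci_low = ci_low, ci_high = ci_high, class = cls,
    F_mean = colMeans(do.call(rbind, lapply(chains, `[[`, "F_samples"))),
    acceptance = acc, rhat = rhat, samples = pooled, chains = m_chains,
    populations = pops, cfg = cfg
  ), class = "bayesass_fit")
  fit$net_emigration <- vapply(pops, function(p) net_emigration(fit, p), numeric(1))
  fit
}

# split R-hat per m entry across chains
apply_split_rhat <- function(m_chains, K) {
  out <- matrix(NA_real_, K, K)
  for (e in seq_len(K * K)) {
    halves <- unlist(lapply(m_chains, function(s) {
      x <- s[, e]
      n2 <- floor(length(x) / 2)
      if (n2 < 2) return(list())
      list(x[seq_len(n2)], x[(n2 + 1):(2 * n2)])
    }), recursive = FALSE)
    if (length(halves) < 2) next
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    n <- length(halves[[1]]); mch <- length(halves)
    W <- mean(vars); B <- n * stats::var(means)
    if (W <= 1e-300) { out[((e - 1) %/% K) + 1, ((e - 1) %% K) + 1] <- 1; next }
    vhat <- (n - 1) / n * W + B / n
    out[((e - 1) %/% K) + 1, ((e - 1) %% K) + 1] <- sqrt(vhat / W)
  }
  out
}

#' @export
print.bayesass_fit <- function(x, ...) {
  K <- length(x$populations)
  cat("<bayesass_fit> ", K, " populations, ",
      nrow(x$samples), " pooled posterior draws\n", sep = "")
  cat("posterior mean migration (rows = receiving, cols = source):\n")
  print(round(x$mean, 3))
  cat("max split R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Tidy a migration fit into the directional gene-flow table
#'
#' One row per ordered population pair in the published table layout:
#' `from` (source), `to` (receiving), posterior mean, 95% credible bounds,
#' qualitative class; diagonal entries (the self proportion) carry
#' `self = TRUE`.
#'
#' @param x a `bayesass_fit`.
#' @param ... unused.
#' @method tidy bayesass_fit
#' @export
tidy.bayesass_fit <- function(x, ...) {
  pops <- x$populations
  grid <- expand.grid(to = pops, from = pops, stringsAsFactors = FALSE)
  tibble::tibble(
    from = grid$from, to = grid$to,
    mean = x$mean[cbind(grid$to, grid$from)],
    ci_low = x$ci_low[cbind(grid$to, grid$from)],
    ci_high = x$ci_high[cbind(grid$to, grid$from)],
    class = x$class[cbind(grid$to, grid$from)],
    self = grid$from == grid$to
  )
}

#' @method glance bayesass_fit
#' @export
glance.bayesass_fit <- function(x, ...) {
  off <- row(x$mean) != col(x$mean)
  tibble::tibble(
    n_populations = length(x$populations),
    n_draws = nrow(x$samples),
    max_rhat = max(x$rhat, na.rm = TRUE),
    max_offdiag_m = max(x$mean[off]),
    acc_m = x$acceptance[["m"]],
    acc_F = x$acceptance[["F"]],
    acc_p = x$acceptance[["p"]]
  )
}

#' Posterior mean migration heatmap
#' @param object a `bayesass_fit`.
#' @param ... unused.
#' @method autoplot bayesass_fit
#' @export
autoplot.bayesass_fit <- function(object, ...) {
  df <- tidy.bayesass_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    ggplot2::labs(x = "source population", y = "receiving population",
                  fill = "m") +
    ggplot2::theme_minimal()
}

#' Pilot-tune the MCMC proposal widths
#'
#' Runs short pilot chains and adjusts each delta by bisection until the
#' corresponding proposal family accepts between 40% and 60% of its moves
#' (the published tuning target), for at most `max_rounds` rounds. A delta
#' pinned at its bound with acceptance still outside the window is kept with
#' a warning.
#'
#' @param g a `genotype_tbl`.
#' @param cfg starting `mcmc_config`.
#' @param pilot_iter iterations per pilot run (>= 10,000 recommended).
#' @param max_rounds bisection rounds.
#' @return an `mcmc_config` with tuned deltas and an `acceptance` attribute
#'   from the final pilot.
#' @export
tune_deltas <- function(g, cfg = mcmc_config(), pilot_iter = 10000,
                        max_rounds = 20) {
  deltas <- c(m = cfg$delta_m, F = cfg$delta_F, p = cfg$delta_p)
  lo <- c(m = 0, F = 0, p = 0); hi <- c(m = 1, F = 1, p = 1)
  acc <- NULL
  for (round in seq_len(max_rounds)) {
    pilot <- mcmc_config(n_iter = pilot_iter, burn_in = floor(pilot_iter / 2),
                         thin = max(1, floor(pilot_iter / 100)), n_chains = 1,
                         delta_p = deltas[["p"]], delta_F = deltas[["F"]],
                         delta_m = deltas[["m"]], seed = cfg$seed)
    fit <- suppressWarnings(run_bayesass(g, pilot))
    acc <- fit$acceptance
    in_window <- acc >= 0.40 & acc <= 0.60
    if (all(in_window, na.rm = TRUE)) break
    for (fam in c("m", "F", "p")) {
      a <- acc[[fam]]
      if (is.na(a) || (a >= 0.40 && a <= 0.60)) next
      if (a > 0.60) {        # moves too timid: widen
        lo[fam] <- deltas[fam]
        deltas[fam] <- (deltas[fam] + hi[fam]) / 2
      } else {               # too bold: narrow
        hi[fam] <- deltas[fam]
        deltas[fam] <- (lo[fam] + deltas[fam]) / 2
      }
    }
  }
  out_window <- !(acc >= 0.40 & acc <= 0.60)
  pinned <- abs(deltas - 1) < 1e-6 | deltas < 1e-6
  if (any(out_window & pinned, na.rm = TRUE)) {
    warning("acceptance window unattainable for family ",
            paste(names(deltas)[out_window & pinned], collapse = ", "),
            "; nearest delta kept")
  }
  out <- mcmc_config(n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
                     n_chains = cfg$n_chains, delta_p = deltas[["p"]],
                     delta_F = deltas[["F"]], delta_m = deltas[["m"]],
                     seed = cfg$seed)
  attr(out, "acceptance") <- acc
  out
}

#' Qualitative gene-flow class of a migration rate
#'
#' The published thresholds: `m < 0.030` low, `0.030 <= m <= 0.100` moderate
#' (both boundaries assigned to the moderate class by declared convention),
#' `m > 0.100` high.
#'
#' @param m migration rate in `[0, 1]`.
#' @export
classify_gene_flow <- function(m) {
  if (!is.finite(m) || m < 0 || m > 1) stop("migration rate must lie in [0, 1]")
  if (m < 0.030) "low" else if (m <= 0.100) "moderate" else "high"
}

#' Net emigration of one population
#'
#' Sum of outgoing minus sum of incoming posterior mean gene flow under the
#' `m[i, j]` = "into i from j" convention: outgoing is `sum_i m[i, pop]`,
#' incoming `sum_j m[pop, j]` (off-diagonal only). Net emigration sums to 0
#' over all populations.
#'
#' @param mm a `bayesass_fit` or a plain directional matrix with population
#'   dimnames.
#' @param pop population label.
#' @export
net_emigration <- function(mm, pop) {
  m <- if (inherits(mm, "bayesass_fit")) mm$mean else as.matrix(mm)
  if (!pop %in% rownames(m)) stop("unknown population label: ", pop)
  out <- sum(m[rownames(m) != pop, pop])
  inc <- sum(m[pop, colnames(m) != pop])
  out - inc
}
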