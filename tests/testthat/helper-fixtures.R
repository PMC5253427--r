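# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately coded from first principles (explicit edge lists,
# ANOVA mean squares, closed-form partial correlation, brute-force loops)
# so they stay independent of the package's own implementation paths.

# small genotype table from an allele array: al[ind, locus, slot]
g_from_alleles <- function(al, pop = NULL, x = NULL, y = NULL,
                           behaviour = NULL) {
  n <- dim(al)[1]; L <- dim(al)[2]
  df <- tibble::tibble(
    individual_id = sprintf("i%02d", seq_len(n)),
    population_id = if (is.null(pop)) "p1" else pop,
    x = if (is.null(x)) as.numeric(seq_len(n)) else x,
    y = if (is.null(y)) 0 else y
  )
  if (!is.null(behaviour)) df$behaviour <- behaviour
  for (l in seq_len(L)) {
    df[[sprintf("loc%d_a1", l)]] <- as.integer(al[, l, 1])
    df[[sprintf("loc%d_a2", l)]] <- as.integer(al[, l, 2])
  }
  genotype_table(df)
}

random_genotypes <- function(n = 10, L = 3, n_alleles = 4, n_pops = 2,
                             seed = 1, missing_rate = 0) {
  set.seed(seed)
  al <- array(sample.int(n_alleles, n * L * 2, replace = TRUE), dim = c(n, L, 2))
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    for (l in seq_len(L)) {
      al[drop[, l], l, 1] <- NA
      al[drop[, l], l, 2] <- NA
    }
  }
  pop <- sprintf("p%d", rep_len(seq_len(n_pops), n))
  g_from_alleles(al, pop = pop, x = runif(n, 0, 100), y = runif(n, 0, 100))
}

# --- independent Dijkstra over an explicit edge list -----------------------
# Edges built directly from the raster with the declared 8-connectivity
# convention; plain O(V^2) Dijkstra, no graph library.
dijkstra_oracle <- function(surface, from_cell, to_cell) {
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v); cs <- surface$cell_size
  id <- function(r, c) (c - 1) * nr + r
  nv <- nr * nc
  adj <- vector("list", nv)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(v[r2, c2])) next
      w <- (v[r, c] + v[r2, c2]) / 2 * cs * if (dr != 0 && dc != 0) sqrt(2) else 1
      adj[[id(r, c)]] <- rbind(adj[[id(r, c)]], c(id(r2, c2), w))
    }
  }
  dist <- rep(Inf, nv)
  done <- rep(FALSE, nv)
  s <- id(from_cell[1], from_cell[2])
  t <- id(to_cell[1], to_cell[2])
  dist[s] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    done[u] <- TRUE
    if (u == t) break
    for (k in seq_len(NROW(adj[[u]]))) {
      if (is.null(adj[[u]])) break
      vtx <- adj[[u]][k, 1]; w <- adj[[u]][k, 2]
      if (dist[u] + w < dist[vtx]) dist[vtx] <- dist[u] + w
    }
  }
  dist[t]
}

# --- Weir-Cockerham theta via the gene-level ANOVA mean squares ------------
wc_theta_oracle <- function(g, pair) {
  lociv <- attr(g, "loci")
  A <- 0; ABC <- 0
  for (l in lociv) {
    a1 <- g[[paste0(l, "_a1")]]; a2 <- g[[paste0(l, "_a2")]]
    keep <- g$population_id %in% pair & !is.na(a1)
    if (!any(keep)) next
    pops <- g$population_id[keep]
    x1 <- a1[keep]; x2 <- a2[keep]
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) next
    n_i <- table(factor(pops, levels = pair))
    if (any(n_i < 1)) next
    n_tot <- sum(n_i)
    r <- 2
    n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    for (a in alleles) {
      xcnt <- (x1 == a) + (x2 == a)                      # copies per individual
      p_i <- tapply(xcnt, factor(pops, levels = pair), sum) / (2 * n_i)
      p_bar <- sum(xcnt) / (2 * n_tot)
      het <- (x1 == a) != (x2 == a)
      SSG <- sum(het) / 2
      SSI <- sum((xcnt - 2 * p_i[match(pops, pair)])^2) / 2
      SSP <- 2 * sum(n_i * (p_i - p_bar)^2)
      MSG <- SSG / n_tot
      MSI <- SSI / (n_tot - r)
      MSP <- SSP / (r - 1)
      av <- (MSP - MSI) / (2 * n_c)
      bv <- (MSI - MSG) / 2
      cv <- MSG
      A <- A + av
      ABC <- ABC + av + bv + cv
    }
  }
  A / ABC
}

# --- all permutations of 1..n (for exhaustive Mantel enumeration) ----------
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

mantel_enum_oracle <- function(G, X, tail = "greater") {
  n <- nrow(G)
  gv <- G[lower.tri(G)]
  r_obs <- cor(gv, X[lower.tri(X)])
  rs <- vapply(all_perms(n), function(p) {
    Xp <- X[p, p]
    cor(gv, Xp[lower.tri(Xp)])
  }, numeric(1))
  cnt <- switch(tail,
    greater = sum(rs >= r_obs - 1e-12),
    less = sum(rs <= r_obs + 1e-12),
    two_sided = sum(abs(rs) >= abs(r_obs) - 1e-12))
  list(r = r_obs, p = cnt / length(rs))
}

# --- brute-force segment/feature crossing count ----------------------------
crossing_oracle <- function(p, q, features) {
  cross <- function(a, b, c, d) {
    s1 <- c(b[1] - a[1], b[2] - a[2]); s2 <- c(d[1] - c[1], d[2] - c[2])
    den <- s1[1] * s2[2] - s1[2] * s2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((c[1] - a[1]) * s2[2] - (c[2] - a[2]) * s2[1]) / den
    u <- ((c[1] - a[1]) * s1[2] - (c[2] - a[2]) * s1[1]) / den
    t >= -1e-12 && t <= 1 + 1e-12 && u >= -1e-12 && u <= 1 + 1e-12
  }
  sum(vapply(features, function(f) {
    any(vapply(seq_len(nrow(f) - 1), function(e)
      cross(p, q, f[e, ], f[e + 1, ]), logical(1)))
  }, logical(1)))
}

# island-model simulation wrapper used by several tests
island_fst_mean <- function(K, N, m, n_gen, n_sample, seed,
                            n_loci = 14, alleles = c(5, 15)) {
  cfg <- sim_config(n_populations = K, n_individuals_per_pop = n_sample,
                    n_loci = n_loci, n_alleles_per_locus = alleles,
                    n_generations = n_gen, pop_sizes = N,
                    migration_model = "island", island_m = m,
                    behaviour_fraction_migratory = 0,
                    behaviour_fraction_sedentary = 0,
                    rng_seed = seed)
  sim <- simulate_genotypes(cfg)
  f <- pairwise_fst(sim$genotypes)
  mean(dm_vec(f), na.rm = TRUE)
}

# --- relatedness randomization with both tie-inclusive and tie-randomized p
# (the pair of interest must be individuals 1 and 2 of g)
relatedness_significance_detail <- function(g, freqs, n_rand = 99) {
  lv <- attr(g, "loci")
  sub <- genotype_table(g[1:2, ], loci = lv)
  r_obs <- ml_relatedness(sub, freqs = freqs)$estimates$r_hat[1]
  L <- length(lv)
  P0 <- matrix(NA_real_, n_rand, L); P1 <- P0; P2 <- P0
  for (li in seq_len(L)) {
    f <- freqs[freqs$locus == lv[li], ]
    pfun <- stats::setNames(f$freq, f$allele)
    pa <- function(a) unname(pfun[as.character(a)])
    draws <- matrix(sample(f$allele, 4 * n_rand, replace = TRUE, prob = f$freq),
                    ncol = 4)
    for (b in seq_len(n_rand)) {
      pr <- landgenr:::genotype_pair_probs(draws[b, 1:2], draws[b, 3:4], pa)
      P0[b, li] <- pr[1]; P1[b, li] <- pr[2]; P2[b, li] <- pr[3]
    }
  }
  fit <- landgenr:::ml_k_cpp(P0, P1, P2)
  r_null <- fit[, 2] / 2 + fit[, 3]
  gt <- sum(r_null > r_obs + 1e-12)
  eq <- sum(abs(r_null - r_obs) <= 1e-12)
  p <- (1 + gt + eq) / (n_rand + 1)
  p_rand <- (gt + runif(1) * (1 + eq)) / (n_rand + 1)
  list(p = p, p_rand = p_rand, r_obs = r_obs)
}
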