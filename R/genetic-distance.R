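#' Observed allele frequencies
#'
#' Counts observed alleles per locus, either within each local population or
#' pooled over the whole sample. Missing genotypes are excluded locus-wise
#' (pairwise deletion), so gene counts can differ among loci. A locus with no
#' scored genotype in a group is dropped from the result with a warning;
#' downstream estimators treat it as absent for that group.
#'
#' @param g a `genotype_tbl`.
#' @param by `"population"` or `"pooled"`.
#' @return an `allele_freqs` tibble: `population`, `locus`, `allele`, `count`,
#'   `freq`, `n_genes` (scored gene copies at that locus in that group).
#' @examples
#' g <- genotype_table(tibble::tibble(
#'   individual_id = c("i1", "i2"), population_id = "p1",
#'   loc1_a1 = c(1L, 1L), loc1_a2 = c(1L, 2L)))
#' allele_frequencies(g)            # p1: allele 1 at 0.75, allele 2 at 0.25
#' @export
allele_frequencies <- function(g, by = c("population", "pooled")) {
  by <- match.arg(by)
  groups <- if (by == "pooled") rep("pooled", nrow(g)) else g$population_id
  out <- list()
  for (l in loci(g)) {
    al <- locus_alleles(g, l)
    for (grp in unique(groups)) {
      gen <- al[groups == grp, , drop = FALSE]
      obs <- c(gen[, 1], gen[, 2])
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) {
        warning("locus ", l, " entirely missing in group ", grp, "; excluded")
        next
      }
      tab <- table(obs)
      out[[length(out) + 1]] <- tibble::tibble(
        population = grp, locus = l,
        allele = as.integer(names(tab)),
        count = as.integer(tab),
        freq = as.numeric(tab) / length(obs),
        n_genes = length(obs)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("allele_freqs", class(res))
  attr(res, "by") <- by
  res
}

#' Rousset's a_r genetic distance between individuals
#'
#' The individual-pair analogue of F_ST/(1 - F_ST), built from
#' identity-in-state probabilities. Per locus l, `Q_w(l)` is the probability
#' that the two gene copies within an individual are identical in state,
#' averaged over ALL individuals scored at that locus (sample-wide
#' reference), and `Q_ij(l)` is the mean identity over the four
#' between-individual gene pairs of i and j. Then
#'
#'   a_r(i, j) = sum_l (Q_w(l) - Q_ij(l)) / sum_l (1 - Q_w(l)),
#'
#' both sums running over the loci where BOTH i and j are scored, so the
#' statistic is a ratio over a common locus set. Negative values are
#' reported as computed; the diagonal is 0 by convention.
#'
#' @param g a `genotype_tbl` with at least 2 individuals.
#' @return a `dist_mat` of kind `"genetic_ar"` labelled by individual.
#' @export
rousset_ar <- function(g) {
  n <- nrow(g)
  if (n < 2) stop("need at least 2 individuals")
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  any_locus <- FALSE
  for (l in loci(g)) {
    al <- locus_alleles(g, l)
    scored <- !is.na(al[, 1])
    if (sum(scored) < 1) next
    qw_ind <- as.numeric(al[scored, 1] == al[scored, 2])
    Qw <- mean(qw_ind)
    a1 <- al[, 1]; a2 <- al[, 2]
    # mean identity over the 4 between-individual gene pairs
    Qij <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
            outer(a2, a1, "==") + outer(a2, a2, "==")) / 4
    ok <- outer(scored, scored, "&")
    contrib_num <- (Qw - Qij); contrib_num[!ok] <- 0
    num <- num + contrib_num
    den <- den + ok * (1 - Qw)
    any_locus <- TRUE
  }
  if (!any_locus) stop("no scored loci")
  if (all(den[lower.tri(den)] == 0)) {
    stop("degenerate data: every usable locus has within-individual identity 1 ",
         "(all individuals homozygous for one shared allele)")
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  diag(vals) <- 0
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]  # exact symmetry
  dist_mat(vals, kind = "genetic_ar", labels = g$individual_id)
}

#' Pairwise Weir-Cockerham F_ST between local populations
#'
#' Multi-locus theta for every population pair, combining the standard
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components as a ratio of sums over loci and
#' alleles: theta = sum(a) / sum(a + b + c). Missing genotypes are excluded
#' locus-wise; negative estimates are retained as computed. A pair with no
#' locus scored in both populations gets `NA` with a warning.
#'
#' @param g a `genotype_tbl` with >= 2 populations.
#' @return a `dist_mat` of kind `"fst"` labelled by population.
#' @export
pairwise_fst <- function(g) {
  pops <- unique(g$population_id)
  if (length(pops) < 2) stop("need at least 2 populations")
  K <- length(pops)
  vals <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    sub <- g[g$population_id %in% pops[c(i, j)], , drop = FALSE]
    th <- wc_theta_pair(sub, pops[c(i, j)], loci(g))
    if (is.na(th)) warning("no shared scored locus for pair ", pops[i], "-", pops[j])
    vals[i, j] <- vals[j, i] <- th
  }
  dist_mat(vals, kind = "fst", labels = pops)
}

# Weir & Cockerham (1984) variance components for one population pair,
# summed over loci and alleles; returns theta-hat.
wc_theta_pair <- function(g, pair, locus_names) {
  r <- 2
  A <- 0; ABC <- 0
  used <- FALSE
  for (l in locus_names) {
    al <- cbind(g[[paste0(l, "_a1")]], g[[paste0(l, "_a2")]])
    pop <- g$population_id
    scored <- !is.na(al[, 1])
    n_i <- vapply(pair, function(p) sum(scored & pop == p), numeric(1))
    if (any(n_i < 1)) next
    alleles <- sort(unique(c(al[scored, 1], al[scored, 2])))
    if (length(alleles) < 2) next      # monomorphic locus carries no information
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    if (n_bar <= 1 || n_c <= 0) next
    for (a in alleles) {
      p_i <- vapply(pair, function(p) {
        idx <- scored & pop == p
        mean(c(al[idx, 1], al[idx, 2]) == a)
      }, numeric(1))
      h_i <- vapply(pair, function(p) {
        idx <- scored & pop == p
        mean((al[idx, 1] == a) != (al[idx, 2] == a))
      }, numeric(1))
      p_bar <- sum(n_i * p_i) / (r * n_bar)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / (r * n_bar)
      a_comp <- (n_bar / n_c) *
        (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
      b_comp <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
      c_comp <- h_bar / 2
      A <- A + a_comp
      ABC <- ABC + a_comp + b_comp + c_comp
      used <- TRUE
    }
  }
  if (!used || ABC == 0) return(NA_real_)
  A / ABC
}
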