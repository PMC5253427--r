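#' Maximum-likelihood pairwise relatedness
#'
#' For every pair of individuals, maximises the multilocus likelihood of the
#' IBD-coefficient triple (k0, k1, k2) — the probabilities that the pair
#' shares 0, 1 or 2 genes identical by descent at a locus — over the simplex,
#' using the standard genotype-pair probabilities given pooled allele
#' frequencies. Relatedness is `r_hat = k1/2 + k2`. The genealogical
#' constraint `k1^2 >= 4 k0 k2` is deliberately NOT imposed. Optimisation is
#' a coarse simplex grid (step 0.05) followed by deterministic local
#' refinement, with grid ties broken toward larger k0 (less related).
#'
#' With `null_alleles = TRUE`, a per-locus null allele is appended to the
#' allele set before likelihood evaluation, its frequency estimated from the
#' heterozygote deficit (Brookfield estimator 1,
#' `(He - Ho) / (1 + He)` floored at 0); observed homozygotes are then
#' treated as possibly null-heterozygous through the enlarged frequency set.
#'
#' @param g a `genotype_tbl`.
#' @param freqs pooled `allele_freqs` (computed from `g` if `NULL`).
#' @param null_alleles accommodate null alleles?
#' @return list with `matrix` (a `dist_mat` of kind `"relatedness"`, r_hat
#'   truncated into `[0,1]` only by construction of k) and `estimates` (a
#'   tibble: `id1`, `id2`, `k0`, `k1`, `k2`, `r_hat`, `category`,
#'   `n_loci`).
#' @export
ml_relatedness <- function(g, freqs = NULL, null_alleles = FALSE) {
  if (nrow(g) < 2) stop("need at least 2 individuals")
  if (is.null(freqs)) freqs <- allele_frequencies(g, by = "pooled")
  stopifnot(attr(freqs, "by") == "pooled" || all(freqs$population == "pooled"))
  pl <- pair_locus_probs(g, freqs, null_alleles)
  fit <- ml_k_cpp(pl$P0, pl$P1, pl$P2)
  n <- nrow(g)
  idx <- pl$pairs
  r_hat <- fit[, 2] / 2 + fit[, 3]
  n_loci <- rowSums(!is.na(pl$P0))
  undef <- n_loci == 0
  if (any(undef)) {
    warning(sum(undef), " pair(s) share no scored locus; entries undefined")
    r_hat[undef] <- NA_real_
  }
  vals <- matrix(NA_real_, n, n)
  vals[idx] <- r_hat
  vals[idx[, c(2, 1), drop = FALSE]] <- r_hat
  diag(vals) <- 0
  est <- tibble::tibble(
    id1 = g$individual_id[idx[, 2]], id2 = g$individual_id[idx[, 1]],
    k0 = fit[, 1], k1 = fit[, 2], k2 = fit[, 3],
    r_hat = r_hat,
    category = ifelse(is.na(r_hat), NA_character_,
                      vapply(pmin(pmax(r_hat, 0), 1), categorize_relatedness,
                             character(1))),
    n_loci = n_loci
  )
  list(matrix = dist_mat(vals, kind = "relatedness", labels = g$individual_id),
       estimates = est)
}

# genotype-pair probabilities P(G_i, G_j | 0/1/2 genes IBD) per pair per
# locus, from pooled frequencies; NA where either individual unscored.
pair_locus_probs <- function(g, freqs, null_alleles = FALSE) {
  n <- nrow(g)
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE) # (row=i>j, col=j)
  L <- length(loci(g))
  P0 <- matrix(NA_real_, nrow(pairs), L)
  P1 <- P0; P2 <- P0
  for (li in seq_len(L)) {
    l <- loci(g)[li]
    al <- locus_alleles(g, l)
    f <- freqs[freqs$locus == l, ]
    if (nrow(f) == 0) next
    pfun <- stats::setNames(f$freq, f$allele)
    if (null_alleles) {
      pn <- null_allele_freq(al, pfun)
      if (pn > 0) pfun <- c(pfun * (1 - pn), "null" = pn)
    }
    pa <- function(a) unname(pfun[as.character(a)])
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      gi <- al[i, ]; gj <- al[j, ]
      if (is.na(gi[1]) || is.na(gj[1])) next
      pr <- genotype_pair_probs(gi, gj, pa)
      P0[k, li] <- pr[1]; P1[k, li] <- pr[2]; P2[k, li] <- pr[3]
    }
  }
  list(P0 = P0, P1 = P1, P2 = P2, pairs = pairs)
}

# standard unordered-genotype pair probabilities given 0/1/2 IBD genes
genotype_pair_probs <- function(gi, gj, pa) {
  gi <- sort(gi); gj <- sort(gj)
  a <- gi[1]; b <- gi[2]; c <- gj[1]; d <- gj[2]
  p <- pa
  prob_geno <- function(x) {
    if (x[1] == x[2]) p(x[1])^2 else 2 * p(x[1]) * p(x[2])
  }
  P0 <- prob_geno(gi) * prob_geno(gj)
  same <- identical(gi, gj)
  P2 <- if (same) prob_geno(gi) else 0
  # one shared IBD gene
  if (a == b && c == d) {
    P1 <- if (a == c) p(a)^3 else 0
  } else if (a == b) {            # gi homozygous aa, gj heterozygous cd
    P1 <- if (a == c || a == d) p(a)^2 * p(if (a == c) d else c) else 0
  } else if (c == d) {            # gj homozygous
    P1 <- if (c == a || c == b) p(c)^2 * p(if (c == a) b else a) else 0
  } else {                        # both heterozygous
    shared <- intersect(gi, gj)
    if (length(shared) == 2) {
      P1 <- p(a) * p(b) * (p(a) + p(b))
    } else if (length(shared) == 1) {
      s <- shared
      oth_i <- setdiff(gi, s); oth_j <- setdiff(gj, s)
      P1 <- p(s) * p(oth_i) * p(oth_j)
    } else P1 <- 0
  }
  c(P0, P1, P2)
}

# Brookfield (1996) estimator 1 of a locus null-allele frequency from the
# heterozygote deficit
null_allele_freq <- function(al, pfun) {
  scored <- !is.na(al[, 1])
  if (sum(scored) == 0) return(0)
  Ho <- mean(al[scored, 1] != al[scored, 2])
  He <- 1 - sum(pfun^2)
  max(0, (He - Ho) / (1 + He))
}

#' Translate a relatedness value into the reporting category
#'
#' The printed translation table: exactly 0 is unrelated, (0, 0.25] weakly
#' related, (0.25, 0.5] moderately related, (0.5, 1) highly related, exactly
#' 1 fully related (closed intervals at the printed endpoints: 0.2500 is
#' still weak, 0.2501 moderate).
#'
#' @param r_hat relatedness in `[0, 1]`.
#' @return one of `"unrelated"`, `"weak"`, `"moderate"`, `"high"`, `"full"`.
#' @export
categorize_relatedness <- function(r_hat) {
  if (!is.finite(r_hat) || r_hat < 0 || r_hat > 1) {
    stop("r_hat must lie in [0, 1], got ", r_hat)
  }
  if (r_hat == 0) "unrelated"
  else if (r_hat == 1) "full"
  else if (r_hat <= 0.25) "weak"
  else if (r_hat <= 0.5) "moderate"
  else "high"
}

#' Allele-randomization significance for a pair's relatedness
#'
#' Builds the null distribution of `r_hat` for one pair by independently
#' re-drawing both individuals' alleles from the pooled frequencies
#' (randomizing alleles among individuals, locus structure and missingness
#' pattern preserved) and refitting the ML relatedness each time:
#' `p = (1 + #\{r_null >= r_obs\}) / (n_rand + 1)`.
#'
#' @param g a `genotype_tbl`.
#' @param pair character vector of two `individual_id`s.
#' @param n_rand randomizations (study protocol: 5,000).
#' @param seed optional seed.
#' @param freqs pooled `allele_freqs` (computed if `NULL`).
#' @return list with `r_obs`, `p_value`, `n_rand`.
#' @export
relatedness_significance <- function(g, pair, n_rand = 5000, seed = NULL,
                                     freqs = NULL) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (n_rand < 100) warning("n_rand < 100 gives poor p-value resolution")
  if (is.null(freqs)) freqs <- allele_frequencies(g, by = "pooled")
  ids <- match(pair, g$individual_id)
  if (anyNA(ids)) stop("unknown individual id: ", pair[is.na(ids)][1])
  if (!is.null(seed)) set.seed(seed)
  sub <- g[ids, , drop = FALSE]
  sub <- genotype_table(sub, loci = loci(g))
  obs <- ml_relatedness(sub, freqs = freqs)
  r_obs <- obs$estimates$r_hat[1]
  L <- length(loci(g))
  scored <- !is.na(as.matrix(sub[paste0(loci(g), "_a1")]))
  # draw all null pairs at once, then one C++ call for all fits
  P0 <- matrix(NA_real_, n_rand, L); P1 <- P0; P2 <- P0
  for (li in seq_len(L)) {
    l <- loci(g)[li]
    if (!scored[1, li] || !scored[2, li]) next
    f <- freqs[freqs$locus == l, ]
    pfun <- stats::setNames(f$freq, f$allele)
    draws <- matrix(sample(f$allele, 4 * n_rand, replace = TRUE, prob = f$freq),
                    ncol = 4)
    pa <- function(a) unname(pfun[as.character(a)])
    for (b in seq_len(n_rand)) {
      pr <- genotype_pair_probs(draws[b, 1:2], draws[b, 3:4], pa)
      P0[b, li] <- pr[1]; P1[b, li] <- pr[2]; P2[b, li] <- pr[3]
    }
  }
  fit <- ml_k_cpp(P0, P1, P2)
  r_null <- fit[, 2] / 2 + fit[, 3]
  p <- (1 + sum(r_null >= r_obs - 1e-12, na.rm = TRUE)) / (n_rand + 1)
  list(r_obs = r_obs, p_value = p, n_rand = n_rand)
}
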