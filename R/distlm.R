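#' Gower-centred inner-product matrix of a distance matrix
#'
#' The McArdle-Anderson machinery behind every distance-based linear model:
#' `A = -D^2 / 2`, double-centred as `G = (I - 11'/n) A (I - 11'/n)`. For a
#' Euclidean distance matrix this is the centred inner-product (Gram) matrix
#' of the underlying coordinates; for non-Euclidean genetic distances it may
#' have negative eigenvalues, and the trace arithmetic is used as-is.
#'
#' @param d a `dist_mat` (symmetric, zero diagonal).
#' @return numeric matrix with zero row/column sums.
#' @export
gower_center <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -D^2 / 2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# hat matrix of a design (with intercept already included)
hat_of <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("singular design: collinear columns ",
         paste(colnames(X)[qr_x$pivot[seq_len(ncol(X)) > qr_x$rank]], collapse = ", "))
  }
  Q <- qr.Q(qr_x)
  tcrossprod(Q)
}

# Build the design columns of one predictor (or declared group) from a
# predictor tibble; categoricals are dummy-coded against a first-level
# reference, groups enter as a block.
design_cols <- function(preds, vars) {
  cols <- lapply(vars, function(v) {
    x <- preds[[v]]
    if (is.null(x)) stop("predictor '", v, "' not found")
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2) stop("categorical predictor '", v, "' has < 2 levels")
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(v, levels(f)[-1])
    }
    m
  })
  do.call(cbind, cols)
}

# core pseudo-F given Gower matrix and hat matrices; uses tr(HGH) = sum(G*H)
trHGH <- function(G, H) sum(G * H)

distlm_stat <- function(G, H_full, H_cov = NULL, q_added, n) {
  trG <- sum(diag(G))
  ss_full <- trHGH(G, H_full)
  ss_cov <- if (is.null(H_cov)) 0 else trHGH(G, H_cov)
  q_full <- round(sum(diag(H_full))) - 1       # columns beyond intercept
  resid <- trG - ss_full
  Fstat <- ((ss_full - ss_cov) / q_added) / (resid / (n - q_full - 1))
  pct <- 100 * (ss_full - ss_cov) / trG
  c(F = Fstat, pct = pct)
}

#' Marginal distance-based linear model tests
#'
#' Tests each predictor (or declared multi-column group) alone against a
#' response distance matrix. The pseudo-F is
#' `[tr(HGH)/q] / [tr((I-H)G(I-H))/(n-q-1)]` with `G` the Gower-centred
#' response and `H` the hat matrix of intercept + predictor columns; for a
#' univariate Euclidean response this reduces exactly to the classical
#' regression ANOVA F. The permutation null permutes the unit labels of the
#' response matrix. `% var` is `100 tr(HGH) / tr(G)`.
#'
#' @param d response `dist_mat`.
#' @param preds tibble of predictors, rows aligned with `d`'s labels (a
#'   `unit` column, if present, is matched against the labels).
#' @param groups optional named list of character vectors declaring
#'   multi-column groups (e.g. `list(coordinates = c("x", "y"))`); ungrouped
#'   columns are tested singly.
#' @param n_perm permutations (study protocol: 9,999).
#' @param seed optional seed.
#' @return a `distlm` tibble: `predictor`, `df`, `pseudo_F`, `pct_var`,
#'   `p.value`, `test_type`.
#' @export
distlm_marginal <- function(d, preds, groups = NULL, n_perm = 9999, seed = NULL) {
  pr <- distlm_prepare(d, preds, groups)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(pr$terms, function(vars) {
    X <- cbind(`(Intercept)` = 1, design_cols(pr$preds, vars))
    H <- hat_of(X)
    q <- ncol(X) - 1
    obs <- distlm_stat(pr$G, H, NULL, q, pr$n)
    Fp <- distlm_perm_marginal(pr$G, H, q, pr$n, n_perm)
    tibble::tibble(predictor = paste(vars, collapse = "+"), df = q,
                   pseudo_F = unname(obs["F"]), pct_var = unname(obs["pct"]),
                   p.value = (1 + sum(Fp >= obs["F"] - 1e-12)) / (n_perm + 1),
                   test_type = "marginal")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distlm", class(out))
  out
}

distlm_perm_marginal <- function(G, H, q, n, n_perm) {
  trG <- sum(diag(G))
  vapply(seq_len(n_perm), function(b) {
    pidx <- sample.int(n)
    Gp <- G[pidx, pidx]
    ss <- sum(Gp * H)
    (ss / q) / ((trG - ss) / (n - q - 1))
  }, numeric(1))
}

#' Conditional (covariate-adjusted) distance-based tests
#'
#' Tests the variation added by each predictor over a fixed covariate block
#' (in the study design: the individual coordinates). The added pseudo-F
#' compares `tr(H_full G H_full) - tr(H_cov G H_cov)` against the full-model
#' residual; added `% var` may legitimately be negative. Permutation is of
#' the residual matrix under the reduced (covariate-only) model
#' (Freedman-Lane style): `R = (I - H_cov) G (I - H_cov)` is unit-permuted
#' and the statistic recomputed on it.
#'
#' @inheritParams distlm_marginal
#' @param covariates character vector of covariate column names (always
#'   entered as one block).
#' @export
distlm_conditional <- function(d, preds, covariates, groups = NULL,
                               n_perm = 9999, seed = NULL) {
  pr <- distlm_prepare(d, preds, groups)
  if (!is.null(seed)) set.seed(seed)
  Xc <- cbind(`(Intercept)` = 1, design_cols(pr$preds, covariates))
  Hc <- hat_of(Xc)
  terms <- pr$terms[!vapply(pr$terms, function(v) all(v %in% covariates), logical(1))]
  rows <- lapply(terms, function(vars) {
    X <- cbind(Xc, design_cols(pr$preds, vars))
    H <- hat_of(X)
    q_add <- ncol(X) - ncol(Xc)
    obs <- distlm_stat(pr$G, H, Hc, q_add, pr$n)
    R <- (diag(pr$n) - Hc) %*% pr$G %*% (diag(pr$n) - Hc)
    q_full <- ncol(X) - 1
    Fp <- vapply(seq_len(n_perm), function(b) {
      pidx <- sample.int(pr$n)
      Rp <- R[pidx, pidx]
      ss_f <- sum(Rp * H); ss_c <- sum(Rp * Hc)
      ((ss_f - ss_c) / q_add) / ((sum(diag(Rp)) - ss_f) / (pr$n - q_full - 1))
    }, numeric(1))
    tibble::tibble(predictor = paste(vars, collapse = "+"), df = q_add,
                   pseudo_F = unname(obs["F"]), pct_var = unname(obs["pct"]),
                   p.value = (1 + sum(Fp >= obs["F"] - 1e-12)) / (n_perm + 1),
                   test_type = "conditional")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distlm", class(out))
  out
}

#' Forward-selection distance-based model building
#'
#' Greedy sequential fitting: at each step the predictor/group adding the
#' most explained variation (`tr(HGH)`) enters, with an added pseudo-F and a
#' residual-permutation p-value conditional on the terms already entered.
#' By default every predictor is entered (`enter_all = TRUE`, the shape of
#' the published sequential tables); with `enter_all = FALSE` selection stops
#' when no candidate achieves `p < alpha`.
#'
#' @inheritParams distlm_marginal
#' @param enter_all enter every predictor regardless of significance?
#' @param alpha stopping threshold when `enter_all = FALSE`.
#' @export
distlm_forward <- function(d, preds, groups = NULL, n_perm = 9999, seed = NULL,
                           enter_all = TRUE, alpha = 0.05) {
  pr <- distlm_prepare(d, preds, groups)
  if (!is.null(seed)) set.seed(seed)
  remaining <- pr$terms
  entered_X <- matrix(1, pr$n, 1, dimnames = list(NULL, "(Intercept)"))
  rows <- list()
  while (length(remaining) > 0) {
    Hc <- hat_of(entered_X)
    ss_c_obs <- trHGH(pr$G, Hc)
    gains <- vapply(remaining, function(vars) {
      X <- tryCatch(cbind(entered_X, design_cols(pr$preds, vars)), error = function(e) NULL)
      if (is.null(X)) return(-Inf)
      H <- tryCatch(hat_of(X), error = function(e) NULL)
      if (is.null(H)) return(-Inf)   # collinear with what is already entered
      trHGH(pr$G, H) - ss_c_obs
    }, numeric(1))
    best <- which.max(gains)
    vars <- remaining[[best]]
    Xb <- tryCatch(cbind(entered_X, design_cols(pr$preds, vars)), error = function(e) NULL)
    Hb <- tryCatch(hat_of(Xb), error = function(e) NULL)
    if (is.null(Hb)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        predictor = paste(vars, collapse = "+"), df = NA_integer_,
        pseudo_F = NA_real_, pct_var = 0, p.value = NA_real_,
        test_type = "sequential")
      remaining <- remaining[-best]
      next
    }
    q_add <- ncol(Xb) - ncol(entered_X)
    obs <- distlm_stat(pr$G, Hb, Hc, q_add, pr$n)
    R <- (diag(pr$n) - Hc) %*% pr$G %*% (diag(pr$n) - Hc)
    q_full <- ncol(Xb) - 1
    Fp <- vapply(seq_len(n_perm), function(b) {
      pidx <- sample.int(pr$n)
      Rp <- R[pidx, pidx]
      ss_f <- sum(Rp * Hb); ss_c <- sum(Rp * Hc)
      ((ss_f - ss_c) / q_add) / ((sum(diag(Rp)) - ss_f) / (pr$n - q_full - 1))
    }, numeric(1))
    pval <- (1 + sum(Fp >= obs["F"] - 1e-12)) / (n_perm + 1)
    if (!enter_all && pval >= alpha) break
    rows[[length(rows) + 1]] <- tibble::tibble(
      predictor = paste(vars, collapse = "+"), df = q_add,
      pseudo_F = unname(obs["F"]), pct_var = unname(obs["pct"]), p.value = pval,
      test_type = "sequential")
    entered_X <- Xb
    remaining <- remaining[-best]
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distlm", class(out))
  out
}

#' Population-level tests of size effects on differentiation and dispersal
#'
#' The local-population analysis: effective (`n_effective`, N_e) and census
#' (`n_census`, N_c) sizes tested against pairwise F_ST and the two
#' directional migration matrices M1 (upper-triangle direction) and M2
#' (lower-triangle direction), each converted to a dissimilarity as `1 - m`
#' and symmetrized, marginally and with mean inter-centroid geographic
#' distance as a covariate (F_ST additionally as a covariate for the
#' dispersal responses).
#'
#' @param fst `dist_mat` of kind `"fst"` labelled by population.
#' @param migration a `bayesass_fit` (or a plain directional matrix with
#'   population dimnames) whose two directions become M1/M2 responses; `NULL`
#'   to test F_ST only.
#' @param attrs `population_attributes` tibble.
#' @param n_perm,seed as elsewhere.
#' @return a `distlm` tibble with a `response` column.
#' @export
distlm_population_level <- function(fst, migration = NULL, attrs,
                                    n_perm = 9999, seed = NULL) {
  pops <- dm_labels(fst)
  if (length(pops) < 4) stop("need at least 4 populations for permutational tests")
  attrs <- attrs[match(pops, attrs$population_id), , drop = FALSE]
  if (anyNA(attrs$population_id)) stop("attrs missing populations")
  cen <- as.matrix(stats::dist(cbind(attrs$centroid_x, attrs$centroid_y)))
  dimnames(cen) <- list(pops, pops)
  geo <- dist_mat(cen, kind = "euclidean", labels = pops)
  preds <- tibble::tibble(unit = pops,
                          n_effective = attrs$n_effective,
                          n_census = attrs$n_census,
                          geo_dist = rowMeans(cen))
  responses <- list(fst = fst)
  if (!is.null(migration)) {
    mm <- if (inherits(migration, "bayesass_fit")) migration$mean else as.matrix(migration)
    mm <- mm[pops, pops]
    up <- mm; up[lower.tri(up)] <- t(mm)[lower.tri(mm)]   # direction 1 everywhere
    lo <- t(mm); lo[lower.tri(lo)] <- mm[lower.tri(mm)]   # direction 2
    m1 <- 1 - up; m2 <- 1 - lo
    diag(m1) <- 0; diag(m2) <- 0
    responses$m1 <- dist_mat((m1 + t(m1)) / 2, kind = "other", labels = pops)
    responses$m2 <- dist_mat((m2 + t(m2)) / 2, kind = "other", labels = pops)
  }
  out <- list()
  for (rn in names(responses)) {
    marg <- distlm_marginal(responses[[rn]], preds[c("unit", "n_effective", "n_census")],
                            n_perm = n_perm, seed = seed)
    marg$response <- rn
    cond <- distlm_conditional(responses[[rn]], preds, covariates = "geo_dist",
                               groups = list(n_effective = "n_effective",
                                             n_census = "n_census"),
                               n_perm = n_perm, seed = seed)
    cond$response <- rn
    out[[length(out) + 1]] <- marg
    out[[length(out) + 1]] <- cond
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("distlm", class(res))
  res
}

# shared alignment/validation for the distlm family
distlm_prepare <- function(d, preds, groups) {
  stopifnot(inherits(d, "dist_mat"))
  labs <- dm_labels(d)
  preds <- tibble::as_tibble(preds)
  if ("unit" %in% names(preds)) {
    idx <- match(labs, preds$unit)
    if (anyNA(idx)) stop("predictor table missing units: ",
                         paste(labs[is.na(idx)][1], collapse = ", "))
    preds <- preds[idx, , drop = FALSE]
    preds$unit <- NULL
  } else if (nrow(preds) != length(labs)) {
    stop("predictor rows (", nrow(preds), ") != matrix units (", length(labs), ")")
  }
  cc <- stats::complete.cases(preds)
  if (!all(cc)) {
    message(sum(!cc), " unit(s) dropped for missing predictor values")
    preds <- preds[cc, , drop = FALSE]
    d <- dist_mat(unclass(d)[cc, cc], kind = dm_kind(d), labels = labs[cc])
  }
  vars <- names(preds)
  if (is.null(groups)) groups <- list()
  grouped <- unlist(groups, use.names = FALSE)
  terms <- c(groups, as.list(stats::setNames(setdiff(vars, grouped),
                                             setdiff(vars, grouped))))
  list(G = gower_center(d), preds = preds, n = nrow(preds), terms = terms)
}

#' @method glance distlm
#' @export
glance.distlm <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x),
                 total_pct_var = sum(x$pct_var, na.rm = TRUE),
                 min_p = min(x$p.value, na.rm = TRUE))
}
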