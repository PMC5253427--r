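#' Simple Mantel test between two distance matrices
#'
#' Pearson correlation of the strict lower-triangle vectorizations, with a
#' permutation null obtained by jointly permuting the row/column labels of
#' `x`. The p-value includes the observed statistic:
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)` for `tail = "greater"`
#' (mirrored for `"less"`; `"two_sided"` uses `|r|`), so the smallest
#' attainable p is `1 / (n_perm + 1)`. With `exact = TRUE` (or whenever
#' `factorial(n) <= n_perm`) all `n!` label permutations are enumerated,
#' identity included, and `p = #\{r_perm >= r_obs\} / n!`.
#'
#' Missing entries (e.g. disconnected least-cost pairs) are dropped by
#' pairwise deletion inside every permutation.
#'
#' @param g response `dist_mat` (conventionally the genetic matrix).
#' @param x predictor `dist_mat`, same labels.
#' @param n_perm number of permutations (the study protocol used 100,000).
#' @param tail `"greater"`, `"less"` or `"two_sided"`.
#' @param seed optional integer seed for reproducible permutations.
#' @param exact force full enumeration (n <= 9 only).
#' @return a `mantel_result`: list with `r`, `p`, `n`, `n_perm`, `tail`,
#'   `exact`, `controlled` (NULL here).
#' @export
mantel_test <- function(g, x, n_perm = 100000,
                        tail = c("greater", "less", "two_sided"),
                        seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  al <- align_matrices(g, x)
  G <- unclass(al[[1]]); X <- unclass(al[[2]])
  n <- nrow(G)
  if (n < 4) stop("need at least 4 units for a Mantel test")
  gv <- G[lower.tri(G)]
  xv <- X[lower.tri(X)]
  ok <- !is.na(gv) & !is.na(xv)
  if (stats::var(gv[ok]) == 0 || stats::var(xv[ok]) == 0) {
    stop("degenerate matrix: zero variance in a vectorized matrix")
  }
  r_obs <- stats::cor(gv[ok], xv[ok])
  enum <- exact || (n <= 9 && factorial(n) <= n_perm)
  if (!is.null(seed)) set.seed(seed)
  if (enum) {
    if (n > 9) stop("exact enumeration limited to n <= 9")
    r_perm <- mantel_enum_cpp(X, gv)
    denom <- length(r_perm)
    cnt <- switch(tail,
      greater = sum(r_perm >= r_obs - 1e-12, na.rm = TRUE),
      less = sum(r_perm <= r_obs + 1e-12, na.rm = TRUE),
      two_sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12, na.rm = TRUE))
    p <- cnt / denom
  } else {
    r_perm <- mantel_perm_cpp(X, gv, n_perm)
    cnt <- switch(tail,
      greater = sum(r_perm >= r_obs - 1e-12, na.rm = TRUE),
      less = sum(r_perm <= r_obs + 1e-12, na.rm = TRUE),
      two_sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12, na.rm = TRUE))
    p <- (1 + cnt) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n = n, n_perm = if (enum) length(r_perm) else n_perm,
                 tail = tail, exact = enum, controlled = NULL),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between `g` and `a` after removing the linear effect of the
#' control matrix `c` from both: each lower-triangle vector is residualized
#' on `vec(c)` by simple linear regression, and `r` is the Pearson
#' correlation of the residuals. The permutation null permutes the labels of
#' the residualized predictor matrix (residual-matrix permutation, Legendre's
#' "method 3"), preserving the control structure.
#'
#' @param g response `dist_mat`.
#' @param a predictor `dist_mat` being tested.
#' @param c control `dist_mat` partialled out.
#' @inheritParams mantel_test
#' @return a `mantel_result` with `controlled` naming the control matrix.
#' @export
partial_mantel <- function(g, a, c, n_perm = 100000,
                           tail = c("greater", "less", "two_sided"),
                           seed = NULL) {
  tail <- match.arg(tail)
  al <- align_matrices(g, a, c)
  G <- unclass(al[[1]]); A <- unclass(al[[2]]); C <- unclass(al[[3]])
  n <- nrow(G)
  if (n < 4) stop("need at least 4 units")
  lt <- lower.tri(G)
  gv <- G[lt]; av <- A[lt]; cv <- C[lt]
  ok <- !is.na(gv) & !is.na(av) & !is.na(cv)
  if (stats::var(cv[ok]) == 0) stop("degenerate matrix: zero variance in control")
  if (stats::var(gv[ok]) == 0 || stats::var(av[ok]) == 0) {
    stop("degenerate matrix: zero variance")
  }
  r_ac <- stats::cor(av[ok], cv[ok])
  if (abs(r_ac) >= 1 - 1e-12) {
    stop("collinear control: predictor and control matrices are identical or ",
         "perfectly correlated")
  }
  res_on <- function(yv) {
    fit <- stats::lm.fit(cbind(1, cv[ok]), yv[ok])
    out <- rep(NA_real_, length(yv))
    out[ok] <- fit$residuals
    out
  }
  rg <- res_on(gv); ra <- res_on(av)
  r_obs <- stats::cor(rg[ok], ra[ok])
  # residualized predictor back in matrix form for label permutation
  RA <- matrix(NA_real_, n, n)
  RA[lt] <- ra
  RA <- pmin(RA, t(RA), na.rm = TRUE)  # fill upper triangle symmetrically
  diag(RA) <- 0
  if (!is.null(seed)) set.seed(seed)
  r_perm <- mantel_perm_cpp(RA, rg, n_perm)
  cnt <- switch(tail,
    greater = sum(r_perm >= r_obs - 1e-12, na.rm = TRUE),
    less = sum(r_perm <= r_obs + 1e-12, na.rm = TRUE),
    two_sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12, na.rm = TRUE))
  p <- (1 + cnt) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n = n, n_perm = n_perm, tail = tail,
                 exact = FALSE, controlled = "c"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (is.null(x$controlled)) "Mantel test" else "Partial Mantel test",
      sprintf(": r = %.4f, p = %.5g (%s, %d permutations, n = %d)\n",
              x$r, x$p, x$tail, x$n_perm, x$n))
  invisible(x)
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p, n = x$n, n_perm = x$n_perm,
                 tail = x$tail, partial = !is.null(x$controlled))
}

#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' Reciprocal causal modelling over candidate resistance models
#'
#' For every ordered pair of candidate models, the partial Mantel correlation
#' of the genetic matrix with the principal model, controlling for the
#' alternative: `entry[i, j] = r(G, M_j | M_i)` (columns are principal
#' models, rows alternatives; diagonal 0). A model is *fully supported* when
#' its column is all positive (it retains support against every alternative)
#' and its row is all non-positive (no alternative retains support against
#' it); *partially supported* when only the column condition holds;
#' *unsupported* otherwise. Verdicts use the sign of r; per-cell permutation
#' p-values are reported alongside.
#'
#' @param g response `dist_mat`.
#' @param models named list of candidate `dist_mat` objects (K >= 2).
#' @param n_perm permutations per cell.
#' @param seed optional seed.
#' @return an `rcm_support` object: `support` (K x K matrix of partial r),
#'   `p_values`, `verdicts` tibble.
#' @export
rcm <- function(g, models, n_perm = 1000, seed = NULL) {
  if (length(models) < 2) stop("need at least 2 candidate models")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("M", seq_along(models))
  }
  K <- length(models)
  labs <- names(models)
  if (!is.null(seed)) set.seed(seed)
  supp <- matrix(0, K, K, dimnames = list(alternative = labs, principal = labs))
  pv <- matrix(NA_real_, K, K, dimnames = dimnames(supp))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    res <- tryCatch(
      partial_mantel(g, models[[j]], models[[i]], n_perm = n_perm, tail = "greater"),
      error = function(e) NULL)
    if (is.null(res)) {
      supp[i, j] <- NA_real_
      warning("model pair ", labs[i], "/", labs[j], " collinear; cell undefined")
    } else {
      supp[i, j] <- res$r
      pv[i, j] <- res$p
    }
  }
  verdict <- vapply(seq_len(K), function(j) {
    col_ok <- all(supp[-j, j] > 0, na.rm = FALSE)
    row_ok <- all(supp[j, -j] <= 0, na.rm = FALSE)
    if (isTRUE(col_ok) && isTRUE(row_ok)) "fully_supported"
    else if (isTRUE(col_ok)) "partially_supported"
    else "unsupported"
  }, character(1))
  structure(list(
    support = supp, p_values = pv,
    verdicts = tibble::tibble(model = labs, verdict = verdict),
    n_perm = n_perm
  ), class = "rcm_support")
}

#' @export
print.rcm_support <- function(x, ...) {
  cat("<rcm_support> reciprocal causal modelling,", nrow(x$support), "models\n")
  print(round(x$support, 4))
  print(x$verdicts, n = Inf)
  invisible(x)
}

#' @method tidy rcm_support
#' @export
tidy.rcm_support <- function(x, ...) {
  labs <- rownames(x$support)
  idx <- expand.grid(alternative = labs, principal = labs, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    principal = idx$principal, alternative = idx$alternative,
    r = as.vector(x$support[cbind(match(idx$alternative, labs), match(idx$principal, labs))]),
    p.value = as.vector(x$p_values[cbind(match(idx$alternative, labs), match(idx$principal, labs))])
  )
  out[out$principal != out$alternative, ]
}

#' @method glance rcm_support
#' @export
glance.rcm_support <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$support),
    n_fully_supported = sum(x$verdicts$verdict == "fully_supported"),
    n_perm = x$n_perm
  )
}

#' Heatmap of a reciprocal causal modelling support matrix
#'
#' Columns are principal models, rows alternatives; a fully supported model
#' shows a positive (red) column and non-positive (blue) row.
#'
#' @param object an `rcm_support`.
#' @param ... unused.
#' @method autoplot rcm_support
#' @export
autoplot.rcm_support <- function(object, ...) {
  df <- tidy.rcm_support(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$principal, y = .data$alternative,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "principal model", y = "alternative model",
                  fill = "partial r") +
    ggplot2::theme_minimal()
}
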