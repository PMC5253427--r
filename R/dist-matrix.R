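#' Labelled symmetric pairwise distance matrix
#'
#' `dist_mat` is the exchange format between every stage of the pipeline: a
#' base matrix with row/column labels (individual or population identifiers),
#' a `kind` tag saying what the values measure, and a declared diagonal
#' policy. Genetic (`genetic_ar`, `fst`), relatedness, geographic
#' (`euclidean`, `log_euclidean`), least-cost (`lcp`) and barrier-crossing
#' (`barrier_count`) matrices all share this container so Mantel tests,
#' reciprocal causal modelling and distance-based linear models can consume
#' any of them interchangeably.
#'
#' Invariants enforced at construction:
#' * exact symmetry (`values[i, j] == values[j, i]`);
#' * `euclidean`, `log_euclidean`, `lcp` and `barrier_count` matrices have
#'   non-negative off-diagonal entries (`log_euclidean` is exempt: a log
#'   distance below 1 map unit is legitimately negative);
#' * `relatedness` values lie in `[0, 1]`;
#' * unique labels.
#'
#' Missing (`NA`) off-diagonal entries are allowed and mean "undefined for
#' this pair" (e.g. a disconnected least-cost pair); downstream matrix
#' statistics drop such pairs by pairwise deletion.
#'
#' @param values numeric square matrix (or object coercible to one).
#' @param kind one of `"genetic_ar"`, `"fst"`, `"relatedness"`,
#'   `"euclidean"`, `"log_euclidean"`, `"lcp"`, `"barrier_count"`, `"other"`.
#' @param labels character vector of unit labels; defaults to existing
#'   dimnames, else `"u1"..."un"`.
#' @param diagonal `"zero"` (diagonal forced to 0) or `"undefined"`
#'   (diagonal left as supplied, ignored downstream).
#' @return a `dist_mat` object (a classed matrix).
#' @examples
#' m <- dist_mat(as.matrix(dist(cbind(1:4, 0))), kind = "euclidean")
#' dm_kind(m)
#' @export
dist_mat <- function(values, kind = "other", labels = NULL,
                     diagonal = c("zero", "undefined")) {
  diagonal <- match.arg(diagonal)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("distance matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  kind <- match.arg(kind, dm_kinds())
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("u", seq_len(nrow(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") != matrix dimension (", nrow(values), ")")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  dimnames(values) <- list(labels, labels)
  bad <- which(values != t(values) & !(is.na(values) & is.na(t(values))), arr.ind = TRUE)
  if (length(bad) > 0) {
    stop("matrix is not symmetric at [", labels[bad[1, 1]], ", ", labels[bad[1, 2]], "]")
  }
  if (diagonal == "zero") diag(values) <- 0
  off <- values[row(values) != col(values)]
  if (kind %in% c("euclidean", "lcp", "barrier_count") &&
      any(off < 0, na.rm = TRUE)) {
    stop("kind '", kind, "' requires non-negative off-diagonal values")
  }
  if (kind == "relatedness" && any(off < -1e-9 | off > 1 + 1e-9, na.rm = TRUE)) {
    stop("relatedness values must lie in [0, 1]")
  }
  structure(values, class = c("dist_mat", "matrix", "array"),
            kind = kind, diagonal = diagonal)
}

dm_kinds <- function() {
  c("genetic_ar", "fst", "relatedness", "euclidean", "log_euclidean",
    "lcp", "barrier_count", "other")
}

#' @rdname dist_mat
#' @param m a `dist_mat`.
#' @export
dm_kind <- function(m) attr(m, "kind")

#' @rdname dist_mat
#' @export
dm_labels <- function(m) rownames(m)

#' @export
print.dist_mat <- function(x, ...) {
  cat("<dist_mat> kind =", attr(x, "kind"), " n =", nrow(x), "\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6) cat("... (", nrow(x), "units )\n")
  invisible(x)
}

#' Lower-triangle vectorization of a distance matrix
#'
#' The canonical vectorization used by all Mantel-type statistics: the strict
#' lower triangle in column-major order, diagonal excluded.
#'
#' @param m matrix or `dist_mat`.
#' @return numeric vector of length n(n-1)/2.
#' @export
dm_vec <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

#' Read / write a distance matrix as labelled CSV
#'
#' The CSV carries a header row and a leading label column; comment lines
#' starting with `#` before the header may record the `kind` tag and any
#' provenance (seed, permutation count) and are restored on read. Values are
#' printed with 17 significant digits so a write/read round trip is exact to
#' double precision.
#'
#' @param m a `dist_mat`.
#' @param path file path.
#' @param comments optional named character vector written as `# name: value`
#'   header lines.
#' @return `read_matrix()` returns a validated `dist_mat`; an asymmetric file
#'   is rejected.
#' @export
write_matrix <- function(m, path, comments = NULL) {
  stopifnot(inherits(m, "dist_mat"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", attr(m, "kind")), con)
  writeLines(paste0("# diagonal: ", attr(m, "diagonal")), con)
  if (!is.null(comments)) {
    writeLines(paste0("# ", names(comments), ": ", comments), con)
  }
  labs <- rownames(m)
  writeLines(paste(c("label", labs), collapse = ","), con)
  body <- apply(unclass(m), 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(paste(labs, body, sep = ","), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  labs <- header[-1]
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  if (any(lengths(rows) != length(labs) + 1)) {
    stop("matrix CSV row length does not match header in ", path)
  }
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(labs))))
  row_labs <- vapply(rows, `[`, character(1), 1)
  if (!identical(row_labs, labs)) {
    stop("row labels do not match column labels in ", path)
  }
  if (!isTRUE(all.equal(vals, t(vals), tolerance = 0, check.attributes = FALSE)) &&
      !identical(is.na(vals), is.na(t(vals)))) {
    stop("asymmetric matrix in ", path)
  }
  asym <- which(vals != t(vals), arr.ind = TRUE)
  if (length(asym) > 0) stop("asymmetric matrix in ", path)
  dist_mat(vals, kind = meta$kind %||% "other", labels = labs,
           diagonal = meta$diagonal %||% "zero")
}

#' Tidy a distance matrix into a pair tibble
#'
#' One row per unordered pair (strict lower triangle).
#'
#' @param x a `dist_mat`.
#' @param ... unused.
#' @return tibble with columns `item1`, `item2`, `distance`, `kind`.
#' @method tidy dist_mat
#' @export
tidy.dist_mat <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble::tibble(
    item1 = labs[idx[, 2]],
    item2 = labs[idx[, 1]],
    distance = as.vector(x[idx]),
    kind = attr(x, "kind")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align several distance matrices on their common labels
#'
#' @param ... `dist_mat` objects (optionally named).
#' @return list of matrices restricted to the common labels, common order.
#' @keywords internal
align_matrices <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "dist_mat")) ms <- ms[[1]]
  labs <- Reduce(intersect, lapply(ms, rownames))
  if (length(labs) < 3) stop("fewer than 3 common labels across matrices")
  lapply(ms, function(m) {
    dist_mat(unclass(m)[labs, labs, drop = FALSE], kind = attr(m, "kind"),
             labels = labs, diagonal = attr(m, "diagonal") %||% "zero")
  })
}
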