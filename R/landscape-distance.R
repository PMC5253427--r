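#' Pairwise geographic Euclidean distances
#'
#' Straight-line planar distances between individuals, optionally
#' natural-log-transformed (the isolation-by-distance null model uses log
#' distances). With `log_transform = TRUE` a coincident pair (distance 0) is
#' an error naming the pair; the diagonal of the log matrix is set to 0 by
#' convention and is excluded from all vectorized statistics anyway.
#'
#' @param g a `genotype_tbl` with finite coordinates.
#' @param log_transform log-transform distances?
#' @return a `dist_mat` of kind `"euclidean"` or `"log_euclidean"`.
#' @examples
#' g <- genotype_table(tibble::tibble(
#'   individual_id = c("a", "b"), population_id = "p", x = c(0, 3), y = c(0, 4),
#'   l1_a1 = 1L, l1_a2 = 1L))
#' euclidean_matrix(g)["a", "b"]   # 5
#' @export
euclidean_matrix <- function(g, log_transform = FALSE) {
  g <- genotype_table(g, loci = loci(g), require_coords = TRUE)
  d <- as.matrix(stats::dist(cbind(g$x, g$y)))
  dimnames(d) <- list(g$individual_id, g$individual_id)
  if (log_transform) {
    zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (length(zero) > 0) {
      stop("coincident coordinates for pair ",
           g$individual_id[zero[1, 1]], " / ", g$individual_id[zero[1, 2]],
           "; log transform undefined")
    }
    d <- log(d)
    diag(d) <- 0
    return(dist_mat(d, kind = "log_euclidean", labels = g$individual_id))
  }
  dist_mat(d, kind = "euclidean", labels = g$individual_id)
}

#' Least-cost-path distances over a resistance surface
#'
#' Each individual is snapped to the centre of its raster cell; the raster
#' becomes an 8-connected lattice whose edge weight between adjacent cells a
#' and b is `mean(cost_a, cost_b) * cell_size`, scaled by `sqrt(2)` for
#' diagonal moves; the pairwise cost is the shortest-path total weight
#' (Dijkstra, delegated to igraph). Individuals sharing a cell are at cost 0.
#' No-data cells are excluded from the graph; a pair separated by no-data is
#' returned as `NA` (flagged via the `n_disconnected` attribute) and
#' propagates to Mantel/DISTLM by pairwise deletion.
#'
#' @param g a `genotype_tbl` with finite coordinates.
#' @param s a `resistance_surface`.
#' @param surface_id label stored on the result (e.g. `"RSF"`, `"PRR"`).
#' @return a `dist_mat` of kind `"lcp"` with attributes `surface_id` and
#'   `n_disconnected`.
#' @export
lcp_matrix <- function(g, s, surface_id = "surface") {
  g <- genotype_table(g, loci = loci(g), require_coords = TRUE)
  stopifnot(inherits(s, "resistance_surface"))
  cells <- surface_cell_of(s, g$x, g$y)
  onmask <- is.na(s$values[cells])
  if (any(onmask)) {
    stop("individual ", g$individual_id[which(onmask)[1]], " falls on a no-data cell")
  }
  gr <- surface_graph(s)
  node_id <- function(r, c) (c - 1L) * s$n_rows + r
  vids <- node_id(cells[, 1], cells[, 2])
  uniq <- unique(vids)
  dm <- igraph::distances(gr$graph, v = match(uniq, gr$nodes),
                          to = match(uniq, gr$nodes), algorithm = "dijkstra")
  full <- dm[match(vids, uniq), match(vids, uniq), drop = FALSE]
  full[!is.finite(full)] <- NA
  n_disc <- sum(is.na(full[lower.tri(full)]))
  full <- (full + t(full)) / 2   # symmetrize exactly against fp asymmetry
  diag(full) <- 0
  out <- dist_mat(full, kind = "lcp", labels = g$individual_id)
  attr(out, "surface_id") <- surface_id
  attr(out, "n_disconnected") <- n_disc
  out
}

# 8-connected lattice graph over non-masked cells; nodes indexed
# column-major as (col-1)*n_rows + row.
surface_graph <- function(s) {
  nr <- s$n_rows; nc <- s$n_cols
  ok <- !is.na(s$values)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- list(); weights <- list()
  steps <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  for (k in seq_len(nrow(steps))) {
    dr <- steps[k, 1]; dc <- steps[k, 2]; sc <- steps[k, 3]
    r1 <- pmax(1, 1 - dr):pmin(nr, nr - dr)
    c1 <- pmax(1, 1 - dc):pmin(nc, nc - dc)
    rc <- expand.grid(r = r1, c = c1)
    r2 <- rc$r + dr; c2 <- rc$c + dc
    keep <- ok[cbind(rc$r, rc$c)] & ok[cbind(r2, c2)]
    if (!any(keep)) next
    w <- (s$values[cbind(rc$r, rc$c)[keep, , drop = FALSE]] +
          s$values[cbind(r2, c2)[keep, , drop = FALSE]]) / 2 * s$cell_size * sc
    edges[[k]] <- rbind(id(rc$r[keep], rc$c[keep]), id(r2[keep], c2[keep]))
    weights[[k]] <- w
  }
  nodes <- which(as.vector(ok))
  dummyless <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  emat <- do.call(cbind, edges)
  gidx <- match(as.vector(emat), nodes)
  gr <- igraph::add_edges(dummyless, gidx, weight = unlist(weights))
  list(graph = gr, nodes = nodes)
}

#' Barrier-crossing counts along straight lines
#'
#' For every individual pair, the number of distinct barrier features whose
#' geometry intersects the straight segment between the two sampling
#' locations. Counting is per FEATURE, not per crossing: a winding road cut
#' twice by the segment still counts once. For polygons, touching the
#' boundary or having either endpoint (hence a stretch of the segment) inside
#' counts. Tangent contacts and endpoints lying exactly on a feature count as
#' intersections.
#'
#' @param g a `genotype_tbl` with finite coordinates.
#' @param b a `barrier_set`.
#' @return a `dist_mat` of kind `"barrier_count"`.
#' @export
barrier_count_matrix <- function(g, b) {
  g <- genotype_table(g, loci = loci(g), require_coords = TRUE)
  stopifnot(inherits(b, "barrier_set"))
  n <- nrow(g)
  counts <- matrix(0, n, n)
  fid <- b$feature_id %||% seq_along(b$features)
  pr <- which(lower.tri(counts), arr.ind = TRUE)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    p <- c(g$x[j], g$y[j]); q <- c(g$x[i], g$y[i])
    hit_ids <- unique(fid[vapply(seq_along(b$features), function(f) {
      segment_hits_feature(p, q, b$features[[f]], b$geometry[f])
    }, logical(1))])
    counts[i, j] <- counts[j, i] <- length(hit_ids)
  }
  dist_mat(counts, kind = "barrier_count", labels = g$individual_id)
}

segment_hits_feature <- function(p, q, coords, geometry) {
  closed <- geometry == "polygon"
  nseg <- nrow(coords) - 1L + as.integer(closed)
  for (e in seq_len(nseg)) {
    a <- coords[e, ]
    bb <- coords[if (e == nrow(coords)) 1L else e + 1L, ]
    if (segments_intersect(p, q, a, bb)) return(TRUE)
  }
  if (closed && (point_in_polygon(p, coords) || point_in_polygon(q, coords))) {
    return(TRUE)
  }
  FALSE
}

# Standard orientation-based proper/improper segment intersection;
# collinear overlap and endpoint touches count.
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12 * max(1, abs(b[1] - a[1]) + abs(b[2] - a[2]))) 0 else sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
  (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

point_in_polygon <- function(pt, coords) {
  n <- nrow(coords)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
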