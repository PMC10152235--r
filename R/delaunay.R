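# Bowyer-Watson Delaunay triangulation in the plane.
#
# Plain-R incremental construction: points are inserted one at a time
# into a triangle list kept with cached circumcircles; triangles whose
# circumcircle contains the new point are removed and their boundary
# cavity re-triangulated. Points collinear overall produce no triangles
# (every triangle would touch the enclosing super-triangle and is
# dropped). Intended scale is the few hundred to few thousand immune
# cells of one hotspot component.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of a planar point set
#'
#' @param x,y point coordinates (no duplicates; see [build_graph()] for
#'   deduplication of cell tables).
#' @return Integer matrix with 3 columns, one row per triangle (vertex
#'   indices into `x`/`y`); zero rows when fewer than 3 points or all
#'   points are collinear.
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stop_if(length(y) != n, "'x' and 'y' lengths differ")
  if (n < 3L) return(matrix(integer(0), 0, 3))
  stop_if(anyDuplicated(paste(x, y)) > 0L, "duplicate points")

  # enclosing super-triangle
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1) * 20
  px <- c(x, cx - 3 * span, cx + 3 * span, cx)
  py <- c(y, cy - span, cy - span, cy + 3 * span)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tri <- matrix(c(s1, s2, s3), 1, 3)
  cc <- matrix(circumcircle(px[s1], py[s1], px[s2], py[s2], px[s3], py[s3]),
               1, 3)

  for (i in seq_len(n)) {
    bad <- (px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 < cc[, 3] * (1 + 1e-12)
    bad[is.na(bad)] <- TRUE
    badtri <- tri[bad, , drop = FALSE]
    # cavity boundary: edges of bad triangles that appear exactly once
    e <- rbind(badtri[, c(1, 2)], badtri[, c(2, 3)], badtri[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- names(which(table(key) == 1L))
    keep <- key %in% once
    e <- e[keep, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(e)) {
      newtri <- cbind(e, i)
      newcc <- t(apply(newtri, 1, function(tr)
        circumcircle(px[tr[1]], py[tr[1]], px[tr[2]], py[tr[2]],
                     px[tr[3]], py[tr[3]])))
      tri <- rbind(tri, newtri)
      cc <- rbind(cc, newcc)
    }
  }
  real <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  out <- tri[real, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Edge list of a triangulation
#'
#' @param triangles matrix as returned by [delaunay_triangulate()].
#' @return Two-column integer matrix of unique undirected edges
#'   (`i < j`).
#' @export
triangulation_edges <- function(triangles) {
  if (!nrow(triangles)) return(matrix(integer(0), 0, 2))
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Build the pruned Delaunay interaction graph of one immune hotspot
#'
#' Vertices are the immune cells (six lymphocyte subsets) of one IH
#' component; P40+ neoplastic cells and any non-immune classes are
#' dropped. Cells at exactly duplicated coordinates are collapsed to one
#' vertex (first occurrence's class kept; the multiplicity is recorded).
#' Edges are Delaunay edges; connections exceeding `max_edge_um` are
#' excluded. Fewer than 3 non-collinear vertices yield an empty edge
#' set, flagged via `degenerate`.
#'
#' @param cells data.frame with `x_um`, `y_um`, `class`.
#' @param max_edge_um pruning threshold in micrometres (default 250).
#' @return A `delaunay_graph`: list with `vertices` (data.frame `x_um`,
#'   `y_um`, `class`, `multiplicity`), `edges` (data.frame `i`, `j`,
#'   `length_um`), `n_duplicates_collapsed`, `degenerate`.
#' @export
build_graph <- function(cells, max_edge_um = 250) {
  stop_if(!is.numeric(max_edge_um) || length(max_edge_um) != 1L ||
            is.na(max_edge_um) || max_edge_um <= 0,
          "'max_edge_um' must be a positive number (Inf disables pruning)")
  imm <- cells[cells$class %in% immune_subsets(), , drop = FALSE]
  key <- paste(imm$x_um, imm$y_um)
  first <- !duplicated(key)
  v <- imm[first, c("x_um", "y_um", "class"), drop = FALSE]
  v$multiplicity <- as.integer(table(key)[key[first]])
  rownames(v) <- NULL
  ndup <- nrow(imm) - nrow(v)

  edges <- data.frame(i = integer(0), j = integer(0), length_um = numeric(0))
  degenerate <- FALSE
  if (nrow(v) >= 3L) {
    tri <- delaunay_triangulate(v$x_um, v$y_um)
    if (nrow(tri)) {
      e <- triangulation_edges(tri)
      len <- sqrt((v$x_um[e[, 1]] - v$x_um[e[, 2]])^2 +
                  (v$y_um[e[, 1]] - v$y_um[e[, 2]])^2)
      keep <- len <= max_edge_um
      edges <- data.frame(i = e[keep, 1], j = e[keep, 2],
                          length_um = len[keep])
    } else degenerate <- TRUE
  } else degenerate <- TRUE
  structure(list(vertices = v, edges = edges, max_edge_um = max_edge_um,
                 n_duplicates_collapsed = ndup, degenerate = degenerate),
            class = "delaunay_graph")
}
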