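#' Grid specification for the 50 x 50 um lattice
#'
#' @param x0_um,y0_um lattice origin (lower-left corner of grid (1,1)).
#' @param g_um grid side length in micrometres; 50 by default.
#' @param n_cols,n_rows lattice dimensions.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(x0_um, y0_um, g_um = 50, n_cols, n_rows) {
  structure(list(x0 = check_number(x0_um, "x0_um"),
                 y0 = check_number(y0_um, "y0_um"),
                 g = check_number(g_um, "g_um", 0, strict = TRUE),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param cells cell table with `x_um`, `y_um`.
#' @details `grid_spec_for()` derives a lattice covering a cell table's
#'   bounding box, with the origin floored to a multiple of `g_um` so
#'   that identical inputs always map to the same lattice regardless of
#'   sub-grid translation of the bounding box minimum.
#' @export
grid_spec_for <- function(cells, g_um = 50) {
  stop_if(nrow(cells) == 0L, "cannot derive a grid from an empty cell table")
  stop_if(!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)),
          "cell coordinates must be finite")
  x0 <- floor(min(cells$x_um) / g_um) * g_um
  y0 <- floor(min(cells$y_um) / g_um) * g_um
  grid_spec(x0, y0, g_um,
            n_cols = floor((max(cells$x_um) - x0) / g_um) + 1L,
            n_rows = floor((max(cells$y_um) - y0) / g_um) + 1L)
}

grid_centers <- function(spec) {
  rows <- rep(seq_len(spec$n_rows), spec$n_cols)
  cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  data.frame(row = rows, col = cols,
             x = spec$x0 + (cols - 0.5) * spec$g,
             y = spec$y0 + (rows - 0.5) * spec$g)
}

# half-open binning [x0 + c*g, x0 + (c+1)*g); returns 1-based (row, col)
grid_index <- function(spec, x, y) {
  data.frame(row = floor((y - spec$y0) / spec$g) + 1L,
             col = floor((x - spec$x0) / spec$g) + 1L)
}

#' Rasterize a cell table onto a count lattice
#'
#' Bins every cell into exactly one grid via half-open intervals and
#' accumulates per-channel counts (cancer, lymphocyte) according to
#' `channel_map`. A grid is flagged as tissue iff it contains at least
#' one cell of any class, including classes mapped to `"ignored"`.
#'
#' @param cells cell table (`x_um`, `y_um`, `class`).
#' @param spec a [grid_spec()]; derived from `cells` when missing.
#' @param channel_map named character vector class -> one of
#'   `"cancer"`, `"lymphocyte"`, `"ignored"`; [default_channel_map()] by
#'   default.
#' @return A `count_lattice`: list with `spec`, integer matrices
#'   `cancer` and `lymphocyte`, logical matrix `tissue`.
#' @export
rasterize <- function(cells, spec = grid_spec_for(cells),
                      channel_map = default_channel_map()) {
  stop_if(!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)),
          "cell coordinates must be finite")
  unknown <- setdiff(unique(cells$class), names(channel_map))
  stop_if(length(unknown) > 0,
          "classes missing from channel_map: ", paste(unknown, collapse = ", "))
  idx <- grid_index(spec, cells$x_um, cells$y_um)
  outside <- idx$row < 1L | idx$row > spec$n_rows |
    idx$col < 1L | idx$col > spec$n_cols
  stop_if(any(outside), sprintf("%d cell(s) fall outside the lattice bounds",
                                sum(outside)))
  dims <- c(spec$n_rows, spec$n_cols)
  flat <- idx$row + (idx$col - 1L) * spec$n_rows
  channel <- unname(channel_map[cells$class])
  tab <- function(keep) {
    m <- matrix(0L, dims[1], dims[2])
    if (any(keep)) {
      t <- tabulate(flat[keep], nbins = prod(dims))
      m[] <- t
    }
    m
  }
  tissue <- matrix(tabulate(flat, nbins = prod(dims)) > 0L, dims[1], dims[2])
  structure(list(spec = spec,
                 cancer = tab(channel == "cancer"),
                 lymphocyte = tab(channel == "lymphocyte"),
                 tissue = tissue),
            class = "count_lattice")
}

#' Chebyshev-window neighbor weights
#'
#' Order-1 neighbors of a grid are the (up to) 8 grids sharing an edge or
#' vertex (queen contiguity); order k extends shell by shell, so the
#' order-k neighborhood is all grids within Chebyshev distance k — for an
#' interior grid, a (2k+1) x (2k+1) window. The default order 4 matches
#' the hotspot analysis ("fourth-order neighborhood", a 9 x 9 window).
#'
#' @param spec a [grid_spec()].
#' @param max_order neighborhood order k (>= 1); default 4.
#' @param include_self whether a grid is its own neighbor (the Gi*
#'   convention); default `TRUE`.
#' @return A `neighbor_weights` object with a materialized list of
#'   neighbor grid indices (column-major flat ids) per grid.
#' @export
build_neighbors <- function(spec, max_order = 4L, include_self = TRUE) {
  stop_if(max_order < 1L, "'max_order' must be >= 1")
  k <- as.integer(max_order)
  nr <- spec$n_rows; nc <- spec$n_cols
  off <- expand.grid(dr = -k:k, dc = -k:k)
  if (!include_self) off <- off[off$dr != 0L | off$dc != 0L, ]
  nbr <- vector("list", nr * nc)
  for (col in seq_len(nc)) {
    for (row in seq_len(nr)) {
      rr <- row + off$dr; cc <- col + off$dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nbr[[row + (col - 1L) * nr]] <- sort(rr[ok] + (cc[ok] - 1L) * nr)
    }
  }
  structure(list(spec = spec, max_order = k, include_self = include_self,
                 neighbors = nbr),
            class = "neighbor_weights")
}

# summed-area-table window sum: for each cell, sum of M over the
# (2k+1)x(2k+1) Chebyshev window clipped at the lattice border.
window_sum <- function(M, k) {
  nr <- nrow(M); nc <- ncol(M)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  r <- as.vector(row(M)); c <- as.vector(col(M))
  r1 <- pmax(r - k, 1L); r2 <- pmin(r + k, nr)
  c1 <- pmax(c - k, 1L); c2 <- pmin(c + k, nc)
  res <- I[cbind(r2 + 1L, c2 + 1L)] - I[cbind(r1, c2 + 1L)] -
    I[cbind(r2 + 1L, c1)] + I[cbind(r1, c1)]
  matrix(res, nr, nc)
}

#' Getis-Ord local enrichment statistic
#'
#' Computes, for one channel, the Getis-Ord z score of every tissue grid:
#' \deqn{z_i = \frac{\sum_j W_{ij} C_j - \bar{C} \sum_j W_{ij}}
#'   {S \sqrt{\frac{n \sum_j W_{ij}^2 - (\sum_j W_{ij})^2}{n-1}}}}
#' with binary Chebyshev-window weights, \eqn{\bar{C}} and \eqn{S} the
#' mean and population SD of counts over the \eqn{n} population grids.
#' With `include_self = TRUE` this is the Gi* statistic; with `FALSE`,
#' Gi. P values are one-sided upper-tail normal (enrichment only).
#'
#' By default the statistic's population is restricted to tissue grids:
#' empty background grids are excluded from n, mean, SD and from the
#' neighbor sets, so glass/background does not deflate the reference
#' distribution. Set `population = "all"` to use every grid.
#'
#' @param lattice a [rasterize()] result.
#' @param weights a [build_neighbors()] object (its `max_order` and
#'   `include_self` govern the window).
#' @param channel `"cancer"` or `"lymphocyte"`.
#' @param population `"tissue"` (default) or `"all"`.
#' @return List with matrices `z` and `p` (`NA` off-population or when
#'   the statistic is undefined), plus `n`, `mean`, `sd`.
#' @export
getis_ord <- function(lattice, weights, channel = c("cancer", "lymphocyte"),
                      population = c("tissue", "all")) {
  channel <- match.arg(channel)
  population <- match.arg(population)
  x <- lattice[[channel]]
  pop <- if (population == "tissue") lattice$tissue else
    matrix(TRUE, nrow(x), ncol(x))
  n <- sum(pop)
  stop_if(n < 2L, "need at least 2 population grids")
  k <- weights$max_order
  xm <- x * pop
  xbar <- sum(xm) / n
  S <- sqrt(sum((xm * xm)[pop]) / n - xbar^2)
  LS <- window_sum(xm, k)
  W <- window_sum(pop * 1, k)
  if (!weights$include_self) {
    LS <- LS - xm
    W <- W - pop
  }
  z <- matrix(NA_real_, nrow(x), ncol(x))
  p <- matrix(NA_real_, nrow(x), ncol(x))
  if (S > 0) {
    v <- (n * W - W^2) / (n - 1)
    ok <- pop & v > 0
    z[ok] <- (LS[ok] - xbar * W[ok]) / (S * sqrt(v[ok]))
    p[ok] <- stats::pnorm(z[ok], lower.tail = FALSE)
    # window covering the whole population: no contrast, not a hotspot
    p[pop & v <= 0] <- 1
  } else {
    # zero count variance: statistic undefined everywhere, nothing is
    # significant and the caller labels these grids NONE
    p[pop] <- 1
  }
  list(z = z, p = p, n = n, mean = xbar, sd = S,
       channel = channel, population = population)
}

#' Label tissue compartments from per-channel hotspot p values
#'
#' Applies the compartment rules at significance `alpha` (strict `<`):
#' `CH` if only the cancer channel is enriched, `IH_peri` if only the
#' lymphocyte channel, `IH_intra` if both, otherwise `NONE`. Non-tissue
#' grids are `NONE`.
#'
#' @param gi_cancer,gi_lymph [getis_ord()] results for the two channels.
#' @param tissue logical tissue matrix.
#' @param alpha significance threshold, default 0.05.
#' @return A `hotspot_label_map`: list with matrices `z_cancer`,
#'   `z_lymph`, `p_cancer`, `p_lymph`, character matrix `label`, logical
#'   `tissue`, and `alpha`.
#' @export
label_compartments <- function(gi_cancer, gi_lymph, tissue, alpha = 0.05) {
  pc <- gi_cancer$p; pl <- gi_lymph$p
  sig_c <- !is.na(pc) & pc < alpha
  sig_l <- !is.na(pl) & pl < alpha
  label <- matrix("NONE", nrow(pc), ncol(pc))
  label[tissue & sig_c & !sig_l] <- "CH"
  label[tissue & !sig_c & sig_l] <- "IH_peri"
  label[tissue & sig_c & sig_l] <- "IH_intra"
  structure(list(z_cancer = gi_cancer$z, z_lymph = gi_lymph$z,
                 p_cancer = pc, p_lymph = pl, label = label,
                 tissue = tissue, alpha = alpha),
            class = "hotspot_label_map")
}

#' Map hotspot compartments on a slide
#'
#' Convenience wrapper: rasterize, run [getis_ord()] on both channels
#' and label compartments.
#'
#' @inheritParams rasterize
#' @inheritParams getis_ord
#' @param max_order,include_self,alpha see [build_neighbors()] and
#'   [label_compartments()].
#' @return A `hotspot_label_map` (with the lattice attached as
#'   `$lattice`).
#' @export
hotspot_map <- function(cells, spec = grid_spec_for(cells),
                        channel_map = default_channel_map(),
                        max_order = 4L, include_self = TRUE,
                        alpha = 0.05, population = "tissue") {
  lat <- rasterize(cells, spec, channel_map)
  w <- structure(list(spec = spec, max_order = as.integer(max_order),
                      include_self = include_self, neighbors = NULL),
                 class = "neighbor_weights")
  gc <- getis_ord(lat, w, "cancer", population)
  gl <- getis_ord(lat, w, "lymphocyte", population)
  map <- label_compartments(gc, gl, lat$tissue, alpha)
  map$spec <- spec
  map$lattice <- lat
  map
}

#' Per-slide spatial scores
#'
#' Three unitless fractions summarizing intratumoral immune hotspots
#' (areas counted in grids):
#' \itemize{
#' \item `s_intra_immune = |IH_intra| / (|IH_intra| + |IH_peri|)` —
#'   proportion of the immune-rich area interfacing with tumor;
#' \item `s_intra_cancer = |IH_intra| / (|IH_intra| + |CH|)` — amount of
#'   intratumoral immune aggregates relative to the cancer area;
#' \item `s_intra_tissue = |IH_intra| / |tissue|` — fraction of the whole
#'   tissue that is intratumoral immune hotspot.
#' }
#' A score with a zero denominator is `NA` with the reason recorded.
#'
#' @param map a `hotspot_label_map`.
#' @return A `spatial_scores` list: the three scores plus the grid
#'   counts `n_ih_intra`, `n_ih_peri`, `n_ch`, `n_tissue`, and
#'   `undefined` (named reasons for `NA` scores).
#' @export
spatial_scores <- function(map) {
  n_tissue <- sum(map$tissue)
  stop_if(n_tissue == 0L, "no tissue grids")
  n_intra <- sum(map$label == "IH_intra")
  n_peri <- sum(map$label == "IH_peri")
  n_ch <- sum(map$label == "CH")
  undef <- character(0)
  frac <- function(num, den, what) {
    if (den == 0) {
      undef[[what]] <<- "zero denominator"
      NA_real_
    } else num / den
  }
  structure(list(
    s_intra_immune = frac(n_intra, n_intra + n_peri, "s_intra_immune"),
    s_intra_cancer = frac(n_intra, n_intra + n_ch, "s_intra_cancer"),
    s_intra_tissue = n_intra / n_tissue,
    n_ih_intra = n_intra, n_ih_peri = n_peri, n_ch = n_ch,
    n_tissue = n_tissue, undefined = undef),
    class = "spatial_scores")
}
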