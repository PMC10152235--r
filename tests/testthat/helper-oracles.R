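# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations they check.

# Per-grid loop evaluation of the Getis-Ord statistic straight from the
# formula, with tissue-restricted population and Chebyshev neighbors.
gi_loop_oracle <- function(lattice, channel, k = 4, include_self = TRUE) {
  x <- lattice[[channel]]
  pop <- lattice$tissue
  nr <- nrow(x); nc <- ncol(x)
  n <- sum(pop)
  xbar <- mean(x[pop])
  S <- sqrt(mean(x[pop]^2) - xbar^2)
  z <- matrix(NA_real_, nr, nc)
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    if (!pop[row, col]) next
    Wi <- 0; ls <- 0
    for (dc in -k:k) for (dr in -k:k) {
      if (!include_self && dr == 0 && dc == 0) next
      r <- row + dr; c <- col + dc
      if (r < 1 || r > nr || c < 1 || c > nc || !pop[r, c]) next
      Wi <- Wi + 1; ls <- ls + x[r, c]
    }
    den <- S * sqrt((n * Wi - Wi^2) / (n - 1))
    if (is.finite(den) && den > 0) z[row, col] <- (ls - xbar * Wi) / den
  }
  z
}

# Fixpoint label-propagation connected components (independent of the
# package's stack-based region growth): every masked cell starts with a
# unique label and repeatedly takes the minimum label in its
# neighborhood until nothing changes.
floodfill_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (connectivity == 8) {
    dd <- expand.grid(dr = -1:1, dc = -1:1)
    dd <- dd[!(dd$dr == 0 & dd$dc == 0), ]
  } else {
    dd <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  repeat {
    changed <- FALSE
    for (col in seq_len(nc)) for (row in seq_len(nr)) {
      if (!mask[row, col]) next
      for (q in seq_len(nrow(dd))) {
        r <- row + dd$dr[q]; c <- col + dd$dc[q]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] < lab[row, col]) {
          lab[row, col] <- lab[r, c]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# canonical partition representation: list of sorted member-index sets,
# sorted by first member (label values themselves are arbitrary)
partition_of <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  parts <- lapply(ids, function(i) sort(which(lab == i)))
  parts[order(vapply(parts, min, numeric(1)))]
}

# Brute-force Delaunay edges from the empty-circumcircle definition:
# a triangle belongs to the triangulation iff no other point lies
# strictly inside its circumcircle (general position assumed).
delaunay_oracle_edges <- function(x, y) {
  n <- length(x)
  edges <- NULL
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    d <- 2 * (x[a] * (y[b] - y[cc]) + x[b] * (y[cc] - y[a]) +
                x[cc] * (y[a] - y[b]))
    if (abs(d) < 1e-12) next
    a2 <- x[a]^2 + y[a]^2; b2 <- x[b]^2 + y[b]^2; c2 <- x[cc]^2 + y[cc]^2
    ux <- (a2 * (y[b] - y[cc]) + b2 * (y[cc] - y[a]) + c2 * (y[a] - y[b])) / d
    uy <- (a2 * (x[cc] - x[b]) + b2 * (x[a] - x[cc]) + c2 * (x[b] - x[a])) / d
    r2 <- (ux - x[a])^2 + (uy - y[a])^2
    others <- setdiff(seq_len(n), c(a, b, cc))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 - 1e-12))) {
      edges <- rbind(edges, c(a, b), c(a, cc), c(b, cc))
    }
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

sorted_edges <- function(e) {
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# Two-stage grid search of the univariate logistic log-likelihood,
# refined to a 1e-5 step; independent of glm's IRLS.
logistic_grid_oracle <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0g <- seq(-5, 5, by = 0.1); b1g <- seq(-20, 20, by = 0.1)
  best <- c(0, 0); bestll <- -Inf
  for (b0 in b0g) for (b1 in b1g) {
    v <- ll(b0, b1)
    if (v > bestll) { bestll <- v; best <- c(b0, b1) }
  }
  for (step in c(0.01, 1e-3, 1e-4, 1e-5)) {
    b0g <- best[1] + seq(-10, 10) * step
    b1g <- best[2] + seq(-10, 10) * step
    for (b0 in b0g) for (b1 in b1g) {
      v <- ll(b0, b1)
      if (v > bestll) { bestll <- v; best <- c(b0, b1) }
    }
  }
  best
}

# small mixed-class fixture slide used by several suites
demo_mix <- function() {
  c(CD8 = 0.3, CD4_FOXP3neg = 0.35, CD4_FOXP3pos = 0.1,
    CD20_CXCR5neg = 0.1, CD20_CXCR5pos = 0.1, CD79b = 0.05)
}

demo_slide_config <- function(seed = 7) {
  slide_config(
    2500, 2500,
    tumor_nests = list(tumor_nest(c(700, 700), 400, 0.004)),
    immune_fields = list(
      immune_field("inside_nest", demo_mix(), parent_intensity = 1e-4,
                   offspring_per_parent = 50, offspring_sd_um = 50),
      immune_field("distant", demo_mix(), parent_intensity = 1e-4,
                   offspring_per_parent = 50, offspring_sd_um = 50,
                   center = c(1800, 1800), radius_um = 350)),
    stromal_intensity = 0.0015, seed = seed)
}
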