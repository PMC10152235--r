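#' Fit a 2-D affine transform from landmark pairs
#'
#' Least-squares fit of `fixed ~ A %*% moving + t` over paired
#' landmarks; with exactly three non-collinear pairs the fit
#' interpolates them exactly.
#'
#' @param landmarks data.frame with columns `moving_x`, `moving_y`,
#'   `fixed_x`, `fixed_y` (micrometres).
#' @return An `affine_transform`: list with 2x2 matrix `A` and length-2
#'   vector `t`.
#' @export
fit_affine <- function(landmarks) {
  req <- c("moving_x", "moving_y", "fixed_x", "fixed_y")
  stop_if(!all(req %in% names(landmarks)),
          "landmarks need columns: ", paste(req, collapse = ", "))
  n <- nrow(landmarks)
  stop_if(n < 3L, "at least 3 landmark pairs are required for an affine fit")
  X <- cbind(landmarks$moving_x, landmarks$moving_y, 1)
  stop_if(qr(X)$rank < 3L,
          "landmarks are collinear: the affine fit is underdetermined")
  Y <- cbind(landmarks$fixed_x, landmarks$fixed_y)
  B <- qr.solve(X, Y)                     # 3 x 2: rows = (a1, a2, t)
  structure(list(A = t(B[1:2, , drop = FALSE]), t = as.numeric(B[3, ])),
            class = "affine_transform")
}

#' Apply an affine transform to points
#'
#' @param transform an [fit_affine()] result.
#' @param x,y coordinates, or a cell table via `cells`.
#' @param cells optional data.frame with `x_um`, `y_um`; returned with
#'   coordinates replaced.
#' @return data.frame `x`, `y` (or the transformed `cells`).
#' @export
apply_affine <- function(transform, x, y, cells = NULL) {
  if (!is.null(cells)) {
    out <- apply_affine(transform, cells$x_um, cells$y_um)
    cells$x_um <- out$x; cells$y_um <- out$y
    return(cells)
  }
  P <- cbind(x, y) %*% t(transform$A)
  data.frame(x = P[, 1] + transform$t[1], y = P[, 2] + transform$t[2])
}

#' Target registration error
#'
#' Mean distance between transformed moving landmarks and their fixed
#' partners, normalized by the fixed frame's image diagonal and reported
#' as a percentage. By default the same landmarks used for fitting are
#' evaluated (matching how a single averaged error is usually reported);
#' pass held-out pairs for an out-of-sample error.
#'
#' @param transform an [fit_affine()] result.
#' @param landmarks landmark pairs as in [fit_affine()].
#' @param diagonal_um fixed-frame image diagonal (> 0).
#' @return TRE as a percentage of the diagonal.
#' @export
registration_error <- function(transform, landmarks, diagonal_um) {
  check_number(diagonal_um, "diagonal_um", 0, strict = TRUE)
  pred <- apply_affine(transform, landmarks$moving_x, landmarks$moving_y)
  resid <- sqrt((pred$x - landmarks$fixed_x)^2 + (pred$y - landmarks$fixed_y)^2)
  100 * mean(resid) / diagonal_um
}

#' Cross-modality density concordance
#'
#' Pearson correlation of per-grid cell densities between two cell
#' tables mapped to the same frame (e.g. H&E vs IHC after
#' registration), over grids that are tissue in either table.
#'
#' @param cells_a,cells_b cell tables in the fixed frame.
#' @param spec a shared [grid_spec()].
#' @return List with `r`, `p`, `n_grids`.
#' @export
density_concordance <- function(cells_a, cells_b, spec) {
  map_all <- function(cells) {
    cm <- stats::setNames(rep("ignored", length(unique(cells$class))),
                          unique(cells$class))
    rasterize(cells, spec, cm)
  }
  la <- map_all(cells_a); lb <- map_all(cells_b)
  use <- la$tissue | lb$tissue
  stop_if(sum(use) < 3L, "need at least 3 occupied grids")
  da <- tabulate_counts(cells_a, spec)[use]
  db <- tabulate_counts(cells_b, spec)[use]
  ct <- stats::cor.test(da, db, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_grids = sum(use))
}

tabulate_counts <- function(cells, spec) {
  idx <- grid_index(spec, cells$x_um, cells$y_um)
  flat <- idx$row + (idx$col - 1L) * spec$n_rows
  matrix(tabulate(flat, nbins = spec$n_rows * spec$n_cols),
         spec$n_rows, spec$n_cols)
}
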