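#' Segment individual immune hotspots by connectivity
#'
#' Individual immune hotspots (IH) are connected clusters of grids built
#' on the union of `IH_peri` and `IH_intra` labels: each IH is first
#' segregated and indexed regardless of its peri/intra make-up, then its
#' grids retain their compartment sub-labels, so a single IH may span
#' both categories. Connectivity is 8-directional (queen) by default.
#'
#' @param map a `hotspot_label_map`.
#' @param connectivity 8 (default) or 4.
#' @param exclude logical matrix of grids to remove before segmentation
#'   (e.g. a TLS/LAG mask), or `NULL`.
#' @return List of `ih_component` entries: `id`, `grids` (data.frame
#'   `row`, `col`, `label`), `n_grids`, `n_intra`, `n_peri`.
#' @export
connected_components <- function(map, connectivity = 8, exclude = NULL) {
  stop_if(!connectivity %in% c(4, 8), "'connectivity' must be 4 or 8")
  mask <- map$label %in% c("IH_peri", "IH_intra")
  mask <- matrix(mask, nrow(map$label), ncol(map$label))
  if (!is.null(exclude)) mask[exclude] <- FALSE
  lab <- label_mask(mask, connectivity)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  lapply(seq_along(ids), function(i) {
    w <- which(lab == ids[i], arr.ind = TRUE)
    grids <- data.frame(row = w[, 1], col = w[, 2],
                        label = map$label[w])
    structure(list(id = i, grids = grids, n_grids = nrow(grids),
                   n_intra = sum(grids$label == "IH_intra"),
                   n_peri = sum(grids$label == "IH_peri")),
              class = "ih_component")
  })
}

# Two-pass style labeling via iterative stack-based region growth.
# Returns an integer matrix: 0 = background, 1..K component ids in
# row-major discovery order (the partition itself is scan-order
# invariant).
label_mask <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextid <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextid <- nextid + 1L
    stack <- start
    lab[start] <- nextid
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- rr[ok] + (cc[ok] - 1L) * nr
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nextid
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Rasterize an annotation polygon to a grid mask
#'
#' A grid belongs to the mask iff its center falls inside the polygon
#' (even-odd rule). Annotation area outside the lattice is ignored.
#'
#' @param polygon two-column matrix of vertex coordinates in micrometres.
#' @param spec a [grid_spec()].
#' @return Logical matrix (`n_rows` x `n_cols`).
#' @export
rasterize_polygon <- function(polygon, spec) {
  ctr <- grid_centers(spec)
  matrix(point_in_polygon(ctr$x, ctr$y, polygon), spec$n_rows, spec$n_cols)
}

annotation_masks <- function(annotations, spec) {
  masks <- lapply(annotations, function(a) rasterize_polygon(a$polygon, spec))
  combined <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (m in masks) combined <- combined | m
  list(each = masks, combined = combined)
}

#' Segment IH components with TLS/LAG regions excluded
#'
#' Grids inside any annotated TLS/LAG polygon are removed from the
#' IH mask before components are segmented (connectivity is recomputed
#' after exclusion, so an annotation can split one IH into several).
#'
#' @param map a `hotspot_label_map` (with `$spec`).
#' @param annotations list of annotations: each `list(id, kind, polygon)`
#'   with `kind` in `TLS`/`LAG` (see [read_annotations()]).
#' @param connectivity 8 (default) or 4.
#' @return List with `components` (as [connected_components()]),
#'   `excluded_ih_grids` (count of IH grids removed) and `exclude_mask`.
#' @export
exclude_annotated <- function(map, annotations, connectivity = 8) {
  stop_if(is.null(map$spec), "map must carry its grid_spec")
  am <- annotation_masks(annotations, map$spec)
  ih <- map$label %in% c("IH_peri", "IH_intra")
  ih <- matrix(ih, nrow(map$label), ncol(map$label))
  list(components = connected_components(map, connectivity, exclude = am$combined),
       excluded_ih_grids = sum(ih & am$combined),
       exclude_mask = am$combined)
}

#' Assign a TLS/LAG structure to a compartment by majority area
#'
#' The structure's grid mask is intersected with the label map; the
#' compartment covering the largest number of its tissue grids wins. An
#' exact tie between the peritumoral and intratumoral IH compartments is
#' resolved to `IH_intra`; remaining ties favor `IH_peri` over `CH` over
#' `NONE`. A structure overlapping no tissue grid is `NONE`.
#'
#' @param annotation one annotation (`list(id, kind, polygon)`).
#' @param map a `hotspot_label_map` with `$spec`.
#' @return Character scalar compartment.
#' @export
assign_structure_compartment <- function(annotation, map) {
  mask <- rasterize_polygon(annotation$polygon, map$spec)
  labs <- map$label[mask & map$tissue]
  if (!length(labs)) return("NONE")
  counts <- c(IH_intra = sum(labs == "IH_intra"),
              IH_peri = sum(labs == "IH_peri"),
              CH = sum(labs == "CH"),
              NONE = sum(labs == "NONE"))
  # which.max on the precedence-ordered vector implements the tie rules
  names(counts)[which.max(counts)]
}

#' Attach member cells to IH components
#'
#' A cell belongs to a component iff its containing grid is a member
#' grid; cells in excluded (annotated) grids are dropped. The cell's
#' peri/intra sub-compartment is the label of its containing grid.
#'
#' @param components output of [connected_components()].
#' @param cells cell table (`x_um`, `y_um`, `class`).
#' @param spec the [grid_spec()] the map was built on.
#' @return The components, each gaining `cells` (data.frame with an
#'   added `compartment` column).
#' @export
assign_cells_to_components <- function(components, cells, spec) {
  if (!length(components)) return(components)
  idx <- grid_index(spec, cells$x_um, cells$y_um)
  flat <- idx$row + (idx$col - 1L) * spec$n_rows
  inb <- idx$row >= 1L & idx$row <= spec$n_rows &
    idx$col >= 1L & idx$col <= spec$n_cols
  owner <- rep(NA_integer_, prod(spec$n_rows, spec$n_cols))
  glabel <- rep(NA_character_, length(owner))
  for (comp in components) {
    f <- comp$grids$row + (comp$grids$col - 1L) * spec$n_rows
    owner[f] <- comp$id
    glabel[f] <- comp$grids$label
  }
  for (i in seq_along(components)) {
    sel <- inb & !is.na(owner[flat]) & owner[flat] == components[[i]]$id
    memb <- cells[sel, , drop = FALSE]
    memb$compartment <- glabel[flat[sel]]
    rownames(memb) <- NULL
    components[[i]]$cells <- memb
  }
  components
}
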