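#' Read and validate a cell table CSV
#'
#' Expects columns `cell_id`, `x_um`, `y_um`, `class` (extra columns are
#' kept). Unknown class labels and non-numeric coordinates are rejected
#' with the offending rows named.
#'
#' @param path CSV file path.
#' @param vocabulary allowed class labels; by default the union of the
#'   H&E and IHC vocabularies.
#' @return Validated cell table data.frame.
#' @export
read_cell_table <- function(path,
                            vocabulary = c(he_classes(), ihc_classes())) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(nrow(df) == 0L, "empty cell table: ", path)
  req <- c("cell_id", "x_um", "y_um", "class")
  missing <- setdiff(req, names(df))
  stop_if(length(missing) > 0,
          "missing columns: ", paste(missing, collapse = ", "))
  bad_xy <- which(!is.finite(suppressWarnings(as.numeric(df$x_um))) |
                  !is.finite(suppressWarnings(as.numeric(df$y_um))))
  stop_if(length(bad_xy) > 0, "non-numeric coordinates at rows: ",
          paste(utils::head(bad_xy, 10), collapse = ", "))
  df$x_um <- as.numeric(df$x_um); df$y_um <- as.numeric(df$y_um)
  bad_cls <- which(!df$class %in% vocabulary)
  stop_if(length(bad_cls) > 0,
          sprintf("unknown class label(s) %s at row(s) %s",
                  paste(unique(df$class[bad_cls]), collapse = ", "),
                  paste(utils::head(bad_cls, 10), collapse = ", ")))
  df
}

#' @rdname read_cell_table
#' @param cells cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells[, c("cell_id", "x_um", "y_um", "class")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read landmark pairs for serial-section registration
#'
#' CSV with columns `moving_x`, `moving_y`, `fixed_x`, `fixed_y`
#' (micrometres; `*_um` suffixes also accepted).
#'
#' @param path CSV file path.
#' @return data.frame of landmark pairs.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- sub("_um$", "", names(df))
  req <- c("moving_x", "moving_y", "fixed_x", "fixed_y")
  stop_if(!all(req %in% names(df)),
          "landmark file needs columns: ", paste(req, collapse = ", "))
  df
}

#' Read TLS/LAG annotations from GeoJSON
#'
#' A FeatureCollection of Polygon features with property `kind` in
#' `TLS`/`LAG`; coordinates in micrometres. Only the outer ring of each
#' polygon is used.
#'
#' @param path GeoJSON file path.
#' @return List of annotations: `list(id, kind, polygon)`.
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path)
  stop_if(!identical(gj$type, "FeatureCollection"),
          "expected a GeoJSON FeatureCollection")
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    kind <- f$properties$kind %||% "TLS"
    stop_if(!kind %in% c("TLS", "LAG"), "annotation kind must be TLS or LAG")
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(poly) <- c("x", "y")
    # drop the GeoJSON closing vertex
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    list(id = f$properties$id %||% paste0(kind, "_", i), kind = kind,
         polygon = poly)
  })
}

#' @rdname read_annotations
#' @param annotations list of annotations to write.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    ring <- lapply(seq_len(nrow(a$polygon)), function(i)
      as.numeric(a$polygon[i, ]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(id = a$id, kind = a$kind),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patient-level survival table
#'
#' CSV with at least `patient_id`, `time`, `event`; rows with missing
#' time or event are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with `event` coerced to 0/1.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "time", "event")
  stop_if(!all(req %in% names(df)),
          "survival table needs columns: ", paste(req, collapse = ", "))
  stop_if(any(is.na(df$time)) || any(is.na(df$event)),
          "missing time/event values")
  stop_if(any(df$time <= 0), "survival times must be > 0")
  stop_if(!all(df$event %in% c(0, 1)), "event must be 0/1")
  if ("stage" %in% names(df)) df$stage <- factor(df$stage)
  df
}

#' Export a hotspot label map as a tidy CSV
#'
#' One row per tissue grid: `row`, `col`, `z_cancer`, `z_lymph`,
#' `p_cancer`, `p_lymph`, `label`.
#'
#' @param map a `hotspot_label_map`.
#' @param path output CSV path.
#' @export
write_label_map <- function(map, path) {
  w <- which(map$tissue, arr.ind = TRUE)
  df <- data.frame(row = w[, 1], col = w[, 2],
                   z_cancer = map$z_cancer[w], z_lymph = map$z_lymph[w],
                   p_cancer = map$p_cancer[w], p_lymph = map$p_lymph[w],
                   label = map$label[w])
  utils::write.csv(df[order(df$col, df$row), ], path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Registry of the analysis parameters with the pipeline's standard
#' defaults: 50 um grids, order-4 neighborhoods, alpha 0.05, 250 um
#' Delaunay edge pruning, 8-connectivity. The config (with its hash) is
#' serialized into every output directory for provenance.
#'
#' @param grid_um grid size, default 50.
#' @param max_order neighborhood order, default 4.
#' @param alpha hotspot significance threshold, default 0.05.
#' @param max_edge_um Delaunay pruning threshold, default 250.
#' @param connectivity component connectivity, default 8.
#' @param include_self Gi* self-inclusion flag, default TRUE.
#' @param um_per_pixel conversion applied to pixel inputs at ingest
#'   (default 1 = inputs already in micrometres).
#' @param seed integer seed.
#' @param stages character vector of enabled stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid_um = 50, max_order = 4L, alpha = 0.05,
                            max_edge_um = 250, connectivity = 8,
                            include_self = TRUE, um_per_pixel = 1,
                            seed = 1L,
                            stages = c("hotspots", "components",
                                       "interactions")) {
  structure(list(grid_um = grid_um, max_order = as.integer(max_order),
                 alpha = alpha, max_edge_um = max_edge_um,
                 connectivity = connectivity, include_self = include_self,
                 um_per_pixel = um_per_pixel, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @details `config_hash()` returns a short FNV-1a hash of the
#'   serialized config, stamped into output files.
#' @export
config_hash <- function(config) fnv1a(as.character(config_json(config)))
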