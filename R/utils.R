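#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  if (strict) stop_if(x <= min, sprintf("'%s' must be > %g", name, min))
  else stop_if(x < min, sprintf("'%s' must be >= %g", name, min))
  as.numeric(x)
}

#' Immune cell subset vocabulary
#'
#' Class labels used throughout the package. `he_classes()` are the three
#' H&E-derived classes used for hotspot mapping; `immune_subsets()` are the
#' six lymphocyte subsets identified on the two IHC panels (T-cell panel:
#' CD8+, CD4+FOXP3-, CD4+FOXP3+; B-cell panel: CD20+CXCR5-, CD20+CXCR5+,
#' CD79b+); `ihc_classes()` additionally includes the P40+ neoplastic class.
#'
#' @return Character vector of class labels.
#' @export
immune_subsets <- function() {
  c("CD8", "CD4_FOXP3neg", "CD4_FOXP3pos",
    "CD20_CXCR5neg", "CD20_CXCR5pos", "CD79b")
}

#' @rdname immune_subsets
#' @export
he_classes <- function() c("cancer", "stromal", "lymphocyte")

#' @rdname immune_subsets
#' @export
ihc_classes <- function() c(immune_subsets(), "P40")

b_subsets <- function() c("CD20_CXCR5neg", "CD20_CXCR5pos", "CD79b")

#' Default class-to-channel map for hotspot analysis
#'
#' Maps every known cell class to the channel it contributes to on the
#' count lattice: `cancer` (H&E cancer cells and P40+ neoplastic cells),
#' `lymphocyte` (H&E lymphocytes and the six IHC immune subsets) or
#' `ignored` (stromal cells, which still mark tissue presence).
#'
#' @return Named character vector class -> channel.
#' @export
default_channel_map <- function() {
  m <- c(cancer = "cancer", P40 = "cancer",
         stromal = "ignored", lymphocyte = "lymphocyte")
  m[immune_subsets()] <- "lymphocyte"
  m
}

# FNV-1a 32-bit hash of a character string; used to stamp configs into
# outputs without a cryptographic dependency. All arithmetic is kept
# below 2^53 (doubles) by splitting the state into 16-bit halves.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 65536
    h <- h - lo + bitwXor(as.integer(lo), b)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Even-odd point-in-polygon test, vectorized over points.
# poly: matrix/data.frame with columns x, y (closed or open ring).
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Deterministic sub-stream seed derived from a master seed and a stream
# index; keeps per-compartment draws stable when unrelated parts of a
# config are edited. Result stays inside 32-bit signed range.
substream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2017 + 7919 * k) %% 2147483647L
}
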