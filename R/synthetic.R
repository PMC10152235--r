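#' Tumor nest specification
#'
#' A disc-shaped cancer-cell compartment sampled as an inhomogeneous
#' (here: uniform-on-disc) Poisson process.
#'
#' @param center numeric length-2, nest center in micrometres.
#' @param radius_um disc radius (> 0).
#' @param cancer_intensity expected cancer cells per square micrometre.
#' @return A `tumor_nest` list.
#' @export
tumor_nest <- function(center, radius_um, cancer_intensity) {
  stop_if(length(center) != 2L || !all(is.finite(center)),
          "'center' must be two finite coordinates")
  structure(list(center = as.numeric(center),
                 radius_um = check_number(radius_um, "radius_um", 0, strict = TRUE),
                 cancer_intensity = check_number(cancer_intensity, "cancer_intensity", 0)),
            class = "tumor_nest")
}

#' Immune infiltrate field specification
#'
#' Lymphocytes are placed by a Thomas cluster process: parents form a
#' Poisson process restricted to the field's region, each parent spawns a
#' Poisson number of offspring displaced by an isotropic Gaussian, and
#' offspring are labeled i.i.d. from the subset mix.
#'
#' @param region one of `"inside_nest"` (union of tumor nests),
#'   `"margin_band"` (annulus of width `band_um` outside each nest) or
#'   `"distant"` (a free-standing disc given by `center`/`radius_um`, or,
#'   when both are `NULL`, everywhere farther than `band_um` from every
#'   nest).
#' @param mix named numeric vector over the six immune subsets
#'   (see [immune_subsets()]); must sum to 1.
#' @param parent_intensity cluster parents per square micrometre of region.
#' @param offspring_per_parent mean offspring per parent.
#' @param offspring_sd_um Gaussian displacement SD in micrometres.
#' @param center,radius_um disc for `region = "distant"` (optional).
#' @param band_um margin band width; default 200.
#' @return An `immune_field` list.
#' @export
immune_field <- function(region = c("inside_nest", "margin_band", "distant"),
                         mix, parent_intensity, offspring_per_parent,
                         offspring_sd_um, center = NULL, radius_um = NULL,
                         band_um = 200) {
  region <- match.arg(region)
  mix <- check_mix(mix)
  if (!is.null(center)) {
    stop_if(region != "distant", "'center' only applies to distant fields")
    stop_if(length(center) != 2L || !all(is.finite(center)), "bad 'center'")
    radius_um <- check_number(radius_um, "radius_um", 0, strict = TRUE)
  }
  structure(list(region = region, mix = mix,
                 parent_intensity = check_number(parent_intensity, "parent_intensity", 0),
                 offspring_per_parent = check_number(offspring_per_parent, "offspring_per_parent", 0),
                 offspring_sd_um = check_number(offspring_sd_um, "offspring_sd_um", 0),
                 center = if (is.null(center)) NULL else as.numeric(center),
                 radius_um = radius_um,
                 band_um = check_number(band_um, "band_um", 0)),
            class = "immune_field")
}

check_mix <- function(mix) {
  stop_if(is.null(names(mix)) || !all(names(mix) %in% immune_subsets()),
          "'mix' must be named with immune subset labels")
  stop_if(any(!is.finite(mix)) || any(mix < 0), "'mix' must be non-negative and finite")
  stop_if(abs(sum(mix) - 1) > 1e-9, "'mix' must sum to 1 (tolerance 1e-9)")
  full <- stats::setNames(numeric(6), immune_subsets())
  full[names(mix)] <- mix
  full
}

#' Tertiary-lymphoid-structure-like aggregate specification
#'
#' A zoned aggregate: a B-cell-dominant core disc (CD20+CXCR5+ / CD79b+
#' enriched, emulating a germinal center) surrounded by a T-cell-dominant
#' ring. Both zones are uniform Poisson within their geometry.
#'
#' @param center numeric length-2 center in micrometres.
#' @param core_radius_um B-zone radius (> 0).
#' @param ring_width_um T-zone annulus width (> 0).
#' @param core_intensity,ring_intensity cells per square micrometre.
#' @param core_mix,ring_mix subset mixes; defaults are B- and T-dominant.
#' @return A `tls_spec` list.
#' @export
tls_spec <- function(center, core_radius_um, ring_width_um,
                     core_intensity, ring_intensity,
                     core_mix = c(CD20_CXCR5pos = 0.45, CD79b = 0.25,
                                  CD20_CXCR5neg = 0.15, CD4_FOXP3neg = 0.08,
                                  CD8 = 0.04, CD4_FOXP3pos = 0.03),
                     ring_mix = c(CD4_FOXP3neg = 0.45, CD8 = 0.28,
                                  CD4_FOXP3pos = 0.12, CD20_CXCR5neg = 0.08,
                                  CD20_CXCR5pos = 0.04, CD79b = 0.03)) {
  stop_if(length(center) != 2L || !all(is.finite(center)), "bad 'center'")
  structure(list(center = as.numeric(center),
                 core_radius_um = check_number(core_radius_um, "core_radius_um", 0, strict = TRUE),
                 ring_width_um = check_number(ring_width_um, "ring_width_um", 0, strict = TRUE),
                 core_intensity = check_number(core_intensity, "core_intensity", 0),
                 ring_intensity = check_number(ring_intensity, "ring_intensity", 0),
                 core_mix = check_mix(core_mix), ring_mix = check_mix(ring_mix)),
            class = "tls_spec")
}

#' Synthetic slide configuration
#'
#' Describes one virtual slide: slide extent, tumor nests, immune fields,
#' TLS-like aggregates and a uniform stromal background. The configuration
#' plus the seed fully determine the generated cell table.
#'
#' @param width_um,height_um slide extent in micrometres.
#' @param tumor_nests list of [tumor_nest()].
#' @param immune_fields list of [immune_field()].
#' @param tls list of [tls_spec()].
#' @param stromal_intensity stromal cells per square micrometre
#'   (background tissue; these mark tissue but join no channel).
#' @param seed integer master seed.
#' @return A `slide_config` object.
#' @export
slide_config <- function(width_um, height_um, tumor_nests = list(),
                         immune_fields = list(), tls = list(),
                         stromal_intensity = 0, seed = 1L) {
  cfg <- structure(list(
    width_um = check_number(width_um, "width_um", 0, strict = TRUE),
    height_um = check_number(height_um, "height_um", 0, strict = TRUE),
    tumor_nests = tumor_nests, immune_fields = immune_fields, tls = tls,
    stromal_intensity = check_number(stromal_intensity, "stromal_intensity", 0),
    seed = as.integer(seed)), class = "slide_config")
  stop_if(!all(vapply(tumor_nests, inherits, TRUE, "tumor_nest")),
          "'tumor_nests' must be a list of tumor_nest objects")
  stop_if(!all(vapply(immune_fields, inherits, TRUE, "immune_field")),
          "'immune_fields' must be a list of immune_field objects")
  stop_if(!all(vapply(tls, inherits, TRUE, "tls_spec")),
          "'tls' must be a list of tls_spec objects")
  cfg
}

# region membership predicates -------------------------------------------

in_any_nest <- function(x, y, nests, grow = 0) {
  inside <- rep(FALSE, length(x))
  for (nst in nests) {
    d2 <- (x - nst$center[1])^2 + (y - nst$center[2])^2
    inside <- inside | d2 <= (nst$radius_um + grow)^2
  }
  inside
}

field_region_test <- function(field, nests) {
  switch(field$region,
    inside_nest = function(x, y) in_any_nest(x, y, nests),
    margin_band = function(x, y)
      in_any_nest(x, y, nests, grow = field$band_um) & !in_any_nest(x, y, nests),
    distant = if (!is.null(field$center)) {
      function(x, y) (x - field$center[1])^2 + (y - field$center[2])^2 <= field$radius_um^2
    } else {
      function(x, y) !in_any_nest(x, y, nests, grow = field$band_um)
    })
}

rpois_uniform <- function(lambda_total, w, h) {
  n <- stats::rpois(1L, lambda_total)
  data.frame(x = stats::runif(n, 0, w), y = stats::runif(n, 0, h))
}

rdisc <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

rannulus <- function(n, center, r0, r1) {
  r <- sqrt(stats::runif(n, r0^2, r1^2))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

draw_classes <- function(n, mix) {
  if (n == 0L) return(character(0))
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate one synthetic slide
#'
#' Draws the cell point pattern described by a [slide_config()]:
#' stromal background and cancer nests as Poisson processes, immune
#' fields as Thomas cluster processes, TLS-like aggregates as zoned
#' uniform processes. Identical config + seed yields an identical table.
#' Each compartment consumes an independent RNG sub-stream keyed by the
#' master seed, so editing one compartment leaves the others' draws
#' unchanged.
#'
#' @param config a [slide_config()].
#' @return Cell table `data.frame` with columns `cell_id`, `x_um`,
#'   `y_um`, `class`.
#' @export
generate_slide <- function(config) {
  stop_if(!inherits(config, "slide_config"), "'config' must be a slide_config")
  w <- config$width_um; h <- config$height_um
  parts <- list()

  with_stream <- function(k, fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(substream_seed(config$seed, k))
    fun()
  }

  # stromal background (stream 1)
  parts$stromal <- with_stream(1L, function() {
    p <- rpois_uniform(config$stromal_intensity * w * h, w, h)
    if (nrow(p)) cbind(p, class = "stromal") else NULL
  })

  # cancer nests (streams 100+i)
  for (i in seq_along(config$tumor_nests)) {
    nst <- config$tumor_nests[[i]]
    parts[[paste0("nest", i)]] <- with_stream(100L + i, function() {
      n <- stats::rpois(1L, nst$cancer_intensity * pi * nst$radius_um^2)
      p <- rdisc(n, nst$center, nst$radius_um)
      p <- p[p$x >= 0 & p$x <= w & p$y >= 0 & p$y <= h, , drop = FALSE]
      if (nrow(p)) cbind(p, class = "cancer") else NULL
    })
  }

  # immune fields: Thomas process restricted to region (streams 200+i)
  for (i in seq_along(config$immune_fields)) {
    fld <- config$immune_fields[[i]]
    in_region <- field_region_test(fld, config$tumor_nests)
    parts[[paste0("field", i)]] <- with_stream(200L + i, function() {
      par <- rpois_uniform(fld$parent_intensity * w * h, w, h)
      par <- par[in_region(par$x, par$y), , drop = FALSE]
      if (!nrow(par)) return(NULL)
      noff <- stats::rpois(nrow(par), fld$offspring_per_parent)
      idx <- rep.int(seq_len(nrow(par)), noff)
      if (!length(idx)) return(NULL)
      x <- par$x[idx] + stats::rnorm(length(idx), 0, fld$offspring_sd_um)
      y <- par$y[idx] + stats::rnorm(length(idx), 0, fld$offspring_sd_um)
      keep <- x >= 0 & x <= w & y >= 0 & y <= h
      n <- sum(keep)
      if (!n) return(NULL)
      data.frame(x = x[keep], y = y[keep], class = draw_classes(n, fld$mix))
    })
  }

  # TLS-like aggregates (streams 300+i)
  for (i in seq_along(config$tls)) {
    tl <- config$tls[[i]]
    parts[[paste0("tls", i)]] <- with_stream(300L + i, function() {
      nc <- stats::rpois(1L, tl$core_intensity * pi * tl$core_radius_um^2)
      core <- rdisc(nc, tl$center, tl$core_radius_um)
      r1 <- tl$core_radius_um + tl$ring_width_um
      nr <- stats::rpois(1L, tl$ring_intensity * pi * (r1^2 - tl$core_radius_um^2))
      ring <- rannulus(nr, tl$center, tl$core_radius_um, r1)
      p <- rbind(cbind(core, class = draw_classes(nc, tl$core_mix)),
                 cbind(ring, class = draw_classes(nr, tl$ring_mix)))
      p <- p[p$x >= 0 & p$x <= w & p$y >= 0 & p$y <= h, , drop = FALSE]
      if (nrow(p)) p else NULL
    })
  }

  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) {
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), class = character(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  data.frame(cell_id = seq_len(nrow(out)), x_um = out$x, y_um = out$y,
             class = out$class)
}

#' Ground-truth compartment mask of a synthetic slide
#'
#' Labels every grid of `spec` by the generative region its center falls
#' in: `CH` (inside a tumor nest only), `IH_intra` (nest and immune
#' region), `IH_peri` (immune region only) or `NONE`. Immune regions are
#' the supports of the configured immune fields and the outer discs of
#' TLS specs. This is the mask hotspot classification is benchmarked
#' against; it reflects where the generator placed intensity, not where
#' individual random cells landed.
#'
#' @param config a [slide_config()].
#' @param spec a [grid_spec()].
#' @return Character matrix (`n_rows` x `n_cols`) of labels.
#' @export
slide_truth <- function(config, spec) {
  ctr <- grid_centers(spec)
  cancer <- in_any_nest(ctr$x, ctr$y, config$tumor_nests)
  immune <- rep(FALSE, nrow(ctr))
  for (fld in config$immune_fields) {
    immune <- immune | field_region_test(fld, config$tumor_nests)(ctr$x, ctr$y)
  }
  for (tl in config$tls) {
    r1 <- tl$core_radius_um + tl$ring_width_um
    immune <- immune | ((ctr$x - tl$center[1])^2 + (ctr$y - tl$center[2])^2 <= r1^2)
  }
  lab <- rep("NONE", nrow(ctr))
  lab[cancer & !immune] <- "CH"
  lab[cancer & immune] <- "IH_intra"
  lab[!cancer & immune] <- "IH_peri"
  matrix(lab, spec$n_rows, spec$n_cols)
}

#' TLS/LAG annotation polygons of a synthetic slide
#'
#' Returns the configured TLS outer boundaries as polygons (64-gon
#' approximation of the outer circle), in the annotation format consumed
#' by [exclude_annotated()].
#'
#' @param config a [slide_config()].
#' @return List of annotations, each `list(id, kind, polygon)`.
#' @export
tls_annotations <- function(config) {
  lapply(seq_along(config$tls), function(i) {
    tl <- config$tls[[i]]
    r1 <- tl$core_radius_um + tl$ring_width_um
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    list(id = paste0("TLS_", i), kind = "TLS",
         polygon = cbind(x = tl$center[1] + r1 * cos(th),
                         y = tl$center[2] + r1 * sin(th)))
  })
}

#' Generate a synthetic patient cohort
#'
#' Builds `n_patients` slide configurations whose intended intratumoral
#' immune-hotspot fraction (`true_score`) spans low to high, and draws
#' survival outcomes from an exponential proportional-hazards model whose
#' log-hazard includes `spatial_effect` per unit of centered true score,
#' plus mild age, stage and pack-year effects. The hazard coefficients
#' are stored as ground truth for recovery tests.
#'
#' Default clinical covariates mimic an NSCLC resection cohort: age
#' normal(67, 9), six-level pathologic stage with frequencies close to
#' TCGA lung cohorts, gamma-distributed pack-years. Baseline hazard
#' corresponds to a 1,000-day median survival; censoring is
#' administrative at a uniform(500, 3000)-day follow-up.
#'
#' @param n_patients number of patients (>= 2).
#' @param spatial_effect log hazard ratio per unit of true score.
#' @param seed integer seed.
#' @param baseline_hazard events per day at covariate means.
#' @param slide_template optional function(true_score, seed) returning a
#'   [slide_config()]; default builds a two-nest slide whose immune
#'   budget is split between intratumoral and margin fields by the score.
#' @return A `synthetic_cohort` list: `patients` data.frame
#'   (`patient_id`, `true_score`, `age`, `stage`, `pack_years`, `time`,
#'   `event`), `configs` list, and `truth` (the generative coefficients).
#' @export
generate_cohort <- function(n_patients, spatial_effect = log(2), seed = 1L,
                            baseline_hazard = log(2) / 1000,
                            slide_template = NULL) {
  stop_if(!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 2,
          "'n_patients' must be >= 2")
  n <- as.integer(n_patients)
  check_number(spatial_effect, "spatial_effect")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, 9001L))

  true_score <- sample(seq(0.05, 0.95, length.out = n))
  age <- round(stats::rnorm(n, 67, 9))
  stage_levels <- c("ia", "ib", "iia", "iib", "iiia", "iv")
  stage <- factor(sample(stage_levels, n, replace = TRUE,
                         prob = c(0.229, 0.275, 0.122, 0.170, 0.138, 0.066)),
                  levels = stage_levels)
  pack_years <- round(stats::rgamma(n, shape = 4, scale = 11))

  beta <- c(score = spatial_effect, age = 0.02, stage = 0.25, pack_years = 0.004)
  lp <- beta["score"] * (true_score - mean(true_score)) +
    beta["age"] * (age - mean(age)) +
    beta["stage"] * (as.integer(stage) - mean(as.integer(stage))) +
    beta["pack_years"] * (pack_years - mean(pack_years))
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(lp))
  t_censor <- stats::runif(n, 500, 3000)
  time <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)
  time <- pmax(time, 1e-3)

  if (is.null(slide_template)) slide_template <- default_slide_template
  configs <- lapply(seq_len(n), function(i)
    slide_template(true_score[i], substream_seed(seed, 10000L + i)))

  structure(list(
    patients = data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                          true_score = true_score, age = age, stage = stage,
                          pack_years = pack_years, time = time, event = event),
    configs = configs,
    truth = list(beta = beta, baseline_hazard = baseline_hazard)),
    class = "synthetic_cohort")
}

# Two-nest slide whose immune parent budget is split between an
# intratumoral and a margin-band field according to the target score.
default_slide_template <- function(true_score, seed) {
  mix <- c(CD8 = 0.25, CD4_FOXP3neg = 0.35, CD4_FOXP3pos = 0.10,
           CD20_CXCR5neg = 0.12, CD20_CXCR5pos = 0.10, CD79b = 0.08)
  base <- 6e-5
  slide_config(
    width_um = 3000, height_um = 3000,
    tumor_nests = list(
      tumor_nest(c(900, 900), 450, 0.004),
      tumor_nest(c(2100, 2100), 450, 0.004)),
    immune_fields = list(
      immune_field("inside_nest", mix, parent_intensity = base * true_score,
                   offspring_per_parent = 40, offspring_sd_um = 50),
      immune_field("margin_band", mix, parent_intensity = base * (1 - true_score),
                   offspring_per_parent = 40, offspring_sd_um = 50)),
    stromal_intensity = 0.0015, seed = seed)
}
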