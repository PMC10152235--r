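#' All 21 unordered immune subset pairs
#'
#' The 6 same-type pairs plus the 15 mixed pairs, in a fixed order; pair
#' names are `"A|B"` with subsets in [immune_subsets()] order.
#'
#' @return Character vector of length 21.
#' @export
subset_pairs <- function() {
  s <- immune_subsets()
  out <- character(0)
  for (a in seq_along(s)) for (b in a:length(s))
    out <- c(out, paste(s[a], s[b], sep = "|"))
  out
}

pair_key <- function(ca, cb) {
  s <- immune_subsets()
  ia <- match(ca, s); ib <- match(cb, s)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste(s[lo], s[hi], sep = "|")
}

#' Interaction and composition profile of one immune hotspot
#'
#' Pairwise interaction fractions `f(a,b)` — the fraction of graph edges
#' joining subsets a and b among all edges — for the 21 unordered subset
#' pairs, together with composition metrics: per-subset counts and
#' percentages (count divided by the total over the six subsets),
#' Shannon indices of the interaction fractions and of the composition,
#' the CD8+/CD4+FOXP3+ (CD8/Treg) ratio and the B-cell percentage.
#' Vertex multiplicities (duplicated coordinates collapsed by
#' [build_graph()]) are honored in composition counts.
#'
#' @param graph a [build_graph()] result.
#' @return An `interaction_profile`: list with `fractions` (named length
#'   21; `NA` when the graph has no edges), `n_edges`, `counts`,
#'   `percentages`, `h_interaction`, `h_composition`, `cd8_treg_ratio`
#'   (`NA` when the Treg count is 0), `b_cell_pct`.
#' @export
interaction_fractions <- function(graph) {
  v <- graph$vertices
  counts <- stats::setNames(numeric(6), immune_subsets())
  if (nrow(v)) {
    tab <- tapply(v$multiplicity, factor(v$class, immune_subsets()), sum)
    counts[names(tab)] <- ifelse(is.na(tab), 0, tab)
  }
  total <- sum(counts)
  pct <- if (total > 0) counts / total else counts * NA_real_

  frac <- stats::setNames(rep(NA_real_, 21), subset_pairs())
  ne <- nrow(graph$edges)
  if (ne > 0) {
    keys <- pair_key(v$class[graph$edges$i], v$class[graph$edges$j])
    tab <- table(factor(keys, levels = subset_pairs()))
    frac[] <- as.numeric(tab) / ne
  }
  h_int <- if (ne > 0) shannon(frac) else NA_real_
  h_comp <- if (total > 0) shannon(counts) else NA_real_
  treg <- counts[["CD4_FOXP3pos"]]
  structure(list(
    fractions = frac, n_edges = ne, counts = counts, percentages = pct,
    h_interaction = h_int, h_composition = h_comp,
    cd8_treg_ratio = if (treg > 0) counts[["CD8"]] / treg else NA_real_,
    b_cell_pct = if (total > 0) sum(counts[b_subsets()]) / total else NA_real_),
    class = "interaction_profile")
}

#' Shannon diversity index
#'
#' `H = -sum p_k log(p_k)` over categories with positive weight, with
#' weights normalized to proportions. Natural log by default; only the
#' ordering of H values matters downstream, so the base is a flag.
#'
#' @param values non-negative weights (counts, densities or fractions).
#' @param base logarithm base; default `exp(1)`.
#' @return Numeric H.
#' @export
shannon <- function(values, base = exp(1)) {
  values <- values[!is.na(values)]
  stop_if(any(values < 0), "'values' must be non-negative")
  tot <- sum(values)
  stop_if(tot <= 0, "'values' must have positive sum")
  p <- values[values > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-IH interaction profiles for a segmented slide
#'
#' Runs [build_graph()] + [interaction_fractions()] on every component
#' (components must carry cells; see [assign_cells_to_components()]) and
#' returns one row per IH. The IH's compartment is the majority grid
#' label among its grids (tie to `IH_intra`).
#'
#' @param components components with `cells`.
#' @param max_edge_um edge pruning threshold (default 250).
#' @return data.frame: `component_id`, `compartment`, `n_grids`,
#'   `n_edges`, the 21 `f_*` fraction columns, `h_interaction`,
#'   `h_composition`, per-subset `n_*` counts and `pct_*` percentages,
#'   `cd8_treg_ratio`, `b_cell_pct`.
#' @export
profile_components <- function(components, max_edge_um = 250) {
  rows <- lapply(components, function(comp) {
    prof <- interaction_fractions(build_graph(comp$cells, max_edge_um))
    compartment <- if (comp$n_intra >= comp$n_peri) "IH_intra" else "IH_peri"
    d <- data.frame(component_id = comp$id, compartment = compartment,
                    n_grids = comp$n_grids, n_edges = prof$n_edges)
    f <- as.list(prof$fractions)
    names(f) <- paste0("f_", gsub("\\|", ".", names(prof$fractions)))
    cnt <- as.list(prof$counts); names(cnt) <- paste0("n_", names(prof$counts))
    pp <- as.list(prof$percentages)
    names(pp) <- paste0("pct_", names(prof$percentages))
    cbind(d, as.data.frame(f), as.data.frame(cnt), as.data.frame(pp),
          data.frame(h_interaction = prof$h_interaction,
                     h_composition = prof$h_composition,
                     cd8_treg_ratio = prof$cd8_treg_ratio,
                     b_cell_pct = prof$b_cell_pct))
  })
  do.call(rbind, rows)
}

#' Wilcoxon group comparisons with BH adjustment
#'
#' Two-sided Wilcoxon tests per variable — signed-rank on matched pairs
#' when `paired = TRUE` (rows matched by `block`), rank-sum otherwise —
#' followed by Benjamini-Hochberg adjustment across variables.
#'
#' @param data data.frame of observations.
#' @param variables character vector of numeric column names to test.
#' @param group name of the two-level grouping column.
#' @param paired logical; requires `block`.
#' @param block name of the matching column for paired tests.
#' @param alpha significance level applied to adjusted p values.
#' @return data.frame: `variable`, `statistic`, `p`, `p_adj`,
#'   `significant`, `skipped`, `reason`.
#' @export
compare_groups <- function(data, variables, group, paired = FALSE,
                           block = NULL, alpha = 0.05) {
  g <- factor(data[[group]])
  stop_if(nlevels(g) != 2L, "'group' must have exactly 2 levels")
  stop_if(paired && is.null(block), "paired tests need a 'block' column")
  res <- lapply(variables, function(v) {
    x <- data[[v]]
    out <- data.frame(variable = v, statistic = NA_real_, p = NA_real_,
                      skipped = FALSE, reason = "")
    if (paired) {
      wide <- stats::reshape(
        data.frame(b = data[[block]], g = g, x = x)[!is.na(x), ],
        idvar = "b", timevar = "g", direction = "wide")
      a <- wide[[2]]; b <- wide[[3]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2L) {
        out$skipped <- TRUE; out$reason <- "fewer than 2 matched pairs"
        return(out)
      }
      wt <- suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                                                exact = FALSE))
    } else {
      n_per <- table(g[!is.na(x)])
      if (any(n_per < 2L)) {
        out$skipped <- TRUE; out$reason <- "group with fewer than 2 observations"
        return(out)
      }
      wt <- suppressWarnings(stats::wilcox.test(x ~ g, exact = FALSE))
    }
    out$statistic <- unname(wt$statistic); out$p <- wt$p.value
    out
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  tested <- !res$skipped
  res$p_adj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Median split within compartments
#'
#' Labels each observation high/low by the median of its own compartment
#' (intratumoral and peritumoral IH medians computed separately):
#' value > median is `"high"`, value <= median is `"low"`.
#'
#' @param values numeric vector.
#' @param compartment character/factor vector, same length.
#' @return Character vector of `"high"`/`"low"` (`NA` in, `NA` out).
#' @export
classify_by_median <- function(values, compartment) {
  stop_if(length(values) != length(compartment), "length mismatch")
  out <- rep(NA_character_, length(values))
  for (cp in unique(compartment[!is.na(compartment)])) {
    sel <- compartment == cp & !is.na(values)
    stop_if(sum(sel) < 2L, sprintf("fewer than 2 values in compartment '%s'", cp))
    med <- stats::median(values[sel])
    if (all(values[sel] == med)) {
      warning(sprintf("constant values in compartment '%s'; all labeled low", cp))
    }
    out[sel] <- ifelse(values[sel] > med, "high", "low")
  }
  out
}

#' Univariate logistic regressions of compartment on interaction fractions
#'
#' One binomial GLM per interaction fraction, predicting the IH
#' compartment. The outcome is coded 1 = intratumoral IH, 0 =
#' peritumoral IH, so a negative coefficient means the interaction is
#' more frequent in peritumoral IH. Wald two-sided p values are
#' BH-adjusted across the fitted interactions. Complete or
#' quasi-complete separation is flagged `unstable`.
#'
#' @param profiles data.frame from [profile_components()].
#' @param fraction_cols columns to test; default all `f_` columns.
#' @param min_per_class minimum IH per class for a fit (default 10).
#' @return data.frame: `variable`, `coefficient`, `se`, `p`, `p_adj`,
#'   `unstable`, `skipped`, `reason`.
#' @export
interaction_logistic <- function(profiles,
                                 fraction_cols = grep("^f_", names(profiles),
                                                      value = TRUE),
                                 min_per_class = 10L) {
  y <- ifelse(profiles$compartment == "IH_intra", 1L, 0L)
  res <- lapply(fraction_cols, function(v) {
    x <- profiles[[v]]
    ok <- !is.na(x) & !is.na(y)
    out <- data.frame(variable = v, coefficient = NA_real_, se = NA_real_,
                      p = NA_real_, unstable = FALSE, skipped = FALSE,
                      reason = "")
    if (min(table(factor(y[ok], c(0, 1)))) < min_per_class) {
      out$skipped <- TRUE; out$reason <- "fewer IH than min_per_class"
      return(out)
    }
    if (stats::var(x[ok]) == 0) {
      out$skipped <- TRUE; out$reason <- "constant predictor"
      return(out)
    }
    fit <- suppressWarnings(stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
    sm <- summary(fit)$coefficients
    out$coefficient <- sm[2, 1]; out$se <- sm[2, 2]; out$p <- sm[2, 4]
    # separation heuristics: diverging coefficient or degenerate fit
    if (!fit$converged || abs(sm[2, 1]) > 15 || sm[2, 2] > 100) {
      out$unstable <- TRUE
      out$reason <- "possible separation; Wald p unreliable"
    }
    out
  })
  res <- do.call(rbind, res)
  tested <- !res$skipped
  res$p_adj <- NA_real_
  res$p_adj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}
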