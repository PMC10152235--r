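#' Two-group log-rank test
#'
#' Fast standalone log-rank (Mantel-Cox) statistic used by the cutpoint
#' scan and the repeated-split validation. Ties in event times are
#' handled by the standard hypergeometric variance.
#'
#' @param time,event survival time (> 0) and status (0/1).
#' @param group two-level grouping vector.
#' @return List with `chisq`, `df = 1`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(factor(group))
  stop_if(length(unique(g)) != 2L, "exactly 2 groups are required")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g <- g[ord]
  n <- length(time)
  in1 <- g == 1L
  # at-risk counts just before each sorted time
  n_at <- n - seq_len(n) + 1L
  n1_at <- rev(cumsum(rev(in1)))
  # aggregate over distinct times (rows with no events drop out below)
  blk <- cumsum(!duplicated(time))
  first <- which(!duplicated(time))
  d <- as.numeric(rowsum(event, blk))
  d1 <- as.numeric(rowsum(event * in1, blk))
  N <- n_at[first]; N1 <- n1_at[first]
  has_ev <- d > 0
  d <- d[has_ev]; d1 <- d1[has_ev]; N <- N[has_ev]; N1 <- N1[has_ev]
  E1 <- d * N1 / N
  V <- ifelse(N > 1, d * (N1 / N) * (1 - N1 / N) * (N - d) / (N - 1), 0)
  O1 <- sum(d1); E <- sum(E1); Vs <- sum(V)
  chisq <- if (Vs > 0) (O1 - E)^2 / Vs else 0
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE),
       observed = O1, expected = E)
}

# Vectorized log-rank scan: evaluates the two-group chi-squared for
# every threshold at once. Columns of the indicator matrix are the
# candidate dichotomizations; all candidates share the risk-set
# bookkeeping of the time-sorted cohort.
logrank_chisq_at <- function(time, event, x, thresholds) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  n_at <- n - seq_len(n) + 1L
  blk <- cumsum(!duplicated(time))
  first <- which(!duplicated(time))
  d <- as.numeric(rowsum(event, blk))
  has_ev <- d > 0
  d <- d[has_ev]
  N <- n_at[first][has_ev]
  IN1 <- outer(x, thresholds, ">") * 1           # n x K group indicators
  # at-risk count of group 1 just before each sorted time, per candidate
  N1 <- apply(IN1[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  N1 <- N1[first, , drop = FALSE][has_ev, , drop = FALSE]
  D1 <- rowsum(IN1 * event, blk)[has_ev, , drop = FALSE]
  E1 <- d * N1 / N
  # at N = 1 the numerator (N - d) is 0, so clamping the denominator
  # just avoids 0/0
  V <- d * (N1 / N) * (1 - N1 / N) * (N - d) / pmax(N - 1, 1)
  OmE <- colSums(D1) - colSums(E1)
  Vs <- colSums(V)
  ifelse(Vs > 0, OmE^2 / Vs, 0)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the two-group log-rank statistic at every candidate
#' threshold (midpoints between consecutive distinct values of
#' `variable`) that leaves at least `min_prop` of subjects on each side,
#' and returns the maximizing threshold.
#'
#' The reported `p` is the naive log-rank p value at the selected
#' cutpoint; because the cutpoint is optimized over many candidates,
#' this p value is anti-conservative (selection bias) and should only be
#' interpreted after validation on held-out data — as done by
#' [repeated_split_validation()]. `p_method = "bonferroni"` applies a
#' conservative multiplicity correction over the candidate grid.
#'
#' @param data data.frame with `time`, `event` and the score column.
#' @param variable name of the numeric column to dichotomize.
#' @param min_prop minimum proportion of subjects per side (default 0.1).
#' @param min_events minimum number of events required (default 10).
#' @param p_method `"naive"` (default) or `"bonferroni"`.
#' @return A `cutpoint_result`: `threshold`, `statistic` (chi-squared),
#'   `p`, `p_method`, `candidates`, `n`, `n_events`.
#' @export
optimal_cutpoint <- function(data, variable, min_prop = 0.1,
                             min_events = 10L,
                             p_method = c("naive", "bonferroni")) {
  p_method <- match.arg(p_method)
  x <- data[[variable]]
  time <- data$time; event <- data$event
  ok <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  n <- length(x)
  stop_if(sum(event) < min_events,
          sprintf("need at least %d events (have %d)", min_events, sum(event)))
  ux <- sort(unique(x))
  stop_if(length(ux) < 3L, "'variable' needs at least 3 distinct values")
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  n_low <- vapply(mids, function(th) sum(x <= th), numeric(1))
  keep <- n_low >= min_prop * n & (n - n_low) >= min_prop * n
  stop_if(!any(keep), "no candidate threshold satisfies min_prop")
  cand <- mids[keep]
  chisq <- logrank_chisq_at(time, event, x, cand)
  best <- which.max(chisq)
  p <- stats::pchisq(chisq[best], 1L, lower.tail = FALSE)
  if (p_method == "bonferroni") p <- min(1, p * length(cand))
  structure(list(threshold = cand[best], statistic = chisq[best], p = p,
                 p_method = p_method, candidates = cand, n = n,
                 n_events = sum(event)),
            class = "cutpoint_result")
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit estimates per group with a two-sided log-rank test.
#'
#' @param data data.frame with `time`, `event`.
#' @param group grouping vector (>= 2 levels, each non-empty).
#' @return List with `fit` (a [survival::survfit] object), `chisq`,
#'   `df`, `p`.
#' @export
km_logrank <- function(data, group) {
  g <- factor(group)
  stop_if(nlevels(droplevels(g)) < 2L, "at least 2 non-empty groups required")
  df <- data.frame(time = data$time, event = data$event, g = droplevels(g))
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  if (sum(df$event) == 0) {
    # no events anywhere: the groups are trivially indistinguishable
    return(list(fit = fit, chisq = 0, df = nlevels(df$g) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  df_ <- length(sd$n) - 1L
  list(fit = fit, chisq = sd$chisq, df = df_,
       p = stats::pchisq(sd$chisq, df_, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; reports
#' hazard ratios with Wald confidence intervals and p values per
#' covariate, flagging non-convergence and monotone-likelihood
#' (infinite-coefficient) covariates.
#'
#' @param data data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names (the
#'   first is conventionally the dichotomized score).
#' @param conf_level Wald CI level, default 0.95.
#' @return List with `table` (data.frame `term`, `coef`, `hr`, `lower`,
#'   `upper`, `se`, `p`, `flagged`), `fit`, `converged`.
#' @export
cox_fit <- function(data, covariates, conf_level = 0.95) {
  stop_if(sum(data$event) == 0, "no events: Cox model is undefined")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  stop_if(sum(data$event) <= length(stats::coef(fit)),
          "fewer events than parameters")
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  flagged <- !is.finite(co[, "coef"]) | co[, "se(coef)"] > 100
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    lower = ci[, 3], upper = ci[, 4],
                    se = co[, "se(coef)"], p = co[, "Pr(>|z|)"],
                    flagged = flagged, row.names = NULL)
  list(table = tab, fit = fit,
       converged = is.null(fit$info) || fit$iter < fit$control$iter.max)
}

#' Repeated random-split validation of a dichotomized score
#'
#' Repeats `n_splits` times: split the cohort into discovery and
#' validation at `ratio`, optimize the cutpoint of `variable` on
#' discovery by maximally selected log-rank, dichotomize validation at
#' that threshold, and record the validation log-rank p value. Splits
#' where validation is degenerate (a side with no subjects or with no
#' events) are skipped and counted. Summaries are the fraction of
#' significant splits and the mean, SD and normal 95% CI of the
#' validation p values.
#'
#' @param data data.frame with `time`, `event` and the score column.
#' @param variable score column name.
#' @param n_splits number of random splits (default 100).
#' @param ratio discovery fraction (default 0.5 for a 1:1 split).
#' @param seed integer seed for the split sequence.
#' @param alpha significance level (default 0.05).
#' @param min_prop,min_events passed to [optimal_cutpoint()].
#' @return List with `fraction_significant`, `p_mean`, `p_sd`, `p_ci`
#'   (length 2), `n_evaluated`, `n_skipped`, `splits` (per-split
#'   data.frame `threshold`, `p`, `significant`, `skipped`).
#' @export
repeated_split_validation <- function(data, variable, n_splits = 100L,
                                      ratio = 0.5, seed = 1L, alpha = 0.05,
                                      min_prop = 0.1, min_events = 10L) {
  n <- nrow(data)
  stop_if(n < 40L, "need at least 40 subjects")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  res <- data.frame(threshold = rep(NA_real_, n_splits), p = NA_real_,
                    significant = NA, skipped = FALSE)
  for (s in seq_len(n_splits)) {
    disc_idx <- sample.int(n, round(ratio * n))
    disc <- data[disc_idx, ]; val <- data[-disc_idx, ]
    th <- tryCatch(
      optimal_cutpoint(disc, variable, min_prop, min_events)$threshold,
      error = function(e) NA_real_)
    if (is.na(th)) { res$skipped[s] <- TRUE; next }
    grp <- val[[variable]] > th
    ev <- tapply(val$event, grp, sum)
    if (length(ev) < 2L || any(is.na(ev)) || any(ev == 0)) {
      res$skipped[s] <- TRUE
      next
    }
    lt <- logrank_test(val$time, val$event, grp)
    res$threshold[s] <- th; res$p[s] <- lt$p
    res$significant[s] <- lt$p < alpha
  }
  ok <- !res$skipped
  pm <- mean(res$p[ok]); psd <- stats::sd(res$p[ok])
  ci <- pm + c(-1, 1) * stats::qnorm(0.975) * psd / sqrt(sum(ok))
  list(fraction_significant = mean(res$significant[ok]),
       p_mean = pm, p_sd = psd, p_ci = ci,
       n_evaluated = sum(ok), n_skipped = sum(res$skipped), splits = res)
}
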