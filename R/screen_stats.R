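#' DNA-normalized ALP activity per well
#'
#' Divides each well's ALP reading by the DNA (PicoGreen) reading of the same
#' lysate (matched by `well_id`), the normalization that removes differences
#' in viable cell number from the osteogenesis readout. Wells lacking a DNA
#' partner are dropped with a message.
#'
#' @param screen a `screen_table` data.frame.
#' @param condition condition name.
#' @param day assay day (default 14).
#' @return numeric vector of per-well ALP/DNA ratios (named by well).
#' @export
normalize_alp <- function(screen, condition, day = 14L) {
  alp <- screen[screen$condition == condition & screen$assay == "ALP" &
                screen$day == day, ]
  dna <- screen[screen$condition == condition & screen$assay == "DNA" &
                screen$day == day, ]
  if (!nrow(alp)) stop(sprintf("no ALP readings for condition '%s'", condition))
  m <- match(alp$well_id, dna$well_id)
  if (anyNA(m)) {
    message(sum(is.na(m)), " ALP well(s) without DNA partner dropped")
    alp <- alp[!is.na(m), ]
    m <- m[!is.na(m)]
  }
  d <- dna$reading[m]
  if (any(d == 0))
    stop(sprintf("DNA reading is zero in well '%s'",
                 alp$well_id[which(d == 0)[1]]))
  stats::setNames(alp$reading / d, alp$well_id)
}

#' Fold change of DNA-normalized ALP activity versus control
#'
#' Ratio of the mean per-well normalized values (treated over control), with
#' a bootstrap percentile 95\% confidence interval over wells.
#'
#' @param treated numeric vector of per-well normalized values.
#' @param control numeric vector of per-well normalized values.
#' @param n_boot bootstrap resamples (default 2000).
#' @param boot_seed bootstrap seed (fixed default for reproducibility).
#' @return list with `fold`, `ci` (2.5\% and 97.5\% percentiles), `n_treated`,
#'   `n_control`.
#' @export
fold_change <- function(treated, control, n_boot = 2000L, boot_seed = 101L) {
  if (!length(treated) || !length(control)) stop("empty summaries")
  if (mean(control) == 0) stop("control mean is zero")
  fold <- mean(treated) / mean(control)
  ci <- with_seed(boot_seed, {
    bt <- replicate(n_boot, {
      mean(sample(treated, replace = TRUE)) /
        mean(sample(control, replace = TRUE))
    })
    stats::quantile(bt, c(0.025, 0.975), names = FALSE)
  })
  list(fold = fold, ci = ci, n_treated = length(treated),
       n_control = length(control))
}

#' Viability percentage from MTS readings
#'
#' 100 x mean MTS of the condition over mean MTS of the reference condition
#' at the stated day.
#'
#' @param screen a `screen_table`.
#' @param condition condition name.
#' @param reference_condition reference (typically untreated).
#' @param day 0 or 14.
#' @return percentage.
#' @export
viability_percent <- function(screen, condition, reference_condition,
                              day = 14L) {
  num <- screen$reading[screen$condition == condition &
                        screen$assay == "MTS" & screen$day == day]
  den <- screen$reading[screen$condition == reference_condition &
                        screen$assay == "MTS" & screen$day == day]
  if (!length(num) || !length(den))
    stop(sprintf("MTS readings missing at day %d", day))
  if (mean(den) == 0) stop("reference MTS mean is zero")
  100 * mean(num) / mean(den)
}

#' Dunnett many-to-one comparisons against a control
#'
#' For k treatment groups and one control, computes
#' \eqn{t_i = (\bar x_i - \bar x_0) / \sqrt{s^2 (1/n_i + 1/n_0)}} with the
#' variance pooled across all k+1 groups, and adjusts each two-sided p-value
#' over the family by the probability that the maximum absolute component of
#' a k-variate t distribution (df = N - k - 1, correlations
#' \eqn{\lambda_i \lambda_j} with \eqn{\lambda_i = \sqrt{n_i/(n_i+n_0)}};
#' 1/2 in balanced designs) exceeds \eqn{|t_i|}. The multivariate-t integral
#' is evaluated by quasi-Monte-Carlo (Genz-Bretz) under a fixed internal seed
#' with absolute tolerance 1e-4, so results are reproducible; the adjusted p
#' is clamped to be at least the unadjusted two-sample p.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param control numeric vector (n >= 2).
#' @param alpha significance level for the `sig_*` flags (flags are reported
#'   at both 0.05 and 0.01 regardless).
#' @return an object of class `dunnett_result`: data.frame with columns
#'   `condition, n, mean, t, p_unadjusted, p_adjusted, sig_05, sig_01`, and
#'   attributes `k`, `df_error`, `pooled_sd`, `control_mean`, `alpha`.
#' @export
dunnett_test <- function(groups, control, alpha = 0.05) {
  if (!length(groups)) stop("need at least one treatment group")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- sprintf("group%d", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  n0 <- length(control)
  if (any(ns < 2) || n0 < 2) stop("every group needs n >= 2")
  k <- length(groups)
  all_groups <- c(groups, list(.control = control))
  N <- sum(ns) + n0
  df <- N - (k + 1L)
  ss <- sum(vapply(all_groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss / df
  if (s2 <= 0) stop("pooled variance is zero")
  m0 <- mean(control)
  means <- vapply(groups, mean, numeric(1))
  tval <- (means - m0) / sqrt(s2 * (1 / ns + 1 / n0))

  p_adj <- vapply(abs(tval), dunnett_adjusted_p, numeric(1),
                  ns = ns, n0 = n0, df = df)
  p_un <- 2 * stats::pt(-abs(tval), df)
  p_adj <- pmax(p_adj, p_un)   # family adjustment cannot help a comparison

  out <- data.frame(condition = names(groups), n = ns, mean = means,
                    t = tval, p_unadjusted = p_un, p_adjusted = p_adj,
                    sig_05 = p_adj < 0.05, sig_01 = p_adj < 0.01,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, k = k, df_error = df, pooled_sd = sqrt(s2),
            control_mean = m0, alpha = alpha,
            class = c("dunnett_result", "data.frame"))
}

# Two-sided Dunnett family adjustment: P(max_j |T_j| >= t_abs) under the
# k-variate t distribution with the design's product correlation structure,
# evaluated by Genz-Bretz quasi-Monte-Carlo under a fixed seed (abs tol 1e-4).
dunnett_adjusted_p <- function(t_abs, ns, n0, df) {
  k <- length(ns)
  lam <- sqrt(ns / (ns + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  pr <- with_seed(20111, mvtnorm::pmvt(
    lower = rep(-t_abs, k), upper = rep(t_abs, k), df = df, corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-4, maxpts = 50000)))
  min(1, max(0, 1 - as.numeric(pr)))
}

#' Per-condition screen summaries
#'
#' Summarizes every condition of a screen table: mean and SD of
#' DNA-normalized ALP, fold change versus the ALP control, day-0/day-14
#' viability versus the untreated reference, and the AdipoRed fold versus the
#' adipogenic control (when present).
#'
#' @param screen a `screen_table`.
#' @param controls named list mapping `ALP`, `MTS` and (optionally)
#'   `AdipoRed` to control condition names; defaults to the map attached to
#'   the generated table.
#' @return data.frame, one row per condition.
#' @export
summarize_screen <- function(screen, controls = NULL) {
  controls <- controls %||% attr(screen, "control_names")
  if (is.null(controls$ALP) || is.null(controls$MTS))
    stop("'controls' must name ALP and MTS control conditions")
  conds <- unique(screen$condition)
  ctrl_alp <- normalize_alp(screen, controls$ALP)
  rows <- lapply(conds, function(cd) {
    v <- normalize_alp(screen, cd)
    fc <- fold_change(v, ctrl_alp)
    adipo <- NA_real_
    if (!is.null(controls$AdipoRed)) {
      num <- screen$reading[screen$condition == cd & screen$assay == "AdipoRed"]
      den <- screen$reading[screen$condition == controls$AdipoRed &
                            screen$assay == "AdipoRed"]
      if (length(num) && length(den) && mean(den) > 0)
        adipo <- mean(num) / mean(den)
    }
    data.frame(condition = cd, n = length(v),
               mean_alp_norm = mean(v), sd_alp_norm = stats::sd(v),
               fold_change = fc$fold,
               fold_ci_lo = fc$ci[1], fold_ci_hi = fc$ci[2],
               viability_day0 = viability_percent(screen, cd, controls$MTS, 0L),
               viability_day14 = viability_percent(screen, cd, controls$MTS, 14L),
               adipo_fold = adipo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ranked enhancer / inhibitor hit lists
#'
#' Enhancers are conditions with fold change > 1 and Dunnett-adjusted
#' p < alpha, sorted by fold descending; inhibitors have fold < 1 and
#' adjusted p < alpha, sorted ascending. Ties in fold resolve alphabetically
#' by condition name; both lists are truncated to `top_k`.
#'
#' @param summaries data.frame from [summarize_screen()].
#' @param dunnett a `dunnett_result` covering the same conditions.
#' @param top_k list length cutoff.
#' @param alpha adjusted-p threshold.
#' @return list with data.frames `enhancers` and `inhibitors`.
#' @export
rank_hits <- function(summaries, dunnett, top_k = 10L, alpha = 0.05) {
  m <- merge(summaries, dunnett[, c("condition", "p_adjusted")],
             by = "condition")
  sig <- m[m$p_adjusted < alpha, , drop = FALSE]
  enh <- sig[sig$fold_change > 1, , drop = FALSE]
  inh <- sig[sig$fold_change < 1, , drop = FALSE]
  enh <- enh[order(-enh$fold_change, enh$condition), , drop = FALSE]
  inh <- inh[order(inh$fold_change, inh$condition), , drop = FALSE]
  keep <- c("condition", "fold_change", "p_adjusted")
  list(enhancers = utils::head(enh[, keep], top_k),
       inhibitors = utils::head(inh[, keep], top_k))
}
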