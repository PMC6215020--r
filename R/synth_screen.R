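#' Ground-truth effect specification for one screen condition
#'
#' Encodes the true, generator-level effect of one condition in a simulated
#' drug screen: a multiplicative effect on DNA-normalized ALP activity
#' relative to the osteogenic control, a viability fraction relative to
#' untreated cells, and a multiplicative adipogenesis effect relative to the
#' adipogenic control.
#'
#' @param condition_name condition label.
#' @param true_alp_fold multiplicative effect on DNA-normalized ALP (> 0).
#' @param true_viability_frac MTS signal as fraction of untreated, in (0, 1.5].
#' @param true_adipo_fold multiplicative effect on AdipoRed (> 0).
#' @param n_replicates wells per condition and assay (>= 2).
#' @param cv lognormal coefficient of variation of each raw reading (>= 0;
#'   0 gives noiseless readings).
#' @return an object of class `screen_effect_spec`.
#' @export
screen_effect_spec <- function(condition_name,
                               true_alp_fold = 1,
                               true_viability_frac = 1,
                               true_adipo_fold = 1,
                               n_replicates = 6L,
                               cv = 0.10) {
  if (!is.character(condition_name) || length(condition_name) != 1L ||
      !nzchar(condition_name))
    stop_field("condition_name", "must be a non-empty string")
  if (!is.numeric(true_alp_fold) || true_alp_fold <= 0)
    stop_field("true_alp_fold", "must be > 0")
  if (!is.numeric(true_viability_frac) || true_viability_frac <= 0 ||
      true_viability_frac > 1.5)
    stop_field("true_viability_frac", "must lie in (0, 1.5]")
  if (!is.numeric(true_adipo_fold) || true_adipo_fold <= 0)
    stop_field("true_adipo_fold", "must be > 0")
  if (!is.numeric(n_replicates) || n_replicates < 2)
    stop_field("n_replicates", "must be >= 2")
  if (!is.numeric(cv) || cv < 0) stop_field("cv", "must be >= 0")
  structure(list(condition_name = condition_name,
                 true_alp_fold = true_alp_fold,
                 true_viability_frac = true_viability_frac,
                 true_adipo_fold = true_adipo_fold,
                 n_replicates = as.integer(n_replicates),
                 cv = cv),
            class = "screen_effect_spec")
}

# base instrument levels for the four plate-reader assays (arbitrary units);
# the analysis only ever uses ratios, so the absolute scale is immaterial
screen_base_levels <- function() {
  c(ALP = 100, DNA = 50, MTS = 1, AdipoRed = 200)
}

# multiplicative lognormal noise factors with mean exactly 1 and coefficient
# of variation cv (cv = 0 -> exactly 1)
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-well drug-screen plate table
#'
#' Generates per-well plate-reader readings for the four assays under a
#' multiplicative measurement model. For each condition with effect spec
#' \eqn{(\phi, v, \alpha)} (ALP fold, viability fraction, adipo fold):
#' \itemize{
#'   \item ALP (day 14): mean = base ALP level x \eqn{\phi} x \eqn{v} — raw
#'     ALP scales with both per-cell activity and viable cell number;
#'   \item DNA (day 14): mean = base DNA level x \eqn{v} — DNA tracks viable
#'     cell number, so the ALP/DNA ratio cancels viability and isolates
#'     \eqn{\phi};
#'   \item MTS: day 0 mean = base level; day 14 mean = base level x \eqn{v};
#'   \item AdipoRed (day 14): mean = base level x \eqn{\alpha}.
#' }
#' Every reading is its mean times an independent lognormal factor with mean
#' 1 and the condition's coefficient of variation.
#'
#' @param effects list of [screen_effect_spec()].
#' @param control_names named character vector/list mapping assays to control
#'   conditions, e.g. `c(ALP = "os_untreated", MTS = "untreated",
#'   AdipoRed = "ad_untreated")`. Every named control must appear among
#'   `effects`.
#' @param seed integer seed; output is bit-reproducible.
#' @return a `data.frame` (classed `screen_table`) with columns
#'   `well_id, condition, assay, day, reading`. ALP and DNA rows from the same
#'   lysate share a `well_id`.
#' @export
generate_screen <- function(effects, control_names, seed = 1L) {
  if (!length(effects)) stop("'effects' must be non-empty")
  nms <- vapply(effects, function(e) e$condition_name, character(1))
  if (anyDuplicated(nms)) stop("duplicate condition names")
  for (ctrl in unlist(control_names)) {
    if (!ctrl %in% nms)
      stop(sprintf("control condition '%s' missing from effects", ctrl))
  }
  base <- screen_base_levels()
  with_seed(seed, {
    rows <- list()
    for (e in effects) {
      nrep <- e$n_replicates
      wells <- sprintf("%s_w%02d", e$condition_name, seq_len(nrep))
      means <- list(
        list(assay = "ALP", day = 14L,
             mu = base[["ALP"]] * e$true_alp_fold * e$true_viability_frac),
        list(assay = "DNA", day = 14L,
             mu = base[["DNA"]] * e$true_viability_frac),
        list(assay = "MTS", day = 0L, mu = base[["MTS"]]),
        list(assay = "MTS", day = 14L,
             mu = base[["MTS"]] * e$true_viability_frac),
        list(assay = "AdipoRed", day = 14L,
             mu = base[["AdipoRed"]] * e$true_adipo_fold))
      for (m in means) {
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = wells,
          condition = e$condition_name,
          assay = m$assay,
          day = m$day,
          reading = m$mu * lognormal_factor(nrep, e$cv),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "control_names") <- as.list(control_names)
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("screen_table", "data.frame")
    out
  })
}

#' Default screen effect tables
#'
#' Ground-truth effect tables for the three simulated screens analysed in the
#' package. Effect sizes encode the headline results of the epigenetic
#' osteogenesis screen these simulations emulate: the top enhancer raises
#' DNA-normalized ALP 3.5-fold, second-tier enhancers 2.5-fold, the strongest
#' inhibitor suppresses it by 45\% (fold 0.55), and in aged-donor cells the
#' top drug reaches 5.9-fold. Viability fractions reflect day-14 MTS levels
#' of at least 60--85\% for the hit compounds. Conditions not reported to
#' move a readout are set to fold 1.
#'
#' @param n_replicates wells per condition.
#' @param cv lognormal coefficient of variation of raw readings.
#' @return list with `effects` (list of [screen_effect_spec()]) and
#'   `controls` (assay -> control condition map).
#' @export
enhancer_screen_effects <- function(n_replicates = 6L, cv = 0.10) {
  eff <- list(
    screen_effect_spec("untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("os_untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("gemcitabine", 3.5, 0.70, 1.0, n_replicates, cv),
    screen_effect_spec("decitabine", 2.5, 0.85, 1.0, n_replicates, cv),
    screen_effect_spec("icbp112", 2.5, 0.70, 1.0, n_replicates, cv),
    screen_effect_spec("chidamide", 2.3, 0.60, 0.75, n_replicates, cv),
    screen_effect_spec("sirt12iv", 2.2, 0.70, 0.75, n_replicates, cv))
  list(effects = eff,
       controls = list(ALP = "os_untreated", MTS = "untreated",
                       AdipoRed = "untreated"))
}

#' @rdname enhancer_screen_effects
#' @export
inhibitor_screen_effects <- function(n_replicates = 6L, cv = 0.10) {
  eff <- list(
    screen_effect_spec("untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("os_untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("iodosaha", 0.55, 1.0, 0.80, n_replicates, cv),
    screen_effect_spec("scriptaid", 0.64, 0.75, 0.80, n_replicates, cv),
    screen_effect_spec("agk2", 0.64, 1.0, 1.0, n_replicates, cv),
    screen_effect_spec("clamidine", 0.80, 1.0, 1.0, n_replicates, cv),
    screen_effect_spec("delphinidin", 0.90, 1.0, 1.0, n_replicates, cv))
  list(effects = eff,
       controls = list(ALP = "os_untreated", MTS = "untreated",
                       AdipoRed = "untreated"))
}

#' @rdname enhancer_screen_effects
#' @export
aged_donor_screen_effects <- function(n_replicates = 6L, cv = 0.10) {
  eff <- list(
    screen_effect_spec("untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("os_untreated", 1, 1, 1, n_replicates, cv),
    screen_effect_spec("gemcitabine", 5.9, 0.70, 1.0, n_replicates, cv),
    screen_effect_spec("chidamide", 2.3, 0.60, 1.0, n_replicates, cv),
    screen_effect_spec("decitabine", 1.5, 0.85, 1.0, n_replicates, cv),
    screen_effect_spec("icbp112", 1.0, 0.70, 1.0, n_replicates, cv),
    screen_effect_spec("sirt12iv", 1.0, 0.70, 1.0, n_replicates, cv))
  list(effects = eff,
       controls = list(ALP = "os_untreated", MTS = "untreated",
                       AdipoRed = "untreated"))
}
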