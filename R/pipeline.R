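#' Default GLCM configuration of the imaging pipeline
#'
#' 32 gray levels, pair distance 1, symmetric GLCM, range aggregation over
#' the four directions, and detector-referenced quantization: intensities are
#' binned over the fixed range \[0, 2.5\] generator units (the synthetic
#' detector's full scale) rather than per-nucleus min-max, so the descriptor
#' scale does not ride on each nucleus's brightest speckle.
#'
#' @return list of [haralick_profile()] arguments.
#' @export
default_glcm_params <- function() {
  list(n_levels = 32L, d = 1L, symmetric = TRUE, aggregation = "range",
       strategy = "global", global_range = c(0, 2.5))
}

#' Run the imaging pipeline end to end
#'
#' Generates (or accepts) a class-structured nucleus image set and runs
#' segmentation, 26-descriptor Haralick feature extraction, PCA reduction and
#' C4.5 classification, returning the cross-validated and resubstitution
#' classification reports. Images are generated and featurized one at a time,
#' so memory stays flat in the dataset size. Identical configuration and seed
#' give identical outputs.
#'
#' @param specs list of [texture_class_spec()] (e.g.
#'   [enhancer_panel_specs()]).
#' @param n_per_class images per class.
#' @param size_px field edge length in pixels.
#' @param seed master dataset seed.
#' @param seg_params list of [segment_pair()] arguments.
#' @param glcm_params list of [haralick_profile()] arguments.
#' @param variance_target PCA explained-variance target.
#' @param confidence_factor,min_leaf,prune C4.5 hyperparameters.
#' @param cv_k,cv_seed cross-validation folds and fold seed.
#' @param out_dir optional directory: writes `features.csv`, `model.json`,
#'   `report.json` and `provenance.json`.
#' @return list with `features`, `pca`, `tree`, `report_cv`, `report_resub`,
#'   `config`.
#' @export
run_imaging_pipeline <- function(specs, n_per_class = 100L, size_px = 512L,
                                 seed = 11L,
                                 seg_params = list(),
                                 glcm_params = default_glcm_params(),
                                 variance_target = 0.95,
                                 confidence_factor = 0.25, min_leaf = 2L,
                                 prune = TRUE, cv_k = 10L, cv_seed = 13L,
                                 out_dir = NULL) {
  nms <- vapply(specs, function(s) s$class_name, character(1))
  if (anyDuplicated(nms)) stop("duplicate class names in 'specs'")
  manifest <- data.frame(class = rep(nms, each = n_per_class),
                         replicate = rep(seq_len(n_per_class), length(nms)),
                         stringsAsFactors = FALSE)
  manifest$seed <- mapply(derive_seed, key = manifest$class,
                          index = manifest$replicate,
                          MoreArgs = list(master_seed = seed))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sp <- specs[[match(manifest$class[i], nms)]]
    pair <- generate_nucleus_image(sp, size_px = size_px,
                                   seed = manifest$seed[i])
    msk <- do.call(segment_pair, c(list(pair), seg_params))
    if (msk$n_nuclei == 0L) next
    rois <- extract_rois(pair, msk)
    feats <- lapply(rois, function(roi)
      do.call(haralick_profile, c(list(roi$sc35, roi$mask), glcm_params)))
    rows[[i]] <- data.frame(
      nucleus_id = sprintf("img%04d_n%02d", i,
                           vapply(rois, `[[`, integer(1), "nucleus_id")),
      class = pair$class_name,
      do.call(rbind, feats),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  features <- do.call(rbind, rows)
  if (is.null(features) || !nrow(features)) stop("no nuclei segmented")
  rownames(features) <- NULL
  finite <- apply(as.matrix(features[, -(1:2)]), 1,
                  function(r) all(is.finite(r)))
  if (any(!finite)) {
    message(sum(!finite), " nuclei dropped for non-finite descriptors")
    features <- features[finite, , drop = FALSE]
  }

  X <- as.matrix(features[, -(1:2)])
  y <- factor(features$class, levels = nms)
  report_cv <- evaluate_pipeline(X, y, variance_target, confidence_factor,
                                 min_leaf, prune, scheme = "kfold",
                                 k = cv_k, seed = cv_seed)
  pca <- fit_pca(X, variance_target)
  tree <- fit_c45(project(pca, X), y, confidence_factor, min_leaf, prune)
  report_resub <- classification_report(y, predict(tree, project(pca, X)),
                                        "resubstitution")
  config <- list(classes = nms, n_per_class = n_per_class, size_px = size_px,
                 seed = seed, seg_params = seg_params,
                 glcm_params = glcm_params,
                 variance_target = variance_target,
                 confidence_factor = confidence_factor, min_leaf = min_leaf,
                 prune = prune, cv_k = cv_k, cv_seed = cv_seed)
  out <- list(features = features, pca = pca, tree = tree,
              report_cv = report_cv, report_resub = report_resub,
              config = config)
  if (!is.null(out_dir)) write_imaging_artifacts(out, out_dir)
  out
}

#' Run the screen pipeline end to end
#'
#' Generates a simulated plate (or accepts an existing `screen_table`),
#' summarizes all conditions, runs the Dunnett many-to-one test of
#' DNA-normalized ALP against the control, and ranks enhancer/inhibitor
#' hits.
#'
#' @param effects list of [screen_effect_spec()]; ignored when `screen` is
#'   supplied.
#' @param controls assay-to-control map (see [generate_screen()]).
#' @param seed generation seed.
#' @param screen optional pre-existing `screen_table`.
#' @param top_k,alpha hit-list parameters.
#' @param out_dir optional directory: writes `summaries.csv`, `dunnett.csv`,
#'   `hits.json` and `provenance.json`.
#' @return list with `screen`, `summaries`, `dunnett`, `hits`, `config`.
#' @export
run_screen_pipeline <- function(effects = NULL, controls = NULL, seed = 1L,
                                screen = NULL, top_k = 10L, alpha = 0.05,
                                out_dir = NULL) {
  if (is.null(screen)) {
    if (is.null(effects) || is.null(controls))
      stop("supply either 'screen' or both 'effects' and 'controls'")
    screen <- generate_screen(effects, controls, seed = seed)
  }
  controls <- controls %||% attr(screen, "control_names")
  summaries <- summarize_screen(screen, controls)
  treated <- setdiff(unique(screen$condition), controls$ALP)
  groups <- lapply(treated, function(cd) normalize_alp(screen, cd))
  names(groups) <- treated
  dt <- dunnett_test(groups, normalize_alp(screen, controls$ALP),
                     alpha = alpha)
  hits <- rank_hits(summaries, dt, top_k = top_k, alpha = alpha)
  config <- list(controls = controls, seed = seed, top_k = top_k,
                 alpha = alpha)
  out <- list(screen = screen, summaries = summaries, dunnett = dt,
              hits = hits, config = config)
  if (!is.null(out_dir)) write_screen_artifacts(out, out_dir)
  out
}
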