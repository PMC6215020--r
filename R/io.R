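#' Write an image dataset as 16-bit grayscale TIFFs with a manifest
#'
#' One single-plane file per channel, named `{class}_{replicate}_{channel}.tif`,
#' and a `manifest.csv` mapping files to labels and seeds. Intensities are
#' scaled by the dataset-wide maximum of each channel into \[0, 1\] for the
#' 16-bit encoder; the scale factors are recorded in the manifest attributes
#' file. Requires the `tiff` package.
#'
#' @param dataset result of [generate_image_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' required for TIFF export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  sc_max <- max(vapply(dataset$pairs, function(p) max(p$sc35), numeric(1)), 1e-9)
  dna_max <- max(vapply(dataset$pairs, function(p) max(p$dna), numeric(1)), 1e-9)
  man$dna_file <- sprintf("%s_%03d_dna.tif", man$class, man$replicate)
  man$sc35_file <- sprintf("%s_%03d_sc35.tif", man$class, man$replicate)
  for (i in seq_len(nrow(man))) {
    p <- dataset$pairs[[i]]
    tiff::writeTIFF(p$dna / dna_max, file.path(dir, man$dna_file[i]),
                    bits.per.sample = 16L)
    tiff::writeTIFF(p$sc35 / sc_max, file.path(dir, man$sc35_file[i]),
                    bits.per.sample = 16L)
  }
  man$dna_scale <- dna_max
  man$sc35_scale <- sc_max
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read an image dataset written by [write_image_dataset()]
#'
#' @param dir directory holding the TIFFs and `manifest.csv`.
#' @return list with `pairs` (each a `nucleus_image_pair` carrying the two
#'   channels and label; generator truth is not recoverable from disk),
#'   `labels` and `manifest`.
#' @export
read_image_dataset <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' required for TIFF import")
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(man)), function(i) {
    dna <- tiff::readTIFF(file.path(dir, man$dna_file[i])) * man$dna_scale[i]
    sc35 <- tiff::readTIFF(file.path(dir, man$sc35_file[i])) * man$sc35_scale[i]
    structure(list(dna = dna, sc35 = sc35, size_px = nrow(dna),
                   bit_depth = 16L, geometry = NULL,
                   class_name = man$class[i], seed = man$seed[i],
                   truth = NULL),
              class = "nucleus_image_pair")
  })
  list(pairs = pairs, labels = man$class, manifest = man)
}

#' Write / read a screen table as CSV
#'
#' Schema: `well_id,condition,assay,day,reading`.
#'
#' @param screen a `screen_table`.
#' @param path file path.
#' @return `read_screen_csv` returns a `screen_table`.
#' @export
write_screen_csv <- function(screen, path) {
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_csv
#' @param controls optional assay-to-control map re-attached on read.
#' @export
read_screen_csv <- function(path, controls = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "condition", "assay", "day", "reading")
  if (!all(need %in% names(out)))
    stop("screen CSV must have columns ", paste(need, collapse = ","))
  attr(out, "control_names") <- controls
  class(out) <- c("screen_table", "data.frame")
  out
}

# serializable form of a tree node (features named, classes resolved)
node_to_list <- function(node, classes, features) {
  if (node$leaf) {
    list(leaf = TRUE, class = classes[node$class], n = node$n,
         counts = as.list(stats::setNames(node$counts, classes)))
  } else {
    list(leaf = FALSE, feature = features[node$feature],
         threshold = node$threshold,
         left = node_to_list(node$left, classes, features),
         right = node_to_list(node$right, classes, features))
  }
}

#' Export a fitted classifier as JSON
#'
#' Writes the tree structure (split features, thresholds, leaf class
#' distributions) together with the PCA standardization and loadings, so the
#' model can be inspected or re-implemented elsewhere.
#'
#' @param tree a `c45_model`.
#' @param pca the `pca_model` feeding it (optional).
#' @param path output path.
#' @export
write_model_json <- function(tree, pca = NULL, path) {
  obj <- list(
    tree = list(classes = tree$classes, features = tree$features,
                confidence_factor = tree$confidence_factor,
                min_leaf = tree$min_leaf, pruned = tree$pruned,
                n_nodes = tree$n_nodes,
                root = node_to_list(tree$root, tree$classes, tree$features)))
  if (!is.null(pca)) {
    obj$pca <- list(center = as.list(pca$center), scale = as.list(pca$scale),
                    explained = pca$explained, n_retained = pca$n_retained,
                    rotation = pca$rotation[, seq_len(pca$n_retained),
                                            drop = FALSE])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

write_provenance <- function(config, dir) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  prov <- list(package = "speckletex",
               version = as.character(utils::packageVersion("speckletex")),
               config = config,
               config_hash = sum(utf8ToInt(cfg_json) *
                                 seq_along(utf8ToInt(cfg_json))) %% 2147483647)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

write_imaging_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_csv(res$features, file.path(dir, "features.csv"))
  write_model_json(res$tree, res$pca, file.path(dir, "model.json"))
  jsonlite::write_json(
    list(cv = report_to_list(res$report_cv),
         resubstitution = report_to_list(res$report_resub)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_provenance(res$config, dir)
  invisible(dir)
}

write_screen_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_screen_csv(res$screen, file.path(dir, "screen.csv"))
  utils::write.csv(res$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$dunnett), file.path(dir, "dunnett.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$hits, file.path(dir, "hits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_provenance(res$config, dir)
  invisible(dir)
}

report_to_list <- function(rep) {
  list(scheme = rep$scheme,
       percent_correct = rep$percent_correct,
       weighted_precision = rep$weighted_precision,
       weighted_recall = rep$weighted_recall,
       per_class = rep$per_class,
       confusion = as.data.frame.matrix(rep$confusion))
}
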