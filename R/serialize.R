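#' Save a trained hierarchical model to a directory
#'
#' Writes `model.json` (human-readable provenance: threshold, per-model
#' selected features and tuned hyperparameters, normalization state, seed)
#' plus one fitted-learner blob per trainable stage.
#'
#' @param model a fitted [hrqol_train()] model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_hrqol_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_meta <- function(st) {
    if (isTRUE(st$untrainable)) {
      list(untrainable = TRUE)
    } else {
      list(untrainable = FALSE, features = st$features,
           hyperparameters = st$tuning$best,
           cv_auc = st$tuning$best_score, smote = isTRUE(st$smote))
    }
  }
  meta <- list(
    package = "qolminer",
    threshold = model$threshold,
    seed = model$seed,
    n_train = model$n_train,
    feature_inventory = model$feature_inventory,
    normalization = list(max = as.list(model$normalization$max),
                         median = as.list(model$normalization$median)),
    impact = stage_meta(model$impact),
    dimensions = lapply(model$dimensions, stage_meta)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a saved hierarchical model
#'
#' @param dir directory written by [save_hrqol_model()].
#' @return The [hrqol_train()] model object.
#' @export
load_hrqol_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no saved model under ", dir, call. = FALSE)
  model <- readRDS(path)
  stopifnot(inherits(model, "hrqol_model"))
  model
}
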