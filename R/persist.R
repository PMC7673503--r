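# Model persistence: a directory with a human-readable JSON manifest (the
# portable contract: specification, feature set, class map, calibrated
# cutoff) plus the serialized learner state.

#' Save a calibrated model to a directory
#'
#' Writes `manifest.json` (specification, selected genes, class coding,
#' cutoff percentile, target precision) and `state.rds` (the fitted
#' pipeline object).
#'
#' @param model a `pcap_calibrated` from [calibrate_model()].
#' @param dir output directory (created if absent).
#' @param labeling optional `pcap_labels` used in training; records which
#'   metadata values the +1/-1 codes stand for.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir, labeling = NULL) {
  stopifnot(inherits(model, "pcap_calibrated"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model$pipeline$spec
  manifest <- list(
    package = "pcapmeta",
    spec = spec[c("algorithm", "normalization", "oversample", "gene_mode",
                  "alpha", "tuning_budget", "tuning_folds", "rfe_step",
                  "rfe_folds", "smote_k", "seed")],
    features = model$pipeline$features,
    cutoff_percentile = model$cutoff,
    absolute_threshold = model$abs_threshold,
    target_precision = model$x,
    estimated_pcap = model$pcap,
    attainable = model$attainable,
    classes = if (!is.null(labeling)) {
      list(positive = labeling$positive_class,
           negative = labeling$negative_class,
           variable = labeling$variable)
    } else {
      list(positive = "+1", negative = "-1", variable = NA)
    }
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(list(model = model, labeling = labeling),
          file.path(dir, "state.rds"))
  invisible(dir)
}

#' Load a model saved with [save_model()]
#'
#' @param dir directory containing `manifest.json` and `state.rds`.
#' @return list with `model` (`pcap_calibrated`), `labeling` and
#'   `manifest`.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  state <- readRDS(file.path(dir, "state.rds"))
  list(model = state$model, labeling = state$labeling, manifest = manifest)
}
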