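#' Process one field through the imaging pipeline
#'
#' EDF projection (if the input is a stack), rolling-ball + DoG enhancement,
#' watershed segmentation and rule-based false-positive rejection, yielding
#' the classified object records for one field.
#'
#' @param image a `plane` or `zstack`.
#' @param roi logical ROI matrix or NULL for the whole field.
#' @param edf an [edf_params()] object (used only for stacks).
#' @param enh an [enhance_params()] object.
#' @param seg a [segmentation_params()] object.
#' @param rules a [classifier_rules()] object.
#' @param roi_name,subject_id,group labels carried into the records.
#' @return list with `records` (classified), `labels`, `edf_plane`,
#'   `enhanced`, `roi_mean_intensity`.
#' @export
process_field <- function(image, roi = NULL,
                          edf = edf_params(),
                          enh = enhance_params(),
                          seg = segmentation_params(),
                          rules = classifier_rules(),
                          roi_name = "field", subject_id = "", group = "") {
  plane <- if (inherits(image, "zstack")) edf_variance(image, edf)$plane else image
  enhanced <- enhance_plane(plane, enh)
  s <- segment_condensates(enhanced, plane, roi = roi, params = seg,
                           roi_name = roi_name)
  recs <- classify_condensates(s$records, s$labels, plane, rules, seg)
  if (nrow(recs) > 0) {
    recs$subject_id <- subject_id
    recs$group <- group
  }
  list(records = recs, labels = s$labels, edf_plane = plane,
       enhanced = enhanced,
       roi_mean_intensity = mean_intensity(plane, roi))
}

#' Run the full pipeline on an in-memory cohort
#'
#' Applies [process_field()] to every field of a [generate_cohort()] result
#' (or any list of images with matching metadata), builds per-subject area
#' histograms of the accepted objects, and compares the two groups per bin.
#'
#' @param cohort list with `fields` (each holding `plane` or `stack`) and
#'   `meta` (data frame with `subject_id`, `group`).
#' @param bin_edges_um2 area histogram edges (um^2).
#' @param edf,enh,seg,rules stage parameter objects.
#' @param welch use Welch's t in the group comparison.
#' @return list with `records` (combined data frame), `histograms`,
#'   `comparison` (a `group_comparison`), `intensities` (per-subject ROI
#'   mean intensity).
#' @export
run_cohort <- function(cohort, bin_edges_um2 = 1:5,
                       edf = edf_params(), enh = enhance_params(),
                       seg = segmentation_params(),
                       rules = classifier_rules(), welch = FALSE) {
  meta <- cohort$meta
  all_recs <- list(); hists <- list(); intens <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- cohort$fields[[i]]
    image <- if (!is.null(f$plane)) f$plane else f$stack
    res <- process_field(image, edf = edf, enh = enh, seg = seg,
                         rules = rules,
                         subject_id = meta$subject_id[i],
                         group = meta$group[i])
    all_recs[[i]] <- res$records
    hists[[i]] <- histogram_areas(res$records[res$records$accepted, ,
                                              drop = FALSE],
                                  bin_edges_um2,
                                  subject_id = meta$subject_id[i],
                                  group = meta$group[i])
    intens[i] <- res$roi_mean_intensity
  }
  list(records = do.call(rbind, all_recs),
       histograms = hists,
       comparison = compare_groups(hists, welch = welch),
       intensities = data.frame(subject_id = meta$subject_id,
                                group = meta$group,
                                mean_intensity = intens,
                                stringsAsFactors = FALSE))
}

#' Load a pipeline configuration from YAML
#'
#' The file holds `pixel_size_um`, an output directory, optional `seed`,
#' per-stage parameter blocks (`edf`, `enhance`, `segmentation`,
#' `classifier`, `bins`, `welch`) and a `manifest`: a list of images with
#' `path`, `subject_id`, `group`, and optional `roi` (binary TIFF mask
#' path).
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pixel_size_um) || cfg$pixel_size_um <= 0) {
    stop("config must provide a positive pixel_size_um")
  }
  if (is.null(cfg$manifest) || length(cfg$manifest) == 0) {
    stop("config must provide a non-empty manifest")
  }
  for (entry in cfg$manifest) {
    if (is.null(entry$path) || !file.exists(entry$path)) {
      stop("manifest path missing or not found: ", entry$path)
    }
    if (!is.null(entry$roi) && !file.exists(entry$roi)) {
      stop("roi path not found: ", entry$roi)
    }
  }
  build <- function(f, block) do.call(f, as.list(block %||% list()))
  cfg$edf_params <- build(edf_params, cfg$edf)
  cfg$enhance_params <- build(enhance_params, cfg$enhance)
  cfg$segmentation_params <- build(segmentation_params, cfg$segmentation)
  cfg$classifier_rules <- build(classifier_rules, cfg$classifier)
  cfg$bins <- as.numeric(cfg$bins %||% 1:5)
  cfg$welch <- isTRUE(cfg$welch)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline from a configuration over files on disk
#'
#' Processes every manifest image (EDF for multi-page TIFFs), writes per-
#' image records CSV, a combined records CSV, the per-subject histogram
#' CSV, the group-comparison CSV, and a provenance JSON recording every
#' parameter, the package version and the seed. Failures on individual
#' images are caught, logged to the summary, and skipped.
#'
#' @param config a `pipeline_config` (see [load_pipeline_config()]) or a
#'   path to a YAML file.
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `out_dir`.
#' @return invisibly, a summary list: `n_processed`, `n_failed`,
#'   `failures`, `comparison`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  recs <- list(); hists <- list(); failures <- character(0)
  meta_rows <- list()
  for (entry in config$manifest) {
    res <- tryCatch({
      img <- read_image_tiff(entry$path, config$pixel_size_um)
      roi <- if (!is.null(entry$roi)) read_label_tiff(entry$roi) > 0 else NULL
      process_field(img, roi = roi,
                    edf = config$edf_params, enh = config$enhance_params,
                    seg = config$segmentation_params,
                    rules = config$classifier_rules,
                    roi_name = entry$roi_name %||% "field",
                    subject_id = entry$subject_id, group = entry$group)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", entry$path, conditionMessage(res)))
      next
    }
    i <- length(recs) + 1
    recs[[i]] <- res$records
    hists[[i]] <- histogram_areas(res$records[res$records$accepted, ,
                                              drop = FALSE],
                                  config$bins,
                                  roi_name = entry$roi_name %||% "field",
                                  subject_id = entry$subject_id,
                                  group = entry$group)
    meta_rows[[i]] <- data.frame(subject_id = entry$subject_id,
                                 group = entry$group,
                                 mean_intensity = res$roi_mean_intensity,
                                 stringsAsFactors = FALSE)
    utils::write.csv(res$records,
                     file.path(out_dir, paste0(entry$subject_id, "_records.csv")),
                     row.names = FALSE)
  }

  all_recs <- do.call(rbind, recs)
  utils::write.csv(all_recs, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(histograms_to_df(hists),
                   file.path(out_dir, "histograms.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, meta_rows),
                   file.path(out_dir, "intensities.csv"), row.names = FALSE)

  comparison <- tryCatch(compare_groups(hists, welch = config$welch),
                         error = function(e) NULL)
  if (!is.null(comparison)) {
    utils::write.csv(comparison$per_bin,
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(total = comparison$total, groups = comparison$groups,
           n_per_group = comparison$n_per_group),
      file.path(out_dir, "comparison_total.json"),
      auto_unbox = TRUE, digits = NA)
  }

  provenance <- list(
    package = "condensatr",
    version = as.character(utils::packageVersion("condensatr")),
    seed = config$seed,
    pixel_size_um = config$pixel_size_um,
    bins = config$bins,
    welch = config$welch,
    edf = unclass(config$edf_params),
    enhance = unclass(config$enhance_params),
    segmentation = unclass(config$segmentation_params),
    classifier = unclass(config$classifier_rules),
    manifest = config$manifest,
    failures = failures
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary <- list(n_processed = length(recs), n_failed = length(failures),
                  failures = failures, comparison = comparison,
                  out_dir = out_dir)
  if (length(failures)) {
    warning(sprintf("%d image(s) failed: %s", length(failures),
                    paste(failures, collapse = "; ")))
  }
  invisible(summary)
}
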