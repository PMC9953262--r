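.log <- function(level, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg))
}

#' Simulate a study to disk
#'
#' Wraps [generate_dataset()]: writes one curve CSV per measurement, a
#' labels CSV, the ground-truth model table, the generator config as JSON,
#' and a manifest carrying the seed and a content hash so reruns are
#' verifiable.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @param panels,models Optional overrides, as in [generate_dataset()].
#' @param quiet Suppress progress logging.
#' @return The manifest (list), invisibly; files land in `out_dir`.
#' @export
cli_simulate <- function(out_dir, config = generator_config(),
                         panels = default_panels(),
                         models = default_receptor_models(),
                         quiet = FALSE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  if (!quiet) .log("INFO", "simulate: seed=%d protocol=%s replicates=%d",
                   config$seed, config$protocol, config$n_replicates)
  ds <- generate_dataset(config, panels, models)
  files <- character()
  for (i in seq_along(ds$measurements)) {
    me <- ds$measurements[[i]]
    fn <- sprintf("curve_%02d_%s_rep%d.csv", i, me$sample_id, me$replicate)
    write_curves_csv(me$curves, file.path(out_dir, fn),
                     extra_header = c(sample_id = me$sample_id,
                                      group = me$group,
                                      replicate = as.character(me$replicate),
                                      valve_time_s = as.character(me$valve_time)))
    files <- c(files, fn)
  }
  labels <- data.frame(
    file = files,
    sample_id = vapply(ds$measurements, `[[`, character(1), "sample_id"),
    group = vapply(ds$measurements, `[[`, character(1), "group"),
    replicate = vapply(ds$measurements, `[[`, integer(1), "replicate"),
    valve_time_s = vapply(ds$measurements, `[[`, numeric(1), "valve_time"))
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$truth, file.path(out_dir, "truth_models.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(ds$config),
                       file.path(out_dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA)
  hash <- sum(vapply(ds$measurements, function(me)
    sum(vapply(me$curves, function(cu) sum(cu$values), numeric(1))),
    numeric(1)))
  manifest <- list(n_measurements = length(ds$measurements),
                   n_channels = length(ds$measurements[[1L]]$curves),
                   seed = config$seed, protocol = config$protocol,
                   content_checksum = sprintf("%.17g", hash))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) .log("INFO", "simulate: wrote %d measurements to %s",
                   length(files), out_dir)
  invisible(manifest)
}

#' Load a simulated study directory
#'
#' @param dir Directory written by [cli_simulate()].
#' @return A list shaped like [generate_dataset()]'s `measurements`.
#' @export
read_study_dir <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("no labels.csv in ", dir)
  labels <- utils::read.csv(lab_path)
  lapply(seq_len(nrow(labels)), function(i) {
    curves <- read_curves_csv(file.path(dir, labels$file[i]))
    list(curves = curves[seq_along(curves)],
         sample_id = as.character(labels$sample_id[i]),
         group = as.character(labels$group[i]),
         replicate = labels$replicate[i],
         valve_time = labels$valve_time_s[i])
  })
}

#' Fit the response model across a study and write the tau_s grid
#'
#' Wraps [estimate_tau_s_grid()] over per-(receptor, analyte) curves.
#'
#' @param curves Named list of cells as in [estimate_tau_s_grid()].
#' @param schedule Common [switching_schedule()].
#' @param out_csv Output CSV path for the grid.
#' @param config A [fit_config()].
#' @param strict If TRUE, any failed cell raises an error after the grid is
#'   written.
#' @return The grid data.frame, invisibly.
#' @export
cli_fit <- function(curves, schedule, out_csv, config = fit_config(),
                    strict = FALSE) {
  grid <- estimate_tau_s_grid(curves, schedule, config)
  if (nrow(grid) == 0L) warning("empty input: wrote empty grid")
  utils::write.csv(grid, out_csv, row.names = FALSE)
  failed <- grid$receptor[!is.na(grid$error)]
  if (length(failed)) {
    msg <- sprintf("%d grid cell(s) failed", length(failed))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(grid)
}

#' Features + PCA + separation report for a study
#'
#' Runs the analysis stages on an in-memory study or a directory written by
#' [cli_simulate()]: anchored feature extraction, z-score standardization,
#' PCA with scree, and silhouette separation on the selected components.
#' Writes features, scores, loadings, scree and a human-readable report
#' when `out_dir` is given.
#'
#' @param study Directory path or measurements list.
#' @param out_dir Optional output directory.
#' @param offsets Feature anchor offsets (s).
#' @param onset_method `"nominal"` or `"derivative"`.
#' @param components Score components for the separation metric.
#' @param quiet Suppress progress logging.
#' @return List with `features` (feature_matrix), `pca` ([pca()] result),
#'   `scree`, `separation` (NULL with a notice when < 2 groups),
#'   `replicate_deviation`.
#' @export
cli_analyze <- function(study, out_dir = NULL,
                        offsets = c(2, 10, 120, 122, 130),
                        onset_method = c("nominal", "derivative"),
                        components = c(1, 3), quiet = FALSE) {
  onset_method <- match.arg(onset_method)
  measurements <- if (is.character(study)) read_study_dir(study) else study
  if (!quiet) .log("INFO", "analyze: %d measurements, onset=%s",
                   length(measurements), onset_method)
  fm <- assemble_feature_matrix(measurements, onset_method, offsets)
  std <- standardize(fm)
  pc <- pca(std)
  sc <- scree(pc)
  groups <- fm$meta$group
  sep <- NULL
  if (length(unique(groups)) >= 2L) {
    sep <- cluster_separation(pc$scores, groups, components)
  } else if (!quiet) {
    .log("NOTICE", "fewer than 2 groups: separation skipped")
  }
  dev <- if (all(table(fm$meta$sample_id) >= 2L))
    replicate_relative_deviation(fm) else NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_matrix_csv(fm, file.path(out_dir, "features.csv"))
    utils::write.csv(cbind(fm$meta, as.data.frame(pc$scores)),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pc$loadings),
                     file.path(out_dir, "pca_loadings.csv"))
    utils::write.csv(data.frame(component = seq_along(sc), var_ratio = sc),
                     file.path(out_dir, "scree.csv"), row.names = FALSE)
    rpt <- c(
      sprintf("measurements: %d; features: %d", nrow(fm$values), ncol(fm$values)),
      sprintf("variance ratio (first 3 PCs): %s",
              paste(sprintf("%.3f", sc[seq_len(min(3, length(sc)))]),
                    collapse = " ")),
      if (!is.null(sep)) sprintf(
        "silhouette on PCs (%s): %.3f over groups {%s}",
        paste(components, collapse = ","), sep$mean_silhouette,
        paste(unique(groups), collapse = ", "))
      else "separation: skipped (single group)",
      if (!is.null(dev)) sprintf("max replicate relative deviation: %.3f%%",
                                 100 * dev$max_deviation))
    writeLines(rpt, file.path(out_dir, "report.txt"))
  }
  list(features = fm, pca = pc, scree = sc, separation = sep,
       replicate_deviation = dev)
}

#' One-command pipeline: simulate, analyze, report
#'
#' @param out_dir Output directory for all artifacts.
#' @param config A [generator_config()].
#' @param ... Passed to [cli_analyze()].
#' @return The [cli_analyze()] result, invisibly.
#' @export
run_pipeline <- function(out_dir, config = generator_config(), ...) {
  cli_simulate(file.path(out_dir, "data"), config)
  res <- cli_analyze(file.path(out_dir, "data"),
                     out_dir = file.path(out_dir, "analysis"), ...)
  invisible(res)
}
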