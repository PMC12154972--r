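#' Run configuration
#'
#' Bundles everything an end-to-end run needs: the mode, the cohort design
#' (synthetic mode) or cohort directory (real mode), the classification
#' threshold policy, estimator settings, the output directory and the
#' master seed. All randomness in a run flows from the master seed through
#' per-image derived seeds.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param design a [cohort_design()] (synthetic mode).
#' @param seed master integer seed.
#' @param threshold `"auto"` (Otsu per image) or a fixed gray level in
#'   (0, 1) modelling an expert-chosen threshold.
#' @param n_probes perpendicular probes per bundle for thickness.
#' @param out_dir if non-NULL, report files are written there.
#' @param write_images synthetic mode: also export every image + sidecar to
#'   `file.path(out_dir, "cohort")`.
#' @param cohort_dir real mode: directory holding `manifest.csv`, images
#'   and sidecars.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       design = default_cohort_design(), seed = 1L,
                       threshold = "auto", n_probes = 20L,
                       out_dir = NULL, write_images = FALSE,
                       cohort_dir = NULL) {
  mode <- match.arg(mode)
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1))
    stop("threshold must be 'auto' or a gray level in (0, 1)")
  if (mode == "real" && is.null(cohort_dir))
    stop("real mode needs cohort_dir")
  if (mode == "real" && !file.exists(file.path(cohort_dir, "manifest.csv")))
    stop("no manifest.csv found in cohort_dir: ", cohort_dir)
  if (isTRUE(write_images) && is.null(out_dir))
    stop("write_images = TRUE needs out_dir")
  structure(list(mode = mode, design = design, seed = as.integer(seed),
                 threshold = threshold, n_probes = as.integer(n_probes),
                 out_dir = out_dir, write_images = isTRUE(write_images),
                 cohort_dir = cohort_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level fields: `mode`, `seed`, `threshold`, `n_probes`,
#' `out_dir`, `cohort_dir`, `write_images`, and `design` with subfields
#' `preset` (`"null"` or `"ha_effect"`), `n_lm`, `n_tem`, `n_dband`.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  d <- y$design
  dn <- list(n_lm = d$n_lm %||% 40L, n_tem = d$n_tem %||% 40L,
             n_dband = d$n_dband %||% 100L)
  design <- if (identical(d$preset %||% "null", "ha_effect"))
    do.call(ha_effect_design, dn) else do.call(default_cohort_design, dn)
  run_config(mode = y$mode %||% "synthetic", design = design,
             seed = y$seed %||% 1L, threshold = y$threshold %||% "auto",
             n_probes = y$n_probes %||% 20L, out_dir = y$out_dir,
             write_images = isTRUE(y$write_images), cohort_dir = y$cohort_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

variable_units <- c(amorphous_pct = "%", bundle_thickness = "nm",
                    linearity_index = "ratio", fibril_size = "nm",
                    interfibrillar_distance = "nm", d_band_length = "nm")

# measure one image given its JSON-parsed sidecar; returns a records
# data frame (possibly several rows). dband_take limits the number of
# D-band measurements taken from this image.
measure_image <- function(image, sidecar, tags, config, dband_take = Inf) {
  tru <- sidecar$truth  # NULL for real data without ground truth
  rec <- function(variable, value, truth = NA_real_, note = "") {
    data.frame(variable = variable, value = as.numeric(value),
               units = unname(variable_units[variable]),
               condition = tags$condition, timepoint = tags$timepoint,
               layer = tags$layer, replicate = tags$replicate,
               image_index = tags$index,
               truth = as.numeric(truth %||% NA_real_), note = note)
  }
  if (sidecar$kind == "lm") {
    thr <- if (identical(config$threshold, "auto"))
      select_threshold(image, method = "otsu")
    else config$threshold
    res <- amorphous_percentage(image, threshold = thr)
    return(rec("amorphous_pct", res$amorphous_pct,
               truth = if (!is.null(tru)) 100 * tru$amorphous_fraction))
  }
  if (sidecar$kind == "tem_bundle") {
    pl <- trace_centerline(image, sidecar$annotations$seed_point)
    li <- linearity_index(pl)
    th <- bundle_thickness(image, pl, n_probes = config$n_probes)
    return(rbind(rec("linearity_index", li, truth = tru$true_linearity_index),
                 rec("bundle_thickness", th,
                     truth = tru$true_bundle_thickness_nm)))
  }
  # fibril-scale field: transect for diameters/gaps, axes for the D band
  tr <- sidecar$annotations$transect
  tp <- extract_transect(image, tr[1L, ], tr[2L, ])
  seg <- measure_fibrils(tp)
  nd <- length(seg$diameters_nm)
  out <- rec("fibril_size", seg$diameters_nm[(nd + 1L) %/% 2L],
             truth = if (!is.null(tru)) mean(tru$true_fibril_diameters_nm))
  if (length(seg$gaps_nm) > 0L) {
    ng <- length(seg$gaps_nm)
    out <- rbind(out, rec("interfibrillar_distance",
                          seg$gaps_nm[(ng + 1L) %/% 2L],
                          truth = if (!is.null(tru)) mean(tru$true_gaps_nm)))
  }
  axes <- sidecar$annotations$fibril_axes
  take <- min(length(axes), dband_take)
  for (j in seq_len(take)) {
    d <- d_band_period(image, polyline(axes[[j]]))
    out <- rbind(out, rec("d_band_length", as.numeric(d),
                          truth = tru$true_d_period_nm,
                          note = if (attr(d, "low_confidence"))
                            "low_confidence" else ""))
  }
  out
}

# shared measurement loop; `next_item(i)` yields list(image, sidecar, tags)
# or a condition wrapped in list(error=) for real mode
measure_cohort <- function(n_items, next_item, config, n_dband,
                           stop_on_error) {
  records <- vector("list", n_items)
  exclusions <- list()
  quota <- new.env(parent = emptyenv())
  for (i in seq_len(n_items)) {
    item <- next_item(i)
    if (!is.null(item$error)) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(index = i, message = conditionMessage(item$error))
      next
    }
    dband_take <- Inf
    if (item$sidecar$kind == "tem_fibril") {
      qk <- paste0(item$tags$condition, item$tags$timepoint, item$tags$layer,
                   item$tags$replicate)
      used <- get0(qk, envir = quota, ifnotfound = 0L)
      dband_take <- max(0L, ceiling(n_dband / 2) - used)
    }
    res <- tryCatch(
      measure_image(item$image, item$sidecar, item$tags, config, dband_take),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (stop_on_error)
        stop(sprintf("measurement failed on image %d (%s %s): %s", i,
                     item$sidecar$kind,
                     group_key(item$tags$condition, item$tags$timepoint,
                               item$tags$layer),
                     conditionMessage(res)))
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(index = i, message = conditionMessage(res))
      next
    }
    if (item$sidecar$kind == "tem_fibril")
      assign(qk, used + sum(res$variable == "d_band_length"), envir = quota)
    records[[i]] <- res
  }
  list(records = do.call(rbind, records),
       exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                    else data.frame(index = integer(), message = character()))
}

build_report <- function(records, exclusions, config, manifest = NULL) {
  summaries <- summarize_measurements(records)
  comparisons <- run_comparison_plan(records)
  cfg_json <- jsonlite::toJSON(
    list(mode = config$mode, seed = config$seed,
         threshold = config$threshold, n_probes = config$n_probes,
         design_n = config$design$n, overrides = config$design$overrides),
    auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  structure(list(records = records, summaries = summaries,
                 comparisons = comparisons,
                 exclusions = exclusions,
                 manifest = manifest,
                 provenance = list(
                   config = as.character(cfg_json),
                   config_md5 = unname(tools::md5sum(tf)),
                   master_seed = config$seed,
                   package_version = as.character(utils::packageVersion("dermometry")),
                   comparison_note = paste(
                     "pairwise group comparisons on pooled replicates;",
                     "independent-samples tests, two-sided, alpha = 0.05,",
                     "no multiple-testing correction"),
                   thickness_note = paste(
                     "bundle thickness is the mean of perpendicular",
                     "half-depth probe widths along the traced centerline"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %d measurements, %d comparisons (%d significant), %d exclusions>\n",
              nrow(x$records), nrow(x$comparisons),
              sum(x$comparisons$significant), nrow(x$exclusions)))
  invisible(x)
}

#' Run the synthetic end-to-end experiment
#'
#' Generates the designed cohort image by image (streamed, nothing kept in
#' memory beyond the current image), measures all six variables at the
#' design's sample sizes, summarizes every group and runs the full
#' comparison plan. Fully reproducible from the config and master seed.
#'
#' @param config a [run_config()] with `mode = "synthetic"`.
#' @return A `run_report`: `records` (long measurement table),
#'   `summaries`, `comparisons`, `exclusions`, `provenance`.
#' @export
run_synthetic_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"), config$mode == "synthetic")
  sched <- cohort_schedule(config$design, config$seed)
  cohort_dir <- NULL
  if (config$write_images) {
    cohort_dir <- file.path(config$out_dir, "cohort")
    dir.create(cohort_dir, recursive = TRUE, showWarnings = FALSE)
  }
  manifest_paths <- character(nrow(sched))
  next_item <- function(i) {
    row <- sched[i, ]
    gen <- generate_scheduled_image(config$design, row)
    # sidecars pass through JSON even in memory so that in-memory and
    # disk-based runs see bit-identical annotations
    sj <- jsonlite::toJSON(gen$sidecar, auto_unbox = TRUE, digits = NA)
    if (!is.null(cohort_dir)) {
      stem <- sprintf("img_%04d_%s_%s", row$index, row$kind, row$key)
      manifest_paths[i] <<- paste0(stem, ".tiff")
      write_image(gen$image, file.path(cohort_dir, paste0(stem, ".tiff")))
      writeLines(as.character(sj), file.path(cohort_dir, paste0(stem, ".json")))
    }
    list(image = gen$image, sidecar = jsonlite::fromJSON(sj),
         tags = list(condition = row$condition, timepoint = row$timepoint,
                     layer = row$layer, replicate = row$replicate,
                     index = row$index))
  }
  res <- measure_cohort(nrow(sched), next_item, config,
                        config$design$n$dband, stop_on_error = TRUE)
  manifest <- NULL
  if (!is.null(cohort_dir)) {
    manifest <- data.frame(image_path = manifest_paths, kind = sched$kind,
                           condition = sched$condition,
                           timepoint = sched$timepoint, layer = sched$layer,
                           replicate = sched$replicate, seed = sched$seed,
                           pixel_size = ifelse(sched$kind == "lm",
                                               config$design$base$lm$pixel_size_um,
                                        ifelse(sched$kind == "tem_bundle",
                                               config$design$base$bundle$pixel_size_nm,
                                               config$design$base$fibril$pixel_size_nm)),
                           master_seed = config$seed)
    utils::write.csv(manifest, file.path(cohort_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  report <- build_report(res$records, res$exclusions, config, manifest)
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Run the experiment on an ingested (real or exported) cohort
#'
#' Reads `manifest.csv` plus images and JSON sidecars from
#' `config$cohort_dir` and applies the same measurement and statistics path
#' as the synthetic mode. Unreadable or unmeasurable images are excluded
#' per file; the run continues and the report lists the exclusions.
#'
#' @param config a [run_config()] with `mode = "real"`.
#' @return A `run_report`.
#' @export
run_real_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"), config$mode == "real")
  manifest <- utils::read.csv(file.path(config$cohort_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L)
    stop("empty manifest: nothing to measure in ", config$cohort_dir)
  next_item <- function(i) {
    row <- manifest[i, ]
    tryCatch({
      if (is.na(row$pixel_size) || row$pixel_size <= 0)
        stop("missing or invalid pixel size")
      modality <- if (row$kind == "lm") "LM" else "TEM"
      img <- read_image(file.path(config$cohort_dir, row$image_path),
                        row$pixel_size, modality)
      sc <- jsonlite::fromJSON(file.path(
        config$cohort_dir,
        paste0(tools::file_path_sans_ext(row$image_path), ".json")))
      list(image = img, sidecar = sc,
           tags = list(condition = row$condition, timepoint = row$timepoint,
                       layer = row$layer, replicate = row$replicate,
                       index = i))
    }, error = function(e) list(error = e))
  }
  n_dband <- config$design$n$dband
  res <- measure_cohort(nrow(manifest), next_item, config, n_dband,
                        stop_on_error = FALSE)
  if (is.null(res$records) || nrow(res$records) == 0L)
    stop("no image in the cohort could be measured")
  report <- build_report(res$records, res$exclusions, config, manifest)
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write report files
#'
#' Persists `measurements.csv`, `comparisons.csv`, `summaries.json`
#' (variable -> group -> n/mean/sem) and `provenance.json`. All outputs are
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if missing).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  s <- report$summaries
  sj <- lapply(split(s, s$variable), function(d) {
    g <- lapply(seq_len(nrow(d)), function(i)
      list(n = d$n[i], mean = d$mean[i], sem = d$sem[i]))
    names(g) <- group_key(d$condition, d$timepoint, d$layer)
    g
  })
  jsonlite::write_json(sj, file.path(out_dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
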