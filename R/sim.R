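#' Replicate-cohort simulations by resampling measured distributions
#'
#' Full image-pipeline cohorts are expensive, so large replicate studies
#' (type-I error, power/direction-of-effect) are run in two stages: the
#' image pipeline supplies empirical per-group distributions of measured
#' values, and replicate cohorts are drawn from those distributions by
#' bootstrap resampling at the original group sizes. This keeps every
#' simulated value a product of the actual measurement chain (including
#' its noise and biases) while making hundreds of replicates affordable.
#'
#' @name replicate-simulations
NULL

#' Type-I error of the comparison plan under the null
#'
#' For each replicate, a null measurement table is built by pooling all
#' measured values of each variable across groups and resampling every
#' group cell from that common pool (so no group differences exist by
#' construction), then the full comparison plan is run. Reports the
#' fraction of significant results at alpha = 0.05, overall and per test
#' family.
#'
#' @param records long measurement table (e.g. `report$records` from a
#'   null-design [run_synthetic_experiment()] run).
#' @param n_reps number of replicate null cohorts.
#' @param seed integer seed.
#' @return List: `rate_mann_whitney`, `rate_t_test`, `rate_overall`,
#'   `n_tests` (per family), `per_label` (data frame of per-comparison
#'   rejection rates).
#' @export
simulate_null_type1 <- function(records, n_reps = 200L, seed = 1L) {
  set.seed(seed)
  pools <- split(records$value, records$variable)
  cells <- cohort_groups()
  sizes <- group_cell_sizes(records)
  hits <- NULL
  for (r in seq_len(n_reps)) {
    tab <- make_resampled_table(pools, cells, sizes, within_group = FALSE,
                                records = records)
    cmp <- run_comparison_plan(tab)
    hits <- rbind(hits, data.frame(rep = r, variable = cmp$variable,
                                   label = cmp$label, test = cmp$test,
                                   significant = cmp$significant))
  }
  per_label <- stats::aggregate(significant ~ variable + label + test,
                                data = hits, FUN = mean)
  list(rate_mann_whitney = mean(hits$significant[hits$test == "mann_whitney"]),
       rate_t_test = mean(hits$significant[hits$test == "t_test"]),
       rate_overall = mean(hits$significant),
       n_tests = table(hits$test),
       per_label = per_label)
}

#' Power and direction-of-effect over replicate cohorts
#'
#' Each replicate cohort is built cell by cell as
#' `value = truth* + error*`: the per-image truths `truth*` are freshly
#' drawn from the design's own generative laws (so chance group-mean
#' differences of one realized cohort do not masquerade as effects), and
#' the measurement errors `error*` are bootstrap-resampled from the
#' pipeline's empirical residuals `measured - truth` in that variable and
#' cell. The comparison plan is run on each replicate. A replicate is a
#' "pattern success" when, in the inspected comparison, exactly the five
#' effect variables (amorphous fraction, bundle thickness, linearity,
#' fibril size, interfibrillar distance) are significant and the D-band
#' period is not.
#'
#' @param records long measurement table (with `truth` column) from an
#'   effect-design [run_synthetic_experiment()] run.
#' @param design the [cohort_design()] that produced `records`.
#' @param n_reps number of replicate cohorts.
#' @param seed integer seed.
#' @param label the comparison label inspected (default
#'   `"CT_vs_HA_24h_reticular"`).
#' @return List: `pattern_success_rate`, `per_variable_power` (named
#'   significance rates in the inspected comparison), `n_reps`.
#' @export
simulate_effect_pattern <- function(records, design, n_reps = 100L, seed = 1L,
                                    label = "CT_vs_HA_24h_reticular") {
  stopifnot(inherits(design, "cohort_design"))
  if (!"truth" %in% names(records) || all(is.na(records$truth)))
    stop("records must carry ground truth (synthetic cohorts only)")
  set.seed(seed)
  sizes <- group_cell_sizes(records)
  effect_vars <- c("amorphous_pct", "bundle_thickness", "linearity_index",
                   "fibril_size", "interfibrillar_distance")
  sig <- matrix(NA, n_reps, length(measurement_variables()),
                dimnames = list(NULL, measurement_variables()))
  ok <- logical(n_reps)
  # per-cell residual pools and truth samplers, prepared once
  cells <- lapply(seq_len(nrow(sizes)), function(i) {
    sel <- records$variable == sizes$variable[i] &
      records$condition == sizes$condition[i] &
      records$timepoint == sizes$timepoint[i] &
      records$layer == sizes$layer[i]
    key <- group_key(sizes$condition[i], sizes$timepoint[i], sizes$layer[i])
    list(variable = sizes$variable[i], condition = sizes$condition[i],
         timepoint = sizes$timepoint[i], layer = sizes$layer[i],
         n = sizes$value[i],
         residuals = records$value[sel] - records$truth[sel],
         sampler = cell_truth_sampler(design, sizes$variable[i], key,
                                      sizes$layer[i]))
  })
  for (r in seq_len(n_reps)) {
    tab <- do.call(rbind, lapply(cells, function(cl)
      data.frame(variable = cl$variable,
                 value = cl$sampler(cl$n) +
                   sample(cl$residuals, cl$n, replace = TRUE),
                 condition = cl$condition, timepoint = cl$timepoint,
                 layer = cl$layer)))
    cmp <- run_comparison_plan(tab)
    cmp <- cmp[cmp$label == label, ]
    sig[r, cmp$variable] <- cmp$significant
    ok[r] <- all(sig[r, effect_vars]) && !sig[r, "d_band_length"]
  }
  list(pattern_success_rate = mean(ok),
       per_variable_power = colMeans(sig, na.rm = TRUE),
       n_reps = n_reps)
}

rnorm_truncv <- function(n, mean, sd)
  pmin(pmax(stats::rnorm(n, mean, sd), mean - 2.5 * sd), mean + 2.5 * sd)

# function(n) drawing per-image ground truths for one variable in one
# design cell, mirroring the draws of group_image_params()
cell_truth_sampler <- function(design, variable, key, layer) {
  switch(variable,
    amorphous_pct = {
      b <- design$base$lm
      m <- group_override(design, key, "lm_target", b$lm_target[[layer]])
      hw <- b$lm_target_halfwidth
      function(n) 100 * stats::runif(n, m - hw, m + hw)
    },
    bundle_thickness = {
      b <- design$base$bundle
      scl <- group_override(design, key, "thickness_scale", 1)
      nf <- b$n_fibrils[[layer]]
      t0 <- (nf * b$fibril_diameter_nm + (nf - 1) * b$interfibrillar_gap_nm) * scl
      function(n) t0 * rnorm_truncv(n, 1, b$size_cv)
    },
    linearity_index = {
      b <- design$base$bundle
      li <- group_override(design, key, "linearity_index", b$linearity_index)
      function(n) pmax(1, rnorm_truncv(n, li, b$linearity_sd))
    },
    fibril_size = {
      b <- design$base$fibril
      d0 <- group_override(design, key, "fibril_diameter_nm",
                           b$fibril_diameter_nm)
      function(n) pmax(3 * b$pixel_size_nm,
                       rnorm_truncv(n, d0, b$diameter_cv * d0))
    },
    interfibrillar_distance = {
      b <- design$base$fibril
      g0 <- group_override(design, key, "gap_nm", b$interfibrillar_gap_nm)
      function(n) pmax(2 * b$pixel_size_nm,
                       rnorm_truncv(n, g0, b$gap_cv * g0))
    },
    d_band_length = {
      b <- design$base$fibril
      p0 <- group_override(design, key, "d_period_nm", b$d_period_nm)
      function(n) pmax(4 * b$pixel_size_nm,
                       rnorm_truncv(n, p0, b$d_period_sd_nm))
    },
    stop("unknown variable: ", variable))
}

group_cell_sizes <- function(records) {
  stats::aggregate(value ~ variable + condition + timepoint + layer,
                   data = records, FUN = length)
}

make_resampled_table <- function(pools, cells, sizes, within_group, records) {
  out <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    v <- sizes$variable[i]; n <- sizes$value[i]
    src <- if (within_group)
      records$value[records$variable == v &
                    records$condition == sizes$condition[i] &
                    records$timepoint == sizes$timepoint[i] &
                    records$layer == sizes$layer[i]]
    else pools[[v]]
    out[[i]] <- data.frame(variable = v,
                           value = sample(src, n, replace = TRUE),
                           condition = sizes$condition[i],
                           timepoint = sizes$timepoint[i],
                           layer = sizes$layer[i])
  }
  do.call(rbind, out)
}
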