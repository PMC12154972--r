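#' Group summary: mean and standard error of the mean
#'
#' @param values numeric vector, n >= 2, all finite.
#' @return List of class `group_summary`: `n`, `mean`, `sem`
#'   (sd with n - 1 denominator over sqrt(n)).
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a group summary needs at least 2 values")
  if (!all(is.finite(values)))
    stop("group values must be finite")
  structure(list(n = length(values), mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g SEM (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

new_comparison_result <- function(group_a, group_b, test, statistic, p_value,
                                  method_note, n_a, n_b) {
  structure(list(group_a = group_a, group_b = group_b, test = test,
                 statistic = statistic, p_value = p_value,
                 significant = p_value < 0.05, method_note = method_note,
                 n_a = n_a, n_b = n_b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s [%s/%s]: statistic = %.4g, p = %.4g%s\n",
              x$group_a, x$group_b, x$test, x$method_note,
              x$statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-sample Mann-Whitney U test
#'
#' U is computed from midranks of the pooled sample. In `mode = "auto"`,
#' the exact two-sided p-value (from the null distribution of U over all
#' equally likely labelings) is used when `min(n1, n2) <= 8` and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction. `U + U' = n1 * n2` always holds, where `U'` is
#' the statistic with the group labels swapped.
#'
#' @param a,b numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`. `"exact"` requires
#'   tie-free data.
#' @param group_a,group_b labels carried into the result.
#' @return A `comparison_result` with `statistic` = U for sample `a`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "approx"),
                           group_a = "a", group_b = "b") {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- switch(mode,
                      exact = TRUE,
                      approx = FALSE,
                      auto = !ties && min(n1, n2) <= 8L)
  if (use_exact && ties)
    stop("exact Mann-Whitney p-value is not defined with ties; use approx")
  if (use_exact) {
    # exact two-sided p from the null distribution of U
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      stats::pwilcox(U, n1, n2)
    p <- min(1, 2 * p)
    note <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      z <- U - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- 2 * stats::pnorm(-abs(z))
    }
    note <- "normal_approx"
  }
  new_comparison_result(group_a, group_b, "mann_whitney", U, p, note, n1, n2)
}

#' Two-sample t-test
#'
#' Two-sided; `variant = "student"` pools the variances (the default),
#' `"welch"` does not. Degenerate zero-variance inputs follow fixed
#' conventions: identical means give p = 1, distinct means give p = 0,
#' both flagged `"degenerate"` in the method note.
#'
#' @param a,b numeric samples with n >= 2 each.
#' @param variant `"student"` or `"welch"`.
#' @param group_a,group_b labels carried into the result.
#' @return A `comparison_result`.
#' @export
t_test <- function(a, b, variant = c("student", "welch"),
                   group_a = "a", group_b = "b") {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(new_comparison_result(group_a, group_b, "t_test", 0, 1,
                                   "degenerate", length(a), length(b)))
    return(new_comparison_result(group_a, group_b, "t_test",
                                 sign(mean(a) - mean(b)) * Inf, 0,
                                 "degenerate", length(a), length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "student")
  new_comparison_result(group_a, group_b, "t_test",
                        unname(ht$statistic), ht$p.value, variant,
                        length(a), length(b))
}

#' The fixed comparison plan for one variable
#'
#' Within each dermis layer: control vs HA at 24 h and at 48 h, and 24 h vs
#' 48 h within control and within HA (8 comparisons); plus papillary vs
#' reticular within every condition x timepoint cell (4 comparisons).
#'
#' @return A data frame with columns `label`, and the `condition`,
#'   `timepoint`, `layer` of each side (`*_a`, `*_b`); 12 rows.
#' @export
comparison_plan <- function() {
  rows <- list()
  for (lay in c("papillary", "reticular")) {
    for (tp in c(24, 48))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("CT_vs_HA_%dh_%s", tp, lay),
        condition_a = "CT", timepoint_a = tp, layer_a = lay,
        condition_b = "HA", timepoint_b = tp, layer_b = lay)
    for (cond in c("CT", "HA"))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s_24h_vs_48h_%s", cond, lay),
        condition_a = cond, timepoint_a = 24, layer_a = lay,
        condition_b = cond, timepoint_b = 48, layer_b = lay)
  }
  for (cond in c("CT", "HA"))
    for (tp in c(24, 48))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("pap_vs_ret_%s_%dh", cond, tp),
        condition_a = cond, timepoint_a = tp, layer_a = "papillary",
        condition_b = cond, timepoint_b = tp, layer_b = "reticular")
  do.call(rbind, rows)
}

measurement_variables <- function() {
  c("amorphous_pct", "bundle_thickness", "linearity_index",
    "fibril_size", "interfibrillar_distance", "d_band_length")
}

group_key <- function(condition, timepoint, layer)
  sprintf("%s_%dh_%s", condition, as.integer(timepoint), layer)

#' Run the full comparison plan over a measurement table
#'
#' Applies [comparison_plan()] to every variable present in the table.
#' `d_band_length` is compared with the two-sample t-test, every other
#' variable with the Mann-Whitney U test; no multiple-testing correction is
#' applied. Replicates are pooled within condition x timepoint x layer.
#' Comparisons whose groups are missing (or have n < 2) are skipped with a
#' warning.
#'
#' @param records data frame in long format with columns `variable`,
#'   `value`, `condition` (`"CT"`/`"HA"`), `timepoint` (24/48), `layer`
#'   (`"papillary"`/`"reticular"`); extra columns are ignored.
#' @param mw_mode mode passed to [mann_whitney_u()].
#' @param t_variant variant passed to [t_test()].
#' @return Data frame with one row per comparison: `variable`, `label`,
#'   `group_a`, `group_b`, `test`, `statistic`, `p_value`, `significant`,
#'   `method_note`, `n_a`, `n_b`.
#' @export
run_comparison_plan <- function(records, mw_mode = "auto",
                                t_variant = "student") {
  need <- c("variable", "value", "condition", "timepoint", "layer")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  plan <- comparison_plan()
  out <- list()
  skipped <- character(0)
  for (v in intersect(measurement_variables(), unique(records$variable))) {
    rv <- records[records$variable == v, ]
    for (i in seq_len(nrow(plan))) {
      pa <- rv$value[rv$condition == plan$condition_a[i] &
                     rv$timepoint == plan$timepoint_a[i] &
                     rv$layer == plan$layer_a[i]]
      pb <- rv$value[rv$condition == plan$condition_b[i] &
                     rv$timepoint == plan$timepoint_b[i] &
                     rv$layer == plan$layer_b[i]]
      ga <- group_key(plan$condition_a[i], plan$timepoint_a[i], plan$layer_a[i])
      gb <- group_key(plan$condition_b[i], plan$timepoint_b[i], plan$layer_b[i])
      if (length(pa) < 2L || length(pb) < 2L) {
        skipped <- c(skipped, sprintf("%s / %s", v, plan$label[i]))
        next
      }
      cr <- if (v == "d_band_length")
        t_test(pa, pb, t_variant, ga, gb)
      else
        mann_whitney_u(pa, pb, mw_mode, ga, gb)
      out[[length(out) + 1L]] <- data.frame(
        variable = v, label = plan$label[i], group_a = ga, group_b = gb,
        test = cr$test, statistic = cr$statistic, p_value = cr$p_value,
        significant = cr$significant, method_note = cr$method_note,
        n_a = cr$n_a, n_b = cr$n_b)
    }
  }
  if (length(skipped))
    warning("skipped comparisons with missing groups: ",
            paste(skipped, collapse = "; "))
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Group summaries for every variable x group cell
#'
#' @inheritParams run_comparison_plan
#' @return Data frame with `variable`, `condition`, `timepoint`, `layer`,
#'   `n`, `mean`, `sem`, one row per populated cell.
#' @export
summarize_measurements <- function(records) {
  key <- interaction(records$variable, records$condition, records$timepoint,
                     records$layer, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    gs <- summarize_group(d$value)
    data.frame(variable = d$variable[1L], condition = d$condition[1L],
               timepoint = d$timepoint[1L], layer = d$layer[1L],
               n = gs$n, mean = gs$mean, sem = gs$sem)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$variable, out$condition, out$timepoint, out$layer), ]
}
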