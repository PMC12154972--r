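test_that("group summary matches hand computation and translation law", {
  gs <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(gs$mean, 3)
  expect_equal(gs$sem, sqrt(2.5 / 5))
  expect_equal(summarize_group(c(2, 2, 2, 2))$sem, 0)
  shifted <- summarize_group(c(1, 2, 3, 4, 5) + 7)
  expect_equal(shifted$mean, 10); expect_equal(shifted$sem, gs$sem)
  expect_error(summarize_group(3), "at least 2")
})

test_that("Mann-Whitney U: frozen example, symmetry, U + U' identity", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2 extreme labelings of 20, doubled
  expect_identical(r$method_note, "exact")

  # identical multisets: U = n1 n2 / 2 (ties force the approximate path)
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
  expect_equal(r2$p_value, 1)

  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, sample(c(0, 1), 1))
    ra <- mann_whitney_u(a, b); rb <- mann_whitney_u(b, a)
    expect_equal(ra$statistic + rb$statistic, n1 * n2)
    expect_equal(ra$p_value, rb$p_value)
  }
})

test_that("exact Mann-Whitney p equals brute-force enumeration and wilcox.test", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, sample(c(0, 0.8, 2), 1))
    r <- mann_whitney_u(a, b)
    oracle <- brute_force_mw_p(a, b)
    expect_equal(r$statistic, oracle$U)
    expect_equal(r$p_value, oracle$p, tolerance = 1e-12)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(r$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree for n1 = n2 = 8", {
  # 0.0109 is the worst-case deviation of the continuity-corrected normal
  # approximation from the exact distribution over all U at n1 = n2 = 8
  # (the uncorrected approximation is four times worse)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    pe <- mann_whitney_u(a, b, mode = "exact")$p_value
    pa <- mann_whitney_u(a, b, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.011)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(3)
  a <- rlnorm(12); b <- rlnorm(15, 0.4)
  r0 <- mann_whitney_u(a, b)
  for (f in list(log, sqrt, function(x) x^3, function(x) 5 * x - 2)) {
    rf <- mann_whitney_u(f(a), f(b))
    expect_equal(rf$statistic, r0$statistic)
    expect_equal(rf$p_value, r0$p_value)
  }
})

test_that("t-test: closed-form triple, identical samples, degenerate conventions", {
  r <- t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$p_value,
               2 * stats::pt(-sqrt(3 / 2), df = 4), tolerance = 1e-12)

  ra <- t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ra$statistic, 0); expect_equal(ra$p_value, 1)

  # scale invariance of the statistic
  a <- rnorm(6); b <- rnorm(6, 1)
  expect_equal(t_test(3 * a, 3 * b)$statistic, t_test(a, b)$statistic,
               tolerance = 1e-12)

  expect_equal(t_test(c(2, 2), c(2, 2))$p_value, 1)
  rd <- t_test(c(2, 2), c(3, 3))
  expect_equal(rd$p_value, 0)
  expect_identical(rd$method_note, "degenerate")
})

test_that("comparison plan has fixed cardinality and skips missing groups", {
  plan <- comparison_plan()
  expect_equal(nrow(plan), 12L)

  set.seed(5)
  g <- expand.grid(variable = c("amorphous_pct", "bundle_thickness",
                                "linearity_index", "fibril_size",
                                "interfibrillar_distance", "d_band_length"),
                   condition = c("CT", "HA"), timepoint = c(24, 48),
                   layer = c("papillary", "reticular"),
                   stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    data.frame(variable = g$variable[i], value = rnorm(5),
               condition = g$condition[i], timepoint = g$timepoint[i],
               layer = g$layer[i])))
  cmp <- run_comparison_plan(tab)
  expect_equal(nrow(cmp), 6 * 12)
  expect_true(all(cmp$test[cmp$variable == "d_band_length"] == "t_test"))
  expect_true(all(cmp$test[cmp$variable != "d_band_length"] == "mann_whitney"))
  expect_true(all(cmp$significant == (cmp$p_value < 0.05)))

  tab2 <- tab[!(tab$condition == "HA" & tab$timepoint == 48 &
                  tab$layer == "reticular"), ]
  expect_warning(cmp2 <- run_comparison_plan(tab2), "missing group")
  expect_equal(nrow(cmp2), 6 * 9)  # 3 comparisons touch the missing cell
})
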