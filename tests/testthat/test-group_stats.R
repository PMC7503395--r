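test_that("technical replicates collapse to animal means", {
  gm <- grouped_measurements(
    group = rep("g1", 5),
    value = c(10, 12, 14, 7, 9),
    animal = c("a1", "a1", "a1", "a2", "a2"),
    replicate_mode = "animal_mean_as_unit")
  out <- summarize_replicates(gm)
  expect_equal(sort(out$data$value), c(8, 12))
  expect_identical(out$replicate_mode, "cell_as_unit")
  # cell_as_unit passes through untouched
  gm2 <- grouped_measurements(rep("g1", 3), 1:3)
  expect_identical(summarize_replicates(gm2)$data, gm2$data)
  # many-per-animal cohorts reduce to one value per animal per group
  big <- grouped_measurements(
    group = rep(c("A", "B"), each = 600),
    value = rnorm(1200),
    animal = rep(rep(paste0("r", 1:6), each = 100), 2),
    replicate_mode = "animal_mean_as_unit")
  expect_equal(nrow(summarize_replicates(big)$data), 12)
})

test_that("normality gate selects the omnibus branch deterministically", {
  set.seed(4)
  normal <- grouped_measurements(rep(c("A", "B", "C"), each = 20),
                                 rnorm(60))
  c1 <- compare_groups(normal)
  expect_identical(c1$omnibus_test, "anova")
  expect_identical(c1$posthoc_method, "bonferroni")

  set.seed(4)
  skewed <- grouped_measurements(rep(c("A", "B", "C"), each = 20),
                                 rexp(60)^2)
  c2 <- compare_groups(skewed)
  expect_identical(c2$omnibus_test, "kruskal_wallis")
  expect_identical(c2$posthoc_method, "dunn")

  # identical input gives the identical branch (pure function of inputs)
  set.seed(4)
  again <- compare_groups(grouped_measurements(rep(c("A", "B", "C"),
                                                   each = 20), rnorm(60)))
  expect_identical(again$omnibus_test, c1$omnibus_test)
  expect_equal(again$omnibus_p, c1$omnibus_p)
})

test_that("null and strong-effect cases behave as expected", {
  v <- rep(c(5, 7, 9, 11), 2)
  same <- grouped_measurements(rep(c("A", "B"), each = 4), v)
  cmp <- compare_groups(same, posthoc_always = TRUE)
  expect_gt(cmp$omnibus_p, 0.9)
  expect_true(all(cmp$pairwise_p >= 0.9, na.rm = TRUE))

  set.seed(8)
  eff <- grouped_measurements(rep(c("A", "B"), each = 20),
                              c(rnorm(20), rnorm(20, mean = 2)))
  cmp2 <- compare_groups(eff)
  expect_lt(cmp2$omnibus_p, 0.001)
  expect_false(is.null(cmp2$pairwise_p))
  expect_lt(cmp2$pairwise_p["A", "B"], 0.01)
  # symmetric pairwise matrix
  expect_equal(cmp2$pairwise_p["A", "B"], cmp2$pairwise_p["B", "A"])
})

test_that("group-size and group-count preconditions are enforced", {
  expect_error(compare_groups(grouped_measurements(rep("A", 10),
                                                   rnorm(10))),
               "2 groups")
  gm <- grouped_measurements(c("A", "A", "A", "B", "B"),
                             c(1, 2, 3, 4, 5))
  expect_error(compare_groups(gm), "group B")
})

test_that("Bonferroni pairwise p-values equal min(1, raw * m)", {
  set.seed(12)
  g <- rep(c("A", "B", "C"), each = 15)
  v <- rnorm(45) + rep(c(0, 0.5, 2), each = 15)
  cmp <- compare_groups(grouped_measurements(g, v), posthoc_always = TRUE)
  if (cmp$omnibus_test == "anova") {
    raw <- pairwise.t.test(v, g, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    expect_equal(cmp$pairwise_p["A", "B"],
                 min(1, raw["B", "A"] * 3), tolerance = 1e-9)
    expect_equal(cmp$pairwise_p["B", "C"],
                 min(1, raw["C", "B"] * 3), tolerance = 1e-9)
  } else {
    skip("normality gate rejected the simulated normal data")
  }
})

test_that("Dunn z for two groups squares to the Kruskal-Wallis statistic", {
  set.seed(13)
  v <- c(rexp(12), rexp(14, rate = 0.4))
  g <- rep(c("A", "B"), c(12, 14))
  z <- aismature:::dunn_test(v, g)$z["A", "B"]
  H <- kruskal.test(v, g)$statistic
  expect_equal(unname(z^2), unname(H), tolerance = 1e-9)
})

test_that("significance stars follow the printed cutoffs", {
  expect_identical(significance_stars(c(0.04, 0.0009, 0.2, 0.009)),
                   c("*", "***", "", "**"))
  expect_identical(significance_stars(0.05), "")
  expect_identical(significance_stars(0.001), "**")
})

test_that("render_summary reports box and XY styles with stars", {
  set.seed(14)
  gm <- grouped_measurements(rep(c("A", "B"), each = 20),
                             c(rnorm(20), rnorm(20, 3)))
  cmp <- compare_groups(gm, posthoc_always = TRUE)
  box <- render_summary(cmp, "box")
  expect_true(all(c("median", "q1", "q3", "min", "max") %in%
                    names(box$per_group)))
  xy <- render_summary(cmp, "xy")
  expect_true(all(c("mean", "sd") %in% names(xy$per_group)))
  expect_identical(box$pairs$stars, significance_stars(box$pairs$p))
})
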