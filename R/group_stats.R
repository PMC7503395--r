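# Group statistics: replicate handling, normality-gated omnibus test
# (one-way ANOVA vs Kruskal-Wallis), Bonferroni or Dunn post hoc pairwise
# comparisons, and summary rendering with the conventional star cutoffs.

#' Grouped measurements with replicate structure
#'
#' @param group Factor or character vector of group labels.
#' @param value Numeric measurements (finite).
#' @param animal Animal (biological replicate) identifiers; required for
#'   `replicate_mode = "animal_mean_as_unit"`.
#' @param replicate_mode `"cell_as_unit"` (each measurement is an
#'   independent sample, as for single-neuron recordings) or
#'   `"animal_mean_as_unit"` (measurements are technical replicates averaged
#'   per animal, as for AIS morphometry).
#' @return An object of class `"grouped_measurements"`.
#' @export
grouped_measurements <- function(group, value, animal = NULL,
                                 replicate_mode = c("cell_as_unit",
                                                    "animal_mean_as_unit")) {
  replicate_mode <- match.arg(replicate_mode)
  if (length(group) != length(value)) {
    stop("group and value must have equal length", call. = FALSE)
  }
  if (!all(is.finite(value))) stop("values must be finite", call. = FALSE)
  if (is.null(animal)) {
    if (replicate_mode == "animal_mean_as_unit") {
      stop("animal ids are required for animal_mean_as_unit", call. = FALSE)
    }
    animal <- as.character(seq_along(value))
  }
  structure(list(data = data.frame(group = as.character(group),
                                   animal = as.character(animal),
                                   value = as.numeric(value),
                                   stringsAsFactors = FALSE),
                 replicate_mode = replicate_mode),
            class = "grouped_measurements")
}

#' Collapse technical replicates to the unit of analysis
#'
#' Under `animal_mean_as_unit`, measurements are averaged per animal (one
#' value per biological replicate); animals without measurements are
#' excluded with a warning. Under `cell_as_unit` the data pass through
#' unchanged.
#'
#' @param gm A [grouped_measurements()].
#' @return A [grouped_measurements()] in `cell_as_unit` form.
#' @export
summarize_replicates <- function(gm) {
  stopifnot(inherits(gm, "grouped_measurements"))
  if (gm$replicate_mode == "cell_as_unit") return(gm)
  d <- gm$data
  agg <- stats::aggregate(value ~ group + animal, data = d, FUN = mean)
  grouped_measurements(agg$group, agg$value, agg$animal,
                       replicate_mode = "cell_as_unit")
}

# Dunn's test: pairwise rank-based z statistics after Kruskal-Wallis, with
# the standard tie correction; two-sided p-values, Bonferroni-adjusted.
dunn_test <- function(value, group) {
  g <- factor(group)
  k <- nlevels(g)
  N <- length(value)
  r <- rank(value)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  labs <- levels(g)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  z <- p
  m <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
      zij <- (rbar[i] - rbar[j]) / se
      pij <- min(1, 2 * stats::pnorm(-abs(zij)) * m)
      z[i, j] <- z[j, i] <- zij
      p[i, j] <- p[j, i] <- pij
    }
  }
  list(p = p, z = z)
}

# Bonferroni pairwise t tests (pooled SD, as in the classical ANOVA post
# hoc); symmetric matrix of adjusted p-values.
bonferroni_t <- function(value, group) {
  g <- factor(group)
  labs <- levels(g)
  pt <- stats::pairwise.t.test(value, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  k <- length(labs)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in rownames(pt$p.value)) {
    for (j in colnames(pt$p.value)) {
      if (!is.na(pt$p.value[i, j])) {
        p[i, j] <- p[j, i] <- pt$p.value[i, j]
      }
    }
  }
  p
}

#' Compare groups with the normality-gated omnibus pipeline
#'
#' Each group is first tested for normality (Shapiro-Wilk). If every group
#' passes at `alpha`, the omnibus test is one-way ANOVA with
#' Bonferroni-corrected pairwise t tests post hoc; otherwise
#' Kruskal-Wallis with Dunn's multiple-comparison test. Post hoc p-values
#' are computed when the omnibus test is significant (or always, with
#' `posthoc_always = TRUE`). Technical replicates are collapsed first via
#' [summarize_replicates()].
#'
#' @param gm A [grouped_measurements()] with >= 2 groups of >= 3 values.
#' @param alpha Significance level for the normality gate and the omnibus
#'   gate.
#' @param posthoc_always Compute pairwise p-values regardless of the omnibus
#'   outcome.
#' @return An object of class `"group_comparison"`: `omnibus_test`
#'   (`"anova"` or `"kruskal_wallis"`), `omnibus_p`, `normality_p`,
#'   `posthoc_method`, `pairwise_p` (symmetric matrix or `NULL`),
#'   `summaries` (per-group n, mean, sd, median, q1, q3, min, max), `alpha`.
#' @export
compare_groups <- function(gm, alpha = 0.05, posthoc_always = FALSE) {
  stopifnot(inherits(gm, "grouped_measurements"))
  gm <- summarize_replicates(gm)
  d <- gm$data
  counts <- table(d$group)
  if (length(counts) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    stop("insufficient data: fewer than 3 values in group ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  norm_p <- vapply(split(d$value, d$group), function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-normal branch
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  all_normal <- all(norm_p > alpha)
  if (all_normal) {
    fit <- stats::aov(value ~ group, data = d)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    test <- "anova"; posthoc_method <- "bonferroni"
  } else {
    omnibus_p <- stats::kruskal.test(value ~ group, data = d)$p.value
    test <- "kruskal_wallis"; posthoc_method <- "dunn"
  }
  pairwise_p <- NULL
  if (posthoc_always || (is.finite(omnibus_p) && omnibus_p < alpha)) {
    pairwise_p <- if (test == "anova") {
      bonferroni_t(d$value, d$group)
    } else {
      dunn_test(d$value, d$group)$p
    }
  }
  summaries <- do.call(rbind, lapply(split(d$value, d$group), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               median = q[2], q1 = q[1], q3 = q[3],
               min = min(v), max = max(v))
  }))
  summaries <- cbind(group = rownames(summaries), summaries)
  rownames(summaries) <- NULL
  structure(list(omnibus_test = test, omnibus_p = omnibus_p,
                 normality_p = norm_p, posthoc_method = posthoc_method,
                 pairwise_p = pairwise_p, summaries = summaries,
                 alpha = alpha, replicate_mode = gm$replicate_mode),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: p = %.4g (%s post hoc)\n",
              x$omnibus_test, x$omnibus_p, x$posthoc_method))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Significance stars at the conventional cutoffs
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Render a group comparison as report tables
#'
#' Box-plot style reports median/IQR/min-max; XY style reports mean +/- SD.
#' Pairwise comparisons carry significance stars at the printed cutoffs
#' (p < 0.05 / 0.01 / 0.001).
#'
#' @param cmp A [group_comparison()].
#' @param style `"box"` or `"xy"`.
#' @return List with `per_group` and `pairs` data.frames.
#' @export
render_summary <- function(cmp, style = c("box", "xy")) {
  stopifnot(inherits(cmp, "group_comparison"))
  style <- match.arg(style)
  s <- cmp$summaries
  per_group <- if (style == "box") {
    s[, c("group", "n", "median", "q1", "q3", "min", "max")]
  } else {
    s[, c("group", "n", "mean", "sd")]
  }
  pairs <- NULL
  if (!is.null(cmp$pairwise_p)) {
    labs <- rownames(cmp$pairwise_p)
    idx <- which(upper.tri(cmp$pairwise_p), arr.ind = TRUE)
    pairs <- data.frame(group1 = labs[idx[, 1]], group2 = labs[idx[, 2]],
                        p = cmp$pairwise_p[idx],
                        stars = significance_stars(cmp$pairwise_p[idx]),
                        stringsAsFactors = FALSE)
  }
  list(per_group = per_group, pairs = pairs,
       omnibus = data.frame(test = cmp$omnibus_test, p = cmp$omnibus_p,
                            stars = significance_stars(cmp$omnibus_p)))
}
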