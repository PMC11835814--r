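#' @title Cross-context statistical tests
#' @description Thin, uniformly-shaped wrappers around the classical tests
#'   used to compare song statistics across social contexts. Every function
#'   returns a `seq_test_result` with the statistic, degrees of freedom,
#'   p-value and, where meaningful, an effect direction, so results can be
#'   exported as one tidy CSV.
#' @name inference
NULL

.new_test_result <- function(statistic_name, statistic, df, p_value,
                             groups = NULL, effect_direction = NA_character_,
                             extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(c(list(statistic_name = statistic_name,
                   statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), groups = groups,
                   effect_direction = effect_direction), extra),
            class = "seq_test_result")
}

#' @export
print.seq_test_result <- function(x, ...) {
  df_txt <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(x$statistic_name, " = ", format(x$statistic, digits = 4),
      ", df = ", df_txt, ", p = ", format(x$p_value, digits = 4), "\n",
      sep = "")
  if (!is.na(x$effect_direction)) cat("direction:", x$effect_direction, "\n")
  invisible(x)
}

#' Two-proportion test
#'
#' Chi-square test of equal success proportions in two samples, used for the
#' per-bird comparison of target-branch counts between baseline and the best
#' training day. Continuity correction is applied by default.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param continuity Apply Yates continuity correction. Default `TRUE`.
#' @param groups Optional labels for the two groups.
#' @return A `seq_test_result`; `effect_direction` is `"decrease"` when the
#'   second group's proportion is lower, `"increase"` when higher.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, continuity = TRUE,
                                groups = c("group1", "group2")) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  res <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = continuity))
  p1 <- k1 / n1
  p2 <- k2 / n2
  dir <- if (p2 < p1) "decrease" else if (p2 > p1) "increase" else "none"
  .new_test_result("X-squared", res$statistic, res$parameter, res$p.value,
                   groups = groups, effect_direction = dir,
                   extra = list(proportions = c(p1, p2)))
}

#' One-way ANOVA with Tukey pairwise comparisons
#'
#' Omnibus F-test for a group factor (e.g. social context) followed by
#' Tukey honest-significant-difference pairwise comparisons.
#'
#' @param values Numeric response.
#' @param group Factor (or coercible) of group membership; at least two
#'   groups with at least two observations each.
#' @return A `seq_test_result` with an extra `pairwise` data frame
#'   (`comparison`, `diff`, `p_adj`).
#' @export
oneway_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  fstat <- tab["group", "F value"]
  p <- tab["group", "Pr(>F)"]
  if (tab["group", "Sum Sq"] <= .Machine$double.eps * sum(values^2 + 1)) {
    fstat <- 0
    p <- 1
  }
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  .new_test_result("F", fstat, c(tab["group", "Df"], tab["Residuals", "Df"]),
                   min(1, p), groups = levels(group),
                   extra = list(pairwise = pairwise))
}

#' Main-effects N-way ANOVA
#'
#' Fits a least-squares model with main effects only (no interactions) for
#' the supplied factors and reports an F-test per factor, each adjusted for
#' the others (Type II). For the balanced within-subject design of six
#' subjects by three contexts with a balanced context order, the error
#' degrees of freedom are `N - 1 - sum(levels - 1) = 8`.
#'
#' @param values Numeric response.
#' @param factors Named list (or data frame) of factors, e.g.
#'   `list(context = ..., order = ..., subject = ...)`.
#' @return Named list of `seq_test_result`, one per factor.
#' @export
nway_anova_main_effects <- function(values, factors) {
  factors <- as.data.frame(lapply(factors, factor),
                           stringsAsFactors = TRUE)
  stopifnot(nrow(factors) == length(values), ncol(factors) >= 1)
  dat <- cbind(data.frame(.y = values), factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors),
                                                collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (stats::var(values) <= .Machine$double.eps * mean(values^2 + 1)) {
    # constant response: every effect is exactly zero
    df_res <- length(values) - 1 -
      sum(vapply(factors, nlevels, 0L) - 1L)
    return(stats::setNames(lapply(names(factors), function(f) {
      .new_test_result("F", 0, c(nlevels(factors[[f]]) - 1L, df_res), 1,
                       groups = levels(factors[[f]]))
    }), names(factors)))
  }
  dd <- stats::drop1(fit, test = "F")
  df_res <- fit$df.residual
  ss_res <- sum(stats::residuals(fit)^2)
  out <- list()
  for (f in names(factors)) {
    fstat <- dd[f, "F value"]
    p <- dd[f, "Pr(>F)"]
    if (ss_res <= .Machine$double.eps * sum(values^2 + 1) &&
        dd[f, "Sum of Sq"] <= .Machine$double.eps * sum(values^2 + 1)) {
      fstat <- 0; p <- 1
    }
    out[[f]] <- .new_test_result("F", fstat, c(dd[f, "Df"], df_res),
                                 min(1, p), groups = levels(factors[[f]]))
  }
  out
}

#' Paired t-test
#'
#' Two-sided paired t-test on the within-subject differences `x - y`.
#'
#' @param x,y Numeric vectors of equal length (>= 2), paired by position.
#' @return A `seq_test_result`; when the differences have zero variance the
#'   result is flagged `degenerate` with `NA` statistic and p-value 1 for a
#'   zero mean difference.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    # zero variance of differences: t is degenerate; an exactly zero shift
    # is reported as no evidence (t = 0, p = 1)
    return(.new_test_result("t", if (mean(d) == 0) 0 else NA_real_,
                            length(d) - 1,
                            if (mean(d) == 0) 1 else NA_real_,
                            effect_direction = if (mean(d) > 0) "increase"
                            else if (mean(d) < 0) "decrease" else "none",
                            extra = list(degenerate = TRUE,
                                         mean_difference = mean(d))))
  }
  res <- stats::t.test(x, y, paired = TRUE)
  dir <- if (mean(d) > 0) "increase" else if (mean(d) < 0) "decrease"
  else "none"
  .new_test_result("t", res$statistic, res$parameter, res$p.value,
                   effect_direction = dir,
                   extra = list(degenerate = FALSE,
                                mean_difference = mean(d)))
}

#' Pearson correlation test
#'
#' Pearson's r with the two-sided p-value from the t transform,
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `seq_test_result` with `statistic` = r and `df` = n - 2.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance input")
  }
  res <- stats::cor.test(x, y, method = "pearson")
  .new_test_result("r", res$estimate, res$parameter, res$p.value,
                   effect_direction = if (res$estimate > 0) "positive"
                   else if (res$estimate < 0) "negative" else "none",
                   extra = list(t_statistic = unname(res$statistic)))
}

#' Export test results as a tidy CSV
#'
#' @param results Named list of `seq_test_result` (nested lists are
#'   flattened with dotted names).
#' @param path Output CSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_test_results <- function(results, path) {
  flat <- list()
  add <- function(name, r) {
    if (inherits(r, "seq_test_result")) {
      flat[[name]] <<- r
    } else if (is.list(r)) {
      for (nm in names(r)) add(paste(name, nm, sep = "."), r[[nm]])
    }
  }
  for (nm in names(results)) add(nm, results[[nm]])
  df <- do.call(rbind, lapply(names(flat), function(nm) {
    r <- flat[[nm]]
    data.frame(test = nm, statistic_name = r$statistic_name,
               statistic = r$statistic,
               df = paste(format(r$df), collapse = ";"),
               p = r$p_value,
               groups = paste(r$groups, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
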