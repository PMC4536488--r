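# ---------------------------------------------------------------------------
# Statistical layer: per-experiment normalization to the control median
# (set to 100%), natural-log transform, chi-square normality test, one-way
# ANOVA with Dunnett many-to-one post-hoc comparisons against the control
# (two-dataset case: two-sided Student's t-test), and median summaries for
# dot plots.  All tests run on the log-transformed data; dot-plot
# summaries use the untransformed normalized data.
# ---------------------------------------------------------------------------

#' Bundle the per-donor-cell transfer intensities of one condition
#'
#' @param condition condition label.
#' @param values per-donor-cell integrated transfer intensities
#'   (nonnegative).
#' @param is_control whether this is the control condition of its
#'   comparison set.
#' @param background optional per-control-stack background intensities.
#' @param experiment optional per-value experiment/batch labels, carried
#'   through summaries for users who analyse batches separately; the
#'   comparison itself pools values across experiments.
#' @return An object of class `condition_dataset`.
#' @export
condition_dataset <- function(condition, values, is_control = FALSE,
                              background = NULL, experiment = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  if (!is.null(experiment) && length(experiment) != length(values))
    stop("experiment labels must match values in length")
  structure(list(condition = as.character(condition), values = values,
                 is_control = isTRUE(is_control), background = background,
                 experiment = experiment),
            class = "condition_dataset")
}

find_control <- function(datasets) {
  ic <- vapply(datasets, function(d) d$is_control, logical(1))
  if (sum(ic) != 1L)
    stop("exactly one control condition is required, found ", sum(ic))
  which(ic)
}

#' Normalize conditions to the control median (= 100%)
#'
#' Every value of every condition is multiplied by `100 / median(control)`,
#' so the control median becomes exactly 100. Idempotent; invariant under
#' positive rescaling of the raw intensities.
#'
#' @param datasets list of [condition_dataset]s containing exactly one
#'   control.
#' @return the list with normalized values (and backgrounds).
#' @export
normalize_to_control <- function(datasets) {
  ci <- find_control(datasets)
  med <- stats::median(datasets[[ci]]$values)
  if (!is.finite(med) || med <= 0)
    stop("control median must be strictly positive")
  f <- 100 / med
  lapply(datasets, function(d) {
    d$values <- d$values * f
    if (!is.null(d$background)) d$background <- d$background * f
    d
  })
}

#' Natural-log transform of intensity values
#'
#' Transfer intensities are right-skewed; tests run on `log(values)`.
#' Zero values (possible for fully inhibited donors) cannot be logged;
#' they are replaced by a configurable pseudo-count when one is supplied,
#' and are an error otherwise.
#'
#' @param values numeric vector.
#' @param pseudo_count replacement for nonpositive values (intensity
#'   units); `NULL` makes nonpositive values an error.
#' @return log-transformed vector; attribute `n_pseudo` counts
#'   replacements.
#' @export
log_transform <- function(values, pseudo_count = NULL) {
  nz <- sum(values <= 0)
  if (nz > 0) {
    if (is.null(pseudo_count))
      stop(nz, " nonpositive value(s): supply pseudo_count or filter them")
    values[values <= 0] <- pseudo_count
  }
  out <- log(values)
  attr(out, "n_pseudo") <- nz
  out
}

#' Chi-square goodness-of-fit test for normality
#'
#' Bins the sample into equal-probability bins of a normal distribution
#' with the sample mean and SD (`ceil(n/5)` bins, capped at 20), and
#' compares observed to expected counts; degrees of freedom = bins - 3
#' (two estimated parameters).
#'
#' @param values numeric vector, `n >= 30`.
#' @return list with `statistic`, `df`, `p.value`, `bins`.
#' @export
test_normality <- function(values) {
  n <- length(values)
  if (n < 30) stop("normality test requires n >= 30")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero standard deviation")
  k <- min(ceiling(n / 5), 20)
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1), mean(values), s)
  breaks[1] <- -Inf; breaks[k + 1] <- Inf
  obs <- tabulate(findInterval(values, breaks, left.open = TRUE,
                               rightmost.closed = TRUE), nbins = k)
  expd <- n / k
  stat <- sum((obs - expd)^2 / expd)
  df <- k - 3
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), bins = k)
}

#' Compare conditions against the control
#'
#' Normalizes to the control median, log-transforms, then: with two
#' datasets, a two-sided Student's t-test (equal variances by default, the
#' classic form; `welch = TRUE` for the unequal-variance variant); with
#' more, one-way ANOVA followed by Dunnett's many-to-one post-hoc test
#' against the control, with adjusted p-values from the multivariate-t
#' distribution. Significance at `alpha`.
#'
#' @param datasets list of [condition_dataset]s with exactly one control;
#'   each needs at least 2 values.
#' @param alpha significance level (0.05).
#' @param pseudo_count replacement for zero intensities before the log
#'   transform (normalized scale); `NULL` = error on zeros.
#' @param welch use Welch's t-test in the two-dataset case.
#' @param normality run the chi-square normality test per condition where
#'   `n >= 30`.
#' @return An object of class `codeit_stat_report`; see
#'   [print.codeit_stat_report].
#' @export
compare_conditions <- function(datasets, alpha = 0.05, pseudo_count = 1,
                               welch = FALSE, normality = TRUE) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  ns <- vapply(datasets, function(d) length(d$values), integer(1))
  if (any(ns < 2)) stop("every dataset needs at least 2 values")
  ci <- find_control(datasets)
  norm <- normalize_to_control(datasets)
  conds <- vapply(norm, function(d) d$condition, character(1))
  if (anyDuplicated(conds)) stop("condition labels must be unique")

  trans <- lapply(norm, function(d) log_transform(d$values, pseudo_count))
  n_pseudo <- sum(vapply(trans, function(v) attr(v, "n_pseudo"), numeric(1)))

  norm_tests <- if (normality) lapply(seq_along(norm), function(i) {
    if (ns[i] >= 30) test_normality(as.numeric(trans[[i]])) else NULL
  }) else vector("list", length(norm))

  medians <- data.frame(
    condition = conds,
    n = ns,
    median_pct = vapply(norm, function(d) stats::median(d$values), numeric(1)),
    is_control = seq_along(norm) == ci,
    stringsAsFactors = FALSE)

  others <- setdiff(seq_along(norm), ci)
  mean_ctl <- mean(trans[[ci]])
  p_unadj <- vapply(others, function(i)
    stats::t.test(as.numeric(trans[[i]]), as.numeric(trans[[ci]]),
                  var.equal = !welch)$p.value, numeric(1))

  if (length(datasets) == 2L) {
    method <- if (welch) "welch_t" else "student_t"
    p_adj <- p_unadj
    f_stat <- NA_real_; f_p <- NA_real_
    estimates <- mean(trans[[others]]) - mean_ctl
  } else {
    method <- "anova_dunnett"
    df <- data.frame(
      value = unlist(lapply(trans, as.numeric)),
      group = factor(rep(conds, ns), levels = c(conds[ci], conds[others])))
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    f_stat <- an[1, "F value"]; f_p <- an[1, "Pr(>F)"]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    p_adj <- as.numeric(sm$test$pvalues)
    estimates <- as.numeric(sm$test$coefficients)
  }
  comparisons <- data.frame(
    condition = conds[others],
    log_mean_difference = estimates,
    p_unadjusted = p_unadj,
    p_adjusted = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE)

  structure(list(method = method, alpha = alpha,
                 control = conds[ci],
                 medians = medians,
                 anova = list(F = f_stat, p.value = f_p),
                 comparisons = comparisons,
                 normality = stats::setNames(norm_tests, conds),
                 n_pseudo_replaced = n_pseudo),
            class = "codeit_stat_report")
}

#' @export
print.codeit_stat_report <- function(x, ...) {
  cat("Transfer-intensity comparison (control: ", x$control, ", alpha = ",
      x$alpha, ")\n", sep = "")
  cat("Normalized medians (% of control):\n")
  print(x$medians, row.names = FALSE)
  if (x$method == "anova_dunnett")
    cat(sprintf("ANOVA: F = %.3f, p = %.3g; Dunnett post-hoc:\n",
                x$anova$F, x$anova$p.value))
  else
    cat("Two-sided ", if (x$method == "welch_t") "Welch" else "Student",
        " t-test:\n", sep = "")
  print(x$comparisons, row.names = FALSE)
  if (x$n_pseudo_replaced > 0)
    cat("note:", x$n_pseudo_replaced,
        "zero value(s) replaced by the pseudo-count before log transform\n")
  invisible(x)
}

#' @export
summary.codeit_stat_report <- function(object, ...) {
  print(object, ...)
  nt <- Filter(Negate(is.null), object$normality)
  if (length(nt)) {
    cat("Normality (chi-square GOF on log scale):\n")
    for (nm in names(nt))
      cat(sprintf("  %s: X2 = %.2f, df = %d, p = %.3f\n",
                  nm, nt[[nm]]$statistic, nt[[nm]]$df, nt[[nm]]$p.value))
  }
  invisible(object)
}

#' Per-condition medians and dot-plot export table
#'
#' Medians on the untransformed (normalized) scale, plus the per-value long
#' table used for dot plots.
#'
#' @param datasets list of [condition_dataset]s (normalized).
#' @return list with `medians` (condition, n, median) and `points`
#'   (condition, value).
#' @export
summarize_medians <- function(datasets) {
  conds <- vapply(datasets, function(d) d$condition, character(1))
  medians <- data.frame(
    condition = conds,
    n = vapply(datasets, function(d) length(d$values), integer(1)),
    median = vapply(datasets, function(d) stats::median(d$values), numeric(1)),
    stringsAsFactors = FALSE)
  points <- data.frame(
    condition = rep(conds, medians$n),
    value = unlist(lapply(datasets, function(d) d$values)),
    experiment = unlist(lapply(datasets, function(d)
      if (is.null(d$experiment)) rep(NA_character_, length(d$values))
      else as.character(d$experiment))),
    stringsAsFactors = FALSE)
  list(medians = medians, points = points)
}
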