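#' Normality tests per group
#'
#' Shapiro-Wilk and Lilliefors-corrected Kolmogorov-Smirnov (normal null
#' with estimated mean and SD) for each group of per-subject values.
#'
#' @param data A data frame of per-subject scalars.
#' @param value Column of values (ms or Z), tidy-eval.
#' @param group Optional grouping column; omitted means one group.
#' @return A tibble with one row per group x test: `group`, `method`,
#'   `statistic`, `p_value`, `n`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 20), v = rnorm(40))
#' normality_tests(d, v, g)
#' @export
normality_tests <- function(data, value, group = NULL) {
  samples <- split_groups(data, {{ value }}, {{ group }})
  purrr::imap_dfr(samples, function(v, lbl) {
    if (length(v) < 3) abort("Normality tests need n >= 3 per group.")
    if (sd(v) == 0) {
      abort(sprintf("Group '%s' is constant: normality tests are degenerate.",
                    lbl))
    }
    sw <- shapiro.test(v)
    ks <- nortest::lillie.test(v)
    tibble(group = lbl,
           method = c("Shapiro-Wilk", "Kolmogorov-Smirnov (Lilliefors)"),
           statistic = c(unname(sw$statistic), unname(ks$statistic)),
           p_value = c(sw$p.value, ks$p.value), n = length(v))
  })
}

#' Levene's test of variance homogeneity (center = mean)
#'
#' @param data A data frame of per-subject scalars.
#' @param value Value column, tidy-eval.
#' @param group Grouping column (>= 2 groups, each n >= 2).
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`, `method`.
#' @export
variance_homogeneity <- function(data, value, group) {
  samples <- split_groups(data, {{ value }}, {{ group }})
  check_groups(samples, min_groups = 2, min_n = 2)
  v <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)))
  lt <- car::leveneTest(v, g, center = mean)
  tibble(statistic = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
         p_value = lt[1, "Pr(>F)"], method = "Levene (center = mean)")
}

#' One-way omnibus test: classic or Welch ANOVA
#'
#' In `"auto"` mode the variance-homogeneity gate decides: classic one-way
#' ANOVA when Levene's p >= 0.05, Welch's ANOVA (no pooled variance)
#' otherwise — the standard conditional procedure for multi-platform T1
#' comparisons. Both modes are also callable explicitly.
#'
#' @param data A data frame of per-subject scalars.
#' @param value Value column, tidy-eval.
#' @param group Grouping column (>= 2 groups, each n >= 2).
#' @param mode `"auto"`, `"classic"` or `"welch"`.
#' @param levene_alpha Gate level for the auto mode.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `method`, `levene_p` (`NA` unless auto mode).
#' @export
omnibus_anova <- function(data, value, group,
                          mode = c("auto", "classic", "welch"),
                          levene_alpha = 0.05) {
  mode <- match.arg(mode)
  samples <- split_groups(data, {{ value }}, {{ group }})
  check_groups(samples, min_groups = 2, min_n = 2)
  if (all(purrr::map_dbl(samples, sd) == 0)) {
    abort("All groups are constant: the omnibus test is degenerate.")
  }
  v <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)))
  levene_p <- NA_real_
  if (mode == "auto") {
    lt <- car::leveneTest(v, g, center = mean)
    levene_p <- lt[1, "Pr(>F)"]
    mode <- if (levene_p >= levene_alpha) "classic" else "welch"
  }
  res <- oneway.test(v ~ g, var.equal = (mode == "classic"))
  tibble(statistic = unname(res$statistic),
         df1 = unname(res$parameter[[1]]), df2 = unname(res$parameter[[2]]),
         p_value = res$p.value,
         method = if (mode == "classic") "one-way ANOVA" else "Welch's ANOVA",
         levene_p = levene_p)
}

#' Bonferroni-adjusted pairwise independent t-tests
#'
#' Every pair of groups is compared with an independent t-test and the raw
#' p-value is multiplied by the number of pairs `choose(k, 2)`, clamped at
#' 1. The family is all pairwise comparisons within the supplied groups
#' (run the function separately per field strength to mirror per-field
#' post-hoc families).
#'
#' @param data A data frame of per-subject scalars.
#' @param value Value column, tidy-eval.
#' @param group Grouping column.
#' @param var_equal Pooled-variance t-tests when `TRUE` (the classic
#'   post-hoc convention); Welch otherwise.
#' @return A tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p_raw`, `p_adjusted`, `n_pairs`.
#' @export
bonferroni_pairwise <- function(data, value, group, var_equal = TRUE) {
  samples <- split_groups(data, {{ value }}, {{ group }})
  check_groups(samples, min_groups = 2, min_n = 2)
  labs <- names(samples)
  pairs <- utils::combn(labs, 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(j) {
    a <- samples[[pairs[1, j]]]; b <- samples[[pairs[2, j]]]
    tt <- safe_t_test(a, b, var.equal = var_equal)
    tibble(group1 = pairs[1, j], group2 = pairs[2, j],
           statistic = tt$statistic, p_raw = tt$p_value,
           p_adjusted = min(1, tt$p_value * n_pairs), n_pairs = n_pairs)
  })
}

#' Pairwise results as a symmetric adjusted-p matrix
#'
#' @param pairwise A [bonferroni_pairwise()] result.
#' @return A symmetric numeric matrix of adjusted p-values with `NA`
#'   diagonal.
#' @export
pairwise_p_matrix <- function(pairwise) {
  labs <- unique(c(pairwise$group1, pairwise$group2))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (j in seq_len(nrow(pairwise))) {
    m[pairwise$group1[[j]], pairwise$group2[[j]]] <- pairwise$p_adjusted[[j]]
    m[pairwise$group2[[j]], pairwise$group1[[j]]] <- pairwise$p_adjusted[[j]]
  }
  m
}

#' Independent two-sample t-test between two groups
#'
#' @param data A data frame containing exactly two groups.
#' @param value Value column, tidy-eval.
#' @param group Grouping column.
#' @param var_equal Pooled variance when `TRUE`; Welch (default) otherwise.
#' @return A one-row tibble: `statistic` (t, group1 minus group2), `df`
#'   (fractional under Welch), `p_value`, `mean_diff`, `method`.
#' @export
independent_t_test <- function(data, value, group, var_equal = FALSE) {
  samples <- split_groups(data, {{ value }}, {{ group }})
  if (length(samples) != 2) abort("Exactly 2 groups are required.")
  check_groups(samples, min_groups = 2, min_n = 2)
  tt <- safe_t_test(samples[[1]], samples[[2]], var.equal = var_equal)
  tibble(statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
         mean_diff = mean(samples[[1]]) - mean(samples[[2]]),
         method = if (var_equal) "pooled t-test" else "Welch t-test")
}

# t.test wrapper with the degenerate-data convention: two constant samples
# with equal means are "no difference" (t = 0, p = 1), logged.
safe_t_test <- function(a, b, var.equal = FALSE, ...) {
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warn("Both groups constant with equal means: returning t = 0, p = 1.")
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    abort("Both groups constant with different means: t-test undefined.")
  }
  tt <- t.test(a, b, var.equal = var.equal, ...)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' TOST equivalence test between two groups
#'
#' Two one-sided t-tests of the null "the mean difference is at least
#' `epsilon` in magnitude": one test of `diff <= -epsilon` against
#' `diff > -epsilon` and one of `diff >= epsilon` against `diff < epsilon`,
#' both Welch by default. Equivalence within the region of similarity
#' `(-epsilon, epsilon)` is concluded when both reject;
#' `p_tost = max(p1, p2)`. The reported interval is the `(1 - 2 alpha)`
#' confidence interval for the difference (90% at alpha = 0.05, the
#' standard TOST interval); set `ci_level` to report another level.
#'
#' @param data A data frame containing exactly two groups.
#' @param value Value column, tidy-eval (typically mean Z).
#' @param group Grouping column.
#' @param epsilon Half-width of the region of similarity (> 0), same units
#'   as `value`.
#' @param alpha One-sided test level; equivalence is concluded when
#'   `p_tost < alpha`.
#' @param ci_level Confidence level of the reported interval; defaults to
#'   `1 - 2 * alpha`.
#' @param var_equal Pooled variance when `TRUE`; Welch (default) otherwise.
#' @return A one-row tibble: `epsilon`, `p_tost`, `p_lower`, `p_upper`,
#'   `ci_lower`, `ci_upper`, `ci_level`, `mean_diff`, `df`, `equivalent`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 15), v = rnorm(30))
#' tost_equivalence(d, v, g, epsilon = 3)
#' @export
tost_equivalence <- function(data, value, group, epsilon, alpha = 0.05,
                             ci_level = NULL, var_equal = FALSE) {
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  samples <- split_groups(data, {{ value }}, {{ group }})
  if (length(samples) != 2) abort("Exactly 2 groups are required.")
  check_groups(samples, min_groups = 2, min_n = 2)
  ci_level <- ci_level %||% (1 - 2 * alpha)
  a <- samples[[1]]; b <- samples[[2]]
  t_lo <- t.test(a, b, mu = -epsilon, alternative = "greater",
                 var.equal = var_equal)
  t_hi <- t.test(a, b, mu = epsilon, alternative = "less",
                 var.equal = var_equal)
  ci <- t.test(a, b, var.equal = var_equal, conf.level = ci_level)$conf.int
  p_tost <- max(t_lo$p.value, t_hi$p.value)
  tibble(epsilon = epsilon, p_tost = p_tost,
         p_lower = t_lo$p.value, p_upper = t_hi$p.value,
         ci_lower = ci[[1]], ci_upper = ci[[2]], ci_level = ci_level,
         mean_diff = mean(a) - mean(b), df = unname(t_lo$parameter),
         equivalent = p_tost < alpha)
}

#' Classify subjects against a normal range
#'
#' A subject is abnormal when its mean value lies outside the open interval
#' `(mean - k SD, mean + k SD)` — equivalently when `|Z| > k`. The boundary
#' (exactly k SDs from the mean) counts as normal: the inequality is
#' strict. Classifying raw T1 in ms against a reference and classifying the
#' subject's mean Z against the threshold give identical labels.
#'
#' @param data A data frame of per-subject mean values.
#' @param value Value column, tidy-eval.
#' @param ref A [build_reference_stats()] result when `units = "ms"`;
#'   ignored for `units = "z"`.
#' @param k SD-multiplier threshold (the standard clinical choice is 2).
#' @param units `"ms"` (values are T1 means, normalized via `ref`) or
#'   `"z"` (values are already mean Z-scores).
#' @param sidedness `"two"` flags both elevation and reduction; `"high"`
#'   flags only elevation (amyloidosis-style questions).
#' @return The input tibble with columns `z` and `label`
#'   (`"normal"`/`"abnormal"`) appended.
#' @examples
#' r <- build_reference_stats(c(970, 1000, 1030),
#'                            platform_key(1.5, "V", "S", "M"))
#' classify_subjects(data.frame(t1 = c(1000, 1075)), t1, ref = r)
#' @export
classify_subjects <- function(data, value, ref = NULL, k = 2,
                              units = c("ms", "z"),
                              sidedness = c("two", "high")) {
  units <- match.arg(units)
  sidedness <- match.arg(sidedness)
  if (k <= 0) abort("`k` must be positive.")
  v <- dplyr::pull(data, {{ value }})
  z <- if (units == "ms") {
    stopifnot(inherits(ref, "t1z_ref"))
    if (!ref$usable) abort("Reference is unusable (sd = 0): cannot classify.")
    (v - ref$mean) / ref$sd
  } else {
    as.numeric(v)
  }
  abnormal <- if (sidedness == "two") abs(z) > k else z > k
  dplyr::mutate(as_tibble(data), z = z,
                label = ifelse(abnormal, "abnormal", "normal"))
}

#' Sensitivity and specificity of a binary classification
#'
#' @param data A data frame with one row per subject.
#' @param truth Column of true labels, tidy-eval.
#' @param predicted Column of predicted labels, tidy-eval.
#' @param positive The label counted as disease-positive.
#' @param negative The label counted as disease-negative.
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`
#'   (`tp / (tp + fn)`), `specificity` (`tn / (tn + fp)`); a proportion is
#'   `NA` (with a warning) when its class is empty.
#' @examples
#' d <- data.frame(truth = c(rep("abnormal", 25), rep("normal", 14)),
#'                 pred = c(rep("abnormal", 24), "normal",
#'                          rep("normal", 14)))
#' diagnostic_performance(d, truth, pred)
#' @export
diagnostic_performance <- function(data, truth, predicted,
                                   positive = "abnormal",
                                   negative = "normal") {
  tr <- as.character(dplyr::pull(data, {{ truth }}))
  pr <- as.character(dplyr::pull(data, {{ predicted }}))
  if (length(tr) != length(pr)) abort("Label vectors differ in length.")
  levels_ok <- c(positive, negative)
  if (!all(tr %in% levels_ok) || !all(pr %in% levels_ok)) {
    abort(sprintf("Labels must be binary: '%s' or '%s'.", positive, negative))
  }
  tp <- sum(tr == positive & pr == positive)
  fn <- sum(tr == positive & pr == negative)
  tn <- sum(tr == negative & pr == negative)
  fp <- sum(tr == negative & pr == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warn("No disease-positive subjects: sensitivity undefined.")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warn("No disease-negative subjects: specificity undefined.")
    NA_real_
  }
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = sens, specificity = spec)
}

# --- internals ------------------------------------------------------------

# Split a data frame into named numeric samples by an optional group column.
split_groups <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ value }})
  if (!is.numeric(v)) abort("`value` must be numeric.")
  if (any(!is.finite(v))) abort("Values must be finite.")
  gq <- enquo(group)
  if (rlang::quo_is_null(gq)) return(list(all = v))
  g <- dplyr::pull(data, !!gq)
  split(v, factor(g))
}

check_groups <- function(samples, min_groups, min_n) {
  if (length(samples) < min_groups) {
    abort(sprintf("At least %d groups are required.", min_groups))
  }
  bad <- lengths(samples) < min_n
  if (any(bad)) {
    abort(sprintf("Each group needs n >= %d (violated by: %s).", min_n,
                  paste(names(samples)[bad], collapse = ", ")))
  }
  invisible(samples)
}
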