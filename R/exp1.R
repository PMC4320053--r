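# Experiment 1 analysis: proprioceptive drift and ownership ratings across
# the four stimulation groups (sync, async, no_stroke, no_hand).
#
# Localization responses are stored as azimuthal positions in mm from the
# body midline, increasing toward the occluded (left) hand. The rubber hand
# sits midline-ward of the real hand, so a drift *toward the rubber hand*
# is a *decrease* on this axis; inference functions therefore apply
# `toward_rubber_sign` (default -1) to the raw post-minus-pre difference so
# that reported drifts are positive toward the rubber hand.

EXP1_GROUPS <- c("sync", "async", "no_stroke", "no_hand")
RUBBER_HAND_GROUPS <- c("sync", "async", "no_stroke")

#' Construct an Experiment 1 record set
#'
#' Container for per-subject localization and ownership data: a subject
#' table plus matrices of pre-test and post-test localization responses
#' (one row per subject, one column per repeated measurement; 40 in the
#' standard protocol).
#'
#' @param subjects Data frame with columns `subject`, `group` (one of
#'   `"sync"`, `"async"`, `"no_stroke"`, `"no_hand"`), integer
#'   `ownership_pre` and `ownership_post` in `[-3, 3]`, and optionally
#'   `true_x` (true hand azimuth, mm).
#' @param pre,post Numeric matrices of localization responses, mm; rows
#'   match `subjects`.
#' @return An object of class `exp1_records`.
#' @export
exp1_records <- function(subjects, pre, post) {
  if (!is.data.frame(subjects)) stop_input("subjects must be a data frame")
  need <- c("subject", "group", "ownership_pre", "ownership_post")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop_input("subjects is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(subjects$group), EXP1_GROUPS)
  if (length(bad))
    stop_input("unknown group label(s): ", paste(bad, collapse = ", "))
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (nrow(pre) != nrow(subjects) || nrow(post) != nrow(subjects))
    stop_input("localization matrices must have one row per subject")
  if (!all(is.finite(pre)) || !all(is.finite(post)))
    stop_input("localization responses must be finite numbers")
  for (col in c("ownership_pre", "ownership_post")) {
    v <- subjects[[col]]
    if (!all(is.na(v) | (v == round(v) & v >= -3 & v <= 3)))
      stop_input(col, " must contain integers in [-3, 3]")
  }
  if (!"true_x" %in% names(subjects)) subjects$true_x <- NA_real_
  n_expected <- 40L
  flag <- ncol(pre) != n_expected || ncol(post) != n_expected
  if (flag)
    warning(sprintf("expected %d localization responses per phase, got %d/%d",
                    n_expected, ncol(pre), ncol(post)))
  structure(list(subjects = subjects, pre = pre, post = post,
                 length_flag = flag),
            class = "exp1_records")
}

#' @export
print.exp1_records <- function(x, ...) {
  cat(sprintf("Experiment 1 records: %d subjects, %d/%d pre/post responses\n",
              nrow(x$subjects), ncol(x$pre), ncol(x$post)))
  print(table(x$subjects$group))
  invisible(x)
}

#' Default column mapping for Experiment 1 CSV files
#'
#' The deposited data schema is user configuration, not hard-coded: this
#' map names the subject-level columns and the prefixes of the repeated
#' localization columns (e.g. `pre_01` ... `pre_40`).
#'
#' @param subject,group,ownership_pre,ownership_post,true_x Column names.
#' @param pre_prefix,post_prefix Prefixes of the localization columns,
#'   collected in numeric order of their suffixes.
#' @return A named list usable as `column_map` in [load_exp1()].
#' @export
exp1_column_map <- function(subject = "subject", group = "group",
                            ownership_pre = "ownership_pre",
                            ownership_post = "ownership_post",
                            true_x = "true_x_mm",
                            pre_prefix = "pre_", post_prefix = "post_") {
  list(subject = subject, group = group, ownership_pre = ownership_pre,
       ownership_post = ownership_post, true_x = true_x,
       pre_prefix = pre_prefix, post_prefix = post_prefix)
}

collect_prefixed <- function(df, prefix, path) {
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(df), value = TRUE)
  if (!length(cols))
    stop_input("schema error in ", path, ": no columns matching prefix '",
               prefix, "'")
  cols <- cols[order(as.integer(sub(paste0("^", prefix), "", cols)))]
  m <- as.matrix(df[cols])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[cols], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[cols[bad]]]))))[1]
    stop_input("parse error in ", path, ": non-numeric localization in ",
               "column ", cols[bad], ", row ", badrow)
  }
  m
}

#' Load Experiment 1 data from CSV
#'
#' Reads a one-row-per-subject CSV of group labels, ownership ratings and
#' repeated localization responses, validated into an [exp1_records()]
#' object. Missing subject-level columns raise a schema error naming the
#' column; non-numeric localization values raise a parse error with the row
#' index; a localization count other than 40 yields a warning and sets the
#' record set's `length_flag`.
#'
#' @param path CSV file path.
#' @param column_map Mapping from record fields to CSV columns; see
#'   [exp1_column_map()].
#' @return An `exp1_records` object.
#' @export
load_exp1 <- function(path, column_map = exp1_column_map()) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (field in c("subject", "group", "ownership_pre", "ownership_post")) {
    if (!column_map[[field]] %in% names(df))
      stop_input("schema error in ", path, ": missing column '",
                 column_map[[field]], "' (", field, ")")
  }
  subjects <- data.frame(
    subject = df[[column_map$subject]],
    group = df[[column_map$group]],
    ownership_pre = df[[column_map$ownership_pre]],
    ownership_post = df[[column_map$ownership_post]],
    true_x = if (column_map$true_x %in% names(df)) df[[column_map$true_x]]
             else NA_real_,
    stringsAsFactors = FALSE
  )
  exp1_records(subjects,
               collect_prefixed(df, column_map$pre_prefix, path),
               collect_prefixed(df, column_map$post_prefix, path))
}

subset_records <- function(records, idx) {
  exp1_subset <- records
  exp1_subset$subjects <- records$subjects[idx, , drop = FALSE]
  exp1_subset$pre <- records$pre[idx, , drop = FALSE]
  exp1_subset$post <- records$post[idx, , drop = FALSE]
  exp1_subset
}

#' Exclude localization outliers
#'
#' A subject is an outlier when their mean pre-test localization deviates
#' from the sample mean of all subjects' pre-test means by more than `k`
#' sample standard deviations. The screening statistics are computed once
#' on the full input; there is no iterative re-screening.
#'
#' @param records An `exp1_records` object (>= 2 subjects).
#' @param k Exclusion threshold in sample SDs.
#' @return A list with `kept` and `excluded` (`exp1_records`), and `stats`
#'   (the screening mean and SD).
#' @export
exclude_outliers <- function(records, k = 3) {
  if (nrow(records$subjects) < 2L)
    stop_input("need at least 2 records to screen for outliers")
  m <- rowMeans(records$pre)
  center <- mean(m); spread <- stats::sd(m)
  out <- spread > 0 & abs(m - center) > k * spread
  out[is.na(out)] <- FALSE
  if (all(out)) stop_input("outlier screening excluded every record")
  list(kept = subset_records(records, !out),
       excluded = subset_records(records, out),
       stats = list(mean = center, sd = spread, k = k))
}

#' Per-subject proprioceptive drift
#'
#' The raw drift: mean post-test localization minus mean pre-test
#' localization, in the stored coordinate (mm from midline, increasing away
#' from it). On this axis a shift toward the rubber hand is negative; the
#' returned vector carries a `sign_convention` attribute saying so, and the
#' inference functions flip the sign so that reported drifts are positive
#' toward the rubber hand.
#'
#' @param records An `exp1_records` object.
#' @return Named numeric vector (one value per subject), mm, with attribute
#'   `sign_convention`.
#' @export
proprioceptive_drift <- function(records) {
  if (ncol(records$pre) == 0L || ncol(records$post) == 0L)
    stop_input("localization sequences must be non-empty")
  d <- rowMeans(records$post) - rowMeans(records$pre)
  names(d) <- records$subjects$subject
  attr(d, "sign_convention") <-
    "mean(post) - mean(pre) on the midline-outward axis; toward the rubber hand is negative"
  d
}

drift_toward_rubber <- function(records, toward_rubber_sign = -1) {
  unname(proprioceptive_drift(records)) * toward_rubber_sign
}

cohens_d_one <- function(x) mean(x) / stats::sd(x)

cohens_d_two <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Group-level inference on proprioceptive drift
#'
#' Computes, on drifts signed positive toward the rubber hand: per-group
#' one-sample two-tailed t-tests against zero with Cohen's d (mean/SD); a
#' one-way ANOVA across all groups; planned one-tailed independent-groups
#' t-tests (pooled variance) of `sync` against each of `async`,
#' `no_stroke` and `no_hand` with pooled-SD Cohen's d; and a paired t-test
#' of the first 15 versus last 15 post-test localizations across all
#' subjects (a check that the drift does not dissipate over the post-test).
#'
#' @param records An `exp1_records` object with >= 2 groups of >= 2
#'   subjects.
#' @param toward_rubber_sign Sign applied to raw post-minus-pre drifts so
#'   that positive means toward the rubber hand (-1 for the package's
#'   midline-outward coordinate).
#' @return An object of class `rhi_drift`: list with `per_group`,
#'   `anova`, `planned` and `post_stability` components.
#' @export
drift_inference <- function(records, toward_rubber_sign = -1) {
  g <- factor(records$subjects$group,
              levels = intersect(EXP1_GROUPS, unique(records$subjects$group)))
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_input("need at least 2 groups with at least 2 subjects each")
  d <- drift_toward_rubber(records, toward_rubber_sign)

  per_group <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- d[g == lev]
    tt <- stats::t.test(x)
    data.frame(group = lev, n = length(x), mean_drift_mm = mean(x),
               sd_mm = stats::sd(x), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohens_d = cohens_d_one(x))
  }))

  fit <- stats::aov(d ~ g)
  an <- summary(fit)[[1]]
  anova_res <- list(F = an[["F value"]][1], df1 = an[["Df"]][1],
                    df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1])

  planned <- NULL
  if ("sync" %in% levels(g)) {
    others <- intersect(c("async", "no_stroke", "no_hand"), levels(g))
    planned <- do.call(rbind, lapply(others, function(lev) {
      x <- d[g == "sync"]; y <- d[g == lev]
      tt <- stats::t.test(x, y, alternative = "greater", var.equal = TRUE)
      data.frame(comparison = paste0("sync > ", lev),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_one_tailed = tt$p.value, cohens_d = cohens_d_two(x, y))
    }))
  }

  k <- ncol(records$post)
  first <- rowMeans(records$post[, seq_len(min(15L, k)), drop = FALSE])
  last <- rowMeans(records$post[, seq(max(1L, k - 14L), k), drop = FALSE])
  st <- stats::t.test(first, last, paired = TRUE)
  structure(list(per_group = per_group, anova = anova_res, planned = planned,
                 post_stability = list(t = unname(st$statistic),
                                       df = unname(st$parameter),
                                       p = st$p.value),
                 toward_rubber_sign = toward_rubber_sign),
            class = "rhi_drift")
}

#' @export
print.rhi_drift <- function(x, ...) {
  cat("Proprioceptive drift (positive toward the rubber hand)\n")
  print(x$per_group, row.names = FALSE, digits = 4)
  cat(sprintf("ANOVA: F(%d, %d) = %.2f, p = %.4g\n", x$anova$df1,
              x$anova$df2, x$anova$F, x$anova$p))
  if (!is.null(x$planned)) print(x$planned, row.names = FALSE, digits = 4)
  invisible(x)
}

# Exact sign test: two-sided binomial test on the signs of x - mu, zeros
# dropped.
sign_test <- function(x, mu = 0) {
  s <- sign(x - mu)
  pos <- sum(s > 0); n <- sum(s != 0)
  if (n == 0L) stop_input("sign test undefined: no nonzero values")
  bt <- stats::binom.test(pos, n, p = 0.5)
  list(n_nonzero = n, n_positive = pos, p = bt$p.value)
}

#' Inference on ownership ratings
#'
#' Pre-test ownership ratings from the groups that saw a rubber hand
#' (`sync`, `async`, `no_stroke`) are pooled: fraction of positive ratings
#' (> 0, i.e. agreement that the rubber hand is one's own), the median, and
#' an exact sign test of the median against zero (zeros dropped). Change
#' scores (post minus pre) are compared across the three rubber-hand groups
#' with a Kruskal-Wallis test, followed by planned pairwise exact
#' rank-sum comparisons of `sync` against `async` and `no_stroke`.
#'
#' @param records An `exp1_records` object.
#' @return A list with `pooled_pre` (fraction positive, median, sign test),
#'   `change` (per-group medians), `kruskal` and `pairwise` components.
#' @export
ownership_inference <- function(records) {
  sub <- records$subjects
  keep <- sub$group %in% RUBBER_HAND_GROUPS
  if (!any(keep)) stop_input("no rubber-hand group records present")
  pre <- sub$ownership_pre[keep]
  pooled <- list(n = length(pre),
                 fraction_positive = mean(pre > 0),
                 median = stats::median(pre),
                 sign_test = sign_test(pre))

  change <- sub$ownership_post[keep] - sub$ownership_pre[keep]
  g <- factor(sub$group[keep], levels = intersect(RUBBER_HAND_GROUPS,
                                                  unique(sub$group[keep])))
  kw <- if (nlevels(g) > 1L) {
    k <- stats::kruskal.test(change, g)
    list(chisq = unname(k$statistic), df = unname(k$parameter), p = k$p.value)
  } else NULL

  pairwise <- NULL
  if ("sync" %in% levels(g)) {
    others <- intersect(c("async", "no_stroke"), levels(g))
    pairwise <- do.call(rbind, lapply(others, function(lev) {
      wt <- suppressWarnings(
        stats::wilcox.test(change[g == "sync"], change[g == lev]))
      data.frame(comparison = paste0("sync vs ", lev),
                 W = unname(wt$statistic), p = wt$p.value)
    }))
  }
  change_medians <- tapply(change, g, stats::median)
  list(pooled_pre = pooled,
       change = data.frame(group = names(change_medians),
                           median_change = as.numeric(change_medians)),
       kruskal = kw, pairwise = pairwise)
}

#' Correlation between ownership ratings and proprioceptive drift
#'
#' Pearson correlation, over the rubber-hand groups, of the chosen phase's
#' ownership rating with the drift (signed positive toward the rubber
#' hand), with a two-tailed test.
#'
#' @param records An `exp1_records` object.
#' @param phase `"pre"` or `"post"`: which ownership rating to correlate.
#' @param toward_rubber_sign See [drift_inference()].
#' @return A list with `r`, `p`, `df` and `n`.
#' @export
ownership_drift_correlation <- function(records, phase = c("pre", "post"),
                                        toward_rubber_sign = -1) {
  phase <- match.arg(phase)
  keep <- records$subjects$group %in% RUBBER_HAND_GROUPS
  if (sum(keep) < 3L) stop_input("need at least 3 rubber-hand subjects")
  rating <- records$subjects[[paste0("ownership_", phase)]][keep]
  d <- drift_toward_rubber(subset_records(records, keep), toward_rubber_sign)
  if (stats::sd(rating) == 0 || stats::sd(d) == 0)
    stop_input("correlation undefined: a variable has zero variance")
  ct <- stats::cor.test(rating, d)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(d))
}

#' Baseline localization bias toward the midline
#'
#' Pre-test localization accuracy relative to the true hand position:
#' per-subject mean pre-test localization minus the true position, signed
#' so that a bias toward the body midline is positive, with a one-sample t
#' test across subjects, plus the mean of per-subject SDs of the repeated
#' responses (the within-subject localization noise).
#'
#' @param records An `exp1_records` object.
#' @param true_position True hand azimuth, mm; taken from the records'
#'   `true_x` column when omitted.
#' @return A list with `available` (FALSE when no true position is known,
#'   in which case no bias is reported), `mean_bias_mm`,
#'   `mean_within_sd_mm`, `t`, `df`, `p` and the per-subject vectors.
#' @export
baseline_bias <- function(records, true_position = NULL) {
  within_sd <- apply(records$pre, 1, stats::sd)
  truth <- if (!is.null(true_position))
    rep(check_scalar(true_position, "true_position"), nrow(records$pre))
  else records$subjects$true_x
  if (all(is.na(truth)))
    return(list(available = FALSE,
                reason = "true hand position not supplied and absent from data",
                mean_within_sd_mm = mean(within_sd)))
  bias <- truth - rowMeans(records$pre)  # positive = toward the midline
  tt <- tryCatch(stats::t.test(bias), error = function(e) NULL)
  list(available = TRUE, mean_bias_mm = mean(bias),
       mean_within_sd_mm = mean(within_sd),
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
       p = if (is.null(tt)) NA_real_ else tt$p.value,
       per_subject_bias = bias, per_subject_sd = within_sd)
}

# Jarque-Bera normality test (skewness/kurtosis based, chi-squared with
# 2 df under the null).
jarque_bera <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- mean(z^2)
  if (s2 == 0) return(list(statistic = Inf, p = 0))
  skew <- mean(z^3) / s2^1.5
  kurt <- mean(z^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = jb, p = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Normality screening of pre-test localization distributions
#'
#' For each subject's pre-test localization sample, runs Shapiro-Wilk,
#' Anderson-Darling, Jarque-Bera and Lilliefors tests and reports, per
#' test, the fraction of subjects whose data are *not* rejected at `alpha`.
#' Subjects with too few or degenerate (zero-variance) samples are flagged
#' and excluded from the denominators.
#'
#' @param records An `exp1_records` object (>= 8 responses per subject).
#' @param alpha Rejection level.
#' @return A list with `pass_fraction` (named vector over the four tests),
#'   `p_values` (subjects x tests matrix) and `flagged` (logical vector).
#' @export
normality_screen <- function(records, alpha = 0.05) {
  tests <- c("shapiro_wilk", "anderson_darling", "jarque_bera", "lilliefors")
  n_sub <- nrow(records$pre)
  p <- matrix(NA_real_, n_sub, length(tests), dimnames = list(
    records$subjects$subject, tests))
  flagged <- logical(n_sub)
  for (i in seq_len(n_sub)) {
    x <- records$pre[i, ]
    if (length(x) < 8L || stats::sd(x) == 0) { flagged[i] <- TRUE; next }
    p[i, "shapiro_wilk"] <- stats::shapiro.test(x)$p.value
    p[i, "anderson_darling"] <- nortest::ad.test(x)$p.value
    p[i, "jarque_bera"] <- jarque_bera(x)$p
    p[i, "lilliefors"] <- nortest::lillie.test(x)$p.value
  }
  ok <- !flagged
  frac <- if (any(ok)) colMeans(p[ok, , drop = FALSE] >= alpha)
          else stats::setNames(rep(NA_real_, length(tests)), tests)
  list(pass_fraction = frac, p_values = p, flagged = flagged, alpha = alpha)
}
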