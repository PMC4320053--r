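# Experiment 2 analysis: event-related skin conductance responses (SCR)
# and ownership ratings across the plausible-arm, hanging-arm and no-arm
# groups.

EXP2_GROUPS <- c("plausible_arm", "hanging_arm", "no_arm")
EXP2_RATED_GROUPS <- c("plausible_arm", "hanging_arm")

#' Construct an Experiment 2 record set
#'
#' @param subjects Data frame with columns `subject`, `group` (one of
#'   `"plausible_arm"`, `"hanging_arm"`, `"no_arm"`), `ownership` (integer
#'   in `[-3, 3]`, `NA` for the unrated no-arm group), `eye_opening_s` and
#'   `threat_s` (event times, s from recording onset).
#' @param traces Named list (one element per subject, in `subjects` order)
#'   of data frames with columns `time_s` and `conductance_uS`, sampled at
#'   10 Hz.
#' @return An object of class `exp2_records`.
#' @export
exp2_records <- function(subjects, traces) {
  need <- c("subject", "group", "ownership", "eye_opening_s", "threat_s")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop_input("subjects is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(subjects$group), EXP2_GROUPS)
  if (length(bad))
    stop_input("unknown group label(s): ", paste(bad, collapse = ", "))
  if (length(traces) != nrow(subjects))
    stop_input("need one trace per subject")
  v <- subjects$ownership
  if (!all(is.na(v) | (v == round(v) & v >= -3 & v <= 3)))
    stop_input("ownership must contain integers in [-3, 3] or NA")
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (!all(c("time_s", "conductance_uS") %in% names(tr)))
      stop_input("trace ", i, " must have columns time_s and conductance_uS")
    dt <- diff(tr$time_s)
    if (length(dt) && max(abs(dt - 0.1)) > 1e-6)
      stop_input("trace ", i, " is not sampled at 10 Hz")
    span <- range(tr$time_s)
    ev <- c(subjects$eye_opening_s[i], subjects$threat_s[i])
    if (any(ev < span[1] | ev > span[2]))
      stop_input("event times for subject ", subjects$subject[i],
                 " fall outside the recorded trace")
  }
  names(traces) <- subjects$subject
  structure(list(subjects = subjects, traces = traces),
            class = "exp2_records")
}

#' Event-related skin conductance response
#'
#' The SCR to an event is the maximum conductance recorded within a window
#' after the event (by default 1-5 s, a closed interval: samples at both
#' endpoints are included) minus the minimum conductance in that same
#' window, then variance-stabilised as `log10(SCR + 1)`. Both the raw and
#' transformed values are returned. The statistic is invariant to additive
#' baseline shifts of the trace and to upsampling by integer factors.
#'
#' @param trace Data frame with columns `time_s` and `conductance_uS`.
#' @param event_time Event onset, s.
#' @param window Offsets (s) after the event delimiting the response
#'   window.
#' @param log_base Base of the `log(SCR + 1)` transform.
#' @return A list with `raw` (microsiemens) and `transformed`.
#' @examples
#' tr <- data.frame(time_s = seq(0, 10, 0.1), conductance_uS = 5)
#' scr_response(tr, 2)  # constant trace: raw 0, transformed 0
#' @export
scr_response <- function(trace, event_time, window = c(1, 5),
                         log_base = 10) {
  if (!all(c("time_s", "conductance_uS") %in% names(trace)))
    stop_input("trace must have columns time_s and conductance_uS")
  lo <- event_time + window[1]; hi <- event_time + window[2]
  if (lo < min(trace$time_s) - 1e-9 || hi > max(trace$time_s) + 1e-9)
    stop_input("response window [", lo, ", ", hi, "] s lies outside the trace")
  inwin <- trace$time_s >= lo - 1e-9 & trace$time_s <= hi + 1e-9
  y <- trace$conductance_uS[inwin]
  raw <- max(y) - min(y)
  list(raw = raw, transformed = log(raw + 1, base = log_base))
}

#' Load Experiment 2 data from a directory of CSV files
#'
#' Expects `subjects.csv` (columns `subject`, `group`, `ownership`,
#' `eye_opening_s`, `threat_s`) and one trace file per subject at
#' `traces/<subject>.csv` with columns `time_s`, `conductance_uS`.
#'
#' @param dir Directory containing the dataset.
#' @return An `exp2_records` object.
#' @export
load_exp2 <- function(dir) {
  sfile <- file.path(dir, "subjects.csv")
  if (!file.exists(sfile)) stop_input("file not found: ", sfile)
  subjects <- utils::read.csv(sfile, stringsAsFactors = FALSE)
  traces <- lapply(subjects$subject, function(id) {
    tfile <- file.path(dir, "traces", paste0(id, ".csv"))
    if (!file.exists(tfile)) stop_input("missing trace file: ", tfile)
    utils::read.csv(tfile)
  })
  exp2_records(subjects, traces)
}

#' Group-level inference on skin conductance and ownership
#'
#' For each of the two event time-points (eye opening and threat): per-
#' subject transformed SCRs, a one-way ANOVA across the three groups, and
#' planned two-tailed independent-groups t-tests of `plausible_arm` against
#' each control with pooled-SD Cohen's d. Ownership ratings are summarised
#' per rated group (median, fraction positive, exact sign test against
#' zero) and compared between the two rated groups with an exact rank-sum
#' test; Pearson correlations of ownership with each time-point's
#' transformed SCR are computed over the two rated groups.
#'
#' @param records An `exp2_records` object with all three groups present.
#' @param window,log_base Passed to [scr_response()].
#' @return An object of class `rhi_scr`: list with `per_subject`, `anova`,
#'   `planned`, `ownership` and `correlations` components.
#' @export
exp2_inference <- function(records, window = c(1, 5), log_base = 10) {
  sub <- records$subjects
  g <- factor(sub$group, levels = intersect(EXP2_GROUPS, unique(sub$group)))
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_input("need at least 2 groups with at least 2 subjects each")

  scr_at <- function(i, ev)
    scr_response(records$traces[[i]], sub[[ev]][i], window, log_base)
  events <- c(eye_opening = "eye_opening_s", threat = "threat_s")
  per_subject <- data.frame(subject = sub$subject, group = sub$group)
  for (ev in names(events)) {
    vals <- lapply(seq_len(nrow(sub)), scr_at, ev = events[[ev]])
    per_subject[[paste0("scr_", ev, "_raw")]] <-
      vapply(vals, `[[`, numeric(1), "raw")
    per_subject[[paste0("scr_", ev)]] <-
      vapply(vals, `[[`, numeric(1), "transformed")
  }

  anova_one <- function(y) {
    an <- summary(stats::aov(y ~ g))[[1]]
    list(F = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
         p = an[["Pr(>F)"]][1])
  }
  planned_one <- function(y) {
    others <- setdiff(levels(g), "plausible_arm")
    do.call(rbind, lapply(others, function(lev) {
      x1 <- y[g == "plausible_arm"]; x2 <- y[g == lev]
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      data.frame(comparison = paste0("plausible_arm vs ", lev),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = cohens_d_two(x1, x2))
    }))
  }
  anova <- lapply(names(events), function(ev) anova_one(per_subject[[paste0("scr_", ev)]]))
  names(anova) <- names(events)
  planned <- lapply(names(events), function(ev) planned_one(per_subject[[paste0("scr_", ev)]]))
  names(planned) <- names(events)

  rated <- sub$group %in% EXP2_RATED_GROUPS & !is.na(sub$ownership)
  ownership <- do.call(rbind, lapply(
    intersect(EXP2_RATED_GROUPS, unique(sub$group)), function(lev) {
      r <- sub$ownership[rated & sub$group == lev]
      st <- sign_test(r)
      data.frame(group = lev, n = length(r), median = stats::median(r),
                 fraction_positive = mean(r > 0), sign_test_p = st$p)
    }))
  between <- if (length(unique(sub$group[rated])) == 2L) {
    wt <- suppressWarnings(stats::wilcox.test(
      sub$ownership[rated & sub$group == "plausible_arm"],
      sub$ownership[rated & sub$group == "hanging_arm"]))
    list(W = unname(wt$statistic), p = wt$p.value)
  } else NULL

  correlations <- lapply(names(events), function(ev) {
    y <- per_subject[[paste0("scr_", ev)]][rated]
    r <- sub$ownership[rated]
    if (stats::sd(y) == 0 || stats::sd(r) == 0)
      stop_input("correlation undefined: a variable has zero variance")
    ct <- stats::cor.test(r, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(rated))
  })
  names(correlations) <- names(events)

  structure(list(per_subject = per_subject, anova = anova, planned = planned,
                 ownership = ownership, ownership_between = between,
                 correlations = correlations),
            class = "rhi_scr")
}

#' @export
print.rhi_scr <- function(x, ...) {
  cat("Skin conductance responses (log10(SCR + 1))\n")
  for (ev in names(x$anova))
    cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.4g\n", ev, x$anova[[ev]]$df1,
                x$anova[[ev]]$df2, x$anova[[ev]]$F, x$anova[[ev]]$p))
  print(x$ownership, row.names = FALSE, digits = 3)
  for (ev in names(x$correlations))
    cat(sprintf("  ownership ~ %s SCR: r = %.2f, p = %.4g\n", ev,
                x$correlations[[ev]]$r, x$correlations[[ev]]$p))
  invisible(x)
}
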