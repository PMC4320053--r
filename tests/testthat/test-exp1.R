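# Experiment 1 analysis: drift, ownership, baseline bias, normality.

test_that("proprioceptive drift is the post-minus-pre mean difference", {
  set.seed(30)
  pre <- matrix(rnorm(8 * 10, 300, 5), 8, 10)
  rec <- make_exp1(pre, pre)
  expect_equal(as.numeric(proprioceptive_drift(rec)), rep(0, 8))
  rec2 <- make_exp1(pre, pre + 12.5)
  expect_equal(as.numeric(proprioceptive_drift(rec2)), rep(12.5, 8))
  # subject-specific midline-ward shifts come back sign-flipped as
  # drift toward the rubber hand
  shifts <- seq(3, 10, length.out = 8)
  rec3 <- make_exp1(pre, pre - matrix(shifts, 8, 10))
  expect_equal(as.numeric(proprioceptive_drift(rec3)), -shifts)
  d <- drift_inference(rec3)
  byg <- tapply(shifts, rep(c("sync", "async", "no_stroke", "no_hand"), 2),
                mean)
  expect_equal(d$per_group$mean_drift_mm,
               as.numeric(byg[d$per_group$group]), tolerance = 1e-12)
})

test_that("outlier screening excludes exactly the displaced subject", {
  set.seed(31)
  centers <- c(rnorm(19, 300, 10), NA)
  centers[20] <- mean(centers[1:19])  # placeholder, replaced below
  pre <- matrix(rep(centers, 12), 20, 12)
  # displace the 13th subject by 5 screening SDs
  m <- rowMeans(pre)
  pre[13, ] <- pre[13, ] + 5 * sd(m)
  rec <- make_exp1(pre, pre)
  out <- exclude_outliers(rec, k = 3)
  expect_identical(out$excluded$subjects$subject, "s13")
  expect_equal(nrow(out$kept$subjects), 19)
  # threshold limit and degenerate-spread behavior
  expect_equal(nrow(exclude_outliers(rec, k = Inf)$excluded$subjects), 0)
  same <- make_exp1(matrix(300, 6, 12), matrix(300, 6, 12))
  expect_equal(nrow(exclude_outliers(same)$excluded$subjects), 0)
})

test_that("generated cohorts round-trip through the CSV writer and loader", {
  rec <- generate_exp1(exp1_gen_config(n_per_group = 4), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_exp1_csv(rec, path)
  back <- load_exp1(path)
  expect_equal(back$subjects$group, rec$subjects$group)
  expect_equal(back$subjects$ownership_pre, rec$subjects$ownership_pre)
  expect_equal(unname(back$pre), unname(rec$pre), tolerance = 1e-12)
  expect_equal(unname(back$post), unname(rec$post), tolerance = 1e-12)
})

test_that("the loader diagnoses schema problems and short sequences", {
  rec <- generate_exp1(exp1_gen_config(n_per_group = 3), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_exp1_csv(rec, path)
  df <- read.csv(path)
  df2 <- df[setdiff(names(df), "group")]
  p2 <- tempfile(fileext = ".csv"); write.csv(df2, p2, row.names = FALSE)
  expect_error(load_exp1(p2), "group", class = "rhi_input_error")
  df3 <- df; df3$pre_05 <- "oops"
  p3 <- tempfile(fileext = ".csv"); write.csv(df3, p3, row.names = FALSE)
  expect_error(load_exp1(p3), "pre_05", class = "rhi_input_error")
  df4 <- df[setdiff(names(df), "pre_40")]
  p4 <- tempfile(fileext = ".csv"); write.csv(df4, p4, row.names = FALSE)
  expect_warning(short <- load_exp1(p4), "39")
  expect_true(short$length_flag)
})

test_that("drift inference reports coherent group, omnibus and planned statistics", {
  rec <- generate_exp1(seed = 40)
  d <- drift_inference(rec)
  expect_setequal(d$per_group$group,
                  c("sync", "async", "no_stroke", "no_hand"))
  # one-sample d = t / sqrt(n) by construction
  expect_equal(d$per_group$cohens_d,
               d$per_group$t / sqrt(d$per_group$n), tolerance = 1e-12)
  expect_equal(d$anova$df1, 3)
  expect_equal(d$anova$df2, 80)
  expect_equal(d$planned$df, rep(40, 3))
  # groups with identical drift sets give a zero pairwise t
  pre <- matrix(rnorm(8 * 10, 300, 5), 8, 10)
  post2 <- pre - rep(c(5, 3, 5, 3, 5, 3, 5, 3), 10)
  twin2 <- make_exp1(pre, post2, groups = rep(c("sync", "sync", "async",
                                                "async"), 2))
  dd <- drift_inference(twin2)
  expect_equal(dd$planned$t[dd$planned$comparison == "sync > async"], 0,
               tolerance = 1e-9)
  # row order does not matter
  perm <- sample(nrow(rec$subjects))
  rec_perm <- rec
  rec_perm$subjects <- rec$subjects[perm, ]
  rec_perm$pre <- rec$pre[perm, ]
  rec_perm$post <- rec$post[perm, ]
  d2 <- drift_inference(rec_perm)
  expect_equal(d2$anova$F, d$anova$F, tolerance = 1e-10)
  expect_equal(d2$per_group$mean_drift_mm, d$per_group$mean_drift_mm,
               tolerance = 1e-10)
})

test_that("ownership inference pools rubber-hand groups and sign-tests ratings", {
  pre <- matrix(300, 12, 10)
  rec <- make_exp1(pre, pre,
                   groups = rep(c("sync", "async", "no_stroke"), 4),
                   ownership_pre = rep(3L, 12),
                   ownership_post = rep(3L, 12))
  o <- ownership_inference(rec)
  expect_equal(o$pooled_pre$fraction_positive, 1)
  expect_equal(o$pooled_pre$sign_test$p, 2 * 0.5^12, tolerance = 1e-12)
  # symmetric ratings: median zero, sign test at chance
  sym <- make_exp1(pre, pre,
                   groups = rep(c("sync", "async", "no_stroke"), 4),
                   ownership_pre = rep(c(-2L, 2L), 6),
                   ownership_post = rep(c(-2L, 2L), 6))
  os <- ownership_inference(sym)
  expect_equal(os$pooled_pre$median, 0)
  expect_equal(os$pooled_pre$sign_test$p, 1)
  # the no_hand group never enters the pool
  rec4 <- generate_exp1(seed = 8)
  o4 <- ownership_inference(rec4)
  expect_equal(o4$pooled_pre$n, 63)
  expect_equal(o4$kruskal$df, 2)
})

test_that("ownership-drift correlation is exact for proportional data", {
  ratings <- rep(c(-3L, -1L, 0L, 1L, 2L, 3L), 2)
  pre <- matrix(300, 12, 10)
  post <- pre - 4 * matrix(rep(as.numeric(ratings), 10), 12, 10)
  rec <- make_exp1(pre, post,
                   groups = rep(c("sync", "async", "no_stroke"), 4),
                   ownership_pre = ratings, ownership_post = ratings)
  res <- ownership_drift_correlation(rec, "pre")
  expect_equal(res$r, 1, tolerance = 1e-12)
  # zero variance is an error, not a silent NA
  flat <- make_exp1(pre, post,
                    groups = rep(c("sync", "async", "no_stroke"), 4),
                    ownership_pre = rep(2L, 12), ownership_post = ratings)
  expect_error(ownership_drift_correlation(flat, "pre"),
               class = "rhi_input_error")
})

test_that("baseline bias recovers direction and degrades without a true position", {
  pre <- matrix(300, 10, 12)
  rec <- make_exp1(pre, pre, true_x = 300)
  b <- baseline_bias(rec)
  expect_true(b$available)
  expect_equal(b$mean_bias_mm, 0)
  # localizations short of the true position are a midline-ward bias
  rec2 <- make_exp1(pre, pre, true_x = 331.5)
  b2 <- baseline_bias(rec2)
  expect_equal(b2$mean_bias_mm, 31.5)
  rec3 <- make_exp1(pre, pre)
  b3 <- baseline_bias(rec3)
  expect_false(b3$available)
  # explicit argument overrides the records
  b4 <- baseline_bias(rec3, true_position = 310)
  expect_equal(b4$mean_bias_mm, 10)
})

test_that("normality screening separates Gaussian from heavy-tailed cohorts", {
  rec <- generate_exp1(seed = 23)
  ns <- normality_screen(rec)
  expect_true(all(ns$pass_fraction >= 0.90))
  set.seed(77)
  heavy <- matrix(300 + 13 * rt(84 * 40, df = 2), 84, 40)
  rec_h <- make_exp1(heavy, heavy)
  ns_h <- normality_screen(rec_h)
  expect_lt(ns_h$pass_fraction[["shapiro_wilk"]], 0.5)
  # constant sequences are flagged out of the denominators
  const <- make_exp1(matrix(5, 4, 12), matrix(5, 4, 12))
  ns_c <- normality_screen(const)
  expect_true(all(ns_c$flagged))
  expect_true(all(is.na(ns_c$pass_fraction)))
})
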