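test_that("log transform is the natural log and rejects non-positive values", {
  expect_equal(log_transform(c(1, exp(1), exp(2))), c(0, 1, 2))
  expect_error(log_transform(c(1, 0, 2), ids = c("a", "b", "c")), "b")
  set.seed(31)
  x <- runif(20, 0.01, 5)
  expect_equal(exp(log_transform(x)), x, tolerance = 1e-12)
})

test_that("one-way ANOVA reproduces the hand-computed worked example", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("A", "B", "C"), each = 3)
  a <- anova_oneway(vals, grp)
  # SSB = 6, SSW = 6, MSB = 3, MSW = 1 -> F = 3 with df (2, 6)
  expect_equal(a$F, 3, tolerance = 1e-12)
  expect_identical(a$df_between, 2L)
  expect_identical(a$df_within, 6L)
  expect_equal(a$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # sums-of-squares oracle on random data
  set.seed(32)
  v <- rnorm(60); g <- sample(c("NC", "MCI", "AD"), 60, replace = TRUE)
  gm <- tapply(v, g, mean); n <- tapply(v, g, length)
  ssb <- sum(n * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  Fo <- (ssb / 2) / (ssw / (60 - 3))
  expect_equal(anova_oneway(v, g)$F, Fo, tolerance = 1e-10)
})

test_that("identical group means give F near zero", {
  vals <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  grp <- rep(c("A", "B", "C"), each = 3)
  expect_lt(anova_oneway(vals, grp)$F, 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(15, 0.7)
  a <- anova_oneway(c(x, y), rep(c("A", "B"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA rejects degenerate group structures", {
  expect_error(anova_oneway(1:5, rep("A", 5)), "two groups")
  expect_error(anova_oneway(1:4, c("A", "A", "B", "C")), "fewer than 2")
})

test_that("Tukey-Kramer differences follow the stated formula and ordering", {
  set.seed(34)
  vals <- c(rnorm(8, 0), rnorm(10, 0.5), rnorm(5, 1))
  grp <- rep(c("NC", "MCI", "AD"), c(8, 10, 5))
  tk <- tukey_hsd(vals, grp)
  expect_identical(tk$pair, c("NC-MCI", "NC-AD", "MCI-AD"))
  msw <- stats::anova(stats::aov(vals ~ factor(grp)))[["Mean Sq"]][2]
  means <- tapply(vals, factor(grp, c("NC", "MCI", "AD")), mean)
  expect_equal(tk$diff[1], unname(means["NC"] - means["MCI"]), tolerance = 1e-12)
  expect_equal(tk$se[1], sqrt(msw * (1 / 8 + 1 / 10) / 2), tolerance = 1e-12)
  expect_equal(tk$se[2], sqrt(msw * (1 / 8 + 1 / 5) / 2), tolerance = 1e-12)
  # antisymmetry of the difference (neutral labels so level order is honoured)
  grp2 <- c(NC = "g1", MCI = "g2", AD = "g3")[grp]
  t12 <- tukey_hsd(vals, factor(grp2, levels = c("g1", "g2", "g3")))
  t21 <- tukey_hsd(vals, factor(grp2, levels = c("g2", "g1", "g3")))
  expect_equal(t21$diff[t21$pair == "g2-g1"],
               -t12$diff[t12$pair == "g1-g2"], tolerance = 1e-12)
  # cross-check adjusted p against stats::TukeyHSD
  th <- stats::TukeyHSD(stats::aov(vals ~ factor(grp, c("NC", "MCI", "AD"))))[[1]]
  expect_equal(sort(tk$p_adj), sort(unname(th[, "p adj"])), tolerance = 1e-8)
})

test_that("identical groups give zero differences and p near 1", {
  vals <- rep(c(1, 2, 3), 3)
  grp <- rep(c("A", "B", "C"), each = 3)
  tk <- tukey_hsd(vals, grp)
  expect_true(all(abs(tk$diff) < 1e-12))
  expect_true(all(tk$p_adj > 0.999))
})

test_that("with two groups the Tukey p reduces to the two-sided t-test", {
  set.seed(35)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  tk <- tukey_hsd(c(x, y), rep(c("A", "B"), each = 10))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-7)
})

test_that("ANOVA and Tukey respect shift invariance and scale equivariance", {
  set.seed(36)
  vals <- rnorm(30); grp <- rep(c("A", "B", "C"), each = 10)
  a0 <- anova_oneway(vals, grp); t0 <- tukey_hsd(vals, grp)
  a1 <- anova_oneway(vals + 5, grp); t1 <- tukey_hsd(vals + 5, grp)
  a2 <- anova_oneway(vals * 3, grp); t2 <- tukey_hsd(vals * 3, grp)
  expect_equal(a1$F, a0$F, tolerance = 1e-10)
  expect_equal(a2$F, a0$F, tolerance = 1e-10)
  expect_equal(t1$diff, t0$diff, tolerance = 1e-10)
  expect_equal(t2$diff, 3 * t0$diff, tolerance = 1e-10)
  expect_equal(t2$p_adj, t0$p_adj, tolerance = 1e-10)
})

ancova_data <- function(n = 120, beta_age = 0.02, noise = 0.001, seed = 37) {
  set.seed(seed)
  g <- sample(c("NC", "MCI", "AD"), n, replace = TRUE)
  off <- c(NC = 0, MCI = 0.3, AD = 0.6)[g]
  age <- round(rnorm(n, 78, 6), 1)
  gender <- sample(c("M", "F"), n, replace = TRUE)
  y <- exp(-2 + beta_age * age + off + rnorm(n, 0, noise))
  data.frame(subject_id = sprintf("s%03d", seq_len(n)), group = g, age = age,
             gender = gender, metric = y, stringsAsFactors = FALSE)
}

test_that("ANCOVA recovers a forced age slope", {
  d <- ancova_data()
  fit <- ancova_adjusted(d, "metric")
  expect_lt(abs(unname(coef(fit$model)["age"]) - 0.02), 0.001)
  expect_lt(fit$covariates$p[fit$covariates$term == "age"], 1e-6)
  # group contrasts carry the NC-reference sign convention
  expect_lt(fit$contrasts$diff[fit$contrasts$pair == "NC-MCI"], 0)
  expect_lt(fit$contrasts$diff[fit$contrasts$pair == "NC-AD"], 0)
})

test_that("with covariates unrelated to metric and group, adjusted contrasts
          match the unadjusted Tukey differences", {
  set.seed(38)
  n <- 150
  g <- rep(c("NC", "MCI", "AD"), each = 50)
  y <- exp(c(NC = 0, MCI = 0.2, AD = 0.4)[g] + rnorm(n, 0, 0.3))
  d <- data.frame(subject_id = as.character(1:n), group = g,
                  age = rnorm(n, 75, 7),
                  gender = sample(c("M", "F"), n, TRUE), metric = y)
  fit <- ancova_adjusted(d, "metric")
  tk <- tukey_hsd(log(y), g)
  expect_equal(fit$contrasts$diff[1], tk$diff[tk$pair == "NC-MCI"],
               tolerance = 0.05)
  expect_equal(fit$contrasts$diff[2], tk$diff[tk$pair == "NC-AD"],
               tolerance = 0.05)
})

test_that("ANCOVA matches an emmeans cross-check", {
  skip_if_not_installed("emmeans")
  d <- ancova_data(noise = 0.2)
  fit <- ancova_adjusted(d, "metric")
  em <- emmeans::emmeans(fit$model, "group")
  ctr <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                         ref = "NC"))
  # emmeans reports MCI - NC; ours is NC - MCI
  expect_equal(fit$contrasts$diff,
               -ctr$estimate[match(c("MCI - NC", "AD - NC"), ctr$contrast)],
               tolerance = 1e-8)
})

test_that("constant covariates raise a rank-deficiency error", {
  d <- ancova_data()
  d$gender <- "M"
  expect_error(ancova_adjusted(d, "metric"), "gender")
  d2 <- ancova_data(); d2$age <- 70
  expect_error(ancova_adjusted(d2, "metric"), "age")
})

test_that("cohort report assembles the nine metric rows with stars", {
  set.seed(39)
  n <- c(NC = 20, MCI = 20, AD = 20)
  g <- rep(names(n), n)
  mk <- function(off) exp(log(0.1) + off[g] + rnorm(sum(n), 0, 0.2))
  off <- c(NC = 0, MCI = 0.3, AD = 0.6)
  tab <- data.frame(subject_id = as.character(seq_len(sum(n))), group = g,
                    age = rnorm(sum(n), 78, 6),
                    gender = sample(c("M", "F"), sum(n), TRUE))
  for (m in c("rFW_WM", "muFW_WM", "rFW_WM_safe", "muFW_WM_safe",
              "rFW_WMHs", "muFW_WMHs", "rFW_WM_safe_minus_WMHs",
              "muFW_WM_safe_minus_WMHs", "WMH_volume"))
    tab[[m]] <- mk(off)
  rep <- cohort_report(tab)
  expect_identical(nrow(rep), 9L)
  expect_true(all(c("F", "diff_NC_MCI", "se_NC_MCI", "stars_NC_MCI",
                    "diff_NC_AD", "diff_MCI_AD") %in% names(rep)))
  # constructed NC < MCI < AD: negative NC-patient differences, starred
  expect_true(all(rep$diff_NC_MCI < 0))
  expect_true(all(rep$diff_NC_AD < 0))
  expect_true(all(nchar(rep$stars_NC_AD) > 0))
  # serialization
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  write_cohort_report(rep, csvp, jsonp)
  expect_identical(nrow(utils::read.csv(csvp)), 9L)
  expect_length(jsonlite::read_json(jsonp), 9L)
})

test_that("a null cohort shows no systematic stars and two groups degrade
          gracefully", {
  set.seed(40)
  g <- rep(c("NC", "MCI"), c(15, 15))
  tab <- data.frame(subject_id = as.character(1:30), group = g,
                    age = rnorm(30, 78, 6),
                    gender = sample(c("M", "F"), 30, TRUE),
                    muFW_WM_safe = exp(rnorm(30, log(0.15), 0.2)))
  rep <- cohort_report(tab, metrics = "muFW_WM_safe")
  expect_identical(nrow(rep), 1L)
  expect_true("diff_NC_MCI" %in% names(rep))
  expect_false("diff_NC_AD" %in% names(rep))
})
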