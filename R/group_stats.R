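#' Natural-log transform of positive metric values
#'
#' The FW metrics are right-skewed fractions; cohort analyses are run on the
#' natural log scale to improve normality. Non-positive values are a hard
#' error naming the offending subject, because they indicate an upstream
#' problem (an empty mask or an unfittable subject) rather than data to be
#' coerced.
#'
#' @param values numeric vector, all > 0.
#' @param ids optional subject identifiers used in error messages.
#' @return `log(values)`.
#' @export
log_transform <- function(values, ids = NULL) {
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("non-positive metric value(s) for subject(s): ", who)
  }
  log(values)
}

# Internal: canonical group factor. If the labels are the diagnostic groups
# NC/MCI/AD, order them that way (NC is the reference and the pair ordering
# of the report follows); otherwise keep order of appearance.
.group_factor <- function(group) {
  if (is.factor(group)) return(droplevels(group))  # explicit order is honoured
  u <- unique(as.character(group))
  canon <- c("NC", "MCI", "AD")
  lev <- if (all(u %in% canon)) canon[canon %in% u] else u
  factor(as.character(group), levels = lev)
}

.check_groups <- function(values, group) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  if (any(!is.finite(values))) stop("non-finite metric values")
  n <- table(group)
  n <- n[n > 0]
  if (length(n) < 2L) stop("need at least two groups")
  if (any(n < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(n)[n < 2L], collapse = ", "))
}

#' One-way analysis of variance
#'
#' Classical between/within ANOVA for a main effect of group, as used to test
#' for a diagnostic-group effect on each (log-scale) FW metric.
#'
#' @param values numeric outcome (already log-transformed where appropriate).
#' @param group group labels (character or factor).
#' @return list of class `anova_oneway` with `F`, `df_between`, `df_within`,
#'   `p`.
#' @export
anova_oneway <- function(values, group) {
  group <- .group_factor(group)
  .check_groups(values, group)
  fit <- stats::aov(values ~ group)
  tab <- stats::anova(fit)
  structure(list(F = tab[["F value"]][1L],
                 df_between = tab[["Df"]][1L],
                 df_within = tab[["Df"]][2L],
                 p = tab[["Pr(>F)"]][1L]),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' All pairwise group differences after a one-way ANOVA, with the
#' Tukey-Kramer adjustment valid for unequal group sizes. For the pair (i, j)
#' (in group-level order, so NC-MCI, NC-AD, MCI-AD for the diagnostic
#' groups): `diff = mean_i - mean_j`, `se = sqrt(MSW * (1/n_i + 1/n_j) / 2)`,
#' and the adjusted p comes from the studentized range distribution with
#' (k, df_within) parameters.
#'
#' @inheritParams anova_oneway
#' @return data frame with columns `pair`, `group_i`, `group_j`, `diff`,
#'   `se`, `p_adj`.
#' @export
tukey_hsd <- function(values, group) {
  group <- .group_factor(group)
  .check_groups(values, group)
  lev <- levels(group)[table(group)[levels(group)] > 0]
  k <- length(lev)
  ns <- tapply(values, group, length)[lev]
  ms <- tapply(values, group, mean)[lev]
  fit <- stats::aov(values ~ group)
  tab <- stats::anova(fit)
  msw <- tab[["Mean Sq"]][2L]
  dfw <- tab[["Df"]][2L]
  out <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    d <- ms[i] - ms[j]
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]) / 2)
    q <- abs(d) / se
    out[[length(out) + 1L]] <- data.frame(
      pair = paste0(lev[i], "-", lev[j]),
      group_i = lev[i], group_j = lev[j],
      diff = unname(d), se = unname(se),
      p_adj = stats::ptukey(q, k, dfw, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' ANCOVA adjusting group contrasts for age and gender
#'
#' Fits `log(metric) ~ group + age + gender` by least squares (gender as a
#' 0/1 indicator, group as indicators against the NC reference) and reports
#' each covariate's partial F-test together with the covariate-adjusted
#' NC-patient contrasts. With this additive model the adjusted contrasts are
#' the group coefficients themselves, i.e. the comparison at equal age and
#' gender composition.
#'
#' @param table data frame with columns `subject_id`, `group`, `age`,
#'   `gender` (coded `M`/`F`) and the metric column.
#' @param metric name of the metric column.
#' @param log apply [log_transform()] to the metric first (default).
#' @return list of class `ancova_fit` with `covariates` (data frame: term,
#'   F, p), `contrasts` (data frame: pair, diff, se, p), and `model` (the
#'   underlying `lm`).
#' @export
ancova_adjusted <- function(table, metric, log = TRUE) {
  need <- c("subject_id", "group", "age", "gender", metric)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(table$age))) stop("age missing for some subjects")
  if (!all(table$gender %in% c("M", "F")))
    stop("gender must be coded M/F")
  y <- if (log) log_transform(table[[metric]], table$subject_id)
       else table[[metric]]
  df <- data.frame(y = y,
                   group = .group_factor(table$group),
                   age = as.numeric(table$age),
                   gender = as.integer(table$gender == "M"))
  .check_groups(df$y, df$group)
  for (v in c("age", "gender"))
    if (stats::var(df[[v]]) == 0)
      stop("covariate '", v, "' is constant; model is rank deficient")
  fit <- stats::lm(y ~ group + age + gender, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  dr <- stats::drop1(fit, scope = ~ group + age + gender, test = "F")
  covs <- data.frame(term = rownames(dr)[-1L],
                     F = dr[["F value"]][-1L],
                     p = dr[["Pr(>F)"]][-1L],
                     stringsAsFactors = FALSE)
  cf <- summary(fit)$coefficients
  ref <- levels(df$group)[1L]
  others <- levels(df$group)[-1L]
  ctr <- do.call(rbind, lapply(others, function(g) {
    nm <- paste0("group", g)
    data.frame(pair = paste0(ref, "-", g),
               diff = -cf[nm, "Estimate"],
               se = cf[nm, "Std. Error"],
               p = cf[nm, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }))
  structure(list(covariates = covs, contrasts = ctr, model = fit),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("ANCOVA: log-metric ~ group + age + gender\n")
  cat("covariate partial F-tests:\n")
  print(x$covariates, row.names = FALSE)
  cat("adjusted group contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

# Internal: significance stars at the conventional thresholds.
.stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Join subject metrics with demographics into a cohort table
#'
#' Pivots the long (subject, mask) metric records into one row per subject
#' with the nine cohort outcome columns (`rFW_*` and `muFW_*` over the four
#' masks, plus `WMH_volume`), joined with group, age and gender.
#'
#' @param metrics data frame of [subject_metrics()] rows for all subjects.
#' @param demographics data frame with `subject_id`, `group`, `age`,
#'   `gender`.
#' @return a wide data frame, one row per subject.
#' @export
cohort_table <- function(metrics, demographics) {
  need <- c("subject_id", "group", "age", "gender")
  miss <- setdiff(need, names(demographics))
  if (length(miss)) stop("demographics missing column(s): ",
                         paste(miss, collapse = ", "))
  unmatched <- setdiff(unique(metrics$subject_id), demographics$subject_id)
  if (length(unmatched))
    stop("no demographics for subject(s): ", paste(unmatched, collapse = ", "))
  ids <- unique(metrics$subject_id)
  wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (mk in unique(metrics$mask_name)) {
    sub <- metrics[metrics$mask_name == mk, ]
    wide[[paste0("rFW_", mk)]] <- sub$rFW[match(ids, sub$subject_id)]
    wide[[paste0("muFW_", mk)]] <- sub$muFW[match(ids, sub$subject_id)]
  }
  first <- metrics[match(ids, metrics$subject_id), ]
  wide$WMH_volume <- first$wmh_volume
  merge(wide, demographics[, need], by = "subject_id", sort = FALSE)
}

#' Cohort statistics report
#'
#' For each metric: log transform (by default), one-way ANOVA F, and the
#' pairwise Tukey-Kramer differences with standard errors, annotated with
#' significance stars at p < 0.05 (*), < 0.01 (**), < 0.001 (***). This is
#' the group-comparison table of the pipeline, one row per outcome measure.
#'
#' @param table a [cohort_table()] data frame.
#' @param metrics metric column names to analyse; defaults to every `rFW_*`,
#'   `muFW_*` and `WMH_volume` column present.
#' @param log analyse on the natural-log scale (default). Differences are
#'   then log-scale differences.
#' @return a data frame of class `cohort_report`: one row per metric with
#'   columns `metric`, `F`, `df_between`, `df_within`, `p`, `stars`, and for
#'   each group pair `diff_<pair>`, `se_<pair>`, `p_<pair>`, `stars_<pair>`.
#' @export
cohort_report <- function(table, metrics = NULL, log = TRUE) {
  if (is.null(metrics))
    metrics <- intersect(c(grep("^(rFW|muFW)_", names(table), value = TRUE),
                           "WMH_volume"), names(table))
  if (!length(metrics)) stop("no metric columns to analyse")
  group <- .group_factor(table$group)
  rows <- lapply(metrics, function(mn) {
    y <- table[[mn]]
    keep <- !is.na(y)
    yv <- y[keep]; gv <- droplevels(group[keep])
    if (log) yv <- log_transform(yv, table$subject_id[keep])
    a <- anova_oneway(yv, gv)
    tk <- tukey_hsd(yv, gv)
    row <- data.frame(metric = mn, F = a$F, df_between = a$df_between,
                      df_within = a$df_within, p = a$p, stars = .stars(a$p),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tk))) {
      pr <- gsub("-", "_", tk$pair[i])
      row[[paste0("diff_", pr)]] <- tk$diff[i]
      row[[paste0("se_", pr)]] <- tk$se[i]
      row[[paste0("p_", pr)]] <- tk$p_adj[i]
      row[[paste0("stars_", pr)]] <- .stars(tk$p_adj[i])
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_report", class(out))
  attr(out, "log_scale") <- log
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  if (!all(c("metric", "F", "stars") %in% names(x))) return(NextMethod())
  cat(sprintf("Cohort report (%s scale): %d metric(s)\n",
              if (isTRUE(attr(x, "log_scale"))) "log" else "raw", nrow(x)))
  show <- data.frame(metric = x$metric,
                     F = sprintf("%.2f%s", x$F, x$stars),
                     stringsAsFactors = FALSE)
  for (pr in sub("^diff_", "", grep("^diff_", names(x), value = TRUE)))
    show[[pr]] <- sprintf("%.2f (%.2f)%s", x[[paste0("diff_", pr)]],
                          x[[paste0("se_", pr)]], x[[paste0("stars_", pr)]])
  print(show, row.names = FALSE)
  invisible(x)
}

#' Serialize a cohort report
#'
#' @param report a [cohort_report()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_cohort_report <- function(report, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(report)
  if (!is.null(csv_path))
    utils::write.table(df, csv_path, sep = ",", row.names = FALSE, na = "",
                       qmethod = "double")
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
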