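# Cohort statistics mirroring the study's reporting: Shapiro-Wilk
# normality, mean-centered Levene variance homogeneity, paired two-sided
# t-tests at alpha = 0.05, mean +/- SD summary tables.

#' Shapiro-Wilk normality check
#'
#' @param values numeric sample, 3 <= n <= 50.
#' @return list(W, p).
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stop("normality_check requires 3 <= n <= 50, got ", n,
                            call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("zero-variance sample: normality undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Levene variance-homogeneity test (mean-centered)
#'
#' One-way ANOVA F on the absolute deviations from each group's mean.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return list(statistic, p, df).
#' @export
variance_homogeneity <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  z <- c(za, zb)
  g <- rep(1:2, c(length(za), length(zb)))
  k <- 2; n <- length(z)
  zbar <- mean(z)
  means <- tapply(z, g, mean)
  ssb <- sum(tabulate(g) * (means - zbar)^2)
  ssw <- sum((z - means[g])^2)
  if (ssw == 0) return(list(statistic = 0, p = 1, df = c(k - 1, n - k)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df = c(k - 1, n - k))
}

#' Paired two-sided t-test
#'
#' @param x,y paired samples of equal length, n >= 2, with nonzero
#'   difference variance.
#' @return list(t, df, p, mean_diff).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  d <- x - y
  tol <- .Machine$double.eps^0.5 * max(abs(d), 1)
  if (stats::sd(d) <= tol) {
    if (abs(mean(d)) <= tol) {
      # identical samples: no difference and no evidence of one
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    }
    stop("zero variance of differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d))
}

fmt_msd <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
fmt_p <- function(p) {
  out <- sprintf("%.3f", p)
  ifelse(p < 0.0005, "0.000", out)
}

#' Cohort summary and comparison tables
#'
#' Per-metric n/mean/SD/min/max; left-vs-right paired t for the triggering-
#' and stretching-phase loaded forces, pre-vs-post paired t for the maximum
#' rotation angle; Shapiro-Wilk and Levene checks on each compared pair.
#' Subjects missing one side are dropped pairwise (count logged). When
#' Levene rejects homogeneity an unpaired Welch comparison is reported
#' alongside as `test_name = "welch_t"`.
#'
#' @param tbl data.frame from [metrics_table()] over >= 2 subjects with
#'   both sides.
#' @return a `cohort_summary` list: `summary` data.frame, `comparisons`
#'   data.frame, `checks` list.
#' @export
summarize_cohort <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (length(unique(tbl$subject_id)) < 2) {
    stop("cohort summary needs >= 2 subjects", call. = FALSE)
  }
  num_cols <- c(stretch_loaded_max_N = "stretch loaded force (N)",
                trigger_loaded_max_N = "trigger loaded force (N)",
                trigger_time_s = "trigger time (s)",
                extension_amplitude_mm = "extension amplitude (mm)",
                max_rotation_pre_deg = "max rotation pre (deg)",
                max_rotation_post_deg = "max rotation post (deg)")
  summ <- do.call(rbind, lapply(names(num_cols), function(cn) {
    v <- tbl[[cn]]
    v <- v[!is.na(v)]
    data.frame(metric = num_cols[[cn]], n = length(v), mean = mean(v),
               sd = stats::sd(v), min = min(v), max = max(v),
               mean_sd = fmt_msd(v))
  }))

  left <- tbl[tbl$side == "left_rotation", ]
  right <- tbl[tbl$side == "right_rotation", ]
  common <- intersect(left$subject_id, right$subject_id)
  dropped <- length(unique(tbl$subject_id)) - length(common)
  if (dropped > 0) {
    message(dropped, " subject(s) dropped pairwise (missing a side)")
  }
  left <- left[match(common, left$subject_id), ]
  right <- right[match(common, right$subject_id), ]

  comparisons <- list()
  checks <- list()
  cmp <- function(name, x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    sw_x <- tryCatch(normality_check(x), error = function(e) list(W = NA, p = NA))
    sw_y <- tryCatch(normality_check(y), error = function(e) list(W = NA, p = NA))
    lev <- tryCatch(variance_homogeneity(x, y),
                    error = function(e) list(statistic = NA, p = NA))
    pt <- paired_t(x, y)
    test <- "paired_t"
    if (!is.na(lev$p) && lev$p < 0.05) {
      wt <- stats::t.test(x, y, paired = FALSE, var.equal = FALSE)
      message("Levene rejected homogeneity for '", name,
              "'; Welch comparison reported")
      comparisons[[paste0(name, "_welch")]] <<- data.frame(
        comparison = name, test_name = "welch_t", n = length(x),
        statistic = unname(wt$statistic), p = wt$p.value,
        p_display = fmt_p(wt$p.value))
    }
    checks[[name]] <<- list(shapiro_x = sw_x, shapiro_y = sw_y, levene = lev)
    comparisons[[name]] <<- data.frame(
      comparison = name, test_name = test, n = length(x),
      statistic = pt$t, p = pt$p, p_display = fmt_p(pt$p))
  }
  cmp("trigger_loaded_left_vs_right",
      left$trigger_loaded_max_N, right$trigger_loaded_max_N)
  cmp("stretch_loaded_left_vs_right",
      left$stretch_loaded_max_N, right$stretch_loaded_max_N)
  pre <- tapply(tbl$max_rotation_pre_deg, tbl$subject_id, mean, na.rm = TRUE)
  post <- tapply(tbl$max_rotation_post_deg, tbl$subject_id, mean, na.rm = TRUE)
  cmp("rotation_pre_vs_post", pre, post)

  structure(list(summary = summ,
                 comparisons = do.call(rbind, comparisons),
                 checks = checks, n_dropped = dropped),
            class = "cohort_summary")
}

#' Render a cohort summary
#'
#' Pure renderers: identical inputs give byte-identical outputs.
#'
#' @param x a `cohort_summary`.
#' @param dir output directory; writes `summary.csv`, `comparisons.csv` and
#'   `report.md`.
#' @return invisibly, the paths written.
#' @export
render_cohort_summary <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- file.path(dir, c("summary.csv", "comparisons.csv", "report.md"))
  utils::write.csv(x$summary, ps[1], row.names = FALSE)
  utils::write.csv(x$comparisons, ps[2], row.names = FALSE)
  md <- c("# Cohort report", "",
          "## Metrics (mean ± SD)", "",
          sprintf("- %s: n=%d, %s [%.2f, %.2f]", x$summary$metric,
                  x$summary$n, x$summary$mean_sd, x$summary$min,
                  x$summary$max),
          "", "## Comparisons (two-sided, alpha = 0.05)", "",
          sprintf("- %s (%s): statistic=%.3f, P=%s", x$comparisons$comparison,
                  x$comparisons$test_name, x$comparisons$statistic,
                  x$comparisons$p_display))
  writeLines(md, ps[3])
  invisible(ps)
}
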