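#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston implementation with the
#' preconditions made explicit: `3 <= n <= 5000` and a non-constant
#' sample.
#'
#' @param sample numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiroWilk <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (stats::sd(sample) == 0)
    stop("Shapiro-Wilk is undefined for a constant sample")
  ht <- stats::shapiro.test(sample)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, the pooled SD computed over
#' `n1 + n2 - 2` degrees of freedom. The sign is retained.
#'
#' @param a,b numeric samples.
#' @return Scalar effect size.
#' @export
cohensD <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Cohen's d from a t statistic
#'
#' Standard conversion for a two-sample pooled-variance t-test:
#' `d = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes.
#' @return Scalar effect size.
#' @examples
#' dFromT(5.187, 8, 8)  # ~2.59
#' @export
dFromT <- function(t, n1, n2) {
  t * sqrt(1 / n1 + 1 / n2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1). The family is
#' whatever vector is passed in one call; the cohort-level wrappers use
#' the full band x metric x task grid of one analysis run by default.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bhFdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample comparison with normality gating
#'
#' Shapiro-Wilk is applied to each group at `gate_alpha`; if both pass,
#' a two-sided pooled-variance independent-samples t-test
#' (`df = n1 + n2 - 2`) is used, otherwise a two-sided Mann-Whitney U
#' test (U reported for the first sample). Cohen's d from the pooled SD
#' is always reported.
#'
#' @param a,b numeric samples (first sample = patient group by
#'   convention in the cohort wrappers).
#' @param gate_alpha normality gate level (default 0.05).
#' @return List with `test` (`"t"` or `"mann-whitney"`), `statistic`,
#'   `df` (NA for Mann-Whitney), `p`, `cohens_d`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`.
#' @export
compareGroups <- function(a, b, gate_alpha = 0.05) {
  normal <- length(a) >= 3 && length(b) >= 3 &&
    stats::sd(a) > 0 && stats::sd(b) > 0 &&
    shapiroWilk(a)$p > gate_alpha && shapiroWilk(b)$p > gate_alpha
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test = "t", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    res <- list(test = "mann-whitney", statistic = unname(ht$statistic),
                df = NA_real_, p = ht$p.value)
  }
  c(res, list(cohens_d = cohensD(a, b),
              mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b)))
}

## all permutations of 1..n as an n! x n matrix (small n only)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row + seq_len(nrow(sub))
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation of a network metric with MAS severity
#'
#' Rank correlation (midranks for ties) between patient metric values and
#' numeric MAS codes (0, 1, 1.5, 2; see [masCode()]). The two-sided p
#' comes from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` by default; an exact permutation p
#' is available for `n <= 9`.
#'
#' @param metrics numeric metric values (one per patient).
#' @param mas numeric MAS codes, same length (`n >= 4`).
#' @param exact use the exact permutation null (only for `n <= 9`).
#' @return List with `rho` and `p`.
#' @export
spearmanMas <- function(metrics, mas, exact = FALSE) {
  ok <- stats::complete.cases(metrics, mas)
  x <- metrics[ok]; y <- mas[ok]
  n <- length(x)
  if (n < 4) stop("Spearman correlation requires n >= 4")
  rho <- stats::cor(x, y, method = "spearman")
  if (is.na(rho)) stop("correlation undefined (constant input)")
  if (exact) {
    if (n > 9) stop("exact permutation p only supported for n <= 9")
    rx <- rank(x); ry <- rank(y)
    perms <- allPermutations(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= obs - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

#' Group comparisons over a cohort metric table
#'
#' Runs [compareGroups()] (patient vs control) for every task x band x
#' metric cell of an aggregate metric table and adjusts p-values by
#' Benjamini-Hochberg FDR. The FDR family is the full grid of one run by
#' default, or per task.
#'
#' @param metric_table data.frame with columns `subject_id`, `task`,
#'   `band`, and one column per metric (see [cohortMetricTable()]); must
#'   contain only aggregate rows (one per subject x task x band).
#' @param manifest cohort manifest with `subject_id` and `group`.
#' @param metrics metric columns to compare.
#' @param gate_alpha normality gate level.
#' @param fdr_scope `"run"` (one family) or `"task"` (family per task).
#' @return data.frame, one row per comparison: task, band, metric, test,
#'   statistic, df, p, p_fdr, cohens_d, patient/control mean and SD.
#' @export
compareCohortMetrics <- function(metric_table, manifest,
                                 metrics = c("cc", "le", "ge", "sw"),
                                 gate_alpha = 0.05,
                                 fdr_scope = c("run", "task")) {
  fdr_scope <- match.arg(fdr_scope)
  tab <- merge(metric_table, manifest[, c("subject_id", "group")],
               by = "subject_id")
  cells <- unique(tab[, c("task", "band")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- tab[tab$task == cells$task[r] & tab$band == cells$band[r], ]
    for (m in metrics) {
      a <- sub[[m]][sub$group == "patient"]
      b <- sub[[m]][sub$group == "control"]
      cmp <- compareGroups(a, b, gate_alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        task = cells$task[r], band = cells$band[r], metric = m,
        test = cmp$test, statistic = cmp$statistic, df = cmp$df,
        p = cmp$p, cohens_d = cmp$cohens_d,
        patient_mean = cmp$mean_a, patient_sd = cmp$sd_a,
        control_mean = cmp$mean_b, control_sd = cmp$sd_b,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (fdr_scope == "run") {
    out$p_fdr <- bhFdr(out$p)
  } else {
    out$p_fdr <- NA_real_
    for (tk in unique(out$task)) {
      sel <- out$task == tk
      out$p_fdr[sel] <- bhFdr(out$p[sel])
    }
  }
  out
}

#' Spearman correlations of metrics with MAS within patients
#'
#' @inheritParams compareCohortMetrics
#' @param manifest cohort manifest with `subject_id`, `group`, and the
#'   MAS grade column.
#' @param mas_column which MAS grade to correlate (default upper limb).
#' @param exact forwarded to [spearmanMas()].
#' @return data.frame: task, band, metric, n, rho, p.
#' @export
correlateWithMas <- function(metric_table, manifest,
                             metrics = c("cc", "le", "ge", "sw"),
                             mas_column = c("mas_upper", "mas_hand"),
                             exact = FALSE) {
  mas_column <- match.arg(mas_column)
  pat <- manifest[manifest$group == "patient",
                  c("subject_id", mas_column)]
  pat$mas_num <- masCode(pat[[mas_column]])
  tab <- merge(metric_table, pat, by = "subject_id")
  cells <- unique(tab[, c("task", "band")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- tab[tab$task == cells$task[r] & tab$band == cells$band[r], ]
    for (m in metrics) {
      sp <- tryCatch(spearmanMas(sub[[m]], sub$mas_num, exact = exact),
                     error = function(e) list(rho = NA_real_,
                                              p = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        task = cells$task[r], band = cells$band[r], metric = m,
        n = nrow(sub), rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
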