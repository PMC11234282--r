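#' Mean of a parametric map over an ROI
#'
#' @param map A [quant_map()] (or plain 3-D array).
#' @param roi_mask Logical array.
#' @return List: `mean`, `sd`, `n_voxels`.
#' @export
extract_roi <- function(map, roi_mask) {
  vals <- if (inherits(map, "quant_map")) {
    sel <- roi_mask & map$mask
    if (!any(sel)) stop("ROI does not overlap the valid map region")
    map$values[sel]
  } else {
    if (!any(roi_mask)) stop("empty ROI")
    map[roi_mask]
  }
  list(mean = mean(vals), sd = stats::sd(vals), n_voxels = length(vals))
}

#' Relative change between treated and control sides
#'
#' Percent reduction 100 (1 - ipsi/contra), reported raw and rounded to the
#' nearest integer (ties away from zero), the convention used for headline
#' percentages.
#'
#' @param mean_ipsi,mean_contra Means in the same unit; `mean_contra > 0`.
#' @return List: `raw` (\%), `rounded` (integer \%).
#' @export
relative_change <- function(mean_ipsi, mean_contra) {
  if (mean_contra <= 0) stop("mean_contra must be > 0")
  raw <- 100 * (1 - mean_ipsi / mean_contra)
  list(raw = raw, rounded = as.integer(sign(raw) * floor(abs(raw) + 0.5)))
}

#' Exact two-tailed Wilcoxon signed-rank test
#'
#' Paired nonparametric test. Zero differences are dropped (count
#' reported); ties among absolute differences are mid-ranked. For n <= 25
#' the null distribution of the positive-rank sum W is computed exactly by
#' convolution over the (doubled, hence integer) ranks — identical to full
#' enumeration of all 2^n sign assignments; above that a normal
#' approximation with tie correction and continuity correction is used.
#' The two-tailed p is min(1, 2 min(P(W' <= W), P(W' >= W))).
#'
#' @param x Ipsilateral values, or differences if `y` is `NULL`.
#' @param y Contralateral values (paired with `x`).
#' @return List: `p_value`, `statistic` (W), `n` (non-zero pairs),
#'   `n_zero` (dropped), `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1, all(is.finite(d)))
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    dr <- as.integer(round(2 * r))        # doubled ranks are integers
    total <- sum(dr)
    f <- numeric(total + 1L); f[1] <- 1   # f[k+1] = #assignments with sum k
    for (k in dr) {
      g <- numeric(total + 1L)
      g[(k + 1L):(total + 1L)] <- f[seq_len(total + 1L - k)]
      f <- f + g
    }
    w2 <- round(2 * W)
    p_le <- sum(f[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(p_value = p, statistic = W, n = n, n_zero = n_zero, method = method)
}

#' Paired ROI summary for one metric
#'
#' Mean +/- SD per side, relative change under both conventions (ratio of
#' group means, and mean of per-subject ratios), and the exact Wilcoxon
#' signed-rank p-value.
#'
#' @param ipsi,contra Per-subject ROI means (same unit, paired).
#' @param metric,timepoint Optional labels.
#' @return A `roi_report` list.
#' @export
roi_report <- function(ipsi, contra, metric = NA_character_,
                       timepoint = NA_character_) {
  stopifnot(length(ipsi) == length(contra), length(ipsi) >= 1,
            !anyNA(ipsi), !anyNA(contra))
  rc_means <- if (mean(contra) > 0) relative_change(mean(ipsi), mean(contra))
    else list(raw = NA_real_, rounded = NA_integer_)
  rc_subj <- ifelse(contra > 0, 100 * (1 - ipsi / contra), NA_real_)
  wt <- tryCatch(wilcoxon_exact(ipsi, contra),
                 error = function(e) list(p_value = NA_real_, statistic = NA_real_,
                                          n = 0L, n_zero = length(ipsi),
                                          method = "degenerate"))
  structure(list(metric = metric, timepoint = timepoint,
                 n = length(ipsi),
                 mean_ipsi = mean(ipsi), sd_ipsi = stats::sd(ipsi),
                 mean_contra = mean(contra), sd_contra = stats::sd(contra),
                 relative_change_pct = rc_means$raw,
                 relative_change_rounded = rc_means$rounded,
                 relative_change_subjectwise_pct = mean(rc_subj, na.rm = TRUE),
                 p_value = wt$p_value, statistic = wt$statistic,
                 n_zero_dropped = wt$n_zero, test = "wilcoxon_signed_rank",
                 test_method = wt$method),
            class = "roi_report")
}

#' Assemble the study report
#'
#' Collects per-group, per-timepoint ROI statistics, cavitation verdicts
#' and histology quantifications into one machine-readable structure, with
#' every configuration constant echoed.
#'
#' @param roi_stats data.frame with columns `group`, `timepoint`, `metric`,
#'   `subject`, `ipsi`, `contra` (may be empty).
#' @param verdicts data.frame with columns `subject`, `label`,
#'   `pct_inertial`, `pct_consecutive` (may be `NULL`).
#' @param histology data.frame of [quantify_roi()] rows (may be `NULL`).
#' @param config Named list echoed into the report.
#' @return A nested list (serialisable with [jsonlite::write_json()]):
#'   `schema`, `config`, `groups`, `cavitation`, `histology`.
#' @export
assemble_report <- function(roi_stats = NULL, verdicts = NULL,
                            histology = NULL, config = list()) {
  report <- list(schema = "sonoperm-report/1", config = config,
                 groups = list(), cavitation = NULL, histology = NULL)
  if (!is.null(roi_stats) && nrow(roi_stats) > 0) {
    need <- c("group", "timepoint", "metric", "subject", "ipsi", "contra")
    stopifnot(all(need %in% names(roi_stats)))
    cells <- unique(roi_stats[c("group", "timepoint", "metric")])
    for (i in seq_len(nrow(cells))) {
      sel <- roi_stats$group == cells$group[i] &
        roi_stats$timepoint == cells$timepoint[i] &
        roi_stats$metric == cells$metric[i]
      sub <- roi_stats[sel, ]
      if (anyDuplicated(sub$subject))
        stop("duplicate subject within a group/timepoint/metric cell")
      rep_i <- roi_report(sub$ipsi, sub$contra, cells$metric[i],
                          cells$timepoint[i])
      key <- paste(cells$group[i], cells$timepoint[i], cells$metric[i],
                   sep = "/")
      report$groups[[key]] <- unclass(rep_i)
    }
  }
  if (!is.null(verdicts) && nrow(verdicts) > 0) {
    tab <- table(factor(verdicts$label, levels = c("soft", "mild", "hard")))
    report$cavitation <- list(
      n = nrow(verdicts),
      counts = as.list(tab),
      fractions_pct = as.list(100 * as.numeric(tab) / nrow(verdicts)) |>
        stats::setNames(names(tab)),
      subjects = verdicts)
  }
  if (!is.null(histology) && nrow(histology) > 0)
    report$histology <- histology
  report
}
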