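#' Box-plot statistics with the extreme-outlier rule
#'
#' Quartiles (type-7 convention), mean, sd, whiskers, and outliers flagged by
#' the extreme rule: values above `q3 + 3 (q3 - q1) / 2` or below
#' `q1 - 3 (q3 - q1) / 2`.
#'
#' @param x Numeric vector (NAs dropped).
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`, `outliers` (list column).
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(tibble::tibble(n = 0L, mean = NA_real_, sd = NA_real_,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          whisker_lo = NA_real_, whisker_hi = NA_real_,
                          n_outliers = 0L, outliers = list(numeric(0))))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  span <- 3 * (q[3] - q[1]) / 2
  lo <- q[1] - span
  hi <- q[3] + span
  out <- x[x < lo | x > hi]
  inl <- x[x >= lo & x <= hi]
  tibble::tibble(
    n = length(x), mean = mean(x), sd = stats::sd(x),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = if (length(inl)) min(inl) else NA_real_,
    whisker_hi = if (length(inl)) max(inl) else NA_real_,
    n_outliers = length(out), outliers = list(out)
  )
}

#' Summarise perturbation results
#'
#' Per-group box statistics (mean, sd, quartiles, whiskers, extreme outliers)
#' of the percentage changes in one or several [run_constriction_experiment()]
#' / [run_deformation_experiment()] results. Empty groups are dropped with a
#' message.
#'
#' @param results A `perturbation_result` or a list of them (e.g. the 25
#'   repeats of one scenario).
#' @param group Grouping column: `"class"`, `"cap_order"`, or `"none"` (whole
#'   network).
#' @param metric Which percentage change to summarise (`"velocity_pct"`,
#'   `"flow_pct"`, `"pressure_pct"`, `"hd_pct"`, `"po2_pct"`).
#' @param constricted_only Restrict to the constricted segments themselves
#'   (default `FALSE`).
#' @return A tibble, one row per group.
#' @export
summarize_changes <- function(results, group = c("class", "cap_order", "none"),
                              metric = "velocity_pct",
                              constricted_only = FALSE) {
  group <- match.arg(group)
  if (inherits(results, "perturbation_result")) results <- list(results)
  tbl <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    s <- r$segments
    if (constricted_only) s <- s[s$segment_id %in% r$constricted, ]
    s$replicate <- i
    s
  }))
  if (!metric %in% names(tbl)) stop("metric '", metric, "' not present")
  key <- if (group == "none") rep("all", nrow(tbl)) else tbl[[group]]
  keep <- !is.na(key) & !is.na(tbl[[metric]])
  tbl <- tbl[keep, ]
  key <- key[keep]
  if (!nrow(tbl)) {
    message("no data after grouping; empty summary")
    return(tibble::tibble())
  }
  parts <- split(tbl[[metric]], key)
  out <- dplyr::bind_rows(lapply(parts, box_stats))
  out <- dplyr::bind_cols(tibble::tibble(group = names(parts)), out)
  names(out)[1] <- if (group == "none") "group" else group
  out
}
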