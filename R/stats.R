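#' Two-sided paired t-test
#'
#' Classical paired t: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' within-pair differences `d = a - b`, with `n - 1` degrees of freedom
#' and a two-sided p-value.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`, paired by
#'   position.
#' @param comparison Label carried into the result.
#' @return One-row data frame: `comparison`, `test`, `statistic`, `df`,
#'   `p`, `n`.
#' @export
paired_t <- function(a, b, comparison = "paired") {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate paired test: all differences identical", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  data.frame(comparison = comparison, test = "paired_t",
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, n = n, stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Tests a within-subject condition effect with subject as the blocking
#' factor (one observation per subject x condition cell). The F statistic
#' is `MS_condition / MS_error` where the error stratum is the
#' subject-by-condition residual.
#'
#' @param values Either a numeric matrix (rows = subjects, columns =
#'   conditions) or a long data frame with columns `subject`, `condition`,
#'   `value`.
#' @param comparison Label carried into the result.
#' @return One-row data frame: `comparison`, `test`, `statistic` (F),
#'   `df` (string "df1,df2"), `p`, `n` (subjects).
#' @export
rm_anova <- function(values, comparison = "rm_anova") {
  long <- rm_anova_long(values)
  tab <- table(long$subject, long$condition)
  if (any(tab != 1L)) {
    miss <- which(tab == 0L, arr.ind = TRUE)
    lab <- apply(miss, 1, function(i)
      paste0(rownames(tab)[i[1]], ":", colnames(tab)[i[2]]))
    stop(sprintf("incomplete subject x condition table (missing cells: %s)",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  fit <- stats::aov(value ~ condition + Error(subject),
                    data = transform(long, subject = factor(subject),
                                     condition = factor(condition)))
  s <- summary(fit)[["Error: Within"]][[1]]
  data.frame(comparison = comparison, test = "rm_anova",
             statistic = s["condition", "F value"],
             df = sprintf("%d,%d", s["condition", "Df"], s["Residuals", "Df"]),
             p = s["condition", "Pr(>F)"], n = nrow(tab),
             stringsAsFactors = FALSE)
}

rm_anova_long <- function(values) {
  if (is.matrix(values)) {
    if (is.null(colnames(values)))
      colnames(values) <- paste0("c", seq_len(ncol(values)))
    data.frame(subject = rep(seq_len(nrow(values)), ncol(values)),
               condition = rep(colnames(values), each = nrow(values)),
               value = as.vector(values), stringsAsFactors = FALSE)
  } else if (is.data.frame(values)) {
    stopifnot(all(c("subject", "condition", "value") %in% names(values)))
    values[c("subject", "condition", "value")]
  } else stop("`values` must be a matrix or long data frame", call. = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `q_i = min_{j >= i} p_j * m / j`, returned in the original
#' order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Normalize a stream segment to relative time 0-100%
#'
#' Resamples the stream over `[start, end]` onto `n` equally spaced
#' relative time points by linear interpolation, so epochs of different
#' durations can be overlaid or averaged. With `n = 1` the single sample
#' is taken at the epoch midpoint.
#'
#' @param x An `sts_ts`.
#' @param epoch One-row epoch data frame with `start_s`, `end_s`.
#' @param n Number of output samples (default 100).
#' @return Numeric vector of `n` interpolated values.
#' @export
time_normalize <- function(x, epoch, n = 100) {
  stopifnot(inherits(x, "sts_ts"))
  if (!is.finite(epoch$start_s) || !is.finite(epoch$end_s) ||
      epoch$end_s <= epoch$start_s)
    stop("empty epoch", call. = FALSE)
  tq <- if (n == 1L) (epoch$start_s + epoch$end_s) / 2 else
    seq(epoch$start_s, epoch$end_s, length.out = n)
  stats::approx(ts_time(x), x$values, xout = tq, rule = 2)$y
}

#' z-transform a vector
#'
#' Centers on the mean and scales to unit standard deviation. The default
#' uses the population standard deviation (divisor `n`); set
#' `sample_sd = TRUE` for the `n - 1` divisor.
#'
#' @param x Numeric vector with positive spread.
#' @param sample_sd Use the sample (n-1) standard deviation.
#' @return Standardized vector: mean 0, sd 1 under the chosen convention.
#' @export
z_transform <- function(x, sample_sd = FALSE) {
  if (!all(is.finite(x))) stop("non-finite values", call. = FALSE)
  s <- if (sample_sd) stats::sd(x) else
    sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0) stop("zero-variance input", call. = FALSE)
  (x - mean(x)) / s
}

#' Run the full statistical battery on a feature table
#'
#' Reproduces the study's comparisons from a per-epoch feature table:
#' \itemize{
#'   \item per condition, left vs right iEMG and left vs right maximum
#'     EMG (paired t; jacket-on epochs);
#'   \item the three pairwise between-condition comparisons of maximum
#'     trunk flexion angle (jacket-on), BH-corrected as a family of three;
#'   \item for each of the four features (iEMG, maximum EMG, mean AP COP,
#'     maximum trunk angle) and each condition, jacket vs no jacket
#'     (paired t, reported unadjusted);
#'   \item three-condition repeated-measures ANOVAs for iEMG and maximum
#'     EMG (jacket-on).
#' }
#' Bilateral features (iEMG, maximum EMG) enter the jacket and condition
#' comparisons as the left/right mean. The analysis unit is the
#' per-subject mean over repetitions (`unit = "subject"`, n = subjects);
#' `unit = "epoch"` instead pairs individual repetitions.
#'
#' @param features Feature table from [build_feature_table()] (or rows
#'   from several subjects bound together).
#' @param unit `"subject"` (default) or `"epoch"`.
#' @param alpha Significance level used only for the `significant` column.
#' @return Data frame of class `sts_stats`: one row per comparison with
#'   `comparison`, `test`, `statistic`, `df`, `p`, `p_adjusted` (NA where
#'   no family correction applies) and `significant`.
#' @export
run_sts_comparisons <- function(features, unit = c("subject", "epoch"),
                                alpha = 0.05) {
  unit <- match.arg(unit)
  conds <- c("both-hands-on-knees", "one-hand-on-table", "both-hands-on-table")
  for (cn in conds)
    if (!cn %in% features$condition)
      stop(sprintf("condition '%s' absent from feature table", cn),
           call. = FALSE)
  for (j in c(TRUE, FALSE))
    if (!j %in% features$jacket)
      stop(sprintf("jacket level '%s' absent from feature table", j),
           call. = FALSE)

  features$iemg_mean <- (features$iemg_left + features$iemg_right) / 2
  features$max_emg_mean <- (features$max_emg_left + features$max_emg_right) / 2

  agg <- function(df) {
    if (unit == "subject")
      stats::aggregate(df[setdiff(names(df), c("subject", "condition",
                                               "jacket", "rep"))],
                       by = df[c("subject", "condition", "jacket")], mean,
                       na.rm = TRUE)
    else df
  }
  fx <- agg(features)
  res <- list()

  # left vs right, per condition, jacket on
  for (cn in conds) {
    sub <- fx[fx$condition == cn & fx$jacket, ]
    res[[length(res) + 1L]] <-
      paired_t(sub$iemg_left, sub$iemg_right,
               sprintf("iemg left vs right | %s", cn))
    res[[length(res) + 1L]] <-
      paired_t(sub$max_emg_left, sub$max_emg_right,
               sprintf("max_emg left vs right | %s", cn))
  }

  # pairwise condition comparisons of trunk angle (jacket on), BH family
  angle_rows <- list()
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  on <- fx[fx$jacket, ]
  for (pr in pairs) {
    a <- on[on$condition == pr[1], ]
    b <- on[on$condition == pr[2], ]
    m <- merge_on_unit(a, b, unit)
    angle_rows[[length(angle_rows) + 1L]] <-
      paired_t(m$max_trunk_angle.x, m$max_trunk_angle.y,
               sprintf("max_trunk_angle %s vs %s", pr[1], pr[2]))
  }
  angle_df <- do.call(rbind, angle_rows)
  angle_df$p_adjusted <- bh_adjust(angle_df$p)

  # jacket vs no jacket per feature and condition
  for (feat in c("iemg_mean", "max_emg_mean", "mean_cop_ap",
                 "max_trunk_angle")) {
    for (cn in conds) {
      a <- fx[fx$condition == cn & fx$jacket, ]
      b <- fx[fx$condition == cn & !fx$jacket, ]
      m <- merge_on_unit(a, b, unit)
      res[[length(res) + 1L]] <-
        paired_t(m[[paste0(feat, ".x")]], m[[paste0(feat, ".y")]],
                 sprintf("%s jacket vs none | %s", feat, cn))
    }
  }

  # three-condition ANOVAs (jacket on)
  for (feat in c("iemg_mean", "max_emg_mean")) {
    long <- data.frame(subject = on$subject, condition = on$condition,
                       value = on[[feat]])
    if (unit == "epoch") {   # average epochs within subject for the ANOVA cell
      long <- stats::aggregate(value ~ subject + condition, long, mean)
    }
    res[[length(res) + 1L]] <-
      rm_anova(long, sprintf("%s across conditions", feat))
  }

  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  out <- rbind(out, angle_df)
  out$significant <- ifelse(is.na(out$p_adjusted), out$p < alpha,
                            out$p_adjusted < alpha)
  rownames(out) <- NULL
  class(out) <- c("sts_stats", "data.frame")
  out
}

# pair two per-unit subsets by subject (and rep when unit = "epoch")
merge_on_unit <- function(a, b, unit) {
  keys <- if (unit == "epoch") c("subject", "rep") else "subject"
  m <- merge(a, b, by = keys)
  if (!nrow(m)) stop("no paired units between groups", call. = FALSE)
  m[order(m$subject), ]
}
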