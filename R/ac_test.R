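# Audic-Claverie test for digital expression data.
#
# For a tag observed x times in library A (total N_A) and y times in
# library B (total N_B), the probability of y given x under equal
# expression is
#
#   p(y|x) = (N_B/N_A)^y * (x+y)! / ( x! y! (1 + N_B/N_A)^(x+y+1) )
#
# evaluated in log space. Over k = 0,1,2,... the p(k|x) sum to exactly 1
# (they form a negative binomial), which licenses complement evaluation
# of tails.

ac_check_args <- function(x, y, N_A, N_B) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N_A < 1) || any(N_B < 1)) stop("library totals must be >= 1")
}

ac_log_prob <- function(x, y, N_A, N_B) {
  r <- N_B / N_A
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Audic-Claverie conditional probability p(y | x)
#'
#' The probability of observing a tag \code{y} times in library B given
#' \code{x} observations in library A (library totals \code{N_A},
#' \code{N_B}), under the null hypothesis of equal expression.
#'
#' @param x,y non-negative tag counts in libraries A and B (vectorised).
#' @param N_A,N_B positive library totals.
#' @return numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' ac_probability(0, 0, 1000, 1000)  # 0.5
#' ac_probability(5, 15, 1894, 2670)
ac_probability <- function(x, y, N_A, N_B) {
  ac_check_args(x, y, N_A, N_B)
  exp(ac_log_prob(x, y, N_A, N_B))
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Audic-Claverie tail probabilities and two-sided p-value
#'
#' \code{p_left} is the probability of observing at most \code{y} tags in
#' library B, \code{p_right} of observing at least \code{y}; they share
#' the point mass at \code{y}, so \code{p_left + p_right - p(y|x) = 1}.
#' The two-sided p-value doubles the smaller tail and caps at 1. The left
#' tail is accumulated in log space; the right tail is summed directly
#' upward from \code{y} so that small right tails retain full relative
#' accuracy.
#'
#' @inheritParams ac_probability
#' @return for scalar input, a named list \code{p_left}, \code{p_right},
#'   \code{p_two_sided}; for vector input, a data.frame of those columns.
#' @export
#' @examples
#' ac_two_sided(0, 12, 1894, 2670)
ac_two_sided <- function(x, y, N_A, N_B) {
  ac_check_args(x, y, N_A, N_B)
  one <- function(x, y) {
    p_left <- exp(logsumexp(ac_log_prob(x, 0:y, N_A, N_B)))
    p_left <- min(p_left, 1)
    # right tail: direct ascending summation; successive-term ratio is
    # (x+k+1)/(k+1) * N_B/(N_A+N_B), eventually < 1
    q <- N_B / (N_A + N_B)
    term <- exp(ac_log_prob(x, y, N_A, N_B))
    acc <- term
    k <- y
    repeat {
      term <- term * (x + k + 1) / (k + 1) * q
      acc <- acc + term
      k <- k + 1
      if (term < acc * 1e-17 && (x + k + 1) / (k + 1) * q < 1) break
    }
    p_right <- min(acc, 1)
    list(p_left = p_left, p_right = p_right,
         p_two_sided = min(1, 2 * min(p_left, p_right)))
  }
  if (length(x) == 1 && length(y) == 1) return(one(x, y))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  res <- mapply(one, x, y, SIMPLIFY = FALSE)
  data.frame(p_left = vapply(res, `[[`, 0, "p_left"),
             p_right = vapply(res, `[[`, 0, "p_right"),
             p_two_sided = vapply(res, `[[`, 0, "p_two_sided"))
}

#' Library-size corrected representation ratio (Dif)
#'
#' The per-tag ratio of counts in library A over library B, multiplied by
#' the correction coefficient C = round(N_B_total / N_A_total, decimals),
#' so that a tag represented proportionally equally in both libraries has
#' Dif of about 1. A tag absent from B gives +Inf; absent from A gives 0.
#'
#' @param n_A,n_B per-tag counts (vectorised); not both zero.
#' @param T_A,T_B library totals.
#' @param decimals decimal places the correction coefficient is rounded
#'   to before use (2 by convention: totals 1894 and 2670 give C = 1.41).
#' @return numeric vector of Dif values (possibly \code{Inf}).
#' @export
#' @examples
#' dif_statistic(5, 2, 1894, 2670)
dif_statistic <- function(n_A, n_B, T_A, T_B, decimals = 2L) {
  if (any(n_A + n_B < 1)) stop("a tag must be observed in at least one library")
  if (T_A < 1 || T_B < 1) stop("library totals must be >= 1")
  C <- round(T_B / T_A, decimals)
  ifelse(n_B == 0, Inf, n_A / n_B * C)
}

#' Correction coefficient for library-size imbalance
#'
#' @inheritParams dif_statistic
#' @return \code{round(T_B / T_A, decimals)}.
#' @export
#' @examples
#' correction_coefficient(1894, 2670)  # 1.41
correction_coefficient <- function(T_A, T_B, decimals = 2L) {
  stopifnot(T_A >= 1, T_B >= 1)
  round(T_B / T_A, decimals)
}

#' Classify Dif values against the significance band
#'
#' Values inside \code{[band_low, band_high]} are consistent with equal
#' representation; values outside the band (including 0 and +Inf) are
#' flagged significant.
#'
#' @param dif numeric vector of Dif values.
#' @param band_low,band_high the non-significance band, default 0.6-1.6.
#' @return logical vector, \code{TRUE} where significant.
#' @export
classify_dif <- function(dif, band_low = 0.6, band_high = 1.6) {
  stopifnot(band_low < band_high)
  dif < band_low | dif > band_high
}

DIF_BINS <- data.frame(
  label = c("2.7-3.7", "1.7-2.6", "0.6-1.6", "0.3-0.5"),
  lower = c(2.7, 1.7, 0.6, 0.3),
  upper = c(3.7, 2.6, 1.6, 0.5),
  stringsAsFactors = FALSE
)

#' Binned report of Dif values
#'
#' Assigns each tag's Dif, rounded to one decimal, to the ranges
#' 2.7-3.7, 1.7-2.6, 0.6-1.6 (the non-significance band) and 0.3-0.5;
#' anything outside all four goes to an explicit \code{out_of_table} bin
#' so the report is exhaustive. Percentages are weighted by library-A
#' tag counts by default ("relative content" of library A), or one per
#' unique tag.
#'
#' @param results data.frame with columns \code{dif} and \code{count_A}
#'   (e.g. the \code{$results} of a \code{\link{sage_test}} fit).
#' @param weighting \code{"by_tag_count"} (library-A abundance weighted,
#'   default) or \code{"by_unique_tag"}.
#' @param band_label label of the non-significance bin.
#' @return data.frame of class \code{"binned_report"} with columns
#'   \code{label}, \code{lower}, \code{upper}, \code{percent},
#'   \code{significant}; attribute \code{total_significant_percent}.
#' @export
binned_report <- function(results,
                          weighting = c("by_tag_count", "by_unique_tag"),
                          band_label = "0.6-1.6") {
  weighting <- match.arg(weighting)
  if (NROW(results) == 0) stop("binned_report needs at least one result")
  d <- round(results$dif, 1)
  w <- if (weighting == "by_tag_count") results$count_A else rep(1, NROW(results))
  bins <- rbind(DIF_BINS,
                data.frame(label = "out_of_table", lower = NA, upper = NA))
  assign_bin <- rep("out_of_table", length(d))
  for (i in seq_len(nrow(DIF_BINS))) {
    in_bin <- !is.na(d) & is.finite(d) &
      d >= DIF_BINS$lower[i] & d <= DIF_BINS$upper[i]
    assign_bin[in_bin] <- DIF_BINS$label[i]
  }
  mass <- vapply(bins$label, function(lb) sum(w[assign_bin == lb]), 0)
  total <- sum(mass)
  if (total <= 0) stop("total weight is zero; cannot form percentages")
  bins$percent <- 100 * mass / total
  bins$significant <- bins$label != band_label
  attr(bins, "total_significant_percent") <-
    sum(bins$percent[bins$significant])
  attr(bins, "weighting") <- weighting
  class(bins) <- c("binned_report", "data.frame")
  bins
}

#' @export
print.binned_report <- function(x, ...) {
  cat("Dif binned report (", attr(x, "weighting"), ")\n", sep = "")
  print.data.frame(data.frame(range = x$label,
                              percent = sprintf("%.1f", x$percent)), ...)
  cat(sprintf("Total significant: %.1f%%\n",
              attr(x, "total_significant_percent")))
  invisible(x)
}

#' Differential representation test for two SAGE tag libraries
#'
#' Fits the two-library differential-expression analysis: for every tag
#' the Audic-Claverie two-sided p-value and the library-size corrected
#' Dif ratio, with significance calls from both. This is the central
#' fitting function of the package; the returned object has
#' \code{print}, \code{summary} and \code{plot} methods.
#'
#' @param table a \code{\link{tag_count_table}}.
#' @param alpha significance level for the Audic-Claverie test (default
#'   0.05).
#' @param correction multiple-testing correction: \code{"none"} (default;
#'   shallow libraries rarely support correction) or
#'   \code{"benjamini_hochberg"}.
#' @param band non-significance band for the Dif statistic,
#'   default \code{c(0.6, 1.6)}.
#' @param dif_decimals rounding of the correction coefficient.
#' @return object of class \code{"sage_test"}: list with \code{results}
#'   (one row per tag: counts, Dif, bin, tail and two-sided p-values,
#'   significance flags, adjusted p), \code{totals}, \code{labels},
#'   \code{coefficient}, \code{alpha}, \code{correction}, \code{band},
#'   \code{call}.
#' @export
#' @examples
#' tab <- tag_count_table(c("CATGAAACCCGGGTTTAAACC", "CATGTTTGGGCCCAAATTTGG"),
#'                        c(30L, 5L), c(4L, 7L))
#' fit <- sage_test(tab)
#' summary(fit)
sage_test <- function(table, alpha = 0.05,
                      correction = c("none", "benjamini_hochberg"),
                      band = c(0.6, 1.6), dif_decimals = 2L) {
  stopifnot(inherits(table, "tag_count_table"), alpha > 0, alpha < 1)
  correction <- match.arg(correction)
  N_A <- attr(table, "total_A")
  N_B <- attr(table, "total_B")
  tails <- ac_two_sided(table$count_A, table$count_B, N_A, N_B)
  dif <- dif_statistic(table$count_A, table$count_B, N_A, N_B,
                       decimals = dif_decimals)
  res <- data.frame(tag = table$tag,
                    count_A = table$count_A, count_B = table$count_B,
                    dif = dif,
                    p_left = tails$p_left, p_right = tails$p_right,
                    p_two_sided = tails$p_two_sided,
                    stringsAsFactors = FALSE)
  res$significant_by_dif <- classify_dif(dif, band[1], band[2])
  if (correction == "benjamini_hochberg") {
    res$adjusted_p <- stats::p.adjust(res$p_two_sided, method = "BH")
    res$significant_by_test <- res$adjusted_p <= alpha
  } else {
    res$adjusted_p <- NA_real_
    res$significant_by_test <- res$p_two_sided <= alpha
  }
  d <- round(res$dif, 1)
  res$bin <- "out_of_table"
  for (i in seq_len(nrow(DIF_BINS))) {
    hit <- is.finite(d) & d >= DIF_BINS$lower[i] & d <= DIF_BINS$upper[i]
    res$bin[hit] <- DIF_BINS$label[i]
  }
  structure(list(results = res,
                 totals = c(A = N_A, B = N_B),
                 labels = attr(table, "labels"),
                 coefficient = correction_coefficient(N_A, N_B, dif_decimals),
                 alpha = alpha, correction = correction, band = band,
                 call = match.call()),
            class = "sage_test")
}

#' @export
print.sage_test <- function(x, ...) {
  cat("Two-library SAGE differential representation test\n")
  cat(sprintf("  libraries: %s (N = %d), %s (N = %d)\n",
              x$labels[1], x$totals["A"], x$labels[2], x$totals["B"]))
  cat(sprintf("  correction coefficient C = %.2f; Dif band [%.1f, %.1f]\n",
              x$coefficient, x$band[1], x$band[2]))
  cat(sprintf("  unique tags: %d\n", nrow(x$results)))
  cat(sprintf("  significant by test (alpha = %g, correction = %s): %d\n",
              x$alpha, x$correction, sum(x$results$significant_by_test)))
  cat(sprintf("  outside Dif band: %d\n", sum(x$results$significant_by_dif)))
  invisible(x)
}

#' @export
summary.sage_test <- function(object, weighting = "by_tag_count", ...) {
  rep <- binned_report(object$results, weighting = weighting)
  structure(list(fit = object, report = rep,
                 n_significant = sum(object$results$significant_by_test),
                 n_outside_band = sum(object$results$significant_by_dif)),
            class = "summary.sage_test")
}

#' @export
print.summary.sage_test <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @export
plot.sage_test <- function(x, ...) {
  r <- x$results
  m <- (r$count_A / x$totals["A"] + r$count_B / x$totals["B"]) / 2
  d <- r$dif
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  d[d == 0] <- min(d[d > 0]) / 2
  graphics::plot(m, d, log = "xy",
                 col = ifelse(r$significant_by_test, "firebrick", "grey40"),
                 pch = 16, cex = 0.6,
                 xlab = "mean relative abundance",
                 ylab = "Dif (library-size corrected ratio)", ...)
  graphics::abline(h = x$band, lty = 2)
  invisible(x)
}

#' Sensitivity of the significant-tag count to the threshold
#'
#' Reports how many tags the Audic-Claverie test calls significant over a
#' grid of alpha levels; useful when the threshold behind a published
#' significant-tag count is not stated.
#'
#' @param fit a \code{\link{sage_test}} object.
#' @param alphas numeric vector of significance levels.
#' @return data.frame with columns \code{alpha}, \code{n_significant}.
#' @export
threshold_sensitivity <- function(fit, alphas = c(0.001, 0.005, 0.01, 0.02,
                                                  0.05, 0.1)) {
  stopifnot(inherits(fit, "sage_test"))
  data.frame(alpha = alphas,
             n_significant = vapply(alphas, function(a) {
               sum(fit$results$p_two_sided <= a)
             }, 0L))
}
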