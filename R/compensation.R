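#' Standardize migration start dates within years
#'
#' Subtracts each year's median start date, removing annual climate
#' variation so timing classes compare like with like across years.
#'
#' @param start_dates numeric start days.
#' @param year year of each animal-year (recycled if scalar).
#' @return standardized start dates (days relative to the annual median).
#' @export
standardize_start <- function(start_dates, year = 1L) {
  if (length(year) == 1) year <- rep(year, length(start_dates))
  stopifnot(length(year) == length(start_dates))
  start_dates - stats::ave(start_dates, year, FUN = stats::median)
}

#' Classify migration timing into early / mid / late
#'
#' Pooled quartiles of the standardized start dates (type-7,
#' linear-interpolation quantiles): early = at or below the 25% quartile,
#' late = at or above the 75% quartile, mid otherwise. When ties make a
#' value satisfy both rules (e.g. all starts equal), early wins.
#'
#' @param standardized_start from [standardize_start()]; length >= 4.
#' @return factor with levels `early`, `mid`, `late`.
#' @export
classify_timing <- function(standardized_start) {
  stopifnot(length(standardized_start) >= 4)
  q <- stats::quantile(standardized_start, c(0.25, 0.75), type = 7,
                       names = FALSE)
  out <- ifelse(standardized_start <= q[1], "early",
                ifelse(standardized_start >= q[2], "late", "mid"))
  factor(out, levels = c("early", "mid", "late"))
}

#' Classify compensation from start and end mismatch
#'
#' Uses the signed Days-From-Peak mismatch at the start and end of spring
#' migration (package sign convention; only magnitudes matter here) and a
#' 7-day tolerance window. Classes, evaluated in precedence order:
#' \describe{
#'   \item{perfect}{started within `window` days of peak and stayed
#'     within `window` days at the end — a perfect surfer.}
#'   \item{full}{started more than `window` days from peak and ended
#'     strictly closer to peak than it started.}
#'   \item{partial}{started more than `window` days from peak and ended
#'     within `window` days of its starting mismatch magnitude.}
#'   \item{non}{drifted further from peak (or left the window having
#'     started inside it).}
#' }
#'
#' @param dfp_start,dfp_end signed mismatches, days (vectorized).
#' @param window tolerance, days (default 7).
#' @return factor with levels `non`, `perfect`, `partial`, `full`
#'   (increasing degree of behavioral adjustment).
#' @export
classify_compensation <- function(dfp_start, dfp_end, window = 7) {
  stopifnot(length(dfp_start) == length(dfp_end), window >= 0,
            all(is.finite(dfp_start)), all(is.finite(dfp_end)))
  s <- abs(dfp_start)
  e <- abs(dfp_end)
  out <- ifelse(s <= window & e <= window, "perfect",
         ifelse(s > window & e < s, "full",
         ifelse(s > window & abs(e - s) <= window, "partial", "non")))
  factor(out, levels = c("non", "perfect", "partial", "full"))
}

#' Per-class summaries and utility tests for a compensation cohort
#'
#' Per timing class: mean start/end mismatch, movement rate and stopover
#' days with normal-theory 95% CIs (omitted for classes under 2
#' animal-years); paired t and Wilcoxon signed-rank tests comparing
#' absolute mismatch at start vs end (overall and per class); one-way
#' ANOVAs of movement rate and stopover days across timing classes; and
#' two-sided z-tests of the start and end mismatches against zero.
#'
#' @param records data frame with columns `timing_class`, `dfp_start`,
#'   `dfp_end`, and optionally `rate`, `stopover_days`.
#' @return list with `class_means`, `paired_tests`, `anova`, `z_tests`.
#' @export
cohort_summary <- function(records) {
  need <- c("timing_class", "dfp_start", "dfp_end")
  stopifnot(all(need %in% names(records)))
  cls <- factor(records$timing_class, levels = c("early", "mid", "late"))

  ci <- function(v) {
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 2) return(c(mean = mean(v), lo = NA_real_, hi = NA_real_, n = n))
    half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
    c(mean = mean(v), lo = mean(v) - half, hi = mean(v) + half, n = n)
  }
  vars <- intersect(c("dfp_start", "dfp_end", "rate", "stopover_days"),
                    names(records))
  class_means <- do.call(rbind, lapply(levels(cls), function(k) {
    sub <- records[cls == k, , drop = FALSE]
    row <- data.frame(timing_class = k, n = nrow(sub))
    for (v in vars) {
      s <- ci(sub[[v]])
      row[[paste0(v, "_mean")]] <- s[["mean"]]
      row[[paste0(v, "_lo")]] <- s[["lo"]]
      row[[paste0(v, "_hi")]] <- s[["hi"]]
    }
    row
  }))

  paired <- function(sub, label) {
    d <- abs(sub$dfp_start) - abs(sub$dfp_end)
    if (length(d) < 2 || stats::sd(d) == 0) {
      tt <- list(statistic = 0, p.value = 1)
      wt <- list(statistic = NA_real_, p.value = 1)
    } else {
      t0 <- stats::t.test(abs(sub$dfp_start), abs(sub$dfp_end),
                          paired = TRUE)
      w0 <- suppressWarnings(
        stats::wilcox.test(abs(sub$dfp_start), abs(sub$dfp_end),
                           paired = TRUE))
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
      wt <- list(statistic = unname(w0$statistic), p.value = w0$p.value)
    }
    data.frame(group = label, n = nrow(sub),
               t = tt$statistic, t_p = tt$p.value,
               wilcoxon_V = wt$statistic, wilcoxon_p = wt$p.value)
  }
  paired_tests <- rbind(
    paired(records, "all"),
    do.call(rbind, lapply(levels(cls), function(k)
      paired(records[cls == k, , drop = FALSE], k))))

  anova_one <- function(v) {
    if (!v %in% names(records)) return(NULL)
    ok <- is.finite(records[[v]])
    fit <- stats::aov(records[[v]][ok] ~ cls[ok])
    s <- summary(fit)[[1]]
    data.frame(response = v, F = s$`F value`[1], df1 = s$Df[1],
               df2 = s$Df[2], p = s$`Pr(>F)`[1])
  }
  anova <- do.call(rbind, lapply(c("rate", "stopover_days"), anova_one))

  ztest <- function(v, label) {
    v <- v[is.finite(v)]
    z <- mean(v) / (stats::sd(v) / sqrt(length(v)))
    data.frame(quantity = label, z = z,
               p = 2 * stats::pnorm(-abs(z)), n = length(v))
  }
  z_tests <- rbind(ztest(records$dfp_start, "start_mismatch"),
                   ztest(records$dfp_end, "end_mismatch"))

  list(class_means = class_means, paired_tests = paired_tests,
       anova = anova, z_tests = z_tests)
}
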