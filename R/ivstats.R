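#' Steady-state current of a voltage-clamp trace
#'
#' Mean clamp current over the final `window_ms` of the voltage step
#' (default 50 ms, mirroring the current-clamp steady-state convention).
#'
#' @param trace a current [new_trace()] from a voltage-step protocol.
#' @param window_ms averaging window (ms), must not exceed the step
#'   duration.
#' @return steady-state current (pA).
#' @export
steady_state_current <- function(trace, window_ms = 50) {
  stopifnot(inherits(trace, "trace"))
  p <- trace$protocol
  if (is.null(p) || p$mode != "voltage_step")
    stop("steady_state_current needs a voltage_step trace")
  if (window_ms > p$stim_ms)
    stop("window (", window_ms, " ms) exceeds the step duration (",
         p$stim_ms, " ms)")
  # the step occupies [pre, pre + stim); the sample at the offset time
  # already sits at the post-step potential, so the window ends one sample
  # before it
  off <- p$pre_ms + p$stim_ms
  idx <- window_idx(trace, off - window_ms, off - trace$dt)
  mean(trace$samples[idx[1]:idx[2]])
}

#' Current-voltage relation of one cell
#'
#' @param traces list of current traces from the subthreshold voltage-step
#'   protocol (one per command voltage).
#' @param window_ms steady-state window (ms).
#' @param cell_id,condition metadata carried into the result.
#' @return an `iv_curve`: data.frame with columns `v` (mV, increasing),
#'   `i` (pA), `cell_id`, `condition`.
#' @export
iv_curve <- function(traces, window_ms = 50, cell_id = NA_character_,
                     condition = NA_character_) {
  v <- vapply(traces, `[[`, numeric(1), "amplitude")
  i <- vapply(traces, steady_state_current, numeric(1), window_ms = window_ms)
  ord <- order(v)
  structure(data.frame(v = v[ord], i = i[ord], cell_id = cell_id,
                       condition = condition, stringsAsFactors = FALSE),
            class = c("iv_curve", "data.frame"))
}

#' Reversal potential of a subthreshold I-V curve
#'
#' Linear interpolation of the zero-current crossing between the bracketing
#' points; a point lying exactly at zero returns its voltage.
#'
#' @param curve an [iv_curve()] (or data.frame with `v`, `i`).
#' @return reversal potential (mV); `NA` when the curve has no sign change.
#' @export
reversal_potential <- function(curve) {
  v <- curve$v
  i <- curve$i
  stopifnot(!is.unsorted(v, strictly = TRUE))
  z <- which(i == 0)
  if (length(z)) return(v[z[1]])
  s <- which(diff(sign(i)) != 0)
  if (!length(s)) return(NA_real_)
  k <- s[1]
  v[k] - i[k] * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' OLS slope of an I-V segment
#'
#' Ordinary-least-squares slope of current on voltage within one of the two
#' analysis segments (in pA/mV, numerically equal to nS).
#'
#' @param curve an [iv_curve()].
#' @param segment numeric `c(lo, hi)` voltage interval (mV), inclusive;
#'   canonical segments are `c(-77, -62)` and `c(-62, -47)`.
#' @return slope (nS).
#' @export
segment_slope <- function(curve, segment = c(-77, -62)) {
  sel <- curve$v >= segment[1] & curve$v <= segment[2]
  if (sum(sel) < 2) stop("need >= 2 points in the segment")
  unname(coef(lm(i ~ v, data = curve[sel, ]))[2])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement), delegated to [stats::p.adjust()] after validating the
#' inputs.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-bin mixed-effects comparison of I-V data across conditions
#'
#' Groups steady-state currents into 5 mV voltage bins (the canonical
#' 7-step protocol gives 6 bins, -77/-72 through -52/-47, with shared
#' endpoints) and fits, per bin and per non-reference condition, a linear
#' mixed-effects model `i ~ condition + (1 | cell_id)` (cell as random
#' intercept, delegated to `lme4`). Reports the Wald z-score of the
#' condition effect, the two-sided normal p-value, and Benjamini-Hochberg
#' adjusted p-values across all bins and comparisons.
#'
#' @param iv_data data.frame with columns `v`, `i`, `cell_id`, `condition`
#'   (rows from several [iv_curve()]s; >= 2 conditions, >= 2 cells each).
#' @param reference reference condition label (default: first level).
#' @param bin_width bin width (mV), default 5.
#' @return data.frame with one row per (bin, condition): `bin`, `v_lo`,
#'   `v_hi`, `condition`, `estimate`, `se`, `z`, `p`, `p_fdr`, plus
#'   attribute `"skipped"` listing degenerate bins.
#' @export
bin_and_compare <- function(iv_data, reference = NULL, bin_width = 5) {
  stopifnot(all(c("v", "i", "cell_id", "condition") %in% names(iv_data)))
  conds <- unique(iv_data$condition)
  if (length(conds) < 2) stop("need >= 2 conditions")
  if (is.null(reference)) reference <- conds[1]
  iv_data$condition <- stats::relevel(factor(iv_data$condition),
                                      ref = reference)

  # bins anchored at the lowest command voltage: the canonical -77..-47
  # protocol gives bins [-77,-72], ..., [-52,-47] with shared endpoints
  edges <- seq(min(iv_data$v), max(iv_data$v), by = bin_width)
  if (length(edges) < 2) stop("voltage range narrower than one bin")

  rows <- list()
  skipped <- character(0)
  for (b in seq_len(length(edges) - 1)) {
    sel <- iv_data$v >= edges[b] & iv_data$v <= edges[b + 1]
    dat <- iv_data[sel, ]
    enough <- length(unique(dat$condition)) >= 2 &&
      all(table(unique(dat[c("cell_id", "condition")])$condition) >= 2)
    if (!enough) {
      skipped <- c(skipped, sprintf("bin %d [%g, %g]", b, edges[b], edges[b + 1]))
      next
    }
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(i ~ condition + (1 | cell_id), data = dat,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, sprintf("bin %d [%g, %g]", b, edges[b], edges[b + 1]))
      next
    }
    cf <- summary(fit)$coefficients
    eff <- grep("^condition", rownames(cf), value = TRUE)
    for (e in eff) {
      z <- cf[e, "t value"]
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, v_lo = edges[b], v_hi = edges[b + 1],
        condition = sub("^condition", "", e),
        estimate = cf[e, "Estimate"], se = cf[e, "Std. Error"],
        z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_fdr <- bh_adjust(out$p)
  attr(out, "skipped") <- skipped
  attr(out, "thresholds") <- c(`-log10(0.05)` = 1.3, `-log10(0.01)` = 2)
  out
}

#' Digital trace subtraction
#'
#' Samplewise `a - b`; used e.g. to isolate the toxin-sensitive current by
#' subtracting the sevoflurane trace from the sevoflurane + TsTX trace.
#'
#' @param a,b [new_trace()]s of equal kind, dt and length.
#' @return a [new_trace()] whose metadata records both parents.
#' @export
subtract_traces <- function(a, b) {
  if (a$kind != b$kind) stop("trace kind mismatch")
  if (!isTRUE(all.equal(a$dt, b$dt))) stop("trace dt mismatch")
  if (length(a$samples) != length(b$samples)) stop("trace length mismatch")
  out <- new_trace(a$kind, a$samples - b$samples, a$dt, a$protocol,
                   a$amplitude)
  out$meta$parents <- c(a = a$meta$cell_id, b = b$meta$cell_id)
  out$meta$operation <- "a - b"
  out
}

#' Minimum per-group sample size for one-way ANOVA
#'
#' Smallest integer `n` per group such that the noncentral-F power of the
#' one-way ANOVA F test reaches `target_power`, with noncentrality
#' `lambda = f^2 * k * n` and degrees of freedom `(k - 1, k(n - 1))`.
#'
#' @param k number of groups, >= 2.
#' @param cohen_f standardized effect size f, > 0.
#' @param alpha significance level.
#' @param target_power required power.
#' @param n_max search limit (an error past it signals unattainable power).
#' @return list with `n` (per group), `N` (total), and `power` achieved.
#' @export
anova_min_sample_size <- function(k, cohen_f, alpha = 0.05,
                                  target_power = 0.80, n_max = 10000) {
  stopifnot(k >= 2, cohen_f > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  for (n in 2:n_max) {
    pw <- anova_power(k, n, cohen_f, alpha)
    if (pw >= target_power)
      return(list(n = n, N = k * n, power = pw))
  }
  stop("target power not attainable within n <= ", n_max)
}

#' Power of the one-way ANOVA F test
#' @inheritParams anova_min_sample_size
#' @param n per-group sample size, >= 2.
#' @return power in (0, 1).
#' @export
anova_power <- function(k, n, cohen_f, alpha = 0.05) {
  df1 <- k - 1
  df2 <- k * (n - 1)
  lambda <- cohen_f^2 * k * n
  1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

#' Normalize fitted conductances to the control-group median and compare
#'
#' Divides every fitted parameter value by the median of the reference
#' condition (per parameter) and runs unpaired Mann-Whitney U tests of each
#' treatment condition against the reference.
#'
#' @param fits data.frame with columns `condition`, `parameter`, `value`
#'   (one row per cell x parameter).
#' @param reference reference condition label.
#' @param alternative passed to [stats::wilcox.test()] (default
#'   `"two.sided"`).
#' @return list with `normalized` (the input with a `norm_value` column)
#'   and `tests` (data.frame: parameter, condition, W, p).
#' @export
compare_conductances <- function(fits, reference = "aCSF",
                                 alternative = "two.sided") {
  stopifnot(all(c("condition", "parameter", "value") %in% names(fits)))
  if (!reference %in% fits$condition) stop("reference condition absent")
  fits$norm_value <- NA_real_
  rows <- list()
  for (par in unique(fits$parameter)) {
    sel <- fits$parameter == par
    ref_med <- median(fits$value[sel & fits$condition == reference])
    fits$norm_value[sel] <- fits$value[sel] / ref_med
    for (cond in setdiff(unique(fits$condition[sel]), reference)) {
      x <- fits$norm_value[sel & fits$condition == cond]
      y <- fits$norm_value[sel & fits$condition == reference]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                         exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(parameter = par,
                                             condition = cond,
                                             W = unname(wt$statistic),
                                             p = wt$p.value,
                                             stringsAsFactors = FALSE)
    }
  }
  list(normalized = fits, tests = do.call(rbind, rows))
}
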