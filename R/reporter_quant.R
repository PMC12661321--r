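#' Frameshifting efficiency from dual-luciferase replicates
#'
#' Efficiency is the ratio of firefly/Renilla luciferase ratios between test
#' constructs and their in-frame controls, expressed as a percentage. With
#' `method = "mean_of_ratios"` (default) the per-replicate F/R ratios are
#' averaged within each class first; `"ratio_of_means"` instead ratios the
#' summed firefly over summed Renilla signal per class. The standard
#' deviation is propagated to first order from the two class-level
#' coefficients of variation; `sd_method = "bootstrap"` resamples replicates
#' instead.
#'
#' @param tests,controls data.frames with numeric columns `firefly` and
#'   `renilla` (one row per replicate well); controls are the in-frame
#'   constructs defining 100%.
#' @param method replicate combination rule.
#' @param sd_method `"propagation"` (first-order, default) or
#'   `"bootstrap"`.
#' @param n_boot bootstrap resamples when `sd_method = "bootstrap"`.
#' @return object of class `reporter_result`: list with efficiency_pct,
#'   sd_pct (NA when either class has < 2 replicates), n_test, n_control,
#'   method.
#' @export
fs_from_luciferase <- function(tests, controls,
                               method = c("mean_of_ratios", "ratio_of_means"),
                               sd_method = c("propagation", "bootstrap"),
                               n_boot = 2000L) {
  method <- match.arg(method)
  sd_method <- match.arg(sd_method)
  check <- function(df, what) {
    stopifnot(all(c("firefly", "renilla") %in% names(df)))
    if (nrow(df) < 1L) stop("need at least one ", what, " replicate")
    if (any(df$firefly < 0)) stop("negative firefly reading in ", what)
    bad <- which(df$renilla <= 0)
    if (length(bad)) {
      stop("zero/negative renilla reading in ", what, " replicate ", bad[1])
    }
  }
  check(tests, "test"); check(controls, "control")
  class_stat <- function(df) {
    if (method == "mean_of_ratios") {
      r <- df$firefly / df$renilla
      list(center = mean(r), sd = stats::sd(r), n = nrow(df))
    } else {
      r <- df$firefly / df$renilla
      list(center = sum(df$firefly) / sum(df$renilla), sd = stats::sd(r),
           n = nrow(df))
    }
  }
  st <- class_stat(tests); sc <- class_stat(controls)
  eff <- 100 * st$center / sc$center
  sd_pct <- NA_real_
  if (st$n >= 2L && sc$n >= 2L) {
    if (sd_method == "propagation") {
      cv_t <- if (st$center > 0) st$sd / st$center else 0
      cv_c <- sc$sd / sc$center
      sd_pct <- eff * sqrt(cv_t^2 + cv_c^2)
    } else {
      reps <- vapply(seq_len(n_boot), function(i) {
        ti <- tests[sample.int(nrow(tests), replace = TRUE), , drop = FALSE]
        ci <- controls[sample.int(nrow(controls), replace = TRUE), , drop = FALSE]
        100 * class_stat(ti)$center / class_stat(ci)$center
      }, numeric(1))
      sd_pct <- stats::sd(reps)
    }
  }
  structure(list(efficiency_pct = eff, sd_pct = sd_pct,
                 n_test = st$n, n_control = sc$n, method = method),
            class = "reporter_result")
}

#' @export
print.reporter_result <- function(x, ...) {
  cat(sprintf("Reporter frameshifting efficiency: %.2f%%", x$efficiency_pct),
      if (!is.na(x$sd_pct)) sprintf(" ± %.2f", x$sd_pct),
      sprintf("  (n_test=%d, n_control=%d, %s)\n", x$n_test, x$n_control,
              x$method), sep = "")
  invisible(x)
}

#' Fold change of frameshifting efficiency between contexts
#'
#' Ratio of a context construct's efficiency over the bare-heptamer
#' efficiency, e.g. the 1.5-fold stimulation seen when the ABP140 flanking
#' context raises Ty1-heptamer frameshifting from ~40% to ~60%.
#'
#' @param context_result,heptamer_result `reporter_result` objects (or bare
#'   efficiency percentages).
#' @return fold change (numeric); NA with a warning when the denominator is
#'   zero.
#' @export
context_fold_change <- function(context_result, heptamer_result) {
  val <- function(x) if (inherits(x, "reporter_result")) x$efficiency_pct else as.numeric(x)
  num <- val(context_result); den <- val(heptamer_result)
  if (is.na(num) || is.na(den)) stop("both efficiencies must be defined")
  if (den == 0) {
    warning("heptamer efficiency is zero: fold change undefined")
    return(NA_real_)
  }
  num / den
}
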