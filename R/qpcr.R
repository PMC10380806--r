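## Phenotype and qPCR validation arithmetic: percent change under
## treatment, Pearson correlation between grain traits, and 2^-ddCT
## relative expression.

#' Signed percent change of a treatment mean relative to control
#'
#' `100 * (treatment - control) / control`; reductions are negative
#' (a value of -9.92 is a 9.92% reduction).
#'
#' @param control_mean,treatment_mean trait means (control > 0).
#' @return signed percent change.
#' @export
percent_change <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0)) stop("control_mean must be > 0")
  100 * (treatment_mean - control_mean) / control_mean
}

#' Pearson correlation with a two-sided t test
#'
#' Computes the correlation `cov(x, y) / (sd(x) * sd(y))`, denoted r
#' below; the two-sided p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (the `cor.test` convention).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return list with `r`, `n`, `statistic`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, n = n, statistic = tstat, p_value = p)
}

#' Relative expression by the comparative threshold cycle method
#'
#' CT replicates are averaged per cell;
#' `dCT = mean(CT_target) - mean(CT_reference)` per condition,
#' `ddCT = dCT_treatment - dCT_control`, and the treatment fold change
#' is `2^-ddCT`. Control expression is 1.0 by construction.
#'
#' @param ct_target_control,ct_target_treatment CT replicates of the
#'   target gene.
#' @param ct_ref_control,ct_ref_treatment CT replicates of the
#'   reference gene (e.g. U6 for MIRNAs, actin-2 for target mRNAs).
#' @return list of class `QpcrRecord`: `dct_control`,
#'   `dct_treatment`, `ddct`, `fold_change`, `control_fold_change`
#'   (always 1).
#' @export
ddct_fold_change <- function(ct_target_control, ct_target_treatment,
                             ct_ref_control, ct_ref_treatment) {
  for (v in list(ct_target_control, ct_target_treatment,
                 ct_ref_control, ct_ref_treatment))
    if (!length(v) || anyNA(v)) stop("missing CT values")
  dct_c <- mean(ct_target_control) - mean(ct_ref_control)
  dct_t <- mean(ct_target_treatment) - mean(ct_ref_treatment)
  ddct <- dct_t - dct_c
  structure(list(dct_control = dct_c, dct_treatment = dct_t,
                 ddct = ddct, fold_change = 2^(-ddct),
                 control_fold_change = 1.0),
            class = "QpcrRecord")
}

#' @export
print.QpcrRecord <- function(x, ...) {
  cat(sprintf("ddCT = %.3f -> fold change %.3f (control = 1.0)\n",
              x$ddct, x$fold_change))
  invisible(x)
}
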