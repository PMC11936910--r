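#' Bland-Altman analysis of paired measurements
#'
#' Summarises the differences `x - y` between two methods measuring the same
#' quantity: mean bias, SD of the differences, and the limits of agreement
#' `bias +/- 1.96 SD`, together with the percentage of differences falling
#' inside the limits.
#'
#' @param x,y Paired measurements (e.g. two-point and model-based AUC).
#' @return A list of class `bland_altman`: `mean_bias`, `sd_diff`, `lower`,
#'   `upper`, `pct_within`, `n`.
#' @examples
#' bland_altman(c(52, 61, 70), c(50, 60, 75))
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  structure(list(mean_bias = m, sd_diff = s, lower = lo, upper = hi,
                 pct_within = 100 * mean(d >= lo & d <= hi), n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, SD %.2f, limits [%.2f, %.2f], %.1f%% within\n",
              x$n, x$mean_bias, x$sd_diff, x$lower, x$upper, x$pct_within))
  invisible(x)
}

# inside/outside therapeutic-window dichotomy (both boundaries inclusive);
# below- and above-window exposures are pooled as "outside"
window_class <- function(auc, window = c(50, 100)) {
  factor(ifelse(auc >= window[1] & auc <= window[2], "inside", "outside"),
         levels = c("inside", "outside"))
}

#' Cohen's kappa for therapeutic-window classification agreement
#'
#' Classifies each subject's AUC as inside or outside the therapeutic window
#' under both estimation methods and computes Cohen's
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. When both methods give the same
#' constant classification the chance agreement \eqn{p_e} is 1 and kappa is
#' undefined; it is then reported as 1 with `degenerate = TRUE`.
#'
#' @param x,y Paired AUC values (mg.h/L) from the two methods.
#' @param window Therapeutic window.
#' @return A list of class `window_kappa`: `kappa`, the 2x2 `table`
#'   (rows = `x`, columns = `y`), `p_o`, `p_e`, `degenerate`.
#' @examples
#' window_kappa(c(60, 70, 120, 40), c(55, 110, 130, 45))
#' @export
window_kappa <- function(x, y, window = c(50, 100)) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  tab <- table(x = window_class(x, window), y = window_class(y, window))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  degenerate <- abs(1 - p_e) < .Machine$double.eps^0.5
  kappa <- if (degenerate) {
    if (p_o == 1) 1 else NA_real_
  } else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, table = tab, p_o = p_o, p_e = p_e,
                 degenerate = degenerate),
            class = "window_kappa")
}

#' @export
print.window_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa on window classification: %.3f%s\n", x$kappa,
              if (x$degenerate) " (degenerate: both methods constant)" else ""))
  print(x$table)
  invisible(x)
}

#' McNemar's test for paired window classification
#'
#' Tests whether the two AUC methods disagree symmetrically about the
#' therapeutic window. With `b` and `c` the discordant counts, the
#' continuity-corrected statistic \eqn{(|b-c|-1)^2/(b+c)} is referred to
#' chi-square(1) when `b + c >= exact_threshold`; otherwise the exact
#' two-sided binomial form `Binom(b, b + c, 1/2)` is used. No discordant
#' pairs gives `p = 1` with a flag.
#'
#' @inheritParams window_kappa
#' @param exact_threshold Use the exact binomial form below this many
#'   discordant pairs (default 25).
#' @param correct Apply the continuity correction in the asymptotic form.
#' @return A list of class `mcnemar_window`: `statistic` (NA for the exact
#'   form), `p.value`, `method`, discordant counts `b` and `c`.
#' @examples
#' mcnemar_window(c(60, 70, 120, 40), c(55, 110, 130, 45))
#' @export
mcnemar_window <- function(x, y, window = c(50, 100), exact_threshold = 25,
                           correct = TRUE) {
  tab <- table(x = window_class(x, window), y = window_class(y, window))
  b <- tab[1, 2]; cc <- tab[2, 1]
  if (b + cc == 0) {
    return(structure(list(statistic = NA_real_, p.value = 1,
                          method = "no discordant pairs", b = b, c = cc),
                     class = "mcnemar_window"))
  }
  if (b + cc < exact_threshold) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    out <- list(statistic = NA_real_, p.value = p, method = "exact binomial",
                b = b, c = cc)
  } else {
    mt <- stats::mcnemar.test(tab, correct = correct)
    out <- list(statistic = unname(mt$statistic), p.value = mt$p.value,
                method = if (correct) "chi-square, continuity-corrected"
                         else "chi-square", b = b, c = cc)
  }
  structure(out, class = "mcnemar_window")
}

#' @export
print.mcnemar_window <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, p = %.3g\n",
              x$method, x$b, x$c, x$p.value))
  invisible(x)
}

#' Agreement analysis between two AUC estimation methods
#'
#' Combines the continuous and categorical agreement analyses for a table of
#' paired AUC estimates: Bland-Altman statistics on the differences
#' (two-point minus model-based), and Cohen's kappa plus McNemar's test on
#' the inside/outside therapeutic-window classification.
#'
#' @param pairs A data.frame with columns `auc_two_point` and `auc_model`
#'   (e.g. from [auc_two_point_table()]); rows with a missing estimate are
#'   dropped with their count recorded.
#' @param window Therapeutic window (mg.h/L).
#' @return A list of class `auc_agreement` with elements `bland_altman`,
#'   `kappa`, `mcnemar`, `n_pairs`, `n_dropped`.
#' @examples
#' pairs <- data.frame(auc_two_point = c(62, 88, 120, 45),
#'                     auc_model = c(58, 95, 104, 52))
#' auc_agreement(pairs)
#' @export
auc_agreement <- function(pairs, window = c(50, 100)) {
  stopifnot(is.data.frame(pairs),
            all(c("auc_two_point", "auc_model") %in% names(pairs)))
  ok <- is.finite(pairs$auc_two_point) & is.finite(pairs$auc_model)
  x <- pairs$auc_two_point[ok]; y <- pairs$auc_model[ok]
  structure(list(bland_altman = bland_altman(x, y),
                 kappa = window_kappa(x, y, window),
                 mcnemar = mcnemar_window(x, y, window),
                 window = window, n_pairs = sum(ok), n_dropped = sum(!ok)),
            class = "auc_agreement")
}

#' @export
print.auc_agreement <- function(x, ...) {
  cat(sprintf("AUC agreement, two-point vs model-based (%d pairs, %d dropped)\n",
              x$n_pairs, x$n_dropped))
  print(x$bland_altman)
  print(x$kappa)
  print(x$mcnemar)
  invisible(x)
}
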