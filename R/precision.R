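#' Estimate von Mises memory precision from baseline offsets
#'
#' Maximum-likelihood concentration of a mean-zero von Mises fitted to
#' high-confidence baseline response offsets. Restricting to
#' high-confidence reports removes guesses, so no guess component is
#' fitted here (the full mixture lives in [fit_standard_wm()]). The MLE
#' solves `A1(kappa) = mean(cos(offset))` where `A1 = I1/I0`; degenerate
#' samples (all offsets at zero, or resultant at the uniform limit) are
#' capped and flagged via the `"capped"`/`"unidentifiable"` attributes.
#'
#' @param offsets signed offsets in degrees (>= 20 required).
#' @param max_kappa cap for the estimate on degenerate data.
#' @return estimated concentration (numeric scalar) with possible
#'   flag attributes.
#' @export
estimate_precision <- function(offsets, max_kappa = 1e4) {
  if (length(offsets) < 20) {
    stop("insufficient-data: need >= 20 offsets", call. = FALSE)
  }
  C <- mean(cos(offsets * pi / 180))
  if (C <= 1e-8) {
    stop("unidentifiable-kappa: resultant length is zero or negative",
         call. = FALSE)
  }
  if (vm_A1(max_kappa) <= C) {
    out <- max_kappa
    attr(out, "capped") <- TRUE
    warning("kappa estimate capped at ", max_kappa, call. = FALSE)
    return(out)
  }
  stats::uniroot(function(k) vm_A1(k) - C, lower = 1e-8, upper = max_kappa,
                 tol = 1e-10)$root
}

#' Correlation between memory precision and similarity-induced bias
#'
#' Pearson correlation across participants between estimated memory
#' precision (baseline kappa) and mean signed bias, with bivariate
#' outlier exclusion (beyond `outlier_sd` SDs from the mean on either
#' variable). Results are always reported both with and without the
#' excluded participants.
#'
#' @param precision named or plain numeric vector of per-participant
#'   kappa estimates.
#' @param bias numeric vector of per-participant mean signed biases,
#'   aligned with `precision`.
#' @param ids optional participant identifiers.
#' @param outlier_sd exclusion threshold in SD units (default 3).
#' @return object of class `precision_bias_cor`: list with `included`
#'   and `all` (each `r`, `df`, `p`, `n`) and `excluded_ids`.
#' @export
precision_bias_correlation <- function(precision, bias, ids = seq_along(precision),
                                       outlier_sd = 3) {
  stopifnot(length(precision) == length(bias))
  z <- function(x) (x - mean(x)) / stats::sd(x)
  out_mask <- abs(z(precision)) > outlier_sd | abs(z(bias)) > outlier_sd
  run <- function(p, b) {
    if (length(p) < 4) stop("insufficient-data: need >= 4 pairs", call. = FALSE)
    ct <- stats::cor.test(p, b, method = "pearson")
    list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
         n = length(p))
  }
  res <- list(
    included = run(precision[!out_mask], bias[!out_mask]),
    all = run(precision, bias),
    excluded_ids = ids[out_mask]
  )
  class(res) <- "precision_bias_cor"
  res
}

#' @export
print.precision_bias_cor <- function(x, ...) {
  cat(sprintf("Precision-bias correlation: r(%d) = %.3f, p = %.4g",
              x$included$df, x$included$r, x$included$p))
  if (length(x$excluded_ids)) {
    cat(sprintf("  [%d outlier(s) excluded; with outliers r(%d) = %.3f]",
                length(x$excluded_ids), x$all$df, x$all$r))
  }
  cat("\n")
  invisible(x)
}
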