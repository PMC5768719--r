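#' @export
print.gsmr <- function(x, digits = 4, ...) {
  cat("GSMR (", x$direction, "): ",
      x$exposure %||% "exposure", " -> ", x$outcome %||% "outcome", "\n", sep = "")
  cat("  bxy = ", signif(x$bxy, digits), " (se ", signif(x$se, digits),
      "), chi2(1) = ", signif(x$chi2, digits),
      ", p = ", format(x$pval, digits = digits, scientific = TRUE), "\n", sep = "")
  cat("  instruments: ", x$n_instruments_used, " used of ",
      x$n_instruments_input, " input", sep = "")
  if (length(x$flagged_pleiotropic) > 0L)
    cat(" (", length(x$flagged_pleiotropic), " removed as pleiotropic)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.gsmr <- function(object, level = 0.95, ...) {
  structure(list(fit = object, ci = confint(object, level = level),
                 level = level),
            class = "summary.gsmr")
}

#' @export
print.summary.gsmr <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("  ", round(100 * x$level), "% CI: [", signif(x$ci[1], digits), ", ",
      signif(x$ci[2], digits), "]\n", sep = "")
  if (!is.null(f$outcome_type) && identical(f$outcome_type, "binary"))
    cat("  OR per SD of exposure: ", signif(exp(f$bxy), digits), "\n", sep = "")
  if (!is.null(f$heidi))
    cat("  HEIDI target: ", attr(f$heidi, "target"), "; ",
        length(attr(f$heidi, "removed") %||% character()),
        " SNP(s) removed at p < ", attr(f$heidi, "threshold"), "\n", sep = "")
  invisible(x)
}

#' @export
coef.gsmr <- function(object, ...) {
  stats::setNames(object$bxy, "bxy")
}

#' @export
vcov.gsmr <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("bxy", "bxy"))
}

#' @export
confint.gsmr <- function(object, parm = "bxy", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(object$bxy - z * object$se, object$bxy + z * object$se)
}

#' Per-instrument deviations from the fitted causal model
#'
#' @param object a \code{gsmr} fit.
#' @param ... unused.
#' @return Named vector \code{bxy(i) - bxy_hat}, one per retained
#'   instrument.
#' @export
residuals.gsmr <- function(object, ...) {
  stats::setNames(object$per_snp$bxy - object$bxy, object$per_snp$SNP)
}

#' Effect-size scatter plot of a GSMR fit
#'
#' SNP-outcome effects against SNP-exposure effects with +/- 1 SE error
#' bars and the fitted line through the origin with slope \code{bxy}.
#'
#' @param x a \code{gsmr} fit.
#' @param ... passed to [plot()].
#' @export
plot.gsmr <- function(x, ...) {
  inst <- x$instruments
  plot(inst$bzx, inst$bzy,
       xlab = "SNP effect on exposure (bzx)",
       ylab = "SNP effect on outcome (bzy)",
       pch = 19, ...)
  graphics::arrows(inst$bzx, inst$bzy - inst$se_bzy, inst$bzx,
                   inst$bzy + inst$se_bzy, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  graphics::arrows(inst$bzx - inst$se_bzx, inst$bzy, inst$bzx + inst$se_bzx,
                   inst$bzy, angle = 90, code = 3, length = 0.02,
                   col = "grey60")
  graphics::abline(a = 0, b = x$bxy, col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
print.gsmr_bidirectional <- function(x, ...) {
  cat("Bidirectional GSMR\n")
  for (dir in c("forward", "reverse")) {
    if (!is.null(x[[dir]])) print(x[[dir]], ...)
    else cat("  ", dir, ": skipped (", x$skipped[[dir]], ")\n", sep = "")
  }
  if (length(x$instrument_overlap) > 0L)
    cat("  instrument overlap:", length(x$instrument_overlap), "SNP(s)\n")
  invisible(x)
}

#' @export
print.heidi_report <- function(x, ...) {
  cat("HEIDI-outlier report: target ", attr(x, "target"),
      ", threshold ", attr(x, "threshold"), "\n", sep = "")
  cat("  ", sum(x$flagged), " of ", nrow(x), " instrument(s) flagged\n",
      sep = "")
  invisible(x)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("GWAS summary dataset '", attr(x, "trait_name"), "' (",
      attr(x, "trait_type"), "): ", nrow(x), " SNP(s)\n", sep = "")
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}
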