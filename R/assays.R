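#' Fit an electrolyte-leakage freezing-tolerance curve (LT50)
#'
#' Fits the four-parameter logistic
#' `L(T) = bottom + (top - bottom) / (1 + 10^(slope * (lt50 - T)))`
#' to leakage fractions measured at a series of freezing temperatures, by
#' least squares on temperature directly. LT50 is the inflection point:
#' the temperature of 50% relative electrolyte leakage, the standard
#' readout of freezing tolerance. Technical replicates are averaged per
#' temperature before fitting. Initialization uses a deterministic
#' multistart grid (8 starts: slope in {-1, -0.25, 0.25, 1} crossed with
#' LT50 at the lower/upper quartile of the temperature range); the start
#' with the lowest residual sum of squares wins, ties going to the first.
#'
#' @param temperature Temperatures in degrees C (any order).
#' @param leakage Leakage fractions in \[0, 1\], same length.
#' @param replicate Optional replicate labels; values sharing a
#'   temperature are averaged regardless.
#' @return An `lt50_fit` object with components `lt50`, `bottom`, `top`,
#'   `hill_slope`, `converged`, `sse`, `in_range` (whether LT50 lies
#'   within the measured range), `data`, and methods `print`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @export
fit_lt50 <- function(temperature, leakage, replicate = NULL) {
  if (length(temperature) != length(leakage)) {
    stop("temperature and leakage must have equal length", call. = FALSE)
  }
  if (any(leakage < 0 | leakage > 1)) {
    stop("leakage must be a fraction in [0, 1]", call. = FALSE)
  }
  mt <- tapply(leakage, temperature, mean)
  temps <- as.numeric(names(mt))
  leak <- as.numeric(mt)
  if (length(temps) < 4L) {
    stop("need >= 4 distinct temperatures to fit", call. = FALSE)
  }
  if (stats::sd(leak) == 0) {
    stop("leakage is constant; LT50 is not identifiable", call. = FALSE)
  }
  dat <- data.frame(temp = temps, leak = leak)
  rng <- range(temps)
  starts <- expand.grid(
    slope = c(-1, -0.25, 0.25, 1),
    lt50 = rng[1L] + c(0.25, 0.75) * diff(rng)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        leak ~ bottom + (top - bottom) / (1 + 10^(slope * (lt50 - temp))),
        data = dat,
        start = list(bottom = min(leak), top = max(leak),
                     slope = starts$slope[i], lt50 = starts$lt50[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    out <- structure(list(lt50 = NA_real_, bottom = NA_real_, top = NA_real_,
                          hill_slope = NA_real_, converged = FALSE,
                          sse = NA_real_, in_range = NA, data = dat),
                     class = "lt50_fit")
    return(out)
  }
  cf <- stats::coef(best$fit)
  bottom <- cf[["bottom"]]; top <- cf[["top"]]
  slope <- cf[["slope"]]; lt50 <- cf[["lt50"]]
  # the 4PL is invariant under (bottom, top, slope) -> (top, bottom, -slope);
  # canonicalize so bottom < top
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp; slope <- -slope
  }
  structure(list(lt50 = lt50, bottom = bottom, top = top,
                 hill_slope = slope, converged = TRUE, sse = best$sse,
                 in_range = lt50 >= rng[1L] && lt50 <= rng[2L], data = dat),
            class = "lt50_fit")
}

#' @export
print.lt50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("lt50_fit: did not converge from any start\n")
    return(invisible(x))
  }
  cat(sprintf("lt50_fit: LT50 = %.2f C (bottom %.3f, top %.3f, slope %.3f)\n",
              x$lt50, x$bottom, x$top, x$hill_slope))
  if (!x$in_range) cat("  note: LT50 outside the measured temperature range\n")
  invisible(x)
}

#' @method coef lt50_fit
#' @export
coef.lt50_fit <- function(object, ...) {
  c(lt50 = object$lt50, bottom = object$bottom, top = object$top,
    hill_slope = object$hill_slope)
}

#' @export
predict.lt50_fit <- function(object, newdata = NULL, ...) {
  temps <- if (is.null(newdata)) object$data$temp else {
    if (is.list(newdata)) newdata$temp else as.numeric(newdata)
  }
  with(object, bottom + (top - bottom) /
         (1 + 10^(hill_slope * (lt50 - temps))))
}

#' @method residuals lt50_fit
#' @export
residuals.lt50_fit <- function(object, ...) {
  object$data$leak - predict(object)
}

#' @method plot lt50_fit
#' @export
plot.lt50_fit <- function(x, ..., main = "Electrolyte leakage") {
  graphics::plot(x$data$temp, x$data$leak, xlab = "temperature (C)",
                 ylab = "leakage fraction", main = main, ...)
  if (x$converged) {
    tt <- seq(min(x$data$temp), max(x$data$temp), length.out = 200)
    graphics::lines(tt, predict(x, tt))
    graphics::abline(v = x$lt50, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Read electrolyte-leakage measurements
#' @param path CSV with columns `sample`, `temperature_c`,
#'   `leakage_fraction`, `replicate`.
#' @return Data frame, validated.
#' @export
read_el_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "temperature_c", "leakage_fraction")
  if (!all(req %in% names(df))) {
    stop("EL file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$leakage_fraction < 0 | df$leakage_fraction > 1)) {
    stop("leakage_fraction outside [0, 1]", call. = FALSE)
  }
  df
}

#' Read a qPCR Ct table
#' @param path CSV with columns `sample`, `gene`, `ct` and optionally
#'   `is_housekeeping`.
#' @return Data frame, validated (`ct > 0`).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "gene", "ct")
  if (!all(req %in% names(df))) {
    stop("Ct file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  df
}

#' Relative transcript abundance from qPCR Ct values
#'
#' Normalizes the target gene's Ct against the mean Ct of the
#' housekeeping genes and expresses abundance as `2^-dCt`, where
#' `dCt = Ct_target - mean(Ct_housekeeping)` per sample.
#'
#' @param ct Data frame with columns `sample`, `gene`, `ct` (multiple
#'   technical measurements of the same gene in a sample are averaged).
#' @param target_gene Gene of interest.
#' @param housekeeping Housekeeping gene set; all must be measured in
#'   every sample carrying the target.
#' @return Named numeric vector of relative abundances per sample.
#' @export
delta_ct_expression <- function(ct, target_gene,
                                housekeeping = c("ACTIN2", "PDF", "TIP41")) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  samples <- unique(ct$sample[ct$gene == target_gene])
  if (length(samples) == 0L) {
    stop("target gene ", target_gene, " not present in the Ct table",
         call. = FALSE)
  }
  out <- vapply(samples, function(s) {
    sub <- ct[ct$sample == s, , drop = FALSE]
    hk <- vapply(housekeeping, function(h) {
      v <- sub$ct[sub$gene == h]
      if (length(v) == 0L) {
        stop(sprintf("sample %s: missing housekeeping gene %s", s, h),
             call. = FALSE)
      }
      mean(v)
    }, numeric(1L))
    dct <- mean(sub$ct[sub$gene == target_gene]) - mean(hk)
    2^(-dct)
  }, numeric(1L))
  stats::setNames(out, samples)
}
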