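#' Non-compartmental metrics of a simulated profile
#'
#' Cmax is the maximum concentration on `[0, t_last]`, Tmax the first time it
#' is attained, and AUC0-t the linear-trapezoid area over the dense output
#' grid up to `t_last`.
#'
#' @param result A `lai_simulation` or a data frame with columns `time_h` and
#'   `cp_ng_per_mL` (or `time`/`cp`).
#' @param t_last End of the observation window (h); defaults to the last time
#'   point. Must not exceed the simulated horizon.
#' @return A list of class `pk_metrics` with `cmax` (ng/mL), `tmax` (h),
#'   `auc0t` (ng*h/mL) and `t_last` (h).
#' @export
pk_metrics <- function(result, t_last = NULL) {
  if (inherits(result, "lai_simulation")) {
    t <- result$time; c <- result$cp
  } else {
    df <- as.data.frame(result)
    t <- if ("time_h" %in% names(df)) df$time_h else df$time
    c <- if ("cp_ng_per_mL" %in% names(df)) df$cp_ng_per_mL else df$cp
  }
  if (length(t) == 0) stop("empty profile", call. = FALSE)
  if (is.null(t_last)) t_last <- max(t)
  if (t_last > max(t) + 1e-9) {
    stop("t_last exceeds the simulated horizon", call. = FALSE)
  }
  keep <- t <= t_last + 1e-12
  t <- t[keep]; c <- c[keep]
  i <- which.max(c)
  structure(
    list(cmax = c[i], tmax = t[i], auc0t = auc_trapezoid(t, c),
         t_last = t_last),
    class = "pk_metrics"
  )
}

#' Linear trapezoid AUC
#'
#' @param t Time grid (h), strictly increasing.
#' @param c Concentrations (ng/mL).
#' @return Area (ng*h/mL).
#' @export
auc_trapezoid <- function(t, c) {
  stopifnot(length(t) == length(c), !is.unsorted(t, strictly = TRUE))
  if (length(t) < 2) return(0)
  sum(diff(t) * (c[-length(c)] + c[-1]) / 2)
}

#' Fold error of a simulated metric
#'
#' `FE = simulated / observed`, the standard validation ratio.
#'
#' @param simulated,observed Metric values; `observed` must be positive.
#' @return Fold error (dimensionless), vectorized.
#' @export
fold_error <- function(simulated, observed) {
  if (any(observed <= 0)) stop("observed must be > 0", call. = FALSE)
  simulated / observed
}

#' Is a fold error within an acceptance band?
#'
#' A prediction passes when `|FE - 1| * 100 <= band`, i.e. the band is
#' symmetric and absolute around unity (FE 0.75 and 1.25 both sit on the edge
#' of a 25% band).
#'
#' @param fe Fold error(s), > 0.
#' @param band Half-width of the band in percent (default 25).
#' @return Logical, vectorized.
#' @export
within_band <- function(fe, band = 25) {
  stopifnot(all(fe > 0))
  abs(fe - 1) * 100 <= band
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("Cmax %.4g ng/mL | Tmax %.5g h | AUC0-%g %.6g ng*h/mL\n",
              x$cmax, x$tmax, x$t_last, x$auc0t))
  invisible(x)
}
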