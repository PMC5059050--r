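#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survivor function under right censoring: at
#' each distinct event time \eqn{t} with \eqn{d_t} events among \eqn{n_t} at
#' risk, the survival probability is multiplied by \eqn{1 - d_t/n_t};
#' censored observations leave the risk set just after their time. Greenwood
#' standard errors accompany each step:
#' \eqn{\widehat{Var}[S(t)] = S(t)^2 \sum_{s \le t} d_s / (n_s (n_s - d_s))}.
#'
#' @param time positive event/censoring times.
#' @param event logical (or 0/1): `TRUE` = event, `FALSE` = censored.
#' @return An object of class `km_curve`: list with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `surv`, `se`, and `n` (sample
#'   size).
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, TRUE, FALSE))
#' km$surv  # 4/5, 8/15, 4/15
km_estimate <- function(time, event) {
  if (length(time) == 0) abort("km_estimate needs at least one observation")
  event <- as.logical(event)
  if (length(event) != length(time)) abort("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be positive and finite")

  n <- length(time)
  ut <- sort(unique(time[event]))
  if (length(ut) == 0) {
    curve <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                  surv = numeric(0), se = numeric(0), n = n)
    return(structure(curve, class = "km_curve"))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  gw[!is.finite(gw)] <- NA  # S drops to 0: Greenwood variance undefined
  se <- surv * sqrt(gw)
  structure(
    list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv, se = se, n = n),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s)\n", x$n, length(x$time)))
  if (length(x$time) > 0) {
    print(utils::head(tibble(time = x$time, n_risk = x$n_risk,
                             n_event = x$n_event, surv = x$surv, se = x$se), 10))
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: \eqn{S(t)} is the product-limit
#' value at the last event time at or before `t`, and 1 before the first
#' event (in particular \eqn{S(0) = 1}).
#'
#' @param curve a [km_estimate()] result.
#' @param t_days numeric vector of times (days), each `>= 0`.
#' @return Numeric vector of survival proportions.
#' @export
km_survival_at <- function(curve, t_days) {
  if (any(t_days < 0)) abort("t_days must be >= 0")
  if (length(curve$time) == 0) return(rep(1, length(t_days)))
  idx <- findInterval(t_days, curve$time)
  out <- c(1, curve$surv)[idx + 1]
  out
}

#' Tidy a Kaplan-Meier curve into a long tibble
#'
#' @param curve a `km_curve`; `label` an optional stratum label column.
#' @param label optional stratum label.
#' @return Tibble with `time`, `n_risk`, `n_event`, `surv`, `se` (and
#'   `stratum` when labelled), including the `time = 0, surv = 1` anchor row.
#' @export
km_tidy <- function(curve, label = NULL) {
  out <- tibble(
    time = c(0, curve$time),
    n_risk = c(curve$n, curve$n_risk),
    n_event = c(0, curve$n_event),
    surv = c(1, curve$surv),
    se = c(0, curve$se)
  )
  if (!is.null(label)) out$stratum <- label
  out
}

#' Plot Kaplan-Meier persistence curves
#'
#' Step plot of one or more tidied curves (see [km_tidy()]).
#'
#' @param curves a tibble of stacked [km_tidy()] outputs with a `stratum`
#'   column.
#' @return A ggplot object.
#' @export
plot_km_curves <- function(curves) {
  if (!"stratum" %in% names(curves)) curves$stratum <- "all"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since first fill", y = "Proportion persistent",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
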