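# Perturbation search: how much would survival or recruitment have had
# to change over a window of years to avert an observed decline?

#' Incremental perturbation search over a decline window
#'
#' Starting from the fitted state in `window[1]`, multiplies either all
#' annual survival rates within the window or all recruitment cohorts
#' entering during the window by `1 + k * increment` (linear
#' accumulation, k = 0, 1, 2, ...), re-projects the population through
#' the window with the other quantity held at its fitted value, and
#' stops at the smallest k for which the end/start total-abundance
#' ratio reaches `target_ratio`. Perturbed survival is capped at 0.999
#' per year. The trajectory is a pure projection of the fitted
#' estimates; the objective is not re-minimized.
#'
#' @param recon a fitted `moose_reconstruction`.
#' @param window length-2 calendar years `(start, end)` inside the span.
#' @param target_ratio required `N_total(end) / N_total(start)`,
#'   in (0, 1].
#' @param quantity `"survival"` or `"recruitment"`.
#' @param increment relative step per increment (default 0.001 = 0.1%).
#' @param max_steps search cap; exceeding it (or saturating the
#'   survival cap) without reaching the target is an error reporting the
#'   best ratio achieved.
#' @return list of class `sensitivity_result`: `perturbed_quantity`,
#'   `steps`, `percent_change`, `achieved_ratio`, `baseline_ratio`.
#' @export
sensitivity_search <- function(recon, window = c(2009, 2013),
                               target_ratio = 0.9,
                               quantity = c("survival", "recruitment"),
                               increment = 0.001, max_steps = 100000L) {
  quantity <- match.arg(quantity)
  stopifnot(target_ratio > 0, target_ratio <= 1)
  years <- recon$theta$years
  si <- match(window[1], years)
  ei <- match(window[2], years)
  if (is.na(si) || is.na(ei) || ei <= si) {
    stop("window years outside the fitted span")
  }
  N <- recon$abundance
  s_fit <- recon$theta$survival[si:(ei - 1)]
  r_fit <- N[(si + 1):ei, 1]

  ratio_at <- function(k) {
    mult <- 1 + k * increment
    s <- s_fit
    r <- r_fit
    if (quantity == "survival") s <- pmin(s * mult, 0.999) else r <- r * mult
    row <- N[si, ]
    for (t in seq_along(s)) {
      row <- c(r[t],
               (row[1] * 0.5 + row[2]) * s[t],
               (row[1] * 0.5 + row[3]) * s[t])
    }
    sum(row) / sum(N[si, ])
  }

  saturated <- if (quantity == "survival") {
    ceiling((0.999 / min(s_fit) - 1) / increment)
  } else max_steps

  k <- 0L
  ratio <- ratio_at(0L)
  baseline <- ratio
  while (ratio < target_ratio) {
    if (k >= max_steps || k > saturated) {
      stop(sprintf(
        "target ratio %.3f unreachable for %s (best %.3f at +%.1f%%)",
        target_ratio, quantity, ratio, k * increment * 100))
    }
    k <- k + 1L
    ratio <- ratio_at(k)
  }
  structure(list(perturbed_quantity = quantity, steps = k,
                 percent_change = k * increment * 100,
                 achieved_ratio = ratio, baseline_ratio = baseline,
                 window = window, target_ratio = target_ratio),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    paste0("Sensitivity of %d-%d decline to %s:\n",
           "  +%.1f%% (%d steps of 0.1%%) raises the end/start ratio ",
           "from %.3f to %.3f (target %.2f)\n"),
    x$window[1], x$window[2], x$perturbed_quantity, x$percent_change,
    x$steps, x$baseline_ratio, x$achieved_ratio, x$target_ratio))
  invisible(x)
}
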