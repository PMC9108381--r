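# Deterministic economic comparison: ICER with dominance handling,
# cost-utility quadrant, net health/monetary benefit, required effect size.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_mis - cost_conv) / (qaly_mis - qaly_conv)`, reported as a number
#' only where the ratio is meaningful: a positive incremental effect with
#' non-negative incremental cost. A cheaper-and-better intervention is
#' `"dominant"`, a dearer-and-worse one `"dominated"`; zero incremental
#' effect is `"indeterminate"`, and a negative incremental effect with cost
#' savings is `"less_costly_less_effective"` (the south-west trade-off,
#' where a signed ratio would invert its meaning). The raw ratio is
#' available with `unsafe = TRUE`.
#'
#' @param cost_mis,cost_conv Mean cost per patient of the MIS and
#'   conventional strategies (EUR).
#' @param qaly_mis,qaly_conv Mean QALY per patient of each strategy.
#' @param unsafe Return the raw ratio regardless of sign (for plotting).
#' @return EUR per QALY (numeric) or a dominance tag (character).
#' @examples
#' icer(33127.15, 14190.06, 0.32, 0.09) # 82335.17
#' @export
icer <- function(cost_mis, cost_conv, qaly_mis, qaly_conv, unsafe = FALSE) {
  vals <- c(cost_mis, cost_conv, qaly_mis, qaly_conv)
  if (any(!is.finite(vals))) abort("icer(): inputs must be finite")
  dc <- cost_mis - cost_conv
  de <- qaly_mis - qaly_conv
  if (isTRUE(unsafe)) return(dc / de)
  if (de == 0) return("indeterminate")
  if (dc == 0) return(0)
  if (de > 0 && dc < 0) return("dominant")
  if (de < 0 && dc > 0) return("dominated")
  if (de < 0) return("less_costly_less_effective")
  dc / de
}

#' Cost-utility plane quadrant
#'
#' North-east: costlier and more effective; south-east: cheaper and more
#' effective; north-west: costlier and less effective; south-west: cheaper
#' and less effective. A zero incremental cost or effect sits on an axis.
#'
#' @param delta_cost,delta_qaly Incremental cost (EUR) and effect (QALY);
#'   vectorised.
#' @return Character vector in `{"NE", "SE", "NW", "SW", "axis"}`.
#' @export
quadrant <- function(delta_cost, delta_qaly) {
  case_when(
    delta_cost == 0 | delta_qaly == 0 ~ "axis",
    delta_cost > 0 & delta_qaly > 0 ~ "NE",
    delta_cost < 0 & delta_qaly > 0 ~ "SE",
    delta_cost > 0 & delta_qaly < 0 ~ "NW",
    TRUE ~ "SW")
}

#' Net health and net monetary benefit
#'
#' At willingness-to-pay `lambda`, `nhb = delta_qaly - delta_cost / lambda`
#' (QALY) and `nmb = lambda * delta_qaly - delta_cost` (EUR);
#' `nmb = lambda * nhb` identically.
#'
#' @param delta_cost,delta_qaly Incremental cost (EUR) and effect (QALY).
#' @param lambda Willingness-to-pay threshold in EUR per QALY (> 0);
#'   default 30,000.
#' @return `nhb()`: QALY; `nmb()`: EUR.
#' @export
nhb <- function(delta_cost, delta_qaly, lambda = 30000) {
  if (any(lambda <= 0)) abort("nhb(): lambda must be > 0")
  delta_qaly - delta_cost / lambda
}

#' @rdname nhb
#' @export
nmb <- function(delta_cost, delta_qaly, lambda = 30000) {
  if (any(lambda <= 0)) abort("nmb(): lambda must be > 0")
  lambda * delta_qaly - delta_cost
}

#' MIS-arm QALY required to meet a willingness-to-pay threshold
#'
#' The effect size the intervention would need so that its ICER against
#' the conventional arm equals `lambda`:
#' `qaly_conv + delta_cost / lambda`.
#'
#' @param delta_cost Incremental cost of the intervention (EUR).
#' @param qaly_conv Mean QALY of the conventional arm.
#' @param lambda Willingness-to-pay threshold (EUR per QALY, > 0).
#' @return Required MIS-arm mean QALY.
#' @examples
#' required_qaly_at_threshold(18937.1, 0.09, 30000) # ~0.72
#' @export
required_qaly_at_threshold <- function(delta_cost, qaly_conv,
                                       lambda = 30000) {
  if (any(lambda <= 0)) {
    abort("required_qaly_at_threshold(): lambda must be > 0")
  }
  qaly_conv + delta_cost / lambda
}

#' Compare a minimally invasive strategy with conventional management
#'
#' Builds the full deterministic comparison: incremental cost and effect,
#' ICER (with dominance handling), cost-utility quadrant, net health and
#' monetary benefit at `lambda`, and the MIS-arm QALY required to meet
#' `lambda` exactly.
#'
#' @inheritParams icer
#' @param lambda Willingness-to-pay threshold (EUR per QALY).
#' @param label Name for the comparison (e.g. `"catheter"`).
#' @return An object of class `econ_comparison`; see [tidy.econ_comparison()]
#'   and [glance.econ_comparison()].
#' @examples
#' compare_strategies(33127.15, 14190.06, 0.32, 0.09, label = "catheter")
#' @export
compare_strategies <- function(cost_mis, cost_conv, qaly_mis, qaly_conv,
                               lambda = 30000, label = "MIS") {
  delta_cost <- cost_mis - cost_conv
  delta_qaly <- qaly_mis - qaly_conv
  structure(list(
    label = label,
    cost_mis = cost_mis, cost_conv = cost_conv,
    qaly_mis = qaly_mis, qaly_conv = qaly_conv,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer = icer(cost_mis, cost_conv, qaly_mis, qaly_conv),
    quadrant = quadrant(delta_cost, delta_qaly),
    lambda = lambda,
    nhb = nhb(delta_cost, delta_qaly, lambda),
    nmb = nmb(delta_cost, delta_qaly, lambda),
    required_qaly = required_qaly_at_threshold(delta_cost, qaly_conv,
                                               lambda)),
    class = "econ_comparison")
}

#' @export
print.econ_comparison <- function(x, ...) {
  cat("<econ_comparison> ", x$label, "\n", sep = "")
  cat(sprintf("  cost:  MIS %.2f vs conventional %.2f  (delta %.2f EUR)\n",
              x$cost_mis, x$cost_conv, x$delta_cost))
  cat(sprintf("  QALY:  MIS %.3f vs conventional %.3f  (delta %.3f)\n",
              x$qaly_mis, x$qaly_conv, x$delta_qaly))
  icer_str <- if (is.numeric(x$icer)) sprintf("%.2f EUR/QALY", x$icer)
              else x$icer
  cat("  ICER: ", icer_str, "  [quadrant ", x$quadrant, "]\n", sep = "")
  cat(sprintf("  at lambda = %.0f: NHB %.4f QALY, NMB %.2f EUR; required MIS QALY %.2f\n",
              x$lambda, x$nhb, x$nmb, x$required_qaly))
  invisible(x)
}

#' Tidy an economic comparison
#'
#' @param x An `econ_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A tibble with one row per quantity (`term`, `value`,
#'   `unit`).
#' @export
tidy.econ_comparison <- function(x, ...) {
  tibble(
    term = c("cost_mis", "cost_conv", "delta_cost", "qaly_mis", "qaly_conv",
             "delta_qaly", "icer", "nhb", "nmb", "required_qaly"),
    value = c(x$cost_mis, x$cost_conv, x$delta_cost, x$qaly_mis,
              x$qaly_conv, x$delta_qaly,
              if (is.numeric(x$icer)) x$icer else NA_real_,
              x$nhb, x$nmb, x$required_qaly),
    unit = c("EUR", "EUR", "EUR", "QALY", "QALY", "QALY", "EUR/QALY",
             "QALY", "EUR", "QALY"))
}

#' Glance at an economic comparison
#'
#' @param x An `econ_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A one-row tibble with the comparison's headline quantities.
#' @export
glance.econ_comparison <- function(x, ...) {
  tibble(
    label = x$label,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = if (is.numeric(x$icer)) x$icer else NA_real_,
    icer_tag = if (is.numeric(x$icer)) "ratio" else x$icer,
    quadrant = x$quadrant, lambda = x$lambda,
    nhb = x$nhb, nmb = x$nmb, required_qaly = x$required_qaly)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
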