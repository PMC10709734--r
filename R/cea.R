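#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes the incremental cost `dC = C1 - C0`, incremental effect
#' `dE = E1 - E0`, the incremental cost-effectiveness ratio
#' `ICER = dC / dE`, each strategy's cost-effectiveness ratio
#' `CER = C / E`, the net monetary benefit `NMB = wtp * dE - dC`, and a
#' dominance classification.  A negative ICER is ambiguous on its own, so
#' the sign is always reported together with the dominance label.
#'
#' Inputs may be `"strategy_result"` objects or plain lists with
#' `total_cost` and `total_qaly` (e.g. published per-patient summaries).
#'
#' @param intervention,comparator Strategies to compare (intervention
#'   minus comparator).
#' @param wtp Willingness-to-pay threshold in yuan per QALY; the default
#'   85,700 is the Chinese per-capita-GDP threshold.
#' @return An object of class `"cea_result"`: list with per-strategy
#'   `cost` and `effect`, `delta_cost`, `delta_effect`, `icer` (`NA` when
#'   `delta_effect` is 0), `cer` (named, intervention and comparator),
#'   `nmb`, `wtp` and `dominance` (one of `"intervention_dominant"`,
#'   `"comparator_dominant"`, `"tradeoff_ne"`, `"tradeoff_sw"`,
#'   `"equivalent"`).
#' @examples
#' s1 <- list(name = "TILs testing", total_cost = 150040, total_qaly = 9.71)
#' s2 <- list(name = "No testing", total_cost = 191016, total_qaly = 9.24)
#' compute_cea(s1, s2)
#' @export
compute_cea <- function(intervention, comparator, wtp = 85700) {
  g <- function(x, what) {
    v <- x[[what]]
    if (is.null(v) || !is.numeric(v)) {
      stop("strategy lacks numeric `", what, "`", call. = FALSE)
    }
    v
  }
  c1 <- g(intervention, "total_cost"); e1 <- g(intervention, "total_qaly")
  c0 <- g(comparator, "total_cost"); e0 <- g(comparator, "total_qaly")
  if (e1 <= 0 || e0 <= 0) {
    stop("CER requires positive QALY totals", call. = FALSE)
  }
  dc <- c1 - c0
  de <- e1 - e0
  icer <- if (de == 0) NA_real_ else dc / de
  dominance <- if (dc == 0 && de == 0) "equivalent"
    else if (dc <= 0 && de >= 0) "intervention_dominant"
    else if (dc >= 0 && de <= 0) "comparator_dominant"
    else if (dc > 0) "tradeoff_ne" else "tradeoff_sw"
  structure(
    list(
      intervention = intervention$name %||% "intervention",
      comparator = comparator$name %||% "comparator",
      cost = c(intervention = c1, comparator = c0),
      effect = c(intervention = e1, comparator = e0),
      delta_cost = dc, delta_effect = de, icer = icer,
      cer = c(intervention = c1 / e1, comparator = c0 / e0),
      nmb = wtp * de - dc, wtp = wtp, dominance = dominance
    ),
    class = "cea_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", x$intervention, "vs", x$comparator, "\n")
  cat(sprintf("  dC = %.2f yuan, dE = %.4f QALYs\n", x$delta_cost,
              x$delta_effect))
  cat(sprintf("  ICER = %s yuan/QALY [%s]\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.2f", x$icer),
              x$dominance))
  cat(sprintf("  CER: %.2f (%s) vs %.2f (%s)\n",
              x$cer[["intervention"]], x$intervention,
              x$cer[["comparator"]], x$comparator))
  cat(sprintf("  NMB at WTP %.0f: %.2f yuan\n", x$wtp, x$nmb))
  invisible(x)
}
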