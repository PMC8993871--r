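# Bland-Altman method agreement between two per-fiber morphometry sources,
# conventionally A = automated and B = ground truth; differences are B - A
# plotted against the pairwise average.

#' Pair one metric across two morphometry tables via an instance match
#'
#' One pair per matched (pred, truth) fiber, ordered by truth id; unmatched
#' fibers on either side are excluded and counted.
#'
#' @param tblA Morphometry table of source A (automated; ids = pred ids).
#' @param tblB Morphometry table of source B (ground truth; ids = truth ids).
#' @param match A [match_instances] result built from the fiber sets
#'   underlying `tblA` (pred) and `tblB` (truth).
#' @param metric Column name to pair (e.g. `"axon_diameter_um"`,
#'   `"myelin_thickness_um"`, `"g_ratio"`).
#' @return A `paired_measurements` list: `metric`, `pairs` tibble
#'   (`pred_id`, `truth_id`, `value_A`, `value_B`), `n_excluded_A`,
#'   `n_excluded_B`.
#' @export
pair_by_match <- function(tblA, tblB, match, metric) {
  stopifnot(inherits(match, "match_result"))
  if (!metric %in% names(tblA) || !metric %in% names(tblB))
    stop_invalid("metric '%s' is not a column of both tables", metric)
  p <- match$pairs[order(match$pairs$truth_id), , drop = FALSE]
  ia <- base::match(p$pred_id, tblA$fiber_id)
  ib <- base::match(p$truth_id, tblB$fiber_id)
  ok <- !is.na(ia) & !is.na(ib)
  structure(list(
    metric = metric,
    pairs = tibble::tibble(pred_id = p$pred_id[ok], truth_id = p$truth_id[ok],
                           value_A = tblA[[metric]][ia[ok]],
                           value_B = tblB[[metric]][ib[ok]]),
    n_excluded_A = nrow(tblA) - sum(ok),
    n_excluded_B = nrow(tblB) - sum(ok)),
    class = "paired_measurements")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = B_i - A_i`; bias is their mean, `sd_diff` their sample
#' standard deviation (n - 1 denominator), and the 95% limits of agreement
#' `bias -/+ 1.96 * sd_diff` comprise about 95% of the differences between
#' the two methods. Scatter coordinates `((A_i+B_i)/2, d_i)` are emitted for
#' the difference-vs-average plot.
#'
#' @param pm A [pair_by_match] result, or a list with numeric vectors
#'   `value_A` and `value_B` in its `pairs` field; at least 2 pairs.
#' @return An `agreement_result`: `metric`, `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `scatter` tibble (`average`, `difference`).
#' @export
bland_altman <- function(pm) {
  a <- pm$pairs$value_A; b <- pm$pairs$value_B
  n <- length(a)
  if (n == 0L) stop_invalid("no pairs to analyze")
  if (n < 2L)
    stop(structure(class = c("nervemorph_insufficient_data", "error",
                             "condition"),
                   list(message = "limits of agreement need at least 2 pairs",
                        call = sys.call(-1))))
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("paired values must be finite")
  d <- b - a
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(metric = pm$metric %||% NA_character_, n = n,
                 bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 scatter = tibble::tibble(average = (a + b) / 2,
                                          difference = d)),
            class = "agreement_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> %s: n %d, bias %.4f, SD %.4f, 95%% LoA [%.4f, %.4f]\n",
    x$metric, x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}
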