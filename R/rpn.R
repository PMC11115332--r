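#' Traditional risk priority number
#'
#' The classic FMEA score: the product of the Occurrence, Severity and
#' Detection ratings, each an integer on the 1-10 ordinal scale, giving an
#' RPN between 1 and 1000. Higher means higher-priority risk.
#'
#' @param o,s,d Integer ratings in 1..10.
#' @return Integer RPN in 1..1000.
#' @examples
#' traditional_rpn(5, 7, 3)  # 105
#' @export
traditional_rpn <- function(o, s, d) {
  for (v in list(o = o, s = s, d = d)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v != round(v) || v < 1 || v > 10) {
      fr_stop("range", "O, S and D must each be integers in 1..10")
    }
  }
  as.integer(o * s * d)
}

#' Multiplicative fuzzy risk priority number
#'
#' The fuzzy analogue of the RPN: the componentwise product of the three
#' factor TFNs, `(a1 a2 a3, b1 b2 b3, c1 c2 c3)`. The result is defuzzified
#' to a crisp priority and labelled with the nearest category of the output
#' scale (the crisp value is first rescaled onto the output universe `[0,1]`
#' by the product of the factor scale maxima, 1000 for three 1-10 scales).
#'
#' @param o,s,d Factor TFNs (non-negative).
#' @param output_scale Output [linguistic_scale()] on `[0, 1]`; defaults to
#'   the five-level VL..VH ladder of [default_scales()].
#' @param defuzz Defuzzification method for the crisp value.
#' @param scale_max Per-factor support maxima used to rescale the crisp
#'   product onto `[0, 1]` for labelling.
#' @return A list of class `"frpn"`: `frpn` (the product TFN), `crisp`,
#'   `norm` (crisp rescaled to `[0, 1]`), `label`.
#' @examples
#' fuzzy_rpn(tfn(9, 10, 10), tfn(9, 10, 10), tfn(8, 10, 10))
#' @export
fuzzy_rpn <- function(o, s, d, output_scale = NULL,
                      defuzz = "centroid_mean", scale_max = c(10, 10, 10)) {
  if (is.null(output_scale)) output_scale <- default_scales()$rpn_output
  prod_tfn <- tfn_multiply(tfn_multiply(as_tfn(o), as_tfn(s)), as_tfn(d))
  crisp <- defuzzify(prod_tfn, defuzz)
  norm <- crisp / prod(scale_max)
  structure(list(frpn = prod_tfn, crisp = crisp, norm = norm,
                 label = nearest_output_label(output_scale, norm)),
            class = "frpn")
}

#' @export
print.frpn <- function(x, ...) {
  cat(sprintf("F-RPN %s  crisp %.4f  [%s %.3f]\n",
              format(x$frpn), x$crisp, x$label, x$norm))
  invisible(x)
}

# output category whose TFN centroid is nearest to the crisp value;
# exact ties go to the higher category
nearest_output_label <- function(scale, value) {
  cents <- vapply(scale$tfns, defuzzify, numeric(1))
  d <- abs(cents - value)
  scale$labels[max(which(d == min(d)))]
}

#' Competition ranking
#'
#' Ranks values so that tied entries share the minimum rank of their block
#' (1, 1, 3, ...), stable in input order within ties.
#'
#' @param x Numeric scores.
#' @param decreasing Rank 1 = largest (default) or smallest.
#' @return Integer ranks.
#' @export
competition_rank <- function(x, decreasing = TRUE) {
  if (decreasing) rank(-x, ties.method = "min") else rank(x, ties.method = "min")
}

#' Rank a list of fuzzy RPN results
#'
#' Orders [fuzzy_rpn()] results by descending crisp value under competition
#' ranking (ties share the minimum rank, stable by `fm_id` order).
#'
#' @param results List of `"frpn"` objects.
#' @param fm_ids Character identifiers, one per result.
#' @return `data.frame` with `fm_id`, `crisp`, `label`, `rank`.
#' @export
rank_by_frpn <- function(results, fm_ids = paste0("FM", seq_along(results))) {
  stopifnot(length(results) >= 1L, length(fm_ids) == length(results))
  crisp <- vapply(results, function(r) r$crisp, numeric(1))
  data.frame(fm_id = as.character(fm_ids), crisp = crisp,
             label = vapply(results, function(r) r$label, character(1)),
             rank = competition_rank(crisp), stringsAsFactors = FALSE)
}

#' Rank failure modes by fuzzy RPN
#'
#' Scores every failure mode of a register with the multiplicative F-RPN of
#' its expert-aggregated O, S, D ratings and ranks them from riskiest down
#' (competition ranking on the crisp value; ties keep register order).
#'
#' @param register A [risk_register()].
#' @param scales Scale registry.
#' @inheritParams fuzzy_rpn
#' @return `data.frame` of class `"frpn_ranking"`: `fm_id`, the product TFN
#'   components, `crisp`, `norm`, `label`, `rank`.
#' @export
frpn_rank <- function(register, scales = default_scales(),
                      defuzz = "centroid_mean") {
  ids <- complete_fm_ids(register, scales)
  res <- lapply(ids, function(id) {
    fuzzy_rpn(aggregate_experts(register, id, "occurrence", scales),
              aggregate_experts(register, id, "severity", scales),
              aggregate_experts(register, id, "detection", scales),
              output_scale = scales$rpn_output, defuzz = defuzz)
  })
  out <- data.frame(fm_id = ids,
                    alpha = vapply(res, function(r) r$frpn[[1]], numeric(1)),
                    beta = vapply(res, function(r) r$frpn[[2]], numeric(1)),
                    gamma = vapply(res, function(r) r$frpn[[3]], numeric(1)),
                    crisp = vapply(res, function(r) r$crisp, numeric(1)),
                    norm = vapply(res, function(r) r$norm, numeric(1)),
                    label = vapply(res, function(r) r$label, character(1)),
                    stringsAsFactors = FALSE)
  out$rank <- competition_rank(out$crisp)
  class(out) <- c("frpn_ranking", "data.frame")
  out
}

#' @export
print.frpn_ranking <- function(x, ...) {
  cat("Fuzzy RPN ranking, riskiest first:\n")
  cols <- intersect(c("fm_id", "crisp", "norm", "label", "rank"), names(x))
  df <- as.data.frame(x)[order(x$rank, x$fm_id), cols]
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
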