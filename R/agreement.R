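#' Rank agreement between two rankings
#'
#' Standard agreement statistics between a method's ranking and a reference
#' ranking over the same alternatives: Spearman's rho and Kendall's tau on
#' the rank vectors, the fraction of shared members among the top-`k`
#' alternatives, and the mean absolute rank difference. Identical rankings
#' give rho = tau = overlap = 1 and mean difference 0; an exact reversal
#' gives rho = -1.
#'
#' Rankings may be given as `data.frame`s with `fm_id` and `rank` columns,
#' as named numeric rank vectors, or as character vectors of alternative
#' ids ordered best-first. The two rankings normally cover the same
#' alternatives; when they do not (e.g. two printed top-5 excerpts), the
#' correlation and rank-difference statistics are computed on the shared
#' alternatives (and are `NA` with fewer than two of them), while the
#' top-`k` overlap always compares the two heads as given. Rankings with no
#' shared alternative at all are rejected.
#'
#' @param ranking,reference The two rankings.
#' @param k Size of the head compared for the overlap statistic.
#' @return Object of class `"agreement_report"`: list with `spearman_rho`,
#'   `kendall_tau`, `top_k_overlap`, `mean_abs_rank_diff`, `k`, `n`.
#' @export
rank_agreement <- function(ranking, reference, k = 5L) {
  a <- as_rank_vector(ranking)
  b <- as_rank_vector(reference)
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) {
    fr_stop("mismatched_alternatives",
            "the two rankings share no alternatives")
  }
  k <- min(k, length(a), length(b))
  top <- function(r) names(sort(r))[seq_len(k)]
  ac <- a[common]; bc <- b[common]
  can_cor <- length(common) >= 2L && stats::sd(ac) > 0 && stats::sd(bc) > 0
  structure(list(
    spearman_rho = if (can_cor) stats::cor(ac, bc, method = "spearman") else NA_real_,
    kendall_tau = if (can_cor) stats::cor(ac, bc, method = "kendall") else NA_real_,
    top_k_overlap = length(intersect(top(a), top(b))) / k,
    mean_abs_rank_diff = if (length(common)) mean(abs(ac - bc)) else NA_real_,
    k = k, n = length(common)), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("Rank agreement over %d alternatives:\n",
                     "  Spearman rho       %+.3f\n",
                     "  Kendall tau        %+.3f\n",
                     "  top-%d overlap      %.2f\n",
                     "  mean |rank diff|   %.2f\n"),
              x$n, x$spearman_rho, x$kendall_tau, x$k, x$top_k_overlap,
              x$mean_abs_rank_diff))
  invisible(x)
}

# coerce the accepted ranking shapes to a named rank vector
as_rank_vector <- function(r) {
  if (is.data.frame(r)) {
    stopifnot(all(c("fm_id", "rank") %in% names(r)))
    return(setNames(as.numeric(r$rank), as.character(r$fm_id)))
  }
  if (is.character(r)) return(setNames(seq_along(r), r))
  if (is.numeric(r) && !is.null(names(r))) return(r)
  fr_stop("invalid_ranking",
          "a ranking must be a data.frame(fm_id, rank), a named rank vector, or an ordered id vector")
}
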