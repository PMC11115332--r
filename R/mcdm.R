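#' Fuzzy decision matrices
#'
#' A fuzzy decision matrix holds one TFN per (alternative, criterion) cell,
#' plus per-criterion directions ("benefit": larger is preferable; "cost":
#' smaller is preferable) and weights. For risk ranking the three FMEA
#' factors are all benefit criteria — higher grades mean more dangerous —
#' with equal crisp weights 1/3 by default.
#'
#' Weights may be crisp (must sum to 1 within 1e-9) or fuzzy (their
#' defuzzified values should sum to 1 within 0.05; a warning is issued
#' otherwise).
#'
#' @param entries List of rows, each a list of TFNs (one per criterion), or
#'   a 3-dimensional array `[alternative, criterion, component]`.
#' @param alternatives Character identifiers of the alternatives (rows).
#' @param criteria Character names of the criteria (columns).
#' @param directions Character vector, `"benefit"` or `"cost"` per criterion.
#' @param weights Numeric vector of crisp weights, or list of TFN weights;
#'   defaults to equal crisp weights.
#' @return Object of class `"fdm"`.
#' @export
fuzzy_decision_matrix <- function(entries, alternatives, criteria,
                                  directions = rep("benefit", length(criteria)),
                                  weights = NULL) {
  m <- length(alternatives); n <- length(criteria)
  stopifnot(m >= 1L, n >= 1L, length(directions) == n,
            all(directions %in% c("benefit", "cost")))
  arr <- array(NA_real_, dim = c(m, n, 3L),
               dimnames = list(alternatives, criteria, c("alpha", "beta", "gamma")))
  if (is.array(entries) && length(dim(entries)) == 3L) {
    arr[] <- entries
  } else {
    stopifnot(length(entries) == m)
    for (i in seq_len(m)) {
      row <- entries[[i]]
      stopifnot(length(row) == n)
      for (j in seq_len(n)) arr[i, j, ] <- unclass(as_tfn(row[[j]]))
    }
  }
  if (anyNA(arr)) {
    fr_stop("incomplete_matrix", "fuzzy decision matrix has missing cells")
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (is.numeric(weights) && !is.list(weights)) {
    stopifnot(length(weights) == n)
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
      fr_stop("invalid_weights", "crisp criterion weights must be non-negative and sum to 1")
    }
  } else {
    weights <- lapply(weights, as_tfn)
    stopifnot(length(weights) == n)
    wsum <- sum(vapply(weights, defuzzify, numeric(1)))
    if (abs(wsum - 1) > 0.05) {
      warning(sprintf("defuzzified fuzzy weights sum to %.3f, not 1", wsum),
              call. = FALSE)
    }
  }
  structure(list(entries = arr, alternatives = as.character(alternatives),
                 criteria = as.character(criteria), directions = directions,
                 weights = weights),
            class = "fdm")
}

#' @export
print.fdm <- function(x, ...) {
  cat(sprintf("Fuzzy decision matrix: %d alternatives x %d criteria (%s)\n",
              length(x$alternatives), length(x$criteria),
              paste(x$criteria, collapse = ", ")))
  invisible(x)
}

# cell (i, j) as a TFN
fdm_cell <- function(m, i, j) tfn(m$entries[i, j, ])

# crisp weight vector (fuzzy weights defuzzified)
crisp_weights <- function(m) {
  if (is.list(m$weights)) vapply(m$weights, defuzzify, numeric(1))
  else m$weights
}

# per-column fuzzy extreme in the stated direction
column_extreme <- function(m, j, best = TRUE) {
  cells <- lapply(seq_along(m$alternatives), function(i) fdm_cell(m, i, j))
  benefit <- m$directions[j] == "benefit"
  if (xor(best, !benefit)) tfn_max(cells) else tfn_min(cells)
}

#' Build a decision matrix from a risk register
#'
#' Aggregates each failure mode's expert ratings into one TFN per FMEA
#' factor and assembles the `m x 3` fuzzy decision matrix with benefit
#' criteria `occurrence`, `severity`, `detection` and equal crisp weights.
#' Failure modes with missing ratings on any factor are dropped with a
#' warning.
#'
#' @param register A [risk_register()].
#' @param scales Scale registry.
#' @param weights Criterion weights (default equal).
#' @param directions Criterion directions (default all benefit).
#' @return An [fuzzy_decision_matrix()].
#' @export
build_matrix_from_register <- function(register, scales = default_scales(),
                                       weights = NULL,
                                       directions = rep("benefit", 3L)) {
  ids <- complete_fm_ids(register, scales)
  factors <- c("occurrence", "severity", "detection")
  rows <- lapply(ids, function(id)
    lapply(factors, function(f) aggregate_experts(register, id, f, scales)))
  fuzzy_decision_matrix(rows, ids, factors, directions, weights)
}

#' Fuzzy ARAS ranking
#'
#' Additive Ratio Assessment in a fuzzy setting. A hypothetical ideal
#' alternative (per-criterion fuzzy max for benefit, min for cost) is
#' appended; cost columns are inverted componentwise; every column is then
#' normalised by its crisp (defuzzified) column sum, weighted, and summed
#' into the fuzzy optimality score of each alternative. The crisp utility
#' degree `K_i = S_i / S_0` compares each alternative with the ideal one, so
#' `0 < K_i <= 1` and the ideal row scores exactly 1. Ranks are descending
#' in `K` (competition ranking).
#'
#' Normalising by the crisp column sum (rather than an undefined fuzzy
#' division) preserves the TFN ordering and is exact for crisp inputs.
#'
#' @param m A [fuzzy_decision_matrix()].
#' @param defuzz Defuzzification method.
#' @return Object of class `"aras_result"`: `data.frame` in `$table` with
#'   `fm_id`, `S`, `K`, `rank`; ideal-row score in `$S0`.
#' @export
aras_rank <- function(m, defuzz = "centroid_mean") {
  stopifnot(inherits(m, "fdm"))
  nalt <- length(m$alternatives); ncrit <- length(m$criteria)
  w <- m$weights
  # working matrix with the ideal row first
  rows <- vector("list", nalt + 1L)
  rows[[1]] <- lapply(seq_len(ncrit), function(j) column_extreme(m, j, best = TRUE))
  for (i in seq_len(nalt)) {
    rows[[i + 1L]] <- lapply(seq_len(ncrit), function(j) fdm_cell(m, i, j))
  }
  S_f <- replicate(nalt + 1L, tfn(0, 0, 0), simplify = FALSE)
  for (j in seq_len(ncrit)) {
    col <- lapply(rows, `[[`, j)
    if (m$directions[j] == "cost") {
      col <- lapply(col, function(x) {
        if (x[[1]] <= 0) {
          fr_stop("zero_column",
                  sprintf("cost criterion %s requires strictly positive entries",
                          dQuote(m$criteria[j])))
        }
        tfn(rev(1 / unclass(x)))
      })
    }
    den <- sum(vapply(col, defuzzify, numeric(1), method = defuzz))
    if (abs(den) < 1e-12) {
      fr_stop("zero_column",
              sprintf("normalisation denominator of criterion %s is zero",
                      dQuote(m$criteria[j])))
    }
    wj <- if (is.list(w)) w[[j]] else w[j]
    for (i in seq_along(col)) {
      nrm <- tfn(unclass(col[[i]]) / den)
      wcell <- if (is_tfn(wj)) tfn_multiply(nrm, wj) else tfn_scale(nrm, wj)
      S_f[[i]] <- tfn_add(S_f[[i]], wcell)
    }
  }
  S <- vapply(S_f, defuzzify, numeric(1), method = defuzz)
  S0 <- S[1]
  K <- S[-1] / S0
  tab <- data.frame(fm_id = m$alternatives, S = S[-1], K = K,
                    rank = competition_rank(K), stringsAsFactors = FALSE)
  structure(list(table = tab, S0 = S0, S_fuzzy = S_f[-1], defuzz = defuzz),
            class = "aras_result")
}

#' @export
print.aras_result <- function(x, ...) {
  cat("Fuzzy ARAS ranking (K = S_i / S_0, higher = riskier):\n")
  print(x$table[order(x$table$rank, x$table$fm_id), ], row.names = FALSE, digits = 6)
  invisible(x)
}

#' Fuzzy VIKOR compromise ranking
#'
#' For each criterion the fuzzy best and worst values are taken over the
#' alternatives; each alternative accumulates a weighted normalised distance
#' to the best value — summed into the group utility `S_i`, maximised into
#' the individual regret `R_i` — and the two are merged into the compromise
#' index `Q_i` with trade-off weight `v` (weight of the "majority of
#' criteria" strategy, default 0.5). Computation stays fuzzy through the
#' merge: componentwise differences are re-sorted when disordered and only
#' the final `Q`, `S`, `R` are defuzzified (the centroid mean is invariant
#' under that re-sort). Lower `Q` is better, i.e. rank 1 is the riskiest
#' failure mode under the risk orientation used here.
#'
#' A criterion whose best and worst values coincide carries no information
#' and contributes zero (with a warning); if every criterion is constant the
#' matrix is degenerate and an error is raised. The classic acceptability
#' checks are reported: Condition 1 ("acceptable advantage",
#' `Q(2) - Q(1) >= 1/(m-1)`) and Condition 2 ("acceptable stability": the Q
#' leader also leads both the S and the R ranking). When a condition fails
#' the compromise set is enlarged in the standard way.
#'
#' @param m A [fuzzy_decision_matrix()].
#' @param v Trade-off weight in `[0, 1]`.
#' @param defuzz Defuzzification method.
#' @return Object of class `"vikor_result"`: `$table` with `fm_id`, `S`,
#'   `R`, `Q`, `one_minus_Q`, per-index ranks; `$condition1`, `$condition2`,
#'   `$compromise_set`.
#' @export
vikor_rank <- function(m, v = 0.5, defuzz = "centroid_mean") {
  stopifnot(inherits(m, "fdm"), v >= 0, v <= 1)
  nalt <- length(m$alternatives); ncrit <- length(m$criteria)
  if (nalt < 2L) {
    fr_stop("degenerate_criterion", "VIKOR needs at least two alternatives")
  }
  w <- crisp_weights(m)
  terms <- vector("list", nalt)  # per alternative: list of per-criterion TFNs
  for (i in seq_len(nalt)) terms[[i]] <- vector("list", ncrit)
  informative <- logical(ncrit)
  for (j in seq_len(ncrit)) {
    fstar <- column_extreme(m, j, best = TRUE)
    fworst <- column_extreme(m, j, best = FALSE)
    den <- defuzzify(fstar, defuzz) - defuzzify(fworst, defuzz)
    if (abs(den) < 1e-12) {
      warning(sprintf("criterion %s is constant across alternatives; it contributes 0",
                      dQuote(m$criteria[j])), call. = FALSE)
      for (i in seq_len(nalt)) terms[[i]][[j]] <- tfn(0, 0, 0)
      next
    }
    informative[j] <- TRUE
    for (i in seq_len(nalt)) {
      diff <- (unclass(fstar) - m$entries[i, j, ]) * (w[j] / den)
      terms[[i]][[j]] <- tfn(sort(diff))
    }
  }
  if (!any(informative)) {
    fr_stop("degenerate_criterion", "all criteria are constant across alternatives")
  }
  S_f <- lapply(terms, function(ts) tfn(Reduce(`+`, lapply(ts, unclass))))
  R_f <- lapply(terms, tfn_max, method = defuzz)
  S <- vapply(S_f, defuzzify, numeric(1), method = defuzz)
  R <- vapply(R_f, defuzzify, numeric(1), method = defuzz)
  Sstar <- min(S); Sminus <- max(S)
  Rstar <- min(R); Rminus <- max(R)
  q_part <- function(x_f, lo, hi, wt) {
    if (hi - lo < 1e-12) return(c(0, 0, 0))
    sort(wt * (unclass(x_f) - lo) / (hi - lo))
  }
  Q_f <- lapply(seq_len(nalt), function(i) {
    tfn(sort(q_part(S_f[[i]], Sstar, Sminus, v) +
             q_part(R_f[[i]], Rstar, Rminus, 1 - v)))
  })
  Q <- vapply(Q_f, defuzzify, numeric(1), method = defuzz)
  tab <- data.frame(fm_id = m$alternatives, S = S, R = R, Q = Q,
                    one_minus_Q = 1 - Q,
                    rank_Q = competition_rank(Q, decreasing = FALSE),
                    rank_S = competition_rank(S, decreasing = FALSE),
                    rank_R = competition_rank(R, decreasing = FALSE),
                    stringsAsFactors = FALSE)
  ord <- order(tab$Q, seq_len(nalt))
  q_sorted <- tab$Q[ord]
  thresh <- 1 / (nalt - 1)
  cond1 <- (q_sorted[2] - q_sorted[1]) >= thresh
  leader <- ord[1]
  cond2 <- tab$rank_S[leader] == 1L && tab$rank_R[leader] == 1L
  if (cond1 && cond2) {
    compromise <- tab$fm_id[leader]
  } else if (!cond1) {
    in_set <- q_sorted - q_sorted[1] < thresh
    compromise <- tab$fm_id[ord[in_set]]
  } else {
    compromise <- tab$fm_id[ord[1:2]]
  }
  structure(list(table = tab, v = v, condition1 = cond1, condition2 = cond2,
                 compromise_set = compromise, defuzz = defuzz),
            class = "vikor_result")
}

#' @export
print.vikor_result <- function(x, ...) {
  cat(sprintf("Fuzzy VIKOR ranking (v = %g; lower Q = riskier here):\n", x$v))
  print(x$table[order(x$table$rank_Q, x$table$fm_id), ], row.names = FALSE, digits = 6)
  cat(sprintf("Condition 1 (acceptable advantage): %s\n", x$condition1))
  cat(sprintf("Condition 2 (acceptable stability): %s\n", x$condition2))
  cat("Compromise set:", paste(x$compromise_set, collapse = ", "), "\n")
  invisible(x)
}

#' Fuzzy WASPAS ranking
#'
#' Weighted Aggregated Sum Product Assessment: each column is normalised
#' componentwise against its fuzzy column extreme (divide by the max for
#' benefit criteria, divide the min by the entry for cost criteria), then
#' two utilities are computed per alternative — the weighted-sum score `Q_i`
#' and the weighted-product score `P_i` (components raised to the crisp
#' weights) — and blended into `K' = lambda Q + (1 - lambda) P`. With
#' normalised entries in `[0, 1]` and weights summing to one, `P_i <= Q_i`
#' (weighted AM-GM), and the alternative matching every column maximum gets
#' `K' = 1`. Ranks are descending in `K'`.
#'
#' @param m A [fuzzy_decision_matrix()].
#' @param lambda Blend weight in `[0, 1]`, or `"auto"` for the data-driven
#'   value `sum(P) / (sum(Q) + sum(P))`.
#' @param defuzz Defuzzification method.
#' @return Object of class `"waspas_result"`: `$table` with `fm_id`, `Q`,
#'   `P`, `K`, `rank`; `$lambda` as used.
#' @export
waspas_rank <- function(m, lambda = 0.5, defuzz = "centroid_mean") {
  stopifnot(inherits(m, "fdm"))
  auto <- identical(lambda, "auto")
  if (!auto) stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  nalt <- length(m$alternatives); ncrit <- length(m$criteria)
  w <- crisp_weights(m)
  wf <- m$weights
  Q_f <- replicate(nalt, tfn(0, 0, 0), simplify = FALSE)
  P_f <- replicate(nalt, tfn(1, 1, 1), simplify = FALSE)
  for (j in seq_len(ncrit)) {
    benefit <- m$directions[j] == "benefit"
    ref <- unclass(column_extreme(m, j, best = TRUE))
    for (i in seq_len(nalt)) {
      x <- m$entries[i, j, ]
      nrm <- if (benefit) {
        ifelse(ref > 0, x / ref, ifelse(x == 0, 1, 0))
      } else {
        if (any(x <= 0)) {
          fr_stop("zero_entry",
                  sprintf("cost criterion %s requires strictly positive entries",
                          dQuote(m$criteria[j])))
        }
        ref / x
      }
      nrm <- sort(pmin(nrm, 1))
      if (all(nrm == 0)) {
        fr_stop("zero_entry",
                sprintf("zero normalised entry for %s on criterion %s breaks the product model",
                        dQuote(m$alternatives[i]), dQuote(m$criteria[j])))
      }
      wj_f <- if (is.list(wf)) wf[[j]] else wf[j]
      wsum_cell <- if (is_tfn(wj_f)) tfn_multiply(tfn(nrm), wj_f)
                   else tfn_scale(tfn(nrm), wj_f)
      Q_f[[i]] <- tfn_add(Q_f[[i]], wsum_cell)
      P_f[[i]] <- tfn(unclass(P_f[[i]]) * nrm^w[j])
    }
  }
  Q <- vapply(Q_f, defuzzify, numeric(1), method = defuzz)
  P <- vapply(P_f, defuzzify, numeric(1), method = defuzz)
  lam <- if (auto) sum(P) / (sum(Q) + sum(P)) else lambda
  K <- lam * Q + (1 - lam) * P
  tab <- data.frame(fm_id = m$alternatives, Q = Q, P = P, K = K,
                    rank = competition_rank(K), stringsAsFactors = FALSE)
  structure(list(table = tab, lambda = lam, lambda_auto = auto, defuzz = defuzz),
            class = "waspas_result")
}

#' @export
print.waspas_result <- function(x, ...) {
  cat(sprintf("Fuzzy WASPAS ranking (lambda = %.3f%s; higher K' = riskier):\n",
              x$lambda, if (x$lambda_auto) ", data-driven" else ""))
  print(x$table[order(x$table$rank, x$table$fm_id), ], row.names = FALSE, digits = 6)
  invisible(x)
}
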