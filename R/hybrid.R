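#' Method index matrices
#'
#' Input to the hybrid ranker: one row per failure mode, one column per
#' MCDM method, each cell a benefit index in `[0, 1]` (higher = riskier).
#' The VIKOR index, where lower is better, must already be transformed to
#' the efficiency form `1 - Q_i` — [to_benefit_indices()] does this.
#' Values outside `[0, 1]` by more than 1e-9 raise an error; values within
#' that tolerance are clipped onto the bounds.
#'
#' @param x Numeric matrix (or data.frame with an `fm_id` column followed by
#'   numeric method columns).
#' @param fm_ids Optional row identifiers (defaults to rownames).
#' @param methods Optional column names.
#' @return Numeric matrix of class `"method_index_matrix"`.
#' @export
method_index_matrix <- function(x, fm_ids = NULL, methods = NULL) {
  if (is.data.frame(x)) {
    idcol <- match("fm_id", names(x))
    if (!is.na(idcol)) {
      if (is.null(fm_ids)) fm_ids <- as.character(x[[idcol]])
      x <- x[, -idcol, drop = FALSE]
    }
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2L || ncol(x) < 1L) {
    fr_stop("invalid_index_matrix",
            "need at least two failure modes and one method column")
  }
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    fr_stop("range", "method indices must lie in [0, 1]")
  }
  x <- pmin(pmax(x, 0), 1)
  if (!is.null(fm_ids)) rownames(x) <- fm_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("FM", seq_len(nrow(x)))
  if (!is.null(methods)) colnames(x) <- methods
  if (is.null(colnames(x))) colnames(x) <- paste0("method", seq_len(ncol(x)))
  structure(x, class = c("method_index_matrix", class(x)))
}

#' Collect per-method benefit indices
#'
#' Assembles the hybrid ranker's input from the three rankers' results:
#' ARAS utility `K_i`, VIKOR efficiency `1 - Q_i`, and WASPAS joint utility
#' `K'_i`. All three results must cover the same alternatives.
#'
#' @param aras An `"aras_result"` from [aras_rank()].
#' @param vikor A `"vikor_result"` from [vikor_rank()].
#' @param waspas A `"waspas_result"` from [waspas_rank()].
#' @return A [method_index_matrix()] with columns
#'   `aras_k`, `vikor_1mq`, `waspas_k`.
#' @export
to_benefit_indices <- function(aras, vikor, waspas) {
  stopifnot(inherits(aras, "aras_result"), inherits(vikor, "vikor_result"),
            inherits(waspas, "waspas_result"))
  ids <- aras$table$fm_id
  if (!identical(sort(ids), sort(vikor$table$fm_id)) ||
      !identical(sort(ids), sort(waspas$table$fm_id))) {
    fr_stop("mismatched_alternatives",
            "the three results do not cover the same failure modes")
  }
  vi <- vikor$table$one_minus_Q[match(ids, vikor$table$fm_id)]
  wa <- waspas$table$K[match(ids, waspas$table$fm_id)]
  method_index_matrix(cbind(aras_k = aras$table$K, vikor_1mq = vi, waspas_k = wa),
                      fm_ids = ids)
}

#' Ideal index vectors
#'
#' Positive and negative ideal solutions of a method index matrix: the
#' per-column maximum (`eta_plus`) and minimum (`eta_minus`) over all
#' failure modes.
#'
#' @param m A [method_index_matrix()].
#' @return List with numeric vectors `eta_plus` and `eta_minus`.
#' @export
ideal_vectors <- function(m) {
  m <- as_index_matrix(m)
  list(eta_plus = apply(m, 2, max), eta_minus = apply(m, 2, min))
}

#' Distances to the ideal index vectors
#'
#' Euclidean distance of every failure mode's index row to the positive
#' (`psi_plus`) and negative (`psi_minus`) ideal vectors. A row that attains
#' every column maximum has `psi_plus = 0`.
#'
#' @param m A [method_index_matrix()].
#' @return `data.frame` with `fm_id`, `psi_plus`, `psi_minus`.
#' @export
ideal_distances <- function(m) {
  m <- as_index_matrix(m)
  eta <- ideal_vectors(m)
  dp <- sqrt(rowSums(sweep(m, 2, eta$eta_plus)^2))
  dm <- sqrt(rowSums(sweep(m, 2, eta$eta_minus)^2))
  data.frame(fm_id = rownames(m), psi_plus = unname(dp),
             psi_minus = unname(dm), stringsAsFactors = FALSE)
}

#' Hybrid ranking by the ultimate utility index
#'
#' The hybrid aggregation of several MCDM rankings: each failure mode's
#' ultimate utility index is its share of the summed negative-ideal
#' distances minus its share of the summed positive-ideal distances,
#'
#' \deqn{UUI_c = \psi^-_c / \sum_c \psi^-_c - \psi^+_c / \sum_c \psi^+_c,}
#'
#' so `UUI` lies in `[-1, 1]`, sums to zero over the failure modes, and a
#' higher value means a higher risk priority. Ranks are descending in `UUI`
#' with competition tie handling. The matrix is degenerate (an error) when
#' all rows are identical, since both distance sums vanish.
#'
#' @param m A [method_index_matrix()] (or anything
#'   [method_index_matrix()] accepts).
#' @return Object of class `"hybrid_result"`: `$table` with `fm_id`,
#'   `psi_plus`, `psi_minus`, `uui`, `rank`; `$eta_plus`, `$eta_minus`,
#'   `$sum_psi_plus`, `$sum_psi_minus`.
#' @examples
#' idx <- method_index_matrix(rbind(a = c(1, 0.9), b = c(0.5, 0.2), c = c(0.7, 0.6)))
#' hybrid_rank(idx)
#' @export
hybrid_rank <- function(m) {
  if (!inherits(m, "method_index_matrix")) m <- method_index_matrix(m)
  d <- ideal_distances(m)
  sp <- sum(d$psi_plus); sm <- sum(d$psi_minus)
  if (sp <= 0 || sm <= 0) {
    fr_stop("degenerate_matrix",
            "all index rows are identical; the hybrid ranking is undefined")
  }
  d$uui <- d$psi_minus / sm - d$psi_plus / sp
  d$rank <- competition_rank(d$uui)
  eta <- ideal_vectors(m)
  structure(list(table = d, eta_plus = eta$eta_plus, eta_minus = eta$eta_minus,
                 sum_psi_plus = sp, sum_psi_minus = sm),
            class = "hybrid_result")
}

#' @rdname hybrid_rank
#' @export
ultimate_utility <- hybrid_rank

#' @export
print.hybrid_result <- function(x, digits = 6, ...) {
  cat("Hybrid MCDM ranking (ultimate utility index, riskiest first):\n")
  tab <- x$table[order(x$table$rank, x$table$fm_id), ]
  tab[2:4] <- lapply(tab[2:4], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("sum psi+: %.*f   sum psi-: %.*f\n",
              digits, x$sum_psi_plus, digits, x$sum_psi_minus))
  invisible(x)
}

#' @export
plot.hybrid_result <- function(x, ...) {
  tab <- x$table[order(-x$table$uui), ]
  graphics::barplot(tab$uui, names.arg = tab$fm_id, las = 2,
                    ylab = "Ultimate utility index",
                    main = "Hybrid risk ranking", ...)
  invisible(x)
}

# lenient validation for the distance helpers: >= 1 row allowed
as_index_matrix <- function(m) {
  if (inherits(m, "method_index_matrix")) return(m)
  if (is.data.frame(m) || is.matrix(m)) {
    if (is.data.frame(m) && "fm_id" %in% names(m)) {
      rn <- as.character(m$fm_id); m <- as.matrix(m[setdiff(names(m), "fm_id")])
      rownames(m) <- rn
    }
    m <- as.matrix(m)
    if (any(m < -1e-9 | m > 1 + 1e-9)) {
      fr_stop("range", "method indices must lie in [0, 1]")
    }
    m <- pmin(pmax(m, 0), 1)
    if (is.null(rownames(m))) rownames(m) <- paste0("FM", seq_len(nrow(m)))
    return(m)
  }
  fr_stop("invalid_index_matrix", "expected a matrix of method indices")
}
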