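#' Risk registers
#'
#' A risk register holds the expert-elicited ratings of a set of failure
#' modes on the three FMEA factors — Occurrence (O), Severity (S) and
#' Detection (D). Each rating is either a linguistic label from the matching
#' scale or a TFN literal `"(a,b,c)"`. Ratings are per expert; expert
#' weights are non-negative and sum to one (uniform by default, since the
#' worked example assigned expert weights without publishing them).
#'
#' @param ratings `data.frame` with columns `fm_id`, `expert_id`,
#'   `occurrence`, `severity`, `detection` (character cells: labels or TFN
#'   literals; `NA` allowed for unpublished ratings).
#' @param modes Optional `data.frame` of failure-mode metadata with columns
#'   `fm_id`, `description`, `cause`, `effect`.
#' @param expert_weights Optional named numeric vector of weights keyed by
#'   `expert_id`; defaults to uniform.
#' @return Object of class `"risk_register"`.
#' @export
risk_register <- function(ratings, modes = NULL, expert_weights = NULL) {
  req <- c("fm_id", "expert_id", "occurrence", "severity", "detection")
  if (!is.data.frame(ratings) || !all(req %in% names(ratings))) {
    fr_stop("invalid_register",
            sprintf("ratings must be a data.frame with columns %s",
                    paste(req, collapse = ", ")))
  }
  ratings <- as.data.frame(ratings, stringsAsFactors = FALSE)
  ratings$fm_id <- as.character(ratings$fm_id)
  ratings$expert_id <- as.character(ratings$expert_id)
  if (nrow(ratings) == 0L) {
    fr_stop("invalid_register", "the risk register has no ratings")
  }
  experts <- unique(ratings$expert_id)
  if (is.null(expert_weights)) {
    expert_weights <- setNames(rep(1 / length(experts), length(experts)), experts)
  } else {
    if (!all(experts %in% names(expert_weights)) || any(expert_weights < 0)) {
      fr_stop("invalid_register",
              "expert_weights must cover every expert and be non-negative")
    }
    if (abs(sum(expert_weights) - 1) > 1e-9) {
      fr_stop("invalid_register", "expert weights must sum to 1 (within 1e-9)")
    }
  }
  if (!is.null(modes)) {
    modes <- as.data.frame(modes, stringsAsFactors = FALSE)
    modes$fm_id <- as.character(modes$fm_id)
    if (anyDuplicated(modes$fm_id)) {
      fr_stop("invalid_register", "duplicate fm_id in failure-mode metadata")
    }
  }
  structure(list(ratings = ratings, modes = modes,
                 expert_weights = expert_weights),
            class = "risk_register")
}

#' @export
print.risk_register <- function(x, ...) {
  cat("Risk register:",
      length(unique(x$ratings$fm_id)), "failure modes,",
      length(x$expert_weights), "expert(s)\n")
  invisible(x)
}

#' @rdname risk_register
#' @param x Object to test.
#' @export
is_risk_register <- function(x) inherits(x, "risk_register")

#' Failure-mode identifiers of a register, in first-appearance order
#' @param register A [risk_register()].
#' @export
register_fm_ids <- function(register) unique(register$ratings$fm_id)

#' Read / write a risk register
#'
#' The ratings CSV has header `fm_id,expert_id,occurrence,severity,detection`;
#' an optional metadata CSV has header `fm_id,description,cause,effect`.
#'
#' @param path Ratings CSV path.
#' @param modes_path Optional metadata CSV path.
#' @inheritParams risk_register
#' @return `read_register()`: a [risk_register()].
#' @export
read_register <- function(path, modes_path = NULL, expert_weights = NULL) {
  ratings <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  modes <- if (!is.null(modes_path)) {
    utils::read.csv(modes_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  risk_register(ratings, modes, expert_weights)
}

#' @rdname read_register
#' @param register A [risk_register()].
#' @export
write_register <- function(register, path, modes_path = NULL) {
  utils::write.csv(register$ratings, path, row.names = FALSE)
  if (!is.null(modes_path) && !is.null(register$modes)) {
    utils::write.csv(register$modes, modes_path, row.names = FALSE)
  }
  invisible(path)
}

# resolve one rating cell (label or TFN literal) to a TFN
resolve_rating <- function(cell, scale) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NULL)
  if (grepl("^\\s*\\(", cell)) return(parse_tfn(cell))
  lookup_label(scale, cell)
}

# failure modes whose three factor ratings all resolve; warns about the rest
complete_fm_ids <- function(register, scales = default_scales()) {
  ids <- register_fm_ids(register)
  ok <- vapply(ids, function(id) {
    !inherits(tryCatch(lapply(c("occurrence", "severity", "detection"),
                              function(f) aggregate_experts(register, id, f, scales)),
                       fuzzrisk_error_missing_rating = function(e) e),
              "condition")
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("%d failure mode(s) dropped for missing ratings: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")), call. = FALSE)
  }
  ids[ok]
}

#' Aggregate expert ratings for one failure mode and factor
#'
#' The panel consensus is the expert-weight-weighted componentwise mean of
#' the experts' TFN ratings (the worked example records the average of the
#' experts' comments as the parameter value). Experts with missing ratings
#' for the cell are dropped and the remaining weights renormalised.
#'
#' @param register A [risk_register()].
#' @param fm_id Failure-mode identifier.
#' @param factor One of `"occurrence"`, `"severity"`, `"detection"`.
#' @param scales Scale registry, as from [default_scales()].
#' @return The aggregated [tfn()].
#' @export
aggregate_experts <- function(register, fm_id, factor = c("occurrence", "severity", "detection"),
                              scales = default_scales()) {
  factor <- match.arg(factor)
  rows <- register$ratings[register$ratings$fm_id == fm_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    fr_stop("missing_rating", sprintf("no ratings for failure mode %s", dQuote(fm_id)))
  }
  scale <- scales[[factor]]
  acc <- c(0, 0, 0); wsum <- 0
  for (i in seq_len(nrow(rows))) {
    t <- resolve_rating(rows[[factor]][i], scale)
    if (is.null(t)) next
    w <- register$expert_weights[[rows$expert_id[i]]]
    acc <- acc + w * unclass(t)
    wsum <- wsum + w
  }
  if (wsum == 0) {
    fr_stop("missing_rating",
            sprintf("no %s rating recorded for failure mode %s", factor, dQuote(fm_id)))
  }
  tfn(acc / wsum)
}
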