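#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is an ordered triple `(alpha, beta, gamma)`
#' with `alpha <= beta <= gamma`: `beta` is the modal (most possible) value,
#' `alpha` and `gamma` the pessimistic and optimistic support bounds. Its
#' membership function is the piecewise-linear triangle peaking at `beta`.
#' All fuzzy quantities in this package (linguistic ratings, weights, risk
#' indices) are TFNs.
#'
#' @param alpha Left support bound, or a numeric vector of length 3.
#' @param beta Modal value.
#' @param gamma Right support bound.
#' @param repair How to handle an unordered triple: `"error"` (default)
#'   rejects it; `"sort"` re-sorts the components with a warning. The sort
#'   mode exists for intermediate results of componentwise fuzzy subtraction
#'   (fuzzy VIKOR), where disordered triples arise legitimately.
#' @return An object of class `"tfn"`: a named numeric vector
#'   `c(alpha=, beta=, gamma=)`.
#' @examples
#' tfn(1, 2, 3)
#' tfn(c(5, 6, 7))
#' tfn(3, 1, 2, repair = "sort")
#' @export
tfn <- function(alpha, beta = NULL, gamma = NULL, repair = c("error", "sort")) {
  repair <- match.arg(repair)
  if (is.null(beta) && is.null(gamma)) {
    x <- as.numeric(alpha)
  } else {
    x <- c(as.numeric(alpha), as.numeric(beta), as.numeric(gamma))
  }
  if (length(x) != 3L || anyNA(x) || !all(is.finite(x))) {
    fr_stop("invalid_tfn", "a TFN needs three finite numeric components")
  }
  if (is.unsorted(x)) {
    if (repair == "sort") {
      warning("unordered TFN triple (", paste(x, collapse = ", "),
              ") re-sorted", call. = FALSE)
      x <- sort(x)
    } else {
      fr_stop("invalid_tfn",
              sprintf("TFN components must satisfy alpha <= beta <= gamma, got (%s); use repair = \"sort\" to re-order",
                      paste(x, collapse = ", ")))
    }
  }
  structure(setNames(x, c("alpha", "beta", "gamma")), class = "tfn")
}

#' @rdname tfn
#' @param x Object to test or coerce.
#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' @rdname tfn
#' @param ... Passed on to [tfn()].
#' @export
as_tfn <- function(x, ...) {
  if (is_tfn(x)) return(x)
  if (is.character(x)) return(parse_tfn(x, ...))
  if (is.numeric(x) && length(x) == 1L) return(tfn(x, x, x))
  if (is.numeric(x) && length(x) == 3L) return(tfn(x, ...))
  if (is.list(x) && length(x) == 3L) return(tfn(unlist(x), ...))
  fr_stop("invalid_tfn", "cannot interpret object as a TFN")
}

#' Parse a TFN literal
#'
#' Accepts the string form `"(a,b,c)"` (decimal or integer components,
#' optional whitespace) and the bare form `"a,b,c"`.
#'
#' @param text Character scalar.
#' @inheritParams tfn
#' @return A [tfn()].
#' @export
parse_tfn <- function(text, repair = "error") {
  stopifnot(is.character(text), length(text) == 1L)
  body <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(text))
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) != 3L || anyNA(vals)) {
    fr_stop("invalid_tfn", sprintf("cannot parse TFN literal %s", dQuote(text)))
  }
  tfn(vals, repair = repair)
}

#' @export
format.tfn <- function(x, digits = 6L, ...) {
  sprintf("(%s)", paste(format(unclass(x), digits = digits, trim = TRUE),
                        collapse = ","))
}

#' @export
print.tfn <- function(x, ...) {
  cat("TFN ", format(x, ...), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.tfn <- function(x, ...) format(x, ...)

#' TFN arithmetic
#'
#' Componentwise fuzzy arithmetic on non-negative TFNs: addition
#' `(a,b,c) + (d,e,f) = (a+d, b+e, c+f)`, multiplication
#' `(a,b,c) * (d,e,f) = (ad, be, cf)`, and scaling by a non-negative crisp
#' factor. Multiplication and scaling are restricted to non-negative supports
#' (all rating scales here are non-negative); violations raise a
#' `fuzzrisk_error_negative_support` condition.
#'
#' @param a,b TFNs (or objects coercible via [as_tfn()]).
#' @return A [tfn()].
#' @examples
#' tfn_add(tfn(1, 2, 3), tfn(2, 3, 4))
#' tfn_multiply(tfn(2, 3, 4), tfn(1, 2, 3))
#' tfn_scale(tfn(2, 4, 6), 0.5)
#' @export
tfn_add <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  tfn(unclass(a) + unclass(b))
}

#' @rdname tfn_add
#' @export
tfn_multiply <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  if (any(unclass(a) < 0) || any(unclass(b) < 0)) {
    fr_stop("negative_support",
            "TFN multiplication is defined for non-negative supports only")
  }
  tfn(unclass(a) * unclass(b))
}

#' @rdname tfn_add
#' @param k Non-negative crisp scale factor.
#' @export
tfn_scale <- function(a, k) {
  a <- as_tfn(a)
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k < 0) {
    fr_stop("negative_support", "TFN scaling requires a non-negative factor")
  }
  tfn(unclass(a) * k)
}

#' @export
Ops.tfn <- function(e1, e2) {
  if (.Generic == "+") return(tfn_add(e1, e2))
  if (.Generic == "*") {
    if (is_tfn(e1) && is.numeric(e2) && !is_tfn(e2) && length(e2) == 1L) {
      return(tfn_scale(e1, e2))
    }
    if (is_tfn(e2) && is.numeric(e1) && !is_tfn(e1) && length(e1) == 1L) {
      return(tfn_scale(e2, e1))
    }
    return(tfn_multiply(e1, e2))
  }
  if (.Generic == "==") return(isTRUE(all.equal(unclass(as_tfn(e1)), unclass(as_tfn(e2)))))
  fr_stop("unsupported_op",
          sprintf("operation %s is not defined for TFNs", dQuote(.Generic)))
}

#' Triangle membership function
#'
#' Degree of membership of a crisp value `x` in the TFN `a`: 0 outside the
#' support, rising linearly to 1 at the modal value, falling linearly back
#' to 0. A degenerate leg (`alpha == beta` or `beta == gamma`) evaluates to 1
#' at the shared point.
#'
#' @param a A [tfn()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
tfn_membership <- function(a, x) {
  a <- as_tfn(a)
  al <- a[[1]]; be <- a[[2]]; ga <- a[[3]]
  mu <- numeric(length(x))
  left <- x >= al & x < be
  if (be > al) mu[left] <- (x[left] - al) / (be - al)
  right <- x > be & x <= ga
  if (ga > be) mu[right] <- (ga - x[right]) / (ga - be)
  mu[x == be] <- 1
  mu
}

#' Defuzzification of a TFN
#'
#' Collapses a TFN to a crisp representative value. `centroid_mean` is the
#' centre of area of the triangle, `(alpha + beta + gamma) / 3`.
#' `graded_mean` is the graded-mean integration value
#' `(alpha + 4 beta + gamma) / 6`, which weights the modal value four-fold;
#' `likert_mean` is the same formula under the name used when defuzzifying
#' Likert-style expert triples. The two families coincide exactly when the
#' TFN is symmetric about `beta`.
#'
#' @param a A [tfn()].
#' @param method One of `"centroid_mean"`, `"graded_mean"`, `"likert_mean"`.
#' @return Crisp numeric value, always inside `[alpha, gamma]`.
#' @examples
#' defuzzify(tfn(5, 7, 9), "likert_mean")  # 7
#' defuzzify(tfn(3, 5, 5), "likert_mean")  # 4.666...
#' @export
defuzzify <- function(a, method = c("centroid_mean", "graded_mean", "likert_mean")) {
  a <- as_tfn(a)
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("centroid_mean", "graded_mean", "likert_mean")) {
    fr_stop("unknown_method",
            sprintf("unknown defuzzification method %s", dQuote(method)))
  }
  method <- match.arg(method)
  switch(method,
         centroid_mean = sum(unclass(a)) / 3,
         graded_mean = ,
         likert_mean = (a[[1]] + 4 * a[[2]] + a[[3]]) / 6)
}

#' Total order on TFNs
#'
#' Compares two TFNs by defuzzified value; exact ties are broken by the
#' modal value `beta`, then `alpha`, then `gamma`. This realises "fuzzy max"
#' and "fuzzy min" operations needed by the rankers.
#'
#' @param a,b TFNs.
#' @inheritParams defuzzify
#' @return `-1L` if `a < b`, `0L` if equal, `1L` if `a > b`.
#' @export
tfn_compare <- function(a, b, method = "centroid_mean") {
  a <- as_tfn(a); b <- as_tfn(b)
  keys_a <- c(defuzzify(a, method), a[[2]], a[[1]], a[[3]])
  keys_b <- c(defuzzify(b, method), b[[2]], b[[1]], b[[3]])
  for (i in seq_along(keys_a)) {
    if (keys_a[i] < keys_b[i]) return(-1L)
    if (keys_a[i] > keys_b[i]) return(1L)
  }
  0L
}

#' @rdname tfn_compare
#' @param xs List of TFNs.
#' @export
tfn_max <- function(xs, method = "centroid_mean") {
  best <- as_tfn(xs[[1]])
  for (x in xs[-1]) if (tfn_compare(as_tfn(x), best, method) > 0L) best <- as_tfn(x)
  best
}

#' @rdname tfn_compare
#' @export
tfn_min <- function(xs, method = "centroid_mean") {
  worst <- as_tfn(xs[[1]])
  for (x in xs[-1]) if (tfn_compare(as_tfn(x), worst, method) < 0L) worst <- as_tfn(x)
  worst
}

# --- internal helpers --------------------------------------------------------

# stack a list of TFNs into an n x 3 matrix
tfn_mat <- function(xs) {
  m <- do.call(rbind, lapply(xs, function(x) unclass(as_tfn(x))))
  colnames(m) <- c("alpha", "beta", "gamma")
  m
}

# classed error helper; every package error carries class fuzzrisk_error_<what>
fr_stop <- function(what, msg) {
  stop(structure(class = c(paste0("fuzzrisk_error_", what),
                           "fuzzrisk_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
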