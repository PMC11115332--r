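#' Fuzzy variables for Mamdani inference
#'
#' A fuzzy variable couples a linguistic scale (its term set) with a closed
#' universe of discourse and a sampling grid. Every term's TFN support must
#' lie inside the universe; the grid needs at least 100 points for the
#' discrete centroid to be meaningful.
#'
#' @param name Variable name (matched against rule antecedents).
#' @param scale A [linguistic_scale()] providing the terms.
#' @param universe Length-2 numeric, `c(min, max)`.
#' @param resolution Number of grid points (>= 100).
#' @return Object of class `"fuzzy_variable"`.
#' @export
fuzzy_variable <- function(name, scale, universe, resolution = 1001L) {
  stopifnot(inherits(scale, "linguistic_scale"),
            is.numeric(universe), length(universe) == 2L,
            universe[1] < universe[2])
  if (resolution < 100L) {
    fr_stop("invalid_variable", "grid resolution must be at least 100 points")
  }
  for (t in scale$tfns) {
    if (t[[1]] < universe[1] - 1e-12 || t[[3]] > universe[2] + 1e-12) {
      fr_stop("invalid_variable",
              sprintf("term support %s of variable %s exceeds universe [%g, %g]",
                      format(t), dQuote(name), universe[1], universe[2]))
    }
  }
  structure(list(name = name, scale = scale, universe = universe,
                 resolution = as.integer(resolution)),
            class = "fuzzy_variable")
}

#' Fuzzify a crisp value
#'
#' Evaluates every term's membership function of a fuzzy variable at `x`.
#'
#' @param var A [fuzzy_variable()].
#' @param x Crisp value inside the variable's universe.
#' @return Named numeric vector of degrees in `[0, 1]`, one per term.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "fuzzy_variable"))
  if (x < var$universe[1] - 1e-12 || x > var$universe[2] + 1e-12) {
    fr_stop("out_of_universe",
            sprintf("value %g outside universe [%g, %g] of variable %s",
                    x, var$universe[1], var$universe[2], dQuote(var$name)))
  }
  setNames(vapply(var$scale$tfns, tfn_membership, numeric(1), x = x),
           var$scale$labels)
}

#' Fuzzy if-then rules and rule bases
#'
#' A rule maps term labels of the input variables to a term of the output
#' variable; the antecedent degrees are combined with `AND` (min) or `OR`
#' (max). A rule base is a validated list of rules over a fixed set of
#' variables: every referenced label must exist, and two rules may not share
#' the same antecedent set.
#'
#' @param antecedents Named character vector, variable name -> term label.
#' @param consequent Output term label.
#' @param op `"AND"` or `"OR"`.
#' @return `fuzzy_rule()`: object of class `"fuzzy_rule"`.
#' @export
fuzzy_rule <- function(antecedents, consequent, op = c("AND", "OR")) {
  op <- match.arg(op)
  stopifnot(is.character(antecedents), !is.null(names(antecedents)),
            all(nzchar(names(antecedents))),
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedents = antecedents, consequent = consequent, op = op),
            class = "fuzzy_rule")
}

#' @rdname fuzzy_rule
#' @param rules List of [fuzzy_rule()]s.
#' @param input_vars Named list of input [fuzzy_variable()]s.
#' @param output_var Output [fuzzy_variable()].
#' @return `rule_base()`: object of class `"rule_base"`.
#' @export
rule_base <- function(rules, input_vars, output_var) {
  stopifnot(length(rules) >= 1L, inherits(output_var, "fuzzy_variable"))
  keys <- character(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    stopifnot(inherits(r, "fuzzy_rule"))
    for (vn in names(r$antecedents)) {
      if (!vn %in% names(input_vars)) {
        fr_stop("invalid_rule", sprintf("rule references unknown variable %s", dQuote(vn)))
      }
      label_index(input_vars[[vn]]$scale, r$antecedents[[vn]])  # errors if absent
    }
    label_index(output_var$scale, r$consequent)
    keys[i] <- paste(sort(paste(names(r$antecedents), tolower(r$antecedents),
                                sep = "=")), collapse = "|")
  }
  if (anyDuplicated(keys)) {
    fr_stop("invalid_rule", "duplicate antecedent sets in rule base")
  }
  n_combo <- prod(vapply(input_vars, function(v) length(v$scale$labels), numeric(1)))
  structure(list(rules = rules, input_vars = input_vars,
                 output_var = output_var,
                 coverage = length(rules) >= n_combo),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("Mamdani rule base: %d rules over {%s} -> %s%s\n",
              length(x$rules), paste(names(x$input_vars), collapse = ", "),
              x$output_var$name,
              if (x$coverage) " (complete coverage)" else ""))
  invisible(x)
}

#' Default complete rule base
#'
#' The published study does not include its rule base, so this constructor
#' provides a deterministic, complete and monotone one: for every
#' combination of input terms, the consequent is the output category whose
#' ordinal position is the rounded mean of the three antecedent ordinal
#' positions, each rescaled to `[0, 1]` within its own ladder. All three
#' factors therefore carry equal importance, extremes are preserved (all
#' inputs at the top category map to the top output category) and raising
#' any antecedent can only raise the consequent.
#'
#' @param input_vars Named list of input [fuzzy_variable()]s.
#' @param output_var Output [fuzzy_variable()].
#' @param op Antecedent connective, default `"AND"`.
#' @return A [rule_base()].
#' @export
default_rule_base <- function(input_vars, output_var, op = "AND") {
  n_out <- length(output_var$scale$labels)
  sizes <- vapply(input_vars, function(v) length(v$scale$labels), integer(1))
  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  rules <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- as.integer(grid[i, ])
    pos <- mapply(function(k, n) if (n > 1L) (k - 1) / (n - 1) else 0.5,
                  idx, sizes)
    out_idx <- 1L + as.integer(round(mean(pos) * (n_out - 1)))
    ants <- setNames(mapply(function(v, k) v$scale$labels[k],
                            input_vars, idx), names(input_vars))
    rules[[i]] <- fuzzy_rule(ants, output_var$scale$labels[out_idx], op)
  }
  rule_base(rules, input_vars, output_var)
}

#' Mamdani max-min inference
#'
#' Classic Mamdani pipeline: fuzzify the crisp inputs, evaluate each rule's
#' firing strength (min across antecedent degrees for AND, max for OR), clip
#' the consequent term's membership at the firing strength (min implication),
#' aggregate all clipped sets by pointwise max over the output grid, and
#' defuzzify by the discrete centroid `sum(x * mu) / sum(mu)`.
#'
#' TFN inputs are accepted and fuzzified at their defuzzified value, because
#' expert ratings are aggregated before inference.
#'
#' @param rb A [rule_base()].
#' @param inputs Named list/vector of crisp values (or TFNs), one per input
#'   variable.
#' @param resolution Optional override of the output grid resolution.
#' @return Crisp output value within the output universe.
#' @export
mamdani_infer <- function(rb, inputs, resolution = NULL) {
  stopifnot(inherits(rb, "rule_base"))
  vars <- rb$input_vars
  missing <- setdiff(names(vars), names(inputs))
  if (length(missing)) {
    fr_stop("missing_input",
            sprintf("no input supplied for variable(s): %s",
                    paste(missing, collapse = ", ")))
  }
  degrees <- lapply(names(vars), function(vn) {
    x <- inputs[[vn]]
    if (is_tfn(x)) x <- defuzzify(x)
    fuzzify(vars[[vn]], as.numeric(x))
  })
  names(degrees) <- names(vars)

  out <- rb$output_var
  n <- if (is.null(resolution)) out$resolution else as.integer(resolution)
  xs <- seq(out$universe[1], out$universe[2], length.out = n)
  agg <- numeric(n)
  fired <- FALSE
  for (r in rb$rules) {
    ds <- mapply(function(vn, lbl) degrees[[vn]][[lbl]],
                 names(r$antecedents), r$antecedents)
    strength <- if (r$op == "AND") min(ds) else max(ds)
    if (strength <= 0) next
    fired <- TRUE
    mu <- pmin(tfn_membership(lookup_label(out$scale, r$consequent), xs), strength)
    agg <- pmax(agg, mu)
  }
  if (!fired) {
    fr_stop("no_rule_fired",
            "no rule fired for these inputs; the rule base does not cover them")
  }
  sum(xs * agg) / sum(agg)
}

#' Mamdani fuzzy RPN over a register
#'
#' Runs the full inference pipeline for every failure mode of a register:
#' expert ratings are aggregated to one TFN per factor, fuzzified on the
#' `[1, 10]` input universes, pushed through the rule base, and defuzzified
#' on the `[0, 1]` output universe. Failure modes are ranked riskiest-first.
#'
#' @param register A [risk_register()].
#' @param scales Scale registry.
#' @param rb Optional [rule_base()]; [default_rule_base()] over the given
#'   scales when `NULL`.
#' @param resolution Output grid resolution.
#' @return `data.frame` with `fm_id`, `crisp`, `label`, `rank`.
#' @export
mamdani_frpn <- function(register, scales = default_scales(), rb = NULL,
                         resolution = 1001L) {
  vars <- mamdani_variables(scales, resolution)
  if (is.null(rb)) rb <- default_rule_base(vars$inputs, vars$output)
  ids <- complete_fm_ids(register, scales)
  crisp <- vapply(ids, function(id) {
    mamdani_infer(rb, list(
      occurrence = aggregate_experts(register, id, "occurrence", scales),
      severity = aggregate_experts(register, id, "severity", scales),
      detection = aggregate_experts(register, id, "detection", scales)))
  }, numeric(1))
  out <- data.frame(fm_id = ids, crisp = unname(crisp),
                    label = vapply(unname(crisp), function(v)
                      nearest_output_label(scales$rpn_output, v), character(1)),
                    rank = competition_rank(unname(crisp)),
                    stringsAsFactors = FALSE)
  class(out) <- c("frpn_ranking", "data.frame")
  out
}

#' @rdname mamdani_frpn
#' @export
mamdani_variables <- function(scales = default_scales(), resolution = 1001L) {
  list(inputs = list(
         occurrence = fuzzy_variable("occurrence", scales$occurrence,
                                     c(1, 10), resolution),
         severity = fuzzy_variable("severity", scales$severity,
                                   c(1, 10), resolution),
         detection = fuzzy_variable("detection", scales$detection,
                                    c(1, 10), resolution)),
       output = fuzzy_variable("rpn", scales$rpn_output, c(0, 1), resolution))
}

#' Read / write a rule base as JSON
#'
#' Format: `{"rules": [{"if": {"occurrence": "High", ...}, "op": "AND",
#' "then": "VH"}, ...]}`.
#'
#' @param path JSON file path.
#' @inheritParams rule_base
#' @export
read_rule_base <- function(path, input_vars, output_var) {
  raw <- jsonlite::read_json(path)
  rules <- lapply(raw$rules, function(r) {
    fuzzy_rule(unlist(r[["if"]]), r[["then"]],
               if (is.null(r$op)) "AND" else r$op)
  })
  rule_base(rules, input_vars, output_var)
}

#' @rdname read_rule_base
#' @param rb A [rule_base()].
#' @export
write_rule_base <- function(rb, path) {
  obj <- list(rules = lapply(rb$rules, function(r) {
    list(`if` = as.list(r$antecedents), op = r$op, then = r$consequent)
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
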