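#' Linguistic rating scales
#'
#' A linguistic scale maps ordered category labels (e.g. "Moderate") to
#' triangular fuzzy numbers. FMEA elicitation uses four scales: Occurrence
#' and Severity on nine levels over `[1, 10]`, Detection on a coarser ladder
#' over `[1, 10]` (higher = harder to detect), and a five-level output scale
#' for the fuzzy risk priority number on `[0, 1]`.
#'
#' Entries are kept ordered by non-decreasing defuzzified value; the
#' constructor re-orders stably if needed.
#'
#' @param name Scale name, e.g. `"severity"`.
#' @param labels Character vector of unique category labels.
#' @param tfns List of TFNs (or TFN literals), one per label.
#' @param descriptions Optional character vector of category descriptions.
#' @return Object of class `"linguistic_scale"`.
#' @export
linguistic_scale <- function(name, labels, tfns, descriptions = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(labels), length(labels) >= 1L,
            length(tfns) == length(labels))
  if (anyDuplicated(tolower(trimws(labels)))) {
    fr_stop("invalid_scale",
            sprintf("duplicate labels in scale %s", dQuote(name)))
  }
  tfns <- lapply(tfns, as_tfn)
  vals <- vapply(tfns, defuzzify, numeric(1))
  ord <- order(vals)          # stable; enforces the non-decreasing invariant
  s <- list(name = name,
            labels = labels[ord],
            tfns = tfns[ord],
            descriptions = if (!is.null(descriptions)) descriptions[ord])
  structure(s, class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("Linguistic scale:", x$name, sprintf("(%d levels)\n", length(x$labels)))
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-24s %s\n", x$labels[i], format(x$tfns[[i]])))
  }
  invisible(x)
}

#' Look up a label in a linguistic scale
#'
#' Matching is case-insensitive and whitespace-tolerant, because elicited
#' registers are often typed by hand. An unknown label raises a
#' `fuzzrisk_error_unknown_label` condition listing the valid labels.
#'
#' @param scale A [linguistic_scale()].
#' @param label Character label.
#' @return The label's [tfn()].
#' @examples
#' lookup_label(default_scales()$severity, "Moderate")
#' @export
lookup_label <- function(scale, label) {
  stopifnot(inherits(scale, "linguistic_scale"))
  i <- match(tolower(trimws(label)), tolower(trimws(scale$labels)))
  if (is.na(i)) {
    fr_stop("unknown_label",
            sprintf("label %s not in scale %s; valid labels: %s",
                    dQuote(label), dQuote(scale$name),
                    paste(scale$labels, collapse = ", ")))
  }
  scale$tfns[[i]]
}

# ordinal position of a label within a scale (1 = lowest)
label_index <- function(scale, label) {
  i <- match(tolower(trimws(label)), tolower(trimws(scale$labels)))
  if (is.na(i)) {
    fr_stop("unknown_label",
            sprintf("label %s not in scale %s", dQuote(label), dQuote(scale$name)))
  }
  i
}

#' Default FMEA rating scales
#'
#' The four scales used by the transplant-risk worked example. Severity runs
#' over nine levels from "Very minor" `(1,2,3)` up to "Dangerous without
#' warning" `(9,10,10)`. The published occurrence table repeats the severity
#' wording verbatim (a typesetting slip), so the default occurrence scale
#' keeps the same nine TFNs but carries conventional occurrence labels from
#' "Remote" (failure unlikely) up to "Very High" (failure almost inevitable).
#' Detection is graded by how hard a defect is to spot, from "Very High"
#' chance of discovery `(1,1,3)` to "Remote" / "Very Low" chance `(8,10,10)`
#' — larger values mean poorer detectability, i.e. more risk. The output
#' scale places five categories VL..VH on `[0, 1]`.
#'
#' All scales are overridable: supply your own via [read_scales()] or
#' [linguistic_scale()].
#'
#' @return Named list of [linguistic_scale()] objects:
#'   `occurrence`, `severity`, `detection`, `rpn_output`.
#' @export
default_scales <- function() {
  sev_tfns <- list(tfn(1, 2, 3), tfn(2, 3, 4), tfn(3, 4, 5), tfn(4, 5, 6),
                   tfn(5, 6, 7), tfn(6, 7, 8), tfn(7, 8, 9), tfn(8, 9, 10),
                   tfn(9, 10, 10))
  severity <- linguistic_scale(
    "severity",
    c("Very minor", "minor", "very Low", "Low", "Moderate", "high",
      "very high", "Dangerous with warnings", "Dangerous without warning"),
    sev_tfns,
    c("Natural function with minor effects",
      "Normal performance with slight reduction",
      "Normal performance with reduced capability",
      "Abnormal performance with little impact",
      "Abnormal and repairable performance",
      "Abnormal performance",
      "Destructive changes",
      "Extremely high event intensity with alert",
      "Extreme intensity without warning"))
  occurrence <- linguistic_scale(
    "occurrence",
    c("Remote", "Very Remote", "Very Low", "Low", "Moderately Low",
      "Moderate", "Moderately High", "High", "Very High"),
    sev_tfns,
    c("Failure unlikely", "Rare failures", "Isolated failures",
      "Relatively few failures", "Occasional failures", "Moderately frequent",
      "Frequent failures", "Repeated failures", "Failure almost inevitable"))
  detection <- linguistic_scale(
    "detection",
    c("Very High", "High", "Moderate", "Low", "Very Low", "Remote"),
    list(tfn(1, 1, 3), tfn(1, 3, 5), tfn(3, 5, 7), tfn(5, 7, 9),
         tfn(8, 10, 10), tfn(8, 10, 10)),
    c("Chance of discovery is very high", "High chance of discovery",
      "Probability so-so", "Low chance by experiment",
      "Very low chance of discovery", "No chance to discover"))
  rpn_output <- linguistic_scale(
    "rpn_output",
    c("VL", "L", "M", "H", "VH"),
    list(tfn(0, 0, 0.25), tfn(0, 0.25, 0.5), tfn(0.25, 0.5, 0.75),
         tfn(0.5, 0.75, 1), tfn(0.75, 1, 1)),
    c("Very Low", "Low", "Moderate", "High", "Very High"))
  list(occurrence = occurrence, severity = severity,
       detection = detection, rpn_output = rpn_output)
}

#' Read / write a scale registry
#'
#' JSON format: an object keyed by scale name, each value an array of
#' `{"label": "...", "tfn": [a, b, c]}` entries (optionally with a
#' `"description"` field).
#'
#' @param path File path.
#' @return `read_scales()`: named list of [linguistic_scale()]s.
#' @export
read_scales <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(names(raw), function(nm) {
    entries <- raw[[nm]]
    linguistic_scale(
      nm,
      vapply(entries, function(e) e$label, character(1)),
      lapply(entries, function(e) as_tfn(unlist(e$tfn))),
      descriptions = vapply(entries, function(e)
        if (is.null(e$description)) NA_character_ else e$description,
        character(1)))
  })
  setNames(out, names(raw))
}

#' @rdname read_scales
#' @param scales Named list of [linguistic_scale()]s.
#' @export
write_scales <- function(scales, path) {
  obj <- lapply(scales, function(s) {
    lapply(seq_along(s$labels), function(i) {
      e <- list(label = s$labels[i], tfn = as.numeric(unclass(s$tfns[[i]])))
      if (!is.null(s$descriptions) && !is.na(s$descriptions[i])) {
        e$description <- s$descriptions[i]
      }
      e
    })
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
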