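#' Packaged worked-example fixtures
#'
#' The package ships the printed tables of its transplant-risk worked
#' example as plain-text fixtures:
#'
#' * `"table6"` — the failure-mode register: linguistic O/S/D grades for the
#'   ten failure modes whose ratings were published, descriptions for all
#'   twenty, and the published fuzzy-FMEA output labels/crisp values as
#'   reference columns. Unpublished ratings are left missing rather than
#'   invented.
#' * `"table7"` — the per-method benefit index matrix (ARAS `K`, VIKOR
#'   `1 - Q`, WASPAS `K'`) for all twenty failure modes, with the published
#'   per-method ranks attached as `attr(, "ranks")`.
#' * `"table8_expected"` — the published hybrid results (`psi_plus`,
#'   `psi_minus`, `uui`, rank), with the published column sums as
#'   `attr(, "sums")`.
#' * `"table11"` — the validation panel's (optimistic, neutral, pessimistic)
#'   Likert triples and their published defuzzified values.
#' * `"scales"` — the default linguistic-scale registry (same content as
#'   [default_scales()]).
#' * `"likert_scale"` — the odd-point Likert mapping used by the validation
#'   panel.
#'
#' @param name Fixture name.
#' @return See above; an unknown name raises
#'   `fuzzrisk_error_unknown_fixture`.
#' @examples
#' t7 <- load_fixture("table7")
#' hybrid_rank(t7)
#' @export
load_fixture <- function(name = c("table6", "table7", "table8_expected",
                                  "table11", "scales", "likert_scale")) {
  if (!name[1] %in% c("table6", "table7", "table8_expected", "table11",
                      "scales", "likert_scale")) {
    fr_stop("unknown_fixture", sprintf("unknown fixture %s", dQuote(name[1])))
  }
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "fuzzrisk",
                                  mustWork = TRUE)
  switch(name,
    table6 = read_register(path("table6_ratings.csv"),
                           path("table6_modes.csv")),
    table7 = {
      df <- utils::read.csv(path("table7_indices.csv"), stringsAsFactors = FALSE)
      m <- method_index_matrix(df[, c("aras_k", "vikor_1mq", "waspas_k")],
                               fm_ids = df$fm_id)
      attr(m, "ranks") <- data.frame(
        fm_id = df$fm_id, aras = df$aras_rank, vikor = df$vikor_rank,
        waspas = df$waspas_rank, stringsAsFactors = FALSE)
      m
    },
    table8_expected = {
      df <- utils::read.csv(path("table8_expected.csv"), stringsAsFactors = FALSE)
      sums <- df[df$fm_id == "SUM", ]
      df <- df[df$fm_id != "SUM", ]
      attr(df, "sums") <- c(psi_plus = sums$psi_plus, psi_minus = sums$psi_minus)
      df
    },
    table11 = {
      df <- utils::read.csv(path("table11_expert_panel.csv"),
                            stringsAsFactors = FALSE)
      bad <- with(df, optimistic > neutral | neutral > pessimistic)
      if (any(bad)) {
        warning("non-monotone Likert triple(s) stored as printed: rows ",
                paste(which(bad), collapse = ", "), call. = FALSE)
      }
      df
    },
    scales = default_scales(),
    likert_scale = data.frame(
      score = c(1L, 3L, 5L, 7L, 9L),
      meaning = c("strongly disagree", "disagree", "neutral",
                  "agree", "strongly agree"),
      stringsAsFactors = FALSE))
}

#' Defuzzify an expert validation panel
#'
#' Turns each (optimistic, neutral, pessimistic) Likert triple into a crisp
#' agreement score with the weighted mean `(alpha + 4 beta + gamma) / 6`
#' (the modal, neutral answer counts four-fold). Rounding is left to the
#' caller; displayed values in the worked example are rounded to 2 decimals.
#'
#' @param triples `data.frame` with columns `optimistic`, `neutral`,
#'   `pessimistic` (plus any identifier columns, which are preserved).
#' @return The input with a `defuzzified` column (re)computed.
#' @export
defuzzify_expert_panel <- function(triples) {
  stopifnot(all(c("optimistic", "neutral", "pessimistic") %in% names(triples)))
  triples$defuzzified <- vapply(seq_len(nrow(triples)), function(i) {
    defuzzify(tfn(triples$optimistic[i], triples$neutral[i],
                  triples$pessimistic[i]),
              "likert_mean")
  }, numeric(1))
  triples
}

#' Tally failure causes
#'
#' Counts how many failure modes share each recorded cause — the input to a
#' Pareto-style "vital few" reading of a register.
#'
#' @param register A [risk_register()] with mode metadata.
#' @return `data.frame` with `cause` and `n`, most frequent first.
#' @export
cause_tally <- function(register) {
  stopifnot(is_risk_register(register), !is.null(register$modes))
  causes <- register$modes$cause
  causes <- causes[!is.na(causes) & nzchar(causes)]
  tab <- sort(table(causes), decreasing = TRUE)
  data.frame(cause = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
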