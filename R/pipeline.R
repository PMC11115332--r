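#' Pipeline configuration
#'
#' Bundles the tunable settings of the end-to-end ranking pipeline. The
#' defaults are the worked example's stated settings: centroid
#' defuzzification, VIKOR trade-off `v = 0.5`, WASPAS blend
#' `lambda = 0.5`, equal benefit criteria, 1001-point inference grid.
#'
#' @param scales Scale registry (or path to a scales JSON).
#' @param rules Optional [rule_base()] (or path to a rule-base JSON); the
#'   deterministic [default_rule_base()] when `NULL`.
#' @param defuzz Defuzzification method.
#' @param vikor_v VIKOR trade-off weight.
#' @param waspas_lambda WASPAS blend weight or `"auto"`.
#' @param weights Criterion weights (default equal crisp 1/3).
#' @param directions Criterion directions (default all `"benefit"`).
#' @param grid_resolution Mamdani output grid resolution.
#' @param use_mamdani Score F-RPN by Mamdani inference (`TRUE`) in addition
#'   to the multiplicative product.
#' @param precision Decimal places used when rendering reports.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scales = default_scales(), rules = NULL,
                            defuzz = "centroid_mean", vikor_v = 0.5,
                            waspas_lambda = 0.5, weights = NULL,
                            directions = rep("benefit", 3L),
                            grid_resolution = 1001L, use_mamdani = FALSE,
                            precision = 6L) {
  if (is.character(scales)) scales <- read_scales(scales)
  structure(list(scales = scales, rules = rules, defuzz = defuzz,
                 vikor_v = vikor_v, waspas_lambda = waspas_lambda,
                 weights = weights, directions = directions,
                 grid_resolution = as.integer(grid_resolution),
                 use_mamdani = isTRUE(use_mamdani),
                 precision = as.integer(precision)),
            class = "pipeline_config")
}

#' Run the full risk-ranking pipeline
#'
#' Executes the complete analysis on a risk register: expert aggregation,
#' multiplicative fuzzy RPN (optionally Mamdani inference), the three fuzzy
#' MCDM rankers, and the hybrid ultimate-utility aggregation. The result is
#' one row per failure mode carrying every method's index and rank.
#'
#' @param register A [risk_register()] or path to a ratings CSV.
#' @param config A [pipeline_config()].
#' @return Object of class `"run_report"`: `$table` (per-failure-mode
#'   results), `$hybrid` (the full `"hybrid_result"`), `$vikor`
#'   (conditions and compromise set), `$config`.
#' @export
run_pipeline <- function(register, config = pipeline_config()) {
  if (is.character(register)) register <- read_register(register)
  stopifnot(is_risk_register(register), inherits(config, "pipeline_config"))
  scales <- config$scales

  frpn <- frpn_rank(register, scales, defuzz = config$defuzz)
  mam <- if (config$use_mamdani) {
    mamdani_frpn(register, scales, config$rules, config$grid_resolution)
  }
  m <- build_matrix_from_register(register, scales, config$weights,
                                  config$directions)
  aras <- aras_rank(m, config$defuzz)
  vikor <- vikor_rank(m, config$vikor_v, config$defuzz)
  waspas <- waspas_rank(m, config$waspas_lambda, config$defuzz)
  idx <- to_benefit_indices(aras, vikor, waspas)
  hybrid <- hybrid_rank(idx)

  ids <- aras$table$fm_id
  tab <- data.frame(
    fm_id = ids,
    frpn_crisp = frpn$norm[match(ids, frpn$fm_id)],
    frpn_label = frpn$label[match(ids, frpn$fm_id)],
    frpn_rank = frpn$rank[match(ids, frpn$fm_id)],
    aras_k = aras$table$K,
    aras_rank = aras$table$rank,
    vikor_q = vikor$table$Q[match(ids, vikor$table$fm_id)],
    vikor_1mq = vikor$table$one_minus_Q[match(ids, vikor$table$fm_id)],
    vikor_rank = vikor$table$rank_Q[match(ids, vikor$table$fm_id)],
    waspas_k = waspas$table$K[match(ids, waspas$table$fm_id)],
    waspas_rank = waspas$table$rank[match(ids, waspas$table$fm_id)],
    psi_plus = hybrid$table$psi_plus[match(ids, hybrid$table$fm_id)],
    psi_minus = hybrid$table$psi_minus[match(ids, hybrid$table$fm_id)],
    uui = hybrid$table$uui[match(ids, hybrid$table$fm_id)],
    hybrid_rank = hybrid$table$rank[match(ids, hybrid$table$fm_id)],
    stringsAsFactors = FALSE)
  if (!is.null(mam)) {
    tab$mamdani_crisp <- mam$crisp[match(ids, mam$fm_id)]
    tab$mamdani_rank <- mam$rank[match(ids, mam$fm_id)]
  }
  structure(list(table = tab, hybrid = hybrid,
                 vikor = vikor[c("condition1", "condition2", "compromise_set")],
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Risk-ranking pipeline report",
      sprintf("(%d failure modes)\n", nrow(x$table)))
  cols <- c("fm_id", "frpn_rank", "aras_rank", "vikor_rank", "waspas_rank",
            "uui", "hybrid_rank")
  print(x$table[order(x$table$hybrid_rank, x$table$fm_id), cols],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render a pipeline report to a file
#'
#' Writes the per-failure-mode table as CSV, JSON (with a schema version
#' field; round-trips losslessly) or markdown (which appends a per-method
#' top-5 summary). Numeric cells are rounded to the configured precision.
#'
#' @param report A `"run_report"`.
#' @param path Output file path.
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @param precision Decimal places (default: the report's configuration).
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("csv", "json", "markdown"),
                          precision = NULL) {
  stopifnot(inherits(report, "run_report"))
  if (!is.character(format) || !format[1] %in% c("csv", "json", "markdown")) {
    fr_stop("unsupported_format",
            sprintf("unsupported report format %s", dQuote(format[1])))
  }
  format <- match.arg(format)
  if (is.null(precision)) precision <- report$config$precision
  tab <- report$table
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "fm_id"
  tab[num] <- lapply(tab[num], round, digits = precision)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(list(schema_version = "1.0", results = tab),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    lines <- c("# Risk-ranking report", "",
               paste0("| ", paste(names(tab), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
               vapply(seq_len(nrow(tab)), function(i)
                 paste0("| ", paste(unlist(tab[i, ]), collapse = " | "), " |"),
                 character(1)),
               "", "## Top 5 per method", "")
    for (mcol in grep("_rank$", names(tab), value = TRUE)) {
      ord <- tab$fm_id[order(tab[[mcol]], tab$fm_id)]
      lines <- c(lines, sprintf("- **%s**: %s", sub("_rank$", "", mcol),
                                paste(utils::head(ord, 5), collapse = " > ")))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path JSON file written by [render_report()].
#' @return The per-failure-mode `data.frame`.
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$results
}
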