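scales <- default_scales()
vars <- mamdani_variables(scales, 1001L)

test_that("fuzzification evaluates every term's membership", {
  d <- fuzzify(vars$inputs$severity, 6)
  expect_equal(d[["Moderate"]], 1)        # (5,6,7) peaks at 6
  expect_equal(d[["Low"]], 0)             # (4,5,6) support edge
  expect_equal(sum(d > 0), 1L)
  # midway between adjacent unit-spaced modal points: both degrees 0.5
  d2 <- fuzzify(vars$inputs$severity, 6.5)
  expect_equal(d2[["Moderate"]], 0.5)
  expect_equal(d2[["high"]], 0.5)
  expect_error(fuzzify(vars$inputs$severity, 11),
               class = "fuzzrisk_error_out_of_universe")
})

test_that("rule bases validate labels and reject duplicate antecedents", {
  r <- fuzzy_rule(c(occurrence = "High", severity = "Moderate",
                    detection = "Low"), "H")
  rb <- rule_base(list(r), vars$inputs, vars$output)
  expect_false(rb$coverage)
  expect_error(
    rule_base(list(fuzzy_rule(c(occurrence = "Nope"), "H")),
              vars$inputs, vars$output),
    class = "fuzzrisk_error_unknown_label")
  expect_error(rule_base(list(r, r), vars$inputs, vars$output),
               class = "fuzzrisk_error_invalid_rule")
  expect_error(fuzzy_variable("x", scales$severity, c(1, 10), 50),
               class = "fuzzrisk_error_invalid_variable")
})

test_that("the default rule base is complete and preserves extremes", {
  rb <- default_rule_base(vars$inputs, vars$output)
  n_comb <- prod(vapply(vars$inputs, function(v) length(v$scale$labels),
                        numeric(1)))
  expect_length(rb$rules, n_comb)
  expect_true(rb$coverage)
  key <- function(ants) {
    for (r in rb$rules) {
      if (identical(r$antecedents[names(ants)], ants)) return(r$consequent)
    }
    NA_character_
  }
  top <- c(occurrence = "Very High",
           severity = "Dangerous without warning", detection = "Remote")
  expect_equal(key(top), "VH")
  bottom <- c(occurrence = "Remote", severity = "Very minor",
              detection = "Very High")
  expect_equal(key(bottom), "VL")
  mid <- c(occurrence = "Moderately Low", severity = "Moderate",
           detection = "Moderate")   # all mid-ladder -> middle output
  expect_equal(key(mid), "M")
})

test_that("single fired rule yields the consequent's centroid", {
  # severity 6 / occurrence mid / detection mid fire exactly one rule at 1
  rb <- default_rule_base(vars$inputs, vars$output)
  cons_of <- function(o, s, d) {
    for (r in rb$rules) {
      if (identical(unname(r$antecedents[c("occurrence", "severity", "detection")]),
                    c(o, s, d))) return(r$consequent)
    }
  }
  out <- mamdani_infer(rb, list(occurrence = 6, severity = 6, detection = 5))
  lbl <- cons_of("Moderately Low", "Moderate", "Moderate")
  expected <- defuzzify(lookup_label(scales$rpn_output, lbl), "centroid_mean")
  expect_equal(out, expected, tolerance = 2e-3)
})

test_that("symmetric clipped consequents defuzzify to the midpoint", {
  # toy system: one input on [0,1] with two complementary terms, two output
  # terms mirrored about 0.5; at x = 0.5 both rules fire at strength 0.5
  inp <- fuzzy_variable("x", linguistic_scale("x", c("low", "high"),
                        list(tfn(0, 0, 1), tfn(0, 1, 1))), c(0, 1), 1001L)
  outv <- fuzzy_variable("y", linguistic_scale("y", c("A", "B"),
                         list(tfn(0, 0.25, 0.5), tfn(0.5, 0.75, 1))), c(0, 1), 1001L)
  rb <- rule_base(list(fuzzy_rule(c(x = "low"), "A"),
                       fuzzy_rule(c(x = "high"), "B")), list(x = inp), outv)
  expect_equal(mamdani_infer(rb, list(x = 0.5)), 0.5, tolerance = 1e-9)
})

test_that("uncovered inputs raise a no-rule-fired error", {
  rb <- default_rule_base(vars$inputs, vars$output)
  # occurrence = 1 lies outside every occurrence term's open support
  expect_error(mamdani_infer(rb, list(occurrence = 1, severity = 5, detection = 5)),
               class = "fuzzrisk_error_no_rule_fired")
  expect_error(mamdani_infer(rb, list(severity = 5, detection = 5)),
               class = "fuzzrisk_error_missing_input")
})

test_that("output stays in the universe and converges with the grid", {
  rb <- default_rule_base(vars$inputs, vars$output)
  set.seed(9)
  for (i in 1:10) {
    ins <- list(occurrence = stats::runif(1, 2, 10),
                severity = stats::runif(1, 2, 10),
                detection = stats::runif(1, 1, 10))
    coarse <- mamdani_infer(rb, ins, resolution = 101L)
    fine <- mamdani_infer(rb, ins, resolution = 1001L)
    expect_gte(fine, 0); expect_lte(fine, 1)
    expect_false(is.na(fine))
    expect_lt(abs(fine - coarse), 0.5 * (1 / 100))  # < half a coarse-grid step
  }
})

test_that("default-rule-base inference is monotone in each crisp input", {
  rb <- default_rule_base(vars$inputs, vars$output)
  xs <- seq(2, 10, by = 0.5)
  base <- list(occurrence = 5.5, severity = 5.5, detection = 5.5)
  for (vn in c("occurrence", "severity", "detection")) {
    outs <- vapply(xs, function(x) {
      ins <- base; ins[[vn]] <- x
      mamdani_infer(rb, ins, resolution = 501L)
    }, numeric(1))
    expect_true(all(diff(outs) >= -1e-9))
  }
})

test_that("inference agrees with an independent straightforward oracle", {
  rb <- default_rule_base(vars$inputs, vars$output)
  in_scales <- lapply(vars$inputs, function(v) v$scale)
  set.seed(77)
  for (i in 1:50) {
    ins <- list(occurrence = stats::runif(1, 2, 10),
                severity = stats::runif(1, 2, 10),
                detection = stats::runif(1, 1, 10))
    mine <- mamdani_infer(rb, ins, resolution = 501L)
    ref <- oracle_mamdani(rb$rules, in_scales, scales$rpn_output,
                          ins, c(0, 1), 501L)
    expect_equal(mine, ref, tolerance = 1e-3)
  }
})

test_that("TFN inputs are fuzzified at their defuzzified value", {
  rb <- default_rule_base(vars$inputs, vars$output)
  t <- tfn(5, 6, 7)
  expect_equal(
    mamdani_infer(rb, list(occurrence = t, severity = 6, detection = 5)),
    mamdani_infer(rb, list(occurrence = 6, severity = 6, detection = 5)))
})

test_that("rule-base JSON round-trips", {
  rb <- rule_base(list(
    fuzzy_rule(c(occurrence = "High", severity = "very high",
                 detection = "Low"), "VH"),
    fuzzy_rule(c(occurrence = "Remote", severity = "Very minor",
                 detection = "Very High"), "VL", op = "OR")),
    vars$inputs, vars$output)
  tmp <- tempfile(fileext = ".json")
  write_rule_base(rb, tmp)
  back <- read_rule_base(tmp, vars$inputs, vars$output)
  expect_equal(length(back$rules), 2L)
  expect_equal(back$rules[[1]]$consequent, "VH")
  expect_equal(back$rules[[2]]$op, "OR")
})
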