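scales <- default_scales()

test_that("default scales resolve the worked example's labels", {
  expect_equal(unclass(lookup_label(scales$severity, "Moderate")),
               unclass(tfn(5, 6, 7)))
  expect_equal(unclass(lookup_label(scales$detection, "Low")),
               unclass(tfn(5, 7, 9)))
  expect_equal(unclass(lookup_label(scales$rpn_output, "H")),
               unclass(tfn(0.5, 0.75, 1)))
  expect_equal(unclass(lookup_label(scales$occurrence, "Very High")),
               unclass(tfn(9, 10, 10)))
  # case-insensitive, whitespace-tolerant
  expect_equal(unclass(lookup_label(scales$severity, " moderate ")),
               unclass(tfn(5, 6, 7)))
  err <- tryCatch(lookup_label(scales$severity, "Extreme"), error = identity)
  expect_s3_class(err, "fuzzrisk_error_unknown_label")
  expect_match(conditionMessage(err), "Moderate")  # lists valid labels
})

test_that("scales keep entries ordered by defuzzified value", {
  for (s in scales) {
    v <- vapply(s$tfns, defuzzify, numeric(1))
    expect_true(!is.unsorted(v))
  }
  expect_error(
    linguistic_scale("x", c("a", "A"), list(tfn(1, 2, 3), tfn(2, 3, 4))),
    class = "fuzzrisk_error_invalid_scale")
})

test_that("register construction validates weights and columns", {
  df <- data.frame(fm_id = "FM1", expert_id = "E1", occurrence = "High",
                   severity = "Moderate", detection = "Low")
  reg <- risk_register(df)
  expect_equal(sum(reg$expert_weights), 1)
  expect_error(risk_register(df[, 1:3]), class = "fuzzrisk_error_invalid_register")
  expect_error(risk_register(df, expert_weights = c(E1 = 0.9)),
               class = "fuzzrisk_error_invalid_register")
})

test_that("expert aggregation is the weighted componentwise mean", {
  one <- risk_register(data.frame(
    fm_id = "FM1", expert_id = "E1", occurrence = "(5,6,7)",
    severity = "Moderate", detection = "Low"))
  expect_equal(unclass(aggregate_experts(one, "FM1", "occurrence")),
               unclass(tfn(5, 6, 7)))

  two <- risk_register(data.frame(
    fm_id = "FM1", expert_id = c("E1", "E2"),
    occurrence = c("(4,5,6)", "(6,7,8)"),
    severity = "Moderate", detection = "Low"))
  expect_equal(unclass(aggregate_experts(two, "FM1", "occurrence")),
               unclass(tfn(5, 6, 7)))

  weighted <- risk_register(data.frame(
    fm_id = "FM1", expert_id = c("E1", "E2"),
    occurrence = c("(0,0,0)", "(4,4,4)"),
    severity = "Moderate", detection = "Low"),
    expert_weights = c(E1 = 0.75, E2 = 0.25))
  expect_equal(unclass(aggregate_experts(weighted, "FM1", "occurrence")),
               unclass(tfn(1, 1, 1)))

  # identical ratings aggregate to that rating exactly
  same <- risk_register(data.frame(
    fm_id = "FM1", expert_id = c("E1", "E2", "E3"),
    occurrence = "High", severity = "Moderate", detection = "Low"))
  expect_equal(unclass(aggregate_experts(same, "FM1", "occurrence")),
               unclass(lookup_label(scales$occurrence, "High")))

  expect_error(aggregate_experts(one, "FM99", "severity"),
               class = "fuzzrisk_error_missing_rating")
})

test_that("traditional RPN is the integer product with range checks", {
  expect_identical(traditional_rpn(10, 10, 10), 1000L)
  expect_identical(traditional_rpn(1, 1, 1), 1L)
  expect_identical(traditional_rpn(5, 7, 3), 105L)
  expect_error(traditional_rpn(0, 5, 5), class = "fuzzrisk_error_range")
  expect_error(traditional_rpn(5, 11, 5), class = "fuzzrisk_error_range")
  expect_error(traditional_rpn(5, 2.5, 5), class = "fuzzrisk_error_range")
})

test_that("multiplicative fuzzy RPN is the componentwise triple product", {
  r <- fuzzy_rpn(tfn(1, 1, 1), tfn(1, 1, 1), tfn(1, 1, 1))
  expect_equal(unclass(r$frpn), unclass(tfn(1, 1, 1)))
  r2 <- fuzzy_rpn(tfn(9, 10, 10), tfn(9, 10, 10), tfn(8, 10, 10))
  expect_equal(unclass(r2$frpn), unclass(tfn(648, 1000, 1000)))
  expect_equal(r2$crisp, defuzzify(tfn(648, 1000, 1000)))
  expect_equal(r2$label, "VH")
  # crisp value cross-checked against product + numeric centroid oracle
  o <- tfn(0.3, 0.5, 0.7); s <- tfn(0.5, 0.6, 0.7); d <- tfn(0.5, 0.7, 0.9)
  r3 <- fuzzy_rpn(o, s, d, scale_max = c(1, 1, 1))
  prod_oracle <- tfn(unclass(o) * unclass(s) * unclass(d))
  expect_equal(r3$crisp, numeric_centroid(prod_oracle), tolerance = 1e-9)
})

test_that("fuzzy RPN of degenerate integer TFNs equals the traditional RPN", {
  set.seed(5)
  for (i in 1:20) {
    osd <- sample(1:10, 3, replace = TRUE)
    r <- fuzzy_rpn(tfn(rep(osd[1], 3)), tfn(rep(osd[2], 3)), tfn(rep(osd[3], 3)))
    expect_equal(r$crisp, traditional_rpn(osd[1], osd[2], osd[3]))
  }
})

test_that("ranking uses competition ranks, stable within ties", {
  fake <- function(crisp) structure(list(crisp = crisp, label = "M"),
                                    class = "frpn")
  r <- rank_by_frpn(list(fake(0.9), fake(0.5)), c("A", "B"))
  expect_equal(r$rank, c(1L, 2L))
  r2 <- rank_by_frpn(list(fake(0.5), fake(0.5)), c("A", "B"))
  expect_equal(r2$rank, c(1L, 1L))
  expect_equal(r2$fm_id, c("A", "B"))
  expect_equal(competition_rank(c(3, 3, 1)), c(1L, 1L, 3L))
})

test_that("the worked-example register ranks FM1 first by F-RPN", {
  reg <- load_fixture("table6")
  f <- suppressWarnings(frpn_rank(reg))
  expect_equal(f$fm_id[f$rank == 1L], "FM1")
  expect_equal(nrow(f), 10L)  # only the published rating rows are scored
})

test_that("raising one factor never lowers the crisp F-RPN", {
  set.seed(33)
  for (i in 1:50) {
    o <- rand_tfn(1, 10); s <- rand_tfn(1, 10); d <- rand_tfn(1, 10)
    base <- fuzzy_rpn(o, s, d)$crisp
    bump <- tfn(unclass(o) + stats::runif(1, 0, 2))
    expect_gte(fuzzy_rpn(bump, s, d)$crisp, base)
    bump_s <- tfn(unclass(s) + stats::runif(1, 0, 2))
    expect_gte(fuzzy_rpn(o, bump_s, d)$crisp, base)
  }
})

test_that("a componentwise-dominant failure mode ranks first", {
  set.seed(44)
  for (i in 1:20) {
    reg <- generate_register(5, 3, dominance_fraction = 1, noise = 0, seed = i)
    f <- frpn_rank(reg)
    expect_equal(f$fm_id[f$rank == 1L], attr(reg, "dominance_chain")[1])
  }
})

test_that("register CSV round-trips losslessly", {
  reg <- load_fixture("table6")
  tmp <- tempfile(fileext = ".csv"); tmpm <- tempfile(fileext = ".csv")
  write_register(reg, tmp, tmpm)
  back <- read_register(tmp, tmpm)
  expect_equal(back$ratings, reg$ratings)
  expect_equal(back$modes, reg$modes)
})
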