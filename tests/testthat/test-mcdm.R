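crisp3 <- function(x) tfn(x, x, x)

test_that("decision matrices validate completeness and weights", {
  rows <- list(list(tfn(1, 2, 3), tfn(2, 3, 4)),
               list(tfn(3, 4, 5), tfn(4, 5, 6)))
  m <- fuzzy_decision_matrix(rows, c("A", "B"), c("c1", "c2"))
  expect_s3_class(m, "fdm")
  expect_equal(m$weights, c(0.5, 0.5))
  expect_error(
    fuzzy_decision_matrix(rows, c("A", "B"), c("c1", "c2"),
                          weights = c(0.9, 0.2)),
    class = "fuzzrisk_error_invalid_weights")
  expect_warning(
    fuzzy_decision_matrix(rows, c("A", "B"), c("c1", "c2"),
                          weights = list(tfn(0.1, 0.2, 0.3), tfn(0.1, 0.2, 0.3))),
    "sum to")
})

test_that("ARAS utility degrees match the hand-computed two-alternative case", {
  # crisp entries A = (1, 1), B = (0.5, 0.5), equal weights, benefit
  m <- fuzzy_decision_matrix(
    list(list(crisp3(1), crisp3(1)), list(crisp3(0.5), crisp3(0.5))),
    c("A", "B"), c("c1", "c2"))
  res <- aras_rank(m)
  expect_equal(res$S0, 0.4)
  expect_equal(res$table$S, c(0.4, 0.2))
  expect_equal(res$table$K, c(1, 0.5))
  expect_equal(res$table$rank, c(1L, 2L))
})

test_that("ARAS K is bounded by the appended ideal row", {
  set.seed(12)
  for (i in 1:20) {
    m <- dominant_matrix(5, 3)
    res <- aras_rank(m)
    expect_true(all(res$table$K > 0 & res$table$K <= 1 + 1e-12))
    expect_equal(res$table$fm_id[res$table$rank == 1L], "A1")
  }
})

test_that("VIKOR gives Q = 0 to an all-best alternative and 1 to an all-worst one", {
  m <- fuzzy_decision_matrix(
    list(list(tfn(7, 8, 9), tfn(7, 8, 9)), list(tfn(1, 2, 3), tfn(1, 2, 3))),
    c("best", "worst"), c("c1", "c2"))
  res <- vikor_rank(m)
  best <- res$table[res$table$fm_id == "best", ]
  worst <- res$table[res$table$fm_id == "worst", ]
  expect_equal(best$S, 0); expect_equal(best$R, 0); expect_equal(best$Q, 0)
  expect_equal(best$rank_Q, 1L)
  expect_equal(worst$S, 1)          # weights sum
  expect_equal(worst$R, 0.5)        # max single weight
  expect_equal(worst$Q, 1)
  expect_true(res$condition2)
})

test_that("VIKOR Q stays in [0,1] and conditions follow the Q gaps", {
  set.seed(23)
  for (i in 1:20) {
    m <- dominant_matrix(6, 3)
    res <- vikor_rank(m)
    expect_true(all(res$table$Q >= -1e-9 & res$table$Q <= 1 + 1e-9))
    expect_equal(res$table$fm_id[res$table$rank_Q == 1L], "A1")
    ord <- order(res$table$Q)
    gap <- res$table$Q[ord[2]] - res$table$Q[ord[1]]
    expect_equal(res$condition1, gap >= 1 / (nrow(res$table) - 1))
    if (res$condition1 && res$condition2) {
      expect_equal(res$compromise_set, "A1")
    } else {
      expect_true("A1" %in% res$compromise_set)
    }
  }
})

test_that("a constant criterion contributes zero; all-constant is degenerate", {
  m <- fuzzy_decision_matrix(
    list(list(tfn(5, 6, 7), tfn(2, 3, 4)), list(tfn(5, 6, 7), tfn(4, 5, 6))),
    c("A", "B"), c("const", "live"))
  expect_warning(res <- vikor_rank(m), "constant")
  expect_equal(res$table$fm_id[res$table$rank_Q == 1L], "B")
  m2 <- fuzzy_decision_matrix(
    list(list(tfn(5, 6, 7)), list(tfn(5, 6, 7))), c("A", "B"), "const")
  expect_warning(
    expect_error(vikor_rank(m2), class = "fuzzrisk_error_degenerate_criterion"))
})

test_that("WASPAS blends the sum and product models", {
  # normalized crisp rows: A = (1, 1), B = (1, 0.25)
  m <- fuzzy_decision_matrix(
    list(list(crisp3(4), crisp3(4)), list(crisp3(4), crisp3(1))),
    c("A", "B"), c("c1", "c2"))
  res <- waspas_rank(m, lambda = 0.5)
  a <- res$table[res$table$fm_id == "A", ]
  b <- res$table[res$table$fm_id == "B", ]
  expect_equal(a$Q, 1); expect_equal(a$P, 1); expect_equal(a$K, 1)
  expect_equal(b$Q, 0.625)
  expect_equal(b$P, 0.5)      # 1^0.5 * 0.25^0.5
  expect_equal(b$K, 0.5625)
  # lambda endpoints collapse to pure WSM / WPM
  expect_equal(waspas_rank(m, 1)$table$K, res$table$Q)
  expect_equal(waspas_rank(m, 0)$table$K, res$table$P)
  # data-driven lambda
  auto <- waspas_rank(m, "auto")
  lam <- sum(res$table$P) / (sum(res$table$Q) + sum(res$table$P))
  expect_equal(auto$lambda, lam)
  expect_equal(auto$table$K, lam * res$table$Q + (1 - lam) * res$table$P)
})

test_that("WASPAS P <= Q (weighted AM-GM) and K' in (0,1]", {
  set.seed(31)
  for (i in 1:20) {
    m <- dominant_matrix(5, 3)
    res <- waspas_rank(m)
    expect_true(all(res$table$P <= res$table$Q + 1e-12))
    expect_true(all(res$table$K > 0 & res$table$K <= 1 + 1e-12))
    expect_equal(res$table$fm_id[res$table$rank == 1L], "A1")
  }
})

test_that("registers translate to 3-criterion benefit matrices", {
  reg <- risk_register(data.frame(
    fm_id = "FM1", expert_id = "E1", occurrence = "High",
    severity = "Moderate", detection = "Low"))
  m <- build_matrix_from_register(reg)
  expect_equal(dim(m$entries), c(1L, 3L, 3L))
  expect_equal(m$criteria, c("occurrence", "severity", "detection"))
  expect_equal(m$directions, rep("benefit", 3))
  expect_equal(m$weights, rep(1 / 3, 3))

  t6 <- suppressWarnings(build_matrix_from_register(load_fixture("table6")))
  expect_equal(length(t6$alternatives), 10L)
  expect_equal(unname(t6$entries["FM1", "occurrence", ]), c(9, 10, 10))
  expect_equal(unname(t6$entries["FM1", "severity", ]), c(9, 10, 10))
  expect_equal(unname(t6$entries["FM1", "detection", ]), c(5, 7, 9))

  # identical failure modes produce identical rows
  reg2 <- risk_register(data.frame(
    fm_id = c("X", "Y"), expert_id = "E1", occurrence = "High",
    severity = "Moderate", detection = "Low"))
  m2 <- build_matrix_from_register(reg2)
  expect_equal(m2$entries["X", , ], m2$entries["Y", , ])
})

test_that("rescaling one criterion's column leaves ARAS and WASPAS ranks unchanged", {
  set.seed(61)
  for (i in 1:10) {
    rows <- lapply(1:5, function(i) lapply(1:3, function(j) rand_tfn(1, 10)))
    m1 <- fuzzy_decision_matrix(rows, paste0("A", 1:5), paste0("c", 1:3))
    rows2 <- rows
    for (r in seq_along(rows2)) rows2[[r]][[2]] <- tfn_scale(rows2[[r]][[2]], 3.7)
    m2 <- fuzzy_decision_matrix(rows2, paste0("A", 1:5), paste0("c", 1:3))
    expect_equal(aras_rank(m1)$table$rank, aras_rank(m2)$table$rank)
    expect_equal(waspas_rank(m1)$table$rank, waspas_rank(m2)$table$rank)
    expect_equal(aras_rank(m1)$table$K, aras_rank(m2)$table$K, tolerance = 1e-9)
  }
})

test_that("all three rankers agree on the top alternative for dominant inputs", {
  for (seed in 1:10) {
    reg <- generate_register(6, 3, dominance_fraction = 1, noise = 0, seed = seed)
    m <- build_matrix_from_register(reg)
    expect_equal(aras_rank(m)$table$rank[1], 1L)
    expect_equal(vikor_rank(m)$table$rank_Q[1], 1L)
    expect_equal(waspas_rank(m)$table$rank[1], 1L)
  }
})

test_that("cost criteria reverse the preference direction", {
  # on a cost criterion the smaller entry is preferable
  m <- fuzzy_decision_matrix(
    list(list(tfn(1, 2, 3)), list(tfn(7, 8, 9))), c("cheap", "dear"), "price",
    directions = "cost", weights = 1)
  a <- aras_rank(m)
  expect_equal(a$table$fm_id[a$table$rank == 1L], "cheap")
  w <- waspas_rank(m)
  expect_equal(w$table$fm_id[w$table$rank == 1L], "cheap")
  v <- vikor_rank(m)
  expect_equal(v$table$fm_id[v$table$rank_Q == 1L], "cheap")
})
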