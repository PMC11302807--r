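test_that("consensus scoring: exact means and agreed values", {
  expect_identical(as.character(consensus(c(5, 5, 6))), "16/3")
  expect_identical(as.character(consensus(c(4, 4, 5))), "13/3")
  expect_identical(as.character(consensus(4)), "4")
  expect_identical(as.character(consensus(c(7, 7, 7),
                                          method = "agreed_value")), "7")
  expect_error(consensus(numeric(0)), "non-empty")
  expect_error(consensus(c(5, 11)), "\\[1, 10\\]")
  expect_error(consensus(c(5, 6), method = "agreed_value"), "single")
})

test_that("RPN is the exact product, displayed to two decimals", {
  expect_equal(as.numeric(rpn(7, 8, 4)), 224)
  expect_equal(as.numeric(rpn(1, 1, 1)), 1)
  r <- rpn(rational(4), rational(16, 3), rational(13, 3))
  expect_identical(c(r$num, r$den), c(832, 9))
  expect_identical(format(r), "92.44")
  expect_identical(format(rpn(rational(8, 3), 5, rational(20, 3))), "88.89")
  # integer scores always give integer RPNs; thirds give multiples of 1/27
  for (i in 1:20) {
    o <- sample(1:10, 1); s <- sample(1:10, 1); d <- sample(1:10, 1)
    expect_identical(rpn(o, s, d)$den, 1)
    rt <- rpn(rational(3 * o + 1, 3), rational(3 * s + 2, 3), rational(d))
    expect_true(27 %% rt$den == 0)
  }
})

test_that("score cells parse as rater lists, fractions and thirds", {
  expect_identical(as.character(parse_scores("5;5;6")), "16/3")
  expect_identical(as.character(parse_scores("16/3")), "16/3")
  expect_identical(as.character(parse_scores("5.33")), "16/3")
  expect_identical(as.character(parse_scores("7.67")), "23/3")
  expect_identical(as.character(parse_scores("4")), "4")
  # opt-in literal-decimal mode
  expect_identical(as.character(parse_scores("5.33", mode = "decimal")),
                   "533/100")
  expect_error(parse_scores("11"), "outside")
  expect_error(parse_scores("abc"), "malformed")
})

test_that("invalid risk matrices are rejected at construction", {
  expect_s3_class(default_risk_matrix(), "risk_matrix")
  # monotone all-medium grid still violates the severity override
  expect_error(risk_matrix(matrix("medium", 10, 10)), "S = 9-10")
  g <- unclass(default_risk_matrix())
  g[3, ] <- "high"             # high at S=3 but medium above: not monotone
  expect_error(risk_matrix(g), "monotone")
  g <- unclass(default_risk_matrix())
  g[10, 1] <- "low"            # also caught (as a monotonicity break)
  expect_error(risk_matrix(g))
  expect_error(risk_matrix(matrix("L", 5, 5)), "10 x 10")
  expect_error(risk_matrix(matrix("X", 10, 10)), "L/M/H")
})

test_that("risk matrix files round-trip and are validated on load", {
  m <- default_risk_matrix()
  path <- withr::local_tempfile(fileext = ".txt")
  write_risk_matrix(m, path)
  expect_equal(read_risk_matrix(path), m)
  writeLines(rep(paste(rep("L", 10), collapse = " "), 10), path)
  expect_error(read_risk_matrix(path), "S = 9-10")
})

test_that("classification applies the severity override and ceilings", {
  m <- default_risk_matrix()
  expect_identical(classify_risk(S = 9, O = 1, m), "high")
  expect_identical(classify_risk(S = 10, O = 1, m), "high")
  expect_identical(classify_risk(S = 1, O = 1, m), "low")
  # fractional severity 8.67 ceilings to 9: override applies
  expect_identical(classify_risk(rational(26, 3), rational(1), m), "high")
  # raising O at fixed S never lowers the level
  lvl <- match(classify_risk(rep(1:10, each = 10),
                             rep(1:10, times = 10), m),
               c("low", "medium", "high"))
  grid <- matrix(lvl, 10, 10, byrow = TRUE)
  expect_true(all(apply(grid, 1, diff) >= 0))
  expect_true(all(apply(grid, 2, diff) >= 0))
})

test_that("top-fraction flags use ceiling k and include cutoff ties", {
  distinct <- as_register(data.frame(id = paste0("m", 1:10),
                                     O = 1:10, S = 5, D = 5))
  flags <- top_fraction(distinct, 0.2)
  expect_identical(distinct$id[flags], c("m9", "m10"))

  tied <- as_register(data.frame(id = paste0("m", 1:5), O = 4, S = 4, D = 4))
  expect_true(all(top_fraction(tied, 0.2)))  # all tied with the k-th value

  expect_true(all(top_fraction(distinct, 1.0)))
  expect_length(top_fraction(as_register(
    data.frame(id = character(0), O = character(0), S = character(0),
               D = character(0))), 0.2), 0)
  expect_error(top_fraction(distinct, 0), "fraction")
})

test_that("grouped and global top-fraction match a brute-force ranking", {
  for (seed in 1:10) {
    sr <- synth_register(synth_spec(seed = seed, n_modes = 37))
    reg <- fmea(sr$register, fraction = 0.2)
    expect_setequal(reg$id[reg$top_rpn],
                    brute_force_top_ids(reg$id, sr$truth$rpn, 0.2))
    byrole <- top_fraction(reg, 0.2, key = "rpn", group_by = "role")
    want <- unlist(lapply(split(seq_len(nrow(reg)), reg$role), function(i) {
      brute_force_top_ids(reg$id[i], sr$truth$rpn[i], 0.2)
    }), use.names = FALSE)
    expect_setequal(reg$id[byrole], want)
    # removing a non-flagged item never changes which items are flagged
    keep <- which(!reg$top_rpn)[1]
    if (!is.na(keep)) {
      reduced <- as_register(as.data.frame(reg)[-keep,
                                                c("id", "role", "O", "S",
                                                  "D")])
      f2 <- top_fraction(reduced, 0.2)
      expect_true(all(reg$id[reg$top_rpn] %in% reduced$id[f2]))
    }
  }
})

test_that("summary counts partition the register", {
  empty <- fmea(as_register(data.frame(id = character(0), O = character(0),
                                       S = character(0), D = character(0))))
  s0 <- fmea_summary(empty)
  expect_equal(unlist(s0), c(total = 0, high = 0, medium = 0, low = 0,
                             n_top_rpn = 0, n_top_severity = 0))
  for (seed in 1:10) {
    sr <- synth_register(synth_spec(seed = seed, n_modes = 30))
    reg <- fmea(sr$register)
    expect_identical(reg$risk_level, sr$truth$risk_level)
    s <- fmea_summary(reg)
    expect_equal(s$high + s$medium + s$low, s$total)
    expect_equal(s$high, sum(sr$truth$risk_level == "high"))
  }
})

test_that("the audit flags printed RPNs that disagree with recomputation", {
  reg <- as_register(data.frame(
    id = c("ok", "err"),
    O = c("3", "3.67"), S = c("7.67", "4.67"), D = c("3", "3"),
    printed_rpn = c(69, 51.13)))
  out <- audit_register(reg, tolerance = 0.1)
  expect_identical(out$id, "err")
  expect_equal(out$recomputed, 51.33)
  expect_equal(out$discrepancy, abs(51.13 - 462 / 9), tolerance = 1e-9)
  expect_equal(nrow(audit_register(reg, tolerance = Inf)), 0)
  expect_equal(nrow(audit_register(as_register(
    data.frame(id = "x", O = 1, S = 1, D = 1)))), 0)
})
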