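# Published five-fraction SBRT figures that the fixtures must reproduce to
# the cent when re-rolled through the cost engine.

published_stage_grid <- function(modality) {
  stages <- c("consultation", "simulation", "planning", "treatment",
              "on-treatment visit", "follow-up")
  people <- c("rtt", "cma", "nurse", "physicist", "attending",
              "dosimetrist", "resident")
  vals <- if (modality == "CTgRT") c(
    0.00, 255.60, 0.00,  340.80, 0.00, 0.00,
    4.80,   0.00, 0.00,    0.00, 4.80, 4.80,
    22.40,  2.56, 0.00,    0.00, 9.60, 12.80,
    0.00, 278.46, 163.80, 489.06, 0.00, 0.00,
    341.00, 44.00, 154.00, 176.00, 57.20, 132.00,
    0.00,   0.00, 242.82,   0.00, 0.00, 0.00,
    0.00,   0.00,  33.63,   0.00, 0.00, 0.00
  ) else c(
    14.20, 149.81, 0.00, 1150.20, 0.00, 0.00,
    4.80,    0.00, 0.00,    0.00, 4.80, 4.80,
    22.40,   0.00, 0.00,    0.00, 9.60, 12.80,
    0.00,   29.25, 124.02, 1053.00, 0.00, 0.00,
    385.00, 57.20, 154.00, 550.00, 57.20, 132.00,
    0.00,   22.80, 222.30, 456.00, 0.00, 0.00,
    0.00,    0.00,  61.95,   0.00, 0.00, 0.00
  )
  matrix(vals, nrow = 7, byrow = TRUE, dimnames = list(people, stages))
}

test_that("the published CCR table loads with the printed rates", {
  res <- paper_resources()
  expect_equal(nrow(res), 15)
  expect_equal(table(res$category)[["personnel"]], 7)
  expect_equal(table(res$category)[["equipment"]], 5)
  expect_equal(table(res$category)[["space"]], 3)
  expect_equal(res$ccr[res$name == "Medical physicist"], 2.34)
  expect_equal(res$ccr[res$id == "eq_mridian"], 8.01)
  expect_equal(res$ccr[res$id == "rtt"], 0.71)
  expect_true(all(res$ccr > 0))
  expect_equal(res$daily_hours[res$id == "eq_petct"], 8)
})

test_that("every published personnel stage cell reproduces to the cent", {
  res <- paper_resources()
  for (modality in c("CTgRT", "MRgRT")) {
    bd <- rollup(paper_workflow(modality), res)
    want <- published_stage_grid(modality)
    got <- bd$cell_costs[rownames(want), colnames(want)]
    expect_equal(round_half_away(got, 2), want,
                 ignore_attr = FALSE, tolerance = 1e-9)
    # stage totals of the personnel block
    expect_equal(round_half_away(colSums(got), 2), colSums(want),
                 tolerance = 1e-9)
  }
})

test_that("modality personnel totals and the difference total match", {
  res <- paper_resources()
  bmr <- rollup(paper_workflow("MRgRT"), res)
  bct <- rollup(paper_workflow("CTgRT"), res)
  expect_equal(round_half_away(bct$category_totals[["personnel"]], 2),
               2770.13)
  expect_equal(round_half_away(bmr$category_totals[["personnel"]], 2),
               4678.13)
  d <- compare_costs(bct, bmr)
  expect_equal(round_half_away(d$category_totals[["personnel"]], 2),
               -1908.00)
  # difference grid equals the element-wise difference of the two grids
  want <- published_stage_grid("CTgRT") - published_stage_grid("MRgRT")
  got <- d$cell_costs[rownames(want), colnames(want)]
  expect_equal(round_half_away(got, 2), want, tolerance = 1e-9)
})

test_that("equipment, space and grand totals match the published rollup", {
  res <- paper_resources()
  bmr <- rollup(paper_workflow("MRgRT"), res)
  bct <- rollup(paper_workflow("CTgRT"), res)
  expect_equal(round_half_away(bmr$category_totals[["equipment"]], 2),
               4471.15)
  expect_equal(round_half_away(bmr$category_totals[["space"]], 2), 199.04)
  expect_equal(round_half_away(bct$category_totals[["equipment"]], 2),
               1343.97)
  expect_equal(round_half_away(bct$category_totals[["space"]], 2), 74.85)
  expect_equal(round_half_away(bmr$grand_total, 2), 9348.32)
  expect_equal(round_half_away(bct$grand_total, 2), 4188.95)
})

test_that("the packaged register reproduces every non-errata printed RPN", {
  reg <- fmea(paper_register())
  expect_equal(nrow(reg), 47)
  expect_equal(reg$rpn_display[reg$id == "fm01"], 224)
  expect_equal(reg$rpn_display[reg$id == "fm08"], 92.44)
  expect_equal(reg$rpn_display[reg$id == "fm09"], 88.89)
  expect_equal(reg$rpn_display[reg$id == "fm16"], 69.33)
  expect_equal(reg$rpn_display[reg$id == "fm30"], 40.3)
  expect_equal(reg$rpn_display[reg$id == "fm37"], 34.67)
  errata <- c("fm22", "fm23")
  ok <- !reg$id %in% errata
  expect_equal(reg$rpn_display[ok], reg$printed_rpn[ok])
  audit <- audit_register(reg, tolerance = 0.1)
  expect_setequal(audit$id, errata)
  expect_equal(audit$recomputed[audit$id == "fm23"], 51.33)
  expect_equal(audit$recomputed[audit$id == "fm22"], 52.15)
  # summary partition over the packaged subset
  s <- fmea_summary(reg)
  expect_equal(s$high + s$medium + s$low, 47)
})

test_that("per-role top-RPN flag counts are ceil(fraction x role size)", {
  reg <- fmea(paper_register(), fraction = 0.2, group_by = "role")
  counts <- table(reg$role)
  flagged <- tapply(reg$top_rpn, reg$role, sum)
  # the packaged register has distinct per-role RPN cutoffs except ties;
  # with ties the flagged count can only exceed the ceiling
  expect_true(all(flagged >= ceiling(0.2 * counts)))
  # and the global flags rank the whole register
  regg <- fmea(paper_register(), fraction = 0.2)
  expect_setequal(regg$id[regg$top_rpn],
                  brute_force_top_ids(regg$id, regg$rpn, 0.2))
})
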