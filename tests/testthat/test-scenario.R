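test_that("edits apply structurally and never touch the baseline", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  iv <- intervention("drop-consult", edit_remove_step("consult"))
  out <- apply_intervention(wf, iv)
  expect_length(out$steps, 2)
  expect_length(wf$steps, 3)  # baseline untouched
  expect_equal(attr(out, "time_saved"), 20)
  expect_error(apply_intervention(wf, intervention(
    "bad", edit_remove_step("ghost"))), "no step 'ghost'")
})

test_that("null and zero edits change nothing", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  iv0 <- intervention("null", edit_reduce_minutes("rtt", 0,
                                                  stage = "treatment"))
  sv <- intervention_savings(wf, res, iv0)
  expect_equal(sv$total, 0)
  expect_equal(sv$time_saved, 0)
  sc <- combine_interventions(wf, res, list())
  expect_equal(sc$reduced_total, sc$baseline_total)
})

test_that("reductions clamp at zero minutes with a warning", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  iv <- intervention("huge", edit_reduce_minutes("rtt", 10000,
                                                 stage = "treatment"))
  expect_warning(out <- apply_intervention(wf, iv), "clamped")
  bd <- rollup(out, res)
  expect_equal(bd$cell_costs["rtt", "treatment"], 0)
  expect_gte(min(bd$cell_costs), 0)
})

test_that("savings equal the rollup difference and decompose by category", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  iv <- intervention("trim", edit_reduce_minutes(
    list(list(resource = "rtt", headcount = 3), list(resource = "machine"),
         list(resource = "vault")),
    delta_minutes = 5, per_fraction = TRUE, stage = "treatment"))
  sv <- intervention_savings(wf, res, iv)
  base <- rollup(wf, res)
  after <- rollup(apply_intervention(wf, iv), res)
  expect_equal(sv$total, base$grand_total - after$grand_total,
               tolerance = 1e-9)
  expect_equal(sv$personnel + sv$equipment + sv$space, sv$total,
               tolerance = 1e-9)
  expect_equal(sv$personnel,
               base$category_totals[["personnel"]] -
                 after$category_totals[["personnel"]], tolerance = 1e-9)
  # 3 heads x 5 min x 5 fx x 0.71 + machine & vault 5 x 5 x (8.01 + 0.36)
  expect_equal(sv$total, 3 * 5 * 5 * 0.71 + 25 * 8.37, tolerance = 1e-9)
  expect_equal(sv$time_saved, 25)
})

test_that("shrink-only interventions never increase any cost cell", {
  for (seed in 1:10) {
    sw <- synth_workflow(synth_spec(seed = seed))
    rid <- sw$resources$id[1]
    iv <- intervention("shrink", list(
      edit_reduce_minutes(rid, 3),
      edit_scale_minutes(resources = sw$resources$id[2], factor = 0.5)))
    base <- rollup(sw$workflow, sw$resources)
    suppressWarnings(after <- rollup(apply_intervention(sw$workflow, iv),
                                     sw$resources))
    expect_true(all(after$cell_costs <= base$cell_costs + 1e-9))
  }
})

test_that("scaling a step by factor 1 is the identity, by 0 zeroes it", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  same <- apply_intervention(wf, intervention(
    "id", edit_scale_minutes(step_id = "deliver", factor = 1)))
  expect_equal(rollup(same, res)$grand_total, rollup(wf, res)$grand_total)
  gone <- apply_intervention(wf, intervention(
    "zero", edit_scale_minutes(step_id = "deliver", factor = 0)))
  expect_equal(rollup(gone, res)$cell_costs[, "treatment"],
               c(rtt = 0, physicist = 0, machine = 0, vault = 0))
  expect_error(edit_scale_minutes(step_id = "x", factor = 1.2), "factor")
})

test_that("dose-rate savings scale the beam-limited time inversely", {
  expect_equal(dose_rate_delta(7, 600, 600), 0)
  expect_equal(dose_rate_delta(7, 600, 1400), 4)
  expect_equal(dose_rate_delta(35.18, 600, 1400), 35.18 * 4 / 7)
  expect_error(dose_rate_delta(7, 0, 1400), "positive")
})

test_that("dependency ordering is enforced and disjoint edits commute", {
  res <- tiny_resources()
  wf <- tiny_workflow()
  a <- intervention("a", edit_remove_step("consult"))
  b <- intervention("b", edit_remove_step("qa"), requires = "a")
  expect_error(combine_interventions(wf, res, list(b, a)), "requires")
  sc <- combine_interventions(wf, res, list(a, b))
  expect_equal(sc$reduced_total,
               rollup(wf, res)$cell_costs["rtt", "treatment"] +
                 sum(rollup(wf, res)$cell_costs[c("machine", "vault"), ]),
               tolerance = 1e-9)
  # disjoint single-step edits commute
  a2 <- intervention("a", edit_remove_step("consult"))
  b2 <- intervention("b", edit_remove_step("qa"))
  s1 <- combine_interventions(wf, res, list(a2, b2))
  s2 <- combine_interventions(wf, res, list(b2, a2))
  expect_equal(s1$reduced_total, s2$reduced_total, tolerance = 1e-12)
  # per-intervention savings sum to the combined saving
  expect_equal(sum(vapply(s1$per_intervention, `[[`, 0, "total")),
               s1$combined$total, tolerance = 1e-9)
})

test_that("intervention files round-trip through the reader", {
  ivs <- paper_interventions()
  expect_named(ivs, c("auto_segmentation", "mlc_tracking", "vmat",
                      "dose_rate_upgrade", "synthetic_ct"))
  expect_identical(ivs$vmat$requires, "mlc_tracking")
  expect_equal(ivs$dose_rate_upgrade$edits[[1]]$delta_minutes,
               35.18 * (1 - 600 / 1400), tolerance = 1e-12)
  expect_identical(ivs$synthetic_ct$edits[[1]]$type, "remove_step")
})
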