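# small in-code builders shared across test files

tiny_resources <- function() {
  as_resources(data.frame(
    id = c("rtt", "physicist", "machine", "vault"),
    category = c("personnel", "personnel", "equipment", "space"),
    ccr = c(0.71, 2.34, 8.01, 0.36),
    stringsAsFactors = FALSE
  ))
}

tiny_workflow <- function(n_fractions = 5) {
  workflow("tiny", n_fractions = n_fractions, steps = list(
    process_step("consult", "consultation",
                 resource_usage("rtt", minutes = 20)),
    process_step("qa", "planning",
                 resource_usage("physicist", minutes = 60),
                 occurrence_prob = 0.5),
    process_step("deliver", "treatment", per_fraction = TRUE, usages = list(
      resource_usage("rtt", minutes = 30, headcount = 3),
      resource_usage("machine", minutes = 40),
      resource_usage("vault", minutes = 40)
    ))
  ))
}

# independent brute-force cost enumeration: one row per usage, summed flat
brute_force_total <- function(wf, resources) {
  total <- 0
  for (st in wf$steps) {
    for (u in st$usages) {
      ccr <- resources$ccr[resources$id == u$resource]
      reps <- if (st$per_fraction) wf$n_fractions else 1
      total <- total + ccr * u$minutes * u$headcount *
        st$occurrence_prob * reps
    }
  }
  total
}

# independent top-k ranking: full sort, ceiling k, ties at the cutoff kept
brute_force_top_ids <- function(ids, values, fraction) {
  k <- ceiling(fraction * length(values))
  ord <- order(values, decreasing = TRUE)
  cutoff <- values[ord[k]]
  ids[values >= cutoff]
}
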