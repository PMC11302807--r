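#' Synthetic workflows and registers with known ground truth
#'
#' Seeded generators used to exercise the costing and FMEA engines on
#' inputs whose correct answers are known by construction: workflows whose
#' expected rollup total is available analytically from the generating
#' distributions, and registers with planted RPNs, risk levels and top-k
#' sets. The defaults emulate the shape of clinical process maps — a few
#' stages, a handful of steps each, step durations log-normal around a
#' 15-minute median, most steps applying to every patient — but make no
#' claim about any specific clinic.
#'
#' @name synthetic
NULL

#' Specification for synthetic generation
#'
#' @param seed integer seed; the spec fully determines the output.
#' @param n_stages number of workflow stages.
#' @param steps_per_stage integer range `c(min, max)` of steps per stage.
#' @param minutes_meanlog,minutes_sdlog log-normal parameters for step
#'   minutes (defaults: median 15 min, log-sd 0.5).
#' @param headcount_probs probabilities of headcount 1, 2, 3 for personnel
#'   usages (non-personnel always 1).
#' @param p_certain probability a step applies to every patient
#'   (occurrence 1); otherwise occurrence ~ Uniform(0.2, 0.9).
#' @param p_per_fraction probability a step repeats every fraction.
#' @param n_fractions treatment fractions.
#' @param n_resources resources in the generated table (cycled over
#'   personnel/equipment/space).
#' @param n_modes,n_raters register size and raters per score.
#' @param score_probs length-10 probability vector over scores 1..10 for
#'   each of O, S, D (default: discrete triangular peaked at 3).
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_stages = 4L, steps_per_stage = c(2L, 6L),
                       minutes_meanlog = log(15), minutes_sdlog = 0.5,
                       headcount_probs = c(0.6, 0.3, 0.1),
                       p_certain = 0.8, p_per_fraction = 0.2,
                       n_fractions = 5L, n_resources = 6L,
                       n_modes = 40L, n_raters = 3L,
                       score_probs = NULL) {
  if (is.null(score_probs)) {
    score_probs <- pmax(0, 3 - abs(1:10 - 3)) + 0.25
    score_probs <- score_probs / sum(score_probs)
  }
  stopifnot(length(score_probs) == 10, abs(sum(score_probs) - 1) < 1e-8,
            length(steps_per_stage) == 2, steps_per_stage[1] >= 0,
            steps_per_stage[2] >= steps_per_stage[1])
  structure(list(seed = as.integer(seed), n_stages = n_stages,
                 steps_per_stage = steps_per_stage,
                 minutes_meanlog = minutes_meanlog,
                 minutes_sdlog = minutes_sdlog,
                 headcount_probs = headcount_probs / sum(headcount_probs),
                 p_certain = p_certain,
                 p_per_fraction = p_per_fraction,
                 n_fractions = as.integer(n_fractions),
                 n_resources = as.integer(n_resources),
                 n_modes = as.integer(n_modes),
                 n_raters = as.integer(n_raters),
                 score_probs = score_probs),
            class = "synth_spec")
}

synth_resources <- function(spec) {
  n <- spec$n_resources
  cats <- rep_len(RESOURCE_CATEGORIES, n)
  # fixed ccr ladder: deterministic given n, so expectations are analytic
  ccr <- round(0.25 * seq_len(n), 2)
  as_resources(data.frame(
    id = sprintf("res%02d", seq_len(n)),
    name = sprintf("%s %d", cats, seq_len(n)),
    category = cats,
    annual_days = 260,
    daily_hours = ifelse(cats == "personnel", 8, 10),
    ccr = ccr,
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic workflow
#'
#' @param spec a [synth_spec()].
#' @return list with `workflow` (an `rt_workflow`), `resources` (its
#'   resource table) and `expected_total`: the analytic expectation of
#'   `rollup(workflow, resources)$grand_total` over the generating
#'   distributions, i.e.
#'   `E[steps] * E[minutes] * E[occurrence] * E[fraction multiplier] *
#'    mean over resources of ccr * E[headcount | category]`.
#' @export
synth_workflow <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  resources <- synth_resources(spec)
  stages <- sprintf("stage%02d", seq_len(spec$n_stages))
  steps <- list()
  k <- 0
  for (sg in stages) {
    lo <- spec$steps_per_stage[1]
    hi <- spec$steps_per_stage[2]
    n_steps <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    for (i in seq_len(max(0, n_steps))) {
      k <- k + 1
      ri <- sample.int(nrow(resources), 1L)
      hc <- if (resources$category[ri] == "personnel") {
        sample(1:3, 1L, prob = spec$headcount_probs)
      } else 1L
      minutes <- stats::rlnorm(1, spec$minutes_meanlog, spec$minutes_sdlog)
      prob <- if (stats::runif(1) < spec$p_certain) 1 else
        stats::runif(1, 0.2, 0.9)
      steps[[k]] <- process_step(
        id = sprintf("s%03d", k), stage = sg,
        usages = resource_usage(resources$id[ri], minutes, hc),
        occurrence_prob = prob,
        per_fraction = stats::runif(1) < spec$p_per_fraction)
    }
  }
  wf <- workflow(modality = sprintf("synthetic-%d", spec$seed),
                 steps = steps, n_fractions = spec$n_fractions,
                 stages = stages)
  e_steps <- spec$n_stages * mean(seq(spec$steps_per_stage[1],
                                      spec$steps_per_stage[2]))
  e_minutes <- exp(spec$minutes_meanlog + spec$minutes_sdlog^2 / 2)
  e_occ <- spec$p_certain + (1 - spec$p_certain) * 0.55
  e_frac <- spec$p_per_fraction * spec$n_fractions +
    (1 - spec$p_per_fraction)
  e_hc <- sum(1:3 * spec$headcount_probs)
  per_res <- ifelse(resources$category == "personnel", e_hc, 1) *
    resources$ccr
  list(workflow = wf, resources = resources,
       expected_total = e_steps * e_minutes * e_occ * e_frac *
         mean(per_res))
}

#' Generate a synthetic failure-mode register with planted ground truth
#'
#' Scores are integer rater draws from the per-dimension distribution,
#' stored as rater-list cells (`"5;3;4"`). The ground truth is computed by
#' the generator with direct bookkeeping — exact rational means and
#' products, grid indexing for levels, full sort for the top set — so
#' engine results can be checked against it.
#'
#' @param spec a [synth_spec()].
#' @param matrix `risk_matrix` used for the planted levels.
#' @param fraction top fraction for the planted top-RPN set.
#' @return list with `register` (an `fmea_register`) and `truth`: planted
#'   `rpn` (numeric), `risk_level`, and `top_rpn_ids`.
#' @export
synth_register <- function(spec, matrix = default_risk_matrix(),
                           fraction = 0.2) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  roles <- c("Therapist", "Physicist", "Dosimetrist", "Attending physician")
  n <- spec$n_modes
  draw <- function() base::matrix(sample(1:10, n * spec$n_raters,
                                         replace = TRUE,
                                         prob = spec$score_probs),
                                  nrow = n)
  Om <- draw(); Sm <- draw(); Dm <- draw()
  cell <- function(m) apply(m, 1, paste, collapse = ";")
  reg <- data.frame(
    id = sprintf("fm%03d", seq_len(max(n, 0))),
    role = if (n > 0) sample(roles, n, replace = TRUE) else character(0),
    O = if (n > 0) cell(Om) else character(0),
    S = if (n > 0) cell(Sm) else character(0),
    D = if (n > 0) cell(Dm) else character(0),
    stringsAsFactors = FALSE
  )
  register <- as_register(reg)
  if (n == 0) {
    return(list(register = register,
                truth = list(rpn = numeric(0), risk_level = character(0),
                             top_rpn_ids = character(0))))
  }
  # planted truth by direct bookkeeping
  r <- spec$n_raters
  rpn_exact <- rational(rowSums(Om), r) * rational(rowSums(Sm), r) *
    rational(rowSums(Dm), r)
  s_ceil <- ceiling(rowSums(Sm) / r - 1e-12)
  o_ceil <- ceiling(rowSums(Om) / r - 1e-12)
  level <- unclass(matrix)[cbind(pmin(10, s_ceil), pmin(10, o_ceil))]
  level[s_ceil >= 9] <- "high"
  rpn_num <- as.numeric(rpn_exact)
  top_ids <- character(0)
  if (n > 0) {
    k <- ceiling(fraction * n)
    cutoff <- sort(rpn_num, decreasing = TRUE)[k]
    top_ids <- reg$id[rpn_num >= cutoff]
  }
  list(register = register,
       truth = list(rpn = rpn_num, risk_level = as.character(level),
                    top_rpn_ids = top_ids))
}
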