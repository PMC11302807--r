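#' Technology interventions and cost-savings analysis
#'
#' An intervention expresses a technology change as edits to a process map:
#' removing a step (e.g. synthetic CT eliminating the CT simulation),
#' reducing the minutes of a set of concurrently-occupied resources (e.g.
#' MLC tracking shaving delivery time for the whole treatment crew, machine
#' and vault), or scaling minutes by a factor. Savings are computed by
#' re-rolling the edited workflow and differencing against the baseline, so
#' personnel/equipment/space components always decompose consistently.
#'
#' Time saved is elapsed workflow time: a `reduce_minutes` edit counts its
#' delta once per occurrence (the affected resources work concurrently), and
#' a removed step counts its longest usage.
#'
#' @name scenario
NULL

#' Intervention edit constructors
#'
#' @param step_id id of the step to remove / scale.
#' @return a list of class `wf_edit`.
#' @export
edit_remove_step <- function(step_id) {
  structure(list(type = "remove_step", step_id = step_id),
            class = "wf_edit")
}

#' @rdname edit_remove_step
#' @param resources affected resource set: a character vector of resource
#'   ids, or a list of `list(resource =, headcount =)` records for
#'   multi-head personnel.
#' @param delta_minutes minutes removed per occurrence from each affected
#'   resource (per head).
#' @param per_fraction logical: the reduction recurs every treatment
#'   fraction.
#' @param stage restrict matching to steps of this stage (NULL = any).
#' @export
edit_reduce_minutes <- function(resources, delta_minutes,
                                per_fraction = FALSE, stage = NULL) {
  if (delta_minutes < 0) stop("delta_minutes must be >= 0", call. = FALSE)
  structure(list(type = "reduce_minutes",
                 resources = normalise_resource_set(resources),
                 delta_minutes = delta_minutes,
                 per_fraction = isTRUE(per_fraction),
                 stage = stage),
            class = "wf_edit")
}

#' @rdname edit_remove_step
#' @param factor scale factor in [0, 1] applied to matched usage minutes.
#' @export
edit_scale_minutes <- function(step_id = NULL, resources = NULL, factor,
                               stage = NULL) {
  if (!is.numeric(factor) || factor < 0 || factor > 1) {
    stop("factor must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(step_id) && is.null(resources)) {
    stop("scale_minutes needs a step_id or a resource set", call. = FALSE)
  }
  structure(list(type = "scale_minutes", step_id = step_id,
                 resources = if (is.null(resources)) NULL else
                   normalise_resource_set(resources),
                 factor = factor, stage = stage),
            class = "wf_edit")
}

normalise_resource_set <- function(resources) {
  if (is.character(resources)) {
    resources <- lapply(resources, function(r) list(resource = r,
                                                    headcount = 1L))
  }
  lapply(resources, function(r) {
    list(resource = as.character(r$resource),
         headcount = if (is.null(r$headcount)) 1L else
           as.integer(r$headcount))
  })
}

#' Construct an intervention
#'
#' @param name intervention name.
#' @param edits list of edits built with [edit_remove_step()],
#'   [edit_reduce_minutes()], [edit_scale_minutes()].
#' @param requires names of interventions that must be applied first (e.g. a
#'   VMAT delivery-time delta that is incremental on MLC tracking).
#' @param description free-text note.
#' @return list of class `intervention`.
#' @export
intervention <- function(name, edits, requires = character(0),
                         description = "") {
  if (inherits(edits, "wf_edit")) edits <- list(edits)
  structure(list(name = name, edits = edits,
                 requires = as.character(requires),
                 description = description),
            class = "intervention")
}

#' Minutes saved by a dose-rate increase
#'
#' The MU-delivery portion of beam-on time shrinks inversely with dose rate:
#' raising the rate from `old_rate` to `new_rate` saves
#' `beam_on_minutes * (1 - old_rate / new_rate)`.
#'
#' @param beam_on_minutes MU-limited beam-on minutes at the old rate.
#' @param old_rate,new_rate dose rates in MU/min, positive.
#' @return minutes saved.
#' @examples
#' dose_rate_delta(7, 600, 1400)   # 4
#' @export
dose_rate_delta <- function(beam_on_minutes, old_rate, new_rate) {
  if (old_rate <= 0 || new_rate <= 0) {
    stop("dose rates must be positive", call. = FALSE)
  }
  beam_on_minutes * (1 - old_rate / new_rate)
}

step_elapsed_minutes <- function(step, n_fractions) {
  mult <- step$occurrence_prob * if (step$per_fraction) n_fractions else 1
  max(vapply(step$usages, `[[`, 0, "minutes")) * mult
}

#' Apply an intervention to a workflow
#'
#' Returns an edited copy; the baseline is never modified. Reductions that
#' exceed the minutes available clamp at zero with a warning. The attribute
#' `"time_saved"` on the result records elapsed minutes removed.
#'
#' @param wf baseline `rt_workflow`.
#' @param iv an `intervention`.
#' @param applied names of interventions already applied, used to check
#'   `requires`.
#' @return the edited `rt_workflow`.
#' @export
apply_intervention <- function(wf, iv, applied = character(0)) {
  unmet <- setdiff(iv$requires, applied)
  if (length(unmet)) {
    stop("intervention '", iv$name, "' requires: ",
         paste(unmet, collapse = ", "), call. = FALSE)
  }
  time_saved <- 0
  for (ed in iv$edits) {
    if (ed$type == "remove_step") {
      ids <- vapply(wf$steps, `[[`, "", "id")
      i <- match(ed$step_id, ids)
      if (is.na(i)) {
        stop("intervention '", iv$name, "': no step '", ed$step_id, "'",
             call. = FALSE)
      }
      time_saved <- time_saved +
        step_elapsed_minutes(wf$steps[[i]], wf$n_fractions)
      wf$steps[[i]] <- NULL
    } else if (ed$type == "reduce_minutes") {
      occ <- if (ed$per_fraction) wf$n_fractions else 1
      for (r in ed$resources) {
        target <- ed$delta_minutes * r$headcount * occ  # course person-min
        removed <- 0
        for (si in seq_along(wf$steps)) {
          if (target - removed <= 1e-9) break
          st <- wf$steps[[si]]
          if (!is.null(ed$stage) && st$stage != ed$stage) next
          mult <- st$occurrence_prob *
            if (st$per_fraction) wf$n_fractions else 1
          if (mult == 0) next
          for (ui in seq_along(st$usages)) {
            u <- st$usages[[ui]]
            if (u$resource != r$resource) next
            avail <- u$minutes * u$headcount * mult
            take <- min(avail, target - removed)
            wf$steps[[si]]$usages[[ui]]$minutes <-
              u$minutes - take / (u$headcount * mult)
            removed <- removed + take
            if (target - removed <= 1e-9) break
          }
        }
        if (target - removed > 1e-6) {
          warning("intervention '", iv$name, "': reduction for resource '",
                  r$resource, "' clamped at available minutes (",
                  signif(target - removed, 6), " person-min short)",
                  call. = FALSE)
        }
      }
      time_saved <- time_saved + ed$delta_minutes * occ
    } else if (ed$type == "scale_minutes") {
      fac <- ed$factor
      for (si in seq_along(wf$steps)) {
        st <- wf$steps[[si]]
        if (!is.null(ed$stage) && st$stage != ed$stage) next
        if (!is.null(ed$step_id)) {
          if (st$id != ed$step_id) next
          before <- step_elapsed_minutes(st, wf$n_fractions)
          for (ui in seq_along(st$usages)) {
            wf$steps[[si]]$usages[[ui]]$minutes <-
              st$usages[[ui]]$minutes * fac
          }
          time_saved <- time_saved +
            before - step_elapsed_minutes(wf$steps[[si]], wf$n_fractions)
        } else {
          wanted <- vapply(ed$resources, `[[`, "", "resource")
          hit <- FALSE
          affected <- 0
          for (ui in seq_along(st$usages)) {
            u <- st$usages[[ui]]
            if (!u$resource %in% wanted) next
            wf$steps[[si]]$usages[[ui]]$minutes <- u$minutes * fac
            affected <- max(affected, u$minutes)
            hit <- TRUE
          }
          if (hit) {
            mult <- st$occurrence_prob *
              if (st$per_fraction) wf$n_fractions else 1
            time_saved <- time_saved + (1 - fac) * affected * mult
          }
        }
      }
      if (!is.null(ed$step_id) &&
          !ed$step_id %in% vapply(wf$steps, `[[`, "", "id")) {
        stop("intervention '", iv$name, "': no step '", ed$step_id, "'",
             call. = FALSE)
      }
    } else {
      stop("unknown edit type '", ed$type, "'", call. = FALSE)
    }
  }
  attr(wf, "time_saved") <- time_saved
  wf
}

#' Cost and time savings of an intervention
#'
#' `rollup(baseline) - rollup(apply_intervention(baseline, iv))`, decomposed
#' into personnel, equipment and space components, with elapsed time saved.
#'
#' @param wf baseline `rt_workflow`.
#' @param resources `rt_resources` table.
#' @param iv an `intervention`.
#' @param applied names of interventions already applied (for `requires`).
#' @return list of class `savings_breakdown`: `name`, `personnel`,
#'   `equipment`, `space`, `total` (USD per course), `time_saved` (minutes
#'   per course) and `diff` (the underlying `cost_breakdown` difference).
#' @export
intervention_savings <- function(wf, resources, iv,
                                 applied = character(0)) {
  base <- rollup(wf, resources)
  edited <- apply_intervention(wf, iv, applied = applied)
  after <- rollup(edited, resources)
  diff <- compare_costs(base, after)
  structure(list(name = iv$name,
                 personnel = diff$category_totals[["personnel"]],
                 equipment = diff$category_totals[["equipment"]],
                 space = diff$category_totals[["space"]],
                 total = diff$grand_total,
                 time_saved = attr(edited, "time_saved"),
                 diff = diff),
            class = "savings_breakdown")
}

#' Apply several interventions and report per-intervention plus combined
#' savings
#'
#' Interventions are applied sequentially in the given order (after checking
#' that every `requires` dependency appears earlier in the list); each
#' per-intervention saving is measured against the workflow as edited so
#' far, so overlapping edits compose by sequential application and the
#' per-intervention totals always sum to the combined saving.
#'
#' @param wf baseline `rt_workflow`.
#' @param resources `rt_resources` table.
#' @param interventions list of `intervention` objects.
#' @return list of class `scenario_result`: `baseline_total`,
#'   `per_intervention` (list of `savings_breakdown`), `combined` (a
#'   `savings_breakdown` for the whole suite), `reduced_total` and
#'   `time_saved`.
#' @export
combine_interventions <- function(wf, resources, interventions) {
  base <- rollup(wf, resources)
  current <- wf
  applied <- character(0)
  per <- list()
  time_saved <- 0
  for (iv in interventions) {
    sv <- intervention_savings(current, resources, iv, applied = applied)
    per[[iv$name]] <- sv
    current <- apply_intervention(current, iv, applied = applied)
    applied <- c(applied, iv$name)
    time_saved <- time_saved + sv$time_saved
  }
  after <- rollup(current, resources)
  diff <- compare_costs(base, after)
  combined <- structure(list(name = "combined",
                             personnel = diff$category_totals[["personnel"]],
                             equipment = diff$category_totals[["equipment"]],
                             space = diff$category_totals[["space"]],
                             total = diff$grand_total,
                             time_saved = time_saved,
                             diff = diff),
                        class = "savings_breakdown")
  structure(list(baseline_total = base$grand_total,
                 per_intervention = per,
                 combined = combined,
                 reduced_total = after$grand_total,
                 time_saved = time_saved),
            class = "scenario_result")
}

#' Read interventions from a YAML or JSON file
#'
#' Schema: a list of `{name, description, requires, edits}` where each edit
#' has `type` in `remove_step` / `reduce_minutes` / `scale_minutes` and the
#' matching fields (`step_id`; `resources[{resource, headcount}]`,
#' `delta_minutes`, `per_fraction`, `stage`; `factor`). `delta_minutes`
#' accepts an exact `"a/b"` fraction string.
#'
#' @param path file path.
#' @return named list of `intervention` objects.
#' @export
read_interventions <- function(path) {
  lst <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop("parse error reading interventions '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  out <- lapply(lst, function(x) {
    edits <- lapply(x$edits, function(e) {
      switch(e$type,
        remove_step = edit_remove_step(e$step_id),
        reduce_minutes = edit_reduce_minutes(
          resources = e$resources,
          delta_minutes = parse_minutes(e$delta_minutes, x$name),
          per_fraction = isTRUE(e$per_fraction),
          stage = e$stage),
        scale_minutes = edit_scale_minutes(
          step_id = e$step_id, resources = e$resources,
          factor = e$factor, stage = e$stage),
        stop("unknown edit type '", e$type, "' in intervention '",
             x$name, "'", call. = FALSE))
    })
    intervention(name = x$name, edits = edits,
                 requires = unlist(x$requires) %||% character(0),
                 description = x$description %||% "")
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' @export
print.savings_breakdown <- function(x, ...) {
  f <- function(v) formatC(v, format = "f", digits = 2)
  cat("<savings> ", x$name, ": total $", f(x$total),
      " (personnel $", f(x$personnel), ", equipment $", f(x$equipment),
      ", space $", f(x$space), "), time saved ",
      f(x$time_saved), " min\n", sep = "")
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  f <- function(v) formatC(v, format = "f", digits = 2)
  cat("Scenario analysis: baseline $", f(x$baseline_total), "\n", sep = "")
  for (sv in x$per_intervention) print(sv)
  print(x$combined)
  cat("Reduced grand total: $", f(x$reduced_total), "\n", sep = "")
  invisible(x)
}
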