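#' Staged process maps
#'
#' A workflow is a process map for one treatment modality: an ordered list of
#' stages (default: consultation, simulation, planning, treatment,
#' on-treatment visit, follow-up), a number of treatment fractions, and steps.
#' Each step belongs to a stage, carries resource usages (resource id,
#' headcount, minutes per occurrence), an occurrence probability in [0, 1]
#' (some tasks do not apply to every patient), and a per-fraction flag for
#' steps repeated at every treatment session.
#'
#' Workflow files are YAML (or JSON) with keys
#' `modality`, `n_fractions`, `stages`,
#' `steps[{id, label, stage, occurrence_prob, per_fraction,
#' usages[{resource, headcount, minutes}]}]`.
#' `minutes` may be a number or an exact fraction string `"a/b"` (used by the
#' packaged fixtures to store cost-derived minutes without decimal loss).
#'
#' @name workflow
NULL

DEFAULT_STAGES <- c("consultation", "simulation", "planning", "treatment",
                    "on-treatment visit", "follow-up")

#' Construct a resource usage
#'
#' @param resource resource id (character scalar).
#' @param minutes minutes per occurrence, >= 0.
#' @param headcount positive integer; only meaningful above 1 for personnel.
#' @return list of class `resource_usage`.
#' @export
resource_usage <- function(resource, minutes, headcount = 1L) {
  stopifnot(is.character(resource), length(resource) == 1L)
  if (!is.finite(minutes) || minutes < 0) {
    stop("minutes must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(headcount) || headcount < 1 || headcount != round(headcount)) {
    stop("headcount must be a positive integer", call. = FALSE)
  }
  structure(list(resource = resource, minutes = as.numeric(minutes),
                 headcount = as.integer(headcount)),
            class = "resource_usage")
}

#' Construct a process step
#'
#' @param id unique step id.
#' @param stage stage name (must exist in the parent workflow's stage list).
#' @param usages list of [resource_usage()] records.
#' @param label human-readable label.
#' @param occurrence_prob probability in [0, 1] that the step applies.
#' @param per_fraction logical: repeats every treatment fraction.
#' @return list of class `process_step`.
#' @export
process_step <- function(id, stage, usages, label = id,
                         occurrence_prob = 1, per_fraction = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  if (inherits(usages, "resource_usage")) usages <- list(usages)
  structure(list(id = id, label = label, stage = stage,
                 usages = usages,
                 occurrence_prob = as.numeric(occurrence_prob),
                 per_fraction = isTRUE(per_fraction)),
            class = "process_step")
}

#' Construct a workflow
#'
#' @param modality modality label, e.g. "MRgRT" or "CTgRT".
#' @param steps list of [process_step()] records.
#' @param n_fractions number of treatment fractions (>= 1).
#' @param stages ordered character vector of stage names.
#' @return list of class `rt_workflow`.
#' @export
workflow <- function(modality, steps = list(), n_fractions = 1L,
                     stages = DEFAULT_STAGES) {
  structure(list(modality = modality,
                 n_fractions = as.integer(n_fractions),
                 stages = as.character(stages),
                 steps = steps),
            class = "rt_workflow")
}

#' Validate a workflow against a resource table
#'
#' Checks every structural invariant of the process-map model: fraction
#' count, stage membership, unique step ids, occurrence probabilities in
#' [0, 1], non-negative finite minutes, integer headcounts, and referential
#' integrity of resource ids. Returns issues rather than stopping, so a
#' report can list everything wrong with a file at once.
#'
#' @param wf an `rt_workflow`.
#' @param resources an `rt_resources` table to resolve usage references
#'   against (optional; reference checks are skipped when NULL).
#' @return character vector of human-readable issues; empty iff valid.
#' @export
validate_workflow <- function(wf, resources = NULL) {
  issues <- character(0)
  say <- function(...) issues <<- c(issues, paste0(...))
  if (!inherits(wf, "rt_workflow")) {
    return("not an rt_workflow object")
  }
  if (is.na(wf$n_fractions) || wf$n_fractions < 1) {
    say("n_fractions must be >= 1 (got ", wf$n_fractions, ")")
  }
  if (length(wf$stages) == 0) say("workflow has no stages")
  ids <- vapply(wf$steps, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) say("duplicate step id '", d, "'")
  for (st in wf$steps) {
    if (!st$stage %in% wf$stages) {
      say("step '", st$id, "': unknown stage '", st$stage, "'")
    }
    if (!is.finite(st$occurrence_prob) || st$occurrence_prob < 0 ||
        st$occurrence_prob > 1) {
      say("step '", st$id, "': occurrence_prob ", st$occurrence_prob,
          " outside [0, 1]")
    }
    if (length(st$usages) == 0) {
      say("step '", st$id, "': no resource usages")
    }
    for (u in st$usages) {
      if (!is.finite(u$minutes) || u$minutes < 0) {
        say("step '", st$id, "': usage '", u$resource,
            "' has invalid minutes ", u$minutes)
      }
      if (is.na(u$headcount) || u$headcount < 1 ||
          u$headcount != round(u$headcount)) {
        say("step '", st$id, "': usage '", u$resource,
            "' has invalid headcount ", u$headcount)
      }
      if (!is.null(resources) && !u$resource %in% resources$id) {
        say("step '", st$id, "': usage references unknown resource '",
            u$resource, "'")
      }
      if (!is.null(resources) && u$resource %in% resources$id &&
          u$headcount > 1) {
        cat_ <- resources$category[match(u$resource, resources$id)]
        if (cat_ != "personnel") {
          say("step '", st$id, "': headcount > 1 on non-personnel resource '",
              u$resource, "'")
        }
      }
    }
  }
  issues
}

# parse a minutes field that may be numeric or an exact "a/b" fraction string
parse_minutes <- function(x, where) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^ *-?[0-9.]+ */ *[0-9.]+ *$", x)) {
      parts <- as.numeric(strsplit(x, "/")[[1]])
      return(parts[1] / parts[2])
    }
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) return(num)
  }
  stop("schema error at ", where, ": cannot parse minutes '", x, "'",
       call. = FALSE)
}

workflow_from_list <- function(lst, where = "workflow") {
  need_key <- function(obj, key, ctx) {
    if (is.null(obj[[key]])) {
      stop("schema error at ", ctx, ": missing key '", key, "'",
           call. = FALSE)
    }
    obj[[key]]
  }
  modality <- need_key(lst, "modality", where)
  n_fractions <- need_key(lst, "n_fractions", where)
  stages <- if (is.null(lst$stages)) DEFAULT_STAGES else unlist(lst$stages)
  steps <- lapply(seq_along(lst$steps), function(i) {
    s <- lst$steps[[i]]
    ctx <- paste0(where, "$steps[", i, "]")
    stage <- need_key(s, "stage", ctx)
    if (!stage %in% stages) {
      stop("schema error at ", ctx, ": unknown stage '", stage, "'",
           call. = FALSE)
    }
    usages <- lapply(seq_along(s$usages), function(j) {
      u <- s$usages[[j]]
      uctx <- paste0(ctx, "$usages[", j, "]")
      resource_usage(
        resource = as.character(need_key(u, "resource", uctx)),
        minutes = parse_minutes(need_key(u, "minutes", uctx), uctx),
        headcount = if (is.null(u$headcount)) 1L else u$headcount
      )
    })
    process_step(
      id = as.character(need_key(s, "id", ctx)),
      label = if (is.null(s$label)) as.character(s$id) else s$label,
      stage = stage,
      usages = usages,
      occurrence_prob = if (is.null(s$occurrence_prob)) 1 else
        s$occurrence_prob,
      per_fraction = isTRUE(s$per_fraction)
    )
  })
  workflow(modality = modality, steps = steps, n_fractions = n_fractions,
           stages = stages)
}

workflow_to_list <- function(wf) {
  list(
    modality = wf$modality,
    n_fractions = wf$n_fractions,
    stages = as.list(wf$stages),
    steps = lapply(wf$steps, function(s) {
      list(id = s$id, label = s$label, stage = s$stage,
           occurrence_prob = s$occurrence_prob,
           per_fraction = s$per_fraction,
           usages = lapply(s$usages, function(u) {
             list(resource = u$resource, headcount = u$headcount,
                  minutes = u$minutes)
           }))
    })
  )
}

#' Read a workflow from a YAML or JSON file
#'
#' @param path file path; JSON is detected by a `.json` extension.
#' @return an `rt_workflow`.
#' @export
read_workflow <- function(path) {
  lst <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop("parse error reading workflow '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  workflow_from_list(lst, where = basename(path))
}

#' Write a workflow to a YAML or JSON file
#'
#' `read_workflow(write_workflow(wf, path))` reproduces an equal model.
#'
#' @param wf an `rt_workflow`.
#' @param path output path; `.json` selects JSON.
#' @export
write_workflow <- function(wf, path) {
  lst <- workflow_to_list(wf)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.rt_workflow <- function(x, ...) {
  cat("<workflow> ", x$modality, ": ", length(x$steps), " steps over ",
      length(x$stages), " stages, ", x$n_fractions, " fraction(s)\n",
      sep = "")
  tab <- table(factor(vapply(x$steps, `[[`, "", "stage"),
                      levels = x$stages))
  for (s in x$stages) cat("  ", s, ": ", tab[[s]], " step(s)\n", sep = "")
  invisible(x)
}
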