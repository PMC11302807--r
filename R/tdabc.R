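#' Time-driven activity-based costing engine
#'
#' Costs a staged process map by multiplying each resource usage's minutes by
#' the resource's capacity cost rate (CCR, USD/min), weighting by headcount,
#' occurrence probability, and the fraction count for per-fraction steps, and
#' attributing the result to the (resource, stage) cell. Cell costs aggregate
#' to per-resource, per-stage, per-category (personnel/equipment/space) and
#' grand totals, which agree with each other by construction. All arithmetic
#' is carried in full floating precision; rounding to cents happens only in
#' reports.
#'
#' @name tdabc
NULL

empty_breakdown <- function(resources, stages) {
  m <- matrix(0, nrow = nrow(resources), ncol = length(stages),
              dimnames = list(resources$id, stages))
  structure(list(cell_costs = m,
                 time_totals = stats::setNames(numeric(nrow(resources)),
                                               resources$id),
                 resources = resources,
                 stages = stages),
            class = "cost_breakdown")
}

finish_breakdown <- function(bd) {
  bd$resource_totals <- rowSums(bd$cell_costs)
  bd$stage_totals <- colSums(bd$cell_costs)
  cat_f <- factor(bd$resources$category, levels = RESOURCE_CATEGORIES)
  bd$category_totals <- stats::setNames(
    as.numeric(tapply(bd$resource_totals, cat_f, sum, default = 0)),
    RESOURCE_CATEGORIES)
  bd$category_totals[is.na(bd$category_totals)] <- 0
  bd$grand_total <- sum(bd$cell_costs)
  bd
}

#' Cost contribution of one process step
#'
#' Each usage contributes
#' `ccr x minutes x headcount x occurrence_prob x (n_fractions if the step is
#' per-fraction, else 1)` USD, attributed to its (resource, stage) cell.
#'
#' @param step a [process_step()].
#' @param resources an `rt_resources` table.
#' @param n_fractions fraction count of the enclosing workflow.
#' @param stages stage list of the enclosing workflow.
#' @return a `cost_breakdown` holding this step's contribution only.
#' @export
step_cost <- function(step, resources, n_fractions = 1L,
                      stages = DEFAULT_STAGES) {
  bd <- empty_breakdown(resources, stages)
  mult <- step$occurrence_prob * if (step$per_fraction) n_fractions else 1
  for (u in step$usages) {
    i <- match(u$resource, resources$id)
    if (is.na(i)) {
      stop("step '", step$id, "': unknown resource '", u$resource, "'",
           call. = FALSE)
    }
    person_min <- u$minutes * u$headcount * mult
    bd$cell_costs[i, step$stage] <- bd$cell_costs[i, step$stage] +
      resources$ccr[i] * person_min
    bd$time_totals[i] <- bd$time_totals[i] + person_min
  }
  finish_breakdown(bd)
}

#' Roll a workflow up into a cost breakdown
#'
#' Sums [step_cost()] over every step of the workflow. The result satisfies
#' the conservation identity: the sum over stages, the sum over resources,
#' the sum over the three categories and the grand total are all equal.
#'
#' @param wf a validated `rt_workflow`.
#' @param resources an `rt_resources` table covering every usage.
#' @return a `cost_breakdown` with components `cell_costs`
#'   (resource x stage matrix, USD), `resource_totals`, `stage_totals`,
#'   `category_totals`, `grand_total`, and `time_totals` (person-minutes per
#'   resource).
#' @examples
#' res <- as_resources(data.frame(id = "rtt", category = "personnel",
#'                                ccr = 0.71))
#' wf <- workflow("demo", list(
#'   process_step("consult", "consultation",
#'                resource_usage("rtt", minutes = 20))))
#' rollup(wf, res)$grand_total   # 14.2
#' @export
rollup <- function(wf, resources) {
  issues <- validate_workflow(wf, resources)
  if (length(issues)) {
    stop("invalid workflow:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  }
  bd <- empty_breakdown(resources, wf$stages)
  for (st in wf$steps) {
    mult <- st$occurrence_prob * if (st$per_fraction) wf$n_fractions else 1
    for (u in st$usages) {
      i <- match(u$resource, resources$id)
      person_min <- u$minutes * u$headcount * mult
      bd$cell_costs[i, st$stage] <- bd$cell_costs[i, st$stage] +
        resources$ccr[i] * person_min
      bd$time_totals[i] <- bd$time_totals[i] + person_min
    }
  }
  bd$modality <- wf$modality
  finish_breakdown(bd)
}

#' Difference of two cost breakdowns (a - b)
#'
#' Element-wise subtraction over the union of the two index sets (cells
#' absent from one side count as zero). Published difference tables print
#' the cheaper-minus-dearer orientation (e.g. CTgRT - MRgRT), so negative
#' cells mean the first modality is cheaper there.
#'
#' @param a,b `cost_breakdown` objects.
#' @return a `cost_breakdown` whose cells may be negative.
#' @export
compare_costs <- function(a, b) {
  stages <- union(a$stages, b$stages)
  ids <- union(rownames(a$cell_costs), rownames(b$cell_costs))
  res <- rbind(a$resources,
               b$resources[!b$resources$id %in% a$resources$id, ,
                           drop = FALSE])
  res <- res[match(ids, res$id), , drop = FALSE]
  class(res) <- c("rt_resources", "data.frame")
  bd <- empty_breakdown(res, stages)
  add <- function(m, sgn, src) {
    for (rn in rownames(src$cell_costs)) {
      for (cn in colnames(src$cell_costs)) {
        m[rn, cn] <- m[rn, cn] + sgn * src$cell_costs[rn, cn]
      }
    }
    m
  }
  bd$cell_costs <- add(bd$cell_costs, 1, a)
  bd$cell_costs <- add(bd$cell_costs, -1, b)
  bd$time_totals[names(a$time_totals)] <- a$time_totals
  bd$time_totals[names(b$time_totals)] <-
    bd$time_totals[names(b$time_totals)] - b$time_totals
  bd$modality <- paste0(a$modality %||% "a", " - ", b$modality %||% "b")
  finish_breakdown(bd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost breakdown>", if (!is.null(x$modality)) x$modality, "\n")
  cat("  grand total: $", formatC(x$grand_total, format = "f", digits = 2),
      "\n", sep = "")
  for (ct in names(x$category_totals)) {
    cat("  ", ct, ": $",
        formatC(x$category_totals[[ct]], format = "f", digits = 2), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.cost_breakdown <- function(object, ...) {
  grid <- as.data.frame(object)
  cat("Cost breakdown", if (!is.null(object$modality)) object$modality,
      "(USD)\n\n")
  print(grid, row.names = FALSE)
  invisible(grid)
}

#' Cost grid as a data.frame (stage columns plus a Total column and row)
#'
#' @param x a `cost_breakdown`.
#' @param row.names,optional,... ignored (S3 signature).
#' @param category restrict rows to one resource category, or NULL for all.
#' @param drop_zero drop all-zero resource rows.
#' @param digits round to this many decimals (NA = no rounding).
#' @export
as.data.frame.cost_breakdown <- function(x, row.names = NULL,
                                         optional = FALSE, ...,
                                         category = NULL, drop_zero = TRUE,
                                         digits = 2) {
  keep <- rep(TRUE, nrow(x$resources))
  if (!is.null(category)) keep <- x$resources$category %in% category
  m <- x$cell_costs[keep, , drop = FALSE]
  if (drop_zero) m <- m[rowSums(m != 0) > 0, , drop = FALSE]
  nm <- x$resources$name[match(rownames(m), x$resources$id)]
  out <- data.frame(resource = nm, m, Total = rowSums(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(resource = "Total",
                               t(colSums(m)), Total = sum(m),
                               check.names = FALSE))
  if (!is.na(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round_half_away, digits = digits)
  }
  rownames(out) <- NULL
  out
}
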