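#' Resource tables and capacity cost rates
#'
#' A resource is a costed capacity: a personnel category, a piece of
#' equipment, or a room. Its capacity cost rate (CCR, USD/min) is its annual
#' cost divided by its annual available minutes. Resource tables are plain
#' CSV with columns
#' `id,name,category,annual_cost,annual_days,daily_hours,ccr,useful_life_years`
#' (empty cell = absent optional field). At least one of `annual_cost` and
#' `ccr` must be present per row; when both are, they must agree to 0.5%.
#'
#' @name resources
NULL

RESOURCE_CATEGORIES <- c("personnel", "equipment", "space")

#' Read a resource table from CSV
#'
#' @param path path to a CSV file with the documented header.
#' @return A data.frame of class `rt_resources`, one row per resource, with a
#'   filled `ccr` column (computed from `annual_cost` where not supplied).
#' @export
read_resources <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading resource table '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  as_resources(df)
}

#' Build a resource table from a data.frame
#'
#' @param df data.frame with at least `id`, `category` and one of
#'   `annual_cost`, `ccr`; `annual_days`/`daily_hours` default to 260 and 8.
#' @return `rt_resources` object.
#' @export
as_resources <- function(df) {
  need <- c("id", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("resource table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("name", "annual_cost", "annual_days", "daily_hours", "ccr",
                "useful_life_years")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  df$name <- ifelse(is.na(df$name), df$id, df$name)
  df$annual_days <- ifelse(is.na(df$annual_days), 260, df$annual_days)
  df$daily_hours <- ifelse(is.na(df$daily_hours), 8, df$daily_hours)
  for (col in c("annual_cost", "annual_days", "daily_hours", "ccr",
                "useful_life_years")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate resource id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$category %in% RESOURCE_CATEGORIES
  if (any(bad)) {
    stop("unknown resource category for ",
         paste(df$id[bad], collapse = ", "),
         " (must be personnel/equipment/space)", call. = FALSE)
  }
  if (any(df$annual_days <= 0) || any(df$daily_hours <= 0)) {
    stop("annual_days and daily_hours must be positive", call. = FALSE)
  }
  none <- is.na(df$annual_cost) & is.na(df$ccr)
  if (any(none)) {
    stop("resource(s) with neither annual_cost nor ccr: ",
         paste(df$id[none], collapse = ", "), call. = FALSE)
  }
  both <- !is.na(df$annual_cost) & !is.na(df$ccr)
  if (any(both)) {
    implied <- df$annual_cost[both] /
      (df$annual_days[both] * df$daily_hours[both] * 60)
    rel <- abs(implied - df$ccr[both]) / df$ccr[both]
    if (any(rel > 0.005)) {
      stop("annual_cost and ccr disagree by more than 0.5% for: ",
           paste(df$id[both][rel > 0.005], collapse = ", "), call. = FALSE)
    }
  }
  fill <- is.na(df$ccr)
  df$ccr[fill] <- df$annual_cost[fill] /
    (df$annual_days[fill] * df$daily_hours[fill] * 60)
  rownames(df) <- NULL
  class(df) <- c("rt_resources", "data.frame")
  df
}

#' Write a resource table to CSV
#' @param resources an `rt_resources` table.
#' @param path output path.
#' @export
write_resources <- function(resources, path) {
  utils::write.csv(as.data.frame(resources), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Annual capacity of a resource in minutes
#'
#' `annual_days * daily_hours * 60`: the denominator of the capacity cost
#' rate. 260 days x 8 h (the standard 2080-hour personnel year) gives
#' 124,800 min; 260 days x 10 h (equipment/space availability) gives 156,000.
#'
#' @param resource a one-row slice of an `rt_resources` table, or any list
#'   with `annual_days` and `daily_hours`.
#' @return minutes per year (numeric scalar).
#' @export
capacity_minutes <- function(resource) {
  d <- resource$annual_days
  h <- resource$daily_hours
  if (is.null(d) || is.null(h) || is.na(d) || is.na(h)) {
    stop("annual_days and daily_hours must be set", call. = FALSE)
  }
  if (d <= 0 || h <= 0) stop("annual_days and daily_hours must be positive",
                             call. = FALSE)
  d * h * 60
}

#' Capacity cost rate of a resource
#'
#' Annual cost divided by annual capacity minutes. If the table already
#' carries a `ccr` (as published rate tables usually do), that value is
#' returned and, when an annual cost is also present, checked for
#' consistency to 0.5% relative tolerance.
#'
#' @param resource a one-row resource record.
#' @return USD per minute.
#' @export
compute_ccr <- function(resource) {
  has_cost <- !is.null(resource$annual_cost) && !is.na(resource$annual_cost)
  has_ccr <- !is.null(resource$ccr) && !is.na(resource$ccr)
  if (!has_cost && !has_ccr) {
    stop("unusable resource: neither annual_cost nor ccr", call. = FALSE)
  }
  if (has_cost) {
    implied <- resource$annual_cost / capacity_minutes(resource)
    if (has_ccr) {
      if (abs(implied - resource$ccr) / resource$ccr > 0.005) {
        warning("supplied ccr ", resource$ccr,
                " inconsistent with annual_cost-implied ",
                signif(implied, 6), call. = FALSE)
      }
      return(resource$ccr)
    }
    return(implied)
  }
  resource$ccr
}

resource_row <- function(resources, id) {
  i <- match(id, resources$id)
  if (is.na(i)) stop("unknown resource id '", id, "'", call. = FALSE)
  resources[i, , drop = FALSE]
}

#' @export
print.rt_resources <- function(x, ...) {
  cat("Resource table:", nrow(x), "resources (",
      sum(x$category == "personnel"), "personnel,",
      sum(x$category == "equipment"), "equipment,",
      sum(x$category == "space"), "space )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
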