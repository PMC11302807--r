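#' Report emitters
#'
#' Human- and machine-readable renderings of the engines' results. The same
#' numbers appear in every format: markdown adds currency symbols and
#' thousands separators, csv and json carry bare two-decimal values.
#' These functions back the command-line interface shipped at
#' `inst/cli/rtworkflow.R` (subcommands `tdabc`, `fmea`, `scenario`,
#' `synth`, `fixtures-list`).
#'
#' @name reports
NULL

fmt_usd <- function(x, markdown = FALSE) {
  v <- round_half_away(x, 2)
  if (markdown) {
    paste0(ifelse(v < 0, "-", ""), "$",
           formatC(abs(v), format = "f", digits = 2, big.mark = ","))
  } else {
    formatC(v, format = "f", digits = 2)
  }
}

md_table <- function(df) {
  cells <- as.data.frame(lapply(df, as.character),
                         stringsAsFactors = FALSE, check.names = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, rows)
}

emit <- function(lines, path = NULL) {
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Render a cost breakdown
#'
#' A stage-by-resource grid with Total row and column (the published
#' layout), plus a category summary (personnel / equipment / space / grand
#' total).
#'
#' @param bd a `cost_breakdown` from [rollup()] or [compare_costs()].
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param category restrict the grid to one category (the summary always
#'   covers all three), or NULL.
#' @param path write to this file instead of returning a string.
#' @return a single string (invisibly the path when `path` is given).
#' @export
cost_report <- function(bd, format = c("markdown", "csv", "json"),
                        category = NULL, path = NULL) {
  format <- match.arg(format)
  grid <- as.data.frame(bd, category = category, digits = NA)
  summary_df <- data.frame(
    category = c(RESOURCE_CATEGORIES, "grand_total"),
    cost = c(bd$category_totals[RESOURCE_CATEGORIES], bd$grand_total),
    stringsAsFactors = FALSE)
  if (format == "json") {
    num <- vapply(grid, is.numeric, TRUE)
    grid[num] <- lapply(grid[num], round_half_away, digits = 2)
    summary_df$cost <- round_half_away(summary_df$cost, 2)
    return(emit(jsonlite::toJSON(list(modality = bd$modality %||% "",
                                      grid = grid, summary = summary_df),
                                 dataframe = "rows", auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE), path))
  }
  if (format == "csv") {
    num <- vapply(grid, is.numeric, TRUE)
    grid[num] <- lapply(grid[num], function(x) fmt_usd(x, FALSE))
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(grid, con, row.names = FALSE)
    close(con)
    summary_lines <- paste0("category,cost",
                            collapse = "")
    summary_rows <- paste0(summary_df$category, ",",
                           fmt_usd(summary_df$cost, FALSE))
    return(emit(c(out, "", summary_lines, summary_rows), path))
  }
  num <- vapply(grid, is.numeric, TRUE)
  grid[num] <- lapply(grid[num], function(x) fmt_usd(x, TRUE))
  lines <- c(paste0("## Cost breakdown", if (!is.null(bd$modality))
                      paste0(" — ", bd$modality)),
             "", md_table(grid), "",
             "### Category summary", "",
             md_table(data.frame(category = summary_df$category,
                                 cost = fmt_usd(summary_df$cost, TRUE))))
  emit(lines, path)
}

#' Render a classified FMEA register
#'
#' The register with derived columns, the summary counts, and — when
#' printed RPNs are present — an audit section listing rows whose printed
#' RPN disagrees with exact recomputation.
#'
#' @param register an `fmea_register`, classified by [fmea()] (it is run
#'   with defaults if not).
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param audit_tolerance absolute tolerance for the audit section.
#' @param path write to this file instead of returning a string.
#' @return a single string (invisibly the path when `path` is given).
#' @export
fmea_report <- function(register, format = c("markdown", "csv", "json"),
                        audit_tolerance = 0.1, path = NULL) {
  format <- match.arg(format)
  if (is.null(register$risk_level)) register <- fmea(register)
  s <- fmea_summary(register)
  audit <- audit_register(register, tolerance = audit_tolerance)
  cols <- intersect(c("id", "step", "role", "O", "S", "D", "printed_rpn",
                      "rpn_display", "risk_level", "top_rpn",
                      "top_severity"), names(register))
  tab <- as.data.frame(register)[cols]
  if (format == "json") {
    return(emit(jsonlite::toJSON(list(register = tab,
                                      summary = s, audit = audit),
                                 dataframe = "rows", auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE), path))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    audit_lines <- if (nrow(audit)) {
      c("", "audit_id,printed_rpn,recomputed,discrepancy",
        paste0(audit$id, ",", audit$printed_rpn, ",", audit$recomputed,
               ",", round_half_away(audit$discrepancy, 2)))
    } else character(0)
    return(emit(c(out, audit_lines), path))
  }
  lines <- c("## FMEA register", "", md_table(tab), "",
             "### Summary", "",
             paste0("- total: ", s$total),
             paste0("- high: ", s$high, ", medium: ", s$medium,
                    ", low: ", s$low),
             paste0("- top-RPN flagged: ", s$n_top_rpn,
                    ", top-severity flagged: ", s$n_top_severity))
  if (nrow(audit)) {
    lines <- c(lines, "", "### Audit: printed RPN vs exact recomputation",
               "", md_table(audit))
  }
  emit(lines, path)
}

#' Render a scenario analysis
#'
#' Per-intervention and combined savings with category decomposition, time
#' saved, and the reduced grand total.
#'
#' @param result a `scenario_result` from [combine_interventions()].
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param path write to this file instead of returning a string.
#' @return a single string (invisibly the path when `path` is given).
#' @export
scenario_report <- function(result, format = c("markdown", "csv", "json"),
                            path = NULL) {
  format <- match.arg(format)
  rows <- c(result$per_intervention, list(combined = result$combined))
  tab <- data.frame(
    intervention = vapply(rows, `[[`, "", "name"),
    personnel = vapply(rows, `[[`, 0, "personnel"),
    equipment = vapply(rows, `[[`, 0, "equipment"),
    space = vapply(rows, `[[`, 0, "space"),
    total = vapply(rows, `[[`, 0, "total"),
    time_saved_min = vapply(rows, `[[`, 0, "time_saved"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  footer <- data.frame(
    quantity = c("baseline_total", "reduced_total", "time_saved_min"),
    value = c(result$baseline_total, result$reduced_total,
              result$time_saved))
  if (format == "json") {
    tab[2:6] <- lapply(tab[2:6], round_half_away, digits = 2)
    footer$value <- round_half_away(footer$value, 2)
    return(emit(jsonlite::toJSON(list(savings = tab, totals = footer),
                                 dataframe = "rows", auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE), path))
  }
  if (format == "csv") {
    tab[2:6] <- lapply(tab[2:6], function(x) fmt_usd(x, FALSE))
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    return(emit(c(out, "",
                  "quantity,value",
                  paste0(footer$quantity, ",",
                         fmt_usd(footer$value, FALSE))), path))
  }
  show <- tab
  show[2:5] <- lapply(show[2:5], function(x) fmt_usd(x, TRUE))
  show$time_saved_min <- formatC(show$time_saved_min, format = "f",
                                 digits = 2)
  lines <- c("## Scenario analysis", "", md_table(show), "",
             paste0("- baseline grand total: ",
                    fmt_usd(result$baseline_total, TRUE)),
             paste0("- reduced grand total: ",
                    fmt_usd(result$reduced_total, TRUE)),
             paste0("- total time saved: ",
                    formatC(result$time_saved, format = "f", digits = 2),
                    " min"))
  emit(lines, path)
}
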