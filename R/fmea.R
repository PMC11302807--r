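#' TG-100-style failure modes and effects analysis
#'
#' Failure modes carry occurrence (O), severity (S) and detectability (D)
#' scores on 1..10 scales. Consensus scores may be exact fractions: when
#' three raters score independently and are averaged, values like 5.33 are
#' really 16/3, and the risk priority number RPN = O x S x D must be formed
#' from the exact fractions (832/9 displays as 92.44; multiplying the
#' rounded displays gives 92.32). Registers are CSV files whose score cells
#' accept an integer, a decimal, a fraction `"16/3"`, or a semicolon-
#' separated rater list `"5;5;6"`.
#'
#' Risk levels come from a monotone (severity x occurrence) matrix with a
#' severity override: S = 9-10 is high risk at any occurrence.
#'
#' @name fmea
NULL

RISK_LEVELS <- c("low", "medium", "high")

## ---- score parsing ----------------------------------------------------

#' Parse score cells into exact rationals
#'
#' @param x character (or numeric) vector. Each element may be an integer,
#'   a decimal, a fraction `"a/b"`, or a rater list `"5;5;6"` (averaged).
#' @param mode how to interpret bare decimals. `"thirds"` (default) maps a
#'   two-decimal value to the nearest third when that third rounds back to
#'   the printed value (5.33 -> 16/3), which is the correct reading of
#'   tables produced by averaging three raters. `"decimal"` takes the
#'   decimal literally (5.33 -> 533/100).
#' @return a `rational` vector.
#' @export
parse_scores <- function(x, mode = c("thirds", "decimal")) {
  mode <- match.arg(mode)
  if (length(x) == 0) return(rational(numeric(0)))
  parts <- lapply(as.character(x), parse_score1, mode = mode)
  out <- do.call(c, parts)
  bad <- as.numeric(out) < 1 | as.numeric(out) > 10
  if (any(bad)) {
    stop("score(s) outside [1, 10]: ",
         paste(as.character(out)[bad], collapse = ", "), call. = FALSE)
  }
  out
}

parse_score1 <- function(s, mode) {
  s <- trimws(s)
  if (!nzchar(s) || is.na(s)) stop("empty score cell", call. = FALSE)
  if (grepl(";", s, fixed = TRUE)) {
    raters <- suppressWarnings(as.numeric(strsplit(s, ";")[[1]]))
    return(consensus(raters))
  }
  if (grepl("/", s, fixed = TRUE)) {
    ab <- suppressWarnings(as.numeric(strsplit(s, "/")[[1]]))
    if (length(ab) != 2 || anyNA(ab)) {
      stop("malformed fraction score '", s, "'", call. = FALSE)
    }
    return(rational(ab[1], ab[2]))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("malformed score '", s, "'", call. = FALSE)
  if (v == round(v)) return(rational(v))
  if (mode == "thirds") {
    k <- round(v * 3)
    if (k >= 3 && k <= 30 && round_half_away(rational(k, 3), 2) == v) {
      return(rational(k, 3))
    }
  }
  digits <- nchar(sub("^[^.]*\\.", "", s))
  rational(round(v * 10^digits), 10^digits)
}

#' Consensus score from independent rater scores
#'
#' @param rater_scores integer scores in 1..10, one per rater.
#' @param method `"mean_exact"` returns the exact rational mean (the
#'   independent-scoring path); `"agreed_value"` requires a single value
#'   (the discussion-consensus path).
#' @return a length-1 `rational`.
#' @examples
#' as.character(consensus(c(5, 5, 6)))   # "16/3"
#' @export
consensus <- function(rater_scores, method = c("mean_exact", "agreed_value")) {
  method <- match.arg(method)
  if (length(rater_scores) == 0 || anyNA(rater_scores)) {
    stop("rater scores must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(rater_scores < 1 | rater_scores > 10)) {
    stop("rater scores must lie in [1, 10]", call. = FALSE)
  }
  if (any(rater_scores != round(rater_scores))) {
    stop("rater scores must be integers", call. = FALSE)
  }
  if (method == "agreed_value") {
    if (length(unique(rater_scores)) != 1L) {
      stop("agreed_value requires a single agreed score", call. = FALSE)
    }
    return(rational(rater_scores[1]))
  }
  mean(rational(rater_scores))
}

#' Risk priority number
#'
#' RPN = O x S x D, computed exactly. Integer scores give an integer RPN;
#' thirds give exact multiples of 1/27 (or 1/9, 1/3).
#'
#' @param O,S,D scores as `rational` (or integer) values.
#' @return a `rational`; use [round_half_away()] or `format()` for the
#'   two-decimal display form.
#' @examples
#' as.numeric(rpn(7, 8, 4))                                   # 224
#' format(rpn(rational(4), rational(16, 3), rational(13, 3))) # "92.44"
#' @export
rpn <- function(O, S, D) {
  as_rational(O) * as_rational(S) * as_rational(D)
}

## ---- risk matrix ------------------------------------------------------

#' Construct and validate a risk matrix
#'
#' A 10 x 10 grid assigning a level in {low, medium, high} to every integer
#' (S, O) pair. Validity requires monotonicity (the level never decreases as
#' S or O increases) and the severity override: rows S = 9 and 10 are
#' entirely high. Invalid grids are rejected.
#'
#' @param grid a 10 x 10 character matrix (rows S = 1..10, columns
#'   O = 1..10) of `"low"`/`"medium"`/`"high"` (or `"L"`/`"M"`/`"H"`).
#' @return an object of class `risk_matrix`.
#' @export
risk_matrix <- function(grid) {
  if (!is.matrix(grid) || !all(dim(grid) == c(10, 10))) {
    stop("risk matrix grid must be 10 x 10", call. = FALSE)
  }
  expand <- c(L = "low", M = "medium", H = "high",
              low = "low", medium = "medium", high = "high")
  lv <- expand[as.character(grid)]
  if (anyNA(lv)) stop("risk matrix cells must be L/M/H", call. = FALSE)
  g <- matrix(lv, 10, 10, dimnames = list(S = 1:10, O = 1:10))
  num <- matrix(match(g, RISK_LEVELS), 10, 10)
  if (any(apply(num, 1, diff) < 0) || any(apply(num, 2, diff) < 0)) {
    stop("risk matrix is not monotone in S and O", call. = FALSE)
  }
  if (any(g[9:10, ] != "high")) {
    stop("severity override violated: rows S = 9-10 must be high",
         call. = FALSE)
  }
  structure(g, class = "risk_matrix")
}

#' Default risk matrix
#'
#' The published grid's cell boundaries are not machine-readable, so the
#' packaged default is an assumption, chosen to be monotone and compatible
#' with TG-100 1..10 scales: high when S >= 9 (any O), or S >= 7 and O >= 6,
#' or S >= 5 and O >= 8; low when S <= 2, or S <= 4 and O <= 3; medium
#' elsewhere. Any user grid satisfying [risk_matrix()]'s invariants may be
#' substituted.
#'
#' @return a `risk_matrix`.
#' @export
default_risk_matrix <- function() {
  S <- matrix(1:10, 10, 10)
  O <- matrix(1:10, 10, 10, byrow = TRUE)
  g <- matrix("medium", 10, 10)
  g[S <= 2 | (S <= 4 & O <= 3)] <- "low"
  g[S >= 9 | (S >= 7 & O >= 6) | (S >= 5 & O >= 8)] <- "high"
  risk_matrix(g)
}

#' Read / write a risk matrix file
#'
#' Plain text: 10 whitespace-separated rows (S = 1..10) of 10 cells
#' (O = 1..10) drawn from L/M/H.
#'
#' @param path file path.
#' @return [read_risk_matrix()] returns a validated `risk_matrix`.
#' @export
read_risk_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^ *#", lines)]
  if (length(lines) != 10) {
    stop("risk matrix file must have 10 data rows", call. = FALSE)
  }
  cells <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  if (any(lengths(cells) != 10)) {
    stop("each risk matrix row must have 10 cells", call. = FALSE)
  }
  risk_matrix(do.call(rbind, cells))
}

#' @rdname read_risk_matrix
#' @param matrix a `risk_matrix` to write.
#' @export
write_risk_matrix <- function(matrix, path) {
  abbrev <- c(low = "L", medium = "M", high = "H")
  writeLines(apply(matrix, 1, function(r) paste(abbrev[r], collapse = " ")),
             path)
  invisible(path)
}

#' @export
print.risk_matrix <- function(x, ...) {
  cat("<risk matrix> rows S = 1..10 (bottom high), columns O = 1..10\n")
  abbrev <- c(low = "L", medium = "M", high = "H")
  m <- matrix(abbrev[x], 10, 10, dimnames = dimnames(unclass(x)))
  print(m, quote = FALSE)
  invisible(x)
}

rational_ceiling <- function(x) {
  # exact ceiling of a positive rational vector
  n <- x$num
  d <- x$den
  ifelse(n %% d == 0, n %/% d, n %/% d + 1)
}

#' Classify a failure mode's risk level
#'
#' Looks the matrix up at the ceiling-rounded, 1..10-clamped (S, O) pair.
#' Ceiling is the conservative choice for fractional consensus scores: it
#' never understates risk. Severity >= 9 yields high regardless of
#' occurrence (the override rows of any valid matrix).
#'
#' @param S,O scores (`rational` or numeric in [1, 10]).
#' @param matrix a valid `risk_matrix`.
#' @return character vector of `"low"`/`"medium"`/`"high"`.
#' @export
classify_risk <- function(S, O, matrix = default_risk_matrix()) {
  if (!inherits(matrix, "risk_matrix")) matrix <- risk_matrix(matrix)
  si <- pmin(10, pmax(1, if (is_rational(S)) rational_ceiling(S)
                         else ceiling(S)))
  oi <- pmin(10, pmax(1, if (is_rational(O)) rational_ceiling(O)
                         else ceiling(O)))
  out <- unclass(matrix)[cbind(si, oi)]
  out[si >= 9] <- "high"
  out
}

## ---- registers --------------------------------------------------------

register_scores <- function(reg, col) {
  parse_scores(reg[[col]], mode = attr(reg, "score_mode") %||% "thirds")
}

#' Build a failure-mode register
#'
#' @param df data.frame with columns `id`, `O`, `S`, `D` (score cells as
#'   accepted by [parse_scores()]); optional `step`, `role`, `description`,
#'   `cause`, `effect`, `printed_rpn`.
#' @param score_mode decimal interpretation passed to [parse_scores()].
#' @return data.frame of class `fmea_register`.
#' @export
as_register <- function(df, score_mode = c("thirds", "decimal")) {
  score_mode <- match.arg(score_mode)
  miss <- setdiff(c("id", "O", "S", "D"), names(df))
  if (length(miss)) {
    stop("register missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate failure-mode id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  df$id <- as.character(df$id)
  for (col in c("O", "S", "D")) df[[col]] <- as.character(df[[col]])
  rownames(df) <- NULL
  attr(df, "score_mode") <- score_mode
  class(df) <- c("fmea_register", "data.frame")
  # parse now so malformed cells fail at load, with the row named
  for (col in c("O", "S", "D")) {
    for (i in seq_len(nrow(df))) {
      tryCatch(parse_scores(df[[col]][i], mode = score_mode),
               error = function(e) {
                 stop("row '", df$id[i], "', column ", col, ": ",
                      conditionMessage(e), call. = FALSE)
               })
    }
  }
  df
}

#' Read / write a failure-mode register CSV
#'
#' Input columns: `id, step, role, description, cause, effect, O, S, D`
#' (score cells: decimal, fraction `"16/3"`, or rater list `"5;5;6"`), plus
#' optional `printed_rpn`. [fmea()] appends the derived columns `rpn`,
#' `risk_level`, `top_rpn`, `top_severity`, which [write_register()]
#' preserves.
#'
#' @param path CSV path.
#' @param score_mode decimal interpretation, see [parse_scores()].
#' @return [read_register()] returns an `fmea_register`.
#' @export
read_register <- function(path, score_mode = c("thirds", "decimal")) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error reading register '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  as_register(df, score_mode = match.arg(score_mode))
}

#' @rdname read_register
#' @param register an `fmea_register`.
#' @export
write_register <- function(register, path) {
  utils::write.csv(as.data.frame(register), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Flag the top fraction of a register by RPN or severity
#'
#' Ranks descending by the key and flags the `k = ceiling(fraction * n)`
#' highest items; every item tied with the k-th value is included, so the
#' flagged set is well-defined under ties. With `group_by = "role"` the
#' ranking is done independently within each personnel role.
#'
#' @param register an `fmea_register`.
#' @param fraction fraction in (0, 1] to flag (0.2 = top 20%).
#' @param key `"rpn"` or `"severity"`.
#' @param group_by `"none"` or `"role"`.
#' @return logical vector, one flag per register row.
#' @export
top_fraction <- function(register, fraction = 0.2,
                         key = c("rpn", "severity"),
                         group_by = c("none", "role")) {
  key <- match.arg(key)
  group_by <- match.arg(group_by)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(register)
  if (n == 0) return(logical(0))
  vals <- if (key == "rpn") {
    as.numeric(rpn(register_scores(register, "O"),
                   register_scores(register, "S"),
                   register_scores(register, "D")))
  } else {
    as.numeric(register_scores(register, "S"))
  }
  groups <- if (group_by == "role") {
    if (is.null(register$role)) {
      stop("group_by = 'role' requires a role column", call. = FALSE)
    }
    register$role
  } else {
    rep("all", n)
  }
  flags <- logical(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    k <- ceiling(fraction * length(idx))
    cutoff <- sort(vals[idx], decreasing = TRUE)[k]
    flags[idx] <- vals[idx] >= cutoff
  }
  flags
}

#' Score, classify and flag a failure-mode register
#'
#' The main FMEA entry point: computes exact RPNs, risk levels from the
#' matrix, and top-fraction flags for RPN and severity (globally, or per
#' role via `group_by`).
#'
#' @param register an `fmea_register` (see [as_register()]).
#' @param matrix a `risk_matrix`.
#' @param fraction top fraction to flag (default 0.2, the top 20%).
#' @param group_by `"none"` for register-wide top-RPN flags or `"role"` for
#'   per-personnel flags.
#' @return the register with derived columns `rpn` (numeric, exact value),
#'   `rpn_display` (two-decimal display), `risk_level`, `top_rpn`,
#'   `top_severity`.
#' @export
fmea <- function(register, matrix = default_risk_matrix(), fraction = 0.2,
                 group_by = c("none", "role")) {
  group_by <- match.arg(group_by)
  O <- register_scores(register, "O")
  S <- register_scores(register, "S")
  D <- register_scores(register, "D")
  r <- rpn(O, S, D)
  register$rpn <- as.numeric(r)
  register$rpn_display <- round_half_away(r, 2)
  register$risk_level <- classify_risk(S, O, matrix)
  register$top_rpn <- top_fraction(register, fraction, key = "rpn",
                                   group_by = group_by)
  register$top_severity <- top_fraction(register, fraction,
                                        key = "severity",
                                        group_by = group_by)
  attr(register, "fraction") <- fraction
  attr(register, "group_by") <- group_by
  register
}

#' Summary counts of a classified register
#'
#' @param register an `fmea_register` processed by [fmea()].
#' @return named list: `total`, `high`, `medium`, `low`, `n_top_rpn`,
#'   `n_top_severity`; the three levels always partition the total.
#' @export
fmea_summary <- function(register) {
  if (is.null(register$risk_level)) register <- fmea(register)
  lv <- factor(register$risk_level, levels = RISK_LEVELS)
  counts <- table(lv)
  list(total = nrow(register),
       high = as.integer(counts[["high"]]),
       medium = as.integer(counts[["medium"]]),
       low = as.integer(counts[["low"]]),
       n_top_rpn = sum(register$top_rpn %||% logical(0)),
       n_top_severity = sum(register$top_severity %||% logical(0)))
}

#' Audit printed RPNs against exact recomputation
#'
#' Data-quality check for transcribed published tables: recomputes each
#' row's RPN from its (possibly fractional) scores and reports rows whose
#' printed RPN differs by more than the tolerance — typically publication
#' errata.
#'
#' @param register an `fmea_register` with a `printed_rpn` column.
#' @param tolerance absolute tolerance (default 0.1).
#' @return data.frame with columns `id`, `printed_rpn`, `recomputed`
#'   (two-decimal display of the exact value), `discrepancy`; zero rows when
#'   everything agrees within tolerance.
#' @export
audit_register <- function(register, tolerance = 0.1) {
  empty <- data.frame(id = character(0), printed_rpn = numeric(0),
                      recomputed = numeric(0), discrepancy = numeric(0))
  if (is.null(register$printed_rpn) || nrow(register) == 0) return(empty)
  has <- !is.na(register$printed_rpn)
  if (!any(has)) return(empty)
  r <- rpn(register_scores(register, "O"),
           register_scores(register, "S"),
           register_scores(register, "D"))
  exact <- as.numeric(r)
  disc <- abs(register$printed_rpn - exact)
  bad <- has & disc > tolerance
  data.frame(id = register$id[bad],
             printed_rpn = register$printed_rpn[bad],
             recomputed = round_half_away(r, 2)[bad],
             discrepancy = disc[bad],
             row.names = NULL)
}

#' @export
print.fmea_register <- function(x, ...) {
  cat("<FMEA register> ", nrow(x), " failure mode(s)",
      if (!is.null(x$risk_level)) " (classified)", "\n", sep = "")
  cols <- intersect(c("id", "role", "O", "S", "D", "rpn_display",
                      "risk_level", "top_rpn", "top_severity"), names(x))
  print(utils::head(as.data.frame(x)[cols], 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.fmea_register <- function(object, ...) {
  s <- fmea_summary(object)
  cat("FMEA register:", s$total, "failure modes\n")
  cat("  high:", s$high, " medium:", s$medium, " low:", s$low, "\n")
  cat("  top-RPN flagged:", s$n_top_rpn,
      " top-severity flagged:", s$n_top_severity, "\n")
  invisible(s)
}
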