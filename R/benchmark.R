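# Evaluation layer: per-compound errors, MAE, calculated-vs-reference
# regression and cost accounting, plus table rendering in the published
# layout (compound rows, one column per functional, MAE row last).

.check_columns <- function(calc, ref) {
  if (!is.numeric(calc) || !is.numeric(ref)) {
    stop("pKa columns must be numeric", call. = FALSE)
  }
  if (length(calc) != length(ref)) {
    stop("column lengths differ (", length(calc), " vs ", length(ref), ")",
         call. = FALSE)
  }
  if (length(calc) == 0L) stop("columns must be non-empty", call. = FALSE)
  invisible(TRUE)
}

#' Mean absolute error of a calculated pKa column
#'
#' `mean(|calc - ref|)` over the panel; `NA` pairs (unusable published cells)
#' are dropped together. Computed at full precision — rounding to the
#' two-decimal reporting grain happens only in [render_benchmark()].
#'
#' @param calc,ref Numeric pKa columns of equal length.
#' @return The MAE (dimensionless).
#' @examples
#' tab <- reference_benchmark()
#' mae(tab[["CAM-B3LYP"]], builtin_compounds()$pka_ref) # 0.2318...
#' @export
mae <- function(calc, ref) {
  .check_columns(calc, ref)
  keep <- !is.na(calc) & !is.na(ref)
  if (!any(keep)) stop("no complete pairs", call. = FALSE)
  mean(abs(calc[keep] - ref[keep]))
}

#' Signed per-compound pKa deviations
#'
#' `calc - ref` elementwise, plus the compound with the largest absolute
#' deviation — the per-functional "worst case" the benchmark discusses.
#'
#' @param calc,ref Numeric pKa columns of equal length.
#' @param compounds Optional compound names for labeling.
#' @return A list with `delta` (named when `compounds` given) and
#'   `max_abs_compound` / `max_abs_delta` for the largest |deviation| among
#'   complete pairs.
#' @export
delta_pka <- function(calc, ref, compounds = NULL) {
  .check_columns(calc, ref)
  delta <- calc - ref
  if (!is.null(compounds)) names(delta) <- compounds
  i <- which.max(abs(delta))
  list(delta = delta,
       max_abs_compound = if (!is.null(compounds)) compounds[i] else i,
       max_abs_delta = delta[[i]])
}

#' Calculated-versus-reference linear regression
#'
#' Ordinary least squares of the calculated pKa column on the reference
#' column (slope 1 / intercept 0 being the ideal method), with Pearson's r
#' and the coefficient of determination (COD, r^2). No points are excluded;
#' incomplete pairs are dropped. The orientation can be flipped for
#' exploratory fits that regress the reference on the calculation.
#'
#' @param calc,ref Numeric pKa columns (>= 3 complete pairs; the predictor
#'   must have nonzero variance).
#' @param orientation `"calc_on_ref"` (default) or `"ref_on_calc"`.
#' @return A list with `slope`, `intercept`, `pearson_r`, `cod`, `n`.
#' @export
pka_regression <- function(calc, ref,
                           orientation = c("calc_on_ref", "ref_on_calc")) {
  orientation <- match.arg(orientation)
  .check_columns(calc, ref)
  keep <- !is.na(calc) & !is.na(ref)
  x <- if (orientation == "calc_on_ref") ref[keep] else calc[keep]
  y <- if (orientation == "calc_on_ref") calc[keep] else ref[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) <= .Machine$double.eps) {
    stop("predictor column has (near-)zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = r, cod = r^2, n = length(x))
}

#' Computational cost per conjugated pair
#'
#' The benchmark's cost measure: per functional, the mean over compounds of
#' the summed wall time of the acid and its conjugate base.
#'
#' @param times Data.frame with columns `compound`, `functional`, `kind`
#'   (`"acid"` or `"base"`) and `minutes`.
#' @return Named numeric vector, minutes per pair, one entry per functional.
#' @examples
#' t <- data.frame(compound = "Benzoic Acid", functional = "CAM-B3LYP",
#'                 kind = c("acid", "base"), minutes = c(30, 22))
#' cost_summary(t) # 52
#' @export
cost_summary <- function(times) {
  needed <- c("compound", "functional", "kind", "minutes")
  if (!is.data.frame(times) || !all(needed %in% names(times)) ||
      nrow(times) == 0L) {
    stop("`times` must be a non-empty data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  times <- times[times$kind %in% c("acid", "base"), ]
  out <- c()
  for (f in unique(times$functional)) {
    tf <- times[times$functional == f, ]
    pair_sum <- vapply(unique(tf$compound), function(cmp) {
      a <- tf$minutes[tf$compound == cmp & tf$kind == "acid"]
      b <- tf$minutes[tf$compound == cmp & tf$kind == "base"]
      if (length(a) != 1L || length(b) != 1L) {
        stop("unpaired acid/base times for '", cmp, "' under ", f,
             call. = FALSE)
      }
      a + b
    }, numeric(1))
    out[f] <- mean(pair_sum)
  }
  out
}

#' Assemble a benchmark table
#'
#' Bundles the panel's reference pKa column with one calculated column per
#' functional, recomputing the MAE row and the regression summaries from the
#' columns themselves (so the table is always self-consistent), and attaching
#' an optional cost row.
#'
#' @param compounds Character vector of compound names (row order).
#' @param reference Numeric reference pKa column.
#' @param columns Named list or data.frame of calculated pKa columns, one per
#'   functional, each aligned with `compounds`.
#' @param cost Optional named numeric vector of minutes per pair.
#' @return An object of class `benchmark_table` with fields `compounds`,
#'   `reference`, `columns`, `mae_row`, `regression`, `cost`.
#' @export
benchmark_table <- function(compounds, reference, columns, cost = NULL) {
  columns <- as.list(columns)
  if (!length(columns)) stop("need at least one functional column", call. = FALSE)
  bad <- vapply(columns, function(col) length(col) != length(compounds),
                logical(1))
  if (any(bad)) {
    stop("column length mismatch for: ", paste(names(columns)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (length(reference) != length(compounds)) {
    stop("`reference` must align with `compounds`", call. = FALSE)
  }
  mae_row <- vapply(columns, function(col) {
    if (length(col) == 0L || !any(!is.na(col) & !is.na(reference))) {
      return(NA_real_)
    }
    mae(col, reference)
  }, numeric(1))
  regression <- lapply(columns, function(col) {
    tryCatch(pka_regression(col, reference), error = function(e) NULL)
  })
  out <- list(compounds = compounds, reference = reference, columns = columns,
              mae_row = mae_row, regression = regression, cost = cost)
  class(out) <- "benchmark_table"
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(render_benchmark(x, "markdown"))
  invisible(x)
}

.fmt2 <- function(v) ifelse(is.na(v), "", formatC(v, format = "f", digits = 2))

.benchmark_frame <- function(table) {
  df <- data.frame(COMPOUND = table$compounds,
                   pKa_ref = table$reference,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (f in names(table$columns)) df[[f]] <- table$columns[[f]]
  df
}

#' Render a benchmark table
#'
#' Deterministic text rendering in the published layout: compound rows with
#' the reference column first, functionals in their given order, pKa at two
#' decimals, and the (recomputed) MAE row last. JSON output is lossless and
#' round-trips through [read_benchmark()].
#'
#' @param table A [benchmark_table()].
#' @param format `"csv"`, `"markdown"` or `"json"`.
#' @return The rendered table as one character scalar.
#' @export
render_benchmark <- function(table, format = c("csv", "markdown", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "benchmark_table"))
  df <- .benchmark_frame(table)
  if (format == "json") {
    payload <- list(compounds = table$compounds, reference = table$reference,
                    columns = table$columns, mae_row = as.list(table$mae_row),
                    regression = table$regression, cost = as.list(table$cost))
    return(as.character(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                                         null = "null")))
  }
  body <- df
  for (col in names(body)[-1]) body[[col]] <- .fmt2(body[[col]])
  rows <- body
  if (any(!is.na(table$mae_row))) {
    rows <- rbind(body, c("MAE", "", .fmt2(table$mae_row)))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE, quote = TRUE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  widths <- nchar(names(rows))
  if (nrow(rows)) {
    widths <- pmax(widths, apply(rows, 2, function(col) max(nchar(col))))
  }
  pad <- function(v) mapply(formatC, v, width = widths, flag = "-")
  lines <- c(
    paste0("| ", paste(pad(names(rows)), collapse = " | "), " |"),
    paste0("|-", paste(strrep("-", widths), collapse = "-|-"), "-|"),
    if (nrow(rows)) {
      apply(rows, 1, function(r) paste0("| ", paste(pad(r), collapse = " | "), " |"))
    }
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname render_benchmark
#' @param text JSON text (or a file path to it) produced by
#'   `render_benchmark(..., format = "json")`.
#' @export
read_benchmark <- function(text) {
  if (length(text) == 1L && !grepl("[{\n]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  p <- jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = TRUE)
  cost <- if (length(p$cost)) unlist(p$cost) else NULL
  benchmark_table(compounds = p$compounds, reference = p$reference,
                  columns = as.list(as.data.frame(p$columns,
                                                  check.names = FALSE)),
                  cost = cost)
}
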