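#' Cleveland heart-disease table schema
#'
#' Canonical column order, feature kinds and declared value ranges for the
#' 13-predictor Cleveland heart-disease table. Two dialects of the nominal
#' encodings are declared: `"uci"`, the integer codes used in the distributed
#' processed file (`cp` 1-4, `slope` 1-3, `thal` 3/6/7), and `"zero_based"`,
#' the 0-based prose codes (`cp` 0-3, `slope` 0-2, `thal` 1-3).
#'
#' @param dialect `"uci"` (default) or `"zero_based"`; selects the declared
#'   nominal level sets.
#' @return A tibble with one row per predictor: `feature`, `kind`
#'   (`"numeric"`/`"nominal"`), `levels` (list-column of allowed codes for
#'   nominal features), `lower`, `upper` (declared bounds for numeric
#'   features, `NA` when open).
#' @export
#' @examples
#' cleveland_schema()
cleveland_schema <- function(dialect = c("uci", "zero_based")) {
  dialect <- match.arg(dialect)
  lv <- function(...) list(c(...))
  base <- tibble::tribble(
    ~feature,   ~kind,     ~levels,      ~lower, ~upper,
    "age",      "numeric", list(NULL),   29,     77,
    "sex",      "nominal", lv(0, 1),     NA,     NA,
    "cp",       "nominal", lv(1:4),      NA,     NA,
    "trestbps", "numeric", list(NULL),   NA,     NA,
    "chol",     "numeric", list(NULL),   NA,     NA,
    "fbs",      "nominal", lv(0, 1),     NA,     NA,
    "restecg",  "nominal", lv(0:2),      NA,     NA,
    "thalach",  "numeric", list(NULL),   NA,     NA,
    "exang",    "nominal", lv(0, 1),     NA,     NA,
    "oldpeak",  "numeric", list(NULL),   0,      6.2,
    "slope",    "nominal", lv(1:3),      NA,     NA,
    "ca",       "nominal", lv(0:3),      NA,     NA,
    "thal",     "nominal", lv(3, 6, 7),  NA,     NA
  )
  if (dialect == "zero_based") {
    base$levels[base$feature == "cp"] <- lv(0:3)
    base$levels[base$feature == "slope"] <- lv(0:2)
    base$levels[base$feature == "thal"] <- lv(1:3)
  }
  base
}

cleveland_columns <- function() c(cleveland_schema()$feature, "target")

#' Feature kinds for a predictor table
#'
#' Returns the per-feature kind tag (`"numeric"` or `"nominal"`) used by the
#' mutual-information scorer and the synthetic generator. Kinds attached by
#' [read_cleveland()] or [generate_cohort()] (as the `"kinds"` attribute) are
#' used when present; otherwise a column is tagged nominal when its
#' non-missing values are whole numbers with at most eight distinct codes.
#'
#' @param data A data frame of predictors.
#' @return Named character vector over the predictor columns.
#' @export
feature_kinds <- function(data) {
  preds <- predictor_names(data)
  k <- attr(data, "kinds")
  if (!is.null(k) && all(preds %in% names(k))) {
    return(k[preds])
  }
  vapply(preds, function(nm) {
    v <- data[[nm]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return("numeric")
    u <- unique(v)
    if (all(abs(v - round(v)) < 1e-8) && length(u) <= 8) "nominal" else "numeric"
  }, character(1))
}

predictor_names <- function(data) setdiff(names(data), "target")

predictor_frame <- function(data) {
  as_tibble(data)[predictor_names(data)]
}

#' Read a Cleveland-dialect clinical table
#'
#' Parses the UCI processed-Cleveland CSV dialect: 14 comma-separated fields
#' per line, no header, `"?"` for missing, the final field an integer disease
#' stage 0-4. Returns the 13 predictors in canonical schema order plus the
#' raw `target` column; `"?"` tokens become `NA`.
#'
#' Generic CSVs with a header are also accepted: pass `header = TRUE` and
#' (optionally) `target_col` naming the outcome column, which is renamed to
#' `target`.
#'
#' @param source Path to a file, or a character vector of raw lines.
#' @param header Does the source carry a header row? Default `FALSE`
#'   (Cleveland dialect).
#' @param target_col Name of the outcome column when `header = TRUE`.
#' @return A tibble with columns `age` ... `thal`, `target`, in row order of
#'   the source, with a `"kinds"` attribute giving each predictor's kind.
#' @export
#' @examples
#' lines <- c(
#'   "63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
#'   "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2"
#' )
#' read_cleveland(lines)
read_cleveland <- function(source, header = FALSE, target_col = "target") {
  lines <- if (length(source) == 1 && !grepl(",", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty input: no data lines found")

  if (header) {
    cols <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
    cols <- trimws(cols)
    lines <- lines[-1]
  } else {
    cols <- cleveland_columns()
  }

  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(cols))
  if (length(bad) > 0) {
    abort(sprintf(
      "line %d has %d fields; expected %d", bad[1], nf[bad[1]], length(cols)
    ))
  }
  mat <- matrix(trimws(unlist(fields)), nrow = length(lines), byrow = TRUE)
  parsed <- apply(mat, 2, function(col) {
    col[col == "?"] <- NA_character_
    out <- suppressWarnings(as.numeric(col))
    tok <- which(!is.na(col) & is.na(out))
    if (length(tok) > 0) {
      abort(sprintf(
        "non-numeric token '%s' at line %d (only '?' marks missing)",
        col[tok[1]], tok[1]
      ))
    }
    out
  })
  if (is.null(dim(mat)) || nrow(mat) == 1) parsed <- matrix(parsed, nrow = 1)
  out <- as_tibble(as.data.frame(parsed, col.names = cols))
  names(out) <- cols
  if (!header) {
    out$target <- as.integer(out$target)
    attr(out, "kinds") <- setNames(cleveland_schema()$kind, cleveland_schema()$feature)
  } else {
    if (target_col %in% names(out) && target_col != "target") {
      names(out)[names(out) == target_col] <- "target"
    }
    attr(out, "kinds") <- feature_kinds(out)
  }
  out
}

#' Write a table back to the Cleveland dialect
#'
#' Inverse of [read_cleveland()]: comma-separated fields, no header, `NA`
#' written as `"?"`. Round-tripping preserves values and missingness.
#'
#' @param data Tibble as returned by [read_cleveland()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleveland <- function(data, path) {
  cols <- intersect(cleveland_columns(), names(data))
  m <- vapply(cols, function(nm) {
    v <- data[[nm]]
    s <- vapply(v, function(x) {
      if (is.na(x)) "?" else format(x, scientific = FALSE, trim = TRUE)
    }, character(1))
    s
  }, character(nrow(data)))
  if (nrow(data) == 1) m <- matrix(m, nrow = 1)
  writeLines(apply(m, 1, paste, collapse = ","), path)
  invisible(path)
}

#' Collapse the raw disease stage to a binary label
#'
#' The raw Cleveland target is an integer stage 0-4; stage 0 means no disease
#' and any positive stage means disease present. Idempotent on its own output.
#'
#' @param raw Integer vector with values in 0..4.
#' @return Integer vector of 0/1 labels (1 = heart disease).
#' @export
#' @examples
#' binarize_target(c(0, 1, 3, 0))
binarize_target <- function(raw) {
  if (any(is.na(raw))) abort("target contains missing values")
  if (any(raw < 0 | raw > 4 | raw != round(raw))) {
    abort("target values must be integers in 0..4")
  }
  as.integer(raw > 0)
}

column_mode <- function(v) {
  v <- v[!is.na(v)]
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

#' Resolve missing values
#'
#' Two strategies: `"mode"` replaces each missing cell with its column's most
#' frequent non-missing value (keeps every row); `"drop_rows"` removes any
#' row containing a missing value. Non-missing cells are never altered.
#'
#' @param data Tibble with `NA` marking missing cells.
#' @param strategy `"mode"` (default) or `"drop_rows"`.
#' @return Tibble with no missing values, same attributes.
#' @export
impute_missing <- function(data, strategy = c("mode", "drop_rows")) {
  strategy <- match.arg(strategy)
  kinds <- attr(data, "kinds")
  out <- as_tibble(data)
  if (strategy == "drop_rows") {
    out <- out[complete.cases(out), , drop = FALSE]
  } else {
    for (nm in names(out)) {
      miss <- is.na(out[[nm]])
      if (!any(miss)) next
      if (all(miss)) abort(sprintf("column '%s' is entirely missing", nm))
      out[[nm]][miss] <- column_mode(out[[nm]])
    }
  }
  attr(out, "kinds") <- kinds
  out
}

#' Validate a table against the Cleveland schema
#'
#' Reports, per feature, values outside the declared ranges: nominal codes
#' not in the declared level set and numeric values outside declared bounds.
#' Missing cells are ignored. An empty report means the table is valid.
#'
#' @param data Tibble of predictors (a `target` column is ignored).
#' @param dialect Nominal encoding dialect, see [cleveland_schema()].
#' @return Tibble with columns `feature`, `row`, `value`, `problem`; zero
#'   rows when valid.
#' @export
schema_validate <- function(data, dialect = c("uci", "zero_based")) {
  schema <- cleveland_schema(match.arg(dialect))
  preds <- intersect(schema$feature, predictor_names(data))
  rows <- purrr::map_dfr(preds, function(nm) {
    spec <- schema[schema$feature == nm, ]
    v <- data[[nm]]
    idx <- which(!is.na(v))
    if (spec$kind == "nominal") {
      lev <- unlist(spec$levels)
      bad <- idx[!(v[idx] %in% lev)]
      if (length(bad) == 0) return(NULL)
      tibble(
        feature = nm, row = bad, value = v[bad],
        problem = sprintf("level not in {%s}", paste(lev, collapse = ","))
      )
    } else {
      lo <- spec$lower
      hi <- spec$upper
      bad <- idx[(!is.na(lo) & v[idx] < lo) | (!is.na(hi) & v[idx] > hi)]
      if (length(bad) == 0) return(NULL)
      tibble(
        feature = nm, row = bad, value = v[bad],
        problem = sprintf("outside [%s, %s]", lo, hi)
      )
    }
  })
  if (nrow(rows) == 0) {
    rows <- tibble(
      feature = character(), row = integer(),
      value = numeric(), problem = character()
    )
  }
  rows
}

#' Structural checks for the canonical Cleveland file
#'
#' Verifies the distributed processed-Cleveland file: 303 records, 13
#' predictor attributes, age range 29-77, and that dropping incomplete rows
#' leaves 297 records. Intended to run against a locally available copy of
#' the file; it is not downloaded by the package.
#'
#' @param path Path to a processed-Cleveland file.
#' @return Tibble with columns `check`, `expected`, `observed`, `pass`.
#' @export
check_cleveland_file <- function(path) {
  tab <- read_cleveland(path)
  complete <- impute_missing(tab, "drop_rows")
  tibble(
    check = c("n_records", "n_predictors", "age_min", "age_max", "n_complete"),
    expected = c(303, 13, 29, 77, 297),
    observed = c(
      nrow(tab), length(predictor_names(tab)),
      min(tab$age, na.rm = TRUE), max(tab$age, na.rm = TRUE),
      nrow(complete)
    )
  ) |>
    dplyr::mutate(pass = .data$expected == .data$observed)
}
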