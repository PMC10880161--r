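#' @importFrom rlang .data
NULL

MODEL_COLUMNS <- c("feature", "coef", "min", "max", "type", "position")
PREDICTOR_TYPES <- c("continuous", "discrete", "nominal", "ordinal")
LABEL_POSITIONS <- c("up", "down")

#' Construct a logistic-model specification
#'
#' A `nomo_model` is a tibble of predictor rows (columns `feature`, `coef`,
#' `min`, `max`, `type`, `position`) carrying the model intercept and the
#' optional decision threshold as attributes. It is the sole input to
#' nomogram construction: no training data is ever required, only the
#' fitted coefficients and each predictor's plausible range.
#'
#' Predictor names containing `"::"` are interpreted as one-hot indicator
#' levels of a nominal variable, `"<parent>::<level>"`. All levels of one
#' parent share a single (dashed) axis in the rendered nomogram; the
#' reference level of the one-hot coding is implicit and sits at 0 points.
#' Such rows must have `min = 0`, `max = 1`.
#'
#' @param predictors Data frame with the six template columns; one row per
#'   predictor, in display order.
#' @param intercept Model intercept on the log-odds scale.
#' @param threshold Optional probability cutoff strictly inside (0, 1)
#'   separating predicted high- from low-risk cases, or `NULL`.
#' @return A `nomo_model` tibble.
#' @examples
#' m <- nomo_model(
#'   tibble::tibble(
#'     feature = c("age", "smoker"),
#'     coef = c(0.04, 0.8), min = c(20, 0), max = c(90, 1),
#'     type = c("continuous", "nominal"), position = c("up", "down")
#'   ),
#'   intercept = -3, threshold = 0.5
#' )
#' model_intercept(m)
#' @export
nomo_model <- function(predictors, intercept, threshold = NULL) {
  predictors <- tibble::as_tibble(predictors)[MODEL_COLUMNS]
  rep <- validate_model(predictors_to_raw(predictors, intercept, threshold))
  if (nrow(rep$errors) > 0) {
    stop("invalid model specification:\n",
         paste(format_report_rows(rep$errors), collapse = "\n"),
         call. = FALSE)
  }
  build_model(predictors, intercept, threshold)
}

build_model <- function(predictors, intercept, threshold) {
  # drop degenerate zero-range, zero-coefficient rows (warned by validation)
  drop <- predictors$max == predictors$min & predictors$coef == 0
  predictors <- predictors[!drop, , drop = FALSE]
  structure(
    predictors,
    intercept = as.numeric(intercept),
    threshold = if (is.null(threshold) || is.na(threshold)) NULL
                else as.numeric(threshold),
    class = c("nomo_model", class(tibble::tibble()))
  )
}

#' @rdname nomo_model
#' @param model A `nomo_model`.
#' @export
model_intercept <- function(model) attr(model, "intercept")

#' @rdname nomo_model
#' @export
model_threshold <- function(model) attr(model, "threshold")

#' Nominal one-hot group membership
#'
#' Returns the parent variable name for each predictor row: the part before
#' `"::"` for one-hot level indicators, `NA` for ordinary predictors. Rows
#' sharing a parent are rendered on a single axis.
#'
#' @param model A `nomo_model` (or any data frame with a `feature` column).
#' @return Character vector, one element per predictor row.
#' @export
nominal_parent <- function(model) {
  ifelse(grepl("::", model$feature, fixed = TRUE),
         sub("::.*$", "", model$feature), NA_character_)
}

#' Read a model-metadata template
#'
#' Reads the six-column nomogram template (`feature`, `coef`, `min`, `max`,
#' `type`, `position`) from a CSV file or the first sheet of an XLSX
#' workbook. The first two data rows are reserved: row 1 carries the model
#' intercept in the `coef` column, row 2 the probability threshold (left
#' blank when the model has none). Remaining rows are predictors, kept in
#' file order. The header spelling `family coef` is accepted as an alias
#' for `coef`.
#'
#' @param path Path to a `.csv` or `.xlsx` template.
#' @return A validated [nomo_model()].
#' @seealso [write_model_template()], [validate_model()]
#' @export
read_model_template <- function(path) {
  if (!file.exists(path)) {
    stop("template file not found: ", path, call. = FALSE)
  }
  raw <- read_raw_template(path)
  rep <- validate_model(raw)
  if (nrow(rep$errors) > 0) {
    stop("invalid model template '", path, "':\n",
         paste(format_report_rows(rep$errors), collapse = "\n"),
         call. = FALSE)
  }
  raw_to_model(raw)
}

read_raw_template <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    readxl::read_excel(path, sheet = 1, col_types = "text")
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE)
  }
  names(raw) <- sub("^family[ ._]?coef$", "coef", trimws(tolower(names(raw))))
  raw
}

raw_to_model <- function(raw) {
  pred <- raw[-(1:2), MODEL_COLUMNS]
  pred$coef <- as.numeric(pred$coef)
  pred$min <- as.numeric(pred$min)
  pred$max <- as.numeric(pred$max)
  pred$type <- trimws(pred$type)
  pred$position <- trimws(pred$position)
  thr_txt <- trimws(as.character(raw$coef[2]))
  build_model(
    tibble::as_tibble(pred),
    intercept = as.numeric(raw$coef[1]),
    threshold = if (is.na(thr_txt) || thr_txt == "") NULL
                else as.numeric(thr_txt)
  )
}

predictors_to_raw <- function(predictors, intercept, threshold) {
  thr <- if (is.null(threshold)) NA_real_ else as.numeric(threshold)
  header <- tibble::tibble(
    feature = c("intercept", "threshold"),
    coef = c(as.numeric(intercept), thr),
    min = NA_real_, max = NA_real_,
    type = NA_character_, position = NA_character_
  )
  dplyr::bind_rows(header, tibble::as_tibble(predictors))
}

#' Write a model template
#'
#' Writes a `nomo_model` back to the six-column CSV template dialect, with
#' the intercept and (possibly blank) threshold in the two reserved rows.
#' Re-reading the file with [read_model_template()] reproduces the model
#' field for field, and rewriting the re-read model is byte-stable.
#'
#' @param model A `nomo_model`.
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_model_template <- function(model, path) {
  stopifnot(inherits(model, "nomo_model"))
  raw <- predictors_to_raw(tibble::as_tibble(model),
                           model_intercept(model), model_threshold(model))
  readr::write_csv(raw, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate raw template rows
#'
#' Checks every template invariant on a raw (all-character or typed) table
#' and reports each violation with its row and column rather than failing:
#' missing columns, a non-numeric intercept, a threshold outside (0, 1),
#' non-numeric predictor cells, unknown `type`/`position` tokens,
#' `max < min`, duplicate names, and malformed one-hot rows. Degenerate
#' predictors (zero coefficient, or zero range with zero coefficient) are
#' warnings, not errors: they carry no information but break nothing.
#'
#' @param raw Data frame in template layout: header columns plus the two
#'   reserved rows ahead of the predictors.
#' @return A `nomo_validation` list with tibbles `errors` and `warnings`,
#'   each with columns `row`, `column`, `message`. Row numbers count data
#'   rows, so predictor rows start at 3.
#' @export
validate_model <- function(raw) {
  errors <- list()
  warnings <- list()
  note <- function(store, row, column, message) {
    c(store, list(tibble::tibble(row = row, column = column,
                                 message = message)))
  }

  raw <- tibble::as_tibble(raw)
  names(raw) <- sub("^family[ ._]?coef$", "coef",
                    trimws(tolower(names(raw))))
  missing_cols <- setdiff(MODEL_COLUMNS, names(raw))
  for (col in missing_cols) {
    errors <- note(errors, NA_integer_, col,
                   paste0("missing required column '", col, "'"))
  }
  if (length(missing_cols) == 0 && nrow(raw) < 3) {
    errors <- note(errors, NA_integer_, "feature",
                   "template needs at least 3 rows: intercept, threshold, and one predictor")
  }

  if (length(errors) == 0) {
    num <- function(x) suppressWarnings(as.numeric(x))
    blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

    if (is.na(num(raw$coef[1]))) {
      errors <- note(errors, 1L, "coef", "intercept must be numeric")
    }
    if (!blank(raw$coef[2])) {
      thr <- num(raw$coef[2])
      if (is.na(thr)) {
        errors <- note(errors, 2L, "coef", "threshold must be numeric or blank")
      } else if (thr <= 0 || thr >= 1) {
        errors <- note(errors, 2L, "coef",
                       "threshold must lie strictly between 0 and 1")
      }
    }

    pred <- raw[-(1:2), , drop = FALSE]
    seen <- character()
    for (i in seq_len(nrow(pred))) {
      row <- i + 2L
      name <- trimws(as.character(pred$feature[i]))
      cf <- num(pred$coef[i]); lo <- num(pred$min[i]); hi <- num(pred$max[i])
      for (col in c("coef", "min", "max")) {
        if (is.na(num(pred[[col]][i]))) {
          errors <- note(errors, row, col,
                         paste0("'", col, "' must be numeric on predictor rows"))
        }
      }
      type <- trimws(as.character(pred$type[i]))
      if (!type %in% PREDICTOR_TYPES) {
        errors <- note(errors, row, "type",
                       paste0("unknown type '", type, "'; expected one of ",
                              paste(PREDICTOR_TYPES, collapse = ", ")))
      }
      pos <- trimws(as.character(pred$position[i]))
      if (!pos %in% LABEL_POSITIONS) {
        errors <- note(errors, row, "position",
                       paste0("unknown position '", pos,
                              "'; expected 'up' or 'down'"))
      }
      if (!is.na(lo) && !is.na(hi)) {
        if (hi < lo) {
          errors <- note(errors, row, "max", "max must be >= min")
        } else if (hi == lo) {
          if (!is.na(cf) && cf == 0) {
            warnings <- note(warnings, row, "max",
                             "degenerate predictor (max = min, coef = 0) will be dropped")
          } else {
            errors <- note(errors, row, "max",
                           "max = min with a nonzero coefficient: the value-to-points map is undefined")
          }
        }
      }
      if (!is.na(cf) && cf == 0 && !identical(lo, hi)) {
        warnings <- note(warnings, row, "coef",
                         "zero coefficient: predictor carries no points")
      }
      if (grepl("::", name, fixed = TRUE) &&
          !is.na(lo) && !is.na(hi) && !(lo == 0 && hi == 1)) {
        errors <- note(errors, row, "min",
                       "one-hot level rows ('parent::level') must have min = 0, max = 1")
      }
      if (name %in% seen) {
        errors <- note(errors, row, "feature",
                       paste0("duplicate predictor name '", name, "'"))
      }
      seen <- c(seen, name)
    }
  }

  empty <- tibble::tibble(row = integer(), column = character(),
                          message = character())
  structure(
    list(errors = if (length(errors)) dplyr::bind_rows(errors) else empty,
         warnings = if (length(warnings)) dplyr::bind_rows(warnings) else empty),
    class = "nomo_validation"
  )
}

format_report_rows <- function(tbl) {
  sprintf("  row %s, column '%s': %s",
          ifelse(is.na(tbl$row), "-", tbl$row), tbl$column, tbl$message)
}

#' @export
print.nomo_validation <- function(x, ...) {
  cat("Template validation:",
      nrow(x$errors), "error(s),", nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) cat("Errors:\n",
                          paste(format_report_rows(x$errors), collapse = "\n"),
                          "\n", sep = "")
  if (nrow(x$warnings)) cat("Warnings:\n",
                            paste(format_report_rows(x$warnings), collapse = "\n"),
                            "\n", sep = "")
  invisible(x)
}

#' @export
print.nomo_model <- function(x, ...) {
  thr <- model_threshold(x)
  cat("<nomo_model> ", nrow(x), " predictor(s), intercept ",
      format(model_intercept(x)),
      if (!is.null(thr)) paste0(", threshold ", format(thr)) else "",
      "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
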