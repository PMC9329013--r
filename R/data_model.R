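#' Read a heart-disease dataset from CSV
#'
#' Reads a comma-separated file (header row required, UTF-8, decimal point)
#' holding the 13 clinical features and optionally the binary outcome,
#' validates it against the schema and returns a [heart_dataset()].
#' Header names are matched case-insensitively and the common column
#' spellings of the public heart dataset (`age`, `trestbps`, `thalach`,
#' `target`, ...) are accepted as aliases.
#'
#' @param path Path to a CSV file.
#' @param has_outcome Logical; require an outcome column (default `TRUE`).
#' @param drop_missing Drop rows with missing cells instead of erroring.
#' @param normalized Set `TRUE` when reading back an already-normalized CSV.
#' @return A `heart_dataset`.
#' @export
#' @examples
#' sim <- generate_heart_data(table2_default_spec(n = 5))
#' f <- tempfile(fileext = ".csv")
#' write_heart_data(sim$data, f)
#' read_heart_data(f)
read_heart_data <- function(path, has_outcome = TRUE, drop_missing = FALSE,
                            normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty dataset file: ", path, call. = FALSE)
  }
  data <- heart_dataset(raw, has_outcome = has_outcome,
                        drop_missing = drop_missing, normalized = normalized)
  message("read ", nrow(data), " row(s) from ", path)
  data
}

#' Write a heart dataset to CSV
#'
#' @param data A `heart_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heart_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit min-max normalization parameters
#'
#' Records, per feature, the observed minimum and maximum used by the
#' standardization `y = (x - xmin) / (xmax - xmin)` that maps every feature
#' into `[0, 1]`. Constant (zero-range) columns are rejected because the
#' mapping would be degenerate.
#'
#' @param data A raw-scale `heart_dataset`.
#' @return A `minmax_params` object: a data frame with columns `feature`,
#'   `xmin`, `xmax`.
#' @seealso [normalize_heart()], [denormalize_heart()]
#' @export
fit_normalization <- function(data) {
  stopifnot(inherits(data, "heart_dataset"))
  if (is_normalized(data)) {
    stop("data is already normalized; fit parameters on the raw scale",
         call. = FALSE)
  }
  X <- feature_matrix(data)
  xmin <- apply(X, 2, min)
  xmax <- apply(X, 2, max)
  degenerate <- xmax <= xmin
  if (any(degenerate)) {
    stop("constant (degenerate) feature column(s): ",
         paste(HEART_FEATURES[degenerate], collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(feature = HEART_FEATURES, xmin = unname(xmin),
               xmax = unname(xmax), stringsAsFactors = FALSE),
    class = c("minmax_params", "data.frame")
  )
}

#' @keywords internal
#' @noRd
check_params <- function(params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!identical(params$feature, HEART_FEATURES)) {
    stop("normalization parameters do not cover the 13 schema features in order",
         call. = FALSE)
  }
  invisible(params)
}

#' Apply min-max standardization
#'
#' Maps each feature cell by `(x - xmin) / (xmax - xmin)`. Values observed
#' outside the fitted range (e.g. a new patient at prediction time) map
#' outside `[0, 1]`; by default they pass through with a warning, or are
#' clamped to `[0, 1]` with `clamp = TRUE`.
#'
#' @param data A raw-scale `heart_dataset`.
#' @param params A `minmax_params` object from [fit_normalization()].
#' @param clamp Clamp out-of-range normalized values into `[0, 1]`.
#' @return A normalized `heart_dataset`.
#' @export
normalize_heart <- function(data, params, clamp = FALSE) {
  stopifnot(inherits(data, "heart_dataset"))
  check_params(params)
  if (is_normalized(data)) stop("data is already normalized", call. = FALSE)
  out <- as.data.frame(data)
  for (i in seq_along(HEART_FEATURES)) {
    feat <- HEART_FEATURES[i]
    y <- (out[[feat]] - params$xmin[i]) / (params$xmax[i] - params$xmin[i])
    if (any(y < 0 | y > 1)) {
      if (clamp) {
        y <- pmin(pmax(y, 0), 1)
      } else {
        warning("feature '", feat, "' has value(s) outside the fitted ",
                "range; normalized values fall outside [0, 1]", call. = FALSE)
      }
    }
    out[[feat]] <- y
  }
  structure(out, normalized = TRUE,
            class = c("heart_dataset", "data.frame"))
}

#' Invert min-max standardization
#'
#' Maps each normalized cell back to the raw scale by
#' `x = y * (xmax - xmin) + xmin`; the exact inverse of [normalize_heart()]
#' up to floating-point round-off.
#'
#' @inheritParams normalize_heart
#' @param data A normalized `heart_dataset`.
#' @return A raw-scale `heart_dataset`.
#' @export
denormalize_heart <- function(data, params) {
  stopifnot(inherits(data, "heart_dataset"))
  check_params(params)
  if (!is_normalized(data)) stop("data is not normalized", call. = FALSE)
  out <- as.data.frame(data)
  for (i in seq_along(HEART_FEATURES)) {
    feat <- HEART_FEATURES[i]
    out[[feat]] <- out[[feat]] * (params$xmax[i] - params$xmin[i]) +
      params$xmin[i]
  }
  structure(out, normalized = FALSE,
            class = c("heart_dataset", "data.frame"))
}

#' Save or load normalization parameters as JSON
#'
#' The sidecar format is `{"<feature>": {"min": ..., "max": ...}, ...}` so
#' that fitted models can be shipped together with the scaling they assume.
#'
#' @param params A `minmax_params` object.
#' @param path JSON file path.
#' @return `write_normalization()` returns `path` invisibly;
#'   `read_normalization()` returns a `minmax_params`.
#' @export
write_normalization <- function(params, path) {
  check_params(params)
  obj <- stats::setNames(
    lapply(seq_len(nrow(params)), function(i) {
      list(min = params$xmin[i], max = params$xmax[i])
    }),
    params$feature
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_feats <- setdiff(HEART_FEATURES, names(obj))
  if (length(missing_feats)) {
    stop("normalization file missing feature(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(
      feature = HEART_FEATURES,
      xmin = vapply(HEART_FEATURES, function(f) obj[[f]][["min"]], 0),
      xmax = vapply(HEART_FEATURES, function(f) obj[[f]][["max"]], 0),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    class = c("minmax_params", "data.frame")
  )
}
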