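#' Clinical feature schema for heart-disease identification
#'
#' The models in this package operate on a fixed, ordered set of 13 clinical
#' features plus a binary heart-disease outcome (`Hd`). The feature order is
#' load-bearing: the cascade fits features in this order and the neural
#' network's input-weight columns are indexed by it, so every dataset, model
#' and prediction in the package shares this single ordering constant.
#'
#' Features (in order): `Ac` age (years), `Sc` sex (1 = male, 0 = female),
#' `Cp` chest-pain type (1-3), `Bp` resting blood pressure (mm Hg), `Ch`
#' serum cholesterol (mg/dl), `Fb` fasting blood sugar > 120 mg/dl (0/1),
#' `Re` resting ECG result (0-2), `Hr` maximum heart rate (bpm), `Ex`
#' exercise-induced angina (0/1), `Op` exercise-induced ST depression, `Sp`
#' slope of the peak-exercise ST segment (0-2), `Ca` number of major vessels
#' coloured by fluoroscopy (0-3), `Th` thalassemia code (1-3).
#'
#' @return A data frame with one row per feature: `name` (symbol used
#'   throughout the package), `type` (`"continuous"`, `"binary"` or
#'   `"ordinal"`), and `domain` (list column: the admissible codes for
#'   categorical features, or the plausible raw range for continuous ones,
#'   used only by the synthetic generator).
#' @seealso [read_heart_data()], [fit_cascade()], [ann_weights()]
#' @export
#' @examples
#' heart_schema()$name
heart_schema <- function() {
  data.frame(
    name = HEART_FEATURES,
    type = c("continuous", "binary", "ordinal", "continuous", "continuous",
             "binary", "ordinal", "continuous", "binary", "continuous",
             "ordinal", "ordinal", "ordinal"),
    domain = I(list(
      c(29, 77),    # Ac: raw age range
      c(0, 1),      # Sc
      c(1, 2, 3),   # Cp
      c(94, 200),   # Bp
      c(126, 564),  # Ch
      c(0, 1),      # Fb
      c(0, 1, 2),   # Re
      c(71, 202),   # Hr
      c(0, 1),      # Ex
      c(0, 6.2),    # Op
      c(0, 1, 2),   # Sp
      c(0, 1, 2, 3),# Ca
      c(1, 2, 3)    # Th
    )),
    stringsAsFactors = FALSE
  )
}

# The single source of truth for feature order (Ac first, Th last).
HEART_FEATURES <- c("Ac", "Sc", "Cp", "Bp", "Ch", "Fb", "Re",
                    "Hr", "Ex", "Op", "Sp", "Ca", "Th")

HEART_OUTCOME <- "Hd"

# Common column spellings of the public heart dataset, mapped onto the
# package symbols. Matching is case-insensitive.
HEART_ALIASES <- c(
  age = "Ac", sex = "Sc", cp = "Cp", chestpain = "Cp",
  trestbps = "Bp", restbp = "Bp", bp = "Bp",
  chol = "Ch", cholesterol = "Ch",
  fbs = "Fb", restecg = "Re",
  thalach = "Hr", maxhr = "Hr", thalachh = "Hr",
  exang = "Ex", oldpeak = "Op", slope = "Sp", slp = "Sp",
  ca = "Ca", caa = "Ca", thal = "Th", thall = "Th",
  target = "Hd", num = "Hd", output = "Hd", disease = "Hd"
)

#' @keywords internal
#' @noRd
canonical_names <- function(nms) {
  out <- character(length(nms))
  all_canon <- c(HEART_FEATURES, HEART_OUTCOME)
  for (i in seq_along(nms)) {
    lower <- tolower(nms[i])
    hit <- match(lower, tolower(all_canon))
    if (!is.na(hit)) {
      out[i] <- all_canon[hit]
    } else if (lower %in% names(HEART_ALIASES)) {
      out[i] <- HEART_ALIASES[[lower]]
    } else {
      stop("unknown column '", nms[i], "': not a feature symbol (",
           paste(HEART_FEATURES, collapse = ", "), ", ", HEART_OUTCOME,
           ") or a recognised alias", call. = FALSE)
    }
  }
  out
}

#' @keywords internal
#' @noRd
check_feature_domains <- function(data) {
  sch <- heart_schema()
  for (i in seq_len(nrow(sch))) {
    if (sch$type[i] == "continuous") next
    feat <- sch$name[i]
    dom <- sch$domain[[i]]
    bad <- which(!(data[[feat]] %in% dom))
    if (length(bad)) {
      stop("feature '", feat, "' has value ", data[[feat]][bad[1]],
           " outside its domain {", paste(dom, collapse = ", "),
           "} at row ", bad[1], call. = FALSE)
    }
  }
  invisible(data)
}

#' Construct a validated heart dataset
#'
#' Wraps a data frame holding the 13 clinical features (and optionally the
#' `Hd` outcome) into the container the rest of the package expects:
#' columns reordered to schema order, categorical codes checked against
#' their domains, missing values rejected or dropped.
#'
#' @param data A data frame whose columns cover the 13 schema features
#'   (canonical symbols or common aliases, case-insensitive), plus
#'   optionally the outcome.
#' @param has_outcome Logical; must an `Hd` column be present?
#' @param drop_missing If `TRUE`, rows containing missing cells are dropped
#'   (with a message reporting the count); if `FALSE` (default) any missing
#'   cell is an error.
#' @param normalized Logical flag recording whether the features are on the
#'   min-max normalized scale (each column in `[0, 1]`).
#' @param binary_outcome If `TRUE` (default) the outcome must be coded 0/1,
#'   as in clinical data; set `FALSE` for benchmark datasets carrying a
#'   continuous regression target in the outcome column.
#' @return A `heart_dataset`: a data frame in schema column order with
#'   attribute `normalized`.
#' @export
heart_dataset <- function(data, has_outcome = TRUE, drop_missing = FALSE,
                          normalized = FALSE, binary_outcome = TRUE) {
  stopifnot(is.data.frame(data))
  names(data) <- canonical_names(names(data))
  missing_feats <- setdiff(HEART_FEATURES, names(data))
  if (length(missing_feats)) {
    stop("dataset is missing feature column(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  if (has_outcome && !(HEART_OUTCOME %in% names(data))) {
    stop("dataset is missing the outcome column '", HEART_OUTCOME, "'",
         call. = FALSE)
  }
  keep <- c(HEART_FEATURES, intersect(HEART_OUTCOME, names(data)))
  data <- data[, keep, drop = FALSE]

  for (nm in keep) {
    if (!is.numeric(data[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[nm]]))) &
                     !is.na(data[[nm]]))
      stop("non-numeric value in column '", nm, "'",
           if (length(bad)) paste0(" at row ", bad[1]) else "", call. = FALSE)
    }
  }

  incomplete <- !stats::complete.cases(data)
  if (any(incomplete)) {
    if (drop_missing) {
      message("dropping ", sum(incomplete), " row(s) with missing values")
      data <- data[!incomplete, , drop = FALSE]
    } else {
      stop(sum(incomplete), " row(s) contain missing values (first at row ",
           which(incomplete)[1], "); use drop_missing = TRUE to drop them",
           call. = FALSE)
    }
  }
  if (nrow(data) == 0) stop("dataset has no complete rows", call. = FALSE)

  if (!normalized) check_feature_domains(data)
  if (binary_outcome && HEART_OUTCOME %in% names(data)) {
    bad <- which(!(data[[HEART_OUTCOME]] %in% c(0, 1)))
    if (length(bad)) {
      stop("outcome '", HEART_OUTCOME, "' must be 0/1; offending row ",
           bad[1], call. = FALSE)
    }
  }
  if (normalized) {
    rng <- range(as.matrix(data[, HEART_FEATURES]))
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("normalized dataset has feature values outside [0, 1]",
           call. = FALSE)
    }
  }

  rownames(data) <- NULL
  structure(data, normalized = normalized,
            class = c("heart_dataset", "data.frame"))
}

#' Test or query the normalization state of a heart dataset
#' @param data A `heart_dataset`.
#' @return Logical scalar.
#' @export
is_normalized <- function(data) isTRUE(attr(data, "normalized"))

#' @keywords internal
#' @noRd
feature_matrix <- function(data) {
  as.matrix(as.data.frame(data)[, HEART_FEATURES, drop = FALSE])
}

#' @export
print.heart_dataset <- function(x, ...) {
  cat("Heart dataset: ", nrow(x), " patients, ",
      length(HEART_FEATURES), " features",
      if (HEART_OUTCOME %in% names(x)) " + outcome Hd" else "",
      " (", if (is_normalized(x)) "normalized" else "raw", " scale)\n",
      sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
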