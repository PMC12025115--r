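#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate select all_of across filter arrange group_by ungroup
#'   summarise bind_rows bind_cols left_join pull n rename count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl imap walk
NULL

#' Reserved metadata column names
#'
#' Columns with these names are never treated as compositional parts.
#' @noRd
.reserved_meta <- c("sample_id", "specimen", "prep", "cluster", "label")

#' Identify the compositional part columns of a table
#'
#' Parts are the numeric columns of `data` that are not reserved metadata
#' (`sample_id`, `specimen`, `prep`, `cluster`, `label`). All compositional
#' verbs in spicoda accept an explicit `parts` character vector; when it is
#' omitted they fall back to this rule.
#'
#' @param data A data frame of samples (rows) by parts and metadata (columns).
#' @return Character vector of part column names, in column order.
#' @examples
#' coda_parts(tibble::tibble(sample_id = "s1", C = 10, O = 60, Ca = 30))
#' @export
coda_parts <- function(data) {
  stopifnot(is.data.frame(data))
  nm <- names(data)
  is_num <- vapply(data, is.numeric, logical(1))
  nm[is_num & !(nm %in% .reserved_meta)]
}

#' Validate a composition table
#'
#' Checks the structural invariants every downstream operation relies on:
#' part values are non-negative and finite, no row is entirely zero, and
#' sample identifiers (when present) are unique.
#'
#' @inheritParams coda_parts
#' @param parts Character vector of part column names.
#' @param require_positive If `TRUE`, require strictly positive values
#'   (the precondition of the log-ratio transforms).
#' @return `data`, invisibly, if valid; otherwise an error describing the
#'   offending sample and part.
#' @export
validate_composition <- function(data, parts = coda_parts(data),
                                 require_positive = FALSE) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(parts, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing part column(s): ", paste(missing, collapse = ", ")),
          class = "spicoda_format_error")
  }
  if (anyDuplicated(parts)) {
    abort("Duplicate part names.", class = "spicoda_validation_error")
  }
  ids <- .sample_ids(data)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "spicoda_validation_error")
  }
  x <- .part_matrix(data, parts)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(paste0("Non-finite value in part '", parts[bad[2]],
                 "', sample '", ids[bad[1]], "'."),
          class = "spicoda_validation_error")
  }
  lim <- if (require_positive) 0 else -1e-12
  if (any(x <= lim)) {
    bad <- which(x <= lim, arr.ind = TRUE)[1, ]
    abort(paste0(if (require_positive) "Non-positive" else "Negative",
                 " value in part '", parts[bad[2]],
                 "', sample '", ids[bad[1]], "'."),
          class = "spicoda_validation_error")
  }
  if (any(rowSums(x) <= 0)) {
    abort(paste0("Sample '", ids[which(rowSums(x) <= 0)[1]],
                 "' has zero total across parts."),
          class = "spicoda_validation_error")
  }
  invisible(data)
}

.sample_ids <- function(data) {
  if ("sample_id" %in% names(data)) as.character(data$sample_id)
  else as.character(seq_len(nrow(data)))
}

.part_matrix <- function(data, parts) {
  x <- as.matrix(as.data.frame(data)[, parts, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- .sample_ids(data)
  x
}

.set_parts <- function(data, m) {
  for (j in colnames(m)) data[[j]] <- as.numeric(m[, j])
  data
}

#' Read an elemental composition table from CSV
#'
#' Expects a comma-separated file with a header row and dot decimals. The
#' named `part_columns` must be present and parse as non-negative reals; all
#' other columns are carried along as metadata. Rows are *not* re-closed on
#' input — closure is an explicit, separate step ([close_composition()]).
#'
#' @param path Path to a CSV file.
#' @param part_columns Character vector naming the compositional part columns
#'   (e.g. `c("C", "O", "Ca", "Mg", "Cl", "F", "P")`).
#' @return A tibble with one row per sample, validated but unmodified.
#' @seealso [write_composition_csv()], [close_composition()], [amalgamate()]
#' @export
read_composition_csv <- function(path, part_columns) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "spicoda_format_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(part_columns, names(data))
  if (length(missing) > 0) {
    abort(paste0("CSV is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "spicoda_format_error")
  }
  for (p in part_columns) {
    if (!is.numeric(data[[p]])) {
      v <- suppressWarnings(as.numeric(data[[p]]))
      if (any(is.na(v) & !is.na(data[[p]]))) {
        abort(paste0("Column '", p, "' contains non-numeric values."),
              class = "spicoda_format_error")
      }
      data[[p]] <- v
    }
  }
  validate_composition(data, part_columns)
  data
}

#' Write a composition table to CSV
#'
#' @inheritParams validate_composition
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_composition_csv <- function(data, path, parts = coda_parts(data)) {
  validate_composition(data, parts)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Close compositions to a constant sum
#'
#' Rescales every row so its parts sum to `kappa` (default 100, the percent
#' scale of EDX output). Ratios within a row are unchanged; closure is
#' idempotent.
#'
#' @inheritParams validate_composition
#' @param kappa Positive closure constant; 100 for percentages.
#' @return The table with part columns rescaled.
#' @examples
#' d <- tibble::tibble(a = 1, b = 1, c = 2)
#' close_composition(d)  # 25, 25, 50
#' @export
close_composition <- function(data, parts = coda_parts(data), kappa = 100) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  validate_composition(data, parts)
  x <- .part_matrix(data, parts)
  .set_parts(data, x * (kappa / rowSums(x)))
}

#' Amalgamate parts into a single new part
#'
#' Replaces the listed parts by one part equal to their row-wise sum, on the
#' raw (percent) scale. In the spicule workflow the low-represented elements
#' Cl, F and P are amalgamated into `"Traces"` before any log-ratio
#' transform, so that sporadic non-detections (zeros) in single trace
#' elements do not break the log scale. Row sums are unchanged, so
#' amalgamation and closure commute.
#'
#' @inheritParams validate_composition
#' @param parts_to_merge Character vector of part names to merge.
#' @param new_name Name of the amalgamated part (default `"Traces"`).
#' @return The table with `parts_to_merge` replaced by `new_name`, placed at
#'   the position of the first merged column.
#' @export
amalgamate <- function(data, parts_to_merge, new_name = "Traces",
                       parts = coda_parts(data)) {
  validate_composition(data, parts)
  unknown <- setdiff(parts_to_merge, parts)
  if (length(unknown) > 0) {
    abort(paste0("Unknown part(s): ", paste(unknown, collapse = ", ")),
          class = "spicoda_validation_error")
  }
  if (new_name %in% setdiff(names(data), parts_to_merge)) {
    abort(paste0("Column '", new_name, "' already exists."),
          class = "spicoda_validation_error")
  }
  x <- .part_matrix(data, parts_to_merge)
  pos <- match(parts_to_merge[1], names(data))
  keep <- setdiff(names(data), parts_to_merge)
  out <- data[, keep, drop = FALSE]
  # place the new part where the first merged column used to sit
  after_n <- sum(match(keep, names(data)) < pos)
  out <- tibble::add_column(out, !!new_name := unname(rowSums(x)),
                            .after = after_n)
  out
}

#' Replace zero parts by a small detection-limit value
#'
#' Multiplicative zero replacement: each zero entry becomes `delta` (percent)
#' and the non-zero parts of that row are scaled down so the row sum is
#' preserved. The default `delta = 0.005` is half the smallest resolution at
#' which the quantified percentages are reported (0.01), a conventional
#' below-detection-limit imputation that keeps log ratios finite without
#' materially distorting the large parts.
#'
#' @inheritParams validate_composition
#' @param delta Replacement value on the percent scale.
#' @param quiet If `FALSE` (default), report the number of replaced entries.
#' @return The table with zeros replaced; row sums unchanged.
#' @export
replace_zeros <- function(data, parts = coda_parts(data), delta = 0.005,
                          quiet = FALSE) {
  stopifnot(delta > 0)
  validate_composition(data, parts)
  x <- .part_matrix(data, parts)
  nz <- x == 0
  n_rep <- sum(nz)
  if (n_rep > 0) {
    for (i in which(rowSums(nz) > 0)) {
      s <- sum(x[i, ])
      z <- sum(nz[i, ])
      if (delta * z >= s) {
        abort("delta too large for row total.",
              class = "spicoda_validation_error")
      }
      x[i, !nz[i, ]] <- x[i, !nz[i, ]] * (s - delta * z) / s
      x[i, nz[i, ]] <- delta
    }
    if (!quiet) inform(paste0("Replaced ", n_rep, " zero value(s) with delta = ",
                              format(delta), "."))
  }
  .set_parts(data, x)
}
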