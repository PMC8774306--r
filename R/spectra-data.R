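#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr group_by summarise ungroup arrange mutate filter select
#'   distinct n count across bind_rows left_join pull
#' @importFrom tibble tibble as_tibble new_tibble
NULL

# A spectra table is a plain tibble with one row per (case, replicate,
# excitation): columns case_id, label ("normal"/"cancer"), replicate,
# excitation_nm, then one em_<nm> column per emission channel. The emission
# grid lives in the column names so a CSV round-trips without a sidecar.

spectra_meta_cols <- c("case_id", "label", "replicate", "excitation_nm")

emission_cols <- function(data) {
  grep("^em_", names(data), value = TRUE)
}

#' Emission wavelength grid of a spectra table
#'
#' @param data A spectra table (see [read_spectra()]).
#' @return Numeric vector of emission wavelengths in nm, one per channel.
#' @export
emission_grid <- function(data) {
  as.numeric(sub("^em_", "", emission_cols(data)))
}

#' Excitation wavelengths of a spectra table
#'
#' @param data A spectra table.
#' @return Sorted unique excitation wavelengths in nm. Flattening uses this
#'   order (excitation-major).
#' @export
excitation_wavelengths <- function(data) {
  sort(unique(data$excitation_nm))
}

#' Validate a labelled spectra table
#'
#' Checks the structural invariants of the tabular spectra format: required
#' columns, a strictly increasing emission grid, finite non-negative
#' intensities, binary labels, one label per case, and a complete excitation
#' block for every (case, replicate) spectrum.
#'
#' @param data A data frame in the spectra table layout.
#' @return The validated data as a tibble, labels normalised to lower case,
#'   rows in canonical (case_id, replicate, excitation_nm) order.
#' @export
validate_spectra <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "fluordx_format_error")
  }
  data <- as_tibble(data)
  missing <- setdiff(spectra_meta_cols, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("Spectra table is missing column(s): ",
             paste(missing, collapse = ", "), "."),
      class = "fluordx_format_error"
    )
  }
  em <- emission_cols(data)
  if (length(em) < 1) {
    abort("Spectra table has no emission channel (em_<nm>) columns.",
          class = "fluordx_format_error")
  }
  grid <- as.numeric(sub("^em_", "", em))
  if (anyNA(grid) || any(diff(grid) <= 0)) {
    abort("Emission grid (em_<nm> column names) must be strictly increasing.",
          class = "fluordx_format_error")
  }
  data$label <- tolower(as.character(data$label))
  if (nrow(data) == 0) {
    return(data)
  }
  bad <- setdiff(unique(data$label), c("normal", "cancer"))
  if (length(bad) > 0) {
    abort(paste0("Unknown label token(s): ", paste(bad, collapse = ", "),
                 ". Labels must be 'normal' or 'cancer'."),
          class = "fluordx_value_error")
  }
  intens <- as.matrix(data[em])
  if (anyNA(intens) || !all(is.finite(intens))) {
    abort("Intensities must be finite and non-missing for every channel.",
          class = "fluordx_consistency_error")
  }
  if (any(intens < 0)) {
    abort("Intensities must be non-negative.",
          class = "fluordx_consistency_error")
  }
  multi <- data |>
    distinct(.data$case_id, .data$label) |>
    count(.data$case_id) |>
    filter(n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("Case(s) with more than one label: ",
                 paste(multi$case_id, collapse = ", "), "."),
          class = "fluordx_consistency_error")
  }
  # every spectrum must carry the full excitation block, exactly once
  exc <- excitation_wavelengths(data)
  blocks <- data |>
    count(.data$case_id, .data$replicate, name = "n_rows")
  if (any(blocks$n_rows != length(exc))) {
    abort("Every (case, replicate) spectrum must have one row per excitation.",
          class = "fluordx_consistency_error")
  }
  dup <- data |>
    count(.data$case_id, .data$replicate, .data$excitation_nm) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort("Duplicated (case, replicate, excitation) rows.",
          class = "fluordx_consistency_error")
  }
  arrange(data, .data$case_id, .data$replicate, .data$excitation_nm)
}

#' Read a labelled spectra table from CSV
#'
#' The expected layout has header columns `case_id`, `label`, `replicate`,
#' `excitation_nm`, followed by one `em_<nm>` column per emission channel.
#' Gzip-compressed files are handled transparently by extension.
#'
#' @param path Path to a CSV (or CSV.gz) file.
#' @return A validated spectra tibble.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fluordx_io_error")
  }
  # base read.csv parses doubles with strtod (correctly rounded), so the
  # %.17g representation written by write_spectra() round-trips bit-exactly
  data <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA,
                    stringsAsFactors = FALSE),
    error = function(e) {
      abort(paste0("Could not parse spectra table: ", conditionMessage(e)),
            class = "fluordx_format_error")
    }
  )
  if (nrow(data) > 0 && all(spectra_meta_cols %in% names(data))) {
    data$case_id <- as.character(data$case_id)
    data$replicate <- as.integer(data$replicate)
    # whole-number intensities/wavelengths parse as integer; keep doubles
    data$excitation_nm <- as.double(data$excitation_nm)
    for (col in grep("^em_", names(data), value = TRUE)) {
      data[[col]] <- as.double(data[[col]])
    }
  }
  validate_spectra(data)
}

#' Write a labelled spectra table to CSV
#'
#' Rows are written in deterministic (case_id, replicate, excitation)
#' order at full floating-point precision, so `read_spectra(write_spectra(x))`
#' round-trips exactly.
#'
#' @param data A spectra tibble.
#' @param path Output path; a `.gz` extension enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path) {
  data <- validate_spectra(data)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("Directory does not exist: ", dir), class = "fluordx_io_error")
  }
  # 17 significant digits guarantee a bit-exact double round trip
  out <- mutate(data, across(dplyr::where(is.double),
                             ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-class case and spectrum counts
#'
#' @param data A spectra tibble.
#' @return A tibble with one row per class plus a `total` row and columns
#'   `label`, `n_cases`, `n_spectra`.
#' @export
#' @examples
#' cfg <- cohort_config(n_cancer_cases = 2, n_normal_cases = 2,
#'                      replicates_per_case = 3, seed = 1)
#' spectra_summary(generate_cohort(cfg))
spectra_summary <- function(data) {
  data <- validate_spectra(data)
  per_class <- tibble(label = c("cancer", "normal")) |>
    left_join(
      data |>
        distinct(.data$case_id, .data$replicate, .data$label) |>
        group_by(.data$label) |>
        summarise(n_cases = dplyr::n_distinct(.data$case_id),
                  n_spectra = n(), .groups = "drop"),
      by = "label"
    ) |>
    mutate(across(c("n_cases", "n_spectra"), ~ ifelse(is.na(.x), 0L, .x)))
  bind_rows(
    per_class,
    tibble(label = "total",
           n_cases = sum(per_class$n_cases),
           n_spectra = sum(per_class$n_spectra))
  )
}

#' Flatten a spectrum matrix to a feature vector
#'
#' Concatenates the emission-channel blocks in excitation order
#' (excitation-major), the layout fed to the dense network. The fixed order
#' makes trained models reproducible.
#'
#' @param m Numeric matrix, `n_excitations` rows by `n_channels` columns.
#' @return Numeric vector of length `n_excitations * n_channels`.
#' @seealso [unflatten_spectrum()]
#' @export
flatten_spectrum <- function(m) {
  m <- as.matrix(m)
  as.vector(t(m))
}

#' Restore a spectrum matrix from a flattened feature vector
#'
#' Inverse of [flatten_spectrum()].
#'
#' @param v Numeric vector of length `n_excitations * n_channels`.
#' @param n_excitations,n_channels Matrix dimensions.
#' @return Numeric matrix `n_excitations` by `n_channels`.
#' @export
unflatten_spectrum <- function(v, n_excitations, n_channels) {
  if (length(v) != n_excitations * n_channels) {
    abort("Vector length does not match n_excitations * n_channels.",
          class = "fluordx_shape_error")
  }
  matrix(v, nrow = n_excitations, ncol = n_channels, byrow = TRUE)
}

#' Flatten every spectrum of a cohort into feature vectors
#'
#' @param data A spectra tibble.
#' @return A tibble with one row per spectrum: `case_id`, `replicate`,
#'   `label`, and a `features` list-column holding each flattened vector.
#' @export
spectra_features <- function(data) {
  fm <- feature_matrix(data)
  mutate(fm$meta,
         features = purrr::map(seq_len(nrow(fm$x)), ~ fm$x[.x, ]))
}

# Internal fast path: n_spectra x (n_exc * n_channels) matrix + metadata.
feature_matrix <- function(data) {
  data <- validate_spectra(data)
  em <- emission_cols(data)
  exc <- excitation_wavelengths(data)
  n_exc <- length(exc)
  meta <- data |>
    distinct(.data$case_id, .data$replicate, .data$label)
  intens <- as.matrix(data[em])
  # rows are already (case, replicate, excitation)-ordered, so each run of
  # n_exc rows is one spectrum; row-major reshape = excitation-major features
  x <- matrix(as.vector(t(intens)), ncol = n_exc * length(em), byrow = TRUE)
  rownames(x) <- NULL
  list(x = x, meta = meta, n_excitations = n_exc, n_channels = length(em))
}
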