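#' Default endogenous fluorophore table
#'
#' Literature-flavoured excitation/emission bands for the main skin
#' autofluorescence contributors. The `cancer_multiplier` column scales each
#' fluorophore's band in cancer tissue: collagen, NADH and FAD bands are
#' reduced in basal cell carcinoma, while porphyrin emission tends to rise.
#'
#' @return A tibble with columns `name`, `excitation_peak`, `excitation_width`,
#'   `emission_center`, `emission_width` (all nm), `base_amplitude` (a.u.)
#'   and `cancer_multiplier` (dimensionless).
#' @export
default_fluorophores <- function() {
  tibble::tribble(
    ~name,        ~excitation_peak, ~excitation_width, ~emission_center,
    ~emission_width, ~base_amplitude, ~cancer_multiplier,
    "collagen",   340, 30, 390, 40, 1.0, 0.6,
    "NADH",       360, 30, 460, 50, 0.9, 0.7,
    "FAD",        450, 30, 525, 45, 0.8, 0.7,
    "porphyrin",  405, 25, 635, 25, 0.4, 1.3
  )
}

#' Configure the synthetic fluorescence cohort generator
#'
#' Describes a labelled multispectral cohort: fluorophore emission bands
#' whose amplitudes differ between normal skin and cancer, per-case
#' log-normal heterogeneity, and additive replicate noise. The
#' `"published"` preset fixes the published cohort geometry: 137 cancer
#' and 149 normal cases whose replicate counts are allocated round-robin so
#' cancer spectra total 486 and normal spectra total 318 (804 in all).
#'
#' @param fluorophores Fluorophore tibble, see [default_fluorophores()].
#' @param excitations Excitation laser wavelengths in nm.
#' @param emission_range Emission grid limits in nm, `c(start, stop)`.
#' @param n_channels Number of emission channels per excitation.
#' @param baseline_offset Constant background intensity in a.u.
#' @param case_effect_sd Log-scale sd of the per-case multiplicative factor
#'   drawn once per fluorophore per case (biological heterogeneity).
#' @param noise_sd Additive Gaussian replicate noise sd, as a fraction of the
#'   case's maximum clean intensity.
#' @param replicates_per_case Measurements per case (`"default"` preset).
#' @param n_cancer_cases,n_normal_cases Cohort composition.
#' @param preset `"default"` (fixed replicate count per case) or
#'   `"published"` (published case and spectra totals).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `cohort_config` object (list).
#' @export
cohort_config <- function(fluorophores = default_fluorophores(),
                          excitations = c(365, 405, 450, 532),
                          emission_range = c(380, 760),
                          n_channels = 88,
                          baseline_offset = 0.05,
                          case_effect_sd = 0.3,
                          noise_sd = 0.1,
                          replicates_per_case = 5,
                          n_cancer_cases = 137,
                          n_normal_cases = 149,
                          preset = c("default", "published"),
                          seed = NULL) {
  preset <- match.arg(preset)
  stopifnot(
    is.data.frame(fluorophores),
    all(c("name", "excitation_peak", "excitation_width", "emission_center",
          "emission_width", "base_amplitude", "cancer_multiplier") %in%
          names(fluorophores)),
    all(fluorophores$excitation_width > 0),
    all(fluorophores$emission_width > 0),
    all(fluorophores$base_amplitude >= 0),
    all(fluorophores$cancer_multiplier >= 0),
    length(excitations) >= 1,
    n_channels >= 1,
    baseline_offset >= 0,
    case_effect_sd >= 0,
    noise_sd >= 0,
    replicates_per_case >= 1,
    n_cancer_cases >= 0,
    n_normal_cases >= 0
  )
  if (preset == "published") {
    n_cancer_cases <- 137L
    n_normal_cases <- 149L
  }
  structure(
    list(
      fluorophores = tibble::as_tibble(fluorophores),
      excitations = as.numeric(excitations),
      emission_grid = seq(emission_range[1], emission_range[2],
                          length.out = n_channels),
      baseline_offset = baseline_offset,
      case_effect_sd = case_effect_sd,
      noise_sd = noise_sd,
      replicates_per_case = as.integer(replicates_per_case),
      n_cancer_cases = as.integer(n_cancer_cases),
      n_normal_cases = as.integer(n_normal_cases),
      preset = preset,
      seed = seed
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  preset:", x$preset, "\n")
  cat("  cases:", x$n_cancer_cases, "cancer /", x$n_normal_cases, "normal\n")
  cat("  excitations (nm):", paste(x$excitations, collapse = ", "), "\n")
  cat("  emission grid:", length(x$emission_grid), "channels,",
      min(x$emission_grid), "-", max(x$emission_grid), "nm\n")
  cat("  fluorophores:", paste(x$fluorophores$name, collapse = ", "), "\n")
  cat("  case_effect_sd:", x$case_effect_sd, " noise_sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Gaussian emission band
#'
#' `amplitude * exp(-(grid - center)^2 / (2 * width^2))`, the simulator's
#' spectral primitive.
#'
#' @param grid Wavelengths in nm at which to evaluate the band.
#' @param center Band centre in nm.
#' @param width Band sd in nm; must be positive.
#' @param amplitude Peak intensity in a.u.
#' @return Numeric vector of intensities over `grid`.
#' @export
gaussian_band <- function(grid, center, width, amplitude) {
  if (!is.numeric(width) || width <= 0) {
    abort("`width` must be > 0.", class = "fluordx_value_error")
  }
  amplitude * exp(-(grid - center)^2 / (2 * width^2))
}

# Noiseless class spectrum as a plain vector (hot path).
expected_intensity <- function(config, label, excitation,
                               case_factors = NULL) {
  fl <- config$fluorophores
  mult <- if (identical(label, "cancer")) fl$cancer_multiplier else rep(1, nrow(fl))
  cf <- case_factors %||% rep(1, nrow(fl))
  eff <- exp(-(excitation - fl$excitation_peak)^2 /
               (2 * fl$excitation_width^2))
  out <- rep(config$baseline_offset, length(config$emission_grid))
  for (i in seq_len(nrow(fl))) {
    out <- out + fl$base_amplitude[i] * mult[i] * cf[i] * eff[i] *
      gaussian_band(config$emission_grid, fl$emission_center[i],
                    fl$emission_width[i], 1)
  }
  out
}

#' Noiseless expected spectrum for a class and excitation
#'
#' The clean spectrum is the baseline offset plus the sum over fluorophores
#' of `base_amplitude * multiplier(label) * excitation_efficiency * band`,
#' where the excitation efficiency is Gaussian in the excitation wavelength
#' about each fluorophore's excitation peak.
#'
#' @param config A [cohort_config()].
#' @param label `"normal"` or `"cancer"`.
#' @param excitation One of the configured excitation wavelengths (nm).
#' @return A tibble with columns `emission_nm` and `intensity`.
#' @export
expected_spectrum <- function(config, label, excitation) {
  stopifnot(inherits(config, "cohort_config"))
  label <- match.arg(tolower(label), c("normal", "cancer"))
  if (!excitation %in% config$excitations) {
    abort("`excitation` is not one of the configured excitation wavelengths.",
          class = "fluordx_value_error")
  }
  tibble(emission_nm = config$emission_grid,
         intensity = expected_intensity(config, label, excitation))
}

#' Generate one labelled case with replicate measurements
#'
#' Draws one log-normal factor per fluorophore for the case (biological
#' heterogeneity shared across that case's replicates), then adds
#' independent Gaussian noise per replicate, clamping intensities at zero.
#'
#' @param config A [cohort_config()].
#' @param label `"normal"` or `"cancer"`.
#' @param case_id Identifier for the generated case.
#' @param replicates Number of measurements; defaults to
#'   `config$replicates_per_case`.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return A spectra tibble with `replicates * length(excitations)` rows.
#' @export
generate_case <- function(config, label, case_id = "case_1",
                          replicates = NULL, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  label <- match.arg(tolower(label), c("normal", "cancer"))
  replicates <- as.integer(replicates %||% config$replicates_per_case)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)

  nf <- nrow(config$fluorophores)
  case_factors <- if (config$case_effect_sd > 0) {
    stats::rlnorm(nf, meanlog = 0, sdlog = config$case_effect_sd)
  } else {
    rep(1, nf)
  }
  clean <- vapply(config$excitations, function(ex) {
    expected_intensity(config, label, ex, case_factors)
  }, numeric(length(config$emission_grid)))  # channels x excitations
  clean <- t(clean)                          # excitations x channels
  sd_abs <- config$noise_sd * max(clean)

  n_exc <- length(config$excitations)
  n_chan <- length(config$emission_grid)
  rows <- purrr::map(seq_len(replicates), function(r) {
    noisy <- clean
    if (sd_abs > 0) {
      noisy <- noisy + matrix(stats::rnorm(n_exc * n_chan, sd = sd_abs),
                              nrow = n_exc)
    }
    noisy <- pmax(noisy, 0)
    colnames(noisy) <- paste0("em_", format_grid(config$emission_grid))
    out <- as_tibble(noisy)
    dplyr::bind_cols(
      tibble(case_id = case_id, label = label, replicate = r,
             excitation_nm = config$excitations),
      out
    )
  })
  bind_rows(rows)
}

format_grid <- function(grid) {
  # stable channel names; sub-nm grids keep enough digits to stay unique
  out <- formatC(grid, format = "fg", digits = 10)
  trimws(out)
}

#' Generate a labelled synthetic fluorescence cohort
#'
#' @param config A [cohort_config()]. With `preset = "published"` the
#'   cohort has 137 cancer and 149 normal cases and replicate counts are
#'   allocated deterministically (round-robin, remainder to the first cases)
#'   so that spectra total 486 cancer + 318 normal = 804.
#' @return A validated spectra tibble.
#' @export
#' @examples
#' cfg <- cohort_config(n_cancer_cases = 3, n_normal_cases = 3,
#'                      replicates_per_case = 2, n_channels = 8, seed = 42)
#' generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  alloc <- function(n_cases, total) {
    if (n_cases == 0) return(integer(0))
    if (total < n_cases) {
      abort("Replicate allocation impossible: total spectra < cases.",
            class = "fluordx_value_error")
    }
    base <- total %/% n_cases
    rem <- total - base * n_cases
    base + as.integer(seq_len(n_cases) <= rem)
  }
  if (config$preset == "published") {
    cancer_reps <- alloc(config$n_cancer_cases, 486L)
    normal_reps <- alloc(config$n_normal_cases, 318L)
  } else {
    cancer_reps <- rep(config$replicates_per_case, config$n_cancer_cases)
    normal_reps <- rep(config$replicates_per_case, config$n_normal_cases)
  }

  gen_class <- function(label, reps) {
    if (length(reps) == 0) return(NULL)
    ids <- sprintf("%s_%03d", label, seq_along(reps))
    bind_rows(purrr::map2(ids, reps, function(id, k) {
      generate_case(config, label, case_id = id, replicates = k)
    }))
  }
  out <- bind_rows(gen_class("cancer", cancer_reps),
                   gen_class("normal", normal_reps))
  if (is.null(out) || nrow(out) == 0) {
    abort("Empty cohort: both class counts are zero.",
          class = "fluordx_value_error")
  }
  validate_spectra(out)
}

#' Preset cohort configurations for simulation studies
#'
#' Convenience wrappers around [cohort_config()]:
#' * `strong_effect_config()` — all cancer multipliers 0.3 and
#'   `noise_sd = 0.05`: a strongly separable cohort used for parameter
#'   recovery checks.
#' * `null_config()` — all cancer multipliers 1: cancer and normal spectra
#'   share one distribution, so any classifier should score at chance.
#'
#' @param ... Passed on to [cohort_config()] (e.g. `seed`, `preset`).
#' @return A `cohort_config`.
#' @export
strong_effect_config <- function(...) {
  fl <- default_fluorophores()
  fl$cancer_multiplier <- 0.3
  cohort_config(fluorophores = fl, noise_sd = 0.05, ...)
}

#' @rdname strong_effect_config
#' @export
null_config <- function(...) {
  fl <- default_fluorophores()
  fl$cancer_multiplier <- 1
  cohort_config(fluorophores = fl, ...)
}
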