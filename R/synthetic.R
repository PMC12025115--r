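#' Define a synthetic cluster of compositions
#'
#' A cluster is parameterised exactly by the quantities a center table
#' reports: its compositional center (percent, summing to 100), its total
#' variance, and its size. Samples are drawn from an additive logistic-normal
#' model: ILR coordinates are spherical Gaussian around `ilr(center)` with
#' per-coordinate variance `total_variance / (D - 1)`, so the expected total
#' variance equals the target. Optionally, per-element non-detection
#' probabilities can zero out trace elements (Cl, F, P) before closure, to
#' emulate sporadic non-detections in EDX data.
#'
#' @param name Cluster name.
#' @param center Named numeric vector of positive percentages (parts), e.g.
#'   `c(C = 20.07, O = 46.05, Ca = 19.80, Mg = 1.60, Traces = 12.48)`.
#' @param total_variance Positive target total (metric) variance.
#' @param n Number of samples.
#' @param trace_zero_prob Optional named vector of probabilities in `[0, 1]`
#'   for parts to be set to zero per sample (e.g. `c(P = 1)` for an element
#'   absent from the cluster).
#' @return A `cluster_spec` object (validated list).
#' @export
cluster_spec <- function(name, center, total_variance, n,
                         trace_zero_prob = NULL) {
  if (is.null(names(center)) || any(center <= 0)) {
    abort("center must be a named vector of positive percentages.",
          class = "spicoda_validation_error")
  }
  if (!is.numeric(total_variance) || total_variance <= 0) {
    abort("total_variance must be positive.",
          class = "spicoda_validation_error")
  }
  if (!is.numeric(n) || n < 1) {
    abort("n must be a positive count.", class = "spicoda_validation_error")
  }
  if (!is.null(trace_zero_prob)) {
    if (is.null(names(trace_zero_prob)) ||
        !all(names(trace_zero_prob) %in% names(center)) ||
        any(trace_zero_prob < 0 | trace_zero_prob > 1)) {
      abort("trace_zero_prob must be named by parts with values in [0, 1].",
            class = "spicoda_validation_error")
    }
  }
  structure(list(name = as.character(name),
                 center = center / sum(center) * 100,
                 total_variance = total_variance, n = as.integer(n),
                 trace_zero_prob = trace_zero_prob),
            class = "cluster_spec")
}

#' Built-in scenario: spicule section clusters
#'
#' The three clusters found on polished spicule sections of the dorid
#' nudibranch *Onchidoris muricata*: sizes 14/41/45, centers and total
#' variances as published for SC I-III. These are the defaults of every
#' section-scenario simulation in the package.
#'
#' @return List of three `cluster_spec` objects.
#' @export
section_cluster_specs <- function() {
  list(
    cluster_spec("SC I",
                 c(C = 20.07, O = 46.05, Ca = 19.80, Mg = 1.60, Traces = 12.48),
                 total_variance = 0.1063, n = 14),
    cluster_spec("SC II",
                 c(C = 9.47, O = 61.96, Ca = 21.72, Mg = 3.94, Traces = 2.90),
                 total_variance = 0.2553, n = 41),
    cluster_spec("SC III",
                 c(C = 8.06, O = 53.49, Ca = 33.82, Mg = 2.88, Traces = 1.74),
                 total_variance = 0.2567, n = 45))
}

#' Built-in scenario: spicule fracture clusters
#'
#' The four clusters found on fractured spicules (FC I-IV): sizes
#' 19/27/19/40, higher total variances than the section clusters, reflecting
#' the topographic noise of fracture surfaces.
#'
#' @return List of four `cluster_spec` objects.
#' @export
fracture_cluster_specs <- function() {
  list(
    cluster_spec("FC I",
                 c(C = 14.79, O = 29.69, Ca = 36.53, Mg = 1.26, Traces = 17.72),
                 total_variance = 0.7958, n = 19),
    cluster_spec("FC II",
                 c(C = 11.58, O = 53.55, Ca = 29.59, Mg = 3.20, Traces = 2.07),
                 total_variance = 0.7080, n = 27),
    cluster_spec("FC III",
                 c(C = 10.46, O = 62.46, Ca = 16.75, Mg = 5.32, Traces = 5.00),
                 total_variance = 0.3288, n = 19),
    cluster_spec("FC IV",
                 c(C = 17.31, O = 53.32, Ca = 15.91, Mg = 1.91, Traces = 11.54),
                 total_variance = 0.9920, n = 40))
}

#' Generate a synthetic composition table from cluster specs
#'
#' Draws each cluster from the logistic-normal model of [cluster_spec()]:
#' spherical Gaussian ILR coordinates around the center, inverse-transformed
#' and closed to 100. If a spec carries `trace_zero_prob`, the named parts
#' are zeroed per sample with those probabilities before closure (downstream
#' analysis then amalgamates and delta-replaces them). Deterministic given
#' `seed`; clusters are generated in list order.
#'
#' @param specs List of `cluster_spec` objects (all with the same parts).
#' @param seed Integer seed (mandatory).
#' @param prep Value for the `prep` metadata column (`"section"` or
#'   `"fracture"`), recycled.
#' @return A tibble: `sample_id`, `prep`, `true_cluster`, and one column per
#'   part (percent, rows summing to 100).
#' @export
generate_clusters <- function(specs, seed, prep = "section") {
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory.", class = "spicoda_validation_error")
  }
  if (length(specs) == 0) abort("specs must be non-empty.",
                                class = "spicoda_validation_error")
  if (!all(vapply(specs, inherits, logical(1), "cluster_spec"))) {
    abort("All specs must be cluster_spec objects.",
          class = "spicoda_validation_error")
  }
  parts <- names(specs[[1]]$center)
  if (!all(vapply(specs, function(s) identical(names(s$center), parts),
                  logical(1)))) {
    abort("All specs must share the same parts in the same order.",
          class = "spicoda_validation_error")
  }
  set.seed(seed)
  basis <- make_sbp_basis(parts)
  D <- length(parts)
  out <- purrr::map_dfr(specs, function(s) {
    # basis rows sum to zero, so ilr(center) = basis %*% log(center)
    mu <- drop(unclass(basis) %*% log(s$center))
    sd <- sqrt(s$total_variance / (D - 1))
    z <- matrix(stats::rnorm(s$n * (D - 1), 0, sd), s$n, D - 1)
    z <- sweep(z, 2, mu, `+`)
    comp <- ilr_inverse(z, basis, kappa = 100)
    if (!is.null(s$trace_zero_prob)) {
      for (p in names(s$trace_zero_prob)) {
        hit <- stats::runif(s$n) < s$trace_zero_prob[[p]]
        comp[[p]][hit] <- 0
      }
      m <- as.matrix(comp)
      comp <- as_tibble(as.data.frame(m * (100 / rowSums(m))))
    }
    dplyr::bind_cols(tibble(true_cluster = s$name), comp)
  })
  dplyr::bind_cols(
    tibble(sample_id = sprintf("s%03d", seq_len(nrow(out))),
           prep = rep_len(prep, nrow(out))),
    out)
}

#' Generate a synthetic Raman spectrum
#'
#' A sum of pseudo-Voigt bands (equal-weight Gaussian/Lorentzian mix) on a
#' polynomial baseline, plus iid Gaussian noise. Deterministic given `seed`.
#'
#' @param bands Data frame or list of rows with columns/elements `center`
#'   (cm^-1), `fwhm`, `amplitude`.
#' @param baseline Numeric polynomial coefficients (intercept first),
#'   evaluated on the shift grid.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param grid `c(start, stop, step)` of the shift grid.
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @param eta Lorentzian fraction of the pseudo-Voigt profile.
#' @return A `raman_spectrum` tibble: `shift`, `intensity`.
#' @export
generate_raman_spectrum <- function(bands, baseline = 0, noise_sd = 0,
                                    grid = c(100, 1500, 1), seed = NULL,
                                    eta = 0.5) {
  stopifnot(length(grid) == 3, grid[2] > grid[1], grid[3] > 0)
  shift <- seq(grid[1], grid[2], by = grid[3])
  if (is.data.frame(bands)) bands <- purrr::transpose(as.list(bands))
  bands <- lapply(bands, as.list)
  intensity <- numeric(length(shift))
  for (b in bands) {
    if (b$center < grid[1] || b$center > grid[2]) {
      abort(paste0("Band center ", b$center, " outside the grid."),
            class = "spicoda_validation_error")
    }
    u <- (shift - b$center) / b$fwhm
    gauss <- exp(-4 * log(2) * u^2)
    lorentz <- 1 / (1 + 4 * u^2)
    intensity <- intensity + b$amplitude * (eta * lorentz + (1 - eta) * gauss)
  }
  intensity <- intensity +
    drop(outer(shift, seq_along(baseline) - 1, `^`) %*% baseline)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("seed is mandatory when noise_sd > 0.",
                             class = "spicoda_validation_error")
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length(shift), 0, noise_sd)
  }
  structure(tibble(shift = shift, intensity = intensity),
            class = c("raman_spectrum", class(tibble())))
}

#' Read a simulation scenario from YAML
#'
#' Scenario files hold a `seed`, an optional `prep` tag, and a list of
#' `clusters`, each with `name`, `center` (named map), `total_variance`,
#' `n`, and optional `trace_zero_prob`.
#'
#' @param path YAML file path.
#' @return List with `specs` (list of `cluster_spec`), `seed`, `prep`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$clusters) || length(y$clusters) == 0) {
    abort("Scenario must define a non-empty 'clusters' list.",
          class = "spicoda_validation_error")
  }
  specs <- lapply(y$clusters, function(cl) {
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; undo that
    names(cl)[names(cl) == "FALSE"] <- "n"
    for (f in c("name", "center", "total_variance", "n")) {
      if (is.null(cl[[f]])) {
        abort(paste0("Cluster entry missing field '", f, "'."),
              class = "spicoda_validation_error")
      }
    }
    cluster_spec(cl$name, unlist(cl$center), cl$total_variance, cl$n,
                 if (!is.null(cl$trace_zero_prob)) unlist(cl$trace_zero_prob))
  })
  list(specs = specs, seed = y$seed, prep = y$prep %||% "section")
}
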