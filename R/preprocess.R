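#' Discard plots with low seedling emergence
#'
#' Within each environment, plots whose stand count falls strictly more than
#' two interquartile ranges below the first quartile are discarded. Quartiles
#' use the default linear-interpolation definition (type 7).
#'
#' @param plots Plot tibble with `environment` and `stand_count`.
#' @return List with `retained` (tibble) and `removed` (tibble of
#'   environment, plot_id, stand_count, threshold).
#' @export
filter_low_emergence <- function(plots) {
  if (all(is.na(plots$stand_count)))
    abort("all stand counts missing; cannot apply emergence filter",
          class = "phenosel_validation_error")
  flagged <- plots |>
    group_by(.data$environment) |>
    mutate(
      .q1 = quantile(.data$stand_count, 0.25, na.rm = TRUE, type = 7),
      .iqr = IQR(.data$stand_count, na.rm = TRUE, type = 7),
      .thr = .data$.q1 - 2 * .data$.iqr,
      .drop_plot = !is.na(.data$stand_count) & .data$stand_count < .data$.thr
    ) |>
    ungroup()
  removed <- flagged |>
    filter(.data$.drop_plot) |>
    select("environment", "plot_id", "stand_count", threshold = ".thr")
  retained <- flagged |>
    filter(!.data$.drop_plot) |>
    select(-".q1", -".iqr", -".thr", -".drop_plot")
  list(retained = retained, removed = removed)
}

#' Remove shattered plots from yield analyses
#'
#' Yield observations from plots with a pre-harvest shattering score of 4 or
#' more are excluded. Phenomic records for those plots are unaffected; apply
#' this filter to the yield analysis table only.
#'
#' @param plots Plot tibble with `shatter_score`.
#' @return List with `retained` and `removed` tibbles.
#' @export
filter_shattered <- function(plots) {
  drop <- !is.na(plots$shatter_score) & plots$shatter_score >= 4
  list(retained = plots[!drop, , drop = FALSE],
       removed = plots[drop, c("environment", "plot_id", "shatter_score")])
}

#' Adjust seed yield to 13% moisture
#'
#' Dry-matter-preserving rescale:
#' \eqn{y_{13} = y_{wet} (1 - m) / 0.87}.
#'
#' @param yield_wet Wet yield, kg/ha.
#' @param moisture Measured moisture as a proportion in `[0, 1)`.
#' @return Yield at 13% moisture, kg/ha.
#' @export
#' @examples
#' adjust_moisture(2000, 0.13)  # 2000
#' adjust_moisture(1000, 0.10)  # 1034.48
adjust_moisture <- function(yield_wet, moisture) {
  if (any(moisture >= 1, na.rm = TRUE) || any(moisture < 0, na.rm = TRUE))
    abort("moisture must lie in [0, 1)", class = "phenosel_validation_error")
  yield_wet * (1 - moisture) / 0.87
}

#' Normalize canopy temperature by data-collection pass
#'
#' Thermal measurements drift with ambient temperature over the course of
#' data collection. Centring each pass at zero removes the additive ambient
#' drift while preserving within-pass genotype contrasts.
#'
#' @param data Tibble of canopy records.
#' @param ct Column holding canopy temperature (tidy-eval).
#' @param pass Column holding the pass identifier (tidy-eval).
#' @return `data` with the temperature column replaced by its pass-centred
#'   value (mean of every pass is 0).
#' @export
normalize_ct_by_pass <- function(data, ct, pass) {
  ct_q <- rlang::enquo(ct)
  pass_q <- rlang::enquo(pass)
  sizes <- data |>
    filter(!is.na(!!ct_q)) |>
    count(!!pass_q)
  if (any(sizes$n < 2))
    warn(paste0(sum(sizes$n < 2), " pass(es) with a single plot; ",
                "their values are centred to 0"))
  data |>
    group_by(!!pass_q) |>
    mutate(!!rlang::as_name(ct_q) :=
             !!ct_q - mean(!!ct_q, na.rm = TRUE)) |>
    ungroup()
}

#' Average the two reflectance scans of each plot
#'
#' Each plot is scanned twice; the plot spectrum is the arithmetic per-band
#' mean. A plot with a missing scan value at some band falls back to the
#' remaining scan, with a warning.
#'
#' @param spectra Spectra tibble with `environment`, `plot_id`, `scan` and
#'   wavelength-named band columns (as from [simulate_panel()] or
#'   [read_spectra()]).
#' @return Tibble with one row per plot and the same band columns.
#' @export
average_plot_reflectance <- function(spectra) {
  band_cols <- setdiff(names(spectra), c("environment", "plot_id", "scan"))
  n_na <- sum(is.na(spectra[, band_cols]))
  if (n_na > 0)
    warn(paste0(n_na, " missing scan value(s); single-scan fallback used"))
  out <- spectra |>
    group_by(.data$environment, .data$plot_id) |>
    summarise(across(all_of(band_cols), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  for (a in c("wavelengths", "stage"))
    if (!is.null(attr(spectra, a))) attr(out, a) <- attr(spectra, a)
  out
}

#' Repeatability from variance components
#'
#' Entry-mean repeatability over `e` environments and `r` replicates:
#' \deqn{H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g\times e}/e +
#'   \sigma^2_\varepsilon/(re)}}
#' Negative component estimates are truncated at zero before the ratio so
#' that \eqn{H^2 \in [0, 1]}.
#'
#' @param sigma2_g,sigma2_gxe,sigma2_eps Variance components.
#' @param r Number of replicates. @param e Number of environments.
#' @return Repeatability in `[0, 1]` (0 when all components are 0).
#' @export
#' @examples
#' repeatability(2, 2, 4, r = 2, e = 2)  # 0.5
repeatability <- function(sigma2_g, sigma2_gxe, sigma2_eps, r, e) {
  sigma2_g <- pmax(sigma2_g, 0)
  sigma2_gxe <- pmax(sigma2_gxe, 0)
  sigma2_eps <- pmax(sigma2_eps, 0)
  denom <- sigma2_g + sigma2_gxe / e + sigma2_eps / (r * e)
  ifelse(denom <= 0, 0, sigma2_g / denom)
}

#' Estimate per-band repeatability across environments
#'
#' For every band column, fits the full random trial model (environment,
#' replicate, block within replicate, genotype, genotype-by-environment) by
#' REML and computes entry-mean repeatability from the genotype, G-by-E and
#' residual components via [repeatability()].
#'
#' @param data Plot-level tibble with design columns (`environment`,
#'   `replicate`, `block`, `genotype`) and band columns.
#' @param bands Character vector of band column names; default: every column
#'   whose name parses as a number.
#' @return Tibble with one row per band: `band`, `sigma2_g`, `sigma2_gxe`,
#'   `sigma2_eps`, `r`, `e`, `H2`.
#' @export
estimate_band_repeatability <- function(data, bands = NULL) {
  if (is.null(bands)) {
    cand <- setdiff(names(data),
                    c("environment", "replicate", "block", "pass", "plot_id",
                      "genotype", "scan"))
    bands <- cand[!is.na(suppressWarnings(as.numeric(cand)))]
  }
  if (length(bands) == 0)
    abort("no band columns found", class = "phenosel_validation_error")
  e <- length(unique(data$environment))
  if (e < 2)
    abort("repeatability across environments needs >= 2 environments; the single-environment reduced formula is not supported",
          class = "phenosel_validation_error")
  r <- length(unique(data$replicate))
  rows <- map(bands, function(b) {
    fit <- fit_mixed_model(data, response = b)
    vc <- setNames(fit$vc$variance, fit$vc$term)
    g <- max(vc[["genotype"]], 0)
    gxe <- max(vc[["genotype:environment"]], 0)
    eps <- max(vc[["residual"]], 0)
    tibble(band = b, sigma2_g = g, sigma2_gxe = gxe, sigma2_eps = eps,
           r = r, e = e, H2 = repeatability(g, gxe, eps, r, e))
  })
  list_rbind(rows)
}

#' Retain bands passing the repeatability threshold
#'
#' Bands with \eqn{H^2} strictly below the threshold are dropped (a band at
#' exactly the threshold is retained).
#'
#' @param estimates Tibble from [estimate_band_repeatability()].
#' @param threshold Repeatability cutoff (default 0.3).
#' @return Character vector of retained band names, with attribute `dropped`.
#' @export
filter_bands_by_repeatability <- function(estimates, threshold = 0.3) {
  keep <- estimates$H2 >= threshold
  out <- estimates$band[keep]
  attr(out, "dropped") <- estimates$band[!keep]
  out
}

#' Bin wavebands into fixed-width mean-reflectance features
#'
#' Retained 1-nm (or coarser) bands are grouped into contiguous blocks of
#' `width` nm, anchored at the lowest wavelength of each contiguous segment;
#' each feature is the arithmetic mean reflectance of its block. Trailing
#' partial blocks (narrower than `width`) are dropped, so a contiguous run
#' of 1780 1-nm bands yields exactly 178 features. Features are labelled
#' `R<center>` with the block-centre wavelength in nm (e.g. `R705` averages
#' 700-709 nm).
#'
#' @param data Plot-level tibble with wavelength-named band columns.
#' @param bands Band columns to use (character wavelengths); default every
#'   numeric-named column.
#' @param width Block width in nm (default 10).
#' @return Tibble of identifier columns plus binned features, with a
#'   `bin_map` attribute (tibble: label, start, end, center, n_bands).
#' @export
bin_wavebands <- function(data, bands = NULL, width = 10) {
  id_cols <- intersect(c("environment", "replicate", "block", "pass",
                         "plot_id", "genotype"), names(data))
  if (is.null(bands)) {
    cand <- setdiff(names(data), c(id_cols, "scan"))
    bands <- cand[!is.na(suppressWarnings(as.numeric(cand)))]
  }
  if (length(bands) == 0)
    abort("empty band set; nothing to bin", class = "phenosel_validation_error")
  wl <- as.numeric(bands)
  o <- order(wl)
  wl <- wl[o]; bands <- bands[o]
  step <- if (length(wl) > 1) min(diff(wl)) else 1
  seg <- cumsum(c(1, diff(wl) > step + 1e-9))
  per_bin <- max(1L, round(width / step))

  bin_rows <- list()
  out <- data[, id_cols, drop = FALSE]
  k <- 0L
  for (s in unique(seg)) {
    idx <- which(seg == s)
    n_full <- floor(length(idx) / per_bin)
    if (n_full == 0) next
    for (b in seq_len(n_full)) {
      k <- k + 1L
      take <- idx[(b - 1) * per_bin + seq_len(per_bin)]
      start <- wl[take[1]]
      center <- start + floor(width / 2)
      label <- paste0("R", center)
      vals <- rowMeans(data[, bands[take], drop = FALSE])
      out[[label]] <- vals
      bin_rows[[k]] <- tibble(label = label, start = start,
                              end = start + width - 1, center = center,
                              n_bands = per_bin)
    }
  }
  if (k == 0)
    abort("no complete bins; band set too sparse for the requested width",
          class = "phenosel_validation_error")
  out <- as_tibble(out)
  attr(out, "bin_map") <- list_rbind(bin_rows)
  out
}

#' Registry of vegetation-index definitions
#'
#' Standard literature definitions of the indices computed by the pipeline;
#' each formula reads \eqn{R_\lambda} from the feature (binned or raw band)
#' containing wavelength \eqn{\lambda}. The registry is a plain tibble and
#' can be extended or replaced by the caller.
#'
#' @return Tibble with columns `name`, `bands` (list of nm), `fn` (list of
#'   functions of a named reflectance list).
#' @export
vi_registry <- function() {
  tibble(
    name = c("NDVI", "VREI2", "NWI", "RARSb", "RARSc", "NMDI"),
    bands = list(
      c(800, 670),
      c(734, 747, 715, 726),
      c(970, 900),
      c(675, 650, 700),
      c(760, 500),
      c(860, 1640, 2130)
    ),
    fn = list(
      function(R) (R[["800"]] - R[["670"]]) / (R[["800"]] + R[["670"]]),
      function(R) (R[["734"]] - R[["747"]]) / (R[["715"]] + R[["726"]]),
      function(R) (R[["970"]] - R[["900"]]) / (R[["970"]] + R[["900"]]),
      function(R) R[["675"]] / (R[["650"]] * R[["700"]]),
      function(R) R[["760"]] / R[["500"]],
      function(R) (R[["860"]] - (R[["1640"]] - R[["2130"]])) /
        (R[["860"]] + (R[["1640"]] - R[["2130"]]))
    )
  )
}

# locate, for wavelength lambda, the feature column holding it
.find_band_column <- function(data, lambda) {
  bm <- attr(data, "bin_map")
  if (!is.null(bm)) {
    hit <- which(bm$start <= lambda & lambda <= bm$end)
    if (length(hit) == 0) return(NA_character_)
    return(bm$label[hit[1]])
  }
  cand <- names(data)
  wl <- suppressWarnings(as.numeric(cand))
  ok <- which(!is.na(wl))
  if (length(ok) == 0) return(NA_character_)
  step <- if (length(ok) > 1) min(diff(sort(wl[ok]))) else 1
  d <- abs(wl[ok] - lambda)
  if (min(d) > step / 2 + 1e-9) return(NA_character_)
  cand[ok[which.min(d)]]
}

#' Compute vegetation indices
#'
#' Adds one column per registered index, computed from binned features (via
#' their `bin_map`) or from raw wavelength-named columns. A zero denominator
#' yields `NaN` with a warning; a missing required band is an error naming
#' the index and the wavelength.
#'
#' @param data Plot-level tibble of binned or raw spectra.
#' @param definitions Registry tibble, see [vi_registry()].
#' @return `data` with appended index columns.
#' @export
compute_vi <- function(data, definitions = vi_registry()) {
  for (i in seq_len(nrow(definitions))) {
    nm <- definitions$name[i]
    need <- definitions$bands[[i]]
    cols <- vapply(need, function(l) .find_band_column(data, l), character(1))
    if (any(is.na(cols)))
      abort(paste0("VI ", nm, ": no feature covering ",
                   paste(need[is.na(cols)], collapse = ", "), " nm"),
            class = "phenosel_validation_error")
    R <- setNames(lapply(cols, function(cl) data[[cl]]), as.character(need))
    vals <- definitions$fn[[i]](R)
    if (any(!is.finite(vals) & !is.na(vals)) || any(is.nan(vals)))
      warn(paste0("VI ", nm, ": non-finite value(s) (zero denominator?)"))
    vals[is.infinite(vals)] <- NaN
    data[[nm]] <- vals
  }
  data
}
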