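#' Configuration for synthetic fiber-bundle phase images
#'
#' Describes the synthetic imaging conditions: an elliptical fiber field
#' (oblique polish foreshortens one axis by cos 20 degrees), a large diffuse
#' DC background on which a weak sinusoidal AC signal rides (the epithelial
#' contribution is roughly 10% of the backscattering signal), camera
#' quantisation, a dark offset from internal reflections, and additive
#' noise.
#'
#' Per-frequency DC levels and AC amplitudes are given as named numeric
#' vectors keyed by frequency label; the ground-truth amplitudes are
#' carried through so that pipeline recovery can be checked exactly.
#'
#' @param field_diameter_um fiber-field (major-axis) diameter, um.
#' @param ellipticity minor/major axis ratio of the field, default
#'   `cos(20 deg)`.
#' @param pitch_um pixel pitch, um.
#' @param frequencies named numeric vector of spatial frequencies (1/mm);
#'   names are the nominal labels.
#' @param dc_level per-frequency DC background in camera counts (scalar or
#'   named vector).
#' @param ac_amplitude per-frequency true AC amplitude in counts (scalar or
#'   named vector); the default is 10% of `dc_level`.
#' @param dark_offset additive instrument-reflection level, counts.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param shot_noise_scale variance-per-count scale of signal-dependent
#'   noise; the per-pixel noise s.d. is
#'   `sqrt(read_noise_sd^2 + shot_noise_scale * signal)`.
#' @param bit_depth camera bit depth (8 or 16).
#' @param acetowhitening_gain static multiplier applied to the AC amplitude
#'   (models contrast enhancement by acetic acid; 1 = none).
#' @param pattern_phase_deg global phase offset of the projection pattern.
#' @return a `synth_scan_config` list.
#' @export
synth_scan_config <- function(field_diameter_um = 900,
                              ellipticity = cos(20 * pi / 180),
                              pitch_um = 2,
                              frequencies = c(`3` = 2.7, `6` = 5.5,
                                              `9` = 9.0, `15` = 14.5),
                              dc_level = 180,
                              ac_amplitude = NULL,
                              dark_offset = 8,
                              read_noise_sd = 1.5,
                              shot_noise_scale = 0.05,
                              bit_depth = 8,
                              acetowhitening_gain = 1,
                              pattern_phase_deg = 0) {
  labs <- names(frequencies)
  expand <- function(x, default = NULL) {
    if (is.null(x)) x <- default
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(labs)), labs)
    stopifnot(all(labs %in% names(x)))
    x[labs]
  }
  dc <- expand(dc_level)
  ac <- expand(ac_amplitude, default = 0.1 * dc)
  if (any(ac < 0) || any(ac > dc)) {
    stop("AC amplitudes must satisfy 0 <= AC <= DC", call. = FALSE)
  }
  structure(list(field_diameter_um = field_diameter_um,
                 ellipticity = ellipticity, pitch_um = pitch_um,
                 frequencies = frequencies, dc_level = dc,
                 ac_amplitude = ac * acetowhitening_gain,
                 dark_offset = dark_offset,
                 read_noise_sd = read_noise_sd,
                 shot_noise_scale = shot_noise_scale,
                 bit_depth = bit_depth,
                 pattern_phase_deg = pattern_phase_deg),
            class = "synth_scan_config")
}

#' Elliptical fiber-field mask
#'
#' The terminal surface of an obliquely polished image guide appears
#' elliptical; the minor/major axis ratio equals the cosine of the polish
#' angle (about 0.94 at 20 degrees). The mask is centred in a square raster
#' slightly larger than the field.
#'
#' @param config a [synth_scan_config()].
#' @param margin fractional raster margin around the field.
#' @return logical matrix; `TRUE` inside the ellipse.
#' @export
make_fiber_mask <- function(config, margin = 0.08) {
  a_um <- config$field_diameter_um / 2                  # major semi-axis
  b_um <- a_um * config$ellipticity                     # minor semi-axis
  n <- ceiling(config$field_diameter_um * (1 + margin) / config$pitch_um)
  if (n < 4) stop("degenerate raster: increase field size or reduce pitch",
                  call. = FALSE)
  ctr <- (n + 1) / 2
  # minor axis along x (rows): the polish tilts the field along the
  # modulation axis
  xs <- (seq_len(n) - ctr) * config$pitch_um
  ys <- (seq_len(n) - ctr) * config$pitch_um
  outer(xs^2 / b_um^2, ys^2 / a_um^2, `+`) <= 1
}

#' Render one synthetic three-phase stack
#'
#' Produces the three phase images of a scan at one spatial frequency:
#' \deqn{P_i = \mathrm{clip\&quantise}\left[\mathrm{dark} + DC +
#'   AC\cos(2\pi f x + \phi_0 + \phi_i) + \mathrm{noise}\right]}
#' with projection phases \eqn{\phi_i} of 0, 120 and 240 degrees inside the
#' fiber mask (outside, only dark level and noise). The generating `DC` and
#' `AC` are attached as `truth`.
#'
#' @param config a [synth_scan_config()].
#' @param f_label frequency label (name in `config$frequencies`).
#' @param phases_deg projection phases, degrees.
#' @param noise logical; `FALSE` renders a noiseless, unquantised stack
#'   (exact ground truth for pipeline identity checks).
#' @param quantize logical; round to integer camera counts and clip to the
#'   bit-depth range (implied by `noise = TRUE`).
#' @return a [phase_stack()] with attribute `truth` (list `dc`, `ac`,
#'   `dark`).
#' @export
make_phase_stack <- function(config, f_label,
                             phases_deg = c(0, 120, 240),
                             noise = TRUE, quantize = noise) {
  stopifnot(inherits(config, "synth_scan_config"))
  f_label <- as.character(f_label)
  if (!f_label %in% names(config$frequencies)) {
    stop(sprintf("unknown frequency label '%s'", f_label), call. = FALSE)
  }
  f <- config$frequencies[[f_label]]
  nyq <- 1 / (2 * config$pitch_um / 1000)
  if (f >= nyq) stop("projection frequency at or above pixel Nyquist",
                     call. = FALSE)
  mask <- make_fiber_mask(config)
  n <- nrow(mask)
  x_mm <- (seq_len(n) - (n + 1) / 2) * config$pitch_um / 1000
  dc <- config$dc_level[[f_label]]
  ac <- config$ac_amplitude[[f_label]]
  vmax <- 2^config$bit_depth - 1
  if (config$dark_offset + dc + ac > vmax) {
    warning("signal exceeds the camera range; clipping", call. = FALSE)
  }
  phi0 <- config$pattern_phase_deg * pi / 180
  imgs <- lapply(phases_deg, function(ph) {
    carrier <- cos(2 * pi * f * x_mm + phi0 + ph * pi / 180)
    img <- config$dark_offset +
      (dc + ac * matrix(carrier, n, n)) * mask
    if (noise) {
      sd <- sqrt(config$read_noise_sd^2 +
                   config$shot_noise_scale * pmax(img, 0))
      img <- img + matrix(stats::rnorm(n * n, 0, sd), n, n)
    }
    if (quantize) img <- pmin(pmax(round(img), 0), vmax)
    img
  })
  out <- phase_stack(imgs[[1]], imgs[[2]], imgs[[3]], f = f,
                     pitch_um = config$pitch_um, mask = mask)
  attr(out, "truth") <- list(dc = dc, ac = ac, dark = config$dark_offset)
  out
}

#' Render the matching dark stack
#'
#' Dark references share the instrument-reflection offset (and, when
#' `noise = TRUE`, the read noise) but carry no tissue signal.
#'
#' @inheritParams make_phase_stack
#' @return a [phase_stack()].
#' @export
make_dark_stack <- function(config, f_label, noise = TRUE,
                            quantize = noise) {
  stopifnot(inherits(config, "synth_scan_config"))
  f_label <- as.character(f_label)
  f <- config$frequencies[[f_label]]
  mask <- make_fiber_mask(config)
  n <- nrow(mask)
  vmax <- 2^config$bit_depth - 1
  imgs <- lapply(1:3, function(i) {
    img <- matrix(config$dark_offset, n, n)
    if (noise) img <- img + matrix(stats::rnorm(n * n, 0,
                                                config$read_noise_sd), n, n)
    if (quantize) img <- pmin(pmax(round(img), 0), vmax)
    img
  })
  phase_stack(imgs[[1]], imgs[[2]], imgs[[3]], f = f,
              pitch_um = config$pitch_um, mask = mask)
}

#' Configuration for a synthetic multi-case study
#'
#' Describes a cohort of cases (patients) with per-category scan counts and
#' group-dependent distributions of the normalised low-frequency
#' reflectance `R3` and the backscattering ratio `R9/R3`. Distributions are
#' lognormal (positive, multiplicative spread, matching the ratio-scale
#' variability seen between and within patients), with a multiplicative
#' per-case random effect.
#'
#' The default scan counts reproduce the packaged study table
#' (see [load_study_table()]); the default category medians are
#' qualitative and encode the expected effect direction: dysplastic
#' squamous epithelium (CIN2/CIN3) raises high-frequency backscattering and
#' the 9/3 ratio while slightly lowering the f = 3/mm reflectance.
#'
#' @param counts data.frame with column `case` and one column per category
#'   (`BC`, `AIS`, `BS`, `CIN1`, `CIN2`, `CIN3`) of scan counts; default is
#'   the packaged study table.
#' @param r3_median,ratio_median named vectors of per-category medians for
#'   `R3` and the ratio.
#' @param r3_sdlog,ratio_sdlog within-case lognormal dispersions.
#' @param case_sdlog_r3,case_sdlog_ratio dispersions of the per-case
#'   multiplicative random effects.
#' @param r6_frac,r15_slope auxiliary parameters filling in `R6` and `R15`
#'   from `R3` and the ratio (geometric interpolation in frequency).
#' @return a `synth_study_config` list.
#' @export
synth_study_config <- function(counts = NULL,
                               r3_median = c(BC = 0.60, AIS = 0.80,
                                             BS = 1.00, CIN1 = 1.00,
                                             CIN2 = 0.90, CIN3 = 0.85),
                               ratio_median = c(BC = 0.40, AIS = 0.50,
                                                BS = 0.35, CIN1 = 0.40,
                                                CIN2 = 0.55, CIN3 = 0.65),
                               r3_sdlog = 0.25, ratio_sdlog = 0.15,
                               case_sdlog_r3 = 0.30,
                               case_sdlog_ratio = 0.08,
                               r6_frac = 0.55, r15_slope = 0.85) {
  if (is.null(counts)) counts <- load_study_table()$table
  cats <- c("BC", "AIS", "BS", "CIN1", "CIN2", "CIN3")
  stopifnot(all(c("case", cats) %in% names(counts)),
            all(as.matrix(counts[cats]) >= 0),
            all(r3_sdlog > 0, ratio_sdlog > 0))
  structure(list(counts = counts, r3_median = r3_median,
                 ratio_median = ratio_median, r3_sdlog = r3_sdlog,
                 ratio_sdlog = ratio_sdlog,
                 case_sdlog_r3 = case_sdlog_r3,
                 case_sdlog_ratio = case_sdlog_ratio,
                 r6_frac = r6_frac, r15_slope = r15_slope,
                 categories = cats),
            class = "synth_study_config")
}

#' Generate a synthetic multi-case study table
#'
#' Draws one point-scan record per scheduled scan: lognormal `R3` and
#' `ratio` around category medians, scaled by per-case lognormal random
#' effects, then fills in `R9 = ratio * R3`, a geometric `R6`, and an
#' `R15` extrapolated along the ratio trend. Use [make_phase_stack()] to
#' render image stacks for individual scans if needed.
#'
#' @param config a [synth_study_config()].
#' @param seed optional RNG seed.
#' @return data.frame of class `point_scan_table` with columns `case`,
#'   `category`, `R3`, `R6`, `R9`, `R15`, `ratio`; the per-case effects are
#'   attached as attribute `case_effects`.
#' @export
make_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_study_config"))
  if (!is.null(seed)) set.seed(seed)
  cnt <- config$counts
  cats <- config$categories
  eff_r3 <- stats::rlnorm(nrow(cnt), 0, config$case_sdlog_r3)
  eff_ratio <- stats::rlnorm(nrow(cnt), 0, config$case_sdlog_ratio)
  rows <- list()
  for (i in seq_len(nrow(cnt))) {
    for (cat in cats) {
      k <- cnt[[cat]][i]
      if (k == 0) next
      r3 <- config$r3_median[[cat]] * eff_r3[i] *
        stats::rlnorm(k, 0, config$r3_sdlog)
      ratio <- config$ratio_median[[cat]] * eff_ratio[i] *
        stats::rlnorm(k, 0, config$ratio_sdlog)
      r9 <- ratio * r3
      # geometric interpolation between R3 and R9 for R6; extrapolation
      # beyond R9 for R15, damped by r15_slope
      r6 <- r3 * ratio^config$r6_frac
      r15 <- r9 * ratio^config$r15_slope
      rows[[length(rows) + 1L]] <- data.frame(
        case = cnt$case[i], category = cat, R3 = r3, R6 = r6, R9 = r9,
        R15 = r15, ratio = ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "case_effects") <- data.frame(case = cnt$case, eff_r3 = eff_r3,
                                          eff_ratio = eff_ratio)
  class(out) <- c("point_scan_table", "data.frame")
  out
}
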