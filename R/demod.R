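#' Three-phase structured-illumination stack
#'
#' Bundles the three reflectance images captured under sinusoidal projection
#' patterns whose phases differ by 120 degrees, together with the pixel
#' pitch, the spatial-frequency label and the fiber-field mask.
#'
#' @param P1,P2,P3 numeric matrices of equal dimension, nonnegative
#'   intensities.
#' @param f spatial frequency of the projected pattern, 1/mm.
#' @param pitch_um pixel pitch on the tissue, micrometres.
#' @param mask logical matrix of the same dimension marking pixels inside
#'   the fiber field; `NULL` means all pixels.
#' @param wavelength_nm optional illumination wavelength tag.
#' @return An object of class `phase_stack`.
#' @export
phase_stack <- function(P1, P2, P3, f, pitch_um, mask = NULL,
                        wavelength_nm = NA_real_) {
  if (!all(dim(P1) == dim(P2)) || !all(dim(P1) == dim(P3))) {
    stop("phase images must share one shape", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(P1), ncol(P1))
  if (!all(dim(mask) == dim(P1))) {
    stop("mask shape must match the images", call. = FALSE)
  }
  structure(list(P1 = P1, P2 = P2, P3 = P3, f = f, pitch_um = pitch_um,
                 mask = mask, wavelength_nm = wavelength_nm),
            class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  cat(sprintf("<phase_stack> %dx%d px, f = %.3g/mm, pitch %.3g um\n",
              nrow(x$P1), ncol(x$P1), x$f, x$pitch_um))
  invisible(x)
}

#' Dark-reference subtraction
#'
#' Subtracts, phase by phase, a dark stack recorded with the probe immersed
#' in a non-scattering black target; such a stack captures internal system
#' reflections only. Results are clipped at zero (camera counts cannot go
#' negative).
#'
#' @param stack,dark [phase_stack()] objects with matching shapes and
#'   frequency labels.
#' @return the corrected `phase_stack`.
#' @export
subtract_dark <- function(stack, dark) {
  stopifnot(inherits(stack, "phase_stack"), inherits(dark, "phase_stack"))
  if (!all(dim(stack$P1) == dim(dark$P1))) {
    stop("dark stack shape mismatch", call. = FALSE)
  }
  if (!isTRUE(all.equal(stack$f, dark$f))) {
    stop("dark stack frequency label mismatch", call. = FALSE)
  }
  out <- stack
  for (p in c("P1", "P2", "P3")) out[[p]] <- pmax(stack[[p]] - dark[[p]], 0)
  out
}

#' Software binning by block averaging
#'
#' Replaces each non-overlapping `k x k` block by its mean, increasing the
#' effective dynamic range. Trailing rows/columns that do not fill a block
#' are dropped.
#'
#' @param image numeric matrix.
#' @param k block edge length (default 8).
#' @return the binned matrix, `floor(nrow/k) x floor(ncol/k)`.
#' @export
bin_image <- function(image, k = 8) {
  stopifnot(k >= 1, k == round(k))
  k <- as.integer(k)
  nr <- nrow(image) %/% k
  nc <- ncol(image) %/% k
  if (nr < 1 || nc < 1) stop("image smaller than one block", call. = FALSE)
  im <- image[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  # average rows within blocks, then columns
  m <- matrix(colMeans(matrix(im, nrow = k)), nrow = nr)
  t(matrix(colMeans(matrix(t(m), nrow = k)), nrow = nc))
}

#' Bin a logical mask by block majority
#'
#' @param mask logical matrix.
#' @param k block edge length.
#' @return logical matrix; a block is inside if at least half its pixels
#'   are.
#' @export
bin_mask <- function(mask, k = 8) {
  bin_image(mask * 1, k) >= 0.5
}

#' Bin a full phase stack
#'
#' Applies [bin_image()] to all three phases and [bin_mask()] to the mask,
#' scaling the pixel pitch by `k`.
#'
#' @param stack a [phase_stack()].
#' @param k block edge length.
#' @return the binned `phase_stack`.
#' @export
bin_stack <- function(stack, k = 8) {
  stopifnot(inherits(stack, "phase_stack"))
  phase_stack(bin_image(stack$P1, k), bin_image(stack$P2, k),
              bin_image(stack$P3, k), f = stack$f,
              pitch_um = stack$pitch_um * k,
              mask = bin_mask(stack$mask, k),
              wavelength_nm = stack$wavelength_nm)
}

#' Butterworth high-pass filtering of a phase image
#'
#' Suppresses the slowly varying diffuse background and projection-boundary
#' artifacts before demodulation. The filter is realised in the 2-D Fourier
#' domain with a radially symmetric gain
#' \deqn{|H(\rho)| = 1 / \sqrt{1 + (f_c/\rho)^{2n}},}
#' with `n = order` poles and cutoff \eqn{f_c} set to `cutoff_ratio` times
#' the projection frequency (default one quarter). The mean (zero-frequency)
#' component is removed entirely. Pixels outside the fiber mask are filled
#' with the in-mask mean and the image is mirror-extended before the FFT to
#' limit ringing; the returned image has the original size.
#'
#' @param image numeric matrix.
#' @param f_proj projection spatial frequency, 1/mm.
#' @param order filter order (number of poles), default 2.
#' @param cutoff_ratio cutoff as a fraction of `f_proj`, default 0.25.
#' @param pitch_um pixel pitch, micrometres.
#' @param mask optional logical matrix; masked-out pixels are replaced
#'   before filtering and carry no meaning afterwards.
#' @return the filtered matrix (zero-mean up to edge effects).
#' @export
butterworth_highpass <- function(image, f_proj, order = 2,
                                 cutoff_ratio = 0.25, pitch_um,
                                 mask = NULL) {
  stopifnot(f_proj > 0, pitch_um > 0, order >= 1)
  pitch_mm <- pitch_um / 1000
  f_c <- cutoff_ratio * f_proj
  nyq <- 1 / (2 * pitch_mm)
  if (f_c >= nyq) {
    stop(sprintf("cutoff %.3g/mm is at or above the pixel Nyquist %.3g/mm",
                 f_c, nyq), call. = FALSE)
  }
  if (!is.null(mask) && !all(mask)) {
    fill <- mean(image[mask])
    image[!mask] <- fill
  }
  nr <- nrow(image); nc <- ncol(image)
  # mirror extension doubles each dimension and makes the signal continuous
  # across the periodic FFT boundary
  big <- rbind(cbind(image, image[, nc:1]),
               cbind(image[nr:1, ], image[nr:1, nc:1]))
  M <- nrow(big); Nn <- ncol(big)
  fx <- c(0:(M %/% 2), -((M - M %/% 2 - 1):1)) / (M * pitch_mm)
  fy <- c(0:(Nn %/% 2), -((Nn - Nn %/% 2 - 1):1)) / (Nn * pitch_mm)
  rho <- sqrt(outer(fx^2, fy^2, `+`))
  gain <- 1 / sqrt(1 + (f_c / rho)^(2 * order))
  gain[rho == 0] <- 0                     # remove DC entirely
  out <- Re(stats::fft(stats::fft(big) * gain, inverse = TRUE)) / (M * Nn)
  out[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' High-pass filter all three phases of a stack
#'
#' @param stack a [phase_stack()].
#' @inheritParams butterworth_highpass
#' @return the filtered `phase_stack` (the stack's own frequency label and
#'   pitch are used).
#' @export
highpass_stack <- function(stack, order = 2, cutoff_ratio = 0.25) {
  stopifnot(inherits(stack, "phase_stack"))
  out <- stack
  for (p in c("P1", "P2", "P3")) {
    out[[p]] <- butterworth_highpass(stack[[p]], f_proj = stack$f,
                                     order = order,
                                     cutoff_ratio = cutoff_ratio,
                                     pitch_um = stack$pitch_um,
                                     mask = stack$mask)
  }
  out
}

#' Three-phase AC/DC demodulation
#'
#' Recovers, pixel by pixel, the mean reflectance (DC) and the modulation
#' amplitude (AC) from three images acquired under projection phases 0, 120
#' and 240 degrees:
#' \deqn{DC = (P_1 + P_2 + P_3)/3,}
#' \deqn{AC = \frac{\sqrt 2}{3}\sqrt{(P_1-P_2)^2 + (P_2-P_3)^2 + (P_3-P_1)^2}.}
#' For an ideal sinusoid \eqn{P_i = A_0 + A_1 \cos(\phi + 2\pi f x -
#' (i-1)\,2\pi/3)} this returns exactly \eqn{DC = A_0} and \eqn{AC = A_1}
#' regardless of the local pattern phase.
#'
#' @param stack a [phase_stack()].
#' @return An object of class `demod_result` with matrices `DC`, `AC`, the
#'   `mask`, frequency `f` and `pitch_um`.
#' @export
demodulate <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  P1 <- stack$P1; P2 <- stack$P2; P3 <- stack$P3
  DC <- (P1 + P2 + P3) / 3
  AC <- sqrt(2) / 3 * sqrt((P1 - P2)^2 + (P2 - P3)^2 + (P3 - P1)^2)
  if (any(!is.finite(AC[stack$mask])) || any(!is.finite(DC[stack$mask]))) {
    stop("non-finite values inside the fiber mask", call. = FALSE)
  }
  structure(list(DC = DC, AC = AC, mask = stack$mask, f = stack$f,
                 pitch_um = stack$pitch_um),
            class = "demod_result")
}

#' @export
print.demod_result <- function(x, ...) {
  cat(sprintf("<demod_result> %dx%d px, f = %.3g/mm, mean AC = %.4g, mean DC = %.4g\n",
              nrow(x$DC), ncol(x$DC), x$f,
              mean(x$AC[x$mask]), mean(x$DC[x$mask])))
  invisible(x)
}

#' Mean over the central circular region of interest
#'
#' Averages an image over a central circular subsection of the fiber field,
#' avoiding the projection-boundary artifacts near the field edge. The
#' circle is centred on the mask centroid; its default diameter of 600 um
#' corresponds to the central portion of a 900-um field.
#'
#' @param image numeric matrix.
#' @param mask logical matrix marking the fiber field.
#' @param roi_diameter_um ROI diameter, micrometres; alternatively set it
#'   as a fraction of the mask minor axis via `roi_fraction`.
#' @param pitch_um pixel pitch, micrometres.
#' @param roi_fraction if not `NULL`, overrides `roi_diameter_um` with
#'   `roi_fraction` times the mask minor-axis extent.
#' @return scalar mean over in-ROI, in-mask pixels.
#' @export
roi_mean <- function(image, mask, roi_diameter_um = 600, pitch_um,
                     roi_fraction = NULL) {
  stopifnot(all(dim(image) == dim(mask)))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  if (!is.null(roi_fraction)) {
    # minor axis of the mask footprint, in pixels
    minor_px <- min(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
    r_px <- roi_fraction * minor_px / 2
  } else {
    r_px <- (roi_diameter_um / pitch_um) / 2
  }
  rr <- row(image) - cx
  cc <- col(image) - cy
  inside <- (rr^2 + cc^2 <= r_px^2) & mask
  if (!any(inside)) stop("ROI contains no pixels", call. = FALSE)
  mean(image[inside])
}

#' Normalise tissue reflectance to a scattering reference
#'
#' Divides tissue AC values by those of a reference measurement (a lipid
#' emulsion of known reduced scattering) acquired with identical settings,
#' yielding the dimensionless factor by which tissue backscattering exceeds
#' the reference.
#'
#' @param tissue_ac scalar or matrix of tissue AC values.
#' @param reference_ac matching scalar or matrix, strictly positive.
#' @return `tissue_ac / reference_ac`.
#' @export
normalize_to_reference <- function(tissue_ac, reference_ac) {
  if (any(reference_ac <= 0)) {
    stop("reference AC must be strictly positive", call. = FALSE)
  }
  tissue_ac / reference_ac
}

#' Full per-scan demodulation pipeline
#'
#' Processes one point scan through the canonical pipeline, per spatial
#' frequency: dark subtraction, `k x k` software binning, Butterworth
#' high-pass filtering of each phase image, three-phase demodulation, ROI
#' averaging, and normalisation to the identically processed reference
#' scan.
#'
#' @param stacks named list of [phase_stack()] objects, one per frequency
#'   label (e.g. `"3"`, `"6"`, `"9"`, `"15"`).
#' @param darks matching named list of dark stacks.
#' @param references matching named list of reference (e.g. Intralipid)
#'   stacks; their own darks in `reference_darks` (defaults to `darks`).
#' @param reference_darks named list of dark stacks for the reference scan.
#' @param bin_k binning factor (default 8).
#' @param order,cutoff_ratio high-pass parameters, see
#'   [butterworth_highpass()].
#' @param roi_diameter_um,roi_fraction ROI settings, see [roi_mean()].
#' @param highpass set `FALSE` to skip filtering (noiseless synthetic
#'   data).
#' @return data.frame with one row per frequency: `f_label`, `f`, `ac_roi`,
#'   `dc_roi`, `ref_ac_roi`, `R_norm`.
#' @export
process_scan <- function(stacks, darks, references,
                         reference_darks = darks, bin_k = 8,
                         order = 2, cutoff_ratio = 0.25,
                         roi_diameter_um = 600, roi_fraction = NULL,
                         highpass = TRUE) {
  labs <- names(stacks)
  if (is.null(labs) || any(!nzchar(labs))) {
    stop("`stacks` must be a named list keyed by frequency label",
         call. = FALSE)
  }
  for (nm in labs) {
    if (is.null(darks[[nm]])) stop(sprintf("missing dark for f = %s", nm),
                                   call. = FALSE)
    if (is.null(references[[nm]])) {
      stop(sprintf("missing reference for f = %s", nm), call. = FALSE)
    }
  }
  one <- function(stack, dark) {
    s <- subtract_dark(stack, dark)
    s <- bin_stack(s, bin_k)
    if (highpass) s <- highpass_stack(s, order = order,
                                      cutoff_ratio = cutoff_ratio)
    d <- demodulate(s)
    list(ac = roi_mean(d$AC, d$mask, roi_diameter_um, d$pitch_um,
                       roi_fraction),
         dc = roi_mean(d$DC, d$mask, roi_diameter_um, d$pitch_um,
                       roi_fraction))
  }
  rows <- lapply(labs, function(nm) {
    tis <- one(stacks[[nm]], darks[[nm]])
    ref <- one(references[[nm]], reference_darks[[nm]])
    data.frame(f_label = nm, f = stacks[[nm]]$f, ac_roi = tis$ac,
               dc_roi = tis$dc, ref_ac_roi = ref$ac,
               R_norm = normalize_to_reference(tis$ac, ref$ac))
  })
  do.call(rbind, rows)
}
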