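#' Pixelwise backscattering-ratio map and its ROI mean
#'
#' Computes the depth-dependent backscattering ratio
#' \eqn{R(9\,\mathrm{mm}^{-1})/R(3\,\mathrm{mm}^{-1})} for every imaging
#' pixel and then averages over the central ROI. The pixelwise-then-average
#' order is deliberate (and pinned by tests): it differs from the ratio of
#' ROI means on heterogeneous images.
#'
#' @param ac9,ac3 AC images (matrices of equal shape) at the high and low
#'   spatial frequency.
#' @param mask logical matrix of valid pixels.
#' @param pitch_um pixel pitch, micrometres.
#' @param roi_diameter_um ROI diameter passed to [roi_mean()].
#' @return list with the `ratio` image (NA where the denominator is not
#'   positive), the working `mask`, and the scalar `roi` mean.
#' @export
ratio_map <- function(ac9, ac3, mask = NULL, pitch_um,
                      roi_diameter_um = 600) {
  if (!all(dim(ac9) == dim(ac3))) stop("image shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ac9), ncol(ac9))
  bad <- mask & !(ac3 > 0)
  if (any(bad)) {
    warning(sprintf("masking %d pixels with non-positive denominator",
                    sum(bad)), call. = FALSE)
    mask <- mask & !bad
  }
  ratio <- matrix(NA_real_, nrow(ac9), ncol(ac9))
  ratio[mask] <- ac9[mask] / ac3[mask]
  list(ratio = ratio, mask = mask,
       roi = roi_mean(ratio, mask, roi_diameter_um, pitch_um))
}

#' Case-wise reference normalisation of point scans
#'
#' Removes between-patient variability by dividing every point measurement
#' of a case by that case's mean value over its benign-squamous (BS) scans:
#' in `"reflectance"` mode all four reflectances are divided by the
#' case-mean BS `R3`; in `"ratio"` mode the ratio is divided by the
#' case-mean BS ratio. Cases without BS scans cannot be referenced and are
#' dropped with a warning.
#'
#' @param scans data.frame with columns `case`, `category`, `R3`, `R6`,
#'   `R9`, `R15`, `ratio` (see [make_study()]).
#' @param mode `"reflectance"` or `"ratio"`.
#' @return the normalised data.frame (same columns, possibly fewer rows).
#' @export
case_reference <- function(scans, mode = c("reflectance", "ratio")) {
  mode <- match.arg(mode)
  col <- if (mode == "reflectance") "R3" else "ratio"
  ref <- vapply(split(scans, scans$case), function(d) {
    bs <- d[[col]][d$category == "BS"]
    if (length(bs) == 0L) NA_real_ else mean(bs)
  }, numeric(1))
  keep <- !is.na(ref[as.character(scans$case)])
  if (!all(keep)) {
    warning(sprintf("dropping %d scans from cases without BS reference",
                    sum(!keep)), call. = FALSE)
  }
  out <- scans[keep, , drop = FALSE]
  r <- ref[as.character(out$case)]
  if (mode == "reflectance") {
    for (v in c("R3", "R6", "R9", "R15")) out[[v]] <- out[[v]] / r
  } else {
    out$ratio <- out$ratio / r
  }
  rownames(out) <- NULL
  out
}

#' Per-category five-number summaries
#'
#' Summarises a scan variable per diagnostic category with median, first
#' and third quartile (linear-interpolation convention, quantile type 7)
#' and the minimum/maximum whiskers, matching a boxplot with whiskers at
#' the extremes. Empty categories are omitted.
#'
#' @param scans a point-scan data.frame.
#' @param value column to summarise (default `"ratio"`).
#' @param categories category order for the output.
#' @return data.frame with columns `category`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
summarize_groups <- function(scans, value = "ratio",
                             categories = c("BC", "AIS", "BS", "CIN1",
                                            "CIN2", "CIN3")) {
  stopifnot(value %in% names(scans))
  rows <- lapply(categories, function(cat) {
    x <- scans[[value]][scans$category == cat]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(category = cat, n = length(x), min = min(x), q1 = q[1],
               median = q[2], q3 = q[3], max = max(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear threshold classification of squamous scans
#'
#' Classifies point scans in the (`R3`, `ratio`) plane by a straight
#' decision line: scans with `ratio > intercept + slope * R3` are called
#' positive for high-grade squamous intraepithelial lesions (HSIL, i.e.
#' CIN2 or CIN3). Sensitivity is evaluated over CIN2 and CIN3 scans and
#' specificity over the negatives BS and CIN1; columnar categories (BC,
#' AIS) lie outside this binary squamous task and are excluded.
#'
#' @param scans data.frame with `category`, `R3`, `ratio`.
#' @param slope,intercept decision line in the (`R3`, `ratio`) plane.
#' @return list with `labels` (logical, per squamous scan), the squamous
#'   subset `scans`, the 2x2 `confusion` table, `sensitivity` and
#'   `specificity`.
#' @export
classify_linear <- function(scans, slope, intercept) {
  pos_cats <- c("CIN2", "CIN3")
  neg_cats <- c("BS", "CIN1")
  d <- scans[scans$category %in% c(pos_cats, neg_cats), , drop = FALSE]
  if (nrow(d) == 0L) stop("no squamous scans to classify", call. = FALSE)
  truth <- d$category %in% pos_cats
  if (all(truth) || !any(truth)) {
    stop("degenerate single-class input", call. = FALSE)
  }
  called <- d$ratio > intercept + slope * d$R3
  tp <- sum(called & truth); fn <- sum(!called & truth)
  tn <- sum(!called & !truth); fp <- sum(called & !truth)
  list(labels = called, scans = d,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(called = c("positive", "negative"),
                                          truth = c("HSIL", "LSIL/BS"))),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Load the packaged per-case study table
#'
#' Reads the packaged table of point-scan counts per case and diagnostic
#' category (or a user-supplied CSV in the same layout) and computes the
#' category sums and grand total.
#'
#' @param path CSV path; default is the packaged `table2.csv` fixture.
#' @return list with the `table` (data.frame), `category_totals` (named
#'   vector) and `grand_total`.
#' @export
load_study_table <- function(path = system.file("extdata", "table2.csv",
                                                package = "domscope")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("study table not found", call. = FALSE)
  }
  tab <- utils::read.csv(path, check.names = TRUE)
  cats <- c("BC", "AIS", "BS", "CIN1", "CIN2", "CIN3")
  if (!all(c("case", cats) %in% names(tab))) {
    stop("malformed study table: expected columns case, BC, AIS, BS, CIN1, CIN2, CIN3",
         call. = FALSE)
  }
  totals <- vapply(tab[cats], sum, numeric(1))
  list(table = tab, category_totals = totals,
       grand_total = sum(totals))
}
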