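#' Fit an ADC map by monoexponential least squares
#'
#' Per voxel, fits the ordinary least-squares line of `log(S)` against the
#' b-value; the apparent diffusion coefficient is minus the slope (positive
#' for decaying signal). Voxels where noise drives the signal upward with b
#' yield negative ADCs; these are preserved because they carry information
#' about the noise distribution. Voxels with any non-positive signal cannot
#' be log-transformed: their ADC is set to 0 and flagged in the `valid`
#' attribute.
#'
#' @param images numeric array `[b, row, col]` (e.g. the `data` of a
#'   `dwi_clinical_image`) or a list of matrices, one per b-value, in
#'   scanner signal units.
#' @param b_values numeric vector of at least 2 distinct b-values, s/mm^2.
#' @param source provenance tag, one of `"noa1"`, `"noa_n"`, `"dnif"`,
#'   `"ground_truth"`.
#' @return a `dwi_adc_map`: `data` (matrix, mm^2/s), `b_values_used`,
#'   `source`, and attribute-style element `valid` (logical matrix).
#' @export
fit_adc <- function(images, b_values,
                    source = c("noa_n", "noa1", "dnif", "ground_truth")) {
  source <- match.arg(source)
  if (is.list(images))
    images <- aperm(simplify2array(images), c(3, 1, 2))
  if (inherits(images, "dwi_clinical_image")) images <- images$data
  stopifnot(is.array(images), length(dim(images)) == 3L)
  b <- as.numeric(b_values)
  if (length(unique(b)) < 2L)
    stop("need at least 2 distinct b-values to fit an ADC")
  if (dim(images)[1] != length(b))
    stop("first axis of images (", dim(images)[1],
         ") must match length of b_values (", length(b), ")")
  nb <- length(b)
  d <- dim(images)[2:3]
  smat <- matrix(images, nrow = nb)          # nb x (rows*cols)
  valid <- colSums(smat > 0) == nb
  adc <- numeric(ncol(smat))
  if (any(valid)) {
    ls <- log(smat[, valid, drop = FALSE])
    bc <- b - mean(b)
    slope <- colSums(bc * ls) / sum(bc * bc)
    adc[valid] <- -slope
  }
  structure(list(data = matrix(adc, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2]),
                 b_values_used = b, source = source),
            class = "dwi_adc_map")
}

adc_data <- function(adc) {
  if (inherits(adc, "dwi_adc_map")) adc$data else adc
}

#' ROI summary statistics of an ADC map
#'
#' Mean, population standard deviation (divisor `n`), and coefficient of
#' variation (`std / mean`) over the masked voxels; negative ADCs are
#' included.
#'
#' @param adc a `dwi_adc_map` or plain matrix, mm^2/s.
#' @param mask logical matrix, same shape, with at least one `TRUE` voxel.
#' @return list with `mean_adc`, `std_adc`, `cov`, `n_voxels`.
#' @export
roi_stats <- function(adc, mask) {
  x <- adc_data(adc)
  stopifnot(is.logical(mask), all(dim(x) == dim(mask)))
  if (!any(mask)) stop("ROI mask is empty")
  v <- x[mask]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  list(mean_adc = m, std_adc = s,
       cov = if (m != 0) s / m else NA_real_,
       n_voxels = length(v))
}

#' Relative difference of means (RDM), percent
#'
#' `|mean(test) - mean(ref)| / mean(ref) * 100` over an ROI — the summary
#' used to compare ADC means from fast or denoised images against the
#' clinical-standard protocol.
#'
#' @param adc_test,adc_ref ADC maps (`dwi_adc_map` or matrix) of equal shape.
#' @param mask logical ROI mask.
#' @return RDM in percent.
#' @export
rdm <- function(adc_test, adc_ref, mask) {
  mt <- roi_stats(adc_test, mask)$mean_adc
  mr <- roi_stats(adc_ref, mask)$mean_adc
  if (mr == 0) stop("reference ROI mean is zero; RDM undefined")
  abs(mt - mr) / mr * 100
}

#' Mean absolute voxel-wise difference (MAVD)
#'
#' Mean of `|a - b|` over the ROI, in mm^2/s. Multiply by 1e6 to report on
#' the conventional 1e-6 mm^2/s scale.
#'
#' @param adc_a,adc_b ADC maps of equal shape.
#' @param mask logical ROI mask, nonempty.
#' @return MAVD in mm^2/s.
#' @export
mavd <- function(adc_a, adc_b, mask) {
  a <- adc_data(adc_a); b <- adc_data(adc_b)
  stopifnot(all(dim(a) == dim(b)), is.logical(mask),
            all(dim(a) == dim(mask)))
  if (!any(mask)) stop("ROI mask is empty")
  mean(abs(a[mask] - b[mask]))
}
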