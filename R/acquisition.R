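#' Acquisition protocol for the simulated scanner
#'
#' Describes how the scanner samples a phantom: the b-values, the number of
#' orthogonal diffusion-encoding directions (3 for whole-body DWI, 1 models a
#' single-direction fast protocol), the number of repeated acquisitions, the
#' Gaussian channel noise level `noise_sigma` behind the Rician magnitude
#' model, and the integer intensity ceiling of the scanner output (4095 for
#' the whole-body preset, 939 for the lung preset).
#'
#' @param b_values numeric vector of b-values in s/mm^2 (non-negative,
#'   nonempty). Default is the whole-body protocol `c(50, 600, 900)`.
#' @param n_directions 1 or 3.
#' @param n_acquisitions integer >= 1, repeats per direction.
#' @param noise_sigma per-channel Gaussian noise standard deviation, signal
#'   units, > 0.
#' @param intensity_ceiling positive integer clip level.
#' @param seed integer seed for the noise draws.
#' @return an object of class `dwi_protocol`.
#' @export
acquisition_protocol <- function(b_values = c(50, 600, 900),
                                 n_directions = 3L, n_acquisitions = 3L,
                                 noise_sigma = 100,
                                 intensity_ceiling = 4095L, seed = 1L) {
  stopifnot(length(b_values) >= 1L, all(b_values >= 0),
            n_directions %in% c(1L, 3L), n_acquisitions >= 1L,
            intensity_ceiling > 0)
  if (!is.numeric(noise_sigma) || noise_sigma <= 0)
    stop("noise_sigma must be > 0 (use acquire(..., noiseless = TRUE) for ",
         "the zero-noise limit)")
  structure(list(b_values = as.numeric(b_values),
                 n_directions = as.integer(n_directions),
                 n_acquisitions = as.integer(n_acquisitions),
                 noise_sigma = noise_sigma,
                 intensity_ceiling = as.integer(intensity_ceiling),
                 seed = as.integer(seed)),
            class = "dwi_protocol")
}

#' Simulate repeated noisy acquisitions of a phantom
#'
#' Each (b-value, direction, acquisition) image is an independent Rician
#' magnitude image `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`
#' drawn around the noiseless signal `S`, then clipped to
#' `[0, intensity_ceiling]` as an integer-range scanner would. Deterministic
#' for a fixed protocol seed.
#'
#' @param gt a `dwi_ground_truth`.
#' @param protocol a [acquisition_protocol()].
#' @param noiseless if `TRUE`, skip the noise draw entirely (the
#'   `sigma -> 0` limit); clipping still applies.
#' @return a `dwi_stack`: list with `data`, a 5-D array indexed
#'   `[b, direction, acquisition, row, col]`, and `protocol`.
#' @export
acquire <- function(gt, protocol, noiseless = FALSE) {
  stopifnot(inherits(gt, "dwi_ground_truth"), inherits(protocol, "dwi_protocol"))
  gs <- dim(gt$s0_map)
  nb <- length(protocol$b_values)
  nd <- protocol$n_directions
  na <- protocol$n_acquisitions
  dat <- array(0, dim = c(nb, nd, na, gs[1], gs[2]))
  set.seed(protocol$seed)
  for (ib in seq_len(nb)) {
    for (id in seq_len(nd)) {
      s <- noiseless_signal(gt, protocol$b_values[ib], id)
      for (ia in seq_len(na)) {
        img <- if (noiseless) s else {
          n1 <- matrix(rnorm(length(s), 0, protocol$noise_sigma), gs[1], gs[2])
          n2 <- matrix(rnorm(length(s), 0, protocol$noise_sigma), gs[1], gs[2])
          sqrt((s + n1)^2 + n2^2)
        }
        dat[ib, id, ia, , ] <- pmin(pmax(img, 0), protocol$intensity_ceiling)
      }
    }
  }
  structure(list(data = dat, protocol = protocol), class = "dwi_stack")
}

#' Trace-weighted images: geometric mean over directions
#'
#' Collapses the direction axis of a stack by the voxel-wise geometric mean,
#' the operation clinical scanners use to form direction-independent
#' ("trace-weighted") diffusion images. Computed as an exact product root;
#' zero voxels give zero.
#'
#' @param stack a `dwi_stack`.
#' @return a `dwi_trace_stack`: `data` is `[b, acquisition, row, col]`.
#' @export
trace_weighted <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  d <- dim(stack$data)
  nd <- d[2]
  out <- array(0, dim = d[-2])
  for (ib in seq_len(d[1])) {
    for (ia in seq_len(d[3])) {
      prod <- array(1, dim = d[4:5])
      for (id in seq_len(nd)) prod <- prod * stack$data[ib, id, ia, , ]
      out[ib, ia, , ] <- prod^(1 / nd)
    }
  }
  structure(list(data = out, protocol = stack$protocol),
            class = "dwi_trace_stack")
}

#' Clinical-standard image: arithmetic mean over acquisitions
#'
#' Averages the trace-weighted images over the acquisition axis, yielding the
#' NOA_N image a clinical protocol stores (N = directions x acquisitions;
#' e.g. 3 directions x 3 acquisitions give NOA_9).
#'
#' @param traces a `dwi_trace_stack`.
#' @return a `dwi_clinical_image`: `data` is `[b, row, col]`, plus `noa`.
#' @export
average_acquisitions <- function(traces) {
  stopifnot(inherits(traces, "dwi_trace_stack"))
  d <- dim(traces$data)
  out <- array(0, dim = d[-2])
  for (ib in seq_len(d[1])) {
    acc <- array(0, dim = d[3:4])
    for (ia in seq_len(d[2])) acc <- acc + traces$data[ib, ia, , ]
    out[ib, , ] <- acc / d[2]
  }
  noa <- traces$protocol$n_directions * traces$protocol$n_acquisitions
  structure(list(data = out, noa = as.integer(noa),
                 protocol = traces$protocol),
            class = "dwi_clinical_image")
}

#' Normalize scanner intensities to \[0, 1\]
#'
#' @param img numeric array in scanner units.
#' @param ceiling positive intensity ceiling (4095 whole-body, 939 lung).
#' @return `clip(img, 0, ceiling) / ceiling`.
#' @export
normalize_intensity <- function(img, ceiling) {
  stopifnot(ceiling > 0)
  pmin(pmax(img, 0), ceiling) / ceiling
}

#' @rdname normalize_intensity
#' @export
denormalize_intensity <- function(img, ceiling) {
  stopifnot(ceiling > 0)
  img * ceiling
}
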