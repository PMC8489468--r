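#' Describe one tissue compartment of a synthetic phantom
#'
#' A compartment is a parametric shape (ellipse or rectangle) carrying a
#' proton-density-like baseline signal `s0` and an apparent diffusion
#' coefficient `adc` in mm^2/s. An optional per-direction ADC 3-vector
#' models anisotropic diffusion along the three orthogonal encoding
#' directions; when given it supersedes `adc`.
#'
#' @param label character, unique name of the compartment.
#' @param shape `"ellipse"` or `"rectangle"`.
#' @param center numeric length-2, (row, col) center in pixel units.
#' @param radii numeric length-2, semi-axes (ellipse) or half-sides
#'   (rectangle) in pixels.
#' @param rotation rotation angle in degrees, counter-clockwise.
#' @param s0 baseline signal (arbitrary scanner units), must be > 0.
#' @param adc apparent diffusion coefficient in mm^2/s, in \[0, 4e-3\].
#' @param adc_per_direction optional numeric length-3 of non-negative
#'   per-direction ADCs (mm^2/s); overrides `adc` when supplied.
#' @param is_lesion logical; lesion compartments get a ground-truth ROI mask.
#' @return an object of class `dwi_compartment`.
#' @export
compartment <- function(label, shape = c("ellipse", "rectangle"),
                        center, radii, rotation = 0,
                        s0, adc, adc_per_direction = NULL,
                        is_lesion = FALSE) {
  shape <- match.arg(shape)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            length(center) == 2L, length(radii) == 2L,
            is.numeric(s0), length(s0) == 1L, s0 > 0,
            is.numeric(adc), length(adc) == 1L)
  if (adc < 0 || adc > 4e-3)
    stop("adc must lie in [0, 4e-3] mm^2/s, got ", adc)
  if (!is.null(adc_per_direction)) {
    stopifnot(length(adc_per_direction) == 3L)
    if (any(adc_per_direction < 0))
      stop("adc_per_direction entries must be >= 0")
  }
  structure(list(label = label, shape = shape,
                 center = as.numeric(center), radii = as.numeric(radii),
                 rotation = as.numeric(rotation), s0 = as.numeric(s0),
                 adc = as.numeric(adc),
                 adc_per_direction = if (is.null(adc_per_direction)) NULL else
                   as.numeric(adc_per_direction),
                 is_lesion = isTRUE(is_lesion)),
            class = "dwi_compartment")
}

#' Specify a synthetic 2D DWI phantom
#'
#' @param grid_shape integer length-2 (rows, cols), each >= 16.
#' @param compartments list of [compartment()] objects; later compartments
#'   overwrite earlier ones where their geometries overlap.
#' @param background_s0 baseline signal of background voxels (>= 0).
#' @param background_adc ADC of background voxels, mm^2/s. Default 2.0e-3
#'   (free-water-like).
#' @param seed integer seed recorded with the spec; phantom rasterization is
#'   deterministic, the seed feeds downstream randomized consumers.
#' @return an object of class `dwi_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, compartments, background_s0 = 0,
                         background_adc = 2.0e-3, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 16L),
            length(compartments) >= 1L,
            all(vapply(compartments, inherits, TRUE, "dwi_compartment")),
            background_s0 >= 0, background_adc >= 0)
  for (cm in compartments) {
    lo <- cm$center - max(cm$radii)
    hi <- cm$center + max(cm$radii)
    if (any(lo < 0) || any(hi > grid_shape))
      stop("compartment '", cm$label, "' does not lie inside the grid")
  }
  structure(list(grid_shape = grid_shape, compartments = compartments,
                 background_s0 = as.numeric(background_s0),
                 background_adc = as.numeric(background_adc),
                 seed = as.integer(seed)),
            class = "dwi_phantom_spec")
}

# pixel (i, j) has its center at (i - 0.5, j - 0.5); no anti-aliasing so ROI
# masks are exactly reproducible
rasterize_compartment <- function(cm, grid_shape) {
  ci <- matrix(seq_len(grid_shape[1]) - 0.5, grid_shape[1], grid_shape[2])
  cj <- matrix(rep(seq_len(grid_shape[2]) - 0.5, each = grid_shape[1]),
               grid_shape[1], grid_shape[2])
  th <- cm$rotation * pi / 180
  u <- cos(th) * (ci - cm$center[1]) + sin(th) * (cj - cm$center[2])
  v <- -sin(th) * (ci - cm$center[1]) + cos(th) * (cj - cm$center[2])
  mask <- if (cm$shape == "ellipse") {
    (u / cm$radii[1])^2 + (v / cm$radii[2])^2 <= 1
  } else {
    abs(u) <= cm$radii[1] & abs(v) <= cm$radii[2]
  }
  if (!any(mask))
    stop("compartment '", cm$label, "' rasterizes to zero area")
  mask
}

#' Generate the ground-truth maps of a phantom
#'
#' Rasterizes every compartment onto the pixel grid (center-of-pixel
#' inclusion, later compartments overwrite earlier ones) and returns the true
#' S0 map, ADC map, optional per-direction ADC maps, and one boolean ROI mask
#' per lesion compartment.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `dwi_ground_truth` with elements `s0_map`,
#'   `adc_map`, `adc_dir_maps` (list of 3 matrices or `NULL`), `roi_masks`
#'   (named list of logical matrices), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "dwi_phantom_spec"))
  gs <- spec$grid_shape
  s0 <- matrix(spec$background_s0, gs[1], gs[2])
  adc <- matrix(spec$background_adc, gs[1], gs[2])
  any_aniso <- any(vapply(spec$compartments,
                          function(cm) !is.null(cm$adc_per_direction), TRUE))
  dir_maps <- if (any_aniso) {
    lapply(1:3, function(d) matrix(spec$background_adc, gs[1], gs[2]))
  } else NULL
  roi <- list()
  for (cm in spec$compartments) {
    m <- rasterize_compartment(cm, gs)
    s0[m] <- cm$s0
    mean_adc <- if (is.null(cm$adc_per_direction)) cm$adc else
      mean(cm$adc_per_direction)
    adc[m] <- mean_adc
    if (any_aniso) {
      for (d in 1:3) {
        val <- if (is.null(cm$adc_per_direction)) cm$adc else
          cm$adc_per_direction[d]
        dir_maps[[d]][m] <- val
      }
    }
    if (cm$is_lesion) roi[[cm$label]] <- m
  }
  structure(list(s0_map = s0, adc_map = adc, adc_dir_maps = dir_maps,
                 roi_masks = roi, spec = spec),
            class = "dwi_ground_truth")
}

#' Noiseless diffusion-weighted signal of a phantom
#'
#' Monoexponential decay per voxel: `S = S0 * exp(-b * ADC_d)` where `ADC_d`
#' is the per-direction ADC if the phantom is anisotropic and the isotropic
#' ADC map otherwise.
#'
#' @param gt a `dwi_ground_truth`.
#' @param b diffusion weighting in s/mm^2, must be >= 0.
#' @param direction encoding direction index in 1..3.
#' @return numeric matrix of noiseless signal.
#' @export
noiseless_signal <- function(gt, b, direction = 1L) {
  stopifnot(inherits(gt, "dwi_ground_truth"), direction %in% 1:3)
  if (!is.numeric(b) || length(b) != 1L || b < 0)
    stop("b must be a single non-negative value (s/mm^2)")
  adc <- if (is.null(gt$adc_dir_maps)) gt$adc_map else
    gt$adc_dir_maps[[direction]]
  gt$s0_map * exp(-b * adc)
}

#' Serialize / deserialize a phantom specification (JSON)
#'
#' @param spec a `dwi_phantom_spec`.
#' @param path JSON file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` the spec.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dwi_phantom_spec"))
  x <- unclass(spec)
  x$compartments <- lapply(x$compartments, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  comps <- lapply(x$compartments, function(cm)
    compartment(cm$label, cm$shape, unlist(cm$center), unlist(cm$radii),
                cm$rotation, cm$s0, cm$adc,
                adc_per_direction = if (is.null(cm$adc_per_direction)) NULL else
                  unlist(cm$adc_per_direction),
                is_lesion = isTRUE(cm$is_lesion)))
  phantom_spec(unlist(x$grid_shape), comps, x$background_s0,
               x$background_adc, x$seed)
}

#' Randomized phantom specification
#'
#' Draws a plausible torso-section-like phantom: a large healthy-tissue
#' ellipse (ADC near 1.4e-3 mm^2/s), one or two focal lesions with lower ADC
#' (0.6e-3 to 1.0e-3 mm^2/s, the cellular-tumor range), and near-zero-signal
#' background (air). Geometry, signal levels, and lesion ADCs are drawn from
#' the ranges below so a training set spans realistic contrast.
#'
#' @param seed integer seed.
#' @param grid_shape (rows, cols), default `c(64, 64)`.
#' @param n_lesions number of lesion compartments (1 or 2).
#' @return a `dwi_phantom_spec`.
#' @export
random_phantom_spec <- function(seed, grid_shape = c(64L, 64L),
                                n_lesions = 1L) {
  set.seed(as.integer(seed))
  gs <- as.integer(grid_shape)
  ctr <- gs / 2 + runif(2, -2, 2)
  body <- compartment("tissue", "ellipse", center = ctr,
                      radii = c(runif(1, 0.30, 0.40) * gs[1],
                                runif(1, 0.30, 0.42) * gs[2]),
                      rotation = runif(1, 0, 180),
                      s0 = runif(1, 1500, 2600),
                      adc = runif(1, 1.2e-3, 1.6e-3))
  comps <- list(body)
  for (l in seq_len(n_lesions)) {
    off <- runif(2, -0.12, 0.12) * gs
    comps[[l + 1L]] <- compartment(
      paste0("lesion", l), "ellipse", center = ctr + off,
      radii = runif(2, 0.08, 0.14) * gs,
      rotation = runif(1, 0, 180),
      s0 = runif(1, 2200, 3400),
      adc = runif(1, 0.6e-3, 1.0e-3),
      is_lesion = TRUE)
  }
  phantom_spec(gs, comps, background_s0 = 0, seed = seed)
}
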