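#' Full-reference image-quality metrics
#'
#' MSE, SSIM (Gaussian-window, see [ssim()]), and PSNR between a test image
#' and a reference. PSNR is `10 * log10(data_range^2 / MSE)`, reported as
#' `Inf` when the images are identical.
#'
#' @param test,ref numeric matrices of equal shape.
#' @param data_range dynamic range (1.0 for normalized images).
#' @return list with `mse`, `ssim`, `psnr`.
#' @export
image_metrics <- function(test, ref, data_range = 1.0) {
  stopifnot(is.matrix(test), is.matrix(ref), all(dim(test) == dim(ref)),
            data_range > 0)
  mse <- mean((test - ref)^2)
  list(mse = mse,
       ssim = ssim(test, ref, data_range = data_range),
       psnr = if (mse == 0) Inf else 10 * log10(data_range^2 / mse))
}

# two-sided signed-rank p for non-zero differences d.
# n <= 15: exact by enumerating every sign assignment of the midranks
# (valid under ties); 16-25 without ties: exact via wilcox.test; otherwise
# normal approximation with continuity correction.
signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  if (n <= 15L) {
    v_obs <- sum(r[d > 0])
    v <- 0
    for (ri in r) v <- c(v, v + ri)
    p <- 2 * min(mean(v <= v_obs + 1e-9), mean(v >= v_obs - 1e-9))
    return(min(1, p))
  }
  exact <- n <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, alternative = "two.sided", mu = 0, exact = exact,
                correct = TRUE)$p.value)
}

#' Paired Wilcoxon signed-rank comparisons with Benjamini-Hochberg control
#'
#' Runs a two-sided Wilcoxon signed-rank test on each named set of paired
#' scores and adjusts the p-values for multiple comparisons across the whole
#' family with the Benjamini-Hochberg step-up procedure. Zero differences
#' are discarded before ranking (Wilcoxon's convention); the exact null
#' distribution is used for up to 25 non-tied pairs and the normal
#' approximation with continuity correction beyond. A comparison whose
#' differences are all zero is undefined and flagged rather than an error.
#'
#' @param paired_scores named list; each element is a 2-column matrix or
#'   data frame of paired values (method A, method B).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data frame with one row per comparison: `comparison`, `n_pairs`,
#'   `n_nonzero`, `raw_p`, `adjusted_p`, `significant`, `defined`.
#' @export
#' @details For up to 15 non-zero differences the exact two-sided p-value is
#'   computed by full enumeration of the `2^n` sign assignments of the
#'   (mid)ranks, which remains exact under tied absolute differences; for
#'   16-25 untied differences the exact signed-rank distribution of
#'   `stats::wilcox.test` is used.
wilcoxon_bh <- function(paired_scores, alpha = 0.05) {
  stopifnot(is.list(paired_scores), length(paired_scores) >= 1L)
  nms <- names(paired_scores)
  if (is.null(nms)) nms <- paste0("comparison", seq_along(paired_scores))
  rows <- lapply(seq_along(paired_scores), function(i) {
    m <- as.matrix(paired_scores[[i]])
    stopifnot(ncol(m) == 2L)
    d <- m[, 1] - m[, 2]
    nz <- d[d != 0]
    if (length(nz) == 0L)
      return(data.frame(comparison = nms[i], n_pairs = nrow(m),
                        n_nonzero = 0L, raw_p = NA_real_, defined = FALSE))
    p <- signed_rank_p(nz)
    data.frame(comparison = nms[i], n_pairs = nrow(m),
               n_nonzero = length(nz), raw_p = p, defined = TRUE)
  })
  rep <- do.call(rbind, rows)
  rep$adjusted_p <- NA_real_
  ok <- rep$defined
  rep$adjusted_p[ok] <- p.adjust(rep$raw_p[ok], method = "BH")
  rep$significant <- !is.na(rep$adjusted_p) & rep$adjusted_p < alpha
  rep
}
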