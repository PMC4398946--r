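#' Gaussian spatial smoothing of a volume series
#'
#' Per-volume separable 3D Gaussian smoothing with SD
#' `fwhm / (2 * sqrt(2 * log(2)))` per axis, expressed in mm and converted
#' to voxels per axis. Kernels are truncated at 3 SD and renormalised at the
#' grid edges so constant volumes are preserved exactly. `fwhm_mm = 0` is
#' the identity.
#'
#' @param series a [volume_series()].
#' @param fwhm_mm smoothing kernel full width at half maximum, mm (>= 0).
#' @return The smoothed [volume_series()].
#' @export
smooth_volumes <- function(series, fwhm_mm = 2) {
  stopifnot(inherits(series, "volume_series"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(series)
  sd_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(series$data)
  arr <- series$data
  for (ax in 1:3) {
    sd_vox <- sd_mm / series$voxel_mm[ax]
    S <- gaussian_matrix(d[ax], sd_vox)
    if (is.null(S)) next
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    m <- S %*% matrix(a, nrow = d[ax])
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  series$data <- arr
  series
}

# n x n truncated, row-renormalised Gaussian smoothing matrix (NULL if the
# kernel is effectively a delta)
gaussian_matrix <- function(n, sd_vox) {
  r <- ceiling(3 * sd_vox)
  if (r < 1) return(NULL)
  i <- seq_len(n)
  D <- outer(i, i, "-")
  S <- exp(-D^2 / (2 * sd_vox^2))
  S[abs(D) > r] <- 0
  S / rowSums(S)
}

#' Global signal scaling
#'
#' Rescales every volume so that its mean over in-brain voxels equals 100,
#' the convention under which GLM betas read directly as percent signal
#' change. In-brain voxels are those whose temporal mean exceeds 1/8 of the
#' grand mean.
#'
#' @param series a [volume_series()].
#' @return The scaled series, with a logical `inbrain` component recording
#'   the in-brain voxel mask.
#' @export
global_scale <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  m <- as_voxel_matrix(series)
  tmean <- rowMeans(m)
  inbrain <- tmean > mean(tmean) / 8
  if (!any(inbrain)) stop("global scaling failed: no in-brain voxels")
  gmeans <- colMeans(m[inbrain, , drop = FALSE])
  if (any(gmeans <= 0))
    stop("global scaling failed: volume with non-positive global mean")
  out <- from_voxel_matrix(series, sweep(m, 2, 100 / gmeans, "*"))
  out$inbrain <- array(inbrain, dim = dim(series$data)[1:3])
  out
}

#' Build the sparse-design GLM design matrix
#'
#' One indicator column per condition (the silent baseline is the implicit
#' intercept), a constant column, and discrete-cosine drift regressors
#' implementing the high-pass filter: all DCT basis functions whose period
#' `2 * T / k` exceeds `highpass_cutoff_s` are included, where `T` is the
#' session length in seconds.
#'
#' @param schedule a [make_schedule()] result.
#' @param highpass_cutoff_s high-pass cutoff period in seconds.
#' @return A numeric matrix of class `design_matrix` with attributes
#'   `condition_cols` (column indices of the condition indicators),
#'   `conditions`, and `nuisance_cols`.
#' @export
build_design <- function(schedule, highpass_cutoff_s = 300) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (highpass_cutoff_s <= 0) stop("'highpass_cutoff_s' must be > 0")
  n <- nrow(schedule)
  conds <- schedule_conditions(schedule)
  X_cond <- sapply(conds, function(cc) as.numeric(schedule$condition == cc))
  T_total <- n * attr(schedule, "TR_s")
  K <- max(0L, ceiling(2 * T_total / highpass_cutoff_s) - 1L)
  t0 <- seq_len(n) - 0.5
  drift <- if (K > 0)
    sapply(seq_len(K), function(k) cos(pi * k * t0 / n)) else NULL
  X <- cbind(X_cond, constant = 1, drift)
  colnames(X) <- c(conds, "constant",
                   if (K > 0) paste0("drift_", seq_len(K)))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(X, condition_cols = seq_along(conds), conditions = conds,
            nuisance_cols = (length(conds) + 1L):ncol(X),
            class = c("design_matrix", class(X)))
}

#' Voxel-wise ordinary least squares GLM
#'
#' Fits the design to every voxel's time series and returns per-condition
#' response-estimate coefficients (betas) and t-values for each condition
#' against the silent baseline, plus an omnibus F statistic testing all
#' condition coefficients jointly zero. On globally scaled data the betas
#' are in percent-signal-change units. Voxels with (numerically) zero
#' residual variance get t-values computed against a variance floor, so
#' noiseless responding voxels keep a finite t whose across-condition
#' ordering equals the beta ordering; exactly constant voxels get omnibus
#' p = 1 and are treated as non-significant.
#'
#' @param series a (preprocessed) [volume_series()].
#' @param design a [build_design()] matrix, row-aligned with the series.
#' @return A list of class `stat_maps`: `beta` and `t` (voxels x
#'   conditions), `F`, `p_omnibus`, `sigma2` (per-voxel vectors), `df`
#'   residual degrees of freedom, `conditions`, and the grid geometry.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(series, "volume_series"), inherits(design, "design_matrix"))
  X <- unclass(design)
  attr(X, "condition_cols") <- attr(X, "conditions") <- attr(X, "nuisance_cols") <- NULL
  n <- nrow(X)
  if (n != n_volumes(series)) stop("series and design are not row-aligned")
  Y <- t(as_voxel_matrix(series))            # time x voxels
  cc <- attr(design, "condition_cols")

  XtX <- crossprod(X)
  Ci <- chol2inv(chol(XtX))
  beta <- Ci %*% crossprod(X, Y)             # p x V
  fitted <- X %*% beta
  res <- Y - fitted
  rss <- colSums(res^2)
  df <- n - ncol(X)
  sigma2 <- rss / df

  scale_ref <- colMeans(Y^2)
  tol <- 1e-18 * pmax(scale_ref, 1)
  sigma2_eff <- pmax(sigma2, tol)
  zero_res <- rss <= tol

  se <- sqrt(outer(diag(Ci)[cc], sigma2_eff))  # k x V
  # exactly-fitted voxels: finite t proportional to beta (the design factor
  # is dropped so the across-condition ordering equals the beta ordering)
  if (any(zero_res))
    se[, zero_res] <- rep(sqrt(tol[zero_res]), each = length(cc))
  tval <- beta[cc, , drop = FALSE] / se

  # omnibus F: reduced model without the condition columns
  X0 <- X[, -cc, drop = FALSE]
  H0 <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  rss0 <- colSums((Y - H0 %*% Y)^2)
  q <- length(cc)
  Fstat <- ((rss0 - rss) / q) / sigma2_eff
  p <- stats::pf(Fstat, q, df, lower.tail = FALSE)
  # exactly-fitted voxels: significant if conditions explain signal, inert if flat
  p[zero_res & (rss0 - rss) > tol] <- 0
  p[zero_res & (rss0 - rss) <= tol] <- 1

  structure(
    list(beta = t(beta[cc, , drop = FALSE]), t = t(tval),
         F = Fstat, p_omnibus = p, sigma2 = sigma2, df = df,
         conditions = attr(design, "conditions"),
         dim = dim(series$data)[1:3], voxel_mm = series$voxel_mm,
         origin_mm = series$origin_mm),
    class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf("<stat_maps> %d voxels, %d conditions, %d residual df\n",
              nrow(x$beta), ncol(x$beta), x$df))
  invisible(x)
}

#' Omnibus significance mask
#'
#' Voxels whose omnibus stimuli-vs-baseline F test is significant at
#' `alpha`, optionally Bonferroni-corrected over voxels with a defined test.
#'
#' @param statmaps a [fit_glm()] result.
#' @param alpha significance level in (0, 1).
#' @param correction `"none"` (the mapping default, p < 0.001 uncorrected)
#'   or `"bonferroni"` for family-wise error control over the volume.
#' @return Logical 3D array (the mask), with attribute `alpha_effective`.
#' @export
omnibus_mask <- function(statmaps, alpha = 0.001,
                         correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(statmaps, "stat_maps"))
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]")
  p <- statmaps$p_omnibus
  n_valid <- sum(is.finite(p) & p < 1)
  p_adj <- if (correction == "bonferroni") pmin(1, p * max(n_valid, 1)) else p
  mask <- is.finite(p_adj) & (p_adj < alpha | (alpha == 1 & p_adj < 1))
  structure(array(mask, dim = statmaps$dim),
            alpha_effective = alpha, correction = correction)
}
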