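kinetic_result <- function(vt = NA_real_, dvr = NA_real_, t_star, r2, route,
                           intercept = NA_real_, n_points = NA_integer_) {
  bpnd <- if (is.na(dvr)) NA_real_ else dvr - 1
  structure(list(vt = vt, dvr = dvr, bpnd = bpnd, t_star = t_star,
                 logan_r2 = r2, route = route, intercept = intercept,
                 n_points = n_points),
            class = "kinetic_result")
}

#' @export
print.kinetic_result <- function(x, ...) {
  cat(sprintf("<kinetic_result> route=%s t*=%.1f min, R2=%.4f\n",
              x$route, x$t_star, x$logan_r2))
  if (!is.na(x$vt)) cat(sprintf("  Vt   = %.4f\n", x$vt))
  if (!is.na(x$dvr)) cat(sprintf("  DVR  = %.4f  BP_ND = %.4f\n", x$dvr, x$bpnd))
  invisible(x)
}

# Cumulative trapezoid of (times, values) anchored at (0, 0).
cumtrapz0 <- function(times, values) {
  tt <- c(0, times); vv <- c(0, values)
  (pracma::cumtrapz(tt, vv))[-1]
}

# Cumulative integral of an analytic input evaluated on a fine grid,
# interpolated at the requested times.
cum_input_integral <- function(input_fun, times, step = 1 / 60) {
  grid <- seq(0, max(times), by = step)
  if (max(grid) < max(times)) grid <- c(grid, max(times))
  ci <- pracma::cumtrapz(grid, input_fun(grid))
  stats::approx(grid, ci, xout = times)$y
}

logan_ols <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  list(slope = unname(slope), intercept = unname(fit$coefficients[1]),
       r2 = max(0, min(1, r2)))
}

logan_tail <- function(tissue, t_star) {
  sel <- which(tissue$times >= t_star)
  if (length(sel) < 3)
    stop("insufficient data: fewer than 3 frames at or after t* = ", t_star)
  if (any(tissue$activity[sel] <= 0))
    stop("non-positive tissue activity after t*; Logan transform undefined")
  sel
}

#' Logan graphical analysis with an arterial input (Vt)
#'
#' Ordinary least squares of the Logan-transformed data restricted to
#' `t >= t_star`: the running integral of tissue activity divided by the
#' instantaneous tissue activity, against the running integral of the
#' (metabolite-corrected) plasma input divided by tissue activity. In the
#' linear regime the slope is the total distribution volume Vt. Integrals
#' use the trapezoidal rule anchored at zero activity at time zero; an
#' analytic input is integrated on a fine grid.
#'
#' @param tissue A [tac] of frame-averaged tissue activity at frame midpoints.
#' @param input The input function: an [arterial_input_model], a function of
#'   time, an [aif_params], or a sampled [tac] covering the scan span.
#' @param t_star Start of the linear segment, minutes.
#' @return A `kinetic_result` with `vt`, the terminal-segment R^2, and the
#'   intercept.
#' @export
logan_vt <- function(tissue, input, t_star = 20) {
  stopifnot(inherits(tissue, "tac"))
  sel <- logan_tail(tissue, t_star)
  ct <- tissue$activity
  cum_ct <- cumtrapz0(tissue$times, ct)
  cum_cp <- if (inherits(input, "arterial_input_model")) {
    cum_input_integral(corrected_input_fun(input), tissue$times)
  } else if (is.function(input) || inherits(input, "aif_params")) {
    cum_input_integral(as_input_fun(input, max(tissue$times)), tissue$times)
  } else if (inherits(input, "tac")) {
    if (max(input$times) < max(tissue$times) - 1e-9)
      stop("input curve does not cover the tissue span")
    stats::approx(input$times, cumtrapz0(input$times, input$activity),
                  xout = tissue$times)$y
  } else stop("unsupported input type")
  fit <- logan_ols(cum_cp[sel] / ct[sel], cum_ct[sel] / ct[sel])
  kinetic_result(vt = fit$slope, t_star = t_star, r2 = fit$r2,
                 route = "arterial", intercept = fit$intercept,
                 n_points = length(sel))
}

#' Logan reference-tissue analysis (DVR / BP_ND)
#'
#' The reference-tissue form of the Logan plot with a fixed reference efflux
#' rate k2': OLS of the tissue Logan ordinate against
#' `(integral of reference + reference/k2') / tissue`, restricted to
#' `t >= t_star`. The slope is the distribution volume ratio DVR and
#' `BP_ND = DVR - 1`.
#'
#' @param tissue,reference [tac]s on a common frame-midpoint support (the
#'   reference is linearly interpolated to the tissue times if needed).
#' @param k2_prime Reference-region efflux rate, 1/min, > 0.
#' @param t_star Start of the linear segment, minutes.
#' @return A `kinetic_result` with `dvr`, `bpnd`, R^2.
#' @export
logan_reference_bpnd <- function(tissue, reference, k2_prime, t_star = 20) {
  stopifnot(inherits(tissue, "tac"), inherits(reference, "tac"))
  if (k2_prime <= 0) stop("k2_prime must be > 0")
  sel <- logan_tail(tissue, t_star)
  ct <- tissue$activity
  cref <- if (isTRUE(all.equal(reference$times, tissue$times))) {
    reference$activity
  } else {
    stats::approx(reference$times, reference$activity, xout = tissue$times,
                  rule = 2)$y
  }
  cum_ct <- cumtrapz0(tissue$times, ct)
  cum_ref <- cumtrapz0(tissue$times, cref)
  x <- (cum_ref[sel] + cref[sel] / k2_prime) / ct[sel]
  y <- cum_ct[sel] / ct[sel]
  fit <- logan_ols(x, y)
  kinetic_result(dvr = fit$slope, t_star = t_star, r2 = fit$r2,
                 route = "reference", intercept = fit$intercept,
                 n_points = length(sel))
}

# One-tissue-compartment fit of a tissue curve against an analytic input:
# C(t) = K1 * exp(-k2 t) (*) Cp(t), computed by an exact-exponential
# recursive convolution on a fine grid.
fit_1tcm <- function(tissue, input, step = 1 / 60) {
  stopifnot(inherits(tissue, "tac"))
  cp <- as_input_fun(input, max(tissue$times))
  grid <- seq(0, max(tissue$times) + step, by = step)
  cpg <- cp(grid)
  conv <- function(K1, k2) {
    e <- exp(-k2 * step)
    n <- length(grid)
    out <- numeric(n)
    for (i in 2:n) out[i] <- out[i - 1] * e + K1 * step * (cpg[i] + cpg[i - 1] * e) / 2
    out
  }
  resid_fn <- function(theta) {
    m <- conv(exp(theta[1]), exp(theta[2]))
    stats::approx(grid, m, xout = tissue$times)$y - tissue$activity
  }
  fit <- minpack.lm::nls.lm(par = log(c(0.3, 0.1)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(K1 = exp(fit$par[1]), k2 = exp(fit$par[2]),
       rms = sqrt(mean(fit$fvec^2)))
}

#' Average reference-region efflux rate k2'
#'
#' Fits a one-tissue-compartment model (K1, k2) to each arterially sampled
#' subject's cerebellar curve against that subject's metabolite-corrected
#' input and returns the across-subject mean k2. This is the "average k2'"
#' plugged into the reference-tissue Logan model for the subjects without
#' blood data.
#'
#' @param subjects List, one element per arterial subject, each with
#'   `cerebellum` (a [tac]) and `input` (an [arterial_input_model], function,
#'   or [aif_params]).
#' @param fallback Optional value returned (with a warning) when no arterial
#'   subject is supplied; if `NULL` (default), that case is an error.
#' @return Mean cerebellar k2 across subjects, 1/min, with attribute
#'   `per_subject`.
#' @export
estimate_k2_prime <- function(subjects, fallback = NULL) {
  if (length(subjects) == 0) {
    if (!is.null(fallback)) {
      warning("no arterial subjects; falling back to configured k2' = ",
              fallback)
      return(fallback)
    }
    stop("configuration error: no arterial subjects to estimate k2' from")
  }
  k2 <- vapply(subjects, function(s)
    fit_1tcm(s$cerebellum, s$input)$k2, numeric(1))
  structure(mean(k2), per_subject = k2)
}

#' Parametric BP_ND image
#'
#' A 3D BP_ND (or other voxel-wise) map with its affine and provenance.
#'
#' @param values 3D numeric array; 0 outside the analysis mask.
#' @param affine 4x4 voxel-to-world transform.
#' @param route Provenance string (e.g. `"reference"`).
#' @param ... Further provenance fields (k2_prime, t_star, ...).
#' @return An object of class `parametric_image`.
#' @export
parametric_image <- function(values, affine, route = "reference", ...) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  structure(list(values = values, affine = check_affine(affine),
                 route = route, config = list(...)),
            class = "parametric_image")
}

check_same_grid <- function(dims_a, affine_a, dims_b, affine_b, what = "atlas") {
  if (!all(dims_a == dims_b))
    stop("grid mismatch: ", what, " dimensions differ from the image")
  if (max(abs(affine_a - affine_b)) > 1e-4)
    stop("grid mismatch: ", what, " affine differs from the image")
  invisible(TRUE)
}

#' Voxel-wise reference-Logan BP_ND image
#'
#' Applies the reference-tissue Logan model at every in-mask voxel using the
#' mean cerebellar curve of the same image as the reference. The OLS slope is
#' computed in closed form simultaneously for all voxels, so whole-image
#' fitting is a single vectorized pass. Voxels outside the mask, and voxels
#' whose terminal tissue activity is non-positive (where the Logan transform
#' is undefined), are set to 0.
#'
#' @param image A [dynamic_image].
#' @param atlas A [voi_atlas] on the same grid (supplies the cerebellar
#'   reference label and the default mask).
#' @param k2_prime Reference efflux rate, 1/min.
#' @param t_star Start of the linear segment, minutes.
#' @param mask Logical 3D array; defaults to all labelled atlas voxels.
#' @return A [parametric_image] of BP_ND.
#' @export
parametric_bpnd_image <- function(image, atlas, k2_prime, t_star = 20,
                                  mask = NULL) {
  stopifnot(inherits(image, "dynamic_image"), inherits(atlas, "voi_atlas"))
  dims <- dim(image$voxels)[1:3]
  check_same_grid(dims, image$affine, dim(atlas$labels), atlas$affine)
  ref_idx <- which(atlas_mask(atlas, "cerebellum"))
  if (length(ref_idx) == 0) stop("configuration error: empty cerebellum label")
  if (is.null(mask)) mask <- atlas$labels > 0
  if (!all(dim(mask) == dims)) stop("mask must match the image grid")

  nk <- dim(image$voxels)[4]
  flat <- matrix(image$voxels, prod(dims), nk)
  ref <- colMeans(flat[ref_idx, , drop = FALSE])
  t_mid <- frame_midpoints(image$schedule)
  sel <- which(t_mid >= t_star)
  if (length(sel) < 3)
    stop("insufficient data: fewer than 3 frames at or after t*")

  idx <- which(mask)
  Y <- flat[idx, , drop = FALSE]
  dtv <- diff(c(0, t_mid))
  # cumulative trapezoid across frames, zero-anchored, as a matrix product
  U <- upper.tri(matrix(0, nk, nk), diag = TRUE) * 1
  Acol <- (cbind(0, Y[, -nk, drop = FALSE]) + Y) / 2
  cumY <- sweep(Acol, 2, dtv, "*") %*% U
  cum_ref <- cumtrapz0(t_mid, ref)

  Ysel <- Y[, sel, drop = FALSE]
  ok <- rowSums(Ysel <= 0) == 0
  x <- sweep(1 / Ysel, 2, cum_ref[sel] + ref[sel] / k2_prime, "*")
  y <- cumY[, sel, drop = FALSE] / Ysel
  m <- length(sel)
  sx <- rowSums(x); sy <- rowSums(y)
  slope <- (rowSums(x * y) - sx * sy / m) / (rowSums(x * x) - sx^2 / m)
  bpnd <- slope - 1
  bpnd[!ok | !is.finite(bpnd)] <- 0

  out <- array(0, dims)
  out[idx] <- bpnd
  parametric_image(out, image$affine, route = "reference",
                   k2_prime = k2_prime, t_star = t_star,
                   n_undefined = sum(!ok))
}

#' Cross-validate cerebellum-normalized Vt against reference-Logan BP_ND
#'
#' For each arterially sampled subject, regional Vt is estimated by the
#' arterial Logan plot and divided by the cerebellar Vt; the same regions are
#' quantified by the reference-tissue Logan model (DVR = BP_ND + 1). The
#' per-region percent discrepancy `100 |Vt/Vt_cb - DVR| / DVR` is tabulated,
#' with per-subject means and the cohort mean +/- SD.
#'
#' @param subjects List, one per subject, each with `tacs` (named list of
#'   regional [tac]s including `"cerebellum"`) and `input` (see [logan_vt()]).
#' @param k2_prime Reference efflux rate; if `NULL`, estimated from the
#'   subjects via [estimate_k2_prime()].
#' @param t_star Start of the Logan linear segment, minutes.
#' @param regions Regions to compare; default all non-cerebellum regions of
#'   the first subject.
#' @return List with `table` (subject x region rows), `per_subject` (mean
#'   percent difference per subject), `mean`, `sd`.
#' @export
crossvalidate_vt_normalization <- function(subjects, k2_prime = NULL,
                                           t_star = 20, regions = NULL) {
  if (length(subjects) == 0) stop("no subjects supplied")
  keep <- vapply(subjects, function(s)
    !is.null(s$tacs[["cerebellum"]]) && !is.null(s$input), logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " subject(s) missing blood data or curves; skipped")
    subjects <- subjects[keep]
  }
  if (is.null(regions))
    regions <- setdiff(names(subjects[[1]]$tacs), "cerebellum")
  if (is.null(k2_prime))
    k2_prime <- estimate_k2_prime(lapply(subjects, function(s)
      list(cerebellum = s$tacs[["cerebellum"]], input = s$input)))
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    vt_cb <- logan_vt(s$tacs[["cerebellum"]], s$input, t_star)$vt
    for (r in regions) {
      vt_r <- logan_vt(s$tacs[[r]], s$input, t_star)$vt
      dvr <- logan_reference_bpnd(s$tacs[[r]], s$tacs[["cerebellum"]],
                                  k2_prime, t_star)$dvr
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, region = r, vt = vt_r, vt_norm = vt_r / vt_cb, dvr = dvr,
        diff_pct = 100 * abs(vt_r / vt_cb - dvr) / dvr)
    }
  }
  tab <- do.call(rbind, rows)
  per_subject <- tapply(tab$diff_pct, tab$subject, mean)
  list(table = tab, per_subject = as.numeric(per_subject),
       mean = mean(per_subject), sd = stats::sd(per_subject),
       k2_prime = as.numeric(k2_prime))
}
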