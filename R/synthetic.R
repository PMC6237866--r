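#' Arterial plasma model parameters
#'
#' Parameterizes the total-plasma activity curve as a linear rise from zero to
#' the peak followed by a tri-exponential decay. The peak value is the sum of
#' the three amplitudes, which makes the curve continuous at the peak.
#'
#' @param peak_time Time of the plasma peak, minutes.
#' @param amplitudes Three non-negative amplitudes A1..A3, kBq/mL.
#' @param decay_rates Three positive, distinct decay rates (1/min).
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(peak_time, amplitudes, decay_rates) {
  if (peak_time <= 0) stop("peak_time must be > 0")
  if (length(amplitudes) != 3L || length(decay_rates) != 3L)
    stop("amplitudes and decay_rates must each have length 3")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (any(decay_rates <= 0)) stop("decay rates must be > 0")
  if (any(duplicated(decay_rates))) stop("decay rates must be distinct")
  structure(list(peak_time = peak_time, amplitudes = as.numeric(amplitudes),
                 decay_rates = as.numeric(decay_rates),
                 peak_value = sum(amplitudes)),
            class = "aif_params")
}

#' @rdname aif_params
#' @export
default_aif_params <- function() {
  # peak 40 s after injection start (30 s infusion + circulation), on the
  # arterial sampling grid; fast distribution phase, slow terminal washout
  aif_params(peak_time = 2 / 3, amplitudes = c(80, 15, 5),
             decay_rates = c(4, 0.5, 0.02))
}

#' @rdname aif_params
#' @param params An `aif_params` object.
#' @param t Times, minutes.
#' @return `aif_value()`: plasma activity (kBq/mL) at `t`.
#' @export
aif_value <- function(params, t) {
  stopifnot(inherits(params, "aif_params"))
  out <- numeric(length(t))
  rise <- t <= params$peak_time
  out[rise] <- params$peak_value * t[rise] / params$peak_time
  td <- t[!rise] - params$peak_time
  out[!rise] <- colSums(params$amplitudes * exp(-outer(params$decay_rates, td)))
  pmax(out, 0)
}

#' Simulate a plasma time-activity curve
#'
#' Evaluates the linear-rise/tri-exponential plasma model at the given sample
#' times.
#'
#' @inheritParams aif_value
#' @param times Sample times, minutes, strictly increasing, starting at >= 0.
#' @return A [tac] labelled `"plasma"`.
#' @export
simulate_aif <- function(params, times) {
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("times must be strictly increasing and non-negative")
  tac(times, aif_value(params, times), label = "plasma")
}

#' Hill model of the plasma parent fraction
#'
#' The fraction of plasma activity carried by intact (unmetabolized) tracer:
#' `f(t) = 1 - a * t^b / (t^b + c)`, which starts at 1, decreases
#' monotonically, and is bounded below by `1 - a`.
#'
#' @param a Asymptotic metabolized fraction, in \[0, 1\].
#' @param b Hill exponent, > 0 (unitless).
#' @param c Half-saturation constant, > 0 (units min^b).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(a, b, c) {
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  if (b <= 0 || c <= 0) stop("b and c must be > 0")
  structure(list(a = a, b = b, c = c), class = "hill_params")
}

#' @rdname hill_params
#' @export
default_hill_params <- function() hill_params(a = 0.55, b = 1.0, c = 6.6)

#' @rdname hill_params
#' @param params A `hill_params` object.
#' @param t Times, minutes, >= 0.
#' @return `parent_fraction()`: parent fraction in \[0, 1\] at `t`.
#' @export
parent_fraction <- function(params, t) {
  stopifnot(inherits(params, "hill_params"))
  if (any(t < 0)) stop("t must be >= 0")
  tb <- t^params$b
  1 - params$a * tb / (tb + params$c)
}

#' Two-tissue-compartment model parameters
#'
#' Rate constants of the reversible two-tissue compartment model: plasma to
#' free/nonspecific (K1), efflux (k2), exchange with the specifically bound
#' compartment (k3, k4), and fractional blood volume vB. The ground-truth
#' total distribution volume is `Vt = (K1/k2) * (1 + k3/k4)`; a reference
#' region has `k3 = 0` and `Vt = K1/k2`.
#'
#' @param K1 mL/cm^3/min. @param k2,k3,k4 1/min. @param vB fraction, default 0.
#' @return An object of class `tcm_params`.
#' @export
tcm_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  if (any(c(K1, k2, k3, k4) < 0)) stop("rate constants must be >= 0")
  if (k3 > 0 && k4 <= 0) stop("k4 must be > 0 when k3 > 0")
  if (vB < 0 || vB >= 1) stop("vB must be in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "tcm_params")
}

#' @rdname tcm_params
#' @param params A `tcm_params` object.
#' @return `tcm_vt()`: the analytic total distribution volume.
#' @export
tcm_vt <- function(params) {
  with(params, if (k3 > 0) (K1 / k2) * (1 + k3 / k4) else K1 / k2)
}

# 2TCM parameters realizing a target BP_ND against the default reference
# kinetics (K1 = 0.3, k2 = 0.1, so Vt_ref = 3): k3 = bpnd * k4. k4 = 0.1/min
# keeps the slow eigenvalue fast enough that a 60-min Logan analysis sits in
# its linear regime, as required of a tracer quantifiable with this protocol.
bpnd_to_tcm <- function(bpnd, K1 = 0.3, k2 = 0.1, k4 = 0.1) {
  if (bpnd < 0) stop("bpnd must be >= 0")
  if (bpnd == 0) tcm_params(K1, k2) else tcm_params(K1, k2, k3 = bpnd * k4, k4 = k4)
}

as_input_fun <- function(input, span_end) {
  if (is.function(input)) return(input)
  if (inherits(input, "arterial_input_model"))
    return(corrected_input_fun(input))
  if (inherits(input, "aif_params")) return(function(t) aif_value(input, t))
  if (inherits(input, "tac")) {
    if (max(input$times) < span_end - 1e-9)
      stop("input curve does not cover the schedule span")
    return(tac_fun(input, extrapolate = TRUE))
  }
  stop("input must be a function, aif_params, or tac")
}

#' Simulate a two-tissue-compartment time-activity curve
#'
#' Integrates `dC1/dt = K1*Cp - (k2+k3)*C1 + k4*C2`,
#' `dC2/dt = k3*C1 - k4*C2` against the supplied input function on a fine
#' uniform grid (default 5 s, which subdivides even the 10-s early frames),
#' then averages the tissue curve `(1-vB)*(C1+C2) + vB*Cp` over each frame by
#' the trapezoidal rule.
#'
#' @param params A [tcm_params].
#' @param input Input function: an `aif_params`, a [tac] covering the
#'   schedule span, or a function of time (minutes) returning kBq/mL.
#' @param schedule A [frame_schedule].
#' @param step Integration step, minutes. Must divide the frame boundaries.
#' @return A [tac] of frame-averaged tissue activity at frame midpoints.
#' @export
simulate_2tcm <- function(params, input, schedule, step = 1 / 12) {
  stopifnot(inherits(params, "tcm_params"), inherits(schedule, "frame_schedule"))
  sol <- solve_2tcm_grid(params, input, max(schedule$end), step)
  tac(frame_midpoints(schedule),
      frame_average(sol$tissue, sol$times, schedule, step),
      label = "tissue")
}

#' @rdname simulate_2tcm
#' @param t_end End of the integration span, minutes.
#' @return `solve_2tcm_grid()`: the fine-grid solution as a list with
#'   `times` and `tissue` (before frame averaging).
#' @export
solve_2tcm_grid <- function(params, input, t_end, step = 1 / 12) {
  stopifnot(inherits(params, "tcm_params"))
  cp <- as_input_fun(input, t_end)
  grid <- seq(0, t_end, by = step)
  deriv <- function(t, y, p) {
    cpt <- cp(t)
    list(c(p$K1 * cpt - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  sol <- deSolve::ode(y = c(C1 = 0, C2 = 0), times = grid, func = deriv,
                      parms = params, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  tissue <- (1 - params$vB) * (sol[, "C1"] + sol[, "C2"]) +
    params$vB * cp(grid)
  list(times = grid, tissue = unname(tissue))
}

# Trapezoidal mean of a fine-grid curve over each frame of a schedule.
frame_average <- function(values, grid, schedule, step) {
  i0 <- round(schedule$start / step) + 1L
  i1 <- round(schedule$end / step) + 1L
  if (max(i1) > length(grid) || any(abs(grid[i1] - schedule$end) > 1e-9))
    stop("integration grid is not aligned with the frame boundaries")
  vapply(seq_len(nrow(schedule)), function(k) {
    v <- values[i0[k]:i1[k]]
    (sum(v) - (v[1] + v[length(v)]) / 2) * step / (schedule$end[k] - schedule$start[k])
  }, numeric(1))
}

# Per-frame noise SDs for the count-statistics surrogate: SD proportional to
# sqrt(activity / duration), normalized so the SD at the last frame equals
# noise_fraction * activity at the last frame.
tac_noise_sd <- function(activity, schedule, noise_fraction) {
  dur <- frame_durations(schedule)
  n <- length(activity)
  raw <- sqrt(pmax(activity, 0) / dur)
  ref <- raw[n]
  if (ref <= 0 || noise_fraction == 0) return(rep(0, n))
  noise_fraction * activity[n] * raw / ref
}

#' Add frame-duration-weighted Gaussian noise to a time-activity curve
#'
#' The variance surrogate for dynamic-PET counting noise: per-frame SD is
#' proportional to `sqrt(activity / frame_duration)`, scaled so the relative
#' SD at the last (longest, lowest-rate) frame equals `noise_fraction`. Noisy
#' activities are floored at 0. Deterministic given `seed`.
#'
#' @param x A [tac] on the schedule's frame midpoints.
#' @param schedule The [frame_schedule] the curve was framed with.
#' @param noise_fraction Relative noise scale, >= 0.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [tac] with the same times.
#' @export
add_tac_noise <- function(x, schedule, noise_fraction, seed) {
  stopifnot(inherits(x, "tac"))
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  if (noise_fraction == 0) return(x)
  sd <- tac_noise_sd(x$activity, schedule, noise_fraction)
  noisy <- withr::with_seed(seed,
    pmax(x$activity + stats::rnorm(length(sd), 0, sd), 0))
  tac(x$times, noisy, label = x$label)
}

#' Block-structured default atlas
#'
#' A 16 x 16 x 12 grid at 2.0 mm isotropic resolution with rectangular labels
#' for the cerebellum (reference), medulla, the 5 thalamic subregions
#' (anterior medial/lateral, central medial/lateral, posterior), left/right
#' amygdala, left/right hypothalamus, the right supraoptic-nucleus locus, and
#' left/right cortex. World coordinates are MNI-like mm (x < 0 is left).
#'
#' @return A [voi_atlas].
#' @export
default_atlas <- function() {
  dims <- c(16L, 16L, 12L)
  labels <- array(0L, dims)
  blocks <- list(
    cerebellum     = list(x = 5:12,  y = 5:12,  z = 1:3),
    medulla        = list(x = 7:9,   y = 7:9,   z = 4:5),
    thalamus_am    = list(x = 6:8,   y = 9:11,  z = 8:9),
    thalamus_al    = list(x = 9:11,  y = 9:11,  z = 8:9),
    thalamus_cm    = list(x = 6:8,   y = 6:8,   z = 8:9),
    thalamus_cl    = list(x = 9:11,  y = 6:8,   z = 8:9),
    thalamus_p     = list(x = 6:11,  y = 3:5,   z = 8:9),
    amygdala_l     = list(x = 2:4,   y = 6:8,   z = 6:7),
    amygdala_r     = list(x = 13:15, y = 6:8,   z = 6:7),
    hypothalamus_l = list(x = 6:7,   y = 9:10,  z = 6:7),
    hypothalamus_r = list(x = 10:11, y = 9:10,  z = 6:7),
    son_r          = list(x = 12L,   y = 9:10,  z = 6:7),
    cortex_l       = list(x = 2:3,   y = 2:14,  z = 10:12),
    cortex_r       = list(x = 14:15, y = 2:14,  z = 10:12))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    labels[b$x, b$y, b$z] <- i
  }
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- c(-16, -16, -12)
  voi_atlas(labels, stats::setNames(seq_along(blocks), names(blocks)), affine)
}

#' @rdname default_atlas
#' @return `thalamus_subregions()`: the 5 thalamic subregion names.
#' @export
thalamus_subregions <- function() {
  paste0("thalamus_", c("am", "al", "cm", "cl", "p"))
}

#' Default per-region, per-sex ground-truth BP_ND means
#'
#' Ordered thalamus > medulla ~ amygdala ~ hypothalamus > cortex >
#' cerebellum = 0, with a male > female mean shift in every region except the
#' right hypothalamus, where the tendency reverses. Absolute levels are
#' configurable; these defaults set the thalamic subregions around 1.3-1.6.
#'
#' @return Data frame with columns `region`, `F`, `M`.
#' @export
default_region_bpnd <- function() {
  f <- c(cerebellum = 0, medulla = 1.1,
         thalamus_am = 1.4, thalamus_al = 1.3, thalamus_cm = 1.5,
         thalamus_cl = 1.35, thalamus_p = 1.6,
         amygdala_l = 1.0, amygdala_r = 1.0,
         hypothalamus_l = 0.9, hypothalamus_r = 0.9, son_r = 1.1,
         cortex_l = 0.45, cortex_r = 0.45)
  m <- f * 1.15
  m["hypothalamus_r"] <- f[["hypothalamus_r"]] * 0.9
  m["cerebellum"] <- 0
  data.frame(region = names(f), F = unname(f), M = unname(m),
             check.names = FALSE)
}

default_trait_links <- function() {
  list(
    list(trait = "baq_total", region = "amygdala_l",
         direction = "positive", target_r2 = 0.83, sex = "F"),
    list(trait = "tci_cooperativeness", region = "thalamus",
         direction = "negative", target_r2 = 0.71, sex = "all"))
}

#' Cohort simulation specification
#'
#' Defines the synthetic study: group sizes (10 females, 11 males by default,
#' with 4 males arterially sampled), per-region per-sex BP_ND means, the
#' between-subject SD, trait-to-region association links with target
#' population R^2, the TAC noise scale, and the seed that fully determines
#' the cohort.
#'
#' @param n_female,n_male Group sizes.
#' @param n_arterial Number of (male) subjects with arterial blood sampling.
#' @param region_bpnd_means Data frame as [default_region_bpnd()].
#' @param between_subject_sd Between-subject SD of regional BP_ND truths.
#' @param trait_links List of links, each
#'   `list(trait=, region=, direction="positive"|"negative", target_r2=, sex="F"|"M"|"all")`.
#'   The region may be `"thalamus"`, meaning the mean of the 5 subregions.
#' @param noise_fraction TAC/voxel noise scale (see [add_tac_noise()]).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 10, n_male = 11, n_arterial = 4,
                        region_bpnd_means = default_region_bpnd(),
                        between_subject_sd = 0.15,
                        trait_links = default_trait_links(),
                        noise_fraction = 0.02, seed = 1L) {
  for (lk in trait_links) {
    if (lk$target_r2 <= 0 || lk$target_r2 >= 1)
      stop("target_r2 must be in (0, 1); got ", lk$target_r2)
    if (!lk$direction %in% c("positive", "negative"))
      stop("link direction must be 'positive' or 'negative'")
  }
  if (n_arterial > n_male) stop("n_arterial cannot exceed n_male")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  structure(list(n_female = n_female, n_male = n_male, n_arterial = n_arterial,
                 region_bpnd_means = region_bpnd_means,
                 between_subject_sd = between_subject_sd,
                 trait_links = trait_links, noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

link_region_values <- function(bpnd, region) {
  if (region == "thalamus") {
    rowMeans(bpnd[, thalamus_subregions(), drop = FALSE])
  } else {
    if (!region %in% colnames(bpnd)) stop("link region not in atlas: ", region)
    bpnd[, region]
  }
}

# Theoretical population variance of the linked BP_ND value for the subjects
# a link applies to (mixture of the per-sex means plus between-subject SD).
link_bpnd_variance <- function(spec, region, sexes) {
  means <- spec$region_bpnd_means
  get_mean <- function(sx) {
    if (region == "thalamus") {
      mean(means[[sx]][match(thalamus_subregions(), means$region)])
    } else means[[sx]][match(region, means$region)]
  }
  sd2 <- spec$between_subject_sd^2
  if (region == "thalamus") sd2 <- sd2 / length(thalamus_subregions())
  if (length(unique(sexes)) == 1L) return(sd2)
  p <- mean(sexes == "F")
  mf <- get_mean("F"); mm <- get_mean("M")
  mbar <- p * mf + (1 - p) * mm
  sd2 + p * (mf - mbar)^2 + (1 - p) * (mm - mbar)^2
}

trait_base <- function(trait) {
  if (trait == "baq_total") c(mean = 60, sd = 12) else c(mean = 50, sd = 10)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject regional BP_ND truths around the per-sex means, trait
#' scores with the configured linear BP_ND links (error variance set so the
#' population R^2 equals each link's target), plasma hormone levels
#' independent of BP_ND, blood data for arterially sampled subjects, and
#' (optionally) per-subject 4D phantom images. Everything is a pure function
#' of `(spec, atlas)`.
#'
#' @param spec A [cohort_spec].
#' @param atlas A [voi_atlas]; region names must cover the spec's mean table.
#' @param make_images If `FALSE`, skip the (comparatively expensive) 4D
#'   phantoms and return truths, traits and blood data only.
#' @return A list with elements `subjects` (covariate data frame), `truth`
#'   (per-subject regional BP_ND matrix, k2', reference Vt, plasma/metabolite
#'   parameters), `blood` (per arterial subject: plasma [tac] and
#'   parent-fraction samples), and `images` (named list of [dynamic_image],
#'   if requested).
#' @export
generate_cohort <- function(spec, atlas = default_atlas(), make_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "voi_atlas"))
  regions <- spec$region_bpnd_means$region
  missing <- setdiff(regions, atlas_regions(atlas))
  if (length(missing))
    stop("regions in the spec without an atlas label: ",
         paste(missing, collapse = ", "))
  n <- spec$n_female + spec$n_male
  schedule <- standard_frame_schedule()
  hill <- default_hill_params()

  drawn <- withr::with_seed(spec$seed, {
    sex <- c(rep("F", spec$n_female), rep("M", spec$n_male))
    id <- sprintf("S%02d", seq_len(n))
    age <- round(ifelse(sex == "F", stats::rnorm(n, 34.7, 6.4),
                        stats::rnorm(n, 31.7, 8.1)), 1)
    age <- pmin(pmax(age, 20), 55)
    arterial <- sex == "M" & cumsum(sex == "M") <= spec$n_arterial

    bpnd <- matrix(0, n, length(regions), dimnames = list(id, regions))
    for (r in regions) {
      m <- ifelse(sex == "F",
                  spec$region_bpnd_means$F[match(r, regions)],
                  spec$region_bpnd_means$M[match(r, regions)])
      bpnd[, r] <- if (r == "cerebellum") 0 else
        pmax(stats::rnorm(n, m, spec$between_subject_sd), 0)
    }

    traits <- sapply(c("baq_total", tci_trait_names()), function(tr) {
      b <- trait_base(tr)
      round(stats::rnorm(n, b["mean"], b["sd"]), 0)
    })
    for (lk in spec$trait_links) {
      sel <- if (lk$sex == "all") rep(TRUE, n) else sex == lk$sex
      bvals <- link_region_values(bpnd, lk$region)[sel]
      varb <- link_bpnd_variance(spec, lk$region, sex[sel])
      sigma2 <- varb * (1 - lk$target_r2) / lk$target_r2
      dir <- if (lk$direction == "positive") 1 else -1
      raw <- dir * bvals + stats::rnorm(sum(sel), 0, sqrt(sigma2))
      b <- trait_base(lk$trait)
      mu_raw <- dir * mean(bvals)
      sd_raw <- sqrt(varb / lk$target_r2)
      traits[sel, lk$trait] <- round(b["mean"] + b["sd"] * (raw - mu_raw) / sd_raw, 1)
    }

    estradiol <- ifelse(sex == "F", round(exp(stats::rnorm(n, log(80), 0.4)), 1), NA)
    free_testosterone <- ifelse(sex == "M", round(exp(stats::rnorm(n, log(10), 0.3)), 2), NA)

    aif_scale <- exp(stats::rnorm(n, 0, 0.08))
    subseed <- sample.int(.Machine$integer.max %/% 2L, 3L * n)
    list(sex = sex, id = id, age = age, arterial = arterial, bpnd = bpnd,
         traits = traits, estradiol = estradiol,
         free_testosterone = free_testosterone, aif_scale = aif_scale,
         subseed = matrix(subseed, n, 3))
  })

  subjects <- data.frame(id = drawn$id, sex = factor(drawn$sex, c("F", "M")),
                         age = drawn$age, baq_total = drawn$traits[, "baq_total"],
                         drawn$traits[, tci_trait_names()],
                         arterial_sampled = drawn$arterial,
                         estradiol = drawn$estradiol,
                         free_testosterone = drawn$free_testosterone,
                         check.names = FALSE)

  base_aif <- default_aif_params()
  subject_aif <- lapply(seq_len(n), function(i)
    aif_params(base_aif$peak_time, base_aif$amplitudes * drawn$aif_scale[i],
               base_aif$decay_rates))

  blood <- list()
  for (i in which(drawn$arterial)) {
    blood[[drawn$id[i]]] <- simulate_blood_data(
      subject_aif[[i]], hill, noise_fraction = spec$noise_fraction,
      seed = drawn$subseed[i, 2])
  }

  images <- NULL
  if (make_images) {
    images <- lapply(seq_len(n), function(i) {
      pars <- regional_tcm_params(drawn$bpnd[i, ])
      input <- corrected_input_from(subject_aif[[i]], hill)
      build_phantom(atlas, pars, input, schedule,
                    noise_fraction = spec$noise_fraction,
                    seed = drawn$subseed[i, 1])
    })
    names(images) <- drawn$id
  }

  list(subjects = subjects,
       truth = list(bpnd = drawn$bpnd, k2_prime = 0.1, vt_ref = 3,
                    aif = subject_aif, hill = hill,
                    noise_fraction = spec$noise_fraction),
       blood = blood, images = images, atlas = atlas, schedule = schedule,
       spec = spec)
}

# Metabolite-corrected plasma input as a function of time.
corrected_input_from <- function(aif, hill) {
  force(aif); force(hill)
  function(t) aif_value(aif, t) * parent_fraction(hill, t)
}

# 2TCM parameter set per region realizing a subject's BP_ND truths.
regional_tcm_params <- function(bpnd_by_region) {
  stats::setNames(lapply(names(bpnd_by_region), function(r)
    bpnd_to_tcm(bpnd_by_region[[r]])), names(bpnd_by_region))
}

#' Simulate blood data for one subject
#'
#' Plasma samples on the arterial sampling grid with multiplicative Gaussian
#' measurement noise, and parent-fraction samples on the venous (metabolite)
#' grid with additive noise clipped to \[0, 1\].
#'
#' @param aif An [aif_params] for the subject's total plasma curve.
#' @param hill A [hill_params] metabolite model.
#' @param noise_fraction Relative SD of the plasma measurement noise.
#' @param parent_sd Additive SD of the parent-fraction measurements.
#' @param seed Integer seed.
#' @return List with `plasma` (a [tac]) and `parent`
#'   (data frame `time`, `fraction`).
#' @export
simulate_blood_data <- function(aif, hill, noise_fraction = 0.03,
                                parent_sd = 0.02, seed = 1L) {
  t_p <- arterial_sample_times()
  t_f <- venous_sample_times()
  clean <- aif_value(aif, t_p)
  frac <- parent_fraction(hill, t_f)
  withr::with_seed(seed, {
    plasma <- pmax(clean * (1 + stats::rnorm(length(clean), 0, noise_fraction)), 0)
    fr <- pmin(pmax(frac + stats::rnorm(length(frac), 0, parent_sd), 0), 1)
    list(plasma = tac(t_p, plasma, label = "plasma"),
         parent = data.frame(time = t_f, fraction = fr))
  })
}

#' Build a 4D phantom image from regional kinetics
#'
#' Every voxel of each atlas region carries that region's simulated 2TCM
#' curve plus independent frame-duration-weighted noise; background voxels
#' are 0. The cerebellum (reference) parameters must have `k3 = 0`.
#'
#' @param atlas A [voi_atlas].
#' @param regional_params Named list of [tcm_params], one per atlas region.
#' @param input Input function (see [simulate_2tcm()]).
#' @param schedule A [frame_schedule].
#' @param noise_fraction Voxel noise scale; 0 for a noiseless phantom.
#' @param seed Integer seed.
#' @return A [dynamic_image].
#' @export
build_phantom <- function(atlas, regional_params, input, schedule,
                          noise_fraction = 0, seed = 1L) {
  stopifnot(inherits(atlas, "voi_atlas"))
  missing <- setdiff(atlas_regions(atlas), names(regional_params))
  if (length(missing))
    stop("missing tcm parameters for region(s): ", paste(missing, collapse = ", "))
  if ("cerebellum" %in% atlas_regions(atlas) &&
      regional_params[["cerebellum"]]$k3 != 0)
    stop("reference-region (cerebellum) parameters must have k3 = 0")
  dims <- dim(atlas$labels)
  nk <- n_frames(schedule)
  vox <- array(0, c(dims, nk))
  curves <- lapply(atlas_regions(atlas), function(r)
    simulate_2tcm(regional_params[[r]], input, schedule))
  names(curves) <- atlas_regions(atlas)
  flat <- matrix(vox, prod(dims), nk)
  noise_draw <- withr::with_seed(seed, {
    lapply(atlas_regions(atlas), function(r) {
      idx <- which(atlas$labels == atlas$name_map[[r]])
      if (noise_fraction == 0) return(NULL)
      sd <- tac_noise_sd(curves[[r]]$activity, schedule, noise_fraction)
      matrix(stats::rnorm(length(idx) * nk, 0, rep(sd, each = length(idx))),
             length(idx), nk)
    })
  })
  names(noise_draw) <- atlas_regions(atlas)
  for (r in atlas_regions(atlas)) {
    idx <- which(atlas$labels == atlas$name_map[[r]])
    base <- matrix(curves[[r]]$activity, length(idx), nk, byrow = TRUE)
    if (!is.null(noise_draw[[r]])) base <- pmax(base + noise_draw[[r]], 0)
    flat[idx, ] <- base
  }
  dynamic_image(array(flat, c(dims, nk)), atlas$affine, schedule)
}

#' Simulate regional time-activity curves for one subject
#'
#' Region-level (not voxel-level) curves for a subject with the given BP_ND
#' truths: the 2TCM curve per region plus frame-weighted noise. Used for
#' blood-route analyses where no image is needed.
#'
#' @param bpnd_by_region Named numeric vector of BP_ND truths (cerebellum 0).
#' @param input Input function (see [simulate_2tcm()]).
#' @param schedule A [frame_schedule].
#' @param noise_fraction,seed As in [add_tac_noise()].
#' @return Named list of [tac] objects.
#' @export
simulate_subject_tacs <- function(bpnd_by_region, input, schedule,
                                  noise_fraction = 0, seed = 1L) {
  pars <- regional_tcm_params(bpnd_by_region)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                             length(pars)))
  out <- lapply(seq_along(pars), function(i) {
    cl <- simulate_2tcm(pars[[i]], input, schedule)
    cl$label <- names(pars)[i]
    if (noise_fraction > 0)
      cl <- add_tac_noise(cl, schedule, noise_fraction, seeds[i])
    cl
  })
  stats::setNames(out, names(pars))
}

#' Simulate a BP_ND parametric image directly
#'
#' Draws voxel values around per-region BP_ND levels with independent
#' Gaussian voxel noise (background 0), bypassing the kinetic stage. Used by
#' the statistical layers' calibration simulations, where the quantity of
#' interest is the BP_ND map itself.
#'
#' @param region_bpnd Named numeric vector of regional BP_ND levels.
#' @param atlas A [voi_atlas].
#' @param voxel_sd Voxel-level SD around the regional level.
#' @param seed Integer seed.
#' @return A [parametric_image].
#' @export
simulate_bpnd_image <- function(region_bpnd, atlas, voxel_sd = 0.1, seed = 1L) {
  stopifnot(inherits(atlas, "voi_atlas"))
  arr <- array(0, dim(atlas$labels))
  withr::with_seed(seed, {
    for (r in names(region_bpnd)) {
      idx <- which(atlas$labels == atlas$name_map[[r]])
      arr[idx] <- region_bpnd[[r]] + stats::rnorm(length(idx), 0, voxel_sd)
    }
  })
  parametric_image(arr, atlas$affine, route = "simulated")
}
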