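# Session-level fixture cache: helpers are sourced once per test run, so
# moderately expensive noiseless simulations are shared across test files.
.fx <- new.env()

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_schedule <- function() fx_get("schedule", standard_frame_schedule)
fx_aif <- function() default_aif_params()
fx_hill <- function() default_hill_params()

# Metabolite-corrected input driving all tissue simulations.
fx_input <- function() {
  aif <- fx_aif(); hill <- fx_hill()
  function(t) aif_value(aif, t) * parent_fraction(hill, t)
}

fx_atlas <- function() fx_get("atlas", default_atlas)

# Noiseless reference (cerebellum-like, 1TCM, Vt = 3) and target (BP_ND 1.5)
# curves on the standard schedule.
fx_ref_tac <- function() fx_get("ref_tac", function()
  simulate_2tcm(tcm_params(0.3, 0.1), fx_input(), fx_schedule()))

fx_target_tac <- function() fx_get("target_tac", function()
  simulate_2tcm(tcm_params(0.3, 0.1, k3 = 0.15, k4 = 0.1), fx_input(),
                fx_schedule()))

# Small noiseless phantom + its parametric image, shared by several files.
fx_truth_bpnd <- function() {
  m <- default_region_bpnd()
  stats::setNames(m$F, m$region)
}

fx_phantom <- function() fx_get("phantom", function()
  build_phantom(fx_atlas(), petkin:::regional_tcm_params(fx_truth_bpnd()),
                fx_input(), fx_schedule(), noise_fraction = 0, seed = 1))

fx_bpnd_image <- function() fx_get("bpnd_image", function()
  parametric_bpnd_image(fx_phantom(), fx_atlas(), k2_prime = 0.1, t_star = 20))

# Composite thalamus truth as extraction reports it (voxel-weighted).
fx_thalamus_truth <- function() {
  atlas <- fx_atlas()
  bp <- fx_truth_bpnd()
  sub <- thalamus_subregions()
  nv <- vapply(sub, function(r) sum(atlas_mask(atlas, r)), numeric(1))
  sum(bp[sub] * nv) / sum(nv)
}
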