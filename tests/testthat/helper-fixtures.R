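# Shared fixtures, built in code and cached for the session.

# Compact phantom for unit tests: 64 x 64 at 3 mm.
small_spec <- function(gap_mm = 0, ...) {
  phantom_spec(grid_n = 64L, pixel_mm = 3,
               body_radius_mm = c(80, 60),
               bone_radius_mm = 10,
               aaa_outer_radius_mm = 16,
               aaa_wall_thickness_mm = 5,
               gap_mm = gap_mm,
               non_aaa_radius_mm = 7,
               ...)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small contact phantom + system model + noise-free data, built once.
small_fixture <- function() {
  memo("small_fixture", {
    sp <- small_spec(gap_mm = 0)
    ph <- generate_phantom(sp)
    geom <- default_geometry(ph$activity, n_angles = 48L)
    model <- build_system_model(ph$ct, geom)
    expected <- forward_project(ph$activity, model)
    list(spec = sp, phantom = ph, geom = geom, model = model,
         clean = sinogram(expected$values, geom))
  })
}

# Noise-free OSEM+PSF reconstruction of the small phantom at clinical
# settings, shared by several files.
small_psf_fit <- function() {
  memo("small_psf_fit", {
    fx <- small_fixture()
    osem(fx$clean, fx$model, recon_config())
  })
}

# Independent plain-MLEM oracle: a direct transcription of the EM update
# using only the public forward/back projection operators.
mlem_reference <- function(data, model, n_iter, init_value = 1,
                           eps = 1e-10) {
  gn <- model$grid_n
  ones <- sinogram(matrix(1, model$geometry$n_angles, model$geometry$n_bins),
                   model$geometry)
  sens <- back_project(ones, model)$values
  x <- matrix(init_value, gn, gn)
  x[sens <= 0] <- 0
  for (i in seq_len(n_iter)) {
    lam <- forward_project(image_grid(x, model$pixel_mm), model)$values
    ratio <- sinogram(data$values / (lam + eps), model$geometry)
    back <- back_project(ratio, model)$values
    upd <- sens > 0
    x[upd] <- x[upd] * back[upd] / sens[upd]
  }
  x
}

# Default-scale (128 px) replicate study, run once and reused by the
# acceptance checks.
default_study <- function() {
  memo("default_study", run_study(study_config(master_seed = 1L)))
}
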