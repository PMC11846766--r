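# fixture generators: toy particle clouds, plus a cache for the slow
# secondary-ossification runs shared by several acceptance checks

make_block <- function(n = 4, spacing = 10, E = 1, nu = 0.4) {
  g <- seq(spacing / 2, by = spacing, length.out = n)
  cl <- mp_cloud(as.matrix(expand.grid(g, g, g)), V = spacing^3)
  cl$E[] <- E; cl$nu[] <- nu
  cl
}

make_column <- function(n = 20, spacing = 10, E = 1, nu = 0.4) {
  z <- seq(spacing / 2, by = spacing, length.out = n)
  cl <- mp_cloud(cbind(spacing / 2, spacing / 2, z), V = spacing^3)
  cl$E[] <- E; cl$nu[] <- nu
  cl
}

# set row i of a row-major tensor column to a 3x3 matrix
set_tensor <- function(cloud, field, i, M) {
  cloud[[field]][i, ] <- as.numeric(t(M))
  cloud
}

.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# the two secondary-ossification scenarios shared by the acceptance suite
coarse_with_resting <- function() cached_run("resting", function()
  run_simulation(preset_coarse(seed = 1, T_mat = 0.5)))

coarse_no_resting <- function() cached_run("noresting", function()
  run_simulation(preset_coarse(seed = 1, days = 5.8, resting_enabled = FALSE)))

subset_cloud_first <- function(cl) ossiforge:::subset_cloud(cl, 1L)
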