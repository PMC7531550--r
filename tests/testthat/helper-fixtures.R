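# Shared fixtures, built lazily and cached for the session so that the
# expensive objects (a fully timed run design and its event model) are
# constructed once.

.fixtures <- new.env(parent = emptyenv())

fixture_structure <- function() {
  if (is.null(.fixtures$ts)) .fixtures$ts <- task_structure()
  .fixtures$ts
}

# one deterministic fully timed run design (not efficiency-selected)
fixture_design <- function() {
  if (is.null(.fixtures$des)) {
    ts <- fixture_structure()
    .fixtures$des <- episode_timings(transition_balanced_order(6, 101),
                                     ts, seed = 102)
  }
  .fixtures$des
}

# its event-based design matrix
fixture_event_dm <- function() {
  if (is.null(.fixtures$dm))
    .fixtures$dm <- build_event_design(fixture_design(), TR = 1.373)
  .fixtures$dm
}

# a noiseless planted-geometry model and its condition means
fixture_noiseless_model <- function() {
  pattern_model(g_room = 0.4, g_task = 0.6, g_step = 1, g_item = 0.8,
                g_vis = 0.5, n_voxels = 60, noise_sd = 0, ar_sd = 0,
                drift_amplitude = 0)
}

fixture_noiseless_means <- function() {
  if (is.null(.fixtures$means))
    .fixtures$means <- plant_condition_patterns(fixture_noiseless_model(),
                                                fixture_structure(),
                                                seed = 103)
  .fixtures$means
}

# noiseless RDM implied by planted means (identity noise)
fixture_noiseless_rdm <- function() {
  if (is.null(.fixtures$rdm)) {
    m <- fixture_noiseless_means()
    .fixtures$rdm <- compute_rdm(m, m, normalize = TRUE)
  }
  .fixtures$rdm
}

fixture_model_rdms <- function() {
  if (is.null(.fixtures$mod))
    .fixtures$mod <- build_model_rdms(fixture_structure())
  .fixtures$mod
}

# construct an RDM object directly from a matrix + condition table
rdm_from_matrix <- function(mat, conditions, n_voxels = 1L,
                            normalized = FALSE) {
  structure(list(mat = mat, conditions = conditions, n_voxels = n_voxels,
                 normalized = normalized), class = "rdm")
}
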