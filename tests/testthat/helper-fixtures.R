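# shared desk-scale fixtures, built in code at test time

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a small simulated session with responses filled in
small_session <- function(attention_type = "endogenous", n_runs = 1L,
                          seed = 11L, tilt = 2, exclusion_rate = 0) {
  s <- generate_session(attention_type, n_runs = n_runs,
                        trials_per_run = 40L, seed = seed)
  simulate_responses(s, observer_model(), tilt = tilt,
                     exclusion_rate = exclusion_rate, seed = seed + 1L)
}

# noiseless single-ROI-scale attention run plus its ground truth
noiseless_run <- function(session, gt, n_per_roi = 4L, seed = 21L) {
  simulate_attention_run(session, 1L, gt,
                         noise = noise_params(0, 0, 0, 0),
                         voxels = voxel_grid(n_per_roi, 1), seed = seed)
}

# an amplitude table built directly from known per-cell means (bypassing
# the GLM) for statistics-level tests: one row per participant x roi x
# attention x epoch x validity x laterality x cue side
amp_table_from_means <- function(mean_fun, participants = paste0("P", 1:5),
                                 attention_types = c("endogenous", "exogenous")) {
  g <- expand.grid(participant = participants,
                   attention_type = attention_types,
                   roi = names(roi_hierarchy), cue_side = c("left", "right"),
                   cue_epoch = c("pre", "post"),
                   validity = c("valid", "invalid"),
                   laterality = c("contralateral", "ipsilateral"),
                   stringsAsFactors = FALSE)
  g$hemisphere <- laterality_to_hemisphere(g$laterality, g$cue_side)
  g$rank <- roi_hierarchy[g$roi]
  g$beta_psc <- vapply(seq_len(nrow(g)), function(i) mean_fun(g[i, ]),
                       numeric(1))
  g
}
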