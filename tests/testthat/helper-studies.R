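# Shared, lazily computed study runs for the acceptance checks.  One cache
# per session so several criteria can reuse the same simulations.

.study_cache <- new.env(parent = emptyenv())

study_run <- function(preset, kind, loading, seed, gamma_max) {
  key <- paste(preset, kind, loading, seed, gamma_max, sep = "|")
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- preset_study(
      preset, kind = kind, loading = loading, seed = seed,
      gamma_max = gamma_max, snapshot_gammas = c(0.05, 0.35),
      keep_events = TRUE)
  }
  .study_cache[[key]]
}

# seed panels for the seed-averaged criteria
T1_SEEDS <- c(5L, 11L, 23L, 31L, 47L)
T2_SEEDS <- c(4L, 7L, 11L, 23L, 31L)

# strain at which one percent of the EPS springs have begun to uncoil
stiffening_onset <- function(sim) {
  neps <- sum(sim$network$springs$phase == "EPS")
  i <- which(sim$steps$n_unfolded_springs > 0.01 * neps)[1]
  if (is.na(i)) NA_real_ else sim$steps$gamma[i]
}

# macroscopic stress at the step nearest gamma
stress_at <- function(sim, gamma) {
  st <- sim$steps
  st$tau[which.min(abs(st$gamma - gamma))]
}

first_rupture <- function(sim) {
  st <- sim$steps
  i <- which(st$n_ruptured > 0)[1]
  if (is.na(i)) c(gamma = NA_real_, tau = NA_real_)
  else c(gamma = st$gamma[i], tau = st$tau[i])
}

max_force_ratio <- function(sim) {
  m5 <- localization_map(sim, 0.05)
  m35 <- localization_map(sim, 0.35)
  max(m35$force) / max(m5$force)
}
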