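# Independent oracles used across tests.

# Brute-force single-linkage agglomeration: repeatedly merge the two
# clusters with the smallest inter-cluster minimum distance while that
# distance is <= cut. O(n^3); only for tiny instances.
brute_force_single_linkage <- function(dist_mat, cut) {
  n <- nrow(dist_mat)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- min(dist_mat[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# cluster assignments agree up to relabeling
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

# convenience: a small noise-free clean-binder cycle
make_clean_cycle <- function(kd_eq = 480e-6, conc = 500e-6, mw = 276,
                             noise_sd = 0, dmso_actual = 5, seed = 1,
                             stoich_n = 1, schedule = injection_schedule()) {
  prof <- compound_profile(
    "X", "clean_binder", mw = mw,
    kinetics = kinetic_model(ka = 0.5 / kd_eq, kd_rate = 0.5, stoich_n = stoich_n)
  )
  simulate_cycle(
    prof, conc, surface_def("C1r", 92000, 9200), schedule,
    artifact_model(noise_sd = noise_sd, dmso_actual = dmso_actual),
    seed = seed
  )
}
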