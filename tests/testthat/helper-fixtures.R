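# Shared helpers: tiny builders and independent oracles used across tests.

noiseless <- list(intensity_sd = 0, jitter_sd_rad = 0)

# Independent pair-angle oracle: plain acos of normalized dot products,
# deliberately a different formula than the package's atan2-based one.
oracle_pair_angles_deg <- function(xyz, center = c(0, 0, 0)) {
  v <- sweep(xyz, 2, center)
  v <- v / sqrt(rowSums(v^2))
  idx <- utils::combn(nrow(v), 2)
  sapply(seq_len(ncol(idx)), function(k)
    acos(min(max(sum(v[idx[1, k], ] * v[idx[2, k], ]), -1), 1)) * 180 / pi)
}

# Uniform random points on the unit sphere (independent of package code).
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  a <- stats::runif(n, 0, 2 * pi)
  cbind(sqrt(1 - z^2) * cos(a), sqrt(1 - z^2) * sin(a), z)
}

# Classify one fixture from the suite using the package pipeline.
classify_fixture <- function(fx) {
  sp_str <- if (length(fx$trajectories))
    unlist(lapply(fx$trajectories, function(tr) instantaneous_speeds(tr)$speed_nm_s))
  sp_def <- if (!is.null(fx$defect_tracks))
    unlist(lapply(fx$defect_tracks, function(tr) instantaneous_speeds(tr)$speed_nm_s))
  classify_pattern(fx$maps, sp_str, fx$defects, sp_def)
}

# Small Gaussian-blob equirect map sequence built directly (no renderer),
# for feature-tracker tests. Columns advance `step_px` per frame with wrap.
blob_maps <- function(n_frames, n_theta = 60, n_phi = 120, row = 30, col0 = 30,
                      step_px = 3, sigma_px = 3, amplitude = 1) {
  g <- sphere_geometry(18)
  maps <- lapply(seq_len(n_frames), function(f) {
    M <- matrix(0, n_theta, n_phi)
    cc <- ((col0 + (f - 1) * step_px - 1) %% n_phi) + 1
    for (i in seq_len(n_theta)) for (j in seq_len(n_phi)) {
      dj <- min(abs(j - cc), n_phi - abs(j - cc))
      M[i, j] <- amplitude * exp(-((i - row)^2 + dj^2) / (2 * sigma_px^2))
    }
    equirect_map(M, g)
  })
  equirect_seq(maps, (seq_len(n_frames) - 1) * 60)
}
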