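# Shared fixtures: built in code at test time.

# two flat rectangular marker sheets at z = z0 +/- gap/2 on a 1 nm grid
flat_sheets_frame <- function(nx = 10, ny = 10, gap = 4, z0 = 10,
                              box = c(nx, ny, 2 * z0)) {
  g <- expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5)
  n <- nrow(g)
  coords <- rbind(cbind(g$x, g$y, z0 + gap / 2),
                  cbind(g$x, g$y, z0 - gap / 2))
  mc_frame(coords,
           bead_kind = rep("lipid_marker", 2 * n),
           lipid_type = rep("DOPC", 2 * n),
           molecule_id = seq_len(2 * n),
           box = box)
}

# small curved membrane used across modules (fast to generate/trace)
small_sinusoid_spec <- function(seed = 3, n_chol = 0, sigma = 0.1, ...) {
  membrane_spec(curve_sinusoid(A = 5, wavelength = 50, z0 = 15),
                box = c(50, 10, 30), n_x = 70, n_y = 12,
                n_chol = n_chol, sigma = sigma, seed = seed, ...)
}

# residence table from explicit per-frame states; states is a list of
# (leaflet, domain) character pairs per frame for a single molecule
residence_from_states <- function(states, frame_dt = 4, molecule_id = 1L) {
  do.call(rbind, lapply(seq_along(states), function(i) {
    data.frame(frame = i, time = (i - 1) * frame_dt,
               molecule_id = molecule_id,
               leaflet = states[[i]][1], domain = states[[i]][2])
  }))
}

# circle midline object of radius R sampled at approximately unit arc step
circle_midline <- function(R, s = 1, box = c(10 * R, 10, 10 * R)) {
  N <- round(2 * pi * R / s)
  u <- seq(0, 2 * pi, length.out = N + 1)[1:N]
  mc_midline(cbind(box[1] / 2 + R * cos(u), 0, box[3] / 2 + R * sin(u)),
             s = 2 * pi * R / N, box = box)
}
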