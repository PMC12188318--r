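# Shared fixtures: all synthetic, built in code at test time.

# small phantom for fast tests
tiny_phantom <- function(seed = 1, grid = 32, spacing = 6, n_nodes = 80) {
  make_phantom(grid = grid, spacing = spacing,
               liver_semiaxes = c(45, 35, 55), n_nodes = n_nodes,
               tumor_offset = c(10, -8, -18), tumor_radius = 7,
               seed = seed)
}

tiny_geometry <- function(angle = 0, cols = 64, rows = 48, pitch = 5) {
  cone_beam_geometry(gantry_angle_deg = angle, sad = 1000, sdd = 1500,
                     detector_cols = cols, detector_rows = rows,
                     pixel_pitch_mm = pitch)
}

# deterministic random cloud in a box (mm)
random_cloud <- function(n, seed = 1, half = 60) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -half, half), n, 3)
}

rotation_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# arbitrary rigid rotation from three angles (degrees)
rotation_xyz <- function(ax, ay, az) {
  cx <- cos(ax * pi / 180); sx <- sin(ax * pi / 180)
  cy <- cos(ay * pi / 180); sy <- sin(ay * pi / 180)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx %*% Ry %*% rotation_z(az)
}
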