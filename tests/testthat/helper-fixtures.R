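# Shared fixtures, built in code at test time.

# standard two-basin hinge fixture used across tests
hinge_fixture <- function(n = 100, k = 30, hinge = 15, angle = 30,
                          noise_sd = 0.1, seed = 7, bimodal = TRUE) {
  make_hinge_ensemble(k, hinge, angle, n, noise_sd = noise_sd,
                      seed = seed, bimodal = bimodal)
}

# a random non-degenerate cloud trace (reproducible)
random_trace <- function(k = 12, seed = 1, scale = 5) {
  set.seed(seed)
  ca_trace(matrix(stats::rnorm(3 * k, sd = scale), k, 3),
           label = sprintf("rand%d", seed))
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_move <- function(trace, R, t) {
  ca_trace(trace$coords %*% t(R) + matrix(t, nrow(trace$coords), 3,
                                          byrow = TRUE),
           label = trace$label)
}

# straight chain with exact 3.8 A spacing: zero surrogate energy
ideal_chain <- function(k = 10, spacing = 3.8) {
  ca_trace(cbind(spacing * (seq_len(k) - 1), 0, 0), label = "ideal")
}

# brute-force minimum RMSD over a grid of Euler angles, refined locally;
# independent of the Kabsch implementation
grid_search_lrmsd <- function(a, b, coarse = 15) {
  A <- sweep(a$coords, 2, colMeans(a$coords))
  B <- sweep(b$coords, 2, colMeans(b$coords))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  grid <- expand.grid(z = seq(0, 2 * pi, by = coarse * pi / 180),
                      y = seq(0, pi, by = coarse * pi / 180),
                      x = seq(0, 2 * pi, by = coarse * pi / 180))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))$value
}

write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.000   8.000   9.500  1.00  0.00           C",
    "END"), path)
  path
}
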