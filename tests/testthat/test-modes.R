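test_that("PCA matches a brute-force covariance eigendecomposition", {
  # n = 2: exactly one nonzero eigenvalue, equal to the leading
  # eigenvalue of the 3k x 3k sample covariance of the centred columns
  t1 <- make_helix(6)
  t2 <- ca_trace(t1$coords + matrix(c(rep(0, 12), 0.5, -0.2, 0.3,
                                      0.1, 0.4, -0.6), 6, 3,
                                    byrow = TRUE))
  ens <- ca_ensemble(list(t1, t2), superposed = TRUE)
  basis <- extract_pca(ens)
  A <- trace_matrix(ens)
  Ac <- A - rowMeans(A)
  C <- Ac %*% t(Ac) / (2 - 1)              # sample covariance oracle
  ev <- eigen(C, symmetric = TRUE)$values
  expect_equal(basis$eigenvalues[1], ev[1], tolerance = 1e-10)
  expect_lt(sum(basis$eigenvalues[-1]), 1e-10 * ev[1])
})

test_that("PCA eigenvalues conserve the total centred variance", {
  ens <- superpose_ensemble(hinge_fixture(n = 40))
  basis <- extract_pca(ens)
  A <- trace_matrix(ens)
  Ac <- A - rowMeans(A)
  total <- sum(Ac^2) / (ncol(A) - 1)
  expect_equal(sum(basis$eigenvalues), total, tolerance = 1e-8 * total)
  # eigenvalues sorted high to low, axes orthonormal
  expect_true(all(diff(basis$eigenvalues) <= 1e-12))
  G <- crossprod(basis$axes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("PCA of identical traces has zero variance everywhere", {
  tr <- make_helix(8)
  ens <- ca_ensemble(list(tr, tr, tr), superposed = TRUE)
  basis <- extract_pca(ens)
  expect_lt(max(basis$eigenvalues), 1e-20)
  expect_error(extract_pca(ca_ensemble(list(tr))), "at least 2")
  expect_error(extract_pca(ca_ensemble(list(tr, tr), superposed = FALSE)),
               "superpose")
})

test_that("cumulative-variance selection picks the smallest prefix", {
  fake <- function(e) {
    b <- extract_pca(superpose_ensemble(hinge_fixture(n = 10, k = 5,
                                                      hinge = 3)))
    b$eigenvalues <- c(e, rep(0, length(b$eigenvalues) - length(e)))
    b
  }
  expect_equal(select_top_m(fake(c(8, 1, 1)), 0.8)$m, 1L)
  expect_equal(select_top_m(fake(c(5, 3, 1, 1)), 0.8)$m, 2L)
  expect_equal(select_top_m(fake(c(5, 3, 1, 1)), 1.0)$m, 4L)
  expect_error(select_top_m(fake(c(1)), 0), "variance_threshold")
  expect_error(select_top_m(fake(c(1)), 1.2), "variance_threshold")
})

test_that("two-body network Hessian matches the analytic solution", {
  # pair beyond the cutoff: no interaction
  far <- ca_trace(rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0)))
  expect_equal(build_anm_hessian(far, cutoff = 15), matrix(0, 9, 9))
  # two atoms within cutoff along x: unique nonzero eigenvalue 2*gamma
  # with eigenvector (1,0,0,-1,0,0)/sqrt(2); embed as the only
  # interacting pair of a 3-atom chain
  g <- 1.7
  tr <- ca_trace(rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0)))
  H <- build_anm_hessian(tr, cutoff = 15, gamma = g)
  Hp <- H[1:6, 1:6]
  ev <- eigen(Hp, symmetric = TRUE)
  expect_equal(ev$values[1], 2 * g, tolerance = 1e-12)
  expect_lt(max(abs(ev$values[-1])), 1e-12)
  v <- ev$vectors[, 1]
  expect_equal(abs(v), c(1, 0, 0, 1, 0, 0) / sqrt(2), tolerance = 1e-10)
  expect_error(build_anm_hessian(tr, cutoff = -1), "positive")
})

test_that("network Hessian annihilates rigid-body displacements", {
  tr <- random_trace(9, seed = 5, scale = 3)
  H <- build_anm_hessian(tr, cutoff = 15)
  expect_equal(H, t(H))
  lam_max <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  k <- n_residues(tr)
  # 3 translations
  for (a in 1:3) {
    u <- rep(0, 3 * k); u[seq(a, 3 * k, by = 3)] <- 1
    expect_lt(max(abs(H %*% u)), 1e-8 * lam_max)
  }
  # 3 infinitesimal rotations about the centroid
  Xc <- sweep(tr$coords, 2, colMeans(tr$coords))
  gens <- list(function(p) c(0, -p[3], p[2]),
               function(p) c(p[3], 0, -p[1]),
               function(p) c(-p[2], p[1], 0))
  for (gen in gens) {
    u <- as.vector(t(t(apply(Xc, 1, gen))))
    expect_lt(max(abs(H %*% u)), 1e-8 * lam_max * max(abs(u)))
  }
})

test_that("normal-mode extraction discards exactly 6 rigid modes", {
  # minimal case: 3 mutually-connected non-collinear atoms
  tri <- ca_trace(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0)))
  b <- extract_nma(tri, cutoff = 15)
  expect_equal(ncol(b$axes), 3L)              # 9 - 6
  expect_true(all(b$eigenvalues > 0))
  # helix: d = 3k - 6, frequencies ascending, modes orthonormal
  h <- make_helix(20)
  bh <- extract_nma(h)
  expect_equal(ncol(bh$axes), 3L * 20L - 6L)
  expect_true(all(diff(bh$frequencies) >= -1e-12))
  G <- crossprod(bh$axes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # disconnected network reports the rigid-mode count
  expect_error(extract_nma(ca_trace(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                          c(1.9, 3.3, 0), c(100, 0, 0),
                                          c(103.8, 0, 0),
                                          c(101.9, 3.3, 0))),
                           cutoff = 15),
               "found 12")
})

test_that("retained modes satisfy the eigenproblem of the dense solver", {
  h <- make_helix(12)
  H <- build_anm_hessian(h)
  b <- extract_nma(h)
  lam_max <- max(b$eigenvalues)
  for (j in seq_len(ncol(b$axes))) {
    res <- H %*% b$axes[, j] - b$eigenvalues[j] * b$axes[, j]
    expect_lt(max(abs(res)), 1e-8 * lam_max)
  }
})

test_that("in-package network Hessian agrees with bio3d's ANM force field", {
  h <- make_helix(10)
  H <- build_anm_hessian(h, cutoff = 15, gamma = 1)
  pfc <- bio3d::load.enmff("anm")
  Hb <- bio3d::build.hessian(as.vector(t(h$coords)), pfc = pfc,
                             cutoff = 15)
  expect_equal(unname(as.matrix(Hb)), H, tolerance = 1e-8)
})

test_that("projection and reconstruction are exact inverses at full rank", {
  h <- make_helix(10)
  basis <- extract_nma(h)
  d <- ncol(basis$axes)
  # origin projects to zero
  expect_lt(max(abs(project_trace(h, basis, m = d)$coords)), 1e-9)
  # a pure displacement along axis 1 projects to (a, 0, ..., 0)
  a <- 2.5
  moved <- ca_trace(h$coords + t(matrix(a * basis$axes[, 1], 3, 10)))
  co <- project_trace(moved, basis, m = d)$coords
  # normal modes are orthogonal to the rigid subspace, so superposition
  # leaves the displacement essentially untouched (second-order effects
  # only) and orthonormality gives back the pure axis-1 coordinate
  expect_equal(co[1], a, tolerance = 1e-4)
  expect_lt(max(abs(co[-1])), 1e-3 * a)
  # random trace: coordinates match an independent per-axis dot product
  x <- ca_trace(h$coords + matrix(stats::rnorm(30, sd = 0.05), 10, 3))
  conf <- project_trace(x, basis, m = d)
  fitted <- kabsch_superpose(x, h)$trace
  dx <- as.vector(t(fitted$coords)) - as.vector(t(h$coords))
  manual <- vapply(seq_len(d), function(i) sum(basis$axes[, i] * dx),
                   numeric(1))
  expect_equal(conf$coords, manual, tolerance = 1e-10)
  # round trip at m = d
  expect_lt(lrmsd(reconstruct_trace(conf, basis), x), 1e-6)
  # all-zero conformation reconstructs the origin
  expect_equal(reconstruct_trace(rep(0, d), basis)$coords, h$coords)
})

test_that("truncated reconstruction error equals the residual norm", {
  h <- make_helix(10)
  basis <- extract_nma(h)
  d <- ncol(basis$axes)
  set.seed(21)
  x <- ca_trace(h$coords + matrix(stats::rnorm(30, sd = 0.1), 10, 3))
  conf <- project_trace(x, basis, m = d)
  prev <- Inf
  for (m in c(3, 10, 20, d)) {
    err <- lrmsd(reconstruct_trace(conf$coords[seq_len(m)], basis), x)
    # monotone in m, and bounded by the dropped-coordinate norm / sqrt(k)
    expect_lte(err, prev + 1e-9)
    resid <- sqrt(sum(conf$coords[-seq_len(m)]^2))
    expect_lte(err, resid / sqrt(10) + 1e-9)
    prev <- err
  }
})

test_that("loss curve decreases monotonically and vanishes at full rank", {
  ens <- hinge_fixture(n = 12, k = 12, hinge = 6, noise_sd = 0)
  basis <- extract_nma(ens$traces[[1]])
  tab <- loss_curve(ens, basis)
  d <- ncol(basis$axes)
  expect_equal(nrow(tab), d)
  expect_true(all(diff(tab$mean_lrmsd) <= 1e-9))
  expect_lt(tab$mean_lrmsd[d], 1e-6)
  expect_lt(tab$median_lrmsd[d], 1e-6)
  # the i at which the mean first halves matches a direct recomputation
  first_half <- which(tab$mean_lrmsd < 0.5 * tab$mean_lrmsd[1])[1]
  manual <- vapply(seq_len(d), function(i) {
    mean(vapply(ens$traces, function(tr) {
      co <- project_trace(tr, basis, m = d)$coords[seq_len(i)]
      lrmsd(reconstruct_trace(co, basis), tr)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(first_half, which(manual < 0.5 * manual[1])[1])
})

test_that("basis comparison is orthonormality-consistent", {
  b <- extract_nma(make_helix(10))
  d <- ncol(b$axes)
  expect_equal(compare_bases(b, b, top = d), diag(d), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank comparison against a PCA basis: rows have unit squared sum
  ens <- superpose_ensemble(hinge_fixture(n = 40, k = 10, hinge = 5))
  p <- extract_pca(ens)
  # pad PCA axes count to d via the same ensemble (svd returns min(3k,n))
  top <- min(d, ncol(p$axes))
  M <- compare_bases(b, p, top = top)
  expect_true(all(M >= 0 & M <= 1 + 1e-12))
  expect_error(compare_bases(b, p, top = 500), "exceeds")
  # permutation consistency
  perm <- sample(seq_len(top))
  b2 <- b
  b2$axes <- b$axes[, perm]
  M2 <- compare_bases(b2, p, top = top)
  expect_equal(unname(M2), unname(M[perm, , drop = FALSE]))
})

test_that("slow single-structure modes cover the ensemble's top PC", {
  ens <- hinge_fixture(n = 100, noise_sd = 0)
  pca <- extract_pca(superpose_ensemble(ens))
  nma <- extract_nma(make_hinge_trace(30, 15, -30), m = 10)
  M <- compare_bases(nma, pca, top = 10)
  expect_gt(max(M[, 1]), 0.7)
})

test_that("basis serialization round-trips bitwise", {
  b <- extract_nma(make_helix(8), m = 5)
  dir <- tempfile("basis")
  write_basis(b, dir)
  b2 <- read_basis(dir)
  expect_identical(b2$axes, b$axes)
  expect_identical(b2$eigenvalues, b$eigenvalues)
  expect_identical(b2$frequencies, b$frequencies)
  expect_identical(b2$origin$coords, b$origin$coords)
  expect_identical(b2$m, b$m)
  expect_identical(b2$kind, b$kind)
})
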