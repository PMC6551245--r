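# Variable-basis extraction: PCA of a superposed ensemble, anisotropic
# elastic-network normal modes of a single structure, projection and
# reconstruction, basis comparison, and the mode-count loss analysis.

new_mode_basis <- function(kind, axes, eigenvalues, frequencies, origin,
                           m, cutoff = NA_real_, gamma = NA_real_) {
  structure(list(kind = kind, axes = axes, eigenvalues = eigenvalues,
                 frequencies = frequencies, origin = origin,
                 m = as.integer(m), k = n_residues(origin),
                 cutoff = cutoff, gamma = gamma),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("%s mode basis: k = %d residues, d = %d axes, m = %d retained\n",
              x$kind, x$k, ncol(x$axes), x$m))
  invisible(x)
}

# deterministic sign convention: largest-magnitude component positive
fix_axis_signs <- function(U) {
  flip <- vapply(seq_len(ncol(U)), function(j) {
    v <- U[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  sweep(U, 2, flip, `*`)
}

#' Extract a principal-component basis from a structure ensemble
#'
#' Stacks the n member traces into a 3k x n matrix A, centres each
#' column by subtracting the mean trace, and takes the singular value
#' decomposition of A / sqrt(n - 1).  The left singular vectors are the
#' principal components (extrinsic modes of motion); the squared
#' singular values are the eigenvalues e_i, i.e. the variance of the
#' ensemble projected on each axis, ordered high to low.
#'
#' @param ensemble a superposed `ca_ensemble` (see
#'   [superpose_ensemble()]) with n >= 2 members.
#' @return a `mode_basis` of kind `"PCA"`, with the mean trace as
#'   origin and `m` initialised to the number of axes (narrow with
#'   [select_top_m()]).
#' @export
extract_pca <- function(ensemble) {
  n <- length(ensemble)
  if (n < 2L) stop("PCA needs at least 2 traces")
  if (!isTRUE(ensemble$superposed))
    stop("ensemble must be superposed first; see superpose_ensemble()")
  A <- trace_matrix(ensemble)
  mu <- rowMeans(A)
  B <- (A - mu) / sqrt(n - 1)
  d <- min(nrow(B), ncol(B))
  s <- svd(B, nu = d, nv = 0)
  U <- fix_axis_signs(s$u)
  e <- s$d[seq_len(d)]^2
  origin <- ca_trace(vector_as_coords(mu), label = "mean")
  new_mode_basis("PCA", axes = U, eigenvalues = e, frequencies = NULL,
                 origin = origin, m = d)
}

#' Retain the top principal components by cumulative variance
#'
#' Sets `m` to the smallest number of leading axes whose eigenvalues
#' cumulatively capture at least `variance_threshold` of the total
#' variance (the conventional choice is 0.8).
#'
#' @param basis a PCA `mode_basis`.
#' @param variance_threshold fraction in (0, 1].
#' @return the basis with `m` updated.
#' @export
select_top_m <- function(basis, variance_threshold = 0.8) {
  if (basis$kind != "PCA") stop("cumulative-variance selection applies to PCA bases")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  e <- basis$eigenvalues
  total <- sum(e)
  if (total == 0) stop("degenerate ensemble: total variance is zero")
  frac <- cumsum(e) / total
  basis$m <- if (variance_threshold == 1) sum(e > 0)
  else which(frac >= variance_threshold - 1e-12)[1]
  basis
}

#' Anisotropic elastic-network Hessian of a CA trace
#'
#' Builds the 3k x 3k Hessian of an anisotropic network model: every CA
#' pair within `cutoff` is joined by a Hookean spring of constant
#' `gamma`, giving the 3x3 off-diagonal block -gamma * r r^T / |r|^2
#' for the pair and diagonal blocks that are the negative sums of the
#' row's off-diagonal blocks.  The matrix is symmetric positive
#' semi-definite and annihilates rigid-body displacements.
#'
#' @param trace a `ca_trace` with k >= 3.
#' @param cutoff interaction distance, Angstrom.
#' @param gamma uniform spring constant.
#' @return 3k x 3k numeric matrix.
#' @export
build_anm_hessian <- function(trace, cutoff = 15, gamma = 1) {
  if (cutoff <= 0 || gamma <= 0) stop("cutoff and gamma must be positive")
  X <- trace$coords
  k <- nrow(X)
  if (k < 3L) stop("trace must have at least 3 residues")
  H <- matrix(0, 3 * k, 3 * k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      r <- X[j, ] - X[i, ]
      d2 <- sum(r^2)
      if (d2 > cutoff^2 || d2 == 0) next
      blk <- -gamma * tcrossprod(r) / d2
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

#' Extract an elastic-network normal-mode basis from one structure
#'
#' Diagonalises the anisotropic network Hessian of a single CA trace.
#' The six zero-eigenvalue modes (three translations, three infinitesimal
#' rotations of the free network) are discarded; the remaining
#' d = 3k - 6 modes are renumbered 1..d ordered by frequency
#' f_i = sqrt(lambda_i), low to high, so the first axes are the slow,
#' collective intrinsic motions.
#'
#' @param trace a `ca_trace` with k >= 3, not collinear.
#' @param cutoff,gamma network parameters, see [build_anm_hessian()].
#' @param m number of modes retained as variable axes (default 10).
#' @param zero_tol eigenvalues below `zero_tol * max(lambda)` count as
#'   rigid-body modes; exactly six are expected for a connected,
#'   non-degenerate network.
#' @return a `mode_basis` of kind `"NMA"` with the input trace as
#'   origin.
#' @export
extract_nma <- function(trace, cutoff = 15, gamma = 1, m = 10,
                        zero_tol = 1e-8) {
  H <- build_anm_hessian(trace, cutoff = cutoff, gamma = gamma)
  eig <- eigen(H, symmetric = TRUE)
  lam <- rev(eig$values)             # ascending
  V <- eig$vectors[, rev(seq_along(eig$values))]
  n_zero <- sum(lam < zero_tol * max(lam))
  if (n_zero != 6L)
    stop(sprintf(paste0("expected 6 rigid-body modes, found %d: ",
                        "the elastic network is degenerate or disconnected"),
                 n_zero))
  keep <- seq.int(7L, length(lam))
  lam <- lam[keep]
  U <- fix_axis_signs(V[, keep, drop = FALSE])
  m <- min(as.integer(m), length(lam))
  new_mode_basis("NMA", axes = U, eigenvalues = lam,
                 frequencies = sqrt(lam), origin = trace, m = m,
                 cutoff = cutoff, gamma = gamma)
}

#' Project a trace onto a mode basis
#'
#' The trace is first rigidly superposed onto the basis origin (the
#' ensemble mean for PCA, the source structure for NMA); the coordinates
#' are the dot products of the displacement from the origin with the
#' first m axes.  The result is a point in the m-dimensional variable
#' space.
#'
#' @param trace a `ca_trace` compatible with the basis.
#' @param basis a `mode_basis`.
#' @param m number of coordinates (default the basis's retained m).
#' @return a `conformation` (see [conformation()]).
#' @export
project_trace <- function(trace, basis, m = basis$m) {
  if (n_residues(trace) != basis$k)
    stop("trace length does not match basis")
  d <- ncol(basis$axes)
  if (m < 1L || m > d) stop("m out of range 1..", d)
  fitted <- kabsch_superpose(trace, basis$origin)$trace
  dx <- trace_as_vector(fitted) - trace_as_vector(basis$origin)
  conformation(as.numeric(crossprod(basis$axes[, seq_len(m), drop = FALSE],
                                    dx)),
               provenance = trace$label)
}

#' Reconstruct a CA trace from a conformation
#'
#' Inverse of [project_trace()]: the origin trace plus the linear
#' combination of basis axes weighted by the conformation coordinates.
#' With all d coordinates the reconstruction is exact (complete
#' orthonormal basis); with m < d it is the least-squares truncation.
#'
#' @param conf a `conformation` (or bare numeric coordinate vector).
#' @param basis a `mode_basis`.
#' @return a `ca_trace`.
#' @export
reconstruct_trace <- function(conf, basis) {
  v <- if (inherits(conf, "conformation")) conf$coords else as.numeric(conf)
  d <- ncol(basis$axes)
  if (length(v) > d) stop("conformation has more coordinates than the basis")
  x <- trace_as_vector(basis$origin) +
    as.numeric(basis$axes[, seq_along(v), drop = FALSE] %*% v)
  ca_trace(vector_as_coords(x), label = "reconstructed")
}

#' Reconstruction-loss curve over mode count
#'
#' For each i in 1..d, every ensemble member is projected onto the
#' first i axes, reconstructed, and compared to the original by lRMSD.
#' The mean and median error per i quantify how many modes are needed
#' to recover the observed structural variation, guiding the choice of
#' the reduced dimensionality m.
#'
#' @param ensemble a `ca_ensemble`.
#' @param basis a `mode_basis` of compatible k.
#' @return data.frame with columns `i`, `mean_lrmsd`, `median_lrmsd`.
#' @export
loss_curve <- function(ensemble, basis) {
  if (length(ensemble) < 1L) stop("empty ensemble")
  d <- ncol(basis$axes)
  origin_v <- trace_as_vector(basis$origin)
  # project once with full d coords; truncation then reuses prefixes
  errs <- vapply(ensemble$traces, function(tr) {
    conf <- project_trace(tr, basis, m = d)
    vapply(seq_len(d), function(i) {
      rec <- reconstruct_trace(conf$coords[seq_len(i)], basis)
      lrmsd(rec, tr)
    }, numeric(1))
  }, numeric(d))
  errs <- matrix(errs, nrow = d)
  data.frame(i = seq_len(d),
             mean_lrmsd = rowMeans(errs),
             median_lrmsd = apply(errs, 1, stats::median))
}

#' Pairwise axis similarity of two bases
#'
#' Absolute dot products between the leading `top` axes of two bases
#' over the same 3k space, in each basis's native ordering (PCA:
#' eigenvalue high to low; NMA: frequency low to high).  Values near 1
#' indicate that an axis of one basis is captured by an axis of the
#' other.
#'
#' @param a,b `mode_basis` objects with equal k.
#' @param top number of leading axes compared from each basis.
#' @return `top` x `top` matrix with entries in [0, 1]; rows follow
#'   `a`, columns follow `b`.
#' @export
compare_bases <- function(a, b, top = 10) {
  if (nrow(a$axes) != nrow(b$axes))
    stop("bases are over spaces of different dimension")
  if (top > ncol(a$axes) || top > ncol(b$axes))
    stop("top exceeds the number of available axes")
  ia <- seq_len(top)
  M <- abs(crossprod(a$axes[, ia, drop = FALSE], b$axes[, ia, drop = FALSE]))
  dimnames(M) <- list(paste0(a$kind, ia), paste0(b$kind, ia))
  M
}

#' Save a mode basis as a plain-text directory
#'
#' Axes and eigenvalues/frequencies are written as delimited text, the
#' origin trace as a CA-only PDB, and kind/k/m/network parameters as a
#' small YAML metadata file.
#'
#' @param basis a `mode_basis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_basis <- function(basis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 17 significant digits round-trip doubles exactly through text
  utils::write.table(formatC(basis$axes, digits = 17, format = "g"),
                     file.path(dir, "axes.tsv"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  spec <- data.frame(eigenvalue = formatC(basis$eigenvalues, digits = 17,
                                          format = "g"))
  if (!is.null(basis$frequencies))
    spec$frequency <- formatC(basis$frequencies, digits = 17, format = "g")
  utils::write.table(spec, file.path(dir, "spectrum.tsv"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  write_pdb_ca(basis$origin, file.path(dir, "origin.pdb"))
  # PDB coordinates are truncated to 0.001 A; keep a full-precision copy
  utils::write.table(formatC(basis$origin$coords, digits = 17, format = "g"),
                     file.path(dir, "origin.tsv"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  yaml::write_yaml(list(kind = basis$kind, k = basis$k, m = basis$m,
                        cutoff = basis$cutoff, gamma = basis$gamma,
                        origin_label = basis$origin$label),
                   file.path(dir, "basis.yaml"))
  invisible(dir)
}

#' Load a mode basis written by [write_basis()]
#'
#' @param dir basis directory.
#' @return a `mode_basis`.
#' @export
read_basis <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "basis.yaml"))
  axes <- as.matrix(utils::read.table(file.path(dir, "axes.tsv"),
                                      sep = "\t"))
  dimnames(axes) <- NULL
  spec <- utils::read.table(file.path(dir, "spectrum.tsv"), header = TRUE,
                            sep = "\t")
  origin_tsv <- file.path(dir, "origin.tsv")
  origin <- if (file.exists(origin_tsv)) {
    ca_trace(as.matrix(utils::read.table(origin_tsv, sep = "\t")))
  } else {
    read_pdb_ca(file.path(dir, "origin.pdb"))
  }
  origin$label <- meta$origin_label
  new_mode_basis(meta$kind, axes = axes, eigenvalues = spec$eigenvalue,
                 frequencies = spec$frequency, origin = origin,
                 m = meta$m,
                 cutoff = if (is.null(meta$cutoff)) NA_real_ else meta$cutoff,
                 gamma = if (is.null(meta$gamma)) NA_real_ else meta$gamma)
}
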