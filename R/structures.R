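# CA-trace containers, structure I/O, rigid-body geometry and synthetic
# fixture generators.

#' Construct a CA trace
#'
#' A CA trace is the ordered chain of alpha-carbon coordinates of one
#' protein structure, the coarse-grained unit of all geometry in this
#' package.
#'
#' @param coords numeric matrix, k x 3, coordinates in Angstrom.
#' @param label free-text identifier.
#' @return an object of class `ca_trace` with elements `coords` and
#'   `label`.
#' @export
ca_trace <- function(coords, label = "trace") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be a k x 3 matrix")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(coords = coords, label = as.character(label)[1]),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("CA trace '%s': %d residues\n", x$label, nrow(x$coords)))
  invisible(x)
}

#' Number of residues of a trace
#' @param trace a `ca_trace`.
#' @return integer residue count k.
#' @export
n_residues <- function(trace) nrow(trace$coords)

# k x 3 coordinate matrix <-> length-3k vector (x1,y1,z1,x2,...)
trace_as_vector <- function(trace) as.vector(t(trace$coords))

vector_as_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Construct a structure ensemble
#'
#' An ensemble is a set of CA traces of identical length, together with
#' its superposition state.  The stacked 3k x n trace matrix and the mean
#' trace are derived on demand via [trace_matrix()] and [mean_trace()].
#'
#' @param traces list of `ca_trace` objects with equal residue counts.
#' @param superposed logical; whether the traces have already been
#'   brought into a common rigid-body frame.
#' @return object of class `ca_ensemble`.
#' @export
ca_ensemble <- function(traces, superposed = FALSE) {
  if (length(traces) < 1L) stop("ensemble needs at least one trace")
  ks <- vapply(traces, n_residues, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all traces in an ensemble must have the same number of residues")
  structure(list(traces = traces, superposed = isTRUE(superposed)),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("CA ensemble: n = %d traces, k = %d residues, superposed = %s\n",
              length(x$traces), n_residues(x$traces[[1]]), x$superposed))
  invisible(x)
}

#' @export
length.ca_ensemble <- function(x) length(x$traces)

#' Stacked trace matrix of an ensemble
#'
#' @param ensemble a `ca_ensemble`.
#' @return 3k x n matrix with one column of stacked (x,y,z) coordinates
#'   per member trace.
#' @export
trace_matrix <- function(ensemble) {
  vapply(ensemble$traces, trace_as_vector,
         numeric(3L * n_residues(ensemble$traces[[1]])))
}

#' Mean trace of an ensemble
#'
#' @param ensemble a `ca_ensemble`.
#' @return `ca_trace` whose coordinates are the per-atom average.
#' @export
mean_trace <- function(ensemble) {
  ca_trace(vector_as_coords(rowMeans(trace_matrix(ensemble))),
           label = "mean")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `target` and returns the transformed trace.
#'
#' @param mobile,target `ca_trace` objects with equal residue counts.
#' @return list with elements `trace` (the superposed mobile trace),
#'   `rotation` (3 x 3 proper rotation, determinant +1) and
#'   `translation` (length-3 vector); the transform maps a centred
#'   mobile coordinate row r to `r %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, target) {
  if (n_residues(mobile) != n_residues(target))
    stop("traces must have the same number of residues")
  M <- mobile$coords
  Tm <- target$coords
  cm <- colMeans(M)
  ct <- colMeans(Tm)
  Mc <- sweep(M, 2, cm)
  Tc <- sweep(Tm, 2, ct)
  H <- crossprod(Mc, Tc)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))    # reflection correction
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  new_coords <- Mc %*% t(R) + matrix(ct, nrow(M), 3, byrow = TRUE)
  list(trace = ca_trace(new_coords, label = mobile$label),
       rotation = R,
       translation = as.numeric(ct - cm %*% t(R)))
}

#' Least RMSD between two traces
#'
#' RMSD after optimal rigid-body superposition; zero iff the traces
#' differ only by a rigid motion (within numerical tolerance).
#'
#' @param a,b `ca_trace` objects with equal residue counts.
#' @return lRMSD in Angstrom.
#' @export
lrmsd <- function(a, b) {
  fit <- kabsch_superpose(a, b)
  sqrt(mean(rowSums((fit$trace$coords - b$coords)^2)))
}

# plain RMSD without superposition
rmsd_raw <- function(a, b) {
  sqrt(mean(rowSums((a$coords - b$coords)^2)))
}

#' Ideal helical CA trace
#'
#' Generates a regular helix used as the synthetic backbone of the test
#' fixtures.  The defaults approximate an alpha-helix so that the
#' consecutive CA-CA distance is close to the canonical 3.8 Angstrom.
#'
#' @param k residue count (>= 3).
#' @param rise rise per residue along the helix axis, Angstrom.
#' @param turn rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @return a `ca_trace` of k residues.
#' @export
make_helix <- function(k, rise = 1.5, turn = 100, radius = 2.3) {
  if (k < 3L) stop("k must be at least 3")
  if (rise <= 0 || turn <= 0 || radius <= 0)
    stop("rise, turn and radius must be positive")
  i <- seq_len(k) - 1L
  th <- i * turn * pi / 180
  ca_trace(cbind(radius * cos(th), radius * sin(th), i * rise),
           label = sprintf("helix_k%d", k))
}

# rotate points (rows) about the x-direction axis through `origin` by
# `angle` degrees
rotate_about_x <- function(coords, origin, angle) {
  a <- angle * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(a), -sin(a),
                0, sin(a),  cos(a)), 3, 3, byrow = TRUE)
  sweep(sweep(coords, 2, origin) %*% t(R), 2, origin, `+`)
}

#' Synthetic two-state hinge-motion ensemble
#'
#' Emulates a multi-basin conformational ensemble: a helical chain whose
#' C-terminal arm is rotated about a hinge residue, plus isotropic
#' Gaussian noise on every coordinate.  With `bimodal = TRUE` the hinge
#' angle is drawn from a two-component Gaussian mixture centred at
#' +/- `angle_range` (component sd `mode_sd`), emulating two distinct
#' functional states separated by a collective hinge motion; with
#' `bimodal = FALSE` it is uniform in [-angle_range, +angle_range].
#'
#' @param k residue count.
#' @param hinge_index residue about which the C-terminal arm rotates
#'   (1-based; must satisfy 1 < hinge_index < k).
#' @param angle_range hinge half-amplitude, degrees.
#' @param n ensemble size (>= 2).
#' @param noise_sd per-coordinate Gaussian noise, Angstrom.
#' @param seed integer RNG seed; the same seed reproduces the ensemble
#'   bit for bit.
#' @param bimodal draw hinge angles from the two-state mixture rather
#'   than uniformly.
#' @param mode_sd sd of each mixture component, degrees.
#' @param ... geometry arguments forwarded to [make_helix()].
#' @return a `ca_ensemble` of n traces (not superposed).  Each trace
#'   carries its generating hinge angle in attribute `"hinge_angle"`.
#' @export
make_hinge_ensemble <- function(k, hinge_index, angle_range, n,
                                noise_sd = 0, seed = 1, bimodal = FALSE,
                                mode_sd = 3, ...) {
  if (hinge_index <= 1L || hinge_index >= k)
    stop("hinge_index must satisfy 1 < hinge_index < k")
  if (n < 2L) stop("n must be at least 2")
  base <- make_helix(k, ...)
  arm <- seq.int(hinge_index + 1L, k)
  origin <- base$coords[hinge_index, ]
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  if (bimodal) {
    comp <- sample(c(-1, 1), n, replace = TRUE)
    angles <- stats::rnorm(n, mean = comp * angle_range, sd = mode_sd)
  } else {
    angles <- stats::runif(n, -angle_range, angle_range)
  }
  traces <- vector("list", n)
  for (j in seq_len(n)) {
    xyz <- base$coords
    xyz[arm, ] <- rotate_about_x(xyz[arm, , drop = FALSE], origin, angles[j])
    xyz <- xyz + matrix(stats::rnorm(3L * k, sd = noise_sd), k, 3)
    tr <- ca_trace(xyz, label = sprintf("hinge_%03d", j))
    attr(tr, "hinge_angle") <- angles[j]
    traces[[j]] <- tr
  }
  ca_ensemble(traces, superposed = FALSE)
}

#' Deterministic hinge trace at a given angle
#'
#' The noise-free member of the hinge family: the helix with its
#' C-terminal arm rotated about the hinge by exactly `angle` degrees.
#' Useful as a reference structure for one of the two states of the
#' bimodal fixture.
#'
#' @param k residue count.
#' @param hinge_index hinge residue (1-based).
#' @param angle rotation of the C-terminal arm, degrees.
#' @param ... geometry arguments forwarded to [make_helix()].
#' @return a `ca_trace`.
#' @export
make_hinge_trace <- function(k, hinge_index, angle, ...) {
  if (hinge_index <= 1L || hinge_index >= k)
    stop("hinge_index must satisfy 1 < hinge_index < k")
  base <- make_helix(k, ...)
  arm <- seq.int(hinge_index + 1L, k)
  xyz <- base$coords
  xyz[arm, ] <- rotate_about_x(xyz[arm, , drop = FALSE],
                               xyz[hinge_index, ], angle)
  ca_trace(xyz, label = sprintf("hinge_%+.1fdeg", angle))
}

#' Measure the hinge angle of a fixture trace
#'
#' Recovers the rotation applied to the C-terminal arm of a
#' [make_hinge_ensemble()] member by comparing the yz-orientation of the
#' chain tip, relative to the hinge, with the unperturbed helix.
#'
#' @param trace a `ca_trace` from the hinge fixture.
#' @param hinge_index hinge residue used at generation time.
#' @param ... geometry arguments matching the generating call.
#' @return signed angle in degrees.
#' @export
measure_hinge_angle <- function(trace, hinge_index, ...) {
  k <- n_residues(trace)
  base <- make_helix(k, ...)
  v0 <- base$coords[k, 2:3] - base$coords[hinge_index, 2:3]
  v1 <- trace$coords[k, 2:3] - trace$coords[hinge_index, 2:3]
  (atan2(v1[2], v1[1]) - atan2(v0[2], v0[1])) * 180 / pi
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read CA atoms from a PDB file
#'
#' Extracts the alpha-carbon trace(s) of a PDB file.  Only ATOM records
#' with atom name CA are used; alternate locations other than blank or
#' 'A' are dropped, and residues lacking a CA are skipped with a
#' warning.  Multi-model (NMR-style) files yield one trace per model
#' when `model_policy = "all"`.
#'
#' @param path PDB file path.
#' @param model_policy `"first"` returns a single `ca_trace` from the
#'   first model; `"all"` returns a `ca_ensemble` with one trace per
#'   model.
#' @param chain optional chain identifier; default uses all chains in
#'   record order.
#' @return a `ca_trace` or, for `model_policy = "all"`, a `ca_ensemble`.
#' @export
read_pdb_ca <- function(path, model_policy = c("first", "all"),
                        chain = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = (model_policy == "all"),
                         verbose = FALSE)
  atoms <- pdb$atom
  keep <- atoms$type == "ATOM" & atoms$elety == "CA" &
    (is.na(atoms$alt) | atoms$alt %in% c("", "A"))
  if (!is.null(chain)) {
    avail <- unique(atoms$chain[keep])
    if (!chain %in% avail)
      stop(sprintf("chain '%s' not present; available chains: %s",
                   chain, paste(avail, collapse = ", ")))
    keep <- keep & atoms$chain == chain
  }
  if (!any(keep)) stop("no CA atoms found in ", path)
  idx <- which(keep)
  label <- tools::file_path_sans_ext(basename(path))
  xyz_idx <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L && model_policy == "all") {
    traces <- lapply(seq_len(nrow(xyz)), function(mdl) {
      ca_trace(vector_as_coords(xyz[mdl, xyz_idx]),
               label = sprintf("%s_model%d", label, mdl))
    })
    return(ca_ensemble(traces, superposed = FALSE))
  }
  v <- if (is.matrix(xyz)) xyz[1, xyz_idx] else xyz[xyz_idx]
  tr <- ca_trace(vector_as_coords(v), label = label)
  if (model_policy == "all") ca_ensemble(list(tr), superposed = FALSE)
  else tr
}

#' Write a trace or ensemble as a CA-only PDB file
#'
#' Traces are written as ATOM records named CA (residue ALA, chain A);
#' ensembles as multi-model files bracketed by MODEL/ENDMDL.
#'
#' @param x a `ca_trace` or `ca_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(x, path) {
  fmt_model <- function(coords) {
    k <- nrow(coords)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_len(k), seq_len(k), coords[, 1], coords[, 2], coords[, 3])
  }
  lines <- if (inherits(x, "ca_ensemble")) {
    unlist(lapply(seq_along(x$traces), function(j) {
      c(sprintf("MODEL     %4d", j), fmt_model(x$traces[[j]]$coords),
        "ENDMDL")
    }))
  } else {
    fmt_model(x$coords)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Iteratively superpose an ensemble onto its running mean
#'
#' Each trace is rigidly superposed onto the current mean trace; the
#' mean is recomputed and the procedure repeats until the mean moves
#' less than `tol` (max RMSD displacement) or `max_rounds` is reached.
#' Plain centring alone would not remove relative rotations between
#' members, so basis extraction from ensembles requires this step.
#'
#' @param ensemble a `ca_ensemble`.
#' @param tol convergence tolerance on the mean trace, Angstrom.
#' @param max_rounds maximum refinement rounds.
#' @return the superposed `ca_ensemble` (`superposed = TRUE`).
#' @export
superpose_ensemble <- function(ensemble, tol = 1e-6, max_rounds = 20) {
  traces <- ensemble$traces
  # anchor the frame on the current mean when already superposed, so
  # re-running is idempotent; otherwise on the first member
  ref <- if (isTRUE(ensemble$superposed))
    mean_trace(ensemble) else traces[[1]]
  for (round in seq_len(max_rounds)) {
    traces <- lapply(traces, function(tr) {
      out <- kabsch_superpose(tr, ref)$trace
      attr(out, "hinge_angle") <- attr(tr, "hinge_angle")
      out
    })
    new_mean <- mean_trace(ca_ensemble(traces, superposed = TRUE))
    if (round > 1 && rmsd_raw(new_mean, ref) < tol) {
      ref <- new_mean
      break
    }
    ref <- new_mean
  }
  ca_ensemble(traces, superposed = TRUE)
}
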