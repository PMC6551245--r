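# Coarse-grained CA-level surrogate energy and chain regularizer.
#
# Scores are unitless: the model keeps chains chemically sensible
# (bond-like consecutive spacing, no steric overlap, optional network
# restraint to a reference shape) and ranks conformations, but makes no
# claim of physical energies.  An external all-atom refinement stage
# can be plugged in through `external_minimizer`.

#' Construct a CA-level energy model
#'
#' The surrogate energy of a trace is
#' `bond_k * sum_i (d_{i,i+1} - bond_length)^2 +
#'  clash_k * sum_{|i-j| >= 2, d_ij < clash_radius} (clash_radius - d_ij)^2`
#' plus, when `network_k > 0` and a reference is given, an elastic
#' restraint `network_k * sum (d_ij - d_ij^ref)^2` over all pairs
#' within `network_radius` in the reference.
#'
#' @param bond_k force constant of the consecutive-CA bond term.
#' @param bond_length target consecutive CA-CA distance, Angstrom.
#' @param clash_k repulsion constant for non-bonded overlaps.
#' @param clash_radius distance under which non-bonded pairs are
#'   penalised, Angstrom.
#' @param network_k restraint constant towards the reference network
#'   (0 disables the term).
#' @param reference optional `ca_trace` defining the reference network.
#' @param network_radius reference pairs within this distance form the
#'   restraint network, Angstrom.
#' @param external_minimizer optional shell command implementing an
#'   external refinement stage; see [regularize_trace()].
#' @return object of class `energy_model`.
#' @export
energy_model <- function(bond_k = 1, bond_length = 3.8, clash_k = 1,
                         clash_radius = 4, network_k = 0,
                         reference = NULL, network_radius = 10,
                         external_minimizer = NULL) {
  if (bond_k < 0 || clash_k < 0 || network_k < 0)
    stop("force constants must be non-negative")
  if (bond_length <= 0) stop("bond_length must be positive")
  pairs <- NULL
  if (network_k > 0) {
    if (is.null(reference))
      stop("network_k > 0 requires a reference trace")
    D <- as.matrix(stats::dist(reference$coords))
    sel <- which(upper.tri(D) & D < network_radius, arr.ind = TRUE)
    pairs <- cbind(sel, d0 = D[sel])
  }
  structure(list(bond_k = bond_k, bond_length = bond_length,
                 clash_k = clash_k, clash_radius = clash_radius,
                 network_k = network_k, reference = reference,
                 network_radius = network_radius, network_pairs = pairs,
                 external_minimizer = external_minimizer),
            class = "energy_model")
}

# energy and its gradient in one pass; gradient is k x 3
ca_energy_grad <- function(coords, model) {
  k <- nrow(coords)
  G <- matrix(0, k, 3)
  E <- 0
  # consecutive-CA bond term
  if (model$bond_k > 0 && k >= 2) {
    B <- coords[-1, , drop = FALSE] - coords[-k, , drop = FALSE]
    d <- sqrt(rowSums(B^2))
    dev <- d - model$bond_length
    E <- E + model$bond_k * sum(dev^2)
    coef <- 2 * model$bond_k * dev / pmax(d, 1e-12)
    Fb <- B * coef
    G[-k, ] <- G[-k, ] - Fb
    G[-1, ] <- G[-1, ] + Fb
  }
  # steric clash term over non-bonded pairs
  if (model$clash_k > 0 && k >= 3) {
    D <- as.matrix(stats::dist(coords))
    sep <- abs(row(D) - col(D))
    sel <- which(upper.tri(D) & sep >= 2 & D < model$clash_radius,
                 arr.ind = TRUE)
    if (nrow(sel) > 0) {
      i <- sel[, 1]; j <- sel[, 2]
      d <- D[sel]
      E <- E + model$clash_k * sum((model$clash_radius - d)^2)
      coef <- -2 * model$clash_k * (model$clash_radius - d) / pmax(d, 1e-12)
      V <- (coords[i, , drop = FALSE] - coords[j, , drop = FALSE]) * coef
      for (a in 1:3) {
        G[, a] <- G[, a] + tab_sum(V[, a], i, k) - tab_sum(V[, a], j, k)
      }
    }
  }
  # reference-network restraint
  if (model$network_k > 0 && !is.null(model$network_pairs)) {
    P <- model$network_pairs
    i <- P[, 1]; j <- P[, 2]; d0 <- P[, 3]
    V <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    d <- sqrt(rowSums(V^2))
    dev <- d - d0
    E <- E + model$network_k * sum(dev^2)
    coef <- 2 * model$network_k * dev / pmax(d, 1e-12)
    Vc <- V * coef
    for (a in 1:3) {
      G[, a] <- G[, a] + tab_sum(Vc[, a], i, k) - tab_sum(Vc[, a], j, k)
    }
  }
  list(energy = E, grad = G)
}

# sum `x` into bins `idx` over 1..k (dense)
tab_sum <- function(x, idx, k) {
  out <- numeric(k)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Surrogate energy of a CA trace
#'
#' Evaluates the coarse-grained CA energy of [energy_model()]:
#' quadratic penalties on consecutive-CA bond deviations, non-bonded
#' clashes, and (optionally) deviations from a reference elastic
#' network.  Deterministic, finite, and invariant under rigid motions
#' of the trace.
#'
#' @param trace a `ca_trace` with k >= 2.
#' @param model an `energy_model`.
#' @return unitless energy score (0 for an ideal chain).
#' @export
ca_energy <- function(trace, model = energy_model()) {
  if (n_residues(trace) < 2L) stop("trace must have at least 2 residues")
  ca_energy_grad(trace$coords, model)$energy
}

#' Regularize a CA trace by gradient descent on the surrogate energy
#'
#' Steepest descent with step halving: from the input trace, steps of
#' size `step` are taken along the negative energy gradient; a step
#' that would increase the energy is halved up to 10 times, and if the
#' energy still increases the descent aborts with a divergence error.
#' Descent stops when the gradient norm falls below `grad_tol` or
#' after `max_iter` iterations.  The returned trace never has higher
#' energy than the input.
#'
#' If `model$external_minimizer` is set, it is run instead: the command
#' receives the input CA-PDB path and an output path as its two
#' arguments and must exit 0, leaving a parseable PDB at the output
#' path.
#'
#' @param trace a `ca_trace`.
#' @param model an `energy_model`.
#' @param max_iter maximum descent iterations.
#' @param step initial step size.
#' @param grad_tol stopping threshold on the gradient norm.
#' @return the regularized `ca_trace`.
#' @export
regularize_trace <- function(trace, model = energy_model(),
                             max_iter = 200, step = 0.01,
                             grad_tol = 1e-4) {
  if (!is.null(model$external_minimizer)) {
    tin <- tempfile(fileext = ".pdb"); tout <- tempfile(fileext = ".pdb")
    on.exit(unlink(c(tin, tout)))
    write_pdb_ca(trace, tin)
    status <- system2(model$external_minimizer, args = c(tin, tout))
    if (status != 0L)
      stop("external minimizer failed with status ", status)
    out <- read_pdb_ca(tout)
    out$label <- trace$label
    return(out)
  }
  X <- trace$coords
  eg <- ca_energy_grad(X, model)
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(eg$grad^2))
    if (gnorm < grad_tol) break
    h <- step
    ok <- FALSE
    for (halving in 0:10) {
      Xn <- X - h * eg$grad
      egn <- ca_energy_grad(Xn, model)
      if (egn$energy <= eg$energy) { ok <- TRUE; break }
      h <- h / 2
    }
    if (!ok)
      stop("regularization diverged: energy increases along the gradient ",
           "after 10 step halvings")
    X <- Xn
    eg <- egn
  }
  out <- ca_trace(X, label = trace$label)
  out
}
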