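# Conformations in variable space and the variation operator's global
# motion vectors.

#' Construct a conformation
#'
#' A conformation is a point in the m-dimensional variable space of a
#' mode basis, optionally annotated with a surrogate energy (a unitless
#' score, see [ca_energy()]).
#'
#' @param coords numeric coordinate vector in the basis.
#' @param energy optional energy annotation.
#' @param provenance free-text tag recording where the point came from.
#' @return object of class `conformation`.
#' @export
conformation <- function(coords, energy = NA_real_, provenance = "") {
  structure(list(coords = as.numeric(coords), energy = energy,
                 provenance = provenance),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation (%d coords, energy %s): %s\n",
              length(x$coords),
              if (is.na(x$energy)) "unset" else format(x$energy),
              x$provenance))
  invisible(x)
}

#' Global motion vector for a PCA basis
#'
#' Draws the per-axis displacements of the variation operator:
#' g_i = s_i * delta_i with independent fair signs s_i in {-1, +1},
#' delta_1 = `delta`, and delta_i = delta * e_i / e_1 for i > 1, so
#' that step sizes are proportional to the variance captured by each
#' principal component.
#'
#' @param basis a PCA `mode_basis`.
#' @param delta step size along the first axis (Angstrom in 3k space).
#' @param m number of axes displaced (default the basis's m).
#' @return object of class `motion_vector` with elements `components`
#'   (length m) and `signs`.
#' @export
motion_vector_pca <- function(basis, delta = 2, m = basis$m) {
  if (basis$kind != "PCA") stop("basis is not a PCA basis")
  if (delta <= 0) stop("delta must be positive")
  if (m < 1L || m > ncol(basis$axes)) stop("m out of range")
  e <- basis$eigenvalues[seq_len(m)]
  if (e[1] == 0) stop("degenerate ensemble: leading eigenvalue is zero")
  s <- sample(c(-1, 1), m, replace = TRUE)
  structure(list(components = s * delta * e / e[1], signs = s),
            class = "motion_vector")
}

#' Global motion vector for an NMA basis
#'
#' Draws the per-axis displacements
#' g_i = s_i * delta * sqrt(2/m) / f_i over the first m
#' frequency-ordered normal modes, with independent fair signs s_i.
#' The 1/f_i scaling gives larger displacements along slower modes;
#' under the quadratic network model a full displacement along any
#' single scaled axis carries the same energy delta^2 / m, so no mode
#' is favoured energetically.
#'
#' @param basis an NMA `mode_basis`.
#' @param delta step-size parameter.
#' @param m number of modes displaced (default the basis's m).
#' @return object of class `motion_vector`.
#' @export
motion_vector_nma <- function(basis, delta = 0.5, m = basis$m) {
  if (basis$kind != "NMA") stop("basis is not an NMA basis")
  if (delta <= 0) stop("delta must be positive")
  if (m < 1L || m > ncol(basis$axes)) stop("m out of range")
  f <- basis$frequencies[seq_len(m)]
  if (any(f <= 0))
    stop("zero-frequency mode among the first m: rigid modes must be discarded")
  s <- sample(c(-1, 1), m, replace = TRUE)
  structure(list(components = s * delta * sqrt(2 / m) / f, signs = s),
            class = "motion_vector")
}

#' Apply a motion vector to a conformation
#'
#' Coordinate-wise addition in variable space; the result's energy is
#' unset until the corresponding structure is evaluated.
#'
#' @param conf a `conformation`.
#' @param g a `motion_vector` of the same dimension.
#' @return the displaced `conformation`.
#' @export
apply_motion <- function(conf, g) {
  if (length(conf$coords) != length(g$components))
    stop("dimension mismatch between conformation and motion vector")
  conformation(conf$coords + g$components, energy = NA_real_,
               provenance = conf$provenance)
}
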