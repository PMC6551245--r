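# Stochastic-optimization exploration loop: initial population by
# projection, grid-weighted selection, variation, regularization,
# re-projection; plus deformation series and landscape tables.

#' Construct a population of conformations
#'
#' @param members list of `conformation` objects (each carrying an
#'   evaluated energy and, in attribute `"trace"`, its CA trace).
#' @param basis the `mode_basis` the members live in.
#' @return object of class `population`.
#' @export
population <- function(members, basis) {
  structure(list(members = members, basis = basis), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d conformations over a %s basis (m = %d)\n",
              length(x$members), x$basis$kind, x$basis$m))
  invisible(x)
}

#' @export
length.population <- function(x) length(x$members)

#' Energies of a population
#' @param pop a `population`.
#' @return numeric vector of member energies.
#' @export
population_energies <- function(pop) {
  vapply(pop$members, function(m) m$energy, numeric(1))
}

#' Coordinates of a population
#' @param pop a `population`.
#' @return n x m matrix of member coordinates.
#' @export
population_coords <- function(pop) {
  t(vapply(pop$members, function(m) m$coords,
           numeric(length(pop$members[[1]]$coords))))
}

#' Initial population by projection
#'
#' Projects each input trace onto the basis (with the basis's retained
#' m) and evaluates its surrogate energy, yielding the population that
#' seeds the exploration loop.
#'
#' @param input a `ca_ensemble`, a single `ca_trace`, or a list of
#'   traces.
#' @param basis a `mode_basis`.
#' @param model an `energy_model`.
#' @return a `population` with one member per input trace.
#' @export
init_population <- function(input, basis, model = energy_model()) {
  traces <- if (inherits(input, "ca_ensemble")) input$traces
  else if (inherits(input, "ca_trace")) list(input)
  else input
  if (length(traces) < 1L) stop("empty input")
  members <- lapply(traces, function(tr) {
    conf <- project_trace(tr, basis)
    conf$energy <- ca_energy(tr, model)
    attr(conf, "trace") <- tr
    conf
  })
  population(members, basis)
}

#' Construct the selection grid weighting
#'
#' The selection operator works over a 2D grid spanned by two variable
#' axes; cells count how many population members they hold, and the
#' weighting penalises members sitting in crowded or high-energy
#' regions.
#'
#' @param bounds 2 x 2 matrix, rows = axes, columns = (lo, hi).
#' @param axis_pair indices of the two variables defining the grid.
#' @param n_cells cells per axis.
#' @param temperature energy-softening scale; `NULL` recomputes it each
#'   step as the interquartile range of the current population energies
#'   (floored at 1e-6).
#' @param crowd_exponent crowding penalty exponent alpha.
#' @return object of class `grid_weighting`.
#' @export
grid_weighting <- function(bounds, axis_pair = c(1L, 2L), n_cells = 100,
                           temperature = NULL, crowd_exponent = 1) {
  bounds <- matrix(as.numeric(bounds), 2, 2)
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 2] <= bounds[, 1])) stop("bounds must satisfy lo < hi")
  if (n_cells < 1L) stop("n_cells must be at least 1")
  if (!is.null(temperature) && temperature <= 0)
    stop("temperature must be positive")
  structure(list(axis_pair = as.integer(axis_pair),
                 n_cells = as.integer(n_cells), bounds = bounds,
                 temperature = temperature,
                 crowd_exponent = crowd_exponent),
            class = "grid_weighting")
}

#' Default grid from an initial population
#'
#' Bounds are the initial population's bounding box over the two grid
#' axes, expanded threefold symmetrically about its centre so the
#' exploration has room to move outward; degenerate (near-point) boxes
#' fall back to a minimum half-width of 5 on each axis.
#'
#' @param pop a `population`.
#' @inheritParams grid_weighting
#' @return a `grid_weighting`.
#' @export
default_grid <- function(pop, axis_pair = c(1L, 2L), n_cells = 100,
                         temperature = NULL, crowd_exponent = 1) {
  co <- population_coords(pop)[, axis_pair, drop = FALSE]
  centre <- (apply(co, 2, max) + apply(co, 2, min)) / 2
  half <- pmax(3 * (apply(co, 2, max) - apply(co, 2, min)) / 2, 5)
  grid_weighting(cbind(centre - half, centre + half),
                 axis_pair = axis_pair, n_cells = n_cells,
                 temperature = temperature,
                 crowd_exponent = crowd_exponent)
}

#' Assign a conformation to a grid cell
#'
#' Half-open binning `[lo, hi)` on each grid axis; coordinates below
#' the lower bound clamp to the first cell and coordinates at or above
#' the upper bound clamp to the last cell.
#'
#' @param conf a `conformation` (or bare coordinate vector).
#' @param grid a `grid_weighting`.
#' @return integer pair of 0-based cell indices.
#' @export
grid_assign <- function(conf, grid) {
  v <- if (inherits(conf, "conformation")) conf$coords else as.numeric(conf)
  v <- v[grid$axis_pair]
  lo <- grid$bounds[, 1]
  hi <- grid$bounds[, 2]
  cell <- floor((v - lo) / (hi - lo) * grid$n_cells)
  as.integer(pmin(pmax(cell, 0), grid$n_cells - 1L))
}

#' Selection weights over a population
#'
#' Member C gets weight proportional to
#' `(1 + n_cell(C))^(-alpha) * exp(-(E(C) - E_min) / T)`,
#' where `n_cell` counts the members sharing C's grid cell, so that
#' both crowded and high-energy regions are penalised; weights are
#' normalised to sum to 1.
#'
#' @param pop a `population`.
#' @param grid a `grid_weighting`.
#' @return numeric probability vector, one entry per member.
#' @export
selection_weights <- function(pop, grid) {
  n <- length(pop)
  if (n < 1L) stop("empty population")
  cells <- vapply(pop$members, grid_assign, integer(2), grid = grid)
  key <- cells[1, ] * grid$n_cells + cells[2, ]
  occ <- as.vector(table(key)[as.character(key)])
  E <- population_energies(pop)
  Tval <- grid$temperature
  if (is.null(Tval)) Tval <- max(stats::IQR(E), 1e-6)
  w <- (1 + occ)^(-grid$crowd_exponent) * exp(-(E - min(E)) / Tval)
  w / sum(w)
}

#' One selection-variation step of the exploration loop
#'
#' Selects a parent per [selection_weights()], displaces it by a fresh
#' global motion vector, reconstructs the CA trace, regularizes it
#' under the energy model, re-projects the regularized trace into the
#' variable space, evaluates its energy, and appends the resulting
#' member.  The parent is never removed; a successful step grows the
#' population by exactly one.  If regularization diverges the
#' candidate is discarded and the population is returned unchanged
#' (with attribute `"discarded" = TRUE`).
#'
#' @param pop a `population`.
#' @param grid a `grid_weighting`.
#' @param model an `energy_model`.
#' @param delta step-size parameter of the motion vector.
#' @param regularize logical; skip chain regularization when `FALSE`.
#' @return the grown `population`.
#' @export
explore_step <- function(pop, grid, model = energy_model(), delta = NULL,
                         regularize = TRUE) {
  basis <- pop$basis
  if (is.null(delta)) delta <- if (basis$kind == "PCA") 2 else 0.5
  w <- selection_weights(pop, grid)
  parent <- pop$members[[sample.int(length(pop), 1, prob = w)]]
  g <- if (basis$kind == "PCA") motion_vector_pca(basis, delta = delta)
  else motion_vector_nma(basis, delta = delta)
  child <- apply_motion(parent, g)
  tr <- reconstruct_trace(child, basis)
  if (regularize) {
    tr <- tryCatch(regularize_trace(tr, model), error = function(e) NULL)
    if (is.null(tr)) {
      attr(pop, "discarded") <- TRUE
      return(pop)
    }
    child <- project_trace(tr, basis)
  } else {
    child$coords <- project_trace(tr, basis)$coords
  }
  child$energy <- ca_energy(tr, model)
  child$provenance <- "explored"
  attr(child, "trace") <- tr
  pop$members <- c(pop$members, list(child))
  attr(pop, "discarded") <- FALSE
  pop
}

#' Run the exploration loop
#'
#' Initialises a population by projecting the input structures, then
#' applies [explore_step()] for `iterations` rounds under a fixed RNG
#' seed, growing a sample-based representation of the energy landscape
#' one conformation at a time.
#'
#' @param input a `ca_ensemble`, `ca_trace`, or list of traces seeding
#'   the population.
#' @param basis a `mode_basis`.
#' @param grid optional `grid_weighting`; defaults to
#'   [default_grid()] of the initial population.
#' @param model an `energy_model`.
#' @param iterations number of selection-variation steps.
#' @param delta step-size parameter (default 2 for PCA, 0.5 for NMA).
#' @param seed integer RNG seed making the run reproducible.
#' @param regularize logical; passed to [explore_step()].
#' @return the final `population`, with a run log in attribute
#'   `"log"` (seed, parameters, accepted and discarded counts).
#' @export
explore_run <- function(input, basis, grid = NULL,
                        model = energy_model(), iterations = 2000,
                        delta = NULL, seed = 1, regularize = TRUE) {
  if (iterations < 0) stop("iterations must be non-negative")
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  pop <- init_population(input, basis, model)
  if (is.null(grid)) grid <- default_grid(pop)
  discarded <- 0L
  for (it in seq_len(iterations)) {
    n0 <- length(pop)
    pop <- explore_step(pop, grid, model, delta = delta,
                        regularize = regularize)
    if (length(pop) == n0) discarded <- discarded + 1L
  }
  attr(pop, "log") <- list(seed = seed, iterations = iterations,
                           delta = delta, kind = basis$kind,
                           m = basis$m,
                           accepted = iterations - discarded,
                           discarded = discarded)
  attr(pop, "grid") <- grid
  pop
}

#' Deformation series along a single variable axis
#'
#' Reconstructs the structures at coordinates `delta * i`, i = 1..n,
#' along one chosen axis, starting from the basis origin — a direct
#' visualisation of the collective motion that axis encodes.
#'
#' @param basis a `mode_basis`.
#' @param axis axis index (within the basis's retained m).
#' @param delta per-step displacement along the axis.
#' @param n number of structures.
#' @param model an `energy_model` (used when `regularize = TRUE`).
#' @param regularize regularize each reconstructed trace.
#' @return list of n `ca_trace` objects.
#' @export
deformation_series <- function(basis, axis = 1, delta = 1, n = 10,
                               model = energy_model(),
                               regularize = FALSE) {
  if (axis < 1L || axis > basis$m) stop("axis out of range 1..", basis$m)
  lapply(seq_len(n), function(i) {
    v <- numeric(axis)
    v[axis] <- delta * i
    tr <- reconstruct_trace(v, basis)
    if (regularize) tr <- regularize_trace(tr, model)
    tr$label <- sprintf("axis%d_step%02d", axis, i)
    tr
  })
}

#' Landscape projection table
#'
#' One row per population member with its coordinates on a chosen axis
#' pair, its surrogate energy and provenance; projections of optional
#' reference structures are appended with their own labels, mirroring
#' landscape plots that overlay experimentally known structures.
#'
#' @param pop a `population`.
#' @param axis_pair indices of the two projection axes.
#' @param references optional list of `ca_trace` reference structures.
#' @param model an `energy_model` used to score the references.
#' @return data.frame with columns `coord_a`, `coord_b`, `energy`,
#'   `provenance`.
#' @export
landscape_table <- function(pop, axis_pair = c(1L, 2L),
                            references = NULL,
                            model = energy_model()) {
  if (length(pop) < 1L) stop("empty population")
  co <- population_coords(pop)
  out <- data.frame(coord_a = co[, axis_pair[1]],
                    coord_b = co[, axis_pair[2]],
                    energy = population_energies(pop),
                    provenance = vapply(pop$members,
                                        function(m) m$provenance,
                                        character(1)),
                    stringsAsFactors = FALSE)
  for (ref in references) {
    conf <- project_trace(ref, pop$basis)
    out <- rbind(out, data.frame(coord_a = conf$coords[axis_pair[1]],
                                 coord_b = conf$coords[axis_pair[2]],
                                 energy = ca_energy(ref, model),
                                 provenance = ref$label,
                                 stringsAsFactors = FALSE))
  }
  out
}
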