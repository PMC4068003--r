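#' Subsampling schemes
#'
#' Experiments observe only a small subset of the neurons in a circuit.
#' `sampling_scheme` describes which units of a raster are kept: either
#' `n` units chosen uniformly at random, or (for lattice-indexed rasters)
#' a centered square grid of `n = m^2` units with a fixed spacing in lattice
#' units, emulating electrode arrays of different pitch.
#'
#' @param kind `"random"` or `"grid"`.
#' @param n number of units to keep (a perfect square for `"grid"`).
#' @param spacing grid spacing in lattice units (grid kind only).
#' @param seed optional integer seed for the random selection.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("random", "grid"), n = 100, spacing = 1,
                            seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, spacing >= 1)
  if (kind == "grid" && (sqrt(n) %% 1) != 0)
    stop("grid scheme needs a perfect-square n")
  structure(list(kind = kind, n = as.integer(n),
                 spacing = as.integer(spacing), seed = seed),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  if (x$kind == "random") {
    cat(sprintf("sampling_scheme: %d random units\n", x$n))
  } else {
    m <- sqrt(x$n)
    cat(sprintf("sampling_scheme: %dx%d grid, spacing %d\n", m, m, x$spacing))
  }
  invisible(x)
}

#' Lattice coordinates selected by a grid scheme
#'
#' Returns the unit ids (row-major, 1-based) of the centered `m x m` grid
#' with the given spacing on an `L x L` lattice.
#'
#' @param scheme a grid [sampling_scheme()].
#' @param L lattice side.
#' @return integer unit ids, ascending.
#' @export
grid_units <- function(scheme, L) {
  stopifnot(scheme$kind == "grid")
  m <- as.integer(sqrt(scheme$n))
  span <- (m - 1L) * scheme$spacing
  if (span >= L) stop("grid scheme does not fit on the lattice")
  off <- (L - 1L - span) %/% 2L
  coords <- off + scheme$spacing * (0:(m - 1L))  # 0-based rows/cols
  ids <- outer(coords * L, coords + 1L, "+")
  sort(as.integer(ids))
}

#' Restrict a raster to a subset of units
#'
#' Keeps only the spikes of the selected units; spike times and the recording
#' duration are untouched. Unit ids are relabelled to `1:n` preserving their
#' original order, and the selection is recorded in the output metadata so a
#' subsampled raster can be traced back to its source units.
#'
#' @param raster a [spike_raster()].
#' @param scheme a [sampling_scheme()]; for `"grid"` the raster must come
#'   from a lattice model (its `meta$cfg$L` supplies the lattice side) or
#'   `L` must be given.
#' @param L lattice side override for grid schemes.
#' @return a [spike_raster()] with `n` units.
#' @export
subsample <- function(raster, scheme, L = NULL) {
  stopifnot(inherits(raster, "spike_raster"), inherits(scheme, "sampling_scheme"))
  if (scheme$n > raster$n_units)
    stop("scheme selects more units than the raster contains")
  if (scheme$kind == "random") {
    if (!is.null(scheme$seed)) set.seed(scheme$seed)
    sel <- sort(sample.int(raster$n_units, scheme$n))
  } else {
    if (is.null(L)) L <- raster$meta$cfg$L
    if (is.null(L)) stop("grid scheme needs a lattice-indexed raster (or L)")
    sel <- grid_units(scheme, L)
  }
  keep <- raster$units %in% sel
  relabel <- integer(raster$n_units)
  relabel[sel] <- seq_along(sel)
  spike_raster(raster$times[keep], relabel[raster$units[keep]],
               length(sel), raster$duration,
               is_input = if (!is.null(raster$is_input)) raster$is_input[keep],
               meta = c(raster$meta,
                        list(subsampled_from = raster$n_units,
                             selected_units = sel,
                             scheme = unclass(scheme))))
}
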