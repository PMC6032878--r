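#' Grid lattice utilities
#'
#' All gridded artifacts share one coordinate convention: cell centres sit at
#' odd multiples of half the resolution (for 0.5 degrees: -179.75, -179.25,
#' ...), and a cell owns the half-open interval `[lon, lon + res)` west to
#' east.  Every module goes through these helpers so the convention cannot
#' drift between writers and readers.
#'
#' @param index integer lattice index (0-based from the south-west origin).
#' @param resolution_deg angular cell size in degrees.
#' @name lattice
NULL

#' @rdname lattice
#' @param origin lower (west/south) edge of index 0, degrees.
#' @return `lattice_centre()`: the coordinate of the cell centre in degrees.
#' @export
lattice_centre <- function(index, resolution_deg = 0.5, origin = -180) {
  stopifnot(is.numeric(index), resolution_deg > 0)
  origin + (index + 0.5) * resolution_deg
}

#' @rdname lattice
#' @param coord coordinate in degrees.
#' @return `lattice_index()`: 0-based index of the owning cell.
#' @export
lattice_index <- function(coord, resolution_deg = 0.5, origin = -180) {
  as.integer(floor((coord - origin) / resolution_deg + 1e-9))
}

#' @rdname lattice
#' @param lat latitude of the cell centre, degrees.
#' @return `cell_area_ha()`: spherical cell area in hectares.
#' @export
cell_area_ha <- function(lat, resolution_deg = 0.5) {
  r_earth_m <- 6371000
  dlat <- resolution_deg * pi / 180
  band <- 2 * pi * r_earth_m^2 *
    (sin((lat + resolution_deg / 2) * pi / 180) -
     sin((lat - resolution_deg / 2) * pi / 180))
  band * (resolution_deg / 360) / 1e4  # m^2 -> ha
}

is_on_lattice <- function(coord, resolution_deg = 0.5, origin = -180) {
  centre <- lattice_centre(lattice_index(coord, resolution_deg, origin),
                           resolution_deg, origin)
  abs(coord - centre) < 1e-6
}
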