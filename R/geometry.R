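# Synthetic vessel geometry: reference shapes, two-sinusoid radius
# perturbation, and structured tube meshing with frozen node ordering.
# All coordinates are in millimetres; the vessel axis is x (right-handed).

#' Construct a reference vessel
#'
#' A reference vessel is a straight tube described by its axial stations
#' `s` (mm, uniform, starting at 0) and a strictly positive baseline radius
#' profile `r0(s)` (mm), plus the circumferential and radial mesh
#' resolution used when the vessel is meshed.
#'
#' @param id Character label for the vessel.
#' @param s Numeric vector of axial stations in mm; uniform spacing,
#'   strictly increasing, `s[1] == 0`. At least 3 stations.
#' @param r0 Numeric vector of baseline radii in mm, one per station,
#'   all positive.
#' @param n_circ Number of circumferential points per surface ring.
#' @param n_rad Number of interior node rings per station (the axis node
#'   is added on top of these).
#' @return An object of class `reference_vessel`.
#' @export
reference_vessel <- function(id, s, r0, n_circ = 32L, n_rad = 4L) {
  s <- as.numeric(s)
  r0 <- as.numeric(r0)
  if (length(s) < 3L) stop("need at least 3 axial stations")
  if (length(r0) != length(s)) stop("r0 must have one value per station")
  if (s[1] != 0) stop("axial stations must start at 0")
  ds <- diff(s)
  if (any(ds <= 0)) stop("axial stations must be strictly increasing")
  if (max(ds) - min(ds) > 1e-9 * max(ds)) stop("station spacing must be uniform")
  if (any(r0 <= 0)) stop("baseline radii must be positive")
  if (n_circ < 3L) stop("n_circ must be at least 3")
  if (n_rad < 1L) stop("n_rad must be at least 1")
  structure(
    list(id = as.character(id), s = s, r0 = r0, length = s[length(s)],
         n_ax = length(s), n_circ = as.integer(n_circ), n_rad = as.integer(n_rad)),
    class = "reference_vessel")
}

#' Build the default family of reference vessels
#'
#' Creates `n` geometrically distinct straight-tube reference vessels of
#' length `length_mm` and mean radius `radius_mm`. Each reference gets its
#' own low-frequency cosine modulation of the radius profile (distinct
#' amplitude and frequency per reference) so the family spans a range of
#' tapers and bulges and downstream shape embeddings can form one cluster
#' per reference.
#'
#' @param n Number of reference vessels.
#' @param length_mm Vessel length in mm.
#' @param radius_mm Mean baseline radius in mm.
#' @param n_ax Number of axial stations.
#' @param n_circ Circumferential resolution.
#' @param n_rad Interior radial rings per station.
#' @return A list of [reference_vessel()] objects.
#' @export
reference_vessels <- function(n = 7L, length_mm = 30, radius_mm = 1.5,
                              n_ax = 101L, n_circ = 32L, n_rad = 4L) {
  if (n < 1L) stop("need at least one reference vessel")
  s <- seq(0, length_mm, length.out = n_ax)
  # fixed per-reference modulation: amplitudes 0.04..0.16, frequencies
  # 0.5..1.4 cycles per vessel length
  amp <- 0.04 + 0.02 * (seq_len(n) - 1L)
  freq <- 0.5 + 0.15 * (seq_len(n) - 1L)
  lapply(seq_len(n), function(k) {
    r0 <- radius_mm * (1 + amp[k] * cos(2 * pi * freq[k] * s / length_mm))
    reference_vessel(sprintf("V%d", k), s, r0, n_circ = n_circ, n_rad = n_rad)
  })
}

#' Default perturbation parameter bounds
#'
#' Bounds for the randomised two-sinusoid radius perturbation: amplitude
#' fraction `|a_j| <= a_max`, vertical offset fraction `|d_j| <= d_max`,
#' frequency `f_j` in `[f_min, f_max]` cycles per vessel length, phase free
#' in `[0, 2*pi)`. With the defaults the perturbation bracket
#' `1 + sum_j (a_j sin(.) + d_j)` is at least `1 - 2*(a_max + d_max) = 0.78`,
#' so radii stay positive and deviations stay small but significant.
#'
#' @param a_max Maximum sinusoid amplitude (dimensionless fraction).
#' @param d_max Maximum vertical offset (dimensionless fraction).
#' @param f_min,f_max Frequency range in cycles per vessel length.
#' @return A list with elements `a_max`, `d_max`, `f_min`, `f_max`.
#' @export
perturbation_bounds <- function(a_max = 0.08, d_max = 0.03,
                                f_min = 0.5, f_max = 2.5) {
  if (a_max < 0 || d_max < 0) stop("bounds must be non-negative")
  if (f_min <= 0 || f_max < f_min) stop("invalid frequency range")
  if (2 * (a_max + d_max) >= 0.5)
    stop("bounds too large: perturbation bracket could fall below 0.5")
  list(a_max = a_max, d_max = d_max, f_min = f_min, f_max = f_max)
}

#' Draw a random two-sinusoid perturbation
#'
#' Draws amplitude, frequency, phase and vertical offset for the two
#' sinusoid components uniformly within `bounds`, using the current RNG
#' state (seed it upstream for reproducibility).
#'
#' @param bounds Output of [perturbation_bounds()].
#' @return A `perturbation_params` object: list with `a`, `f`, `phi`, `d`
#'   (each length 2).
#' @export
draw_perturbation <- function(bounds = perturbation_bounds()) {
  structure(
    list(a = stats::runif(2, -bounds$a_max, bounds$a_max),
         f = stats::runif(2, bounds$f_min, bounds$f_max),
         phi = stats::runif(2, 0, 2 * pi),
         d = stats::runif(2, -bounds$d_max, bounds$d_max)),
    class = "perturbation_params")
}

#' Construct explicit perturbation parameters
#'
#' @param a Length-2 sinusoid amplitudes (dimensionless fractions).
#' @param f Length-2 frequencies, cycles per vessel length.
#' @param phi Length-2 phases in radians.
#' @param d Length-2 vertical offsets (dimensionless fractions).
#' @return A `perturbation_params` object.
#' @export
perturbation_params <- function(a = c(0, 0), f = c(1, 1),
                                phi = c(0, 0), d = c(0, 0)) {
  stopifnot(length(a) == 2, length(f) == 2, length(phi) == 2, length(d) == 2)
  structure(list(a = as.numeric(a), f = as.numeric(f),
                 phi = as.numeric(phi), d = as.numeric(d)),
            class = "perturbation_params")
}

#' Apply a two-sinusoid radius perturbation
#'
#' Modulates the baseline radius profile of a reference vessel as
#' `r(s) = r0(s) * (1 + sum_{j=1,2} (a_j sin(2*pi*f_j*s/L + phi_j) + d_j))`,
#' the composite-of-two-sinusoids rule that distributes a smooth, bounded
#' perturbation along the vessel length.
#'
#' @param ref A [reference_vessel()].
#' @param params A `perturbation_params` object.
#' @param bounds Bounds the parameters must respect; see
#'   [perturbation_bounds()].
#' @return Numeric vector of perturbed radii (mm), one per station.
#' @export
perturb_radius <- function(ref, params, bounds = perturbation_bounds()) {
  stopifnot(inherits(ref, "reference_vessel"),
            inherits(params, "perturbation_params"))
  if (any(abs(params$a) > bounds$a_max + 1e-12) ||
      any(abs(params$d) > bounds$d_max + 1e-12) ||
      any(params$f < bounds$f_min - 1e-12) ||
      any(params$f > bounds$f_max + 1e-12))
    stop("perturbation parameters outside bounds")
  bracket <- 1
  for (j in 1:2) {
    bracket <- bracket +
      params$a[j] * sin(2 * pi * params$f[j] * ref$s / ref$length + params$phi[j]) +
      params$d[j]
  }
  r <- ref$r0 * bracket
  if (any(r <= 0)) stop("perturbation drives radius non-positive")
  r
}

#' Mesh a radius profile into a structured tube grid
#'
#' Builds the fixed-topology surface and volume node sets for a radius
#' profile on a reference vessel's stations. Node ordering is frozen:
#' station-major, then ring (axis node first, rings inside out), then
#' angle. Per station there are `n_circ` surface nodes (one ring at radius
#' `r(s)`) and `n_rad * n_circ + 1` volume nodes (the axis node plus
#' `n_rad` strictly interior rings at radii `r * l / (n_rad + 1)`,
#' `l = 1..n_rad`). So `Ns = n_ax * n_circ` and
#' `Nv = n_ax * (n_rad * n_circ + 1)`. Every geometry built at one
#' resolution therefore has identical node counts and ordering — the
#' common-basis requirement of the mesh-domain POD stage.
#'
#' @param r Numeric vector of station radii (mm), all positive.
#' @param ref The parent [reference_vessel()] (supplies stations and
#'   resolution).
#' @param mesh_id Identifier for the resulting geometry.
#' @param nodes If `FALSE`, skip building the coordinate arrays and store
#'   only the radius profile and resolution (sufficient for the surrogate
#'   solver and POD stages; the shape-embedding stage needs coordinates).
#' @return A `vessel_geometry` object with elements `mesh_id`,
#'   `parent_id`, `s`, `r`, `surface` (Ns x 3 or NULL), `volume`
#'   (Nv x 3 or NULL), `surface_station`, `volume_station` (station index
#'   per node), and the resolution fields.
#' @export
build_mesh <- function(r, ref, mesh_id = ref$id, nodes = TRUE) {
  stopifnot(inherits(ref, "reference_vessel"))
  r <- as.numeric(r)
  if (length(r) != ref$n_ax) stop("radius profile length must match stations")
  if (any(r <= 0)) stop("radii must be positive")
  n_ax <- ref$n_ax; n_circ <- ref$n_circ; n_rad <- ref$n_rad
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  ct <- cos(theta); st <- sin(theta)
  surface_station <- rep(seq_len(n_ax), each = n_circ)
  volume_station <- rep(seq_len(n_ax), each = n_rad * n_circ + 1L)
  surface <- volume <- NULL
  if (nodes) {
    rs <- r[surface_station]
    surface <- cbind(x = ref$s[surface_station],
                     y = rs * rep(ct, times = n_ax),
                     z = rs * rep(st, times = n_ax))
    # per-station volume block: axis node, then rings l = 1..n_rad
    frac <- seq_len(n_rad) / (n_rad + 1L)
    ring_y <- c(0, as.vector(outer(ct, frac)))   # length n_rad*n_circ + 1
    ring_z <- c(0, as.vector(outer(st, frac)))
    rv <- r[volume_station]
    volume <- cbind(x = ref$s[volume_station],
                    y = rv * rep(ring_y, times = n_ax),
                    z = rv * rep(ring_z, times = n_ax))
  }
  structure(
    list(mesh_id = as.character(mesh_id), parent_id = ref$id,
         s = ref$s, r = r, length = ref$length,
         n_ax = n_ax, n_circ = n_circ, n_rad = n_rad,
         n_surface = n_ax * n_circ,
         n_volume = n_ax * (n_rad * n_circ + 1L),
         surface = surface, volume = volume,
         surface_station = surface_station,
         volume_station = volume_station),
    class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> %s (parent %s): %d stations, Ns=%d, Nv=%d%s\n",
              x$mesh_id, x$parent_id, x$n_ax, x$n_surface, x$n_volume,
              if (is.null(x$surface)) " (profile only)" else ""))
  invisible(x)
}

#' Generate the phantom vessel dataset
#'
#' For each reference vessel, emits the unperturbed reference geometry
#' plus `n_perturb` randomly perturbed phantoms, all at the reference's
#' resolution. With 7 references and 200 perturbations each this yields
#' the 1407-mesh dataset the pipeline is built around. Fully reproducible:
#' the same seed gives bitwise-identical parameter draws and geometries.
#'
#' @param refs List of [reference_vessel()] objects.
#' @param n_perturb Number of random phantoms per reference (>= 0).
#' @param seed Integer RNG seed.
#' @param bounds Perturbation bounds; see [perturbation_bounds()].
#' @param nodes Build full coordinate arrays (see [build_mesh()]).
#' @return A `vessel_dataset`: a list of `vessel_geometry` objects with a
#'   `params` attribute, a data frame logging the perturbation parameters
#'   of every mesh (columns mesh_id, parent_id, a1, f1, phi1, d1, a2, f2,
#'   phi2, d2).
#' @export
generate_dataset <- function(refs, n_perturb = 200L, seed = 1L,
                             bounds = perturbation_bounds(), nodes = TRUE) {
  if (inherits(refs, "reference_vessel")) refs <- list(refs)
  if (n_perturb < 0L) stop("n_perturb must be non-negative")
  set.seed(seed)
  geoms <- vector("list", length(refs) * (n_perturb + 1L))
  log <- vector("list", length(geoms))
  pos <- 0L
  for (ref in refs) {
    for (i in 0:n_perturb) {
      pos <- pos + 1L
      mesh_id <- sprintf("%s_%03d", ref$id, i)
      if (i == 0L) {
        params <- perturbation_params(f = c(bounds$f_min, bounds$f_min))
        r <- ref$r0
      } else {
        params <- draw_perturbation(bounds)
        r <- perturb_radius(ref, params, bounds)
      }
      geoms[[pos]] <- build_mesh(r, ref, mesh_id = mesh_id, nodes = nodes)
      log[[pos]] <- data.frame(
        mesh_id = mesh_id, parent_id = ref$id,
        a1 = params$a[1], f1 = params$f[1], phi1 = params$phi[1], d1 = params$d[1],
        a2 = params$a[2], f2 = params$f[2], phi2 = params$phi[2], d2 = params$d[2])
    }
  }
  structure(geoms, class = "vessel_dataset",
            params = do.call(rbind, log), seed = seed)
}

#' @export
print.vessel_dataset <- function(x, ...) {
  parents <- unique(vapply(x, `[[`, "", "parent_id"))
  cat(sprintf("<vessel_dataset> %d geometries from %d reference vessel(s)\n",
              length(x), length(parents)))
  invisible(x)
}

#' Perturbation parameter log of a dataset
#' @param dataset A `vessel_dataset`.
#' @return Data frame of per-mesh perturbation parameters.
#' @export
dataset_params <- function(dataset) attr(dataset, "params")

# ---- exports -------------------------------------------------------------

#' Write a radius profile as CSV
#'
#' Columns: `station_index`, `s_mm`, `r_mm`.
#' @param geom A `vessel_geometry`.
#' @param path Output file path.
#' @export
write_radius_csv <- function(geom, path) {
  utils::write.csv(
    data.frame(station_index = seq_len(geom$n_ax), s_mm = geom$s, r_mm = geom$r),
    path, row.names = FALSE)
  invisible(path)
}

#' Write the vessel surface as a legacy VTK polydata file
#'
#' Emits the surface nodes and the quad facets joining consecutive rings,
#' optionally with a per-node scalar array.
#'
#' @param geom A `vessel_geometry` built with `nodes = TRUE`.
#' @param path Output `.vtk` path.
#' @param point_data Optional named list of numeric vectors (one value per
#'   surface node) written as POINT_DATA scalar arrays.
#' @export
write_vtk_surface <- function(geom, path, point_data = NULL) {
  if (is.null(geom$surface)) stop("geometry has no surface nodes")
  nc <- geom$n_circ
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("coropod surface %s", geom$mesh_id),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", geom$n_surface)), con)
  utils::write.table(format(geom$surface, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  quads <- list()
  for (i in seq_len(geom$n_ax - 1L)) {
    base <- (i - 1L) * nc
    m <- seq_len(nc) - 1L
    m2 <- (m + 1L) %% nc
    quads[[i]] <- cbind(4L, base + m, base + m2, base + nc + m2, base + nc + m)
  }
  quads <- do.call(rbind, quads)
  writeLines(sprintf("POLYGONS %d %d", nrow(quads), length(quads)), con)
  utils::write.table(quads, con, row.names = FALSE, col.names = FALSE)
  .write_vtk_point_data(con, point_data, geom$n_surface)
  invisible(path)
}

#' Write the vessel volume nodes as a legacy VTK unstructured grid
#'
#' Volume nodes are written as vertex cells (a point cloud with intact
#' node ordering), optionally with per-node scalar arrays.
#'
#' @inheritParams write_vtk_surface
#' @param point_data Optional named list of numeric vectors, one value per
#'   volume node.
#' @export
write_vtk_volume <- function(geom, path, point_data = NULL) {
  if (is.null(geom$volume)) stop("geometry has no volume nodes")
  nv <- geom$n_volume
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("coropod volume %s", geom$mesh_id),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  utils::write.table(format(geom$volume, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nv, 2L * nv), con)
  utils::write.table(cbind(1L, seq_len(nv) - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nv), con)
  writeLines(as.character(rep(1L, nv)), con)
  .write_vtk_point_data(con, point_data, nv)
  invisible(path)
}

.write_vtk_point_data <- function(con, point_data, n) {
  if (is.null(point_data)) return(invisible())
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (length(v) != n) stop("point data length mismatch for ", nm)
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(v, digits = 10, trim = TRUE), con)
  }
  invisible()
}
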