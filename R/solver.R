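# Surrogate flow solver: Carreau-Yasuda rheology and a quasi-1D steady
# generalized-Newtonian tube-flow model behind a pluggable solver contract.

#' Carreau-Yasuda blood rheology parameters
#'
#' Kinematic-viscosity parameters of the Carreau-Yasuda shear-thinning
#' model. Defaults are the standard blood coefficients: zero-shear
#' viscosity `nu0 = 56e-6` m^2/s, infinite-shear viscosity
#' `nu_inf = 3.45e-6` m^2/s, relaxation time `tau = 3.313` s, transition
#' exponent `alpha = 2`, power-law index `n = 0.3568`.
#'
#' @param nu_inf Infinite-shear kinematic viscosity, m^2/s.
#' @param nu0 Zero-shear kinematic viscosity, m^2/s.
#' @param tau Relaxation time, s.
#' @param alpha Transition exponent (dimensionless, > 0).
#' @param n Power-law index (dimensionless, in (0, 1)).
#' @return A `rheology_params` object.
#' @export
blood_rheology <- function(nu_inf = 3.45e-6, nu0 = 56e-6, tau = 3.313,
                           alpha = 2, n = 0.3568) {
  # nu0 == nu_inf is allowed as the degenerate Newtonian limit
  if (!(nu0 >= nu_inf && nu_inf > 0)) stop("need nu0 >= nu_inf > 0")
  if (tau <= 0 || alpha <= 0) stop("tau and alpha must be positive")
  if (n <= 0 || n >= 1) stop("power-law index n must lie in (0, 1)")
  structure(list(nu_inf = nu_inf, nu0 = nu0, tau = tau, alpha = alpha, n = n),
            class = "rheology_params")
}

#' Carreau-Yasuda kinematic viscosity
#'
#' `nu = nu_inf + (nu0 - nu_inf) * (1 + (tau*gamma_dot)^alpha)^((n-1)/alpha)`.
#' Strictly decreasing in the strain rate (shear thinning), bounded by
#' `nu0` at zero shear and `nu_inf` in the infinite-shear limit.
#'
#' @param gamma_dot Strain rate(s), 1/s, non-negative; vectorised.
#' @param rheo A [blood_rheology()] object.
#' @return Kinematic viscosity in m^2/s, same length as `gamma_dot`.
#' @export
kinematic_viscosity <- function(gamma_dot, rheo = blood_rheology()) {
  stopifnot(inherits(rheo, "rheology_params"))
  if (any(gamma_dot < 0)) stop("strain rate must be non-negative")
  rheo$nu_inf + (rheo$nu0 - rheo$nu_inf) *
    (1 + (rheo$tau * gamma_dot)^rheo$alpha)^((rheo$n - 1) / rheo$alpha)
}

#' Solver boundary conditions and fluid properties
#'
#' @param u_inlet Constant inlet speed in cm/s (default 100).
#' @param p_outlet Outlet pressure in Pa (fixed reference, default 0).
#' @param density Blood density in kg/m^3 (default 1060).
#' @return A `solver_config` object.
#' @export
solver_config <- function(u_inlet = 100, p_outlet = 0, density = 1060) {
  if (u_inlet <= 0) stop("inlet speed must be positive")
  if (density <= 0) stop("density must be positive")
  structure(list(u_inlet = u_inlet, p_outlet = p_outlet, density = density),
            class = "solver_config")
}

#' Poiseuille wall shear rate
#'
#' The fully developed tube-flow estimate of the wall strain rate,
#' `gamma_dot_w = 4 Q / (pi r^3)`, equivalently `4 U / r` for mean speed
#' `U = Q / (pi r^2)`. Scales as `r^-3` at fixed flow rate.
#'
#' @param Q Volumetric flow rate, m^3/s (> 0); vectorised with `r`.
#' @param r Local tube radius, m (> 0).
#' @return Wall shear rate in 1/s.
#' @export
wall_shear_rate <- function(Q, r) {
  if (any(Q <= 0)) stop("flow rate must be positive")
  if (any(r <= 0)) stop("radius must be positive")
  4 * Q / (pi * r^3)
}

#' Solve steady flow through a vessel with the quasi-1D surrogate
#'
#' Station-by-station application of fully developed generalized-Newtonian
#' tube flow to the slowly varying radius profile. The flow rate
#' `Q = U_in * pi * r(0)^2` is conserved exactly along the vessel; per
#' station the wall shear rate is the Poiseuille estimate
#' `4Q/(pi r^3)`, the wall shear stress is
#' `tau_w = rho * nu(gamma_dot_w) * gamma_dot_w` with Carreau-Yasuda
#' viscosity, and the pressure follows the axial force balance
#' `dp/ds = -2 tau_w / r` integrated upstream from the zero-pressure
#' outlet by the trapezoidal rule. The WSS value of a station is assigned
#' to each of its surface nodes and the pressure to each of its volume
#' nodes (radial variation neglected). In the Newtonian limit
#' (`nu0 == nu_inf`) the pressure drop reduces to the closed-form
#' Poiseuille result
#' `dp = 8 rho nu L Q / (pi r^4)` on a uniform tube.
#'
#' @param geom A `vessel_geometry` (coordinates not required).
#' @param cfg A [solver_config()].
#' @param rheo A [blood_rheology()].
#' @return A `flow_solution`: list with `mesh_id`, `pressure` (Pa, one
#'   value per volume node), `wss` (Pa, one value per surface node), and
#'   the per-station profiles `station_pressure`, `station_wss`, `Q`
#'   (m^3/s).
#' @export
solve_flow <- function(geom, cfg = solver_config(), rheo = blood_rheology()) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(cfg, "solver_config"))
  r_m <- geom$r * 1e-3
  s_m <- geom$s * 1e-3
  U <- cfg$u_inlet / 100                       # cm/s -> m/s
  Q <- U * pi * r_m[1]^2
  gw <- wall_shear_rate(Q, r_m)
  nu <- kinematic_viscosity(gw, rheo)
  tau_w <- cfg$density * nu * gw               # Pa
  g <- 2 * tau_w / r_m                         # -dp/ds, Pa/m
  n <- length(s_m)
  seg <- 0.5 * (g[-1] + g[-n]) * diff(s_m)     # trapezoidal segments
  p <- cfg$p_outlet + rev(c(0, cumsum(rev(seg))))
  structure(
    list(mesh_id = geom$mesh_id,
         pressure = p[geom$volume_station],
         wss = tau_w[geom$surface_station],
         station_pressure = p, station_wss = tau_w, Q = Q),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %s: dp = %.1f Pa, WSS %.2f-%.2f Pa\n",
              x$mesh_id, x$station_pressure[1] - x$station_pressure[length(x$station_pressure)],
              min(x$wss), max(x$wss)))
  invisible(x)
}

# ---- pluggable solver registry ------------------------------------------

.solver_registry <- new.env(parent = emptyenv())

#' Register a flow-solver backend
#'
#' Any function mapping `(vessel_geometry, solver_config, rheology_params)`
#' to a `flow_solution` honouring the solution invariants (outlet pressure
#' zero, positive WSS, pressure non-increasing downstream) can be
#' registered by name and selected in a pipeline config. The quasi-1D
#' surrogate is pre-registered as `"quasi1d"`.
#'
#' @param name Backend name.
#' @param fun Solver function.
#' @export
register_solver <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .solver_registry)
  invisible(name)
}

#' Look up a registered flow-solver backend
#' @param name Backend name.
#' @return The solver function.
#' @export
get_solver <- function(name = "quasi1d") {
  if (!exists(name, envir = .solver_registry))
    stop("unknown solver backend: ", name)
  get(name, envir = .solver_registry)
}

#' List registered solver backends
#' @return Character vector of backend names.
#' @export
list_solvers <- function() ls(.solver_registry)

#' Write a flow field as CSV
#'
#' Columns `node_id`, `value`; one row per node.
#' @param values Numeric field values.
#' @param path Output file path.
#' @export
write_field_csv <- function(values, path) {
  utils::write.csv(data.frame(node_id = seq_along(values) - 1L, value = values),
                   path, row.names = FALSE)
  invisible(path)
}

.onLoad <- function(libname, pkgname) {
  register_solver("quasi1d", solve_flow)
}
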