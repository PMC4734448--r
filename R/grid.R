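#' Construct a coastal model grid
#'
#' Builds the regular 2D depth-averaged grid on which river tracers are
#' transported. Cells are square-ish rectangles of size `dx` by `dy` metres;
#' `mask` flags water cells (`TRUE`) versus land (`FALSE`). The grid is a
#' desk-scale analogue of a regional coastal model domain, with resolution
#' left configurable.
#'
#' @param nx,ny Number of cells in the x (cross-shore) and y (alongshore)
#'   directions. Both must be at least 3.
#' @param dx,dy Cell size in metres (> 0).
#' @param mask Logical matrix of dimension `nx` by `ny`; `TRUE` marks water.
#'   Default: all water.
#' @return An object of class `"plume_grid"`: a list with `nx`, `ny`, `dx`,
#'   `dy`, `mask`, and cell-centre coordinate vectors `x`, `y` (metres).
#' @examples
#' g <- make_grid(10, 8, dx = 2000, dy = 2000)
#' @export
make_grid <- function(nx, ny, dx = 2000, dy = 2000, mask = NULL) {
  if (nx < 3 || ny < 3) stop("grid must be at least 3 x 3 cells")
  if (dx <= 0 || dy <= 0) stop("cell sizes dx, dy must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(as.integer(nx), as.integer(ny))))
    stop("mask must be an nx x ny matrix")
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("grid must contain at least one water cell")
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
         mask = mask,
         x = (seq_len(nx) - 0.5) * dx,
         y = (seq_len(ny) - 0.5) * dy),
    class = "plume_grid")
}

#' @export
print.plume_grid <- function(x, ...) {
  cat(sprintf("Coastal grid: %d x %d cells of %.0f x %.0f m (%d water, %d land)\n",
              x$nx, x$ny, x$dx, x$dy, sum(x$mask), sum(!x$mask)))
  invisible(x)
}

#' Construct a prescribed flow field
#'
#' The flow is exogenous: tracers are passive and do not feed back on it.
#' Velocities are defined at cell centres and must be zero on land.
#'
#' @param grid A [make_grid()] object.
#' @param u,v Velocity components (m/s), either scalars (recycled over water
#'   cells) or `nx` by `ny` matrices. Land cells are forced to zero.
#' @param description Optional free-text note, e.g. the direction of the
#'   residual coastal current the field represents.
#' @return An object of class `"flow_field"` with matrices `u`, `v`.
#' @export
make_flow <- function(grid, u = 0, v = 0, description = NULL) {
  stopifnot(inherits(grid, "plume_grid"))
  expand <- function(w) {
    if (length(w) == 1L) w <- matrix(w, grid$nx, grid$ny)
    w <- as.matrix(w)
    if (!identical(dim(w), dim(grid$mask))) stop("velocity must be scalar or nx x ny")
    if (any(!is.finite(w))) stop("velocities must be finite")
    w[!grid$mask] <- 0
    w
  }
  structure(list(u = expand(u), v = expand(v), grid = grid,
                 description = description),
            class = "flow_field")
}

#' Define a river tracer source
#'
#' Each river releases its own conservative tracer at unit concentration at
#' its mouth cell; discharge modulates how strongly the mouth cell is pushed
#' towards the source concentration.
#'
#' @param grid A [make_grid()] object.
#' @param mouth Integer vector `c(ix, iy)`: grid indices of the mouth cell
#'   (must be water).
#' @param discharge Either a single non-negative number (ML/day, constant) or
#'   a data frame with columns `date` (Date) and `discharge` (ML/day).
#' @param name Tracer name (defaults to `"river"`).
#' @return An object of class `"river_source"`.
#' @export
river_source <- function(grid, mouth, discharge, name = "river") {
  stopifnot(inherits(grid, "plume_grid"), length(mouth) == 2L)
  mouth <- as.integer(mouth)
  if (mouth[1] < 1 || mouth[1] > grid$nx || mouth[2] < 1 || mouth[2] > grid$ny)
    stop("river mouth lies off the grid")
  if (!grid$mask[mouth[1], mouth[2]]) stop("river mouth must be a water cell")
  if (is.data.frame(discharge)) {
    if (!all(c("date", "discharge") %in% names(discharge)))
      stop("discharge table needs columns 'date' and 'discharge'")
    discharge$date <- as.Date(discharge$date)
    if (any(discharge$discharge < 0)) stop("discharge must be non-negative")
  } else {
    if (length(discharge) != 1L || discharge < 0)
      stop("discharge must be a single non-negative number or a date table")
  }
  structure(list(mouth = mouth, discharge = discharge, name = name,
                 source_concentration = 1.0),
            class = "river_source")
}

#' Transport solver parameters
#'
#' @param K Horizontal diffusivity (m^2/s, >= 0).
#' @param dt Time step (s, > 0). For daily recording `dt` must divide 86400.
#' @param depth Effective mixed-layer depth (m) of the depth-averaged column,
#'   used to convert river volume flux into a concentration forcing.
#' @param boundary_mode `"closed"` (no flux through the domain edge) or
#'   `"open"` (zero-gradient advective outflow at edges; lost mass is
#'   budgeted, not conserved).
#' @return An object of class `"transport_params"`.
#' @export
transport_params <- function(K = 50, dt = 600, depth = 5,
                             boundary_mode = c("open", "closed")) {
  boundary_mode <- match.arg(boundary_mode)
  if (K < 0) stop("diffusivity K must be non-negative")
  if (dt <= 0) stop("time step dt must be positive")
  if (depth <= 0) stop("depth must be positive")
  structure(list(K = K, dt = dt, depth = depth, boundary_mode = boundary_mode),
            class = "transport_params")
}

# Stability guard for the explicit scheme: Courant number <= 1, diffusion
# number K dt (1/dx^2 + 1/dy^2) <= 1/2, and the joint positivity
# (monotonicity) constraint of the combined upwind + centred-diffusion
# update, Cx + Cy + 2 ax + 2 ay <= 1, which the two individual bounds do
# not imply on their own.
check_stability <- function(flow, params) {
  g <- flow$grid
  cx <- max(abs(flow$u)) * params$dt / g$dx
  cy <- max(abs(flow$v)) * params$dt / g$dy
  ax <- params$K * params$dt / g$dx^2
  ay <- params$K * params$dt / g$dy^2
  cfl <- max(cx, cy)
  dif <- ax + ay
  if (cfl > 1)
    stop(sprintf("CFL condition violated (Courant number %.3f > 1); reduce dt", cfl))
  if (dif > 0.5)
    stop(sprintf("diffusion number %.3f > 0.5; reduce dt or K", dif))
  joint <- cx + cy + 2 * (ax + ay)
  if (joint > 1)
    stop(sprintf(
      "combined advection-diffusion positivity number %.3f > 1; reduce dt", joint))
  invisible(list(cfl = cfl, diffusion_number = dif, positivity = joint))
}

# Discharge (ML/d) of a source on a given date; constant sources ignore date.
source_discharge <- function(source, date) {
  d <- source$discharge
  if (!is.data.frame(d)) return(as.numeric(d))
  i <- match(as.Date(date), d$date)
  if (is.na(i)) 0 else d$discharge[i]
}
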