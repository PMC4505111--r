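# Reference 1D cable solver with Hodgkin-Huxley dynamics. Plays the role of
# a standard compartment simulator for verifying the 3D model on long thin
# cylinders: c_m dV/dt = (d sigma_in / 4) d2V/dx2 - j_ion(V, n, m, h) + j_stim
# with sealed ends and extracellular potential identically zero (the 1D
# model's assumption). Axial resistivity derives from the same sigma_in as
# the 3D solver (R_i = 1/sigma_in), keeping comparisons parameter-consistent.

#' 1D cable configuration
#'
#' @param length cable length (um).
#' @param diameter cable diameter (um).
#' @param sigma_in axial (intracellular) conductivity (mS/cm).
#' @param n_comp number of compartments (>= 3).
#' @param params a [hh_parameters()].
#' @param passive logical: leak-only membrane (no Na/K channels).
#' @param stim_amplitude_nA injected current (nA), spread over the first
#'   `stim_length` um of membrane; positive = depolarizing.
#' @param stim_length axial extent of the injection (um).
#' @param stim_t_on,stim_t_off injection window (ms).
#' @param dt time step (ms).
#' @param t_end end time (ms).
#' @param probes probe positions (um) within `[0, length]`.
#' @return object of class `nc_cable_config`.
#' @export
cable1d_config <- function(length, diameter, sigma_in = 2, n_comp = 200,
                           params = hh_parameters(), passive = FALSE,
                           stim_amplitude_nA = 0, stim_length = length / 50,
                           stim_t_on = 0, stim_t_off = Inf,
                           dt = 0.01, t_end = 5,
                           probes = c(0, length / 2, length)) {
  stopifnot(length > 0, diameter > 0, n_comp >= 3, dt > 0, t_end > 0)
  if (any(probes < 0 | probes > length)) stop("probes must lie in [0, length]")
  structure(list(length = length, diameter = diameter, sigma_in = sigma_in,
                 n_comp = as.integer(n_comp), params = params,
                 passive = passive, stim_amplitude_nA = stim_amplitude_nA,
                 stim_length = stim_length, stim_t_on = stim_t_on,
                 stim_t_off = stim_t_off, dt = dt, t_end = t_end,
                 probes = probes), class = "nc_cable_config")
}

#' Trace set container
#'
#' @param time time grid (ms).
#' @param v matrix of membrane potentials (mV), one column per probe.
#' @param positions probe positions (um).
#' @return object of class `nc_traces`.
#' @export
trace_set <- function(time, v, positions = NULL) {
  v <- as.matrix(v)
  stopifnot(length(time) == nrow(v), all(is.finite(v)))
  structure(list(time = time, v = v, positions = positions),
            class = "nc_traces")
}

#' Solve the 1D cable equation
#'
#' Backward-Euler diffusion step with implicitly advanced (staggered) gating,
#' sealed (zero axial flux) ends. Compartment potentials are interpolated
#' linearly to the probe positions.
#'
#' @param config a [cable1d_config()].
#' @return a [trace_set()].
#' @export
solve_cable_1d <- function(config) {
  p <- config$params
  n <- config$n_comp
  dx <- config$length / n
  xc <- (seq_len(n) - 0.5) * dx
  sig <- config$sigma_in * UNIT$sigma        # uS/um
  D <- config$diameter * sig / 4             # uS (times mV/um^2 -> nA/um^2)
  cm <- p$c_m * UNIT$c_mem                   # nF/um^2
  lam <- D / dx^2

  # constant part of the implicit operator (sealed ends: missing neighbor)
  main <- rep(2 * lam, n); main[1] <- lam; main[n] <- lam
  A0 <- Matrix::sparseMatrix(
    i = c(seq_len(n), seq_len(n - 1), 2:n),
    j = c(seq_len(n), 2:n, seq_len(n - 1)),
    x = c(main, rep(-lam, 2 * (n - 1))), dims = c(n, n))

  stim_mask <- xc <= config$stim_length
  stim_area <- pi * config$diameter * dx * sum(stim_mask)  # membrane area (um^2)
  jst_on <- if (any(stim_mask))
    -config$stim_amplitude_nA / stim_area else 0  # outward density, nA/um^2

  v <- numeric(n)
  g0 <- gating_steady_state(0)
  gat <- list(n = rep(g0$n, n), m = rep(g0$m, n), h = rep(g0$h, n))
  gl <- p$g_l * UNIT$g_mem

  n_steps <- round(config$t_end / config$dt)
  tgrid <- seq_len(n_steps) * config$dt
  vm <- matrix(0, n_steps, length(config$probes))
  dt <- config$dt

  for (k in seq_len(n_steps)) {
    t <- k * dt
    gat <- advance_gating(gat, v, dt, scheme = "implicit")
    if (config$passive) {
      g <- rep(gl, n); ge <- rep(gl * p$e_pas, n)
    } else {
      aff <- hh_affine(gat$n, gat$m, gat$h, p)
      g <- aff$g * UNIT$g_mem; ge <- aff$ge * UNIT$g_mem
    }
    jst <- if (t > config$stim_t_on && t <= config$stim_t_off) jst_on else 0
    A <- A0 + Matrix::Diagonal(n, cm / dt + g)
    rhs <- cm / dt * v + ge - jst * stim_mask
    v <- as.numeric(Matrix::solve(A, rhs))
    vm[k, ] <- stats::approx(xc, v, xout = pmin(pmax(config$probes, xc[1]),
                                                xc[n]), rule = 2)$y
  }
  trace_set(tgrid, vm, config$probes)
}

#' Relative L2-in-time error between two trace sets
#'
#' `||a - b|| / ||b||` with the L2([0,T]) norm evaluated by trapezoidal
#' quadrature after linear resampling onto a common time grid; multi-probe
#' trace sets are combined by summing squared norms over probes before the
#' ratio.
#'
#' @param a,b [trace_set()]s with the same number of probes (`b` is the
#'   reference).
#' @param interval optional time interval `c(t0, t1)` (ms); defaults to the
#'   overlap of the two time grids.
#' @return dimensionless relative error.
#' @export
relative_l2_error <- function(a, b, interval = NULL) {
  stopifnot(ncol(a$v) == ncol(b$v))
  if (is.null(interval))
    interval <- c(max(min(a$time), min(b$time)), min(max(a$time), max(b$time)))
  grid <- sort(unique(c(a$time, b$time)))
  grid <- grid[grid >= interval[1] & grid <= interval[2]]
  if (length(grid) < 2) stop("empty comparison interval")
  num <- den <- 0
  for (j in seq_len(ncol(a$v))) {
    av <- stats::approx(a$time, a$v[, j], grid, rule = 2)$y
    bv <- stats::approx(b$time, b$v[, j], grid, rule = 2)$y
    num <- num + trapz(grid, (av - bv)^2)
    den <- den + trapz(grid, bv^2)
  }
  if (den == 0) stop("reference trace set has zero norm; ratio undefined")
  sqrt(num / den)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1))) / 2

#' Action-potential conduction velocity from traces
#'
#' Distance between the first and last probe divided by the difference of
#' their first upward threshold-crossing times (linear interpolation between
#' samples). The default threshold is half the spike amplitude over all
#' probes.
#'
#' @param traces a [trace_set()].
#' @param positions probe positions (um); default from the trace set.
#' @param threshold crossing threshold (mV).
#' @return velocity in m/s (= mm/ms).
#' @export
conduction_velocity <- function(traces, positions = traces$positions,
                                threshold = NULL) {
  if (is.null(positions) || length(positions) < 2)
    stop("need at least two probe positions")
  if (is.null(threshold)) threshold <- max(traces$v) / 2
  tc <- vapply(seq_len(ncol(traces$v)), function(j)
    first_upward_crossing(traces$time, traces$v[, j], threshold), numeric(1))
  j1 <- which.min(positions); j2 <- which.max(positions)
  dtc <- tc[j2] - tc[j1]
  if (dtc <= 0) stop("threshold crossings are not ordered with distance")
  dx_um <- positions[j2] - positions[j1]
  (dx_um / dtc) * 1e-3  # um/ms -> m/s
}

first_upward_crossing <- function(t, v, thr) {
  above <- v > thr
  k <- which(above & !c(FALSE, utils::head(above, -1)))[1]
  if (is.na(k)) stop("no spike detected: probe never crosses the threshold")
  if (k == 1) return(t[1])
  t[k - 1] + (t[k] - t[k - 1]) * (thr - v[k - 1]) / (v[k] - v[k - 1])
}
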