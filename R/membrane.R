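# Membrane dynamics: Hodgkin-Huxley channels, synapse latches, stimuli, and
# the total transmembrane current density. The voltage convention is the
# shifted one (resting potential = 0 mV, depolarization positive); rate
# constants are the classical squid values at 6.3 degrees C.
#
# User-facing membrane units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2. The volume
# solver converts to its internal nA/um^2 scale (1 uA/cm^2 = 1e-5 nA/um^2).

# unit conversions to the internal mV-ms-um-nA system
UNIT <- list(
  sigma = 0.1,    # mS/cm   -> uS/um
  g_mem = 1e-5,   # mS/cm^2 -> uS/um^2
  c_mem = 1e-5,   # uF/cm^2 -> nF/um^2
  j_mem = 1e-5    # uA/cm^2 -> nA/um^2
)

#' Hodgkin-Huxley membrane parameters
#'
#' Classical squid-axon defaults in the shifted voltage convention
#' (rest = 0 mV): peak conductances in mS/cm^2, reversal potentials in mV,
#' specific capacitances in uF/cm^2. `c_m_myelin` is the capacitance used on
#' myelinated patches, which carry only capacitive current.
#'
#' @param g_na,g_k,g_l peak sodium/potassium/leak conductances (mS/cm^2).
#' @param e_na,e_k,e_l reversal potentials (mV, shifted convention).
#' @param e_pas reversal potential of purely passive (leak-only) patches
#'   (mV); 0 keeps passive membrane at rest, the role a `pas` mechanism's
#'   reversal plays in compartment simulators.
#' @param c_m specific membrane capacitance (uF/cm^2).
#' @param c_m_myelin capacitance of myelin sheaths (uF/cm^2).
#' @return object of class `nc_hh`.
#' @export
hh_parameters <- function(g_na = 120, g_k = 36, g_l = 0.3,
                          e_na = 115, e_k = -12, e_l = 10.6, e_pas = 0,
                          c_m = 1, c_m_myelin = 0.04) {
  if (any(c(g_na, g_k, g_l) < 0)) stop("conductances must be >= 0")
  if (c_m <= 0 || c_m_myelin <= 0) stop("capacitances must be positive")
  structure(list(g_na = g_na, g_k = g_k, g_l = g_l, e_na = e_na, e_k = e_k,
                 e_l = e_l, e_pas = e_pas, c_m = c_m, c_m_myelin = c_m_myelin),
            class = "nc_hh")
}

# x/expm1(x) with its removable singularity at x = 0
xexpm1 <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2, x / expm1(x))

#' Hodgkin-Huxley gating rate constants
#'
#' Classical voltage-dependent opening/closing rates (1/ms) of the gating
#' variables n, m, h in the shifted convention, with the removable
#' singularities of alpha_n (at 10 mV) and alpha_m (at 25 mV) evaluated by
#' their analytic limits.
#'
#' @param v_m membrane potential (mV), vectorized.
#' @return list with components `a_n`, `b_n`, `a_m`, `b_m`, `a_h`, `b_h`.
#' @export
gating_rates <- function(v_m) {
  list(a_n = 0.1 * xexpm1((10 - v_m) / 10),
       b_n = 0.125 * exp(-v_m / 80),
       a_m = 1.0 * xexpm1((25 - v_m) / 10),
       b_m = 4 * exp(-v_m / 18),
       a_h = 0.07 * exp(-v_m / 20),
       b_h = 1 / (exp((30 - v_m) / 10) + 1))
}

#' Gating steady states and time constants
#' @param v_m membrane potential (mV), vectorized.
#' @return list of `n`, `m`, `h` steady-state values (and `tau_n` etc., ms).
#' @export
gating_steady_state <- function(v_m) {
  r <- gating_rates(v_m)
  list(n = r$a_n / (r$a_n + r$b_n), m = r$a_m / (r$a_m + r$b_m),
       h = r$a_h / (r$a_h + r$b_h),
       tau_n = 1 / (r$a_n + r$b_n), tau_m = 1 / (r$a_m + r$b_m),
       tau_h = 1 / (r$a_h + r$b_h))
}

#' Hodgkin-Huxley channel current density
#'
#' `m^3 h g_na (v - e_na) + n^4 g_k (v - e_k) + g_l (v - e_l)`; positive is
#' outward.
#'
#' @param v_m membrane potential (mV).
#' @param n,m,h gating variables in \[0, 1\].
#' @param params a [hh_parameters()].
#' @return current density (uA/cm^2).
#' @export
hh_current <- function(v_m, n, m, h, params = hh_parameters()) {
  stopifnot(all(n >= 0 & n <= 1), all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  m^3 * h * params$g_na * (v_m - params$e_na) +
    n^4 * params$g_k * (v_m - params$e_k) +
    params$g_l * (v_m - params$e_l)
}

# channel conductance and channel reversal-weighted term, used by the solver:
# j_hh = g_tot * v - g_e   (affine in v for frozen gating)
hh_affine <- function(n, m, h, params) {
  gna <- m^3 * h * params$g_na
  gk <- n^4 * params$g_k
  g <- gna + gk + params$g_l
  list(g = g, ge = gna * params$e_na + gk * params$e_k + params$g_l * params$e_l)
}

#' Advance the gating variables by one time step
#'
#' One step of `dx/dt = alpha(v)(1-x) - beta(v)x` per gating variable at
#' frozen membrane potential. `implicit` is backward Euler; `rush_larsen` is
#' the exact exponential relaxation towards the steady state. Results are
#' clamped to \[0, 1\].
#'
#' @param gating list with numeric `n`, `m`, `h`.
#' @param v_m membrane potential (mV), scalar or same length.
#' @param dt time step (ms).
#' @param scheme `"implicit"` or `"rush_larsen"`.
#' @return updated gating list.
#' @export
advance_gating <- function(gating, v_m, dt, scheme = c("implicit", "rush_larsen")) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0)
  r <- gating_rates(v_m)
  step1 <- function(x, a, b) {
    if (scheme == "implicit") y <- (x + dt * a) / (1 + dt * (a + b))
    else {
      xinf <- a / (a + b)
      y <- xinf + (x - xinf) * exp(-dt * (a + b))
    }
    pmin(1, pmax(0, y))
  }
  list(n = step1(gating$n, r$a_n, r$b_n),
       m = step1(gating$m, r$a_m, r$b_m),
       h = step1(gating$h, r$a_h, r$b_h))
}

# ---- synapses and stimuli ---------------------------------------------------

#' Chemical synapse specification
#'
#' A latched threshold synapse: when the area-weighted mean membrane
#' potential on the presynaptic patch (`SYNAPSE_PRE` of `pre_cell`) exceeds
#' `threshold`, the latch fires and a predefined postsynaptic current pulse
#' of `amplitude_nA` is injected on the postsynaptic patch (`SYNAPSE_POST` of
#' `post_cell`) for `duration` ms, regardless of the presynaptic potential
#' afterwards.
#'
#' @param pre_cell,post_cell cell ids carrying the pre/post patches; must
#'   differ.
#' @param threshold latch threshold (mV).
#' @param amplitude_nA postsynaptic current amplitude (nA; converted to a
#'   density over the post patch area by the solver). Positive = inward
#'   (depolarizing).
#' @param duration pulse duration (ms).
#' @param shape `"rectangular"` or `"alpha"` (alpha function peaking at
#'   `duration / 3` with peak `amplitude_nA`).
#' @return object of class `nc_synapse`.
#' @export
synapse_spec <- function(pre_cell, post_cell, threshold = 5,
                         amplitude_nA = 1, duration = 2,
                         shape = c("rectangular", "alpha")) {
  shape <- match.arg(shape)
  if (pre_cell == post_cell) stop("pre and post patches must lie on distinct cells")
  if (duration <= 0) stop("duration must be positive")
  structure(list(pre_cell = pre_cell, post_cell = post_cell,
                 threshold = threshold, amplitude_nA = amplitude_nA,
                 duration = duration, shape = shape), class = "nc_synapse")
}

#' Update a synapse latch
#'
#' Sets the latch the first time the presynaptic potential exceeds the
#' threshold; once set it stays set (repeated crossings are idempotent).
#'
#' @param syn a [synapse_spec()].
#' @param state latch state list (`fired`, `t_fire`); use
#'   `list(fired = FALSE, t_fire = NA_real_)` initially.
#' @param v_m_pre presynaptic membrane potential (mV, area-weighted mean over
#'   the pre patch).
#' @param t current time (ms).
#' @return updated state.
#' @export
update_synapse <- function(syn, state, v_m_pre, t) {
  if (!state$fired && v_m_pre > syn$threshold) {
    state$fired <- TRUE
    state$t_fire <- t
  }
  state
}

#' Postsynaptic current of a latched synapse
#'
#' Zero before the latch fires; after firing at `t_fire`, the configured
#' pulse on `(t_fire, t_fire + duration]` and zero afterwards.
#'
#' @param syn a [synapse_spec()].
#' @param state latch state (see [update_synapse()]).
#' @param t time (ms).
#' @return current (nA) injected on the post patch (positive = depolarizing).
#' @export
synaptic_current <- function(syn, state, t) {
  if (!state$fired) return(0)
  s <- t - state$t_fire
  if (s <= 0 || s > syn$duration) return(0)
  if (syn$shape == "rectangular") syn$amplitude_nA
  else {
    tau <- syn$duration / 3
    syn$amplitude_nA * (s / tau) * exp(1 - s / tau)
  }
}

#' Stimulus specification
#'
#' A rectangular current pulse injected on the `STIMULUS` patch of a cell
#' between `t_on` and `t_off`. The amplitude is a total current in nA,
#' converted to a density over the patch area by the solver. Positive =
#' inward (depolarizing).
#'
#' @param cell cell id whose `STIMULUS` patch receives the current.
#' @param amplitude_nA pulse amplitude (nA).
#' @param t_on,t_off pulse window (ms), `t_off > t_on`.
#' @return object of class `nc_stimulus`.
#' @export
stimulus_spec <- function(cell = 1, amplitude_nA, t_on = 0, t_off = Inf) {
  if (!(t_off > t_on)) stop("t_off must exceed t_on")
  structure(list(cell = cell, amplitude_nA = amplitude_nA,
                 t_on = t_on, t_off = t_off), class = "nc_stimulus")
}

stimulus_current <- function(stim, t) {
  if (t > stim$t_on && t <= stim$t_off) stim$amplitude_nA else 0
}

# ---- membrane model ---------------------------------------------------------

# dynamics class per patch label; STIMULUS and SYNAPSE_PRE sit on otherwise
# ordinary membrane, so they default to active Hodgkin-Huxley dynamics,
# SYNAPSE_POST sits on the (passive) dendrite
DEFAULT_PATCH_DYNAMICS <- c(ACTIVE = "hh", STIMULUS = "hh", SYNAPSE_PRE = "hh",
                            DENDRITE = "passive", SYNAPSE_POST = "passive",
                            MYELIN = "capacitive")

#' Membrane model: parameters, patch dynamics, stimuli and synapses
#'
#' Bundles everything defining the total transmembrane current density:
#' Hodgkin-Huxley parameters, the dynamics class of each membrane patch label
#' (`"hh"`, `"passive"` = capacitive + leak, `"capacitive"` = capacitive
#' only, using the myelin capacitance), plus stimulus and synapse
#' specifications.
#'
#' @param params a [hh_parameters()].
#' @param patch_dynamics named character vector mapping patch labels to
#'   dynamics classes; defaults give active soma/nodes, passive dendrites and
#'   purely capacitive myelin.
#' @param stimuli list of [stimulus_spec()].
#' @param synapses list of [synapse_spec()].
#' @return object of class `nc_membrane`.
#' @export
membrane_model <- function(params = hh_parameters(),
                           patch_dynamics = DEFAULT_PATCH_DYNAMICS,
                           stimuli = list(), synapses = list()) {
  pd <- DEFAULT_PATCH_DYNAMICS
  pd[names(patch_dynamics)] <- patch_dynamics
  if (!all(pd %in% c("hh", "passive", "capacitive")))
    stop("patch dynamics must be 'hh', 'passive' or 'capacitive'")
  if (inherits(stimuli, "nc_stimulus")) stimuli <- list(stimuli)
  if (inherits(synapses, "nc_synapse")) synapses <- list(synapses)
  structure(list(params = params, patch_dynamics = pd, stimuli = stimuli,
                 synapses = synapses), class = "nc_membrane")
}

#' Total transmembrane current density on one patch
#'
#' Evaluates `j_all = c dV/dt + [active] j_HH + [stimulus] j_stm +
#' [synapse] j_syn` for a given patch label: active patches carry the full
#' channel current, passive patches only the leak, myelin only the capacitive
#' term (with the myelin capacitance).
#'
#' @param patch_label one of the membrane patch labels.
#' @param v_m membrane potential (mV).
#' @param dvdt time derivative of `v_m` (mV/ms).
#' @param gating list of gating values `n`, `m`, `h`.
#' @param model a [membrane_model()].
#' @param stim_density stimulus current density to add on a `STIMULUS` patch
#'   (uA/cm^2, positive outward).
#' @param syn_density synaptic current density to add on a `SYNAPSE_POST`
#'   patch (uA/cm^2, positive outward).
#' @return current density (uA/cm^2, positive outward).
#' @export
total_current_density <- function(patch_label, v_m, dvdt, gating, model,
                                  stim_density = 0, syn_density = 0) {
  dyn <- unname(model$patch_dynamics[patch_label])
  if (anyNA(dyn)) stop("unknown membrane patch label: ", patch_label)
  p <- model$params
  cm <- ifelse(dyn == "capacitive", p$c_m_myelin, p$c_m)
  j <- cm * dvdt
  j <- j + ifelse(dyn == "hh",
                  hh_current(v_m, gating$n, gating$m, gating$h, p),
                  ifelse(dyn == "passive", p$g_l * (v_m - p$e_pas), 0))
  unname(j + ifelse(patch_label == "STIMULUS", stim_density, 0) +
           ifelse(patch_label == "SYNAPSE_POST", syn_density, 0))
}
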