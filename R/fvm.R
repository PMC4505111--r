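# Vertex-centered finite-volume core: assembly and implicit solution of the
# coupled system
#   -div(sigma_out grad phi_out) = 0        in the extracellular space,
#   -lap(phi_out_in)             = 0        in the cell (extension field),
#    phi_out_in = phi_out                   on the membrane,
#   -div(sigma_in grad v_m)      = 0        in the cell,
# with the membrane Neumann fluxes
#   -sigma_out grad(phi_out) . n = j_all(v_m),
#   -sigma_in  grad(v_m)     . n = j_all(v_m) + j_eph,
#   j_eph = sigma_in grad(phi_out_in) . n,
# discretized on the barycentric dual grid, backward Euler in time, Newton
# per step. Internal units: mV, ms, um, nA (conductivities converted from
# mS/cm, membrane densities from uA/cm^2).

#' Assemble a finite-volume stiffness operator
#'
#' Builds the sparse operator of the negative divergence of `sigma` times the
#' gradient, restricted to one subdomain: row k holds
#' `-sigma * a_kj` with `a_kj = int_{dB_k} grad b_j . n dS`, evaluated
#' analytically (piecewise-linear shape functions have constant gradients per
#' tetrahedron, so each dual sub-face contributes gradient times integrated
#' normal). Interior row sums vanish (constants lie in the kernel).
#'
#' @param mesh a [nc_mesh()].
#' @param dual a [build_dual_grid()] result (accepted for interface
#'   completeness; the per-tet sub-face normals are recomputed internally).
#' @param sigma conductivity (mS/cm).
#' @param subdomain `"INTRA"` or `"EXTRA"`.
#' @return list with `L` (sparse dgCMatrix over the subdomain's vertices) and
#'   `dof` (the global vertex index of each row/column).
#' @export
assemble_stiffness <- function(mesh, dual = NULL, sigma, subdomain) {
  sel <- mesh$subdomain == subdomain
  if (!any(sel)) stop("subdomain ", subdomain, " contains no tetrahedra")
  tets <- mesh$tets[sel, , drop = FALSE]
  sig <- sigma * UNIT$sigma
  nrm <- tet_dual_normals(mesh$vertices, tets)
  grd <- tet_shape_gradients(mesh$vertices, tets)
  dof <- sort(unique(as.vector(tets)))
  loc <- match(tets, dof)
  dim(loc) <- dim(tets)
  nt <- nrow(tets)

  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ii <- jj <- vector("list", 48); xx <- vector("list", 48)
  b <- 0L
  for (e in 1:6) {
    i <- edges[e, 1]; j <- edges[e, 2]
    Ne <- nrm[, e, , drop = FALSE]; dim(Ne) <- c(nt, 3)
    for (l in 1:4) {
      gl <- grd[, l, , drop = FALSE]; dim(gl) <- c(nt, 3)
      flux <- rowSums(Ne * gl)  # int over subface of grad b_l . n_(i->j)
      ii[[b + 1L]] <- loc[, i]; jj[[b + 1L]] <- loc[, l]; xx[[b + 1L]] <- -sig * flux
      ii[[b + 2L]] <- loc[, j]; jj[[b + 2L]] <- loc[, l]; xx[[b + 2L]] <- sig * flux
      b <- b + 2L
    }
  }
  L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(dof), length(dof)))
  list(L = L, dof = dof)
}

#' Solver configuration
#'
#' @param dt time step (ms).
#' @param t_end end time (ms).
#' @param sigma_in,sigma_out intra-/extracellular conductivities (mS/cm).
#' @param newton_abs_tol,newton_rel_tol Newton termination on the residual
#'   1-norm (nA scale). The 1-norm bounds every signed sum of residual
#'   entries, so a converged step satisfies the global flux balance to
#'   `newton_abs_tol`.
#' @param newton_max_iter maximum Newton iterations per step.
#' @param jacobian `"each_step"` refactors the Jacobian every step;
#'   `"frozen"` reuses one factorization as a chord iteration (the true
#'   residual still decides convergence; refactoring is triggered on slow
#'   progress).
#' @param gating `"staggered"` advances the gating once per step at the
#'   previous potential; `"nested"` re-advances it inside each Newton
#'   iteration at the current iterate (fully implicit coupling).
#' @param boundary far-boundary condition of the extracellular problem:
#'   `"grounded"` (phi_out = 0 on the outer boundary) or `"insulated"`
#'   (zero Neumann with a one-point gauge pin).
#' @param ephaptic logical: include the ephaptic current in the
#'   membrane-potential boundary condition.
#' @param linear_solver `"direct"` (one sparse LU of the monolithic
#'   Jacobian) or `"segregated"` (block Gauss-Seidel over the three fields
#'   with sparse Cholesky factorizations; much lighter on refined meshes).
#' @param record_every record traces every this many steps.
#' @return object of class `nc_solver_config`.
#' @export
solver_config <- function(dt = 0.01, t_end = 1, sigma_in = 2, sigma_out = 20,
                          newton_abs_tol = 1e-6, newton_rel_tol = 1e-10,
                          newton_max_iter = 25,
                          jacobian = c("each_step", "frozen"),
                          gating = c("staggered", "nested"),
                          boundary = c("grounded", "insulated"),
                          ephaptic = TRUE,
                          linear_solver = c("direct", "segregated"),
                          record_every = 1L) {
  stopifnot(dt > 0, t_end > 0, newton_abs_tol > 0, newton_rel_tol > 0)
  structure(list(dt = dt, t_end = t_end, sigma_in = sigma_in,
                 sigma_out = sigma_out, newton_abs_tol = newton_abs_tol,
                 newton_rel_tol = newton_rel_tol,
                 newton_max_iter = newton_max_iter,
                 jacobian = match.arg(jacobian), gating = match.arg(gating),
                 boundary = match.arg(boundary), ephaptic = ephaptic,
                 linear_solver = match.arg(linear_solver),
                 record_every = as.integer(record_every)),
            class = "nc_solver_config")
}

#' Set up the coupled finite-volume system
#'
#' Precomputes dof maps, stiffness operators, membrane-vertex quadrature
#' weights and stimulus/synapse patch weights for a mesh and membrane model.
#'
#' @param mesh a [nc_mesh()].
#' @param model a [membrane_model()].
#' @param config a [solver_config()].
#' @return object of class `nc_system`.
#' @export
fvm_system <- function(mesh, model, config = solver_config()) {
  dual <- build_dual_grid(mesh, subfaces = FALSE)
  Ain <- assemble_stiffness(mesh, dual, config$sigma_in, "INTRA")
  Aex <- assemble_stiffness(mesh, dual, config$sigma_out, "EXTRA")
  n_i <- length(Ain$dof); n_e <- length(Aex$dof)

  mem <- dual$membrane
  mv <- sort(unique(mem$vertex))
  n_m <- length(mv)
  mem$mvi <- match(mem$vertex, mv)
  mem_intra <- match(mv, Ain$dof)   # membrane vertices in intra dof numbering
  mem_extra <- match(mv, Aex$dof)
  if (anyNA(mem_intra) || anyNA(mem_extra))
    stop("membrane vertex missing from a subdomain dof set")

  # Dirichlet (grounded) outer boundary dofs of the extracellular problem
  outer <- intersect(mesh$outer_vertices, Aex$dof)
  if (config$boundary == "grounded") {
    fixed <- match(outer, Aex$dof)
  } else {
    # gauge pin: one outer vertex
    fixed <- match(outer[1], Aex$dof)
  }
  free <- setdiff(seq_len(n_e), fixed)
  mem_extra_free <- match(mem_extra, free)
  if (anyNA(mem_extra_free)) stop("membrane vertex on the outer boundary")

  dyn <- model$patch_dynamics[mem$patch]
  p <- model$params
  # constant per-(vertex,patch)-row coefficients, internal units
  c_row <- ifelse(dyn == "capacitive", p$c_m_myelin, p$c_m) * UNIT$c_mem * mem$area
  Ca <- tapply2(mem$mvi, c_row, n_m)                     # nF per vertex
  hh_row <- dyn == "hh"
  pas_row <- dyn == "passive"
  gl_int <- p$g_l * UNIT$g_mem
  Gpas <- tapply2(mem$mvi[pas_row], gl_int * mem$area[pas_row], n_m)
  Gepas <- Gpas * p$e_pas
  A_hh <- tapply2(mem$mvi[hh_row], mem$area[hh_row], n_m)  # active area per vtx

  # stimulus and synapse weight vectors over membrane vertices
  wpatch <- function(patch, cell) {
    rows <- mem$patch == patch & mem$cell == cell
    if (!any(rows)) stop("no ", patch, " patch on cell ", cell)
    w <- tapply2(mem$mvi[rows], mem$area[rows], n_m)
    w / sum(w)
  }
  stim_w <- lapply(model$stimuli, function(s) wpatch("STIMULUS", s$cell))
  syn_wpost <- lapply(model$synapses, function(s) wpatch("SYNAPSE_POST", s$post_cell))
  syn_wpre <- lapply(model$synapses, function(s) wpatch("SYNAPSE_PRE", s$pre_cell))

  # membrane row selectors on the intra dof set
  D_mem <- Matrix::sparseMatrix(i = mem_intra, j = mem_intra, x = 1,
                                dims = c(n_i, n_i))
  I_int <- Matrix::Diagonal(n_i) - D_mem
  Lin_mod <- I_int %*% Ain$L + D_mem          # extension rows: Dirichlet on membrane
  Lin_mem <- D_mem %*% Ain$L                  # membrane rows of L_in (flux recovery)

  cells <- sort(unique(mem$cell))
  cell_of_mv <- integer(n_m)
  cell_of_mv[mem$mvi] <- mem$cell

  structure(list(mesh = mesh, model = model, config = config, dual = dual,
                 Lin = Ain$L, Lex = Aex$L, intra_dof = Ain$dof,
                 extra_dof = Aex$dof, free = free, fixed = fixed,
                 mv = mv, mem = mem, mem_intra = mem_intra,
                 mem_extra = mem_extra, mem_extra_free = mem_extra_free,
                 Ca = Ca, Gpas = Gpas, Gepas = Gepas, A_hh = A_hh,
                 A_mem = tapply2(mem$mvi, mem$area, n_m),
                 stim_w = stim_w, syn_wpost = syn_wpost, syn_wpre = syn_wpre,
                 Lin_mod = Lin_mod, Lin_mem = Lin_mem,
                 cells = cells, cell_of_mv = cell_of_mv,
                 n_i = n_i, n_e = n_e, n_f = length(free), n_m = n_m,
                 env = new.env(parent = emptyenv())),
            class = "nc_system")
}

#' Initial system state
#'
#' Rest: all potentials zero, gating at its resting steady state, synapse
#' latches unset.
#'
#' @param sys a [fvm_system()].
#' @return object of class `nc_state` with nodal coefficients `phi_out`
#'   (extracellular potential, mV, over extracellular dofs), `phi_ext`
#'   (intracellular extension of the extracellular potential), `v_m`
#'   (membrane potential extended into the cell), gating variables on
#'   membrane vertices, synapse latch states and time `t` (ms).
#' @export
initial_state <- function(sys) {
  g0 <- gating_steady_state(0)
  structure(list(
    phi_out = numeric(sys$n_e),
    phi_ext = numeric(sys$n_i),
    v_m = numeric(sys$n_i),
    gating = list(n = rep(g0$n, sys$n_m), m = rep(g0$m, sys$n_m),
                  h = rep(g0$h, sys$n_m)),
    syn_states = lapply(sys$model$synapses,
                        function(s) list(fired = FALSE, t_fire = NA_real_)),
    t = 0, newton_iters = NA_integer_, flux_balance = NULL,
    j_all_vertex = NULL), class = "nc_state")
}

# per-vertex affine membrane current F(v) = Ca (v - v_prev)/dt + Ga v - Ge + Jx
# (nA, outward positive); returns also dF/dv
membrane_current_terms <- function(sys, gating, t, syn_states) {
  p <- sys$model$params
  aff <- hh_affine(gating$n, gating$m, gating$h, p)
  Ga <- sys$Gpas + sys$A_hh * aff$g * UNIT$g_mem
  Ge <- sys$Gepas + sys$A_hh * aff$ge * UNIT$g_mem
  Jx <- numeric(sys$n_m)
  for (s in seq_along(sys$model$stimuli)) {
    amp <- stimulus_current(sys$model$stimuli[[s]], t)
    if (amp != 0) Jx <- Jx - amp * sys$stim_w[[s]]  # inward = negative outward
  }
  for (s in seq_along(sys$model$synapses)) {
    cur <- synaptic_current(sys$model$synapses[[s]], syn_states[[s]], t)
    if (cur != 0) Jx <- Jx - cur * sys$syn_wpost[[s]]
  }
  list(Ga = Ga, Ge = Ge, Jx = Jx)
}

# residual of the coupled system at the new time level
fvm_residual_blocks <- function(sys, phi_f, phi_ext, v, v_prev_m, dt, terms) {
  vm <- v[sys$mem_intra]
  F_ <- sys$Ca * (vm - v_prev_m) / dt + terms$Ga * vm - terms$Ge + terms$Jx
  phi_full <- numeric(sys$n_e)
  phi_full[sys$free] <- phi_f

  r1 <- (sys$Lex %*% phi_full)[sys$free]
  r1[sys$mem_extra_free] <- r1[sys$mem_extra_free] - F_

  r2 <- as.numeric(sys$Lin_mod %*% phi_ext)
  r2[sys$mem_intra] <- phi_ext[sys$mem_intra] - phi_full[sys$mem_extra]

  r3 <- as.numeric(sys$Lin %*% v)
  eph <- if (sys$config$ephaptic)
    as.numeric(sys$Lin_mem %*% phi_ext)[sys$mem_intra] else 0
  r3[sys$mem_intra] <- r3[sys$mem_intra] + F_ + eph

  list(r = c(as.numeric(r1), r2, r3), F_ = F_)
}

# Linear solver for the Newton correction J dx = -r.
#
# "direct": one sparse LU of the monolithic Jacobian.
#
# "segregated": block Gauss-Seidel sweep in the order (v, phi_out, phi_ext)
# using sparse Cholesky factorizations of the three SPD field blocks (the
# box-scheme stiffness is symmetric); the only coupling dropped from the
# sweep is the (small) ephaptic block, which the outer chord iteration picks
# up through the true residual. Far cheaper in memory and time on refined
# meshes than the monolithic LU.
make_linear_solver <- function(sys, dFdv) {
  if (sys$config$linear_solver == "direct") {
    f <- Matrix::lu(fvm_jacobian(sys, dFdv))
    return(list(solve = function(r) {
      dx <- as.numeric(Matrix::solve(f, -r))
      list(dphi = dx[seq_len(sys$n_f)],
           dext = dx[sys$n_f + seq_len(sys$n_i)],
           dv = dx[sys$n_f + sys$n_i + seq_len(sys$n_i)])
    }))
  }
  n_f <- sys$n_f; n_i <- sys$n_i
  sym <- function(A) Matrix::forceSymmetric(A)
  A33 <- sym(sys$Lin + Matrix::sparseMatrix(i = sys$mem_intra,
                                            j = sys$mem_intra, x = dFdv,
                                            dims = c(n_i, n_i)))
  ch33 <- Matrix::Cholesky(A33, LDL = FALSE)
  if (is.null(sys$env$ch11)) {
    sys$env$ch11 <- Matrix::Cholesky(sym(sys$Lex[sys$free, sys$free]),
                                     LDL = FALSE)
    int <- setdiff(seq_len(n_i), sys$mem_intra)
    sys$env$int <- int
    sys$env$Lin_im <- sys$Lin[int, sys$mem_intra, drop = FALSE]
    sys$env$ch22 <- Matrix::Cholesky(sym(sys$Lin[int, int]), LDL = FALSE)
  }
  env <- sys$env
  list(solve = function(r) {
    r1 <- r[seq_len(n_f)]
    r2 <- r[n_f + seq_len(n_i)]
    r3 <- r[n_f + n_i + seq_len(n_i)]
    dv <- as.numeric(Matrix::solve(ch33, -r3, system = "A"))
    b1 <- -r1
    b1[sys$mem_extra_free] <- b1[sys$mem_extra_free] + dFdv * dv[sys$mem_intra]
    dphi <- as.numeric(Matrix::solve(env$ch11, b1, system = "A"))
    b2 <- -r2
    dext <- numeric(n_i)
    dext[sys$mem_intra] <- b2[sys$mem_intra] + dphi[sys$mem_extra_free]
    rhs2 <- b2[env$int] - as.numeric(env$Lin_im %*% dext[sys$mem_intra])
    dext[env$int] <- as.numeric(Matrix::solve(env$ch22, rhs2, system = "A"))
    list(dphi = dphi, dext = dext, dv = dv)
  })
}

fvm_jacobian <- function(sys, dFdv) {
  n_f <- sys$n_f; n_i <- sys$n_i
  n <- n_f + 2L * n_i
  trip <- function(A, ro, co) {
    A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
    list(i = A@i + 1L + ro, j = A@j + 1L + co, x = A@x)
  }
  blocks <- list(
    trip(sys$Lex[sys$free, sys$free], 0L, 0L),
    list(i = sys$mem_extra_free, j = n_f + n_i + sys$mem_intra, x = -dFdv),
    list(i = n_f + sys$mem_intra, j = sys$mem_extra_free, x = rep(-1, sys$n_m)),
    trip(sys$Lin_mod, n_f, n_f),
    trip(sys$Lin, n_f + n_i, n_f + n_i),
    list(i = n_f + n_i + sys$mem_intra, j = n_f + n_i + sys$mem_intra, x = dFdv)
  )
  if (sys$config$ephaptic)
    blocks <- c(blocks, list(trip(sys$Lin_mem, n_f + n_i, n_f)))
  Matrix::sparseMatrix(i = unlist(lapply(blocks, `[[`, "i")),
                       j = unlist(lapply(blocks, `[[`, "j")),
                       x = unlist(lapply(blocks, `[[`, "x")),
                       dims = c(n, n))
}

#' One implicit time step (Newton iteration)
#'
#' Advances the coupled system by one backward-Euler step of size `dt`,
#' solving the nonlinear algebraic system with Newton's method (the inner
#' sparse linear systems by a direct sparse LU). With staggered gating the
#' per-step system is affine and converges in one iteration; nested gating
#' re-evaluates the gating variables at every iterate.
#'
#' @param sys a [fvm_system()].
#' @param state previous [initial_state()]-shaped state.
#' @param dt time step (ms); defaults to the configured one.
#' @param factor an optional reusable Jacobian factorization (chord mode),
#'   as returned in the `factor` attribute of a previous call.
#' @return the new state; `newton_iters`, `flux_balance` (nA, per cell) and
#'   `j_all_vertex` (nA/um^2 per membrane vertex) are filled in, and the
#'   factorization used is attached as attribute `factor`.
#' @export
newton_step <- function(sys, state, dt = sys$config$dt, factor = NULL) {
  cfg <- sys$config
  v_prev_m <- state$v_m[sys$mem_intra]
  t_new <- state$t + dt

  # latch synapses on the previous step's presynaptic potential
  syn_states <- state$syn_states
  for (s in seq_along(sys$model$synapses)) {
    v_pre <- sum(sys$syn_wpre[[s]] * v_prev_m)
    syn_states[[s]] <- update_synapse(sys$model$synapses[[s]], syn_states[[s]],
                                      v_pre, t_new)
  }

  gating <- advance_gating(state$gating, v_prev_m, dt, scheme = "implicit")
  terms <- membrane_current_terms(sys, gating, t_new, syn_states)
  dFdv <- sys$Ca / dt + terms$Ga

  phi_f <- state$phi_out[sys$free]
  phi_ext <- state$phi_ext
  v <- state$v_m

  rb <- fvm_residual_blocks(sys, phi_f, phi_ext, v, v_prev_m, dt, terms)
  r0 <- sum(abs(rb$r))
  tol <- max(cfg$newton_abs_tol, cfg$newton_rel_tol * r0)
  it <- 0L
  r_last <- r0
  while (sum(abs(rb$r)) > tol || it == 0L) {
    if (it >= cfg$newton_max_iter)
      stop("Newton did not converge in ", cfg$newton_max_iter,
           " iterations (residual ", format(sum(abs(rb$r))),
           "); consider a smaller dt")
    if (is.null(factor)) factor <- make_linear_solver(sys, dFdv)
    dx <- factor$solve(rb$r)
    phi_f <- phi_f + dx$dphi
    phi_ext <- phi_ext + dx$dext
    v <- v + dx$dv
    if (cfg$gating == "nested") {
      gating <- advance_gating(state$gating, v[sys$mem_intra], dt,
                               scheme = "implicit")
      terms <- membrane_current_terms(sys, gating, t_new, syn_states)
    }
    rb <- fvm_residual_blocks(sys, phi_f, phi_ext, v, v_prev_m, dt, terms)
    it <- it + 1L
    rn <- sum(abs(rb$r))
    if (rn > tol && rn > 0.5 * r_last) {
      factor <- NULL  # stalling: rebuild the factorization at current gating
    }
    r_last <- rn
  }

  if (cfg$gating == "staggered")
    gating <- advance_gating(state$gating, v[sys$mem_intra], dt,
                             scheme = "implicit")

  phi_full <- numeric(sys$n_e)
  phi_full[sys$free] <- phi_f
  state$phi_out <- phi_full
  state$phi_ext <- phi_ext
  state$v_m <- v
  state$gating <- gating
  state$syn_states <- syn_states
  state$t <- t_new
  state$newton_iters <- it
  state$j_all_vertex <- rb$F_ / sys$A_mem
  state$flux_balance <- vapply(sys$cells, function(cl)
    sum(rb$F_[sys$cell_of_mv == cl]), numeric(1))
  names(state$flux_balance) <- paste0("cell_", sys$cells)
  attr(state, "factor") <- factor
  state
}

#' Total transmembrane current of one cell
#'
#' Area-weighted sum of the total membrane current density over all membrane
#' vertices of a cell at a converged state; vanishes (to solver tolerance)
#' because the intracellular potential problem is a pure Neumann Laplace
#' problem.
#'
#' @param sys a [fvm_system()].
#' @param state a converged [newton_step()] state.
#' @param cell cell id (default: first cell).
#' @return total flux (nA).
#' @export
total_membrane_flux <- function(sys, state, cell = sys$cells[1]) {
  if (is.null(state$flux_balance)) stop("state carries no converged step")
  unname(state$flux_balance[paste0("cell_", cell)])
}

#' Ephaptic membrane current
#'
#' The finite-volume boundary flux of the extension field through the
#' membrane piece of each membrane vertex's control volume, scaled by the
#' intracellular conductivity: the extra current entering the
#' membrane-potential equation when the extracellular potential feeds back
#' on the cell.
#'
#' @param sys a [fvm_system()].
#' @param state a system state.
#' @return per-membrane-vertex current (nA), ordered like `sys$mv`.
#' @export
ephaptic_flux <- function(sys, state) {
  as.numeric(sys$Lin_mem %*% state$phi_ext)[sys$mem_intra]
}

#' Run a simulation
#'
#' Advances the system from rest (or `state0`) to `t_end` in steps of `dt`,
#' recording the membrane potential and extracellular potential at the
#' mesh's marker vertices at every `record_every`-th step.
#'
#' @param mesh a [nc_mesh()] with markers.
#' @param model a [membrane_model()].
#' @param config a [solver_config()].
#' @param state0 optional initial state.
#' @param probes named integer vector of probe vertex ids; defaults to the
#'   mesh markers.
#' @param progress logical; print per-step diagnostics.
#' @param on_step optional callback `f(state, step_index, sys)` invoked after
#'   every converged step (e.g. to write field snapshots).
#' @return list with `time` (ms), `v_m` and `phi_out` (matrices, one column
#'   per probe; `NA` where the probe vertex does not carry the field),
#'   `flux_balance` (matrix, per cell), `newton_iters`, and the final
#'   `state` and `system`.
#' @export
run_simulation <- function(mesh, model, config, state0 = NULL,
                           probes = mesh$markers, progress = FALSE,
                           on_step = NULL) {
  sys <- fvm_system(mesh, model, config)
  state <- if (is.null(state0)) initial_state(sys) else state0
  n_steps <- round(config$t_end / config$dt)
  rec_steps <- seq_len(n_steps)[seq_len(n_steps) %% config$record_every == 0]
  pin <- match(probes, sys$intra_dof)
  pex <- match(probes, sys$extra_dof)

  tm <- numeric(length(rec_steps))
  vm <- matrix(NA_real_, length(rec_steps), length(probes),
               dimnames = list(NULL, names(probes)))
  po <- vm
  fb <- matrix(NA_real_, length(rec_steps), length(sys$cells))
  colnames(fb) <- paste0("cell_", sys$cells)
  ni <- integer(length(rec_steps))

  factor <- NULL
  ri <- 0L
  for (k in seq_len(n_steps)) {
    state <- newton_step(sys, state, config$dt, factor = factor)
    factor <- if (config$jacobian == "frozen") attr(state, "factor") else NULL
    if (k %in% rec_steps) {
      ri <- ri + 1L
      tm[ri] <- state$t
      vm[ri, !is.na(pin)] <- state$v_m[pin[!is.na(pin)]]
      po[ri, !is.na(pex)] <- state$phi_out[pex[!is.na(pex)]]
      fb[ri, ] <- state$flux_balance
      ni[ri] <- state$newton_iters
    }
    if (!is.null(on_step)) on_step(state, k, sys)
    if (progress && k %% 50L == 0L)
      message(sprintf("t = %.3f ms  |flux| = %.2e nA  newton = %d",
                      state$t, max(abs(state$flux_balance)), state$newton_iters))
  }
  list(time = tm, v_m = vm, phi_out = po, flux_balance = fb,
       newton_iters = ni, state = state, system = sys)
}

#' Number of time steps of a configuration
#'
#' Dry-run step counter: the number of backward-Euler steps
#' `round(t_end / dt)` a simulation with this configuration executes.
#'
#' @param config a [solver_config()].
#' @return integer step count.
#' @export
count_steps <- function(config) as.integer(round(config$t_end / config$dt))
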