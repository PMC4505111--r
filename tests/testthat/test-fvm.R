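test_that("box-scheme stiffness matches the P1 finite-element oracle", {
  mesh <- small_sphere()
  As <- assemble_stiffness(mesh, NULL, sigma = 2, subdomain = "INTRA")
  # independent oracle: element-wise FEM stiffness V * grad(b_k) . grad(b_j)
  sel <- mesh$subdomain == "INTRA"
  tets <- mesh$tets[sel, ]
  v <- mesh$vertices
  a <- v[tets[, 1], ]
  e1 <- v[tets[, 2], ] - a; e2 <- v[tets[, 3], ] - a; e3 <- v[tets[, 4], ] - a
  cr <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                             u[, 3] * w[, 1] - u[, 1] * w[, 3],
                             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  c1 <- cr(e2, e3); det <- rowSums(e1 * c1)
  g <- array(0, c(nrow(tets), 4, 3))
  g[, 2, ] <- c1 / det; g[, 3, ] <- cr(e3, e1) / det; g[, 4, ] <- cr(e1, e2) / det
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  vol <- abs(det) / 6
  loc <- match(tets, As$dof); dim(loc) <- dim(tets)
  K <- matrix(0, length(As$dof), length(As$dof))
  for (i in 1:4) for (j in 1:4) {
    val <- 0.2 * vol * rowSums(g[, i, ] * g[, j, ])  # sigma = 2 mS/cm = 0.2 uS/um
    for (tt in seq_along(val))
      K[loc[tt, i], loc[tt, j]] <- K[loc[tt, i], loc[tt, j]] + val[tt]
  }
  expect_lt(max(abs(as.matrix(As$L) - K)) / max(abs(K)), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(As$L))), 1e-12 * max(abs(As$L)))
})

test_that("linear potential fields pass the patch test exactly", {
  # Dirichlet data phi = x on the boundary of a box reproduces phi = x at
  # every interior node
  g <- neurocable3d:::cartesian_tet_grid(4, 3, 3, 0.7, c(-1, 0, 0.3))
  mesh <- nc_mesh(g$vertices, g$tets, rep("EXTRA", nrow(g$tets)))
  As <- assemble_stiffness(mesh, NULL, sigma = 3, subdomain = "EXTRA")
  bnd <- match(mesh$outer_vertices, As$dof)
  int <- setdiff(seq_along(As$dof), bnd)
  phi_exact <- mesh$vertices[As$dof, 1]
  rhs <- -as.numeric(As$L[int, bnd] %*% phi_exact[bnd])
  phi_int <- as.numeric(Matrix::solve(As$L[int, int], rhs))
  expect_equal(phi_int, phi_exact[int], tolerance = 1e-10)
})

test_that("harmonic spherical-harmonic fields converge at second order", {
  # exterior harmonic Y_10 * r^-2 on a spherical shell, Dirichlet at both
  # boundaries, nodal error must drop ~4x per refinement of the angular and
  # radial resolution
  err <- numeric(2)
  for (lev in 1:2) {
    mesh <- build_sphere_domain(10, 30, subdiv = lev,
                                n_layers_in = 2, n_layers_out = 3 * lev)
    As <- assemble_stiffness(mesh, NULL, sigma = 1, subdomain = "EXTRA")
    x <- mesh$vertices[As$dof, ]
    r <- sqrt(rowSums(x^2))
    exact <- x[, 3] / r / r^2  # ~ Y_10(theta) r^-2 up to normalization
    mem <- match(sort(unique(as.vector(mesh$membrane_tris))), As$dof)
    out <- match(intersect(mesh$outer_vertices, As$dof), As$dof)
    bnd <- union(mem, out)
    int <- setdiff(seq_along(As$dof), bnd)
    rhs <- -as.numeric(As$L[int, bnd] %*% exact[bnd])
    num <- as.numeric(Matrix::solve(As$L[int, int], rhs))
    err[lev] <- sqrt(mean((num - exact[int])^2)) / max(abs(exact))
  }
  expect_gt(err[1] / err[2], 2.5)  # O(h^2): ideally 4
})

test_that("rest is stationary when all reversal potentials vanish", {
  mesh <- small_sphere()
  model <- membrane_model(hh_parameters(g_l = 0, e_na = 0, e_k = 0, e_l = 0))
  sys <- fvm_system(mesh, model, solver_config(dt = 0.01, t_end = 0.1))
  st <- initial_state(sys)
  st1 <- newton_step(sys, st)
  expect_equal(st1$newton_iters, 1L)
  expect_lt(max(abs(st1$v_m)), 1e-12)
  expect_lt(max(abs(st1$phi_out)), 1e-12)
  expect_equal(unname(st1$flux_balance), 0, tolerance = 1e-14)
})

test_that("converged steps balance the membrane flux and couple the fields", {
  out <- small_sphere_run()
  sys <- out$system
  st <- out$state
  # global flux balance at every recorded step (pure Neumann intracellular
  # problem), within the Newton tolerance (residual 1-norm)
  expect_lt(max(abs(out$flux_balance)), out$system$config$newton_abs_tol)
  expect_equal(total_membrane_flux(sys, st), unname(st$flux_balance[1]))
  # Dirichlet coupling phi_out_in = phi_out on the membrane
  expect_lt(max(abs(st$phi_ext[sys$mem_intra] - st$phi_out[sys$mem_extra])),
            1e-12)
  # something actually happened
  expect_gt(max(out$v_m), 50)
  # in/outflux split is large while the net vanishes
  F_ <- st$j_all_vertex * sys$A_mem
  expect_gt(sum(pmax(F_, 0)), 1e3 * abs(sum(F_)))
})

test_that("membrane current density recomputes from the membrane module", {
  # dual route: the solver's per-vertex current density against an
  # independent evaluation of the patch-wise density from the state fields
  out <- small_sphere_run()
  sys <- out$system
  st <- out$state
  dt <- sys$config$dt
  # rebuild v at the previous step from the recorded trace is not available;
  # instead take one more step and compare against total_current_density
  st2 <- newton_step(sys, st)
  vm2 <- st2$v_m[sys$mem_intra]
  vm1 <- st$v_m[sys$mem_intra]
  dvdt <- (vm2 - vm1) / dt
  # staggered scheme: the step's currents use the gating advanced at the
  # previous potential
  g2 <- advance_gating(st$gating, vm1, dt, scheme = "implicit")
  mem <- sys$mem
  stim <- sys$model$stimuli[[1]]
  amp <- neurocable3d:::stimulus_current(stim, st2$t)
  j_oracle <- numeric(sys$n_m)
  for (k in seq_len(sys$n_m)) {
    gk <- list(n = g2$n[k], m = g2$m[k], h = g2$h[k])
    rows <- which(mem$mvi == k)
    jk <- sum(vapply(rows, function(r)
      mem$area[r] * neurocable3d:::UNIT$j_mem *
        total_current_density(mem$patch[r], vm2[k], dvdt[k], gk, sys$model),
      numeric(1)))
    jk <- jk - amp * sys$stim_w[[1]][k]  # inward stimulus current (nA)
    j_oracle[k] <- jk / sys$A_mem[k]
  }
  expect_equal(st2$j_all_vertex, j_oracle, tolerance = 1e-10)
})

test_that("ephaptic flux vanishes for constant fields and is exact for linear ones", {
  mesh <- build_cylinder_domain(200, 40, 60, resolution = 12)
  model <- membrane_model()
  sys <- fvm_system(mesh, model, solver_config())
  st <- initial_state(sys)
  st$phi_ext <- rep(3.7, sys$n_i)
  expect_lt(max(abs(ephaptic_flux(sys, st))), 1e-10)
  # linear field z: flux through each membrane piece = sigma_in * (z-area)
  st$phi_ext <- mesh$vertices[sys$intra_dof, 3]
  flux <- ephaptic_flux(sys, st)
  mg <- membrane_geometry(mesh)
  mv <- sys$mv
  nz_area <- numeric(length(mv))
  for (tt in seq_len(nrow(mesh$membrane_tris))) {
    for (vv in mesh$membrane_tris[tt, ]) {
      k <- match(vv, mv)
      nz_area[k] <- nz_area[k] + mg$area[tt] / 3 * mg$normal[tt, 3]
    }
  }
  sig <- 2 * neurocable3d:::UNIT$sigma
  expect_equal(flux, sig * nz_area, tolerance = 1e-10)
})

test_that("a purely passive membrane solves in one Newton iteration", {
  mesh <- small_sphere()
  model <- membrane_model(hh_parameters(g_na = 0, g_k = 0),
                          stimuli = list(stimulus_spec(1, 0.5, 0, Inf)))
  out <- run_simulation(mesh, model,
                        solver_config(dt = 0.05, t_end = 0.25))
  expect_true(all(out$newton_iters == 1L))
})

test_that("backward Euler shows first-order step-size convergence", {
  mesh <- small_sphere()
  model <- membrane_model(stimuli = list(stimulus_spec(1, 1, 0, Inf)))
  probe <- mesh$markers["pole_north"]
  vT <- function(dt) {
    cfg <- solver_config(dt = dt, t_end = 0.2, jacobian = "frozen")
    out <- run_simulation(mesh, model, cfg, probes = probe)
    out$v_m[nrow(out$v_m), 1]
  }
  v1 <- vT(0.02); v2 <- vT(0.01); v4 <- vT(0.005)
  rate <- (v1 - v4) / (v2 - v4)  # ~ (2e)/(e) with first order: limit 3... use
  # Richardson: e(dt) ~ C dt  =>  (v1 - v2)/(v2 - v4) ~ 2
  ratio <- (v1 - v2) / (v2 - v4)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("spikes propagate causally along the cylinder", {
  out <- small_cylinder_run()
  fuc <- neurocable3d:::first_upward_crossing
  t_stim <- fuc(out$time, out$v_m[, "end_stim"], max(out$v_m) / 2)
  t_mid <- fuc(out$time, out$v_m[, "mid"], max(out$v_m) / 2)
  t_far <- fuc(out$time, out$v_m[, "end_far"], max(out$v_m) / 2)
  expect_lt(t_stim, t_mid)
  expect_lt(t_mid, t_far)
})

test_that("axisymmetric stimulation yields an axisymmetric extracellular field", {
  # all m != 0 multipole components stay at discretization-noise level
  out <- small_sphere_run()
  exp_ <- fit_multipole(out$system$mesh, out$state$j_all_vertex,
                        sigma_out = 20, l_max = 4, units = "nA/um2")
  l_of <- rep(0:4, times = 2 * (0:4) + 1)
  m_of <- unlist(lapply(0:4, function(l) -l:l))
  ax <- abs(exp_$b[m_of == 0 & l_of > 0])
  nonax <- abs(exp_$b[m_of != 0])
  # the jagged boundary of the discrete stimulus cap sets the symmetry error
  # floor of the coarse icosphere
  expect_lt(max(nonax), 0.2 * max(ax))
})

test_that("the step counter reports round(t_end / dt)", {
  expect_identical(count_steps(solver_config(dt = 0.01, t_end = 14)), 1400L)
  expect_identical(count_steps(solver_config(dt = 0.05, t_end = 2.5)), 50L)
})
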