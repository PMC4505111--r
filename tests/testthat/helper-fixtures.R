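# Shared fixtures, built once per test run. All geometry is generated
# programmatically; nothing is read from disk.

unit_tet <- function() {
  list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       tets = matrix(1:4, 1))
}

# small sphere domain shared by several tests
fix_env <- new.env()

small_sphere <- function() {
  if (is.null(fix_env$sphere))
    fix_env$sphere <- build_sphere_domain(10, 40, subdiv = 1,
                                          stim_cap_deg = 35)
  fix_env$sphere
}

# a short, coarse active cylinder simulation (shared)
small_cylinder_run <- function() {
  if (is.null(fix_env$cyl_run)) {
    mesh <- build_cylinder_domain(600, 100, extracellular_margin = 150,
                                  resolution = 50, resolution_axial = 60)
    model <- membrane_model(stimuli = list(stimulus_spec(1, 400, t_on = 0,
                                                         t_off = 0.5)))
    cfg <- solver_config(dt = 0.05, t_end = 2.5, sigma_in = 2, sigma_out = 20,
                         jacobian = "frozen")
    fix_env$cyl_run <- run_simulation(mesh, model, cfg)
  }
  fix_env$cyl_run
}

# a short stimulated sphere simulation (shared; used by multipole and
# coupling tests)
small_sphere_run <- function() {
  if (is.null(fix_env$sph_run)) {
    mesh <- small_sphere()
    model <- membrane_model(stimuli = list(stimulus_spec(1, 1.5, t_on = 0.05,
                                                         t_off = 0.5)))
    cfg <- solver_config(dt = 0.02, t_end = 0.6, sigma_in = 2, sigma_out = 20,
                         newton_rel_tol = 1e-12, jacobian = "frozen")
    fix_env$sph_run <- run_simulation(mesh, model, cfg)
  }
  fix_env$sph_run
}

# brute-force volume of the barycentric corner piece of a tetrahedron around
# local vertex `k`: the hexahedron (vertex, 3 edge midpoints, 3 face
# barycenters, tet barycenter), decomposed into 6 tetrahedra
corner_piece_volume <- function(v, k) {
  oth <- setdiff(1:4, k)
  p <- v[k, ]
  m <- lapply(oth, function(j) (v[k, ] + v[j, ]) / 2)
  f <- lapply(1:3, function(a) {
    pair <- oth[-a]
    (v[k, ] + v[pair[1], ] + v[pair[2], ]) / 3
  })
  cc <- colMeans(v)
  # hexahedron corners in the standard ordering (p; m1 m2 m3 adjacent;
  # f3 f2 f1 opposite edges; c): split into 6 tets around diagonal p-c
  tetvol <- function(a, b, d, e) abs(det(rbind(b - a, d - a, e - a))) / 6
  # faces of the hexahedron around the main diagonal (p, c):
  vol <- tetvol(p, m[[1]], f[[3]], cc) + tetvol(p, f[[3]], m[[2]], cc) +
    tetvol(p, m[[2]], f[[1]], cc) + tetvol(p, f[[1]], m[[3]], cc) +
    tetvol(p, m[[3]], f[[2]], cc) + tetvol(p, f[[2]], m[[1]], cc)
  vol
}
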