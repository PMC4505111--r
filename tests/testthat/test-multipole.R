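test_that("real spherical harmonics match frozen reference values", {
  # reference: scipy.special real spherical harmonics at the direction
  # (0.2, 0.5, sqrt(0.71)), frozen to 8 digits
  d <- rbind(c(0.2, 0.5, sqrt(1 - 0.04 - 0.25)))
  B <- sph_harm_basis(3, d)
  ref <- c(0.28209479,
           0.24430126, 0.41170379, 0.0977205,
           0.10925484, 0.46029884, 0.35639247, 0.18411953, -0.11471759,
           -0.03835283, 0.24356725, 0.58273339, 0.17294418, 0.23309336,
           -0.25574561, -0.08378619)
  expect_equal(as.numeric(B), ref, tolerance = 1e-7)
})

test_that("the basis is orthonormal under the triangle quadrature", {
  ico <- icosphere(3)
  tris <- ico$tris
  a <- ico$vertices[tris[, 1], ]; b <- ico$vertices[tris[, 2], ]
  cc <- ico$vertices[tris[, 3], ]
  ar <- sqrt(rowSums(neurocable3d:::cross3(b - a, cc - a)^2)) / 2
  dirs <- (a + b + cc) / 3
  dirs <- dirs / sqrt(rowSums(dirs^2))
  B <- sph_harm_basis(4, dirs)
  G <- crossprod(B, B * ar)
  expect_lt(max(abs(G - diag(diag(G)))), 2e-3)
  expect_equal(unname(diag(G)), rep(1, 25), tolerance = 5e-3)
})

test_that("single-harmonic fluxes fit to single coefficients", {
  mesh <- small_sphere()
  mg <- membrane_geometry(mesh)
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  R <- 10
  # flux = Y_00 (uniform net flux, an artificial input): only b_00 survives
  f00 <- sph_harm_basis(0, dirs)[, 1]
  e0 <- fit_multipole(mesh, f00, sigma_out = 10, l_max = 4,
                      method = "least_squares", units = "nA/um2")
  expect_gt(abs(e0$b[["l0m0"]]), 0)
  expect_lt(max(abs(e0$b[-1])), 1e-10 * abs(e0$b[["l0m0"]]))
  # flux = Y_10: only b_10, magnitude R^3/2 for unit conductivity
  # (sigma_out = 10 mS/cm = 1 uS/um)
  f10 <- sph_harm_basis(1, dirs)[, 3]
  e1 <- fit_multipole(mesh, f10, sigma_out = 10, l_max = 4,
                      method = "least_squares", units = "nA/um2")
  expect_equal(e1$b[["l1m0"]], R^3 / 2, tolerance = 1e-10)
  other <- e1$b[setdiff(names(e1$b), "l1m0")]
  expect_lt(max(abs(other)), 1e-8 * abs(e1$b[["l1m0"]]))
})

test_that("the monopole tracks the total flux and vanishes for balanced patterns", {
  mesh <- small_sphere()
  mg <- membrane_geometry(mesh)
  ntri <- nrow(mesh$membrane_tris)
  expect_equal(monopole_coefficient(mesh, rep(0, ntri)), 0)
  # antisymmetric cos(theta) flux: zero surface integral by symmetry
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  b00 <- monopole_coefficient(mesh, dirs[, 3], units = "nA/um2")
  scale <- monopole_coefficient(mesh, abs(dirs[, 3]), units = "nA/um2")
  expect_lt(abs(b00), 1e-10 * abs(scale))
})

test_that("the exterior series decays like a multipole", {
  mesh <- small_sphere()
  mg <- membrane_geometry(mesh)
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  f10 <- sph_harm_basis(1, dirs)[, 3]
  e1 <- fit_multipole(mesh, f10, sigma_out = 10, l_max = 4,
                      method = "least_squares", units = "nA/um2")
  # pure dipole: |Phi(2r)| / |Phi(r)| = 1/4 along a fixed direction
  p1 <- evaluate_potential(e1, 30, theta = 0.4, phi = 1.1)
  p2 <- evaluate_potential(e1, 60, theta = 0.4, phi = 1.1)
  expect_equal(p2 / p1, 1 / 4, tolerance = 1e-12)
  expect_error(evaluate_potential(e1, 5, 0, 0), "exterior")
  # zero expansion evaluates to zero
  e0 <- e1; e0$b[] <- 0
  expect_equal(evaluate_potential(e0, 25, 1, 2), 0)
  # with b_00 = 0, r^2 |Phi| stays bounded as r grows
  th <- seq(0.1, pi - 0.1, length.out = 7)
  m3 <- max(abs(evaluate_potential(e1, rep(30, 7), th, th * 0)) * 30^2)
  m100 <- max(abs(evaluate_potential(e1, rep(1000, 7), th, th * 0)) * 1000^2)
  expect_lt(m100, m3 * (1 + 1e-9))
})

test_that("fitting is a left inverse of reconstruction (Parseval consistency)", {
  mesh <- small_sphere()
  set.seed(7)
  e <- fit_multipole(mesh, runif(nrow(mesh$membrane_tris), -1, 1),
                     sigma_out = 20, l_max = 6, method = "least_squares",
                     units = "nA/um2")
  f_rec <- flux_from_expansion(e, mesh, units = "nA/um2")
  e2 <- fit_multipole(mesh, f_rec, sigma_out = 20, l_max = 6,
                      method = "least_squares", units = "nA/um2")
  expect_equal(e2$b, e$b, tolerance = 1e-10)
})

test_that("the series agrees with an independent volumetric exterior solve", {
  # independent oracle: solve the exterior Neumann problem with the 3D
  # finite-volume operator on a wide shell (grounded far boundary) and
  # compare with the truncated series at twice the membrane radius
  mesh <- build_sphere_domain(10, 100, subdiv = 2, n_layers_in = 2,
                              n_layers_out = 12)
  mg <- membrane_geometry(mesh)
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  f10 <- sph_harm_basis(1, dirs)[, 3]  # nA/um^2, dipole pattern
  sigma_out <- 10
  e1 <- fit_multipole(mesh, f10, sigma_out = sigma_out, l_max = 2,
                      units = "nA/um2")

  As <- assemble_stiffness(mesh, NULL, sigma_out, "EXTRA")
  mv <- sort(unique(as.vector(mesh$membrane_tris)))
  # vertex-weighted membrane current: area/3 per incident triangle, flux at
  # the triangle midpoint
  F_ <- numeric(length(As$dof))
  for (tt in seq_len(nrow(mesh$membrane_tris))) {
    for (vv in mesh$membrane_tris[tt, ]) {
      k <- match(vv, As$dof)
      F_[k] <- F_[k] + mg$area[tt] / 3 * f10[tt]
    }
  }
  out <- match(intersect(mesh$outer_vertices, As$dof), As$dof)
  free <- setdiff(seq_along(As$dof), out)
  phi <- numeric(length(As$dof))
  phi[free] <- as.numeric(Matrix::solve(As$L[free, free], F_[free]))
  # compare at vertices near r = 2R
  x <- mesh$vertices[As$dof, ]
  r <- sqrt(rowSums(x^2))
  sel <- which(abs(r - 20) < 2)
  th <- acos(x[sel, 3] / r[sel])
  ph <- atan2(x[sel, 2], x[sel, 1])
  series <- evaluate_potential(e1, r[sel], th, ph)
  # both routes are discretized (coarse shell, truncated series), so the
  # agreement is checked at the discretization level
  expect_lt(max(abs(series - phi[sel])) / max(abs(phi[sel])), 0.12)
})
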