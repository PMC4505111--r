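# Spherical-harmonics multipole analysis of the extracellular potential of a
# spherical cell. The exterior potential is
#   Phi_out(r, theta, phi) = sum_lm b_lm r^-(l+1) Y_lm(theta, phi),
# and matching the radial derivative at r = R to the membrane flux
# (-sigma_out dPhi/dr = j_all) gives
#   b_lm = R^(l+2) / ((l+1) sigma_out) * int j_all Y_lm dOmega.
# The monopole coefficient b_00 is proportional to the total transmembrane
# current, which vanishes for a resistive-volume cell, so the potential
# decays at least like r^-2.
#
# Real, orthonormal spherical harmonics (no Condon-Shortley phase).

# Fully normalized associated Legendre functions Pbar_l^m(x) for all
# 0 <= l <= lmax, 0 <= m <= l, such that Y_l0 = Pbar_l0(cos theta) and
# Y_lm = sqrt(2) Pbar_lm(cos theta) {cos,sin}(m phi) are orthonormal on the
# unit sphere. Standard stable three-term recurrence.
# Returns a matrix (length(x) rows, one column per (l, m) with m <= l).
legendre_norm <- function(lmax, x) {
  nx <- length(x)
  ncol_ <- (lmax + 1) * (lmax + 2) / 2
  P <- matrix(0, nx, ncol_)
  idx <- function(l, m) l * (l + 1) / 2 + m + 1
  sx <- sqrt(pmax(0, 1 - x^2))
  P[, idx(0, 0)] <- sqrt(1 / (4 * pi))
  if (lmax == 0) return(P)
  for (m in seq_len(lmax)) {
    P[, idx(m, m)] <- sqrt((2 * m + 1) / (2 * m)) * sx * P[, idx(m - 1, m - 1)]
  }
  for (m in 0:(lmax - 1)) {
    P[, idx(m + 1, m)] <- sqrt(2 * m + 3) * x * P[, idx(m, m)]
    if (m + 2 <= lmax) for (l in (m + 2):lmax) {
      a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
      P[, idx(l, m)] <- a * (x * P[, idx(l - 1, m)] - b * P[, idx(l - 2, m)])
    }
  }
  P
}

#' Real orthonormal spherical-harmonics basis
#'
#' Evaluates all real spherical harmonics up to degree `l_max` at unit
#' directions, orthonormal over the unit sphere
#' (`int Y_lm Y_l'm' dOmega = delta`).
#'
#' @param l_max maximum degree.
#' @param dirs matrix (n x 3) of unit direction vectors.
#' @return matrix (n x (l_max+1)^2); column order `l^2 + l + m + 1`,
#'   with negative m the sine and positive m the cosine harmonics.
#' @export
sph_harm_basis <- function(l_max, dirs) {
  dirs <- as.matrix(dirs)
  ct <- dirs[, 3] / sqrt(rowSums(dirs^2))
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- legendre_norm(l_max, ct)
  pidx <- function(l, m) l * (l + 1) / 2 + m + 1
  B <- matrix(0, nrow(dirs), (l_max + 1)^2)
  for (l in 0:l_max) {
    B[, l^2 + l + 1] <- P[, pidx(l, 0)]
    if (l > 0) for (m in seq_len(l)) {
      B[, l^2 + l + m + 1] <- sqrt(2) * P[, pidx(l, m)] * cos(m * phi)
      B[, l^2 + l - m + 1] <- sqrt(2) * P[, pidx(l, m)] * sin(m * phi)
    }
  }
  colnames(B) <- sph_harm_labels(l_max)
  B
}

sph_harm_labels <- function(l_max) {
  unlist(lapply(0:l_max, function(l) paste0("l", l, "m", -l:l)))
}

# membrane triangle quadrature of a sphere mesh: solid-angle weights at
# triangle centroids plus the per-triangle flux (vertex values averaged)
sphere_quadrature <- function(mesh, flux) {
  tris <- mesh$membrane_tris
  if (!nrow(tris)) stop("mesh has no membrane")
  # closed surface: every membrane edge must be shared by exactly 2 triangles
  ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  if (any(table(key) != 2)) stop("membrane surface is not closed")
  mg <- membrane_geometry(mesh)
  mv <- sort(unique(as.vector(tris)))
  rad <- sqrt(rowSums(mesh$vertices[mv, , drop = FALSE]^2))
  R <- mean(rad)
  if (diff(range(rad)) > 1e-6 * R)
    stop("membrane is not a sphere centred at the origin")
  if (length(flux) == length(mv)) {
    fv <- numeric(nrow(mesh$vertices))
    fv[mv] <- flux
    ftri <- (fv[tris[, 1]] + fv[tris[, 2]] + fv[tris[, 3]]) / 3
  } else if (length(flux) == nrow(tris)) {
    ftri <- flux
  } else stop("flux must have one value per membrane vertex or per triangle")
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  list(R = R, w = mg$area / R^2, dirs = dirs, f = ftri)
}

#' Fit a multipole expansion to a membrane flux field
#'
#' Expands the exterior extracellular potential of a spherical cell in real
#' spherical harmonics from the total transmembrane current density on the
#' (closed, triangulated) membrane sphere:
#' `b_lm = R^(l+2) / ((l+1) sigma_out) * int j_all Y_lm dOmega`.
#'
#' With `method = "quadrature"` the surface integral uses the
#' triangle-midpoint rule (vertex fluxes averaged per triangle, directions at
#' triangle centroids); the monopole coefficient is then exactly proportional
#' to the dual-grid total membrane flux of the finite-volume solver. With
#' `method = "least_squares"` the coefficients solve the weighted
#' normal equations instead, which makes fitting an exact left inverse of
#' evaluation on the same grid (re-fitting a reconstructed flux returns the
#' coefficients unchanged).
#'
#' @param mesh a sphere-domain [nc_mesh()] (membrane centred at the origin).
#' @param flux total transmembrane current density, per membrane vertex (in
#'   the order of the sorted unique membrane vertex ids, as returned in
#'   `state$j_all_vertex`) or per membrane triangle. Units uA/cm^2 unless
#'   `units = "nA/um2"`.
#' @param sigma_out extracellular conductivity (mS/cm).
#' @param l_max truncation degree (default 8).
#' @param method `"quadrature"` or `"least_squares"`.
#' @param units unit of `flux`.
#' @return object of class `nc_multipole`: list with `R` (um), `l_max`,
#'   `sigma_out` and coefficient vector `b` (mV um^(l+1)), names
#'   `l<l>m<m>`.
#' @export
fit_multipole <- function(mesh, flux, sigma_out = 20, l_max = 8,
                          method = c("quadrature", "least_squares"),
                          units = c("uA/cm2", "nA/um2")) {
  method <- match.arg(method)
  units <- match.arg(units)
  q <- sphere_quadrature(mesh, flux)
  f <- q$f * if (units == "uA/cm2") UNIT$j_mem else 1  # nA/um^2
  B <- sph_harm_basis(l_max, q$dirs)
  wf <- q$w * f
  c_lm <- as.numeric(crossprod(B, wf))                  # int j Y dOmega
  if (method == "least_squares") {
    G <- crossprod(B, B * q$w)
    c_lm <- solve(G, c_lm)
  }
  l_of <- rep(0:l_max, times = 2 * (0:l_max) + 1)
  sig <- sigma_out * UNIT$sigma
  b <- q$R^(l_of + 2) / ((l_of + 1) * sig) * c_lm
  names(b) <- sph_harm_labels(l_max)
  structure(list(R = q$R, l_max = l_max, sigma_out = sigma_out, b = b,
                 method = method), class = "nc_multipole")
}

#' Monopole coefficient of the extracellular potential
#'
#' `b_00 = R^2 / sigma_out * int j_all Y_00 dOmega`, proportional to the
#' total transmembrane current; approximately zero for any converged
#' simulation state because the fluxes balance over the whole membrane.
#'
#' @inheritParams fit_multipole
#' @return monopole coefficient (mV um).
#' @export
monopole_coefficient <- function(mesh, flux, sigma_out = 20,
                                 units = c("uA/cm2", "nA/um2")) {
  fit_multipole(mesh, flux, sigma_out, l_max = 0, method = "quadrature",
                units = units)$b[["l0m0"]]
}

#' Evaluate a multipole expansion
#'
#' Truncated series value of the exterior potential at spherical coordinates
#' `(r, theta, phi)`; only valid outside the membrane sphere (`r > R`). With
#' a vanishing monopole the magnitude decays at least like `r^-2`.
#'
#' @param exp_ a [fit_multipole()] expansion.
#' @param r radius (um), `> R`.
#' @param theta polar angle (rad).
#' @param phi azimuthal angle (rad).
#' @return potential (mV), vectorized over equal-length inputs.
#' @export
evaluate_potential <- function(exp_, r, theta, phi) {
  if (any(r <= exp_$R))
    stop("exterior expansion only: need r > R = ", exp_$R)
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  B <- sph_harm_basis(exp_$l_max, dirs)
  l_of <- rep(0:exp_$l_max, times = 2 * (0:exp_$l_max) + 1)
  rad <- outer(r, -(l_of + 1), `^`)
  as.numeric((B * rad) %*% exp_$b)
}

#' Membrane flux field of a multipole expansion
#'
#' Inverts the radial-derivative matching: the total transmembrane current
#' density (per membrane triangle, at triangle centroids) whose expansion is
#' `exp_`. Used for round-trip consistency checks of the fit.
#'
#' @param exp_ a [fit_multipole()] expansion.
#' @param mesh the sphere-domain mesh the expansion was fitted on.
#' @param units output unit.
#' @return per-membrane-triangle flux density.
#' @export
flux_from_expansion <- function(exp_, mesh, units = c("uA/cm2", "nA/um2")) {
  units <- match.arg(units)
  mg <- membrane_geometry(mesh)
  dirs <- mg$bary / sqrt(rowSums(mg$bary^2))
  B <- sph_harm_basis(exp_$l_max, dirs)
  l_of <- rep(0:exp_$l_max, times = 2 * (0:exp_$l_max) + 1)
  sig <- exp_$sigma_out * UNIT$sigma
  c_lm <- exp_$b * (l_of + 1) * sig / exp_$R^(l_of + 2)
  f <- as.numeric(B %*% c_lm)  # nA/um^2
  f / if (units == "uA/cm2") UNIT$j_mem else 1
}
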