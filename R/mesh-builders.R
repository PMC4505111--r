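# Programmatic mesh builders. All constructions are deterministic and
# parametric (no randomized meshing), so identical arguments always give
# identical meshes.

# ---- simplex splitting helpers ----------------------------------------------

# Split triangular prisms into 3 tets each with the index-based rule of
# Dompierre et al. (consistent across shared quad faces: every quad is cut by
# the diagonal through its smallest global vertex id).
# prisms: n x 6 matrix, columns (p0,p1,p2) bottom triangle, (p3,p4,p5) top,
# with p3 vertically above p0 etc.
split_prisms <- function(prisms) {
  perms <- rbind(c(1, 2, 3, 4, 5, 6),
                 c(2, 3, 1, 5, 6, 4),
                 c(3, 1, 2, 6, 4, 5),
                 c(4, 6, 5, 1, 3, 2),
                 c(5, 4, 6, 2, 1, 3),
                 c(6, 5, 4, 3, 2, 1))
  n <- nrow(prisms)
  smallest <- max.col(-prisms, ties.method = "first")
  I <- matrix(0L, n, 6)
  for (s in 1:6) {
    idx <- which(smallest == s)
    if (length(idx)) I[idx, ] <- prisms[idx, perms[s, ], drop = FALSE]
  }
  caseA <- pmin(I[, 2], I[, 6]) < pmin(I[, 3], I[, 5])
  tets <- matrix(0L, 3 * n, 4)
  a <- which(caseA); b <- which(!caseA)
  if (length(a)) {
    tets[a, ]         <- I[a, c(1, 2, 3, 6), drop = FALSE]
    tets[n + a, ]     <- I[a, c(1, 2, 6, 5), drop = FALSE]
    tets[2 * n + a, ] <- I[a, c(1, 5, 6, 4), drop = FALSE]
  }
  if (length(b)) {
    tets[b, ]         <- I[b, c(1, 2, 3, 5), drop = FALSE]
    tets[n + b, ]     <- I[b, c(1, 5, 3, 6), drop = FALSE]
    tets[2 * n + b, ] <- I[b, c(1, 5, 6, 4), drop = FALSE]
  }
  tets
}

# ---- icosphere --------------------------------------------------------------

#' Icosphere triangulation of the unit sphere
#'
#' Starts from a regular icosahedron and applies `subdiv` rounds of 4-fold
#' triangle subdivision with projection onto the unit sphere, giving
#' `20 * 4^subdiv` triangles.
#'
#' @param subdiv non-negative integer subdivision level.
#' @return list with `vertices` (n x 3, unit norm) and `tris` (m x 3).
#' @export
icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
    key <- paste(lo, hi, sep = "-")
    uk <- !duplicated(key)
    mid <- nrow(v) + match(key, key[uk])
    newv <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
    newv <- newv / sqrt(rowSums(newv^2))
    v <- rbind(v, newv)
    n <- nrow(f)
    m12 <- mid[seq_len(n)]; m23 <- mid[n + seq_len(n)]; m13 <- mid[2 * n + seq_len(n)]
    f <- rbind(cbind(f[, 1], m12, m13), cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]), cbind(m12, m23, m13))
  }
  list(vertices = v, tris = f)
}

# ---- sphere domain ----------------------------------------------------------

#' Spherical cell in a concentric extracellular shell
#'
#' Builds a tetrahedral mesh of an intracellular ball of the given radius
#' inside an extracellular shell, both discretized by radially stacked
#' icosphere layers. The membrane is the triangulated sphere at `radius`.
#' Membrane patches default to `ACTIVE`, with an optional polar stimulus cap.
#'
#' @param radius membrane radius (um).
#' @param extracellular_radius outer radius of the extracellular shell (um);
#'   must exceed `radius`.
#' @param subdiv icosphere subdivision level of the angular discretization.
#' @param n_layers_in,n_layers_out number of radial layers inside/outside.
#' @param stim_cap_deg polar half-angle (degrees, around +z) of a `STIMULUS`
#'   patch, or `NULL` for a fully `ACTIVE` membrane.
#' @return a [nc_mesh()] with markers `pole_north` (inside the stimulus cap)
#'   and `pole_south` on the membrane.
#' @export
build_sphere_domain <- function(radius, extracellular_radius, subdiv = 2,
                                n_layers_in = max(2L, round(subdiv + 1)),
                                n_layers_out = n_layers_in,
                                stim_cap_deg = NULL) {
  if (!(extracellular_radius > radius && radius > 0))
    stop("need extracellular_radius > radius > 0")
  ico <- icosphere(subdiv)
  nv <- nrow(ico$vertices)

  radii_in <- radius * seq_len(n_layers_in) / n_layers_in
  # geometric grading outwards
  g <- (extracellular_radius / radius)^(1 / n_layers_out)
  radii_out <- radius * g^seq_len(n_layers_out)
  radii_out[n_layers_out] <- extracellular_radius
  radii <- c(radii_in, radii_out)
  nl <- length(radii)

  verts <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) ico$vertices * r)))
  layer_ids <- function(l) 1L + (l - 1L) * nv + seq_len(nv)

  # innermost fan: center to layer 1
  tets_fan <- cbind(1L, matrix(layer_ids(1L)[t(ico$tris)], ncol = 3, byrow = TRUE))
  # prisms between consecutive layers
  prisms <- do.call(rbind, lapply(seq_len(nl - 1L), function(l) {
    b <- layer_ids(l); t_ <- layer_ids(l + 1L)
    cbind(matrix(b[t(ico$tris)], ncol = 3, byrow = TRUE),
          matrix(t_[t(ico$tris)], ncol = 3, byrow = TRUE))
  }))
  tets_pr <- split_prisms(prisms)
  tets <- rbind(tets_fan, tets_pr)

  ntri <- nrow(ico$tris)
  layer_of_prism <- rep(seq_len(nl - 1L), each = ntri)
  intra_prism <- layer_of_prism < n_layers_in  # prism below the membrane layer
  sub <- c(rep("INTRA", nrow(tets_fan)), rep(ifelse(intra_prism, "INTRA", "EXTRA"), 3))

  patch_fun <- function(bary, cell, nrm) {
    if (is.null(stim_cap_deg)) return(rep("ACTIVE", nrow(bary)))
    ang <- acos(pmax(-1, pmin(1, bary[, 3] / sqrt(rowSums(bary^2))))) * 180 / pi
    ifelse(ang < stim_cap_deg, "STIMULUS", "ACTIVE")
  }

  mem_layer <- layer_ids(n_layers_in)
  north <- mem_layer[which.max(ico$vertices[, 3])]
  south <- mem_layer[which.min(ico$vertices[, 3])]
  nc_mesh(verts, tets, sub, patch_assign = patch_fun,
          markers = c(pole_north = north, pole_south = south))
}

# ---- structured disk / cylinder ---------------------------------------------

# 2D triangulated disk: center + concentric rings of n_seg points at the given
# radii. Returns vertices (x, y), triangles, and per-vertex ring index.
disk2d <- function(radii, n_seg) {
  K <- length(radii)
  ang <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  verts <- rbind(c(0, 0),
                 do.call(rbind, lapply(radii, function(r) cbind(r * cos(ang), r * sin(ang)))))
  ring <- c(0L, rep(seq_len(K), each = n_seg))
  rid <- function(j) 1L + (j - 1L) * n_seg + seq_len(n_seg)
  nxt <- c(seq_len(n_seg)[-1], 1L)
  r1 <- rid(1L)
  tris <- cbind(1L, r1, r1[nxt])
  if (K > 1) for (j in seq_len(K - 1L)) {
    a <- rid(j); b <- rid(j + 1L)
    tris <- rbind(tris, cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
  }
  # ring index of each triangle's outermost vertex
  tri_ring <- pmax(ring[tris[, 1]], ring[tris[, 2]], ring[tris[, 3]])
  list(verts = verts, tris = tris, ring = ring, tri_ring = tri_ring)
}

#' Cylindrical cell embedded in an extracellular sleeve
#'
#' Builds a tetrahedral mesh of an intracellular cylinder (axis along z,
#' spanning `0 <= z <= length`) inside a coaxial extracellular cylinder that
#' extends `extracellular_margin` beyond the membrane radially and beyond both
#' end caps. The cross-section is a structured triangulated `n_seg`-gon disk,
#' so the intracellular cross-section is the inscribed regular polygon of the
#' stated diameter. Membrane patches default to `ACTIVE`, with the `z = 0` end
#' cap labeled `STIMULUS`.
#'
#' Recording markers are placed on the cylinder axis at the stimulated end,
#' the midpoint, and the far end.
#'
#' @param length cylinder length (um).
#' @param diameter cylinder diameter (um).
#' @param extracellular_margin radial/axial extent of the extracellular
#'   region beyond the membrane (um).
#' @param resolution target cross-sectional edge length (um); must not exceed
#'   the diameter.
#' @param resolution_axial target axial layer height (um); defaults to
#'   `resolution` (long thin cylinders are meshed anisotropically by passing a
#'   larger value).
#' @param n_seg number of polygon segments of the cross-section.
#' @param stim_band_axial axial extent (um) of a lateral `STIMULUS` band at
#'   the `z = 0` end instead of the default stimulated end cap; align it
#'   with the axial grid so refinements keep the identical patch.
#' @return a [nc_mesh()] with markers `end_stim`, `mid`, `end_far`.
#' @export
build_cylinder_domain <- function(length, diameter,
                                  extracellular_margin = 2.5 * diameter,
                                  resolution = diameter / 4,
                                  resolution_axial = resolution,
                                  n_seg = max(8L, round(pi * diameter / resolution)),
                                  stim_band_axial = NULL) {
  if (length <= 0 || diameter <= 0 || resolution <= 0)
    stop("length, diameter and resolution must be positive")
  if (resolution > diameter)
    stop("resolution larger than diameter: cannot resolve the cross-section")
  R <- diameter / 2
  K_in <- max(1L, round(R / resolution))
  radii_in <- R * seq_len(K_in) / K_in
  r_out <- R + extracellular_margin
  K_out <- max(2L, ceiling(log(r_out / R) / log(1.6)))
  g <- (r_out / R)^(1 / K_out)
  radii_out <- R * g^seq_len(K_out)
  radii_out[K_out] <- r_out
  d2 <- disk2d(c(radii_in, radii_out), n_seg)

  nz <- max(2L, round(length / resolution_axial))
  z_in <- seq(0, length, length.out = nz + 1L)
  n_mz <- max(2L, ceiling(extracellular_margin / (2 * resolution_axial)))
  z_lo <- seq(-extracellular_margin, 0, length.out = n_mz + 1L)
  z_hi <- seq(length, length + extracellular_margin, length.out = n_mz + 1L)
  zp <- c(z_lo[-(n_mz + 1L)], z_in, z_hi[-1])
  np <- nrow(d2$verts)
  verts <- do.call(rbind, lapply(zp, function(z) cbind(d2$verts, z)))

  lay_in <- function(l) (l - 1L) * np  # offset of plane l
  prisms <- do.call(rbind, lapply(seq_len(length(zp) - 1L), function(l) {
    cbind(d2$tris + lay_in(l), d2$tris + lay_in(l + 1L))
  }))
  ntri <- nrow(d2$tris)
  layer <- rep(seq_len(length(zp) - 1L), each = ntri)
  tri_id <- rep(seq_len(ntri), length(zp) - 1L)
  z0 <- zp[layer]; z1 <- zp[layer + 1L]
  inside_ax <- z0 >= -1e-9 & z1 <= length + 1e-9
  inside_rad <- d2$tri_ring[tri_id] <= K_in
  intra <- inside_ax & inside_rad
  tets <- split_prisms(prisms)
  sub <- rep(ifelse(intra, "INTRA", "EXTRA"), 3)

  patch_fun <- function(bary, cell, nrm) {
    if (is.null(stim_band_axial)) {
      # stimulated end cap
      ifelse(abs(bary[, 3]) < 1e-9 & nrm[, 3] < -0.5, "STIMULUS", "ACTIVE")
    } else {
      # lateral band at the z = 0 end (matches a 1D current injection over
      # the same axial extent); the cap stays active
      lateral <- abs(nrm[, 3]) < 0.5
      ifelse(lateral & bary[, 3] < stim_band_axial, "STIMULUS", "ACTIVE")
    }
  }
  axis_ids <- 1L + (match(c(0, length / 2, length), zp) - 1L) * np
  if (anyNA(axis_ids)) { # midpoint plane may not exist exactly; take nearest
    axis_ids <- 1L + (sapply(c(0, length / 2, length),
                             function(z) which.min(abs(zp - z))) - 1L) * np
  }
  nc_mesh(verts, tets, sub, patch_assign = patch_fun,
          markers = c(end_stim = axis_ids[1], mid = axis_ids[2],
                      end_far = axis_ids[3]))
}

# ---- idealized multi-cell network (Cartesian builder) -----------------------

#' Geometry specification for an idealized neuron
#'
#' Describes one idealized cell of a network domain: a straight neurite laid
#' out along the x axis with a dendrite section, a soma, and a myelinated axon
#' with regularly spaced nodes of Ranvier. Cross-sections are square with the
#' equal-area side of the stated diameter (the network builder works on a
#' Cartesian grid; the curved-geometry builders are [build_cylinder_domain()]
#' and [build_sphere_domain()]).
#'
#' @param soma_diameter,axon_diameter,dendrite_diameter diameters (um).
#' @param soma_length,axon_length,dendrite_length section lengths (um).
#' @param n_nodes number of nodes of Ranvier on the axon.
#' @param node_length axial length of each node of Ranvier (um).
#' @return object of class `nc_neuron_spec`.
#' @export
neuron_geometry_spec <- function(soma_diameter = 20, axon_diameter = 5,
                                 dendrite_diameter = 10, soma_length = 20,
                                 axon_length = 100, dendrite_length = 40,
                                 n_nodes = 2, node_length = 5) {
  if (any(c(soma_diameter, axon_diameter, dendrite_diameter) <= 0))
    stop("all diameters must be positive")
  structure(list(soma_diameter = soma_diameter, axon_diameter = axon_diameter,
                 dendrite_diameter = dendrite_diameter,
                 soma_length = soma_length, axon_length = axon_length,
                 dendrite_length = dendrite_length, n_nodes = n_nodes,
                 node_length = node_length), class = "nc_neuron_spec")
}

#' Idealized multi-cell network domain
#'
#' Builds a conforming tetrahedral mesh of `n_cells` idealized neurons
#' (see [neuron_geometry_spec()]) embedded in a shared extracellular box on a
#' uniform Cartesian grid (each grid hexahedron is split into six tetrahedra
#' with mirror-consistent diagonals). Cells are parallel rods along x, stacked
#' along y with the given separation; cell `i` runs dendrite -> soma -> axon in
#' +x for odd `i` and -x for even `i`, so axon tips face the next cell's
#' dendrite. Membrane patches: passive `DENDRITE`, `ACTIVE` soma and nodes of
#' Ranvier, `MYELIN` sheaths, `SYNAPSE_PRE` at the axon tip, `SYNAPSE_POST` on
#' the facing dendrite of the next cell, and `STIMULUS` patches on the
#' dendrites of the cells in `stimulus_cells`.
#'
#' @param spec a [neuron_geometry_spec()].
#' @param n_cells number of cells (>= 1).
#' @param separation face-to-face distance between neighboring cells (um).
#' @param margin extracellular margin around the bounding box of the cells (um).
#' @param h grid spacing (um).
#' @param synapses logical; create synapse patch pairs between consecutive
#'   cells.
#' @param stimulus_cells integer vector of cell ids receiving a `STIMULUS`
#'   patch on their dendrite.
#' @return a [nc_mesh()] with markers `soma_<i>` (a membrane vertex over each
#'   soma).
#' @export
build_network_domain <- function(spec, n_cells = 4, separation = 300,
                                 margin = 40, h = 5, synapses = TRUE,
                                 stimulus_cells = c(1L, n_cells)) {
  stopifnot(inherits(spec, "nc_neuron_spec"), n_cells >= 1)
  side <- function(d) d * sqrt(pi) / 2  # equal-area square side
  Lcell <- spec$dendrite_length + spec$soma_length + spec$axon_length
  wmax <- max(side(spec$soma_diameter), side(spec$dendrite_diameter),
              side(spec$axon_diameter))
  if (separation <= 0) stop("cells overlap: separation must be positive")

  # snap all geometry to the grid; widths to even multiples of h so that
  # cell boundaries fall on grid planes and voxel centres never tie
  sn <- function(x) round(x / h) * h
  sn2 <- function(x) 2 * h * pmax(1, round(x / (2 * h)))
  w_soma <- sn2(side(spec$soma_diameter))
  w_dend <- sn2(side(spec$dendrite_diameter))
  w_axon <- sn2(side(spec$axon_diameter))
  margin <- h * ceiling(margin / h)
  L_dend <- max(h, sn(spec$dendrite_length))
  L_soma <- max(h, sn(spec$soma_length))
  L_axon <- max(h, sn(spec$axon_length))
  L_node <- max(h, sn(spec$node_length))
  Lcell <- L_dend + L_soma + L_axon
  wmax <- max(w_soma, w_dend, w_axon)
  sep <- sn(separation)

  x0 <- 0; x1 <- Lcell
  nx <- round((x1 - x0 + 2 * margin) / h)
  ny <- round((n_cells * wmax + (n_cells - 1) * sep + 2 * margin) / h)
  nzg <- round((wmax + 2 * margin) / h)
  ox <- x0 - margin
  oy <- -margin
  oz <- -margin

  # cell i occupies y in [yc - w/2, yc + w/2]
  yc <- (seq_len(n_cells) - 1L) * (wmax + sep) + wmax / 2
  zc <- wmax / 2
  dir <- ifelse(seq_len(n_cells) %% 2L == 1L, 1, -1)  # +x or -x layout

  # section of a point along the cell axis: returns width and patch class
  # sections (in local axial coordinate s in [0, Lcell], dendrite first)
  node_starts <- if (spec$n_nodes > 0)
    L_dend + L_soma + (seq_len(spec$n_nodes)) * (L_axon / (spec$n_nodes + 1L))
  else numeric()
  node_starts <- sn(node_starts)

  cell_section <- function(s) {
    # returns list(width, kind) vectorized over s
    kind <- ifelse(s < L_dend, "DENDRITE",
            ifelse(s < L_dend + L_soma, "SOMA", "MYELIN"))
    for (ns in node_starts)
      kind[s >= ns & s < ns + L_node & kind == "MYELIN"] <- "NODE"
    width <- ifelse(kind == "DENDRITE", w_dend,
             ifelse(kind == "SOMA", w_soma, w_axon))
    list(width = width, kind = kind)
  }

  # classify a point: 0 = extracellular, i = inside cell i
  classify <- function(p) {
    out <- integer(nrow(p))
    for (i in seq_len(n_cells)) {
      s <- if (dir[i] > 0) p[, 1] - x0 else x1 - p[, 1]
      sec <- cell_section(s)
      inside <- s > 0 & s < Lcell &
        abs(p[, 2] - yc[i]) < sec$width / 2 &
        abs(p[, 3] - zc) < sec$width / 2
      out[inside] <- i
    }
    out
  }

  grid <- cartesian_tet_grid(nx, ny, nzg, h, c(ox, oy, oz))
  hex_centers <- grid$hex_centers
  lab <- classify(hex_centers)
  cell_of_tet <- lab[grid$hex_of_tet]
  sub <- ifelse(cell_of_tet > 0L, "INTRA", "EXTRA")

  syn_len <- max(2 * h, sn(10))  # axial extent of synapse patches
  patch_fun <- function(bary, cell, nrm) {
    k <- nrow(bary)
    patch <- character(k)
    for (i in unique(cell)) {
      sel <- cell == i
      s <- if (dir[i] > 0) bary[sel, 1] - x0 else x1 - bary[sel, 1]
      sec <- cell_section(s)
      p <- ifelse(sec$kind == "DENDRITE", "DENDRITE",
           ifelse(sec$kind == "SOMA", "ACTIVE",
           ifelse(sec$kind == "NODE", "ACTIVE", "MYELIN")))
      # synapse pre: tip of the axon (last syn_len of the cell, all faces)
      if (synapses && i < n_cells) p[s > Lcell - syn_len] <- "SYNAPSE_PRE"
      # synapse post: start of the dendrite of cells 2..n (facing the tip)
      if (synapses && i > 1) p[s < syn_len] <- "SYNAPSE_POST"
      # stimulus: a dendrite stretch (after the post patch region)
      if (i %in% stimulus_cells) {
        stim_lo <- syn_len + h
        p[s >= stim_lo & s < stim_lo + syn_len & sec$kind == "DENDRITE"] <- "STIMULUS"
      }
      patch[sel] <- p
    }
    patch
  }

  mesh <- nc_mesh(grid$vertices, grid$tets, sub, cell_of_tet,
                  patch_assign = patch_fun)
  # soma markers: a membrane vertex over each soma
  mg <- membrane_geometry(mesh)
  markers <- integer(0)
  for (i in seq_len(n_cells)) {
    s_b <- if (dir[i] > 0) mg$bary[, 1] - x0 else x1 - mg$bary[, 1]
    on_soma <- which(mesh$cell_of_tri == i & s_b > L_dend & s_b < L_dend + L_soma)
    if (length(on_soma)) {
      tri <- on_soma[which.max(mg$bary[on_soma, 3])]
      markers <- c(markers, stats::setNames(mesh$membrane_tris[tri, 1],
                                            paste0("soma_", i)))
    }
  }
  mesh$markers <- markers
  mesh
}

# Uniform Cartesian grid of (nx x ny x nz) hexahedra of spacing h at origin,
# each split into 6 Kuhn tetrahedra, mirror-reflected by parity so that
# neighboring hexahedra share face diagonals.
cartesian_tet_grid <- function(nx, ny, nz, h, origin = c(0, 0, 0)) {
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)  # 0-based ijk
  ii <- rep(0:nx, times = (ny + 1L) * (nz + 1L))
  jj <- rep(rep(0:ny, each = nx + 1L), times = nz + 1L)
  kk <- rep(0:nz, each = (nx + 1L) * (ny + 1L))
  vertices <- cbind(origin[1] + ii * h, origin[2] + jj * h, origin[3] + kk * h)

  hx <- rep(0:(nx - 1L), times = ny * nz)
  hy <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  hz <- rep(0:(nz - 1L), each = nx * ny)
  nhex <- length(hx)
  # local corner offsets (dx,dy,dz) of the 6 Kuhn tets around diagonal
  # (0,0,0)-(1,1,1); mirrored per axis by hex parity below
  kuhn <- rbind(
    c(0,0,0, 1,0,0, 1,1,0, 1,1,1),
    c(0,0,0, 1,1,0, 0,1,0, 1,1,1),
    c(0,0,0, 0,1,0, 0,1,1, 1,1,1),
    c(0,0,0, 0,1,1, 0,0,1, 1,1,1),
    c(0,0,0, 0,0,1, 1,0,1, 1,1,1),
    c(0,0,0, 1,0,1, 1,0,0, 1,1,1))

  px <- hx %% 2L; py <- hy %% 2L; pz <- hz %% 2L
  tets <- matrix(0L, 6L * nhex, 4L)
  for (t_ in 1:6) {
    off <- matrix(kuhn[t_, ], 4, 3, byrow = TRUE)
    for (c_ in 1:4) {
      dx <- abs(off[c_, 1] - px)  # mirror per-axis by parity
      dy <- abs(off[c_, 2] - py)
      dz <- abs(off[c_, 3] - pz)
      tets[(seq_len(nhex) - 1L) * 6L + t_, c_] <- vid(hx + dx, hy + dy, hz + dz)
    }
  }
  list(vertices = vertices, tets = tets,
       hex_of_tet = (seq_len(6L * nhex) - 1L) %/% 6L + 1L,
       hex_centers = cbind(origin[1] + (hx + 0.5) * h,
                           origin[2] + (hy + 0.5) * h,
                           origin[3] + (hz + 0.5) * h))
}
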