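# Subdomain and membrane-patch label sets used throughout the package.
SUBDOMAINS <- c("INTRA", "EXTRA")
PATCHES <- c("DENDRITE", "ACTIVE", "MYELIN", "SYNAPSE_PRE", "SYNAPSE_POST",
             "STIMULUS")

#' Labeled tetrahedral mesh
#'
#' A `nc_mesh` represents a tetrahedral discretization of the computational
#' domain, split into an intracellular region (one or more cells) and the
#' surrounding extracellular region. The interface between the two regions is
#' the neuronal membrane, stored as a set of oriented triangles whose normals
#' point from the intracellular to the extracellular side. Each membrane
#' triangle carries a patch label (`DENDRITE`, `ACTIVE`, `MYELIN`,
#' `SYNAPSE_PRE`, `SYNAPSE_POST`, `STIMULUS`) selecting the membrane dynamics
#' active there, and a cell id for multi-cell domains.
#'
#' Coordinates are in micrometers.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates (um).
#' @param tets integer matrix (m x 4) of vertex indices (1-based).
#' @param subdomain character vector of length m, `"INTRA"` or `"EXTRA"`.
#' @param cell_of_tet integer vector of length m; cell membership of
#'   intracellular tetrahedra (0 for extracellular ones).
#' @param patch_assign either a function `f(barycenters, cells, normals)`
#'   returning a patch label per membrane triangle, or a named character
#'   vector keyed by sorted vertex triples (`"i-j-k"`), or a single label.
#' @param markers named integer vector of vertex indices used as recording
#'   probes.
#' @return an object of class `nc_mesh`.
#' @export
nc_mesh <- function(vertices, tets, subdomain, cell_of_tet = NULL,
                    patch_assign = "ACTIVE", markers = integer()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(tets) == 4)
  if (length(subdomain) != nrow(tets))
    stop("subdomain must have one label per tetrahedron")
  if (!all(subdomain %in% SUBDOMAINS))
    stop("unknown subdomain label(s): ",
         paste(setdiff(unique(subdomain), SUBDOMAINS), collapse = ", "))
  if (max(tets) > nrow(vertices) || min(tets) < 1)
    stop("tetrahedron references a non-existent vertex")
  if (is.null(cell_of_tet))
    cell_of_tet <- ifelse(subdomain == "INTRA", 1L, 0L)

  # orient all tets positively; reject degenerate ones
  vol <- tet_volumes_signed(vertices, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  vol <- abs(vol)
  scale3 <- max(abs(vertices))^3
  bad <- which(vol <= 1e-12 * scale3)
  if (length(bad))
    stop("degenerate (zero-volume) tetrahedron at index ", bad[1])

  m <- membrane_from_labels(vertices, tets, subdomain, cell_of_tet)
  patch <- resolve_patches(patch_assign, vertices, m)

  structure(list(
    vertices = vertices,
    tets = tets,
    subdomain = subdomain,
    cell_of_tet = as.integer(cell_of_tet),
    membrane_tris = m$tris,
    patch_of_tri = patch,
    cell_of_tri = m$cell,
    intra_tet_of_tri = m$intra_tet,
    outer_vertices = m$outer_vertices,
    markers = markers
  ), class = "nc_mesh")
}

#' @export
print.nc_mesh <- function(x, ...) {
  cat("<nc_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$tets), " tets (",
      sum(x$subdomain == "INTRA"), " intra / ",
      sum(x$subdomain == "EXTRA"), " extra), ",
      nrow(x$membrane_tris), " membrane triangles, ",
      length(unique(x$cell_of_tri)), " cell(s)\n", sep = "")
  tb <- table(x$patch_of_tri)
  cat("  patches:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Signed volumes of all tets, det/6.
tet_volumes_signed <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c_ <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Tetrahedron volumes of a mesh
#' @param mesh a [nc_mesh()].
#' @return numeric vector of volumes (um^3), all positive.
#' @export
tet_volumes <- function(mesh) abs(tet_volumes_signed(mesh$vertices, mesh$tets))

# All 16 = 4*m faces as sorted triples plus owning tet / local face index.
tet_faces <- function(tets) {
  m <- nrow(tets)
  f <- rbind(tets[, c(2, 3, 4), drop = FALSE], tets[, c(1, 4, 3), drop = FALSE],
             tets[, c(1, 2, 4), drop = FALSE], tets[, c(1, 3, 2), drop = FALSE])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  list(key = cbind(lo, mid, hi), owner = rep.int(seq_len(m), 4))
}

face_key_chr <- function(key) paste(key[, 1], key[, 2], key[, 3], sep = "-")

# Detect membrane triangles (faces shared by one INTRA and one EXTRA tet),
# orient them intra -> extra, and collect outer boundary vertices.
membrane_from_labels <- function(vertices, tets, subdomain, cell_of_tet) {
  tf <- tet_faces(tets)
  nv <- max(tets)
  kc <- if (nv^3 < 2^52) {  # composite numeric key, exact in doubles
    (tf$key[, 1] - 1) * nv * nv + (tf$key[, 2] - 1) * nv + tf$key[, 3]
  } else face_key_chr(tf$key)
  o <- order(kc)
  kc_s <- kc[o]
  owner_s <- tf$owner[o]
  n <- length(kc_s)
  first <- !duplicated(kc_s)
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  if (any(cnt > 2)) stop("non-manifold mesh: face shared by > 2 tets")

  idx1 <- which(first)
  # paired faces
  paired <- idx1[cnt[grp[idx1]] == 2]
  t1 <- owner_s[paired]
  t2 <- owner_s[paired + 1L]
  is_mem <- subdomain[t1] != subdomain[t2]
  intra_tet <- ifelse(subdomain[t1] == "INTRA", t1, t2)[is_mem]
  mem_keys <- tf$key[o, , drop = FALSE][paired, , drop = FALSE][is_mem, , drop = FALSE]

  # boundary faces (owned once)
  single <- idx1[cnt[grp[idx1]] == 1]
  bkeys <- tf$key[o, , drop = FALSE][single, , drop = FALSE]
  outer_vertices <- sort(unique(as.vector(bkeys)))

  # also guard: INTRA tets of different cells must not touch by a face
  both_intra <- subdomain[t1] == "INTRA" & subdomain[t2] == "INTRA"
  if (any(both_intra & cell_of_tet[t1] != cell_of_tet[t2]))
    stop("two different cells share a face; cells must be separated by ",
         "extracellular space")

  if (nrow(mem_keys) == 0)
    return(list(tris = matrix(integer(), 0, 3), cell = integer(),
                intra_tet = integer(), outer_vertices = outer_vertices))

  # orient: normal of (v1,v2,v3) must point away from the intra tet barycenter
  tris <- mem_keys
  a <- vertices[tris[, 1], , drop = FALSE]
  b <- vertices[tris[, 2], , drop = FALSE]
  c_ <- vertices[tris[, 3], , drop = FALSE]
  nrm <- cross3(b - a, c_ - a)
  tb <- (a + b + c_) / 3
  ib <- (vertices[tets[intra_tet, 1], , drop = FALSE] +
         vertices[tets[intra_tet, 2], , drop = FALSE] +
         vertices[tets[intra_tet, 3], , drop = FALSE] +
         vertices[tets[intra_tet, 4], , drop = FALSE]) / 4
  flip <- rowSums(nrm * (tb - ib)) < 0
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]

  list(tris = tris, cell = cell_of_tet[intra_tet], intra_tet = intra_tet,
       outer_vertices = outer_vertices)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

resolve_patches <- function(patch_assign, vertices, m) {
  k <- nrow(m$tris)
  if (k == 0) return(character())
  if (is.function(patch_assign)) {
    a <- vertices[m$tris[, 1], , drop = FALSE]
    b <- vertices[m$tris[, 2], , drop = FALSE]
    c_ <- vertices[m$tris[, 3], , drop = FALSE]
    bary <- (a + b + c_) / 3
    nrm <- cross3(b - a, c_ - a)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    patch <- patch_assign(bary, m$cell, nrm)
  } else if (length(patch_assign) == 1 && is.null(names(patch_assign))) {
    patch <- rep(patch_assign, k)
  } else {
    lo <- pmin(m$tris[, 1], m$tris[, 2], m$tris[, 3])
    hi <- pmax(m$tris[, 1], m$tris[, 2], m$tris[, 3])
    mid <- rowSums(m$tris) - lo - hi
    patch <- unname(patch_assign[paste(lo, mid, hi, sep = "-")])
    if (anyNA(patch)) stop("patch table does not cover every membrane triangle")
  }
  if (length(patch) != k) stop("patch assignment has wrong length")
  if (!all(patch %in% PATCHES))
    stop("unknown membrane patch label(s): ",
         paste(setdiff(unique(patch), PATCHES), collapse = ", "))
  patch
}

#' Membrane triangle geometry
#'
#' Areas, unit normals (pointing intra -> extra) and barycenters of the
#' membrane triangles.
#' @param mesh a [nc_mesh()].
#' @return list with `area` (um^2), `normal` (k x 3), `bary` (k x 3).
#' @export
membrane_geometry <- function(mesh) {
  tris <- mesh$membrane_tris
  a <- mesh$vertices[tris[, 1], , drop = FALSE]
  b <- mesh$vertices[tris[, 2], , drop = FALSE]
  c_ <- mesh$vertices[tris[, 3], , drop = FALSE]
  n2 <- cross3(b - a, c_ - a)
  len <- sqrt(rowSums(n2^2))
  list(area = len / 2, normal = n2 / len, bary = (a + b + c_) / 3)
}

#' Uniform (red) refinement of a tetrahedral mesh
#'
#' Splits every tetrahedron into eight children through its edge midpoints
#' (four corner tetrahedra plus a central octahedron cut along its shortest
#' diagonal). Subdomain, cell and membrane patch labels are inherited; the
#' total volume is preserved exactly and the tetrahedron count multiplies
#' by eight.
#'
#' @param mesh a [nc_mesh()].
#' @return the refined [nc_mesh()].
#' @export
refine_mesh <- function(mesh) {
  v <- mesh$vertices
  tets <- mesh$tets
  m <- nrow(tets)

  # global edge midpoint table
  ed <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
              tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
  key <- (lo - 1) * nrow(v) + hi  # exact numeric edge key
  uk <- !duplicated(key)
  mid_ids <- nrow(v) + match(key, key[uk])
  newv <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
  v2 <- rbind(v, newv)

  M <- matrix(mid_ids, nrow = m, ncol = 6)  # columns: 12,13,14,23,24,34
  p1 <- tets[, 1]; p2 <- tets[, 2]; p3 <- tets[, 3]; p4 <- tets[, 4]
  m12 <- M[, 1]; m13 <- M[, 2]; m14 <- M[, 3]
  m23 <- M[, 4]; m24 <- M[, 5]; m34 <- M[, 6]

  corner <- rbind(cbind(p1, m12, m13, m14), cbind(m12, p2, m23, m24),
                  cbind(m13, m23, p3, m34), cbind(m14, m24, m34, p4))
  # central octahedron vertices m12 m13 m14 m23 m24 m34; the three diagonals
  # are (m12,m34), (m13,m24), (m14,m23). Cut along the shortest one.
  d1 <- rowSums((v2[m12, , drop = FALSE] - v2[m34, , drop = FALSE])^2)
  d2 <- rowSums((v2[m13, , drop = FALSE] - v2[m24, , drop = FALSE])^2)
  d3 <- rowSums((v2[m14, , drop = FALSE] - v2[m23, , drop = FALSE])^2)
  which_d <- max.col(-cbind(d1, d2, d3), ties.method = "first")

  oct <- matrix(0L, 4 * m, 4)
  for (case in 1:3) {
    idx <- which(which_d == case)
    if (!length(idx)) next
    if (case == 1) {        # diagonal m12-m34
      t_ <- rbind(cbind(m12[idx], m34[idx], m13[idx], m14[idx]),
                  cbind(m12[idx], m34[idx], m14[idx], m24[idx]),
                  cbind(m12[idx], m34[idx], m24[idx], m23[idx]),
                  cbind(m12[idx], m34[idx], m23[idx], m13[idx]))
    } else if (case == 2) { # diagonal m13-m24
      t_ <- rbind(cbind(m13[idx], m24[idx], m12[idx], m14[idx]),
                  cbind(m13[idx], m24[idx], m14[idx], m34[idx]),
                  cbind(m13[idx], m24[idx], m34[idx], m23[idx]),
                  cbind(m13[idx], m24[idx], m23[idx], m12[idx]))
    } else {                # diagonal m14-m23
      t_ <- rbind(cbind(m14[idx], m23[idx], m12[idx], m24[idx]),
                  cbind(m14[idx], m23[idx], m24[idx], m34[idx]),
                  cbind(m14[idx], m23[idx], m34[idx], m13[idx]),
                  cbind(m14[idx], m23[idx], m13[idx], m12[idx]))
    }
    rows <- rep(idx, 4) + m * rep(0:3, each = length(idx))
    oct[rows, ] <- t_
  }

  tets2 <- rbind(corner, oct)
  sub2 <- rep(mesh$subdomain, 8)
  cell2 <- rep(mesh$cell_of_tet, 8)

  # inherit patch labels: children of membrane tri (a,b,c) with midpoints
  mt <- mesh$membrane_tris
  patch_tab <- character()
  if (nrow(mt)) {
    ekey <- function(i, j) (pmin(i, j) - 1) * nrow(v) + pmax(i, j)
    all_mid <- function(i, j) nrow(v) + match(ekey(i, j), key[uk])
    a <- mt[, 1]; b <- mt[, 2]; c_ <- mt[, 3]
    mab <- all_mid(a, b); mac <- all_mid(a, c_); mbc <- all_mid(b, c_)
    ch <- rbind(cbind(a, mab, mac), cbind(mab, b, mbc),
                cbind(mac, mbc, c_), cbind(mab, mbc, mac))
    lo <- pmin(ch[, 1], ch[, 2], ch[, 3]); hi <- pmax(ch[, 1], ch[, 2], ch[, 3])
    midc <- rowSums(ch) - lo - hi
    patch_tab <- stats::setNames(rep(mesh$patch_of_tri, 4),
                                 paste(lo, midc, hi, sep = "-"))
  }

  nc_mesh(v2, tets2, sub2, cell2,
          patch_assign = if (length(patch_tab)) patch_tab else "ACTIVE",
          markers = mesh$markers)
}
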