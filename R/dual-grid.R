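# Barycentric (box-method) dual grid. Each tetrahedron is subdivided by its
# edge midpoints, face barycenters and barycenter; the corner piece around
# each vertex joins that vertex's control volume B_k. The finite-volume
# operators integrate fluxes over the polygonal sub-faces separating the
# corner pieces inside every tetrahedron.

# Per-tet dual sub-face integrated normals. For each tet and each of its six
# edges (local pairs 12,13,14,23,24,34) the dual face separating the two
# corner control volumes is the quad (edge midpoint, face barycenter,
# tet barycenter, other face barycenter); its area-weighted normal is
# returned oriented from the lower to the higher local vertex.
# Returns an array dim (ntet, 6, 3).
tet_dual_normals <- function(vertices, tets) {
  nt <- nrow(tets)
  x <- lapply(1:4, function(i) vertices[tets[, i], , drop = FALSE])
  cbar <- (x[[1]] + x[[2]] + x[[3]] + x[[4]]) / 4
  # face barycenter opposite local vertex l
  fb <- lapply(1:4, function(l) {
    oth <- setdiff(1:4, l)
    (x[[oth[1]]] + x[[oth[2]]] + x[[oth[3]]]) / 3
  })
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  out <- array(0, dim = c(nt, 6, 3))
  for (e in 1:6) {
    i <- edges[e, 1]; j <- edges[e, 2]
    oth <- setdiff(1:4, c(i, j))
    m <- (x[[i]] + x[[j]]) / 2
    fa <- fb[[oth[1]]]  # face containing edge (i,j), opposite oth[1]
    fbq <- fb[[oth[2]]]
    n1 <- cross3(fa - m, cbar - m) / 2
    n2 <- cross3(cbar - m, fbq - m) / 2
    N <- n1 + n2
    s <- sign(rowSums(N * (x[[j]] - x[[i]])))
    out[, e, ] <- N * s
  }
  out
}

# Constant P1 shape-function gradients per tet: array (ntet, 4, 3).
tet_shape_gradients <- function(vertices, tets) {
  nt <- nrow(tets)
  a <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - a
  e2 <- vertices[tets[, 3], , drop = FALSE] - a
  e3 <- vertices[tets[, 4], , drop = FALSE] - a
  # rows of inv(J)^T where J = [e1; e2; e3]: grad b_{i+1} = cof_i / det
  c1 <- cross3(e2, e3)
  c2 <- cross3(e3, e1)
  c3 <- cross3(e1, e2)
  det <- rowSums(e1 * c1)
  g <- array(0, dim = c(nt, 4, 3))
  g[, 2, ] <- c1 / det
  g[, 3, ] <- c2 / det
  g[, 4, ] <- c3 / det
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  g
}

#' Build the barycentric dual grid
#'
#' Constructs per-vertex control volumes split by subdomain, aggregated
#' sub-face normals per mesh edge, and per-vertex membrane areas split by
#' patch label. Control volumes partition each subdomain's volume exactly
#' (each tetrahedron contributes a quarter of its volume to each corner;
#' each membrane triangle a third of its area to each corner).
#'
#' @param mesh a [nc_mesh()].
#' @param subfaces logical; aggregate the per-edge sub-face normals (needed
#'   only for diagnostics; the solver uses the per-tetrahedron normals
#'   directly).
#' @return object of class `nc_dual` with elements
#'   \describe{
#'     \item{volume_intra, volume_extra}{numeric vectors over all vertices
#'       (um^3), zero where a vertex has no control volume in the subdomain.}
#'     \item{subface_normals}{data frame (k, j, subdomain, nx, ny, nz):
#'       aggregated area-weighted normal of the dual faces separating B_k and
#'       B_j, oriented k -> j, for every edge k < j of each subdomain.}
#'     \item{membrane}{data frame (vertex, patch, cell, area): membrane area
#'       of Gamma intersected with each control volume, per patch label.}
#'   }
#' @export
build_dual_grid <- function(mesh, subfaces = TRUE) {
  v <- mesh$vertices
  tets <- mesh$tets
  nv <- nrow(v)
  vol <- tet_volumes(mesh)

  acc <- function(sel) {
    out <- numeric(nv)
    if (any(sel)) {
      idx <- as.vector(tets[sel, , drop = FALSE])
      w <- rep(vol[sel] / 4, 4)
      out <- unname(tapply2(idx, w, nv))
    }
    out
  }
  vol_in <- acc(mesh$subdomain == "INTRA")
  vol_ex <- acc(mesh$subdomain == "EXTRA")

  # aggregated edge normals per subdomain
  sf <- list()
  if (subfaces) {
  nrm <- tet_dual_normals(v, tets)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (sd in SUBDOMAINS) {
    sel <- mesh$subdomain == sd
    if (!any(sel)) next
    ts <- tets[sel, , drop = FALSE]
    ns <- nrm[sel, , , drop = FALSE]
    kk <- jj <- integer(0); NN <- NULL
    for (e in 1:6) {
      i <- ts[, edges[e, 1]]; j <- ts[, edges[e, 2]]
      Ne <- ns[, e, ]
      if (is.null(dim(Ne))) Ne <- matrix(Ne, ncol = 3)
      flip <- i > j
      tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
      Ne[flip, ] <- -Ne[flip, , drop = FALSE]
      kk <- c(kk, i); jj <- c(jj, j)
      NN <- rbind(NN, Ne)
    }
    key <- paste(kk, jj, sep = "-")
    agg <- rowsum(NN, key)
    ks <- as.integer(sub("-.*", "", rownames(agg)))
    js <- as.integer(sub(".*-", "", rownames(agg)))
    sf[[sd]] <- data.frame(k = ks, j = js, subdomain = sd,
                           nx = agg[, 1], ny = agg[, 2], nz = agg[, 3])
  }
  }
  subface <- if (length(sf)) do.call(rbind, sf) else NULL
  if (!is.null(subface)) rownames(subface) <- NULL

  # membrane areas per vertex and patch
  mem <- NULL
  if (nrow(mesh$membrane_tris)) {
    mg <- membrane_geometry(mesh)
    vtx <- as.vector(t(mesh$membrane_tris))
    patch <- rep(mesh$patch_of_tri, each = 3)
    cell <- rep(mesh$cell_of_tri, each = 3)
    area <- rep(mg$area / 3, each = 3)
    key <- paste(vtx, patch, cell, sep = "|")
    a <- rowsum(area, key)
    parts <- strsplit(rownames(a), "|", fixed = TRUE)
    mem <- data.frame(vertex = as.integer(vapply(parts, `[`, "", 1)),
                      patch = vapply(parts, `[`, "", 2),
                      cell = as.integer(vapply(parts, `[`, "", 3)),
                      area = a[, 1])
    rownames(mem) <- NULL
  }

  structure(list(volume_intra = vol_in, volume_extra = vol_ex,
                 subface_normals = subface, membrane = mem),
            class = "nc_dual")
}

# fast accumulate: sum w by integer index into a vector of length n
tapply2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
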