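# Mesh file I/O: VTK unstructured XML (.vtu) and Gmsh MSH 4.1, ASCII.
# Subdomain, cell and patch labels travel as cell data (vtu) or physical
# groups (msh). Round trips preserve coordinates to full double precision
# (written with 17 significant digits), connectivity and all labels.
# Binary variants of either format are rejected with a clear error.

PATCH_CODE <- stats::setNames(seq_along(PATCHES), PATCHES)

#' Write a labeled mesh to disk
#'
#' @param mesh a [nc_mesh()].
#' @param path output file path.
#' @param format `"vtu"` (VTK unstructured XML, ASCII) or `"msh"`
#'   (Gmsh 4.1, ASCII); guessed from the file extension by default.
#' @param point_data optional named list of per-vertex numeric vectors
#'   written as point data (vtu only), e.g. field snapshots.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtu", "msh"),
                       point_data = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     vtu = "vtu", msh = "msh",
                     stop("unknown mesh format for extension '",
                          tools::file_ext(path), "' (use vtu or msh)"))
  if (format == "vtu") write_vtu(mesh, path, point_data) else write_msh(mesh, path)
  invisible(path)
}

#' Read a labeled mesh from disk
#'
#' Accepts the ASCII subsets of VTK unstructured XML and Gmsh MSH 4.1 that
#' [write_mesh()] produces (tetrahedra carrying subdomain and cell labels,
#' membrane triangles carrying patch labels). Meshes without subdomain
#' labels are rejected.
#'
#' @param path input file path.
#' @param format `"vtu"`, `"msh"`, or `"auto"` (from the extension).
#' @return a [nc_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "vtu", "msh")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     vtu = "vtu", msh = "msh",
                     stop("unknown mesh format for extension '",
                          tools::file_ext(path), "'"))
  if (format == "vtu") read_vtu(path) else read_msh(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# ---- VTU --------------------------------------------------------------------

write_vtu <- function(mesh, path, point_data = NULL) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$tets)
  nm <- nrow(mesh$membrane_tris)
  con <- c(as.vector(t(mesh$tets)) - 1L, as.vector(t(mesh$membrane_tris)) - 1L)
  off <- c(seq_len(nt) * 4L, nt * 4L + seq_len(nm) * 3L)
  types <- c(rep(10L, nt), rep(5L, nm))
  sub <- c(ifelse(mesh$subdomain == "INTRA", 1L, 2L), rep(0L, nm))
  cid <- c(mesh$cell_of_tet, mesh$cell_of_tri)
  pat <- c(rep(0L, nt), unname(PATCH_CODE[mesh$patch_of_tri]))

  da <- function(name, type, values, ncomp = NULL) {
    c(sprintf("<DataArray type=\"%s\" Name=\"%s\"%s format=\"ascii\">", type,
              name, if (is.null(ncomp)) "" else sprintf(" NumberOfComponents=\"%d\"", ncomp)),
      paste(values, collapse = " "), "</DataArray>")
  }
  lines <- c(
    "<?xml version=\"1.0\"?>",
    "<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">",
    "<UnstructuredGrid>",
    sprintf("<Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", nv, nt + nm),
    "<Points>",
    da("Points", "Float64", fmt_num(as.vector(t(mesh$vertices))), ncomp = 3),
    "</Points>", "<Cells>",
    da("connectivity", "Int32", con), da("offsets", "Int32", off),
    da("types", "UInt8", types), "</Cells>", "<CellData>",
    da("subdomain", "Int32", sub), da("cell_id", "Int32", cid),
    da("patch", "Int32", pat), "</CellData>")
  if (!is.null(point_data)) {
    lines <- c(lines, "<PointData>")
    for (nm_ in names(point_data))
      lines <- c(lines, da(nm_, "Float64", fmt_num(point_data[[nm_]])))
    lines <- c(lines, "</PointData>")
  }
  lines <- c(lines, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(lines, path)
}

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(xml2::xml_name(piece))) stop("not a VTK UnstructuredGrid file")
  get_da <- function(xpath, required = TRUE) {
    node <- xml2::xml_find_first(doc, xpath)
    if (is.na(xml2::xml_name(node))) {
      if (required) stop("missing DataArray: ", xpath)
      return(NULL)
    }
    fmt <- xml2::xml_attr(node, "format")
    if (!identical(fmt, "ascii"))
      stop("only ASCII .vtu is supported (found format '", fmt, "')")
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- get_da(".//Points/DataArray")
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  con <- as.integer(get_da(".//Cells/DataArray[@Name='connectivity']")) + 1L
  off <- as.integer(get_da(".//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(get_da(".//Cells/DataArray[@Name='types']"))
  sub <- get_da(".//CellData/DataArray[@Name='subdomain']", required = FALSE)
  cid <- get_da(".//CellData/DataArray[@Name='cell_id']", required = FALSE)
  pat <- get_da(".//CellData/DataArray[@Name='patch']", required = FALSE)
  if (is.null(sub)) stop("mesh file carries no subdomain labels")

  starts <- c(1, utils::head(off, -1) + 1)
  is_tet <- types == 10
  is_tri <- types == 5
  tets <- t(vapply(which(is_tet), function(k) con[starts[k]:(starts[k] + 3)],
                   integer(4)))
  sub_t <- sub[is_tet]
  if (any(sub_t == 0)) stop("mesh file carries unlabeled tetrahedra")
  subdomain <- ifelse(sub_t == 1, "INTRA", "EXTRA")
  cell_of_tet <- if (is.null(cid)) NULL else as.integer(cid[is_tet])

  patch_assign <- "ACTIVE"
  if (any(is_tri) && !is.null(pat)) {
    tris <- t(vapply(which(is_tri), function(k) con[starts[k]:(starts[k] + 2)],
                     integer(3)))
    lo <- pmin(tris[, 1], tris[, 2], tris[, 3])
    hi <- pmax(tris[, 1], tris[, 2], tris[, 3])
    mid <- rowSums(tris) - lo - hi
    patch_assign <- stats::setNames(PATCHES[pat[is_tri]],
                                    paste(lo, mid, hi, sep = "-"))
  }
  nc_mesh(verts, tets, subdomain, cell_of_tet, patch_assign = patch_assign)
}

# ---- Gmsh MSH 4.1 -----------------------------------------------------------

write_msh <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  # physical groups: volumes 1 = EXTRA, 100+cell = INTRA cell; surfaces
  # 200 + patch_code*100? keep simple: 200 + patch code + 10*cell
  vol_tag <- ifelse(mesh$subdomain == "EXTRA", 1L, 100L + mesh$cell_of_tet)
  surf_tag <- 200L + unname(PATCH_CODE[mesh$patch_of_tri]) +
    10L * mesh$cell_of_tri
  uvol <- sort(unique(vol_tag))
  usurf <- sort(unique(surf_tag))

  pn <- c(sprintf("2 %d \"%s\"", usurf,
                  paste0("PATCH_", PATCHES[(usurf - 200L) %% 10L],
                         "_cell_", (usurf - 200L) %/% 10L)),
          sprintf("3 %d \"%s\"", uvol,
                  ifelse(uvol == 1L, "EXTRA", paste0("INTRA_cell_", uvol - 100L))))
  bb <- apply(mesh$vertices, 2, range)
  ent_s <- sprintf("%d %s %s 1 %d", usurf,
                   paste(fmt_num(bb[1, ]), collapse = " "),
                   paste(fmt_num(bb[2, ]), collapse = " "), usurf)
  ent_v <- sprintf("%d %s %s 1 %d 0", uvol,
                   paste(fmt_num(bb[1, ]), collapse = " "),
                   paste(fmt_num(bb[2, ]), collapse = " "), uvol)

  lines <- c("$MeshFormat", "4.1 0 8", "$EndMeshFormat",
             "$PhysicalNames", length(pn), pn, "$EndPhysicalNames",
             "$Entities",
             sprintf("0 0 %d %d", length(usurf), length(uvol)),
             ent_s, ent_v, "$EndEntities")

  # nodes: single block attached to the first volume entity
  lines <- c(lines, "$Nodes",
             sprintf("1 %d 1 %d", nv, nv),
             sprintf("3 %d 0 %d", uvol[1], nv),
             as.character(seq_len(nv)),
             apply(mesh$vertices, 1, function(r) paste(fmt_num(r), collapse = " ")),
             "$EndNodes")

  # elements: one block per entity
  blocks <- character(0)
  eid <- 0L
  nblk <- 0L
  for (s in usurf) {
    idx <- which(surf_tag == s)
    tri <- mesh$membrane_tris[idx, , drop = FALSE]
    blocks <- c(blocks, sprintf("2 %d 2 %d", s, length(idx)),
                paste(eid + seq_along(idx), tri[, 1], tri[, 2], tri[, 3]))
    eid <- eid + length(idx); nblk <- nblk + 1L
  }
  for (vtag in uvol) {
    idx <- which(vol_tag == vtag)
    tt <- mesh$tets[idx, , drop = FALSE]
    blocks <- c(blocks, sprintf("3 %d 4 %d", vtag, length(idx)),
                paste(eid + seq_along(idx), tt[, 1], tt[, 2], tt[, 3], tt[, 4]))
    eid <- eid + length(idx); nblk <- nblk + 1L
  }
  lines <- c(lines, "$Elements",
             sprintf("%d %d 1 %d", nblk, eid, eid), blocks, "$EndElements")
  writeLines(lines, path)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    a <- match(paste0("$", name), lines)
    b <- match(paste0("$End", name), lines)
    if (is.na(a) || is.na(b)) return(NULL)
    lines[(a + 1):(b - 1)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh MSH file")
  f <- scan(text = fmt[1], quiet = TRUE)
  if (f[2] != 0) stop("only ASCII MSH is supported (binary flag set)")
  if (f[1] < 4.1 - 1e-9) stop("only MSH format 4.1 is supported, found ", f[1])

  # physical names -> entity tag meaning
  pn <- sect("PhysicalNames")
  if (is.null(pn)) stop("mesh file carries no physical groups (labels required)")
  pn <- pn[-1]
  ptag <- as.integer(vapply(strsplit(pn, " "), `[`, "", 2))
  pname <- gsub("\"", "", vapply(strsplit(pn, " "), `[`, "", 3))

  nd <- sect("Nodes")
  hdr <- scan(text = nd[1], quiet = TRUE)
  nnodes <- hdr[2]
  # parse blocks
  pos <- 2
  tags <- integer(0); coords <- NULL
  while (pos <= length(nd) && length(tags) < nnodes) {
    bh <- scan(text = nd[pos], quiet = TRUE)
    nb <- bh[4]
    btags <- as.integer(nd[pos + seq_len(nb)])
    bcoord <- do.call(rbind, lapply(nd[pos + nb + seq_len(nb)], function(s)
      scan(text = s, quiet = TRUE)))
    tags <- c(tags, btags); coords <- rbind(coords, bcoord[, 1:3, drop = FALSE])
    pos <- pos + 2 * nb + 1
  }
  verts <- matrix(NA_real_, max(tags), 3)
  verts[tags, ] <- coords

  el <- sect("Elements")
  hdr <- scan(text = el[1], quiet = TRUE)
  nblk <- hdr[1]
  pos <- 2
  tets <- NULL; vol_tags <- integer(0)
  tris <- NULL; tri_tags <- integer(0)
  for (b in seq_len(nblk)) {
    bh <- scan(text = el[pos], quiet = TRUE)
    edim <- bh[1]; etag <- bh[2]; etype <- bh[3]; ne <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(ne)], function(s)
      as.integer(scan(text = s, quiet = TRUE))))
    if (etype == 4) {        # 4-node tet
      tets <- rbind(tets, rows[, 2:5, drop = FALSE])
      vol_tags <- c(vol_tags, rep(etag, ne))
    } else if (etype == 2) { # 3-node triangle
      tris <- rbind(tris, rows[, 2:4, drop = FALSE])
      tri_tags <- c(tri_tags, rep(etag, ne))
    }
    pos <- pos + ne + 1
  }
  if (is.null(tets)) stop("mesh file contains no tetrahedra")
  name_of <- stats::setNames(pname, ptag)
  vn <- name_of[as.character(vol_tags)]
  if (anyNA(vn)) stop("mesh file carries unlabeled tetrahedra")
  subdomain <- ifelse(vn == "EXTRA", "EXTRA", "INTRA")
  cell_of_tet <- integer(length(vn))
  ii <- subdomain == "INTRA"
  cell_of_tet[ii] <- as.integer(sub("INTRA_cell_", "", vn[ii]))

  patch_assign <- "ACTIVE"
  if (!is.null(tris)) {
    tn <- name_of[as.character(tri_tags)]
    lab <- sub("_cell_.*$", "", sub("^PATCH_", "", tn))
    lo <- pmin(tris[, 1], tris[, 2], tris[, 3])
    hi <- pmax(tris[, 1], tris[, 2], tris[, 3])
    mid <- rowSums(tris) - lo - hi
    patch_assign <- stats::setNames(lab, paste(lo, mid, hi, sep = "-"))
  }
  nc_mesh(verts, tets, subdomain, cell_of_tet, patch_assign = patch_assign)
}
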