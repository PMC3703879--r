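#' @include meshing.R
NULL

## Mesh I/O: Gmsh MSH 4.1 (ASCII) round-trip with region and face-group
## preservation, and VTU (ASCII XML) export for visualization.

## gmsh tet10 ordering differs from VTK in the last two mid-edge nodes
.vtkToGmsh <- c(1:8, 10, 9)

#' Write a Tet10Mesh as Gmsh MSH 4.1 (ASCII)
#'
#' Regions are written as 3D physical groups, face groups as 2D physical
#' groups of 6-node triangles.  Coordinates are printed with 17 significant
#' digits so a write/read round trip is bit-exact.
#'
#' @param mesh a \code{\link{Tet10Mesh}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeMSH <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  regions <- sort(unique(mesh@regionTag))
  fgroups <- names(mesh@faceGroups)
  fgroups <- fgroups[vapply(mesh@faceGroups, nrow, 1L) > 0]
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(regions) + length(fgroups)))
  for (i in seq_along(fgroups)) w(sprintf('2 %d "%s"', i, fgroups[i]))
  for (i in seq_along(regions))
    w(sprintf('3 %d "%s"', length(fgroups) + i, regions[i]))
  w("$EndPhysicalNames")
  n <- nNodes(mesh)
  w("$Nodes", sprintf("1 %d 1 %d", n, n), sprintf("3 1 0 %d", n))
  w(format(seq_len(n)))
  w(sprintf("%.17g %.17g %.17g", mesh@nodes[, 1], mesh@nodes[, 2],
            mesh@nodes[, 3]))
  w("$EndNodes")
  nblk <- length(regions) + length(fgroups)
  ntot <- nElements(mesh) + sum(vapply(mesh@faceGroups[fgroups], nrow, 1L))
  w("$Elements", sprintf("%d %d 1 %d", nblk, ntot, ntot))
  eid <- 1L
  for (i in seq_along(fgroups)) {
    ff <- mesh@faceGroups[[fgroups[i]]]
    w(sprintf("2 %d 9 %d", i, nrow(ff)))
    ids <- eid:(eid + nrow(ff) - 1L)
    w(paste(ids, ff[, 1], ff[, 2], ff[, 3], ff[, 4], ff[, 5], ff[, 6]))
    eid <- eid + nrow(ff)
  }
  for (i in seq_along(regions)) {
    sel <- which(mesh@regionTag == regions[i])
    el <- mesh@elems[sel, .vtkToGmsh, drop = FALSE]
    w(sprintf("3 %d 11 %d", length(fgroups) + i, length(sel)))
    ids <- eid:(eid + length(sel) - 1L)
    w(paste(ids, el[, 1], el[, 2], el[, 3], el[, 4], el[, 5], el[, 6],
            el[, 7], el[, 8], el[, 9], el[, 10]))
    eid <- eid + length(sel)
  }
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 4.1 (ASCII) file written by \code{\link{writeMSH}}
#'
#' @param path input file
#' @return a \code{\link{Tet10Mesh}} (quality recomputed)
#' @export
readMSH <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name)) + 1L
    b <- which(lines == paste0("$End", name)) - 1L
    lines[a:b]
  }
  pn <- sec("PhysicalNames")
  npn <- as.integer(pn[1])
  pdim <- integer(npn); ptag <- integer(npn); pname <- character(npn)
  for (i in seq_len(npn)) {
    parts <- strsplit(pn[1 + i], " ")[[1]]
    pdim[i] <- as.integer(parts[1]); ptag[i] <- as.integer(parts[2])
    pname[i] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  nd <- sec("Nodes")
  hdr <- as.integer(strsplit(nd[1], " ")[[1]])
  nn <- hdr[2]
  coords <- do.call(rbind, strsplit(nd[(3 + nn):(2 + 2 * nn)], " "))
  nodes <- matrix(as.numeric(coords), nn, 3)
  el <- sec("Elements")
  hdr <- as.integer(strsplit(el[1], " ")[[1]])
  pos <- 2L
  tets <- NULL; tags <- character(0)
  fgroups <- list()
  for (b in seq_len(hdr[1])) {
    bh <- as.integer(strsplit(el[pos], " ")[[1]])
    cnt <- bh[4]
    body <- el[(pos + 1L):(pos + cnt)]
    M <- do.call(rbind, lapply(strsplit(body, " +"), as.integer))
    nm <- pname[pdim == bh[1] & ptag == bh[2]]
    if (bh[3] == 9) {
      fgroups[[nm]] <- unname(M[, 2:7, drop = FALSE])
    } else if (bh[3] == 11) {
      e <- M[, 2:11, drop = FALSE][, order(.vtkToGmsh), drop = FALSE]
      tets <- rbind(tets, e)
      tags <- c(tags, rep(nm, cnt))
    }
    pos <- pos + 1L + cnt
  }
  for (gn in c("coronal_cuts", "load_patch", "free_surface",
               "bone_implant_interface"))
    if (is.null(fgroups[[gn]])) fgroups[[gn]] <- matrix(0L, 0, 6)
  q <- as.numeric(tet_quality(nodes, tets[, 1:4, drop = FALSE]))
  new("Tet10Mesh", nodes = nodes, elems = tets, regionTag = tags,
      faceGroups = fgroups, quality = q, info = list(source = path))
}

#' Export mesh and fields as VTU (ASCII)
#'
#' Writes quadratic tetrahedra (VTK cell type 24) with optional nodal point
#' data (e.g. displacements) and per-element cell data (e.g. region id,
#' element-mean stresses) for inspection in ParaView.
#'
#' @param mesh a \code{\link{Tet10Mesh}}
#' @param path output .vtu file
#' @param pointData named list of per-node vectors/matrices
#' @param cellData named list of per-element vectors/matrices
#' @return the path, invisibly
#' @export
writeVTU <- function(mesh, path, pointData = list(), cellData = list()) {
  n <- nNodes(mesh); m <- nElements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w("<Points>",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(apply(mesh@nodes, 1, num), collapse = "\n"))
  w("</DataArray>", "</Points>")
  w("<Cells>", '<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(apply(mesh@elems - 1L, 1, paste, collapse = " "), collapse = "\n"))
  w("</DataArray>",
    '<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 10L, collapse = " "))
  w("</DataArray>", '<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(24L, m), collapse = " "))
  w("</DataArray>", "</Cells>")
  writeArrays <- function(data, count) {
    for (nm in names(data)) {
      v <- data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      if (is.matrix(v)) w(paste(apply(v, 1, num), collapse = "\n"))
      else w(paste(format(v, digits = 9, trim = TRUE), collapse = " "))
      w("</DataArray>")
    }
  }
  w("<PointData>"); writeArrays(pointData, n); w("</PointData>")
  cellData <- c(list(region = as.numeric(factor(mesh@regionTag))), cellData)
  w("<CellData>"); writeArrays(cellData, m); w("</CellData>")
  w("</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  invisible(path)
}
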