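# Isosurface extraction and triangle-mesh export. The extractor is a
# marching-tetrahedra variant: each grid cube is split into the six Kuhn
# tetrahedra around the (0,0,0)-(1,1,1) diagonal, which splits shared cube
# faces identically from both sides (no cracks), and each tetrahedron
# contributes 0, 1 or 2 triangles with vertices placed by linear
# interpolation along crossing edges. Triangles are oriented so normals
# point from the >= level side towards the < level side (outward for a
# hotspot). This variant is fixed — it is part of the package's
# reproducibility contract.

# cube corner c has 0/1 offsets (dx,dy,dz) with c = dx + 2*dy + 4*dz + 1
CUBE_OFFSETS <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

# Kuhn 6-tetrahedra decomposition (1-based corner ids)
KUHN_TETS <- matrix(c(1, 2, 4, 8,
                      1, 2, 6, 8,
                      1, 3, 4, 8,
                      1, 3, 7, 8,
                      1, 5, 6, 8,
                      1, 5, 7, 8), ncol = 4, byrow = TRUE)

# per-case triangle table: for inside-sets of a tetrahedron's 4 vertices,
# triangles given as rows of (inside vertex, outside vertex) edges
tet_case_table <- local({
  lapply(0:15, function(code) {
    ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0)
    outs <- setdiff(1:4, ins)
    if (length(ins) %in% c(0L, 4L)) return(NULL)
    tris <- if (length(ins) == 1L) {
      list(rbind(c(ins, outs[1]), c(ins, outs[2]), c(ins, outs[3])))
    } else if (length(ins) == 3L) {
      list(rbind(c(ins[1], outs), c(ins[2], outs), c(ins[3], outs)))
    } else {
      a <- ins[1]; b <- ins[2]; cc <- outs[1]; dd <- outs[2]
      q <- rbind(c(a, cc), c(a, dd), c(b, dd), c(b, cc))
      list(q[c(1, 2, 3), ], q[c(1, 3, 4), ])
    }
    list(ins = ins, outs = outs, tris = tris)
  })
})

#' Triangle mesh
#'
#' Vertices in millimetres (world or anatomic coordinates, tagged by
#' `frame`), faces as 1-based vertex-index triples with consistent outward
#' orientation, and a scalar label (`"bone"`, `"hotspot"`, ...). Degenerate
#' faces (repeated vertex index) are rejected; an empty mesh is valid.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label Scalar label string.
#' @param frame Coordinate tag, e.g. `"world"` or `"anatomic"`.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, label = "surface",
                          frame = "world") {
  vertices <- if (length(vertices) == 0L) matrix(numeric(0), 0, 3) else
    rbind_pts(vertices)
  faces <- if (length(faces) == 0L) matrix(integer(0), 0, 3) else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    faces
  }
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
      stop("faces must not repeat a vertex")
    }
  }
  structure(list(vertices = vertices, faces = faces, label = label,
                 frame = frame),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s' (%s frame): %d vertices, %d faces>\n",
              x$label, x$frame, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract an isosurface mesh from a volume
#'
#' Marching-tetrahedra isosurface at `level`, with vertices mapped through
#' the volume affine into world mm (and then into an anatomical frame when
#' one is given). The surface encloses the region with intensity >= level;
#' triangle normals point outward. A level outside the data range yields an
#' empty mesh.
#'
#' @param vol An [image_volume()].
#' @param level Iso level in raw intensity units (finite).
#' @param frame Optional `anatomic_frame`; vertices are reported in its
#'   coordinates and the mesh tagged `"anatomic"`.
#' @param label Mesh label (default by modality: CT -> bone,
#'   SPECT -> hotspot).
#' @return A [triangle_mesh()].
#' @export
extract_isosurface <- function(vol, level, frame = NULL, label = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level)) {
    stop("iso level must be a finite number")
  }
  label <- label %||% if (vol$modality == "CT") "bone" else "hotspot"
  frame_tag <- if (is.null(frame)) "world" else "anatomic"
  d <- dim(vol$voxels)
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                         label = label, frame = frame_tag)
  if (any(d < 2L) || level <= min(vol$voxels) || level > max(vol$voxels)) {
    return(empty)
  }
  v <- vol$voxels
  nc <- d - 1L
  # 8 shifted views giving each cube's corner values; prefilter straddling
  corner_val <- function(cid) {
    o <- CUBE_OFFSETS[cid, ]
    v[(1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]),
      (1 + o[3]):(nc[3] + o[3])]
  }
  vmin <- corner_val(1); vmax <- vmin
  for (cid in 2:8) {
    cv <- corner_val(cid)
    vmin <- pmin(vmin, cv)
    vmax <- pmax(vmax, cv)
  }
  active <- which(vmax >= level & vmin < level)
  if (length(active) == 0L) return(empty)
  base <- arrayInd(active, nc) - 1L            # cube base voxel, 0-based
  vals8 <- matrix(0, length(active), 8)
  for (cid in 1:8) vals8[, cid] <- corner_val(cid)[active]
  tri_a <- list(); tri_b <- list(); tri_c <- list()
  ref_in <- list(); ref_out <- list()
  for (tt in seq_len(nrow(KUHN_TETS))) {
    corners <- KUHN_TETS[tt, ]
    tv <- vals8[, corners, drop = FALSE]
    inside <- tv >= level
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] +
      8L * inside[, 4]
    for (cs in 1:14) {
      entry <- tet_case_table[[cs + 1L]]
      if (is.null(entry)) next
      sel <- which(code == cs)
      if (length(sel) == 0L) next
      bsel <- base[sel, , drop = FALSE]
      vsel <- tv[sel, , drop = FALSE]
      pos <- function(tvert) {          # index-space position of tet vertex
        bsel + matrix(CUBE_OFFSETS[corners[tvert], ], nrow(bsel), 3,
                      byrow = TRUE)
      }
      edge_point <- function(edge) {    # edge = c(inside id, outside id)
        P <- pos(edge[1]); Q <- pos(edge[2])
        vp <- vsel[, edge[1]]; vq <- vsel[, edge[2]]
        t <- (level - vp) / (vq - vp)
        P + t * (Q - P)
      }
      cin <- Reduce(`+`, lapply(entry$ins, pos)) / length(entry$ins)
      cout <- Reduce(`+`, lapply(entry$outs, pos)) / length(entry$outs)
      for (tri in entry$tris) {
        tri_a[[length(tri_a) + 1L]] <- edge_point(tri[1, ])
        tri_b[[length(tri_b) + 1L]] <- edge_point(tri[2, ])
        tri_c[[length(tri_c) + 1L]] <- edge_point(tri[3, ])
        ref_in[[length(ref_in) + 1L]] <- cin
        ref_out[[length(ref_out) + 1L]] <- cout
      }
    }
  }
  A <- do.call(rbind, tri_a); B <- do.call(rbind, tri_b)
  C <- do.call(rbind, tri_c)
  Rin <- do.call(rbind, ref_in); Rout <- do.call(rbind, ref_out)
  to_final <- function(p) {
    w <- index_to_world(vol, p)
    if (is.null(frame)) w else world_to_anatomic(w, frame)
  }
  A <- to_final(A); B <- to_final(B); C <- to_final(C)
  dirw <- to_final(Rout) - to_final(Rin)
  # orient normals from inside (>= level) towards outside
  nrm <- cross_rows(B - A, C - A)
  flip <- rowSums(nrm * dirw) < 0
  if (any(flip)) {
    tmp <- B[flip, , drop = FALSE]
    B[flip, ] <- C[flip, , drop = FALSE]
    C[flip, ] <- tmp
  }
  soup_to_mesh(A, B, C, label = label, frame = frame_tag)
}

cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# merge duplicate vertices (shared tetrahedron edges produce identical
# interpolated points) and drop degenerate triangles
soup_to_mesh <- function(A, B, C, label, frame) {
  pts <- rbind(A, B, C)
  key <- paste(sprintf("%.9g", round(pts[, 1], 7)),
               sprintf("%.9g", round(pts[, 2], 7)),
               sprintf("%.9g", round(pts[, 3], 7)))
  uk <- !duplicated(key)
  verts <- pts[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  ntri <- nrow(A)
  faces <- cbind(idx[seq_len(ntri)],
                 idx[ntri + seq_len(ntri)],
                 idx[2 * ntri + seq_len(ntri)])
  good <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  faces <- faces[good, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  triangle_mesh(verts[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3),
                label = label, frame = frame)
}

#' Surface area and enclosed volume of a mesh
#'
#' Area is the sum of triangle areas; enclosed volume uses the divergence
#' theorem on the outward-oriented faces (sum of signed tetrahedron
#' volumes against the origin).
#'
#' @param mesh A [triangle_mesh()].
#' @return Area in mm^2 / volume in mm^3.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(sqrt(rowSums(cross_rows(B - A, C - A)^2))) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(A * cross_rows(B, C))) / 6
}

#' Write a mesh to STL, PLY or OBJ
#'
#' ASCII variants of the three formats. PLY and OBJ preserve the indexed
#' vertex structure; STL is a triangle soup (faces only) and refuses an
#' empty mesh, which it cannot represent meaningfully.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format `"STL"`, `"PLY"` or `"OBJ"`; default from the extension.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- toupper(format %||% tools::file_ext(path))
  if (!format %in% c("STL", "PLY", "OBJ")) {
    stop("unknown mesh format: ", format)
  }
  V <- mesh$vertices
  F <- mesh$faces
  if (format == "STL") {
    if (nrow(F) == 0L) stop("cannot write an empty mesh as STL")
    A <- V[F[, 1], , drop = FALSE]
    B <- V[F[, 2], , drop = FALSE]
    C <- V[F[, 3], , drop = FALSE]
    n <- cross_rows(B - A, C - A)
    len <- sqrt(rowSums(n^2))
    n <- n / ifelse(len > 0, len, 1)
    lines <- c(
      sprintf("solid %s", mesh$label),
      as.vector(rbind(
        sprintf("  facet normal %.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", A[, 1], A[, 2], A[, 3]),
        sprintf("      vertex %.9g %.9g %.9g", B[, 1], B[, 2], B[, 3]),
        sprintf("      vertex %.9g %.9g %.9g", C[, 1], C[, 2], C[, 3]),
        "    endloop",
        "  endfacet")),
      sprintf("endsolid %s", mesh$label)
    )
  } else if (format == "PLY") {
    lines <- c(
      "ply", "format ascii 1.0",
      sprintf("comment orthospect mesh label=%s frame=%s",
              mesh$label, mesh$frame),
      sprintf("element vertex %d", nrow(V)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(F)),
      "property list uchar int vertex_indices",
      "end_header",
      if (nrow(V) > 0L) sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]),
      if (nrow(F) > 0L) sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L,
                                F[, 3] - 1L)
    )
  } else {
    lines <- c(
      sprintf("# orthospect mesh label=%s frame=%s", mesh$label, mesh$frame),
      sprintf("o %s", mesh$label),
      if (nrow(V) > 0L) sprintf("v %.17g %.17g %.17g", V[, 1], V[, 2],
                                V[, 3]),
      if (nrow(F) > 0L) sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' Supports ASCII PLY and OBJ (indexed) and ASCII STL (triangle soup; each
#' facet's three vertices become distinct mesh vertices).
#'
#' @param path Mesh file path.
#' @param format Optional override, as in [write_mesh()].
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- toupper(format %||% tools::file_ext(path))
  lines <- readLines(path)
  if (format == "PLY") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    hdr_end <- which(lines == "end_header")[1]
    meta <- grep("^comment orthospect mesh", lines, value = TRUE)
    label <- if (length(meta)) sub(".*label=(\\S+).*", "\\1", meta[1]) else
      "surface"
    frame <- if (length(meta)) sub(".*frame=(\\S+).*", "\\1", meta[1]) else
      "world"
    verts <- if (nv > 0L) {
      do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(l) {
        as.numeric(strsplit(trimws(l), " +")[[1]])
      }))
    } else matrix(numeric(0), 0, 3)
    faces <- if (nf > 0L) {
      do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
        as.integer(strsplit(trimws(l), " +")[[1]])[2:4] + 1L
      }))
    } else matrix(integer(0), 0, 3)
    triangle_mesh(verts, faces, label = label, frame = frame)
  } else if (format == "OBJ") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    verts <- if (length(vl)) {
      do.call(rbind, lapply(vl, function(l) {
        as.numeric(strsplit(trimws(sub("^v ", "", l)), " +")[[1]])
      }))
    } else matrix(numeric(0), 0, 3)
    faces <- if (length(fl)) {
      do.call(rbind, lapply(fl, function(l) {
        as.integer(sub("/.*", "", strsplit(trimws(sub("^f ", "", l)),
                                           " +")[[1]]))
      }))
    } else matrix(integer(0), 0, 3)
    triangle_mesh(verts, faces)
  } else if (format == "STL") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    verts <- if (length(vl)) {
      do.call(rbind, lapply(vl, function(l) {
        as.numeric(strsplit(trimws(sub(".*vertex ", "", l)), " +")[[1]])
      }))
    } else matrix(numeric(0), 0, 3)
    nf <- nrow(verts) / 3
    faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
    triangle_mesh(verts, faces)
  } else {
    stop("unknown mesh format: ", format)
  }
}

#' Export a bone + hotspot scene
#'
#' Writes the bone and hotspot meshes as two PLY files plus a JSON manifest
#' describing them, for loading into any standard mesh viewer. Both meshes
#' must be expressed in the same coordinate frame.
#'
#' @param bone,hotspot [triangle_mesh()] objects in the same frame.
#' @param path Output prefix; files `<path>_bone.ply`, `<path>_hotspot.ply`
#'   and `<path>_scene.json` are written.
#' @return Manifest list, invisibly.
#' @export
scene_export <- function(bone, hotspot, path) {
  stopifnot(inherits(bone, "triangle_mesh"), inherits(hotspot,
                                                      "triangle_mesh"))
  if (!identical(bone$frame, hotspot$frame)) {
    stop("bone and hotspot meshes are in different frames (",
         bone$frame, " vs ", hotspot$frame, ")")
  }
  bone_path <- paste0(path, "_bone.ply")
  hot_path <- paste0(path, "_hotspot.ply")
  write_mesh(bone, bone_path, "PLY")
  write_mesh(hotspot, hot_path, "PLY")
  manifest <- list(
    frame = bone$frame,
    meshes = list(
      list(label = bone$label, file = basename(bone_path),
           vertices = nrow(bone$vertices), faces = nrow(bone$faces)),
      list(label = hotspot$label, file = basename(hot_path),
           vertices = nrow(hotspot$vertices), faces = nrow(hotspot$faces))
    )
  )
  jsonlite::write_json(manifest, paste0(path, "_scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
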