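# File interfaces: triangle meshes (ASCII PLY / OBJ / STL), landmark CSVs,
# viability tables and pose-space summaries.

#' Read a triangle mesh (PLY, OBJ or STL)
#'
#' Format is chosen by file extension.  PLY and STL are read in their ASCII
#' forms; OBJ faces with more than three vertices are fan-triangulated.
#'
#' @param path file path ending in .ply, .obj or .stl.
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .read_ply(path),
         obj = .read_obj(path),
         stl = .read_stl_ascii(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh (ASCII PLY, OBJ or STL)
#'
#' @param mesh a [triangle_mesh].
#' @param path output path ending in .ply, .obj or .stl.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = .write_ply(mesh, path),
         obj = .write_obj(mesh, path),
         stl = .write_stl_ascii(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") stop("not a PLY file: ", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("malformed PLY header")
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY is supported")
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)[1]))
  body <- lines[(end + 1):length(lines)]
  vl <- body[seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
              nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- body[nv + seq_len(nf)]
  fparts <- strsplit(trimws(fl), "\\s+")
  f <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("PLY faces must be triangles")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  triangle_mesh(v, f)
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, scientific = FALSE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v ", "", vl)),
                                         "\\s+"))), ncol = 3, byrow = TRUE)
  fs <- lapply(strsplit(trimws(sub("^f ", "", fl)), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*$", "", p))
    if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices")
    # fan-triangulate polygons
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  })
  triangle_mesh(v, do.call(rbind, fs))
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1], mesh$vertices[, 2],
                   mesh$vertices[, 3]), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1])) {
    stop("only ASCII STL is supported")
  }
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "",
                                                         vl)), "\\s+"))),
                   ncol = 3, byrow = TRUE)
  if (nrow(coords) %% 3 != 0) stop("malformed STL")
  # STL duplicates vertices per facet; merge identical coordinates
  key <- apply(round(coords, 12), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  v <- coords[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

.write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    n <- .cross3(v[f[2], ] - v[f[1], ], v[f[3], ] - v[f[1], ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(paste("  facet normal", n[1], n[2], n[3]),
                 "    outer loop",
                 paste("      vertex", v[f[1], 1], v[f[1], 2], v[f[1], 3]),
                 paste("      vertex", v[f[2], 1], v[f[2], 2], v[f[2], 3]),
                 paste("      vertex", v[f[3], 1], v[f[3], 2], v[f[3], 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

#' Read a landmark CSV
#'
#' Expected columns: `specimen`, `structure`, `x`, `y`, `z` (mm).
#'
#' @param path CSV path.
#' @return Data frame of landmarks.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "structure", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a pose viability table as CSV
#'
#' Columns `z_deg`, `y_deg`, `x_deg`, `code`, `disarticulated`.
#'
#' @param table a `pose_viability` table.
#' @param path output CSV path.
#' @export
write_viability_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("z_deg", "y_deg", "x_deg",
                                            "code", "disarticulated")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pose viability table from CSV
#' @param path CSV path written by [write_viability_csv()].
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("z_deg", "y_deg", "x_deg")) df[[col]] <- as.numeric(df[[col]])
  df$code <- as.integer(df$code)
  df$disarticulated <- as.logical(df$disarticulated)
  structure(df, class = c("pose_viability", "data.frame"))
}
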