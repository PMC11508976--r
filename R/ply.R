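# Minimal ASCII PLY reader/writer for colored polylines. Curves are
# written as a shared vertex list (with optional uchar RGB) plus an edge
# element chaining consecutive vertices of each curve; a comment line per
# curve records rib, side and the vertex range so our own reader can
# reassemble the curves.

#' Write a painted (or plain) template to an ASCII PLY file
#'
#' Vertices carry `x y z` plus `red green blue` (0-255); every rib
#' centerline becomes a chain of edges. Viewers that understand PLY edge
#' elements (e.g. MeshLab) render the heat map directly.
#'
#' @param x A `painted_template` (colored) or `thorax_template`
#'   (uncolored, written mid-gray).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_heatmap_ply <- function(x, path) {
  if (inherits(x, "thorax_template")) {
    curves <- lapply(x$curves, function(cu) {
      cu$color <- matrix(128L, nrow(cu$vertices), 3)
      cu
    })
  } else if (inherits(x, "painted_template")) {
    curves <- x$curves
  } else {
    stop("x must be a thorax_template or painted_template", call. = FALSE)
  }

  nv <- vapply(curves, function(cu) nrow(cu$vertices), integer(1))
  offsets <- cumsum(c(0L, utils::head(nv, -1)))
  total_v <- sum(nv)
  total_e <- sum(nv - 1L)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment ribmap polyline heat map"), con)
  writeLines(sprintf("comment curve %s %s %d %d",
                     vapply(curves, function(cu) cu$rib_index, numeric(1)),
                     vapply(curves, function(cu) cu$side, character(1)),
                     offsets, nv), con)
  writeLines(c(
    sprintf("element vertex %d", total_v),
    "property float x",
    "property float y",
    "property float z",
    "property uchar red",
    "property uchar green",
    "property uchar blue",
    sprintf("element edge %d", total_e),
    "property int vertex1",
    "property int vertex2",
    "end_header"), con)
  for (cu in curves) {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                       cu$vertices[, 1], cu$vertices[, 2], cu$vertices[, 3],
                       cu$color[, 1], cu$color[, 2], cu$color[, 3]), con)
  }
  for (i in seq_along(curves)) {
    idx <- offsets[i] + seq_len(nv[i]) - 1L
    writeLines(sprintf("%d %d", utils::head(idx, -1), utils::tail(idx, -1)),
               con)
  }
  invisible(path)
}

#' Read a PLY polyline file written by [write_heatmap_ply()]
#'
#' @param path PLY file path.
#' @return List with `vertices` (n x 3), `colors` (n x 3, 0-255), `edges`
#'   (m x 2, 0-based), and `curves`: a data frame of per-curve `rib`,
#'   `side`, `offset`, `n`.
#' @export
read_heatmap_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply") {
    stop("not a PLY file: ", path, call. = FALSE)
  }
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("PLY header not terminated", call. = FALSE)
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  ne <- as.integer(sub("element edge ", "",
                       grep("^element edge ", header, value = TRUE)))
  if (length(nv) != 1L || is.na(nv)) {
    stop("PLY file lacks a vertex element", call. = FALSE)
  }
  if (length(ne) == 0L) ne <- 0L

  cc <- grep("^comment curve ", header, value = TRUE)
  curves <- NULL
  if (length(cc)) {
    parts <- do.call(rbind, strsplit(sub("^comment curve ", "", cc), " "))
    curves <- data.frame(rib = as.integer(parts[, 1]),
                         side = parts[, 2],
                         offset = as.integer(parts[, 3]),
                         n = as.integer(parts[, 4]),
                         stringsAsFactors = FALSE)
  }

  body <- lines[-seq_len(endh)]
  vdat <- utils::read.table(text = body[seq_len(nv)])
  vertices <- as.matrix(vdat[, 1:3])
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  colors <- if (ncol(vdat) >= 6L) {
    m <- as.matrix(vdat[, 4:6])
    dimnames(m) <- list(NULL, c("r", "g", "b"))
    m
  } else NULL
  edges <- if (ne > 0L) {
    as.matrix(utils::read.table(text = body[nv + seq_len(ne)]))[, 1:2,
                                                                drop = FALSE]
  } else matrix(integer(), 0, 2)
  dimnames(edges) <- list(NULL, c("vertex1", "vertex2"))
  list(vertices = vertices, colors = colors, edges = edges, curves = curves)
}
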