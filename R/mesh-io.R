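# Mesh import/export: OBJ and ASCII PLY, with a sidecar CSV mapping facet
# index to role, material and plant id.

#' Export a canopy scene as OBJ or PLY
#'
#' Writes the triangle mesh in Wavefront OBJ (`export_obj`) or ASCII PLY
#' (`export_ply`). A sidecar CSV (same path, extension `.facets.csv`) maps
#' facet index to role, material id and plant id.
#'
#' @param scene A [canopy_scene()] or [generate_plant()] mesh.
#' @param file Output path.
#' @param sidecar Write the facet-attribute sidecar CSV.
#' @return `file`, invisibly.
#' @export
export_obj <- function(scene, file, sidecar = TRUE) {
  v <- scene$vertices; f <- scene$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# canopylight mesh export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  if (sidecar) write_sidecar(scene, file)
  invisible(file)
}

#' @rdname export_obj
#' @export
export_ply <- function(scene, file, sidecar = TRUE) {
  v <- scene$vertices; f <- scene$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (sidecar) write_sidecar(scene, file)
  invisible(file)
}

write_sidecar <- function(scene, file) {
  d <- data.frame(facet = seq_len(nrow(scene$faces)),
                  role = scene$role,
                  material = if (!is.null(scene$material)) scene$material
                             else NA_integer_,
                  plant = if (!is.null(scene$plant_id)) scene$plant_id
                          else NA_integer_)
  write.csv(d, paste0(file, ".facets.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Import an OBJ mesh as a canopy scene
#'
#' Reads vertices and triangular faces from a Wavefront OBJ file; facet
#' roles come from the sidecar CSV when present (all facets default to
#' "leaf" otherwise, with the substrate appended by [canopy_scene()]).
#'
#' @param file OBJ path.
#' @param tile Tile dimensions of the periodic scene.
#' @return A [canopy_scene()].
#' @export
import_obj <- function(file, tile = c(0.2, 0.2)) {
  lines <- readLines(file)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  role <- rep("leaf", nrow(f))
  sc_file <- paste0(file, ".facets.csv")
  if (file.exists(sc_file)) {
    sc <- read.csv(sc_file)
    role <- as.character(sc$role[seq_len(nrow(f))])
  }
  keep <- role != "substrate"
  pl <- bare_mesh(v, f[keep, , drop = FALSE], role[keep])
  attr(pl, "position") <- c(0, 0)
  canopy_scene(list(pl), tile)
}
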