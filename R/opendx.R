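# OpenDX scalar regular-grid I/O.  The DX text format is what molecular
# viewers (PyMOL, VMD, ChimeraX) read for iso-surface display; the data array
# runs with the z index fastest.  A JSON sidecar echoes the geometry exactly.

#' Write a grid as an OpenDX scalar field
#'
#' Emits a standard `object 1 class gridpositions` scalar regular-grid file
#' (three values per data line, z index fastest) plus a JSON sidecar
#' `<path>.json` holding origin/shape/spacing at full precision.
#'
#' @param grid A [grid3d()].
#' @param path Output file path (conventionally `*.dx`).
#' @param sidecar Write the JSON geometry sidecar (default TRUE).
#' @return `path`, invisibly.
#' @seealso [read_dx()]
#' @export
write_dx <- function(grid, path, sidecar = TRUE) {
  assert_grid(grid)
  n <- grid$shape
  s <- grid$spacing
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))  # z fastest
  header <- c(
    "# OpenDX scalar field written by probemap",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.8e %.8e %.8e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.8e 0 0", s),
    sprintf("delta 0 %.8e 0", s),
    sprintf("delta 0 0 %.8e", s),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))
  )
  pad <- (3L - length(vals) %% 3L) %% 3L
  body <- matrix(c(sprintf("%.8e", vals), rep("", pad)), nrow = 3L)
  data_lines <- trimws(apply(body, 2L, paste, collapse = " "))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"density\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, data_lines, footer), path)
  if (sidecar) {
    jsonlite::write_json(
      list(origin = grid$origin, shape = grid$shape, spacing = grid$spacing),
      paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read an OpenDX scalar field into a grid
#'
#' Parses the `gridpositions` / `gridconnections` / `data follows` layout
#' written by [write_dx()] (and by common MD analysis tools).  Only uniform
#' axis-aligned deltas are supported.  A malformed header or an item count
#' that disagrees with the data length is a parse error naming the offending
#' line.
#'
#' @param path Path of the DX file.
#' @return A [grid3d()].
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop_data("DX file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(lines)
  keep <- !startsWith(strip, "#") & nzchar(strip)
  idx_all <- which(keep)

  grab <- function(pattern, what) {
    hit <- grep(pattern, strip[keep])
    if (!length(hit))
      stop_data("DX parse error: missing '%s' declaration in %s", what, path)
    idx_all[hit[1L]]
  }
  pos_line <- grab("^object .*class gridpositions", "gridpositions")
  counts <- suppressWarnings(as.integer(
    utils::tail(strsplit(strip[pos_line], "\\s+")[[1L]], 3L)))
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 1L))
    stop_data("DX parse error at line %d: bad gridpositions counts: '%s'",
              pos_line, strip[pos_line])

  org_line <- grab("^origin ", "origin")
  origin <- suppressWarnings(as.numeric(
    strsplit(strip[org_line], "\\s+")[[1L]][-1L]))
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_data("DX parse error at line %d: bad origin: '%s'",
              org_line, strip[org_line])

  delta_lines <- idx_all[grep("^delta ", strip[keep])]
  if (length(delta_lines) != 3L)
    stop_data("DX parse error: expected 3 delta lines, found %d in %s",
              length(delta_lines), path)
  deltas <- t(vapply(strip[delta_lines], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]][-1L]))
    if (length(v) != 3L || any(!is.finite(v)))
      stop_data("DX parse error: bad delta line: '%s'", l)
    v
  }, numeric(3L), USE.NAMES = FALSE))
  off_diag <- deltas; diag(off_diag) <- 0
  if (any(abs(off_diag) > 1e-12))
    stop_data("DX parse error: non-axis-aligned deltas are not supported")
  spac <- diag(deltas)
  if (max(spac) - min(spac) > 1e-9 * max(spac))
    stop_data("DX parse error: non-cubic voxels are not supported")

  arr_line <- grab("^object .*class array .*data follows", "data array")
  items <- suppressWarnings(as.integer(
    sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", strip[arr_line])))
  if (is.na(items))
    stop_data("DX parse error at line %d: bad item count: '%s'",
              arr_line, strip[arr_line])
  if (items != prod(counts))
    stop_data("DX parse error at line %d: declared %d items but counts imply %d",
              arr_line, items, prod(counts))

  vals <- numeric(0)
  i <- arr_line + 1L
  while (length(vals) < items && i <= length(lines)) {
    l <- strip[i]
    if (nzchar(l) && !startsWith(l, "#")) {
      if (grepl("^(attribute|object)", l)) break
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]]))
      if (any(is.na(v)))
        stop_data("DX parse error at line %d: non-numeric data: '%s'", i, l)
      vals <- c(vals, v)
    }
    i <- i + 1L
  }
  if (length(vals) != items)
    stop_data("DX parse error: data block ending at line %d holds %d values, expected %d",
              i - 1L, length(vals), items)

  g <- grid3d(origin, counts, spac[1L])
  g$values <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))
  g
}
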