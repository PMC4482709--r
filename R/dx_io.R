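# OpenDX scalar-field output for density grids, readable by VMD/PyMOL/Chimera.
# Convention: the data stream varies z fastest, then y, then x (the standard
# OpenDX gridpositions ordering used by VMD volmap), documented here and
# honoured by read_dx().

#' Write a density grid as an OpenDX scalar field
#'
#' @param grid A `density_grid` (see [water_density()]), or any list with
#'   `origin`, `spacing`, `dims`, `values` fields.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  dims <- as.integer(grid$dims)
  stopifnot(length(dims) == 3L, all(dims > 0L))
  vals <- as.numeric(grid$values)
  if (length(vals) != prod(dims)) stop("values length does not match dims")
  if (any(!is.finite(vals))) stop("non-finite voxel value; cannot serialise")
  # reorder from R's x-fastest array layout to DX's z-fastest stream
  arr <- array(vals, dim = dims)
  stream <- as.numeric(aperm(arr, c(3L, 2L, 1L)))
  s <- grid$spacing
  header <- c(
    "# OpenDX density written by poretraj",
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1L], dims[2L], dims[3L]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1L], grid$origin[2L], grid$origin[3L]),
    sprintf("delta %.6f 0.000000 0.000000", s),
    sprintf("delta 0.000000 %.6f 0.000000", s),
    sprintf("delta 0.000000 0.000000 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1L], dims[2L], dims[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(stream))
  )
  n <- length(stream)
  pad <- (3L - n %% 3L) %% 3L
  m <- matrix(c(sprintf("%.10g", stream), rep("", pad)), ncol = 3L,
              byrow = TRUE)
  data_lines <- trimws(apply(m, 1L, paste, collapse = " "))
  writeLines(c(header, data_lines,
               'attribute "dep" string "positions"',
               'object "density" class field'), path)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path File path.
#' @return A list with `origin`, `spacing`, `dims`, `values` (3D array,
#'   x-fastest in R layout).
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1L]
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1L]])
  org <- as.numeric(strsplit(trimws(sub("^origin", "",
    grep("^origin", lines, value = TRUE)[1L])), "\\s+")[[1L]])
  deltas <- grep("^delta", lines, value = TRUE)
  spacing <- as.numeric(strsplit(trimws(sub("^delta", "", deltas[1L])),
                                 "\\s+")[[1L]])[1L]
  start <- grep("data follows", lines)[1L]
  end <- grep("^attribute|^object \"", lines)
  end <- if (length(end[end > start])) min(end[end > start]) - 1L else length(lines)
  stream <- as.numeric(unlist(strsplit(trimws(lines[(start + 1L):end]),
                                       "\\s+")))
  stream <- stream[!is.na(stream)]
  arr <- aperm(array(stream, dim = rev(dims)), c(3L, 2L, 1L))
  list(origin = org, spacing = spacing, dims = dims, values = arr)
}
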