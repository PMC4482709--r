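# Fixed-column PDB reading/writing. Multi-model PDB is the canonical
# trajectory format here: desk-scale, text-only, viewable everywhere.
# Binary formats (DCD/XTC) are deliberately not supported.

pdb_is_atom_record <- function(line) {
  rec <- substr(line, 1L, 6L)
  rec == "ATOM  " || rec == "HETATM" ||
    substr(rec, 1L, 4L) == "ATOM" || substr(rec, 1L, 6L) == "HETATM"
}

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54L) {
    stop("malformed PDB ATOM/HETATM record (short line) at line ", lineno)
  }
  num <- function(from, to, what) {
    fld <- trimws(substr(line, from, to))
    v <- suppressWarnings(as.numeric(fld))
    if (is.na(v)) {
      stop("malformed PDB ", what, " field at line ", lineno, ": '", fld, "'")
    }
    v
  }
  serial <- num(7L, 11L, "serial")
  resseq <- num(23L, 26L, "resSeq")
  list(
    record = trimws(substr(line, 1L, 6L)),
    serial = as.integer(serial),
    name = trimws(substr(line, 13L, 16L)),
    altloc = substr(line, 17L, 17L),
    resname = trimws(substr(line, 18L, 20L)),
    chain = substr(line, 22L, 22L),
    resseq = as.integer(resseq),
    x = num(31L, 38L, "x"),
    y = num(39L, 46L, "y"),
    z = num(47L, 54L, "z"),
    occupancy = if (nchar(line) >= 60L &&
                    nzchar(trimws(substr(line, 55L, 60L))))
      num(55L, 60L, "occupancy") else 1,
    bfactor = if (nchar(line) >= 66L &&
                  nzchar(trimws(substr(line, 61L, 66L))))
      num(61L, 66L, "bfactor") else 0,
    element = if (nchar(line) >= 78L) trimws(substr(line, 77L, 78L)) else ""
  )
}

#' Read a PDB file or text
#'
#' Parses fixed-column ATOM/HETATM/MODEL/ENDMDL records. Alternate locations
#' other than blank or "A" are dropped (single-conformer analysis). When the
#' element columns are blank the element is inferred from the atom name.
#'
#' @param input A file path, a single string containing newlines, or a
#'   character vector of lines.
#' @param multi If TRUE return a `mol_trajectory` whose topology is model 1
#'   and whose frames are all models (a file without MODEL records yields a
#'   1-frame trajectory). If FALSE (default) return a `mol_structure` from
#'   the first model.
#' @param frame_interval_ns Frame interval attached to a returned trajectory.
#' @return A `mol_structure` or `mol_trajectory`.
#' @export
read_pdb <- function(input, multi = FALSE, frame_interval_ns = 0.1) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else if (length(input) == 1L) {
    lines <- strsplit(input, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- input
  }

  models <- list()
  current <- list()
  in_model <- FALSE
  saw_model_record <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    rec <- substr(line, 1L, 6L)
    if (substr(rec, 1L, 5L) == "MODEL") {
      saw_model_record <- TRUE
      in_model <- TRUE
      current <- list()
    } else if (substr(rec, 1L, 6L) == "ENDMDL") {
      models[[length(models) + 1L]] <- current
      in_model <- FALSE
      current <- list()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      at <- parse_pdb_atom_line(line, i)
      if (!(at$altloc %in% c(" ", "", "A"))) next
      current[[length(current) + 1L]] <- at
    }
  }
  if (length(current)) models[[length(models) + 1L]] <- current
  if (!length(models) || !length(models[[1L]])) {
    stop("no ATOM/HETATM records found")
  }

  model_df <- function(atoms) {
    data.frame(
      serial = vapply(atoms, `[[`, integer(1L), "serial"),
      name = vapply(atoms, `[[`, character(1L), "name"),
      resname = vapply(atoms, `[[`, character(1L), "resname"),
      chain = vapply(atoms, `[[`, character(1L), "chain"),
      resseq = vapply(atoms, `[[`, integer(1L), "resseq"),
      x = vapply(atoms, `[[`, numeric(1L), "x"),
      y = vapply(atoms, `[[`, numeric(1L), "y"),
      z = vapply(atoms, `[[`, numeric(1L), "z"),
      occupancy = vapply(atoms, `[[`, numeric(1L), "occupancy"),
      bfactor = vapply(atoms, `[[`, numeric(1L), "bfactor"),
      element = vapply(atoms, `[[`, character(1L), "element"),
      hetatm = vapply(atoms, function(a) a$record == "HETATM", logical(1L)),
      stringsAsFactors = FALSE
    )
  }

  df1 <- model_df(models[[1L]])
  blank <- !nzchar(df1$element)
  if (any(blank)) df1$element[blank] <- infer_element(df1$name[blank])
  topo <- mol_structure(df1, metadata = list(n_models = length(models)))

  if (!multi) return(topo)

  n <- nrow(df1)
  frames <- array(NA_real_, dim = c(n, 3L, length(models)))
  for (m in seq_along(models)) {
    if (length(models[[m]]) != n) {
      stop("topology mismatch: model ", m, " has ", length(models[[m]]),
           " atoms but model 1 has ", n)
    }
    dfm <- if (m == 1L) df1 else model_df(models[[m]])
    if (m > 1L && !identical(paste(dfm$chain, dfm$resseq, dfm$name),
                             paste(df1$chain, df1$resseq, df1$name))) {
      stop("topology mismatch: atom identities differ between model 1 and model ", m)
    }
    frames[, , m] <- cbind(dfm$x, dfm$y, dfm$z)
  }
  if (!saw_model_record && length(models) == 1L) {
    # single-model file requested as trajectory: 1 frame
  }
  mol_trajectory(topo, frames, frame_interval_ns = frame_interval_ns)
}

structure_pdb_lines <- function(s) {
  a <- s$atoms
  xyz <- c(a$x, a$y, a$z)
  bad <- !is.finite(xyz) | xyz <= -1000 | xyz >= 10000
  if (any(bad)) {
    stop("coordinate ", format(xyz[which(bad)[1L]]),
         " not representable in PDB fixed columns (must be in (-1000, 10000))")
  }
  # PDB convention: names of <4 chars for 1-letter elements start in col 14
  fmt_name <- ifelse(nchar(a$name) >= 4L,
                     sprintf("%-4s", a$name),
                     sprintf(" %-3s", a$name))
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$hetatm, "HETATM", "ATOM"),
          a$serial %% 100000L, fmt_name, a$resname, a$chain,
          a$resseq %% 10000L, a$x, a$y, a$z, a$occupancy, a$bfactor,
          a$element)
}

#' Write PDB text
#'
#' Serialises a structure (single model) or a trajectory (MODEL/ENDMDL
#' blocks). Round trip through [read_pdb()] preserves atom identities
#' exactly and coordinates to 1e-3 Angstrom. Coordinates must lie in
#' (-1000, 10000) to fit the fixed 8.3 columns.
#'
#' @param x A `mol_structure` or `mol_trajectory`.
#' @param path Optional output file path; when NULL the text is returned.
#' @return Character scalar of PDB text (invisibly when `path` is given).
#' @export
write_pdb <- function(x, path = NULL) {
  if (inherits(x, "mol_structure")) {
    lines <- c(structure_pdb_lines(x), "END")
  } else if (inherits(x, "mol_trajectory")) {
    blocks <- lapply(seq_len(n_frames(x)), function(f) {
      s <- frame_structure(x, f)
      c(sprintf("MODEL     %4d", f), structure_pdb_lines(s), "ENDMDL")
    })
    lines <- c(unlist(blocks), "END")
  } else {
    stop("x must be a mol_structure or mol_trajectory")
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}
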