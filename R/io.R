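#' Read and write single-cell spectra tables
#'
#' The canonical on-disk format is a UTF-8 delimited text table (comma or
#' tab): first column the wavenumber, one further column per cell, and a
#' header whose cell columns encode the labels as
#' `cellline/treatment/sampleid`. Files stored descending in wavenumber (the
#' instrument convention) are flipped to ascending on read, absorbances with
#' them. A leading `#` provenance line, as written by [write_spectra()], is
#' ignored on read.
#'
#' A small subset of JCAMP-DX is also supported: single-spectrum files whose
#' `##XYDATA=(X++(Y..Y))` block uses the affine scaling given by
#' `##XFACTOR`/`##YFACTOR` with an equally spaced abscissa defined by
#' `##FIRSTX`, `##LASTX` and `##NPOINTS`.
#'
#' @param path File to read or write.
#' @param dialect `"table"` (default) or `"jcamp"`.
#' @param sep Field separator for the table dialect; auto-detected on read
#'   (comma or tab).
#' @return A spectra table (see [as_spectra()]).
#' @export
read_spectra <- function(path, dialect = c("table", "jcamp"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "jcamp") return(read_jcamp(path))

  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("format error: no data rows")
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- length(fields[[1]])
  if (ncols < 2) abort("format error: need a wavenumber column plus spectra")
  header <- trimws(fields[[1]])
  body <- fields[-1]
  ragged <- which(lengths(body) != ncols)
  if (length(ragged) > 0) {
    abort(sprintf("format error: row %d has %d fields, expected %d",
                  ragged[1], lengths(body)[ragged[1]], ncols))
  }
  num <- matrix(NA_real_, nrow = length(body), ncol = ncols)
  for (j in seq_len(ncols)) {
    col <- vapply(body, `[[`, character(1), j)
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(sprintf("parse error: non-numeric value '%s' at data row %d, column %d",
                    col[bad[1]], bad[1], j))
    }
    num[, j] <- v
  }
  wn <- num[, 1]
  if (anyDuplicated(wn)) abort("format error: duplicate wavenumbers")
  ord <- order(wn)
  wn <- wn[ord]
  A <- t(num[ord, -1, drop = FALSE])

  labels <- parse_column_labels(header[-1])
  spectra_from_matrix(wn, A, labels)
}

parse_column_labels <- function(cols) {
  parts <- strsplit(cols, "/", fixed = TRUE)
  tibble::tibble(
    sample_id = vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) >= 3) p[[3]] else paste0("s", i)
    }, character(1)),
    cell_line = vapply(parts, function(p)
      if (length(p) >= 1 && nzchar(p[[1]])) p[[1]] else "unknown", character(1)),
    treatment = vapply(parts, function(p)
      if (length(p) >= 2) p[[2]] else "unknown", character(1))
  )
}

#' @rdname read_spectra
#' @param spectra A spectra table.
#' @param seed Optional integer recorded in the provenance header (use for
#'   synthetic data so files are self-describing).
#' @export
write_spectra <- function(spectra, path, sep = ",", seed = NULL) {
  m <- spc_matrix(spectra)
  prov <- sprintf("# ftirmcell %s%s",
                  as.character(packageVersion("ftirmcell")),
                  if (is.null(seed)) "" else paste0(" seed=", seed))
  header <- c("wavenumber",
              paste(m$labels$cell_line, m$labels$treatment,
                    m$labels$sample_id, sep = "/"))
  rows <- vapply(seq_along(m$wn), function(i) {
    paste(c(fmt_num(m$wn[i]), fmt_num(m$A[, i])), collapse = sep)
  }, character(1))
  writeLines(c(prov, paste(header, collapse = sep), rows), path,
             useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

# Minimal JCAMP-DX (X++(Y..Y)) reader: equally spaced X from
# FIRSTX/LASTX/NPOINTS, affine Y scaling via YFACTOR, X checked against the
# per-line leading abscissa after XFACTOR scaling.
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[[1]]))
  }
  need <- function(key) {
    v <- get_field(key)
    if (is.null(v)) abort(paste0("JCAMP-DX: missing ##", key, "="))
    v
  }
  xy <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(xy) == 0) abort("JCAMP-DX: no ##XYDATA= block")
  form <- toupper(gsub("[[:space:]]", "", sub("^##XYDATA=", "", lines[[xy[1]]],
                                              ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    abort("JCAMP-DX: only the (X++(Y..Y)) form is supported")
  }
  endl <- grep("^##END", lines, ignore.case = TRUE)
  endl <- if (length(endl) > 0) min(endl[endl > xy[1]]) else length(lines) + 1
  data_lines <- lines[(xy[1] + 1):(endl - 1)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]

  xfac <- as.numeric(need("XFACTOR"))
  yfac <- as.numeric(need("YFACTOR"))
  firstx <- as.numeric(need("FIRSTX"))
  lastx <- as.numeric(need("LASTX"))
  npoints <- as.integer(need("NPOINTS"))
  title <- get_field("TITLE") %||% "jcamp"

  y <- numeric(0)
  for (ln in data_lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) abort(paste0("JCAMP-DX: non-numeric token in '", ln, "'"))
    xline <- vals[1] * xfac
    expect_x <- firstx + (lastx - firstx) * length(y) / (npoints - 1)
    if (abs(xline - expect_x) > abs(lastx - firstx) / (npoints - 1) / 2 + 1e-9) {
      abort(sprintf("JCAMP-DX: line abscissa %g does not match expected %g",
                    xline, expect_x))
    }
    y <- c(y, vals[-1] * yfac)
  }
  if (length(y) != npoints) {
    abort(sprintf("JCAMP-DX: decoded %d points, ##NPOINTS says %d",
                  length(y), npoints))
  }
  wn <- seq(firstx, lastx, length.out = npoints)
  if (wn[1] > wn[npoints]) {   # stored descending: flip both
    wn <- rev(wn)
    y <- rev(y)
  }
  as_spectra(tibble::tibble(sample_id = title, wavenumber = wn,
                            absorbance = y))
}

#' Hyperspectral single-cell maps
#'
#' A `hypermap` holds one spectrum per pixel of an `nx` by `ny` raster with a
#' physical step in micrometres between neighbouring points (e.g. single-cell
#' maps recorded at 1.5 um spacing). Pixels are indexed `(px, py)` with
#' `(1, 1)` the top-left corner, `px` increasing rightwards and `py`
#' downwards; spectra are stored row-major (all of row `py = 1`, then row 2,
#' ...).
#'
#' @param wn Ascending wavenumber grid shared by all pixels.
#' @param cube Matrix of absorbances, one row per pixel in row-major order,
#'   `nx * ny` rows and `length(wn)` columns.
#' @param nx,ny Pixel counts along x and y.
#' @param step_um Distance between neighbouring pixels in micrometres (> 0).
#' @return An object of class `hypermap`.
#' @export
hypermap <- function(wn, cube, nx, ny, step_um) {
  wn <- as.numeric(wn)
  if (is.unsorted(wn, strictly = TRUE)) abort("hypermap grid must be ascending")
  if (!is.matrix(cube) || nrow(cube) != nx * ny || ncol(cube) != length(wn)) {
    abort("cube must be an (nx*ny) x length(wn) matrix in row-major pixel order")
  }
  if (step_um <= 0) abort("step_um must be > 0")
  structure(list(wn = wn, cube = cube, nx = as.integer(nx),
                 ny = as.integer(ny), step_um = step_um),
            class = "hypermap")
}

#' @export
print.hypermap <- function(x, ...) {
  cat(sprintf("<hypermap> %d x %d pixels, %.3g um step (%g x %g um), %d points %g-%g cm^-1\n",
              x$nx, x$ny, x$step_um, (x$nx - 1) * x$step_um,
              (x$ny - 1) * x$step_um, length(x$wn), min(x$wn), max(x$wn)))
  invisible(x)
}

#' @export
as_tibble.hypermap <- function(x, ...) {
  idx <- seq_len(x$nx * x$ny)
  px <- ((idx - 1) %% x$nx) + 1
  py <- ((idx - 1) %/% x$nx) + 1
  tibble::tibble(
    px = rep(px, each = length(x$wn)),
    py = rep(py, each = length(x$wn)),
    wavenumber = rep(x$wn, times = length(idx)),
    absorbance = as.vector(t(x$cube))
  )
}

#' Read and write hyperspectral maps
#'
#' The map container is a directory holding `geometry.txt` (key=value lines
#' for `nx`, `ny`, `step_um`) and `spectra.csv`, a delimited table whose
#' first column is the wavenumber and whose remaining columns are the pixels
#' in row-major order.
#'
#' @param dir Directory to read from or write into (created if missing).
#' @param map A `hypermap`.
#' @param seed Optional integer recorded in the provenance header.
#' @return `read_hypermap()` returns a `hypermap`.
#' @export
read_hypermap <- function(dir) {
  geo_path <- file.path(dir, "geometry.txt")
  spc_path <- file.path(dir, "spectra.csv")
  if (!file.exists(geo_path) || !file.exists(spc_path)) {
    abort("map directory must contain geometry.txt and spectra.csv")
  }
  geo_lines <- readLines(geo_path, warn = FALSE)
  geo_lines <- geo_lines[!startsWith(geo_lines, "#")]
  kv <- strsplit(geo_lines[nzchar(trimws(geo_lines))], "=", fixed = TRUE)
  geo <- setNames(vapply(kv, function(p) trimws(p[[2]]), character(1)),
                  vapply(kv, function(p) trimws(p[[1]]), character(1)))
  nx <- as.integer(geo[["nx"]]); ny <- as.integer(geo[["ny"]])
  step_um <- as.numeric(geo[["step_um"]])

  s <- read_spectra(spc_path)
  m <- spc_matrix(s)
  # pixel columns were written as p000001, p000002, ... in row-major order
  ord <- order(m$labels$sample_id)
  hypermap(m$wn, m$A[ord, , drop = FALSE], nx, ny, step_um)
}

#' @rdname read_hypermap
#' @export
write_hypermap <- function(map, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(c(sprintf("# ftirmcell %s%s",
                       as.character(packageVersion("ftirmcell")),
                       if (is.null(seed)) "" else paste0(" seed=", seed)),
               paste0("nx=", map$nx), paste0("ny=", map$ny),
               paste0("step_um=", fmt_num(map$step_um))),
             file.path(dir, "geometry.txt"))
  labels <- tibble::tibble(
    sample_id = sprintf("p%06d", seq_len(map$nx * map$ny)),
    cell_line = "map", treatment = "map")
  s <- spectra_from_matrix(map$wn, map$cube, labels)
  write_spectra(s, file.path(dir, "spectra.csv"), seed = seed)
  invisible(dir)
}
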