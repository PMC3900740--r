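#' Write a reflection table
#'
#' Plain-text exchange format: header lines `# cell a b gamma`, `# dmin d`,
#' `# friedel +`, then one record per line `h k amplitude phase_deg` on the
#' hemisphere h > 0 (or h = 0, k > 0).
#'
#' @param sf An [sfset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(sf, path) {
  stopifnot(inherits(sf, "sfset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell %.6f %.6f %.6f", sf$cell$a, sf$cell$b, sf$cell$gamma),
    sprintf("# dmin %.6f", sf$d_min),
    "# friedel +"), con)
  writeLines(sprintf("%d %d %.8g %.6f", sf$hk$h, sf$hk$k, sf$hk$amp,
                     sf$hk$phase), con)
  invisible(path)
}

#' Read a reflection table
#'
#' Parses the format written by [write_reflections()]; duplicate (h,k)
#' records and out-of-hemisphere indices are rejected.
#'
#' @param path Input file path.
#' @return An [sfset()].
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cell_line <- grep("^# cell", hdr, value = TRUE)
  dmin_line <- grep("^# dmin", hdr, value = TRUE)
  if (length(cell_line) != 1 || length(dmin_line) != 1)
    stop("malformed reflection table header (need '# cell' and '# dmin')")
  cv <- as.numeric(strsplit(trimws(sub("^# cell", "", cell_line)),
                            "\\s+")[[1]])
  if (length(cv) != 3 || any(!is.finite(cv)))
    stop("malformed '# cell' header line")
  d_min <- as.numeric(trimws(sub("^# dmin", "", dmin_line)))
  rec <- utils::read.table(text = body,
                           col.names = c("h", "k", "amp", "phase"))
  sfset(unit_cell_2d(cv[1], cv[2], cv[3]), d_min,
        rec$h, rec$k, rec$amp, rec$phase)
}

#' Write a projection or difference map as a CCP4/MRC volume
#'
#' Minimal MRC2014 writer: mode 2 (32-bit float), a single section
#' (nz = 1), cell constants in the header (c axis written as 1 Angstrom),
#' "MAP " stamp and little-endian machine stamp. A JSON sidecar
#' (`<path>.json`) records the cell, mean, sigma and, for difference maps,
#' the contour step and background level.
#'
#' @param map A [projection_map] or `difference_map`.
#' @param path Output `.mrc` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, c("projection_map", "difference_map")))
  g <- map$grid
  nx <- nrow(g); ny <- ncol(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, 1))              # NX NY NZ
  wi(2)                         # MODE 2 = float32
  wi(c(0, 0, 0))                # NXSTART..
  wi(c(nx, ny, 1))              # MX MY MZ
  wf(c(map$cell$a, map$cell$b, 1))        # cell lengths
  wf(c(90, 90, map$cell$gamma))           # cell angles
  wi(c(1, 2, 3))                # axis order
  wf(c(min(g), max(g), mean(g)))          # DMIN DMAX DMEAN
  wi(1)                         # ISPG (plane-group use: p1/p2 noted in json)
  wi(0)                         # NSYMBT
  writeBin(raw(25 * 4), con)    # EXTRA (words 25-49)
  wf(c(0, 0, 0))                # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(g)))  # RMS
  wi(0)                         # NLABL
  writeBin(raw(800), con)       # labels
  wf(as.numeric(g))             # column-major = x fastest
  meta <- list(cell = unclass(map$cell), mean = mean(g),
               sigma = stats::sd(as.numeric(g)))
  if (inherits(map, "difference_map")) {
    meta$contour_step <- map$contour_step
    meta$background_levels <- map$background_levels
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CCP4/MRC 2D map
#'
#' Counterpart of [write_map()]. Only single-section (nz = 1) mode-2
#' volumes are accepted; anything else signals a format error.
#'
#' @param path Input `.mrc` path.
#' @return A [projection_map] (or a `difference_map` if the JSON sidecar
#'   carries a contour step).
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (expect 2, float32)")
  if (dims[3] != 1) stop("map has nz = ", dims[3], "; expected a 2D map")
  ri(3); ri(3)
  clen <- rf(3); cang <- rf(3)
  seek(con, 1024)
  vals <- rf(dims[1] * dims[2])
  g <- matrix(vals, dims[1], dims[2])
  map <- new_projection_map(g, unit_cell_2d(clen[1], clen[2], cang[3]))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$contour_step)) {
      map <- structure(list(grid = g, cell = map$cell,
                            contour_step = meta$contour_step,
                            background_levels = meta$background_levels,
                            sigma = stats::sd(vals)),
                       class = "difference_map")
    }
  }
  map
}

#' Write titration counts as CSV
#'
#' @param counts A `titration_series` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' Read titration counts from CSV
#'
#' @param path CSV written by [write_counts()].
#' @param pH Condition pH to attach.
#' @return A `titration_series` data frame.
#' @export
read_counts <- function(path, pH = NA) {
  df <- utils::read.csv(path)
  out <- titration_counts(df$na_mM, df$region, df$positive, df$negative,
                          pH = pH)
  if ("corrected" %in% names(df)) {
    out$corrected <- as.integer(df$corrected)
    attr(out, "corrected") <- TRUE
  }
  out
}
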