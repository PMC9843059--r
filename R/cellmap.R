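#' Construct a cell map
#'
#' A cell map is the per-slide output of nucleus segmentation/classification:
#' one row per detected nucleus with its centroid pixel coordinates and one of
#' the six cell-type labels (see [cell_types()]).  Coordinates are 0-based
#' pixel positions, origin at the top-left corner, x rightward and y downward,
#' with the slide extent half-open: `0 <= x < width_px`, `0 <= y < height_px`.
#'
#' @param slide_id Character scalar slide identifier.
#' @param patient_id Character scalar patient identifier.
#' @param width_px,height_px Slide extent in pixels (positive integers).
#' @param cells A data.frame with columns `cell_id`, `x`, `y`, `cell_type`.
#' @param microns_per_pixel Spatial resolution; default 0.25 um/px (40x).
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(slide_id, patient_id, width_px, height_px, cells,
                     microns_per_pixel = 0.25) {
  if (missing(cells) || is.null(cells)) {
    cells <- data.frame(cell_id = character(), x = numeric(), y = numeric(),
                        cell_type = character(), stringsAsFactors = FALSE)
  }
  m <- structure(
    list(slide_id = as.character(slide_id),
         patient_id = as.character(patient_id),
         width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         microns_per_pixel = as.numeric(microns_per_pixel),
         cells = as.data.frame(cells, stringsAsFactors = FALSE)),
    class = "cell_map")
  validate_cell_map(m)
}

#' Validate a cell map
#'
#' Checks the `cell_map` invariants: positive extent, finite coordinates
#' inside the half-open slide extent, cell types drawn from the six-label
#' vocabulary, and cell ids unique within the slide.
#'
#' @param m A `cell_map`.
#' @return `m`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cell_map <- function(m) {
  stopifnot(inherits(m, "cell_map"))
  if (is.na(m$width_px) || is.na(m$height_px) ||
      m$width_px <= 0L || m$height_px <= 0L)
    tme_stop("cell_map: slide extent must be positive integers")
  if (!is.finite(m$microns_per_pixel) || m$microns_per_pixel <= 0)
    tme_stop("cell_map: microns_per_pixel must be a positive real")
  need <- c("cell_id", "x", "y", "cell_type")
  miss <- setdiff(need, names(m$cells))
  if (length(miss))
    tme_stop(sprintf("cell_map: cells table missing column(s): %s",
                     paste(miss, collapse = ", ")))
  cs <- m$cells
  if (nrow(cs)) {
    bad_type <- which(!(cs$cell_type %in% cell_types()))
    if (length(bad_type))
      tme_stop(sprintf(
        "cell_map: unknown cell type '%s' at row %d",
        cs$cell_type[bad_type[1]], bad_type[1]))
    if (any(!is.finite(cs$x)) || any(!is.finite(cs$y)))
      tme_stop("cell_map: non-finite coordinates")
    out <- which(cs$x < 0 | cs$x >= m$width_px |
                 cs$y < 0 | cs$y >= m$height_px)
    if (length(out))
      tme_stop(sprintf(
        "cell_map: coordinates outside [0,%d) x [0,%d) at row %d",
        m$width_px, m$height_px, out[1]))
    if (anyDuplicated(cs$cell_id))
      tme_stop("cell_map: duplicate cell_id within slide")
  }
  invisible(m)
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map '%s' (patient %s): %d x %d px, %.2f um/px, %d cells\n",
              x$slide_id, x$patient_id, x$width_px, x$height_px,
              x$microns_per_pixel, nrow(x$cells)))
  if (nrow(x$cells)) {
    tab <- table(factor(x$cells$cell_type, levels = cell_types()))
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# metadata keys serialized as leading "#key=value" comment lines
.cellmap_meta_keys <- c("width_px", "height_px", "microns_per_pixel")

#' Write a cell map to a CSV file
#'
#' Serializes a `cell_map` to the package's tabular dialect: UTF-8 CSV with a
#' mandatory header `slide_id,patient_id,cell_id,x_px,y_px,cell_type`,
#' preceded by `#key=value` comment lines carrying the slide extent and
#' resolution.  Rows are ordered by `cell_id`, so the same map always yields a
#' byte-identical file.
#'
#' @param m A `cell_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(m, path) {
  validate_cell_map(m)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    tme_stop(sprintf("write_cell_map: cannot open '%s' for writing", path)))
  on.exit(close(con))
  meta <- sprintf("#%s=%s", .cellmap_meta_keys,
                  c(m$width_px, m$height_px,
                    format(m$microns_per_pixel, digits = 15)))
  cs <- m$cells[order(m$cells$cell_id), , drop = FALSE]
  lines <- c(meta, "slide_id,patient_id,cell_id,x_px,y_px,cell_type")
  if (nrow(cs)) {
    lines <- c(lines, sprintf("%s,%s,%s,%s,%s,%s",
                              m$slide_id, m$patient_id, cs$cell_id,
                              format(cs$x, digits = 15, trim = TRUE,
                                     scientific = FALSE),
                              format(cs$y, digits = 15, trim = TRUE,
                                     scientific = FALSE),
                              cs$cell_type))
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cell map from a CSV file
#'
#' Inverse of [write_cell_map()].  Unknown cell-type labels and coordinates
#' outside the declared slide extent are rejected with located error
#' messages; row order is preserved.
#'
#' @param path Input file path.
#' @return A `cell_map`.
#' @export
read_cell_map <- function(path) {
  if (!file.exists(path))
    tme_stop(sprintf("read_cell_map: no such file '%s'", path))
  all_lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", all_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  for (k in .cellmap_meta_keys)
    if (is.null(meta[[k]]))
      tme_stop(sprintf("read_cell_map: missing '#%s=' metadata line", k))
  body <- all_lines[!grepl("^#", all_lines)]
  if (!length(body))
    tme_stop("read_cell_map: missing header row")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("slide_id", "patient_id", "cell_id", "x_px", "y_px", "cell_type")
  miss <- setdiff(need, header)
  if (length(miss))
    tme_stop(sprintf("read_cell_map: missing column(s): %s",
                     paste(miss, collapse = ", ")))
  if (length(body) > 1) {
    df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                        header), stringsAsFactors = FALSE)
  }
  bad <- which(!(df$cell_type %in% cell_types()))
  if (length(bad))
    tme_stop(sprintf("read_cell_map: unknown cell type '%s' at data row %d",
                     df$cell_type[bad[1]], bad[1]))
  slide_id <- if (nrow(df)) unique(df$slide_id) else "unknown"
  patient_id <- if (nrow(df)) unique(df$patient_id) else "unknown"
  if (length(slide_id) != 1 || length(patient_id) != 1)
    tme_stop("read_cell_map: file mixes multiple slide or patient ids")
  cell_map(slide_id, patient_id,
           width_px = as.integer(meta$width_px),
           height_px = as.integer(meta$height_px),
           microns_per_pixel = as.numeric(meta$microns_per_pixel),
           cells = data.frame(cell_id = df$cell_id,
                              x = as.numeric(df$x_px),
                              y = as.numeric(df$y_px),
                              cell_type = df$cell_type,
                              stringsAsFactors = FALSE))
}
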