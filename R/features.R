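#' Detect tumor tiles (tumor region of interest)
#'
#' Partitions the slide into a regular grid of square tiles and classifies a
#' tile as tumor region iff it contains at least `min_tumor_cells` tumor
#' nuclei (default: 10 per 500 x 500 pixel tile).  Edge tiles narrower than
#' `tile_size_px` use the same absolute count threshold; they are not
#' area-prorated.
#'
#' @param m A `cell_map`.
#' @param tile_size_px Tile side in pixels (default 500).
#' @param min_tumor_cells Minimum tumor-nucleus count for selection
#'   (default 10).
#' @return An object of class `tumor_roi`: the tile grid with per-tile tumor
#'   counts and the selected tile set.
#' @export
detect_tumor_tiles <- function(m, tile_size_px = 500L, min_tumor_cells = 10L) {
  validate_cell_map(m)
  if (tile_size_px <= 0) tme_stop("detect_tumor_tiles: tile_size_px must be > 0")
  n_cols <- as.integer(ceiling(m$width_px / tile_size_px))
  n_rows <- as.integer(ceiling(m$height_px / tile_size_px))
  counts <- matrix(0L, nrow = n_rows, ncol = n_cols)
  tum <- m$cells[m$cells$cell_type == "tumor", , drop = FALSE]
  if (nrow(tum)) {
    r <- pmin(floor(tum$y / tile_size_px) + 1L, n_rows)
    c <- pmin(floor(tum$x / tile_size_px) + 1L, n_cols)
    tab <- table(factor(r, levels = seq_len(n_rows)),
                 factor(c, levels = seq_len(n_cols)))
    counts <- matrix(as.integer(tab), nrow = n_rows)
  }
  sel <- which(counts >= min_tumor_cells, arr.ind = TRUE)
  selected <- data.frame(tile_row = as.integer(sel[, 1]),
                         tile_col = as.integer(sel[, 2]),
                         n_tumor = counts[sel])
  selected <- selected[order(selected$tile_row, selected$tile_col), ,
                       drop = FALSE]
  rownames(selected) <- NULL
  structure(list(tile_size_px = as.integer(tile_size_px),
                 min_tumor_cells = as.integer(min_tumor_cells),
                 n_rows = n_rows, n_cols = n_cols,
                 counts = counts, selected = selected),
            class = "tumor_roi")
}

#' @export
print.tumor_roi <- function(x, ...) {
  cat(sprintf("tumor_roi: %d/%d tiles selected (%d px tiles, >= %d tumor cells)\n",
              nrow(x$selected), x$n_rows * x$n_cols, x$tile_size_px,
              x$min_tumor_cells))
  invisible(x)
}

# tile membership of every cell of a map, as (row, col) indices
.cell_tiles <- function(m, roi) {
  r <- pmin(floor(m$cells$y / roi$tile_size_px) + 1L, roi$n_rows)
  c <- pmin(floor(m$cells$x / roi$tile_size_px) + 1L, roi$n_cols)
  cbind(r, c)
}

#' Tumor/stroma ratio within the tumor region
#'
#' The number of tumor cells divided by the number of stroma cells, both
#' counted over the selected tumor tiles of the slide.
#'
#' @param m A `cell_map`.
#' @param roi A `tumor_roi` computed from `m`.
#' @return A single numeric; `NA` when the ROI is empty or contains no stroma
#'   cells (undefined ratio).  The tumor and stroma counts are attached as
#'   attributes `n_tumor` and `n_stroma`.
#' @export
compute_tsr <- function(m, roi) {
  stopifnot(inherits(roi, "tumor_roi"))
  if (!nrow(roi$selected))
    return(structure(NA_real_, n_tumor = 0L, n_stroma = 0L))
  rc <- .cell_tiles(m, roi)
  key <- paste(rc[, 1], rc[, 2])
  sel_key <- paste(roi$selected$tile_row, roi$selected$tile_col)
  inside <- key %in% sel_key
  n_tumor <- sum(inside & m$cells$cell_type == "tumor")
  n_stroma <- sum(inside & m$cells$cell_type == "stroma")
  val <- if (n_stroma == 0L) NA_real_ else n_tumor / n_stroma
  structure(val, n_tumor = n_tumor, n_stroma = n_stroma)
}

#' Sample image patches from the tumor region
#'
#' Draws up to `max_patches` square patches, each centered on the center of a
#' selected tumor tile (sampled uniformly without replacement) and clamped to
#' lie fully within the slide.  Overlap between patches is permitted.
#' Deterministic given `seed`.
#'
#' @param roi A `tumor_roi`.
#' @param m The `cell_map` the ROI was computed from.
#' @param side_px Patch side in pixels (default 1024).
#' @param max_patches Maximum number of patches (default 100).
#' @param seed Integer seed for tile sampling.
#' @return List of `tme_patch` objects (`x0`, `y0`, `side_px`, member
#'   `cells`); empty with a warning when the ROI is empty.
#' @export
sample_patches <- function(roi, m, side_px = 1024L, max_patches = 100L,
                           seed = 1L) {
  stopifnot(inherits(roi, "tumor_roi"))
  validate_cell_map(m)
  if (!nrow(roi$selected)) {
    warning("sample_patches: empty tumor ROI, no patches sampled")
    return(list())
  }
  if (side_px > m$width_px || side_px > m$height_px)
    tme_stop("sample_patches: patch side exceeds slide extent")
  n <- nrow(roi$selected)
  k <- min(n, max_patches)
  idx <- withr::with_seed(seed, sample.int(n, k))
  ts <- roi$tile_size_px
  cx <- (roi$selected$tile_col[idx] - 0.5) * ts
  cy <- (roi$selected$tile_row[idx] - 0.5) * ts
  x0 <- pmax(0, pmin(round(cx - side_px / 2), m$width_px - side_px))
  y0 <- pmax(0, pmin(round(cy - side_px / 2), m$height_px - side_px))
  lapply(seq_len(k), function(i) {
    keep <- m$cells$x >= x0[i] & m$cells$x < x0[i] + side_px &
            m$cells$y >= y0[i] & m$cells$y < y0[i] + side_px
    structure(list(x0 = x0[i], y0 = y0[i], side_px = as.integer(side_px),
                   tile_row = roi$selected$tile_row[idx[i]],
                   tile_col = roi$selected$tile_col[idx[i]],
                   cells = m$cells[keep, , drop = FALSE]),
              class = "tme_patch")
  })
}

#' Delaunay neighbor graph of a patch
#'
#' Triangulates the member-cell centroids of a patch; the edge set of the
#' Delaunay triangulation defines which cells are spatial neighbors.
#' Patches with fewer than 3 cells, or with all cells collinear, yield a
#' degenerate graph with zero edges (flagged, and excluded downstream from
#' interaction averaging).  Exactly duplicated centroids beyond the first are
#' excluded from the triangulation.
#'
#' @param patch A `tme_patch` (or any data.frame with `x`, `y`, `cell_type`).
#' @return An object of class `neighbor_graph`: vertex cell types, an edge
#'   data.frame (`i`, `j` vertex indices), and a `degenerate` flag.
#' @export
build_delaunay <- function(patch) {
  cells <- if (inherits(patch, "tme_patch")) patch$cells else
    as.data.frame(patch)
  n <- nrow(cells)
  empty <- data.frame(i = integer(), j = integer())
  g <- structure(list(cell_id = cells$cell_id, cell_type = cells$cell_type,
                      n_vertices = n, edges = empty, degenerate = TRUE),
                 class = "neighbor_graph")
  if (n < 3L) return(g)
  xy <- cbind(cells$x, cells$y)
  dup <- duplicated(xy)
  uid <- which(!dup)
  if (length(uid) < 3L) return(g)
  ctr <- sweep(xy[uid, , drop = FALSE], 2, colMeans(xy[uid, , drop = FALSE]))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1)) return(g)  # collinear
  dd <- deldir::deldir(xy[uid, 1], xy[uid, 2], suppressMsge = TRUE)
  e <- dd$delsgs
  edges <- data.frame(i = uid[pmin(e$ind1, e$ind2)],
                      j = uid[pmax(e$ind1, e$ind2)])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  g$edges <- edges
  g$degenerate <- FALSE
  g
}

#' Tumor--X cellular interaction fractions of a patch
#'
#' For each cell type k, the interaction I(tumor, k) is the fraction of
#' Delaunay connections incident to tumor cells whose other endpoint is of
#' type k: the number of tumor--k edges divided by the number of edges
#' incident to at least one tumor cell.  A tumor--tumor edge is a single
#' connection, counted once in both numerator and denominator, so the six
#' fractions sum to one whenever any tumor-incident edge exists.
#'
#' @param graph A `neighbor_graph` from [build_delaunay()].
#' @return Named numeric vector of length 6 (`interaction_tumor_<type>`),
#'   each in `[0, 1]`; all `NA` when the graph is degenerate or has no
#'   tumor-incident edge (undefined interactions).
#' @export
patch_interactions <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  out <- stats::setNames(rep(NA_real_, 6), paste0("interaction_tumor_",
                                                  cell_types()))
  if (graph$degenerate || !nrow(graph$edges)) return(out)
  t1 <- graph$cell_type[graph$edges$i]
  t2 <- graph$cell_type[graph$edges$j]
  inc <- t1 == "tumor" | t2 == "tumor"
  denom <- sum(inc)
  if (denom == 0L) return(out)
  other <- ifelse(t1 == "tumor", t2, t1)  # tumor-tumor edges map to "tumor"
  num <- table(factor(other[inc], levels = cell_types()))
  out[] <- as.numeric(num) / denom
  out
}

#' Per-patch cell-type densities
#'
#' Counts of cells of each of the six types within one patch.  The slide
#' level reports the mean per-patch count over the sampled patches; a
#' `per_100` switch there rescales to counts per one hundred patches.
#'
#' @param patch A `tme_patch`.
#' @return Named numeric vector of length 6 (`density_<type>`).
#' @export
patch_densities <- function(patch) {
  cells <- if (inherits(patch, "tme_patch")) patch$cells else
    as.data.frame(patch)
  counts <- table(factor(cells$cell_type, levels = cell_types()))
  stats::setNames(as.numeric(counts), paste0("density_", cell_types()))
}

#' Slide-level image features
#'
#' The full per-slide feature extraction: tumor-tile detection, random patch
#' sampling from the tumor region, per-patch densities and Delaunay
#' interaction fractions, and averaging across patches.  Interaction
#' fractions are averaged only over patches where they are defined; all
#' sampled patches contribute to the density means.  Also computes the
#' tumor/stroma ratio over the ROI.
#'
#' @param m A `cell_map`.
#' @param seed Integer seed controlling patch sampling.
#' @param tile_size_px,min_tumor_cells Tumor-tile rule (defaults 500 px, 10).
#' @param side_px,max_patches Patch sampling rule (defaults 1024 px, 100).
#' @param density_per_100 If `TRUE`, report densities as counts per one
#'   hundred patches (i.e. per-patch mean times 100).
#' @return One-row data.frame: ids, `level = "slide"`, the 12 features,
#'   `tsr`, `n_patches_used` and a `flag` column (`NA`, `"no_tumor"` for
#'   slides without tumor tiles, or `"no_interactions"`).
#' @export
slide_features <- function(m, seed = 1L, tile_size_px = 500L,
                           min_tumor_cells = 10L, side_px = 1024L,
                           max_patches = 100L, density_per_100 = FALSE) {
  validate_cell_map(m)
  base <- data.frame(slide_id = m$slide_id, patient_id = m$patient_id,
                     level = "slide", stringsAsFactors = FALSE)
  feats <- stats::setNames(rep(NA_real_, 12), feature_names())
  roi <- detect_tumor_tiles(m, tile_size_px, min_tumor_cells)
  if (!nrow(roi$selected)) {
    res <- cbind(base, as.data.frame(as.list(feats)), tsr = NA_real_,
                 n_patches_used = 0L, flag = "no_tumor",
                 stringsAsFactors = FALSE)
    return(res)
  }
  patches <- sample_patches(roi, m, side_px = side_px,
                            max_patches = max_patches, seed = seed)
  dens <- t(vapply(patches, patch_densities, numeric(6)))
  inter <- t(vapply(patches, function(p)
    patch_interactions(build_delaunay(p)), numeric(6)))
  dmean <- colMeans(dens)
  if (density_per_100) dmean <- dmean * 100
  defined <- stats::complete.cases(inter)
  flag <- NA_character_
  if (any(defined)) {
    imean <- colMeans(inter[defined, , drop = FALSE])
  } else {
    imean <- rep(NA_real_, 6)
    flag <- "no_interactions"
  }
  feats[1:6] <- dmean
  feats[7:12] <- imean
  tsr <- compute_tsr(m, roi)
  cbind(base, as.data.frame(as.list(feats)), tsr = as.numeric(tsr),
        n_patches_used = length(patches), flag = flag,
        stringsAsFactors = FALSE)
}

#' Patient-level image features
#'
#' Unweighted mean of slide-level feature vectors per patient, for patients
#' with multiple slides.  Slides flagged `no_tumor` are excluded; a patient
#' with no usable slide is an error (such patients were excluded from the
#' analysis cohorts).
#'
#' @param slide_df Data.frame of slide-level rows from [slide_features()].
#' @return Data.frame, one row per patient, `level = "patient"`.
#' @export
patient_features <- function(slide_df) {
  stopifnot(is.data.frame(slide_df), nrow(slide_df) >= 1)
  usable <- is.na(slide_df$flag) | slide_df$flag != "no_tumor"
  slide_df <- slide_df[usable, , drop = FALSE]
  if (!nrow(slide_df))
    tme_stop("patient_features: no non-flagged slide-level vectors")
  cols <- c(feature_names(), "tsr")
  by_pat <- split(slide_df, slide_df$patient_id)
  rows <- lapply(by_pat, function(d) {
    means <- colMeans(d[, cols, drop = FALSE], na.rm = TRUE)
    means[vapply(cols, function(cc) all(is.na(d[[cc]])), logical(1))] <- NA
    cbind(data.frame(patient_id = d$patient_id[1], level = "patient",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)),
          n_slides = nrow(d),
          n_patches_used = sum(d$n_patches_used))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}
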