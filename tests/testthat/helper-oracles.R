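# Independent oracles used across the suite.  These deliberately recompute
# quantities by brute force / direct definition, sharing no code with the
# package internals they check.

# Brute-force Delaunay edge set: an edge belongs to the triangulation iff it
# is a side of some triangle whose circumcircle contains no other point
# (empty-circumcircle property, checked over all point triples).
brute_delaunay_edges <- function(x, y, eps = 1e-9) {
  n <- length(x)
  stopifnot(n >= 3)
  tri <- utils::combn(n, 3)
  a <- tri[1, ]; b <- tri[2, ]; cc <- tri[3, ]
  ax <- x[a]; ay <- y[a]; bx <- x[b]; by <- y[b]; cx <- x[cc]; cy <- y[cc]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  # count points strictly inside each circumcircle (vertices sit on it)
  inside_ct <- rowSums(
    (outer(ux, x, "-")^2 + outer(uy, y, "-")^2) < r2 * (1 - eps))
  keep <- which(ok & inside_ct == 0)
  if (!length(keep)) return(data.frame(i = integer(), j = integer()))
  vs <- apply(tri[, keep, drop = FALSE], 2, sort)
  e <- rbind(t(vs[c(1, 2), , drop = FALSE]),
             t(vs[c(1, 3), , drop = FALSE]),
             t(vs[c(2, 3), , drop = FALSE]))
  e <- unique(as.data.frame(e))
  names(e) <- c("i", "j")
  e <- e[order(e$i, e$j), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# direct per-edge enumeration of tumor-incident connections
oracle_interactions <- function(edges, types) {
  out <- stats::setNames(rep(NA_real_, 6),
                         paste0("interaction_tumor_", cell_types()))
  cnt <- stats::setNames(numeric(6), cell_types())
  denom <- 0
  for (r in seq_len(nrow(edges))) {
    ti <- types[edges$i[r]]
    tj <- types[edges$j[r]]
    if (ti != "tumor" && tj != "tumor") next
    denom <- denom + 1
    other <- if (ti == "tumor" && tj == "tumor") "tumor" else
      if (ti == "tumor") tj else ti
    cnt[other] <- cnt[other] + 1
  }
  if (denom == 0) return(out)
  out[] <- cnt / denom
  out
}

# full running-sum GSEA enrichment score evaluated at every list position
brute_es <- function(rho, set_idx, exponent = 1) {
  N <- length(rho)
  w <- abs(rho)^exponent
  hit <- seq_len(N) %in% set_idx
  m <- sum(hit)
  nr <- sum(w[hit])
  steps <- ifelse(hit, w / nr, -1 / (N - m))
  run <- cumsum(steps)
  hi <- max(run, 0)
  lo <- min(run, 0)
  if (hi >= -lo) hi else lo
}

# hand log-rank statistic: hypergeometric observed-minus-expected sums
hand_logrank_chisq <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# random synthetic patch: uniform cell positions, weighted type mix
random_patch <- function(n, seed, side = 1024,
                         probs = c(0.45, 0.3, 0.12, 0.06, 0.04, 0.03)) {
  withr::with_seed(seed, data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    x = stats::runif(n, 0, side),
    y = stats::runif(n, 0, side),
    cell_type = sample(cell_types(), n, replace = TRUE, prob = probs),
    stringsAsFactors = FALSE))
}

# minimal valid cell map around an explicit cell table
make_map <- function(cells, width = 1000L, height = 1000L, slide = "S1",
                     patient = "P1") {
  cells$cell_id <- cells$cell_id %||% sprintf("c%05d", seq_len(nrow(cells)))
  cell_map(slide, patient, width, height, cells)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
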