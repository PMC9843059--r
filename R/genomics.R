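#' Filter genes by zero-expression fraction
#'
#' Removes genes whose expression is zero in more than `max_zero_fraction`
#' of patients (default: more than 20%); a gene zero in exactly that
#' fraction is retained.
#'
#' @param expr Gene-by-patient numeric matrix.
#' @param max_zero_fraction Maximum tolerated zero fraction (default 0.20).
#' @return The filtered matrix.
#' @export
filter_genes <- function(expr, max_zero_fraction = 0.20) {
  stopifnot(is.matrix(expr))
  if (max_zero_fraction < 0 || max_zero_fraction > 1)
    tme_stop("filter_genes: max_zero_fraction must be in [0, 1]")
  if (!nrow(expr) || !ncol(expr))
    tme_stop("filter_genes: empty expression matrix")
  zf <- rowMeans(expr == 0)
  expr[zf <= max_zero_fraction, , drop = FALSE]
}

#' Rank genes by Spearman correlation with an image feature
#'
#' Correlates each gene's expression with a per-patient image feature using
#' Spearman's rank correlation (average ranks for ties), aligning patients
#' by id.  Zero-variance genes are excluded from the ranking and reported in
#' the `excluded` attribute.  Per-gene p-values use the large-sample t
#' approximation.
#'
#' @param expr Gene-by-patient matrix (patient ids as colnames).
#' @param feature Numeric vector of feature values named by patient id.
#' @return A `gene_ranking` data.frame (`gene`, `rho`, `p`) ordered by `rho`
#'   descending, with attributes `feature_name`, `n` and `excluded`.
#' @export
rank_genes <- function(expr, feature) {
  stopifnot(is.matrix(expr), !is.null(names(feature)))
  common <- intersect(colnames(expr), names(feature))
  if (length(common) < 3)
    tme_stop("rank_genes: need >= 3 patients common to expression and feature")
  e <- expr[, common, drop = FALSE]
  f <- feature[common]
  gene_sd <- apply(e, 1, stats::sd)
  excluded <- rownames(e)[gene_sd == 0]
  e <- e[gene_sd > 0, , drop = FALSE]
  n <- length(common)
  rho <- as.numeric(stats::cor(t(e), f, method = "spearman"))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  out <- data.frame(gene = rownames(e), rho = rho, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_name") <- attr(feature, "feature_name") %||% NA_character_
  attr(out, "n") <- n
  attr(out, "excluded") <- excluded
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; thin validation wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    tme_stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# weighted KS enrichment score of a gene set in a ranked list.
# positions: ranks (ascending order positions) of the set members in the
# ranked list; w: per-gene weights |rho|^exponent over the full list.
# The running sum rises by w/sum(w in set) at hits and falls by 1/(N-m)
# between them, so its extremes occur exactly at hit boundaries.
.gsea_es <- function(positions, w, N) {
  m <- length(positions)
  pos <- sort.int(positions)
  wr <- w[pos]
  NR <- sum(wr)
  if (NR == 0 || m >= N) return(list(es = NA_real_, peak = NA_integer_))
  cw <- cumsum(wr) / NR
  k <- seq_len(m)
  after <- cw - (pos - k) / (N - m)          # value just after each hit
  before <- c(0, cw[-m]) - (pos - k) / (N - m)  # value just before each hit
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) {
    list(es = hi, peak = pos[which.max(after)])
  } else {
    list(es = lo, peak = pos[which.min(before)])
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment of gene sets in a
#' correlation-ranked gene list.  The enrichment score (ES) is the signed
#' extremum of the running sum over the rho-ordered list, with hit
#' increments weighted by `|rho|^weight_exponent`.  The null distribution is
#' obtained by gene-label permutation: `n_permutations` random same-size
#' gene sets per set size.  P-values use the +1-smoothed rule
#' `(b + 1) / (n + 1)` where `b` counts null scores of the same sign with
#' magnitude at least the observed; they are BH-adjusted across sets.
#'
#' @param ranking A `gene_ranking` from [rank_genes()].
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_permutations Number of null permutations (default 10000).
#' @param weight_exponent Weight exponent on `|rho|` (default 1; 0 gives the
#'   classical unweighted KS statistic).
#' @param min_size,max_size Set-size filter after restriction to ranked
#'   genes (defaults 5 and 500).
#' @param seed Integer seed for the permutation null.
#' @return Data.frame `set`, `size`, `es`, `nes`, `p`, `padj`,
#'   `leading_edge` (slash-separated gene symbols), ordered by `p` then set
#'   name.  Empty (with a warning) when no set survives size filtering.
#' @export
preranked_gsea <- function(ranking, sets, n_permutations = 10000L,
                           weight_exponent = 1, min_size = 5L,
                           max_size = 500L, seed = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  genes <- ranking$gene
  N <- length(genes)
  w <- abs(ranking$rho)^weight_exponent
  members <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("preranked_gsea: no gene set survives size filtering")
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), padj = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE))
  }
  members <- members[keep]
  obs <- lapply(members, .gsea_es, w = w, N = N)
  es <- vapply(obs, `[[`, numeric(1), "es")
  # one shared null per distinct set size, from gene-label permutations
  null_by_size <- list()
  withr::with_seed(seed, {
    for (m in sort(unique(lengths(members)))) {
      null_by_size[[as.character(m)]] <- vapply(seq_len(n_permutations),
        function(i) .gsea_es(sample.int(N, m), w, N)$es, numeric(1))
    }
  })
  p <- nes <- rep(NA_real_, length(members))
  for (i in seq_along(members)) {
    nul <- null_by_size[[as.character(length(members[[i]]))]]
    if (is.na(es[i])) next
    same_sign <- nul[sign(nul) == sign(es[i])]
    b <- sum(sign(nul) == sign(es[i]) & abs(nul) >= abs(es[i]))
    p[i] <- (b + 1) / (n_permutations + 1)
    denom <- mean(abs(same_sign))
    nes[i] <- if (length(same_sign) && denom > 0) es[i] / denom else NA_real_
  }
  le <- vapply(seq_along(members), function(i) {
    pos <- sort.int(members[[i]])
    pk <- obs[[i]]$peak
    if (is.na(pk)) return(NA_character_)
    lead <- if (es[i] >= 0) pos[pos <= pk] else pos[pos >= pk]
    paste(genes[lead], collapse = "/")
  }, character(1))
  out <- data.frame(set = names(members), size = lengths(members),
                    es = es, nes = nes, p = p, padj = bh_adjust(p),
                    leading_edge = le, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient-ID-shuffle negative control
#'
#' Randomly permutes the patient assignment of the image-feature vector,
#' then reruns the correlation ranking and preranked GSEA.  Genuine
#' feature-expression associations should vanish under the shuffle: an
#' enrichment that survives indicates an artifact.
#'
#' @param expr Gene-by-patient matrix.
#' @param feature Named per-patient feature vector.
#' @param sets Named list of gene sets.
#' @param seed Integer seed (controls both the shuffle and the GSEA null).
#' @param ... Passed on to [preranked_gsea()].
#' @return A list: `enrichment` (the GSEA table under the shuffle),
#'   `significant` (sets at adjusted p < 0.05), and `permutation` (the
#'   shuffled patient-id assignment).
#' @export
shuffle_control <- function(expr, feature, sets, seed = 1L, ...) {
  ids <- names(feature)
  perm <- withr::with_seed(seed, sample(ids))
  shuffled <- stats::setNames(as.numeric(feature), perm)
  ranking <- rank_genes(expr, shuffled)
  enr <- preranked_gsea(ranking, sets, seed = stage_seed(seed, "gsea"), ...)
  list(enrichment = enr,
       significant = enr[!is.na(enr$padj) & enr$padj < 0.05, , drop = FALSE],
       permutation = stats::setNames(perm, ids))
}

#' Built-in marker gene panels
#'
#' Small literature marker panels summarizing the biology read out against
#' the tumor-stroma interaction: activated fibroblast/angiogenesis markers,
#' the HGF- and EGFR-driven arms of PIP3/PI3K activation, their shared PI3K
#' adaptors, and mesenchymal versus epithelial (EMT) markers.
#'
#' @return Named list of uppercase gene-symbol vectors.
#' @export
marker_panels <- function() {
  list(
    fibroblast_angiogenesis = c("ACTA2", "PECAM1"),
    hgf_arm = c("HGF", "MET"),
    egfr_arm = c("EGFR", "ERBB3"),
    shared_pi3k = c("GAB1", "GRB2", "PIK3R1", "PIK3CA"),
    mesenchymal = c("VIM", "TGFB1", "FGFR1", "ZEB1"),
    epithelial = c("CDH1", "CTNNA1", "JUP"))
}

#' Marker-panel expression summary along an image feature
#'
#' Bins patients into `n_bins` equal-size groups by increasing feature value
#' and reports, per marker gene, the mean standardized (z-scored) expression
#' in each bin, plus the gene's Spearman correlation with the feature.
#' Genes missing from the matrix are reported, not fatal.
#'
#' @param expr Gene-by-patient matrix.
#' @param feature Named per-patient feature vector.
#' @param panels Named list of gene panels (default [marker_panels()]).
#' @param n_bins Number of feature-quantile bins (default 5).
#' @return A list: `bins` (long data.frame `panel`, `gene`, `bin`,
#'   `mean_z`, `n`), `correlations` (`panel`, `gene`, `rho`, `p`), and
#'   `missing` (genes not found).
#' @export
marker_panel_summary <- function(expr, feature, panels = marker_panels(),
                                 n_bins = 5L) {
  common <- intersect(colnames(expr), names(feature))
  if (n_bins > length(common))
    tme_stop("marker_panel_summary: n_bins exceeds patient count")
  f <- feature[common]
  # balanced quantile bins via ranks (ties broken by patient order)
  bin <- as.integer(floor((rank(f, ties.method = "first") - 1) *
                            n_bins / length(f)) + 1)
  all_genes <- unique(unlist(panels))
  missing <- setdiff(all_genes, rownames(expr))
  if (length(missing))
    warning(sprintf("marker_panel_summary: gene(s) not in matrix: %s",
                    paste(missing, collapse = ", ")))
  bins_rows <- list()
  cor_rows <- list()
  n <- length(common)
  for (pn in names(panels)) {
    for (g in intersect(panels[[pn]], rownames(expr))) {
      v <- expr[g, common]
      z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
      mz <- tapply(z, bin, mean)
      bins_rows[[length(bins_rows) + 1L]] <- data.frame(
        panel = pn, gene = g, bin = as.integer(names(mz)),
        mean_z = as.numeric(mz),
        n = as.integer(table(bin)[names(mz)]), stringsAsFactors = FALSE)
      rho <- suppressWarnings(stats::cor(v, f, method = "spearman"))
      pval <- if (is.na(rho)) NA_real_ else {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
      }
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        panel = pn, gene = g, rho = rho, p = pval, stringsAsFactors = FALSE)
    }
  }
  list(bins = do.call(rbind, bins_rows),
       correlations = do.call(rbind, cor_rows),
       missing = missing)
}
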