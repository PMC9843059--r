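#' Simulate a cell map (marked spatial point pattern)
#'
#' Generates the centroid map of one synthetic slide with the spatial
#' structure the feature extraction assumes: tumor cells as uniform-density
#' clusters inside circular nests, stroma cells as a background Poisson
#' process of which a fraction `mixing` is relocated into the nests
#' (`mixing = 0`: pure nests with only incidental background stroma;
#' `mixing = 1`: all stroma intermixed with tumor), and the four remaining
#' types as sparse uniform background.  Pure function of its parameters and
#' seed.
#'
#' Default intensities give, at 0.25 um/px, on the order of 400-600 nuclei
#' per 1024 x 1024 patch inside tumor nests, comparable to densely cellular
#' adenocarcinoma regions.
#'
#' @param slide_id,patient_id Identifiers.
#' @param width_px,height_px Slide extent (default 4000 x 4000 px).
#' @param n_nests Number of circular tumor nests (default 5).
#' @param nest_radius_px Nest radius (default 500 px).
#' @param intensities Named vector, expected cells per px^2: `tumor` within
#'   nests; the rest over the whole slide.
#' @param mixing Fraction of stroma cells relocated into nests, in `[0, 1]`
#'   (default 0.25).
#' @param seed Integer seed.
#' @return A `cell_map`.
#' @export
simulate_cell_map <- function(slide_id = "S1", patient_id = "P1",
                              width_px = 4000L, height_px = 4000L,
                              n_nests = 5L, nest_radius_px = 500,
                              intensities = c(tumor = 4e-4, stroma = 1.5e-4,
                                              lymphocyte = 2e-5,
                                              red_blood_cell = 1e-5,
                                              macrophage = 6e-6,
                                              karyorrhexis = 6e-6),
                              mixing = 0.25, seed = 1L) {
  if (width_px <= 0 || height_px <= 0)
    tme_stop("simulate_cell_map: slide extent must be positive")
  if (mixing < 0 || mixing > 1)
    tme_stop("simulate_cell_map: mixing must be in [0, 1]")
  if (any(intensities < 0))
    tme_stop("simulate_cell_map: intensities must be >= 0")
  miss <- setdiff(cell_types(), names(intensities))
  if (length(miss))
    tme_stop(sprintf("simulate_cell_map: missing intensity for: %s",
                     paste(miss, collapse = ", ")))
  r <- nest_radius_px
  withr::with_seed(seed, {
    margin <- min(r, width_px / 2 - 1, height_px / 2 - 1)
    cx <- stats::runif(n_nests, margin, width_px - margin)
    cy <- stats::runif(n_nests, margin, height_px - margin)
    in_nest <- function(n) {
      # uniform in a random nest's disk, clamped to the slide
      nest <- sample.int(n_nests, n, replace = TRUE)
      rad <- r * sqrt(stats::runif(n))
      ang <- stats::runif(n, 0, 2 * pi)
      x <- pmin(pmax(cx[nest] + rad * cos(ang), 0), width_px - 1e-6)
      y <- pmin(pmax(cy[nest] + rad * sin(ang), 0), height_px - 1e-6)
      cbind(x, y)
    }
    uniform <- function(n) cbind(stats::runif(n, 0, width_px - 1e-6),
                                 stats::runif(n, 0, height_px - 1e-6))
    pts <- list()
    n_tumor <- stats::rpois(1, intensities[["tumor"]] * n_nests * pi * r^2)
    pts$tumor <- in_nest(n_tumor)
    n_stroma <- stats::rpois(1, intensities[["stroma"]] * width_px * height_px)
    reloc <- stats::runif(n_stroma) < mixing
    pts$stroma <- rbind(in_nest(sum(reloc)), uniform(sum(!reloc)))
    for (ty in c("lymphocyte", "red_blood_cell", "macrophage",
                 "karyorrhexis")) {
      n <- stats::rpois(1, intensities[[ty]] * width_px * height_px)
      pts[[ty]] <- uniform(n)
    }
    cells <- do.call(rbind, lapply(names(pts), function(ty) {
      p <- pts[[ty]]
      if (!nrow(p)) return(NULL)
      data.frame(x = p[, 1], y = p[, 2], cell_type = ty,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(cells))
      cells <- data.frame(x = numeric(), y = numeric(),
                          cell_type = character(), stringsAsFactors = FALSE)
    cells$cell_id <- sprintf("%s_c%06d", slide_id, seq_len(nrow(cells)))
    cell_map(slide_id, patient_id, width_px, height_px,
             cells[, c("cell_id", "x", "y", "cell_type")])
  })
}

#' Simulate a per-patient image-feature matrix
#'
#' Generates plausible patient-level feature vectors without paying for full
#' cell-map simulation: the six tumor--X interaction fractions are drawn from
#' a Dirichlet distribution (so they sum to one, with tumor-tumor dominant
#' and tumor-stroma the main minority, as in tumor-rich regions), and the
#' six densities are log-normal per-patch mean counts.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param dirichlet_alpha Dirichlet concentration over the six interactions.
#' @param density_meanlog,density_sdlog Log-normal parameters of the six
#'   densities.
#' @return Data.frame with `patient_id` and the 12 feature columns.
#' @export
simulate_feature_matrix <- function(n, seed = 1L,
                                    dirichlet_alpha = c(tumor = 7,
                                                        stroma = 2.5,
                                                        lymphocyte = 1.2,
                                                        red_blood_cell = 0.5,
                                                        macrophage = 0.4,
                                                        karyorrhexis = 0.4),
                                    density_meanlog = log(c(300, 120, 40, 15,
                                                            5, 5)),
                                    density_sdlog = 0.4) {
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n * 6, shape = rep(dirichlet_alpha, each = n)),
                nrow = n)
    inter <- g / rowSums(g)
    dens <- exp(matrix(stats::rnorm(n * 6,
                                    mean = rep(density_meanlog, each = n),
                                    sd = density_sdlog), nrow = n))
    out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out[paste0("density_", cell_types())] <- as.data.frame(dens)
    out[paste0("interaction_tumor_", cell_types())] <- as.data.frame(inter)
    out
  })
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' Generates overall-survival outcomes for patients with given image
#' features: exponential baseline hazard, linear predictor `beta' f` over
#' the named features, a treatment term whose log hazard ratio may differ
#' between the true benefit groups (effect modification), and independent
#' exponential censoring.  The true benefit group is defined by the feature
#' linear predictor (at or below its median = `benefit`), mirroring the
#' predicted-group-by-treatment interaction design.
#'
#' @param features Data.frame with `patient_id` and feature columns.
#' @param betas Named numeric vector of per-unit log hazard ratios (names
#'   must be feature columns).  Default plants the reported per-10% hazard
#'   ratios 0.73 (tumor-tumor, protective) and 1.53 (tumor-stroma, harmful)
#'   on the interaction fractions' 0--1 scale.
#' @param baseline_rate Exponential baseline hazard per month (default 0.02).
#' @param censoring_rate Exponential censoring hazard per month (default
#'   0.008; 0 disables censoring so every event is observed).
#' @param treat_prob Probability of EGFR TKI treatment (default 0.7).
#' @param trt_loghr Treatment log hazard ratio: a single number (homogeneous
#'   effect) or a named length-2 vector `c(benefit = , nonbenefit = )`.
#'   Default 0 (no treatment effect).
#' @param seed Integer seed.
#' @return Cohort data.frame in the [read_clinical()] schema plus columns
#'   `true_group` and `lp` (the feature linear predictor).
#' @export
simulate_cohort <- function(features,
                            betas = c(interaction_tumor_tumor = log(0.73) / 0.1,
                                      interaction_tumor_stroma = log(1.53) / 0.1),
                            baseline_rate = 0.02, censoring_rate = 0.008,
                            treat_prob = 0.7, trt_loghr = 0, seed = 1L) {
  n <- nrow(features)
  if (n < 2) tme_stop("simulate_cohort: need >= 2 patients")
  if (baseline_rate <= 0 || censoring_rate < 0)
    tme_stop("simulate_cohort: invalid hazard rates")
  miss <- setdiff(names(betas), names(features))
  if (length(miss))
    tme_stop(sprintf("simulate_cohort: betas name absent feature(s): %s",
                     paste(miss, collapse = ", ")))
  lp <- if (length(betas)) {
    as.numeric(as.matrix(features[, names(betas), drop = FALSE]) %*% betas)
  } else rep(0, n)
  true_group <- ifelse(lp <= stats::median(lp), "benefit", "nonbenefit")
  if (length(trt_loghr) == 1L && is.null(names(trt_loghr)))
    trt_loghr <- c(benefit = unname(trt_loghr), nonbenefit = unname(trt_loghr))
  withr::with_seed(seed, {
    trt <- stats::rbinom(n, 1, treat_prob)
    rate <- baseline_rate * exp(lp + trt * trt_loghr[true_group])
    t_event <- stats::rexp(n, rate)
    t_cens <- if (censoring_rate > 0) stats::rexp(n, censoring_rate) else
      rep(Inf, n)
    data.frame(patient_id = features$patient_id,
               os_months = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               tki_treated = trt,
               egfr_class = sample(c("sensitizing", "other"), n, TRUE,
                                   prob = c(0.85, 0.15)),
               age = round(stats::rnorm(n, 65, 10)),
               sex = sample(c("female", "male"), n, TRUE),
               smoking_status = sample(c("never", "former", "current"), n,
                                       TRUE, prob = c(0.6, 0.3, 0.1)),
               surgery = stats::rbinom(n, 1, 0.3),
               true_group = true_group,
               lp = lp,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an expression matrix with planted feature correlations
#'
#' Builds a gene-by-patient matrix in which a block of genes carries a
#' planted monotone association with a per-patient image feature and the
#' remaining genes are independent noise.  Correlated genes are Gaussian
#' copula draws: the latent gene value is `rho_lat * z + sqrt(1 - rho_lat^2)
#' * noise`, where `z` are the normal scores of the feature ranks and
#' `rho_lat = 2 sin(pi rho_S / 6)` is the latent correlation giving Spearman
#' correlation `rho_S` under bivariate normality (calibration tolerance
#' about +/- 0.02 at moderate n).  Values are shifted per gene to be
#' nonnegative.  Also returns planted and decoy gene sets for enrichment
#' testing.
#'
#' @param feature Named per-patient feature vector (>= 10 patients).
#' @param n_genes Total genes (default 2000).
#' @param n_correlated Correlated genes (default 60).
#' @param target_rho Target Spearman correlation of correlated genes
#'   (default 0.3, the modest strength typical of image-transcriptome
#'   associations; `|target_rho| <= 1`).  Note that genes correlated with
#'   the same feature are mutually correlated (pairwise latent correlation
#'   `rho_lat^2`), so strong planted correlations make gene-label
#'   permutation GSEA anti-conservative for the planted set.
#' @param planted_set_size Size of the planted (truly enriched) set, taken
#'   from the correlated genes (default 30).
#' @param n_decoy_sets,decoy_set_size Decoy sets of null genes (defaults 40
#'   and 30).
#' @param noise_scale Scale of expression values (default 1; ranks, and so
#'   every Spearman-based result, are invariant to it).
#' @param seed Integer seed.
#' @return List: `expression` (matrix), `sets` (named list; the planted set
#'   is `"planted_set"`), `correlated_genes`.
#' @export
simulate_expression <- function(feature, n_genes = 2000L, n_correlated = 60L,
                                target_rho = 0.3, planted_set_size = 30L,
                                n_decoy_sets = 40L, decoy_set_size = 30L,
                                noise_scale = 1, seed = 1L) {
  n <- length(feature)
  if (n < 10) tme_stop("simulate_expression: need >= 10 patients")
  if (abs(target_rho) > 1)
    tme_stop("simulate_expression: |target_rho| must be <= 1")
  if (n_correlated < planted_set_size)
    tme_stop("simulate_expression: planted set larger than correlated block")
  if (n_genes - n_correlated < n_decoy_sets * decoy_set_size)
    tme_stop("simulate_expression: not enough null genes for decoy sets")
  rho_lat <- 2 * sin(pi * target_rho / 6)
  z <- stats::qnorm((rank(feature, ties.method = "average") - 0.375) /
                      (n + 0.25))
  withr::with_seed(seed, {
    genes <- c(sprintf("CORR%04d", seq_len(n_correlated)),
               sprintf("NULL%04d", seq_len(n_genes - n_correlated)))
    expr <- matrix(0, nrow = n_genes, ncol = n,
                   dimnames = list(genes, names(feature)))
    for (i in seq_len(n_correlated)) {
      lat <- rho_lat * z + sqrt(1 - rho_lat^2) * stats::rnorm(n)
      expr[i, ] <- lat
    }
    expr[(n_correlated + 1):n_genes, ] <-
      matrix(stats::rnorm((n_genes - n_correlated) * n),
             nrow = n_genes - n_correlated)
    expr <- expr * noise_scale
    expr <- expr - apply(expr, 1, min)  # shift each gene to be nonnegative
    null_genes <- genes[(n_correlated + 1):n_genes]
    decoy_pool <- sample(null_genes)
    sets <- list(planted_set = genes[seq_len(planted_set_size)])
    for (k in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy_set_%02d", k)]] <-
        decoy_pool[((k - 1) * decoy_set_size + 1):(k * decoy_set_size)]
    }
    list(expression = expr, sets = sets,
         correlated_genes = genes[seq_len(n_correlated)])
  })
}
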