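# nested default configuration; validate_config() merges user values into
# this template and rejects keys it does not know
.default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, features = TRUE, fit = TRUE,
                  predict = TRUE, evaluate = TRUE, gsea = TRUE),
    inputs = list(cell_maps = NULL, clinical = NULL, expression = NULL,
                  gmt = NULL),
    simulate = list(n_patients = 40L,
                    cellmap = list(width_px = 4000L, height_px = 4000L,
                                   n_nests = 5L, nest_radius_px = 500,
                                   mixing = 0.25),
                    cohort = list(baseline_rate = 0.02,
                                  censoring_rate = 0.008,
                                  treat_prob = 0.7,
                                  trt_loghr_benefit = log(0.2),
                                  trt_loghr_nonbenefit = 0),
                    expression = list(n_genes = 2000L, n_correlated = 60L,
                                      target_rho = 0.3,
                                      planted_set_size = 30L,
                                      n_decoy_sets = 40L,
                                      decoy_set_size = 30L)),
    features = list(tile_size_px = 500L, min_tumor_cells = 10L,
                    patch_side_px = 1024L, max_patches = 100L,
                    density_per_100 = FALSE),
    fit = list(alpha = 0.5, nfolds = 5L, treated_only = TRUE,
               lambda = "lambda.min"),
    predict = list(threshold = NULL),
    evaluate = list(adjusters = c("age", "sex", "smoking_status", "surgery")),
    gsea = list(feature_name = "interaction_tumor_stroma",
                n_permutations = 10000L, weight_exponent = 1,
                min_size = 5L, max_size = 500L, max_zero_fraction = 0.20,
                shuffle_control = TRUE))
}

.merge_config <- function(default, user, path = "") {
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    tme_stop(sprintf("validate_config: unknown key '%s%s'",
                     path, unknown[1]))
  for (k in names(user)) {
    if (is.list(default[[k]]) && !is.null(names(default[[k]]))) {
      if (!is.list(user[[k]]))
        tme_stop(sprintf("validate_config: '%s%s' must be a mapping", path, k))
      default[[k]] <- .merge_config(default[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      default[k] <- user[k]
    }
  }
  default
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), fills
#' defaults — tumor-tile rule 10 per 500 x 500 px, 1024 px patches capped at
#' 100, gene zero-fraction cutoff 0.20, elastic-net mixing 0.5 with 5 CV
#' folds — rejects unknown keys, and checks parameter ranges and stage
#' dependencies (every enabled stage must get its inputs either from an
#' enabled earlier stage or from an existing input path).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config))
      tme_stop(sprintf("validate_config: no such file '%s'", config))
    yaml::read_yaml(config)
  } else config
  cfg <- .merge_config(.default_config(), user)
  if (is.null(cfg$out_dir))
    tme_stop("validate_config: missing required key 'out_dir'")
  pos <- c("features.tile_size_px", "features.min_tumor_cells",
           "features.patch_side_px", "features.max_patches",
           "fit.nfolds", "gsea.n_permutations", "gsea.min_size",
           "gsea.max_size", "simulate.n_patients")
  for (key in pos) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || v <= 0)
      tme_stop(sprintf("validate_config: '%s' must be positive", key))
  }
  if (cfg$fit$alpha < 0 || cfg$fit$alpha > 1)
    tme_stop("validate_config: 'fit.alpha' must be in [0, 1]")
  if (cfg$gsea$max_zero_fraction < 0 || cfg$gsea$max_zero_fraction > 1)
    tme_stop("validate_config: 'gsea.max_zero_fraction' must be in [0, 1]")
  st <- cfg$stages
  need_input <- function(stage, what, path) {
    if (is.null(path) || !all(file.exists(path)))
      tme_stop(sprintf(
        "validate_config: stage '%s' enabled but %s neither produced by an enabled earlier stage nor found at 'inputs.%s'",
        stage, what, what))
  }
  if (isTRUE(st$features) && !isTRUE(st$simulate))
    need_input("features", "cell_maps", cfg$inputs$cell_maps)
  if (isTRUE(st$fit) && !isTRUE(st$features))
    tme_stop("validate_config: stage 'fit' enabled but stage 'features' is not")
  if ((isTRUE(st$fit) || isTRUE(st$evaluate)) && !isTRUE(st$simulate))
    need_input("fit/evaluate", "clinical", cfg$inputs$clinical)
  if (isTRUE(st$gsea) && !isTRUE(st$simulate)) {
    need_input("gsea", "expression", cfg$inputs$expression)
    need_input("gsea", "gmt", cfg$inputs$gmt)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — cell-map simulation,
#' feature extraction, cohort/expression simulation, elastic-net Cox fit,
#' risk scoring and median split, survival evaluation (log-rank, per-group
#' treatment hazard ratios, treatment-by-group interaction Cox), and
#' GSEA with its patient-ID-shuffle control — writing every artifact plus a
#' run manifest into `out_dir`.  Per-stage seeds are derived from the global
#' seed by stage-name hashing, so toggling one stage never perturbs
#' another's randomness.  Deterministic given the configuration.
#'
#' @param config A `pipeline_config` (or path / list accepted by
#'   [validate_config()]).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  status <- "ok"
  failed_stage <- NA_character_
  emit_manifest <- function() {
    manifest <- list(package = "tmebenefit",
                     version = as.character(utils::packageVersion("tmebenefit")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     seed = cfg$seed, status = status,
                     failed_stage = failed_stage,
                     config = unclass(cfg),
                     artifacts = names(artifacts))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      status <<- "failed"
      failed_stage <<- stage
      emit_manifest()
      tme_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                       conditionMessage(e)))
    })
  }
  maps <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate_cellmaps", function() {
      sdir <- file.path(out, "simulated", "cellmaps")
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      sseed <- stage_seed(cfg$seed, "simulate_cellmaps")
      cm <- cfg$simulate$cellmap
      maps <<- lapply(seq_len(cfg$simulate$n_patients), function(i) {
        simulate_cell_map(slide_id = sprintf("S%04d", i),
                          patient_id = sprintf("P%04d", i),
                          width_px = cm$width_px, height_px = cm$height_px,
                          n_nests = cm$n_nests,
                          nest_radius_px = cm$nest_radius_px,
                          mixing = cm$mixing,
                          seed = stage_seed(sseed, sprintf("map%04d", i)))
      })
      for (m in maps) write_cell_map(m, file.path(sdir,
                                                  paste0(m$slide_id, ".csv")))
      artifacts$cell_maps <<- sdir
    })
  }
  feats_slide <- feats <- NULL
  if (isTRUE(cfg$stages$features)) {
    run_stage("features", function() {
      if (is.null(maps)) {
        paths <- cfg$inputs$cell_maps
        if (length(paths) == 1 && dir.exists(paths))
          paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
        maps <<- lapply(paths, read_cell_map)
      }
      fseed <- stage_seed(cfg$seed, "features")
      fp <- cfg$features
      feats_slide <<- do.call(rbind, lapply(maps, function(m)
        slide_features(m, seed = stage_seed(fseed, m$slide_id),
                       tile_size_px = fp$tile_size_px,
                       min_tumor_cells = fp$min_tumor_cells,
                       side_px = fp$patch_side_px,
                       max_patches = fp$max_patches,
                       density_per_100 = fp$density_per_100)))
      feats <<- patient_features(feats_slide)
      p1 <- file.path(out, "features_slide.csv")
      p2 <- file.path(out, "features_patient.csv")
      utils::write.csv(feats_slide, p1, row.names = FALSE, na = "")
      utils::write.csv(feats, p2, row.names = FALSE, na = "")
      artifacts$features_slide <<- p1
      artifacts$features_patient <<- p2
    })
  }
  clinical <- NULL
  if (isTRUE(cfg$stages$simulate) && !is.null(feats)) {
    run_stage("simulate_cohort", function() {
      cp <- cfg$simulate$cohort
      clinical <<- simulate_cohort(
        feats, baseline_rate = cp$baseline_rate,
        censoring_rate = cp$censoring_rate, treat_prob = cp$treat_prob,
        trt_loghr = c(benefit = cp$trt_loghr_benefit,
                      nonbenefit = cp$trt_loghr_nonbenefit),
        seed = stage_seed(cfg$seed, "simulate_cohort"))
      p <- file.path(out, "simulated", "clinical.csv")
      write_clinical(clinical, p)
      artifacts$clinical <<- p
    })
  } else if (!is.null(cfg$inputs$clinical)) {
    clinical <- read_clinical(cfg$inputs$clinical)
  }
  model <- NULL
  if (isTRUE(cfg$stages$fit)) {
    run_stage("fit", function() {
      model <<- fit_penalized_cox(feats, clinical, alpha = cfg$fit$alpha,
                                  nfolds = cfg$fit$nfolds,
                                  seed = stage_seed(cfg$seed, "fit"),
                                  treated_only = cfg$fit$treated_only,
                                  lambda = cfg$fit$lambda)
      p <- file.path(out, "model.txt")
      write_risk_model(model, p)
      artifacts$model <<- p
    })
  }
  assignment <- NULL
  if (isTRUE(cfg$stages$predict)) {
    run_stage("predict", function() {
      scores <- score_patients(model, feats)
      assignment <<- median_split(scores, threshold = cfg$predict$threshold)
      p <- file.path(out, "assignments.csv")
      utils::write.csv(assignment, p, row.names = FALSE)
      artifacts$assignments <<- p
    })
  }
  if (isTRUE(cfg$stages$evaluate)) {
    run_stage("evaluate", function() {
      d <- merge(clinical, assignment, by = "patient_id")
      treated <- d[d$tki_treated == 1, , drop = FALSE]
      lr <- km_logrank(treated$os_months, treated$event, treated$group)
      icx <- interaction_cox(d, d$group, adjusters = cfg$evaluate$adjusters)
      by_group <- lapply(split(d, d$group), function(g) {
        if (length(unique(g$tki_treated)) < 2 || sum(g$event) < 1)
          return(NULL)
        cox_hr(g$os_months, g$event, g$tki_treated == 0)
      })
      ev <- list(logrank = lr[c("chisq", "df", "p")],
                 groups = lr$groups,
                 interaction = icx$interaction,
                 untreated_vs_treated_hr = by_group)
      p1 <- file.path(out, "evaluation.json")
      jsonlite::write_json(ev, p1, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
      p2 <- file.path(out, "km.csv")
      utils::write.csv(lr$km, p2, row.names = FALSE)
      artifacts$evaluation <<- p1
      artifacts$km <<- p2
    })
  }
  if (isTRUE(cfg$stages$gsea)) {
    run_stage("gsea", function() {
      gp <- cfg$gsea
      if (isTRUE(cfg$stages$simulate)) {
        fv <- stats::setNames(feats[[gp$feature_name]], feats$patient_id)
        sim <- simulate_expression(
          fv, n_genes = cfg$simulate$expression$n_genes,
          n_correlated = cfg$simulate$expression$n_correlated,
          target_rho = cfg$simulate$expression$target_rho,
          planted_set_size = cfg$simulate$expression$planted_set_size,
          n_decoy_sets = cfg$simulate$expression$n_decoy_sets,
          decoy_set_size = cfg$simulate$expression$decoy_set_size,
          seed = stage_seed(cfg$seed, "simulate_expression"))
        expr <- sim$expression
        sets <- sim$sets
        pe <- file.path(out, "simulated", "expression.tsv")
        pg <- file.path(out, "simulated", "sets.gmt")
        write_expression(expr, pe)
        write_gmt(sets, pg)
        artifacts$expression <<- pe
        artifacts$gmt <<- pg
      } else {
        expr <- read_expression(cfg$inputs$expression)
        sets <- read_gmt(cfg$inputs$gmt)
        fv <- stats::setNames(feats[[gp$feature_name]], feats$patient_id)
      }
      expr <- filter_genes(expr, gp$max_zero_fraction)
      ranking <- rank_genes(expr, fv)
      enr <- preranked_gsea(ranking, sets,
                            n_permutations = gp$n_permutations,
                            weight_exponent = gp$weight_exponent,
                            min_size = gp$min_size, max_size = gp$max_size,
                            seed = stage_seed(cfg$seed, "gsea"))
      p1 <- file.path(out, "gsea.csv")
      utils::write.csv(enr, p1, row.names = FALSE)
      artifacts$gsea <<- p1
      if (isTRUE(gp$shuffle_control)) {
        ctl <- shuffle_control(expr, fv, sets,
                               seed = stage_seed(cfg$seed, "shuffle"),
                               n_permutations = gp$n_permutations,
                               weight_exponent = gp$weight_exponent,
                               min_size = gp$min_size,
                               max_size = gp$max_size)
        p2 <- file.path(out, "gsea_shuffle.csv")
        utils::write.csv(ctl$enrichment, p2, row.names = FALSE)
        artifacts$gsea_shuffle <<- p2
      }
    })
  }
  emit_manifest()
  invisible(artifacts)
}
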