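#' Cell-type vocabulary
#'
#' The six nucleus classes emitted by the upstream HD-staining segmentation
#' model: tumor, stroma, lymphocyte, red blood cell, macrophage and
#' karyorrhexis (fragmented nuclei of dying cells).
#'
#' @return Character vector of the six cell-type labels, in canonical order.
#' @export
cell_types <- function() {
  c("tumor", "stroma", "lymphocyte", "red_blood_cell", "macrophage",
    "karyorrhexis")
}

#' Names of the 12 image features
#'
#' Six per-patch cell densities plus six tumor--X Delaunay interaction
#' fractions, in canonical order.
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c(paste0("density_", cell_types()),
    paste0("interaction_tumor_", cell_types()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' Hashes the stage name into the global seed so that enabling or disabling
#' one pipeline stage never perturbs the randomness of another.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# stop() with a class so callers/tests can distinguish validation failures
tme_stop <- function(msg, class = "tme_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
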