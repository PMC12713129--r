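#' Analysis thresholds and pipeline settings
#'
#' Bundles every tunable threshold used downstream. Defaults follow the
#' conventions of replicate-level and cell-level differential expression
#' around the clock: BH-adjusted p below `alpha` combined with an absolute
#' log2 fold-change cutoff that depends on the contrast (0.2 for pseudobulk
#' timepoint contrasts, 0.58 for the adult-vs-aged contrast, 0.15 for
#' cell-level shifts), a `min_pct` detection screen, a minimum cell count
#' per timepoint for a cell type to enter DEG counting, and marker-calling
#' thresholds (25% expressing, log2FC 0.405).
#'
#' @param alpha adjusted p-value threshold, in (0,1).
#' @param lfc_pseudobulk absolute log2FC cutoff for pseudobulk timepoint
#'   contrasts.
#' @param lfc_aged absolute log2FC cutoff for the adult-vs-aged contrast
#'   (about a 50% change).
#' @param lfc_cell absolute log2FC cutoff for cell-level shift contrasts
#'   (about a 10% change).
#' @param min_pct minimum fraction of cells detecting a gene, in at least
#'   one contrast side, for the gene to be tested.
#' @param min_cells_per_timepoint minimum cells a cell type must have at
#'   every contrasted timepoint to be included in DEG counting.
#' @param marker_min_pct,marker_lfc thresholds for one-vs-rest marker
#'   calling.
#' @param kmeans_k clusters for temporal ordering; `NULL` means one per
#'   distinct timepoint.
#' @param period_lo,period_hi free-period search bounds in hours.
#' @param seed integer seed used by stochastic steps.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(alpha = 0.05,
                            lfc_pseudobulk = 0.2,
                            lfc_aged = 0.58,
                            lfc_cell = 0.15,
                            min_pct = 0.05,
                            min_cells_per_timepoint = 250,
                            marker_min_pct = 0.25,
                            marker_lfc = 0.405,
                            kmeans_k = NULL,
                            period_lo = 20,
                            period_hi = 28,
                            seed = 1L) {
  cfg <- list(alpha = alpha, lfc_pseudobulk = lfc_pseudobulk,
              lfc_aged = lfc_aged, lfc_cell = lfc_cell, min_pct = min_pct,
              min_cells_per_timepoint = min_cells_per_timepoint,
              marker_min_pct = marker_min_pct, marker_lfc = marker_lfc,
              kmeans_k = kmeans_k, period_lo = period_lo,
              period_hi = period_hi, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.numeric(cfg$alpha), length(cfg$alpha) == 1L,
            cfg$alpha > 0, cfg$alpha < 1)
  for (f in c("lfc_pseudobulk", "lfc_aged", "lfc_cell", "min_pct",
              "min_cells_per_timepoint", "marker_min_pct", "marker_lfc",
              "period_lo", "period_hi")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("pipeline_config: '", f, "' must be a positive scalar",
           call. = FALSE)
  }
  if (cfg$period_lo >= cfg$period_hi)
    stop("pipeline_config: period_lo must be < period_hi", call. = FALSE)
  invisible(cfg)
}

#' Read or write a pipeline configuration
#'
#' Configurations are stored as flat JSON. Fields missing from the file
#' fall back to the [pipeline_config()] defaults; unknown fields are an
#' error so typos do not pass silently.
#'
#' @param path file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @param config a `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-24s %s\n", f,
                if (is.null(v)) "<auto>" else format(v)))
  }
  invisible(x)
}
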