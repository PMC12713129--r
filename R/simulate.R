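#' Canonical gene panels used by the simulator
#'
#' `clock_panel_genes()` returns the core clock genes planted by the
#' simulator: positive-arm genes peak at ZT0, repressor-arm genes peak in
#' antiphase at ZT12. `cme_signature_genes()` returns the 13-gene
#' clathrin-mediated endocytosis signature used for temporal ordering of
#' samples.
#'
#' @return A data.frame (`gene`, `arm`, `phase_hours`) for the clock
#'   panel; a character vector for the CME signature.
#' @export
clock_panel_genes <- function() {
  data.frame(
    gene = c("Arntl", "Clock", "Npas2", "Nfil3",
             "Per1", "Per2", "Cry1", "Cry2", "Nr1d1", "Nr1d2", "Dbp"),
    arm = c(rep("positive", 4L), rep("repressor", 7L)),
    phase_hours = c(rep(0, 4L), rep(12, 7L)),
    stringsAsFactors = FALSE)
}

#' @rdname clock_panel_genes
#' @export
cme_signature_genes <- function() {
  c("Cltc", "Ap2b1", "Fcho2", "Dab2", "Cd2ap", "Clint1", "Itsn1",
    "Eps15", "Eps15l1", "Scamp1", "Aftph", "Mrc1", "Msr1")
}

#' Simulation design
#'
#' Describes the synthetic single-cell experiment: a small number of
#' Zeitgeber timepoints with biological replicates, several cell types of
#' unequal abundance, negative-binomial counts whose log2 mean follows a
#' planted cosine for rhythmic genes, and a logistic detection (dropout)
#' step tied to expression level.
#'
#' Defaults mirror a diurnal atlas design: 4 timepoints every 6 hours,
#' 3 replicates per timepoint. Per-cell size factors are log-normal(0,
#' 0.3). Dropout probability for a cell-level mean `mu` is
#' `1 - plogis(dropout_slope * (log2(mu) - dropout_midpoint))`, so lowly
#' expressed genes drop out more often.
#'
#' @param n_genes number of background genes (panels are appended).
#' @param n_cell_types number of cell types (named from a fixed list,
#'   first type `"BAM"`).
#' @param timepoints hours in `[0, 24)`, strictly increasing.
#' @param n_replicates_per_timepoint biological replicates per timepoint.
#' @param cells_per_sample_per_type length-2 integer range; cell numbers
#'   per sample and type are drawn uniformly from it, then scaled by the
#'   decaying type-abundance weights.
#' @param rhythmic_fraction fraction of background genes that are
#'   rhythmic, in `[0, 1]`.
#' @param amplitude_log2 peak-to-mesor cosine amplitude on the log2-mean
#'   scale (peak-to-trough log2FC is twice this).
#' @param phase_sampler function(n) drawing rhythmic-gene acrophases in
#'   `[0, 24)`; default uniform.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param nb_dispersion negative-binomial dispersion (scalar, or one per
#'   gene including panel genes).
#' @param dropout_midpoint,dropout_slope logistic detection parameters on
#'   the log2-mean scale.
#' @param rhythmic_cell_types cell types carrying the planted rhythm;
#'   default all.
#' @param include_clock_panel append the always-rhythmic clock panel.
#' @param include_cme_panel append the 13-gene CME signature as rhythmic
#'   genes with acrophases spread evenly over the cycle.
#' @param seed integer; identical config + seed gives identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_cell_types = 3L,
                       timepoints = c(0, 6, 12, 18),
                       n_replicates_per_timepoint = 3L,
                       cells_per_sample_per_type = c(300L, 500L),
                       rhythmic_fraction = 0.1,
                       amplitude_log2 = 0.5,
                       phase_sampler = function(n) stats::runif(n, 0, 24),
                       baseline_meanlog = log(2),
                       baseline_sdlog = 1,
                       nb_dispersion = 0.1,
                       dropout_midpoint = 1,
                       dropout_slope = 1,
                       rhythmic_cell_types = NULL,
                       include_clock_panel = FALSE,
                       include_cme_panel = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("invalid config: n_genes must be >= 1",
                             call. = FALSE)
  if (cfg$n_cell_types < 1L)
    stop("invalid config: n_cell_types must be >= 1", call. = FALSE)
  tp <- cfg$timepoints
  if (length(tp) < 1L || any(tp < 0) || any(tp >= 24) ||
      any(diff(tp) <= 0))
    stop("invalid config: timepoints must be strictly increasing in [0,24)",
         call. = FALSE)
  if (cfg$rhythmic_fraction < 0 || cfg$rhythmic_fraction > 1)
    stop("invalid config: rhythmic_fraction must lie in [0,1]",
         call. = FALSE)
  if (any(cfg$nb_dispersion <= 0))
    stop("invalid config: dispersions must be > 0", call. = FALSE)
  if (length(cfg$cells_per_sample_per_type) != 2L ||
      any(cfg$cells_per_sample_per_type < 1L))
    stop("invalid config: cells_per_sample_per_type must be a positive range",
         call. = FALSE)
  if (cfg$amplitude_log2 <= 0)
    stop("invalid config: amplitude_log2 must be > 0", call. = FALSE)
  invisible(cfg)
}

# deterministic per-sample stream seed; kept < 2^31
stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed %% 100003L) * 10007 + index * 101 + 17) %%
               2147483647)
}

.celltype_names <- c("BAM", "MDM", "Microglia", "cDC", "TNK", "B", "NK",
                     "Monocyte", "Neutrophil", "ILC")

#' Simulate a diurnal single-cell experiment
#'
#' Draws the planted per-gene truth (rhythmic flags, amplitudes, phases,
#' baselines), then generates each sample from its own RNG stream seeded
#' from `(seed, sample index)` so samples are reproducible independently
#' of generation order. For a rhythmic gene `g` in a rhythm-carrying cell
#' type, the cell-level mean at time `t` is
#' `baseline_g * 2^(A_g * cos(2*pi*(t - phi_g)/24)) * sizefactor_cell`;
#' counts are negative binomial with gene dispersion, then an independent
#' Bernoulli detection step zeroes the count with probability
#' `1 - plogis(dropout_slope * (log2(mean) - dropout_midpoint))`.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (a [cell_counts()] object) and `truth`
#'   (list of `genes` and `cells` data.frames holding the planted
#'   parameters).
#' @export
simulate_cell_counts <- function(config) {
  validate_sim_config(config)
  cfg <- config

  set.seed(cfg$seed)
  genes <- draw_gene_truth(cfg)
  G <- nrow(genes)
  disp <- rep_len(cfg$nb_dispersion, G)
  genes$dispersion <- disp

  types <- .celltype_names[seq_len(cfg$n_cell_types)]
  abund <- 0.6^(seq_len(cfg$n_cell_types) - 1L)
  rhythmic_types <- if (is.null(cfg$rhythmic_cell_types)) types
                    else cfg$rhythmic_cell_types

  design <- expand.grid(replicate = seq_len(cfg$n_replicates_per_timepoint),
                        timepoint = cfg$timepoints)
  design$sample <- paste0("ZT", design$timepoint, "_rep", design$replicate)

  blocks <- vector("list", nrow(design))
  cellmeta <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    set.seed(stream_seed(cfg$seed, i))
    t <- design$timepoint[i]
    rng <- cfg$cells_per_sample_per_type
    n_by_type <- pmax(1L, round(abund *
      (rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, cfg$n_cell_types,
                            replace = TRUE) - 1L)))
    n_cells <- sum(n_by_type)
    ct <- rep(types, n_by_type)
    sf <- stats::rlnorm(n_cells, 0, 0.3)

    # genes x cells matrix of planted means for this sample
    log2base <- matrix(log2(genes$baseline_mean), G, n_cells)
    osc <- genes$is_rhythmic &
      matrix(ct %in% rhythmic_types, G, n_cells, byrow = TRUE)
    shift <- genes$amplitude_log2 *
      cos(2 * pi * (t - genes$phase_hours) / 24)
    shift[!genes$is_rhythmic] <- 0
    log2mu <- log2base + shift * osc +
      matrix(log2(sf), G, n_cells, byrow = TRUE)
    mu <- 2^log2mu
    k <- stats::rnbinom(length(mu), mu = mu,
                        size = rep(1 / disp, n_cells))
    detected <- stats::rbinom(length(mu), 1L,
                              stats::plogis(cfg$dropout_slope *
                                              (log2mu - cfg$dropout_midpoint)))
    m <- matrix(k * detected, G, n_cells)
    blocks[[i]] <- methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "CsparseMatrix")
    cellmeta[[i]] <- data.frame(
      barcode = sprintf("%s_c%04d", design$sample[i], seq_len(n_cells)),
      sample = design$sample[i],
      timepoint_hours = t,
      cell_type = ct,
      size_factor = sf,
      stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, blocks)
  cells <- do.call(rbind, cellmeta)
  cc <- cell_counts(counts, genes$gene_id,
                    cells[c("barcode", "sample", "timepoint_hours",
                            "cell_type")])
  list(counts = cc, truth = list(genes = genes, cells = cells))
}

draw_gene_truth <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  n_r <- round(cfg$rhythmic_fraction * n)
  is_r <- rep(FALSE, n)
  if (n_r > 0) is_r[sample.int(n, n_r)] <- TRUE
  phase <- rep(NA_real_, n)
  if (n_r > 0) phase[is_r] <- cfg$phase_sampler(n_r) %% 24
  amp <- ifelse(is_r, cfg$amplitude_log2, NA_real_)
  genes <- data.frame(gene_id = ids, is_rhythmic = is_r,
                      amplitude_log2 = amp, phase_hours = phase,
                      baseline_mean = stats::rlnorm(n, cfg$baseline_meanlog,
                                                    cfg$baseline_sdlog),
                      panel = "background", stringsAsFactors = FALSE)
  # Panels model canonically well-behaved genes: core clock genes have
  # large diurnal amplitude relative to clock-controlled output genes,
  # and both panels get moderate baseline expression so they are
  # detectable at the simulated depth.
  if (isTRUE(cfg$include_clock_panel)) {
    cp <- clock_panel_genes()
    genes <- rbind(genes, data.frame(
      gene_id = cp$gene, is_rhythmic = TRUE,
      amplitude_log2 = max(cfg$amplitude_log2, 1),
      phase_hours = cp$phase_hours,
      baseline_mean = stats::rlnorm(nrow(cp), log(4), 0.5),
      panel = paste0("clock_", substr(cp$arm, 1, 3)),
      stringsAsFactors = FALSE))
  }
  if (isTRUE(cfg$include_cme_panel)) {
    cme <- cme_signature_genes()
    genes <- rbind(genes, data.frame(
      gene_id = cme, is_rhythmic = TRUE,
      amplitude_log2 = cfg$amplitude_log2,
      phase_hours = 24 * (seq_along(cme) - 1L) / length(cme),
      baseline_mean = stats::rlnorm(length(cme), log(4), 0.5),
      panel = "cme", stringsAsFactors = FALSE))
  }
  genes
}

#' Simulate a rhythmic binding time series
#'
#' `value = mesor + amplitude * cos(2*pi*(t - phase)/period) + N(0, sd)`,
#' emulating a sparse binding profile sampled every few hours over one
#' cycle.
#'
#' @param mesor midline level.
#' @param amplitude cosine amplitude (>= 0).
#' @param phase_hours acrophase in hours.
#' @param period_hours period in hours (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param times sampling times in hours (nonempty, sorted).
#' @param seed integer seed.
#' @return data.frame with columns `time_hours`, `value`.
#' @export
simulate_binding_series <- function(mesor, amplitude, phase_hours,
                                    period_hours, noise_sd = 0,
                                    times = seq(0, 20, by = 4),
                                    seed = 1L) {
  if (period_hours <= 0) stop("period_hours must be > 0", call. = FALSE)
  if (length(times) == 0L) stop("times must be nonempty", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  v <- mesor + amplitude * cos(2 * pi * (times - phase_hours) /
                                 period_hours) +
    stats::rnorm(length(times), 0, noise_sd)
  data.frame(time_hours = times, value = v)
}

#' Simulate a promoter sequence with planted motifs
#'
#' Uniform-random ACGT background with motifs overwritten at stated
#' 0-based positions. Overlapping plants or plants extending past the end
#' are errors.
#'
#' @param length sequence length in bp.
#' @param planted_motifs data.frame with columns `position` (0-based) and
#'   `motif`, or an empty/`NULL` value for background only.
#' @param seed integer seed.
#' @return list with `sequence` (single string) and `planted` (the
#'   data.frame of plants, possibly empty).
#' @export
simulate_promoter <- function(length, planted_motifs = NULL, seed = 1L) {
  stopifnot(length >= 1L)
  if (is.null(planted_motifs))
    planted_motifs <- data.frame(position = integer(),
                                 motif = character())
  stopifnot(all(c("position", "motif") %in% names(planted_motifs)))
  pm <- planted_motifs[order(planted_motifs$position), , drop = FALSE]
  if (nrow(pm)) {
    if (any(grepl("[^ACGT]", pm$motif)))
      stop("motifs must be over ACGT", call. = FALSE)
    ends <- pm$position + nchar(pm$motif)   # half-open
    if (any(pm$position < 0L) || any(ends > length))
      stop("planted motif does not fit within sequence", call. = FALSE)
    if (nrow(pm) > 1L && any(pm$position[-1L] < ends[-nrow(pm)]))
      stop("overlapping planted motifs", call. = FALSE)
  }
  set.seed(as.integer(seed))
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  for (i in seq_len(nrow(pm))) {
    idx <- pm$position[i] + seq_len(nchar(pm$motif[i]))
    chars[idx] <- strsplit(pm$motif[i], "")[[1L]]
  }
  list(sequence = paste(chars, collapse = ""), planted = pm)
}

#' Write a simulated experiment to disk
#'
#' Writes the Matrix Market counts plus cell and gene TSVs (the gene TSV
#' carries the planted ground truth columns `is_rhythmic`,
#' `amplitude_log2`, `phase_hours`).
#'
#' @param sim result of [simulate_cell_counts()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_counts(sim$counts, dir,
               gene_meta = sim$truth$genes[c("gene_id", "is_rhythmic",
                                             "amplitude_log2",
                                             "phase_hours")])
  invisible(dir)
}
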