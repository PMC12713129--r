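# Shared fixtures, generated once per test run and memoized. All seeds
# are pinned; fixture parameters are part of the stated test conditions
# and are never adjusted to outcomes.

.fx <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (!exists(name, envir = .fx)) assign(name, make(), envir = .fx)
  get(name, envir = .fx)
}

# small general-purpose simulation for module tests
small_sim <- function() memo("small_sim", function() {
  cfg <- sim_config(n_genes = 200L, n_cell_types = 2L,
                    cells_per_sample_per_type = c(80L, 120L),
                    rhythmic_fraction = 0.2, amplitude_log2 = 0.5,
                    include_clock_panel = TRUE, seed = 11L)
  simulate_cell_counts(cfg)
})

# the standard rhythm-recovery fixture: 4 timepoints x 3 replicates,
# 400 cells/sample of one cell type, 10% rhythmic background genes with
# peak-to-trough log2FC 0.8, clock and CME panels planted
std_fixture <- function() memo("std_fixture", function() {
  cfg <- sim_config(n_genes = 600L, n_cell_types = 1L,
                    cells_per_sample_per_type = c(400L, 400L),
                    rhythmic_fraction = 0.1, amplitude_log2 = 0.4,
                    include_clock_panel = TRUE, include_cme_panel = TRUE,
                    seed = 515L)
  sim <- simulate_cell_counts(cfg)
  ctr <- timepoint_shift_contrasts(sim$counts)
  calls <- peak_trough_filter(ctr)
  list(sim = sim, contrasts = ctr, calls = calls)
})

# cell-level null: no planted rhythm, 2000 genes, 4 timepoints x 3
# replicates x 100 cells
null_hurdle <- function() memo("null_hurdle", function() {
  cfg <- sim_config(n_genes = 2000L, n_cell_types = 1L,
                    cells_per_sample_per_type = c(100L, 100L),
                    rhythmic_fraction = 0, seed = 404L)
  sim <- simulate_cell_counts(cfg)
  list(sim = sim, contrasts = timepoint_shift_contrasts(sim$counts))
})

# replicate-level NB null for the pseudobulk Wald engine: dispersion
# 0.02 (biological replicates of inbred mice are tight, CV ~ 14%)
null_pseudobulk_counts <- function() memo("null_pb", function() {
  set.seed(606L)
  G <- 2000L
  mu <- stats::rlnorm(G, log(300), 1)
  matrix(stats::rnbinom(G * 6L, mu = mu, size = 1 / 0.02), G, 6L,
         dimnames = list(sprintf("g%04d", seq_len(G)), paste0("s", 1:6)))
})

# noiseless per-sample signature with phases spread over the cycle:
# 4 timepoints x 3 replicates, 13 genes
noiseless_signature <- function(noise_sd = 0, seed = 1L) {
  tps <- rep(c(0, 6, 12, 18), each = 3L)
  phases <- 24 * (seq_len(13L) - 1L) / 13L
  set.seed(seed)
  mat <- outer(tps, phases, function(t, ph) cos(2 * pi * (t - ph) / 24)) +
    matrix(stats::rnorm(length(tps) * 13L, 0, noise_sd),
           length(tps), 13L)
  suppressWarnings(signature_from_matrix(mat, tps))
}

# exhaustive two-sided rank-sum p by enumerating all splits (no ties)
enum_ranksum_p <- function(xA, xB) {
  nA <- length(xA)
  all <- c(xA, xB)
  r <- rank(all)
  Uobs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  splits <- utils::combn(length(all), nA)
  Uall <- apply(splits, 2L, function(idx)
    sum(r[idx]) - nA * (nA + 1) / 2)
  min(1, 2 * min(mean(Uall <= Uobs), mean(Uall >= Uobs)))
}

# brute-force E-box scan over every offset
brute_ebox <- function(s, include_noncanonical = FALSE) {
  s <- toupper(s)
  n <- nchar(s)
  rows <- list()
  for (st in 0:(n - 6L)) {
    w <- substr(s, st + 1L, st + 6L)
    if (w == "CACGTG") {
      rows[[length(rows) + 1L]] <-
        data.frame(start = st, strand = "+", motif_class = "canonical")
    } else if (include_noncanonical) {
      fwd <- grepl("^CA[ACGT][ACGT]TG$", w)
      rc <- chartr("ACGTN", "TGCAN",
                   paste(rev(strsplit(w, "")[[1L]]), collapse = ""))
      rev <- grepl("^CA[ACGT][ACGT]TG$", rc)
      if (fwd || rev)
        rows[[length(rows) + 1L]] <-
          data.frame(start = st, strand = if (fwd) "+" else "-",
                     motif_class = "non-canonical")
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), strand = character(),
                      motif_class = character()))
  do.call(rbind, rows)
}
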