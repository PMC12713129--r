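test_that("pseudobulk aggregation sums counts and conserves totals", {
  # two cells of one sample: counts 1 and 2 sum to 3
  cc <- cell_counts(matrix(c(1, 2), 1L, 2L), "g1",
                    data.frame(barcode = c("a", "b"), sample = "s1",
                               timepoint_hours = 0, cell_type = "BAM"))
  pb <- aggregate_pseudobulk(cc)
  expect_equal(unname(pb$counts[1L, 1L]), 3)

  sim <- small_sim()
  pb <- aggregate_pseudobulk(sim$counts, group_keys = c("sample",
                                                        "cell_type"))
  expect_equal(sum(pb$counts), sum(sim$counts$counts))
  expect_equal(unname(colSums(pb$counts)),
               as.numeric(tapply(Matrix::colSums(sim$counts$counts),
                                 interaction(sim$counts$cells[
                                   c("sample", "cell_type")],
                                   drop = TRUE, lex.order = TRUE),
                                 sum)[colnames(pb$counts)]))
})

test_that("pseudobulk matches a brute-force loop oracle", {
  set.seed(31)
  G <- 50L; n <- 200L
  counts <- matrix(rpois(G * n, 2), G, n)
  ann <- data.frame(barcode = sprintf("c%03d", 1:n),
                    sample = sample(paste0("s", 1:4), n, replace = TRUE),
                    timepoint_hours = 0,
                    cell_type = sample(c("BAM", "MDM"), n,
                                       replace = TRUE))
  cc <- cell_counts(counts, sprintf("g%02d", 1:G), ann)
  pb <- aggregate_pseudobulk(cc, group_keys = c("sample", "cell_type"))
  for (key in colnames(pb$counts)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    idx <- ann$sample == parts[1L] & ann$cell_type == parts[2L]
    oracle <- numeric(G)
    for (j in which(idx)) oracle <- oracle + counts[, j]
    expect_equal(unname(pb$counts[, key]), oracle)
  }
})

test_that("median-of-ratios size factors follow the definition", {
  m <- matrix(c(10, 20, 5, 10, 40, 80), 3L, 2L, byrow = TRUE)
  colnames(m) <- c("a", "b")
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(a = c(3, 7, 11), b = c(3, 7, 11), c = c(3, 7, 11))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # a gene with a zero anywhere is excluded from the reference set:
  # adding an extreme zero-containing gene must not move the factors
  m2 <- rbind(m, c(0, 1000))
  expect_equal(size_factors(m2), sf)

  allzero <- matrix(c(0, 5, 3, 0), 2L, 2L)
  expect_warning(size_factors(allzero), "library-size")
})

test_that("nb_de honors its contracts on degenerate designs", {
  counts <- null_pseudobulk_counts()
  expect_error(nb_de(counts, list(1L, 2:4)), "2 samples")

  dup <- counts[1:200, c(1, 2, 3, 1, 2, 3)]
  colnames(dup) <- paste0("s", 1:6)
  de <- nb_de(dup, list(1:3, 4:6))
  expect_equal(de$log2fc, rep(0, nrow(de)))

  # pass flag is exactly (padj < alpha) & (|lfc| >= threshold)
  de2 <- nb_de(counts[1:500, ], list(1:3, 4:6), alpha = 0.05,
               lfc_threshold = 0.2)
  expect_equal(de2$pass, de2$padj < 0.05 & abs(de2$log2fc) >= 0.2)
  expect_true(all(de2$padj >= de2$p))
  expect_true(all(de2$p >= 0 & de2$padj <= 1))
  # BH is monotone in raw-p rank
  o <- order(de2$p)
  expect_true(all(diff(de2$padj[o]) >= -1e-15))
})

test_that("nb_de is symmetric under group swap", {
  counts <- null_pseudobulk_counts()[1:400, ]
  a <- nb_de(counts, list(1:3, 4:6))
  b <- nb_de(counts, list(4:6, 1:3))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("nb_de recovers planted antiphase effects with n = 3", {
  # all rhythmic genes peak at ZT0, so the ZT0-vs-ZT12 log2FC extremum
  # is the full peak-to-trough 2A = 1.0
  cfg <- sim_config(n_genes = 300L, n_cell_types = 1L,
                    cells_per_sample_per_type = c(150L, 200L),
                    rhythmic_fraction = 0.3, amplitude_log2 = 0.5,
                    phase_sampler = function(n) rep(0, n), seed = 23L)
  sim <- simulate_cell_counts(cfg)
  pb <- aggregate_pseudobulk(sim$counts)
  des <- pb$design
  de <- nb_de(pb, list(rownames(des)[des$timepoint_hours == 0],
                       rownames(des)[des$timepoint_hours == 12]))
  tr <- sim$truth$genes
  rhythmic <- tr$gene_id[tr$is_rhythmic]
  sens <- mean(rhythmic %in% de$gene[de$pass])
  expect_gt(sens, 0.8)
  # planted direction: ZT12 (group B) is the trough
  hit <- de[de$gene %in% rhythmic & de$pass, ]
  expect_true(all(hit$log2fc < 0))
})

test_that("DEG counting enforces the per-timepoint cell floor", {
  cfg <- sim_config(n_genes = 150L, n_cell_types = 2L,
                    cells_per_sample_per_type = c(450L, 500L),
                    rhythmic_fraction = 0.3, amplitude_log2 = 0.5,
                    phase_sampler = function(n) rep(0, n),
                    rhythmic_cell_types = "BAM", seed = 29L)
  sim <- simulate_cell_counts(cfg)
  tab <- count_degs_per_celltype(sim$counts, 0, 12,
                                 pipeline_config(min_cells_per_timepoint
                                                 = 250))
  expect_true(all(tab$included))
  # only BAM carries rhythm: strictly the largest DEG count
  expect_gt(tab$n_deg[tab$cell_type == "BAM"],
            max(tab$n_deg[tab$cell_type != "BAM"]))

  # raising the floor beyond the second type's abundance excludes it
  n2 <- min(tab$n_cells_tA[2L], tab$n_cells_tB[2L])
  tab2 <- count_degs_per_celltype(sim$counts, 0, 12,
                                  pipeline_config(min_cells_per_timepoint
                                                  = n2 + 1L))
  expect_false(tab2$included[2L])
  expect_match(tab2$reason[2L], "fewer than")
  expect_true(is.na(tab2$n_deg[2L]))
  expect_error(count_degs_per_celltype(sim$counts, 0, 3),
               "absent")
})

test_that("minimum detectable log2FC behaves like a power calculation", {
  d3 <- min_detectable_lfc(3L, 0.04, 0.05, 0.8)
  d6 <- min_detectable_lfc(6L, 0.04, 0.05, 0.8)
  d12 <- min_detectable_lfc(12L, 0.04, 0.05, 0.8)
  expect_gt(d3, d6)
  expect_gt(d6, d12)
  expect_error(min_detectable_lfc(3L, 0.04, 0.05, 0.04), "power_target")
  expect_error(min_detectable_lfc(3L, 0.04, 0.05, 1))

  # large-n, power 0.5: the bound approaches t_crit * SE(difference)
  n <- 200L
  d <- min_detectable_lfc(n, 0.09, 0.05, 0.5)
  expect_equal(d, qt(0.975, 2L * n - 2L) * sqrt(2 * 0.09 / n),
               tolerance = 1e-3)
})

test_that("log2FC to percent conversion matches printed conventions", {
  expect_equal(lfc_to_percent(0)$percent, 0)
  expect_equal(lfc_to_percent(1)$percent, 100)
  expect_equal(lfc_to_percent(-1)$percent, 100)
  p15 <- lfc_to_percent(0.15)
  expect_equal(p15$percent, 10.9, tolerance = 1e-2)
  expect_equal(p15$percent_rounded, 10)
  p58 <- lfc_to_percent(0.58)
  expect_equal(p58$percent, 49.5, tolerance = 1e-2)
  expect_equal(p58$percent_rounded, 50)
  expect_equal(lfc_to_percent(0.24)$percent_rounded, 20)
})
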