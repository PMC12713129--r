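make_cc <- function(counts, tp = NULL, ct = "BAM") {
  n <- ncol(counts)
  if (is.null(tp)) tp <- rep(0, n)
  cell_counts(counts, sprintf("g%03d", seq_len(nrow(counts))),
              data.frame(barcode = sprintf("c%04d", seq_len(n)),
                         sample = paste0("s", tp),
                         timepoint_hours = tp, cell_type = ct))
}

test_that("CDR covariate is the scaled per-cell detection fraction", {
  counts <- cbind(c(1, 1, 1, 1), c(2, 3, 0, 0))
  cc <- make_cc(counts)
  raw <- compute_cdr(cc, scale = FALSE)
  expect_equal(raw, c(1, 0.5))
  z <- compute_cdr(cc)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  # invariant to gene order
  cc2 <- make_cc(counts[c(3, 1, 4, 2), ])
  expect_equal(compute_cdr(cc2), z, ignore_attr = TRUE)

  expect_error(compute_cdr(make_cc(matrix(1, 2, 1))), "2 cells")
  expect_warning(z0 <- compute_cdr(make_cc(matrix(1, 3, 4))),
                 "identical detection")
  expect_equal(z0, rep(0, 4), ignore_attr = TRUE)
})

test_that("hurdle fit flags degenerate genes instead of crashing", {
  X <- cbind(t0 = rep(1, 10), cdr = rnorm(10))
  # fewer than 3 detected cells: skipped with reason
  f <- fit_hurdle(rep(0, 10), rep(FALSE, 10), X)
  expect_match(f$skipped, "fewer than 3")
  # all detected cells share one value: zero residual variance
  y <- c(rep(1.5, 5), rep(0, 5))
  f2 <- fit_hurdle(y, y > 0, X)
  expect_true(f2$cont$degenerate)
  expect_true(is.finite(f2$disc$loglik))
})

test_that("hurdle parts recover planted effects and stay null-centered", {
  set.seed(91)
  n <- 500L
  tp <- rep(c(0, 6, 12, 18), each = n / 4L)
  X <- cbind(sapply(c(0, 6, 12, 18), function(t) as.numeric(tp == t)),
             cdr = rnorm(n, 0, 1))
  colnames(X)[1:4] <- paste0("t", c(0, 6, 12, 18))

  # planted continuous shift of 1.0 log2 at ZT0, constant detection 0.8
  nrep <- 40L
  co <- replicate(nrep, {
    det <- rbinom(n, 1L, 0.8) == 1L
    y <- rnorm(n, 2 + (tp == 0) * 1.0, 0.5)
    y[!det] <- 0
    fit <- fit_hurdle(y, det, X)
    fit$cont$coef[1L] - mean(fit$cont$coef[2:4])
  })
  expect_equal(mean(co), 1.0, tolerance = 3 * sd(co) / sqrt(nrep))

  # null: both parts centered at zero effect
  nullco <- replicate(nrep, {
    det <- rbinom(n, 1L, 0.6) == 1L
    y <- rnorm(n, 2, 0.5)
    y[!det] <- 0
    fit <- fit_hurdle(y, det, X)
    c(fit$cont$coef[1L] - mean(fit$cont$coef[2:4]),
      fit$disc$coef[1L] - mean(fit$disc$coef[2:4]))
  })
  expect_lt(abs(mean(nullco[1L, ])), 3 * sd(nullco[1L, ]) / sqrt(nrep))
  expect_lt(abs(mean(nullco[2L, ])), 3 * sd(nullco[2L, ]) / sqrt(nrep))
})

test_that("shift contrasts are signed correctly and sum to zero", {
  fx <- std_fixture()
  ctr <- fx$contrasts
  expect_true(all(ctr$stat >= 0))
  expect_true(all(ctr$df == 2L))
  expect_true(all(ctr$padj >= ctr$p - 1e-15))

  # balanced design: per-gene shifts sum to ~0 by construction
  sums <- tapply(ctr$shift_log2fc, ctr$gene, sum)
  expect_lt(max(abs(sums)), 1e-10)

  # clock genes: positive arm up at ZT0, down at ZT12; repressor arm
  # the opposite
  arntl <- ctr[ctr$gene == "Arntl", ]
  expect_gt(arntl$shift_log2fc[arntl$timepoint == 0], 0)
  expect_lt(arntl$shift_log2fc[arntl$timepoint == 12], 0)
  per2 <- ctr[ctr$gene == "Per2", ]
  expect_lt(per2$shift_log2fc[per2$timepoint == 0], 0)
  expect_gt(per2$shift_log2fc[per2$timepoint == 12], 0)

  expect_error(timepoint_shift_contrasts(
    subset_cells(fx$sim$counts,
                 cells = fx$sim$counts$cells$timepoint_hours %in% c(0, 12))),
    "3 distinct timepoints")
})

test_that("peak-and-trough filter implements the calling rules", {
  base <- data.frame(gene = "g", timepoint = c(0, 6, 12, 18),
                     shift_log2fc = 0, stat = 0, df = 2L, p = 1,
                     padj = 1, pct_in = 0.5, pct_out = 0.5)
  cfg <- pipeline_config(alpha = 0.05, lfc_cell = 0.15, min_pct = 0.05)

  # significant positive at ZT12 and negative at ZT0: rhythmic
  d <- base
  d$shift_log2fc <- c(-0.3, 0, 0.4, 0)
  d$padj <- c(0.01, 0.9, 0.01, 0.9)
  call <- peak_trough_filter(d, cfg)
  expect_true(call$rhythmic)
  expect_equal(call$peak_time, 12)
  expect_equal(call$trough_time, 0)

  # a single significant timepoint is not rhythmic
  d2 <- base
  d2$shift_log2fc <- c(0.5, 0, 0, 0)
  d2$padj <- c(0.001, 1, 1, 1)
  expect_false(peak_trough_filter(d2, cfg)$rhythmic)

  # two significant positives without a negative are not rhythmic
  d3 <- base
  d3$shift_log2fc <- c(0.5, 0.4, 0, 0)
  d3$padj <- c(0.001, 0.001, 1, 1)
  expect_false(peak_trough_filter(d3, cfg)$rhythmic)

  # sub-threshold |shift| does not count as significant
  d4 <- base
  d4$shift_log2fc <- c(0.1, 0, -0.1, 0)
  d4$padj <- c(0.001, 1, 0.001, 1)
  expect_false(peak_trough_filter(d4, cfg)$rhythmic)

  # peak ties break toward the smaller timepoint
  d5 <- base
  d5$shift_log2fc <- c(0.4, 0.4, -0.4, 0)
  d5$padj <- c(0.001, 0.001, 0.001, 1)
  expect_equal(peak_trough_filter(d5, cfg)$peak_time, 0)
})

test_that("rhythm calls are a subset of tested genes", {
  fx <- std_fixture()
  tested <- unique(fx$contrasts$gene)
  called <- fx$calls$gene[fx$calls$rhythmic]
  expect_true(all(called %in% tested))
  expect_true(all(tested %in% fx$sim$counts$gene_ids))
  rhy <- fx$calls[fx$calls$rhythmic, ]
  expect_true(all(rhy$peak_time != rhy$trough_time))
})

test_that("wilcoxon DE matches an exhaustive enumeration oracle", {
  set.seed(55)
  # Latin-square counts: distinct values per gene, equal library sizes,
  # so log-normalization cannot create ties; all 252 splits enumerated
  v <- sort(sample(10:99, 10L))
  counts <- t(sapply(1:8, function(g) v[((g + 0:9) %% 10L) + 1L]))
  cc <- make_cc(counts, tp = rep(c(0, 12), each = 5))
  de <- wilcoxon_de(cc, groupA = 1:5, groupB = 6:10, min_pct = 0.05)
  Y <- log2(1 + sweep(as.matrix(counts), 2,
                      median(colSums(counts)) / colSums(counts), "*"))
  for (g in seq_len(nrow(counts))) {
    expect_equal(de$p[g], enum_ranksum_p(Y[g, 1:5], Y[g, 6:10]),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon DE screens, ties and identical groups behave", {
  # identical groups: log2FC 0 and p ~ 1
  m <- matrix(rpois(40 * 12, 5), 40, 12)
  cc <- make_cc(cbind(m, m), tp = rep(c(0, 12), each = 12))
  de <- wilcoxon_de(cc, groupA = 1:12, groupB = 13:24)
  expect_equal(de$log2fc, rep(0, nrow(de)))
  expect_true(all(de$p > 0.9))

  # gene expressed in 4% of cells in both groups is excluded at 0.05
  n <- 50L
  counts <- rbind(lowgene = c(rep(1, 2), rep(0, n - 2),
                              rep(1, 2), rep(0, n - 2)),
                  okgene = rpois(2 * n, 3))
  cc2 <- cell_counts(counts, c("lowgene", "okgene"),
                     data.frame(barcode = sprintf("c%03d", 1:(2 * n)),
                                sample = rep(c("a", "b"), each = n),
                                timepoint_hours = rep(c(0, 12), each = n),
                                cell_type = "BAM"))
  de2 <- wilcoxon_de(cc2, groupA = 1:n, groupB = (n + 1):(2 * n),
                     min_pct = 0.05)
  expect_false("lowgene" %in% de2$gene)
  expect_true("okgene" %in% de2$gene)
})

test_that("marker calling finds a planted cell-type marker", {
  set.seed(77)
  n <- 120L   # 60 BAM + 60 MDM cells
  ct <- rep(c("BAM", "MDM"), each = n / 2L)
  counts <- matrix(rpois(30 * n, 4), 30, n)
  counts[5L, ct == "BAM"] <- rpois(n / 2L, 40)  # strong BAM marker
  cc <- cell_counts(counts, sprintf("g%03d", 1:30),
                    data.frame(barcode = sprintf("c%03d", 1:n),
                               sample = rep(c("s1", "s2"), n / 2L),
                               timepoint_hours = 0, cell_type = ct))
  mk <- find_markers(cc)
  expect_true(any(mk$cell_type == "BAM" & mk$gene == "g005"))
  expect_true(all(mk$log2fc >= pipeline_config()$marker_lfc))
})
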