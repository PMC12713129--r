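#' Aggregate single cells into replicate-level pseudobulk
#'
#' Sums counts per gene over all cells sharing a grouping key. The default
#' key is the biological sample; adding `cell_type` gives one pseudobulk
#' column per sample x cell type combination. Groups with zero cells are
#' absent, not zero columns, and the total count is conserved.
#'
#' @param cells a [cell_counts()] object.
#' @param group_keys character vector of cell annotation columns to group
#'   by (subset of `sample`, `cell_type`, `timepoint_hours`).
#' @param cell_type optional single cell type to restrict to before
#'   aggregating.
#' @return An object of class `pseudobulk`: list with `counts` (dense
#'   gene x sample matrix), `design` (one row per pseudobulk sample:
#'   grouping columns plus `timepoint_hours` and `n_cells`).
#' @export
aggregate_pseudobulk <- function(cells,
                                 group_keys = c("sample"),
                                 cell_type = NULL) {
  stopifnot(inherits(cells, "cell_counts"))
  ann <- cells$cells
  counts <- cells$counts
  if (!is.null(cell_type)) {
    keep <- ann$cell_type == cell_type
    ann <- ann[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  stopifnot(all(group_keys %in% names(ann)))
  if (ncol(counts) == 0L) {
    return(structure(list(counts = matrix(0, nrow(counts), 0,
                                          dimnames = list(cells$gene_ids,
                                                          NULL)),
                          design = ann[0, , drop = FALSE]),
                     class = "pseudobulk"))
  }
  key <- interaction(ann[group_keys], drop = TRUE, lex.order = TRUE)
  # sparse membership indicator; the product does the group summation
  memb <- Matrix::sparseMatrix(i = seq_along(key),
                               j = as.integer(key), x = 1,
                               dims = c(length(key), nlevels(key)))
  pb <- as.matrix(counts %*% memb)
  colnames(pb) <- levels(key)
  rownames(pb) <- cells$gene_ids
  first <- match(levels(key), key)
  design <- ann[first, unique(c(group_keys, "sample", "timepoint_hours",
                                "cell_type")), drop = FALSE]
  design$n_cells <- as.integer(table(key)[levels(key)])
  rownames(design) <- levels(key)
  structure(list(counts = pb, design = design), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (genes with nonzero counts in every sample) of the ratio of the
#' sample's count to the gene's geometric mean across samples. Factors
#' are rescaled to unit geometric mean. If no gene is positive in every
#' sample, falls back to library-size ratios with a warning.
#'
#' @param counts gene x sample count matrix, or a `pseudobulk` object.
#' @return Positive numeric vector, one per sample, geometric mean 1.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "pseudobulk")) counts <- counts$counts
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene with positive counts in all samples; ",
            "using library-size ratios")
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls)))
    return(sf)
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2L, stats::median))
  sf / exp(mean(log(sf)))
}

# profile NB log-likelihood pieces for a single group at fixed dispersion.
# Solves sum_i (k_i - s_i q) / (1 + a s_i q) = 0 for q by Newton on log q;
# with a > 0 this is the NB score equation, with a = 0 it reduces to the
# Poisson weighted mean.
nb_group_mean <- function(k, s, a) {
  q <- sum(k) / sum(s)
  if (q <= 0) return(list(q = 0, info = sum(s) ))
  lq <- log(q)
  for (iter in 1:50) {
    mu <- s * exp(lq)
    w <- 1 + a * mu
    score <- sum((k - mu) / w)
    # derivative of score wrt log q
    dsc <- -sum(mu * (1 + a * k) / w^2)
    step <- score / dsc
    if (!is.finite(step)) break
    step <- max(min(step, 5), -5)
    lq <- lq - step
    if (abs(step) < 1e-12) break
  }
  q <- exp(lq)
  mu <- s * q
  list(q = q, info = sum(mu / (1 + a * mu)))
}

# method-of-moments dispersion on normalized counts, pooled within groups
mom_dispersion <- function(norm, group) {
  lv <- split(seq_along(group), group)
  m <- rowMeans(norm)
  num <- 0; den <- 0
  for (idx in lv) {
    if (length(idx) < 2L) next
    sub <- norm[, idx, drop = FALSE]
    num <- num + rowSums((sub - rowMeans(sub))^2)
    den <- den + (length(idx) - 1L)
  }
  v <- num / den
  pmax((v - m) / m^2, 1e-8)
}

#' Two-group negative-binomial Wald test on pseudobulk counts
#'
#' Per gene: size factors from median-of-ratios, gene dispersion by
#' method of moments on normalized counts (floored at 1e-8 and shrunk
#' 50/50 toward a fitted mean-dispersion trend `a0 + a1/mean`), group
#' means by profile NB likelihood with size-factor offsets, and a Wald
#' test on the log fold-change. BH correction is applied across all genes
#' that are not all-zero in both groups jointly. A gene passes when its
#' adjusted p is below `alpha` and `|log2FC| >= lfc_threshold`.
#'
#' @param pb a `pseudobulk` object or gene x sample count matrix.
#' @param contrast length-2 list/vector naming the sample columns of
#'   group A and group B (log2FC is B over A), or a factor over columns.
#' @param alpha adjusted-p threshold.
#' @param lfc_threshold absolute log2FC threshold for the pass flag.
#' @return data.frame (one row per tested gene): `gene`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p`, `padj`, `pass`.
#' @export
nb_de <- function(pb, contrast, alpha = 0.05, lfc_threshold = 0.2) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else pb
  if (is.list(contrast) || (is.vector(contrast) && length(contrast) == 2L &&
                            !is.factor(contrast))) {
    idxA <- resolve_cols(counts, contrast[[1L]])
    idxB <- resolve_cols(counts, contrast[[2L]])
  } else stop("contrast must be a length-2 list of column selections",
              call. = FALSE)
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("design error: each contrast group needs >= 2 samples",
         call. = FALSE)
  sub <- counts[, c(idxA, idxB), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(idxA), length(idxB)))
  sf <- size_factors(sub)
  norm <- sweep(sub, 2L, sf, "/")

  keep <- rowSums(sub) > 0
  genes <- rownames(sub)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(sub)))

  a_mom <- mom_dispersion(norm[keep, , drop = FALSE], grp)
  m <- rowMeans(norm[keep, , drop = FALSE])
  # gamma-GLM-style trend alpha(m) = a0 + a1/m fitted by least squares on
  # the MoM estimates, clamped nonnegative
  tr <- stats::lm.fit(cbind(1, 1 / m), a_mom)$coefficients
  a_trend <- pmax(tr[1L] + tr[2L] / m, 1e-8)
  a_hat <- pmax(0.5 * a_mom + 0.5 * a_trend, 1e-8)

  ki <- which(keep)
  n <- length(ki)
  log2fc <- se <- stat <- p <- numeric(n)
  base_mean <- m
  isA <- grp == "A"
  for (j in seq_len(n)) {
    k <- sub[ki[j], ]
    a <- a_hat[j]
    fA <- nb_group_mean(k[isA], sf[isA], a)
    fB <- nb_group_mean(k[!isA], sf[!isA], a)
    qA <- fA$q; qB <- fB$q
    if (qA == 0 || qB == 0) {         # 0.5 normalized pseudocount guard
      qA2 <- qA + 0.5; qB2 <- qB + 0.5
      lfc_nat <- log(qB2 / qA2)
      infoA <- sum(sf[isA] * qA2 / (1 + a * sf[isA] * qA2))
      infoB <- sum(sf[!isA] * qB2 / (1 + a * sf[!isA] * qB2))
    } else {
      lfc_nat <- log(qB / qA)
      infoA <- fA$info; infoB <- fB$info
    }
    se_nat <- sqrt(1 / infoA + 1 / infoB)
    z <- lfc_nat / se_nat
    log2fc[j] <- lfc_nat / log(2)
    se[j] <- se_nat / log(2)
    stat[j] <- z
    p[j] <- 2 * stats::pnorm(-abs(z))
  }
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = genes[ki], base_mean = base_mean,
                    log2fc = log2fc, se = se, stat = stat, p = p,
                    padj = padj,
                    pass = padj < alpha & abs(log2fc) >= lfc_threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

resolve_cols <- function(counts, sel) {
  if (is.character(sel)) {
    idx <- match(sel, colnames(counts))
    if (anyNA(idx)) stop("unknown sample column(s): ",
                         paste(sel[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    idx
  } else as.integer(sel)
}

#' Count timepoint DEGs per cell type
#'
#' For each cell type with at least `min_cells_per_timepoint` cells at
#' BOTH contrasted timepoints, aggregates per replicate and runs
#' [nb_de()]; reports the number of passing genes. Cell types failing the
#' inclusion rule are reported with the reason rather than dropped
#' silently.
#'
#' @param cells a [cell_counts()] object.
#' @param tA,tB the two timepoints (hours) to contrast.
#' @param config a [pipeline_config()].
#' @return data.frame: `cell_type`, `n_cells_tA`, `n_cells_tB`,
#'   `included`, `reason`, `n_deg`.
#' @export
count_degs_per_celltype <- function(cells, tA, tB,
                                    config = pipeline_config()) {
  stopifnot(inherits(cells, "cell_counts"))
  tps <- unique(cells$cells$timepoint_hours)
  if (!all(c(tA, tB) %in% tps))
    stop("contrasted timepoints absent from the design", call. = FALSE)
  ann <- cells$cells
  types <- sort(unique(ann$cell_type))
  out <- lapply(types, function(ct) {
    nA <- sum(ann$cell_type == ct & ann$timepoint_hours == tA)
    nB <- sum(ann$cell_type == ct & ann$timepoint_hours == tB)
    row <- data.frame(cell_type = ct, n_cells_tA = nA, n_cells_tB = nB,
                      included = FALSE, reason = "", n_deg = NA_integer_,
                      stringsAsFactors = FALSE)
    if (min(nA, nB) < config$min_cells_per_timepoint) {
      row$reason <- sprintf("fewer than %d cells at a timepoint",
                            config$min_cells_per_timepoint)
      return(row)
    }
    pb <- aggregate_pseudobulk(cells, cell_type = ct)
    des <- pb$design
    gA <- rownames(des)[des$timepoint_hours == tA]
    gB <- rownames(des)[des$timepoint_hours == tB]
    if (length(gA) < 2L || length(gB) < 2L) {
      row$reason <- "fewer than 2 replicates in a group"
      return(row)
    }
    de <- nb_de(pb, list(gA, gB), alpha = config$alpha,
                lfc_threshold = config$lfc_pseudobulk)
    row$included <- TRUE
    row$n_deg <- sum(de$pass)
    row
  })
  do.call(rbind, out)
}

#' Smallest detectable log2 fold-change at a target power
#'
#' Solves, by bisection, for the smallest absolute log2-scale difference
#' `d` such that a two-sided two-sample t-test with `n_per_group`
#' replicates per group and common variance `variance_log2` reaches
#' `power_target` at level `alpha`. Power is computed from the
#' noncentral-t distribution with `2n - 2` degrees of freedom and
#' noncentrality `d / sqrt(2 * variance_log2 / n)`.
#'
#' @param n_per_group replicates per group (>= 2).
#' @param variance_log2 common variance of the log2 group means' inputs.
#' @param alpha two-sided type-I level.
#' @param power_target desired power, in (alpha, 1).
#' @return The minimal detectable |log2FC|.
#' @export
min_detectable_lfc <- function(n_per_group, variance_log2, alpha = 0.05,
                               power_target = 0.8) {
  stopifnot(n_per_group >= 2L, variance_log2 > 0)
  if (power_target <= alpha || power_target >= 1)
    stop("power_target must lie in (alpha, 1)", call. = FALSE)
  df <- 2L * n_per_group - 2L
  tcrit <- stats::qt(1 - alpha / 2, df)
  sed <- sqrt(2 * variance_log2 / n_per_group)
  pw <- function(d) {
    ncp <- d / sed
    stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
  }
  lo <- 0
  hi <- sed
  while (pw(hi) < power_target) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) < power_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Convert a log2 fold-change to a percent change
#'
#' `100 * (2^|lfc| - 1)`, plus the convenience rounding to the nearest
#' multiple of 5 used when quoting cutoffs as "approximately an X%
#' change".
#'
#' @param lfc log2 fold-change (any sign; magnitude is used).
#' @return list with `percent` (exact) and `percent_rounded` (nearest
#'   multiple of 5).
#' @export
lfc_to_percent <- function(lfc) {
  pct <- 100 * (2^abs(lfc) - 1)
  list(percent = pct, percent_rounded = 5 * round(pct / 5))
}
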