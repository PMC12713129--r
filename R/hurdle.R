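#' Cellular detection rate covariate
#'
#' The fraction of genes detected (count > 0) in each cell, centered and
#' scaled to unit variance over the analysis subset. This nuisance
#' covariate absorbs per-cell differences in capture efficiency in the
#' cell-level hurdle model.
#'
#' @param cells a [cell_counts()] object.
#' @param scale center/scale to mean 0, variance 1 (default). With all
#'   cells at identical detection the covariate is dropped (all zeros)
#'   with a warning.
#' @return Numeric vector, one value per cell; attribute `"dropped"` is
#'   `TRUE` when the zero-variance fallback fired.
#' @export
compute_cdr <- function(cells, scale = TRUE) {
  stopifnot(inherits(cells, "cell_counts"))
  n <- ncol(cells$counts)
  if (n < 2L) stop("CDR scaling needs at least 2 cells", call. = FALSE)
  cdr <- Matrix::colSums(cells$counts > 0) / nrow(cells$counts)
  if (!scale) return(cdr)
  s <- stats::sd(cdr)
  if (s == 0) {
    warning("all cells have identical detection rate; CDR covariate dropped")
    out <- rep(0, n)
    attr(out, "dropped") <- TRUE
    return(out)
  }
  out <- (cdr - mean(cdr)) / s
  attr(out, "dropped") <- FALSE
  out
}

# log2(1 + counts scaled to the median library size)
log_normalize <- function(cells) {
  libs <- Matrix::colSums(cells$counts)
  libs[libs == 0] <- 1
  target <- stats::median(libs)
  norm <- cells$counts %*% Matrix::Diagonal(x = target / libs)
  methods::as(log2(1 + norm), "CsparseMatrix")
}

# ridge-penalized logistic IRLS; lambda on non-intercept columns.
# Returns unpenalized log-likelihood at the penalized optimum.
logistic_ridge <- function(X, y, lambda = 1e-4, maxit = 100L,
                           tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p))
  if ("(Intercept)" %in% colnames(X))
    pen[which(colnames(X) == "(Intercept)"),
        which(colnames(X) == "(Intercept)")] <- 0
  beta <- rep(0, p)
  beta[1L] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    newbeta <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL)
    if (is.null(newbeta)) break
    newbeta <- drop(newbeta)
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta
      converged <- TRUE
      break
    }
    beta <- newbeta
  }
  eta <- drop(X %*% beta)
  # log(1+e^eta) computed overflow-safe
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  list(coef = beta, loglik = ll, converged = converged)
}

# OLS with Gaussian ML log-likelihood; rank-deficient designs handled by
# pivoting. Zero residual variance is flagged degenerate.
gaussian_ml <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  degenerate <- rss <= 1e-12 || n <= fit$rank
  ll <- if (degenerate) NA_real_ else
    -n / 2 * (log(2 * pi * rss / n) + 1)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank, n = n,
       loglik = ll, degenerate = degenerate)
}

#' Fit the two-part hurdle model for one gene
#'
#' Discrete part: ridge-penalized (1e-4 on non-intercept terms) logistic
#' regression of detection (count > 0) on the design. Continuous part:
#' ordinary least squares of log2(1 + median-library-normalized count) on
#' the same design over detected cells only.
#'
#' @param y numeric vector of log-normalized expression values, one per
#'   cell (zeros for undetected cells).
#' @param detected logical vector, `TRUE` where the raw count is > 0.
#' @param X design matrix (e.g. timepoint indicators plus CDR).
#' @return list with elements `disc`, `cont` (each with `coef`,
#'   `loglik`, convergence/degeneracy flags) and `skipped` (reason string
#'   or `NA`).
#' @export
fit_hurdle <- function(y, detected, X) {
  stopifnot(length(y) == nrow(X), length(detected) == length(y))
  if (sum(detected) < 3L)
    return(list(disc = NULL, cont = NULL,
                skipped = "fewer than 3 detected cells"))
  disc <- logistic_ridge(X, as.numeric(detected))
  cont <- gaussian_ml(X[detected, , drop = FALSE], y[detected])
  list(disc = disc, cont = cont, skipped = NA_character_)
}

# Build cell-means design: one indicator per timepoint, plus CDR.
timepoint_design <- function(timepoint, cdr) {
  tps <- sort(unique(timepoint))
  X <- sapply(tps, function(t) as.numeric(timepoint == t))
  colnames(X) <- paste0("t", tps)
  cbind(X, cdr = cdr)
}

# Reduced design constraining beta_tau = mean(beta_others): the tau
# column is removed and its cells get 1/(T-1) weight in every other
# timepoint column.
reduce_design <- function(X, tau_col) {
  tcols <- grep("^t", colnames(X))
  others <- setdiff(tcols, tau_col)
  Xr <- X
  at_tau <- X[, tau_col] == 1
  Xr[at_tau, others] <- 1 / length(others)
  Xr[, -tau_col, drop = FALSE]
}

#' Per-timepoint shift contrasts under the hurdle model
#'
#' For every gene passing the detection screen and every timepoint `tau`,
#' compares the full hurdle model (separate mean per timepoint, CDR
#' covariate in both parts) against a reduced model in which the
#' `tau` level is constrained to equal the average of the other
#' timepoints. The likelihood-ratio statistic sums the discrete and
#' continuous components (df = 2). The reported shift is the
#' model-implied expected expression at `tau` (detection probability
#' times continuous mean, at average CDR) minus the mean of the other
#' timepoints' expected expression; in a balanced design the four shifts
#' sum to zero. BH correction is applied jointly across all gene x
#' timepoint tests.
#'
#' @param cells a [cell_counts()] object.
#' @param cell_type optional cell type to restrict to.
#' @param config a [pipeline_config()]; uses `alpha`, `min_pct`.
#' @return data.frame with one row per gene x timepoint: `gene`,
#'   `timepoint`, `shift_log2fc`, `stat`, `df`, `p`, `padj`, `pct_in`,
#'   `pct_out`.
#' @export
timepoint_shift_contrasts <- function(cells, cell_type = NULL,
                                      config = pipeline_config()) {
  stopifnot(inherits(cells, "cell_counts"))
  if (!is.null(cell_type))
    cells <- subset_cells(cells, cells = cells$cells$cell_type == cell_type)
  tp <- cells$cells$timepoint_hours
  tps <- sort(unique(tp))
  if (length(tps) < 3L)
    stop("shift contrasts need >= 3 distinct timepoints", call. = FALSE)
  cdr <- compute_cdr(cells)
  X <- timepoint_design(tp, cdr)
  Y <- log_normalize(cells)
  det_mat <- cells$counts > 0

  # detection fraction per gene per timepoint for the min_pct screen
  pct <- sapply(tps, function(t) Matrix::rowMeans(det_mat[, tp == t,
                                                          drop = FALSE]))
  if (!is.matrix(pct)) pct <- matrix(pct, nrow = 1L)
  testable <- apply(pct, 1L, max) >= config$min_pct &
    Matrix::rowSums(det_mat) >= 3L

  rows <- vector("list", sum(testable) * length(tps))
  ri <- 0L
  tcols <- seq_along(tps)
  for (g in which(testable)) {
    y <- as.numeric(Y[g, ])
    det <- as.logical(det_mat[g, ])
    full <- fit_hurdle(y, det, X)
    if (!is.na(full$skipped) || is.null(full$cont) ||
        full$cont$degenerate) next
    # model-implied expected expression per timepoint at CDR = 0
    pdet <- stats::plogis(full$disc$coef[tcols])
    mucont <- full$cont$coef[tcols]
    mucont[is.na(mucont)] <- 0
    ey <- pdet * mucont
    ll_full <- full$disc$loglik + full$cont$loglik
    for (k in tcols) {
      if (sum(tp == tps[k]) == 0L) next
      Xr <- reduce_design(X, k)
      red <- fit_hurdle(y, det, Xr)
      if (!is.na(red$skipped) || red$cont$degenerate) next
      stat <- 2 * (ll_full - (red$disc$loglik + red$cont$loglik))
      stat <- max(stat, 0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        gene = cells$gene_ids[g], timepoint = tps[k],
        shift_log2fc = ey[k] - mean(ey[-k]),
        stat = stat, df = 2L,
        p = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
        pct_in = pct[g, k], pct_out = mean(pct[g, -k]),
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L)
    return(data.frame(gene = character(), timepoint = numeric(),
                      shift_log2fc = numeric(), stat = numeric(),
                      df = integer(), p = numeric(), padj = numeric(),
                      pct_in = numeric(), pct_out = numeric()))
  out <- do.call(rbind, rows[seq_len(ri)])
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[c("gene", "timepoint", "shift_log2fc", "stat", "df", "p", "padj",
        "pct_in", "pct_out")]
}

#' Peak-and-trough rhythmicity filter
#'
#' A gene is called rhythmic when at least two timepoints show a
#' significant shift from the average (adjusted p below `alpha`,
#' `|shift| >= lfc_cell`, detection fraction at least `min_pct` on one
#' side of the contrast), with at least one significant positive and one
#' significant negative shift. The peak is the timepoint with the largest
#' significant positive shift, the trough the most negative; ties break
#' toward the smaller timepoint.
#'
#' @param contrasts output of [timepoint_shift_contrasts()].
#' @param config a [pipeline_config()].
#' @return data.frame per gene: `gene`, `tested`, `rhythmic`, `n_sig`,
#'   `sig_times`, `peak_time`, `trough_time`.
#' @export
peak_trough_filter <- function(contrasts, config = pipeline_config()) {
  need <- c("gene", "timepoint", "shift_log2fc", "padj", "pct_in",
            "pct_out")
  stopifnot(all(need %in% names(contrasts)))
  by_gene <- split(contrasts, contrasts$gene)
  out <- lapply(by_gene, function(d) {
    d <- d[order(d$timepoint), , drop = FALSE]
    sig <- d$padj < config$alpha &
      abs(d$shift_log2fc) >= config$lfc_cell &
      pmax(d$pct_in, d$pct_out) >= config$min_pct
    pos <- sig & d$shift_log2fc > 0
    neg <- sig & d$shift_log2fc < 0
    rhythmic <- sum(sig) >= 2L && any(pos) && any(neg)
    peak <- trough <- NA_real_
    if (rhythmic) {
      peak <- d$timepoint[pos][which.max(d$shift_log2fc[pos])]
      trough <- d$timepoint[neg][which.min(d$shift_log2fc[neg])]
    }
    data.frame(gene = d$gene[1L], tested = TRUE, rhythmic = rhythmic,
               n_sig = sum(sig),
               sig_times = paste(d$timepoint[sig], collapse = ","),
               peak_time = peak, trough_time = trough,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# two-sided rank-sum p; exact (no ties, feasible) else tie-corrected
# normal approximation without continuity correction
ranksum_p <- function(xA, xB) {
  nA <- length(xA); nB <- length(xB)
  r <- rank(c(xA, xB))
  W <- sum(r[seq_len(nA)])
  U <- W - nA * (nA + 1) / 2
  ties <- table(c(xA, xB))
  has_ties <- any(ties > 1L)
  if (!has_ties && choose(nA + nB, nA) <= 2e4) {
    p <- 2 * min(stats::pwilcox(U, nA, nB),
                 stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE))
    return(min(p, 1))
  }
  mu <- nA * nB / 2
  n <- nA + nB
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- nA * nB / 12 * (n + 1 - tiecor)
  if (sig2 <= 0) return(1)
  z <- (U - mu) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Cell-level cross-check of the pseudobulk contrasts and the engine
#' behind marker calling. Genes detected in at least `min_pct` of cells
#' in one of the groups are tested with a two-sided Wilcoxon rank-sum on
#' log-normalized expression (exact when there are no ties and the group
#' sizes are small; otherwise tie-corrected normal approximation). The
#' log2FC is the difference of group means of log2(1 + normalized)
#' expression.
#'
#' @param cells a [cell_counts()] object.
#' @param groupA,groupB logical or integer cell selections.
#' @param min_pct detection screen.
#' @param lfc_threshold absolute log2FC required for the pass flag.
#' @param alpha adjusted-p threshold for the pass flag.
#' @return data.frame per tested gene: `gene`, `log2fc`, `pct_A`,
#'   `pct_B`, `p`, `padj`, `pass`.
#' @export
wilcoxon_de <- function(cells, groupA, groupB, min_pct = 0.05,
                        lfc_threshold = 0.2, alpha = 0.05) {
  stopifnot(inherits(cells, "cell_counts"))
  Y <- log_normalize(cells)
  YA <- Y[, groupA, drop = FALSE]
  YB <- Y[, groupB, drop = FALSE]
  if (ncol(YA) == 0L || ncol(YB) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  pctA <- Matrix::rowMeans(YA > 0)
  pctB <- Matrix::rowMeans(YB > 0)
  testable <- pmax(pctA, pctB) >= min_pct
  idx <- which(testable)
  p <- lfc <- numeric(length(idx))
  for (j in seq_along(idx)) {
    a <- as.numeric(YA[idx[j], ])
    b <- as.numeric(YB[idx[j], ])
    p[j] <- ranksum_p(a, b)
    lfc[j] <- mean(b) - mean(a)
  }
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = cells$gene_ids[idx], log2fc = lfc,
             pct_A = pctA[idx], pct_B = pctB[idx], p = p, padj = padj,
             pass = padj < alpha & abs(lfc) >= lfc_threshold,
             stringsAsFactors = FALSE)
}

#' One-vs-rest marker genes per cell type
#'
#' Runs [wilcoxon_de()] for each cell type against all other cells with
#' the marker thresholds (detection in at least `marker_min_pct` of
#' cells, absolute log2FC at least `marker_lfc`).
#'
#' @param cells a [cell_counts()] object.
#' @param config a [pipeline_config()].
#' @return data.frame of passing markers: `cell_type` plus the
#'   [wilcoxon_de()] columns.
#' @export
find_markers <- function(cells, config = pipeline_config()) {
  types <- sort(unique(cells$cells$cell_type))
  out <- lapply(types, function(ct) {
    inb <- cells$cells$cell_type == ct
    de <- wilcoxon_de(cells, groupA = !inb, groupB = inb,
                      min_pct = config$marker_min_pct,
                      lfc_threshold = config$marker_lfc,
                      alpha = config$alpha)
    de <- de[de$pass & de$log2fc > 0, , drop = FALSE]
    if (nrow(de)) cbind(cell_type = ct, de) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_type = character(), gene = character(),
                      log2fc = numeric(), pct_A = numeric(),
                      pct_B = numeric(), p = numeric(), padj = numeric(),
                      pass = logical())
  rownames(res) <- NULL
  res
}
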