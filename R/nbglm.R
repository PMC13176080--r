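#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: the reference is the
#' per-gene geometric mean across samples over genes with all-positive
#' counts, and each sample's factor is the median of its count/reference
#' ratios. When no gene is positive in all samples, a fallback uses genes
#' positive in at least 90% of samples with zeros masked. Factors are
#' rescaled so their median is 1.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param fallback Allow the masked-zero fallback (default TRUE).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  m <- counts
  allpos <- rowSums(m > 0) == ncol(m)
  if (any(allpos)) {
    sub <- m[allpos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    f <- apply(sub, 2L, function(col) stats::median(col / ref))
  } else {
    if (!fallback)
      stop("no gene has positive counts in all samples and fallback is disabled")
    mostly <- rowMeans(m > 0) >= 0.9
    if (!any(mostly))
      stop("no gene has positive counts in >= 90% of samples; cannot normalize")
    sub <- m[mostly, , drop = FALSE]
    logm <- log(sub)
    logm[!is.finite(logm)] <- NA
    ref <- exp(rowMeans(logm, na.rm = TRUE))
    ratio <- sub / ref
    ratio[sub == 0] <- NA
    f <- apply(ratio, 2L, function(col) stats::median(col, na.rm = TRUE))
  }
  if (any(!is.finite(f) | f <= 0)) stop("degenerate size factors")
  f <- f / stats::median(f)
  names(f) <- colnames(m)
  f
}

# NB log-likelihood; alpha -> 0 collapses to Poisson
nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-8) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood for the dispersion
cr_profile_loglik <- function(log_alpha, y, X, offset) {
  alpha <- exp(log_alpha)
  fit <- tryCatch(
    stats::glm.fit(X, y, family = MASS::negative.binomial(theta = 1 / alpha),
                   offset = offset,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  mu <- fit$fitted.values
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  cr <- determinant(xtwx, logarithm = TRUE)$modulus
  nb_loglik(y, mu, alpha) - 0.5 * as.numeric(cr)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Log-link NB regression of one gene's counts on a design (factor or model
#' matrix) with log-size-factor offsets. The IRLS fit at fixed dispersion
#' uses convergence tolerance 1e-8 and at most 100 iterations. The gene-wise
#' dispersion is initialized by method of moments on Poisson residuals and
#' refined by maximizing the Cox-Reid-adjusted profile likelihood; pass
#' `dispersion` to skip estimation (used to share the full model's
#' dispersion with a reduced model).
#'
#' @param y Integer vector of counts.
#' @param design A factor, or a numeric model matrix (with intercept).
#' @param offset Numeric offset vector on the log scale (e.g. log size
#'   factors); default 0.
#' @param dispersion Optional fixed NB dispersion alpha (variance =
#'   mu + alpha mu^2).
#' @return An `nb_fit`: list with `coefficients`, `dispersion`, `fitted`,
#'   `loglik`, `converged`, `iterations`, `df_model`, and the inputs.
#' @export
fit_nb_glm <- function(y, design, offset = NULL, dispersion = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples")
  X <- if (is.factor(design) || is.character(design)) {
    stats::model.matrix(~f, data.frame(f = factor(design)))
  } else if (is.matrix(design)) design else
    stop("design must be a factor or a model matrix")
  if (nrow(X) != n) stop("design and counts lengths differ")
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (is.null(offset)) offset <- rep(0, n)

  if (is.null(dispersion)) {
    # method-of-moments init from a Poisson fit
    pfit <- stats::glm.fit(X, y, family = stats::poisson(), offset = offset,
                           control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    mu0 <- pfit$fitted.values
    mom <- sum((y - mu0)^2 - mu0) / sum(mu0^2)
    mom <- min(max(mom, 1e-6), 10)
    opt <- stats::optimize(cr_profile_loglik, interval = log(c(1e-6, 10)),
                           y = y, X = X, offset = offset,
                           maximum = TRUE, tol = 1e-4)
    # keep whichever of the optimum and the MoM start profiles higher
    alpha <- if (cr_profile_loglik(log(mom), y, X, offset) > opt$objective)
      mom else exp(opt$maximum)
  } else {
    alpha <- dispersion
    if (alpha < 0) stop("dispersion must be >= 0")
  }

  fam <- if (alpha < 1e-8) stats::poisson()
         else MASS::negative.binomial(theta = 1 / alpha)
  fit <- stats::glm.fit(X, y, family = fam, offset = offset,
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  out <- list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
              dispersion = alpha,
              fitted = fit$fitted.values,
              loglik = nb_loglik(y, fit$fitted.values, alpha),
              converged = isTRUE(fit$converged),
              iterations = fit$iter,
              df_model = ncol(X), y = y, X = X, offset = offset)
  class(out) <- "nb_fit"
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("NB GLM fit: %d obs, %d coefficients, dispersion %.4g, logLik %.3f%s\n",
              length(x$y), x$df_model, x$dispersion, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

# Symmetrized shared dispersion for nested-model LRTs: geometric mean of the
# CR-adjusted profile-ML estimates under the full and reduced designs. The
# full-model estimate alone is biased downward exactly when chance group
# spread inflates the LR (anticonservative); the reduced-model estimate is
# biased upward the same way (conservative). The log-scale midpoint balances
# the two couplings and restores null calibration.
nb_shared_dispersion <- function(y, X_full, X_reduced, offset) {
  est <- function(X) {
    opt <- stats::optimize(cr_profile_loglik, interval = log(c(1e-6, 10)),
                           y = y, X = X, offset = offset,
                           maximum = TRUE, tol = 1e-4)
    exp(opt$maximum)
  }
  sqrt(est(X_full) * est(X_reduced))
}

#' Likelihood-ratio test between nested NB fits
#'
#' The statistic is twice the log-likelihood difference, clipped at zero,
#' referred to a chi-square with `df` degrees of freedom. Both fits must use
#' the same dispersion (fit the reduced model with the full model's
#' estimate) so the likelihoods are comparable.
#'
#' @param full,reduced `nb_fit` objects (reduced nested in full).
#' @param df Positive integer degrees of freedom.
#' @return List with `stat` and `p_value`.
#' @export
lrt_test <- function(full, reduced, df) {
  if (df <= 0) stop("df must be positive")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Two-group differential expression by NB LRT
#'
#' Filters to genes with CPM >= 1 in at least 2 contrast libraries, fits per
#' gene a NB GLM with a two-level condition factor (full) against an
#' intercept-only model (reduced; both share a symmetrized gene-wise
#' dispersion, the geometric mean of the two designs' Cox-Reid profile
#' estimates), and tests by LRT with 1 degree of freedom. log2 fold-change is computed on
#' size-factor-normalized group means with a moderation constant `c` added
#' to both means to avoid infinities at zero. A gene is a DEG iff
#' q <= `alpha_q` and |log2FC| >= `min_lfc`.
#'
#' @param counts Integer count matrix.
#' @param samples Sample sheet.
#' @param contrast `c(control_label, stress_label)`; log2FC is stress vs
#'   control.
#' @param alpha_q Adjusted-p threshold (default 0.05).
#' @param min_lfc Absolute log2FC threshold (default 1).
#' @param lfc_moderation Moderation constant on normalized means
#'   (default 0.5).
#' @return A data.frame of class `de_result` with columns `gene_id`,
#'   `log2_fold_change`, `lrt_stat`, `p_value`, `q_value`, `is_deg`,
#'   `converged`; attribute `n_filtered` counts genes failing the expression
#'   pre-filter.
#' @export
de_two_group <- function(counts, samples, contrast, alpha_q = 0.05,
                         min_lfc = 1, lfc_moderation = 0.5) {
  stopifnot(length(contrast) == 2L)
  samples <- samples[samples$condition %in% contrast, , drop = FALSE]
  for (cc in contrast)
    if (sum(samples$condition == cc) < 2L)
      stop("group '", cc, "' has fewer than 2 replicates")
  m <- counts[, samples$sample_id, drop = FALSE]
  cond <- factor(samples$condition, levels = contrast)

  cpm <- cpm_matrix(m)
  expressed <- rowSums(cpm >= 1) >= 2L
  sf <- size_factors(m)
  offset <- log(sf)
  genes <- rownames(m)[expressed]

  X_full <- stats::model.matrix(~f, data.frame(f = cond))
  X_red <- stats::model.matrix(~1, data.frame(f = cond))
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- m[genes[i], ]
    alpha <- nb_shared_dispersion(as.numeric(y), X_full, X_red, offset)
    full <- fit_nb_glm(y, X_full, offset = offset, dispersion = alpha)
    red <- fit_nb_glm(y, X_red, offset = offset, dispersion = alpha)
    lt <- lrt_test(full, red, df = 1L)
    norm <- y / sf
    mu_c <- mean(norm[cond == contrast[1L]])
    mu_s <- mean(norm[cond == contrast[2L]])
    lfc <- log2((mu_s + lfc_moderation) / (mu_c + lfc_moderation))
    res[[i]] <- data.frame(gene_id = genes[i], log2_fold_change = lfc,
                           lrt_stat = if (full$converged) lt$stat else NA_real_,
                           p_value = if (full$converged) lt$p_value else NA_real_,
                           converged = full$converged,
                           stringsAsFactors = FALSE)
  }
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), log2_fold_change = numeric(0),
               lrt_stat = numeric(0), p_value = numeric(0),
               converged = logical(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$q_value <- bh_adjust(tab$p_value)
  tab$is_deg <- !is.na(tab$q_value) & tab$q_value <= alpha_q &
    abs(tab$log2_fold_change) >= min_lfc
  attr(tab, "n_filtered") <- sum(!expressed)
  attr(tab, "contrast") <- contrast
  class(tab) <- c("de_result", "data.frame")
  tab
}

#' Overlap of up- and down-regulated DEG sets between two contrasts
#'
#' Computes the shared and contrast-specific counts of up-regulated and
#' down-regulated DEGs (the Venn-diagram partition). Both result tables must
#' cover the same gene universe.
#'
#' @param de_1,de_2 `de_result` tables.
#' @return An `overlap_summary`: named list `up_shared`, `up_only_1`,
#'   `up_only_2`, `down_shared`, `down_only_1`, `down_only_2`.
#' @export
overlap_degs <- function(de_1, de_2) {
  u1 <- sort(de_1$gene_id); u2 <- sort(de_2$gene_id)
  if (!identical(u1, u2)) {
    off <- c(setdiff(u1, u2), setdiff(u2, u1))
    stop("DEG tables cover different gene universes; offending ids: ",
         paste(utils::head(off, 10L), collapse = ", "))
  }
  up1 <- de_1$gene_id[de_1$is_deg & de_1$log2_fold_change > 0]
  up2 <- de_2$gene_id[de_2$is_deg & de_2$log2_fold_change > 0]
  dn1 <- de_1$gene_id[de_1$is_deg & de_1$log2_fold_change < 0]
  dn2 <- de_2$gene_id[de_2$is_deg & de_2$log2_fold_change < 0]
  out <- list(up_shared = length(intersect(up1, up2)),
              up_only_1 = length(setdiff(up1, up2)),
              up_only_2 = length(setdiff(up2, up1)),
              down_shared = length(intersect(dn1, dn2)),
              down_only_1 = length(setdiff(dn1, dn2)),
              down_only_2 = length(setdiff(dn2, dn1)))
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("DEG overlap:\n")
  cat(sprintf("  up:   %d shared, %d only in 1, %d only in 2\n",
              x$up_shared, x$up_only_1, x$up_only_2))
  cat(sprintf("  down: %d shared, %d only in 1, %d only in 2\n",
              x$down_shared, x$down_only_1, x$down_only_2))
  invisible(x)
}
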