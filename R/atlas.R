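#' Counts-per-million matrix
#'
#' Scales each sample's counts by its library total times 1e6, so each
#' column sums to one million.
#'
#' @param counts Integer count matrix.
#' @return Numeric matrix of CPM values, same dimensions.
#' @export
cpm_matrix <- function(counts) {
  tot <- colSums(counts)
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero library total: ", paste(zero, collapse = ", "))
  t(t(counts) / tot) * 1e6
}

#' Default tissue-collapsing scheme
#'
#' Maps the nine sampled tissues to six broader categories to increase
#' statistical power: developing + emerging leaves become young leaves,
#' first + third fully expanded leaves become mature leaves, root crown +
#' root tips become roots; stem, floral buds and open flowers map to
#' themselves.
#'
#' @return Named character vector (raw label -> collapsed category).
#' @export
default_tissue_scheme <- function() {
  c("developing leaves" = "young leaves",
    "emerging leaves" = "young leaves",
    "first fully expanded leaves" = "mature leaves",
    "third fully expanded leaves" = "mature leaves",
    "root crown" = "roots",
    "root tips" = "roots",
    "stem" = "stem",
    "floral buds" = "floral buds",
    "open flowers" = "open flowers")
}

#' Collapse tissue labels into broader categories
#'
#' @param samples Sample sheet with a `tissue` column.
#' @param scheme Named character vector mapping raw label to category;
#'   labels absent from the scheme map to themselves unless `strict`.
#' @param strict Error on unmapped labels (default FALSE).
#' @return The sample sheet with `tissue` replaced by collapsed categories.
#' @export
collapse_tissues <- function(samples, scheme = default_tissue_scheme(),
                             strict = FALSE) {
  lab <- samples$tissue
  unmapped <- setdiff(unique(lab), names(scheme))
  if (length(unmapped) && strict)
    stop("tissue label(s) not covered by scheme: ",
         paste(unmapped, collapse = ", "))
  mapped <- ifelse(lab %in% names(scheme), unname(scheme[lab]), lab)
  samples$tissue <- mapped
  samples
}

#' Variance-stabilizing log transform
#'
#' A monotone, parameter-free stand-in for a fitted-dispersion variance
#' stabilization: `log2(count / size_factor + 1)`. Zero counts map to zero
#' and doubling a count together with its sample's factor leaves the value
#' unchanged.
#'
#' @param counts Integer count matrix.
#' @param factors Positive per-sample size factors.
#' @return Numeric matrix of transformed values.
#' @export
vst_like <- function(counts, factors) {
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(t(t(counts) / factors) + 1)
}

#' Expressed and stable gene flags
#'
#' A gene is expressed if its CPM is at least `min_cpm` in at least
#' `min_libs` libraries. Stability is the coefficient of variation (sd/mean)
#' of the variance-stabilized values across all samples, assigned to nested
#' tiers with mixed boundary operators preserved deliberately:
#' CV <= 0.20 (`cv20`), CV < 0.15 (`cv15`), CV < 0.10 (`cv10`); the
#' strictest satisfied tier is reported. Raw-scale CV is available with
#' `cv_scale = "raw"`.
#'
#' @param counts Integer count matrix.
#' @param min_cpm,min_libs Expression rule parameters.
#' @param cv_tiers Tier cutoffs, loosest first.
#' @param cv_scale `"vst"` (default) or `"raw"` scale for the CV.
#' @param factors Optional size factors (computed if missing).
#' @return Data.frame with `gene_id`, `expressed`, `cv`, `tier`.
#' @export
expression_flags <- function(counts, min_cpm = 1, min_libs = 2,
                             cv_tiers = c(0.20, 0.15, 0.10),
                             cv_scale = c("vst", "raw"), factors = NULL) {
  cv_scale <- match.arg(cv_scale)
  cpm <- cpm_matrix(counts)
  expressed <- rowSums(cpm >= min_cpm) >= min_libs
  if (is.null(factors)) factors <- size_factors(counts)
  vals <- if (cv_scale == "vst") vst_like(counts, factors)
          else t(t(counts) / factors)
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  tier <- rep("none", nrow(counts))
  tier[!is.na(cv) & cv <= cv_tiers[1L]] <- "cv20"
  tier[!is.na(cv) & cv < cv_tiers[2L]] <- "cv15"
  tier[!is.na(cv) & cv < cv_tiers[3L]] <- "cv10"
  data.frame(gene_id = rownames(counts), expressed = expressed,
             cv = cv, tier = tier, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Tissue-enrichment atlas
#'
#' For each expressed gene, tests a tissue effect by negative-binomial LRT
#' (full model: tissue factor; reduced: intercept; both models share a
#' symmetrized gene-wise dispersion, the geometric mean of the two designs'
#' Cox-Reid profile estimates), adjusts p-values by BH over the tested
#' genes, computes mean
#' variance-stabilized expression per collapsed tissue category, assigns
#' the gene to its highest-mean category, and calls it enriched when
#' q < `q_threshold` and the top-vs-second log2 difference is at least
#' `min_lfc`.
#'
#' @param counts Integer count matrix.
#' @param samples Sample sheet with tissue labels.
#' @param scheme Tissue-collapsing scheme (see [collapse_tissues()]); use
#'   `NULL` to analyse raw labels.
#' @param q_threshold FDR threshold (default 0.01).
#' @param min_lfc Minimum top-vs-second log2 difference (default 1).
#' @return An `atlas_result`: data.frame with `gene_id`, `lrt_stat`,
#'   `p_value`, `q_value`, `top_tissue`, `second_tissue`, `log2fc_top_second`,
#'   `enriched`, plus attributes `summary` (counts) and `flags` (the
#'   [expression_flags()] table).
#' @export
tissue_enrichment <- function(counts, samples, scheme = default_tissue_scheme(),
                              q_threshold = 0.01, min_lfc = 1) {
  if (!is.null(scheme)) samples <- collapse_tissues(samples, scheme)
  samples <- samples[!is.na(samples$tissue), , drop = FALSE]
  m <- counts[, samples$sample_id, drop = FALSE]
  tis <- factor(samples$tissue)
  if (nlevels(tis) < 2L) stop("need at least 2 tissue categories")
  small <- names(which(table(tis) < 2L))
  if (length(small))
    stop("tissue category with fewer than 2 replicates: ",
         paste(small, collapse = ", "))

  flags <- expression_flags(m)
  sf <- size_factors(m)
  offset <- log(sf)
  vst <- vst_like(m, sf)
  genes <- flags$gene_id[flags$expressed]
  df_lrt <- nlevels(tis) - 1L

  X_full <- stats::model.matrix(~f, data.frame(f = tis))
  X_red <- stats::model.matrix(~1, data.frame(f = tis))
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- m[genes[i], ]
    alpha <- nb_shared_dispersion(as.numeric(y), X_full, X_red, offset)
    full <- fit_nb_glm(y, X_full, offset = offset, dispersion = alpha)
    red <- fit_nb_glm(y, X_red, offset = offset, dispersion = alpha)
    lt <- lrt_test(full, red, df = df_lrt)
    means <- tapply(vst[genes[i], ], tis, mean)
    ord <- order(means, decreasing = TRUE)
    res[[i]] <- data.frame(
      gene_id = genes[i],
      lrt_stat = if (full$converged) lt$stat else NA_real_,
      p_value = if (full$converged) lt$p_value else NA_real_,
      top_tissue = names(means)[ord[1L]],
      second_tissue = names(means)[ord[2L]],
      log2fc_top_second = unname(means[ord[1L]] - means[ord[2L]]),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), lrt_stat = numeric(0),
               p_value = numeric(0), top_tissue = character(0),
               second_tissue = character(0), log2fc_top_second = numeric(0),
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$q_value <- bh_adjust(tab$p_value)
  tab$enriched <- !is.na(tab$q_value) & tab$q_value < q_threshold &
    tab$log2fc_top_second >= min_lfc

  summ <- list(n_genes = nrow(m),
               n_expressed = sum(flags$expressed),
               n_stable_cv20 = sum(flags$expressed & flags$tier %in% c("cv20", "cv15", "cv10")),
               n_stable_cv15 = sum(flags$expressed & flags$tier %in% c("cv15", "cv10")),
               n_stable_cv10 = sum(flags$expressed & flags$tier == "cv10"),
               n_enriched = sum(tab$enriched),
               enriched_by_tissue = as.list(table(tab$top_tissue[tab$enriched])))
  attr(tab, "summary") <- summ
  attr(tab, "flags") <- flags
  class(tab) <- c("atlas_result", "data.frame")
  tab
}

#' @export
print.atlas_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Tissue atlas: %d genes, %d expressed, %d tissue-enriched\n",
              s$n_genes, s$n_expressed, s$n_enriched))
  if (length(s$enriched_by_tissue)) {
    for (k in names(s$enriched_by_tissue))
      cat(sprintf("  %-24s %d\n", k, s$enriched_by_tissue[[k]]))
  }
  invisible(x)
}
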