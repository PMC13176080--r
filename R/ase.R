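#' Per-condition haplotype proportions for a quartet
#'
#' Pools (sums) each haplotype gene's counts over the condition's replicates
#' and divides by the pooled quartet total, so the four proportions sum to 1.
#'
#' @param quartet One-row data.frame (or list) with gene ids `A`-`D`.
#' @param counts Integer count matrix.
#' @param samples Sample sheet data.frame.
#' @param condition Condition label to pool over.
#' @return Named numeric vector `c(A=,B=,C=,D=)` with attribute
#'   `pooled_total`.
#' @export
condition_proportions <- function(quartet, counts, samples, condition) {
  sams <- samples$sample_id[samples$condition == condition]
  if (!length(sams)) stop("condition not present in sample sheet: ", condition)
  g <- as.character(unlist(quartet[c("A", "B", "C", "D")]))
  pooled <- rowSums(counts[g, sams, drop = FALSE])
  tot <- sum(pooled)
  if (tot == 0)
    stop("pooled quartet total is zero in condition '", condition,
         "' (read-support filters should prevent this)")
  p <- as.numeric(pooled) / tot
  names(p) <- c("A", "B", "C", "D")
  attr(p, "pooled_total") <- tot
  p
}

#' Allelic bias and dominance class
#'
#' Bias is the difference between the highest- and lowest-expressing
#' haplotype proportions within a condition. Values near 0 indicate balanced
#' expression; dominance classes use thresholds 0.25 (mild) and 0.5
#' (strong). Strong dominance requires bias strictly above 0.5; a bias of
#' exactly 0.25 or 0.5 is classed mild.
#'
#' @param p Proportion vector from [condition_proportions()].
#' @return List with `bias` and `dominance_class` ("balanced", "mild",
#'   "strong").
#' @export
allelic_bias <- function(p) {
  bias <- max(p) - min(p)
  cls <- if (bias < 0.25) "balanced" else if (bias <= 0.5) "mild" else "strong"
  list(bias = bias, dominance_class = cls)
}

#' Pearson chi-square contrast of haplotype ratios between two conditions
#'
#' Tests independence of haplotype read counts (columns) and condition
#' (rows) on the 2 x 4 table of pooled counts, without continuity correction
#' and without pseudo-counts. Haplotype columns with zero total in both
#' conditions are dropped and the degrees of freedom reduced accordingly.
#' With fewer than 2 non-degenerate columns the p-value is undefined
#' (`NA`, flagged) and the quartet is excluded from FDR adjustment.
#'
#' @param pooled_control,pooled_stress Numeric vectors of 4 pooled haplotype
#'   counts.
#' @return List with `stat`, `df`, `p_value`, and `min_expected` (smallest
#'   expected cell, for flagging unstable tables).
#' @export
contrast_chi_square <- function(pooled_control, pooled_stress) {
  stopifnot(length(pooled_control) == length(pooled_stress))
  if (any(pooled_control < 0) || any(pooled_stress < 0))
    stop("pooled counts must be non-negative")
  if (sum(pooled_control) <= 0 || sum(pooled_stress) <= 0)
    stop("each condition must have a positive pooled total")
  tab <- rbind(control = as.numeric(pooled_control),
               stress = as.numeric(pooled_stress))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    return(list(stat = NA_real_, df = 0L, p_value = NA_real_,
                min_expected = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       min_expected = min(expected))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement. Undefined entries
#' (`NA`) are excluded from the adjustment (they do not count towards the
#' number of tests) and reinserted as `NA` in place; order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Top haplotype, rank switching and delta-max effect size
#'
#' The haplotype with the highest proportion in a condition is its top rank
#' order haplotype; rank switching is recorded when the top haplotype
#' differs between control and stress. The effect size delta is the absolute
#' difference in the maximum haplotype proportion between the two conditions
#' (whether or not the identity of the top haplotype changed). Delta >= 0.10
#' is classed moderate, >= 0.20 pronounced. Argmax ties are broken
#' alphabetically and flagged.
#'
#' @param p_control,p_stress Proportion vectors (named A-D).
#' @return List with `top_control`, `top_stress`, `tie_control`,
#'   `tie_stress`, `rank_switch`, `delta`, `effect_class`.
#' @export
rank_and_delta <- function(p_control, p_stress) {
  top_of <- function(p) {
    i <- which.max(p)                      # first index = alphabetical tie-break
    list(top = names(p)[i], tie = sum(abs(p - p[i]) < 1e-12) > 1L)
  }
  tc <- top_of(p_control)
  ts <- top_of(p_stress)
  delta <- abs(max(p_stress) - max(p_control))
  cls <- if (delta < 0.10) "none" else if (delta < 0.20) "moderate" else "pronounced"
  list(top_control = tc$top, top_stress = ts$top,
       tie_control = tc$tie, tie_stress = ts$tie,
       rank_switch = tc$top != ts$top,
       delta = delta, effect_class = cls)
}

#' Run the full allele-specific expression contrast
#'
#' For each haplotype quartet, computes per-condition proportions, allelic
#' bias/dominance classes, the chi-square contrast with BH FDR across
#' quartets, rank switching and the delta-max effect size, and a summary of
#' dominance, switching and effect-size counts together with the empirical
#' CDF coordinates of bias per condition.
#'
#' @param quartets Data.frame from [select_quartets()].
#' @param counts Integer count matrix.
#' @param samples Sample sheet.
#' @param contrast Character vector `c(control_label, stress_label)`.
#' @param thresholds [filter_thresholds()] used when `filter = TRUE`.
#' @param filter Apply [filter_quartets()] first (default TRUE). Set FALSE
#'   when the quartets are already filtered for this contrast.
#' @param q_threshold Significance threshold on BH q (default 0.05).
#' @param strict_ties Exclude quartets with a tied top haplotype from
#'   rank-switch counts (default FALSE: included, with tie flag set).
#' @return An `ase_result`: list with `table` (per-quartet data.frame),
#'   `summary` (named list of counts), `bias_cdf` (data.frame of CDF
#'   coordinates) and `contrast`.
#' @export
run_ase <- function(quartets, counts, samples, contrast,
                    thresholds = filter_thresholds(), filter = TRUE,
                    q_threshold = 0.05, strict_ties = FALSE) {
  stopifnot(length(contrast) == 2L)
  control <- contrast[1L]; stress <- contrast[2L]
  if (!all(contrast %in% samples$condition))
    stop("contrast condition(s) absent from sample sheet: ",
         paste(setdiff(contrast, samples$condition), collapse = ", "))
  if (filter && nrow(quartets)) {
    quartets <- filter_quartets(quartets, counts, samples, thresholds,
                                conditions = contrast)$kept
  }
  nq <- nrow(quartets)
  if (nq == 0L) {
    warning("no quartets to analyse")
    empty <- empty_ase_table()
    out <- list(table = empty, summary = ase_summary(empty, q_threshold, strict_ties),
                bias_cdf = data.frame(condition = character(0), bias = numeric(0),
                                      cdf = numeric(0)),
                contrast = contrast)
    class(out) <- "ase_result"
    return(out)
  }

  rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    q <- quartets[i, ]
    pc <- condition_proportions(q, counts, samples, control)
    ps <- condition_proportions(q, counts, samples, stress)
    bc <- allelic_bias(pc)
    bs <- allelic_bias(ps)
    chi <- contrast_chi_square(pc * attr(pc, "pooled_total"),
                               ps * attr(ps, "pooled_total"))
    rd <- rank_and_delta(pc, ps)
    rows[[i]] <- data.frame(
      orthogroup_id = q$orthogroup_id,
      total_control = attr(pc, "pooled_total"),
      total_stress = attr(ps, "pooled_total"),
      pA_control = pc[["A"]], pB_control = pc[["B"]],
      pC_control = pc[["C"]], pD_control = pc[["D"]],
      pA_stress = ps[["A"]], pB_stress = ps[["B"]],
      pC_stress = ps[["C"]], pD_stress = ps[["D"]],
      bias_control = bc$bias, class_control = bc$dominance_class,
      bias_stress = bs$bias, class_stress = bs$dominance_class,
      chi2_stat = chi$stat, df = chi$df, p_value = chi$p_value,
      low_expected = !is.na(chi$min_expected) && chi$min_expected < 1,
      top_control = rd$top_control, top_stress = rd$top_stress,
      tie_control = rd$tie_control, tie_stress = rd$tie_stress,
      rank_switch = rd$rank_switch, delta = rd$delta,
      effect_class = rd$effect_class,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q_value <- bh_adjust(tab$p_value)
  tab$significant <- !is.na(tab$q_value) & tab$q_value < q_threshold

  mk_cdf <- function(b, lbl) {
    b <- sort(b)
    data.frame(condition = lbl, bias = b,
               cdf = seq_along(b) / length(b), stringsAsFactors = FALSE)
  }
  cdf <- rbind(mk_cdf(tab$bias_control, control), mk_cdf(tab$bias_stress, stress))

  out <- list(table = tab,
              summary = ase_summary(tab, q_threshold, strict_ties),
              bias_cdf = cdf, contrast = contrast)
  class(out) <- "ase_result"
  out
}

ase_summary <- function(tab, q_threshold, strict_ties) {
  switch_mask <- tab$rank_switch
  if (strict_ties) switch_mask <- switch_mask & !(tab$tie_control | tab$tie_stress)
  strong_any <- tab$class_control == "strong" | tab$class_stress == "strong"
  list(
    n_quartets = nrow(tab),
    control_balanced = sum(tab$class_control == "balanced"),
    control_mild = sum(tab$class_control == "mild"),
    control_strong = sum(tab$class_control == "strong"),
    stress_balanced = sum(tab$class_stress == "balanced"),
    stress_mild = sum(tab$class_stress == "mild"),
    stress_strong = sum(tab$class_stress == "strong"),
    n_rank_switch = sum(switch_mask),
    n_switch_delta_lt_10 = sum(switch_mask & tab$delta < 0.10),
    n_delta_ge_10 = sum(switch_mask & tab$delta >= 0.10),
    n_delta_ge_20 = sum(switch_mask & tab$delta >= 0.20),
    n_strong_and_delta_ge_20 = sum(strong_any & switch_mask & tab$delta >= 0.20),
    n_significant = sum(tab$significant),
    n_p_undefined = sum(is.na(tab$p_value)),
    q_threshold = q_threshold)
}

empty_ase_table <- function() {
  data.frame(orthogroup_id = character(0), total_control = integer(0),
             total_stress = integer(0),
             pA_control = numeric(0), pB_control = numeric(0),
             pC_control = numeric(0), pD_control = numeric(0),
             pA_stress = numeric(0), pB_stress = numeric(0),
             pC_stress = numeric(0), pD_stress = numeric(0),
             bias_control = numeric(0), class_control = character(0),
             bias_stress = numeric(0), class_stress = character(0),
             chi2_stat = numeric(0), df = integer(0), p_value = numeric(0),
             low_expected = logical(0),
             top_control = character(0), top_stress = character(0),
             tie_control = logical(0), tie_stress = logical(0),
             rank_switch = logical(0), delta = numeric(0),
             effect_class = character(0), q_value = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' @export
print.ase_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ASE contrast %s vs %s: %d quartets\n",
              x$contrast[1], x$contrast[2], s$n_quartets))
  cat(sprintf("  dominance (%s): %d balanced / %d mild / %d strong\n",
              x$contrast[1], s$control_balanced, s$control_mild, s$control_strong))
  cat(sprintf("  dominance (%s): %d balanced / %d mild / %d strong\n",
              x$contrast[2], s$stress_balanced, s$stress_mild, s$stress_strong))
  cat(sprintf("  rank switches: %d (delta >= 0.10: %d; >= 0.20: %d)\n",
              s$n_rank_switch, s$n_delta_ge_10, s$n_delta_ge_20))
  cat(sprintf("  significant haplotype-ratio shifts (q < %.2f): %d\n",
              s$q_threshold, s$n_significant))
  invisible(x)
}

#' @export
summary.ase_result <- function(object, ...) object$summary
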