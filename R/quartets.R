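#' Haplotype label from a chromosome identifier
#'
#' In a haplotype-resolved autotetraploid assembly each chromosome carries a
#' trailing letter a-d naming its haplotype (e.g. `chr1a` ... `chr7d`).
#' Identifiers ending in `un` (unanchored, chromosome-associated scaffolds)
#' or with any other suffix are UNPLACED. The rule is case-insensitive and
#' total: no input raises an error.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @return Character vector with values `"A"`, `"B"`, `"C"`, `"D"` or
#'   `"UNPLACED"`.
#' @export
#' @examples
#' haplotype_of(c("chr1a", "chr7d", "chr5un"))
haplotype_of <- function(chrom) {
  chrom <- as.character(chrom)
  out <- rep("UNPLACED", length(chrom))
  lc <- tolower(chrom)
  un <- !is.na(lc) & grepl("un$", lc)
  last <- substring(lc, nchar(lc))
  ok <- !is.na(lc) & nzchar(lc) & !un & last %in% c("a", "b", "c", "d")
  out[ok] <- toupper(last[ok])
  out
}

#' Classify allelic retention of orthogroups
#'
#' Counts orthogroups as tetra-, tri-, bi- or mono-allelic by the number of
#' haplotypes contributing members. Two modes:
#' \describe{
#'   \item{strict}{only orthogroups with no within-haplotype duplicates are
#'     counted (every non-empty haplotype list has exactly one member); the
#'     class is the number of non-empty haplotypes.}
#'   \item{lenient}{within-haplotype duplicates are tolerated; every
#'     orthogroup with at least one member is counted and the class is the
#'     number of haplotypes with at least one member.}
#' }
#' Orthogroups with no members at all are excluded in both modes.
#'
#' @param og An `orthogroup_table`.
#' @param mode `"strict"` or `"lenient"`.
#' @return A `retention_summary`: list with `mode`, `n_orthogroups`, named
#'   integer `counts` (tetra/tri/bi/mono) and `proportions`.
#' @export
classify_retention <- function(og, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  arities <- cbind(lengths(og$A), lengths(og$B), lengths(og$C), lengths(og$D))
  nonempty <- rowSums(arities > 0L)
  keep <- if (mode == "strict") {
    nonempty > 0L & apply(arities, 1L, function(a) all(a[a > 0L] == 1L))
  } else {
    nonempty > 0L
  }
  cls <- nonempty[keep]
  counts <- c(tetra = sum(cls == 4L), tri = sum(cls == 3L),
              bi = sum(cls == 2L), mono = sum(cls == 1L))
  n <- sum(counts)
  out <- list(mode = mode, n_orthogroups = n, counts = counts,
              proportions = if (n > 0) counts / n else counts * NA_real_)
  class(out) <- "retention_summary"
  out
}

#' @export
print.retention_summary <- function(x, ...) {
  cat(sprintf("Allelic retention (%s mode), n = %d orthogroups\n",
              x$mode, x$n_orthogroups))
  for (k in names(x$counts))
    cat(sprintf("  %-5s %6d  (%.1f%%)\n", k, x$counts[[k]],
                100 * x$proportions[[k]]))
  invisible(x)
}

#' Select 1:1:1:1 haplotype quartets
#'
#' Returns exactly the orthogroups that have one gene on each of the four
#' haplotypes, in input order. These quartets are the unit of allele-specific
#' expression analysis.
#'
#' @param og An `orthogroup_table`.
#' @return A data.frame with columns `orthogroup_id`, `A`, `B`, `C`, `D`
#'   (one gene id each).
#' @export
select_quartets <- function(og) {
  keep <- lengths(og$A) == 1L & lengths(og$B) == 1L &
    lengths(og$C) == 1L & lengths(og$D) == 1L
  pull <- function(col) as.character(unlist(og[[col]][keep], use.names = FALSE))
  data.frame(orthogroup_id = og$orthogroup_id[keep],
             A = pull("A"), B = pull("B"), C = pull("C"), D = pull("D"),
             stringsAsFactors = FALSE)
}

#' Read-support filter thresholds for quartets
#'
#' Defaults follow the read-support rule used for haplotype quartets:
#' at least 50 total reads across haplotypes, at least 20 reads per
#' condition, at least 10 reads per gene, and at least 2 replicates with
#' detectable expression (quartet-level count >= `detect_count`) in each
#' condition.
#'
#' @param min_total_reads Grand total across the 4 genes and all contrast
#'   samples.
#' @param min_reads_per_condition Per-condition total across the 4 genes.
#' @param min_reads_per_gene Per-gene total (scope set in
#'   [filter_quartets()]).
#' @param min_detected_replicates Replicates per condition that must reach
#'   `detect_count` at quartet level.
#' @param detect_count Quartet-level count defining a "detectable" replicate.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_total_reads = 50L,
                              min_reads_per_condition = 20L,
                              min_reads_per_gene = 10L,
                              min_detected_replicates = 2L,
                              detect_count = 1L) {
  thr <- list(min_total_reads = as.integer(min_total_reads),
              min_reads_per_condition = as.integer(min_reads_per_condition),
              min_reads_per_gene = as.integer(min_reads_per_gene),
              min_detected_replicates = as.integer(min_detected_replicates),
              detect_count = as.integer(detect_count))
  if (any(vapply(thr, function(v) is.na(v) || v < 0L, logical(1))))
    stop("all thresholds must be non-negative integers")
  class(thr) <- "filter_thresholds"
  thr
}

#' Filter quartets by read support
#'
#' Evaluates, per quartet and per contrast (control vs one stress), the four
#' read-support rules: (F1) grand total across the 4 genes and all contrast
#' samples >= `min_total_reads`; (F2) per-condition total >=
#' `min_reads_per_condition` in every contrast condition; (F3) per-gene total
#' >= `min_reads_per_gene` for each of the 4 genes (summed over all contrast
#' samples, or per condition with `per_gene_scope = "per-condition"`);
#' (F4) in every condition at least `min_detected_replicates` replicates have
#' quartet-level count >= `detect_count`. A quartet is kept iff all four
#' rules hold.
#'
#' @param quartets Data.frame from [select_quartets()].
#' @param counts Integer count matrix (genes x samples).
#' @param samples Sample sheet data.frame.
#' @param thresholds A [filter_thresholds()] object.
#' @param conditions Character vector of the contrast's condition labels;
#'   default: all conditions in `samples`.
#' @param per_gene_scope `"overall"` (default) or `"per-condition"` scope of
#'   the per-gene rule.
#' @return List with `kept` (subset of `quartets`) and `report` (data.frame
#'   with logical columns F1-F4 and `keep`).
#' @export
filter_quartets <- function(quartets, counts, samples,
                            thresholds = filter_thresholds(),
                            conditions = NULL,
                            per_gene_scope = c("overall", "per-condition")) {
  per_gene_scope <- match.arg(per_gene_scope)
  if (is.null(conditions)) conditions <- unique(samples$condition)
  if (length(conditions) < 2L)
    stop("samples must cover at least 2 conditions")
  samples <- samples[samples$condition %in% conditions, , drop = FALSE]
  genes <- c(t(as.matrix(quartets[, c("A", "B", "C", "D")])))
  missing <- setdiff(genes, rownames(counts))
  if (length(missing))
    stop("quartet gene(s) missing from counts matrix: ",
         paste(missing, collapse = ", "))

  nq <- nrow(quartets)
  rep_f <- data.frame(orthogroup_id = quartets$orthogroup_id,
                      F1 = logical(nq), F2 = logical(nq),
                      F3 = logical(nq), F4 = logical(nq),
                      stringsAsFactors = FALSE)
  cond_samples <- split(samples$sample_id, samples$condition)[conditions]
  for (i in seq_len(nq)) {
    g <- as.character(quartets[i, c("A", "B", "C", "D")])
    sub <- counts[g, samples$sample_id, drop = FALSE]
    rep_f$F1[i] <- sum(sub) >= thresholds$min_total_reads
    cond_tot <- vapply(cond_samples, function(s) sum(sub[, s, drop = FALSE]),
                       numeric(1))
    rep_f$F2[i] <- all(cond_tot >= thresholds$min_reads_per_condition)
    if (per_gene_scope == "overall") {
      rep_f$F3[i] <- all(rowSums(sub) >= thresholds$min_reads_per_gene)
    } else {
      per_cond_gene <- vapply(cond_samples,
                              function(s) rowSums(sub[, s, drop = FALSE]),
                              numeric(4))
      rep_f$F3[i] <- all(per_cond_gene >= thresholds$min_reads_per_gene)
    }
    detected <- vapply(cond_samples, function(s) {
      sum(colSums(sub[, s, drop = FALSE]) >= thresholds$detect_count)
    }, numeric(1))
    rep_f$F4[i] <- all(detected >= thresholds$min_detected_replicates)
  }
  rep_f$keep <- rep_f$F1 & rep_f$F2 & rep_f$F3 & rep_f$F4
  list(kept = quartets[rep_f$keep, , drop = FALSE], report = rep_f)
}
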