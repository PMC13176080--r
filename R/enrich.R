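#' One-sided hypergeometric tail p-value for a 2x2 over-representation table
#'
#' Probability of observing at least `k` annotated genes in a study set of
#' size `n` drawn from a population of size `N` containing `K` annotated
#' genes (the upper tail of the hypergeometric distribution, i.e. the
#' one-sided Fisher's exact p-value for over-representation).
#'
#' @param k,n,K,N Table margins (vectorized).
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_p <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact over-representation of functional terms
#'
#' For each term annotated to at least `min_k` study genes, builds the 2x2
#' table of study/non-study vs annotated/non-annotated genes, computes the
#' one-sided (over-representation) Fisher's exact p-value, the sample odds
#' ratio `k (N - n - K + k) / ((n - k)(K - k))` (reported as `Inf` when a
#' denominator cell is zero), and BH-adjusts p across the tested terms.
#' Rows are sorted by q then p.
#'
#' The population should normally be the set of genes that survived the
#' relevant expression filter, not the whole annotation, to guard against
#' detection bias.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param terms Named list mapping gene id -> character vector of term ids
#'   (see [read_term_map()]).
#' @param min_k Minimum study count for a term to be tested (default 1).
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`.
#' @return Data.frame with columns `term`, `k`, `n`, `K`, `N`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(study, population, terms, min_k = 1,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  study <- unique(study); population <- unique(population)
  off <- setdiff(study, population)
  if (length(off))
    stop("study gene(s) not in population: ", paste(off, collapse = ", "))
  n <- length(study); N <- length(population)

  gene_terms <- terms[intersect(names(terms), population)]
  t2g <- split(rep(names(gene_terms), lengths(gene_terms)),
               unlist(gene_terms, use.names = FALSE))
  if (!length(t2g))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE))
  Kv <- lengths(t2g)
  kv <- vapply(t2g, function(g) length(intersect(g, study)), integer(1))
  keep <- kv >= min_k
  term <- names(t2g)[keep]; Kv <- Kv[keep]; kv <- kv[keep]

  p <- if (alternative == "greater") {
    fisher_p(kv, n, Kv, N)
  } else {
    mapply(function(k, K) {
      stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2L),
                         alternative = "two.sided")$p.value
    }, kv, Kv)
  }
  num <- kv * (N - n - Kv + kv)
  den <- (n - kv) * (Kv - kv)
  or <- ifelse(den == 0, Inf, num / den)
  out <- data.frame(term = term, k = as.integer(kv), n = n,
                    K = as.integer(Kv), N = N, odds_ratio = or,
                    p_value = p, q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
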