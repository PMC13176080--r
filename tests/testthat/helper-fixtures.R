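# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# tiny counts matrix with explicit values, genes x samples
mk_counts <- function(values, genes, samples) {
  matrix(as.integer(values), nrow = length(genes), ncol = length(samples),
         byrow = TRUE, dimnames = list(genes, samples))
}

mk_samples <- function(conditions, n_rep = 4L, tissue = "leaf") {
  data.frame(
    sample_id = as.vector(t(outer(conditions, seq_len(n_rep),
                                  function(cc, r) paste0(cc, "_rep", r)))),
    condition = rep(conditions, each = n_rep),
    tissue = tissue,
    replicate = rep(seq_len(n_rep), times = length(conditions)),
    stringsAsFactors = FALSE)
}

# orthogroup table from a named list of 4-element gene-list lists
mk_og <- function(rows) {
  og <- data.frame(orthogroup_id = names(rows), stringsAsFactors = FALSE)
  for (h in 1:4)
    og[[LETTERS[h]]] <- I(lapply(rows, function(r) as.character(r[[h]])))
  class(og) <- c("orthogroup_table", "data.frame")
  og
}

# Crafted 12-quartet read-support fixture: per-quartet 4 x 8 count blocks
# (2 conditions x 4 replicates) chosen to exercise every filter rule and
# several boundary cases. Returns list(quartets, counts, samples).
mk_filter_fixture <- function() {
  samples <- mk_samples(c("control", "stress"))
  blocks <- list(
    # q1: all zero -> fails everything
    matrix(0L, 4, 8),
    # q2: healthy, all cells 10
    matrix(10L, 4, 8),
    # q3: grand total 48 (< 50), balanced otherwise
    matrix(c(rep(2L, 8), rep(2L, 8), rep(1L, 8), rep(1L, 8)), 4, 8, byrow = TRUE),
    # q4: control total 16 (< 20), stress rich
    cbind(matrix(1L, 4, 4), matrix(10L, 4, 4)),
    # q5: gene D starved (total 8 < 10), others rich
    rbind(matrix(10L, 3, 8), matrix(1L, 1, 8)),
    # q6: detection boundary from the rule's definition: control replicate
    # quartet totals (30,30,0,0), stress (30,30,30,30); per-gene totals >= 10
    cbind(matrix(c(10L, 10L, 5L, 5L), 4, 2), matrix(0L, 4, 2),
          matrix(c(10L, 10L, 5L, 5L), 4, 4)),
    # q7: only 1 detected replicate in control
    cbind(matrix(c(20L, 20L, 10L, 10L), 4, 1), matrix(0L, 4, 3),
          matrix(5L, 4, 4)),
    # q8: per-condition gene starvation: gene A has 12 reads overall but
    # only in control (0 in stress) -> per-condition scope differs
    rbind(cbind(matrix(3L, 1, 4), matrix(0L, 1, 4)), matrix(5L, 3, 8)),
    # q9: exactly at every default threshold
    {
      b <- matrix(0L, 4, 8)
      b[1, ] <- c(5L, 5L, 0L, 0L, 5L, 5L, 0L, 0L)   # gene A: 10+10
      b[2, ] <- c(5L, 5L, 0L, 0L, 5L, 5L, 0L, 0L)
      b[3, ] <- c(0L, 0L, 5L, 5L, 0L, 0L, 5L, 5L)
      b[4, ] <- c(0L, 0L, 5L, 5L, 0L, 0L, 5L, 5L)
      b
    },
    # q10-q12: pseudo-random marginal blocks
    NULL, NULL, NULL)
  set.seed(42)
  for (k in 10:12)
    blocks[[k]] <- matrix(as.integer(sample(0:8, 32, replace = TRUE)), 4, 8)

  genes <- as.vector(t(outer(sprintf("Q%02d", 1:12), c("a", "b", "c", "d"),
                             paste, sep = "_")))
  counts <- do.call(rbind, blocks)
  dimnames(counts) <- list(genes, samples$sample_id)
  storage.mode(counts) <- "integer"
  quartets <- data.frame(orthogroup_id = sprintf("Q%02d", 1:12),
                         A = genes[seq(1, 48, 4)], B = genes[seq(2, 48, 4)],
                         C = genes[seq(3, 48, 4)], D = genes[seq(4, 48, 4)],
                         stringsAsFactors = FALSE)
  list(quartets = quartets, counts = counts, samples = samples)
}

# Independent brute-force evaluation of the four read-support rules,
# written as direct loops over the count matrix (no shared code with
# filter_quartets).
brute_force_filter <- function(quartets, counts, samples, thr,
                               per_gene_scope = "overall") {
  conds <- unique(samples$condition)
  keep <- logical(nrow(quartets))
  for (i in seq_len(nrow(quartets))) {
    g <- as.character(quartets[i, c("A", "B", "C", "D")])
    grand <- 0
    ok <- TRUE
    for (gg in g) for (s in samples$sample_id) grand <- grand + counts[gg, s]
    if (grand < thr$min_total_reads) ok <- FALSE
    for (cc in conds) {
      ss <- samples$sample_id[samples$condition == cc]
      ctot <- 0
      for (gg in g) for (s in ss) ctot <- ctot + counts[gg, s]
      if (ctot < thr$min_reads_per_condition) ok <- FALSE
    }
    for (gg in g) {
      if (per_gene_scope == "overall") {
        gtot <- 0
        for (s in samples$sample_id) gtot <- gtot + counts[gg, s]
        if (gtot < thr$min_reads_per_gene) ok <- FALSE
      } else {
        for (cc in conds) {
          ss <- samples$sample_id[samples$condition == cc]
          gtot <- 0
          for (s in ss) gtot <- gtot + counts[gg, s]
          if (gtot < thr$min_reads_per_gene) ok <- FALSE
        }
      }
    }
    for (cc in conds) {
      ss <- samples$sample_id[samples$condition == cc]
      det <- 0
      for (s in ss) {
        qtot <- 0
        for (gg in g) qtot <- qtot + counts[gg, s]
        if (qtot >= thr$detect_count) det <- det + 1
      }
      if (det < thr$min_detected_replicates) ok <- FALSE
    }
    keep[i] <- ok
  }
  keep
}

# Independent per-orthogroup retention classification (exhaustive, one
# orthogroup at a time).
brute_force_retention <- function(og, mode) {
  counts <- c(tetra = 0L, tri = 0L, bi = 0L, mono = 0L)
  for (i in seq_len(nrow(og))) {
    sizes <- c(length(og$A[[i]]), length(og$B[[i]]),
               length(og$C[[i]]), length(og$D[[i]]))
    if (sum(sizes) == 0L) next
    if (mode == "strict" && any(sizes > 1L)) next
    cls <- sum(sizes > 0L)
    key <- c("mono", "bi", "tri", "tetra")[cls]
    counts[key] <- counts[key] + 1L
  }
  counts[c("tetra", "tri", "bi", "mono")]
}

# Textbook step-up BH, written independently of stats::p.adjust.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (pos in seq_len(m)) {
    i <- o[pos]
    cand <- Inf
    for (pos2 in pos:m) {
      j <- o[pos2]
      cand <- min(cand, m * p[j] / pos2)
    }
    q[i] <- min(1, cand)
  }
  q
}
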