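#' Configuration for haplotype-quartet count simulation
#'
#' The generator emulates the statistical structure the quartet ASE analysis
#' assumes: per quartet and condition a true haplotype-proportion vector is
#' drawn from a Dirichlet distribution; each biological replicate's quartet
#' total is negative-binomial and is split multinomially across the four
#' haplotype genes by the condition's true proportions. Planted effect
#' classes tilt the Dirichlet towards dominance (mild/strong) or move the
#' top haplotype between conditions (switch) by `delta_planted` in
#' max-allele proportion.
#'
#' Defaults: 4 biological replicates per condition; mean quartet depth 500
#' reads per replicate so the read-support filters are typically passed;
#' negative-binomial dispersion 0.1 (overdispersed library totals);
#' symmetric Dirichlet total concentration 200, under which unplanted
#' quartets are balanced; planted fractions 3% strong dominance (matching
#' the observed 2.6-3.0% share of strongly dominant quartets), 10% mild,
#' 10% switch with `delta_planted = 0.30`.
#'
#' @param n_quartets Number of quartets.
#' @param n_replicates Replicates per condition.
#' @param conditions Two or more condition labels; the first is the control.
#' @param depth_mean,depth_dispersion NB parameters of the per-replicate
#'   quartet total (dispersion 0 gives Poisson totals).
#' @param concentration Total Dirichlet concentration for balanced quartets.
#' @param frac_strong_bias,frac_mild_bias,frac_switch Planted-class
#'   fractions (must sum to at most 1).
#' @param delta_planted Planted change in max-allele proportion for switch
#'   quartets.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A list of class `quartet_sim_config`.
#' @export
quartet_sim_config <- function(n_quartets = 1000L, n_replicates = 4L,
                               conditions = c("control", "stress"),
                               depth_mean = 500, depth_dispersion = 0.1,
                               concentration = 200,
                               frac_strong_bias = 0.03, frac_mild_bias = 0.10,
                               frac_switch = 0.10, delta_planted = 0.30,
                               seed = 1L) {
  cfg <- list(n_quartets = as.integer(n_quartets),
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              concentration = concentration,
              frac_strong_bias = frac_strong_bias,
              frac_mild_bias = frac_mild_bias,
              frac_switch = frac_switch,
              delta_planted = delta_planted,
              seed = as.integer(seed))
  if (cfg$n_quartets < 0L) stop("n_quartets must be non-negative")
  if (cfg$n_replicates < 1L) stop("need at least 1 replicate per condition")
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$depth_dispersion < 0) stop("depth_dispersion must be non-negative")
  if (cfg$concentration <= 0) stop("concentration must be positive")
  fr <- c(frac_strong_bias, frac_mild_bias, frac_switch)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("planted fractions must lie in [0,1] and sum to at most 1")
  if (delta_planted < 0 || delta_planted > 0.6)
    stop("delta_planted must lie in [0, 0.6]")
  class(cfg) <- "quartet_sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# draw a tilted Dirichlet proportion vector satisfying `accept`, falling
# back to the exact target after max_try rejections
draw_tilted <- function(target, alpha0, accept, max_try = 200L) {
  for (i in seq_len(max_try)) {
    p <- rdirichlet1(alpha0 * target)
    if (accept(p)) return(p)
  }
  target
}

nb_total <- function(n, mu, disp) {
  if (disp < 1e-12) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / disp)
}

#' Simulate haplotype-quartet count data with ground truth
#'
#' Generates a full input set for the quartet ASE pipeline — count matrix,
#' sample sheet, 1:1:1:1 orthogroup table, gene-to-chromosome map — plus a
#' truth table recording each quartet's planted class, true per-condition
#' proportion vectors, true bias and true delta. Gene ids follow
#' `OVQ{k}_{a-d}` and chromosomes `chr{1-7}{a-d}` round-robin.
#'
#' With `arity_noise`, stated fractions of orthogroups are degraded to
#' tri/bi/mono-allelic groups (genes dropped from the orthogroup table) or
#' given a within-haplotype duplicate gene, for allelic-retention tests; the
#' truth table's `arity_class` column records the planted arity.
#'
#' @param cfg A [quartet_sim_config()].
#' @param arity_noise Optional list with fractions `tri`, `bi`, `mono`,
#'   `dup` (defaults 0).
#' @return List with `counts`, `samples`, `orthogroups`, `gene_map`,
#'   `truth`.
#' @export
simulate_quartets <- function(cfg, arity_noise = NULL) {
  stopifnot(inherits(cfg, "quartet_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_quartets
  conds <- cfg$conditions
  haps <- c("a", "b", "c", "d")

  samples <- data.frame(
    sample_id = as.vector(t(outer(conds, seq_len(cfg$n_replicates),
                                  function(cc, r) paste0(cc, "_rep", r)))),
    condition = rep(conds, each = cfg$n_replicates),
    tissue = "leaf",
    replicate = rep(seq_len(cfg$n_replicates), times = length(conds)),
    stringsAsFactors = FALSE)
  class(samples) <- c("sample_sheet", "data.frame")

  og_ids <- if (n) sprintf("OVQ%d", seq_len(n)) else character(0)
  gene_ids <- if (n) as.vector(t(outer(og_ids, haps, paste, sep = "_"))) else character(0)
  chrom_num <- if (n) ((seq_len(n) - 1L) %% 7L) + 1L else integer(0)

  # planted class assignment
  n_strong <- round(cfg$frac_strong_bias * n)
  n_mild <- round(cfg$frac_mild_bias * n)
  n_switch <- round(cfg$frac_switch * n)
  if (n_strong + n_mild + n_switch > n)
    stop("planted fractions are infeasible for n_quartets")
  classes <- rep("balanced", n)
  planted_idx <- if (n) sample.int(n, n_strong + n_mild + n_switch) else integer(0)
  classes[planted_idx[seq_len(n_strong)]] <- "strong"
  classes[planted_idx[n_strong + seq_len(n_mild)]] <- "mild"
  classes[planted_idx[n_strong + n_mild + seq_len(n_switch)]] <- "switch"

  counts <- matrix(0L, nrow = 4L * n, ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  p_ctrl <- matrix(NA_real_, n, 4L)
  p_strs <- matrix(NA_real_, n, 4L)

  for (k in seq_len(n)) {
    cls <- classes[k]
    if (cls == "balanced") {
      p <- rdirichlet1(rep(cfg$concentration / 4, 4L))
      pc <- p; ps <- p
    } else if (cls == "mild") {
      h <- sample.int(4L, 1L)
      target <- rep(0.5 / 3, 4L); target[h] <- 0.5
      p <- draw_tilted(target, 400, function(p) {
        b <- max(p) - min(p); b >= 0.25 && b <= 0.5 && which.max(p) == h
      })
      pc <- p; ps <- p
    } else if (cls == "strong") {
      h <- sample.int(4L, 1L)
      target <- rep(0.10, 4L); target[h] <- 0.70
      p <- draw_tilted(target, 400, function(p) {
        max(p) - min(p) >= 0.55 && which.max(p) == h
      })
      pc <- p; ps <- p
    } else { # switch: top haplotype moves, max proportion changes by delta
      h1 <- sample.int(4L, 1L)
      h2 <- sample(setdiff(seq_len(4L), h1), 1L)
      target <- rep(0.68 / 3, 4L); target[h1] <- 0.32
      pc <- draw_tilted(target, 400, function(p) {
        which.max(p) == h1 && max(p) + cfg$delta_planted <= 0.95
      })
      ms <- max(pc) + cfg$delta_planted
      ps <- numeric(4L)
      ps[h2] <- ms
      rest <- setdiff(seq_len(4L), h2)
      ps[rest] <- pc[rest] / sum(pc[rest]) * (1 - ms)
    }
    p_ctrl[k, ] <- pc
    p_strs[k, ] <- ps
    rows <- 4L * (k - 1L) + seq_len(4L)
    for (ci in seq_along(conds)) {
      p_use <- if (ci == 1L) pc else ps
      for (r in seq_len(cfg$n_replicates)) {
        col <- (ci - 1L) * cfg$n_replicates + r
        tot <- nb_total(1L, cfg$depth_mean, cfg$depth_dispersion)
        counts[rows, col] <- as.integer(stats::rmultinom(1L, tot, p_use))
      }
    }
  }

  og <- data.frame(orthogroup_id = og_ids, stringsAsFactors = FALSE)
  for (h in seq_len(4L))
    og[[LETTERS[h]]] <- I(lapply(seq_len(n), function(k) gene_ids[4L * (k - 1L) + h]))
  if (n == 0L) for (h in LETTERS[1:4]) og[[h]] <- I(list())
  class(og) <- c("orthogroup_table", "data.frame")

  gene_map <- data.frame(
    gene_id = gene_ids,
    chromosome = if (n) paste0("chr", rep(chrom_num, each = 4L), rep(haps, n))
                 else character(0),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    orthogroup_id = og_ids, class = classes,
    pA_control = p_ctrl[, 1L], pB_control = p_ctrl[, 2L],
    pC_control = p_ctrl[, 3L], pD_control = p_ctrl[, 4L],
    pA_stress = p_strs[, 1L], pB_stress = p_strs[, 2L],
    pC_stress = p_strs[, 3L], pD_stress = p_strs[, 4L],
    true_bias_control = apply(p_ctrl, 1L, function(p) max(p) - min(p)),
    true_bias_stress = apply(p_strs, 1L, function(p) max(p) - min(p)),
    true_delta = abs(apply(p_strs, 1L, max) - apply(p_ctrl, 1L, max)),
    true_switch = apply(p_strs, 1L, which.max) != apply(p_ctrl, 1L, which.max),
    arity_class = rep("quartet", n),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    truth <- truth[0L, , drop = FALSE]
    truth$true_bias_control <- numeric(0); truth$true_bias_stress <- numeric(0)
    truth$true_delta <- numeric(0); truth$true_switch <- logical(0)
  }

  out <- list(counts = counts, samples = samples, orthogroups = og,
              gene_map = gene_map, truth = truth)
  if (!is.null(arity_noise)) out <- apply_arity_noise(out, arity_noise, cfg)
  out
}

apply_arity_noise <- function(sim, arity_noise, cfg) {
  fr <- utils::modifyList(list(tri = 0, bi = 0, mono = 0, dup = 0),
                          as.list(arity_noise))
  n <- nrow(sim$orthogroups)
  n_tri <- round(fr$tri * n); n_bi <- round(fr$bi * n)
  n_mono <- round(fr$mono * n); n_dup <- round(fr$dup * n)
  if (n_tri + n_bi + n_mono + n_dup > n)
    stop("arity-noise fractions are infeasible")
  idx <- sample.int(n, n_tri + n_bi + n_mono + n_dup)
  plan <- rep(c("tri", "bi", "mono", "dup"),
              times = c(n_tri, n_bi, n_mono, n_dup))
  og <- sim$orthogroups
  extra_rows <- list()
  for (j in seq_along(idx)) {
    k <- idx[j]
    if (plan[j] == "dup") {
      h <- sample.int(4L, 1L)
      newg <- paste0(og$orthogroup_id[k], "_", letters[h], "2")
      og[[LETTERS[h]]][[k]] <- c(og[[LETTERS[h]]][[k]], newg)
      extra <- nb_total(ncol(sim$counts), cfg$depth_mean / 10, cfg$depth_dispersion)
      extra_rows[[newg]] <- as.integer(extra)
      sim$gene_map <- rbind(sim$gene_map,
                            data.frame(gene_id = newg,
                                       chromosome = sim$gene_map$chromosome[
                                         sim$gene_map$gene_id == paste0(og$orthogroup_id[k], "_", letters[h])],
                                       stringsAsFactors = FALSE))
    } else {
      drop_n <- switch(plan[j], tri = 1L, bi = 2L, mono = 3L)
      drop_h <- sample.int(4L, drop_n)
      for (h in drop_h) og[[LETTERS[h]]][[k]] <- character(0)
    }
    sim$truth$arity_class[k] <- plan[j]
  }
  if (length(extra_rows)) {
    add <- do.call(rbind, extra_rows)
    rownames(add) <- names(extra_rows)
    colnames(add) <- colnames(sim$counts)
    sim$counts <- rbind(sim$counts, add)
  }
  sim$orthogroups <- og
  sim
}

#' Simulate a null condition contrast
#'
#' Identical to [simulate_quartets()] with no switch class: every quartet's
#' true proportion vector is shared between the two conditions, so the true
#' delta is 0 everywhere and the chi-square contrast's null holds exactly.
#' Dominance classes may still be planted (they do not differ between
#' conditions).
#'
#' @param cfg A [quartet_sim_config()]; `frac_switch` is forced to 0.
#' @return As [simulate_quartets()].
#' @export
simulate_null_contrast <- function(cfg) {
  cfg$frac_switch <- 0
  simulate_quartets(cfg)
}

#' Configuration for tissue-atlas count simulation
#'
#' Emulates a multi-tissue expression atlas: per gene a baseline mean is
#' drawn log-normally around `baseline_mean` (sdlog 1, the typical spread of
#' expression levels), counts are negative-binomial per tissue/replicate,
#' and a planted fraction of genes has one tissue's mean multiplied by
#' `2^planted_lfc`. Stable genes have Poisson noise (dispersion ~ 0) and no
#' tissue effect. Defaults follow the study design: the nine sampled
#' tissues, 4 replicates each.
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue labels.
#' @param n_replicates Replicates per tissue.
#' @param baseline_mean Median gene baseline mean count.
#' @param nb_dispersion NB dispersion alpha for ordinary genes.
#' @param frac_enriched Fraction of genes with one tissue up by
#'   `planted_lfc`.
#' @param planted_lfc Planted log2 fold-change (> 0).
#' @param frac_stable Fraction of low-variance (Poisson) genes.
#' @param seed Integer seed.
#' @return A list of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(n_genes = 1000L,
                             tissues = names(default_tissue_scheme()),
                             n_replicates = 4L, baseline_mean = 100,
                             nb_dispersion = 0.05, frac_enriched = 0.1,
                             planted_lfc = 2.0, frac_stable = 0.05,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), tissues = tissues,
              n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
              frac_enriched = frac_enriched, planted_lfc = planted_lfc,
              frac_stable = frac_stable, seed = as.integer(seed))
  if (cfg$n_genes < 0L) stop("n_genes must be non-negative")
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  if (cfg$baseline_mean <= 0) stop("baseline_mean must be positive")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (frac_enriched < 0 || frac_stable < 0 || frac_enriched + frac_stable > 1)
    stop("fractions must be non-negative and sum to at most 1")
  if (planted_lfc <= 0) stop("planted_lfc must be positive")
  class(cfg) <- "atlas_sim_config"
  cfg
}

#' Simulate tissue-atlas count data with ground truth
#'
#' @param cfg An [atlas_sim_config()].
#' @return List with `counts`, `samples`, `truth` (per gene: `base_mean`,
#'   `class` in balanced/enriched/stable, `enriched_tissue`, `planted_lfc`,
#'   `stable`).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "atlas_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  tis <- cfg$tissues
  slug <- gsub("[^A-Za-z0-9]+", "_", tis)
  samples <- data.frame(
    sample_id = as.vector(t(outer(slug, seq_len(cfg$n_replicates),
                                  function(s, r) paste0(s, "_rep", r)))),
    condition = "atlas",
    tissue = rep(tis, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(tis)),
    stringsAsFactors = FALSE)
  class(samples) <- c("sample_sheet", "data.frame")

  genes <- if (n) sprintf("G%04d", seq_len(n)) else character(0)
  n_enr <- round(cfg$frac_enriched * n)
  n_stab <- round(cfg$frac_stable * n)
  classes <- rep("balanced", n)
  pick <- if (n) sample.int(n, n_enr + n_stab) else integer(0)
  classes[pick[seq_len(n_enr)]] <- "enriched"
  classes[pick[n_enr + seq_len(n_stab)]] <- "stable"

  base_mean <- stats::rlnorm(n, meanlog = log(cfg$baseline_mean), sdlog = 1)
  enr_tissue <- rep(NA_character_, n)
  enr_tissue[classes == "enriched"] <- sample(tis, sum(classes == "enriched"),
                                              replace = TRUE)

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (g in seq_len(n)) {
    mu_t <- rep(base_mean[g], length(tis))
    if (classes[g] == "enriched")
      mu_t[tis == enr_tissue[g]] <- base_mean[g] * 2^cfg$planted_lfc
    disp <- if (classes[g] == "stable") 0 else cfg$nb_dispersion
    mu_rep <- rep(mu_t, each = cfg$n_replicates)
    counts[g, ] <- as.integer(nb_total(length(mu_rep), mu_rep, disp))
  }

  truth <- data.frame(gene_id = genes, base_mean = base_mean,
                      class = classes, enriched_tissue = enr_tissue,
                      planted_lfc = ifelse(classes == "enriched",
                                           cfg$planted_lfc, 0),
                      stable = classes == "stable",
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth)
}
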