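#' Read a gene-by-sample count matrix from TSV
#'
#' The file must be tab-separated with a header row naming the samples and a
#' first column of gene identifiers. Counts must be non-negative integers:
#' fractional quantifier output (e.g. multi-mapping-aware estimates) is
#' rejected rather than rounded, because the downstream chi-square and
#' negative-binomial models assume true counts. Row and column order are
#' preserved from the file.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("counts file must have a gene-id column plus at least one sample column")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in counts file: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s) in counts file: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad))
      stop(sprintf("invalid count '%s' at gene '%s', sample '%s': counts must be non-negative integers",
                   raw[bad[1L]], genes[bad[1L]], samples[j]))
    m[, j] <- as.integer(num)
  }
  validate_counts(m)
  m
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts_tsv()]: tab-separated, UTF-8, Unix newlines,
#' first column `gene_id`.
#'
#' @param counts Integer matrix (genes x samples).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con, sep = "\n")
  lines <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], format(counts[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

validate_counts <- function(m) {
  if (!is.matrix(m)) stop("counts must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in counts matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in counts matrix")
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers")
  invisible(m)
}

#' Read an orthogroup table (pseudo-species dialect)
#'
#' Reads the tab-separated orthogroup layout in which the first column is the
#' orthogroup id and one column per haplotype pseudo-species (A-D) holds a
#' comma-separated gene list ("g1, g2"; a plain comma without the space is
#' also accepted). Empty cells denote haplotypes with no members.
#'
#' @param path Path to the TSV file.
#' @param haplotype_cols Character vector of length 4 naming the columns that
#'   hold haplotypes A-D, in that order. Defaults to columns named
#'   `A`,`B`,`C`,`D` if present, otherwise the 2nd-5th columns of the file.
#' @return A data.frame of class `orthogroup_table` with columns
#'   `orthogroup_id` and list-columns `A`,`B`,`C`,`D`.
#' @export
read_orthogroups_tsv <- function(path, haplotype_cols = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 5L)
    stop("orthogroup file must have an id column plus 4 pseudo-species columns; found ",
         ncol(df) - 1L)
  if (is.null(haplotype_cols)) {
    haplotype_cols <- if (all(c("A", "B", "C", "D") %in% colnames(df)))
      c("A", "B", "C", "D") else colnames(df)[2:5]
  }
  if (length(haplotype_cols) != 4L || !all(haplotype_cols %in% colnames(df)))
    stop("haplotype_cols must name 4 columns present in the file")
  og <- data.frame(orthogroup_id = df[[1L]], stringsAsFactors = FALSE)
  if (anyDuplicated(og$orthogroup_id))
    stop("duplicate orthogroup id(s): ",
         paste(unique(og$orthogroup_id[duplicated(og$orthogroup_id)]), collapse = ", "))
  for (h in seq_len(4L)) {
    og[[LETTERS[h]]] <- I(lapply(df[[haplotype_cols[h]]], split_gene_cell))
  }
  all_genes <- unlist(c(og$A, og$B, og$C, og$D), use.names = FALSE)
  reps <- rep(og$orthogroup_id, lengths(og$A) + lengths(og$B) + lengths(og$C) + lengths(og$D))
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup)) {
    # a gene may not be listed under two orthogroups
    owners <- unique(reps[all_genes %in% dup])
    stop("gene(s) listed in more than one orthogroup: ",
         paste(unique(dup), collapse = ", "),
         " (orthogroups ", paste(owners, collapse = ", "), ")")
  }
  class(og) <- c("orthogroup_table", "data.frame")
  og
}

split_gene_cell <- function(cell) {
  cell <- trimws(cell)
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  out <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

#' Write an orthogroup table to TSV
#'
#' @param og An `orthogroup_table` (see [read_orthogroups_tsv()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orthogroups_tsv <- function(og, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("Orthogroup", "A", "B", "C", "D"), collapse = "\t"), con, sep = "\n")
  lines <- vapply(seq_len(nrow(og)), function(i) {
    cells <- vapply(c("A", "B", "C", "D"),
                    function(h) paste(og[[h]][[i]], collapse = ", "), character(1))
    paste(c(og$orthogroup_id[i], cells), collapse = "\t")
  }, character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a TSV with header and columns `sample_id`, `condition`,
#' `replicate`, and optionally `tissue`. Condition and tissue labels are free
#' strings; an optional controlled vocabulary triggers a warning (not an
#' error) on unknown labels.
#'
#' @param path Path to the TSV.
#' @param known_conditions Optional character vector of expected condition
#'   labels; unknown labels warn.
#' @return A data.frame of class `sample_sheet` with columns `sample_id`,
#'   `condition`, `tissue`, `replicate`.
#' @export
read_sample_sheet <- function(path, known_conditions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% colnames(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!"tissue" %in% colnames(df)) df$tissue <- NA_character_
  sheet <- data.frame(sample_id = as.character(df$sample_id),
                      condition = as.character(df$condition),
                      tissue = as.character(df$tissue),
                      replicate = as.integer(df$replicate),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  if (!is.null(known_conditions)) {
    unk <- setdiff(unique(sheet$condition), known_conditions)
    if (length(unk))
      warning("unknown condition label(s): ", paste(unk, collapse = ", "))
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id(s) in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L))
    stop("replicate indices must be positive integers")
  invisible(sheet)
}

#' Write a sample sheet to TSV
#' @param sheet A sample sheet data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_unix(sheet[, c("sample_id", "condition", "tissue", "replicate")], path)
}

#' Read a gene-to-chromosome map
#'
#' Two-column TSV (`gene_id`, `chromosome`) mapping each gene to a chromosome
#' identifier such as `chr3b` or `chr5un`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `gene_id`, `chromosome`.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene map must have columns gene_id, chromosome")
  out <- data.frame(gene_id = df[[1L]], chromosome = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id(s) in gene map: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  out
}

#' Read a gene-to-term annotation map
#'
#' Two-column TSV (`gene_id`, comma-separated term ids). Term identifiers are
#' treated as opaque strings; genes may carry empty term sets.
#'
#' @param path Path to the TSV.
#' @return A named list mapping gene id to a character vector of term ids.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("term map must have columns gene_id, terms")
  terms <- lapply(df[[2L]], split_gene_cell)
  names(terms) <- df[[1L]]
  terms
}

# TSV writer with Unix newlines regardless of platform
write_tsv_unix <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE, digits = 15)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
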