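#' Assign TERT-high / TERT-low groups from TERT read counts
#'
#' Samples with 2 or more RNA-seq quantified reads of TERT are TERT-high;
#' samples with fewer than 2 reads and no known ALT-related alteration
#' (ATRX/DAXX) are TERT-low; samples with fewer than 2 reads but an ALT
#' alteration are excluded. ALT status is a precomputed upstream annotation.
#'
#' @param tert_reads non-negative per-sample read counts.
#' @param alt_flags logical per-sample ALT-alteration flags.
#' @param threshold_reads read-count cut (default 2).
#' @return data.frame with `sample` (names of `tert_reads`, or indices),
#'   `label` in \{"high", "low", "excluded_alt"\}, and `reason` for excluded
#'   samples.
#' @export
assign_tert_groups <- function(tert_reads, alt_flags,
                               threshold_reads = 2L) {
  if (any(tert_reads < 0)) stop("read counts must be non-negative")
  if (length(tert_reads) != length(alt_flags)) {
    stop("tert_reads and alt_flags lengths differ")
  }
  label <- ifelse(tert_reads >= threshold_reads, "high",
                  ifelse(alt_flags, "excluded_alt", "low"))
  reason <- ifelse(label == "excluded_alt",
                   "ALT-related alteration with < threshold TERT reads", "")
  ids <- names(tert_reads)
  if (is.null(ids)) ids <- as.character(seq_along(tert_reads))
  data.frame(sample = ids, label = label, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter mRNAs by minimum average expression in both groups
#'
#' Keeps features whose group-wise mean log2 expression is strictly greater
#' than `min_mean` in BOTH the high and the low group.
#'
#' @param log2_expr features x samples matrix on log2 scale.
#' @param z 0/1 group labels (1 = high).
#' @param min_mean strict lower bound (default 1).
#' @return character vector of kept feature names.
#' @export
filter_expressed_mrna <- function(log2_expr, z, min_mean = 1) {
  z <- check_binary_z(z)
  log2_expr <- as.matrix(log2_expr)
  m_hi <- rowMeans(log2_expr[, z == 1L, drop = FALSE])
  m_lo <- rowMeans(log2_expr[, z == 0L, drop = FALSE])
  rownames(log2_expr)[m_hi > min_mean & m_lo > min_mean]
}

#' Select one methylation probe per gene by strongest anti-correlation
#'
#' For genes with multiple probes, picks the probe whose beta values have the
#' minimum (most negative) Pearson correlation with the gene's expression.
#' Zero-variance probes yield a missing correlation and cannot be selected;
#' genes whose probes are all missing are dropped with a message. Ties are
#' broken by the lexicographically smallest probe identifier.
#'
#' @param meth probes x samples beta-value matrix.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @param gene_expr genes x samples expression matrix (same sample order as
#'   `meth`).
#' @return data.frame with `gene`, `probe`, `r` (the chosen correlation).
#' @export
select_methylation_probe <- function(meth, probe_map, gene_expr) {
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  meth <- as.matrix(meth)
  gene_expr <- as.matrix(gene_expr)
  if (ncol(meth) != ncol(gene_expr)) stop("sample columns must be paired")
  probe_map <- probe_map[probe_map$probe %in% rownames(meth) &
                           probe_map$gene %in% rownames(gene_expr), ,
                         drop = FALSE]
  out <- lapply(split(probe_map$probe, probe_map$gene), function(pr) {
    g <- probe_map$gene[match(pr[1], probe_map$probe)]
    r <- vapply(pr, function(p) safe_cor(meth[p, ], gene_expr[g, ]),
                numeric(1))
    ok <- !is.na(r)
    if (!any(ok)) return(NULL)
    r <- r[ok]; pr <- pr[ok]
    ord <- order(r, pr)   # minimum r, then smallest probe ID
    data.frame(gene = g, probe = pr[ord[1]], r = r[ord[1]],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    message(dropped, " gene(s) dropped: all probes zero-variance")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(gene = character(0), probe = character(0),
                      r = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Filter a MAF-like mutation table into a binary gene x sample matrix
#'
#' Drops samples with `max_mutations` or more mutation rows (strict <
#' retention), binarizes gene x sample incidence (any retained mutation = 1),
#' and keeps genes mutated in at least `min_freq` of the retained samples.
#' All rows are counted by default; supply `classes` to restrict the variant
#' classifications that count.
#'
#' @param maf data.frame with columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification`.
#' @param max_mutations samples with >= this many mutations are dropped
#'   (default 1000).
#' @param min_freq minimum mutation frequency among retained samples
#'   (default 0.05, inclusive).
#' @param classes optional character vector of Variant_Classification values
#'   to count; `NULL` counts everything.
#' @return list with `matrix` (binary genes x samples), `kept_samples`,
#'   `kept_genes`, `dropped_samples`.
#' @export
filter_mutations <- function(maf, max_mutations = 1000L, min_freq = 0.05,
                             classes = NULL) {
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(req %in% names(maf))) {
    stop("MAF table must have columns: ", paste(req, collapse = ", "))
  }
  bad <- which(is.na(maf$Hugo_Symbol) | maf$Hugo_Symbol == "" |
                 is.na(maf$Tumor_Sample_Barcode) |
                 maf$Tumor_Sample_Barcode == "")
  if (length(bad) > 0) {
    stop("malformed MAF rows at lines: ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  if (!is.null(classes)) {
    maf <- maf[maf$Variant_Classification %in% classes, , drop = FALSE]
  }
  per_sample <- table(maf$Tumor_Sample_Barcode)
  kept_samples <- names(per_sample)[per_sample < max_mutations]
  dropped <- setdiff(names(per_sample), kept_samples)
  maf <- maf[maf$Tumor_Sample_Barcode %in% kept_samples, , drop = FALSE]
  genes <- sort(unique(maf$Hugo_Symbol))
  mat <- matrix(0L, nrow = length(genes), ncol = length(kept_samples),
                dimnames = list(genes, sort(kept_samples)))
  if (nrow(maf) > 0) {
    idx <- cbind(match(maf$Hugo_Symbol, rownames(mat)),
                 match(maf$Tumor_Sample_Barcode, colnames(mat)))
    mat[idx] <- 1L
  }
  freq <- rowMeans(mat)
  kept_genes <- rownames(mat)[freq >= min_freq]
  list(matrix = mat[kept_genes, , drop = FALSE],
       kept_samples = colnames(mat),
       kept_genes = kept_genes,
       dropped_samples = dropped)
}

#' Enrichment of one gene set in another by Fisher's exact test
#'
#' Builds the 2x2 table of membership in the methylation-derived set versus
#' the expression-derived set over the universe, and returns the one-sided
#' (enrichment) exact hypergeometric p-value together with the sample odds
#' ratio ad/bc (infinite when an off-diagonal cell is empty).
#'
#' @param meth_genes,expr_genes character sets, both subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `odds_ratio`, `p`, `table` (the 2x2 matrix).
#' @export
methylation_expression_enrichment <- function(meth_genes, expr_genes,
                                              universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  meth_genes <- intersect(unique(meth_genes), universe)
  expr_genes <- intersect(unique(expr_genes), universe)
  a <- length(intersect(meth_genes, expr_genes))
  b <- length(setdiff(meth_genes, expr_genes))
  cc <- length(setdiff(expr_genes, meth_genes))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(meth = c("in", "out"),
                                expr = c("in", "out")))
  # P(X >= a) for X ~ Hypergeom(white = |expr|, black = N - |expr|,
  # drawn = |meth|)
  p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  or <- if (b == 0 || cc == 0) {
    if (a == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  list(odds_ratio = or, p = p, table = tab)
}
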