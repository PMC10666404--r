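# FPKM computation, expression superclustering, and differential exon usage.

#' Compute FPKM from a gene count matrix and gene models
#'
#' FPKM(g, s) = count(g, s) / (libsize(s) / 1e6) / (exonlen(g) / 1e3), with
#' libsize the column sum of the count matrix and exonlen the summed exon
#' length of the gene model. The inputs are attached as provenance
#' attributes (`counts`, `exon_len`, `lib_size`) so the matrix can be
#' re-derived from its own output.
#'
#' @param counts gene x sample numeric matrix of read counts.
#' @param models gene models covering every row of `counts`.
#' @return FPKM matrix with provenance attributes.
#' @export
compute_fpkm <- function(counts, models) {
  missing <- setdiff(rownames(counts), names(models))
  if (length(missing)) {
    stop("gene(s) without model: ", paste(head(missing, 3), collapse = ", "))
  }
  exon_len <- vapply(models[rownames(counts)], function(m) {
    sum(m$exons[, 2] - m$exons[, 1])
  }, numeric(1))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  fpkm <- sweep(counts, 2L, lib / 1e6, "/")
  fpkm <- sweep(fpkm, 1L, exon_len / 1e3, "/")
  attr(fpkm, "counts") <- counts
  attr(fpkm, "exon_len") <- exon_len
  attr(fpkm, "lib_size") <- lib
  fpkm
}

#' Assign expression superclusters
#'
#' Rows are transformed to log2(FPKM + 1) and mean-centered per gene;
#' complete-linkage agglomeration on Euclidean distances is cut into exactly
#' `k` groups. Cluster labels are renumbered by first appearance in the
#' input row order, making the labelling deterministic and invariant to
#' sample-column order (distances do not depend on column order).
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param k number of superclusters.
#' @return data.frame gene, label (1..k); the centered profile matrix is
#'   attached as attribute `profiles`.
#' @export
assign_superclusters <- function(fpkm, k = 8L) {
  if (k > nrow(fpkm)) stop("k exceeds the number of genes")
  if (ncol(fpkm) < 2L) stop("need at least two samples")
  x <- log2(fpkm + 1)
  x <- x - rowMeans(x)
  hc <- stats::hclust(stats::dist(x), method = "complete")
  lab <- stats::cutree(hc, k = k)
  lab <- match(lab, unique(lab))  # renumber by first appearance
  if (length(unique(lab)) != k) stop("degenerate cut: empty cluster")
  out <- data.frame(gene = rownames(fpkm), label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- x
  out
}

#' Test differential exon usage between two conditions
#'
#' Usage of an exon in a replicate is its count divided by the gene total in
#' that replicate (replicates with gene total zero are dropped). Usages are
#' arcsine-square-root transformed and compared by a two-sided Welch t-test;
#' p-values are BH-adjusted across all tested exons. An exon is significant
#' iff q <= alpha and the absolute difference in mean (untransformed) usage
#' is >= min_delta. Genes with fewer than two exons are skipped; exons with
#' fewer than two usable replicates in either condition are flagged
#' untestable.
#'
#' @param exon_counts exon x sample count matrix; rownames "gene:exon".
#' @param gene_of_exon character vector mapping each exon row to its gene.
#' @param design condition design with `sample` column matching the matrix
#'   columns.
#' @param condition_a,condition_b contrasted conditions.
#' @param alpha BH-adjusted significance level.
#' @param min_delta minimum |mean usage difference|.
#' @return data.frame per exon: usage means, delta, p, q, untestable,
#'   significant.
#' @export
test_exon_usage <- function(exon_counts, gene_of_exon, design,
                            condition_a, condition_b,
                            alpha = 0.05, min_delta = 0.1) {
  stopifnot(length(gene_of_exon) == nrow(exon_counts))
  cols_a <- design$sample[design$condition == condition_a]
  cols_b <- design$sample[design$condition == condition_b]
  if (!all(c(cols_a, cols_b) %in% colnames(exon_counts))) {
    stop("count matrix lacks columns for the requested conditions")
  }
  totals <- rowsum(exon_counts, gene_of_exon)
  gene_tot <- totals[gene_of_exon, , drop = FALSE]
  usage <- exon_counts / gene_tot          # NaN where gene total is 0
  usage[gene_tot == 0] <- NA_real_
  multi <- gene_of_exon %in% names(which(table(gene_of_exon) >= 2L))

  ua <- usage[, cols_a, drop = FALSE]
  ub <- usage[, cols_b, drop = FALSE]
  n_a <- rowSums(!is.na(ua)); n_b <- rowSums(!is.na(ub))
  untestable <- multi & (n_a < 2L | n_b < 2L)
  testable <- multi & !untestable

  p <- rep(NA_real_, nrow(exon_counts))
  for (i in which(testable)) {
    xa <- asin(sqrt(ua[i, !is.na(ua[i, ])]))
    xb <- asin(sqrt(ub[i, !is.na(ub[i, ])]))
    if (stats::var(xa) + stats::var(xb) == 0) {
      p[i] <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      p[i] <- stats::t.test(xa, xb)$p.value
    }
  }
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  mean_a <- rowMeans(ua, na.rm = TRUE)
  mean_b <- rowMeans(ub, na.rm = TRUE)
  delta <- mean_a - mean_b
  data.frame(exon = rownames(exon_counts), gene = gene_of_exon,
             skipped_single_exon = !multi,
             usage_a = mean_a, usage_b = mean_b, delta = delta,
             n_a = n_a, n_b = n_b, p = p, q = q,
             untestable = untestable,
             significant = testable & !is.na(q) & q <= alpha &
               abs(delta) >= min_delta,
             stringsAsFactors = FALSE, row.names = NULL)
}
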