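# Duplicate-gene mode classification and expression-direction concordance.
#
# Modes follow common synteny-tool practice: for each duplicated gene the
# nearest same-cluster paralog by gene-rank distance on the same scaffold
# decides the mode (distance 1 = tandem, 2..proximal_max_gap = proximal,
# otherwise dispersed; paralogs only on other scaffolds = dispersed).

#' Classify duplication modes
#'
#' @param clusters data.frame with cluster_id, gene_id ([read_clusters()]).
#' @param models gene-model set with per-scaffold ranks assigned.
#' @param proximal_max_gap maximum rank gap still counted as proximal.
#' @return data.frame gene_id, cluster_id, mode (singleton/tandem/proximal/
#'   dispersed), nearest_rank_gap (NA when no same-scaffold paralog).
#' @export
classify_duplication_modes <- function(clusters, models,
                                       proximal_max_gap = 10L) {
  missing <- setdiff(clusters$gene_id, names(models))
  if (length(missing)) {
    stop("clustered gene(s) missing from models: ",
         paste(head(missing, 3), collapse = ", "))
  }
  scaf <- vapply(models[clusters$gene_id], `[[`, "", "scaffold_id")
  rank <- vapply(models[clusters$gene_id], `[[`, integer(1), "rank")
  mode <- character(nrow(clusters))
  gap <- rep(NA_integer_, nrow(clusters))
  for (cl in unique(clusters$cluster_id)) {
    idx <- which(clusters$cluster_id == cl)
    if (length(idx) == 1L) { mode[idx] <- "singleton"; next }
    for (i in idx) {
      same <- setdiff(idx[scaf[idx] == scaf[i]], i)
      if (length(same) == 0L) { mode[i] <- "dispersed"; next }
      d <- min(abs(rank[same] - rank[i]))
      gap[i] <- d
      mode[i] <- if (d == 1L) "tandem"
        else if (d <= proximal_max_gap) "proximal"
        else "dispersed"
    }
  }
  data.frame(gene_id = clusters$gene_id, cluster_id = clusters$cluster_id,
             mode = mode, nearest_rank_gap = gap, stringsAsFactors = FALSE)
}

#' Summarise DEG direction concordance for one homologous set
#'
#' DEG copies are members with a label other than ".". The pattern key is
#' the direction string sorted "+" before "-"; the concordance fraction is
#' the majority direction's share among DEG copies (a tie gives 0.5).
#'
#' @param members gene ids of the set.
#' @param labels data.frame from [read_deg_labels()].
#' @param contrast column of `labels` to use.
#' @return one-row data.frame: copy_count, deg_count, pattern, concordance
#'   (NA when no DEG copy).
#' @export
summarize_set_concordance <- function(members, labels, contrast) {
  if (!contrast %in% names(labels)) stop("unknown contrast: ", contrast)
  unknown <- setdiff(members, rownames(labels))
  if (length(unknown)) stop("unlabelled gene(s): ",
                            paste(head(unknown, 3), collapse = ", "))
  dirs <- labels[members, contrast]
  deg <- dirs[dirs != "."]
  pattern <- paste(deg[order(factor(deg, levels = c("+", "-")))],
                   collapse = "")
  conc <- if (length(deg) == 0L) NA_real_ else
    max(table(factor(deg, levels = c("+", "-")))) / length(deg)
  data.frame(copy_count = length(members), deg_count = length(deg),
             pattern = pattern, concordance = conc, stringsAsFactors = FALSE)
}

#' Summarise concordance for every homologous set
#'
#' @param clusters data.frame cluster_id, gene_id.
#' @param labels DEG label table.
#' @param contrast contrast column name.
#' @param genes_keep optional gene subset (e.g. dispersed copies only);
#'   members outside it are dropped before summarising.
#' @return data.frame with one row per cluster: cluster_id, copy_count,
#'   deg_count, pattern, concordance.
#' @export
summarize_concordance <- function(clusters, labels, contrast,
                                  genes_keep = NULL) {
  if (!is.null(genes_keep)) {
    clusters <- clusters[clusters$gene_id %in% genes_keep, , drop = FALSE]
  }
  ids <- unique(clusters$cluster_id)
  rows <- lapply(ids, function(cl) {
    s <- summarize_set_concordance(
      clusters$gene_id[clusters$cluster_id == cl], labels, contrast)
    cbind(cluster_id = cl, s, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pattern tables of DEG direction combinations
#'
#' Counts of pattern keys among sets with a given number of DEG copies;
#' sets with fewer than two DEG copies are excluded.
#'
#' @param summaries data.frame from [summarize_concordance()].
#' @return named list, one table per DEG copy count (>= 2).
#' @export
pattern_tables <- function(summaries) {
  s <- summaries[summaries$deg_count >= 2L, , drop = FALSE]
  out <- lapply(split(s$pattern, s$deg_count), function(p) table(p))
  out
}

#' Proportion of sets concordant at a threshold
#'
#' Restricted to sets with at least `min_deg_copies` DEG copies; a set is
#' flagged concordant iff its concordance fraction is >= threshold
#' (inclusive). An empty restriction yields an explicit empty result
#' (proportion NA, n 0), distinct from a zero proportion.
#'
#' @param summaries data.frame from [summarize_concordance()].
#' @param min_deg_copies minimum DEG copies for a set to qualify.
#' @param threshold concordance threshold (inclusive).
#' @return list: proportion, n (qualifying sets), flags (named logical).
#' @export
concordance_at_threshold <- function(summaries, min_deg_copies = 3L,
                                     threshold = 0.8) {
  q <- summaries[summaries$deg_count >= min_deg_copies, , drop = FALSE]
  if (nrow(q) == 0L) {
    return(list(proportion = NA_real_, n = 0L,
                flags = setNames(logical(0), character(0))))
  }
  flags <- setNames(q$concordance >= threshold, q$cluster_id)
  list(proportion = mean(flags), n = nrow(q), flags = flags)
}
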