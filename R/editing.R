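# mRNA editing site calling from DNA-vs-RNA base-count pileups.
#
# A site is called, per condition, when all five criteria hold:
#   (a) divergence score > score_threshold,
#   (b) DNA coverage   > min_dna_coverage (strict),
#   (c) RNA coverage   > min_rna_coverage in every replicate (strict),
#   (d) exactly one alternative base has support in every replicate
#       (count >= alt_support_min_count AND fraction >= alt_support_min_fraction),
#   (e) that alternative base is the same in all replicates.
#
# The score is a per-replicate multinomial log2 likelihood-ratio comparing
# the replicate's own (pseudocounted) composition against the DNA
# composition, averaged over replicates. It is zero exactly when the
# pseudocounted compositions coincide, and non-negative by construction.
# It is a deterministic surrogate for an external caller's score and is not
# claimed to be numerically identical to any published tool; the default
# threshold 1.15 is retained as the operating point.

#' Editing-caller configuration
#'
#' @param score_threshold minimum divergence score (strict `>`).
#' @param min_dna_coverage minimum DNA read coverage (strict `>`).
#' @param min_rna_coverage minimum RNA coverage per replicate (strict `>`).
#' @param require_all_replicates require the same supported alternative base
#'   in every replicate.
#' @param alt_support_min_count,alt_support_min_fraction a base counts as a
#'   putative editing type in a replicate iff its count and fraction reach
#'   both minima.
#' @param pseudocount added to each of the four base counts before
#'   compositions are estimated.
#' @return list of class `editing_config`.
#' @export
editing_config <- function(score_threshold = 1.15, min_dna_coverage = 10L,
                           min_rna_coverage = 5L, require_all_replicates = TRUE,
                           alt_support_min_count = 2L,
                           alt_support_min_fraction = 0.05, pseudocount = 1) {
  stopifnot(score_threshold > 0, min_dna_coverage > 0, min_rna_coverage > 0,
            alt_support_min_fraction > 0, alt_support_min_fraction < 1,
            pseudocount > 0)
  structure(list(score_threshold = score_threshold,
                 min_dna_coverage = min_dna_coverage,
                 min_rna_coverage = min_rna_coverage,
                 require_all_replicates = require_all_replicates,
                 alt_support_min_count = alt_support_min_count,
                 alt_support_min_fraction = alt_support_min_fraction,
                 pseudocount = pseudocount),
            class = "editing_config")
}

#' Divergence score of RNA replicates against a DNA pileup at one site
#'
#' score = (1/R) * sum_r log2 L(n_r | p_r) / L(n_r | p_dna), where n_r are
#' the pseudocounted replicate counts, p_r their maximum-likelihood
#' composition and p_dna the pseudocounted DNA composition; the multinomial
#' coefficient cancels. Non-negative; exactly zero when every replicate's
#' pseudocounted composition equals the DNA composition; invariant under
#' replicate permutation.
#'
#' @param dna_counts length-4 vector of DNA base counts (A,C,G,T).
#' @param rna_counts matrix, one row per replicate, 4 columns.
#' @param pseudocount pseudocount added to every count.
#' @return non-negative numeric score.
#' @export
compute_site_score <- function(dna_counts, rna_counts, pseudocount = 1) {
  rna_counts <- matrix(rna_counts, ncol = 4L)
  if (sum(dna_counts) <= 0 || any(rowSums(rna_counts) <= 0)) {
    stop("zero coverage at site")
  }
  score_matrix(matrix(dna_counts, nrow = 1L),
               lapply(seq_len(nrow(rna_counts)),
                      function(r) rna_counts[r, , drop = FALSE]),
               pseudocount)[1]
}

# Vectorised score over sites: dna (n x 4) and a list of replicate count
# matrices (each n x 4). Returns length-n numeric.
score_matrix <- function(dna, rna_reps, pseudocount = 1) {
  pd <- dna + pseudocount
  pd <- pd / rowSums(pd)
  lpd <- log2(pd)
  acc <- 0
  for (rep_counts in rna_reps) {
    nt <- rep_counts + pseudocount
    tot <- rowSums(nt)
    acc <- acc + rowSums(nt * (log2(nt / tot) - lpd))
  }
  acc / length(rna_reps)
}

#' Classify an edit type on the gene (sense) strand
#'
#' For minus-strand genes both bases are complemented before naming, so the
#' 12 possible types are always reported in transcription orientation.
#'
#' @param dna_base,alt_base reference and alternative base (A/C/G/T),
#'   vectorised.
#' @param strand "+" or "-", vectorised.
#' @return character vector like "A-to-G".
#' @export
classify_edit_type <- function(dna_base, alt_base, strand) {
  if (any(dna_base == alt_base)) stop("edit type requires distinct bases")
  if (!all(dna_base %in% PILEUP_BASES & alt_base %in% PILEUP_BASES)) {
    stop("bases must be one of A/C/G/T")
  }
  neg <- strand == "-"
  d <- ifelse(neg, unname(complement_base(dna_base)), dna_base)
  a <- ifelse(neg, unname(complement_base(alt_base)), alt_base)
  paste0(d, "-to-", a)
}

# Locate the host gene(s) of genomic positions by gene span (min exon start
# to max exon end). Returns a data.frame site_idx, gene_id, strand,
# ambiguous (more than one overlapping gene), or strand "+" with
# gene_id NA for intergenic sites.
assign_sites_to_genes <- function(scaffold, pos, models) {
  gscaf <- vapply(models, `[[`, "", "scaffold_id")
  glo <- vapply(models, function(m) m$exons[1, 1], integer(1))
  ghi <- vapply(models, function(m) m$exons[nrow(m$exons), 2], integer(1))
  gid <- vapply(models, `[[`, "", "gene_id")
  gstr <- vapply(models, `[[`, "", "strand")
  out <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    hit <- which(gscaf == scaffold[i] & glo <= pos[i] & pos[i] < ghi)
    if (length(hit) == 0L) {
      out[[i]] <- data.frame(site_idx = i, gene_id = NA_character_,
                             strand = "+", ambiguous = FALSE)
    } else {
      out[[i]] <- data.frame(site_idx = i, gene_id = gid[hit],
                             strand = gstr[hit],
                             ambiguous = length(hit) > 1L)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call mRNA editing sites per condition
#'
#' Applies the five significance criteria (see file header) to every site
#' present in the DNA pileup, separately per condition. Sites present in the
#' RNA but absent from the DNA pileup are skipped and counted in the
#' `n_skipped_no_dna` attribute. Replicates missing at a site count as zero
#' coverage and therefore fail criterion (c).
#'
#' @param pileup data.frame from [read_pileup_table()] (0-based positions).
#' @param design data.frame from [condition_design()].
#' @param models gene models used to orient edit types; sites outside any
#'   gene are reported on "+" with `intergenic = TRUE`; sites inside several
#'   genes are reported once per gene with `ambiguous = TRUE`.
#' @param config an [editing_config()].
#' @return data.frame of calls: scaffold, pos, condition, gene_id, strand,
#'   intergenic, ambiguous, dna_base, alt_base, edit_type, score,
#'   edit_fraction (pooled alt/total over replicates), alt_count, total_count.
#' @export
call_edit_sites <- function(pileup, design, models, config = editing_config()) {
  dna <- pileup[pileup$sample_kind == "DNA", , drop = FALSE]
  if (nrow(dna) == 0L) stop("pileup contains no DNA rows")
  key <- function(d) paste(d$scaffold, d$pos)
  dkey <- key(dna)
  rna <- pileup[pileup$sample_kind == "RNA", , drop = FALSE]
  n_skipped <- length(setdiff(unique(key(rna)), dkey))
  if (n_skipped > 0L) {
    message(n_skipped, " RNA site(s) absent from DNA pileup were skipped")
  }

  dcounts <- as.matrix(dna[, c("nA", "nC", "nG", "nT")])
  dcov <- rowSums(dcounts)
  dbase <- PILEUP_BASES[max.col(dcounts, ties.method = "first")]
  dbase_idx <- max.col(dcounts, ties.method = "first")
  genes <- assign_sites_to_genes(dna$scaffold, dna$pos, models)

  cfg <- config
  calls <- list()
  for (cond in unique(design$condition)) {
    reps <- sort(unique(design$replicate[design$condition == cond]))
    rep_counts <- lapply(reps, function(r) {
      rows <- rna[rna$condition == cond & rna$replicate == r, , drop = FALSE]
      m <- matrix(0, nrow = nrow(dna), ncol = 4L)
      idx <- match(key(rows), dkey)
      ok <- !is.na(idx)
      m[idx[ok], ] <- as.matrix(rows[ok, c("nA", "nC", "nG", "nT")])
      m
    })
    covs <- do.call(cbind, lapply(rep_counts, rowSums))
    pass_cov <- dcov > cfg$min_dna_coverage &
      apply(covs > cfg$min_rna_coverage, 1L, all)

    # supported alternative bases per replicate: count and fraction minima,
    # consensus base excluded
    supp <- lapply(rep_counts, function(m) {
      frac <- m / pmax(rowSums(m), 1)
      s <- m >= cfg$alt_support_min_count & frac >= cfg$alt_support_min_fraction
      s[cbind(seq_len(nrow(m)), dbase_idx)] <- FALSE
      s
    })
    n_types <- do.call(cbind, lapply(supp, rowSums))
    one_type <- apply(n_types == 1L, 1L, all)
    alt_idx <- do.call(cbind, lapply(supp, function(s) {
      a <- max.col(s + 0, ties.method = "first")
      a[rowSums(s) == 0L] <- NA_integer_
      a
    }))
    same_alt <- apply(alt_idx, 1L, function(x) {
      !anyNA(x) && length(unique(x)) == 1L
    })
    pass_type <- if (cfg$require_all_replicates) one_type & same_alt else
      apply(n_types >= 1L, 1L, any) & one_type

    score <- score_matrix(dcounts, rep_counts, cfg$pseudocount)
    called <- pass_cov & pass_type & score > cfg$score_threshold
    if (!any(called)) next

    w <- which(called)
    pooled <- Reduce(`+`, rep_counts)
    alt_b <- alt_idx[w, 1]
    alt_n <- pooled[cbind(w, alt_b)]
    tot_n <- rowSums(pooled)[w]
    g <- genes[genes$site_idx %in% w, , drop = FALSE]
    g <- g[order(match(g$site_idx, w)), , drop = FALSE]
    m <- match(g$site_idx, w)
    calls[[cond]] <- data.frame(
      scaffold = dna$scaffold[w][m], pos = dna$pos[w][m], condition = cond,
      gene_id = g$gene_id, strand = g$strand,
      intergenic = is.na(g$gene_id), ambiguous = g$ambiguous,
      dna_base = dbase[w][m], alt_base = PILEUP_BASES[alt_b][m],
      edit_type = classify_edit_type(dbase[w][m], PILEUP_BASES[alt_b][m],
                                     g$strand),
      score = score[w][m],
      edit_fraction = (alt_n / tot_n)[m],
      alt_count = alt_n[m], total_count = tot_n[m],
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) {
    do.call(rbind, c(calls, list(make.row.names = FALSE)))
  } else {
    data.frame(scaffold = character(0), pos = integer(0),
               condition = character(0), gene_id = character(0),
               strand = character(0), intergenic = logical(0),
               ambiguous = logical(0), dna_base = character(0),
               alt_base = character(0), edit_type = character(0),
               score = numeric(0), edit_fraction = numeric(0),
               alt_count = numeric(0), total_count = numeric(0),
               stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped_no_dna") <- n_skipped
  out
}

#' Pool alternative/reference counts per condition for a set of sites
#'
#' @param pileup pileup data.frame (0-based positions).
#' @param sites data.frame with scaffold, pos, dna_base, alt_base.
#' @param design condition design.
#' @param condition condition to pool over (replicates summed).
#' @return data.frame with alt, ref (reference = consensus-base reads).
#' @export
pool_site_counts <- function(pileup, sites, design, condition) {
  rna <- pileup[pileup$sample_kind == "RNA" & pileup$condition == condition, ]
  k <- paste(rna$scaffold, rna$pos)
  sk <- paste(sites$scaffold, sites$pos)
  alt <- numeric(nrow(sites)); ref <- numeric(nrow(sites))
  cnt <- as.matrix(rna[, c("nA", "nC", "nG", "nT")])
  for (i in seq_len(nrow(sites))) {
    rows <- which(k == sk[i])
    alt[i] <- sum(cnt[rows, match(sites$alt_base[i], PILEUP_BASES)])
    ref[i] <- sum(cnt[rows, match(sites$dna_base[i], PILEUP_BASES)])
  }
  data.frame(alt = alt, ref = ref)
}

#' Test differential editing between two conditions
#'
#' Two-sided Fisher exact test on the pooled 2x2 table (alt, ref) x
#' (condition A, condition B) per site, Benjamini-Hochberg adjusted across
#' all testable sites of the run. A site is differential iff q <= alpha and
#' the absolute editing-fraction difference is >= min_delta. Sites with zero
#' total reads in either condition are flagged untestable (NA p). Sites
#' called in one condition only remain testable; the categorical
#' condition-specific presence flag is reported alongside.
#'
#' @param sites data.frame with scaffold, pos, dna_base, alt_base and
#'   optionally called_in (character, comma-separated conditions).
#' @param pileup pileup data.frame.
#' @param design condition design.
#' @param condition_a,condition_b the contrasted conditions.
#' @param alpha BH-adjusted significance level.
#' @param min_delta minimum |editing fraction difference|.
#' @return data.frame with per-site counts, fractions, delta, p, q,
#'   untestable and is_differential flags.
#' @export
test_differential_editing <- function(sites, pileup, design, condition_a,
                                      condition_b, alpha = 0.05,
                                      min_delta = 0.1) {
  a <- pool_site_counts(pileup, sites, design, condition_a)
  b <- pool_site_counts(pileup, sites, design, condition_b)
  tot_a <- a$alt + a$ref; tot_b <- b$alt + b$ref
  untestable <- tot_a == 0 | tot_b == 0
  p <- rep(NA_real_, nrow(sites))
  for (i in which(!untestable)) {
    tab <- matrix(c(a$alt[i], a$ref[i], b$alt[i], b$ref[i]), nrow = 2L)
    p[i] <- stats::fisher.test(tab)$p.value
  }
  q <- rep(NA_real_, length(p))
  q[!untestable] <- stats::p.adjust(p[!untestable], method = "BH")
  frac_a <- ifelse(tot_a > 0, a$alt / tot_a, NA_real_)
  frac_b <- ifelse(tot_b > 0, b$alt / tot_b, NA_real_)
  delta <- frac_a - frac_b
  data.frame(sites[, c("scaffold", "pos", "dna_base", "alt_base")],
             alt_a = a$alt, ref_a = a$ref, alt_b = b$alt, ref_b = b$ref,
             frac_a = frac_a, frac_b = frac_b, delta = delta,
             p = p, q = q, untestable = untestable,
             is_differential = !untestable & !is.na(q) & q <= alpha &
               abs(delta) >= min_delta,
             stringsAsFactors = FALSE)
}
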