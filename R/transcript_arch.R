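# Spliced-leader detection, coding-unit segmentation of tandem-repeat
# proteins, CU-to-exon mapping, and spacer/leader motif scanning.

#' Canonical 22-nt dinoflagellate spliced leader (IUPAC, D = A/G/T)
#'
#' The leader is trans-spliced onto the 5' end of mature nuclear mRNAs; its
#' 3' end joins the transcript start, so evidence in assembled transcripts
#' is an SL *suffix* at the transcript 5' end. Configurable in every
#' function that uses it.
#' @export
DINO_SL <- "DCCGTAGCCATTTTGGCTCAAG"

#' Kyte-Doolittle residue hydropathy scale
#'
#' Positive values are hydrophobic. Used by [scan_motifs()] to report mean
#' hydropathy of spacer/leader regions; reported, never thresholded.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

iupac_match <- function(pattern_chars, seq_chars) {
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[pattern_chars], "")
  mapply(function(a, b) b %in% a, allowed, seq_chars)
}

#' Detect spliced-leader evidence at a transcript 5' end
#'
#' The longest SL suffix (length >= min_match) that aligns ungapped to the
#' transcript start with at most `max_mm` mismatches (IUPAC-aware on the SL
#' side) is reported. Matched transcripts carry `trim_offset`, the 0-based
#' position of the first transcript base after the leader.
#'
#' @param transcript transcript sequence (5' to 3').
#' @param sl spliced-leader sequence (IUPAC allowed).
#' @param min_match minimum matched suffix length.
#' @param max_mm maximum mismatches.
#' @return list: matched, match_length, mismatches, trim_offset.
#' @export
detect_sl <- function(transcript, sl = DINO_SL, min_match = 10L, max_mm = 1L) {
  nsl <- nchar(sl)
  no_match <- list(matched = FALSE, match_length = NA_integer_,
                   mismatches = NA_integer_, trim_offset = 0L)
  if (nchar(transcript) < min_match) return(no_match)
  sl_chars <- strsplit(sl, "")[[1]]
  tx_chars <- strsplit(substr(transcript, 1L, nsl), "")[[1]]
  for (len in seq(min(nsl, nchar(transcript)), min_match)) {
    suf <- sl_chars[(nsl - len + 1L):nsl]
    pre <- tx_chars[seq_len(len)]
    mm <- sum(!iupac_match(suf, pre))
    if (mm <= max_mm) {
      return(list(matched = TRUE, match_length = len, mismatches = mm,
                  trim_offset = len))
    }
  }
  no_match
}

#' Detect spliced leaders for a set of transcripts
#'
#' @param transcripts named character vector.
#' @inheritParams detect_sl
#' @return data.frame: transcript_id, matched, match_length, mismatches,
#'   trim_offset.
#' @export
detect_sl_set <- function(transcripts, sl = DINO_SL, min_match = 10L,
                          max_mm = 1L) {
  res <- lapply(transcripts, detect_sl, sl = sl, min_match = min_match,
                max_mm = max_mm)
  data.frame(transcript_id = names(transcripts),
             matched = vapply(res, `[[`, logical(1), "matched"),
             match_length = vapply(res, `[[`, integer(1), "match_length"),
             mismatches = vapply(res, `[[`, integer(1), "mismatches"),
             trim_offset = vapply(res, `[[`, integer(1), "trim_offset"),
             stringsAsFactors = FALSE, row.names = NULL)
}

protein_kmers <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(character(0))
  m <- matrix("", nrow = n - k + 1L, ncol = k)
  for (j in seq_len(k)) m[, j] <- chars[j:(n - k + j)]
  apply(m, 1L, paste, collapse = "")
}

#' Segment a protein into coding units and spacers
#'
#' Multi-CU gene models encode several near-identical (> 95%) full-length
#' protein copies separated by spacers. The segmentation (1) collects exact
#' k-mer self-matches off the main diagonal, (2) votes the dominant period p
#' >= min_unit_len from the match offsets, (3) marks residues covered by
#' matches at period p and merges them into candidate copies, (4) builds a
#' majority-rule consensus over the candidates, and (5) accepts candidates
#' with >= identity_threshold identity to the consensus as complete units;
#' flanking candidates of at least `partial_min_frac` of the consensus
#' length that match a consensus prefix (N-terminal fragment) or suffix
#' (C-terminal fragment) become partial units. Residues between accepted
#' units are spacers; residues before the first / after the last unit are
#' returned as `leading` / `trailing` (candidate leader sequences, not
#' spacers). When no period is found, or fewer than two complete units pass
#' the identity gate, the whole protein is one complete unit.
#'
#' @param protein amino-acid sequence.
#' @param min_unit_len minimum unit length (residues).
#' @param identity_threshold identity gate for complete units.
#' @param k k-mer size for self-matching.
#' @param partial_min_frac minimum fraction of the consensus length for a
#'   flanking fragment to count as a partial unit.
#' @return list of class `cu_segmentation`: n_units, unit_consensus,
#'   complete_units / partial_units / spacers (0-based half-open residue
#'   intervals; partials carry a `tag` of "N-terminal"/"C-terminal"),
#'   leading, trailing, mean_pairwise_identity, period.
#' @export
segment_coding_units <- function(protein, min_unit_len = 50L,
                                 identity_threshold = 0.95, k = 8L,
                                 partial_min_frac = 0.5) {
  n <- nchar(protein)
  if (n == 0L) stop("empty protein sequence")
  chars <- strsplit(protein, "")[[1]]
  single <- function() {
    structure(list(
      n_units = 1L, unit_consensus = protein,
      complete_units = cbind(start = 0L, end = n),
      partial_units = list(), spacers = matrix(integer(0), ncol = 2L),
      leading = NULL, trailing = NULL,
      mean_pairwise_identity = 1, period = NA_integer_),
      class = "cu_segmentation")
  }
  if (n < 2L * min_unit_len + k) return(single())

  kmers <- protein_kmers(chars, k)
  pos_by_kmer <- split(seq_along(kmers), kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) > 1L]
  if (length(pos_by_kmer) == 0L) return(single())
  offs <- unlist(lapply(pos_by_kmer, function(p) {
    d <- outer(p, p, "-"); d[d > 0]
  }), use.names = FALSE)
  offs <- offs[offs >= min_unit_len]
  if (length(offs) == 0L) return(single())
  votes <- table(offs)
  p <- as.integer(names(votes)[which(votes == max(votes))[1]])

  i <- seq_len(length(kmers) - p)
  m <- i[kmers[i] == kmers[i + p]]
  # isolated matches are almost surely spurious (a chance k-mer hit near a
  # unit boundary shifts run starts off the periodic grid and corrupts the
  # column-wise consensus); keep only matches in consecutive runs >= 3
  if (length(m)) {
    run_id <- cumsum(c(1L, diff(m) != 1L))
    m <- m[stats::ave(m, run_id, FUN = length) >= 3]
  }
  if (length(m) == 0L) return(single())
  covered <- logical(n)
  for (x in m) covered[c(x:(x + k - 1L), (x + p):(x + p + k - 1L))] <- TRUE

  runs <- covered_runs(covered, gap_tol = k)

  # snap run edges to the periodic grid: a single chance pairing (e.g. two
  # spacers starting with the same residue) covers a boundary residue class
  # (position mod p) exactly twice, while genuine unit columns are covered
  # once per copy. Trimming run edges whose class is not covered more than
  # twice (or, in two-copy proteins, less than fully) removes boundary
  # extensions that would shift individual runs off-grid and corrupt the
  # column-wise consensus; interior columns are never touched, so copies
  # below 100% identity keep their coverage holes.
  h <- tabulate(((which(covered) - 1L) %% p) + 1L, nbins = p)
  thr <- min(2L, max(h) - 1L)
  for (r in seq_len(nrow(runs))) {
    while (runs[r, 1] < runs[r, 2] && h[(runs[r, 1] %% p) + 1L] <= thr) {
      runs[r, 1] <- runs[r, 1] + 1L
    }
    while (runs[r, 2] > runs[r, 1] && h[((runs[r, 2] - 1L) %% p) + 1L] <= thr) {
      runs[r, 2] <- runs[r, 2] - 1L
    }
  }
  runs <- runs[runs[, 2] > runs[, 1], , drop = FALSE]
  if (nrow(runs) == 0L) return(single())

  # re-join fragments of one copy split by mutation holes: a hole gap lies
  # at residue classes still covered by the other copies (h close to the
  # maximum), whereas a spacer gap has (near-)zero class coverage.
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (r in 2:nrow(runs)) {
      gap <- seq.int(merged[nrow(merged), 2], runs[r, 1] - 1L)
      joinable <- length(gap) < p &&
        all(h[(gap %% p) + 1L] >= max(h) - 1L)
      if (joinable) {
        merged[nrow(merged), 2] <- runs[r, 2]
      } else {
        merged <- rbind(merged, runs[r, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) == 0L) return(single())
  lens <- runs[, 2] - runs[, 1]
  # consensus length: modal length among long runs
  cand <- runs[lens >= 0.8 * max(lens), , drop = FALSE]
  lc <- as.integer(names(sort(table(cand[, 2] - cand[, 1]),
                              decreasing = TRUE))[1])
  if (lc < min_unit_len) return(single())
  cons_chars <- consensus_over(chars, cand, lc)
  consensus <- paste(cons_chars, collapse = "")

  ident_to <- function(iv, target) {
    w <- min(iv[2] - iv[1], length(target))
    if (w == 0L) return(0)
    sum(chars[(iv[1] + 1L):(iv[1] + w)] == target[seq_len(w)]) / length(target)
  }
  complete <- list(); partial <- list()
  for (r in seq_len(nrow(runs))) {
    iv <- runs[r, ]
    id_full <- ident_to(iv, cons_chars)
    if (id_full >= identity_threshold) {
      complete[[length(complete) + 1L]] <- iv
      next
    }
    # flanking fragment? compare against consensus prefix and suffix
    len <- iv[2] - iv[1]
    if ((r == 1L || r == nrow(runs)) && len >= partial_min_frac * lc) {
      frag <- chars[(iv[1] + 1L):iv[2]]
      w <- min(len, lc)
      id_pre <- sum(frag[seq_len(w)] == cons_chars[seq_len(w)]) / len
      id_suf <- sum(frag[seq_len(w)] ==
                      cons_chars[(lc - w + 1L):lc]) / len
      if (max(id_pre, id_suf) >= identity_threshold) {
        partial[[length(partial) + 1L]] <- list(
          interval = iv,
          tag = if (id_pre >= id_suf) "N-terminal" else "C-terminal")
      }
    }
  }
  if (length(complete) < 2L) return(single())

  cu <- do.call(rbind, complete)
  colnames(cu) <- c("start", "end")
  accepted <- rbind(cu, do.call(rbind, lapply(partial, `[[`, "interval")))
  accepted <- accepted[order(accepted[, 1]), , drop = FALSE]
  spacers <- cbind(start = accepted[-nrow(accepted), 2],
                   end = accepted[-1L, 1])
  spacers <- spacers[spacers[, 2] > spacers[, 1], , drop = FALSE]
  lead <- if (accepted[1, 1] > 0L) c(0L, accepted[1, 1]) else NULL
  trail <- if (accepted[nrow(accepted), 2] < n) {
    c(accepted[nrow(accepted), 2], n)
  } else NULL

  # mean pairwise identity among complete units (over consensus length)
  pid <- 1
  if (nrow(cu) > 1L) {
    pairs <- utils::combn(nrow(cu), 2L)
    pid <- mean(apply(pairs, 2L, function(ij) {
      a <- cu[ij[1], ]; b <- cu[ij[2], ]
      w <- min(a[2] - a[1], b[2] - b[1])
      sum(chars[(a[1] + 1L):(a[1] + w)] ==
            chars[(b[1] + 1L):(b[1] + w)]) / lc
    }))
  }
  structure(list(
    n_units = nrow(cu), unit_consensus = consensus,
    complete_units = cu, partial_units = partial, spacers = spacers,
    leading = lead, trailing = trail,
    mean_pairwise_identity = pid, period = p),
    class = "cu_segmentation")
}

# Merge TRUE runs of a logical vector, closing gaps <= gap_tol.
# Returns matrix of 0-based half-open intervals.
covered_runs <- function(covered, gap_tol = 0L) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values] - 1L, ends[r$values])
  if (nrow(iv) <= 1L) return(iv)
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] - out[nrow(out), 2] <= gap_tol) {
      out[nrow(out), 2] <- iv[i, 2]
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

consensus_over <- function(chars, runs, lc) {
  vapply(seq_len(lc), function(j) {
    col <- vapply(seq_len(nrow(runs)), function(r) {
      pos <- runs[r, 1] + j
      if (pos <= runs[r, 2]) chars[pos] else NA_character_
    }, character(1))
    col <- col[!is.na(col)]
    names(sort(table(col), decreasing = TRUE))[1]
  }, character(1))
}

#' @export
print.cu_segmentation <- function(x, ...) {
  cat(sprintf("<cu_segmentation> %d complete unit(s), %d partial, %d spacer(s); mean pairwise identity %.3f\n",
              x$n_units, length(x$partial_units), nrow(x$spacers),
              x$mean_pairwise_identity))
  invisible(x)
}

#' Map coding units and spacers to exons
#'
#' Residue intervals are converted to CDS nucleotide coordinates (x3) and
#' intersected with the gene model's CDS segments in transcription order;
#' each unit/spacer reports the 1-based exon indices it overlaps. Requires
#' protein length x 3 to equal the CDS length (terminal stop excluded).
#'
#' @param seg a `cu_segmentation`.
#' @param model the encoding [gene_model()] (CDS populated).
#' @param protein_length protein length in residues.
#' @return named list of integer vectors (exon indices) for units U1..Un,
#'   partials P1.., spacers S1...
#' @export
map_cu_to_exons <- function(seg, model, protein_length) {
  cds <- model$cds
  if (nrow(cds) == 0L) stop("gene model has no CDS: ", model$gene_id)
  widths <- cds[, 2] - cds[, 1]
  if (sum(widths) != 3L * protein_length) {
    stop("frame error: CDS length ", sum(widths), " != 3 x protein length ",
         protein_length, " for ", model$gene_id)
  }
  # transcription-ordered CDS segments and their host exon indices
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  exon_of_cds <- vapply(seq_len(nrow(cds)), function(i) {
    which(model$exons[, 1] <= cds[i, 1] & cds[i, 2] <= model$exons[, 2])[1]
  }, integer(1))
  exon_rank <- if (model$strand == "+") seq_len(nrow(model$exons)) else
    rev(seq_len(nrow(model$exons)))
  tx_exon <- exon_rank[exon_of_cds][ord]   # 1-based exon index per segment
  w <- widths[ord]
  seg_start <- cumsum(c(0L, w[-length(w)])) # CDS-walk offsets
  seg_end <- cumsum(w)

  overlap_exons <- function(iv) {
    nt0 <- 3L * iv[1]; nt1 <- 3L * iv[2]
    sort(unique(tx_exon[seg_start < nt1 & seg_end > nt0]))
  }
  out <- list()
  for (i in seq_len(nrow(seg$complete_units))) {
    out[[paste0("U", i)]] <- overlap_exons(seg$complete_units[i, ])
  }
  for (i in seq_along(seg$partial_units)) {
    out[[paste0("P", i)]] <- overlap_exons(seg$partial_units[[i]]$interval)
  }
  for (i in seq_len(nrow(seg$spacers))) {
    out[[paste0("S", i)]] <- overlap_exons(seg$spacers[i, ])
  }
  out
}

AA_ALPHABET <- names(KYTE_DOOLITTLE)

#' Scan an amino-acid region for targeting motifs and composition
#'
#' Reports exact hit positions of the query motifs (1-based), the combined
#' serine+alanine fraction, the basic-residue (R+K) fraction, and mean
#' Kyte-Doolittle hydropathy.
#'
#' @param region amino-acid sequence (20-letter alphabet).
#' @param motifs motifs to search (exact matches).
#' @return list: motif_hits (named list of 1-based start positions),
#'   ser_ala_fraction, basic_fraction, mean_hydropathy, length.
#' @export
scan_motifs <- function(region, motifs = c("FVGA", "FVAP")) {
  if (nchar(region) == 0L) stop("empty region")
  chars <- strsplit(region, "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    stop("non-amino-acid symbol in region: ",
         paste(unique(chars[!chars %in% AA_ALPHABET]), collapse = ""))
  }
  hits <- lapply(motifs, function(m) {
    g <- gregexpr(m, region, fixed = TRUE)[[1]]
    if (g[1] == -1L) integer(0) else as.integer(g)
  })
  names(hits) <- motifs
  list(motif_hits = hits,
       ser_ala_fraction = mean(chars %in% c("S", "A")),
       basic_fraction = mean(chars %in% c("R", "K")),
       mean_hydropathy = mean(KYTE_DOOLITTLE[chars]),
       length = length(chars))
}
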