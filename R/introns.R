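# Intron extraction, splice-motif tabulation, and introner-element scanning.
#
# An introner element (IE) is recognised by its terminal repeats: a short
# inverted repeat (8-20 nt) whose two arms sit within a fixed window of the
# two intron ends, together with a small direct repeat (3-5 nt) in the same
# windows. Both patterns are required; the scan is window-limited, not
# anchored to the exact termini.

#' Extract introns from a gene model
#'
#' Introns are the gaps between consecutive exons. `index` counts from the
#' transcription start, and `sense_seq` is the intron sequence in
#' transcription orientation (reverse complement of the genomic slice for
#' minus-strand genes). `next_exon_base` is the first base, in transcription
#' orientation, of the exon downstream of the intron; it is recorded here so
#' that acceptor-junction motifs (AG|G) can be tabulated without re-reading
#' the genome.
#'
#' @param model a [gene_model()].
#' @param genome named character vector of scaffold sequences.
#' @return data.frame with one row per intron (possibly zero rows): gene_id,
#'   index, scaffold, start, end (0-based half-open genomic), strand,
#'   sense_seq, next_exon_base.
#' @export
extract_introns <- function(model, genome) {
  ex <- model$exons
  n <- nrow(ex)
  empty <- data.frame(gene_id = character(0), index = integer(0),
                      scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sense_seq = character(0), next_exon_base = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  seq <- genome[[model$scaffold_id]]
  if (is.null(seq)) stop("scaffold not in genome: ", model$scaffold_id)
  gstart <- ex[-n, 2]          # gap after exon i (genomic order)
  gend <- ex[-1L, 1]
  slice <- substr(rep(seq, n - 1L), gstart + 1L, gend)
  if (model$strand == "+") {
    idx <- seq_len(n - 1L) - 1L
    sense <- slice
    nxt <- substr(rep(seq, n - 1L), ex[-1L, 1] + 1L, ex[-1L, 1] + 1L)
  } else {
    # transcription runs right to left: genomically-last gap is intron 0
    idx <- rev(seq_len(n - 1L)) - 1L
    sense <- revcomp(slice)
    # downstream exon in transcription order is the genomically-preceding
    # exon; its first transcribed base is the complement of its last base
    last_base <- substr(rep(seq, n - 1L), ex[-n, 2], ex[-n, 2])
    nxt <- unname(complement_base(last_base))
  }
  out <- data.frame(gene_id = model$gene_id, index = idx,
                    scaffold = model$scaffold_id,
                    start = gstart, end = gend, strand = model$strand,
                    sense_seq = sense, next_exon_base = nxt,
                    stringsAsFactors = FALSE)
  out[order(out$index), , drop = FALSE]
}

#' Extract introns for a whole gene-model set
#'
#' @param models list of gene models.
#' @param genome named character vector of scaffolds.
#' @return data.frame, rbind of [extract_introns()] per gene.
#' @export
extract_all_introns <- function(models, genome) {
  do.call(rbind, c(lapply(models, extract_introns, genome = genome),
                   list(make.row.names = FALSE)))
}

#' Tabulate splice donor and acceptor motifs
#'
#' Donors are the first two intron bases (GT/GC/GA/other); the acceptor AGG
#' motif means the intron ends with AG and the downstream exon starts with G
#' (junction reading AG|G).
#'
#' @param introns data.frame from [extract_introns()].
#' @return list with `donor_counts`, `donor_pct` (sums to 100),
#'   `acceptor_agg_count`, `acceptor_agg_pct`, `n_introns`.
#' @export
tabulate_splice_motifs <- function(introns) {
  if (nrow(introns) == 0L) stop("no introns to tabulate")
  donor <- substr(introns$sense_seq, 1L, 2L)
  cls <- ifelse(donor %in% c("GT", "GC", "GA"), donor, "other")
  cls <- factor(cls, levels = c("GT", "GC", "GA", "other"))
  cnt <- table(cls)
  agg <- endsWith(introns$sense_seq, "AG") & introns$next_exon_base == "G"
  list(donor_counts = cnt,
       donor_pct = 100 * as.numeric(cnt) / nrow(introns),
       acceptor_agg_count = sum(agg),
       acceptor_agg_pct = 100 * mean(agg),
       n_introns = nrow(introns))
}

#' Scan one intron for introner-element terminal repeats
#'
#' Searches the 5' window (first `window` bases of the sense sequence) and
#' the 3' window (last `window` bases); windows are clipped to the intron if
#' it is shorter than `2 * window`. The intron is IE-positive iff BOTH hold:
#' (a) some substring of the 5' window with length in `ir_range` has its
#' reverse complement present in the 3' window (inverted repeat), and (b)
#' some substring of the 5' window with length in `dr_range` occurs verbatim
#' in the 3' window (direct repeat). The longest qualifying repeat of each
#' kind is reported, ties broken by leftmost 5' start then leftmost 3' start.
#'
#' @param sense_seq intron sequence in transcription orientation.
#' @param window terminal window size (bases).
#' @param ir_range,dr_range inclusive length bounds for inverted and direct
#'   repeats.
#' @return list: `is_IE` (logical), `ir` and `dr` either NULL or a list with
#'   `len`, `start5`, `start3` (0-based offsets within the intron).
#' @export
scan_introner <- function(sense_seq, window = 30L,
                          ir_range = c(8L, 20L), dr_range = c(3L, 5L)) {
  n <- nchar(sense_seq)
  w <- min(window, n)
  w5 <- substr(sense_seq, 1L, w)
  off3 <- n - w            # 0-based offset of the 3' window in the intron
  w3 <- substr(sense_seq, off3 + 1L, n)
  ir <- find_longest_repeat(w5, w3, ir_range, inverted = TRUE)
  dr <- find_longest_repeat(w5, w3, dr_range, inverted = FALSE)
  if (!is.null(ir)) ir$start3 <- ir$start3 + off3
  if (!is.null(dr)) dr$start3 <- dr$start3 + off3
  list(is_IE = !is.null(ir) && !is.null(dr), ir = ir, dr = dr)
}

# Longest substring of `w5` (length within `range`) whose (reverse
# complement | verbatim copy) occurs in `w3`. Returns 0-based starts within
# the windows, or NULL.
find_longest_repeat <- function(w5, w3, range, inverted) {
  n5 <- nchar(w5)
  hi <- min(range[2], n5)
  if (hi < range[1]) return(NULL)
  for (len in hi:range[1]) {
    for (i in seq_len(n5 - len + 1L)) {
      s <- substr(w5, i, i + len - 1L)
      probe <- if (inverted) revcomp(s) else s
      j <- regexpr(probe, w3, fixed = TRUE)
      if (j > 0L) {
        return(list(len = len, start5 = i - 1L, start3 = as.integer(j) - 1L))
      }
    }
  }
  NULL
}

#' Scan a set of introns for introner elements
#'
#' @param introns data.frame from [extract_all_introns()].
#' @inheritParams scan_introner
#' @return the input with columns is_IE, ir_len, ir_start5, ir_start3,
#'   dr_len, dr_start5, dr_start3 appended (repeat offsets are 0-based
#'   within the sense-oriented intron; NA when absent).
#' @export
scan_introners <- function(introns, window = 30L,
                           ir_range = c(8L, 20L), dr_range = c(3L, 5L)) {
  res <- lapply(introns$sense_seq, scan_introner, window = window,
                ir_range = ir_range, dr_range = dr_range)
  pick <- function(field, sub) {
    vapply(res, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_integer_ else as.integer(v[[sub]])
    }, integer(1))
  }
  introns$is_IE <- vapply(res, `[[`, logical(1), "is_IE")
  introns$ir_len <- pick("ir", "len")
  introns$ir_start5 <- pick("ir", "start5")
  introns$ir_start3 <- pick("ir", "start3")
  introns$dr_len <- pick("dr", "len")
  introns$dr_start5 <- pick("dr", "start5")
  introns$dr_start3 <- pick("dr", "start3")
  introns
}
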