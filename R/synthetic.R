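# Seeded synthetic-data generator. Emits a complete dataset (genome, gene
# models, transcripts, proteins, pileups, count tables, homology clusters,
# DEG labels) with truth tables for every planted feature class, emulating
# the statistical structure the analyses assume: introner-bearing introns
# with a configurable GT/GC/GA donor mix, condition-specific edit sites,
# duplicated families with directional DEG labels, dinoSL-prefixed
# transcripts, and multi-coding-unit gene models with FVGA-bearing spacers.
#
# All randomness flows from the single config seed; each feature class draws
# from its own sub-stream (seed + fixed offset) so that outputs do not
# depend on generation order.

STAGE_SEED <- c(genome = 101L, cu = 307L, transcripts = 211L, pileups = 401L,
                counts = 503L, families = 601L)

#' Simulation configuration
#'
#' Defaults follow the study design the generator emulates: six conditions
#' (three temperatures x two growth phases) with three replicates, the
#' genome-wide GC content and Table-2-style splice donor mix of a
#' GC-rich dinoflagellate genome, a 4.95% spliced-leader rate, and
#' multi-CU gene layouts with one complete protein copy per odd exon.
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param n_scaffolds,genes_per_scaffold regular-gene layout.
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   intergenic_length_range structural ranges (bp).
#' @param gc_content background G+C fraction.
#' @param donor_mix named proportions over GT/GC/GA donors (sums to 1).
#' @param acceptor_agg_rate probability the exon after an intron starts
#'   with G (AG|G junction motif rate).
#' @param introner_rate fraction of introns planted IE-positive (the planted
#'   count is `round(rate * n_introns)`).
#' @param ir_length_range,dr_length_range,introner_window repeat-planting
#'   geometry (must satisfy the scanner's defaults).
#' @param conditions,n_replicates RNA design.
#' @param edit_site_count,null_site_count planted and background pileup
#'   sites.
#' @param edit_fraction editing fraction at planted sites (scalar or named
#'   per condition); 0 plants nothing.
#' @param edit_condition_rate probability each condition is edited at a
#'   planted site (at least one always is).
#' @param coverage_dna,coverage_rna fixed coverages (Poisson if
#'   `coverage_poisson`).
#' @param coverage_poisson draw coverages from Poisson instead of fixed.
#' @param edit_noise "binomial" draws alternative-base counts
#'   Binomial(coverage, fraction); "none" uses round(fraction * coverage).
#' @param duplicate_family_spec list of planted families, each
#'   `list(mode =, copies =, dirs =)`.
#' @param proximal_max_gap rank gap bound used when placing families.
#' @param sl_rate fraction of transcripts prefixed with the spliced leader.
#' @param sl_sequence,sl_min_match leader sequence and the detector suffix
#'   length the generator keeps collision-free.
#' @param cu_gene_spec data.frame(n_complete, unit_len, spacer_len, partial)
#'   of multi-CU genes to plant.
#' @param cu_identity pairwise identity of planted unit copies (1 = exact).
#' @param cu_partial_frac partial-fragment length as a fraction of the unit.
#' @param n_superclusters,supercluster_amplitude,depth_scale expression
#'   prototypes: number of planted profiles, their log2 amplitude, and the
#'   count depth multiplier.
#' @param deu_exon_count,deu_delta,deu_gene_total,deu_contrast,deu_noise
#'   differential-exon-usage planting: number of shifted exons, usage shift,
#'   per-replicate gene total, the contrasted condition pair, and
#'   "binomial"/"none" count noise.
#' @param deg_contrast name of the DEG label contrast column.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 3L, genes_per_scaffold = 20L,
                       exon_count_range = c(2L, 5L),
                       exon_length_range = c(90L, 240L),
                       intron_length_range = c(70L, 140L),
                       intergenic_length_range = c(100L, 300L),
                       gc_content = 0.597,
                       donor_mix = c(GT = 0.247, GC = 0.515, GA = 0.238),
                       acceptor_agg_rate = 0.797,
                       introner_rate = 0.1,
                       ir_length_range = c(8L, 20L),
                       dr_length_range = c(3L, 5L),
                       introner_window = 30L,
                       conditions = c("20_ex", "26_ex", "30_ex",
                                      "20_st", "26_st", "30_st"),
                       n_replicates = 3L,
                       edit_site_count = 100L, null_site_count = 200L,
                       edit_fraction = 0.4, edit_condition_rate = 0.5,
                       coverage_dna = 20L, coverage_rna = 10L,
                       coverage_poisson = FALSE,
                       edit_noise = c("binomial", "none"),
                       duplicate_family_spec = default_family_spec(),
                       proximal_max_gap = 10L,
                       sl_rate = 0.0495,
                       sl_sequence = DINO_SL, sl_min_match = 10L,
                       cu_gene_spec = default_cu_spec(),
                       cu_identity = 1.0, cu_partial_frac = 0.6,
                       n_superclusters = 8L, supercluster_amplitude = 4,
                       depth_scale = 50,
                       deu_exon_count = 10L, deu_delta = 0.4,
                       deu_gene_total = 300L,
                       deu_contrast = c("20_st", "26_st"),
                       deu_noise = c("binomial", "none"),
                       deg_contrast = "26_st_vs_20_st") {
  cfg <- list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
              genes_per_scaffold = genes_per_scaffold,
              exon_count_range = exon_count_range,
              exon_length_range = exon_length_range,
              intron_length_range = intron_length_range,
              intergenic_length_range = intergenic_length_range,
              gc_content = gc_content, donor_mix = donor_mix,
              acceptor_agg_rate = acceptor_agg_rate,
              introner_rate = introner_rate,
              ir_length_range = ir_length_range,
              dr_length_range = dr_length_range,
              introner_window = introner_window,
              conditions = conditions, n_replicates = n_replicates,
              edit_site_count = edit_site_count,
              null_site_count = null_site_count,
              edit_fraction = edit_fraction,
              edit_condition_rate = edit_condition_rate,
              coverage_dna = coverage_dna, coverage_rna = coverage_rna,
              coverage_poisson = coverage_poisson,
              edit_noise = match.arg(edit_noise),
              duplicate_family_spec = duplicate_family_spec,
              proximal_max_gap = proximal_max_gap,
              sl_rate = sl_rate, sl_sequence = sl_sequence,
              sl_min_match = sl_min_match,
              cu_gene_spec = cu_gene_spec, cu_identity = cu_identity,
              cu_partial_frac = cu_partial_frac,
              n_superclusters = n_superclusters,
              supercluster_amplitude = supercluster_amplitude,
              depth_scale = depth_scale,
              deu_exon_count = deu_exon_count, deu_delta = deu_delta,
              deu_gene_total = deu_gene_total, deu_contrast = deu_contrast,
              deu_noise = match.arg(deu_noise),
              deg_contrast = deg_contrast)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_family_spec <- function() {
  list(list(mode = "tandem", copies = 2L, dirs = c("+", "+")),
       list(mode = "tandem", copies = 2L, dirs = c("+", "-")),
       list(mode = "proximal", copies = 2L, dirs = c("-", "-")),
       list(mode = "proximal", copies = 2L, dirs = c("+", ".")),
       list(mode = "dispersed", copies = 2L, dirs = c("+", "+")),
       list(mode = "dispersed", copies = 2L, dirs = c("-", "+")),
       list(mode = "dispersed", copies = 3L, dirs = c("+", "+", "+")),
       list(mode = "dispersed", copies = 3L, dirs = c("+", "+", "-")),
       list(mode = "dispersed", copies = 3L, dirs = c("-", "-", ".")),
       list(mode = "dispersed", copies = 4L, dirs = c("+", "+", "+", "-")),
       list(mode = "dispersed", copies = 5L,
            dirs = c("+", "+", "+", "+", "-")))
}

default_cu_spec <- function() {
  data.frame(n_complete = c(4L, 3L, 2L, 1L),
             unit_len = c(100L, 120L, 100L, 150L),
             spacer_len = c(20L, 25L, 20L, 0L),
             partial = c(TRUE, FALSE, FALSE, FALSE))
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$donor_mix) - 1) > 1e-9) {
    stop("donor_mix proportions must sum to 1")
  }
  if (any(unlist(cfg[c("n_scaffolds", "genes_per_scaffold", "coverage_dna",
                       "coverage_rna", "n_replicates")]) <= 0)) {
    stop("all counts must be positive")
  }
  if (any(cfg$edit_fraction < 0 | cfg$edit_fraction > 1)) {
    stop("edit_fraction must lie in [0, 1]")
  }
  if (cfg$introner_rate < 0 || cfg$introner_rate > 1 ||
      cfg$sl_rate < 0 || cfg$sl_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (cfg$intron_length_range[1] < 2L * cfg$introner_window) {
    stop("config error: intron_length_range too small to plant introner ",
         "repeats in disjoint terminal windows (need >= ",
         2L * cfg$introner_window, " bp)")
  }
  if (!all(cfg$deu_contrast %in% cfg$conditions)) {
    stop("deu_contrast conditions absent from design")
  }
  invisible(cfg)
}

# Uniform integer in [lo, hi]; safe when lo == hi (unlike sample(lo:hi, 1)).
rint <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

rand_dna <- function(n, gc, forbidden = NULL, tries = 50L) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (t in seq_len(tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
               collapse = "")
    if (is.null(forbidden) || !grepl(forbidden, s, fixed = TRUE)) return(s)
  }
  stop("could not draw sequence avoiding forbidden motif")
}

# Replace a substring at 0-based offset.
splice_in <- function(s, offset, piece) {
  substr(s, offset + 1L, offset + nchar(piece)) <- piece
  s
}

# Build one intron sense sequence with a planted (or verified-absent)
# introner repeat pair. Returns list(seq, ir_len, ir5, ir3, dr_len) with
# 0-based offsets, or ir fields NA when not IE.
make_intron <- function(len, donor, ie, cfg, tries = 100L) {
  w <- cfg$introner_window
  for (t in seq_len(tries)) {
    s <- paste0(donor, rand_dna(len - 4L, cfg$gc_content), "AG")
    if (ie) {
      ir_len <- rint(cfg$ir_length_range[1], cfg$ir_length_range[2])
      dr_max <- min(cfg$dr_length_range[2], 24L - ir_len)
      dr_len <- rint(cfg$dr_length_range[1], dr_max)
      ir <- rand_dna(ir_len, 0.5)
      dr <- rand_dna(dr_len, 0.5)
      a <- 3L                      # 5' IR offset (blocker at 2)
      b <- len - w + 3L            # 3' reverse-complement offset
      s <- splice_in(s, 2L, "A")
      s <- splice_in(s, a, ir)
      s <- splice_in(s, a + ir_len, "A")
      s <- splice_in(s, a + ir_len + 1L, dr)
      s <- splice_in(s, b - 1L, "A")
      s <- splice_in(s, b, revcomp(ir))
      s <- splice_in(s, b + ir_len, "A")
      s <- splice_in(s, b + ir_len + 1L, dr)
      res <- scan_introner(s, window = w, ir_range = cfg$ir_length_range,
                           dr_range = cfg$dr_length_range)
      ok <- res$is_IE && !is.null(res$ir) && res$ir$len == ir_len &&
        res$ir$start5 == a && res$ir$start3 == b
      if (ok) {
        return(list(seq = s, ir_len = ir_len, ir5 = a, ir3 = b,
                    dr_len = dr_len))
      }
    } else {
      res <- scan_introner(s, window = w, ir_range = cfg$ir_length_range,
                           dr_range = cfg$dr_length_range)
      if (!res$is_IE) {
        return(list(seq = s, ir_len = NA_integer_, ir5 = NA_integer_,
                    ir3 = NA_integer_, dr_len = NA_integer_))
      }
    }
  }
  stop("failed to construct intron after ", tries, " attempts")
}

sl_forbidden <- function(cfg) {
  tail <- substr(cfg$sl_sequence,
                 nchar(cfg$sl_sequence) - cfg$sl_min_match + 1L,
                 nchar(cfg$sl_sequence))
  if (grepl("[^ACGT]", tail)) NULL else tail
}

# Lay out and sequence the regular genes. Returns scaffolds (char vector),
# models (list), introns truth, transcripts (named char), exon metadata.
build_regular_genes <- function(cfg) {
  set.seed(cfg$seed + STAGE_SEED[["genome"]])
  forb <- sl_forbidden(cfg)
  n_scaf <- cfg$n_scaffolds
  g_per <- cfg$genes_per_scaffold

  # pass 1: structures
  struct <- list()
  for (s in seq_len(n_scaf)) {
    for (g in seq_len(g_per)) {
      n_ex <- rint(cfg$exon_count_range[1], cfg$exon_count_range[2])
      struct[[length(struct) + 1L]] <- list(
        scaffold = sprintf("s%02d", s),
        gene_id = sprintf("s%02d_g%03d", s, g),
        strand = sample(c("+", "-"), 1L),
        exon_lens = rint(cfg$exon_length_range[1],
                         cfg$exon_length_range[2], n_ex),
        intron_lens = if (n_ex > 1L) {
          rint(cfg$intron_length_range[1], cfg$intron_length_range[2],
               n_ex - 1L)
        } else integer(0))
    }
  }
  n_introns <- sum(vapply(struct, function(x) length(x$intron_lens), 0L))
  n_ie <- round(cfg$introner_rate * n_introns)
  ie_flags <- rep(FALSE, n_introns)
  if (n_ie > 0L) ie_flags[sample(n_introns, n_ie)] <- TRUE

  scaffolds <- setNames(character(n_scaf), sprintf("s%02d", seq_len(n_scaf)))
  models <- list()
  introns <- list()
  transcripts <- character(0)
  ii <- 0L
  for (st in struct) {
    n_ex <- length(st$exon_lens)
    exon_seqs <- character(n_ex)
    for (j in seq_len(n_ex)) {
      e <- rand_dna(st$exon_lens[j], cfg$gc_content, forbidden = forb)
      if (j > 1L) {
        first <- if (runif(1) < cfg$acceptor_agg_rate) "G" else
          sample(c("A", "C", "T"), 1L)
        e <- splice_in(e, 0L, first)
      }
      exon_seqs[j] <- e
    }
    intr <- vector("list", max(n_ex - 1L, 0L))
    donors <- if (n_ex > 1L) {
      sample(names(cfg$donor_mix), n_ex - 1L, replace = TRUE,
             prob = cfg$donor_mix)
    } else character(0)
    for (j in seq_along(intr)) {
      ii <- ii + 1L
      intr[[j]] <- c(make_intron(st$intron_lens[j], donors[j], ie_flags[ii],
                                 cfg), list(is_IE = ie_flags[ii]))
    }
    gap_len <- rint(cfg$intergenic_length_range[1],
                    cfg$intergenic_length_range[2])
    gap_seq <- rand_dna(gap_len, cfg$gc_content)
    asm <- assemble_gene(st, exon_seqs, lapply(intr, `[[`, "seq"),
                         nchar(scaffolds[[st$scaffold]]) + gap_len, cfg)
    scaffolds[[st$scaffold]] <- paste0(scaffolds[[st$scaffold]],
                                       gap_seq, asm$gene_seq)
    models[[st$gene_id]] <- asm$model
    transcripts[[paste0(st$gene_id, ".t1")]] <- asm$transcript
    for (j in seq_along(intr)) {
      introns[[length(introns) + 1L]] <- data.frame(
        gene_id = st$gene_id, index = j - 1L, scaffold = st$scaffold,
        start = asm$intron_ivls[j, 1], end = asm$intron_ivls[j, 2],
        strand = st$strand, is_IE = intr[[j]]$is_IE,
        ir_len = intr[[j]]$ir_len, ir5 = intr[[j]]$ir5,
        ir3 = intr[[j]]$ir3, dr_len = intr[[j]]$dr_len,
        donor = donors[j], stringsAsFactors = FALSE)
    }
  }
  # terminal intergenic tail
  for (s in names(scaffolds)) {
    scaffolds[[s]] <- paste0(scaffolds[[s]],
                             rand_dna(rint(cfg$intergenic_length_range[1],
                                           cfg$intergenic_length_range[2]),
                                      cfg$gc_content))
  }
  list(scaffolds = scaffolds, models = models,
       introns = do.call(rbind, c(introns, list(make.row.names = FALSE))),
       transcripts = transcripts)
}

# Place a gene built in transcription space onto a scaffold at gene_start.
# Returns the genomic gene sequence, the preceding intergenic gap, exon and
# intron genomic intervals, the model, and the transcript.
assemble_gene <- function(st, exon_seqs, intron_seqs, gene_start, cfg,
                          cds_ivls_tx = NULL) {
  n_ex <- length(exon_seqs)
  tx_parts <- character(0)
  exon_tx <- matrix(0L, nrow = n_ex, ncol = 2L)
  intron_tx <- matrix(0L, nrow = max(n_ex - 1L, 0L), ncol = 2L)
  off <- 0L
  for (j in seq_len(n_ex)) {
    exon_tx[j, ] <- c(off, off + nchar(exon_seqs[j]))
    tx_parts <- c(tx_parts, exon_seqs[j])
    off <- off + nchar(exon_seqs[j])
    if (j < n_ex) {
      intron_tx[j, ] <- c(off, off + nchar(intron_seqs[[j]]))
      tx_parts <- c(tx_parts, intron_seqs[[j]])
      off <- off + nchar(intron_seqs[[j]])
    }
  }
  pre_mrna <- paste(tx_parts, collapse = "")
  L <- nchar(pre_mrna)
  to_genomic <- function(iv) {
    if (st$strand == "+") cbind(gene_start + iv[, 1], gene_start + iv[, 2])
    else cbind(gene_start + L - iv[, 2], gene_start + L - iv[, 1])
  }
  exon_g <- to_genomic(exon_tx)
  exon_g <- exon_g[order(exon_g[, 1]), , drop = FALSE]
  intron_g <- if (n_ex > 1L) {
    g <- to_genomic(intron_tx)
    # keep transcription order for the truth table
    if (st$strand == "+") g else g
  } else matrix(integer(0), ncol = 2L)
  gene_seq <- if (st$strand == "+") pre_mrna else revcomp(pre_mrna)
  cds_g <- if (is.null(cds_ivls_tx)) exon_g else {
    cg <- to_genomic(cds_ivls_tx)
    cg[order(cg[, 1]), , drop = FALSE]
  }
  model <- gene_model(st$gene_id, st$scaffold, st$strand,
                      exons = exon_g, cds = cds_g)
  list(gene_seq = gene_seq,
       model = model,
       transcript = paste(exon_seqs, collapse = ""),
       intron_ivls = intron_g)
}

rand_aa <- function(n, ser_ala = FALSE) {
  aa <- AA_ALPHABET
  p <- if (ser_ala) {
    w <- rep(0.6 / 18, 20); names(w) <- aa
    w[c("S", "A")] <- 0.2
    w
  } else rep(1 / 20, 20)
  paste(sample(aa, n, replace = TRUE, prob = p), collapse = "")
}

# Spacer with exactly one FVGA motif. Boundary residues can be constrained
# (avoid_first/avoid_last) so that no two spacers of one gene share a first
# or last residue: shared boundary residues would make the unit/spacer
# boundary genuinely ambiguous and shift the planted truth by one.
make_spacer <- function(len, avoid_first = character(0),
                        avoid_last = character(0), tries = 100L) {
  for (t in seq_len(tries)) {
    s <- rand_aa(len, ser_ala = TRUE)
    o <- sample.int(len - 3L, 1L) - 1L
    s <- splice_in(s, o, "FVGA")
    n_hits <- length(gregexpr("FVGA", s, fixed = TRUE)[[1]])
    if (n_hits == 1L && !grepl("FVAP", s, fixed = TRUE) &&
        !(substr(s, 1L, 1L) %in% avoid_first) &&
        !(substr(s, len, len) %in% avoid_last)) {
      return(list(seq = s, fvga_offset = o))
    }
  }
  stop("failed to construct spacer")
}

CODONS_BY_AA <- NULL
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_ALPHABET]
}

reverse_translate <- function(aa_seq) {
  tab <- codons_by_aa()
  chars <- strsplit(aa_seq, "")[[1]]
  paste(vapply(chars, function(a) {
    cands <- tab[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

mutate_protein <- function(aa_seq, identity) {
  n <- nchar(aa_seq)
  k <- round((1 - identity) * n)
  if (k == 0L) return(aa_seq)
  pos <- sample.int(n, k)
  chars <- strsplit(aa_seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
  paste(chars, collapse = "")
}

# Build the multi-CU genes on their own scaffold. Returns scaffold seq,
# models, proteins, transcripts, CU truth, spacer-motif truth, and the
# intron truth rows for CU-gene introns (all IE-negative).
build_cu_genes <- function(cfg) {
  set.seed(cfg$seed + STAGE_SEED[["cu"]])
  spec <- cfg$cu_gene_spec
  scaf_id <- sprintf("s%02d", cfg$n_scaffolds + 1L)
  scaffold <- ""
  models <- list(); proteins <- character(0); transcripts <- character(0)
  cu_truth <- list(); motif_truth <- list(); introns <- list()
  for (i in seq_len(nrow(spec))) {
    gene_id <- sprintf("cu_g%02d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    unit <- rand_aa(spec$unit_len[i])
    n_units <- spec$n_complete[i]
    copies <- vapply(seq_len(n_units), function(j) {
      if (cfg$cu_identity >= 1) unit else mutate_protein(unit, cfg$cu_identity)
    }, character(1))
    frag_len <- if (spec$partial[i]) {
      as.integer(round(cfg$cu_partial_frac * spec$unit_len[i]))
    } else 0L
    segments <- list()   # residue-space pieces: kind, seq
    sp_first <- character(0); sp_last <- character(0)
    for (j in seq_len(n_units)) {
      segments[[length(segments) + 1L]] <- list(kind = "unit", seq = copies[j])
      if (j < n_units || frag_len > 0L) {
        if (spec$spacer_len[i] > 0L) {
          sp <- make_spacer(spec$spacer_len[i], avoid_first = sp_first,
                            avoid_last = sp_last)
          sp_first <- c(sp_first, substr(sp$seq, 1L, 1L))
          sp_last <- c(sp_last, substr(sp$seq, nchar(sp$seq), nchar(sp$seq)))
          segments[[length(segments) + 1L]] <-
            list(kind = "spacer", seq = sp$seq, fvga_offset = sp$fvga_offset)
        }
      }
    }
    if (frag_len > 0L) {
      segments[[length(segments) + 1L]] <-
        list(kind = "partial", seq = substr(unit, 1L, frag_len))
    }
    protein <- paste(vapply(segments, `[[`, "", "seq"), collapse = "")
    proteins[[gene_id]] <- protein

    # residue intervals (0-based half-open) + exon sequences via reverse
    # translation, one exon per segment
    off <- 0L; exon_seqs <- character(0); seg_rows <- list()
    kind_counter <- c(unit = 0L, spacer = 0L, partial = 0L)
    for (sg in segments) {
      len <- nchar(sg$seq)
      kind_counter[sg$kind] <- kind_counter[sg$kind] + 1L
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        gene_id = gene_id, kind = sg$kind, idx = kind_counter[[sg$kind]],
        start = off, end = off + len, stringsAsFactors = FALSE)
      if (sg$kind == "spacer") {
        motif_truth[[length(motif_truth) + 1L]] <- data.frame(
          gene_id = gene_id, spacer_idx = kind_counter[["spacer"]],
          fvga_offset = sg$fvga_offset, spacer_len = len,
          stringsAsFactors = FALSE)
      }
      exon_seqs <- c(exon_seqs, reverse_translate(sg$seq))
      off <- off + len
    }
    n_ex <- length(exon_seqs)
    intron_seqs <- list()
    if (n_ex > 1L) {
      for (j in seq_len(n_ex - 1L)) {
        lenj <- rint(cfg$intron_length_range[1],
                     cfg$intron_length_range[2])
        intron_seqs[[j]] <- make_intron(lenj, "GT", FALSE, cfg)
      }
    }
    gene_start <- nchar(scaffold) +
      rint(cfg$intergenic_length_range[1], cfg$intergenic_length_range[2])
    gap <- rand_dna(gene_start - nchar(scaffold), cfg$gc_content)
    st <- list(scaffold = scaf_id, gene_id = gene_id, strand = strand)
    asm <- assemble_gene(st, exon_seqs, lapply(intron_seqs, `[[`, "seq"),
                         gene_start, cfg)
    scaffold <- paste0(scaffold, gap, asm$gene_seq)
    models[[gene_id]] <- asm$model
    transcripts[[paste0(gene_id, ".t1")]] <- asm$transcript
    cu_truth[[length(cu_truth) + 1L]] <-
      do.call(rbind, c(seg_rows, list(make.row.names = FALSE)))
    for (j in seq_along(intron_seqs)) {
      introns[[length(introns) + 1L]] <- data.frame(
        gene_id = gene_id, index = j - 1L, scaffold = scaf_id,
        start = asm$intron_ivls[j, 1], end = asm$intron_ivls[j, 2],
        strand = strand, is_IE = FALSE, ir_len = NA_integer_,
        ir5 = NA_integer_, ir3 = NA_integer_, dr_len = NA_integer_,
        donor = "GT", stringsAsFactors = FALSE)
    }
  }
  scaffold <- paste0(scaffold,
                     rand_dna(rint(cfg$intergenic_length_range[1],
                                   cfg$intergenic_length_range[2]),
                              cfg$gc_content))
  list(scaffold = setNames(scaffold, scaf_id), models = models,
       proteins = proteins, transcripts = transcripts,
       cu_truth = do.call(rbind, c(cu_truth, list(make.row.names = FALSE))),
       motif_truth = if (length(motif_truth)) {
         do.call(rbind, c(motif_truth, list(make.row.names = FALSE)))
       } else data.frame(gene_id = character(0), spacer_idx = integer(0),
                         fvga_offset = integer(0), spacer_len = integer(0)),
       introns = if (length(introns)) {
         do.call(rbind, c(introns, list(make.row.names = FALSE)))
       } else NULL)
}

# Prefix round(sl_rate * n) transcripts with a concrete spliced leader.
tag_spliced_leaders <- function(cfg, transcripts) {
  set.seed(cfg$seed + STAGE_SEED[["transcripts"]])
  forb <- sl_forbidden(cfg)
  if (!is.null(forb) && any(grepl(forb, transcripts, fixed = TRUE))) {
    stop("spliced-leader collision in a transcript body; use another seed")
  }
  n <- length(transcripts)
  n_sl <- round(cfg$sl_rate * n)
  chosen <- if (n_sl > 0L) sort(sample.int(n, n_sl)) else integer(0)
  sl_concrete <- character(length(chosen))
  for (k in seq_along(chosen)) {
    sl <- cfg$sl_sequence
    amb <- gregexpr("[^ACGT]", sl)[[1]]
    if (amb[1] != -1L) {
      for (p in as.integer(amb)) {
        code <- strsplit(Biostrings::IUPAC_CODE_MAP[substr(sl, p, p)], "")[[1]]
        substr(sl, p, p) <- sample(code, 1L)
      }
    }
    sl_concrete[k] <- sl
    transcripts[chosen[k]] <- paste0(sl, transcripts[chosen[k]])
  }
  list(transcripts = transcripts,
       truth = data.frame(transcript_id = names(transcripts)[chosen],
                          sl_seq = sl_concrete, stringsAsFactors = FALSE))
}

# Plant edit sites and emit the pileup table.
build_pileups <- function(cfg, scaffolds, models, design) {
  set.seed(cfg$seed + STAGE_SEED[["pileups"]])
  regular <- models[!startsWith(names(models), "cu_")]
  # candidate exonic positions
  cand <- do.call(rbind, lapply(regular, function(m) {
    pos <- unlist(lapply(seq_len(nrow(m$exons)), function(i) {
      seq.int(m$exons[i, 1], m$exons[i, 2] - 1L)
    }))
    data.frame(scaffold = m$scaffold_id, pos = pos, gene_id = m$gene_id,
               strand = m$strand, stringsAsFactors = FALSE)
  }))
  cand <- cand[!duplicated(paste(cand$scaffold, cand$pos)), ]
  n_edit <- if (all(cfg$edit_fraction == 0)) 0L else cfg$edit_site_count
  n_total <- n_edit + cfg$null_site_count
  if (n_total > nrow(cand)) stop("not enough exonic positions for sites")
  pick <- cand[sample.int(nrow(cand), n_total), , drop = FALSE]
  pick$ref <- substr(scaffolds[pick$scaffold],
                     pick$pos + 1L, pick$pos + 1L)
  pick <- pick[pick$ref %in% PILEUP_BASES, , drop = FALSE]
  pick$planted <- seq_len(nrow(pick)) <= n_edit

  conds <- cfg$conditions
  frac_of <- function(cond) {
    if (length(cfg$edit_fraction) == 1L) cfg$edit_fraction
    else cfg$edit_fraction[[cond]]
  }
  alt <- character(nrow(pick)); fr <- matrix(0, nrow(pick), length(conds),
                                             dimnames = list(NULL, conds))
  for (i in seq_len(nrow(pick))) {
    if (!pick$planted[i]) { alt[i] <- NA_character_; next }
    alt[i] <- sample(setdiff(PILEUP_BASES, pick$ref[i]), 1L)
    repeat {
      on <- runif(length(conds)) < cfg$edit_condition_rate
      if (any(on)) break
    }
    fr[i, on] <- vapply(conds[on], frac_of, numeric(1))
  }
  pick$alt <- alt

  cov_of <- function(target, n) {
    if (cfg$coverage_poisson) stats::rpois(n, target) else rep(target, n)
  }
  rows <- list()
  n <- nrow(pick)
  base_idx <- match(pick$ref, PILEUP_BASES)
  dcov <- cov_of(cfg$coverage_dna, n)
  dmat <- matrix(0L, n, 4L); dmat[cbind(seq_len(n), base_idx)] <- dcov
  rows[[1]] <- data.frame(scaffold = pick$scaffold, pos = pick$pos,
                          sample_kind = "DNA", condition = "DNA",
                          replicate = 0L, nA = dmat[, 1], nC = dmat[, 2],
                          nG = dmat[, 3], nT = dmat[, 4],
                          stringsAsFactors = FALSE)
  alt_idx <- match(pick$alt, PILEUP_BASES)
  for (cond in conds) {
    for (r in seq_len(cfg$n_replicates)) {
      cov <- cov_of(cfg$coverage_rna, n)
      f <- ifelse(pick$planted, fr[, cond], 0)
      k <- if (cfg$edit_noise == "binomial") rbinom(n, cov, f) else
        as.integer(round(f * cov))
      m <- matrix(0L, n, 4L)
      m[cbind(seq_len(n), base_idx)] <- cov - k
      has_alt <- !is.na(alt_idx) & k > 0L
      m[cbind(which(has_alt), alt_idx[has_alt])] <- k[has_alt]
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = pick$scaffold, pos = pick$pos, sample_kind = "RNA",
        condition = cond, replicate = r, nA = m[, 1], nC = m[, 2],
        nG = m[, 3], nT = m[, 4], stringsAsFactors = FALSE)
    }
  }
  pileup <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  truth <- pick[pick$planted, c("scaffold", "pos", "gene_id", "strand",
                                "ref", "alt")]
  if (nrow(truth)) {
    truth$edit_type <- classify_edit_type(truth$ref, truth$alt, truth$strand)
    for (cond in conds) truth[[paste0("f_", cond)]] <- fr[pick$planted, cond]
  } else {
    truth$edit_type <- character(0)
    for (cond in conds) truth[[paste0("f_", cond)]] <- numeric(0)
  }
  rownames(truth) <- NULL
  list(pileup = pileup, truth = truth)
}

supercluster_patterns <- function(n_conditions, k) {
  if (n_conditions == 6L && k == 8L) {
    rbind(c(1, 1, 1, -1, -1, -1), c(-1, -1, -1, 1, 1, 1),
          c(1, -1, 1, -1, 1, -1), c(-1, 1, -1, 1, -1, 1),
          c(1, -1, -1, 1, 1, -1), c(-1, 1, 1, -1, -1, 1),
          c(1, 0, -1, 1, 0, -1), c(-1, 0, 1, -1, 0, 1))
  } else {
    repeat {
      p <- matrix(sample(c(-1, 1), k * n_conditions, replace = TRUE),
                  nrow = k)
      if (nrow(unique(p)) == k) return(p)
    }
  }
}

# Gene counts carrying k planted expression prototypes, and exon counts
# carrying planted differential exon usage.
build_counts <- function(cfg, models, design) {
  set.seed(cfg$seed + STAGE_SEED[["counts"]])
  genes <- names(models)
  k <- cfg$n_superclusters
  pat <- supercluster_patterns(length(cfg$conditions), k)
  proto <- ((seq_along(genes) - 1L) %% k) + 1L
  exon_len <- vapply(models, function(m) sum(m$exons[, 2] - m$exons[, 1]),
                     numeric(1))
  log_target <- 3 + (cfg$supercluster_amplitude / 2) *
    pat[proto, match(design$condition, cfg$conditions), drop = FALSE]
  fpkm_target <- 2^log_target - 1
  counts <- round(fpkm_target * (exon_len / 1e3) * cfg$depth_scale)
  dimnames(counts) <- list(genes, design$sample)

  # exon counts with planted DEU on the contrast pair
  regular <- models[!startsWith(names(models), "cu_")]
  exon_rows <- do.call(rbind, lapply(regular, function(m) {
    n_ex <- nrow(m$exons)
    lens <- m$exons[, 2] - m$exons[, 1]
    tx_order <- if (m$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    data.frame(exon_id = paste0(m$gene_id, ":e", seq_len(n_ex)),
               gene_id = m$gene_id, len = lens[tx_order],
               stringsAsFactors = FALSE)
  }))
  usage_base <- stats::ave(exon_rows$len, exon_rows$gene_id,
                           FUN = function(x) x / sum(x))
  multi <- exon_rows$gene_id %in%
    names(which(table(exon_rows$gene_id) >= 2L))
  cand <- which(multi & !duplicated(exon_rows$gene_id))
  n_deu <- min(cfg$deu_exon_count, length(cand))
  deu_idx <- sort(sample(cand, n_deu))
  usage_b <- usage_base
  for (i in deu_idx) {
    u <- usage_base[i]
    shift <- if (u + cfg$deu_delta <= 0.9) cfg$deu_delta else -cfg$deu_delta
    target <- u + shift
    gi <- exon_rows$gene_id == exon_rows$gene_id[i]
    usage_b[gi] <- usage_base[gi] * (1 - target) / (1 - u)
    usage_b[i] <- target
  }
  cond_a <- cfg$deu_contrast[1]; cond_b <- cfg$deu_contrast[2]
  ex_counts <- matrix(0L, nrow(exon_rows), nrow(design),
                      dimnames = list(exon_rows$exon_id, design$sample))
  for (s in seq_len(nrow(design))) {
    u <- if (design$condition[s] == cond_b) usage_b else usage_base
    ex_counts[, s] <- if (cfg$deu_noise == "binomial") {
      rbinom(nrow(exon_rows), cfg$deu_gene_total, u)
    } else as.integer(round(cfg$deu_gene_total * u))
  }
  deu_truth <- data.frame(exon_id = exon_rows$exon_id[deu_idx],
                          gene_id = exon_rows$gene_id[deu_idx],
                          usage_a = usage_base[deu_idx],
                          usage_b = usage_b[deu_idx],
                          delta = usage_b[deu_idx] - usage_base[deu_idx],
                          stringsAsFactors = FALSE)
  list(gene_counts = counts,
       exon_counts = ex_counts, gene_of_exon = exon_rows$gene_id,
       supercluster_truth = data.frame(gene = genes, prototype = proto,
                                       stringsAsFactors = FALSE),
       deu_truth = deu_truth)
}

# Place duplicate families on the regular-gene rank grid and emit homology
# clusters plus DEG direction labels.
build_families <- function(cfg, models) {
  set.seed(cfg$seed + STAGE_SEED[["families"]])
  regular <- models[!startsWith(names(models), "cu_")]
  scaf <- vapply(regular, `[[`, "", "scaffold_id")
  rank <- vapply(regular, `[[`, integer(1), "rank")
  ids <- names(regular)
  by_scaf <- split(seq_along(ids), scaf)
  free <- lapply(by_scaf, function(i) setNames(rank[i], ids[i]))
  scaf_names <- names(free)

  take <- function(s, r) {
    nm <- names(free[[s]])[free[[s]] == r]
    free[[s]] <<- free[[s]][names(free[[s]]) != nm]
    nm
  }
  fam_rows <- list()
  for (fi in seq_along(cfg$duplicate_family_spec)) {
    fam <- cfg$duplicate_family_spec[[fi]]
    cl <- sprintf("fam%02d", fi)
    members <- character(0)
    if (fam$mode == "tandem") {
      found <- FALSE
      for (s in sample(scaf_names)) {
        rs <- sort(free[[s]])
        adj <- rs[which(diff(rs) == 1L)]
        if (length(adj)) {
          r <- adj[sample.int(length(adj), 1L)]
          members <- c(take(s, r), take(s, r + 1L))
          found <- TRUE; break
        }
      }
      if (!found) stop("no room to place tandem family ", cl)
    } else if (fam$mode == "proximal") {
      found <- FALSE
      for (s in sample(scaf_names)) {
        rs <- sort(free[[s]])
        pairs <- list()
        for (g in 2:cfg$proximal_max_gap) {
          ok <- rs[(rs + g) %in% rs]
          for (r in ok) pairs[[length(pairs) + 1L]] <- c(r, r + g)
        }
        if (length(pairs)) {
          pr <- pairs[[sample.int(length(pairs), 1L)]]
          members <- c(take(s, pr[1]), take(s, pr[2]))
          found <- TRUE; break
        }
      }
      if (!found) stop("no room to place proximal family ", cl)
    } else if (fam$mode == "dispersed") {
      placed_ranks <- list()
      for (ci in seq_len(fam$copies)) {
        pref <- scaf_names[((ci - 1L) %% length(scaf_names)) + 1L]
        order_s <- c(pref, setdiff(scaf_names, pref))
        placed <- FALSE
        for (s in order_s) {
          prev <- placed_ranks[[s]] %||% integer(0)
          ok <- free[[s]][vapply(free[[s]], function(r) {
            length(prev) == 0L || min(abs(r - prev)) > cfg$proximal_max_gap
          }, logical(1))]
          if (length(ok) == 0L) next
          # first copy on a scaffold takes an extreme rank, later copies the
          # farthest free rank, so repeat visits stay beyond the proximal gap
          r <- if (length(prev) == 0L) min(ok) else {
            unname(ok[which.max(vapply(ok, function(x) min(abs(x - prev)),
                                       numeric(1)))])
          }
          placed_ranks[[s]] <- c(prev, r)
          members <- c(members, take(s, r))
          placed <- TRUE
          break
        }
        if (!placed) stop("no room for dispersed family ", cl)
      }
    } else stop("unknown family mode: ", fam$mode)
    fam_rows[[fi]] <- data.frame(cluster_id = cl, gene_id = members,
                                 mode = fam$mode, dir = fam$dirs,
                                 stringsAsFactors = FALSE)
  }
  fam <- if (length(fam_rows)) {
    do.call(rbind, c(fam_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cluster_id = character(0), gene_id = character(0),
               mode = character(0), dir = character(0),
               stringsAsFactors = FALSE)
  }

  # singleton clusters for a handful of unplaced genes
  leftovers <- sort(unlist(lapply(free, names), use.names = FALSE))
  n_sng <- min(10L, length(leftovers))
  sng <- data.frame(cluster_id = sprintf("sng%02d", seq_len(n_sng)),
                    gene_id = leftovers[seq_len(n_sng)],
                    mode = "singleton", dir = ".", stringsAsFactors = FALSE)
  clusters <- rbind(fam[, c("cluster_id", "gene_id")],
                    sng[, c("cluster_id", "gene_id")])

  labels <- data.frame(row.names = names(models))
  lab <- sample(c("+", "-", "."), length(models), replace = TRUE,
                prob = c(0.1, 0.1, 0.8))
  names(lab) <- names(models)
  lab[fam$gene_id] <- fam$dir
  lab[startsWith(names(models), "cu_")] <- "."
  labels[[cfg$deg_contrast]] <- unname(lab[rownames(labels)])

  # self-check: recovered modes must equal the planted modes
  modes <- classify_duplication_modes(clusters, models,
                                      proximal_max_gap = cfg$proximal_max_gap)
  planted <- rbind(fam, sng)
  m <- merge(modes, planted, by = c("cluster_id", "gene_id"))
  if (!all(m$mode.x == m$mode.y)) {
    stop("internal error: family placement does not realise planted modes")
  }
  list(clusters = clusters, labels = labels, truth = planted)
}

#' Generate a complete synthetic dataset
#'
#' Writes genome FASTA, GFF3 gene models, transcript and protein FASTA,
#' pileup TSV, gene/exon count TSVs, homology clusters, DEG labels, the
#' echoed config (YAML) and per-feature truth tables (under `truth/`).
#' Fully deterministic given `config$seed`; running twice produces
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `truth` tables, `paths`, and the in-memory
#'   `genome`, `models`, `transcripts`, `proteins`, `pileup`, `design`,
#'   count matrices.
#' @export
generate_dataset <- function(config, out_dir) {
  cfg <- config
  validate_sim_config(cfg)
  design <- condition_design(cfg$conditions, cfg$n_replicates)

  reg <- build_regular_genes(cfg)
  cu <- build_cu_genes(cfg)
  genome <- c(reg$scaffolds, cu$scaffold)
  models <- assign_gene_ranks(c(reg$models, cu$models))
  class(models) <- "gene_model_set"
  transcripts <- c(reg$transcripts, cu$transcripts)
  sl <- tag_spliced_leaders(cfg, transcripts)
  transcripts <- sl$transcripts
  pile <- build_pileups(cfg, genome, models, design)
  cnt <- build_counts(cfg, models, design)
  fams <- build_families(cfg, models)
  introns <- rbind(reg$introns, cu$introns)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    gff3 = file.path(out_dir, "genes.gff3"),
    transcripts = file.path(out_dir, "transcripts.fasta"),
    proteins = file.path(out_dir, "proteins.fasta"),
    pileup = file.path(out_dir, "pileup.tsv"),
    gene_counts = file.path(out_dir, "gene_counts.tsv"),
    exon_counts = file.path(out_dir, "exon_counts.tsv"),
    clusters = file.path(out_dir, "clusters.tsv"),
    deg_labels = file.path(out_dir, "deg_labels.tsv"),
    config = file.path(out_dir, "config.yaml"))

  write_genome_fasta(genome, paths$genome)
  write_gene_models(models, paths$gff3)
  write_genome_fasta(transcripts, paths$transcripts)
  writeLines(unlist(lapply(names(cu$proteins), function(id) {
    c(paste0(">", id), cu$proteins[[id]])
  })), paths$proteins)
  write_pileup_table(pile$pileup, paths$pileup)
  write_count_table(cnt$gene_counts, paths$gene_counts, id_col = "gene_id")
  write_count_table(cnt$exon_counts, paths$exon_counts, id_col = "exon_id")
  write.table(fams$clusters, paths$clusters, sep = "\t", quote = FALSE,
              row.names = FALSE)
  deg_out <- data.frame(gene_id = rownames(fams$labels), fams$labels,
                        check.names = FALSE)
  deg_con <- file(paths$deg_labels, "w")
  writeLines("# DEG labels precomputed upstream (edgeR glmQLF, BH p <= 0.001, |log2FC| >= 2)",
             deg_con)
  write.table(deg_out, deg_con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(deg_con)
  cfg_plain <- unclass(cfg)
  cfg_plain$cu_gene_spec <- as.list(cfg$cu_gene_spec)
  yaml::write_yaml(cfg_plain, paths$config)

  truth <- list(introns = introns, edit_sites = pile$truth,
                sl_transcripts = sl$truth, cu_units = cu$cu_truth,
                cu_spacer_motifs = cu$motif_truth,
                families = fams$truth,
                superclusters = cnt$supercluster_truth,
                deu_exons = cnt$deu_truth)
  for (nm in names(truth)) {
    write.table(truth[[nm]], file.path(tdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(truth = truth, paths = paths, genome = genome,
                 models = models, transcripts = transcripts,
                 proteins = cu$proteins, pileup = pile$pileup,
                 design = design, gene_counts = cnt$gene_counts,
                 exon_counts = cnt$exon_counts,
                 gene_of_exon = cnt$gene_of_exon,
                 clusters = fams$clusters, deg_labels = fams$labels))
}
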