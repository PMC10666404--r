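# Readers/writers for all on-disk formats. This file is the single place where
# the 1-based inclusive (GFF3, pileup TSV) <-> 0-based half-open (internal)
# conversion happens.

#' Convert GFF3 coordinates to internal 0-based half-open intervals
#'
#' @param start,end 1-based inclusive coordinates.
#' @return integer matrix with columns `start`, `end` (0-based half-open).
#' @export
gff_to_internal <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert internal intervals back to GFF3 1-based inclusive coordinates
#'
#' Involution partner of [gff_to_internal()].
#'
#' @param ivl integer matrix with columns `start`, `end` (0-based half-open).
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
internal_to_gff <- function(ivl) {
  data.frame(start = ivl[, 1] + 1L, end = ivl[, 2])
}

#' Read genome scaffolds from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase scaffold sequences (A/C/G/T/N).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_genome(seqs)
  seqs
}

#' Write scaffold sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

validate_genome <- function(seqs) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("genome sequences must be named by scaffold id")
  }
  if (any(nchar(seqs) == 0L)) stop("empty scaffold sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("scaffold(s) contain non-ACGTN characters: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

#' Construct a gene model
#'
#' Internal constructor used by the GFF3 reader and the synthetic generator.
#' Exons/CDS are 0-based half-open genomic intervals in ascending order
#' regardless of strand; transcription order is derived on demand.
#'
#' @param gene_id,scaffold_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds integer matrices with columns start, end.
#' @param rank 0-based position of the gene among the genes of its scaffold
#'   ordered by start (assigned by [assign_gene_ranks()]).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, cds = exons,
                       rank = NA_integer_) {
  exons <- as_interval_matrix(exons)
  cds <- as_interval_matrix(cds)
  stopifnot(strand %in% c("+", "-"))
  if (nrow(exons) == 0L) stop("gene model must have at least one exon: ", gene_id)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty exon interval in ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in ", gene_id)
  }
  if (nrow(cds) > 0L && !intervals_within(cds, exons)) {
    stop("CDS not contained in exons for gene ", gene_id)
  }
  structure(
    list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         exons = exons, cds = cds, rank = as.integer(rank)),
    class = "gene_model"
  )
}

as_interval_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m
}

# TRUE iff every interval of `inner` lies within the union of `outer`.
intervals_within <- function(inner, outer) {
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, 1] <= inner[i, 1] & inner[i, 2] <= outer[, 2])
  }, logical(1)))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s), %d exon(s), rank %s\n",
              x$gene_id, x$scaffold_id, x$strand, nrow(x$exons),
              ifelse(is.na(x$rank), "NA", x$rank)))
  invisible(x)
}

#' Assign per-scaffold gene ranks
#'
#' Genes on each scaffold are ordered by ascending start (ties broken by
#' gene id, which also covers overlapping models) and numbered from 0.
#'
#' @param models named list of `gene_model`s.
#' @return the list with `rank` filled in.
#' @export
assign_gene_ranks <- function(models) {
  scaf <- vapply(models, `[[`, "", "scaffold_id")
  start <- vapply(models, function(m) m$exons[1, 1], integer(1))
  ids <- vapply(models, `[[`, "", "gene_id")
  for (s in unique(scaf)) {
    idx <- which(scaf == s)
    o <- idx[order(start[idx], ids[idx])]
    for (r in seq_along(o)) models[[o[r]]]$rank <- r - 1L
  }
  models
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 subset (gene/mRNA/exon/CDS with ID/Parent attributes) into a
#' named list of [gene_model()]s. If a gene carries several mRNAs, the first
#' mRNA by ID sort is kept with a warning. Coordinates are converted to
#' 0-based half-open; per-scaffold ranks are assigned.
#'
#' @param gff3_path GFF3 file (1-based inclusive coordinates).
#' @param genome optional named character vector of scaffolds; when given,
#'   exon bounds are validated against scaffold lengths.
#' @return named list of `gene_model`, class `gene_model_set`.
#' @export
read_gene_models <- function(gff3_path, genome = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  typ <- as.character(gr$type)
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = typ,
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(as.list(gr$Parent %||% character(nrow(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  if (nrow(mrna) == 0L) stop("no mRNA features in ", gff3_path)
  # one model per gene: first mRNA by ID sort
  mrna <- mrna[order(mrna$parent, mrna$id), , drop = FALSE]
  dup <- duplicated(mrna$parent)
  if (any(dup)) {
    warning(sum(dup), " additional mRNA(s) ignored; keeping first per gene")
    mrna <- mrna[!dup, , drop = FALSE]
  }
  models <- vector("list", nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    m <- mrna[i, ]
    kids <- df[!is.na(df$parent) & df$parent == m$id, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) stop("mRNA without exons: ", m$id)
    if (!is.null(genome)) {
      slen <- nchar(genome[[m$scaffold]])
      if (is.null(slen)) stop("unknown scaffold in GFF3: ", m$scaffold)
      bad <- ex$start < 1L | ex$end > slen
      if (any(bad)) {
        stop("exon outside scaffold bounds for feature ",
             ex$id[bad][1] %||% m$id, " on ", m$scaffold)
      }
    }
    gene_id <- if (!is.na(m$parent)) m$parent else m$id
    models[[i]] <- gene_model(
      gene_id = gene_id, scaffold_id = m$scaffold, strand = m$strand,
      exons = gff_to_internal(ex$start, ex$end),
      cds = if (nrow(cd)) gff_to_internal(cd$start, cd$end)
            else matrix(integer(0), ncol = 2)
    )
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models <- assign_gene_ranks(models)
  structure(models, class = "gene_model_set")
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with ID/Parent attributes, 1-based
#' inclusive coordinates, sorted by (scaffold, start, gene id).
#'
#' @param models list of `gene_model`.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  scaf <- vapply(models, `[[`, "", "scaffold_id")
  start <- vapply(models, function(m) m$exons[1, 1], integer(1))
  ids <- vapply(models, `[[`, "", "gene_id")
  for (i in order(scaf, start, ids)) {
    m <- models[[i]]
    g1 <- internal_to_gff(m$exons)
    lo <- min(g1$start); hi <- max(g1$end)
    mid <- paste0(m$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tdinoarch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$scaffold_id, lo, hi, m$strand, m$gene_id),
      sprintf("%s\tdinoarch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$scaffold_id, lo, hi, m$strand, mid, m$gene_id),
      sprintf("%s\tdinoarch\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              m$scaffold_id, g1$start, g1$end, m$strand, mid,
              seq_len(nrow(m$exons)), mid))
    if (nrow(m$cds)) {
      c1 <- internal_to_gff(m$cds)
      lines <- c(lines,
        sprintf("%s\tdinoarch\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                m$scaffold_id, c1$start, c1$end, m$strand, mid, mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a condition/replicate design
#'
#' @param conditions character vector of condition names.
#' @param n_replicates replicates per condition.
#' @return data.frame with columns `condition`, `replicate`, `sample`.
#' @export
condition_design <- function(conditions, n_replicates = 3L) {
  d <- expand.grid(replicate = seq_len(n_replicates), condition = conditions,
                   stringsAsFactors = FALSE)[, c("condition", "replicate")]
  d$sample <- paste0(d$condition, "_r", d$replicate)
  d
}

PILEUP_COLS <- c("scaffold", "pos", "sample_kind", "condition", "replicate",
                 "nA", "nC", "nG", "nT")

#' Read a per-site base-count pileup table
#'
#' TSV with header columns scaffold, pos (1-based), sample_kind (DNA/RNA),
#' condition, replicate, nA, nC, nG, nT and an optional `coverage` column
#' that, when present, must equal the count sum of each row. Positions are
#' converted to 0-based. RNA rows must match the design; DNA rows must carry
#' condition "DNA" and replicate 0.
#'
#' @param tsv_path input file.
#' @param design data.frame from [condition_design()].
#' @return data.frame of pileup sites (pos 0-based).
#' @export
read_pileup_table <- function(tsv_path, design) {
  p <- read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!all(PILEUP_COLS %in% names(p))) {
    stop("pileup table missing columns: ",
         paste(setdiff(PILEUP_COLS, names(p)), collapse = ", "))
  }
  cnt <- as.matrix(p[, c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) stop("negative count in pileup table")
  if ("coverage" %in% names(p) && any(rowSums(cnt) != p$coverage)) {
    stop("coverage column inconsistent with base counts")
  }
  rna <- p$sample_kind == "RNA"
  key <- paste(p$condition, p$replicate)
  ok <- key[rna] %in% paste(design$condition, design$replicate)
  if (!all(ok)) {
    stop("RNA pileup rows with condition/replicate absent from design: ",
         paste(unique(key[rna][!ok]), collapse = ", "))
  }
  if (any(p$condition[!rna] != "DNA" | p$replicate[!rna] != 0L)) {
    stop("DNA pileup rows must carry condition 'DNA' and replicate 0")
  }
  p$pos <- as.integer(p$pos) - 1L
  p[, PILEUP_COLS]
}

#' Write a pileup table
#'
#' Inverse of [read_pileup_table()]: positions written 1-based; row order is
#' canonicalised (scaffold, pos, DNA before RNA, condition, replicate) so that
#' write -> read -> write round-trips byte-identically.
#'
#' @param pileup data.frame with 0-based `pos`.
#' @param path output file.
#' @export
write_pileup_table <- function(pileup, path) {
  p <- pileup[, PILEUP_COLS]
  p <- p[order(p$scaffold, p$pos, p$sample_kind != "DNA", p$condition,
               p$replicate), ]
  p$pos <- p$pos + 1L
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param records data.frame with columns chrom, start, end (0-based
#'   half-open), name, score, strand.
#' @param path output file.
#' @export
write_bed_intervals <- function(records, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("BED records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$start >= records$end)) {
    stop("BED interval with start >= end")
  }
  r <- records[order(records$chrom, records$start), need]
  write.table(r, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file written by [write_bed_intervals()]
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end, name, score, strand.
#' @export
read_bed_intervals <- function(path) {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(b) <- c("chrom", "start", "end", "name", "score", "strand")
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  b
}

#' Read an expression count table
#'
#' TSV with row ids in the first column and one column per sample.
#'
#' @param path TSV file.
#' @return numeric matrix, rows = features, columns = samples.
#' @export
read_count_table <- function(path) {
  d <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (any(m < 0)) stop("negative value in count table")
  m
}

#' Write an expression count table
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file.
#' @param id_col header name of the id column.
#' @export
write_count_table <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read homology cluster membership
#'
#' TSV with columns cluster_id, gene_id; a gene may belong to at most one
#' cluster.
#'
#' @param path TSV file.
#' @return data.frame with cluster_id, gene_id.
#' @export
read_clusters <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "gene_id") %in% names(cl))) {
    stop("cluster table needs cluster_id and gene_id columns")
  }
  if (anyDuplicated(cl$gene_id)) {
    stop("gene assigned to more than one cluster: ",
         cl$gene_id[duplicated(cl$gene_id)][1])
  }
  cl
}

#' Read a DEG direction label table
#'
#' TSV with a gene_id column and one column per contrast holding labels from
#' the three-symbol alphabet "+" (up), "-" (down), "." (not significant).
#' Leading "#" comment lines (provenance of the upstream DEG thresholds) are
#' skipped.
#'
#' @param path TSV file.
#' @return data.frame, rownames = gene ids, one column per contrast.
#' @export
read_deg_labels <- function(path) {
  d <- read.delim(path, row.names = 1, comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  ok <- vapply(d, function(col) all(col %in% c("+", "-", ".")), logical(1))
  if (!all(ok)) {
    stop("DEG labels outside {+,-,.} in contrast(s): ",
         paste(names(d)[!ok], collapse = ", "))
  }
  d
}
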