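# End-to-end pipeline: simulate (or load) a dataset, run every analysis
# stage, and write a machine-readable run manifest. Composition only; each
# stage is an exported function tested on its own.

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes simulate -> introner scan -> edit calling -> differential
#' editing -> FPKM -> superclustering -> differential exon usage ->
#' duplication modes -> concordance -> spliced-leader detection -> CU
#' segmentation/motifs, writing per-stage TSV outputs and a JSON manifest
#' with input/output digests and record counts. Re-running with the same
#' config yields byte-identical outputs (the manifest carries no
#' timestamps).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory; data are simulated into
#'   `out_dir/data`, results written to `out_dir/results`.
#' @param edit_contrast condition pair for differential editing (defaults
#'   to the config's DEU contrast).
#' @param k number of expression superclusters.
#' @return (invisibly) the manifest list.
#' @export
run_all <- function(config, out_dir, edit_contrast = config$deu_contrast,
                    k = config$n_superclusters) {
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_dataset(config, data_dir)

  # read everything back through the package's own readers
  genome <- read_genome_fasta(sim$paths$genome)
  models <- read_gene_models(sim$paths$gff3, genome)
  design <- condition_design(config$conditions, config$n_replicates)
  pileup <- read_pileup_table(sim$paths$pileup, design)
  gene_counts <- read_count_table(sim$paths$gene_counts)
  exon_counts <- read_count_table(sim$paths$exon_counts)
  clusters <- read_clusters(sim$paths$clusters)
  labels <- read_deg_labels(sim$paths$deg_labels)
  transcripts <- read_genome_fasta(sim$paths$transcripts)
  proteins <- toupper(as.character(
    Biostrings::readAAStringSet(sim$paths$proteins)))

  counts <- list()
  out <- function(name) file.path(res_dir, name)

  introns <- extract_all_introns(models, genome)
  calls <- scan_introners(introns, window = config$introner_window)
  write.table(calls[, setdiff(names(calls), "sense_seq")],
              out("introner_calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  motifs <- tabulate_splice_motifs(introns)
  write.table(data.frame(class = c(names(motifs$donor_counts), "AGG"),
                         count = c(as.integer(motifs$donor_counts),
                                   motifs$acceptor_agg_count),
                         pct = c(motifs$donor_pct, motifs$acceptor_agg_pct)),
              out("splice_motifs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ie <- calls[calls$is_IE, , drop = FALSE]
  if (nrow(ie)) {
    write_bed_intervals(data.frame(chrom = ie$scaffold, start = ie$start,
                                   end = ie$end,
                                   name = paste0(ie$gene_id, ".i", ie$index),
                                   score = ie$ir_len, strand = ie$strand),
                        out("introners.bed"))
  }
  counts$introns <- nrow(calls)
  counts$introners <- nrow(ie)

  sites <- call_edit_sites(pileup, design, models)
  write.table(sites, out("edit_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$edit_calls <- nrow(sites)
  counts$edit_sites <- length(unique(paste(sites$scaffold, sites$pos)))
  if (nrow(sites)) {
    agg <- aggregate(edit_fraction ~ scaffold + pos, data = sites, FUN = max)
    u <- sites[!duplicated(paste(sites$scaffold, sites$pos)), ]
    u$maxf <- agg$edit_fraction[match(paste(u$scaffold, u$pos),
                                      paste(agg$scaffold, agg$pos))]
    write_bed_intervals(data.frame(chrom = u$scaffold, start = u$pos,
                                   end = u$pos + 1L,
                                   name = u$edit_type,
                                   score = pmin(round(100 * u$maxf), 1000),
                                   strand = u$strand),
                        out("edit_sites.bed"))
    diffres <- test_differential_editing(u, pileup, design,
                                         edit_contrast[1], edit_contrast[2])
    write.table(diffres, out("edit_diff.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts$differential_edits <- sum(diffres$is_differential)
  } else {
    counts$differential_edits <- 0L
  }

  fpkm <- compute_fpkm(gene_counts, models)
  write_count_table(round(fpkm, 4), out("fpkm.tsv"), id_col = "gene_id")
  sc <- assign_superclusters(fpkm, k = k)
  write.table(sc, out("superclusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$superclusters <- length(unique(sc$label))

  gene_of_exon <- sub(":e\\d+$", "", rownames(exon_counts))
  deu <- test_exon_usage(exon_counts, gene_of_exon, design,
                         config$deu_contrast[1], config$deu_contrast[2])
  write.table(deu, out("deu.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$deu_significant <- sum(deu$significant, na.rm = TRUE)

  modes <- classify_duplication_modes(clusters, models,
                                      config$proximal_max_gap)
  write.table(modes, out("duplication_modes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  conc <- summarize_concordance(clusters, labels, config$deg_contrast)
  write.table(conc, out("concordance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  thr <- concordance_at_threshold(conc)
  counts$concordant_sets <- sum(thr$flags)
  counts$concordance_n <- thr$n

  sl <- detect_sl_set(transcripts, sl = config$sl_sequence,
                      min_match = config$sl_min_match, max_mm = 0L)
  write.table(sl, out("sl_detection.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$sl_transcripts <- sum(sl$matched)

  cu_rows <- list()
  for (id in names(proteins)) {
    seg <- segment_coding_units(proteins[[id]])
    plen <- nchar(proteins[[id]])
    emap <- tryCatch(map_cu_to_exons(seg, models[[id]], plen),
                     error = function(e) NULL)
    cu_rows[[id]] <- data.frame(
      gene_id = id, n_units = seg$n_units,
      n_partial = length(seg$partial_units),
      n_spacers = nrow(seg$spacers),
      mean_pairwise_identity = seg$mean_pairwise_identity,
      unit_exons = paste(vapply(seq_len(seg$n_units), function(i) {
        key <- paste0("U", i)
        if (!is.null(emap)) paste(emap[[key]], collapse = ",") else ""
      }, character(1)), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  cu_tab <- do.call(rbind, c(cu_rows, list(make.row.names = FALSE)))
  write.table(cu_tab, out("cu_segmentation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts$cu_genes <- nrow(cu_tab)

  manifest <- list(
    tool = "dinoarch",
    version = as.character(utils::packageVersion("dinoarch")),
    seed = config$seed,
    config_digest = unname(tools::md5sum(sim$paths$config)),
    inputs = as.list(tools::md5sum(sort(unlist(sim$paths)))),
    outputs = as.list(tools::md5sum(sort(list.files(res_dir,
                                                    full.names = TRUE)))),
    stage_counts = counts)
  names(manifest$inputs) <- basename(names(manifest$inputs))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
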