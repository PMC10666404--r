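small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_scaffolds = 2, genes_per_scaffold = 6,
             edit_site_count = 20L, null_site_count = 20L,
             duplicate_family_spec = list(), ...)
}

test_that("the generator is deterministic: same seed, byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(small_cfg(seed = 9), d1)
  generate_dataset(small_cfg(seed = 9), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_dataset(small_cfg(seed = 10), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d3, "genome.fasta"))))
})

test_that("infeasible configurations are rejected before writing anything", {
  expect_error(sim_config(intron_length_range = c(40L, 50L)),
               "config error")
  expect_error(sim_config(donor_mix = c(GT = 0.5, GC = 0.5, GA = 0.5)),
               "sum to 1")
  expect_error(sim_config(edit_fraction = 1.5), "edit_fraction")
  expect_error(sim_config(deu_contrast = c("20_st", "nope")), "absent")
})

test_that("planted introner count follows the configured rate exactly", {
  cfg <- sim_config(seed = 3, n_scaffolds = 2, genes_per_scaffold = 10,
                    introner_rate = 0.3, edit_site_count = 0L,
                    edit_fraction = 0, null_site_count = 5L,
                    duplicate_family_spec = list())
  sim <- generate_dataset(cfg, withr::local_tempdir())
  tr <- sim$truth$introns
  # CU-gene introns are part of the truth table as IE-negative rows
  expect_equal(sum(tr$is_IE),
               round(0.3 * sum(!startsWith(tr$gene_id, "cu_"))))
  # zero edit fraction -> empty edit-site truth
  expect_equal(nrow(sim$truth$edit_sites), 0L)
})

test_that("truth-table identifiers resolve against the emitted files", {
  d <- withr::local_tempdir()
  sim <- generate_dataset(small_cfg(seed = 4), d)
  genome <- read_genome_fasta(file.path(d, "genome.fasta"))
  models <- read_gene_models(file.path(d, "genes.gff3"), genome)
  expect_true(all(sim$truth$introns$gene_id %in% names(models)))
  expect_true(all(sim$truth$families$gene_id %in% names(models)))
  expect_true(all(sim$truth$superclusters$gene %in% names(models)))
  tx <- read_genome_fasta(file.path(d, "transcripts.fasta"))
  expect_true(all(sim$truth$sl_transcripts$transcript_id %in% names(tx)))
  expect_true(all(sim$truth$cu_units$gene_id %in% names(sim$proteins)))
  # every planted edit site exists in the pileup with its reference base
  p <- read_pileup_table(file.path(d, "pileup.tsv"),
                         condition_design(small_cfg()$conditions, 3L))
  key <- paste(p$scaffold, p$pos)
  expect_true(all(paste(sim$truth$edit_sites$scaffold,
                        sim$truth$edit_sites$pos) %in% key))
})

test_that("planted edit-site pileups follow the configured fractions", {
  # deterministic (noise-free) mode: alternative counts are exact
  cfg <- small_cfg(seed = 5, edit_noise = "none", edit_fraction = 0.5,
                   coverage_rna = 10L)
  sim <- generate_dataset(cfg, withr::local_tempdir())
  tr <- sim$truth$edit_sites
  rna <- sim$pileup[sim$pileup$sample_kind == "RNA", ]
  cnt <- as.matrix(rna[, c("nA", "nC", "nG", "nT")])
  for (i in seq_len(min(nrow(tr), 10))) {
    rows <- rna$scaffold == tr$scaffold[i] & rna$pos == tr$pos[i]
    for (cond in cfg$conditions) {
      f <- tr[[paste0("f_", cond)]][i]
      sel <- rows & rna$condition == cond
      alt_counts <- cnt[sel, match(tr$alt[i], c("A", "C", "G", "T"))]
      expect_true(all(alt_counts == round(f * 10)))
    }
  }
  # fraction 1.0: RNA reads are all alternative base
  cfg1 <- small_cfg(seed = 6, edit_noise = "none", edit_fraction = 1.0)
  sim1 <- generate_dataset(cfg1, withr::local_tempdir())
  tr1 <- sim1$truth$edit_sites[1, ]
  rna1 <- sim1$pileup[sim1$pileup$sample_kind == "RNA" &
                        sim1$pileup$scaffold == tr1$scaffold &
                        sim1$pileup$pos == tr1$pos, ]
  edited_conds <- cfg1$conditions[vapply(cfg1$conditions, function(cc) {
    tr1[[paste0("f_", cc)]] > 0
  }, logical(1))]
  sel <- rna1$condition %in% edited_conds
  expect_true(all(as.matrix(rna1[sel, c("nA", "nC", "nG", "nT")])[
    , match(tr1$alt, c("A", "C", "G", "T"))] == cfg1$coverage_rna))
  # non-planted sites match the DNA consensus composition exactly
  dna <- sim1$pileup[sim1$pileup$sample_kind == "DNA", ]
  planted_key <- paste(sim1$truth$edit_sites$scaffold,
                       sim1$truth$edit_sites$pos)
  null_dna <- dna[!(paste(dna$scaffold, dna$pos) %in% planted_key), ]
  rna_all <- sim1$pileup[sim1$pileup$sample_kind == "RNA", ]
  for (i in seq_len(min(nrow(null_dna), 5))) {
    sel <- rna_all$scaffold == null_dna$scaffold[i] &
      rna_all$pos == null_dna$pos[i]
    rc <- as.matrix(rna_all[sel, c("nA", "nC", "nG", "nT")])
    dc <- as.numeric(null_dna[i, c("nA", "nC", "nG", "nT")])
    expect_true(all(t(rc) / colSums(t(rc)) == dc / sum(dc)))
  }
})

test_that("binomial pileup noise reproduces the recorded RNG stream", {
  cfg <- small_cfg(seed = 7, edit_noise = "binomial")
  sim1 <- generate_dataset(cfg, withr::local_tempdir())
  sim2 <- generate_dataset(cfg, withr::local_tempdir())
  expect_identical(sim1$pileup, sim2$pileup)
  # and the planted fractions are respected on average
  tr <- sim1$truth$edit_sites
  rna <- sim1$pileup[sim1$pileup$sample_kind == "RNA", ]
  cnt <- as.matrix(rna[, c("nA", "nC", "nG", "nT")])
  fr <- numeric(0); expected <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    for (cond in cfg$conditions) {
      f <- tr[[paste0("f_", cond)]][i]
      if (f == 0) next
      sel <- rna$scaffold == tr$scaffold[i] & rna$pos == tr$pos[i] &
        rna$condition == cond
      fr <- c(fr, sum(cnt[sel, match(tr$alt[i], c("A", "C", "G", "T"))]) /
                sum(cnt[sel, ]))
      expected <- c(expected, f)
    }
  }
  expect_lt(abs(mean(fr) - mean(expected)), 0.05)
})

test_that("planted spliced leaders never collide with transcript bodies", {
  cfg <- small_cfg(seed = 8, sl_rate = 0.2)
  sim <- generate_dataset(cfg, withr::local_tempdir())
  tagged <- sim$truth$sl_transcripts$transcript_id
  expect_equal(length(tagged), round(0.2 * length(sim$transcripts)))
  bodies <- sim$transcripts
  bodies[tagged] <- substr(bodies[tagged], 23L, nchar(bodies[tagged]))
  tail10 <- substr(DINO_SL, 13, 22)
  expect_false(any(grepl(tail10, bodies, fixed = TRUE)))
})
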