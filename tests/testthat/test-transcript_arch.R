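rand_protein <- function(n) {
  paste(sample(names(KYTE_DOOLITTLE), n, replace = TRUE), collapse = "")
}

test_that("spliced-leader suffixes are matched at transcript starts", {
  body <- "CCCCCCCCCCCCCCCCCCCCCCCCCCCCC"
  # full leader with D realised as T: 22-base exact match
  full <- paste0("TCCGTAGCCATTTTGGCTCAAG", body)
  r <- detect_sl(full)
  expect_true(r$matched)
  expect_equal(r$match_length, 22L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$trim_offset, 22L)
  # last 12 leader bases only
  r12 <- detect_sl(paste0(substr(DINO_SL, 11, 22), body))
  expect_true(r12$matched)
  expect_equal(r12$match_length, 12L)
  # no leader-like prefix
  expect_false(detect_sl(body)$matched)
  # one mismatch tolerated at max_mm = 1, rejected at 0
  mut <- full
  substr(mut, 5, 5) <- "A"  # leader position 5 is T
  expect_true(detect_sl(mut, max_mm = 1)$matched)
  expect_false(detect_sl(mut, max_mm = 0)$matched)
  # too-short suffix below min_match is no evidence
  expect_false(detect_sl(paste0(substr(DINO_SL, 15, 22), body),
                         min_match = 10)$matched)
})

test_that("CU segmentation recovers planted unit/spacer architectures", {
  set.seed(51)
  unit <- rand_protein(100)
  spacers <- replicate(2, rand_protein(20))
  prot <- paste0(unit, spacers[1], unit, spacers[2], unit)
  seg <- segment_coding_units(prot)
  expect_equal(seg$n_units, 3L)
  expect_equal(unname(seg$complete_units[, "start"]), c(0L, 120L, 240L))
  expect_equal(unname(seg$complete_units[, "end"]), c(100L, 220L, 340L))
  expect_equal(nrow(seg$spacers), 2L)
  expect_equal(unname(seg$spacers[, 1]), c(100L, 220L))
  expect_equal(seg$unit_consensus, unit)
  expect_equal(seg$mean_pairwise_identity, 1)
  # single non-repetitive protein -> one unit, no spacers
  seg1 <- segment_coding_units(rand_protein(300))
  expect_equal(seg1$n_units, 1L)
  expect_equal(nrow(seg1$spacers), 0L)
  # trailing N-terminal fragment (60% of the unit) becomes a partial unit
  protp <- paste0(unit, spacers[1], unit, spacers[2], unit,
                  rand_protein(20), substr(unit, 1, 60))
  segp <- segment_coding_units(protp)
  expect_equal(segp$n_units, 3L)
  expect_equal(length(segp$partial_units), 1L)
  expect_equal(segp$partial_units[[1]]$tag, "N-terminal")
  expect_error(segment_coding_units(""), "empty")
})

test_that("units below the identity gate collapse to a single-unit call", {
  set.seed(52)
  unit <- rand_protein(100)
  mutate_to <- function(s, ident) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round((1 - ident) * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(names(KYTE_DOOLITTLE), ch[p]), 1)
    paste(ch, collapse = "")
  }
  prot90 <- paste0(mutate_to(unit, 0.90), rand_protein(20),
                   mutate_to(unit, 0.90), rand_protein(20),
                   mutate_to(unit, 0.90))
  seg <- segment_coding_units(prot90, identity_threshold = 0.95)
  expect_equal(seg$n_units, 1L)
  # lightly diverged copies (98% to the shared original, > 95% to the
  # consensus) still segment at the default gate
  prot98 <- paste0(mutate_to(unit, 0.98), rand_protein(20),
                   mutate_to(unit, 0.98), rand_protein(20),
                   mutate_to(unit, 0.98))
  seg98 <- segment_coding_units(prot98)
  expect_equal(seg98$n_units, 3L)
})

test_that("planted unit counts 1-5 are recovered across seeds", {
  for (seed in 1:10) {
    set.seed(60 + seed)
    for (n_units in 1:5) {
      ul <- sample(60:150, 1)
      sl <- sample(10:40, 1)
      unit <- rand_protein(ul)
      parts <- character(0)
      for (j in seq_len(n_units)) {
        parts <- c(parts, unit,
                   if (j < n_units) rand_protein(sl) else NULL)
      }
      seg <- segment_coding_units(paste(parts, collapse = ""))
      expect_equal(seg$n_units, n_units)
      if (n_units > 1) {
        starts <- (seq_len(n_units) - 1L) * (ul + sl)
        expect_true(all(abs(seg$complete_units[, "start"] - starts) <= 1))
        expect_true(all(abs(seg$complete_units[, "end"] -
                              (starts + ul)) <= 1))
      }
    }
  }
})

test_that("segmentation intervals tile the protein without overlap", {
  set.seed(53)
  unit <- rand_protein(80)
  prot <- paste0(unit, rand_protein(15), unit, rand_protein(25), unit)
  seg <- segment_coding_units(prot)
  iv <- rbind(seg$complete_units, seg$spacers,
              do.call(rbind, lapply(seg$partial_units, `[[`, "interval")))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
  expect_lte(sum(iv[, 2] - iv[, 1]), nchar(prot))
})

test_that("CU-to-exon mapping mirrors a unit-per-odd-exon gene", {
  set.seed(54)
  cfg <- sim_config(seed = 54, n_scaffolds = 1, genes_per_scaffold = 2,
                    edit_site_count = 0L, edit_fraction = 0,
                    null_site_count = 5L, duplicate_family_spec = list())
  sim <- generate_dataset(cfg, withr::local_tempdir())
  # first CU gene: 4 complete units on exons 1,3,5,7 plus a partial
  id <- "cu_g01"
  seg <- segment_coding_units(sim$proteins[[id]])
  expect_equal(seg$n_units, 4L)
  emap <- map_cu_to_exons(seg, sim$models[[id]], nchar(sim$proteins[[id]]))
  expect_equal(emap$U1, 1L)
  expect_equal(emap$U2, 3L)
  expect_equal(emap$U3, 5L)
  expect_equal(emap$U4, 7L)
  expect_equal(emap$S1, 2L)
  # independent residue-by-residue coordinate walk over the CDS
  model <- sim$models[[id]]
  cds <- model$cds
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  exon_rank <- if (model$strand == "+") seq_len(nrow(model$exons)) else
    rev(seq_len(nrow(model$exons)))
  exon_of_seg <- vapply(seq_len(nrow(cds)), function(i) {
    which(model$exons[, 1] <= cds[i, 1] & cds[i, 2] <= model$exons[, 2])[1]
  }, integer(1))
  nt_exon <- rep(exon_rank[exon_of_seg][ord],
                 times = (cds[, 2] - cds[, 1])[ord])
  for (i in seq_len(seg$n_units)) {
    iv <- seg$complete_units[i, ]
    walk <- sort(unique(nt_exon[(3L * iv[1] + 1L):(3L * iv[2])]))
    expect_equal(emap[[paste0("U", i)]], walk)
  }
  # frame error when protein length disagrees with the CDS
  expect_error(map_cu_to_exons(seg, model, 10L), "frame error")
})

test_that("single-exon and junction-spanning units map correctly", {
  # one exon holding two units: every unit maps to exon 1
  set.seed(55)
  unit <- rand_protein(60)
  prot <- paste0(unit, rand_protein(12), unit)
  seg <- segment_coding_units(prot)
  n_nt <- 3L * nchar(prot)
  m1 <- gene_model("g", "s", "+", exons = rbind(c(0L, n_nt)))
  emap <- map_cu_to_exons(seg, m1, nchar(prot))
  expect_equal(emap$U1, 1L)
  expect_equal(emap$U2, 1L)
  # exon boundary in the middle of unit 2 -> unit maps to both exons
  cut <- 3L * (nchar(unit) + 12L + 30L)
  m2 <- gene_model("g", "s", "+", exons = rbind(c(0L, cut), c(cut, n_nt)))
  emap2 <- map_cu_to_exons(seg, m2, nchar(prot))
  expect_equal(emap2$U2, c(1L, 2L))
})

test_that("motif scans report exact hits and compositions", {
  r <- scan_motifs("SSAAFVGASS")
  expect_equal(r$motif_hits$FVGA, 5L)
  expect_equal(r$ser_ala_fraction, 0.7)  # 4 S + 3 A over 10 residues
  r2 <- scan_motifs("RKRK")
  expect_equal(r2$basic_fraction, 1.0)
  expect_equal(length(r2$motif_hits$FVGA), 0L)
  expect_equal(r2$mean_hydropathy, mean(KYTE_DOOLITTLE[c("R", "K")]))
  expect_error(scan_motifs("SSAX1"), "non-amino-acid")
  # planted spacers from the generator contain exactly one FVGA at the
  # recorded offset
  cfg <- sim_config(seed = 56, n_scaffolds = 1, genes_per_scaffold = 2,
                    edit_site_count = 0L, edit_fraction = 0,
                    null_site_count = 5L, duplicate_family_spec = list())
  sim <- generate_dataset(cfg, withr::local_tempdir())
  tr <- sim$truth$cu_spacer_motifs
  units <- sim$truth$cu_units
  for (i in seq_len(nrow(tr))) {
    u <- units[units$gene_id == tr$gene_id[i] & units$kind == "spacer" &
                 units$idx == tr$spacer_idx[i], ]
    spacer <- substr(sim$proteins[[tr$gene_id[i]]], u$start + 1L, u$end)
    hits <- scan_motifs(spacer)$motif_hits$FVGA
    expect_equal(hits, tr$fvga_offset[i] + 1L)  # truth offsets are 0-based
  }
})
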