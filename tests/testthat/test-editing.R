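make_pileup <- function(dna, reps_by_cond, scaffold = "s01", pos = 50L) {
  rows <- list(data.frame(scaffold = scaffold, pos = pos,
                          sample_kind = "DNA", condition = "DNA",
                          replicate = 0L, nA = dna[1], nC = dna[2],
                          nG = dna[3], nT = dna[4]))
  for (cond in names(reps_by_cond)) {
    m <- reps_by_cond[[cond]]
    for (r in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = scaffold, pos = pos, sample_kind = "RNA",
        condition = cond, replicate = r, nA = m[r, 1], nC = m[r, 2],
        nG = m[r, 3], nT = m[r, 4])
    }
  }
  do.call(rbind, rows)
}

one_gene <- function(strand = "+") {
  assign_gene_ranks(list(g1 = gene_model("g1", "s01", strand,
                                         exons = rbind(c(0L, 200L)))))
}

test_that("site score matches the likelihood oracle and its exact cases", {
  # identical compositions after pseudocounting -> exactly zero
  expect_identical(compute_site_score(c(20, 0, 0, 0),
                                      rbind(c(20, 0, 0, 0), c(20, 0, 0, 0),
                                            c(20, 0, 0, 0))), 0)
  # half-edited replicates: equals independent log-likelihood evaluation
  rna <- rbind(c(10, 0, 10, 0), c(10, 0, 10, 0), c(10, 0, 10, 0))
  s <- compute_site_score(c(20, 0, 0, 0), rna)
  expect_equal(s, oracle_site_score(c(20, 0, 0, 0), rna), tolerance = 1e-12)
  expect_equal(s, 11 * log2(121 / 21), tolerance = 1e-9)
  # replicate permutation leaves the score unchanged
  rna2 <- rbind(c(5, 0, 15, 0), c(10, 0, 10, 0), c(20, 0, 0, 0))
  expect_equal(compute_site_score(c(20, 0, 0, 0), rna2),
               compute_site_score(c(20, 0, 0, 0), rna2[c(3, 1, 2), ]))
  # random sites: non-negative and equal to the oracle
  set.seed(21)
  for (i in 1:200) {
    dna <- as.numeric(rmultinom(1, 30, c(0.7, 0.1, 0.1, 0.1)))
    rna <- t(rmultinom(3, 15, runif(4)))
    s <- compute_site_score(dna, rna)
    expect_gte(s, 0)
    expect_equal(s, oracle_site_score(dna, rna), tolerance = 1e-9)
  }
  expect_error(compute_site_score(c(0, 0, 0, 0), rbind(c(1, 1, 1, 1))),
               "coverage")
})

test_that("edit types are named on the gene strand", {
  expect_equal(classify_edit_type("A", "G", "+"), "A-to-G")
  expect_equal(classify_edit_type("T", "C", "-"), "A-to-G")
  expect_error(classify_edit_type("C", "C", "+"), "distinct")
  # strand flip + complement is the identity on types
  set.seed(22)
  for (i in 1:50) {
    b <- sample(c("A", "C", "G", "T"), 2)
    expect_equal(classify_edit_type(b[1], b[2], "+"),
                 classify_edit_type(unname(c(A = "T", C = "G", G = "C",
                                             T = "A")[b[1]]),
                                    unname(c(A = "T", C = "G", G = "C",
                                             T = "A")[b[2]]), "-"))
  }
})

test_that("the five calling criteria gate sites as specified", {
  design <- condition_design("20_st", 3L)
  models <- one_gene()
  edited <- rbind(c(10, 0, 10, 0), c(10, 0, 10, 0), c(10, 0, 10, 0))
  # clean edited site is called A-to-G
  p <- make_pileup(c(20, 0, 0, 0), list("20_st" = edited))
  calls <- call_edit_sites(p, design, models)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$edit_type, "A-to-G")
  expect_equal(calls$edit_fraction, 0.5)
  # DNA coverage exactly at the threshold is NOT called (strict >)
  p10 <- make_pileup(c(10, 0, 0, 0), list("20_st" = edited))
  expect_equal(nrow(call_edit_sites(p10, design, models)), 0L)
  p11 <- make_pileup(c(11, 0, 0, 0), list("20_st" = edited))
  expect_equal(nrow(call_edit_sites(p11, design, models)), 1L)
  # RNA coverage 5 vs 6 per replicate flips eligibility and nothing else
  rna5 <- rbind(c(2, 0, 3, 0), c(3, 0, 3, 0), c(3, 0, 3, 0))  # rep1 cov 5
  rna6 <- rbind(c(3, 0, 3, 0), c(3, 0, 3, 0), c(3, 0, 3, 0))
  expect_equal(nrow(call_edit_sites(make_pileup(c(20, 0, 0, 0),
                                                list("20_st" = rna5)),
                                    design, models)), 0L)
  expect_equal(nrow(call_edit_sites(make_pileup(c(20, 0, 0, 0),
                                                list("20_st" = rna6)),
                                    design, models)), 1L)
  # alternative absent from one replicate: not present in all three
  miss <- rbind(c(10, 0, 10, 0), c(10, 0, 10, 0), c(20, 0, 0, 0))
  expect_equal(nrow(call_edit_sites(make_pileup(c(20, 0, 0, 0),
                                                list("20_st" = miss)),
                                    design, models)), 0L)
  # two supported alternatives -> editing-type count >= 2 -> rejected
  two <- rbind(c(10, 0, 6, 6), c(10, 0, 6, 6), c(10, 0, 6, 6))
  expect_equal(nrow(call_edit_sites(make_pileup(c(22, 0, 0, 0),
                                                list("20_st" = two)),
                                    design, models)), 0L)
  # minus-strand host gene collapses the type
  calls_m <- call_edit_sites(p, design, one_gene("-"))
  expect_equal(calls_m$edit_type, "T-to-C")
})

test_that("RNA-only sites are skipped with a message, not an error", {
  design <- condition_design("20_st", 1L)
  models <- one_gene()
  p <- make_pileup(c(20, 0, 0, 0), list("20_st" = rbind(c(10, 0, 10, 0))))
  extra <- data.frame(scaffold = "s01", pos = 60L, sample_kind = "RNA",
                      condition = "20_st", replicate = 1L,
                      nA = 5L, nC = 0L, nG = 5L, nT = 0L)
  expect_message(res <- call_edit_sites(rbind(p, extra), design, models),
                 "skipped")
  expect_equal(attr(res, "n_skipped_no_dna"), 1L)
})

test_that("Fisher differential test matches the hypergeometric oracle", {
  # strong condition difference: differential
  design <- condition_design(c("A", "B"), 1L)
  pil <- rbind(
    data.frame(scaffold = "s", pos = 5L, sample_kind = "DNA",
               condition = "DNA", replicate = 0L, nA = 30L, nC = 0L,
               nG = 0L, nT = 0L),
    data.frame(scaffold = "s", pos = 5L, sample_kind = "RNA",
               condition = c("A", "B"), replicate = 1L,
               nA = c(15L, 30L), nC = 0L, nG = c(15L, 0L), nT = 0L))
  site <- data.frame(scaffold = "s", pos = 5L, dna_base = "A",
                     alt_base = "G")
  res <- test_differential_editing(site, pil, design, "A", "B")
  expect_true(res$is_differential)
  expect_equal(res$p, oracle_fisher_p(15, 15, 0, 30), tolerance = 1e-12)
  # identical tables -> p = 1, not differential
  pil2 <- pil; pil2$nG[pil2$condition == "B"] <- 15L
  pil2$nA[pil2$condition == "B"] <- 15L
  res2 <- test_differential_editing(site, pil2, design, "A", "B")
  expect_equal(res2$p, 1)
  expect_false(res2$is_differential)
  # small effect is gated by min_delta regardless of p
  pil3 <- pil
  pil3$nA[pil3$condition == "A"] <- 29L; pil3$nG[pil3$condition == "A"] <- 1L
  pil3$nA[pil3$condition == "B"] <- 28L; pil3$nG[pil3$condition == "B"] <- 2L
  res3 <- test_differential_editing(site, pil3, design, "A", "B")
  expect_false(res3$is_differential)
  expect_lt(abs(res3$delta), 0.1)
  # zero coverage in one condition -> untestable
  pil4 <- pil; pil4 <- pil4[!(pil4$condition == "B"), ]
  res4 <- test_differential_editing(site, pil4, design, "A", "B")
  expect_true(res4$untestable)
  expect_true(is.na(res4$p))
})

test_that("Fisher p equals the oracle on random 2x2 tables", {
  set.seed(23)
  for (i in 1:300) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    if (a + b == 0 || c + d == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(p_pkg, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
  }
})
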