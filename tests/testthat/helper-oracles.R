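# Independent oracles used across the suite. Deliberately naive
# implementations (exhaustive enumeration, direct formula evaluation) kept
# separate from the package's own code paths.

# Exhaustive substring-pair search for introner terminal repeats: all
# (start, length) substrings of the 5' window against all positions of the
# 3' window, compared character by character.
oracle_scan_introner <- function(seq, window = 30L, ir_range = c(8L, 20L),
                                 dr_range = c(3L, 5L)) {
  n <- nchar(seq)
  w <- min(window, n)
  ch <- strsplit(seq, "")[[1]]
  w5 <- ch[seq_len(w)]
  off3 <- n - w
  w3 <- ch[(off3 + 1L):n]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  best <- function(range, inverted) {
    hit <- NULL
    if (min(range[2], w) < range[1]) return(NULL)
    for (len in seq(range[1], min(range[2], w))) {
      for (i in seq_len(w - len + 1L)) {
        s <- w5[i:(i + len - 1L)]
        probe <- if (inverted) rev(unname(comp[s])) else s
        for (j in seq_len(w - len + 1L)) {
          if (all(w3[j:(j + len - 1L)] == probe)) {
            cand <- list(len = len, start5 = i - 1L,
                         start3 = off3 + j - 1L)
            if (is.null(hit) || cand$len > hit$len) hit <- cand
            break  # leftmost 3' occurrence for this (len, i)
          }
        }
        if (!is.null(hit) && hit$len == len) break  # leftmost 5' for this len
      }
    }
    hit
  }
  ir <- best(ir_range, inverted = TRUE)
  dr <- best(dr_range, inverted = FALSE)
  list(is_IE = !is.null(ir) && !is.null(dr), ir = ir, dr = dr)
}

# Direct multinomial log2 likelihood-ratio evaluation, written from the
# definition (no shared code with score_matrix).
oracle_site_score <- function(dna, rna, pseudocount = 1) {
  loglik <- function(counts, p) sum(counts * log2(p))
  pd <- (dna + pseudocount) / sum(dna + pseudocount)
  mean(apply(rna, 1L, function(r) {
    nt <- r + pseudocount
    pr <- nt / sum(nt)
    loglik(nt, pr) - loglik(nt, pd)
  }))
}

# Two-sided Fisher exact p as a hypergeometric probability sum, built from
# lchoose (independent of dhyper/fisher.test internals). Table rows are
# (alt, ref) per condition.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Nearest-paralog duplication modes by brute-force pairwise search.
oracle_duplication_modes <- function(clusters, scaf, rank, gap_max = 10L) {
  out <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters$cluster_id[i]
    g <- clusters$gene_id[i]
    others <- clusters$gene_id[clusters$cluster_id == cl &
                                 clusters$gene_id != g]
    if (length(others) == 0L) { out[i] <- "singleton"; next }
    ds <- Inf
    for (o in others) {
      if (scaf[[o]] == scaf[[g]]) ds <- min(ds, abs(rank[[o]] - rank[[g]]))
    }
    out[i] <- if (!is.finite(ds)) "dispersed"
      else if (ds == 1) "tandem"
      else if (ds <= gap_max) "proximal" else "dispersed"
  }
  out
}

# Direction-pattern summary by naive counting.
oracle_concordance <- function(dirs) {
  deg <- dirs[dirs != "."]
  if (length(deg) == 0L) return(list(pattern = "", concordance = NA_real_))
  pattern <- paste(c(rep("+", sum(deg == "+")), rep("-", sum(deg == "-"))),
                   collapse = "")
  list(pattern = pattern,
       concordance = max(sum(deg == "+"), sum(deg == "-")) / length(deg))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small deterministic two-gene fixture on one scaffold used by several
# io/intron tests.
toy_genome <- function() {
  set.seed(42)
  c(sc1 = random_dna(1200), sc2 = random_dna(600))
}

toy_models <- function() {
  m1 <- gene_model("gA", "sc1", "+",
                   exons = rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  m2 <- gene_model("gB", "sc1", "-",
                   exons = rbind(c(600L, 700L), c(800L, 900L)))
  m3 <- gene_model("gC", "sc2", "+", exons = rbind(c(50L, 350L)))
  assign_gene_ranks(list(gA = m1, gB = m2, gC = m3))
}
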