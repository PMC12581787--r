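# Fixture builders and independent brute-force oracles used across the suite.
# Oracles deliberately use naive loops / exhaustive enumeration, never the
# package's own fast paths.

# small structured dataset: genome + population + phenotype
make_sim <- function(seed = 7, n_samples = 60, n_snps = 300, n_chrom = 3,
                     chrom_length = 5e4, n_subpops = 2, fst = 0.2,
                     missing_rate = 0.05, ...) {
  cfg <- sim_config(n_chrom = n_chrom, chrom_length = chrom_length,
                    n_samples = n_samples, n_snps = n_snps,
                    n_subpops = n_subpops, fst_target = fst,
                    missing_rate = missing_rate,
                    n_qtn = min(20, n_snps), seed = seed, ...)
  genome <- simulate_genome(cfg)
  pop <- simulate_population(cfg, genome)
  list(cfg = cfg, genome = genome, vt = pop$vt, truth = pop$truth)
}

# hand-rolled variant table from a genotype matrix
make_vt <- function(geno, chrom = "chr1", qual = NULL) {
  m <- ncol(geno)
  snps <- data.frame(chrom = chrom, pos = seq_len(m) * 100,
                     ref = rep(c("A", "C", "G", "T"), length.out = m),
                     alt = rep(c("G", "T", "A", "C"), length.out = m),
                     qual = if (is.null(qual)) rep(999, m) else qual)
  variant_table(snps, geno)
}

# write a literal VCF text fixture
write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# exhaustive sliding-window alignment oracle for uniqueness_check: tries every
# ungapped placement of the region on both strands of every chromosome
brute_unique <- function(region, genome, self_chrom, self_start,
                         min_identity = 0.6, min_coverage = 0.6) {
  len <- nchar(region)
  self_end <- self_start + len - 1
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (ch in names(genome$seq)) {
    L <- genome$lengths[[ch]]
    gch <- strsplit(genome$seq[[ch]], "")[[1]]
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") region else rc(region), "")[[1]]
      for (d in (1 - len):(L - 1)) {   # region position i <-> genome d + i
        i_lo <- max(1, 1 - d); i_hi <- min(len, L - d)
        span <- i_hi - i_lo + 1
        if (span < min_coverage * len) next
        if (strand == "+" && ch == self_chrom &&
            d + i_lo <= self_end && d + i_hi >= self_start) next
        if (sum(q[i_lo:i_hi] == gch[(d + i_lo):(d + i_hi)]) / span >=
            min_identity) return(FALSE)
      }
    }
  }
  TRUE
}

# brute-force per-pair discrimination (double loop over samples and SNPs)
brute_discrimination <- function(G) {
  n <- nrow(G); m <- ncol(G)
  pairs <- combn(n, 2)
  covers <- matrix(FALSE, m, ncol(pairs))
  for (k in seq_len(m)) for (p in seq_len(ncol(pairs))) {
    a <- G[pairs[1, p], k]; b <- G[pairs[2, p], k]
    covers[k, p] <- !is.na(a) && !is.na(b) && a != b
  }
  list(pairs = pairs, covers = covers)
}

# naive p-distance site loop
brute_p_distance <- function(G) {
  n <- nrow(G)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    s <- 0; nc <- 0
    for (k in seq_len(ncol(G))) {
      if (!is.na(G[i, k]) && !is.na(G[j, k])) {
        s <- s + abs(G[i, k] - G[j, k]); nc <- nc + 1
      }
    }
    D[i, j] <- D[j, i] <- s / (2 * nc)
  }
  D
}

# naive simple-matching kinship
brute_smc <- function(G) {
  n <- nrow(G)
  K <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    sc <- 0; nc <- 0
    for (k in seq_len(ncol(G))) {
      if (!is.na(G[i, k]) && !is.na(G[j, k])) {
        sc <- sc + 1 - abs(G[i, k] - G[j, k]) / 2; nc <- nc + 1
      }
    }
    K[i, j] <- K[j, i] <- sc / nc
  }
  K
}

# two-locus haplotype frequencies by exhaustive likelihood grid (refined)
grid_haplotype <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  tt <- table(factor(g1, 0:2), factor(g2, 0:2))
  loglik <- function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(p < 0)) return(-Inf)
    ll <- 0
    probs <- matrix(0, 3, 3)
    for (x in 0:2) for (y in 0:2) {
      # genotype probability = sum over compatible haplotype pairs
      pr <- 0
      for (h1a in 0:1) for (h1b in 0:1) for (h2a in 0:1) for (h2b in 0:1) {
        if (h1a + h2a == x && h1b + h2b == y) {
          hp <- function(a, b) p[1 + (1 - a) * 2 + (1 - b)]  # index 11,10,01,00
          pr <- pr + hp(h1a, h1b) * hp(h2a, h2b)
        }
      }
      probs[x + 1, y + 1] <- pr
    }
    sum(tt * log(pmax(probs, 1e-300)))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 2001)
  v <- vapply(grid, loglik, 0)
  best <- grid[which.max(v)]
  fine <- seq(max(lo, best - (hi - lo) / 1000), min(hi, best + (hi - lo) / 1000),
              length.out = 2001)
  vf <- vapply(fine, loglik, 0)
  fine[which.max(vf)]
}
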