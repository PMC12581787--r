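test_that("site-quality filter agrees with a brute-force predicate scan", {
  set.seed(11)
  n <- 30; m <- 100
  geno <- matrix(sample(c(0:2, NA), n * m, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), n, m)
  qual <- round(runif(m, 0, 200))
  chrom <- sample(c("chr1", "scaffold_99"), m, TRUE)
  pos <- integer(m)
  for (ch in unique(chrom)) pos[chrom == ch] <- sort(sample.int(1e6,
                                                    sum(chrom == ch)))
  ord <- order(chrom, pos)
  vt <- variant_table(data.frame(chrom = chrom[ord], pos = pos[ord],
                                 ref = "A", alt = "G", qual = qual[ord]),
                      geno[, ord])
  out <- filter_variants(vt, max_missing = 0.2, min_qual = 50,
                         min_maf = 0.15, chrom_set = "chr1")
  expected <- vapply(seq_len(n_snps(vt)), function(i) {
    g <- vt$geno[, i]
    miss <- mean(is.na(g))
    p <- mean(g, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    miss < 0.2 && vt$snps$qual[i] >= 50 && !is.na(maf) && maf >= 0.15 &&
      vt$snps$chrom[i] == "chr1"
  }, TRUE)
  expect_equal(snp_ids(out), snp_ids(vt)[expected])
  # MAF threshold from the design: 0.10 < 0.15 is removed, monomorphic always
  vt2 <- make_vt(cbind(c(rep(0L, 18), rep(1L, 2)), rep(0L, 20)))
  expect_equal(n_snps(filter_variants(vt2, min_maf = 0.15, min_qual = 0)), 0)
  expect_equal(n_snps(filter_variants(vt2, min_maf = 0.05, min_qual = 0)), 1)
})

test_that("gc_content is (G+C)/length, case-insensitive, error on empty", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content(""), "empty")
})

test_that("flank QC: GC window, N veto, truncation policy", {
  seqs <- c(c1 = paste(rep("ACGT", 300), collapse = ""))
  g <- genome_sequence(seqs)
  ok <- flank_qc("c1", 600, g)
  expect_true(ok$pass)
  expect_equal(nchar(ok$region), 201)
  expect_equal(ok$gc, gc_content(ok$region))
  # an N anywhere in the flank fails
  gn <- genome_sequence(c(c1 = paste0(substr(seqs, 1, 549), "N",
                                      substr(seqs, 551, 1200))))
  expect_false(flank_qc("c1", 600, gn)$pass)
  # truncated upstream flank fails
  expect_false(flank_qc("c1", 50, g)$pass)
  expect_error(flank_qc("c1", 5000, g), "off chromosome")
  # GC outside [0.4, 0.6] fails
  gat <- genome_sequence(c(c1 = paste(rep("AT", 600), collapse = "")))
  expect_false(flank_qc("c1", 600, gat)$pass)
})

test_that("uniqueness check agrees with exhaustive sliding-window alignment", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 2e4, dup_count = 2,
                    dup_length = 300, dup_similarity = 0.95, seed = 33)
  g <- simulate_genome(cfg)
  idx <- kmer_index(g)
  dup <- attr(g, "duplicates")
  # planted duplicates: flagged by both engine and oracle
  for (i in seq_len(nrow(dup))) {
    reg <- fetch_seq(g, dup$src_chrom[i], dup$src_start[i],
                     dup$src_start[i] + 200)
    eng <- uniqueness_check(reg, g, dup$src_chrom[i], dup$src_start[i],
                            index = idx)$unique
    ora <- brute_unique(reg, g, dup$src_chrom[i], dup$src_start[i])
    expect_false(eng)
    expect_equal(eng, ora)
  }
  # random unplanted loci: unique by both
  set.seed(1)
  for (p in sample(5000:15000, 4)) {
    hit <- any(mapply(function(s, l) p + 200 >= s & p <= s + l - 1,
                      c(dup$src_start, dup$dst_start),
                      rep(dup$length, 2)))
    if (hit) next
    reg <- fetch_seq(g, "chr1", p, p + 200)
    expect_equal(uniqueness_check(reg, g, "chr1", p, index = idx)$unique,
                 brute_unique(reg, g, "chr1", p))
  }
})

test_that("a planted copy at 50% identity stays below the duplicate threshold", {
  set.seed(44)
  base <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  region <- substr(base, 1001, 1200)
  # copy with every second base randomized -> ~50% + background identity
  seg <- strsplit(region, "")[[1]]
  evens <- seq(2, length(seg), by = 2)
  seg[evens] <- vapply(seg[evens],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       "")
  g <- genome_sequence(c(c1 = paste0(base, paste(seg, collapse = ""),
                                     substr(base, 1, 500))))
  res <- uniqueness_check(region, g, "c1", 1001)
  expect_true(res$unique)
  expect_true(brute_unique(region, g, "c1", 1001))
  # and a verbatim copy is caught
  g2 <- genome_sequence(c(c1 = paste0(base, region)))
  expect_false(uniqueness_check(region, g2, "c1", 1001)$unique)
})

test_that("probe windows: enumeration count, N region, SNP containment", {
  sim <- make_sim(seed = 55, n_chrom = 1, chrom_length = 2e4, n_snps = 20,
                  n_samples = 5, dup_count = 0)
  idx <- kmer_index(sim$genome)
  pos <- 10000
  pw <- probe_windows("chr1", pos, sim$genome, index = idx)
  expect_equal(nrow(pw$windows), 301 - 100 + 1)
  expect_equal(sum(pw$windows$contains_snp), 100)
  in_range <- pw$windows$start <= pos & pos <= pw$windows$start + 99
  expect_equal(pw$windows$contains_snp, in_range)
  # truncated region -> empty
  expect_equal(nrow(probe_windows("chr1", 100, sim$genome, index = idx)$windows), 0)
  expect_false(probe_windows("chr1", 100, sim$genome, index = idx)$pass)
  # all-N region -> zero qualified windows
  gN <- genome_sequence(c(c1 = paste(rep("N", 1000), collapse = "")))
  pwN <- probe_windows("c1", 500, gN, index = kmer_index(sim$genome))
  expect_equal(sum(pwN$windows$qualified), 0)
  expect_false(pwN$pass)
  # chosen probe contains the SNP when possible and respects GC bounds
  expect_true(pw$probe$contains_snp || !any(pw$windows$qualified &
                                              pw$windows$contains_snp))
})

test_that("LD pruning: duplicates collapse, independents survive, post-condition holds", {
  set.seed(66)
  n <- 200
  base <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  # columns 5 and 6 duplicated (r2 = 1)
  base[, 6] <- base[, 5]
  kept <- ld_prune(base, window_snps = 10, step_snps = 2, r2_max = 0.2)
  expect_true(xor(5 %in% kept, 6 %in% kept))
  # independent random columns at large n: all kept
  indep <- matrix(rbinom(n * 25, 2, 0.5), n, 25)
  expect_equal(ld_prune(indep, r2_max = 0.2), 1:25)
  # post-condition oracle: no surviving in-window pair above r2_max
  mixed <- cbind(base, base[, 1:10] + matrix(rbinom(n * 10, 1, 0.15), n, 10) -
                   matrix(rbinom(n * 10, 1, 0.15), n, 10))
  mixed[mixed < 0] <- 0L; mixed[mixed > 2] <- 2L
  w <- 8; s <- 3; r2m <- 0.2
  kept2 <- ld_prune(mixed, window_snps = w, step_snps = s, r2_max = r2m)
  X <- mixed[, kept2, drop = FALSE]
  for (ws in seq(1, max(1, length(kept2) - 1), by = s)) {
    cols <- ws:min(ws + w - 1, length(kept2))
    if (length(cols) < 2) next
    r2 <- suppressWarnings(cor(X[, cols]))^2
    diag(r2) <- NA
    expect_lte(max(r2, na.rm = TRUE), r2m + 1e-12)
  }
})

test_that("cross-reference and panel assembly set arithmetic", {
  a <- data.frame(chrom = "chr1", pos = seq(100, 1000, by = 100), ref = "A",
                  alt = "G")
  b <- data.frame(chrom = "chr1", pos = seq(550, 1450, by = 100), ref = "A",
                  alt = "G")
  # overlap: positions 550..1000 on the same grid -> none actually shared
  man <- assemble_panel(a, b)
  expect_equal(nrow(man), nrow(a) + nrow(b))
  b2 <- a[3:5, ]
  man2 <- assemble_panel(a, b2)
  expect_equal(nrow(man2), nrow(a))
  expect_equal(sum(man2$source == "linkage_map+reseq"), 3)
  expect_true(all(diff(man2$pos) > 0))
  # identical streams collapse to one
  expect_equal(nrow(assemble_panel(a, a)), nrow(a))
  # allele conflict at one locus errors
  bad <- data.frame(chrom = "chr1", pos = 100, ref = "C", alt = "T")
  expect_error(assemble_panel(a, bad), "allele mismatch")
})

test_that("panel summary distances, gap fraction and density correlation", {
  man <- data.frame(chrom = "chr1", pos = c(1000, 601001))
  ps <- panel_summary(man, c(chr1 = 1e6))
  expect_equal(ps$adjacent_distances$chr1, 600001)
  expect_equal(ps$n_adjacent_pairs, 1)
  expect_equal(ps$large_gap_fraction_pct, 100)
  # equal-density panel: per-chromosome count tracks length
  set.seed(77)
  lens <- c(chr1 = 4e6, chr2 = 3e6, chr3 = 2e6, chr4 = 1e6, chr5 = 5e5)
  rows <- do.call(rbind, lapply(names(lens), function(ch)
    data.frame(chrom = ch, pos = sort(sample.int(lens[[ch]],
                                                 round(lens[[ch]] / 2000))))))
  ps2 <- panel_summary(rows, lens)
  expect_gt(ps2$count_length_correlation, 0.9)
  expect_equal(sum(ps2$per_chrom_counts), nrow(rows))
  expect_equal(ps2$n_large_gaps / ps2$n_adjacent_pairs * 100,
               ps2$large_gap_fraction_pct)
})

test_that("effect classification covers all five classes, strand-aware", {
  # plus-strand gene: CDS 101..400 on c1; codon 1 starts at 101
  L <- 1200
  set.seed(88)
  bases <- sample(c("A", "C", "G", "T"), L, TRUE)
  bases[101:109] <- c("A", "T", "G", "G", "C", "T", "T", "A", "T")
  g <- genome_sequence(c(c1 = paste(bases, collapse = "")))
  ft <- structure(list(genes = list(g1 = list(
    id = "g1", chrom = "c1", strand = "+", start = 51, end = 600,
    exons = data.frame(start = c(51, 451), end = c(400, 600)),
    cds = data.frame(start = 101, end = 400, frame = 0L)))),
    class = "feature_table")
  expect_equal(classify_effect("c1", 700, "A", "G", ft, g), "intergenic")
  expect_equal(classify_effect("c1", 420, "A", "G", ft, g), "intronic")
  expect_equal(classify_effect("c1", 60, "A", "G", ft, g), "utr")
  # codon 3 is TAT (Tyr); third position T->C gives TAC, still Tyr
  expect_equal(classify_effect("c1", 109, "T", "C", ft, g), "synonymous")
  # codon 2 GCT (Ala) third position T->C -> GCC, still Ala
  expect_equal(classify_effect("c1", 106, "T", "C", ft, g), "synonymous")
  # codon 1 ATG -> GTG (Met -> Val): nonsynonymous
  expect_equal(classify_effect("c1", 101, "A", "G", ft, g), "nonsynonymous")
})

test_that("minus-strand codon changes verified against direct translation", {
  # minus-strand gene, CDS 201..230 (30 bp); mRNA = revcomp(genome segment)
  set.seed(99)
  bases <- sample(c("A", "C", "G", "T"), 500, TRUE)
  g <- genome_sequence(c(c1 = paste(bases, collapse = "")))
  ft <- structure(list(genes = list(g1 = list(
    id = "g1", chrom = "c1", strand = "-", start = 151, end = 280,
    exons = data.frame(start = 151, end = 280),
    cds = data.frame(start = 201, end = 230, frame = 0L)))),
    class = "feature_table")
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  mrna <- rc(fetch_seq(g, "c1", 201, 230))
  for (pos in c(230, 225, 212, 203)) {
    ref <- fetch_seq(g, "c1", pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    got <- classify_effect("c1", pos, ref, alt, ft, g)
    # independent oracle: substitute in the mRNA and translate both
    mrna_pos <- 230 - pos + 1
    mut <- mrna
    substr(mut, mrna_pos, mrna_pos) <- chartr("ACGT", "TGCA", alt)
    aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(mrna)))
    aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
    expect_equal(got, if (aa1 == aa2) "synonymous" else "nonsynonymous",
                 label = paste("pos", pos))
  }
})

test_that("design funnel is monotone and reports stage counts", {
  sim <- make_sim(seed = 12, n_chrom = 2, chrom_length = 4e4, n_samples = 40,
                  n_snps = 150, dup_count = 3, dup_length = 400,
                  dup_similarity = 0.98)
  map <- simulate_linkage_map(sim$vt, n_map = 60, overlap_fraction = 0.5,
                              seed = 2)
  pd <- design_panel(sim$vt, sim$genome, map = map)
  f <- pd$funnel
  expect_lte(f$reseq_quality, f$reseq_input)
  expect_lte(f$reseq_flank_unique, f$reseq_quality)
  expect_lte(f$reseq_probe, f$reseq_flank_unique)
  expect_lte(f$reseq_pruned, f$reseq_probe)
  expect_lte(f$map_crossref, f$map_input)
  expect_lte(f$map_probe, f$map_crossref)
  expect_lte(f$final, f$reseq_pruned + f$map_probe)
  expect_equal(f$final, nrow(pd$manifest))
  expect_false(any(duplicated(paste(pd$manifest$chrom, pd$manifest$pos))))
})
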