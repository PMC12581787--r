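# Synthetic study generator: genomes with planted duplicate segments,
# structured diploid genotypes (Balding-Nichols divergence, optional block LD),
# linkage-map SNP lists and heritable phenotypes. Same seed + config gives
# byte-identical output.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: 220 accessions in four
#' population clusters on a 15-chromosome genome, panel-scale marker density,
#' divergence near the observed between-group FST (~0.25), and a polygenic
#' trait of moderate heritability (0.35, the middle of the 0.25-0.45 range
#' typical of leaf morphology traits). Chromosome lengths are desk-scale.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_samples number of diploid individuals.
#' @param n_snps number of segregating sites to simulate.
#' @param n_subpops number of subpopulations.
#' @param fst_target expected Balding-Nichols divergence among subpopulations.
#' @param ld_block_bp haplotype-block length for block-copy LD; 0 (default)
#'   simulates independent sites.
#' @param n_founders founder-haplotype pool size per block when LD is on.
#' @param maf_beta shape parameters of the Beta distribution the ancestral
#'   allele frequency is drawn from (then truncated to `[0.05, 0.95]`).
#' @param missing_rate per-call missing probability.
#' @param n_qtn number of causal loci for the default phenotype.
#' @param h2_target realized narrow-sense heritability of the phenotype.
#' @param dup_count,dup_length,dup_similarity planted duplicate segments:
#'   how many source/copy pairs, their length, and per-base identity.
#' @param seed mandatory RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 15, chrom_length = 2e5, n_samples = 220,
                       n_snps = 5000, n_subpops = 4, fst_target = 0.25,
                       ld_block_bp = 0, n_founders = 30,
                       maf_beta = c(0.9, 0.9), missing_rate = 0.05,
                       n_qtn = 50, h2_target = 0.35,
                       dup_count = 8, dup_length = 300, dup_similarity = 0.95,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$fst_target >= 0, cfg$fst_target <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$h2_target >= 0, cfg$h2_target <= 1,
            cfg$n_qtn <= cfg$n_snps, cfg$chrom_length >= 1e4)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference genome with planted duplicate segments
#'
#' Uniform base composition; `dup_count` segment pairs are copied with per-base
#' mismatch probability `1 - dup_similarity` and their coordinates recorded in
#' the `duplicates` attribute (used as ground truth by the redundancy filter
#' tests).
#'
#' @param config a [sim_config()].
#' @return a `genome_sequence`, with attribute `duplicates`: data.frame of
#'   (src_chrom, src_start, dst_chrom, dst_start, length).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  if (config$dup_length > config$chrom_length)
    stop("duplicate segment longer than chromosome")
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = ""), "")
  dup <- data.frame(src_chrom = character(0), src_start = integer(0),
                    dst_chrom = character(0), dst_start = integer(0),
                    length = integer(0))
  L <- config$dup_length
  overlaps_used <- function(ch, st) {
    any(dup$src_chrom == ch & abs(dup$src_start - st) < L) ||
      any(dup$dst_chrom == ch & abs(dup$dst_start - st) < L)
  }
  for (i in seq_len(config$dup_count)) {
    repeat {
      sc <- sample(chroms, 1)
      ss <- sample.int(config$chrom_length - L + 1, 1)
      if (!overlaps_used(sc, ss)) break
    }
    repeat {
      dc <- sample(chroms, 1)
      ds <- sample.int(config$chrom_length - L + 1, 1)
      if ((dc != sc || abs(ds - ss) >= L) && !overlaps_used(dc, ds)) break
    }
    seg <- strsplit(substr(seqs[[sc]], ss, ss + L - 1), "")[[1]]
    flip <- runif(L) < (1 - config$dup_similarity)
    if (any(flip))
      seg[flip] <- vapply(seg[flip], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    substr(seqs[[dc]], ds, ds + L - 1) <- paste(seg, collapse = "")
    dup <- rbind(dup, data.frame(src_chrom = sc, src_start = ss,
                                 dst_chrom = dc, dst_start = ds, length = L))
  }
  g <- genome_sequence(seqs)
  attr(g, "duplicates") <- dup
  g
}

#' Simulate a structured diploid population
#'
#' Sites are placed uniformly at non-N genome positions; the ancestral allele
#' frequency is Beta-distributed, and each subpopulation's frequency is drawn
#' from the Balding-Nichols distribution at `fst_target`. With
#' `ld_block_bp > 0`, haplotypes copy founder haplotypes block-wise, inducing
#' within-block LD. Missing calls are dropped uniformly at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param genome a `genome_sequence` (from [simulate_genome()]).
#' @return list with `vt` (a [variant_table()]) and `truth` (subpopulation
#'   labels, ancestral and subpopulation allele frequencies, config echo).
#' @export
simulate_population <- function(config, genome) {
  set.seed(config$seed + 1L)
  chroms <- names(genome$seq)
  avail <- sum(genome$lengths)
  if (config$n_snps > avail) stop("n_snps exceeds available sites")
  # sample global offsets without replacement, map to (chrom, pos)
  offs <- sort(sample.int(avail, config$n_snps))
  cum <- cumsum(as.numeric(genome$lengths))
  chr_idx <- findInterval(offs - 1, cum) + 1L
  pos <- as.integer(offs - c(0, cum)[chr_idx])
  chrom <- chroms[chr_idx]
  ref <- mapply(function(ch, p) fetch_seq(genome, ch, p, p), chrom, pos,
                USE.NAMES = FALSE)
  nn <- ref == "N"
  if (any(nn)) { # retry N sites by shifting (rare; simulated genomes are N-free)
    keep <- !nn
    chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
  }
  m <- length(pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  p_anc <- 0.05 + 0.9 * rbeta(m, config$maf_beta[1], config$maf_beta[2])
  K <- config$n_subpops
  Fst <- config$fst_target
  p_sub <- matrix(0, K, m)
  for (k in seq_len(K)) {
    p_sub[k, ] <- if (Fst == 0) p_anc else
      rbeta(m, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
  }
  subpop <- rep(seq_len(K), length.out = config$n_samples)
  subpop <- sort(subpop)
  n <- config$n_samples
  geno <- matrix(0L, n, m)
  if (config$ld_block_bp <= 0) {
    for (k in seq_len(K)) {
      rows <- which(subpop == k)
      geno[rows, ] <- matrix(rbinom(length(rows) * m, 2L, rep(p_sub[k, ],
                             each = length(rows))), length(rows), m)
    }
  } else {
    block <- paste(chrom, (pos - 1) %/% config$ld_block_bp)
    block_id <- match(block, unique(block))
    for (k in seq_len(K)) {
      rows <- which(subpop == k)
      hap <- matrix(0L, 2 * length(rows), m)
      for (b in unique(block_id)) {
        cols <- which(block_id == b)
        founders <- matrix(rbinom(config$n_founders * length(cols), 1L,
                                  rep(p_sub[k, cols], each = config$n_founders)),
                           config$n_founders, length(cols))
        pick <- sample.int(config$n_founders, 2 * length(rows), replace = TRUE)
        hap[, cols] <- founders[pick, , drop = FALSE]
      }
      geno[rows, ] <- hap[seq(1, 2 * length(rows), by = 2), , drop = FALSE] +
        hap[seq(2, 2 * length(rows), by = 2), , drop = FALSE]
    }
  }
  if (config$missing_rate > 0)
    geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
  snps <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     qual = round(runif(m, 50, 2000), 1),
                     stringsAsFactors = FALSE)
  ord <- order(match(snps$chrom, chroms), snps$pos)
  vt <- variant_table(snps[ord, ], geno[, ord, drop = FALSE],
                      sprintf("S%03d", seq_len(n)))
  truth <- list(subpop = subpop, p_anc = p_anc[ord],
                p_sub = p_sub[, ord, drop = FALSE],
                fst_target = Fst, config = config)
  list(vt = vt, truth = truth)
}

#' Simulate a heritable phenotype from genotypes
#'
#' `n_qtn` polymorphic loci get i.i.d. normal effects; the genetic values are
#' `W beta` on mean-imputed dosages and the residual is rescaled so the
#' realized variance ratio equals `h2_target` exactly.
#'
#' @param G genotype matrix (samples x SNPs) or a [variant_table()].
#' @param n_qtn number of causal loci; NULL makes every polymorphic locus
#'   causal (the infinitesimal regime the GBLUP model assumes).
#' @param h2_target realized heritability in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `y` (named phenotype vector) and `truth` (`qtn` column
#'   indices, `beta`, `sigma_g2`, `sigma_e2`, `h2`).
#' @export
simulate_phenotype <- function(G, n_qtn, h2_target, seed) {
  if (inherits(G, "variant_table")) G <- genotypes(G)
  set.seed(seed)
  stopifnot(h2_target >= 0, h2_target <= 1)
  W <- impute_mean(G)
  poly <- which(apply(W, 2, function(x) var(x) > 0))
  if (is.null(n_qtn)) n_qtn <- length(poly)
  if (length(poly) < n_qtn) stop("not enough polymorphic loci for n_qtn QTN")
  qtn <- sort(sample(poly, n_qtn))
  beta <- rnorm(n_qtn)
  g <- drop(W[, qtn, drop = FALSE] %*% beta)
  g <- g - mean(g)
  n <- nrow(W)
  if (h2_target == 0) {
    y <- rnorm(n)
    truth <- list(qtn = qtn, beta = beta * 0, sigma_g2 = 0,
                  sigma_e2 = var(y), h2 = 0)
  } else if (h2_target == 1) {
    y <- g
    truth <- list(qtn = qtn, beta = beta, sigma_g2 = var(g), sigma_e2 = 0,
                  h2 = 1)
  } else {
    eps <- rnorm(n)
    eps <- eps - mean(eps)
    eps <- eps * sqrt(var(g) * (1 - h2_target) / (h2_target * var(eps)))
    y <- g + eps
    truth <- list(qtn = qtn, beta = beta, sigma_g2 = var(g),
                  sigma_e2 = var(eps),
                  h2 = var(g) / (var(g) + var(eps)))
  }
  names(y) <- rownames(G)
  list(y = y, truth = truth)
}

#' Simulate a linkage-map SNP list with controlled overlap
#'
#' Exactly `round(overlap_fraction * n_map)` loci are taken from the variant
#' table (same chrom/pos/alleles); the remainder are novel loci absent from it.
#'
#' @param vt a [variant_table()].
#' @param n_map total number of map SNPs.
#' @param overlap_fraction fraction of map SNPs shared with `vt`.
#' @param seed RNG seed.
#' @return data.frame (chrom, pos, ref, alt).
#' @export
simulate_linkage_map <- function(vt, n_map, overlap_fraction, seed) {
  set.seed(seed)
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  n_shared <- round(overlap_fraction * n_map)
  if (n_shared > n_snps(vt)) stop("overlap exceeds variant table size")
  shared <- vt$snps[sort(sample.int(n_snps(vt), n_shared)),
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]
  n_extra <- n_map - n_shared
  extra <- NULL
  if (n_extra > 0) {
    taken <- paste(vt$snps$chrom, vt$snps$pos)
    chrom <- sample(unique(vt$snps$chrom), n_extra, replace = TRUE)
    pos <- sample.int(max(vt$snps$pos), n_extra, replace = TRUE)
    clash <- paste(chrom, pos) %in% taken | duplicated(paste(chrom, pos))
    while (any(clash)) {
      pos[clash] <- sample.int(max(vt$snps$pos), sum(clash), replace = TRUE)
      clash <- paste(chrom, pos) %in% taken | duplicated(paste(chrom, pos))
    }
    ref <- sample(c("A", "C", "G", "T"), n_extra, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    extra <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  }
  out <- rbind(shared, extra)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Simulate F1 offspring genotypes from two parents
#'
#' Each offspring receives one allele per locus from each parent: a homozygote
#' transmits its allele, a heterozygote transmits either with probability 1/2;
#' a missing parental call yields a missing offspring call.
#'
#' @param parent_a,parent_b genotype vectors (codes 0/1/2/NA) over the same loci.
#' @param n_offspring number of F1 individuals.
#' @param seed RNG seed.
#' @return integer matrix `n_offspring x n_loci`.
#' @export
simulate_f1 <- function(parent_a, parent_b, n_offspring, seed) {
  if (length(parent_a) != length(parent_b))
    stop("parents must be genotyped at the same loci")
  set.seed(seed)
  m <- length(parent_a)
  draw <- function(g) {
    al <- matrix(NA_integer_, n_offspring, m)
    al[, which(g == 0)] <- 0L
    al[, which(g == 2)] <- 1L
    het <- which(g == 1)
    if (length(het))
      al[, het] <- matrix(rbinom(n_offspring * length(het), 1L, 0.5),
                          n_offspring, length(het))
    al
  }
  draw(parent_a) + draw(parent_b)
}

#' Toy gene models tiling a simulated genome
#'
#' Places a two-exon gene every `spacing` bp (alternating strand); the CDS is
#' the central part of each exon, frame-consistent, so effect classification
#' has intergenic, intronic, UTR and coding targets.
#'
#' @param genome a `genome_sequence`.
#' @param spacing distance between gene starts (default 20000).
#' @return a `feature_table`.
#' @export
simulate_gene_models <- function(genome, spacing = 20000) {
  genes <- list()
  k <- 0
  for (ch in names(genome$seq)) {
    L <- genome$lengths[[ch]]
    starts <- seq(1000, L - 3000, by = spacing)
    for (s in starts) {
      k <- k + 1
      gid <- sprintf("gene%04d", k)
      # exon1: s..s+599 (CDS s+120..s+419), intron, exon2: s+1000..s+1599
      # (CDS s+1000..s+1300 completes the ORF: 300 + 301 = 601 bp -> pad to 603)
      cds1 <- c(s + 120, s + 419)           # 300 bp
      cds2 <- c(s + 1000, s + 1302)         # 303 bp; total 603 = 201 codons
      genes[[gid]] <- list(id = gid, chrom = ch,
                           strand = if (k %% 2 == 0) "-" else "+",
                           start = s, end = s + 1599,
                           exons = data.frame(start = c(s, s + 1000),
                                              end = c(s + 599, s + 1599)),
                           cds = data.frame(start = c(cds1[1], cds2[1]),
                                            end = c(cds1[2], cds2[2]),
                                            frame = c(0L, 0L)))
    }
  }
  structure(list(genes = genes), class = "feature_table")
}

#' Write a feature table as GFF3
#' @param features a `feature_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in features$genes) {
    writeLines(paste(g$chrom, "panelcraft", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$id), sep = "\t"), con)
    mid <- paste0(g$id, ".t1")
    writeLines(paste(g$chrom, "panelcraft", "mRNA", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", mid, ";Parent=", g$id),
                     sep = "\t"), con)
    for (i in seq_len(nrow(g$exons)))
      writeLines(paste(g$chrom, "panelcraft", "exon", g$exons$start[i],
                       g$exons$end[i], ".", g$strand, ".",
                       paste0("Parent=", mid), sep = "\t"), con)
    for (i in seq_len(nrow(g$cds)))
      writeLines(paste(g$chrom, "panelcraft", "CDS", g$cds$start[i],
                       g$cds$end[i], ".", g$strand, g$cds$frame[i],
                       paste0("ID=", mid, ".cds;Parent=", mid), sep = "\t"), con)
  }
  invisible(path)
}
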