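# Panel-design funnel: site-quality filtering, flank QC, genome-uniqueness
# (redundancy) filtering by k-mer seeded ungapped extension, probe-window
# enumeration, windowed LD pruning, linkage-map cross-referencing, panel
# assembly and characterization statistics.

#' Site-quality filter
#'
#' Retains SNPs with missing rate below `max_missing`, site QUAL at least
#' `min_qual`, MAF at least `min_maf`, and (optionally) a chromosome in the
#' supplied placed-chromosome set. Order is preserved.
#'
#' @param vt a [variant_table()].
#' @param max_missing maximum tolerated missing-call rate (exclusive bound).
#' @param min_qual minimum site quality score (inclusive). Records with
#'   missing QUAL fail.
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param chrom_set character vector of placed chromosome names; SNPs on other
#'   sequences (unplaced contigs) are dropped. NULL keeps all.
#' @return the filtered [variant_table()].
#' @export
filter_variants <- function(vt, max_missing = 0.2, min_qual = 50,
                            min_maf = 0.15, chrom_set = NULL) {
  miss <- snp_missing_rate(vt)
  maf <- snp_maf(vt)
  qual <- vt$snps$qual
  keep <- miss < max_missing &
    (!is.na(qual) & qual >= min_qual) &
    (!is.na(maf) & maf >= min_maf)
  if (!is.null(chrom_set)) keep <- keep & vt$snps$chrom %in% chrom_set
  subset_snps(vt, which(keep))
}

#' GC content of a DNA sequence
#' @param seq DNA string (case-insensitive).
#' @return fraction of G/C bases.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  s <- toupper(seq)
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_gc / nchar(s)
}

#' Flank quality control for a SNP
#'
#' Extracts `flank` bases either side of the SNP (a 2*flank+1 region) and
#' checks GC bounds and N-freedom. SNPs whose flanks run off the chromosome
#' end fail (fixed-length probes require complete flanks).
#'
#' @param chrom,pos SNP locus.
#' @param genome a `genome_sequence`.
#' @param flank flank length (default 100).
#' @param gc_min,gc_max inclusive GC bounds (defaults 0.4 and 0.6).
#' @return list with `region` (the sequence or NA if truncated), `gc`,
#'   `has_n`, and `pass`.
#' @export
flank_qc <- function(chrom, pos, genome, flank = 100, gc_min = 0.4,
                     gc_max = 0.6) {
  L <- genome$lengths[[chrom]]
  if (is.null(L)) stop("unknown chromosome: ", chrom)
  if (pos < 1 || pos > L) stop("SNP position off chromosome")
  if (pos - flank < 1 || pos + flank > L)
    return(list(region = NA_character_, gc = NA_real_, has_n = NA,
                pass = FALSE))
  region <- fetch_seq(genome, chrom, pos - flank, pos + flank)
  gc <- gc_content(region)
  has_n <- grepl("N", region, fixed = TRUE)
  list(region = region, gc = gc, has_n = has_n,
       pass = !has_n && gc >= gc_min && gc <= gc_max)
}

# ---- k-mer seeded uniqueness (redundancy) filter -------------------------

base_codes <- c(A = 0, C = 1, G = 2, T = 3)

# encode every k-mer of a sequence as a base-4 number (double); k-mers
# containing non-ACGT bases get NA
encode_kmers <- function(seq, k) {
  x <- base_codes[strsplit(seq, "")[[1]]]
  L <- length(x)
  if (L < k) return(numeric(0))
  n <- L - k + 1
  code <- numeric(n)
  for (j in 0:(k - 1)) code <- code + x[(1 + j):(n + j)] * 4^(k - 1 - j)
  code
}

#' Build a k-mer index of a genome
#'
#' Forward-strand k-mer positions, sorted by encoded k-mer for binary-search
#' lookup. Build once and pass to [uniqueness_check()] / [probe_windows()] /
#' [design_panel()].
#'
#' @param genome a `genome_sequence`.
#' @param k seed length (default 15).
#' @return a `kmer_index` list.
#' @export
kmer_index <- function(genome, k = 15) {
  codes <- list(); chroms <- list(); poss <- list()
  for (ci in seq_along(genome$seq)) {
    cd <- encode_kmers(genome$seq[[ci]], k)
    ok <- !is.na(cd)
    codes[[ci]] <- cd[ok]
    chroms[[ci]] <- rep.int(ci, sum(ok))
    poss[[ci]] <- which(ok)
  }
  code <- unlist(codes); chrom <- unlist(chroms); pos <- unlist(poss)
  ord <- order(code, method = "radix")
  structure(list(code = code[ord], chrom = chrom[ord], pos = pos[ord],
                 chrom_names = names(genome$seq), k = k),
            class = "kmer_index")
}

# positions of exact genome matches for a vector of encoded k-mers;
# returns data.frame(qoff, chrom, pos)
kmer_hits <- function(index, qcodes) {
  ok <- which(!is.na(qcodes))
  if (!length(ok)) return(data.frame(qoff = integer(0), chrom = integer(0),
                                     pos = integer(0)))
  lo <- findInterval(qcodes[ok] - 0.5, index$code)
  hi <- findInterval(qcodes[ok] + 0.5, index$code)
  n_hit <- hi - lo
  qoff <- rep.int(ok, n_hit)
  idx <- sequence(n_hit, from = lo + 1L)
  data.frame(qoff = qoff, chrom = index$chrom[idx], pos = index$pos[idx])
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# identity of an ungapped alignment of `region` to genome chromosome `chrom`
# along diagonal `diag` (region position i <-> genome position diag + i)
diag_identity <- function(region, genome, chrom, diag) {
  len <- nchar(region)
  L <- genome$lengths[[chrom]]
  i_lo <- max(1, 1 - diag)
  i_hi <- min(len, L - diag)
  if (i_hi < i_lo) return(c(span = 0, matches = 0))
  q <- strsplit(substr(region, i_lo, i_hi), "")[[1]]
  s <- strsplit(fetch_seq(genome, chrom, diag + i_lo, diag + i_hi), "")[[1]]
  c(span = i_hi - i_lo + 1, matches = sum(q == s))
}

#' Genome-uniqueness check for a candidate region
#'
#' Seed-and-extend screen for near-duplicate copies: exact k-mer seeds (both
#' strands) anchor ungapped diagonal alignments; the region is called a
#' duplicate if any non-self alignment covers at least `min_coverage` of the
#' region at identity at least `min_identity`. Like any seeded aligner, copies
#' diverged enough to contain no exact seed k-mer are not detectable.
#'
#' @param region the candidate sequence (extracted from `self_chrom`,
#'   `self_start`).
#' @param genome a `genome_sequence`.
#' @param self_chrom,self_start the region's own locus, used to discount the
#'   self-hit (any alignment overlapping it is ignored).
#' @param min_identity minimum per-base identity over the aligned span.
#' @param min_coverage minimum aligned span as a fraction of region length.
#' @param index optional pre-built [kmer_index()]; built on the fly otherwise.
#' @return list with `unique` (logical) and `hits` (data.frame of qualifying
#'   non-self alignments).
#' @export
uniqueness_check <- function(region, genome, self_chrom, self_start,
                             min_identity = 0.6, min_coverage = 0.6,
                             index = NULL) {
  if (is.null(index)) index <- kmer_index(genome)
  k <- index$k
  len <- nchar(region)
  if (len < k) stop("region shorter than seed length")
  self_end <- self_start + len - 1
  hits_out <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         identity = numeric(0), coverage = numeric(0))
  for (strand in c("+", "-")) {
    q <- if (strand == "+") region else revcomp(region)
    h <- kmer_hits(index, encode_kmers(q, k))
    if (!nrow(h)) next
    diag <- h$pos - h$qoff
    key <- paste(h$chrom, diag)
    keep <- !duplicated(key)
    for (i in which(keep)) {
      ch <- index$chrom_names[h$chrom[i]]
      d <- diag[i]
      g_lo <- d + 1; g_hi <- d + len
      if (strand == "+" && ch == self_chrom &&
          g_lo <= self_end && g_hi >= self_start) next  # self-hit
      al <- diag_identity(q, genome, ch, d)
      if (al["span"] < min_coverage * len) next
      if (al["matches"] / al["span"] < min_identity) next
      hits_out <- rbind(hits_out, data.frame(
        chrom = ch, start = max(1, g_lo), end = min(genome$lengths[[ch]], g_hi),
        strand = strand, identity = unname(al["matches"] / al["span"]),
        coverage = unname(al["span"]) / len))
    }
  }
  list(unique = nrow(hits_out) == 0, hits = hits_out)
}

# Window-level uniqueness, vectorized over all windows of a region: seed
# diagonals are found once for the whole region (both strands), each diagonal
# is scored per-base against the genome, and per-window identity/coverage
# follow from sliding sums. A window is non-unique if any diagonal gives it a
# non-self alignment with span >= min_coverage*window at identity >=
# min_identity. Plus-strand diagonals within `window` bp of the region's own
# location are treated as self-hits.
window_uniqueness <- function(chrom, pos, genome, flank, window, starts_local,
                              min_identity, min_coverage, index) {
  a <- pos - flank                     # chrom coordinate of region position 1
  region <- fetch_seq(genome, chrom, a, pos + flank)
  L <- nchar(region)
  k <- index$k
  dup <- rep(FALSE, length(starts_local))
  score_query <- function(q) {
    h <- kmer_hits(index, encode_kmers(q, k))
    if (!nrow(h)) return(NULL)
    o <- h$pos - h$qoff                # region position i <-> genome o + i
    key <- paste(h$chrom, o)
    list(chrom = h$chrom[!duplicated(key)], o = o[!duplicated(key)])
  }
  qchars_fwd <- strsplit(region, "")[[1]]
  qchars_rev <- strsplit(revcomp(region), "")[[1]]
  for (strand in c("+", "-")) {
    qchars <- if (strand == "+") qchars_fwd else qchars_rev
    q <- paste(qchars, collapse = "")
    dg <- score_query(q)
    if (is.null(dg)) next
    for (t in seq_along(dg$o)) {
      ch <- index$chrom_names[dg$chrom[t]]
      o <- dg$o[t]
      if (strand == "+" && ch == chrom && abs(o - (a - 1)) < window) next
      Lc <- genome$lengths[[ch]]
      i_lo <- max(1, 1 - o); i_hi <- min(L, Lc - o)
      if (i_hi - i_lo + 1 < min_coverage * window) next
      valid <- logical(L)
      valid[i_lo:i_hi] <- TRUE
      mvec <- logical(L)
      s <- strsplit(fetch_seq(genome, ch, o + i_lo, o + i_hi), "")[[1]]
      mvec[i_lo:i_hi] <- qchars[i_lo:i_hi] == s
      cm <- c(0, cumsum(mvec)); cv <- c(0, cumsum(valid))
      ws <- if (strand == "+") starts_local else L - starts_local - window + 2
      span <- cv[ws + window] - cv[ws]
      matches <- cm[ws + window] - cm[ws]
      hit <- span >= min_coverage * window & matches >= min_identity * span &
        span > 0
      dup <- dup | hit
    }
  }
  !dup
}

#' Enumerate and score probe windows around a SNP
#'
#' Takes the `flank` bases either side of the SNP (a `2*flank+1` region,
#' default 301 bp) and slides a `window`-bp window with step `step` across it,
#' scoring each window for GC bounds, N-freedom, genome uniqueness and SNP
#' containment. A SNP passes probe selection if at least one window passes the
#' GC / N / uniqueness checks; among qualifying windows the chosen probe
#' prefers windows containing the SNP, then GC closest to 0.5, then the
#' leftmost start.
#'
#' @param chrom,pos SNP locus.
#' @param genome a `genome_sequence`.
#' @param flank half-width of the evaluated region (default 150).
#' @param window probe length (default 100).
#' @param step window step (default 1).
#' @param gc_min,gc_max inclusive GC bounds.
#' @param index optional [kmer_index()].
#' @return list with `windows` (data.frame: start, seq, gc, has_n, unique,
#'   contains_snp, qualified), `pass`, and `probe` (chosen window row or NULL).
#'   A SNP whose region is truncated by the chromosome end yields zero windows
#'   and `pass = FALSE`.
#' @export
probe_windows <- function(chrom, pos, genome, flank = 150, window = 100,
                          step = 1, gc_min = 0.4, gc_max = 0.6, index = NULL) {
  L <- genome$lengths[[chrom]]
  empty <- list(windows = data.frame(), pass = FALSE, probe = NULL)
  if (pos - flank < 1 || pos + flank > L) return(empty)
  if (is.null(index)) index <- kmer_index(genome)
  region <- fetch_seq(genome, chrom, pos - flank, pos + flank)
  reg_len <- 2 * flank + 1
  starts_local <- seq(1, reg_len - window + 1, by = step)
  uniq <- window_uniqueness(chrom, pos, genome, flank, window, starts_local,
                            min_identity = 0.6, min_coverage = 0.6, index)
  wseq <- substring(region, starts_local, starts_local + window - 1)
  wstart <- pos - flank + starts_local - 1
  w <- data.frame(start = wstart, seq = wseq,
                  gc = vapply(wseq, gc_content, 0, USE.NAMES = FALSE),
                  has_n = grepl("N", wseq, fixed = TRUE),
                  unique = uniq,
                  contains_snp = wstart <= pos & pos <= wstart + window - 1,
                  stringsAsFactors = FALSE)
  w$qualified <- !w$has_n & w$gc >= gc_min & w$gc <= gc_max & w$unique
  probe <- NULL
  if (any(w$qualified)) {
    cand <- w[w$qualified, , drop = FALSE]
    cand <- cand[order(!cand$contains_snp, abs(cand$gc - 0.5), cand$start), ]
    probe <- cand[1, , drop = FALSE]
  }
  list(windows = w, pass = any(w$qualified), probe = probe)
}

#' Windowed LD pruning
#'
#' Greedy pruning over sliding windows of `window_snps` consecutive kept SNPs
#' (step `step_snps`): within a window, the worst pair with squared genotype
#' correlation above `r2_max` repeatedly loses its lower-MAF member (tie: the
#' higher column index). Passes repeat until no in-window pair violates the
#' bound, so the post-condition holds over the final kept set. r2 is computed
#' on mean-imputed dosages; pairs with fewer than 20 co-observed samples are
#' skipped.
#'
#' @param G genotype matrix (samples x SNPs, genomic column order) or a
#'   [variant_table()].
#' @param window_snps,step_snps window size and step, in SNPs (defaults 100, 10).
#' @param r2_max maximum tolerated r-squared (default 0.2).
#' @param min_co minimum co-observed samples for a pair to be evaluated.
#' @return integer vector of kept column indices (increasing).
#' @export
ld_prune <- function(G, window_snps = 100, step_snps = 10, r2_max = 0.2,
                     min_co = 20) {
  if (inherits(G, "variant_table")) G <- G$geno
  m <- ncol(G)
  if (m == 0) return(integer(0))
  X <- impute_mean(G)
  maf <- snp_maf(G)
  maf[is.na(maf)] <- 0
  obs <- !is.na(G)
  kept <- seq_len(m)
  repeat {
    removed_any <- FALSE
    ws <- 1
    while (ws <= length(kept)) {
      idx <- kept[ws:min(ws + window_snps - 1, length(kept))]
      if (length(idx) >= 2) {
        repeat {
          r2 <- suppressWarnings(cor(X[, idx, drop = FALSE]))^2
          co <- crossprod(obs[, idx, drop = FALSE])
          r2[co < min_co] <- NA
          r2[!is.finite(r2)] <- NA
          diag(r2) <- NA
          if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= r2_max) break
          worst <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
          a <- idx[worst[1]]; b <- idx[worst[2]]
          drop_col <- if (maf[a] < maf[b]) a
                      else if (maf[b] < maf[a]) b
                      else max(a, b)
          idx <- setdiff(idx, drop_col)
          kept <- setdiff(kept, drop_col)
          removed_any <- TRUE
          if (length(idx) < 2) break
        }
      }
      ws <- ws + step_snps
    }
    if (!removed_any) break
  }
  kept
}

#' Cross-reference linkage-map SNPs with a variant table
#'
#' Intersection on (chrom, pos, ref, alt), preserving the variant table's
#' order.
#'
#' @param map_snps data.frame with chrom, pos, ref, alt.
#' @param vt a [variant_table()].
#' @return the [variant_table()] subset present in the map.
#' @export
crossref_with_map <- function(map_snps, vt) {
  key_map <- paste(map_snps$chrom, map_snps$pos, map_snps$ref, map_snps$alt)
  key_vt <- paste(vt$snps$chrom, vt$snps$pos, vt$snps$ref, vt$snps$alt)
  subset_snps(vt, which(key_vt %in% key_map))
}

#' Assemble the final panel from the two candidate streams
#'
#' Deduplicated union by locus; on collision (same chrom/pos, same alleles)
#' one record is kept with the source labels merged. Same locus with
#' conflicting alleles is an error.
#'
#' @param reseq data.frame of resequencing-stream candidates (chrom, pos, ref,
#'   alt, plus optional probe columns).
#' @param map data.frame of linkage-map-stream candidates (same columns).
#' @return a `panel_manifest` data.frame (chrom, pos, ref, alt, source, ...),
#'   sorted by chromosome then position.
#' @export
assemble_panel <- function(reseq, map) {
  pick <- function(df, src) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$source <- src
    df
  }
  all_cand <- rbind_fill(pick(reseq, "reseq"), pick(map, "linkage_map"))
  key <- paste(all_cand$chrom, all_cand$pos)
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    if (length(unique(paste(all_cand$ref[rows], all_cand$alt[rows]))) > 1)
      stop("allele mismatch between streams at locus ", k)
    all_cand$source[rows[1]] <- paste(sort(unique(all_cand$source[rows])),
                                      collapse = "+")
  }
  out <- all_cand[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_manifest", "data.frame")
  out
}

# rbind two data.frames, filling missing columns with NA
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, names(b))) b[[cc]] <- NA
  rbind(a[cols], b[cols])
}

#' Panel characterization statistics
#'
#' Adjacent-SNP distances are computed within chromosomes only. Reported: the
#' per-chromosome distance lists, mean adjacent distance, the count and
#' percentage of adjacent pairs farther apart than `gap_bp`, per-chromosome
#' SNP counts, and the Pearson correlation of count with chromosome length.
#'
#' @param manifest a `panel_manifest` (or any data.frame with chrom, pos).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param gap_bp large-gap threshold in bp (default 5e5).
#' @return object of class `panel_summary`.
#' @export
panel_summary <- function(manifest, chrom_lengths, gap_bp = 5e5) {
  sp <- split(manifest$pos, manifest$chrom)
  dists <- lapply(sp, function(p) diff(sort(p)))
  all_d <- unlist(dists, use.names = FALSE)
  if (!length(all_d)) stop("need at least two SNPs on one chromosome")
  counts <- vapply(sp, length, 0L)
  cl <- chrom_lengths[names(counts)]
  r <- if (length(counts) >= 3 && sd(counts) > 0 && sd(cl) > 0)
    cor(counts, cl) else NA_real_
  out <- list(adjacent_distances = dists,
              mean_adjacent_distance = mean(all_d),
              n_adjacent_pairs = length(all_d),
              n_large_gaps = sum(all_d > gap_bp),
              large_gap_fraction_pct = 100 * sum(all_d > gap_bp) / length(all_d),
              per_chrom_counts = counts,
              count_length_correlation = r,
              total_snps = nrow(manifest), gap_bp = gap_bp)
  class(out) <- "panel_summary"
  out
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("panel_summary:", x$total_snps, "SNPs on", length(x$per_chrom_counts),
      "chromosomes\n")
  cat(sprintf("  mean adjacent distance: %.2f kb\n",
              x$mean_adjacent_distance / 1000))
  cat(sprintf("  adjacent pairs > %g kb: %d of %d (%.2f%%)\n", x$gap_bp / 1000,
              x$n_large_gaps, x$n_adjacent_pairs, x$large_gap_fraction_pct))
  cat(sprintf("  count~length Pearson r: %.3f\n", x$count_length_correlation))
  invisible(x)
}

#' Classify the predicted effect of a SNP
#'
#' Position against gene models gives intergenic / intronic / UTR; for coding
#' positions the affected codon is translated with the reference and alternate
#' allele (strand-aware) to separate synonymous from nonsynonymous changes.
#'
#' @param chrom,pos,ref,alt the SNP.
#' @param features a `feature_table`.
#' @param genome a `genome_sequence`.
#' @return one of "intergenic", "intronic", "utr", "synonymous",
#'   "nonsynonymous".
#' @export
classify_effect <- function(chrom, pos, ref, alt, features, genome) {
  for (g in features$genes) {
    if (g$chrom != chrom || pos < g$start || pos > g$end) next
    in_cds <- which(g$cds$start <= pos & pos <= g$cds$end)
    if (length(in_cds)) {
      return(cds_effect(g, pos, alt, genome))
    }
    in_exon <- any(g$exons$start <= pos & pos <= g$exons$end)
    return(if (in_exon) "utr" else "intronic")
  }
  "intergenic"
}

# translate the codon containing `pos` with and without the alternate allele
cds_effect <- function(gene, pos, alt, genome) {
  cds <- gene$cds[order(gene$cds$start), , drop = FALSE]
  lens <- cds$end - cds$start + 1
  if (sum(lens) %% 3 != 0 && cds$frame[1] == 0 && gene$strand == "+")
    warning("CDS length not divisible by 3 for gene ", gene$id)
  if (gene$strand == "+") {
    cds_seq <- paste(mapply(function(s, e) fetch_seq(genome, gene$chrom, s, e),
                            cds$start, cds$end), collapse = "")
    i <- which(cds$start <= pos & pos <= cds$end)
    off <- (if (i > 1) sum(lens[seq_len(i - 1)]) else 0) + (pos - cds$start[i] + 1)
    off <- off - cds$frame[1]
    sub_base <- alt
  } else {
    ord <- order(cds$start, decreasing = TRUE)
    cds_seq <- paste(vapply(ord, function(j)
      revcomp(fetch_seq(genome, gene$chrom, cds$start[j], cds$end[j])), ""),
      collapse = "")
    i <- which(cds$start <= pos & pos <= cds$end)
    before <- sum(lens[cds$start > cds$end[i]])
    off <- before + (cds$end[i] - pos + 1)
    off <- off - cds$frame[ord[1]]
    sub_base <- chartr("ACGT", "TGCA", alt)
  }
  if (off < 1) return("utr")  # inside the frame-trimmed leading bases
  codon_i <- (off - 1) %/% 3
  cpos <- off - codon_i * 3
  codon <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  if (nchar(codon) < 3) return("utr")  # trailing partial codon
  alt_codon <- codon
  substr(alt_codon, cpos, cpos) <- sub_base
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon)))
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Run the full panel-design funnel
#'
#' Applies, in order: site-quality filtering, flank QC plus genome-uniqueness
#' filtering, probe-window selection, and windowed LD pruning to the
#' resequencing stream; cross-references the linkage-map stream and applies
#' the same flank/probe screens; assembles the final panel. Stage counts are
#' recorded so a funnel report can be emitted.
#'
#' @param vt a [variant_table()] (resequencing stream).
#' @param genome a `genome_sequence`.
#' @param map optional data.frame of linkage-map SNPs (chrom, pos, ref, alt).
#' @param chrom_set placed chromosomes (default: the genome's).
#' @param max_missing,min_qual,min_maf site-filter thresholds.
#' @param flank,probe_flank,window flank and probe-window geometry.
#' @param gc_min,gc_max GC bounds.
#' @param min_identity,min_coverage uniqueness thresholds.
#' @param window_snps,step_snps,r2_max LD-pruning parameters.
#' @return list of class `panel_design`: `manifest`, `funnel` (stage counts),
#'   `candidates` (per-SNP QC flags for the resequencing stream).
#' @export
design_panel <- function(vt, genome, map = NULL,
                         chrom_set = names(genome$seq),
                         max_missing = 0.2, min_qual = 50, min_maf = 0.15,
                         flank = 100, probe_flank = 150, window = 100,
                         gc_min = 0.4, gc_max = 0.6,
                         min_identity = 0.6, min_coverage = 0.6,
                         window_snps = 100, step_snps = 10, r2_max = 0.2) {
  index <- kmer_index(genome)
  funnel <- list()
  funnel$reseq_input <- n_snps(vt)
  s1 <- filter_variants(vt, max_missing, min_qual, min_maf, chrom_set)
  funnel$reseq_quality <- n_snps(s1)
  screen <- function(svt) {
    n <- n_snps(svt)
    flank_ok <- logical(n); uniq_ok <- logical(n)
    probe_ok <- logical(n)
    probe_start <- rep(NA_integer_, n); probe_seq <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      ch <- svt$snps$chrom[i]; p <- svt$snps$pos[i]
      fq <- flank_qc(ch, p, genome, flank, gc_min, gc_max)
      flank_ok[i] <- fq$pass
      if (!fq$pass) next
      uq <- uniqueness_check(fq$region, genome, ch, p - flank,
                             min_identity, min_coverage, index = index)
      uniq_ok[i] <- uq$unique
      if (!uq$unique) next
      pw <- probe_windows(ch, p, genome, probe_flank, window, 1,
                          gc_min, gc_max, index = index)
      probe_ok[i] <- pw$pass
      if (pw$pass) {
        probe_start[i] <- pw$probe$start
        probe_seq[i] <- pw$probe$seq
      }
    }
    list(flank_ok = flank_ok, uniq_ok = uniq_ok, probe_ok = probe_ok,
         probe_start = probe_start, probe_seq = probe_seq)
  }
  sc <- screen(s1)
  funnel$reseq_flank_unique <- sum(sc$flank_ok & sc$uniq_ok)
  s2 <- subset_snps(s1, which(sc$probe_ok))
  funnel$reseq_probe <- n_snps(s2)
  kept <- ld_prune(s2, window_snps, step_snps, r2_max)
  s3 <- subset_snps(s2, kept)
  funnel$reseq_pruned <- n_snps(s3)
  reseq_df <- cbind(s3$snps[, c("chrom", "pos", "ref", "alt")],
                    probe_start = sc$probe_start[sc$probe_ok][kept],
                    probe_seq = sc$probe_seq[sc$probe_ok][kept])
  map_df <- reseq_df[0, ]
  if (!is.null(map) && nrow(map) > 0) {
    funnel$map_input <- nrow(map)
    mvt <- crossref_with_map(map, vt)
    funnel$map_crossref <- n_snps(mvt)
    msc <- screen(mvt)
    mkeep <- which(msc$probe_ok)
    funnel$map_probe <- length(mkeep)
    map_df <- cbind(mvt$snps[mkeep, c("chrom", "pos", "ref", "alt")],
                    probe_start = msc$probe_start[mkeep],
                    probe_seq = msc$probe_seq[mkeep])
  }
  manifest <- assemble_panel(reseq_df, map_df)
  funnel$final <- nrow(manifest)
  structure(list(manifest = manifest, funnel = funnel,
                 candidates = data.frame(s1$snps[, c("chrom", "pos")],
                                         flank_pass = sc$flank_ok,
                                         unique_pass = sc$uniq_ok,
                                         probe_pass = sc$probe_ok)),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("panel_design funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-20s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}
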