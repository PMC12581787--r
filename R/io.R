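# Readers and writers for the standard formats. Coordinates are 1-based and
# inclusive throughout (VCF/GFF convention); phased "|" separators are treated
# as "/"; polyploid GT fields are rejected; io never imputes missing calls.

#' Read a VCF into a variant table
#'
#' Parses GT fields into diploid alt-allele dosages. Multi-allelic records can
#' be dropped on import; missing calls (`./.`) become NA.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param biallelic_only drop records whose ALT lists more than one allele
#'   (default TRUE).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    return(variant_table(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), qual = numeric(0)),
      matrix(integer(0), nrow = length(samples), ncol = 0), samples))
  }
  keep <- rep(TRUE, nrow(fix))
  if (biallelic_only) keep <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ploidy_bad <- grepl("^[0-9.]+(/[0-9.]+){2,}$", gt)
  if (any(ploidy_bad, na.rm = TRUE))
    stop("polyploid GT fields found; only diploid VCFs are supported")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     qual = suppressWarnings(as.numeric(fix$QUAL)),
                     stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos)
  variant_table(snps[ord, , drop = FALSE], t(code)[, ord, drop = FALSE], samples)
}

#' Write a variant table as VCF 4.2
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$samples), collapse = "\t")), con)
  if (n_snps(vt) > 0) {
    gtxt <- c("0/0", "0/1", "1/1")[vt$geno + 1L]
    gtxt[is.na(gtxt)] <- "./."
    gtxt <- matrix(gtxt, nrow = nrow(vt$geno))
    qual <- ifelse(is.na(vt$snps$qual), ".", format(vt$snps$qual))
    lines <- paste(vt$snps$chrom, vt$snps$pos, ".", vt$snps$ref, vt$snps$alt,
                   qual, "PASS", ".", "GT", sep = "\t")
    lines <- paste(lines, apply(gtxt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return a `genome_sequence`: named `DNAStringSet` wrapper with a length
#'   table; bases are uppercased.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in FASTA")
  genome_sequence(setNames(toupper(as.character(seqs)), names(seqs)))
}

#' Construct a genome sequence object
#' @param seqs named character vector of chromosome sequences (A/C/G/T/N).
#' @return object of class `genome_sequence` with `$seq` and `$lengths`.
#' @export
genome_sequence <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$seq), "chromosome(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Fetch a genomic subsequence (1-based, inclusive)
#'
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return character string of exactly `end - start + 1` bases.
#' @export
fetch_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  if (start < 1 || end > L || start > end)
    stop(sprintf("range %d-%d out of bounds for %s (length %d)",
                 start, end, chrom, L))
  substr(genome$seq[[chrom]], start, end)
}

#' Write a genome to FASTA
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @param width line width (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seq[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Groups exon and CDS intervals per gene (one transcript per gene expected;
#' for multi-transcript genes the union per feature type is kept). Intervals
#' are stored in ascending coordinate order regardless of strand; strand is
#' recorded and applied by consumers.
#'
#' @param path GFF3 file.
#' @return a `feature_table`: list with `$genes`, a named list of gene models
#'   (`chrom`, `strand`, `start`, `end`, `exons`, `cds` data.frames with
#'   `start`, `end`, and `frame` for CDS).
#' @export
read_gff <- function(path) {
  df <- as.data.frame(rtracklayer::readGFF(path))
  genes <- list()
  if (nrow(df) == 0) return(structure(list(genes = genes), class = "feature_table"))
  df$type <- as.character(df$type)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  get_gene_id <- function(row_id) sub("^gene:", "", row_id)
  for (i in seq_len(nrow(gene_rows))) {
    gid <- get_gene_id(as.character(gene_rows$ID[i]))
    genes[[gid]] <- list(id = gid, chrom = as.character(gene_rows$seqid[i]),
                         strand = as.character(gene_rows$strand[i]),
                         start = gene_rows$start[i], end = gene_rows$end[i],
                         exons = data.frame(start = integer(0), end = integer(0)),
                         cds = data.frame(start = integer(0), end = integer(0),
                                          frame = integer(0)))
  }
  # map features to genes through Parent chains (transcript -> gene)
  parent_of <- setNames(as.character(df$ID), as.character(df$ID))
  pa <- vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
  parent_map <- setNames(pa, as.character(df$ID))
  resolve_gene <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !(sub("^gene:", "", id) %in% names(genes))) {
      if (id %in% seen) return(NA_character_)
      seen <- c(seen, id)
      id <- if (id %in% names(parent_map)) parent_map[[id]] else NA_character_
    }
    if (is.na(id)) NA_character_ else sub("^gene:", "", id)
  }
  for (i in which(df$type %in% c("exon", "CDS"))) {
    pid <- if (!is.na(pa[i])) pa[i] else as.character(df$ID[i])
    gid <- resolve_gene(pid)
    if (is.na(gid)) next
    g <- genes[[gid]]
    if (df$start[i] < g$start || df$end[i] > g$end)
      stop("CDS/exon outside gene span for gene ", gid)
    if (df$type[i] == "exon") {
      g$exons <- rbind(g$exons, data.frame(start = df$start[i], end = df$end[i]))
    } else {
      fr <- suppressWarnings(as.integer(as.character(df$phase[i])))
      if (is.na(fr)) fr <- 0L
      g$cds <- rbind(g$cds, data.frame(start = df$start[i], end = df$end[i],
                                       frame = fr))
    }
    genes[[gid]] <- g
  }
  for (gid in names(genes)) {
    genes[[gid]]$exons <- genes[[gid]]$exons[order(genes[[gid]]$exons$start), , drop = FALSE]
    genes[[gid]]$cds <- genes[[gid]]$cds[order(genes[[gid]]$cds$start), , drop = FALSE]
  }
  structure(list(genes = genes), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", length(x$genes), "gene model(s)\n")
  invisible(x)
}

#' Write / read a panel manifest (TSV)
#'
#' The manifest is a TSV with one row per panel SNP: `chrom`, `pos`, `ref`,
#' `alt`, `source`, and optional probe columns. `read_panel_manifest()` is the
#' exact inverse, so write-then-read round-trips.
#'
#' @param manifest a data.frame (as produced by [assemble_panel()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_panel_manifest <- function(manifest, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "source") %in% names(manifest)))
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_manifest
#' @export
read_panel_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", ref = "character",
                            alt = "character", source = "character"))
}

#' Write / read a Newick tree
#'
#' Thin wrappers over \pkg{ape}; provided so every format the pipeline touches
#' has a single entry point.
#'
#' @param tree an \pkg{ape} `phylo` object.
#' @param path file path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
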