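# Independent oracles and small fixtures shared across tests.
# Every oracle here deliberately takes a different computational route from
# the package implementation it checks.

# r2 from the exhaustive 2x2 haplotype-count table.
r2_count_oracle <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  n <- n11 + n10 + n01 + n00
  d <- (n11 * n00 - n10 * n01) / n^2
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# AUROC by exhaustive positive-negative pair counting.
auroc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Per-transcript category by explicit per-base position-set membership
# (enumerates every base of every feature; no interval arithmetic).
classify_position_oracle <- function(pos, model, splice_window_bp = 2L,
                                     flank_bp = 1000L) {
  prec <- c(exonic = 1, splicing = 1, ncRNA_exonic = 2, UTR5 = 3, UTR3 = 4,
            intronic = 5, ncRNA_intronic = 6, upstream = 7, downstream = 7,
            intergenic = 8)
  p0 <- pos - 1L
  tx <- model$transcripts
  cats <- character(0)
  seq0 <- function(s, e) if (s < e) seq(s, e - 1L) else integer(0)
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    exon_bases <- unlist(mapply(seq0, es, ee, SIMPLIFY = FALSE))
    tx_bases <- seq0(tx$tx_start[i], tx$tx_end[i])
    coding <- tx$cds_end[i] > tx$cds_start[i]
    cds_bases <- seq0(tx$cds_start[i], tx$cds_end[i])
    intron_bases <- setdiff(tx_bases, exon_bases)
    splice_bases <- integer(0)
    if (length(es) > 1) {
      for (k in seq_len(length(es) - 1)) {
        is_ <- ee[k]; ie_ <- es[k + 1]
        splice_bases <- c(splice_bases,
                          seq0(is_, min(is_ + splice_window_bp, ie_)),
                          seq0(max(ie_ - splice_window_bp, is_), ie_))
      }
    }
    up_bases <- if (tx$strand[i] == "+") seq0(tx$tx_start[i] - flank_bp, tx$tx_start[i])
                else seq0(tx$tx_end[i], tx$tx_end[i] + flank_bp)
    down_bases <- if (tx$strand[i] == "+") seq0(tx$tx_end[i], tx$tx_end[i] + flank_bp)
                  else seq0(tx$tx_start[i] - flank_bp, tx$tx_start[i])
    ct <- if (p0 %in% exon_bases) {
      if (!coding) "ncRNA_exonic"
      else if (p0 %in% cds_bases) "exonic"
      else {
        before_cds <- p0 < tx$cds_start[i]
        if (tx$strand[i] == "+") (if (before_cds) "UTR5" else "UTR3")
        else (if (before_cds) "UTR3" else "UTR5")
      }
    } else if (p0 %in% intron_bases) {
      if (!coding) "ncRNA_intronic"
      else if (p0 %in% splice_bases) "splicing" else "intronic"
    } else if (p0 %in% up_bases) "upstream"
      else if (p0 %in% down_bases) "downstream"
      else NA_character_
    if (!is.na(ct)) cats <- c(cats, ct)
  }
  if (length(cats) == 0) return("intergenic")
  names(sort(prec[cats]))[1]
}

# Coding consequence by translating the full wild-type and mutated CDS
# codon-by-codon and comparing the proteins.
coding_effect_oracle <- function(cds_wt, cds_mut) {
  translate1 <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  aa_wt <- translate1(cds_wt); aa_mut <- translate1(cds_mut)
  if (aa_wt == aa_mut) return("synonymous")
  diff_at <- which(strsplit(aa_wt, "")[[1]] != strsplit(aa_mut, "")[[1]])[1]
  if (substr(aa_mut, diff_at, diff_at) == "*") "nonsense" else "missense"
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## ----- fixtures -------------------------------------------------------------

# The worked toy transcript: + strand, tx 1-based 1000-2000, CDS 1200-1800,
# exons 1000-1400 and 1600-2000 (0-based half-open in the model).
toy_model <- function(strand = "+") {
  tx <- data.frame(name = "txA", gene = "GENEA", chrom = "chr1",
                   strand = strand, tx_start = 999L, tx_end = 2000L,
                   cds_start = 1199L, cds_end = 1800L, stringsAsFactors = FALSE)
  tx$exon_starts <- list(c(999L, 1599L))
  tx$exon_ends <- list(c(1400L, 2000L))
  gene_model(tx)
}

# Single-exon coding transcript whose CDS is `cds_seq`, planted at 1-based
# position `cds_at` of a padded toy chromosome; returns model + reference.
toy_cds_fixture <- function(cds_seq, cds_at = 11L, strand = "+",
                            chrom = "chrT") {
  pad <- function(n) paste(rep("G", n), collapse = "")
  genome_seq <- if (strand == "+") {
    paste0(pad(cds_at - 1L), cds_seq, pad(10))
  } else {
    paste0(pad(cds_at - 1L), revcomp(cds_seq), pad(10))
  }
  cds_start0 <- cds_at - 1L
  cds_end0 <- cds_start0 + nchar(cds_seq)
  tx <- data.frame(name = "txC", gene = "GENEC", chrom = chrom,
                   strand = strand, tx_start = cds_start0, tx_end = cds_end0,
                   cds_start = cds_start0, cds_end = cds_end0,
                   stringsAsFactors = FALSE)
  tx$exon_starts <- list(cds_start0)
  tx$exon_ends <- list(cds_end0)
  ref <- Biostrings::DNAStringSet(genome_seq)
  names(ref) <- chrom
  list(model = gene_model(tx), reference = ref, genome = genome_seq,
       cds_start0 = cds_start0, cds_end0 = cds_end0)
}

# Minimal phased VCF on disk; gts is a list of "a|b" vectors per site.
write_tiny_vcf <- function(path, pos, ref, alt, gts, samples, chrom = "chr1",
                           ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(pos))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", chrom),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom, pos[i], ids[i], ref[i], alt[i], ".",
                              "PASS", ".", "GT", gts[[i]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Random panel with all sites guaranteed polymorphic.
random_panel <- function(n_hap, n_sites, seed) {
  set.seed(seed)
  cols <- lapply(seq_len(n_sites), function(j) {
    col <- 0L
    while (length(unique(col)) < 2) col <- rbinom(n_hap, 1, runif(1, 0.15, 0.85))
    col
  })
  sites <- variant_set(data.frame(
    chrom = "chr1", pos = seq(1000L, by = 250L, length.out = n_sites),
    ref = "A", alt = "G", id = sprintf("p%03d", seq_len(n_sites))))
  haplotype_panel(do.call(cbind, cols), sites)
}

# Random CDS: ATG + n_codons sense codons (no internal stop) + TAA.
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  mids <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) { mids[i] <- cd; break }
    }
  }
  paste0("ATG", paste(mids, collapse = ""), "TAA")
}

annotation_rec <- function(id, category) {
  data.frame(variant_id = id, category = category, stringsAsFactors = FALSE)
}
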