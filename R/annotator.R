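# Genic-context classification of variants against a gene model.
#
# One category per variant, resolved across overlapping transcripts by a
# fixed precedence (ANNOVAR-like):
#   exonic = splicing > ncRNA_exonic > UTR5 > UTR3 > intronic >
#   ncRNA_intronic > upstream = downstream > intergenic
# Splicing means the first/last `splice_window_bp` bases of an intron of a
# coding transcript; for non-coding transcripts intronic positions are
# ncRNA_intronic regardless of boundary distance.

ANNOT_CATEGORIES <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                      "ncRNA_exonic", "ncRNA_intronic", "upstream",
                      "downstream", "intergenic")

annot_precedence <- c(exonic = 1, splicing = 1, ncRNA_exonic = 2, UTR5 = 3,
                      UTR3 = 4, intronic = 5, ncRNA_intronic = 6,
                      upstream = 7, downstream = 7, intergenic = 8)

# Category of 1-based position `pos` with respect to one transcript row
# (or NA if beyond the flank).
transcript_category <- function(pos, tx_row, splice_window_bp = 2L,
                                flank_bp = 1000L) {
  p0 <- pos - 1L  # 0-based
  ts <- tx_row$tx_start; te <- tx_row$tx_end
  if (p0 >= ts && p0 < te) {
    es <- tx_row$exon_starts[[1]]; ee <- tx_row$exon_ends[[1]]
    in_exon <- any(es <= p0 & p0 < ee)
    coding <- tx_row$cds_end > tx_row$cds_start
    if (!coding) {
      return(if (in_exon) "ncRNA_exonic" else "ncRNA_intronic")
    }
    if (in_exon) {
      if (p0 >= tx_row$cds_start && p0 < tx_row$cds_end) return("exonic")
      five_prime_side <- if (tx_row$strand == "+") p0 < tx_row$cds_start
                         else p0 >= tx_row$cds_end
      return(if (five_prime_side) "UTR5" else "UTR3")
    }
    # intronic: which intron?
    i <- max(which(ee <= p0))
    intron_start <- ee[i]; intron_end <- es[i + 1]
    near_edge <- (p0 - intron_start) < splice_window_bp ||
      (intron_end - p0) <= splice_window_bp
    return(if (near_edge) "splicing" else "intronic")
  }
  if (p0 >= ts - flank_bp && p0 < te + flank_bp) {
    before <- p0 < ts
    if (tx_row$strand == "+") return(if (before) "upstream" else "downstream")
    return(if (before) "downstream" else "upstream")
  }
  NA_character_
}

#' Classify a variant's genic context
#'
#' @param v one-row [variant_set()] or list with chrom, pos, id.
#' @param model a [gene_model()].
#' @param splice_window_bp intron bases adjacent to an exon boundary called
#'   "splicing" (default 2).
#' @param flank_bp distance outside a transcript called upstream/downstream
#'   (default 1000); beyond it, intergenic.
#' @return one-row data frame: variant_id, category, gene, tss_distance_bp
#'   (signed, transcription orientation, only for
#'   intergenic/upstream/downstream), coding_effect (NA; see
#'   [coding_effect()]).
#' @export
classify_variant <- function(v, model, splice_window_bp = 2L, flank_bp = 1000L) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  tx <- model$transcripts
  if (!v$chrom %in% tx$chrom) {
    warning("chromosome ", v$chrom, " absent from gene model; variant ",
            v$id, " recorded as intergenic", call. = FALSE)
    return(annotation_record(v$id, "intergenic", NA_character_, NA_integer_))
  }
  hits <- query_transcripts(model, v$chrom, v$pos, flank = flank_bp)
  cats <- character(0); genes <- character(0); names_ <- character(0)
  for (i in hits) {
    ct <- transcript_category(v$pos, tx[i, ], splice_window_bp, flank_bp)
    if (!is.na(ct)) {
      cats <- c(cats, ct); genes <- c(genes, tx$gene[i]); names_ <- c(names_, tx$name[i])
    }
  }
  if (length(cats) == 0) {
    nt <- nearest_tss(v, model)
    return(annotation_record(v$id, "intergenic", nt$gene, nt$distance_bp))
  }
  prec <- annot_precedence[cats]
  best <- which(prec == min(prec))
  best <- best[order(genes[best], names_[best])][1]
  category <- cats[best]
  gene <- genes[best]
  tssd <- NA_integer_
  if (category %in% c("upstream", "downstream", "intergenic")) {
    nt <- nearest_tss(v, model)
    tssd <- nt$distance_bp
    if (category == "intergenic") gene <- nt$gene
  }
  annotation_record(v$id, category, gene, tssd)
}

annotation_record <- function(id, category, gene, tss_distance_bp,
                              coding_effect = NA_character_) {
  data.frame(variant_id = id, category = category, gene = gene,
             tss_distance_bp = as.integer(tss_distance_bp),
             coding_effect = coding_effect, stringsAsFactors = FALSE)
}

#' Annotate a variant set
#'
#' Vectorized wrapper around [classify_variant()]; optionally adds coding
#' consequence for exonic SNVs when a reference FASTA is supplied.
#'
#' @param variants a [variant_set()].
#' @param model a [gene_model()].
#' @param reference optional FASTA path or named `Biostrings::DNAStringSet`.
#' @inheritParams classify_variant
#' @return data frame of annotation records, one row per variant.
#' @export
annotate_variants <- function(variants, model, splice_window_bp = 2L,
                              flank_bp = 1000L, reference = NULL) {
  recs <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    classify_variant(variants[i, ], model, splice_window_bp, flank_bp)
  }))
  if (!is.null(reference)) {
    ref <- load_reference(reference)
    tx <- model$transcripts
    for (i in which(recs$category == "exonic" & !variants$is_indel)) {
      v <- as.list(variants[i, ])
      hits <- query_transcripts(model, v$chrom, v$pos, flank = 0L)
      for (k in hits) {
        if (tx$cds_end[k] > tx$cds_start[k] &&
            in_cds_exon(v$pos, tx[k, ])) {
          recs$coding_effect[i] <- coding_effect(v, tx[k, ], ref)
          break
        }
      }
    }
  }
  recs
}

#' Nearest transcription start site
#'
#' TSS is the transcript's 5' end: txStart for + strand, txEnd for - strand.
#' The signed distance is reported in transcription orientation (negative =
#' upstream of the TSS). Equidistant genes tie-break alphabetically.
#'
#' @param v one-row [variant_set()] or list with chrom, pos.
#' @param model a [gene_model()].
#' @return list(gene, distance_bp).
#' @export
nearest_tss <- function(v, model) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  tx <- model$transcripts
  same <- tx[tx$chrom == v$chrom, , drop = FALSE]
  if (nrow(same) == 0) return(list(gene = NA_character_, distance_bp = NA_integer_))
  tss <- ifelse(same$strand == "+", same$tx_start + 1L, same$tx_end)
  dist <- ifelse(same$strand == "+", v$pos - tss, tss - v$pos)
  ord <- order(abs(dist), same$gene, same$name)
  list(gene = same$gene[ord[1]], distance_bp = as.integer(dist[ord[1]]))
}

load_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  stop("reference must be a FASTA path or a DNAStringSet", call. = FALSE)
}

in_cds_exon <- function(pos, tx_row) {
  p0 <- pos - 1L
  es <- tx_row$exon_starts[[1]]; ee <- tx_row$exon_ends[[1]]
  any(es <= p0 & p0 < ee) && p0 >= tx_row$cds_start && p0 < tx_row$cds_end
}

# CDS pieces (0-based half-open) of a transcript in genomic order.
cds_pieces <- function(tx_row) {
  es <- tx_row$exon_starts[[1]]; ee <- tx_row$exon_ends[[1]]
  s <- pmax(es, tx_row$cds_start); e <- pmin(ee, tx_row$cds_end)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

#' Coding consequence of an SNV inside a CDS
#'
#' Translates the codon containing the variant before and after substitution
#' with the standard genetic code (reverse-complemented for minus-strand
#' transcripts). A stop-gain is "nonsense"; an amino-acid change (including
#' stop-loss) is "missense"; otherwise "synonymous".
#'
#' @param v one-row [variant_set()] or list (SNV, inside the CDS of `tx`).
#' @param tx one-row transcript slice of `model$transcripts`.
#' @param reference FASTA path or named `DNAStringSet` covering the CDS.
#' @return one of "synonymous", "missense", "nonsense".
#' @export
coding_effect <- function(v, tx, reference) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  ref <- load_reference(reference)
  seqname <- sub(" .*$", "", names(ref))
  hit <- match(v$chrom, seqname)
  if (is.na(hit)) stop("reference has no sequence for ", v$chrom, call. = FALSE)
  chromseq <- ref[[hit]]
  if (!in_cds_exon(v$pos, tx)) {
    stop("variant ", v$id, " is not in a CDS exon of ", tx$name, call. = FALSE)
  }
  pieces <- cds_pieces(tx)
  cds_seq <- paste(vapply(seq_along(pieces$start), function(i) {
    as.character(Biostrings::subseq(chromseq, pieces$start[i] + 1L, pieces$end[i]))
  }, character(1)), collapse = "")
  # offset of v within the genomic-order CDS (1-based)
  p0 <- v$pos - 1L
  off <- 0L
  for (i in seq_along(pieces$start)) {
    if (p0 >= pieces$start[i] && p0 < pieces$end[i]) {
      off <- off + (p0 - pieces$start[i]) + 1L
      break
    }
    off <- off + (pieces$end[i] - pieces$start[i])
  }
  if (substr(cds_seq, off, off) != v$ref) {
    stop("reference mismatch at ", v$chrom, ":", v$pos, ": reference has ",
         substr(cds_seq, off, off), ", variant claims ", v$ref, call. = FALSE)
  }
  mut_seq <- cds_seq
  substr(mut_seq, off, off) <- v$alt
  if (tx$strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    mut_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut_seq)))
    off <- nchar(cds_seq) - off + 1L
  }
  codon_i <- (off - 1L) %/% 3L
  codon_ref <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_alt <- substr(mut_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon_ref) < 3L) {
    stop("CDS of ", tx$name, " is not a multiple of 3 at the variant codon",
         call. = FALSE)
  }
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Count annotation categories
#'
#' @param records data frame from [annotate_variants()].
#' @return named integer vector of per-category counts (categories present
#'   only); counts sum to the number of records.
#' @export
summarize_categories <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(records$category)
  stats::setNames(as.integer(tab), names(tab))
}
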