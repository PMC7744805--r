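# Core domain types and readers/writers.
#
# Coordinate discipline: variants keep their VCF-style 1-based position in the
# `pos` column; every interval computation inside the package uses 0-based
# half-open coordinates. The two helpers below are the only conversion points.

#' Convert a 1-based position to a 0-based half-open interval (and back)
#'
#' @param pos 1-based position(s).
#' @return `pos_to_interval`: a list with `start` (0-based inclusive) and
#'   `end` (0-based exclusive); `interval_to_pos`: the 1-based position.
#' @export
pos_to_interval <- function(pos) list(start = pos - 1L, end = pos)

#' @rdname pos_to_interval
#' @param start 0-based inclusive start of a width-1 interval.
#' @export
interval_to_pos <- function(start) start + 1L

#' Construct a validated variant set
#'
#' A variant set is a data frame with columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `id` and `is_indel`. Indels are accepted but flagged; only
#' SNVs enter LD and coding-consequence stages.
#'
#' @param df data frame with at least chrom, pos, ref, alt (id optional).
#' @return a `variant_set` data frame.
#' @export
variant_set <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (is.null(df$id)) df$id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df$id[is.na(df$id) | df$id == "." | df$id == ""] <-
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")[is.na(df$id) | df$id == "." | df$id == ""]
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("variant positions must be 1-based integers >= 1", call. = FALSE)
  }
  bad_allele <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad_allele)) {
    stop("alleles must be non-empty strings over ACGT (offending id: ",
         df$id[which(bad_allele)[1]], ")", call. = FALSE)
  }
  if (any(df$ref == df$alt)) {
    stop("ref and alt alleles identical for variant ",
         df$id[which(df$ref == df$alt)[1]], call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate variant id: ", df$id[duplicated(df$id)][1], call. = FALSE)
  }
  df$is_indel <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  rownames(df) <- NULL
  df <- df[, c("chrom", "pos", "ref", "alt", "id", "is_indel",
               setdiff(names(df), c("chrom", "pos", "ref", "alt", "id", "is_indel")))]
  class(df) <- c("variant_set", "data.frame")
  df
}

#' Read variants from TSV or VCF
#'
#' TSV input needs a header with columns chrom, pos, ref, alt and optionally
#' rsid/id. VCF input preserves 1-based positions; multi-allelic records are
#' split into one variant per alternate allele; symbolic alleles (`<DEL>`
#' etc.) are skipped with a warning.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @param chrom_mode chromosome-name normalization (see [normalize_chrom()]).
#' @return a [variant_set()] in input order.
#' @export
read_variants <- function(path, format = c("tsv", "vcf"),
                          chrom_mode = "keep") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
  df$chrom <- normalize_chrom(df$chrom, chrom_mode)
  variant_set(df)
}

read_variants_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1) stop("empty variant file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% header)) {
    stop("variant TSV header must contain chrom, pos, ref, alt", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("malformed variant line %d in %s: expected %d fields, found %d",
                 bad + 1L, path, length(header), nf[bad]), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  posn <- suppressWarnings(as.integer(df$pos))
  if (any(is.na(posn))) {
    bad <- which(is.na(posn))[1]
    stop(sprintf("malformed variant line %d in %s: non-integer pos '%s'",
                 bad + 1L, path, df$pos[bad]), call. = FALSE)
  }
  df$pos <- posn
  idcol <- intersect(c("id", "rsid"), names(df))
  df$id <- if (length(idcol) > 0) df[[idcol[1]]] else NULL
  df[, c("chrom", "pos", "ref", "alt", intersect("id", names(df)))]
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_df(vcf)
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      if (grepl("^<.*>$", a) || a == "*") {
        warning("skipping symbolic/missing allele ", a, " at ",
                fix$CHROM[i], ":", fix$POS[i], call. = FALSE)
        next
      }
      id <- fix$ID[i]
      if (is.na(id) || id == "." || length(alts) > 1) {
        id <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], a, sep = ":")
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a, id = id, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no usable records in VCF: ", path, call. = FALSE)
  do.call(rbind, out)
}

#' Write a variant set as TSV
#' @param variants a [variant_set()].
#' @param path output path.
#' @param meta provenance metadata for the header comment.
#' @export
write_variants <- function(variants, path, meta = character()) {
  write_tsv_header(as.data.frame(variants), path, meta)
}

## ---------------------------------------------------------------------------
## Gene model

#' Read a refGene-style gene model
#'
#' Expects a TSV with header columns name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds (UCSC 0-based half-open;
#' exon lists comma-separated, trailing comma tolerated) and optionally
#' `name2` carrying the gene symbol. `cdsStart == cdsEnd` marks a non-coding
#' transcript.
#'
#' @param path input TSV.
#' @param chrom_mode chromosome-name normalization.
#' @return a `gene_model` object (transcript table + interval index).
#' @export
read_gene_model <- function(path, chrom_mode = "keep") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read_tsv_plain(path)
  need <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("gene model is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_list <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1]])
  tx <- data.frame(
    name = as.character(df$name),
    gene = as.character(df[["name2"]] %||% df$name),
    chrom = normalize_chrom(as.character(df$chrom), chrom_mode),
    strand = as.character(df$strand),
    tx_start = as.integer(df$txStart), tx_end = as.integer(df$txEnd),
    cds_start = as.integer(df$cdsStart), cds_end = as.integer(df$cdsEnd),
    stringsAsFactors = FALSE)
  tx$exon_starts <- lapply(df$exonStarts, parse_list)
  tx$exon_ends <- lapply(df$exonEnds, parse_list)
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) != df$exonCount[i]) {
      stop("transcript ", tx$name[i], ": exonStarts/exonEnds/exonCount disagree",
           call. = FALSE)
    }
  }
  gene_model(tx)
}

#' Construct a gene model from a transcript table
#'
#' @param tx data frame with columns name, gene, chrom, strand, tx_start,
#'   tx_end, cds_start, cds_end and list-columns exon_starts/exon_ends
#'   (0-based half-open).
#' @return a `gene_model`: the validated transcript table plus a
#'   GenomicRanges interval index over transcript spans.
#' @export
gene_model <- function(tx) {
  if (nrow(tx) == 0) stop("gene model has no transcripts", call. = FALSE)
  if (!all(tx$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    if (any(es >= ee)) stop("transcript ", tx$name[i], ": empty exon", call. = FALSE)
    if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)])) {
      stop("transcript ", tx$name[i], ": exons unsorted or overlapping",
           call. = FALSE)
    }
    if (min(es) < tx$tx_start[i] || max(ee) > tx$tx_end[i]) {
      stop("transcript ", tx$name[i], ": exon outside transcript span",
           call. = FALSE)
    }
    if (tx$cds_end[i] > tx$cds_start[i] &&
        (tx$cds_start[i] < tx$tx_start[i] || tx$cds_end[i] > tx$tx_end[i])) {
      stop("transcript ", tx$name[i], ": CDS outside transcript span",
           call. = FALSE)
    }
  }
  # 0-based half-open -> 1-based closed for the GRanges index
  idx <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$tx_start + 1L, end = tx$tx_end),
    strand = tx$strand)
  structure(list(transcripts = tx, index = idx), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$transcripts), "transcripts on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Indices of transcripts whose [tx_start - flank, tx_end + flank) span
# overlaps the 1-based position `pos` on `chrom`.
query_transcripts <- function(model, chrom, pos, flank = 0L) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    q, model$index, maxgap = flank, ignore.strand = TRUE))
  sort(S4Vectors::subjectHits(hits))
}

#' Write a gene model in refGene-style TSV
#' @param model a `gene_model`.
#' @param path output path.
#' @export
write_refgene <- function(model, path) {
  tx <- model$transcripts
  df <- data.frame(
    name = tx$name, chrom = tx$chrom, strand = tx$strand,
    txStart = tx$tx_start, txEnd = tx$tx_end,
    cdsStart = tx$cds_start, cdsEnd = tx$cds_end,
    exonCount = vapply(tx$exon_starts, length, integer(1)),
    exonStarts = vapply(tx$exon_starts, function(v) paste0(paste(v, collapse = ","), ","), character(1)),
    exonEnds = vapply(tx$exon_ends, function(v) paste0(paste(v, collapse = ","), ","), character(1)),
    name2 = tx$gene, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Score matrices

#' Construct a score matrix
#'
#' Variants x methods (or variants x tissues) real-valued scores with explicit
#' missingness (NA) and a per-column direction flag: "higher" (default) means
#' larger scores are more functional; "lower" flags methods whose scale is
#' inverted (FATHMM-style).
#'
#' @param values numeric matrix with variant-id rownames and column ids.
#' @param direction named character vector over columns ("higher"/"lower");
#'   unnamed scalar recycles.
#' @return a `score_matrix`.
#' @export
score_matrix <- function(values, direction = "higher") {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("score matrix needs variant ids as rownames and column ids", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate variant id in score matrix: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column id in score matrix", call. = FALSE)
  }
  if (length(direction) == 1 && is.null(names(direction))) {
    direction <- stats::setNames(rep(direction, ncol(values)), colnames(values))
  }
  if (!all(colnames(values) %in% names(direction))) {
    stop("direction flag missing for some columns", call. = FALSE)
  }
  direction <- direction[colnames(values)]
  if (!all(direction %in% c("higher", "lower"))) {
    stop("direction must be 'higher' or 'lower'", call. = FALSE)
  }
  structure(list(values = values, direction = direction), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$values), "variants x", ncol(x$values),
      "columns;", sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' Read a TSV score table
#'
#' First column is the variant id; remaining header fields are column ids.
#' Blank cells denote missing scores and are tracked, never imputed.
#'
#' @param path input TSV.
#' @param direction per-column direction flags (see [score_matrix()]).
#' @return a `score_matrix`.
#' @export
read_score_table <- function(path, direction = "higher") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("score table needs id + at least one score column",
                         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate variant id row in ", path, ": ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !(is.na(vals) | vals == ""), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell in %s at row %d (id %s), column '%s': '%s'",
                 path, bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- ids
  score_matrix(num, direction)
}

#' Write a score matrix as TSV (round-trip exact)
#'
#' Values are serialized with 17 significant digits so that
#' write-then-read reproduces values, ordering and missingness exactly.
#'
#' @param scores a `score_matrix`.
#' @param path output path.
#' @param meta provenance metadata lines.
#' @param id_col name for the id column.
#' @export
write_score_table <- function(scores, path, meta = character(), id_col = "variant_id") {
  df <- data.frame(id = rownames(scores$values), stringsAsFactors = FALSE)
  names(df) <- id_col
  for (j in colnames(scores$values)) df[[j]] <- scores$values[, j]
  write_tsv_header(df, path, meta)
}
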