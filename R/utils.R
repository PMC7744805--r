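#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif rbinom sd setNames p.adjust
#' @importFrom utils read.table write.table packageVersion head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each stochastic component of the package draws from its own RNG stream so
#' that changing one component's configuration does not perturb the draws of
#' the others. Streams are indexed by small integers; the derived seed always
#' fits in a 32-bit signed integer.
#'
#' @param seed master seed (integer).
#' @param stream stream index (small non-negative integer).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  s <- (abs(as.numeric(seed)) * 1009 + as.numeric(stream) * 9973 + 1)
  as.integer(s %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# md5 of an arbitrary character scalar (via a temp file; no binary deps).
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

md5_file <- function(path) unname(tools::md5sum(path))

finecons_version <- function() as.character(utils::packageVersion("finecons"))

# Format doubles so that write -> read round-trips exactly.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a data frame as TSV with provenance header comments
#'
#' Output files carry `#key=value` comment lines (tool version, configuration
#' hash, free-form metadata) ahead of the column header, so every result file
#' records how it was produced. Timestamps are deliberately excluded: repeat
#' runs with the same configuration are byte-identical.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named character vector written as `#name=value` lines.
#' @export
write_tsv_header <- function(df, path, meta = character()) {
  meta <- c(tool = paste0("finecons ", finecons_version()), meta)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(meta)) {
    writeLines(sprintf("#%s=%s", names(meta)[i], meta[[i]]), con)
  }
  is_num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(is_num)) df[[j]] <- format_num(df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", quote = "", ...)
}

# vcfR::getFIX drops dimensions for single-record files; normalize to a
# data frame.
vcf_fix_df <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  as.data.frame(fix, stringsAsFactors = FALSE)
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Normalize chromosome names
#'
#' Comparisons throughout the package are made on normalized names; the
#' `mode` flag matches panels/gene models that disagree about the "chr"
#' prefix.
#'
#' @param x character vector of chromosome names.
#' @param mode one of "keep", "strip" (remove a leading "chr"), "add".
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x, mode = c("keep", "strip", "add")) {
  mode <- match.arg(mode)
  if (mode == "keep") return(x)
  stripped <- sub("^chr", "", x)
  if (mode == "strip") stripped else paste0("chr", stripped)
}
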