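# LD proxy expansion from a phased haplotype panel.
#
# r2 is computed exactly from phased haplotype columns (allele-indicator
# correlation), not from genotype correlation: the panel is phased by
# precondition, so no EM phasing is needed.

#' Construct a haplotype panel
#'
#' @param haplotypes binary matrix, n_haplotypes x n_sites; entry 1 = alt
#'   allele.
#' @param sites a [variant_set()] of the panel sites (same chromosome,
#'   strictly increasing positions).
#' @param population free-form population tag.
#' @return a `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, sites, population = "") {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype matrix entries must be 0/1", call. = FALSE)
  }
  storage.mode(haplotypes) <- "integer"
  if (ncol(haplotypes) != nrow(sites)) {
    stop("haplotype matrix has ", ncol(haplotypes), " sites but ", nrow(sites),
         " site records", call. = FALSE)
  }
  if (length(unique(sites$chrom)) > 1) {
    stop("panel sites must share one chromosome", call. = FALSE)
  }
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    stop("panel site positions must be strictly increasing", call. = FALSE)
  }
  colnames(haplotypes) <- sites$id
  structure(list(haplotypes = haplotypes, sites = sites,
                 population = population), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "sites",
      if (nzchar(x$population)) paste0("(", x$population, ")") else "", "\n")
  invisible(x)
}

#' Load phased haplotypes from a VCF
#'
#' Every genotype in the requested region must be phased (`|` separator);
#' each diploid sample contributes two haplotype rows. Only biallelic SNVs
#' are kept (others are skipped with a warning).
#'
#' @param path VCF file with phased GTs.
#' @param region optional list(chrom, start, end), 0-based half-open; sites
#'   with `start <= pos-1 < end` on `chrom` are kept.
#' @param samples optional sample-id subset.
#' @param population population tag stored on the panel.
#' @param chrom_mode chromosome-name normalization.
#' @return a [haplotype_panel()].
#' @export
load_haplotypes <- function(path, region = NULL, samples = NULL,
                            population = "", chrom_mode = "keep") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_df(vcf)
  fix$POS <- as.integer(fix$POS)
  fix$CHROM <- normalize_chrom(fix$CHROM, chrom_mode)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    keep <- fix$CHROM == region$chrom &
      (fix$POS - 1L) >= region$start & (fix$POS - 1L) < region$end
    if (!any(keep)) {
      stop(sprintf("empty region %s:%d-%d in %s", region$chrom,
                   region$start, region$end, path), call. = FALSE)
    }
  }
  snv <- is_snv(fix$REF, fix$ALT)
  if (any(keep & !snv)) {
    warning(sum(keep & !snv), " non-SNV/multi-allelic record(s) skipped",
            call. = FALSE)
  }
  keep <- keep & snv
  if (!any(keep)) stop("no biallelic SNVs in requested region", call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss) > 0) stop("sample(s) not in VCF: ",
                               paste(miss, collapse = ", "), call. = FALSE)
    gt <- gt[, samples, drop = FALSE]
  }
  ok_gt <- grepl("^[01]\\|[01]$", gt)
  dim(ok_gt) <- dim(gt)
  bad <- which(!ok_gt, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unphased or non-biallelic genotype '%s' at %s:%d (sample %s)",
                 gt[bad[1, 1], bad[1, 2]], fix$CHROM[bad[1, 1]],
                 fix$POS[bad[1, 1]], colnames(gt)[bad[1, 2]]), call. = FALSE)
  }
  ord <- order(fix$POS)
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  # interleave: sample k -> haplotype rows 2k-1, 2k
  hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  hap[seq(1, nrow(hap), by = 2), ] <- t(h1)
  hap[seq(2, nrow(hap), by = 2), ] <- t(h2)
  rownames(hap) <- paste0(rep(colnames(gt), each = 2), c("_1", "_2"))
  sites <- variant_set(data.frame(chrom = fix$CHROM, pos = fix$POS,
                                  ref = fix$REF, alt = fix$ALT,
                                  id = fix$ID, stringsAsFactors = FALSE))
  haplotype_panel(hap, sites, population)
}

#' Alternate-allele frequency at a panel site
#' @param panel a [haplotype_panel()].
#' @param site_index 1-based site index.
#' @return frequency in \[0, 1\].
#' @export
allele_frequency <- function(panel, site_index) {
  if (site_index < 1 || site_index > ncol(panel$haplotypes)) {
    stop("site index ", site_index, " out of range 1..",
         ncol(panel$haplotypes), call. = FALSE)
  }
  mean(panel$haplotypes[, site_index])
}

#' Pairwise LD (r-squared) between two panel sites
#'
#' Computed from phased haplotype frequencies as D^2 / (pA(1-pA) pB(1-pB))
#' with D = pAB - pA pB; this equals the squared Pearson correlation of the
#' two binary allele-indicator columns. Undefined (an error, distinct from
#' r2 = 0) when either site is monomorphic.
#'
#' @param panel a [haplotype_panel()].
#' @param site_a,site_b 1-based site indices.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(panel, site_a, site_b) {
  for (s in c(site_a, site_b)) {
    if (s < 1 || s > ncol(panel$haplotypes)) {
      stop("site index ", s, " out of range", call. = FALSE)
    }
  }
  a <- panel$haplotypes[, site_a]
  b <- panel$haplotypes[, site_b]
  pa <- mean(a); pb <- mean(b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("r2 undefined: monomorphic site (index ",
         if (pa <= 0 || pa >= 1) site_a else site_b, ")", call. = FALSE)
  }
  d <- mean(a * b) - pa * pb
  min(1, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' LD proxy-search configuration
#'
#' @param r2_threshold minimum r2 for a proxy (default 0.5, the threshold
#'   used for proxy definition).
#' @param window_bp flank searched either side of the index variant (default
#'   500 kb, the LDlink convention; 100 kb / 50 kb presets are common for
#'   score lookups).
#' @param maf_min minimum minor-allele frequency for candidate proxies.
#' @param closed if TRUE (default) the threshold is applied as `>=`; FALSE
#'   applies a strict `>`. The boundary case is measure-zero on real data but
#'   must be deterministic.
#' @return an `ld_config` list.
#' @export
ld_config <- function(r2_threshold = 0.5, window_bp = 500000L, maf_min = 0,
                      closed = TRUE) {
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold must be in [0,1]",
                                                 call. = FALSE)
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0,0.5]", call. = FALSE)
  structure(list(r2_threshold = r2_threshold, window_bp = as.integer(window_bp),
                 maf_min = maf_min, closed = isTRUE(closed)),
            class = "ld_config")
}

# Locate the index variant in the panel; returns list(index, flip) where
# flip=TRUE means the panel's ref/alt are swapped relative to the query.
match_panel_site <- function(panel, variant) {
  sites <- panel$sites
  hit <- which(sites$chrom == variant$chrom & sites$pos == variant$pos)
  if (length(hit) == 0) {
    same_chrom <- which(sites$chrom == variant$chrom)
    nearest <- if (length(same_chrom) > 0) {
      i <- same_chrom[which.min(abs(sites$pos[same_chrom] - variant$pos))]
      sprintf("%s (%s:%d)", sites$id[i], sites$chrom[i], sites$pos[i])
    } else "none on that chromosome"
    stop("index variant ", variant$id, " absent from panel; nearest panel site: ",
         nearest, call. = FALSE)
  }
  i <- hit[1]
  if (sites$ref[i] == variant$ref && sites$alt[i] == variant$alt) {
    return(list(index = i, flip = FALSE))
  }
  ambiguous <- sort(c(variant$ref, variant$alt))
  strand_amb <- identical(ambiguous, c("A", "T")) || identical(ambiguous, c("C", "G"))
  if (sites$ref[i] == variant$alt && sites$alt[i] == variant$ref) {
    if (strand_amb) {
      stop("index variant ", variant$id, ": strand-ambiguous allele swap (",
           variant$ref, "/", variant$alt, ") cannot be resolved", call. = FALSE)
    }
    warning("panel alleles swapped relative to query at ", variant$id,
            "; flipping haplotype coding", call. = FALSE)
    return(list(index = i, flip = TRUE))
  }
  stop("index variant ", variant$id, ": alleles ", variant$ref, "/",
       variant$alt, " do not match panel site ", sites$ref[i], "/",
       sites$alt[i], call. = FALSE)
}

#' Expand an index variant into its LD proxy set
#'
#' All panel sites within the configured window whose r2 with the index
#' variant passes the threshold (and whose MAF passes `maf_min`) are emitted,
#' sorted by descending r2, then ascending absolute distance, then ascending
#' position; the self-record (r2 = 1, distance 0) comes first.
#'
#' @param panel a [haplotype_panel()].
#' @param index_variant one-row [variant_set()] (or list with chrom, pos,
#'   ref, alt, id).
#' @param config an [ld_config()].
#' @return data frame of proxy records: index_id, proxy_id, chrom, pos, r2,
#'   distance_bp.
#' @export
find_proxies <- function(panel, index_variant, config = ld_config()) {
  if (is.data.frame(index_variant)) index_variant <- as.list(index_variant[1, ])
  m <- match_panel_site(panel, index_variant)
  idx_col <- panel$haplotypes[, m$index]
  if (m$flip) idx_col <- 1L - idx_col
  p_idx <- mean(idx_col)
  if (p_idx <= 0 || p_idx >= 1) {
    stop("index variant ", index_variant$id, " is monomorphic in the panel; ",
         "r2 undefined", call. = FALSE)
  }
  sites <- panel$sites
  cand <- which(abs(sites$pos - index_variant$pos) <= config$window_bp)
  cand <- setdiff(cand, m$index)
  recs <- data.frame(index_id = index_variant$id, proxy_id = sites$id[m$index],
                     chrom = sites$chrom[m$index], pos = sites$pos[m$index],
                     r2 = 1.0, distance_bp = 0L, stringsAsFactors = FALSE)
  if (length(cand) > 0) {
    freq <- colMeans(panel$haplotypes[, cand, drop = FALSE])
    maf <- pmin(freq, 1 - freq)
    poly <- freq > 0 & freq < 1 & maf >= config$maf_min
    cand <- cand[poly]
  }
  if (length(cand) > 0) {
    h <- panel$haplotypes[, cand, drop = FALSE]
    pa <- p_idx
    pb <- colMeans(h)
    pab <- colMeans(h * idx_col)
    d <- pab - pa * pb
    r2 <- pmin(1, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
    pass <- if (config$closed) r2 >= config$r2_threshold else r2 > config$r2_threshold
    if (any(pass)) {
      keep <- cand[pass]
      prox <- data.frame(index_id = index_variant$id, proxy_id = sites$id[keep],
                         chrom = sites$chrom[keep], pos = sites$pos[keep],
                         r2 = r2[pass],
                         distance_bp = as.integer(sites$pos[keep] - index_variant$pos),
                         stringsAsFactors = FALSE)
      ord <- order(-prox$r2, abs(prox$distance_bp), prox$pos)
      recs <- rbind(recs, prox[ord, , drop = FALSE])
    }
  }
  rownames(recs) <- NULL
  recs
}
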