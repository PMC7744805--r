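# Synthetic fixtures with the statistical structure every pipeline stage
# assumes: haplotype panels with block LD (copy-with-flip founders), isolated
# toy transcripts with computable ground-truth categories, correlated score
# matrices with planted consensus hits, and sparse-logistic training data.
#
# Every simulator is a pure function of its configuration: the master seed
# expands into per-component substreams so changing one block of the
# configuration does not perturb the draws of the others.

#' Simulation configuration
#'
#' @param seed master seed; every simulator derives its own substream from
#'   it.
#' @param n_haplotypes haplotypes in the panel (even; 2 per sample).
#' @param n_sites panel sites.
#' @param block_sizes site counts per LD block (must sum to `n_sites`);
#'   default: blocks of 10.
#' @param within_block_r2 target mean r2 between sites of a block, achieved
#'   by copy-with-flip from a block founder (flip probability
#'   `(1 - r2^(1/4)) / 2`).
#' @param n_variants variants in simulated score matrices.
#' @param n_methods context-free method columns (default 11).
#' @param method_correlation target inter-method score correlation.
#' @param n_tissues tissue columns (default 127).
#' @param tissue_group_size size of the designated target tissue group.
#' @param hit_q planted consensus hits occupy the top `ceiling(hit_q * n)`
#'   of the target tissue and of every method column (default 0.05).
#' @param n_labeled,n_unlabeled,n_holdout training-set sizes.
#' @param n_features,n_nonzero feature count and sparse support size.
#' @param anchor_noise_sd sd of Gaussian noise added to true probabilities
#'   to form anchors (clipped to \[0, 1\]).
#' @param n_transcripts transcripts in the toy gene model.
#' @return a `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_haplotypes = 200L, n_sites = 40L,
                       block_sizes = NULL, within_block_r2 = 0.8,
                       n_variants = 60L, n_methods = 11L,
                       method_correlation = 0.6, n_tissues = 127L,
                       tissue_group_size = 10L, hit_q = 0.05,
                       n_labeled = 50L, n_unlabeled = 2000L, n_holdout = 500L,
                       n_features = 20L, n_nonzero = 5L,
                       anchor_noise_sd = 0.05, n_transcripts = 8L) {
  if (is.null(block_sizes)) {
    nb <- max(1L, n_sites %/% 10L)
    block_sizes <- rep(n_sites %/% nb, nb)
    block_sizes[nb] <- block_sizes[nb] + n_sites - sum(block_sizes)
  }
  if (sum(block_sizes) != n_sites) {
    stop("block sizes must sum to n_sites", call. = FALSE)
  }
  if (within_block_r2 > 1 || within_block_r2 < 0) {
    stop("infeasible within-block r2 target: must lie in [0,1]", call. = FALSE)
  }
  if (n_haplotypes %% 2L != 0L) stop("n_haplotypes must be even", call. = FALSE)
  if (n_nonzero > n_features) stop("n_nonzero exceeds n_features", call. = FALSE)
  if (method_correlation < 0 || method_correlation > 1) {
    stop("method_correlation must lie in [0,1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a haplotype panel with block LD
#'
#' Within a block, sites are copies of a block founder column with
#' independent per-entry flips; between blocks, sites are independent. Sites
#' that come out monomorphic are redrawn (deterministically within the
#' stream).
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()] on chromosome chr1.
#' @export
simulate_haplotype_panel <- function(config) {
  n <- config$n_haplotypes
  eps <- (1 - config$within_block_r2^(1 / 4)) / 2
  bases <- c("A", "C", "G", "T")
  with_seed(substream_seed(config$seed, 1L), {
    cols <- list(); pos <- integer(0); cursor <- 10000L
    for (b in seq_along(config$block_sizes)) {
      founder <- 0L
      while (length(unique(founder)) < 2) {
        founder <- stats::rbinom(n, 1L, stats::runif(1, 0.2, 0.8))
      }
      for (s in seq_len(config$block_sizes[b])) {
        col <- -1L
        while (length(unique(col)) < 2) {
          flips <- stats::rbinom(n, 1L, eps)
          col <- as.integer(xor(founder, flips))
        }
        cols[[length(cols) + 1]] <- col
        cursor <- cursor + sample(50:400, 1)
        pos <- c(pos, cursor)
      }
      cursor <- cursor + 5000L  # inter-block gap
    }
    refalt <- t(vapply(seq_along(cols), function(i) sample(bases, 2), character(2)))
    sites <- variant_set(data.frame(
      chrom = "chr1", pos = pos, ref = refalt[, 1], alt = refalt[, 2],
      id = sprintf("site_%04d", seq_along(cols)), stringsAsFactors = FALSE))
    haplotype_panel(do.call(cbind, cols), sites, population = "SYNTH")
  })
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain-text VCF).
#' @export
write_panel_vcf <- function(panel, path) {
  n_hap <- nrow(panel$haplotypes)
  if (n_hap %% 2L != 0L) stop("panel must have an even haplotype count",
                              call. = FALSE)
  n_s <- n_hap %/% 2L
  samples <- sprintf("sample_%03d", seq_len(n_s))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=finecons_synth_", finecons_version()),
    sprintf("##contig=<ID=%s>", unique(panel$sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  h <- panel$haplotypes
  for (i in seq_len(nrow(panel$sites))) {
    gts <- paste(h[seq(1, n_hap, 2), i], h[seq(2, n_hap, 2), i], sep = "|")
    writeLines(paste(c(panel$sites$chrom[i], panel$sites$pos[i],
                       panel$sites$id[i], panel$sites$ref[i],
                       panel$sites$alt[i], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Simulate a toy gene model
#'
#' Non-overlapping transcripts (alternating strand, roughly one in four
#' non-coding) on chromosome chr1, separated by gaps wide enough that no
#' position is within the upstream/downstream flank of two transcripts, so
#' the ground-truth category of any position is computable by construction.
#'
#' @param config a [sim_config()].
#' @return a [gene_model()].
#' @export
simulate_gene_model <- function(config) {
  with_seed(substream_seed(config$seed, 2L), {
    rows <- list(); cursor <- 5000L
    for (t in seq_len(config$n_transcripts)) {
      n_ex <- sample(2:5, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(400:1200, max(0, n_ex - 1), replace = TRUE)
      es <- integer(n_ex); ee <- integer(n_ex)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        es[e] <- pos; ee[e] <- pos + ex_len[e]
        pos <- ee[e] + if (e < n_ex) in_len[e] else 0L
      }
      coding <- (t %% 4L) != 0L
      if (coding) {
        cds_start <- es[1] + sample(30:60, 1)
        cds_end <- ee[n_ex] - sample(30:60, 1)
      } else {
        cds_start <- cds_end <- ee[n_ex]
      }
      rows[[t]] <- data.frame(
        name = sprintf("tx%02d", t), gene = sprintf("GENE%02d", t),
        chrom = "chr1", strand = if (t %% 2L == 1L) "+" else "-",
        tx_start = es[1], tx_end = ee[n_ex],
        cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE)
      rows[[t]]$exon_starts <- list(es)
      rows[[t]]$exon_ends <- list(ee)
      # gap > 2 x the 1 kb upstream/downstream flank keeps transcripts
      # isolated, so every position has an unambiguous construction truth
      cursor <- ee[n_ex] + sample(2500:4000, 1)
    }
    gene_model(do.call(rbind, rows))
  })
}

# Per-category 0-based half-open intervals of one transcript, by direct
# layout arithmetic (the construction oracle used for planted variants).
transcript_truth_intervals <- function(tx_row, splice_window_bp = 2L,
                                       flank_bp = 1000L) {
  es <- tx_row$exon_starts[[1]]; ee <- tx_row$exon_ends[[1]]
  cs <- tx_row$cds_start; ce <- tx_row$cds_end
  coding <- ce > cs
  out <- list()
  add <- function(cat, s, e) {
    keep <- s < e
    if (any(keep)) {
      out[[length(out) + 1]] <<- data.frame(category = cat, start = s[keep],
                                            end = e[keep])
    }
  }
  if (coding) {
    add("exonic", pmax(es, cs), pmin(ee, ce))
    left_s <- es[es < cs]; left_e <- pmin(ee[es < cs], cs)
    right_s <- pmax(es[ee > ce], ce); right_e <- ee[ee > ce]
    if (tx_row$strand == "+") {
      add("UTR5", left_s, left_e); add("UTR3", right_s, right_e)
    } else {
      add("UTR3", left_s, left_e); add("UTR5", right_s, right_e)
    }
    if (length(es) > 1) {
      is_ <- ee[-length(ee)]; ie_ <- es[-1]
      w <- splice_window_bp
      add("splicing", is_, pmin(is_ + w, ie_))
      add("splicing", pmax(ie_ - w, is_ + w), ie_)
      add("intronic", is_ + w, ie_ - w)
    }
  } else {
    add("ncRNA_exonic", es, ee)
    if (length(es) > 1) add("ncRNA_intronic", ee[-length(ee)], es[-1])
  }
  if (tx_row$strand == "+") {
    add("upstream", tx_row$tx_start - flank_bp, tx_row$tx_start)
    add("downstream", tx_row$tx_end, tx_row$tx_end + flank_bp)
  } else {
    add("downstream", tx_row$tx_start - flank_bp, tx_row$tx_start)
    add("upstream", tx_row$tx_end, tx_row$tx_end + flank_bp)
  }
  do.call(rbind, out)
}

#' Planted annotation test cases with construction-oracle truth
#'
#' Samples positions whose category is known by construction from the
#' isolated-transcript layout of [simulate_gene_model()], covering all ten
#' categories on both strands.
#'
#' @param model a gene model produced by [simulate_gene_model()].
#' @param n total cases (split roughly evenly over categories).
#' @param splice_window_bp,flank_bp must match the classifier settings.
#' @param seed RNG seed.
#' @return data frame: chrom, pos (1-based), truth_category, id.
#' @export
planted_annotation_cases <- function(model, n = 500L, splice_window_bp = 2L,
                                     flank_bp = 1000L, seed = 1L) {
  tx <- model$transcripts
  ivs <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    transcript_truth_intervals(tx[i, ], splice_window_bp, flank_bp)
  }))
  # intergenic: complement of transcript-flank spans on the covered range
  spans <- data.frame(s = tx$tx_start - flank_bp, e = tx$tx_end + flank_bp)
  spans <- spans[order(spans$s), ]
  lo <- min(spans$s) - 3000L
  gaps_s <- c(lo, spans$e); gaps_e <- c(spans$s, max(spans$e) + 3000L)
  keep <- gaps_s < gaps_e
  ivs <- rbind(ivs, data.frame(category = "intergenic",
                               start = gaps_s[keep], end = gaps_e[keep]))
  cats <- unique(ivs$category)
  per <- ceiling(n / length(cats))
  with_seed(seed, {
    out <- do.call(rbind, lapply(cats, function(ct) {
      sub <- ivs[ivs$category == ct, , drop = FALSE]
      widths <- sub$end - sub$start
      pick <- sample.int(nrow(sub), per, replace = TRUE, prob = widths)
      offs <- floor(stats::runif(per) * widths[pick])
      data.frame(chrom = "chr1", pos = as.integer(sub$start[pick] + offs + 1L),
                 truth_category = ct, stringsAsFactors = FALSE)
    }))
    out <- out[!duplicated(out$pos), , drop = FALSE]
    out$id <- sprintf("case_%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Simulate correlated score matrices with planted consensus hits
#'
#' Background scores share a latent per-variant functionality: each method
#' (and tissue) column is `sqrt(rho) * latent + sqrt(1 - rho) * noise`, which
#' hits an expected inter-column correlation of `rho`. A planted subset of
#' `ceiling(hit_q * n)` variants is then raised above the background maximum
#' of every method column and of the target-tissue column (only), making the
#' planted set recoverable by construction: it is the exact top quantile of
#' the target tissue and of every context-free method.
#'
#' @param config a [sim_config()].
#' @param ids optional variant ids (overrides `config$n_variants`).
#' @return list: `cf` (variants x methods [score_matrix()]), `tissue`
#'   (variants x tissues), `target_tissue`, `tissue_group`, `hits` (planted
#'   variant ids, sorted).
#' @export
simulate_score_matrix <- function(config, ids = NULL) {
  with_seed(substream_seed(config$seed, 3L), {
    if (is.null(ids)) ids <- sprintf("var_%04d", seq_len(config$n_variants))
    n <- length(ids)
    rho <- config$method_correlation
    z <- stats::rnorm(n)
    mk <- function(ncol_, prefix) {
      m <- vapply(seq_len(ncol_), function(j) {
        sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      }, numeric(n))
      m <- matrix(m, nrow = n)
      dimnames(m) <- list(ids, sprintf("%s%03d", prefix, seq_len(ncol_)))
      m
    }
    cf <- mk(config$n_methods, "method_")
    ti <- mk(config$n_tissues, "tissue_")
    k <- ceiling(config$hit_q * n)
    hits <- sort(sample(ids, k))
    jitter <- stats::runif(k, 0, 0.5)
    for (j in seq_len(ncol(cf))) {
      cf[hits, j] <- max(cf[setdiff(ids, hits), j]) + 1 + jitter
    }
    target <- colnames(ti)[1]
    ti[hits, target] <- max(ti) + 1 + jitter
    group <- colnames(ti)[seq_len(min(config$tissue_group_size, ncol(ti)))]
    list(cf = score_matrix(cf), tissue = score_matrix(ti),
         target_tissue = target, tissue_group = group, hits = hits)
  })
}

#' Simulate sparse-logistic training data for the semi-supervised scorer
#'
#' Features are i.i.d. standard normal; the true coefficient vector is
#' sparse; labels are Bernoulli draws from the true probabilities; anchors
#' are the true probabilities plus clipped Gaussian noise. A held-out
#' labeled set from the same truth supports out-of-sample evaluation.
#'
#' @param config a [sim_config()].
#' @return list: `labeled` ([training_set()]), `unlabeled`
#'   ([unlabeled_set()]), `holdout` (features + labels), `beta` (true
#'   coefficients), `prob_unlabeled` (true anchor-free probabilities).
#' @export
simulate_training_data <- function(config) {
  with_seed(substream_seed(config$seed, 4L), {
    p <- config$n_features
    beta <- numeric(p)
    support <- sample.int(p, config$n_nonzero)
    beta[support] <- sample(c(-1, 1), config$n_nonzero, replace = TRUE) *
      stats::runif(config$n_nonzero, 1, 2)
    draw_labeled <- function(n_) {
      X <- matrix(stats::rnorm(n_ * p), n_, p,
                  dimnames = list(NULL, paste0("f", seq_len(p))))
      prob <- sigmoid(drop(X %*% beta))
      y <- stats::rbinom(n_, 1L, prob)
      tries <- 0L
      while (length(unique(y)) < 2 && tries < 100L) {
        y <- stats::rbinom(n_, 1L, prob)
        tries <- tries + 1L
      }
      list(X = X, y = y, prob = prob)
    }
    lab <- draw_labeled(config$n_labeled)
    hold <- draw_labeled(config$n_holdout)
    Xu <- matrix(stats::rnorm(config$n_unlabeled * p), config$n_unlabeled, p,
                 dimnames = list(NULL, paste0("f", seq_len(p))))
    prob_u <- sigmoid(drop(Xu %*% beta))
    anchors <- pmin(1, pmax(0, prob_u + stats::rnorm(config$n_unlabeled, 0,
                                                     config$anchor_noise_sd)))
    list(
      labeled = training_set(lab$X, lab$y,
                             ids = sprintf("lab_%04d", seq_len(config$n_labeled)),
                             tissue = "synthetic_tissue"),
      unlabeled = unlabeled_set(Xu, anchors,
                                ids = sprintf("unl_%05d", seq_len(config$n_unlabeled))),
      holdout = list(features = hold$X, labels = hold$y),
      beta = beta,
      prob_labeled = lab$prob,
      prob_unlabeled = prob_u)
  })
}

#' Write a complete pipeline fixture set
#'
#' Generates and writes every input the pipeline needs: a phased panel VCF,
#' an index-variant TSV, a refGene-style gene model, context-free and tissue
#' score tables covering the LD-expanded variant set (with planted consensus
#' hits), labeled/unlabeled training tables, a tissue-group file, a pipeline
#' YAML configuration, and a truth JSON recording the planted hits.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param n_index number of panel sites used as queried index variants.
#' @param ld_config the [ld_config()] the pipeline will use (the score
#'   tables must cover the expanded set).
#' @return list of file paths plus the truth list (invisible file side
#'   effects).
#' @export
synth_fixture_set <- function(dir, config = sim_config(), n_index = 10L,
                              ld_config = finecons::ld_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_haplotype_panel(config)
  panel_path <- file.path(dir, "panel.vcf")
  write_panel_vcf(panel, panel_path)

  idx <- with_seed(substream_seed(config$seed, 5L), {
    sort(sample.int(nrow(panel$sites), min(n_index, nrow(panel$sites))))
  })
  variants <- panel$sites[idx, , drop = FALSE]
  variants_path <- file.path(dir, "variants.tsv")
  utils::write.table(as.data.frame(variants)[, c("chrom", "pos", "ref", "alt", "id")],
                     variants_path, sep = "\t", quote = FALSE, row.names = FALSE)

  model <- simulate_gene_model(config)
  genemodel_path <- file.path(dir, "refgene.tsv")
  write_refgene(model, genemodel_path)

  # score tables must cover the LD-expanded id set
  expanded <- unique(unlist(lapply(idx, function(i) {
    suppressWarnings(find_proxies(panel, panel$sites[i, ], ld_config)$proxy_id)
  })))
  expanded <- panel$sites$id[panel$sites$id %in% expanded]  # panel order
  sm <- simulate_score_matrix(config, ids = expanded)
  cf_path <- file.path(dir, "cf_scores.tsv")
  tissue_path <- file.path(dir, "tissue_scores.tsv")
  write_score_table(sm$cf, cf_path)
  write_score_table(sm$tissue, tissue_path)
  group_path <- file.path(dir, "tissue_group.txt")
  writeLines(sm$tissue_group, group_path)

  td <- simulate_training_data(config)
  lab_df <- data.frame(id = td$labeled$ids, label = td$labeled$labels,
                       stringsAsFactors = FALSE)
  lab_df <- cbind(lab_df, as.data.frame(td$labeled$features))
  labeled_path <- file.path(dir, "labeled.tsv")
  write_tsv_header(lab_df, labeled_path)
  unl_df <- data.frame(id = td$unlabeled$ids, anchor = td$unlabeled$anchors,
                       stringsAsFactors = FALSE)
  unl_df <- cbind(unl_df, as.data.frame(td$unlabeled$features))
  unlabeled_path <- file.path(dir, "unlabeled.tsv")
  write_tsv_header(unl_df, unlabeled_path)

  truth <- list(hits = sm$hits, target_tissue = sm$target_tissue,
                tissue_group = sm$tissue_group,
                beta_support = which(td$beta != 0),
                n_expanded = length(expanded))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  cfg <- list(
    variants = list(path = variants_path, format = "tsv"),
    panel = list(path = panel_path),
    gene_model = list(path = genemodel_path),
    cf_scores = list(path = cf_path),
    tissue_scores = list(path = tissue_path,
                         target_tissue = sm$target_tissue,
                         group = group_path),
    ld = list(enabled = TRUE, r2_threshold = ld_config$r2_threshold,
              window_bp = ld_config$window_bp, maf_min = ld_config$maf_min),
    annotator = list(splice_window_bp = 2, flank_bp = 1000,
                     keep_categories = "all"),
    genonet = list(labeled = labeled_path, unlabeled = unlabeled_path,
                   gamma_grid = c(0, 0.1, 1, 10), folds = 3,
                   lambda = 1, l1_ratio = 0.5),
    consensus = list(q = config$hit_q, min_method_fraction = 0.5,
                     n_perm = 199, min_methods = NULL),
    seed = config$seed)
  yaml_path <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(cfg, yaml_path)

  list(config_path = yaml_path, variants = variants_path, panel = panel_path,
       gene_model = genemodel_path, cf_scores = cf_path,
       tissue_scores = tissue_path, tissue_group = group_path,
       labeled = labeled_path, unlabeled = unlabeled_path,
       truth_path = truth_path, truth = truth)
}
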