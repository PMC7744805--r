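# End-to-end orchestration: variant read -> LD proxy expansion -> annotation
# -> score ingestion (and optional semi-supervised fitting) -> ranking ->
# average-ranking consensus with permutation p-values -> concordance ->
# tissue-max profile -> consensus prioritization -> report.
#
# Every output file carries the configuration hash in its header; outputs
# contain no timestamps, so repeat runs with the same configuration and seed
# are byte-identical. A stage failure aborts with the stage name; outputs of
# completed stages are preserved under <out>/partial/.

#' Build a pipeline configuration
#'
#' @param x a YAML file path or a nested list with components `variants`
#'   (path, format), `panel` (path; optional), `gene_model` (path),
#'   `cf_scores` (path), `tissue_scores` (path, target_tissue, group = file
#'   of tissue ids or character vector), `ld` (enabled, r2_threshold,
#'   window_bp, maf_min), `annotator` (splice_window_bp, flank_bp,
#'   keep_categories or "all"), optional `genonet` (labeled, unlabeled,
#'   gamma_grid, folds, lambda, l1_ratio), `consensus` (q,
#'   min_method_fraction, n_perm, min_methods or NULL for strict), `seed`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("no such config file: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  defaults <- list(
    ld = list(enabled = TRUE, r2_threshold = 0.5, window_bp = 500000L,
              maf_min = 0),
    annotator = list(splice_window_bp = 2L, flank_bp = 1000L,
                     keep_categories = "all"),
    consensus = list(q = 0.05, min_method_fraction = 0.5, n_perm = 999L,
                     min_methods = NULL),
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      x[[nm]] <- utils::modifyList(defaults[[nm]], x[[nm]] %||% list())
    } else if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  }
  structure(x, class = "pipeline_config")
}

config_hash <- function(config) {
  md5_string(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

#' Validate a pipeline configuration
#'
#' All-or-nothing: either every check passes or the full failure list is
#' returned (never just the first failure).
#'
#' @param config a [pipeline_config()].
#' @return list(ok = logical, errors = character vector of all failures).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  need_file <- function(path, what) {
    if (is.null(path)) errs <<- c(errs, paste0(what, ": path missing"))
    else if (!file.exists(path)) errs <<- c(errs, paste0(what, ": no such file: ", path))
  }
  need_file(config$variants$path, "variants")
  if (!is.null(config$variants$format) &&
      !config$variants$format %in% c("tsv", "vcf")) {
    errs <- c(errs, "variants: format must be 'tsv' or 'vcf'")
  }
  if (isTRUE(config$ld$enabled)) need_file(config$panel$path, "panel")
  need_file(config$gene_model$path, "gene_model")
  need_file(config$cf_scores$path, "cf_scores")
  need_file(config$tissue_scores$path, "tissue_scores")
  if (is.null(config$tissue_scores$target_tissue)) {
    errs <- c(errs, "tissue_scores: target_tissue missing")
  }
  g <- config$tissue_scores$group
  if (is.null(g)) {
    errs <- c(errs, "tissue_scores: group missing")
  } else if (length(g) == 1 && !file.exists(g) && is.character(g)) {
    # single id is acceptable; treated as a one-tissue group
  }
  ld <- config$ld
  if (!is.null(ld$r2_threshold) && (ld$r2_threshold < 0 || ld$r2_threshold > 1)) {
    errs <- c(errs, "ld: r2_threshold must lie in [0,1]")
  }
  if (!is.null(ld$window_bp) && ld$window_bp <= 0) {
    errs <- c(errs, "ld: window_bp must be positive")
  }
  cs <- config$consensus
  if (cs$q <= 0 || cs$q >= 1) {
    errs <- c(errs, "consensus: q must lie strictly in (0,1)")
  }
  if (cs$min_method_fraction <= 0 || cs$min_method_fraction > 1) {
    errs <- c(errs, "consensus: min_method_fraction must lie in (0,1]")
  }
  if (cs$n_perm < 1) errs <- c(errs, "consensus: n_perm must be >= 1")
  if (!is.null(config$genonet)) {
    need_file(config$genonet$labeled, "genonet labeled")
    need_file(config$genonet$unlabeled, "genonet unlabeled")
    if (length(config$genonet$gamma_grid %||% numeric(0)) == 0) {
      errs <- c(errs, "genonet: gamma_grid is empty")
    }
  }
  list(ok = length(errs) == 0, errors = errs)
}

read_tissue_group <- function(g) {
  if (length(g) == 1 && is.character(g) && file.exists(g)) {
    g <- readLines(g)
  }
  g <- g[nzchar(g)]
  if (length(g) == 0) stop("tissue group is empty", call. = FALSE)
  g
}

#' Run the full fine-mapping pipeline
#'
#' Stages run in order; each output file is written with a header recording
#' the configuration hash. Fully deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()] (validated internally).
#' @param out_dir output directory.
#' @param quiet suppress per-stage messages.
#' @return a `pipeline_report` list (also written as report.json /
#'   report.tsv).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- pipeline_config(unclass(config))
  chk <- validate_config(config)
  if (!chk$ok) {
    stop("invalid pipeline configuration:\n  - ",
         paste(chk$errors, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(out_dir, "partial")
  dir.create(partial, showWarnings = FALSE)
  hash <- config_hash(config)
  meta <- c(config_hash = hash)
  say <- function(...) if (!quiet) message("[finecons] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "; partial outputs preserved under ", partial, call. = FALSE)
    })
  }
  report <- list(config_hash = hash, seed = config$seed,
                 input_hashes = list(), counts = list())
  for (f in c(config$variants$path, config$panel$path, config$gene_model$path,
              config$cf_scores$path, config$tissue_scores$path)) {
    if (!is.null(f)) report$input_hashes[[basename(f)]] <- md5_file(f)
  }

  ## 1. variants
  variants <- stage("read_variants", {
    read_variants(config$variants$path, config$variants$format %||% "tsv")
  })
  report$counts$variants_input <- nrow(variants)
  say("read ", nrow(variants), " variants")

  ## 2. LD proxy expansion (optional)
  variants$proxy_of <- NA_character_
  proxy_tab <- NULL
  if (isTRUE(config$ld$enabled) && !is.null(config$panel$path)) {
    expanded <- stage("ld_proxy", {
      panel <- load_haplotypes(config$panel$path)
      cfg <- ld_config(config$ld$r2_threshold, config$ld$window_bp,
                       config$ld$maf_min)
      recs <- list()
      for (i in seq_len(nrow(variants))) {
        if (variants$is_indel[i]) next
        r <- tryCatch(find_proxies(panel, variants[i, ], cfg),
                      error = function(e) {
                        warning("proxy search skipped for ", variants$id[i],
                                ": ", conditionMessage(e), call. = FALSE)
                        NULL
                      })
        if (!is.null(r)) recs[[length(recs) + 1]] <- r
      }
      proxy_tab <- if (length(recs) > 0) do.call(rbind, recs) else
        data.frame(index_id = character(0), proxy_id = character(0),
                   chrom = character(0), pos = integer(0), r2 = numeric(0),
                   distance_bp = integer(0))
      new_ids <- setdiff(proxy_tab$proxy_id, variants$id)
      add <- panel$sites[match(new_ids, panel$sites$id), , drop = FALSE]
      if (nrow(add) > 0) {
        add$proxy_of <- proxy_tab$index_id[match(new_ids, proxy_tab$proxy_id)]
        variants <- rbind(as.data.frame(variants),
                          as.data.frame(add)[, names(variants)])
        variants <- variant_set(variants)
      }
      list(variants = variants, proxy_tab = proxy_tab)
    })
    variants <- expanded$variants
    proxy_tab <- expanded$proxy_tab
    write_tsv_header(proxy_tab, file.path(partial, "proxies.tsv"), meta)
    say("expanded to ", nrow(variants), " variants via ",
        nrow(proxy_tab), " proxy records")
  }
  report$counts$proxy_records <- if (is.null(proxy_tab)) 0L else nrow(proxy_tab)
  report$counts$variants_expanded <- nrow(variants)
  write_tsv_header(as.data.frame(variants),
                   file.path(partial, "variants_expanded.tsv"), meta)

  ## 3. annotation
  model <- stage("read_gene_model", read_gene_model(config$gene_model$path))
  anno <- stage("annotation", {
    annotate_variants(variants, model,
                      splice_window_bp = config$annotator$splice_window_bp,
                      flank_bp = config$annotator$flank_bp)
  })
  anno$proxy_of <- variants$proxy_of[match(anno$variant_id, variants$id)]
  write_tsv_header(anno, file.path(partial, "annotation.tsv"), meta)
  report$counts$annotated <- nrow(anno)
  report$category_summary <- as.list(summarize_categories(anno))
  keep_cats <- config$annotator$keep_categories
  if (!identical(keep_cats, "all")) {
    keep_ids <- anno$variant_id[anno$category %in% keep_cats]
    variants <- variants[variants$id %in% keep_ids, , drop = FALSE]
    say("category filter retained ", nrow(variants), " variants")
  }
  report$counts$after_category_filter <- nrow(variants)

  ## 4. score ingestion
  scores <- stage("score_ingestion", {
    cf <- read_score_table(config$cf_scores$path,
                           direction = config$cf_scores$direction %||% "higher")
    ti <- read_score_table(config$tissue_scores$path)
    ids <- intersect(variants$id, intersect(rownames(cf$values),
                                            rownames(ti$values)))
    if (length(ids) < 2) stop("fewer than 2 analyzed variants are covered ",
                              "by both score tables")
    list(cf = score_matrix(cf$values[ids, , drop = FALSE], cf$direction),
         tissue = score_matrix(ti$values[ids, , drop = FALSE], ti$direction))
  })
  report$counts$scored <- nrow(scores$cf$values)
  say("scores cover ", report$counts$scored, " variants (",
      ncol(scores$cf$values), " methods, ", ncol(scores$tissue$values),
      " tissues)")

  ## 5. optional semi-supervised fitting
  if (!is.null(config$genonet)) {
    gn <- stage("genonet_fit", {
      lab <- read_tsv_plain(config$genonet$labeled)
      unl <- read_tsv_plain(config$genonet$unlabeled)
      feat_cols <- setdiff(names(lab), c("id", "label"))
      labeled <- training_set(as.matrix(lab[, feat_cols]), lab$label,
                              ids = lab$id)
      unlabeled <- unlabeled_set(as.matrix(unl[, setdiff(names(unl), c("id", "anchor"))]),
                                 unl$anchor, ids = unl$id)
      cfg <- fit_config(l1_ratio = config$genonet$l1_ratio %||% 0.5,
                        lambda = config$genonet$lambda %||% 1,
                        seed = substream_seed(config$seed, 12L))
      tune <- tune_gamma(labeled, unlabeled,
                         gamma_grid = config$genonet$gamma_grid,
                         folds = config$genonet$folds %||% 5L, cfg)
      cfg$gamma <- tune$best_gamma
      fit <- fit_semisupervised(labeled, unlabeled, cfg)
      list(tune = tune, fit = fit,
           scores = predict(fit, unlabeled$features), ids = unlabeled$ids)
    })
    write_tsv_header(gn$tune$table, file.path(partial, "genonet_tuning.tsv"), meta)
    write_tsv_header(
      data.frame(feature = c("(intercept)", names(gn$fit$coefficients)),
                 coefficient = c(gn$fit$intercept, gn$fit$coefficients)),
      file.path(partial, "genonet_coefficients.tsv"), meta)
    write_tsv_header(data.frame(variant_id = gn$ids, score = gn$scores),
                     file.path(partial, "genonet_scores.tsv"), meta)
    report$genonet <- list(best_gamma = gn$tune$best_gamma,
                           converged = gn$fit$converged,
                           nonzero_coefficients = sum(gn$fit$coefficients != 0))
    say("semi-supervised fit: best gamma ", gn$tune$best_gamma)
  }

  ## 6. ranking + consensus
  cons <- stage("consensus", {
    table <- rank_scores(scores$cf)
    mm <- config$consensus$min_methods %||% length(table$method_ids)
    pv <- permutation_pvalue(table, n_perm = config$consensus$n_perm,
                             seed = substream_seed(config$seed, 11L),
                             min_methods = mm)
    list(table = table, pv = pv)
  })
  rank_df <- data.frame(variant_id = cons$table$variant_ids,
                        cons$table$ranks, check.names = FALSE)
  write_tsv_header(rank_df, file.path(partial, "ranking.tsv"), meta)
  write_tsv_header(cons$pv, file.path(partial, "consensus.tsv"), meta)
  report$counts$consensus_included <- sum(cons$pv$included)

  ## 7. concordance
  corr <- stage("concordance", pearson_rank_correlation(cons$table))
  corr_df <- data.frame(method = rownames(corr), corr, check.names = FALSE)
  write_tsv_header(corr_df, file.path(partial, "rank_correlation.tsv"), meta)
  target <- config$tissue_scores$target_tissue
  cf_vs_tissue <- stage("concordance", {
    tv <- scores$tissue$values[, target]
    data.frame(method = colnames(scores$cf$values),
               spearman_vs_target_tissue = vapply(
                 seq_len(ncol(scores$cf$values)),
                 function(j) spearman_scores(scores$cf$values[, j], tv),
                 numeric(1)))
  })
  write_tsv_header(cf_vs_tissue, file.path(partial, "cf_vs_tissue.tsv"), meta)

  ## 8. tissue-max profile
  group <- read_tissue_group(config$tissue_scores$group)
  profile <- stage("tissue_profile",
                   tissue_max_profile(scores$tissue, group))
  write_tsv_header(profile, file.path(partial, "tissue_profile.tsv"), meta)
  report$tissue_profile <- as.list(table(profile$classification))

  ## 9. consensus prioritization
  prior <- stage("prioritization", {
    consensus_prioritize(scores$tissue, target, cons$table,
                         q = config$consensus$q,
                         min_method_fraction = config$consensus$min_method_fraction)
  })
  prior$proxy_of <- variants$proxy_of[match(prior$variant_id, variants$id)]
  write_tsv_header(prior, file.path(partial, "prioritized.tsv"), meta)
  report$counts$prioritized <- sum(prior$pass)
  report$prioritized_ids <- prior$variant_id[prior$pass]
  say(sum(prior$pass), " variant(s) pass consensus prioritization")

  ## report + promote partial outputs
  jsonlite::write_json(report, file.path(partial, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flat <- unlist(report)
  write_tsv_header(data.frame(key = names(flat), value = as.character(flat)),
                   file.path(partial, "report.tsv"), meta)
  for (f in list.files(partial, full.names = TRUE)) {
    file.rename(f, file.path(out_dir, basename(f)))
  }
  unlink(partial, recursive = TRUE)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  cat("  prioritized: ", paste(x$prioritized_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}
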