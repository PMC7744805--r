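# Genic-context classification, TSS distances and coding consequences.

test_that("the worked four-position transcript classifies exactly", {
  m <- toy_model("+")
  vv <- function(pos) list(chrom = "chr1", pos = pos, id = paste0("v", pos))
  expect_equal(classify_variant(vv(1100), m)$category, "UTR5")
  expect_equal(classify_variant(vv(1300), m)$category, "exonic")
  expect_equal(classify_variant(vv(1401), m)$category, "splicing")
  expect_equal(classify_variant(vv(1500), m)$category, "intronic")
})

test_that("UTR sides follow strand; non-coding transcripts yield ncRNA classes", {
  m_minus <- toy_model("-")
  expect_equal(classify_variant(list(chrom = "chr1", pos = 1100, id = "v"),
                                m_minus)$category, "UTR3")
  expect_equal(classify_variant(list(chrom = "chr1", pos = 1900, id = "v"),
                                m_minus)$category, "UTR5")

  tx <- toy_model("+")$transcripts
  tx$cds_start <- tx$cds_end <- tx$tx_end  # empty CDS => non-coding
  m_nc <- gene_model(tx)
  expect_equal(classify_variant(list(chrom = "chr1", pos = 1300, id = "v"),
                                m_nc)$category, "ncRNA_exonic")
  expect_equal(classify_variant(list(chrom = "chr1", pos = 1401, id = "v"),
                                m_nc)$category, "ncRNA_intronic")
})

test_that("distal variants are intergenic with the nearest gene reported", {
  m <- toy_model("+")
  r <- classify_variant(list(chrom = "chr1", pos = 1000000, id = "far"), m)
  expect_equal(r$category, "intergenic")
  expect_equal(r$gene, "GENEA")
  expect_equal(r$tss_distance_bp, 1000000L - 1000L)
  expect_warning(
    r2 <- classify_variant(list(chrom = "chr9", pos = 100, id = "off"), m),
    "absent")
  expect_equal(r2$category, "intergenic")
  expect_true(is.na(r2$gene))
})

test_that("TSS distance is strand-oriented with alphabetical tie-break", {
  m <- toy_model("+")
  expect_equal(nearest_tss(list(chrom = "chr1", pos = 1000), m)$distance_bp, 0L)
  m_minus <- toy_model("-")  # TSS at txEnd = 2000 (1-based)
  nt <- nearest_tss(list(chrom = "chr1", pos = 2500), m_minus)
  expect_equal(nt$distance_bp, -500L)  # 500 bp 5' of the TSS

  tx <- rbind(toy_model("+")$transcripts, toy_model("+")$transcripts)
  tx$name <- c("tx1", "tx2"); tx$gene <- c("ZGENE", "AGENE")
  tx$tx_start[2] <- 2999L; tx$tx_end[2] <- 4000L
  tx$cds_start[2] <- 3199L; tx$cds_end[2] <- 3800L
  tx$exon_starts[[2]] <- 2999L; tx$exon_ends[[2]] <- 4000L
  m2 <- gene_model(tx)
  # pos 2000: 1000 from ZGENE TSS (1000) and 1000 from AGENE TSS (3000)
  expect_equal(nearest_tss(list(chrom = "chr1", pos = 2000), m2)$gene, "AGENE")
})

test_that("classification matches the position-set oracle on random models", {
  for (seed in c(21, 22)) {
    m <- simulate_gene_model(sim_config(seed = seed, n_transcripts = 6))
    span <- range(m$transcripts$tx_start, m$transcripts$tx_end)
    set.seed(seed)
    pos <- sort(sample(seq(span[1] - 2000L, span[2] + 2000L), 150))
    for (p in pos) {
      got <- classify_variant(list(chrom = "chr1", pos = p, id = "x"), m)$category
      expect_equal(got, classify_position_oracle(p, m), info = paste("pos", p))
    }
  }
})

test_that("categories are invariant under genome mirroring with strand flip", {
  m <- simulate_gene_model(sim_config(seed = 31, n_transcripts = 5))
  tx <- m$transcripts
  L <- max(tx$tx_end) + 5000L
  mir <- tx
  mir$strand <- ifelse(tx$strand == "+", "-", "+")
  mir$tx_start <- L - tx$tx_end; mir$tx_end <- L - tx$tx_start
  coding <- tx$cds_end > tx$cds_start
  mir$cds_start <- ifelse(coding, L - tx$cds_end, mir$tx_end)
  mir$cds_end <- ifelse(coding, L - tx$cds_start, mir$tx_end)
  for (i in seq_len(nrow(tx))) {
    mir$exon_starts[[i]] <- rev(L - tx$exon_ends[[i]])
    mir$exon_ends[[i]] <- rev(L - tx$exon_starts[[i]])
  }
  m_mir <- gene_model(mir)
  set.seed(31)
  pos <- sample(seq(min(tx$tx_start) - 1500L, max(tx$tx_end) + 1500L), 120)
  for (p in pos) {
    a <- classify_variant(list(chrom = "chr1", pos = p, id = "x"), m)$category
    # 1-based mirror: base at p0 maps to L - 1 - p0, i.e. pos' = L - p + 1
    b <- classify_variant(list(chrom = "chr1", pos = L - p + 1L, id = "x"),
                          m_mir)$category
    expect_equal(a, b, info = paste("pos", p))
  }
})

test_that("coding consequences match hand translation on toy CDS fixtures", {
  fx <- toy_cds_fixture("ATGAAATAG")  # Met Lys Stop; CDS at 1-based 11..19
  tx <- fx$model$transcripts[1, ]
  v_non <- list(chrom = "chrT", pos = 14L, ref = "A", alt = "T", id = "n")
  expect_equal(coding_effect(v_non, tx, fx$reference), "nonsense")   # AAA->TAA
  v_mis <- list(chrom = "chrT", pos = 15L, ref = "A", alt = "G", id = "m")
  expect_equal(coding_effect(v_mis, tx, fx$reference), "missense")   # AAA->AGA
  fx2 <- toy_cds_fixture("ATGCTTAAATAG")  # Met Leu Lys Stop
  tx2 <- fx2$model$transcripts[1, ]
  v_syn <- list(chrom = "chrT", pos = 16L, ref = "T", alt = "C", id = "s")
  expect_equal(coding_effect(v_syn, tx2, fx2$reference), "synonymous")  # CTT->CTC

  v_bad <- list(chrom = "chrT", pos = 14L, ref = "C", alt = "T", id = "b")
  expect_error(coding_effect(v_bad, tx, fx$reference), "reference mismatch")
})

test_that("minus-strand coding consequences agree with the translation oracle", {
  cds <- random_cds(12, seed = 5)
  for (strand in c("+", "-")) {
    fx <- toy_cds_fixture(cds, strand = strand)
    tx <- fx$model$transcripts[1, ]
    set.seed(50 + (strand == "-"))
    for (r in 1:40) {
      cds_off <- sample(nchar(cds), 1)   # 1-based offset within the CDS
      # genomic position and genomic-strand alleles
      if (strand == "+") {
        gpos <- fx$cds_start0 + cds_off
        g_ref <- substr(cds, cds_off, cds_off)
      } else {
        gpos <- fx$cds_end0 - cds_off + 1L
        g_ref <- revcomp(substr(cds, cds_off, cds_off))
      }
      g_alt <- sample(setdiff(c("A", "C", "G", "T"), g_ref), 1)
      got <- coding_effect(list(chrom = "chrT", pos = gpos, ref = g_ref,
                                alt = g_alt, id = "r"), tx, fx$reference)
      mut <- cds
      tx_alt <- if (strand == "+") g_alt else revcomp(g_alt)
      substr(mut, cds_off, cds_off) <- tx_alt
      expect_equal(got, coding_effect_oracle(cds, mut),
                   info = paste(strand, cds_off, g_ref, g_alt))
    }
  }
})

test_that("category counts sum to input size and ignore record order", {
  recs <- rbind(annotation_rec("a", "intronic"), annotation_rec("b", "intronic"),
                annotation_rec("c", "intronic"), annotation_rec("d", "exonic"))
  expect_equal(summarize_categories(recs),
               c(exonic = 1L, intronic = 3L))
  expect_equal(summarize_categories(recs[sample(4), ]),
               summarize_categories(recs))
  expect_length(summarize_categories(recs[0, ]), 0)
})
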