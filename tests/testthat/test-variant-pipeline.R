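row_df <- function(...) {
  defaults <- list(
    `#AlleleID` = 1L, Type = "single nucleotide variant",
    Name = "NM_000001.1(G1):c.4C>T (p.Arg2Cys)", GeneSymbol = "G1",
    ClinicalSignificance = "Pathogenic", `RS# (dbSNP)` = 1,
    PhenotypeList = "not provided", Assembly = "GRCh38",
    ReferenceAlleleVCF = "C", AlternateAlleleVCF = "T"
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  as.data.frame(defaults, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("parsing extracts the protein change from the HGVS name", {
  rec <- parse_variant_summary(row_df())
  expect_equal(rec$p_ref, "Arg")
  expect_equal(rec$p_pos, 2L)
  expect_equal(rec$p_alt, "Cys")

  ter <- parse_variant_summary(row_df(Name = "NM_1.1(G):c.7C>T (p.Gln3Ter)"))
  expect_equal(ter$p_alt, "Ter")
  star <- parse_variant_summary(row_df(Name = "NM_1.1(G):c.7C>T (p.Gln3*)"))
  expect_equal(star$p_alt, "Ter")
  none <- parse_variant_summary(row_df(Name = "NM_1.1(G):c.7C>T"))
  expect_true(is.na(none$p_ref))

  expect_error(parse_variant_summary(row_df(Type = NULL)),
               "missing mandatory column.*Type")
})

test_that("filters drop each exclusion class in order", {
  rows <- rbind(
    row_df(`#AlleleID` = 1L),
    row_df(`#AlleleID` = 2L, Type = "Deletion"),
    row_df(`#AlleleID` = 1L, Assembly = "GRCh37"),
    row_df(`#AlleleID` = 3L, AlternateAlleleVCF = "X"),
    row_df(`#AlleleID` = 4L, ReferenceAlleleVCF = "A",
           AlternateAlleleVCF = "A"),
    row_df(`#AlleleID` = 5L, Name = "NM_1.1(G1):c.9G>A (p.Leu3=)"),
    row_df(`#AlleleID` = 6L, Name = "NM_1.1(G1):c.9G>A")
  )
  rec <- filter_variants(parse_variant_summary(rows))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$allele_id, "1")
  log <- attr(rec, "filter_log")
  expect_equal(log$n_out[log$stage == "snv_type"], 6)
  expect_true(all(log$n_out <= log$n_in))  # monotone chain
})

test_that("significance binning is a case-insensitive word match", {
  expect_equal(as.character(bin_significance(c(
    "Pathogenic", "Pathogenic/Likely pathogenic", "Likely pathogenic",
    "Likely benign", "Benign", "Uncertain significance",
    "Conflicting interpretations of pathogenicity", "risk factor",
    "drug response"
  ))), c("pathogenic", "pathogenic", "pathogenic", "benign", "benign",
         "unspecified", "unspecified", "unspecified", "unspecified"))
})

test_that("codon validation compares the translated reference", {
  cds <- nuc_sequence("G1", "AUGCGAGGG")  # Met Arg Gly
  ok <- parse_variant_summary(row_df(Name = "NM_1.1(G1):c.4C>T (p.Arg2Ter)"))
  expect_true(validate_against_ccds(ok[1, ], cds))
  bad <- parse_variant_summary(row_df(Name = "NM_1.1(G1):c.4C>T (p.Gly2Ter)"))
  expect_false(validate_against_ccds(bad[1, ], cds))
  beyond <- parse_variant_summary(row_df(Name = "NM_1.1(G1):c.40C>T (p.Arg9Ter)"))
  expect_false(validate_against_ccds(beyond[1, ], cds))
})

test_that("mRNA-change inference resolves codon position and strand", {
  cds <- nuc_sequence("G1", "AUGCGAGGGCAA")  # Met Arg Gly Gln
  # CGA(Arg) -> Ter by C>U at codon position 1 (plus strand C>T)
  rec <- parse_variant_summary(row_df(Name = "N(G1):c.4C>T (p.Arg2Ter)"))
  ch <- infer_mrna_change(rec[1, ], cds)
  expect_equal(ch$status, "ok")
  expect_equal(ch$cds_pos, 4L)
  expect_true(ch$is_c2u)

  # GAA-like case: GGG(Gly)->GAG? use Glu codon: plus-strand G>A, not C>U
  cds2 <- nuc_sequence("G1", "GAAUUU")  # Glu Phe
  rec2 <- parse_variant_summary(row_df(
    Name = "N(G1):c.1G>A (p.Glu1Lys)",
    ReferenceAlleleVCF = "G", AlternateAlleleVCF = "A"
  ))
  ch2 <- infer_mrna_change(rec2[1, ], cds2)
  expect_equal(ch2$ref_base, "G")
  expect_false(ch2$is_c2u)

  # minus-strand gene: genomic G>A reads as C>U on the mRNA (Gln -> Ter)
  rec3 <- parse_variant_summary(row_df(
    Name = "N(G1):c.10C>T (p.Gln4Ter)",
    ReferenceAlleleVCF = "G", AlternateAlleleVCF = "A"
  ))
  ch3 <- infer_mrna_change(rec3[1, ], cds)
  expect_equal(ch3$status, "ok")
  expect_equal(ch3$cds_pos, 10L)
  expect_true(ch3$is_c2u)

  # UGG(Trp) -> Ter reachable by G>A at two codon positions: ambiguous
  cds4 <- nuc_sequence("G1", "UGGAAA")
  rec4 <- parse_variant_summary(row_df(
    Name = "N(G1):c.2G>A (p.Trp1Ter)",
    ReferenceAlleleVCF = "G", AlternateAlleleVCF = "A"
  ))
  ch4 <- infer_mrna_change(rec4[1, ], cds4)
  expect_equal(ch4$status, "ambiguous")
  expect_true(ch4$ambiguous)
  expect_false(ch4$is_c2u)

  # alternate amino acid unreachable under the allele pair: inconsistent
  rec5 <- parse_variant_summary(row_df(
    Name = "N(G1):c.1G>A (p.Glu1Trp)",
    ReferenceAlleleVCF = "G", AlternateAlleleVCF = "A"
  ))
  expect_equal(infer_mrna_change(rec5[1, ], cds2)$status, "inconsistent")
})

test_that("inference is invariant under allele complementation", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds <- nuc_sequence("G1", "AUGCGAGGGCAA")
  for (alleles in list(c("C", "T"), c("G", "A"), c("T", "C"), c("A", "G"))) {
    rec <- parse_variant_summary(row_df(
      Name = "N(G1):c.4C>T (p.Arg2Ter)",
      ReferenceAlleleVCF = alleles[1], AlternateAlleleVCF = alleles[2]
    ))
    rec_c <- parse_variant_summary(row_df(
      Name = "N(G1):c.4C>T (p.Arg2Ter)",
      ReferenceAlleleVCF = comp[[alleles[1]]],
      AlternateAlleleVCF = comp[[alleles[2]]]
    ))
    a <- infer_mrna_change(rec[1, ], cds)
    b <- infer_mrna_change(rec_c[1, ], cds)
    expect_identical(unclass(a), unclass(b))
  }
})

test_that("set nesting holds through the pipeline", {
  fix <- make_variant_table(variant_spec_small(), seed = 45)
  res <- run_variant_pipeline(fix$variants, fix$ccds, model = "rules")
  expect_true(all(res$c2u$allele_id %in% res$exonic$allele_id))
  pred_ids <- res$predictions$allele_id[res$predictions$predicted]
  expect_true(all(pred_ids %in% res$c2u$allele_id))
  tab <- res$summary$table
  for (s in unique(tab$set)) {
    expect_equal(sum(tab$n[tab$set == s]),
                 unname(res$summary$totals[[if (s == "exonic") "exonic"
                                            else s]]))
  }
})

test_that("union predictions contain the rules predictions on a fixture", {
  fix <- make_variant_table(variant_spec_small(), seed = 46)
  sites <- make_benchmark(40, ratio = 3, seed = 46)
  cfg <- training_config(hard_negative_fraction = 0, seed = 46)
  ts <- build_training_set(sites, cfg)
  model <- train_rf(ts$x, ts$y, cfg, ntree = 100)
  res_rules <- run_variant_pipeline(fix$variants, fix$ccds, model = "rules")
  res_union <- run_variant_pipeline(fix$variants, fix$ccds, model = "union",
                                    rf_model = model)
  keys <- function(res) sprintf("%s:%d",
                                res$predictions$gene[res$predictions$predicted],
                                res$predictions$c_pos[res$predictions$predicted])
  expect_true(all(keys(res_rules) %in% keys(res_union)))
})

test_that("summaries reproduce printed-scale percentages from raw counts", {
  # full printed-scale bin counts, percentages recomputed from counts
  exonic <- data.frame(bin = rep(c("pathogenic", "benign", "unspecified"),
                                 c(120000, 60000, 437363)))
  c2u <- data.frame(bin = rep(c("pathogenic", "benign", "unspecified"),
                              c(19285, 9459, 72821)))
  preds <- data.frame(
    predicted = TRUE,
    bin = rep(c("pathogenic", "benign", "unspecified"), c(1046, 422, 3132))
  )
  s <- summarize_variant_sets(exonic, c2u, preds)
  tab <- s$table
  expect_equal(tab$pct[tab$set == "c2u"], c(19.0, 9.3, 71.7))
  expect_equal(tab$pct[tab$set == "predicted"], c(22.7, 9.2, 68.1))
  expect_equal(s$rates$pct_of_bin, c(5.4, 4.5, 4.3))

  empty <- summarize_variant_sets(
    exonic[0, , drop = FALSE], c2u[0, , drop = FALSE],
    preds[0, , drop = FALSE]
  )
  expect_true(all(is.na(empty$table$pct)))
})

test_that("the pipeline refuses consensus models without a trained forest", {
  fix <- make_variant_table(variant_spec_small(), seed = 47)
  expect_error(run_variant_pipeline(fix$variants, fix$ccds, model = "union"),
               "rf_model")
})
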