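# Synthetic ClinVar-style variant tables with matched coding sequences.
#
# The generator emits a variant_summary-dialect table plus a CCDS-style
# FASTA such that the variant pipeline's filters, codon validation and
# mRNA-change inference reproduce the requested marginal counts exactly.
# Sites meant to be predicted are planted inside a strong hairpin (4 G.C
# pairs closing a UUC loop, rules total >= 14); other C>U sites sit in
# background rejection-sampled below the rules threshold. Decoy rows
# (non-SNV, GRCh37, like-to-like, non-specific alleles, missing or
# synonymous protein change, missing CCDS, reference-codon mismatch,
# unreachable alternate amino acid) exercise every exclusion path.

# Codon templates. Alleles are the plus-strand genomic (DNA) pair; rows on
# minus-strand genes carry the complemented pair. Uniqueness of the implied
# single-base codon edit (given the recorded amino-acid change and both
# strand interpretations of the allele pair) was checked by enumeration.
VARIANT_TEMPLATES <- list(
  c2u_arg_cys = list(codon = "CGC", ref_aa = "Arg", alt_aa = "Cys",
                     sub_pos = 1L, ref = "C", alt = "T", c2u = TRUE),
  c2u_gln_ter = list(codon = "CAA", ref_aa = "Gln", alt_aa = "Ter",
                     sub_pos = 1L, ref = "C", alt = "T", c2u = TRUE),
  glu_lys = list(codon = "GAA", ref_aa = "Glu", alt_aa = "Lys",
                 sub_pos = 1L, ref = "G", alt = "A", c2u = FALSE),
  gly_asp = list(codon = "GGC", ref_aa = "Gly", alt_aa = "Asp",
                 sub_pos = 2L, ref = "G", alt = "A", c2u = FALSE),
  phe_ser = list(codon = "UUC", ref_aa = "Phe", alt_aa = "Ser",
                 sub_pos = 2L, ref = "T", alt = "C", c2u = FALSE),
  lys_arg = list(codon = "AAA", ref_aa = "Lys", alt_aa = "Arg",
                 sub_pos = 2L, ref = "A", alt = "G", c2u = FALSE),
  # Trp codon UGG reaches Ter by G>A at either position 2 or 3: ambiguous.
  amb_trp_ter = list(codon = "UGG", ref_aa = "Trp", alt_aa = "Ter",
                     sub_pos = NA_integer_, ref = "G", alt = "A",
                     c2u = FALSE)
)

# the 11-nt hairpin planted around predicted sites (C is base 7)
PLANT_MOTIF <- c("G", "C", "G", "C", "U", "U", "C", "G", "C", "G", "C")

SIG_STRINGS <- list(
  pathogenic = c("Pathogenic", "Likely pathogenic",
                 "Pathogenic/Likely pathogenic"),
  benign = c("Benign", "Likely benign", "Benign/Likely benign"),
  unspecified = c("Uncertain significance", "not provided",
                  "Conflicting interpretations of pathogenicity")
)

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Specification of a synthetic variant table
#'
#' Nested marginal counts the generated fixture must reproduce through the
#' pipeline. Bins are named vectors `c(pathogenic=, benign=, unspecified=)`.
#'
#' @param n_exonic Rows surviving every filter (the "exonic" set).
#' @param n_c2u Rows whose inferred mRNA change is C>U.
#' @param c2u_bins Pathogenicity split of the C>U set (sums to `n_c2u`).
#' @param n_predicted C>U rows planted in a calling hairpin.
#' @param predicted_bins Split of the predicted set (sums to `n_predicted`,
#'   each entry at most its `c2u_bins` counterpart).
#' @param n_ambiguous Exonic non-C>U rows with an ambiguous codon edit.
#' @param n_genes Genes to spread rows across.
#' @param n_grch37_dups GRCh37 decoy duplicates of valid rows.
#' @param conditions Pool of phenotype strings for `PhenotypeList`.
#' @return Object of class `variant_table_spec`.
#' @export
variant_table_spec <- function(n_exonic, n_c2u, c2u_bins, n_predicted,
                               predicted_bins, n_ambiguous = 5L,
                               n_genes = 40L, n_grch37_dups = 25L,
                               conditions = default_condition_pool()) {
  bins <- c("pathogenic", "benign", "unspecified")
  stopifnot(setequal(names(c2u_bins), bins),
            setequal(names(predicted_bins), bins))
  c2u_bins <- c2u_bins[bins]; predicted_bins <- predicted_bins[bins]
  if (sum(c2u_bins) != n_c2u) {
    stop("c2u_bins must sum to n_c2u", call. = FALSE)
  }
  if (sum(predicted_bins) != n_predicted) {
    stop("predicted_bins must sum to n_predicted", call. = FALSE)
  }
  if (any(predicted_bins > c2u_bins) || n_predicted > n_c2u ||
      n_c2u + n_ambiguous > n_exonic) {
    stop("nested counts inconsistent (subset sums exceed parents)",
         call. = FALSE)
  }
  structure(
    list(n_exonic = as.integer(n_exonic), n_c2u = as.integer(n_c2u),
         c2u_bins = c2u_bins, n_predicted = as.integer(n_predicted),
         predicted_bins = predicted_bins,
         n_ambiguous = as.integer(n_ambiguous),
         n_genes = as.integer(n_genes),
         n_grch37_dups = as.integer(n_grch37_dups),
         conditions = conditions),
    class = "variant_table_spec"
  )
}

#' @rdname variant_table_spec
#' @export
default_condition_pool <- function() {
  c("Hereditary cancer-predisposing syndrome", "Cardiomyopathy",
    "Epileptic encephalopathy", "Retinitis pigmentosa",
    "Metabolic myopathy", "Hereditary spastic paraplegia",
    "Congenital heart defect", "Maturity-onset diabetes of the young",
    "Sensorineural hearing loss", "Mystery syndrome ZZ")
}

#' Reduced-scale spec mirroring the published marginal proportions
#'
#' A ~1/20-scale count set chosen so that every reported percentage
#' (half-up, one decimal) equals the full-scale analysis: 16.5% of exonic
#' rows are C>U; the C>U set splits 19.0/9.3/71.7% across
#' pathogenic/benign/unspecified; 4.5% of C>U rows are predicted, splitting
#' 22.7/9.2/68.1%; the per-bin prediction rates are 5.4/4.5/4.3%.
#'
#' @return A [variant_table_spec()].
#' @export
variant_spec_mirror <- function() {
  variant_table_spec(
    n_exonic = 30411L, n_c2u = 5033L,
    c2u_bins = c(pathogenic = 955L, benign = 467L, unspecified = 3611L),
    n_predicted = 229L,
    predicted_bins = c(pathogenic = 52L, benign = 21L, unspecified = 156L)
  )
}

#' Small spec for fast tests
#' @param n_genes Genes to spread rows across.
#' @return A [variant_table_spec()] with ~300 exonic rows.
#' @export
variant_spec_small <- function(n_genes = 6L) {
  variant_table_spec(
    n_exonic = 300L, n_c2u = 60L,
    c2u_bins = c(pathogenic = 12L, benign = 6L, unspecified = 42L),
    n_predicted = 10L,
    predicted_bins = c(pathogenic = 3L, benign = 1L, unspecified = 6L),
    n_ambiguous = 2L, n_genes = n_genes, n_grch37_dups = 5L
  )
}

# an 11-codon block housing one C>U site at codon 6 position 1
# (CDS-relative window of the site is entirely inside the block)
gen_c2u_block <- function(template, predicted, convention = "three_prime") {
  repeat {
    block <- draw_background(33L, 0.5)
    if (predicted) {
      block[10:20] <- PLANT_MOTIF
      stopifnot(paste(block[16:18], collapse = "") == template$codon)
      return(block)
    }
    block[16:18] <- strsplit(template$codon, "")[[1]]
    w <- paste(block[1:26], collapse = "")
    tot <- rules_total_string(w, convention)
    if (!rules_classify(tot)) return(block)
  }
}

#' Generate a ClinVar-style variant table with matching coding sequences
#'
#' @param spec A [variant_table_spec()].
#' @param seed Seed; identical seeds reproduce the fixture byte-for-byte.
#' @param convention Loop convention the planted/rejected sites are built
#'   for (must match the convention the pipeline is later run with).
#' @return List with `variants` (data frame in `variant_summary` dialect),
#'   `ccds` (named character vector of DNA coding sequences, CCDS-style
#'   ids) and `manifest` (expected downstream counts, predicted site keys,
#'   and per-bin splits).
#' @export
make_variant_table <- function(spec, seed = 1L, convention = "three_prime") {
  stopifnot(inherits(spec, "variant_table_spec"))
  bins <- c("pathogenic", "benign", "unspecified")

  with_seed(seed, {
    # ---- row plan ----------------------------------------------------------
    c2u_bin <- rep(bins, times = spec$c2u_bins)
    pred_flag <- logical(spec$n_c2u)
    # mark predicted rows inside each bin
    for (b in bins) {
      idx <- which(c2u_bin == b)
      pred_flag[sample(idx, spec$predicted_bins[[b]])] <- TRUE
    }
    c2u_templates <- ifelse(
      pred_flag, "c2u_arg_cys",
      sample(c("c2u_arg_cys", "c2u_gln_ter"), spec$n_c2u, replace = TRUE)
    )
    n_plain <- spec$n_exonic - spec$n_c2u - spec$n_ambiguous
    plain_templates <- sample(c("glu_lys", "gly_asp", "phe_ser", "lys_arg"),
                              n_plain, replace = TRUE)
    plan <- data.frame(
      kind = c(rep("c2u", spec$n_c2u), rep("plain", n_plain),
               rep("ambiguous", spec$n_ambiguous)),
      template = c(c2u_templates, plain_templates,
                   rep("amb_trp_ter", spec$n_ambiguous)),
      predicted = c(pred_flag, rep(FALSE, n_plain + spec$n_ambiguous)),
      bin = c(c2u_bin,
              sample(bins, n_plain + spec$n_ambiguous, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    plan <- plan[sample(nrow(plan)), ]
    plan$gene_idx <- rep_len(seq_len(spec$n_genes), nrow(plan))

    genes <- sprintf("SYGN%02d", seq_len(spec$n_genes))
    strands <- rep_len(c("+", "-"), spec$n_genes)

    # ---- per-gene CDS assembly --------------------------------------------
    cds <- character(spec$n_genes)
    plan$aa_index <- NA_integer_
    plan$cds_pos <- NA_integer_
    for (g in seq_len(spec$n_genes)) {
      rows <- which(plan$gene_idx == g)
      rows <- rows[sample(length(rows))]   # shuffle unit order within gene
      codon_cursor <- 0L
      parts <- character(0)
      for (r in rows) {
        tpl <- VARIANT_TEMPLATES[[plan$template[r]]]
        if (plan$kind[r] == "c2u") {
          block <- gen_c2u_block(tpl, plan$predicted[r], convention)
          plan$aa_index[r] <- codon_cursor + 6L
          parts <- c(parts, paste(block, collapse = ""))
          codon_cursor <- codon_cursor + 11L
        } else {
          plan$aa_index[r] <- codon_cursor + 1L
          parts <- c(parts, tpl$codon)
          codon_cursor <- codon_cursor + 1L
        }
        if (stats::runif(1) < 0.05) {  # occasional filler codon
          parts <- c(parts, paste(draw_background(3L, 0.5), collapse = ""))
          codon_cursor <- codon_cursor + 1L
        }
      }
      cds[g] <- paste(parts, collapse = "")
    }
    sub_pos <- vapply(plan$template,
                      function(t) VARIANT_TEMPLATES[[t]]$sub_pos, integer(1))
    plan$cds_pos <- 3L * (plan$aa_index - 1L) + ifelse(is.na(sub_pos), 1L,
                                                       sub_pos)

    # ---- ClinVar-style rows ------------------------------------------------
    n <- nrow(plan)
    tpls <- VARIANT_TEMPLATES[plan$template]
    ref_plus <- vapply(tpls, `[[`, character(1), "ref")
    alt_plus <- vapply(tpls, `[[`, character(1), "alt")
    minus <- strands[plan$gene_idx] == "-"
    ref_vcf <- ifelse(minus, DNA_COMPLEMENT[ref_plus], ref_plus)
    alt_vcf <- ifelse(minus, DNA_COMPLEMENT[alt_plus], alt_plus)
    gene_sym <- genes[plan$gene_idx]
    ref_aa <- vapply(tpls, `[[`, character(1), "ref_aa")
    alt_aa <- vapply(tpls, `[[`, character(1), "alt_aa")
    name <- sprintf("NM_%06d.1(%s):c.%d%s>%s (p.%s%d%s)",
                    plan$gene_idx, gene_sym, plan$cds_pos,
                    ref_plus, alt_plus, ref_aa, plan$aa_index, alt_aa)
    sig <- vapply(plan$bin, function(b) sample(SIG_STRINGS[[b]], 1L),
                  character(1))
    n_cond <- sample(0:3, n, replace = TRUE, prob = c(0.28, 0.4, 0.22, 0.1))
    phen <- vapply(n_cond, function(k) {
      if (k == 0L) "not provided" else {
        paste(sample(spec$conditions, k), collapse = "|")
      }
    }, character(1))
    variants <- data.frame(
      `#AlleleID` = seq_len(n), Type = "single nucleotide variant",
      Name = name, GeneSymbol = gene_sym, ClinicalSignificance = sig,
      `RS# (dbSNP)` = 100000L + seq_len(n), PhenotypeList = phen,
      Assembly = "GRCh38", ReferenceAlleleVCF = unname(ref_vcf),
      AlternateAlleleVCF = unname(alt_vcf),
      check.names = FALSE, stringsAsFactors = FALSE
    )

    # ---- decoys ------------------------------------------------------------
    decoy <- function(overrides) {
      row <- variants[1, ]
      row$`#AlleleID` <- NA_integer_
      for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
      row
    }
    next_id <- n
    new_id <- function() { next_id <<- next_id + 1L; next_id }
    decoys <- rbind(
      decoy(list(`#AlleleID` = new_id(), Type = "Deletion")),
      decoy(list(`#AlleleID` = new_id(), ReferenceAlleleVCF = "T",
                 AlternateAlleleVCF = "T")),
      decoy(list(`#AlleleID` = new_id(), AlternateAlleleVCF = "na")),
      decoy(list(`#AlleleID` = new_id(),
                 Name = sprintf("NM_000001.1(%s):c.10A>G", genes[1]))),
      decoy(list(`#AlleleID` = new_id(),
                 Name = sprintf("NM_000001.1(%s):c.12G>A (p.Leu4=)",
                                genes[1]))),
      decoy(list(`#AlleleID` = new_id(), GeneSymbol = "NOCCDS",
                 Name = "NM_999999.1(NOCCDS):c.4C>T (p.Arg2Cys)")),
      # reference amino acid not coded at the claimed codon
      decoy(list(`#AlleleID` = new_id(),
                 Name = sprintf("NM_000001.1(%s):c.%d%s>%s (p.His%d%s)",
                                gene_sym[1], plan$cds_pos[1], ref_plus[1],
                                alt_plus[1], plan$aa_index[1], alt_aa[1]))),
      # alternate amino acid unreachable by any allele-consistent edit
      decoy(list(`#AlleleID` = new_id(),
                 Name = sprintf("NM_000001.1(%s):c.%d%s>%s (p.%s%dTrp)",
                                gene_sym[1], plan$cds_pos[1], ref_plus[1],
                                alt_plus[1], ref_aa[1], plan$aa_index[1])))
    )
    dup_idx <- sample(n, min(spec$n_grch37_dups, n))
    grch37 <- variants[dup_idx, ]
    grch37$Assembly <- "GRCh37"
    variants <- rbind(variants, decoys, grch37)
    variants <- variants[sample(nrow(variants)), ]
    rownames(variants) <- NULL

    ccds <- stats::setNames(
      chartr("U", "T", cds),
      sprintf("CCDS%d.1|Hs38.1|%s", seq_len(spec$n_genes), genes)
    )

    predicted_keys <- sprintf("%s:%d", gene_sym[plan$predicted],
                              plan$cds_pos[plan$predicted])
    manifest <- list(
      n_exonic = spec$n_exonic,
      n_c2u = spec$n_c2u,
      c2u_bins = as.list(spec$c2u_bins),
      n_predicted = spec$n_predicted,
      predicted_bins = as.list(spec$predicted_bins),
      n_ambiguous = spec$n_ambiguous,
      predicted_sites = sort(predicted_keys),
      convention = convention,
      seed = seed
    )
    list(variants = variants, ccds = ccds, manifest = manifest)
  })
}

#' Write a variant fixture to disk
#'
#' @param fixture Result of [make_variant_table()].
#' @param dir Output directory (created if needed). Writes
#'   `variants.tsv`, `ccds.fa` and `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_variant_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    fixture$variants, file.path(dir, "variants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  fa <- file(file.path(dir, "ccds.fa"), "w")
  for (i in seq_along(fixture$ccds)) {
    writeLines(c(paste0(">", names(fixture$ccds)[i]), fixture$ccds[[i]]), fa)
  }
  close(fa)
  jsonlite::write_json(fixture$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
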