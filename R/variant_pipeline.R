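# ClinVar-style variant pipeline: parse, filter, validate against coding
# sequences, infer mRNA-level changes, bin significance, predict C>U
# editing sites and summarize proportions.

MANDATORY_COLUMNS <- c("Type", "Name", "GeneSymbol", "ClinicalSignificance",
                       "Assembly", "ReferenceAlleleVCF", "AlternateAlleleVCF")

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Parse a ClinVar `variant_summary`-style table
#'
#' Accepts a path to a tab-separated file or a data frame with
#' `variant_summary` column names. The protein change is parsed from the
#' HGVS `Name` field (`p.Ref###Alt` with three-letter codes, `Ter`/`*` for
#' stop, `=` for synonymous).
#'
#' @param x Path or data frame.
#' @return Data frame of records with normalized columns: `allele_id`,
#'   `gene`, `variant_type`, `assembly`, `ref_allele`, `alt_allele`,
#'   `significance_raw`, `conditions`, `rsid`, `name`, `p_ref`, `p_pos`,
#'   `p_alt` (NA where absent).
#' @export
parse_variant_summary <- function(x) {
  df <- if (is.character(x)) {
    utils::read.delim(x, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
  } else {
    as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)
  }
  missing <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- regmatches(
    df$Name,
    regexec("p\\.([A-Z][a-z]{2})(\\d+)(=|\\*|Ter|[A-Z][a-z]{2})", df$Name)
  )
  p_ref <- vapply(m, function(g) if (length(g)) g[2] else NA_character_,
                  character(1))
  p_pos <- vapply(m, function(g) if (length(g)) g[3] else NA_character_,
                  character(1))
  p_alt <- vapply(m, function(g) if (length(g)) g[4] else NA_character_,
                  character(1))
  p_alt[p_alt %in% "*"] <- "Ter"
  data.frame(
    allele_id = as.character(df[["#AlleleID"]] %||% seq_len(nrow(df))),
    gene = df$GeneSymbol,
    variant_type = df$Type,
    assembly = df$Assembly,
    ref_allele = toupper(df$ReferenceAlleleVCF),
    alt_allele = toupper(df$AlternateAlleleVCF),
    significance_raw = df$ClinicalSignificance,
    conditions = df$PhenotypeList %||% rep("not provided", nrow(df)),
    rsid = as.character(df[["RS# (dbSNP)"]] %||% rep(NA, nrow(df))),
    name = df$Name,
    p_ref = p_ref, p_pos = as.integer(p_pos), p_alt = p_alt,
    stringsAsFactors = FALSE
  )
}

#' Filter records to exonic non-synonymous GRCh38 SNPs
#'
#' Applies, in order: SNV type; GRCh38 assembly; duplicate-allele collapse
#' (first record per allele id); specific single-base alleles; not
#' like-to-like; protein change present and non-synonymous. Per-stage
#' in/out counts are attached as the `"filter_log"` attribute.
#'
#' @param records Parsed records from [parse_variant_summary()].
#' @return Filtered records (each stage's output is a subset of its input).
#' @export
filter_variants <- function(records) {
  log <- list()
  apply_stage <- function(df, stage, keep) {
    out <- df[keep, , drop = FALSE]
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, n_in = nrow(df), n_out = nrow(out),
      stringsAsFactors = FALSE
    )
    out
  }
  r <- records
  r <- apply_stage(r, "snv_type", r$variant_type == "single nucleotide variant")
  r <- apply_stage(r, "grch38", r$assembly == "GRCh38")
  r <- apply_stage(r, "dedup_allele", !duplicated(r$allele_id))
  r <- apply_stage(r, "specific_alleles",
                   r$ref_allele %in% c("A", "C", "G", "T") &
                     r$alt_allele %in% c("A", "C", "G", "T"))
  r <- apply_stage(r, "not_like_to_like", r$ref_allele != r$alt_allele)
  r <- apply_stage(r, "nonsynonymous_aa_change",
                   !is.na(r$p_ref) & !is.na(r$p_alt) &
                     r$p_alt != "=" & r$p_ref != r$p_alt)
  attr(r, "filter_log") <- do.call(rbind, log)
  r
}

# gene symbol for each CCDS record id (last pipe-delimited field, or the
# id itself for plain headers)
ccds_gene_map <- function(seqs) {
  ids <- vapply(seqs, function(s) s$id, character(1))
  genes <- vapply(strsplit(ids, "|", fixed = TRUE), function(p) {
    p[length(p)]
  }, character(1))
  stats::setNames(seqs, genes)
}

#' Validate one record against its coding sequence
#'
#' TRUE iff the standard-code translation of the codon at the recorded
#' amino-acid position equals the recorded reference amino acid. Positions
#' beyond the coding sequence are invalid.
#'
#' @param record Single-row record data frame.
#' @param cds A [nuc_sequence()] coding sequence for the record's gene.
#' @return Logical.
#' @export
validate_against_ccds <- function(record, cds) {
  if (3L * record$p_pos > nchar(cds$residues)) return(FALSE)
  identical(translate_codon(codon_at(cds, record$p_pos)), record$p_ref)
}

#' Infer the mRNA-level change of one record
#'
#' Enumerates the single-base substitutions of the reference codon whose
#' translation equals the recorded alternate amino acid, intersects them
#' with the genomic allele pair read on both strands (plus: ref>alt; minus:
#' complement(ref)>complement(alt)), and returns the unique survivor.
#' Multiple survivors are flagged ambiguous (excluded from the C>U set by
#' the caller); no survivor is an inconsistency.
#'
#' @param record Single-row validated record.
#' @param cds A [nuc_sequence()] coding sequence.
#' @return List of class `mrna_change`: `gene`, `cds_pos`, `ref_base`,
#'   `alt_base`, `is_c2u`, `ambiguous`, `status`
#'   (`"ok"`/`"ambiguous"`/`"inconsistent"`).
#' @export
infer_mrna_change <- function(record, cds) {
  codon <- codon_at(cds, record$p_pos)
  bases <- strsplit(codon$bases, "", fixed = TRUE)[[1]]
  ref_rna <- chartr("T", "U", record$ref_allele)
  alt_rna <- chartr("T", "U", record$alt_allele)
  # allowed mRNA substitution under the two strand interpretations
  allowed <- unique(rbind(
    c(ref_rna, alt_rna),
    c(RNA_COMPLEMENT[[ref_rna]], RNA_COMPLEMENT[[alt_rna]])
  ))
  hits <- list()
  for (pos in 1:3) {
    for (k in seq_len(nrow(allowed))) {
      if (bases[pos] != allowed[k, 1]) next
      mut <- bases
      mut[pos] <- allowed[k, 2]
      if (translate_codon(paste(mut, collapse = "")) == record$p_alt) {
        hits[[length(hits) + 1L]] <- c(pos = pos, ref = allowed[k, 1],
                                       alt = allowed[k, 2])
      }
    }
  }
  keys <- vapply(hits, paste, character(1), collapse = "")
  hits <- hits[!duplicated(keys)]
  status <- if (length(hits) == 0L) "inconsistent"
            else if (length(hits) > 1L) "ambiguous" else "ok"
  if (status != "ok") {
    return(structure(
      list(gene = record$gene, cds_pos = NA_integer_,
           ref_base = NA_character_, alt_base = NA_character_,
           is_c2u = FALSE, ambiguous = status == "ambiguous",
           status = status),
      class = "mrna_change"
    ))
  }
  h <- hits[[1]]
  cds_pos <- 3L * (record$p_pos - 1L) + as.integer(h[["pos"]])
  structure(
    list(gene = record$gene, cds_pos = cds_pos,
         ref_base = h[["ref"]], alt_base = h[["alt"]],
         is_c2u = h[["ref"]] == "C" && h[["alt"]] == "U",
         ambiguous = FALSE, status = "ok"),
    class = "mrna_change"
  )
}

#' Bin a clinical-significance tag
#'
#' Case-insensitive word-boundary match: a tag containing the word
#' "pathogenic" bins as pathogenic; otherwise one containing "benign" bins
#' as benign; anything else is unspecified. Word matching keeps
#' "Conflicting interpretations of pathogenicity" out of the pathogenic bin.
#'
#' @param tag Character vector of significance strings.
#' @return Factor with levels `pathogenic`, `benign`, `unspecified`.
#' @export
bin_significance <- function(tag) {
  low <- tolower(tag)
  out <- ifelse(grepl("\\bpathogenic\\b", low), "pathogenic",
                ifelse(grepl("\\bbenign\\b", low), "benign", "unspecified"))
  factor(out, levels = c("pathogenic", "benign", "unspecified"))
}

#' Run the full variant pipeline
#'
#' Parses and filters the variant table, excludes genes without a usable
#' coding sequence, validates each record's reference codon, infers the
#' mRNA change, bins significance, scores every C>U site with the selected
#' model and summarizes proportions across the three nested sets (exonic,
#' C>U, predicted).
#'
#' @param variants Path or data frame (`variant_summary` dialect).
#' @param ccds Path to a CCDS-style FASTA, a list of [nuc_sequence()]s, or
#'   a named character vector of sequences.
#' @param model `"union"` (default), `"intersection"`, `"rules"` or `"rf"`.
#' @param rf_model A trained [train_rf()] model; required unless
#'   `model = "rules"`.
#' @param convention Loop convention for the rules model.
#' @return List with `exonic` (analyzed records incl. bins and mRNA
#'   change), `c2u` (the C>U subset), `predictions` (per-C>U-site model
#'   outputs incl. the `predicted` call), `summary` (see
#'   [summarize_variant_sets()]) and `log` (filter and exclusion counts).
#' @export
run_variant_pipeline <- function(variants, ccds,
                                 model = c("union", "intersection",
                                           "rules", "rf"),
                                 rf_model = NULL,
                                 convention = "three_prime") {
  model <- match.arg(model)
  if (model != "rules" && is.null(rf_model)) {
    stop("model '", model, "' needs a trained random forest (rf_model); ",
         "train one with train_rf() or use model = 'rules'", call. = FALSE)
  }
  records <- if (is.data.frame(variants) && "p_ref" %in% names(variants)) {
    variants
  } else {
    parse_variant_summary(variants)
  }
  records <- filter_variants(records)
  log <- list(filter = attr(records, "filter_log"))

  seqs <- if (is.character(ccds) && length(ccds) == 1L && file.exists(ccds)) {
    read_fasta(ccds)
  } else if (is.character(ccds)) {
    lapply(stats::setNames(names(ccds), names(ccds)), function(id) {
      nuc_sequence(id, ccds[[id]])
    })
  } else {
    ccds
  }
  by_gene <- ccds_gene_map(seqs)

  has_cds <- records$gene %in% names(by_gene)
  log$genes_without_cds <- sort(unique(records$gene[!has_cds]))
  records <- records[has_cds, , drop = FALSE]

  valid <- vapply(seq_len(nrow(records)), function(i) {
    validate_against_ccds(records[i, ], by_gene[[records$gene[i]]])
  }, logical(1))
  log$n_invalid_codon <- sum(!valid)
  records <- records[valid, , drop = FALSE]

  changes <- lapply(seq_len(nrow(records)), function(i) {
    infer_mrna_change(records[i, ], by_gene[[records$gene[i]]])
  })
  status <- vapply(changes, function(ch) ch$status, character(1))
  log$n_inconsistent <- sum(status == "inconsistent")
  log$n_ambiguous <- sum(status == "ambiguous")
  keep <- status != "inconsistent"
  records <- records[keep, , drop = FALSE]
  changes <- changes[keep]

  records$bin <- bin_significance(records$significance_raw)
  records$cds_pos <- vapply(changes, function(ch) ch$cds_pos, integer(1))
  records$ref_base <- vapply(changes, function(ch) ch$ref_base, character(1))
  records$alt_base <- vapply(changes, function(ch) ch$alt_base, character(1))
  records$is_c2u <- vapply(changes, function(ch) ch$is_c2u, logical(1))
  records$ambiguous <- vapply(changes, function(ch) ch$ambiguous, logical(1))

  c2u <- records[records$is_c2u, , drop = FALSE]
  predictions <- predict_c2u_sites(c2u, by_gene, model, rf_model, convention)
  summary <- summarize_variant_sets(records, c2u, predictions)
  list(exonic = records, c2u = c2u, predictions = predictions,
       summary = summary, log = log, model = model)
}

#' Score the C>U set with the selected model
#'
#' @param c2u C>U records (with `gene` and `cds_pos`).
#' @param ccds_by_gene Named list of [nuc_sequence()]s keyed by gene.
#' @param model,rf_model,convention See [run_variant_pipeline()].
#' @return [site_predictions()] data frame plus a `predicted` column for
#'   the selected model.
#' @export
predict_c2u_sites <- function(c2u, ccds_by_gene,
                              model = c("union", "intersection",
                                        "rules", "rf"),
                              rf_model = NULL, convention = "three_prime") {
  model <- match.arg(model)
  n <- nrow(c2u)
  windows <- lapply(seq_len(n), function(i) {
    cds <- ccds_by_gene[[c2u$gene[i]]]
    base <- substr(cds$residues, c2u$cds_pos[i], c2u$cds_pos[i])
    if (base != "C") {
      stop("C>U site ", c2u$gene[i], ":", c2u$cds_pos[i],
           " does not sit on a C in the coding sequence", call. = FALSE)
    }
    extract_window(cds, c2u$cds_pos[i])
  })
  rules_total <- vapply(windows, function(w) {
    tot <- rules_total_string(window_string(w), convention)
    if (is.na(tot)) NA_integer_ else as.integer(tot)
  }, integer(1))
  rf_prob <- if (!is.null(rf_model) && n > 0L) {
    predict_prob(rf_model, windows)
  } else {
    rep(NA_real_, n)
  }
  preds <- site_predictions(
    gene = c2u$gene, c_pos = c2u$cds_pos,
    rules_total = rules_total,
    rf_prob = ifelse(is.na(rf_prob), 0, rf_prob)
  )
  preds$rf_prob[is.na(rf_prob)] <- NA_real_
  preds$predicted <- switch(model,
    union = preds$union, intersection = preds$intersection,
    rules = preds$rules_call, rf = preds$rf_call
  )
  preds$allele_id <- c2u$allele_id
  preds$bin <- c2u$bin
  preds
}

#' Summarize proportions across the nested variant sets
#'
#' Counts and percentages (half-up, one decimal, recomputed from counts)
#' per pathogenicity bin for the exonic, C>U and predicted sets, plus the
#' per-bin prediction rate (predicted C>U variants as a percentage of each
#' C>U bin).
#'
#' @param exonic,c2u Record data frames with a `bin` column.
#' @param predictions Prediction table with `predicted` and `bin`.
#' @return List with `table` (set, bin, n, pct), `totals` (named sizes) and
#'   `rates` (bin, n_predicted, pct_of_bin). Empty sets yield `NA`
#'   percentages.
#' @export
summarize_variant_sets <- function(exonic, c2u, predictions) {
  bins <- c("pathogenic", "benign", "unspecified")
  predicted <- predictions[predictions$predicted, , drop = FALSE]
  count_set <- function(df, set) {
    n_tot <- nrow(df)
    n <- vapply(bins, function(b) sum(df$bin == b), numeric(1))
    data.frame(
      set = set, bin = bins, n = as.integer(n),
      pct = if (n_tot == 0) NA_real_ else round_half_up(100 * n / n_tot, 1),
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(count_set(exonic, "exonic"), count_set(c2u, "c2u"),
               count_set(predicted, "predicted"))
  c2u_n <- vapply(bins, function(b) sum(c2u$bin == b), numeric(1))
  pred_n <- vapply(bins, function(b) sum(predicted$bin == b), numeric(1))
  rates <- data.frame(
    bin = bins, n_predicted = as.integer(pred_n),
    pct_of_bin = ifelse(c2u_n == 0, NA_real_,
                        round_half_up(100 * pred_n / c2u_n, 1)),
    stringsAsFactors = FALSE
  )
  totals <- c(exonic = nrow(exonic), c2u = nrow(c2u),
              predicted = nrow(predicted))
  pct_c2u_of_exonic <- if (nrow(exonic) == 0) NA_real_ else {
    round_half_up(100 * nrow(c2u) / nrow(exonic), 1)
  }
  pct_predicted_of_c2u <- if (nrow(c2u) == 0) NA_real_ else {
    round_half_up(100 * nrow(predicted) / nrow(c2u), 1)
  }
  list(table = tab, totals = totals, rates = rates,
       pct_c2u_of_exonic = pct_c2u_of_exonic,
       pct_predicted_of_c2u = pct_predicted_of_c2u)
}
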