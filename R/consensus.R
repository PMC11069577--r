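# Union / intersection consensus of the two primary models.

#' Combine rules-based and random-forest calls
#'
#' Pure set operations over positive sites: the union model returns sites
#' called by either primary model, the intersection model only sites called
#' by both.
#'
#' @param rules_calls,rf_calls Named logical vectors over the same site
#'   universe (names are site ids, e.g. `"GENE:123"`).
#' @param mode `"union"` or `"intersection"`.
#' @return Character vector of positive site ids.
#' @export
combine_calls <- function(rules_calls, rf_calls,
                          mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.null(names(rules_calls)) || is.null(names(rf_calls))) {
    stop("calls must be named by site id", call. = FALSE)
  }
  missing_rf <- setdiff(names(rules_calls), names(rf_calls))
  missing_rules <- setdiff(names(rf_calls), names(rules_calls))
  if (length(missing_rf) || length(missing_rules)) {
    stop("site universes differ; missing from rf: ",
         paste(utils::head(missing_rf, 5), collapse = ", "),
         "; missing from rules: ",
         paste(utils::head(missing_rules, 5), collapse = ", "),
         call. = FALSE)
  }
  rf_calls <- rf_calls[names(rules_calls)]
  pos <- if (mode == "union") rules_calls | rf_calls else rules_calls & rf_calls
  names(rules_calls)[pos]
}

#' Per-site prediction table across all models
#'
#' @param gene,c_pos Site identity vectors.
#' @param rules_total Integer rules totals (`NA` = no-structure sentinel).
#' @param rf_prob Random-forest probabilities.
#' @return Data frame with per-model calls; by construction
#'   `union = rules_call | rf_call` and
#'   `intersection = rules_call & rf_call`.
#' @export
site_predictions <- function(gene, c_pos, rules_total, rf_prob) {
  stopifnot(length(gene) == length(c_pos),
            length(gene) == length(rules_total),
            length(gene) == length(rf_prob))
  rules_call <- rules_classify(rules_total)
  rf_call <- ml_classify(rf_prob)
  data.frame(
    gene = gene, c_pos = as.integer(c_pos),
    rules_score = rules_total, rules_call = rules_call,
    rf_prob = rf_prob, rf_call = rf_call,
    union = rules_call | rf_call,
    intersection = rules_call & rf_call,
    stringsAsFactors = FALSE
  )
}
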