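# MeSH-style hierarchy rollup.
#
# The hierarchy is a table of terms with dotted tree numbers (e.g.
# C10.228.140). Condition strings are mapped to terms by an input mapping
# table (curated externally; a qualifier column, when present and
# non-empty, invalidates the mapping). Conditions that map to no term roll
# up to the reserved pseudo-term "Not found", treated as top-level.

NOT_FOUND <- "Not found"

#' Load and validate a term hierarchy
#'
#' @param x Path to a TSV or a data frame with columns `term_id`, `name`
#'   and `tree_numbers` (semicolon-separated dotted paths).
#' @return Object of class `mesh_hierarchy` with `terms` (the input table),
#'   `tree` (long table tree_number/term_id) and fast lookup maps. Every
#'   non-top tree number must have a parent prefix present (orphans are
#'   rejected).
#' @export
load_hierarchy <- function(x) {
  df <- if (is.character(x)) {
    utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term_id", "name", "tree_numbers") %in% names(df)))
  if (anyDuplicated(df$term_id)) {
    stop("duplicate term ids in hierarchy", call. = FALSE)
  }
  tn_list <- strsplit(df$tree_numbers, ";", fixed = TRUE)
  tree <- data.frame(
    tree_number = trimws(unlist(tn_list)),
    term_id = rep(df$term_id, lengths(tn_list)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tree$tree_number)) {
    stop("tree number assigned to more than one term", call. = FALSE)
  }
  depth <- lengths(strsplit(tree$tree_number, ".", fixed = TRUE))
  parent <- vapply(strsplit(tree$tree_number, ".", fixed = TRUE),
                   function(p) paste(p[-length(p)], collapse = "."),
                   character(1))
  orphan <- depth > 1L & !(parent %in% tree$tree_number)
  if (any(orphan)) {
    stop("orphan tree number(s) without a parent: ",
         paste(utils::head(tree$tree_number[orphan], 5), collapse = ", "),
         call. = FALSE)
  }
  tree$depth <- depth
  structure(
    list(terms = df, tree = tree,
         term_of_tn = stats::setNames(tree$term_id, tree$tree_number),
         tns_of_term = split(tree$tree_number, tree$term_id)),
    class = "mesh_hierarchy"
  )
}

#' Level of a term (minimum tree-number depth)
#' @param h A [load_hierarchy()] object.
#' @param term_id Term id (or `"Not found"`, level 1).
#' @return Integer level (1 = top).
#' @export
mesh_level <- function(h, term_id) {
  if (term_id == NOT_FOUND) return(1L)
  tns <- h$tns_of_term[[term_id]]
  if (is.null(tns)) stop("unknown term: ", term_id, call. = FALSE)
  min(lengths(strsplit(tns, ".", fixed = TRUE)))
}

#' Top-level ancestors of a term
#'
#' The union, over all of the term's tree numbers, of the terms owning the
#' top-level prefix of each number. `"Not found"` is its own (pseudo)
#' top-level heading.
#'
#' @param h A [load_hierarchy()] object.
#' @param term_id Term id.
#' @return Character vector of top-level term ids.
#' @export
ancestors_to_top <- function(h, term_id) {
  if (term_id == NOT_FOUND) return(NOT_FOUND)
  tns <- h$tns_of_term[[term_id]]
  if (is.null(tns)) stop("unknown term: ", term_id, call. = FALSE)
  tops <- unique(vapply(strsplit(tns, ".", fixed = TRUE), `[[`, character(1),
                        1L))
  unique(unname(h$term_of_tn[tops]))
}

# conditions -> term ids using the mapping table; unmapped or qualified
# mappings go to "Not found"
map_conditions <- function(conditions, mapping) {
  stopifnot(all(c("condition", "term_id") %in% names(mapping)))
  term <- stats::setNames(mapping$term_id, mapping$condition)
  if ("qualifier" %in% names(mapping)) {
    qual <- !is.na(mapping$qualifier) & nzchar(mapping$qualifier)
    term[mapping$condition[qual]] <- NOT_FOUND
  }
  out <- unname(term[conditions])
  out[is.na(out) | !nzchar(out)] <- NOT_FOUND
  out
}

#' Count top-level headings across variants
#'
#' Maps each variant's conditions to terms, rolls them up to top-level
#' headings, deduplicates the headings per variant (a heading counts at
#' most once per SNP even when several of its conditions fall under it) and
#' tallies.
#'
#' @param variants Data frame with `allele_id` and `conditions`
#'   (`|`-separated condition strings; `"not provided"` or empty = none).
#' @param mapping Data frame `condition`, `term_id` (optional `qualifier`).
#' @param h A [load_hierarchy()] object.
#' @return Data frame `heading` (top-level term id), `count`, sorted by
#'   decreasing count. Variants without conditions contribute nothing.
#' @export
count_headings <- function(variants, mapping, h) {
  per_variant <- lapply(seq_len(nrow(variants)), function(i) {
    raw <- variants$conditions[i]
    if (is.na(raw) || !nzchar(raw) || raw == "not provided") {
      return(character(0))
    }
    conds <- strsplit(raw, "|", fixed = TRUE)[[1]]
    terms <- unique(map_conditions(conds, mapping))
    unique(unlist(lapply(terms, ancestors_to_top, h = h)))
  })
  tally <- table(unlist(per_variant))
  out <- data.frame(
    heading = names(tally),
    count = as.integer(tally),
    stringsAsFactors = FALSE
  )
  out[order(-out$count, out$heading), , drop = FALSE]
}

#' Heading counts per site set and pathogenicity bin
#'
#' @param variants Data frame with `allele_id`, `conditions`, `bin` and a
#'   logical `predicted` column (sites in the predicted set).
#' @param mapping,h See [count_headings()].
#' @return Data frame with columns `set` (`c2u_set` / `predicted_set`),
#'   `scope` (`all` or a bin), `heading`, `count`.
#' @export
heading_count_table <- function(variants, mapping, h) {
  scopes <- c("all", "pathogenic", "benign", "unspecified")
  sets <- list(c2u_set = variants,
               predicted_set = variants[variants$predicted, , drop = FALSE])
  out <- list()
  for (set_name in names(sets)) {
    df <- sets[[set_name]]
    for (sc in scopes) {
      sub <- if (sc == "all") df else df[df$bin == sc, , drop = FALSE]
      if (nrow(sub) == 0L) next
      cnt <- count_headings(sub, mapping, h)
      if (nrow(cnt) == 0L) next
      cnt$set <- set_name
      cnt$scope <- sc
      out[[length(out) + 1L]] <- cnt
    }
  }
  if (length(out) == 0L) {
    return(data.frame(heading = character(0), count = integer(0),
                      set = character(0), scope = character(0)))
  }
  do.call(rbind, out)[, c("set", "scope", "heading", "count")]
}

#' Third-level ("individual disease") coverage under a term
#'
#' Third-level descendants (grandchildren of top-level terms) proxy
#' individual diseases. A third-level term is covered by the predicted set
#' if at least one predicted site maps to it or to any of its descendants;
#' covered by C>U-only if a C>U site (but no predicted site) maps likewise.
#'
#' @param h A [load_hierarchy()] object.
#' @param term_id Top- or second-level term whose grandchild/child
#'   third-level terms are enumerated.
#' @param c2u_terms Term ids that C>U SNPs map to (directly).
#' @param predicted_terms Term ids that predicted editing sites map to.
#' @return List with `n_terms`, `pct_predicted`, `pct_c2u_only` (NA
#'   percentages when the term has no third-level descendants).
#' @export
third_level_coverage <- function(h, term_id, c2u_terms, predicted_terms) {
  tns <- h$tns_of_term[[term_id]]
  if (is.null(tns)) stop("unknown term: ", term_id, call. = FALSE)
  third <- unique(unlist(lapply(tns, function(tn) {
    cand <- h$tree$tree_number[h$tree$depth == 3L]
    cand[startsWith(cand, paste0(tn, "."))]
  })))
  if (length(third) == 0L) {
    return(list(n_terms = 0L, pct_predicted = NA_real_,
                pct_c2u_only = NA_real_))
  }
  covers <- function(site_terms, third_tn) {
    # a site covers the third-level term if one of its term's tree numbers
    # equals the term's number or extends it
    site_tns <- unlist(h$tns_of_term[intersect(site_terms,
                                               names(h$tns_of_term))])
    any(site_tns == third_tn | startsWith(site_tns, paste0(third_tn, ".")))
  }
  pred_cov <- vapply(third, covers, logical(1), site_terms = predicted_terms)
  c2u_cov <- vapply(third, covers, logical(1), site_terms = c2u_terms)
  list(
    n_terms = length(third),
    pct_predicted = round_half_up(100 * mean(pred_cov), 1),
    pct_c2u_only = round_half_up(100 * mean(c2u_cov & !pred_cov), 1)
  )
}

# Fixture ----------------------------------------------------------------------

#' Generate a toy hierarchy and condition mapping
#'
#' A complete `branching`-ary tree of the requested depth with dotted tree
#' numbers, plus a condition list mapped to random terms; a configurable
#' handful of conditions is left unmapped (rolling up to "Not found").
#'
#' @param depth Levels in the hierarchy (>= 3).
#' @param branching Children per node.
#' @param n_conditions Conditions to emit.
#' @param n_unmapped Conditions left out of the mapping.
#' @param seed Seed.
#' @return List with `hierarchy` and `mapping` data frames plus a
#'   `manifest` (top-level ids, per-level term counts).
#' @export
make_mesh_fixture <- function(depth = 3L, branching = 2L, n_conditions = 12L,
                              n_unmapped = 2L, seed = 1L) {
  stopifnot(depth >= 3L, branching >= 1L, n_unmapped <= n_conditions)
  with_seed(seed, {
    tns <- paste0("C", sprintf("%02d", seq_len(branching)))
    all_tns <- tns
    level_tns <- list(tns)
    for (d in seq_len(depth - 1L)) {
      tns <- unlist(lapply(tns, function(p) {
        paste0(p, ".", sprintf("%03d", seq_len(branching) * 100L))
      }))
      level_tns[[d + 1L]] <- tns
      all_tns <- c(all_tns, tns)
    }
    hierarchy <- data.frame(
      term_id = sprintf("T%04d", seq_along(all_tns)),
      name = paste("Term", all_tns),
      tree_numbers = all_tns,
      stringsAsFactors = FALSE
    )
    conditions <- paste("Condition", seq_len(n_conditions))
    mapped <- seq_len(n_conditions - n_unmapped)
    mapping <- data.frame(
      condition = conditions[mapped],
      term_id = sample(hierarchy$term_id, length(mapped), replace = TRUE),
      qualifier = "",
      stringsAsFactors = FALSE
    )
    manifest <- list(
      depth = depth, branching = branching,
      n_terms_per_level = lengths(level_tns),
      top_terms = hierarchy$term_id[seq_len(branching)],
      unmapped_conditions = conditions[setdiff(seq_len(n_conditions),
                                               mapped)]
    )
    list(hierarchy = hierarchy, mapping = mapping, manifest = manifest)
  })
}
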