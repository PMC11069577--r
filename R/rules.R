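# Rules-based stem-loop model.
#
# A cytosine scores if it sits at a configured terminus of the loop of a
# hairpin with a 3-4 nt loop. The stem is extended pairwise outward from the
# loop boundary over Watson-Crick pairs (G.C = 3 points, A.U = 1 point; G.U
# wobble counts as a mismatch). A single mismatch or bulge is tolerated at
# the position two nucleotides 5' of the scored cytosine -- in sequence
# space; when that position falls inside the loop under the active loop
# convention the allowance is disabled. Sequence bonuses: +2 (once) for a
# uracil among the non-C loop residues or a purine immediately 5' of the
# cytosine; -2 for a guanine among the non-C loop residues. A site is called
# an editing site when its best total exceeds 9.

C_POS_IN_WINDOW <- 16L  # window string is 26 nt with the scored C at 16
MISMATCH_OFFSET <- 2L   # permitted mismatch/bulge: 2 nt 5' of the cytosine

RULES_THRESHOLD <- 9L   # call positive iff total > 9

# pair scores; anything not listed is a mismatch (incl. G.U wobble)
.pair_class <- function(a, b) {
  key <- paste0(a, b)
  if (key == "GC" || key == "CG") return("GC")
  if (key == "AU" || key == "UA") return("AU")
  "MM"
}

.loop_spans <- function(convention) {
  # spans in window coordinates (C at 16), loop lengths 3 then 4
  switch(convention,
    three_prime = list(c(14L, 16L), c(13L, 16L)),
    five_prime  = list(c(16L, 18L), c(16L, 19L)),
    stop("unknown loop convention: ", convention, call. = FALSE)
  )
}

# Enumerate maximal stem extensions for one loop placement.
# x: character vector of the 26-nt window; returns list of raw calls.
.extend_calls <- function(x, ls, le, allow_mm, max_stem) {
  n <- length(x)
  mm_pos <- C_POS_IN_WINDOW - MISMATCH_OFFSET
  out <- list()

  recurse <- function(i5, i3, p5, p3, cls, used) {
    extended <- FALSE
    npair <- length(cls)
    if (i5 >= 1L && i3 <= n && npair < max_stem) {
      pc <- .pair_class(x[i5], x[i3])
      if (pc != "MM") {
        recurse(i5 - 1L, i3 + 1L, c(p5, i5), c(p3, i3), c(cls, pc), used)
        extended <- TRUE
      }
    }
    if (!used && allow_mm && i5 == mm_pos && npair < max_stem) {
      if (i5 >= 1L && i3 <= n) {  # paired mismatch
        recurse(i5 - 1L, i3 + 1L, c(p5, i5), c(p3, i3), c(cls, "MM"), TRUE)
        extended <- TRUE
      }
      if (i5 >= 2L) {             # bulge on the 5' arm: skip x[i5]
        recurse(i5 - 1L, i3, p5, p3, cls, TRUE)
        extended <- TRUE
      }
      if (i3 <= n - 1L) {         # bulge on the 3' arm: skip x[i3]
        recurse(i5, i3 + 1L, p5, p3, cls, TRUE)
        extended <- TRUE
      }
    }
    if (!extended) {
      # prune trailing non-scoring elements
      keep <- length(cls)
      while (keep > 0L && cls[keep] == "MM") keep <- keep - 1L
      if (keep > 0L) {
        out[[length(out) + 1L]] <<- list(
          p5 = p5[seq_len(keep)], p3 = p3[seq_len(keep)],
          cls = cls[seq_len(keep)]
        )
      }
    }
  }

  recurse(ls - 1L, le + 1L, integer(0), integer(0), character(0), FALSE)
  out
}

#' Enumerate candidate stem-loops around a window's cytosine
#'
#' Considers loop lengths 3 and 4 with the cytosine at the loop terminus
#' fixed by `convention` (`"three_prime"`, the default, places the C at the
#' 3' end of the loop; `"five_prime"` at the 5' end). For each placement the
#' stem is extended outward; at the single permitted mismatch offset the
#' search branches into a paired mismatch, a 5'-arm bulge and a 3'-arm bulge,
#' each kept as a distinct call.
#'
#' @param window A [site_window()].
#' @param convention Loop-terminus convention.
#' @param max_stem Cap on the number of stem pairs (defensive; unreachable
#'   within a 26-nt window).
#' @return List of `stem_loop` call objects ordered by loop length
#'   (ascending), then stem length (descending), then 5'-most loop start.
#'   Empty when no stem of at least one pair exists.
#' @export
find_stem_loops <- function(window, convention = c("three_prime", "five_prime"),
                            max_stem = 15L) {
  convention <- match.arg(convention)
  x <- strsplit(window_string(window), "", fixed = TRUE)[[1]]
  mm_pos <- C_POS_IN_WINDOW - MISMATCH_OFFSET
  calls <- list()
  for (span in .loop_spans(convention)) {
    ls <- span[1]; le <- span[2]
    allow_mm <- mm_pos < ls  # disabled when the offset falls inside the loop
    raw <- .extend_calls(x, ls, le, allow_mm, max_stem)
    for (r in raw) {
      is_mm <- r$cls == "MM"
      calls[[length(calls) + 1L]] <- structure(
        list(
          loop_span = c(ls, le),
          loop_len = le - ls + 1L,
          arm5_span = if (length(r$p5)) range(r$p5) else c(NA_integer_, NA_integer_),
          arm3_span = if (length(r$p3)) range(r$p3) else c(NA_integer_, NA_integer_),
          pairs = data.frame(p5 = r$p5, p3 = r$p3, class = r$cls,
                             stringsAsFactors = FALSE),
          bulge_pos = if (any(is_mm)) r$p5[which(is_mm)[1]] else NA_integer_,
          n_gc = sum(r$cls == "GC"),
          n_au = sum(r$cls == "AU")
        ),
        class = "stem_loop"
      )
    }
  }
  # deduplicate identical calls arising from different branch paths
  keys <- vapply(calls, function(cl) {
    paste(cl$loop_span[1], cl$loop_span[2],
          paste(cl$pairs$p5, collapse = ","),
          paste(cl$pairs$p3, collapse = ","),
          paste(cl$pairs$class, collapse = ","), sep = "|")
  }, character(1))
  calls <- calls[!duplicated(keys)]
  ord <- order(
    vapply(calls, function(cl) cl$loop_len, integer(1)),
    -vapply(calls, function(cl) nrow(cl$pairs), integer(1)),
    vapply(calls, function(cl) cl$loop_span[1], integer(1))
  )
  calls[ord]
}

#' Stem strength score of a call
#'
#' `3 * (number of G.C pairs) + (number of A.U pairs)`; mismatches and bulges
#' contribute nothing.
#' @param call A `stem_loop` call.
#' @return Integer score.
#' @export
score_stem <- function(call) {
  stopifnot(inherits(call, "stem_loop"))
  3L * call$n_gc + call$n_au
}

#' Sequence bonus of a call
#'
#' +2 (awarded at most once) if a uracil appears among the loop residues
#' other than the scored cytosine, or if the residue immediately 5' of the
#' cytosine is a purine; -2 if a guanine appears among the non-C loop
#' residues. Both may apply, netting 0.
#'
#' @param call A `stem_loop` call.
#' @param window The [site_window()] the call was found in.
#' @return Integer in `{-2, 0, 2}`.
#' @export
sequence_bonus <- function(call, window) {
  stopifnot(inherits(call, "stem_loop"))
  x <- strsplit(window_string(window), "", fixed = TRUE)[[1]]
  loop_idx <- setdiff(seq(call$loop_span[1], call$loop_span[2]),
                      C_POS_IN_WINDOW)
  loop_res <- x[loop_idx]
  neighbor <- x[C_POS_IN_WINDOW - 1L]
  bonus <- 0L
  if ("U" %in% loop_res || neighbor %in% c("A", "G")) bonus <- bonus + 2L
  if ("G" %in% loop_res) bonus <- bonus - 2L
  bonus
}

#' Rules score of a site window
#'
#' The total is the maximum of `score_stem + sequence_bonus` over all
#' candidate calls; when no stem-loop exists the total is `NA` (the
#' no-structure sentinel, always classified negative). Ties are broken by
#' loop length 3 first, then longer stem, then 5'-most loop start (the
#' ordering of [find_stem_loops()]).
#'
#' @inheritParams find_stem_loops
#' @return Object of class `rules_score` with `stem_points`, `bonus`,
#'   `total` and `best_call`.
#' @export
rules_score <- function(window, convention = c("three_prime", "five_prime"),
                        max_stem = 15L) {
  convention <- match.arg(convention)
  calls <- find_stem_loops(window, convention, max_stem)
  if (length(calls) == 0L) {
    return(structure(
      list(stem_points = NA_integer_, bonus = NA_integer_,
           total = NA_integer_, best_call = NULL),
      class = "rules_score"
    ))
  }
  stems <- vapply(calls, score_stem, integer(1))
  bonuses <- vapply(calls, sequence_bonus, integer(1), window = window)
  totals <- stems + bonuses
  best <- which.max(totals)  # first maximum respects the call ordering
  structure(
    list(stem_points = stems[best], bonus = bonuses[best],
         total = totals[best], best_call = calls[[best]]),
    class = "rules_score"
  )
}

#' @export
print.rules_score <- function(x, ...) {
  if (is.na(x$total)) {
    cat("<rules_score> no stem-loop structure (sentinel)\n")
  } else {
    cat("<rules_score> total ", x$total, " (stem ", x$stem_points,
        ", bonus ", sprintf("%+d", x$bonus), "; ", x$best_call$n_gc,
        " GC + ", x$best_call$n_au, " AU, loop ", x$best_call$loop_len,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Rules-based classification
#'
#' A site is called an editing site when its total is defined and greater
#' than 9 (equivalently, an integer score of at least 10).
#'
#' @param score A `rules_score` object or a numeric total (NA = sentinel).
#' @return Logical call (vectorized over numeric totals).
#' @export
rules_classify <- function(score) {
  total <- if (inherits(score, "rules_score")) score$total else score
  !is.na(total) & total > RULES_THRESHOLD
}

#' Scan all cytosines of a coding sequence with the rules model
#'
#' @param seq A [nuc_sequence()].
#' @inheritParams find_stem_loops
#' @return Data frame with one row per cytosine: `gene`, `c_pos`, `score`
#'   (NA for no structure), `stem_gc`, `stem_au`, `bonus`, `loop_len` and
#'   `call` (0/1).
#' @export
rules_scan <- function(seq, convention = c("three_prime", "five_prime")) {
  convention <- match.arg(convention)
  pos <- c_positions(seq)
  rows <- lapply(pos, function(p) {
    rs <- rules_score(extract_window(seq, p), convention)
    data.frame(
      gene = seq$id, c_pos = p,
      score = rs$total,
      stem_gc = if (is.null(rs$best_call)) NA_integer_ else rs$best_call$n_gc,
      stem_au = if (is.null(rs$best_call)) NA_integer_ else rs$best_call$n_au,
      bonus = rs$bonus,
      loop_len = if (is.null(rs$best_call)) NA_integer_ else rs$best_call$loop_len,
      call = as.integer(rules_classify(rs)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows) %||% data.frame(
    gene = character(0), c_pos = integer(0), score = integer(0),
    stem_gc = integer(0), stem_au = integer(0), bonus = integer(0),
    loop_len = integer(0), call = integer(0)
  )
}

# Fast internal path: rules total for a 26-char window string.
# Used by generators and the variant pipeline where only the total matters.
rules_total_string <- function(wstr, convention = "three_prime",
                               max_stem = 15L) {
  x <- strsplit(wstr, "", fixed = TRUE)[[1]]
  mm_pos <- C_POS_IN_WINDOW - MISMATCH_OFFSET
  best <- NA_integer_
  for (span in .loop_spans(convention)) {
    ls <- span[1]; le <- span[2]
    allow_mm <- mm_pos < ls
    raw <- .extend_calls(x, ls, le, allow_mm, max_stem)
    if (length(raw) == 0L) next
    loop_idx <- setdiff(seq(ls, le), C_POS_IN_WINDOW)
    loop_res <- x[loop_idx]
    bonus <- 0L
    if ("U" %in% loop_res || x[C_POS_IN_WINDOW - 1L] %in% c("A", "G")) {
      bonus <- bonus + 2L
    }
    if ("G" %in% loop_res) bonus <- bonus - 2L
    for (r in raw) {
      tot <- 3L * sum(r$cls == "GC") + sum(r$cls == "AU") + bonus
      if (is.na(best) || tot > best) best <- tot
    }
  }
  best
}
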