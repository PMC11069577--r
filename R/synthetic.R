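# Synthetic labeled sites and benchmark sets.
#
# Positives emulate the preferred APOBEC3A/G substrate: the cytosine at the
# configured terminus of a 3-4 nt loop closed by a GC-rich stem, with a
# uracil planted in the loop. Negatives are background sequence around a
# cytosine, optionally rejection-sampled until the rules model scores them
# below threshold. Background composition is uniform (25% per base) at the
# default `background_gc = 0.5`.

#' Parameters of the planted stem-loop motif
#'
#' @param stem_len Number of stem pairs planted (>= 3; default 5).
#' @param gc_fraction Fraction of planted pairs that are G.C (default 0.7;
#'   the rest are A.U).
#' @param loop_len Loop length, 3 or 4.
#' @param plant_u_in_loop Place a uracil among the non-C loop residues.
#' @param background_gc G+C fraction of background sequence (0.5 = uniform).
#' @param reject_high_score_negatives Rejection-sample negatives until their
#'   rules total is below the call threshold.
#' @param max_reject Rejection cap per site (warn and emit the last draw
#'   beyond it).
#' @return Object of class `motif_params`.
#' @export
motif_params <- function(stem_len = 5L, gc_fraction = 0.7, loop_len = 3L,
                         plant_u_in_loop = TRUE, background_gc = 0.5,
                         reject_high_score_negatives = FALSE,
                         max_reject = 50L) {
  stopifnot(stem_len >= 3L, gc_fraction >= 0, gc_fraction <= 1,
            loop_len %in% c(3L, 4L), background_gc > 0, background_gc < 1)
  structure(
    list(stem_len = as.integer(stem_len), gc_fraction = gc_fraction,
         loop_len = as.integer(loop_len),
         plant_u_in_loop = isTRUE(plant_u_in_loop),
         background_gc = background_gc,
         reject_high_score_negatives = isTRUE(reject_high_score_negatives),
         max_reject = as.integer(max_reject)),
    class = "motif_params"
  )
}

# background bases with the requested G+C fraction (caller seeds the RNG)
draw_background <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Build a positive window: hairpin planted so the scored C sits at the
# configured loop terminus. Window coordinates: C at 16.
plant_positive_window <- function(params, convention = "three_prime",
                                  gene = "synth", c_pos = 16L) {
  x <- draw_background(26L, params$background_gc)
  ll <- params$loop_len
  if (convention == "three_prime") {
    ls <- 16L - ll + 1L
    le <- 16L
  } else {
    ls <- 16L
    le <- 16L + ll - 1L
  }
  loop_idx <- setdiff(ls:le, 16L)
  # loop residues: avoid G (penalty); optionally plant a U
  x[loop_idx] <- sample(c("A", "C"), length(loop_idx), replace = TRUE)
  if (params$plant_u_in_loop) x[sample(loop_idx, 1L)] <- "U"
  sl <- min(params$stem_len, ls - 1L, 26L - le)
  gc_pair <- stats::runif(sl) < params$gc_fraction
  for (j in seq_len(sl)) {
    pair <- if (gc_pair[j]) sample(c("G", "C")) else sample(c("A", "U"))
    x[ls - j] <- pair[1]
    x[le + j] <- pair[2]
  }
  x[16L] <- "C"
  site_window(gene, c_pos,
              paste(x[1:15], collapse = ""),
              paste(x[17:26], collapse = ""))
}

plant_negative_window <- function(params, convention = "three_prime",
                                  gene = "synth", c_pos = 16L) {
  draw <- function() {
    x <- draw_background(26L, params$background_gc)
    x[16L] <- "C"
    site_window(gene, c_pos,
                paste(x[1:15], collapse = ""),
                paste(x[17:26], collapse = ""))
  }
  w <- draw()
  if (params$reject_high_score_negatives) {
    tries <- 1L
    while (rules_classify(rules_total_string(window_string(w), convention))) {
      if (tries >= params$max_reject) {
        warning("rejection cap reached for a negative site; emitting last draw",
                call. = FALSE)
        break
      }
      w <- draw()
      tries <- tries + 1L
    }
  }
  w
}

#' Generate one labeled site
#'
#' Draws from the caller's RNG state; seed at the call site (or use
#' [make_benchmark()]).
#'
#' @param label `"editing"` or `"non_editing"`.
#' @param params A [motif_params()].
#' @param convention Loop-terminus convention for planting / rejection.
#' @param gene,c_pos Identity given to the generated window.
#' @return A [labeled_site()] with provenance `"synthetic"`.
#' @export
make_site <- function(label = c("editing", "non_editing"),
                      params = motif_params(),
                      convention = "three_prime",
                      gene = "synth", c_pos = 16L) {
  label <- match.arg(label)
  w <- if (label == "editing") {
    plant_positive_window(params, convention, gene, c_pos)
  } else {
    plant_negative_window(params, convention, gene, c_pos)
  }
  labeled_site(w, label, "synthetic")
}

#' Generate a seeded synthetic benchmark set
#'
#' @param n_pos Number of editing sites (>= 1).
#' @param ratio Negatives per positive (3 for a testing-style set, 468 for a
#'   proportional-style set).
#' @param params A [motif_params()].
#' @param seed Seed; identical seeds give identical sets.
#' @param convention Loop-terminus convention.
#' @return List of [labeled_site()]s, shuffled, with attributes `ratio` and
#'   `n_pos`.
#' @export
make_benchmark <- function(n_pos, ratio = 3, params = motif_params(),
                           seed = 1L, convention = "three_prime") {
  stopifnot(n_pos >= 1L)
  n_neg <- round(ratio * n_pos)
  with_seed(seed, {
    sites <- c(
      lapply(seq_len(n_pos), function(i) {
        make_site("editing", params, convention,
                  gene = sprintf("synthP%04d", i))
      }),
      lapply(seq_len(n_neg), function(i) {
        make_site("non_editing", params, convention,
                  gene = sprintf("synthN%05d", i))
      })
    )
    sites <- sites[sample(length(sites))]
    attr(sites, "ratio") <- ratio
    attr(sites, "n_pos") <- n_pos
    sites
  })
}
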