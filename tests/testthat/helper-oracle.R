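# Independent brute-force oracle for the rules model.
#
# Enumerates, for each loop placement, every stem length n and every
# mismatch/bulge option as explicit index arithmetic (no greedy extension,
# no recursion), scores each valid configuration with the published formula
# and takes the maximum. Shares no code with find_stem_loops().

oracle_pair_points <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
  if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(1)
  NA_real_
}

oracle_rules_total <- function(wstr, convention = "three_prime") {
  x <- strsplit(wstr, "", fixed = TRUE)[[1]]
  n <- length(x)
  cpos <- 16L
  mm_pos <- cpos - 2L
  loops <- if (convention == "three_prime") {
    list(c(14L, 16L), c(13L, 16L))
  } else {
    list(c(16L, 18L), c(16L, 19L))
  }
  best <- NA_real_
  for (lp in loops) {
    ls <- lp[1]; le <- lp[2]
    loop_res <- x[setdiff(ls:le, cpos)]
    bonus <- 0
    if ("U" %in% loop_res || x[cpos - 1L] %in% c("A", "G")) bonus <- bonus + 2
    if ("G" %in% loop_res) bonus <- bonus - 2
    k <- ls - mm_pos  # stem index whose 5' position is the permitted offset
    for (opt in c("none", "mm", "b5", "b3")) {
      if (opt != "none" && k < 1L) next
      for (nn in 1:25) {
        if (opt != "none" && nn < k) next  # option not engaged; same as none
        idx <- seq_len(nn)
        p5 <- ls - idx
        p3 <- le + idx
        if (opt == "b5") p5[idx >= k] <- p5[idx >= k] - 1L
        if (opt == "b3") p3[idx >= k] <- p3[idx >= k] + 1L
        if (min(p5) < 1L || max(p3) > n) break
        pts <- mapply(oracle_pair_points, x[p5], x[p3])
        if (opt == "mm") pts[k] <- 0
        if (any(is.na(pts))) break
        if (sum(pts > 0) >= 1) {  # at least one true pair
          tot <- sum(pts) + bonus
          if (is.na(best) || tot > best) best <- tot
        }
      }
    }
  }
  best
}

# random 26-nt window string with C fixed at position 16
rand_window_string <- function() {
  x <- sample(c("A", "C", "G", "U"), 26, replace = TRUE)
  x[16] <- "C"
  paste(x, collapse = "")
}

rand_site_window <- function(gene = "rnd") {
  x <- strsplit(rand_window_string(), "", fixed = TRUE)[[1]]
  site_window(gene, 16L, paste(x[1:15], collapse = ""),
              paste(x[17:26], collapse = ""))
}
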