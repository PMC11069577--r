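# Sequence input, normalization, window extraction and codon utilities.
#
# All sequences are held internally in the RNA alphabet {A,C,G,U}; DNA input
# (CCDS nucleotide FASTA) is converted on read. Coordinates are 1-based and
# inclusive on the coding sequence, matching HGVS "c." numbering.

RNA_ALPHABET <- c("A", "C", "G", "U")

# Amino-acid code tables -----------------------------------------------------

AA1_TO_AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)
AA3_TO_AA1 <- stats::setNames(names(AA1_TO_AA3), AA1_TO_AA3)

# RNA codon -> 3-letter amino acid, derived from the standard genetic code.
rna_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc1 <- Biostrings::GENETIC_CODE
      names(gc1) <- chartr("T", "U", names(gc1))
      tab <<- stats::setNames(unname(AA1_TO_AA3[gc1]), names(gc1))
    }
    tab
  }
})

# Constructors ---------------------------------------------------------------

#' Create a normalized RNA sequence
#'
#' @param id Sequence identifier (FASTA header token up to first whitespace).
#' @param residues Nucleotide string; `T` is converted to `U` and case is
#'   normalized. Ambiguity codes (N, R, Y, ...) are rejected.
#' @param source_alphabet `"DNA"` or `"RNA"`; inferred from the presence of
#'   `T` when missing.
#' @return An object of class `nuc_sequence` with fields `id`, `residues`
#'   and `source_alphabet`.
#' @export
nuc_sequence <- function(id, residues, source_alphabet = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  raw <- toupper(residues)
  if (nchar(raw) == 0L) {
    stop("empty sequence for record '", id, "'", call. = FALSE)
  }
  if (is.null(source_alphabet)) {
    source_alphabet <- if (grepl("T", raw, fixed = TRUE)) "DNA" else "RNA"
  }
  res <- chartr("T", "U", raw)
  bad <- regmatches(res, regexpr("[^ACGU]", res))
  if (length(bad) > 0L) {
    stop("record '", id, "' contains unsupported residue '", bad,
         "' (ambiguity codes are not accepted)", call. = FALSE)
  }
  structure(
    list(id = id, residues = res, source_alphabet = source_alphabet),
    class = "nuc_sequence"
  )
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat("<nuc_sequence> ", x$id, " (", nchar(x$residues), " nt, from ",
      x$source_alphabet, ")\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Reads a (possibly CCDS-style) nucleotide FASTA file and returns
#' RNA-normalized sequences. Record ids are the header token up to the first
#' whitespace; CCDS-style headers (`>CCDSn.n|Hs...|GENE`) keep the full
#' pipe-delimited token.
#'
#' @param path Path to a FASTA file.
#' @return A list of [nuc_sequence()] objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(Biostrings::width(set) == 0L)) {
    bad <- ids[Biostrings::width(set) == 0L][1L]
    stop("FASTA record '", bad, "' has a header but no sequence",
         call. = FALSE)
  }
  seqs <- unname(as.character(set))
  out <- lapply(seq_along(seqs), function(i) nuc_sequence(ids[i], seqs[i]))
  stats::setNames(out, ids)
}

# Windows --------------------------------------------------------------------

WINDOW_UP <- 15L
WINDOW_DOWN <- 10L

#' Construct a site window directly
#'
#' A site window is the unit consumed by both predictors: a cytosine with 15
#' upstream and 10 downstream nucleotides (5'->3'). Sides shorter than the
#' full width are padded with `U` and flagged.
#'
#' @param gene Gene / sequence identifier.
#' @param c_pos 1-based position of the cytosine in the coding sequence.
#' @param upstream,downstream Flanking residues (5'->3'), at most 15 / 10 nt
#'   before padding.
#' @param padded_up,padded_down Set automatically when a side was padded.
#' @return An object of class `site_window`.
#' @export
site_window <- function(gene, c_pos, upstream, downstream,
                        padded_up = NULL, padded_down = NULL) {
  upstream <- toupper(chartr("T", "U", upstream))
  downstream <- toupper(chartr("T", "U", downstream))
  if (nchar(upstream) > WINDOW_UP || nchar(downstream) > WINDOW_DOWN) {
    stop("window sides exceed 15 upstream / 10 downstream nucleotides",
         call. = FALSE)
  }
  if (grepl("[^ACGU]", upstream) || grepl("[^ACGU]", downstream)) {
    stop("window contains residues outside {A,C,G,U}", call. = FALSE)
  }
  pu <- padded_up %||% (nchar(upstream) < WINDOW_UP)
  pd <- padded_down %||% (nchar(downstream) < WINDOW_DOWN)
  up <- paste0(strrep("U", WINDOW_UP - nchar(upstream)), upstream)
  down <- paste0(downstream, strrep("U", WINDOW_DOWN - nchar(downstream)))
  structure(
    list(gene = gene, c_pos = as.integer(c_pos),
         upstream = up, downstream = down,
         padded_up = pu, padded_down = pd),
    class = "site_window"
  )
}

#' @export
print.site_window <- function(x, ...) {
  cat("<site_window> ", x$gene, " c.", x$c_pos, ": ",
      x$upstream, "[C]", x$downstream,
      if (x$padded_up || x$padded_down) " (padded)" else "", "\n", sep = "")
  invisible(x)
}

#' Full 26-nt window string (upstream + C + downstream)
#' @param window A [site_window()].
#' @return A 26-character string with the scored cytosine at position 16.
#' @export
window_string <- function(window) {
  paste0(window$upstream, "C", window$downstream)
}

#' 25-nt context string (upstream + downstream, C excluded)
#'
#' The representation used by the random-forest encoder and the pairwise
#' identity audit.
#' @param window A [site_window()].
#' @return A 25-character string.
#' @export
context_string <- function(window) {
  paste0(window$upstream, window$downstream)
}

#' Extract the window around a cytosine
#'
#' @param seq A [nuc_sequence()].
#' @param c_pos 1-based position; the residue there must be `C`.
#' @return A [site_window()]; sides truncated by the sequence ends are padded
#'   with `U` and flagged.
#' @export
extract_window <- function(seq, c_pos) {
  stopifnot(inherits(seq, "nuc_sequence"))
  n <- nchar(seq$residues)
  c_pos <- as.integer(c_pos)
  if (c_pos < 1L || c_pos > n) {
    stop("position ", c_pos, " out of range for '", seq$id, "' (length ", n,
         ")", call. = FALSE)
  }
  base <- substr(seq$residues, c_pos, c_pos)
  if (base != "C") {
    stop("residue at position ", c_pos, " of '", seq$id, "' is '", base,
         "', not C", call. = FALSE)
  }
  up <- substr(seq$residues, max(1L, c_pos - WINDOW_UP), c_pos - 1L)
  down <- substr(seq$residues, c_pos + 1L, min(n, c_pos + WINDOW_DOWN))
  site_window(seq$id, c_pos, up, down)
}

#' Positions of all cytosines in a sequence
#' @param seq A [nuc_sequence()].
#' @return Integer vector of 1-based positions.
#' @export
c_positions <- function(seq) {
  stopifnot(inherits(seq, "nuc_sequence"))
  which(strsplit(seq$residues, "", fixed = TRUE)[[1]] == "C")
}

# Codons ---------------------------------------------------------------------

#' Codon at an amino-acid position
#'
#' @param seq A [nuc_sequence()] coding sequence.
#' @param aa_index 1-based amino-acid position.
#' @return List with `bases` (3-nt string) and `aa_index`, class `codon`.
#'   A sequence length not divisible by 3 triggers a warning; trailing bases
#'   are ignored.
#' @export
codon_at <- function(seq, aa_index) {
  stopifnot(inherits(seq, "nuc_sequence"))
  aa_index <- as.integer(aa_index)
  if (aa_index < 1L) stop("aa_index must be >= 1", call. = FALSE)
  n <- nchar(seq$residues)
  if (n %% 3L != 0L) {
    warning("length of '", seq$id, "' (", n,
            ") is not a multiple of 3; trailing bases ignored", call. = FALSE)
  }
  if (3L * aa_index > n) {
    stop("aa_index ", aa_index, " beyond coding sequence '", seq$id,
         "' (", n %/% 3L, " codons)", call. = FALSE)
  }
  start <- 3L * (aa_index - 1L) + 1L
  structure(
    list(bases = substr(seq$residues, start, start + 2L),
         aa_index = aa_index),
    class = "codon"
  )
}

#' Translate a codon with the standard genetic code
#'
#' @param codon A `codon` object from [codon_at()] or a 3-nt RNA string.
#' @return Three-letter amino-acid code; stop codons return `"Ter"`.
#' @export
translate_codon <- function(codon) {
  bases <- if (inherits(codon, "codon")) codon$bases else {
    toupper(chartr("T", "U", codon))
  }
  if (nchar(bases) != 3L || grepl("[^ACGU]", bases)) {
    stop("not a valid RNA codon: '", bases, "'", call. = FALSE)
  }
  unname(rna_codon_table()[bases])
}
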