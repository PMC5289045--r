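# Shared low-level helpers: circular-coordinate arithmetic and sequence ops.
# All genome coordinates in this package are 1-based inclusive; a circular
# interval that wraps the origin is represented with end < start.

.datatable.aware <- TRUE

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' IUPAC ambiguity codes are complemented according to the standard table.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast scalar reverse complement for short patterns (avoids XString
# construction in hot loops).
rc_quick <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x), "")[[1]]),
        collapse = "")
}

# Normalize a raw sequence string: upcase, U -> T, validate alphabet.
normalize_dna <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- unique(strsplit(gsub(paste0("[", paste(IUPAC_DNA, collapse = ""), "]"),
                              "", x), "")[[1]])
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(bad, collapse = " ")), call. = FALSE)
  }
  x
}

# Map arbitrary (possibly <1 or >L) positions onto the circle [1, L].
wrap_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

# Length of a circular interval c(start, end) on a circle of size len.
circ_len <- function(iv, len) {
  if (iv[2] >= iv[1]) iv[2] - iv[1] + 1L else len - iv[1] + 1L + iv[2]
}

# Extract the (possibly wrapping) circular interval from a sequence string.
circ_extract <- function(seq, iv, len = nchar(seq)) {
  if (iv[2] >= iv[1]) {
    substr(seq, iv[1], iv[2])
  } else {
    paste0(substr(seq, iv[1], len), substr(seq, 1, iv[2]))
  }
}

# Substring of given width starting at pos on the circle.
circ_substr <- function(seq, pos, width, len = nchar(seq)) {
  end <- pos + width - 1L
  if (end <= len) {
    substr(seq, pos, end)
  } else {
    paste0(substr(seq, pos, len), substr(seq, 1, end - len))
  }
}

# Positions covered by a circular interval, in order.
circ_positions <- function(iv, len) {
  if (iv[2] >= iv[1]) seq.int(iv[1], iv[2]) else c(seq.int(iv[1], len), seq.int(1L, iv[2]))
}

# Does circular interval iv contain position p?
circ_contains <- function(iv, p, len) {
  if (iv[2] >= iv[1]) p >= iv[1] & p <= iv[2] else p >= iv[1] | p <= iv[2]
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483647)
}

vmessage <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}
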