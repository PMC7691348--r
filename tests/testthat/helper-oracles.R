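# Independent reference implementations used as oracles. These deliberately
# re-derive results with textbook dynamic programming / brute force and must
# stay independent of the package's alignment kernels.

# Textbook Smith-Waterman with affine gaps (full three-matrix DP, O(n*m)
# memory). Gap of length g scores gap_open + g * gap_extend.
sw_oracle <- function(a, b, match = 1L, mismatch = -1L, gap_open = -1L,
                      gap_extend = -1L) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(0L)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  NEG <- -1e9
  H <- matrix(0, la + 1L, lb + 1L)
  E <- matrix(NEG, la + 1L, lb + 1L)  # gap consuming a
  F <- matrix(NEG, la + 1L, lb + 1L)  # gap consuming b
  for (i in 2L:(la + 1L)) {
    for (j in 2L:(lb + 1L)) {
      E[i, j] <- max(E[i - 1L, j] + gap_extend,
                     H[i - 1L, j] + gap_open + gap_extend)
      F[i, j] <- max(F[i, j - 1L] + gap_extend,
                     H[i, j - 1L] + gap_open + gap_extend)
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
    }
  }
  as.integer(max(H))
}

# Brute-force re-translation oracle: apply substitutions to the full CDS and
# diff the translated proteins residue by residue.
translation_oracle <- function(subs, ref) {
  seq <- ref$sequence
  for (i in seq_len(nrow(subs))) {
    p <- subs$position[i] + 1L
    stopifnot(substr(seq, p, p) == subs$ref[i])
    substr(seq, p, p) <- subs$alt[i]
  }
  cds_old <- substr(ref$sequence, ref$cds_offset + 1L,
                    ref$cds_offset + ref$cds_length)
  cds_new <- substr(seq, ref$cds_offset + 1L,
                    ref$cds_offset + ref$cds_length)
  aa_old <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds_old),
                          no.init.codon = TRUE)), "")[[1L]]
  aa_new <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds_new),
                          no.init.codon = TRUE)), "")[[1L]]
  d <- which(aa_old != aa_new)
  tibble::tibble(ref_aa = aa_old[d], residue = d, alt_aa = aa_new[d],
                 label = paste0(aa_old[d], d, aa_new[d]))
}

# unit-cost edit distance oracle (base R, generalised Levenshtein)
edit_distance_oracle <- function(a, b) as.integer(utils::adist(a, b))
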