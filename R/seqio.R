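#' Read a FASTQ file into a read table
#'
#' Parses 4-line FASTQ records into the package's canonical read tibble.
#' Quality strings are length-checked but otherwise ignored: downstream
#' consensus calling is base-space and filters on read support, not base
#' quality. Parsed reads carry no ground-truth columns (those exist only on
#' simulated reads).
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id`, `bases` (upper-case, `ACGTN`
#'   alphabet) and `strand` (always `"+"` for parsed input).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), bases = character(),
                  strand = character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (truncated record at line ", 4L * (length(lines) %/% 4L) + 1L, ")")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", idx[bad[1L]],
         ": header does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", idx[bad[1L]] + 2L,
         ": separator line does not start with '+'")
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", idx[bad[1L]] + 3L,
         ": quality length differs from sequence length")
  }
  bad <- which(stringr::str_detect(seqs, "[^ACGTN]"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", idx[bad[1L]] + 1L,
         ": sequence contains characters outside ACGTN")
  }
  tibble(
    read_id = sub("^@", "", stringr::word(hdr, 1L)),
    bases = seqs,
    strand = "+"
  )
}

#' Write a read table to FASTQ
#'
#' @param reads Tibble with `read_id` and `bases` columns (e.g. from
#'   [simulate_reads()] or [read_fastq()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases") %in% names(reads)))
  qual <- strrep("I", nchar(reads$bases))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O returning plain tibbles.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with columns `name` and `bases`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = stringr::word(names(x), 1L),
         bases = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `name` and `bases` columns, or a named character
#'   vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble(name = names(seqs), bases = unname(seqs))
  }
  x <- Biostrings::DNAStringSet(setNames(seqs$bases, seqs$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reference gene
#'
#' The parental gene against which all variant calls are expressed.
#' Nucleotide coordinates are 0-based half-open internally; amino-acid
#' residues are reported 1-based (so `"A64E"` means residue 64).
#'
#' @param name Reference name.
#' @param sequence Nucleotide sequence (`ACGT`).
#' @param cds_offset 0-based index of the first codon base.
#' @param cds_length CDS length in nt; must be a multiple of 3 and the CDS
#'   must translate without internal stop codons.
#' @return An object of class `reference_gene`.
#' @export
reference_gene <- function(name, sequence,
                           cds_offset = 0L,
                           cds_length = 3L * (nchar(sequence) %/% 3L)) {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0L,
            !stringr::str_detect(sequence, "[^ACGT]"),
            cds_length %% 3L == 0L,
            cds_offset + cds_length <= nchar(sequence))
  ref <- structure(
    list(name = name, sequence = sequence,
         cds_offset = as.integer(cds_offset),
         cds_length = as.integer(cds_length)),
    class = "reference_gene")
  aa <- translate_cds(ref)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", internal, fixed = TRUE)) {
    stop("CDS contains an internal stop codon")
  }
  ref
}

#' @export
print.reference_gene <- function(x, ...) {
  cat("<reference_gene> ", x$name, ": ", nchar(x$sequence), " nt, CDS ",
      x$cds_offset, "..", x$cds_offset + x$cds_length, " (",
      x$cds_length %/% 3L, " codons)\n", sep = "")
  invisible(x)
}

#' Load a reference gene from FASTA
#'
#' @inheritParams read_fasta
#' @inheritParams reference_gene
#' @param which Record name to use; defaults to the first record.
#' @return A [reference_gene()] object.
#' @export
read_reference <- function(path, cds_offset = 0L, cds_length = NULL,
                           which = NULL) {
  fa <- read_fasta(path)
  if (!is.null(which)) fa <- filter(fa, .data$name == which)
  if (nrow(fa) == 0L) stop("no matching FASTA record in ", path)
  if (is.null(cds_length)) {
    cds_length <- 3L * ((nchar(fa$bases[1L]) - cds_offset) %/% 3L)
  }
  reference_gene(fa$name[1L], fa$bases[1L], cds_offset, cds_length)
}

#' Translate the CDS of a reference gene
#'
#' @param ref A [reference_gene()].
#' @return Single-letter amino-acid string (may end in `*`).
#' @export
translate_cds <- function(ref) {
  cds <- substr(ref$sequence, ref$cds_offset + 1L,
                ref$cds_offset + ref$cds_length)
  translate_nt(cds)
}

# translate an in-frame nucleotide string with the standard genetic code
translate_nt <- function(nt) {
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

#' Construct a mutation-call table
#'
#' Canonical representation of reference-relative differences. Positions are
#' 0-based on the reference nucleotide sequence. A substitution has one-base
#' `ref` and `alt`; an insertion has empty `ref` (the inserted bases sit
#' before reference position `position`); a deletion has empty `alt`.
#'
#' @param position Integer vector of 0-based reference positions.
#' @param ref,alt Character vectors of reference / alternative alleles.
#' @param support,fwd_support,rev_support Optional support fractions in
#'   `[0, 1]`.
#' @return A tibble with columns `position`, `kind`, `ref`, `alt` (and any
#'   support columns supplied).
#' @export
mutation_calls <- function(position = integer(), ref = character(),
                           alt = character(), support = NULL,
                           fwd_support = NULL, rev_support = NULL) {
  kind <- dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "substitution",
    nchar(ref) == 0L & nchar(alt) >= 1L ~ "insertion",
    nchar(ref) >= 1L & nchar(alt) == 0L ~ "deletion",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) stop("invalid ref/alt combination in mutation call")
  if (any(kind == "substitution" & ref == alt)) {
    stop("substitution with ref == alt")
  }
  out <- tibble(position = as.integer(position), kind = kind,
                ref = ref, alt = alt)
  if (!is.null(support)) out$support <- support
  if (!is.null(fwd_support)) out$fwd_support <- fwd_support
  if (!is.null(rev_support)) out$rev_support <- rev_support
  out
}

# canonical single-string key for a set of nt mutations (used for dedup)
mutation_key <- function(calls) {
  if (nrow(calls) == 0L) return("")
  k <- paste0(calls$position, ":", calls$ref, ">", calls$alt)
  paste(sort(k), collapse = ";")
}

#' Left-align indel calls against the reference
#'
#' Shifts insertions and deletions to their smallest equivalent reference
#' position so that equivalent calls deduplicate deterministically (the same
#' normalisation VCF uses). Substitutions pass through unchanged. The
#' operation is idempotent.
#'
#' @param calls A mutation-call tibble (see [mutation_calls()]).
#' @param ref_seq Reference nucleotide sequence (plain string) or a
#'   [reference_gene()].
#' @return The calls with indels left-aligned, re-sorted by position.
#' @export
left_align_indels <- function(calls, ref_seq) {
  if (inherits(ref_seq, "reference_gene")) ref_seq <- ref_seq$sequence
  if (nrow(calls) == 0L) return(calls)
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(calls))) {
    kind <- calls$kind[i]
    if (kind == "substitution") next
    p <- calls$position[i]
    if (kind == "deletion") {
      s <- strsplit(calls$ref[i], "", fixed = TRUE)[[1L]]
      len <- length(s)
      # shift while the base entering from the left equals the base leaving
      while (p > 0L && rc[p] == rc[p + len]) p <- p - 1L
      calls$position[i] <- p
      calls$ref[i] <- paste(rc[(p + 1L):(p + len)], collapse = "")
    } else {
      s <- strsplit(calls$alt[i], "", fixed = TRUE)[[1L]]
      while (p > 0L && rc[p] == s[length(s)]) {
        s <- c(rc[p], s[-length(s)])
        p <- p - 1L
      }
      calls$position[i] <- p
      calls$alt[i] <- paste(s, collapse = "")
    }
  }
  arrange(calls, .data$position, .data$kind, .data$alt)
}

#' Translate nucleotide mutation calls to amino-acid mutations
#'
#' Re-translates every codon affected by at least one substitution and
#' reports the differences in the usual `A64E` notation (1-based residue
#' numbers). Synonymous changes yield no amino-acid mutation; substitutions
#' outside the CDS are silent. Any indel inside the CDS makes the variant
#' untranslatable (frameshift) — the result is flagged rather than silently
#' dropped.
#'
#' @param nt_mutations Mutation-call tibble.
#' @param ref A [reference_gene()].
#' @return A tibble with columns `ref_aa`, `residue`, `alt_aa`, `label`,
#'   carrying attributes `translatable` (logical) and `reason` (`NA`,
#'   `"frameshift"`).
#' @export
translate_mutations <- function(nt_mutations, ref) {
  empty <- tibble(ref_aa = character(), residue = integer(),
                  alt_aa = character(), label = character())
  cds_lo <- ref$cds_offset
  cds_hi <- ref$cds_offset + ref$cds_length  # half-open
  if (nrow(nt_mutations) > 0L) {
    indel <- nt_mutations$kind != "substitution"
    in_cds_indel <- indel & nt_mutations$position >= cds_lo &
      nt_mutations$position < cds_hi
    if (any(in_cds_indel)) {
      attr(empty, "translatable") <- FALSE
      attr(empty, "reason") <- "frameshift"
      return(empty)
    }
  }
  subs <- filter(nt_mutations, .data$kind == "substitution",
                 .data$position >= cds_lo, .data$position < cds_hi)
  if (nrow(subs) == 0L) {
    attr(empty, "translatable") <- TRUE
    attr(empty, "reason") <- NA_character_
    return(empty)
  }
  rc <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  codon_idx <- (subs$position - cds_lo) %/% 3L  # 0-based codon index
  out <- purrr::map_dfr(sort(unique(codon_idx)), function(ci) {
    base0 <- cds_lo + 3L * ci  # first base of the codon, 0-based
    old <- rc[(base0 + 1L):(base0 + 3L)]
    new <- old
    rows <- which(codon_idx == ci)
    off <- subs$position[rows] - base0 + 1L
    if (any(old[off] != subs$ref[rows])) {
      stop("reference allele mismatch at position ",
           subs$position[rows[old[off] != subs$ref[rows]][1L]])
    }
    new[off] <- subs$alt[rows]
    aa_old <- translate_nt(paste(old, collapse = ""))
    aa_new <- translate_nt(paste(new, collapse = ""))
    if (aa_old == aa_new) return(NULL)
    tibble(ref_aa = aa_old, residue = ci + 1L, alt_aa = aa_new,
           label = paste0(aa_old, ci + 1L, aa_new))
  })
  if (nrow(out) == 0L) out <- empty
  attr(out, "translatable") <- TRUE
  attr(out, "reason") <- NA_character_
  out
}

#' Parse amino-acid mutation labels
#'
#' Inverse of the `A64E` rendering: splits labels into reference residue,
#' 1-based position and alternative residue.
#'
#' @param labels Character vector like `c("A64E", "R102S")`.
#' @return Tibble with columns `ref_aa`, `residue`, `alt_aa`, `label`.
#' @export
parse_aa_mutations <- function(labels) {
  labels <- labels[nzchar(labels)]
  if (length(labels) == 0L) {
    return(tibble(ref_aa = character(), residue = integer(),
                  alt_aa = character(), label = character()))
  }
  m <- stringr::str_match(labels, "^([A-Z*])(\\d+)([A-Z*])$")
  if (anyNA(m[, 1L])) {
    stop("unparseable amino-acid mutation label: ",
         labels[which(is.na(m[, 1L]))[1L]])
  }
  tibble(ref_aa = m[, 2L], residue = as.integer(m[, 3L]), alt_aa = m[, 4L],
         label = labels)
}

#' Generate a synthetic reference gene
#'
#' A random gene with a valid CDS (ATG start, no internal stop, TAA stop),
#' used by the simulator and the test-bench. With the default length the
#' gene matches the ~1.25 kb amplicons typical of single-gene directed
#' evolution.
#'
#' @param length_nt Total gene length in nt; the CDS is the largest multiple
#'   of 3 fitting at offset 0.
#' @param name Reference name.
#' @param seed Optional RNG seed for reproducibility.
#' @return A [reference_gene()].
#' @export
synthetic_reference <- function(length_nt = 1250L, name = "synthetic_ref",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_codon <- length_nt %/% 3L
  stopifnot(n_codon >= 3L)
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codon)
  codons[1L] <- "ATG"
  body <- random_dna(2L * (n_codon - 2L), 3L)  # oversample, drop stops
  body <- body[!body %in% stops]
  while (length(body) < n_codon - 2L) {
    extra <- random_dna(n_codon, 3L)
    body <- c(body, extra[!extra %in% stops])
  }
  codons[2L:(n_codon - 1L)] <- body[seq_len(n_codon - 2L)]
  codons[n_codon] <- "TAA"
  tail_n <- length_nt - 3L * n_codon
  seq <- paste0(paste(codons, collapse = ""),
                if (tail_n > 0L) random_dna(1L, tail_n) else "")
  reference_gene(name, seq, cds_offset = 0L, cds_length = 3L * n_codon)
}
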