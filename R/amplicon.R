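DNA_BASES <- c("A", "C", "G", "T")

valid_dna <- function(x) all(grepl("^[ACGT]*$", x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mismatches between two equal-length strings
nmismatch_str <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Two-step PCR primer design for diversified amplicon libraries
#'
#' Describes the primer layout of a 2-step PCR amplicon library: the first
#' PCR primers carry a target-hybridizing sequence, a diversifier of random
#' nucleotides (default 10 bp) that raises base diversity over the first
#' sequencing cycles for reliable cluster identification, and a portion of
#' the P5/P7 sequencing adapters; the second PCR extends the partial
#' adapters to the full P5/P7 sequences.
#'
#' The default adapter sequences are clearly labeled placeholders of
#' realistic length (29 and 24 nt); supply the real platform adapters and
#' panel primers via the arguments or a YAML design file for production
#' use.
#'
#' @param target_forward,target_reverse target-hybridizing primer sequences
#'   (given 5'->3' on their own strands).
#' @param full_p5,full_p7 full sequencing adapters; `partial_p5` /
#'   `partial_p7` must be suffixes of the corresponding full adapters.
#' @param partial_p5,partial_p7 adapter portions present after the first
#'   PCR.
#' @param diversifier_length number of random bases (default 10).
#' @param diversifier_both_ends logical; if `FALSE` only the P5 side
#'   carries a diversifier.
#' @return a `primer_design` list.
#' @export
primer_design <- function(
    target_forward = "ACGTGACCTGAAGGACGTTA",
    target_reverse = "TGGACCTAAGGTCAGCATCC",
    full_p5 = "AATGATACGGCGACCACCGAGATCTACA", # placeholder, 28 nt
    full_p7 = "CAAGCAGAAGACGGCATACGAGAT",     # placeholder, 24 nt
    partial_p5 = substr(full_p5, nchar(full_p5) - 15, nchar(full_p5)),
    partial_p7 = substr(full_p7, nchar(full_p7) - 11, nchar(full_p7)),
    diversifier_length = 10L,
    diversifier_both_ends = TRUE) {
  fields <- list(target_forward = target_forward,
                 target_reverse = target_reverse,
                 full_p5 = full_p5, full_p7 = full_p7,
                 partial_p5 = partial_p5, partial_p7 = partial_p7)
  for (nm in names(fields))
    if (!valid_dna(fields[[nm]]) || nchar(fields[[nm]]) == 0)
      stop(nm, " must be a non-empty string over A/C/G/T")
  if (!endsWith(full_p5, partial_p5))
    stop("partial_p5 must be a suffix of full_p5")
  if (!endsWith(full_p7, partial_p7))
    stop("partial_p7 must be a suffix of full_p7")
  stopifnot(diversifier_length >= 0)
  # reverse complements cached once; construct building and trimming are
  # called per read
  structure(c(fields, list(diversifier_length = as.integer(diversifier_length),
                           diversifier_both_ends = diversifier_both_ends,
                           rc_target_reverse = revcomp(target_reverse),
                           rc_partial_p7 = revcomp(partial_p7),
                           rc_full_p7 = revcomp(full_p7))),
            class = "primer_design")
}

random_bases <- function(n) {
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

segment_table <- function(names, widths) {
  end <- cumsum(widths)
  data.frame(segment = names, start = c(0L, end[-length(end)]),
             end = end, stringsAsFactors = FALSE) # 0-based half-open
}

#' Build a first-PCR library construct (partial adapters)
#'
#' Assembles, on the top strand read from the P5 side,
#' `[partial_p5][diversifier][target_fwd][insert][target_rev_rc]`
#' `[diversifier][partial_p7_rc]`, instantiating each diversifier as
#' i.i.d. uniform random bases. The segment map records 0-based half-open
#' coordinates that tile the sequence exactly.
#'
#' @param insert insert (target exon region) sequence, non-empty A/C/G/T.
#' @param design a [primer_design()].
#' @param seed optional integer; the same seed reproduces the diversifiers.
#' @return a `library_construct` list: `sequence`, `segments`,
#'   `stage = "partial"`.
#' @export
build_first_pcr_construct <- function(insert, design = primer_design(),
                                      seed = NULL) {
  stopifnot(inherits(design, "primer_design"))
  if (!nzchar(insert) || !valid_dna(insert))
    stop("insert must be a non-empty string over A/C/G/T")
  build <- function() {
    d1 <- random_bases(design$diversifier_length)
    d2 <- if (design$diversifier_both_ends)
      random_bases(design$diversifier_length) else ""
    parts <- c(p5 = design$partial_p5, diversifier_5 = d1,
               target_forward = design$target_forward, insert = insert,
               target_reverse_rc = design$rc_target_reverse,
               diversifier_3 = d2, p7_rc = design$rc_partial_p7)
    structure(list(sequence = paste(parts, collapse = ""),
                   segments = segment_table(names(parts), nchar(parts)),
                   stage = "partial"),
              class = "library_construct")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Extend a first-PCR construct to full sequencing adapters
#'
#' Replaces the partial P5/P7 adapter portions by the full adapters; all
#' interior segments (diversifiers, primers, insert) are unchanged.
#'
#' @param construct a partial-adapter `library_construct`.
#' @param design the same [primer_design()] used to build it.
#' @return a `library_construct` with `stage = "full"`.
#' @export
build_second_pcr_construct <- function(construct, design = primer_design()) {
  stopifnot(inherits(construct, "library_construct"),
            inherits(design, "primer_design"))
  if (identical(construct$stage, "full"))
    stop("construct already carries full adapters")
  seq <- construct$sequence
  if (!startsWith(seq, design$partial_p5) ||
      !endsWith(seq, design$rc_partial_p7))
    stop("construct lacks recognizable partial adapters for this design")
  interior <- substr(seq, nchar(design$partial_p5) + 1,
                     nchar(seq) - nchar(design$partial_p7))
  segs <- construct$segments
  widths <- segs$end - segs$start
  widths[segs$segment == "p5"] <- nchar(design$full_p5)
  widths[segs$segment == "p7_rc"] <- nchar(design$full_p7)
  structure(list(sequence = paste0(design$full_p5, interior,
                                   design$rc_full_p7),
                 segments = segment_table(segs$segment, widths),
                 stage = "full"),
            class = "library_construct")
}

#' Sequence read from a construct
#'
#' Reads start at the P5 end of the top strand; `read_length` truncates at
#' the 3' end (default: whole construct).
#'
#' @param construct a `library_construct`.
#' @param read_length optional maximum read length.
#' @return character read sequence.
#' @export
read_of <- function(construct, read_length = NULL) {
  s <- construct$sequence
  if (is.null(read_length)) s else substr(s, 1, read_length)
}

# mismatch-tolerant prefix test
prefix_matches <- function(read, pattern, max_mismatch) {
  n <- nchar(pattern)
  nchar(read) >= n &&
    nmismatch_str(substr(read, 1, n), pattern) <= max_mismatch
}

#' Trim a read back to its insert region
#'
#' Matches the full P5 adapter as a read prefix (allowing up to
#' `max_mismatch` substitutions, no indels), removes it together with the
#' diversifier and the target-hybridizing forward primer, then locates the
#' reverse-complemented reverse primer to delimit the insert 3' end (also
#' mismatch-tolerant, including partial matches when the read is truncated).
#' Reads whose adapter cannot be matched are flagged untrimmed and must be
#' excluded downstream.
#'
#' @param read read sequence (character).
#' @param design a [primer_design()].
#' @param max_mismatch substitutions tolerated per adapter/primer match
#'   (default 2).
#' @return list with `insert` (character, `NA` if untrimmed) and `trimmed`
#'   (logical).
#' @export
trim_read <- function(read, design = primer_design(), max_mismatch = 2L) {
  stopifnot(inherits(design, "primer_design"))
  fail <- list(insert = NA_character_, trimmed = FALSE)
  if (!nzchar(read)) return(fail)
  if (!prefix_matches(read, design$full_p5, max_mismatch)) return(fail)
  pos <- nchar(design$full_p5) + design$diversifier_length + 1
  rest <- substr(read, pos, nchar(read))
  if (!prefix_matches(rest, design$target_forward, max_mismatch)) return(fail)
  rest <- substr(rest, nchar(design$target_forward) + 1, nchar(rest))
  rc_rev <- design$rc_target_reverse
  n <- nchar(rest); m <- nchar(rc_rev)
  ins_end <- n
  # exact fast path: last occurrence delimits the insert
  hits <- gregexpr(rc_rev, rest, fixed = TRUE)[[1]]
  if (hits[1] > 0) {
    ins_end <- hits[length(hits)] - 1
  } else if (n >= m && max_mismatch > 0) {
    # mismatch-tolerant scan from the 3' end
    for (s in seq(n - m + 1, 1)) {
      if (nmismatch_str(substr(rest, s, s + m - 1), rc_rev) <= max_mismatch) {
        ins_end <- s - 1
        break
      }
    }
  }
  if (ins_end == n && n >= 4 && m > 4) {
    # truncated read: reverse primer may be partially present at the 3' end
    for (L in seq(min(m - 1, n), 4)) {
      # mismatch budget scales with the overlap so short chance matches
      # inside the insert are not mistaken for a truncated primer
      if (nmismatch_str(substr(rest, n - L + 1, n),
                        substr(rc_rev, 1, L)) <= min(max_mismatch, L %/% 10)) {
        ins_end <- n - L
        break
      }
    }
  }
  list(insert = substr(rest, 1, ins_end), trimmed = TRUE)
}

#' Trim a vector of reads
#'
#' @param reads character vector of reads.
#' @inheritParams trim_read
#' @return data frame with columns `insert` and `trimmed`.
#' @export
trim_reads <- function(reads, design = primer_design(), max_mismatch = 2L) {
  out <- lapply(reads, trim_read, design = design, max_mismatch = max_mismatch)
  data.frame(insert = vapply(out, `[[`, character(1), "insert"),
             trimmed = vapply(out, `[[`, logical(1), "trimmed"))
}

#' Per-cycle base diversity of a read set
#'
#' Shannon entropy (bits) of the base composition at each of the first
#' `n_cycles` sequencing cycles; the maximum for four equifrequent bases is
#' 2 bits. Cluster identification on Illumina flowcells relies on diversity
#' over the first five cycles, which is what the diversifier provides in
#' otherwise monotemplate amplicon libraries.
#'
#' @param reads character vector of reads, all of length >= `offset +
#'   n_cycles`.
#' @param n_cycles number of cycles to evaluate (default 5).
#' @param offset 0-based position at which cycle 1 starts, e.g. the adapter
#'   length when diversity is assessed on post-adapter coordinates.
#' @return numeric vector of length `n_cycles`, entropy in bits per cycle.
#' @export
#' @examples
#' per_cycle_diversity(c("ACGTA", "AAAAA", "CCCCC", "GGGGG"), n_cycles = 3)
per_cycle_diversity <- function(reads, n_cycles = 5L, offset = 0L) {
  if (length(reads) == 0) stop("empty read list")
  if (any(nchar(reads) < offset + n_cycles))
    stop("all reads must have length >= offset + n_cycles")
  vapply(seq_len(n_cycles), function(cyc) {
    bases <- substr(reads, offset + cyc, offset + cyc)
    p <- table(factor(bases, levels = DNA_BASES)) / length(bases)
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
}

#' Read and write FASTA/FASTQ read sets
#'
#' Thin wrappers around Biostrings IO keeping reads as plain character
#' vectors named by read id.
#'
#' @param reads named character vector of sequences.
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `write_reads()` returns `path` invisibly; `read_reads()` a named
#'   character vector.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(x) <- paste0("read", seq_along(reads))
  if (format == "fastq") {
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(x), names(x))
}

#' Read or write a primer design as YAML
#'
#' @param path YAML file path.
#' @param design a [primer_design()].
#' @return `read_primer_design()` returns a `primer_design`.
#' @export
read_primer_design <- function(path) {
  d <- yaml::read_yaml(path)
  do.call(primer_design, d[!startsWith(names(d), "rc_")])
}

#' @rdname read_primer_design
#' @export
write_primer_design <- function(design, path) {
  d <- unclass(design)
  yaml::write_yaml(d[!startsWith(names(d), "rc_")], path)
  invisible(path)
}
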