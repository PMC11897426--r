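# Numeric representations of plasmid nucleotide sequences: k-mer frequency
# vectors for the dense encoder and one-hot windows for the convolutional
# encoder.

#' Read a FASTA file of plasmid sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] enforcing the
#' contracts the pipeline relies on: record ids are the header token before
#' the first whitespace, input order is preserved, duplicate ids and empty
#' records are errors, and CRLF files parse identically to LF. Gzipped
#' input is handled transparently.
#'
#' @param path FASTA file path (optionally gzipped).
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop_("empty FASTA file: %s", path)
  if (!startsWith(first[1L], ">"))
    stop_("sequence data before any FASTA header in %s", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop_("duplicate record id in %s: %s", path, ids[duplicated(ids)][1L])
  if (any(Biostrings::width(set) == 0L))
    stop_("record with empty sequence in %s: %s", path,
          ids[Biostrings::width(set) == 0L][1L])
  stats::setNames(toupper(as.character(set)), ids)
}

#' k-mer frequency vector of a nucleotide sequence
#'
#' Counts overlapping k-mers left to right over the 4^k alphabet in
#' lexicographic A < C < G < T order and normalizes by the number of valid
#' k-mers. Windows containing any non-ACGT symbol (N and other IUPAC
#' ambiguity codes) are skipped; lowercase input is upcased. Plasmids are
#' circular molecules but are encoded as linear by default; `circular =
#' TRUE` appends the first k-1 bases so wrap-around k-mers are counted.
#' Reverse complements are deliberately not collapsed: strand composition
#' is part of the signal and the full 4^k dimension is kept.
#'
#' @param sequence nucleotide string, length at least `k`.
#' @param k word size, between 2 and 6.
#' @param circular count wrap-around k-mers of the circular molecule.
#' @return Named numeric vector of length `4^k` summing to 1 (all zeros if
#'   the sequence contains no valid k-mer).
#' @export
kmer_frequency_vector <- function(sequence, k = 4, circular = FALSE) {
  if (!is_count(k) || k < 2 || k > 6) stop_("k must be an integer in [2, 6]")
  sequence <- toupper(sequence)
  if (nchar(sequence) < k)
    stop_("sequence of length %d is shorter than k = %d", nchar(sequence), k)
  if (circular)
    sequence <- paste0(sequence, substr(sequence, 1L, k - 1L))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  total <- sum(counts)
  if (total == 0) return(counts * 0)
  counts / total
}

#' k-mer frequency matrix for a set of sequences
#'
#' Vectorized form of [kmer_frequency_vector()] used to featurize whole
#' corpora for the dense encoder.
#'
#' @param sequences named character vector (e.g. from [read_fasta()]).
#' @inheritParams kmer_frequency_vector
#' @return Numeric matrix, one row per sequence, `4^k` columns.
#' @export
kmer_frequency_matrix <- function(sequences, k = 4, circular = FALSE) {
  if (!is_count(k) || k < 2 || k > 6) stop_("k must be an integer in [2, 6]")
  seqs <- toupper(sequences)
  if (any(nchar(seqs) < k)) stop_("sequence shorter than k = %d", k)
  if (circular) seqs <- paste0(seqs, substr(seqs, 1L, k - 1L))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  totals <- rowSums(counts)
  out <- counts / pmax(totals, 1)
  rownames(out) <- names(sequences)
  out
}

#' One-hot window stack of a nucleotide sequence
#'
#' Cuts the sequence into windows starting at 0, `stride`, `2*stride`, ...
#' and one-hot encodes each (4 channels per position, rows A, C, G, T;
#' ambiguous bases become all-zero columns). The final partial window is
#' zero-padded to `window_len`; a sequence shorter than `window_len` yields
#' exactly one padded window. Input to the convolutional encoder.
#'
#' @param sequence nucleotide string, non-empty.
#' @param window_len window length in bases (>= 1).
#' @param stride distance between window starts (>= 1).
#' @return Object of class `window_stack`: list of `4 x window_len`
#'   matrices with attributes `window_len` and `stride`.
#' @export
one_hot_windows <- function(sequence, window_len = 2048, stride = 2048) {
  if (!is_count(window_len) || window_len < 1) stop_("window_len must be >= 1")
  if (!is_count(stride) || stride < 1) stop_("stride must be >= 1")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop_("empty sequence")
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- base_idx[chars]                      # NA for ambiguity codes
  starts <- seq(1L, n, by = stride)
  windows <- lapply(starts, function(s) {
    e <- min(s + window_len - 1L, n)
    w <- matrix(0, nrow = 4L, ncol = window_len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    span <- idx[s:e]
    ok <- which(!is.na(span))
    if (length(ok)) w[cbind(span[ok], ok)] <- 1
    w
  })
  structure(windows, window_len = window_len, stride = stride,
            class = "window_stack")
}
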