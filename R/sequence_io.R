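#' Construct a dereplicated sequence pool
#'
#' A \code{SequencePool} holds the dereplicated reads of one HT-SELEX round:
#' unique sequences with their read counts, plus the pool statistics every
#' downstream score needs (total read count \eqn{N}, per-base counts
#' \eqn{n_j}, and the count-weighted length distribution).
#'
#' @param sequences character vector of reads (need not be unique); only
#'   characters A, C, G, T are allowed after normalization.
#' @param counts integer vector of per-read multiplicities (recycled scalar
#'   allowed); identical sequences are merged with summed counts.
#' @return An object of class \code{SequencePool}: a list with elements
#'   \code{sequence} (unique sequences), \code{count}, \code{N} (total reads
#'   with multiplicity), and \code{base_counts} (named A/C/G/T totals,
#'   weighted by multiplicity).
#' @examples
#' pool <- sequence_pool(c("ACGT", "ACGT", "GGGG"))
#' pool$N           # 3
#' pool$count       # 2 1
#' @export
sequence_pool <- function(sequences, counts = 1L) {
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L)
    stop("empty pool: no sequences", call. = FALSE)
  counts <- as.integer(rep_len(counts, length(sequences)))
  if (any(is.na(counts)) || any(counts < 1L))
    stop("counts must be positive integers", call. = FALSE)
  if (any(nchar(sequences) == 0L))
    stop("empty sequence in pool", call. = FALSE)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T}; normalize first",
         call. = FALSE)
  # merge duplicates, order by count desc then sequence for determinism
  agg <- rowsum(counts, group = sequences)
  seqs <- rownames(agg)
  cnts <- as.integer(agg[, 1L])
  ord <- order(-cnts, seqs, method = "radix")
  seqs <- seqs[ord]
  cnts <- cnts[ord]

  bc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                    DNA_BASES)
  base_counts <- setNames(as.numeric(colSums(bc * cnts)), DNA_BASES)

  structure(list(sequence = seqs,
                 count = cnts,
                 N = sum(cnts),
                 base_counts = base_counts),
            class = "SequencePool")
}

#' @export
print.SequencePool <- function(x, ...) {
  cat(sprintf("SequencePool: %d unique sequences, N = %d reads\n",
              length(x$sequence), x$N))
  lens <- nchar(x$sequence)
  cat(sprintf("  lengths %d-%d, base composition %s\n",
              min(lens), max(lens),
              paste(sprintf("%s=%.3f", names(x$base_counts),
                            x$base_counts / sum(x$base_counts)),
                    collapse = " ")))
  invisible(x)
}

#' Count-weighted read-length distribution of a pool
#'
#' @param pool a \code{SequencePool}.
#' @return named integer vector: for each distinct read length, the total
#'   number of reads (with multiplicity) of that length.
#' @export
pool_length_table <- function(pool) {
  stopifnot(inherits(pool, "SequencePool"))
  lens <- nchar(pool$sequence)
  tab <- rowsum(pool$count, group = lens)
  setNames(as.integer(tab[, 1L]), rownames(tab))
}

#' Read an HT-SELEX pool from FASTA/FASTQ
#'
#' Reads one round of (pre-trimmed) HT-SELEX reads, normalizes them
#' (uppercase, U mapped to T), drops reads containing any other character,
#' and dereplicates identical reads into (sequence, count) pairs.  A FASTA
#' header of the form \code{...;count=K} (as written by
#' \code{\link{write_pool_fasta}}) is honoured, so a dereplicated export
#' reads back to the identical pool.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzipped.
#' @param format \code{"auto"} (by extension; default FASTA), \code{"fasta"}
#'   or \code{"fastq"}.  FASTQ qualities are ignored.
#' @param trim_left,trim_right optional fixed-width trims applied to every
#'   read before normalization (default 0: reads are assumed already trimmed
#'   to the random region).
#' @return A \code{\link{sequence_pool}}.
#' @export
read_pool <- function(path, format = c("auto", "fasta", "fastq"),
                      trim_left = 0L, trim_right = 0L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- tryCatch(Biostrings::readBStringSet(path, format = format),
                error = function(e)
                  stop("cannot parse ", path, " as ", format, ": ",
                       conditionMessage(e), call. = FALSE))
  if (length(x) == 0L)
    stop("empty pool: no records in ", path, call. = FALSE)
  seqs <- as.character(x)
  counts <- rep(1L, length(seqs))
  hdr <- names(x)
  if (!is.null(hdr)) {
    m <- regmatches(hdr, regexpr("(?<=;count=)[0-9]+", hdr, perl = TRUE))
    has <- grepl(";count=[0-9]+", hdr)
    if (any(has)) counts[has] <- as.integer(m)
  }
  if (trim_left > 0L || trim_right > 0L) {
    keep <- nchar(seqs) > trim_left + trim_right
    if (!all(keep)) {
      message(sum(!keep), " read(s) shorter than the requested trim dropped")
      seqs <- seqs[keep]; counts <- counts[keep]
    }
    seqs <- substr(seqs, trim_left + 1L, nchar(seqs) - trim_right)
  }
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  ok <- nchar(seqs) > 0L & !grepl("[^ACGT]", seqs)
  if (!all(ok))
    message(sum(counts[!ok]),
            " read(s) with characters outside {A,C,G,T,U} dropped")
  if (!any(ok))
    stop("empty pool: no reads survive alphabet filtering", call. = FALSE)
  sequence_pool(seqs[ok], counts[ok])
}

#' Filter a pool by read frequency
#'
#' Retains exactly the unique sequences whose read count is at least
#' \code{min_count} (inclusive cutoff), recomputing all pool statistics on
#' the retained reads.  \code{min_count = 1} returns the pool unchanged.
#'
#' @param pool a \code{SequencePool}.
#' @param min_count positive integer cutoff.
#' @return the filtered \code{SequencePool}.
#' @export
filter_by_frequency <- function(pool, min_count) {
  stopifnot(inherits(pool, "SequencePool"))
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L)
    stop("min_count must be >= 1", call. = FALSE)
  keep <- pool$count >= min_count
  if (!any(keep))
    stop("empty pool: no sequences with count >= ", min_count, call. = FALSE)
  sequence_pool(pool$sequence[keep], pool$count[keep])
}

#' Write a dereplicated pool as FASTA
#'
#' Headers carry the multiplicity (\code{>seq_00001;count=57}) so that
#' \code{\link{read_pool}} round-trips the pool exactly.
#'
#' @param pool a \code{SequencePool}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "SequencePool"))
  ids <- sprintf("seq_%05d;count=%d", seq_along(pool$sequence), pool$count)
  x <- Biostrings::DNAStringSet(pool$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a pool as TSV (sequence, count, length)
#'
#' @param pool a \code{SequencePool}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "SequencePool"))
  df <- data.frame(sequence = pool$sequence, count = pool$count,
                   length = nchar(pool$sequence))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
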