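# Synthetic HT-SELEX pool generator.
#
# Emulates the features of a late-round SELEX pool that the string scoring
# depends on: a nominal random-region length with a minority of off-length
# reads, a (possibly skewed) base composition, and one or more planted
# motif strings carried by a known fraction of reads.  Ground truth records
# which reads carry which motif, so recovery can be measured exactly.

#' Specification of a synthetic SELEX pool
#'
#' Defaults describe the pool used throughout the package's validation:
#' 10,000 reads of nominal length 30 with 22% off-length reads (length
#' jitter of 1-3 nt either way, matching the commonly reported ~78% of
#' SELEX reads having the expected random-region length), skewed base
#' composition A/C/G/T = 0.3/0.2/0.3/0.2 (to exercise the composition-aware
#' scoring), and one planted 10-mer carried by 20% of reads.
#'
#' @param n_reads number of reads.
#' @param nominal_length random-region length of on-length reads.
#' @param off_length_fraction fraction of reads with jittered length.
#' @param length_jitter positive integer vector of absolute length changes
#'   sampled uniformly (sign also uniform) for off-length reads.
#' @param base_probs background base probabilities (A, C, G, T).
#' @param motifs list of planted motifs, each a
#'   \code{list(string =, prevalence =)}; prevalences are mutually
#'   exclusive per read and must sum to at most 1.
#' @param seed RNG seed; a fixed seed makes the pool byte-identical.
#' @return an object of class \code{SyntheticPoolSpec}.
#' @export
synthetic_pool_spec <- function(n_reads = 10000L,
                                nominal_length = 30L,
                                off_length_fraction = 0.22,
                                length_jitter = 1:3,
                                base_probs = c(A = 0.3, C = 0.2,
                                               G = 0.3, T = 0.2),
                                motifs = list(list(string = "TATGGACTTC",
                                                   prevalence = 0.2)),
                                seed = 1L) {
  n_reads <- as.integer(n_reads)
  nominal_length <- as.integer(nominal_length)
  stopifnot(n_reads >= 1L, nominal_length >= 1L,
            off_length_fraction >= 0, off_length_fraction <= 1,
            all(length_jitter >= 1L))
  base_probs <- alphabet_probs(base_probs)
  prev <- vapply(motifs, function(m) m$prevalence, numeric(1))
  if (length(motifs)) {
    stopifnot(all(prev >= 0), sum(prev) <= 1)
    min_len <- nominal_length -
      if (off_length_fraction > 0) max(length_jitter) else 0L
    for (m in motifs) {
      stopifnot(is.character(m$string), nchar(m$string) >= 1L)
      if (grepl("[^ACGT]", m$string))
        stop("motif must be over {A,C,G,T}", call. = FALSE)
      if (nchar(m$string) > min_len)
        stop("motif '", m$string, "' is longer than the shortest ",
             "possible read (", min_len, ")", call. = FALSE)
    }
  }
  structure(list(n_reads = n_reads, nominal_length = nominal_length,
                 off_length_fraction = off_length_fraction,
                 length_jitter = as.integer(length_jitter),
                 base_probs = base_probs, motifs = motifs,
                 seed = as.integer(seed)),
            class = "SyntheticPoolSpec")
}

#' Generate a synthetic pool with ground truth
#'
#' Draws each read i.i.d. from the background base probabilities, jitters
#' the lengths of an \code{off_length_fraction} subset, and, per read with
#' the configured prevalences, overwrites a uniformly chosen window with a
#' planted motif string.  The global RNG state is restored on exit.
#'
#' @param spec a \code{\link{synthetic_pool_spec}}.
#' @return An object of class \code{SyntheticPool}: list with \code{reads}
#'   (data.frame: read_id, sequence), \code{truth} (data.frame: read_id,
#'   motif, insert_position; carriers only), \code{pool} (the dereplicated
#'   \code{\link{sequence_pool}}) and \code{spec}.
#' @export
generate_pool <- function(spec) {
  stopifnot(inherits(spec, "SyntheticPoolSpec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  n <- spec$n_reads
  lens <- rep(spec$nominal_length, n)
  off <- runif(n) < spec$off_length_fraction
  if (any(off)) {
    mag <- sample(spec$length_jitter, sum(off), replace = TRUE)
    sgn <- sample(c(-1L, 1L), sum(off), replace = TRUE)
    lens[off] <- lens[off] + sgn * mag
  }
  chars <- sample(DNA_BASES, sum(lens), replace = TRUE,
                  prob = spec$base_probs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  big <- paste(chars, collapse = "")
  seqs <- substring(big, starts, ends)

  truth <- data.frame(read_id = character(0), motif = character(0),
                      insert_position = integer(0),
                      stringsAsFactors = FALSE)
  read_id <- sprintf("read_%06d", seq_len(n))
  if (length(spec$motifs)) {
    prev <- vapply(spec$motifs, function(m) m$prevalence, numeric(1))
    u <- runif(n)
    which_motif <- findInterval(u, cumsum(c(0, prev)),
                                left.open = TRUE)  # 0..k; k+1 => none
    which_motif[which_motif > length(prev)] <- 0L
    carriers <- which(which_motif > 0L)
    if (length(carriers)) {
      ms <- vapply(spec$motifs, `[[`, character(1), "string")
      mlen <- nchar(ms)[which_motif[carriers]]
      pos <- 1L + floor(runif(length(carriers)) *
                          (lens[carriers] - mlen + 1L))
      mstr <- ms[which_motif[carriers]]
      substr(seqs[carriers], pos, pos + mlen - 1L) <- mstr
      truth <- data.frame(read_id = read_id[carriers],
                          motif = mstr,
                          insert_position = as.integer(pos),
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(reads = data.frame(read_id = read_id, sequence = seqs,
                                    stringsAsFactors = FALSE),
                 truth = truth,
                 pool = sequence_pool(seqs),
                 spec = spec),
            class = "SyntheticPool")
}

#' @export
print.SyntheticPool <- function(x, ...) {
  cat(sprintf("SyntheticPool: %d reads (%d unique), %d motif carrier(s)\n",
              nrow(x$reads), length(x$pool$sequence), nrow(x$truth)))
  invisible(x)
}

#' Carrier labels for a synthetic pool
#'
#' Binding labels at the unique-sequence level: a sequence is labeled
#' binding iff at least one read with that sequence was generated as a
#' motif carrier.
#'
#' @param sp a \code{SyntheticPool}.
#' @return data.frame with columns \code{sequence} and \code{binding},
#'   one row per unique pool sequence.
#' @export
carrier_labels <- function(sp) {
  stopifnot(inherits(sp, "SyntheticPool"))
  carrier_seqs <- unique(sp$reads$sequence[sp$reads$read_id %in%
                                             sp$truth$read_id])
  data.frame(sequence = sp$pool$sequence,
             binding = sp$pool$sequence %in% carrier_seqs,
             stringsAsFactors = FALSE)
}

#' Write synthetic reads as FASTA (one record per read)
#'
#' @param sp a \code{SyntheticPool}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_synthetic_fasta <- function(sp, path) {
  stopifnot(inherits(sp, "SyntheticPool"))
  x <- Biostrings::DNAStringSet(sp$reads$sequence)
  names(x) <- sp$reads$read_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the ground-truth carrier table as TSV
#'
#' @param sp a \code{SyntheticPool}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_truth_tsv <- function(sp, path) {
  stopifnot(inherits(sp, "SyntheticPool"))
  write.table(sp$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
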