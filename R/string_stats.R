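# Containment-probability machinery.
#
# P_{s,L} is the probability that an i.i.d. random L-mer over {A,C,G,T}
# (base probabilities p_j) contains string s at least once.  It satisfies a
# recurrence over L with a correction term for every border of s (non-empty
# proper prefix that is also a suffix): without the correction, occurrences
# ending at position L that overlap an earlier occurrence would be double
# counted.  Writing m = |s|, Q = prod_j p_j^{n_{s,j}} and, for each border t,
# q_t = prod_j p_j^{n_{t,j}}:
#
#   P_{s,L} = P_{s,L-1}
#           + Q * ( 1 - P_{s,L-m}
#                     - sum_t q_t^{-1} (P_{s,L-m+|t|} - P_{s,L-m+|t|-1}) )
#
# with P_{s,L} = 0 for L < m.  The same quantity is recomputed exactly by
# exact_containment_oracle() (full enumeration in C, and an automaton DP)
# so the recurrence can be validated independently.

.containment_cache <- new.env(parent = emptyenv())

#' Validate a vector of nucleobase probabilities
#'
#' @param p numeric vector of length 4 giving probabilities for A, C, G, T
#'   (in that order if unnamed).  Must be non-negative and sum to 1 within
#'   1e-12.
#' @return named numeric vector (A, C, G, T).
#' @export
alphabet_probs <- function(p) {
  stopifnot(is.numeric(p), length(p) == 4L)
  if (is.null(names(p))) names(p) <- DNA_BASES
  p <- p[DNA_BASES]
  if (any(is.na(p)) || any(p < 0))
    stop("base probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("base probabilities must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  p
}

#' Estimate per-base probabilities from a pool
#'
#' The probability of each nucleobase is estimated as its observed count
#' over the total number of bases, with both counts weighted by read
#' multiplicity.  Because SELEX rounds skew base composition, these
#' estimates (rather than 1/4) parameterize the containment probabilities
#' used in the string Z-scores.
#'
#' @param pool a \code{\link{sequence_pool}}.
#' @return named numeric vector of probabilities (A, C, G, T) summing to 1.
#' @examples
#' estimate_base_probs(sequence_pool(c("AC", "GT")))  # all 0.25
#' @export
estimate_base_probs <- function(pool) {
  stopifnot(inherits(pool, "SequencePool"))
  alphabet_probs(pool$base_counts / sum(pool$base_counts))
}

#' Borders (self-overlapping regions) of a string
#'
#' A border of \code{s} is a non-empty proper prefix of \code{s} that is
#' also a suffix, e.g. \code{"ATATA"} has borders \code{"A"} and
#' \code{"ATA"}.  Borders are the self-overlaps that the containment
#' recurrence must correct for.
#'
#' @param s a single non-empty string.
#' @return character vector of borders, shortest first (possibly empty).
#' @export
border_set <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- nchar(s)
  if (m < 1L) stop("border_set: empty string", call. = FALSE)
  k <- seq_len(m - 1L)
  if (m == 1L) return(character(0))
  pref <- substring(s, 1L, k)
  suff <- substring(s, m - k + 1L, m)
  pref[pref == suff]
}

# composition counts n_{s,j} for a character vector of strings -> matrix
.base_composition <- function(strings) {
  Biostrings::letterFrequency(Biostrings::DNAStringSet(strings), DNA_BASES)
}

# core recurrence given the profile (m, Q, border offsets + q values).
# Returns numeric vector tab with tab[L + 1] = P_{s,L}, L = 0..L_max.
.containment_recurrence <- function(m, Q, border_len, border_q, L_max) {
  tab <- numeric(L_max + 1L)
  if (Q == 0 || L_max < m) return(tab)
  if (any(border_q == 0))
    stop("border with zero probability but Q > 0: inconsistent profile",
         call. = FALSE)
  nb <- length(border_len)
  for (L in m:L_max) {
    corr <- 0
    if (nb) {
      i <- L - m + border_len          # P_{s, L-m+|t|} lives at tab[i + 1]
      corr <- sum((tab[i + 1L] - tab[i]) / border_q)
    }
    tab[L + 1L] <- tab[L] + Q * (1 - tab[L - m + 1L] - corr)
  }
  hi <- max(tab); lo <- min(tab)
  if (hi > 1 + 1e-9 || lo < -1e-9)
    stop("containment probability outside [0,1] beyond tolerance (",
         lo, ", ", hi, ")", call. = FALSE)
  if (hi > 1 || lo < 0) {
    warning("containment probabilities clipped to [0,1] (margin < 1e-9)")
    tab <- pmin(pmax(tab, 0), 1)
  }
  tab
}

# profile of a single string under probs: everything the recurrence needs
.containment_profile <- function(s, probs) {
  comp <- as.vector(.base_composition(s))
  borders <- border_set(s)
  blen <- nchar(borders)
  bq <- if (length(borders)) {
    bc <- .base_composition(borders)
    apply(bc, 1L, function(n) prod(probs^n))
  } else numeric(0)
  list(m = nchar(s), comp = comp, Q = prod(probs^comp),
       border_len = blen, border_q = bq)
}

#' Containment probability table for a string
#'
#' Computes \eqn{P_{s,L}}, the probability that a random i.i.d. L-mer with
#' the given base probabilities contains \code{s}, for all
#' \eqn{L = 0, \dots, L_{max}}, by the border-corrected recurrence.
#' Tables are memoized per (profile, probability vector).
#'
#' @param s a single string over A/C/G/T.
#' @param probs base probabilities, see \code{\link{alphabet_probs}}.
#' @param L_max largest text length needed.
#' @return numeric vector \code{P} of length \code{L_max + 1} with
#'   \code{P[L + 1]} = \eqn{P_{s,L}}; zero for all \eqn{L < |s|}.
#' @examples
#' containment_prob_table("AA", alphabet_probs(c(.5, .5/3, .5/3, .5/3)),
#'                        3)[4]  # 0.375
#' @export
containment_prob_table <- function(s, probs, L_max) {
  stopifnot(is.character(s), length(s) == 1L, nchar(s) >= 1L)
  probs <- alphabet_probs(probs)
  L_max <- as.integer(L_max)
  stopifnot(L_max >= 0L)
  prof <- .containment_profile(s, probs)
  key <- paste(prof$m, paste(prof$comp, collapse = ","),
               paste(prof$border_len, collapse = ","),
               paste(sprintf("%.17g", prof$border_q), collapse = ","),
               paste(sprintf("%.17g", probs), collapse = ","), sep = "|")
  hit <- .containment_cache[[key]]
  if (!is.null(hit) && length(hit) >= L_max + 1L)
    return(hit[seq_len(L_max + 1L)])
  tab <- .containment_recurrence(prof$m, prof$Q, prof$border_len,
                                 prof$border_q, L_max)
  .containment_cache[[key]] <- tab
  tab
}

#' Length-averaged containment probability over a pool
#'
#' Read lengths in a SELEX pool vary (insertions/deletions during
#' selection), so the per-length containment probability is averaged over
#' the observed read-length distribution:
#' \eqn{P_s = (1/N) \sum_i P_{s,L_i}}, the mean over all \eqn{N} reads with
#' multiplicity (computed over distinct lengths only).
#'
#' @param s a single string.
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities.
#' @return the scalar \eqn{P_s}.
#' @export
length_averaged_prob <- function(s, pool, probs) {
  stopifnot(inherits(pool, "SequencePool"))
  lt <- pool_length_table(pool)
  lens <- as.integer(names(lt))
  tab <- containment_prob_table(s, probs, max(lens))
  sum(as.numeric(lt) * tab[lens + 1L]) / pool$N
}

#' Number of reads containing a string
#'
#' \eqn{F_s}: the total count (with multiplicity) of reads that contain at
#' least one occurrence of \code{s}; multiple occurrences within one read
#' still contribute that read's count once.
#'
#' @param s character vector of query strings.
#' @param pool a \code{\link{sequence_pool}}.
#' @return integer vector of containment frequencies, one per query.
#' @export
count_containing_reads <- function(s, pool) {
  stopifnot(inherits(pool, "SequencePool"), is.character(s))
  if (length(s) == 0L) return(integer(0))
  stopifnot(all(nchar(s) >= 1L))
  subject <- Biostrings::DNAStringSet(pool$sequence)
  out <- integer(length(s))
  for (w in unique(nchar(s))) {
    idx <- which(nchar(s) == w)
    if (w > max(nchar(pool$sequence)))
      next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(s[idx]))
    hits <- Biostrings::vwhichPDict(pd, subject)
    u <- unlist(hits)
    if (length(u)) {
      wts <- rep(pool$count, lengths(hits))
      tt <- rowsum(wts, group = u)
      out[idx[as.integer(rownames(tt))]] <- as.integer(tt[, 1L])
    }
  }
  out
}

#' String over-representation Z-score
#'
#' Standardizes the excess of the observed containment fraction
#' \eqn{F_s/N} over its expectation \eqn{P_s} under the pool's base
#' composition, using the binomial standard deviation:
#' \deqn{Z_s = (F_s/N - P_s) / \sqrt{P_s (1 - P_s) / N}.}
#'
#' @param F_s containment frequency (number of reads containing the string).
#' @param N total number of reads (with multiplicity).
#' @param P_s expected containment probability, strictly between 0 and 1.
#' @return the Z-score (vectorized over its arguments).
#' @export
z_score <- function(F_s, N, P_s) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (any(P_s <= 0 | P_s >= 1))
    stop("z_score undefined for P_s outside (0,1); exclude such strings",
         call. = FALSE)
  (F_s / N - P_s) / sqrt(P_s * (1 - P_s) / N)
}

# Batch P_s for equal-length strings: P_{s,L} depends on s only through
# |s|, its composition, and the lengths+compositions of its borders, so
# strings sharing that profile share one recurrence table.  Fully
# vectorized profile extraction; one recurrence per distinct profile.
.batch_length_averaged_prob <- function(strings, probs, length_table, N) {
  if (length(strings) == 0L) return(numeric(0))
  l <- nchar(strings[1L])
  stopifnot(all(nchar(strings) == l))
  lens <- as.integer(names(length_table))
  wts <- as.numeric(length_table)
  L_max <- max(lens)
  n <- length(strings)
  comp <- .base_composition(strings)
  Qvec <- probs[1L]^comp[, 1L] * probs[2L]^comp[, 2L] *
    probs[3L]^comp[, 3L] * probs[4L]^comp[, 4L]
  comp_key <- do.call(paste, c(as.data.frame(comp), list(sep = ",")))
  p_key <- paste(sprintf("%.17g", probs), collapse = ",")
  isb <- matrix(FALSE, nrow = n, ncol = max(l - 1L, 1L))
  qmat <- matrix(NA_real_, nrow = n, ncol = max(l - 1L, 1L))
  parts <- list(paste0("batch|", l), comp_key)
  if (l > 1L) {
    for (k in seq_len(l - 1L)) {
      pref <- substr(strings, 1L, k)
      b <- pref == substr(strings, l - k + 1L, l)
      isb[, k] <- b
      contrib <- character(n)
      if (any(b)) {
        pc <- .base_composition(pref[b])
        q <- probs[1L]^pc[, 1L] * probs[2L]^pc[, 2L] *
          probs[3L]^pc[, 3L] * probs[4L]^pc[, 4L]
        qmat[b, k] <- q
        contrib[b] <- paste0(k, ":", sprintf("%.17g", q))
      }
      parts <- c(parts, list(contrib))
    }
  }
  parts <- c(parts, list(p_key))
  keys <- do.call(paste, c(parts, list(sep = "|")))
  uk <- !duplicated(keys)
  P_u <- vapply(which(uk), function(i) {
    key <- keys[i]
    tab <- .containment_cache[[key]]
    if (is.null(tab) || length(tab) < L_max + 1L) {
      blen <- if (l > 1L) which(isb[i, ]) else integer(0)
      tab <- .containment_recurrence(l, Qvec[i], blen, qmat[i, blen],
                                     L_max)
      .containment_cache[[key]] <- tab
    }
    sum(wts * tab[lens + 1L]) / N
  }, numeric(1))
  P_u[match(keys, keys[uk])]
}

#' Score a batch of candidate strings against a pool
#'
#' Convenience wrapper computing, for each candidate string, the
#' containment frequency \eqn{F_s}, the length-averaged containment
#' probability \eqn{P_s}, and the Z-score.  Strings whose \eqn{P_s} is 0 or
#' 1 (e.g. containing a base with estimated probability 0) cannot be
#' scored; they get \code{Z = NA} and \code{scoreable = FALSE}.
#'
#' @param strings character vector of candidates.
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities (defaults to
#'   \code{estimate_base_probs(pool)}).
#' @return data.frame with columns \code{string}, \code{length}, \code{F},
#'   \code{P}, \code{Z}, \code{scoreable}.
#' @export
string_score_table <- function(strings, pool,
                               probs = estimate_base_probs(pool)) {
  stopifnot(inherits(pool, "SequencePool"))
  probs <- alphabet_probs(probs)
  n <- length(strings)
  F_s <- count_containing_reads(strings, pool)
  lt <- pool_length_table(pool)
  P_s <- numeric(n)
  for (w in unique(nchar(strings))) {
    idx <- which(nchar(strings) == w)
    P_s[idx] <- .batch_length_averaged_prob(strings[idx], probs, lt, pool$N)
  }
  scoreable <- P_s > 0 & P_s < 1
  Z <- rep(NA_real_, n)
  if (any(scoreable))
    Z[scoreable] <- z_score(F_s[scoreable], pool$N, P_s[scoreable])
  data.frame(string = strings, length = nchar(strings), F = F_s, P = P_s,
             Z = Z, scoreable = scoreable, stringsAsFactors = FALSE)
}

#' Exact containment probability oracle
#'
#' Computes the probability that a random i.i.d. L-mer contains \code{s}
#' by two routes that are independent of the recurrence in
#' \code{\link{containment_prob_table}}: \code{"enumerate"} sums the
#' probability of every one of the \eqn{4^L} L-mers that contains \code{s}
#' (compiled exhaustive enumeration; refuses \eqn{4^L > 4\cdot 10^6}, i.e.
#' L > 11), and \code{"automaton"} runs a dynamic program over the states
#' of the KMP failure automaton of \code{s}, tracking the probability that
#' \code{s} has not yet been seen (any L).
#'
#' @param s a single string over A/C/G/T.
#' @param probs base probabilities.
#' @param L text length.
#' @param method \code{"enumerate"} or \code{"automaton"}.
#' @return the containment probability.
#' @export
exact_containment_oracle <- function(s, probs, L,
                                     method = c("enumerate", "automaton")) {
  method <- match.arg(method)
  stopifnot(is.character(s), length(s) == 1L, nchar(s) >= 1L)
  probs <- alphabet_probs(probs)
  L <- as.integer(L)
  stopifnot(L >= 0L)
  if (L < nchar(s)) return(0)
  code <- match(strsplit(s, "")[[1]], DNA_BASES)
  if (anyNA(code)) stop("string contains characters outside {A,C,G,T}",
                        call. = FALSE)
  if (method == "enumerate") {
    if (L > 11L)
      stop("enumeration refused for L > 11 (4^L too large); use automaton",
           call. = FALSE)
    return(enumerate_containment(code, as.numeric(probs), L))
  }
  # KMP automaton DP: states 0..m-1 = length of longest prefix of s matched
  m <- length(code)
  fail <- integer(m)                 # failure function, 1-based over prefix
  k <- 0L
  for (i in 2:max(2L, m)) {
    if (m < 2L) break
    while (k > 0L && code[k + 1L] != code[i]) k <- fail[k]
    if (code[k + 1L] == code[i]) k <- k + 1L
    fail[i] <- k
  }
  delta <- matrix(0L, nrow = m, ncol = 4L)   # from state 0..m-1, on base a
  for (st in 0:(m - 1L)) {
    for (a in 1:4) {
      k <- st
      while (k > 0L && code[k + 1L] != a) k <- fail[k]
      if (code[k + 1L] == a) k <- k + 1L
      delta[st + 1L, a] <- k
    }
  }
  v <- numeric(m); v[1L] <- 1       # mass over non-accepting states
  for (step in seq_len(L)) {
    nv <- numeric(m)
    for (st in which(v > 0)) {
      for (a in 1:4) {
        ns <- delta[st, a]
        if (ns < m) nv[ns + 1L] <- nv[ns + 1L] + v[st] * probs[a]
        # mass reaching state m is absorbed (s has been seen)
      }
    }
    v <- nv
  }
  1 - sum(v)
}
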