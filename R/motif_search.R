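# Z-score-pruned extension search for over-represented strings.
#
# All l_min-mers are scored and those with Z >= 0 kept; survivors are then
# grown one base at a time (both ends by default) up to l_max, keeping a
# child only if its Z-score is at least that of a parent that generated it.
# The union of survivors over all lengths is the selected string set; it is
# a tiny fraction of the 4^l_min + ... + 4^l_max exhaustive search space.

#' Search configuration for over-represented string selection
#'
#' @param l_min minimum string length (default 5).
#' @param l_max maximum string length (default 10).
#' @param extend which end(s) new bases are appended to during extension:
#'   \code{"both"} (default; required for motifs that grow in either
#'   direction), \code{"left"} or \code{"right"}.
#' @return an object of class \code{SearchConfig}.
#' @export
search_config <- function(l_min = 5L, l_max = 10L,
                          extend = c("both", "left", "right")) {
  l_min <- as.integer(l_min); l_max <- as.integer(l_max)
  extend <- match.arg(extend)
  if (is.na(l_min) || l_min < 1L) stop("l_min must be >= 1", call. = FALSE)
  if (is.na(l_max) || l_max < l_min)
    stop("l_max must be >= l_min", call. = FALSE)
  structure(list(l_min = l_min, l_max = l_max, extend = extend),
            class = "SearchConfig")
}

#' Size of the exhaustive string search space
#'
#' Number of distinct strings of lengths \code{l_min} to \code{l_max} over
#' the 4-letter nucleobase alphabet, i.e. \eqn{\sum_l 4^l}: the space the
#' pruned extension search avoids enumerating.
#'
#' @param l_min,l_max length range.
#' @return the count (numeric; 1,397,760 for the default 5--10 range).
#' @export
search_space_size <- function(l_min = 5L, l_max = 10L) {
  stopifnot(l_min >= 1L, l_max >= l_min)
  sum(4^(l_min:l_max))
}

.all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k),
                                  stringsAsFactors = FALSE)))
}

#' Score all seed strings of the minimum length
#'
#' Enumerates all \eqn{4^{l_{min}}} strings, scores each against the pool,
#' and keeps those with \eqn{Z \ge 0}.  Strings whose Z-score is undefined
#' (containment probability 0 or 1) are excluded with a message.
#'
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities (default estimated from the pool).
#' @param config a \code{\link{search_config}}.
#' @return data.frame of surviving seeds: \code{string}, \code{length},
#'   \code{F}, \code{P}, \code{Z}.
#' @export
enumerate_seeds <- function(pool, probs = estimate_base_probs(pool),
                            config = search_config()) {
  stopifnot(inherits(pool, "SequencePool"), inherits(config, "SearchConfig"))
  seeds <- .all_kmers(config$l_min)
  tab <- string_score_table(seeds, pool, probs)
  n_undef <- sum(!tab$scoreable)
  if (n_undef > 0L)
    message(n_undef, " seed string(s) with undefined Z-score excluded")
  keep <- tab$scoreable & tab$Z >= 0
  tab[keep, c("string", "length", "F", "P", "Z")]
}

#' Extend survivor strings by one base
#'
#' Each parent \code{s} proposes children by prepending and/or appending
#' every base (8 candidates per parent for \code{extend = "both"},
#' deduplicated across parents).  A child is retained iff its Z-score is at
#' least the Z-score of at least one parent that generated it (ties kept).
#' Children contained in no read cannot be over-represented and are pruned
#' before scoring.
#'
#' @param survivors data.frame of current-level survivors (as returned by
#'   \code{\link{enumerate_seeds}} or a previous extension).
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities.
#' @param extend extension direction, see \code{\link{search_config}}.
#' @return data.frame of surviving children (same columns).
#' @export
extend_strings <- function(survivors, pool,
                           probs = estimate_base_probs(pool),
                           extend = "both") {
  stopifnot(is.data.frame(survivors), nrow(survivors) >= 1L)
  par_s <- rep(survivors$string, each = 4L)
  par_z <- rep(survivors$Z, each = 4L)
  bases <- rep_len(DNA_BASES, length(par_s))
  child <- character(0); pz <- numeric(0)
  if (extend %in% c("both", "left")) {
    child <- c(child, paste0(bases, par_s)); pz <- c(pz, par_z)
  }
  if (extend %in% c("both", "right")) {
    child <- c(child, paste0(par_s, bases)); pz <- c(pz, par_z)
  }
  # retention needs Z_child >= Z_parent for >= 1 generating parent, i.e.
  # Z_child >= min over that child's parents
  agg <- tapply(pz, child, min)
  cand <- names(agg)
  thr <- as.numeric(agg)
  F_s <- count_containing_reads(cand, pool)
  present <- F_s > 0L            # F = 0 => Z < 0 <= parent Z: never kept
  if (!any(present))
    return(data.frame(string = character(0), length = integer(0),
                      F = integer(0), P = numeric(0), Z = numeric(0)))
  cand <- cand[present]; thr <- thr[present]; F_s <- F_s[present]
  lt <- pool_length_table(pool)
  P_s <- .batch_length_averaged_prob(cand, alphabet_probs(probs), lt,
                                     pool$N)
  ok <- P_s > 0 & P_s < 1
  Z <- rep(NA_real_, length(cand))
  Z[ok] <- z_score(F_s[ok], pool$N, P_s[ok])
  keep <- ok & Z >= thr
  out <- data.frame(string = cand[keep], length = nchar(cand[keep]),
                    F = F_s[keep], P = P_s[keep], Z = Z[keep])
  attr(out, "n_candidates") <- length(agg)
  attr(out, "n_z_evaluated") <- sum(ok)
  out[order(out$string), , drop = FALSE]
}

#' Select over-represented strings by pruned extension search
#'
#' Runs the full selection: score all \code{l_min}-mers, drop those with
#' negative Z, then repeatedly extend survivors by one base (keeping a
#' child only if its Z-score does not fall below a generating parent's)
#' until \code{l_max}.  The selected set is the union of survivors of every
#' length; selection is deterministic given pool and configuration.
#'
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities (default estimated from the pool).
#' @param config a \code{\link{search_config}}.
#' @return An object of class \code{SelectedStrings}: list with
#'   \code{strings} (data.frame: string, length, F, P, Z), \code{m} (number
#'   selected), \code{per_length} (survivors per length),
#'   \code{n_candidates} and \code{n_z_evaluated} (search-effort counters),
#'   \code{search_space} (exhaustive count for the same length range), and
#'   \code{config}.
#' @export
select_strings <- function(pool, probs = estimate_base_probs(pool),
                           config = search_config()) {
  stopifnot(inherits(pool, "SequencePool"), inherits(config, "SearchConfig"))
  min_len <- min(nchar(pool$sequence))
  if (config$l_max > min_len)
    warning("l_max (", config$l_max, ") exceeds the shortest read length (",
            min_len, "); long strings cannot occur in short reads")
  level <- enumerate_seeds(pool, probs, config)
  if (nrow(level) == 0L)
    stop("no seed string of length ", config$l_min,
         " has a non-negative Z-score; nothing to select", call. = FALSE)
  levels <- list(level)
  n_cand <- 4^config$l_min
  n_zeval <- 4^config$l_min
  l <- config$l_min
  while (l + 1L <= config$l_max && nrow(level) > 0L) {
    level <- extend_strings(level, pool, probs, config$extend)
    n_cand <- n_cand + (attr(level, "n_candidates") %||% 0)
    n_zeval <- n_zeval + (attr(level, "n_z_evaluated") %||% 0)
    l <- l + 1L
    if (nrow(level) > 0L) levels[[length(levels) + 1L]] <- level
  }
  strings <- do.call(rbind, lapply(levels, function(d) {
    attr(d, "n_candidates") <- NULL; attr(d, "n_z_evaluated") <- NULL; d
  }))
  rownames(strings) <- NULL
  per_length <- vapply(levels, nrow, integer(1))
  names(per_length) <- vapply(levels, function(d) d$length[1L], numeric(1))
  structure(list(strings = strings,
                 m = nrow(strings),
                 per_length = per_length,
                 n_candidates = n_cand,
                 n_z_evaluated = n_zeval,
                 search_space = search_space_size(config$l_min,
                                                 config$l_max),
                 config = config),
            class = "SelectedStrings")
}

#' @export
print.SelectedStrings <- function(x, ...) {
  cat(sprintf(
    "SelectedStrings: m = %d strings (lengths %d-%d), %s Z-evaluations (%.3g%% of exhaustive %s)\n",
    x$m, x$config$l_min, x$config$l_max,
    format(x$n_z_evaluated, big.mark = ","),
    100 * x$n_z_evaluated / x$search_space,
    format(x$search_space, big.mark = ",")))
  cat("  survivors per length: ",
      paste(names(x$per_length), x$per_length, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top strings by exhaustive enumeration over observed strings
#'
#' Reference for validating the pruned search: for each requested length,
#' every string actually occurring in at least one read is scored and the
#' top \code{n_top} by Z-score returned.  Feasible for moderate pools and
#' lengths; the pruned search exists precisely because this does not scale.
#'
#' @param pool a \code{\link{sequence_pool}}.
#' @param probs base probabilities (default estimated from the pool).
#' @param lengths integer vector of string lengths to scan.
#' @param n_top how many top strings per length (default 1).
#' @return data.frame: \code{string}, \code{length}, \code{F}, \code{P},
#'   \code{Z}, \code{rank_in_length}.
#' @export
exhaustive_top_strings <- function(pool, probs = estimate_base_probs(pool),
                                   lengths, n_top = 1L) {
  stopifnot(inherits(pool, "SequencePool"))
  probs <- alphabet_probs(probs)
  lt <- pool_length_table(pool)
  out <- list()
  for (l in as.integer(lengths)) {
    seq_l <- nchar(pool$sequence)
    idx <- which(seq_l >= l)
    if (length(idx) == 0L) next
    # all distinct (read, l-mer) pairs, then sum read counts per l-mer
    pieces <- lapply(idx, function(i) {
      st <- seq_len(seq_l[i] - l + 1L)
      unique(substring(pool$sequence[i], st, st + l - 1L))
    })
    kmer <- unlist(pieces)
    wts <- rep(pool$count[idx], lengths(pieces))
    Ftab <- rowsum(wts, group = kmer)
    strings <- rownames(Ftab)
    F_s <- as.integer(Ftab[, 1L])
    P_s <- .batch_length_averaged_prob(strings, probs, lt, pool$N)
    ok <- P_s > 0 & P_s < 1
    Z <- rep(NA_real_, length(strings))
    Z[ok] <- z_score(F_s[ok], pool$N, P_s[ok])
    ord <- order(-Z, strings, method = "radix", na.last = TRUE)
    take <- head(ord[ok[ord]], n_top)
    out[[length(out) + 1L]] <-
      data.frame(string = strings[take], length = l, F = F_s[take],
                 P = P_s[take], Z = Z[take],
                 rank_in_length = seq_along(take))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
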