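# Cross-length ranking and greedy cluster extraction.
#
# Z-scores grow with string length under the extension rule, so raw Z is
# not comparable across lengths.  Within each length class of the selected
# set, Z is standardized to Z* = (Z - mean) / sd; strings are ranked by Z*
# and clusters extracted greedily: the i-th cluster is every remaining
# sequence containing the i-th ranked string.

#' Normalize Z-scores within string-length classes
#'
#' For each length class of the selected strings, the class mean and
#' standard deviation of Z are estimated from the selected strings only,
#' and \eqn{Z^* = (Z - \hat\mu_{|s|}) / \hat\sigma_{|s|}} is assigned.
#' The sample (n-1) standard deviation is used; a class with a single
#' string gets \eqn{Z^* = 0} (placed at its class mean).
#'
#' @param selected a \code{SelectedStrings} object from
#'   \code{\link{select_strings}}, or its \code{strings} data.frame.
#' @return the strings data.frame with a \code{Z_star} column, ordered by
#'   decreasing \code{Z_star}.
#' @export
normalize_z <- function(selected) {
  df <- if (inherits(selected, "SelectedStrings")) selected$strings
        else selected
  stopifnot(is.data.frame(df), nrow(df) >= 1L,
            all(c("string", "length", "Z") %in% names(df)))
  zs <- numeric(nrow(df))
  for (l in unique(df$length)) {
    i <- df$length == l
    z <- df$Z[i]
    if (sum(i) < 2L || sd(z) == 0) {
      zs[i] <- 0
    } else {
      zs[i] <- (z - mean(z)) / sd(z)
    }
  }
  df$Z_star <- zs
  df[order(-df$Z_star), , drop = FALSE]
}

#' Rank strings by normalized Z-score
#'
#' Orders strings by \code{Z_star} descending, breaking ties by raw
#' \code{Z} descending, then length descending, then lexicographically —
#' making the ranking fully deterministic.
#'
#' @param ranked data.frame with columns \code{string}, \code{length},
#'   \code{Z}, \code{Z_star} (from \code{\link{normalize_z}}).
#' @return the data.frame sorted in rank order with a \code{rank} column
#'   (1 = best).
#' @export
rank_strings <- function(ranked) {
  stopifnot(is.data.frame(ranked),
            all(c("string", "length", "Z", "Z_star") %in% names(ranked)))
  ord <- order(-ranked$Z_star, -ranked$Z, -ranked$length, ranked$string,
               method = "radix")
  out <- ranked[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Greedy clustering of sequences by ranked strings
#'
#' Iterates over the ranked strings: for each, all remaining unique
#' sequences containing it are extracted as the next cluster and removed.
#' An extraction that matches no remaining sequence does not consume a
#' cluster rank, so cluster ranks are consecutive over non-empty clusters.
#' Sequences containing no selected string remain unassigned
#' (\code{cluster = NA}).  Stops early once every sequence is assigned.
#'
#' @param pool a \code{\link{sequence_pool}}.
#' @param ranked ranked strings from \code{\link{rank_strings}}.
#' @return An object of class \code{ClusterAssignment}: list with
#'   \code{assignment} (data.frame: sequence, count, cluster,
#'   matched_string, string_Z_star), \code{K} (number of non-empty
#'   clusters), \code{cluster_sizes} (unique-sequence and read-count sizes
#'   per cluster) and \code{n_unassigned}.
#' @export
greedy_cluster <- function(pool, ranked) {
  stopifnot(inherits(pool, "SequencePool"), is.data.frame(ranked),
            all(c("string", "Z_star", "rank") %in% names(ranked)))
  n <- length(pool$sequence)
  cluster <- rep(NA_integer_, n)
  matched <- rep(NA_character_, n)
  zstar <- rep(NA_real_, n)
  # precomputed string -> sequence incidence (one multi-pattern scan per
  # string width); greedy extraction then just walks the hit lists in rank
  # order, which is observationally identical to re-scanning the remaining
  # sequences for every string
  strings <- ranked$string
  inc <- vector("list", length(strings))
  subject <- Biostrings::DNAStringSet(pool$sequence)
  max_w <- max(nchar(pool$sequence))
  for (w in unique(nchar(strings))) {
    if (w > max_w) next
    idx <- which(nchar(strings) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(strings[idx]))
    hits <- Biostrings::vwhichPDict(pd, subject)
    u <- unlist(hits)
    if (!length(u)) next
    si <- rep(seq_along(hits), lengths(hits))
    spl <- split(si, u)
    inc[idx[as.integer(names(spl))]] <- spl
  }
  n_left <- n
  k <- 0L
  for (i in seq_len(nrow(ranked))) {
    if (n_left == 0L) break
    hit <- inc[[i]]
    if (is.null(hit)) next
    hit <- hit[is.na(cluster[hit])]
    if (!length(hit)) next
    k <- k + 1L
    cluster[hit] <- k
    matched[hit] <- strings[i]
    zstar[hit] <- ranked$Z_star[i]
    n_left <- n_left - length(hit)
  }
  assignment <- data.frame(sequence = pool$sequence, count = pool$count,
                           cluster = cluster, matched_string = matched,
                           string_Z_star = zstar,
                           stringsAsFactors = FALSE)
  sizes <- if (k > 0L) {
    data.frame(
      cluster = seq_len(k),
      n_unique = as.integer(table(factor(cluster, levels = seq_len(k)))),
      n_reads = as.integer(rowsum(
        assignment$count[!is.na(cluster)],
        group = factor(cluster[!is.na(cluster)], levels = seq_len(k)))))
  } else {
    data.frame(cluster = integer(0), n_unique = integer(0),
               n_reads = integer(0))
  }
  structure(list(assignment = assignment, K = k, cluster_sizes = sizes,
                 n_unassigned = sum(is.na(cluster))),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf(
    "ClusterAssignment: %d clusters over %d unique sequences (%d unassigned)\n",
    x$K, nrow(x$assignment), x$n_unassigned))
  if (x$K > 0L) {
    top <- head(x$cluster_sizes, 5L)
    cat("  top clusters (unique/reads): ",
        paste(sprintf("#%d %d/%d", top$cluster, top$n_unique, top$n_reads),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Write cluster assignments as TSV
#'
#' Columns: sequence, count, cluster_rank (NA for unassigned),
#' matched_string, string_Zstar.
#'
#' @param clusters a \code{ClusterAssignment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  stopifnot(inherits(clusters, "ClusterAssignment"))
  df <- clusters$assignment
  names(df) <- c("sequence", "count", "cluster_rank", "matched_string",
                 "string_Zstar")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write ranked strings as TSV
#'
#' Columns: string, length, F, P, Z, Z_star, rank.
#'
#' @param ranked ranked strings from \code{\link{rank_strings}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_strings_tsv <- function(ranked, path) {
  stopifnot(is.data.frame(ranked))
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
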