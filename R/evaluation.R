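# Cluster-ranking accuracy against binding labels.
#
# The evaluation protocol orders labeled sequences by the rank of the
# cluster they fall in (unassigned sequences strictly last) and asks how
# well that order separates binders from non-binders, summarized as the
# area under the ROC curve.

#' Read a binding-label table
#'
#' Expects a TSV with columns \code{sequence} and \code{binding}
#' (\code{yes}/\code{no}, or TRUE/FALSE, or 1/0).  Sequences are normalized
#' the same way as \code{\link{read_pool}} (uppercase, U to T) so they
#' match pool sequences exactly.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{sequence} (character) and
#'   \code{binding} (logical).
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "binding") %in% names(df)))
    stop("labels file needs columns 'sequence' and 'binding'",
         call. = FALSE)
  df$sequence <- chartr("U", "T", toupper(df$sequence))
  b <- tolower(as.character(df$binding))
  df$binding <- b %in% c("yes", "true", "1", "y")
  df[, c("sequence", "binding")]
}

#' Attach cluster ranks to labeled sequences
#'
#' @param clusters a \code{ClusterAssignment} from
#'   \code{\link{greedy_cluster}}.
#' @param labels data.frame with columns \code{sequence} and \code{binding}
#'   (see \code{\link{read_labels}}).
#' @return data.frame: \code{sequence}, \code{binding},
#'   \code{cluster_rank} (NA when the sequence is absent from the pool or
#'   unassigned).
#' @export
label_assignments <- function(clusters, labels) {
  stopifnot(inherits(clusters, "ClusterAssignment"), is.data.frame(labels),
            all(c("sequence", "binding") %in% names(labels)))
  i <- match(labels$sequence, clusters$assignment$sequence)
  data.frame(sequence = labels$sequence,
             binding = as.logical(labels$binding),
             cluster_rank = clusters$assignment$cluster[i],
             stringsAsFactors = FALSE)
}

#' ROC/AUC of a cluster ranking against binding labels
#'
#' Sequences are scored by \code{-cluster_rank} (so rank 1 scores highest);
#' sequences with no cluster (\code{NA}) score strictly below every real
#' cluster.  Sequences sharing a cluster are tied.  The AUC is the
#' Mann-Whitney U statistic with half credit for ties, divided by
#' \eqn{n_{pos} n_{neg}}; the ROC curve steps through clusters in rank
#' order.
#'
#' @param labeled data.frame with columns \code{binding} (logical) and
#'   \code{cluster_rank} (positive integer or NA), e.g. from
#'   \code{\link{label_assignments}}.
#' @return list with \code{auc} and \code{roc}, a data.frame of
#'   (\code{fpr}, \code{tpr}) points from (0,0) to (1,1).
#' @export
roc_auc_by_cluster_rank <- function(labeled) {
  stopifnot(is.data.frame(labeled),
            all(c("binding", "cluster_rank") %in% names(labeled)))
  y <- as.logical(labeled$binding)
  if (anyNA(y)) stop("binding labels must not be NA", call. = FALSE)
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: need at least one binding and one non-binding ",
         "sequence", call. = FALSE)
  r <- labeled$cluster_rank
  score <- ifelse(is.na(r), -Inf, -as.numeric(r))
  # Mann-Whitney with midranks
  rk <- rank(score, ties.method = "average")
  auc <- (sum(rk[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  # ROC points: thresholds descending through distinct scores
  ord <- order(-score)
  ys <- y[ord]; ss <- score[ord]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- !duplicated(grp, fromLast = TRUE)    # end of each tie group
  roc <- data.frame(fpr = c(0, fp[last] / nneg),
                    tpr = c(0, tp[last] / npos))
  list(auc = auc, roc = roc)
}
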