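# End-to-end pipeline: read -> filter -> base probabilities -> string
# selection -> normalization/ranking -> greedy clustering -> optional ROC.

#' Run the full string-based clustering pipeline
#'
#' @param input path to a FASTA/FASTQ file (optionally gzipped), or a
#'   \code{\link{sequence_pool}} directly.
#' @param format input format for file input, see \code{\link{read_pool}}.
#' @param min_count frequency cutoff: unique sequences with read count
#'   below this are dropped before analysis (default 10).
#' @param l_min,l_max string length range searched (defaults 5 and 10).
#' @param extend extension direction, see \code{\link{search_config}}.
#' @param labels optional binding labels for ROC evaluation: a TSV path or
#'   a data.frame with columns \code{sequence}, \code{binding}.
#' @param out_prefix optional output prefix; when given, writes
#'   \code{<prefix>_strings.tsv}, \code{<prefix>_clusters.tsv},
#'   \code{<prefix>_summary.json} and, with labels,
#'   \code{<prefix>_roc.tsv}.
#' @return (invisibly when writing files) a list with elements \code{pool},
#'   \code{probs}, \code{selected}, \code{ranked}, \code{clusters},
#'   \code{evaluation} (NULL without labels) and \code{summary}.
#' @examples
#' sp <- generate_pool(synthetic_pool_spec(n_reads = 400, seed = 7,
#'                                         nominal_length = 20,
#'                                         motifs = list(list(
#'                                           string = "TATGGACTTC",
#'                                           prevalence = 0.3))))
#' res <- run_fsbc(sp$pool, min_count = 1, l_min = 5, l_max = 6)
#' res$ranked$string[1]
#' @export
run_fsbc <- function(input, format = "auto", min_count = 10L,
                     l_min = 5L, l_max = 10L, extend = "both",
                     labels = NULL, out_prefix = NULL) {
  pool <- if (inherits(input, "SequencePool")) input
          else read_pool(input, format)
  config <- search_config(l_min, l_max, extend)
  pool <- filter_by_frequency(pool, min_count)
  probs <- estimate_base_probs(pool)
  selected <- select_strings(pool, probs, config)
  ranked <- rank_strings(normalize_z(selected))
  clusters <- greedy_cluster(pool, ranked)

  evaluation <- NULL
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- read_labels(labels)
    labeled <- label_assignments(clusters, labels)
    evaluation <- roc_auc_by_cluster_rank(labeled)
    evaluation$labeled <- labeled
  }

  summary <- list(
    N = pool$N,
    n_unique = length(pool$sequence),
    base_probs = as.list(round(probs, 6)),
    m = selected$m,
    per_length = as.list(selected$per_length),
    n_z_evaluated = selected$n_z_evaluated,
    search_space = selected$search_space,
    K = clusters$K,
    n_unassigned = clusters$n_unassigned,
    auc = if (!is.null(evaluation)) evaluation$auc else NULL,
    parameters = list(min_count = min_count, l_min = config$l_min,
                      l_max = config$l_max, extend = config$extend),
    package_version = as.character(utils::packageVersion("fsbc")))

  res <- list(pool = pool, probs = probs, selected = selected,
              ranked = ranked, clusters = clusters,
              evaluation = evaluation, summary = summary)

  if (!is.null(out_prefix)) {
    write_strings_tsv(ranked, paste0(out_prefix, "_strings.tsv"))
    write_clusters_tsv(clusters, paste0(out_prefix, "_clusters.tsv"))
    jsonlite::write_json(summary, paste0(out_prefix, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(evaluation))
      write.table(evaluation$roc, paste0(out_prefix, "_roc.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
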