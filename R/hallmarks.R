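#' Cancer-hallmark profiling of dysregulated circuits
#'
#' Circuit effectors carry text-mining association scores to the ten
#' canonical hallmarks of cancer. After thresholding the scores, each
#' differentially activated circuit contributes one count to every
#' hallmark any of its effector genes is associated with, giving a
#' per-condition hallmark profile (radar-plot-ready counts and
#' fractions).
#'
#' @name hallmarks
NULL

#' Threshold hallmark association scores
#'
#' Keeps annotation rows with score >= cutoff (inclusive). The default
#' 0.15 corresponds to the upper 5% of association scores in the source
#' annotation.
#'
#' @param annotations Data frame (or TSV path) with columns
#'   \code{gene, hallmark, score}.
#' @param cutoff Minimum score kept (default 0.15).
#' @return Filtered annotation data frame.
#' @export
filter_chat <- function(annotations, cutoff = 0.15) {
  ann <- .read_table_arg(annotations)
  req <- c("gene", "hallmark", "score")
  if (!all(req %in% names(ann)))
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  ann$score <- as.numeric(ann$score)
  if (!nrow(ann)) {
    warning("empty hallmark annotation table")
    return(ann)
  }
  if (any(ann$score < 0)) stop("negative hallmark scores")
  ann[ann$score >= cutoff, , drop = FALSE]
}

#' Hallmark profile of significant circuits per condition
#'
#' A circuit counts toward every hallmark that any gene of its effector
#' node passes the score cutoff for (a multi-gene effector passes if any
#' member gene does); circuits whose effector genes carry no retained
#' annotation are tallied as "unannotated". Counts are per circuit, so a
#' multi-hallmark effector contributes to several hallmarks and hallmark
#' counts may sum to more than the number of circuits.
#'
#' @param significant Named list: per condition, character vector of
#'   significant circuit ids.
#' @param catalog The \code{circuit_catalog} the ids refer to.
#' @param annotations Hallmark annotations, already thresholded with
#'   [filter_chat()].
#' @return Data frame \code{condition, hallmark, count, fraction}
#'   (fraction of that condition's significant circuits).
#' @export
hallmark_profile <- function(significant, catalog, annotations) {
  ann <- .read_table_arg(annotations)
  hallmarks <- sort(unique(as.character(ann$hallmark)))
  rows <- list()
  for (cond in names(significant)) {
    ids <- significant[[cond]]
    tally <- stats::setNames(rep(0L, length(hallmarks) + 1L),
                             c(hallmarks, "unannotated"))
    for (id in ids) {
      cc <- catalog[[id]]
      if (is.null(cc)) stop("circuit '", id, "' not in catalog")
      eff_genes <- cc$genes[[cc$effector]]
      hm <- unique(as.character(ann$hallmark[ann$gene %in% eff_genes]))
      if (!length(hm)) hm <- "unannotated"
      tally[hm] <- tally[hm] + 1L
    }
    denom <- max(length(ids), 1L)
    rows[[cond]] <- data.frame(condition = cond,
                               hallmark = names(tally),
                               count = unname(tally),
                               fraction = unname(tally) / denom)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
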