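#' Transcription-factor target enrichment analysis
#'
#' TF activity is estimated indirectly: for each TF regulon (graded
#' target set), a univariate logistic regression of target membership on
#' the normalized rank of the differential-expression statistic yields a
#' log-odds ratio (slope); a positive slope means the TF's targets
#' concentrate in the up-regulated end of the ranking.
#'
#' @name tftea
NULL

.GRADE_LEVELS <- c("A", "B", "C", "D", "E")

#' Load TF regulons from GMT or graded TSV
#'
#' GMT lines are \code{tf<TAB>description<TAB>target...} (grade defaults
#' to A). TSV needs columns \code{tf, target, confidence} with grades
#' A (best) to E. Interactions with a grade worse than
#' \code{min_confidence} are dropped; regulons left with fewer than
#' \code{min_targets} targets are dropped with a message.
#'
#' @param table Path to a .gmt or .tsv file, or a data frame in the TSV
#'   shape.
#' @param min_confidence Worst grade kept (default "C", i.e. keep A-C).
#' @param min_targets Minimum regulon size (default 5).
#' @return Named list of regulons: each a list
#'   \code{tf, targets, confidences}.
#' @export
load_regulons <- function(table, min_confidence = "C", min_targets = 5) {
  stopifnot(min_confidence %in% .GRADE_LEVELS)
  if (is.character(table) && length(table) == 1L &&
      grepl("\\.gmt$", table, ignore.case = TRUE)) {
    lines <- readLines(table)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) < 3L) return(NULL)
      data.frame(tf = p[1], target = p[-(1:2)], confidence = "A")
    }))
  } else {
    df <- .read_table_arg(table)
    req <- c("tf", "target", "confidence")
    if (!all(req %in% names(df)))
      stop("regulon table must have columns: ", paste(req, collapse = ", "))
  }
  df$confidence <- toupper(trimws(as.character(df$confidence)))
  bad <- setdiff(unique(df$confidence), .GRADE_LEVELS)
  if (length(bad))
    stop("malformed confidence grade(s): ", paste(bad, collapse = ", "))
  keep <- match(df$confidence, .GRADE_LEVELS) <=
    match(min_confidence, .GRADE_LEVELS)
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df[c("tf", "target")]), , drop = FALSE]
  regs <- lapply(split(df, df$tf), function(d)
    list(tf = d$tf[1], targets = as.character(d$target),
         confidences = d$confidence))
  small <- vapply(regs, function(r) length(r$targets) < min_targets, TRUE)
  if (any(small))
    message(sum(small), " regulon(s) below ", min_targets,
            " targets dropped: ", paste(names(regs)[small], collapse = ", "))
  regs[!small]
}

#' Ranked gene list from a differential table
#'
#' Genes are ranked by the moderated t statistic (ties broken by gene id
#' for determinism) and assigned evenly spaced normalized ranks r in
#' [0, 1], 0 = most down-regulated, 1 = most up-regulated.
#'
#' @param diff_table Data frame with \code{feature_id} and a statistic
#'   column.
#' @param rank_by Statistic column (default \code{"t_mod"}).
#' @return Data frame \code{gene, stat, r}.
#' @export
ranked_genes <- function(diff_table, rank_by = "t_mod") {
  stopifnot(rank_by %in% names(diff_table))
  ord <- order(diff_table[[rank_by]], diff_table$feature_id)
  n <- nrow(diff_table)
  data.frame(gene = diff_table$feature_id[ord],
             stat = diff_table[[rank_by]][ord],
             r = if (n > 1) seq(0, 1, length.out = n) else 0.5,
             row.names = NULL)
}

#' Logistic-regression enrichment of one regulon on a ranked list
#'
#' Fits membership ~ normalized rank; the slope is the log-odds ratio
#' (LOR) of target membership per unit of rank, with a Wald p-value.
#'
#' @param ranked Data frame from [ranked_genes()].
#' @param regulon One regulon from [load_regulons()].
#' @param min_targets Minimum in-universe targets (default 5).
#' @param lor_cap Cap on |LOR| reported under complete separation.
#' @return One-row data frame \code{tf, n_targets, lor, p, separated,
#'   reason} (lor/p NA with a reason when the fit is degenerate).
#' @export
tftea_enrich <- function(ranked, regulon, min_targets = 5, lor_cap = 30) {
  y <- as.integer(ranked$gene %in% regulon$targets)
  n_in <- sum(y)
  na_row <- function(reason)
    data.frame(tf = regulon$tf, n_targets = n_in, lor = NA_real_,
               p = NA_real_, separated = FALSE, reason = reason)
  if (n_in < min_targets) return(na_row("fewer targets than min_targets"))
  if (n_in == length(y)) return(na_row("regulon covers all ranked genes"))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ r, data = data.frame(y = y, r = ranked$r),
               family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12,
                                            maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  lor <- unname(sm["r", "Estimate"])
  p <- unname(sm["r", "Pr(>|z|)"])
  if (separated) {
    lor <- sign(lor) * min(abs(lor), lor_cap)
    p <- 0
  }
  data.frame(tf = regulon$tf, n_targets = n_in, lor = lor, p = p,
             separated = separated, reason = NA_character_)
}

#' Enrichment of all regulons, per contrast, with cross-contrast summary
#'
#' Runs [tftea_enrich()] for every regulon on each contrast's ranked
#' list, BH-adjusts within each contrast, and summarizes per TF the
#' number of contrasts where it is significant plus the average LOR and
#' FDR over those contrasts.
#'
#' @param ranked_list One ranked data frame or a named list of them (one
#'   per contrast).
#' @param regulons Output of [load_regulons()].
#' @param alpha FDR threshold for the summary (default 0.05).
#' @param min_targets Passed to [tftea_enrich()].
#' @return List with \code{tables} (per contrast, FDR-sorted) and
#'   \code{summary} (data frame \code{tf, n, lor, fdr}).
#' @export
tftea_all <- function(ranked_list, regulons, alpha = 0.05,
                      min_targets = 5) {
  if (is.data.frame(ranked_list)) ranked_list <- list(contrast = ranked_list)
  if (!length(regulons)) {
    warning("no usable regulons")
    empty <- data.frame(tf = character(), n = integer(), lor = numeric(),
                        fdr = numeric())
    return(list(tables = list(), summary = empty))
  }
  tables <- lapply(ranked_list, function(rk) {
    tab <- do.call(rbind, lapply(regulons, tftea_enrich, ranked = rk,
                                 min_targets = min_targets))
    tab$fdr <- bh_adjust(tab$p)
    rownames(tab) <- NULL
    tab[order(tab$fdr, tab$p), ]
  })
  tfs <- sort(unique(unlist(lapply(tables, `[[`, "tf"))))
  summ <- do.call(rbind, lapply(tfs, function(tf) {
    hits <- lapply(tables, function(t) {
      row <- t[t$tf == tf, ]
      if (nrow(row) && !is.na(row$fdr) && row$fdr < alpha) row else NULL
    })
    hits <- hits[!vapply(hits, is.null, TRUE)]
    if (!length(hits)) return(NULL)
    data.frame(tf = tf, n = length(hits),
               lor = mean(vapply(hits, `[[`, 0, "lor")),
               fdr = mean(vapply(hits, `[[`, 0, "fdr")))
  }))
  if (is.null(summ))
    summ <- data.frame(tf = character(), n = integer(), lor = numeric(),
                       fdr = numeric())
  rownames(summ) <- NULL
  summ <- summ[order(-summ$n, summ$fdr), ]
  list(tables = tables, summary = summ)
}
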