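#' Survival association of circuit activities
#'
#' Overall-survival outcomes are built from clinical metadata (time = the
#' maximum of days-to-death and days-to-last-follow-up, censored by vital
#' status), each circuit's activity is screened with a univariate Cox
#' proportional-hazards model (Efron ties), Wald p-values are BH-adjusted
#' across circuits, the proportional-hazards assumption is checked with a
#' scaled-Schoenfeld-residual score test, and Kaplan-Meier comparisons
#' use high/low groups at a +/-0.5 activity z-score cutoff.
#'
#' @name survival-screen
NULL

.DEAD_TOKENS <- c("dead", "deceased")
.ALIVE_TOKENS <- c("alive", "living", "not reported")

#' Build censored survival records from clinical metadata
#'
#' @param clinical Data frame (or TSV path) with columns
#'   \code{sample_id}, \code{days_to_death},
#'   \code{days_to_last_follow_up}, \code{vital_status}. Either day field
#'   may be missing per row; time is the maximum of the available ones.
#' @return Data frame \code{sample_id, time, event} (attribute
#'   \code{n_dropped} counts rows without a usable positive time).
#' @export
build_survival <- function(clinical) {
  cl <- .read_table_arg(clinical)
  req <- c("sample_id", "days_to_death", "days_to_last_follow_up",
           "vital_status")
  if (!all(req %in% names(cl)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  dd <- suppressWarnings(as.numeric(cl$days_to_death))
  df <- suppressWarnings(as.numeric(cl$days_to_last_follow_up))
  time <- pmax(dd, df, na.rm = TRUE)
  vs <- tolower(trimws(as.character(cl$vital_status)))
  bad <- setdiff(unique(vs), c(.DEAD_TOKENS, .ALIVE_TOKENS))
  if (length(bad))
    stop("unparseable vital_status token(s): ", paste(bad, collapse = ", "))
  event <- vs %in% .DEAD_TOKENS
  usable <- !is.na(time) & time > 0
  n_dropped <- sum(!usable)
  if (n_dropped)
    message(n_dropped, " clinical row(s) dropped (no usable positive time)")
  out <- data.frame(sample_id = as.character(cl$sample_id)[usable],
                    time = time[usable], event = event[usable])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-circuit univariate Cox screen
#'
#' One Cox proportional-hazards fit per circuit (Efron tie handling),
#' with Wald p-values BH-adjusted across all screened circuits, Harrell's
#' concordance, and a proportional-hazards diagnostic p-value. Circuits
#' with constant activity are kept in the table as NA with p = 1 so the
#' BH denominator stays reproducible.
#'
#' @param activity An \code{activity_matrix} or plain circuits x samples
#'   matrix.
#' @param records Survival records from [build_survival()].
#' @param standardize Fit on activity z-scores so hazard ratios are per
#'   activity standard deviation (default FALSE: per activity unit, where
#'   extreme hazard ratios simply reflect the narrow activity scale).
#' @return Data frame with one row per circuit: \code{circuit_id, beta,
#'   hr, ci_low, ci_high, concordance, p, fdr, p_zph}.
#' @export
cox_per_circuit <- function(activity, records, standardize = FALSE) {
  vals <- if (inherits(activity, "activity_matrix")) activity$values
          else activity
  common <- intersect(colnames(vals), records$sample_id)
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between activity and records")
  rec <- records[match(common, records$sample_id), ]
  if (sum(rec$event) < 2L) stop("need at least 2 observed events")
  vals <- vals[, common, drop = FALSE]
  surv <- survival::Surv(rec$time, rec$event)

  one <- function(a) {
    if (anyNA(a) || stats::sd(a) == 0)
      return(list(beta = NA_real_, hr = NA_real_, lo = NA_real_,
                  hi = NA_real_, conc = NA_real_, p = 1,
                  zph = NA_real_))
    if (standardize) a <- (a - mean(a)) / stats::sd(a)
    fit <- tryCatch(
      survival::coxph(surv ~ a, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(surv ~ a, ties = "efron"))
      })
    if (is.null(fit))
      return(list(beta = NA_real_, hr = NA_real_, lo = NA_real_,
                  hi = NA_real_, conc = NA_real_, p = 1,
                  zph = NA_real_))
    sm <- summary(fit)
    zph <- zph_test(fit)
    list(beta = unname(stats::coef(fit)),
         hr = unname(sm$conf.int[1, "exp(coef)"]),
         lo = unname(sm$conf.int[1, "lower .95"]),
         hi = unname(sm$conf.int[1, "upper .95"]),
         conc = unname(sm$concordance["C"]),
         p = unname(sm$coefficients[1, "Pr(>|z|)"]),
         zph = zph)
  }
  res <- apply(vals, 1L, one)
  out <- data.frame(
    circuit_id = rownames(vals),
    beta = vapply(res, `[[`, 0, "beta"),
    hr = vapply(res, `[[`, 0, "hr"),
    ci_low = vapply(res, `[[`, 0, "lo"),
    ci_high = vapply(res, `[[`, 0, "hi"),
    concordance = vapply(res, `[[`, 0, "conc"),
    p = vapply(res, `[[`, 0, "p"),
    row.names = NULL
  )
  out$fdr <- bh_adjust(out$p)
  out$p_zph <- vapply(res, `[[`, 0, "zph")
  out[order(out$fdr, out$p), ]
}

#' Proportional-hazards diagnostic
#'
#' Score test for a zero slope of the scaled Schoenfeld residuals against
#' Kaplan-Meier-transformed time (the cox.zph diagnostic).
#'
#' @param fit A \code{coxph} fit.
#' @param transform Time transform (default \code{"km"}).
#' @return The diagnostic p-value (NA if it cannot be computed).
#' @export
zph_test <- function(fit, transform = "km") {
  if (fit$nevent < 3L) return(NA_real_)
  z <- tryCatch(survival::cox.zph(fit, transform = transform,
                                  global = FALSE),
                error = function(e) NULL)
  if (is.null(z)) return(NA_real_)
  unname(z$table[1, "p"])
}

#' High/low activity groups by z-score cutoff
#'
#' Activities are scaled to z-scores; samples above +cutoff are "high",
#' below -cutoff "low", the rest "excluded". With the default 0.5 cutoff
#' and normal activities each tail captures about pnorm(-0.5) = 31% of
#' samples.
#'
#' @param a Per-sample activity vector (named by sample).
#' @param cutoff_z z-score cutoff (default 0.5).
#' @return Factor with levels high/low/excluded, named by sample.
#' @export
km_groups <- function(a, cutoff_z = 0.5) {
  if (length(a) < 3L) stop("need at least 3 samples")
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0) stop("zero-variance activity")
  z <- (a - mean(a)) / s
  lab <- ifelse(z > cutoff_z, "high", ifelse(z < -cutoff_z, "low",
                                             "excluded"))
  if (all(lab == "excluded"))
    warning("all samples within the z-score cutoff; no high/low groups")
  factor(lab, levels = c("high", "low", "excluded"))
}

#' Kaplan-Meier curves and log-rank comparison of high vs low groups
#'
#' @param groups Factor from [km_groups()], aligned with \code{records}.
#' @param records Survival records from [build_survival()].
#' @return List with \code{curves} (data frame \code{group, time,
#'   n_risk, survival}) and \code{logrank_p} (NA when either group is
#'   empty or no events are observed).
#' @export
km_estimate <- function(groups, records) {
  stopifnot(length(groups) == nrow(records))
  keep <- groups %in% c("high", "low")
  g <- droplevels(factor(groups[keep], levels = c("high", "low")))
  rec <- records[keep, ]
  if (!nrow(rec) || sum(rec$event) < 1L)
    return(list(curves = data.frame(group = character(), time = numeric(),
                                    n_risk = numeric(),
                                    survival = numeric()),
                logrank_p = NA_real_))
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = rec)
  strata <- if (is.null(sf$strata)) {
    rep(levels(g)[1], length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  curves <- data.frame(group = strata, time = sf$time, n_risk = sf$n.risk,
                       survival = sf$surv)
  logrank_p <- NA_real_
  if (nlevels(g) == 2L && all(table(g) > 0)) {
    sd_ <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ g,
                                       data = rec),
                    error = function(e) NULL)
    if (!is.null(sd_))
      logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }
  list(curves = curves, logrank_p = logrank_p)
}
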