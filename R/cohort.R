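# Endpoint derivation and cohort summaries from biopsy / laboratory fields.

#' Absolute bone-marrow involvement
#'
#' ABS, the percentage of the entire marrow space (cellular plus fatty)
#' infiltrated, is the product of marrow cellularity and REL:
#' `abs = cellularity * rel / 100`. It never exceeds either factor.
#'
#' @param cellularity percent in \[0,100\].
#' @param rel percent of cellular marrow involved, in \[0,100\].
#' @return ABS in percent.
#' @export
compute_abs <- function(cellularity, rel) {
  if (any(cellularity < 0 | cellularity > 100) || any(rel < 0 | rel > 100))
    stop("cellularity and rel must lie in [0,100]")
  cellularity * rel / 100
}

#' Dichotomize the cohort at an endpoint
#'
#' Endpoints: `involved` (biopsy status); `rel5`/`rel10` and `abs5`/`abs10`
#' (strictly greater than 5\% / 10\% is positive, so a record at exactly the
#' threshold is negative); `ki67` (index >= 30\% is positive, evaluated in
#' involved patients only).
#'
#' @param records cohort data frame with the required field.
#' @param endpoint one of
#'   `c("involved","rel5","rel10","abs5","abs10","ki67")`.
#' @return a list: `labels` (logical, over the evaluated subset), `subset`
#'   (row indices evaluated), `n`, `n_positive`, `percent_positive`
#'   (rounded half-up to one decimal).
#' @export
stratify <- function(records, endpoint = c("involved", "rel5", "rel10",
                                           "abs5", "abs10", "ki67")) {
  endpoint <- match.arg(endpoint)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty cohort")
  need <- switch(endpoint,
                 involved = "involved",
                 rel5 = "rel", rel10 = "rel",
                 abs5 = "abs", abs10 = "abs",
                 ki67 = c("ki67", "involved"))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing field(s): ", paste(miss, collapse = ", "))
  subset <- seq_len(nrow(records))
  labels <- switch(endpoint,
                   involved = as.logical(records$involved),
                   rel5 = records$rel > 5,
                   rel10 = records$rel > 10,
                   abs5 = records$abs > 5,
                   abs10 = records$abs > 10,
                   ki67 = {
                     subset <- which(as.logical(records$involved))
                     records$ki67[subset] >= 30
                   })
  if (anyNA(labels)) stop("missing values in endpoint field")
  n <- length(labels)
  npos <- sum(labels)
  list(labels = labels, subset = subset, n = n, n_positive = npos,
       percent_positive = round_half_up(100 * npos / n, 1))
}

#' Baseline-characteristics cohort summary
#'
#' Mean +/- sample SD (n-1 denominator) for the continuous fields, count
#' and half-up-rounded percentage for the categorical ones, overall and —
#' when a `split` factor is given — per split level.
#'
#' @param records cohort data frame.
#' @param split optional factor (e.g. train/test membership) for per-split
#'   columns.
#' @return a data frame with one row per characteristic.
#' @export
summarize_cohort <- function(records, split = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty cohort")
  groups <- list(overall = seq_len(nrow(records)))
  if (!is.null(split))
    groups <- c(groups, split(seq_len(nrow(records)), split))
  cont <- c(rel = "REL (%)", abs = "ABS (%)", cellularity = "Cellularity (%)",
            wbc = "WBC (1e9/L)", ldh = "LDH (U/L)", ki67 = "Ki-67 (%)")
  fmt_cont <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  fmt_cat <- function(k, n) sprintf("%d/%d (%.1f%%)", k, n,
                                    round_half_up(100 * k / n, 1))
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    r <- records[idx, , drop = FALSE]
    vals <- c(`Bone marrow involvement` = fmt_cat(sum(r$involved), nrow(r)),
              vapply(names(cont), function(cn) fmt_cont(r[[cn]]), ""))
    names(vals) <- c("Bone marrow involvement", unname(cont))
    rows[[g]] <- vals
  }
  out <- data.frame(characteristic = names(rows[[1]]),
                    do.call(cbind, rows), row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}
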