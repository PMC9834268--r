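#' Join assignments and measurements into a tidy screen table
#'
#' Inner join on `anchor_id`: each anchor's decoded condition is replicated
#' across its measurement timepoints. Drug and dose come from the codebook,
#' the dose reported on the delivered (post-merge) scale via the codebook's
#' merge dilution factor. UNASSIGNED anchors are carried (flagged
#' `"unassigned"` in `qc_flags`) but excluded from all condition-level
#' statistics downstream; segmentation failures keep their `"no_spheroid"`
#' flag.
#'
#' @param assignments data frame from [decode_chip()].
#' @param measurements data frame from [score_chip()] (rbind several frames
#'   for a time course).
#' @param codebook a `barcode_codebook`.
#' @param immune_arm logical flag stored per row (co-culture arms).
#' @return a data frame of class `screen_table`, one row per
#'   (anchor, timepoint): `anchor_id`, `condition_label`, `drug`,
#'   `dose_umol` (post-merge), `dose_library_umol`, `timepoint_h`,
#'   `diameter_um`, `viability`, `dead_fraction`, `mean_dead_intensity`,
#'   `immune_arm`, `qc_flags`.
#' @export
build_screen_table <- function(assignments, measurements, codebook,
                               immune_arm = FALSE) {
  stopifnot(inherits(codebook, "barcode_codebook"))
  if (anyDuplicated(assignments$anchor_id)) {
    stop("duplicate anchor_id in assignments")
  }
  dup <- duplicated(measurements[c("anchor_id", "timepoint_h")])
  if (any(dup)) {
    stop("duplicate (anchor, timepoint) measurement rows: anchor ",
         paste(unique(measurements$anchor_id[dup]), collapse = ", "))
  }
  asg <- assignments[c("anchor_id", "condition_label")]
  tab <- merge(measurements, asg, by = "anchor_id")
  code_info <- codebook$codes[c("condition_label", "drug", "dose_umol")]
  names(code_info)[3] <- "dose_library_umol"
  tab <- merge(tab, code_info, by = "condition_label", all.x = TRUE)
  tab$dose_umol <- tab$dose_library_umol / codebook$dilution_factor
  tab$immune_arm <- immune_arm
  unas <- is.na(tab$condition_label)
  tab$qc_flags <- ifelse(
    unas,
    ifelse(tab$qc_flags == "", "unassigned",
           paste(tab$qc_flags, "unassigned", sep = ";")),
    tab$qc_flags)
  ord <- order(tab$timepoint_h, tab$anchor_id)
  cols <- c("anchor_id", "condition_label", "drug", "dose_umol",
            "dose_library_umol", "timepoint_h", "diameter_um", "viability",
            "dead_fraction", "mean_dead_intensity", "immune_arm", "qc_flags")
  out <- tab[ord, cols]
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

# rows usable for condition-level statistics
usable_rows <- function(table) {
  table$qc_flags == "" & !is.na(table$condition_label) &
    !is.na(table$viability)
}

#' Dose-response summary for one drug
#'
#' Mean and sd of `mean_dead_intensity` and `viability` per dose, ordered by
#' dose, with group sizes. Rows flagged in QC are excluded.
#'
#' @param table a [build_screen_table()] result.
#' @param drug drug label present in the table.
#' @param timepoint_h optional: restrict to one timepoint.
#' @return data frame: `drug`, `dose_umol`, `n`, `mean_dead_intensity_mean`,
#'   `mean_dead_intensity_sd`, `viability_mean`, `viability_sd`.
#' @export
dose_response_summary <- function(table, drug, timepoint_h = NULL) {
  if (!drug %in% table$drug) stop("unknown drug label: ", drug)
  sel <- usable_rows(table) & table$drug == drug
  if (!is.null(timepoint_h)) sel <- sel & table$timepoint_h == timepoint_h
  sub <- table[sel, ]
  if (nrow(sub) == 0L) stop("no usable rows for drug ", drug)
  agg <- function(v, f) tapply(v, sub$dose_umol, f)
  doses <- sort(unique(sub$dose_umol))
  key <- as.character(doses)
  data.frame(
    drug = drug,
    dose_umol = doses,
    n = as.integer(agg(sub$viability, length)[key]),
    mean_dead_intensity_mean = as.numeric(agg(sub$mean_dead_intensity, mean)[key]),
    mean_dead_intensity_sd = as.numeric(agg(sub$mean_dead_intensity, stats::sd)[key]),
    viability_mean = as.numeric(agg(sub$viability, mean)[key]),
    viability_sd = as.numeric(agg(sub$viability, stats::sd)[key]),
    row.names = NULL
  )
}

#' Growth and viability time courses
#'
#' Per condition and timepoint: median, quartiles and n of diameter and
#' viability - the paired series behind diameter-versus-viability boxplots.
#' QC-flagged rows are excluded.
#'
#' @param table a [build_screen_table()] result with >= 2 timepoints.
#' @param by grouping column (default `condition_label`).
#' @return data frame: group, `timepoint_h`, `n`, and median/q25/q75 for
#'   `diameter_um` and `viability`.
#' @export
growth_curves <- function(table, by = "condition_label") {
  if (length(unique(table$timepoint_h)) < 2L) {
    stop("growth_curves needs at least two timepoints")
  }
  sub <- table[usable_rows(table), ]
  groups <- interaction(sub[[by]], sub$timepoint_h, drop = TRUE)
  q <- function(v, p) tapply(v, groups, stats::quantile, probs = p)
  first <- !duplicated(groups)
  out <- data.frame(
    group = sub[[by]][first],
    timepoint_h = sub$timepoint_h[first],
    n = as.integer(table(groups)[as.character(groups[first])]),
    diameter_median = as.numeric(q(sub$diameter_um, 0.5)[as.character(groups[first])]),
    diameter_q25 = as.numeric(q(sub$diameter_um, 0.25)[as.character(groups[first])]),
    diameter_q75 = as.numeric(q(sub$diameter_um, 0.75)[as.character(groups[first])]),
    viability_median = as.numeric(q(sub$viability, 0.5)[as.character(groups[first])]),
    viability_q25 = as.numeric(q(sub$viability, 0.25)[as.character(groups[first])]),
    viability_q75 = as.numeric(q(sub$viability, 0.75)[as.character(groups[first])]),
    row.names = NULL
  )
  names(out)[1] <- by
  out[order(out[[by]], out$timepoint_h), ]
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Implemented from sums of squares rather than delegated to a model-fitting
#' routine: residual sums of squares of the nested dummy-coded least-squares
#' fits give Type II sums of squares, `SS(A | B)`, `SS(B | A)` and
#' `SS(AB | A, B)` (identical to the textbook balanced-design decomposition
#' when cell counts are equal). F statistics use the full-model residual mean
#' square.
#'
#' @param table data frame (e.g. a screen table).
#' @param response response column name (default `"viability"`).
#' @param factors length-2 character vector of factor column names
#'   (default condition and timepoint).
#' @param use_qc if `TRUE` (default) QC-flagged screen-table rows are dropped
#'   first; set `FALSE` for plain data frames.
#' @return an object of class `anova_result`: data frame with rows for both
#'   factors, their interaction and residuals; columns `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(table, response = "viability",
                          factors = c("condition_label", "timepoint_h"),
                          use_qc = TRUE) {
  stopifnot(length(factors) == 2L)
  if (use_qc && "qc_flags" %in% names(table)) {
    table <- table[table$qc_flags == "" & !is.na(table[[factors[1]]]), ]
  }
  y <- table[[response]]
  A <- factor(table[[factors[1]]])
  B <- factor(table[[factors[2]]])
  ok <- !is.na(y) & !is.na(A) & !is.na(B)
  y <- y[ok]; A <- droplevels(A[ok]); B <- droplevels(B[ok])
  a <- nlevels(A); b <- nlevels(B); n <- length(y)
  if (a < 2L || b < 2L) stop("each factor needs at least 2 levels")
  counts <- table(A, B)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factors[1], levels(A)[empty[1]],
                 factors[2], levels(B)[empty[2]]))
  }
  if (any(counts < 2L)) stop("each design cell needs at least 2 replicates")

  dummies <- function(f) {
    # treatment-coded indicator columns, first level as reference
    lv <- levels(f)[-1L]
    if (length(lv) == 0L) return(NULL)
    m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
    m
  }
  XA <- dummies(A)
  XB <- dummies(B)
  XAB <- NULL
  for (i in seq_len(ncol(XA))) {
    XAB <- cbind(XAB, XA[, i] * XB)
  }
  one <- matrix(1, n, 1)
  rss <- function(X) {
    fit <- qr(X)
    res <- qr.resid(fit, y)
    sum(res^2)
  }
  rss_full <- rss(cbind(one, XA, XB, XAB))
  rss_ab <- rss(cbind(one, XA, XB))
  rss_a <- rss(cbind(one, XA))
  rss_b <- rss(cbind(one, XB))

  df_a <- a - 1L
  df_b <- b - 1L
  df_int <- df_a * df_b
  df_res <- n - a * b
  if (df_res <= 0L) stop("no residual degrees of freedom")
  ss_a <- rss_b - rss_ab      # SS(A | B)
  ss_b <- rss_a - rss_ab      # SS(B | A)
  ss_int <- rss_ab - rss_full # SS(AB | A, B)
  ms_res <- rss_full / df_res
  if (ms_res <= .Machine$double.eps * max(1, mean(y)^2)) {
    stop("degenerate input: residual variance is zero, F is undefined")
  }
  ss <- c(ss_a, ss_b, ss_int)
  df <- c(df_a, df_b, df_int)
  ms <- ss / df
  f_stat <- ms / ms_res
  p <- stats::pf(f_stat, df, df_res, lower.tail = FALSE)
  out <- data.frame(
    term = c(factors[1], factors[2], "interaction", "residuals"),
    df = c(df, df_res),
    sum_sq = c(ss, rss_full),
    mean_sq = c(ms, ms_res),
    statistic = c(f_stat, NA),
    p_value = c(p, NA)
  )
  class(out) <- c("anova_result", "data.frame")
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type II sums of squares)\n")
  df <- as.data.frame(x)
  df$p_value <- format.pval(df$p_value, digits = 3)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm-adjusted pairwise condition comparisons (optional annotation)
#'
#' Per-timepoint two-sample Welch t-tests of each condition against a
#' reference, Holm-adjusted. Off the main reporting path: the primary analysis
#' applies no multiple-testing correction, this is opt-in rigour.
#'
#' @param table a screen table.
#' @param reference reference condition label.
#' @param response response column.
#' @return data frame of comparisons with raw and Holm-adjusted p-values.
#' @export
pairwise_vs_control <- function(table, reference, response = "viability") {
  sub <- table[usable_rows(table), ]
  if (!reference %in% sub$condition_label) {
    stop("reference condition not present: ", reference)
  }
  combos <- expand.grid(
    condition = setdiff(unique(sub$condition_label), reference),
    timepoint_h = unique(sub$timepoint_h), stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    x <- sub[[response]][sub$condition_label == combos$condition[i] &
                           sub$timepoint_h == combos$timepoint_h[i]]
    yref <- sub[[response]][sub$condition_label == reference &
                              sub$timepoint_h == combos$timepoint_h[i]]
    p <- if (length(x) >= 2 && length(yref) >= 2 &&
             (stats::sd(x) > 0 || stats::sd(yref) > 0)) {
      stats::t.test(x, yref)$p.value
    } else NA_real_
    data.frame(condition = combos$condition[i],
               timepoint_h = combos$timepoint_h[i],
               delta = mean(x) - mean(yref), p_value = p)
  }))
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  res
}
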