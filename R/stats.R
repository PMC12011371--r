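# Study-level statistics: surface-proteome fold-change enrichment, two-rater
# diagnostic concordance with binomial confidence intervals, Mann-Whitney
# group comparison, least-squares scaling relations, and the PEG 300
# dose-to-osmolality calibration.

#' Fold-change enrichment filter for a two-condition abundance table
#'
#' Computes `fold = crowded / max(control, pseudo_floor)` per protein and
#' retains rows with fold strictly greater than `threshold`, sorted by
#' descending fold change (ties broken by gene symbol). `pseudo_floor`
#' defaults to the smallest positive control abundance in the table, so
#' proteins undetected in the control condition get a finite (large) fold
#' change instead of a division by zero.
#'
#' @param table data frame with columns `gene`, `abundance_nd` (control)
#'   and `abundance_oc` (crowded), non-negative, unique gene symbols.
#' @param threshold retention threshold (strict `>`), > 0.
#' @param pseudo_floor denominator floor; `NULL` = smallest positive
#'   control abundance.
#' @return An `enrichment_result` data frame: `gene`, `fold_change`, `rank`;
#'   attribute `threshold`.
#' @export
fold_change_filter <- function(table, threshold = 5, pseudo_floor = NULL) {
  stopifnot(is.data.frame(table), threshold > 0)
  if (nrow(table) == 0) stop("empty abundance table")
  need <- c("gene", "abundance_nd", "abundance_oc")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(table$gene)) stop("gene symbols must be unique")
  if (any(table$abundance_nd < 0) || any(table$abundance_oc < 0)) {
    stop("abundances must be non-negative")
  }
  if (is.null(pseudo_floor)) {
    pos <- table$abundance_nd[table$abundance_nd > 0]
    if (length(pos) == 0) stop("no positive control abundance for the floor")
    pseudo_floor <- min(pos)
  }
  fold <- table$abundance_oc / pmax(table$abundance_nd, pseudo_floor)
  keep <- fold > threshold
  out <- data.frame(gene = table$gene[keep], fold_change = fold[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Diagnostic sensitivity and specificity from a two-rater call table
#'
#' Positives are ROIs of `positive_grade`; negatives are all grades below it,
#' with invasive-carcinoma (IDC) ROIs always excluded from the specificity
#' denominator. Equivocal (`E`) calls — rater disagreement — are excluded
#' from numerator and denominator by default, or counted as negative calls
#' with `equivocal = "as_negative"`. 95% binomial confidence-interval
#' half-widths (Wald by default) are attached.
#'
#' @param table data frame with columns `roi_id`, `grade` (one of normal,
#'   benign, ADH, DCIS_low, DCIS_intermediate, DCIS_high, IDC) and `call`
#'   (`Y`/`N`/`E`).
#' @param positive_grade the positive class (default `"DCIS_high"`).
#' @param equivocal `"exclude"` or `"as_negative"`.
#' @param ci_method `"wald"` or `"wilson"`.
#' @param ci_level confidence level.
#' @return A `diagnostic_result` list: `sensitivity`, `specificity`,
#'   `n_pos_used`, `n_neg_used`, `ci_half_width_sens`, `ci_half_width_spec`.
#' @export
diagnostic_concordance <- function(table, positive_grade = "DCIS_high",
                                   equivocal = c("exclude", "as_negative"),
                                   ci_method = c("wald", "wilson"),
                                   ci_level = 0.95) {
  equivocal <- match.arg(equivocal)
  ci_method <- match.arg(ci_method)
  grades <- c("normal", "benign", "ADH", "DCIS_low", "DCIS_intermediate",
              "DCIS_high", "IDC")
  stopifnot(is.data.frame(table),
            all(c("grade", "call") %in% names(table)))
  if (!all(table$grade %in% grades)) stop("unknown grade label")
  if (!all(table$call %in% c("Y", "N", "E"))) stop("calls must be Y/N/E")
  if (!positive_grade %in% grades) stop("unknown positive grade")
  pos_rank <- match(positive_grade, grades)
  tab <- table
  if (equivocal == "exclude") tab <- tab[tab$call != "E", , drop = FALSE]
  # "as_negative": E behaves as an N call in both directions
  pos <- tab[match(tab$grade, grades) == pos_rank, , drop = FALSE]
  neg <- tab[match(tab$grade, grades) < pos_rank & tab$grade != "IDC", ,
             drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    stop("need at least one usable positive- and negative-grade ROI")
  }
  sens <- sum(pos$call == "Y") / nrow(pos)
  spec <- sum(neg$call != "Y") / nrow(neg)
  structure(list(
    sensitivity = sens, specificity = spec,
    n_pos_used = nrow(pos), n_neg_used = nrow(neg),
    ci_half_width_sens = binom_ci_half_width(sens, nrow(pos), ci_level,
                                             ci_method),
    ci_half_width_spec = binom_ci_half_width(spec, nrow(neg), ci_level,
                                             ci_method)
  ), class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_result> sensitivity %.2f+-%.2f (%d), specificity %.2f+-%.2f (%d)\n",
    x$sensitivity, x$ci_half_width_sens, x$n_pos_used,
    x$specificity, x$ci_half_width_spec, x$n_neg_used))
  invisible(x)
}

#' Wald binomial confidence-interval half-width
#'
#' `z * sqrt(p (1 - p) / n)` with `z = qnorm(1 - (1 - level) / 2)`;
#' truncation to `[0, 1]` and any rounding happen only at display time.
#'
#' @param p observed proportion in `[0, 1]`.
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return The half-width.
#' @export
wald_ci_half_width <- function(p, n, level = 0.95) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
}

binom_ci_half_width <- function(p, n, level, method) {
  if (method == "wald") return(wald_ci_half_width(p, n, level))
  z <- qnorm(1 - (1 - level) / 2)  # wilson: half the score interval
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  half
}

#' Two-sided Mann-Whitney U test
#'
#' `U` is computed from rank sums with midranks for ties. The p-value comes
#' from the exact distribution (via [stats::wilcox.test]) when
#' `n_a * n_b <= 400` and the data are tie-free, otherwise from the normal
#' approximation with tie and continuity corrections; `method` records
#' which was used.
#'
#' @param group_a,group_b numeric samples (each >= 1 observation).
#' @return list: `u` (for `group_a`), `p_value`, `method`
#'   (`"exact"`/`"normal_approx"`).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) < 1 || length(group_b) < 1) stop("empty group")
  na <- length(group_a)
  nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (na * nb <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  list(u = u, p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Ordinary least-squares scaling relation
#'
#' Fits `y = intercept + slope * x` and reports
#' `R^2 = 1 - SS_res / SS_tot`, as used for cross-assay scaling plots
#' (e.g. motility versus invasive fraction).
#'
#' @param x,y paired summary values (>= 3 points; `x` not constant).
#' @return list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
scaling_relation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired points")
  if (diff(range(x)) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(x))
}

#' PEG 300 dose to medium osmolality
#'
#' Linear calibration anchored at 2% (v/v) PEG 300 = 74.4 mOsm/kg,
#' i.e. 37.2 mOsm/kg per percent.
#'
#' @param percent_v_v PEG 300 dose, percent v/v (>= 0).
#' @return Osmolality in mOsm/kg.
#' @export
peg_osmolality <- function(percent_v_v) {
  if (any(percent_v_v < 0)) stop("percent must be non-negative")
  37.2 * percent_v_v
}
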