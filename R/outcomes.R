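#' Classify a simulation endpoint against the extinction threshold
#'
#' Any species whose population is at or below the threshold (10,000
#' cells/mL by default — the density from which daily dilution drives a
#' suppressed population extinct, see [extinction_rationale()]) is counted
#' extinct. The category follows the phase-diagram taxonomy: `coexist`
#' (nobody extinct), `competitor_extinct`, `ecoli_extinct`,
#' `yeast_extinct`, or `multiple_extinct` when two or more species are lost.
#'
#' @param end_state a named vector/list with `N_E`, `N_Y`, `N_B`
#'   (cells/mL), or an `lv_trajectory` (its final state is used).
#' @param extinction_threshold cells/mL at or below which a species is
#'   extinct.
#' @param at_any_time when `end_state` is a trajectory, also count a species
#'   extinct if it dipped to the threshold at any recorded time point
#'   (default: endpoint only).
#' @return an object of class `outcome_label`: list with `category` and
#'   `extinct_set` (subset of `c("E","Y","B")`).
#' @export
#' @examples
#' classify_simulation(c(N_E = 5e8, N_Y = 2e7, N_B = 5e3))
classify_simulation <- function(end_state, extinction_threshold = 1e4,
                                at_any_time = FALSE) {
  if (inherits(end_state, "lv_trajectory") ||
      (is.data.frame(end_state) && all(c("N_E", "N_Y", "N_B") %in% names(end_state)))) {
    df <- as.data.frame(end_state)
    if (at_any_time) {
      s <- c(N_E = min(df$N_E), N_Y = min(df$N_Y), N_B = min(df$N_B))
    } else {
      s <- unlist(df[nrow(df), c("N_E", "N_Y", "N_B")])
    }
  } else {
    s <- .as_state(end_state)
  }
  extinct <- c("E", "Y", "B")[s <= extinction_threshold]
  category <- if (length(extinct) == 0L) "coexist"
    else if (length(extinct) >= 2L) "multiple_extinct"
    else switch(extinct, B = "competitor_extinct", E = "ecoli_extinct",
                Y = "yeast_extinct")
  structure(list(category = category, extinct_set = extinct,
                 end_state = s, threshold = extinction_threshold),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(x$category,
      if (length(x$extinct_set))
        sprintf("(extinct: %s)", paste(x$extinct_set, collapse = ",")),
      "\n")
  invisible(x)
}

#' Majority-rule outcome over experimental replicates
#'
#' Replicated competitions are designated by strict majority, e.g. three of
#' five replicates coexisting designates the condition "coexist". An exact
#' tie (possible only for even replicate numbers) is an error.
#'
#' @param labels character vector of per-replicate labels, each `"coexist"`
#'   or `"extirpated"`.
#' @return the strict-majority label.
#' @export
#' @examples
#' classify_replicates(c("coexist", "coexist", "coexist",
#'                       "extirpated", "extirpated"))
classify_replicates <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("need at least one replicate")
  bad <- setdiff(unique(labels), c("coexist", "extirpated"))
  if (length(bad))
    stop("unknown replicate label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = c("coexist", "extirpated")))
  if (tab["coexist"] == tab["extirpated"]) stop("indeterminate: exact tie")
  names(tab)[which.max(tab)]
}

#' Assay detection-limit check for a subpopulation
#'
#' Selective plating with a selectable marker detects subpopulations down to
#' about 10 cells; colony-morphology screening (no marker; hundreds of
#' colonies inspected) detects frequencies down to about 0.1%.
#'
#' @param subpop subpopulation size, cells; `0 <= subpop <= total`.
#' @param total total population, cells; positive.
#' @param method `"selective_plating"` or `"morphology_screen"`.
#' @return `"detectable"` or `"below_limit"` (boundaries count as
#'   detectable).
#' @export
detection_limit_check <- function(subpop, total,
                                  method = c("selective_plating",
                                             "morphology_screen")) {
  method <- match.arg(method)
  if (total <= 0) stop("`total` must be positive")
  if (subpop < 0 || subpop > total) stop("need 0 <= subpop <= total")
  below <- switch(method,
                  selective_plating = subpop < 10,
                  morphology_screen = subpop / total < 0.001)
  if (below) "below_limit" else "detectable"
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' No continuity correction by default (Yates' correction available via
#' `correct = TRUE`); p-value from the chi-square distribution with 1 df.
#'
#' @param table a 2x2 matrix of non-negative counts with positive marginals.
#' @param correct apply Yates' continuity correction.
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(3, 9, 8, 3), 2))
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column marginals must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Paired t-test with Bonferroni correction
#'
#' Standard paired t statistic `mean(d) / (sd(d)/sqrt(n))` with `n - 1`
#' degrees of freedom, and the Bonferroni-adjusted p-value
#' `min(1, m * p_raw)` for `m` planned comparisons.
#'
#' @param x,y paired measurement vectors of equal length `>= 2`.
#' @param m number of comparisons in the family (`>= 1`).
#' @return list with `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
paired_t_and_bonferroni <- function(x, y, m = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired (equal length)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (m < 1) stop("`m` must be >= 1")
  d <- x - y
  if (sd(d) == 0 && mean(d) != 0)
    stop("zero variance of differences: t statistic undefined")
  if (sd(d) == 0) {
    tt <- list(statistic = 0, parameter = length(x) - 1, p.value = 1)
  } else {
    tt <- t.test(x, y, paired = TRUE)
  }
  p_raw <- unname(tt$p.value)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = p_raw,
       p_adjusted = unname(p.adjust(p_raw, method = "bonferroni", n = m)))
}

#' Phase-diagram colour convention for outcome categories
#'
#' Purple: only the competitor extinct; blue: only *E. coli* extinct; red:
#' only yeast extinct; green: three-species coexistence; grey: two or more
#' species extinct.
#'
#' @return named character vector of colours, one per category.
#' @export
outcome_colors <- function() {
  c(coexist = "#2E8B57", competitor_extinct = "#8B2FA8",
    ecoli_extinct = "#2C5FD8", yeast_extinct = "#D8342C",
    multiple_extinct = "#8C8C8C")
}
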