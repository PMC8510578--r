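#' Fisher's exact test on pooled pre/post decision counts
#'
#' Treats every decision as independent and asks whether the
#' approach/avoid split differs between the two phases, via the two-sided
#' exact test on the 2x2 table with fixed margins (two-sided by the
#' point-probability rule: sum the probabilities of all tables whose
#' hypergeometric probability does not exceed the observed one).
#'
#' A table with any zero margin carries no information and returns p = 1
#' by convention.
#'
#' @param pre,post length-2 non-negative integer vectors of
#'   `(approach, avoid)` counts for the two phases being compared.
#' @return Two-sided exact p-value.
#' @export
fisher_pre_post <- function(pre, post) {
  counts <- c(pre, post)
  if (length(counts) != 4 || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    domain_error("pre and post must each be 2 non-negative integer counts")
  tab <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Two-sided Mann-Whitney U test on per-animal preferences
#'
#' Treats every animal as one measurement (its preference index),
#' ignoring how many decisions each animal made.  Small samples
#' (`min(n, m) <= 8`, no ties) use the exact rank-sum distribution;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param prefs_a,prefs_b non-empty numeric vectors of per-animal
#'   preference indices (undefined preferences must be excluded upstream).
#' @param exact override the branch choice (`TRUE`/`FALSE`); default
#'   `NULL` applies the rule above.
#' @return Two-sided p-value.
#' @export
mannwhitney_groups <- function(prefs_a, prefs_b, exact = NULL) {
  if (!length(prefs_a) || !length(prefs_b))
    domain_error("both groups must be non-empty")
  if (anyNA(prefs_a) || anyNA(prefs_b))
    domain_error("undefined preferences must be excluded upstream")
  ties <- anyDuplicated(c(prefs_a, prefs_b)) > 0
  if (is.null(exact))
    exact <- min(length(prefs_a), length(prefs_b)) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(prefs_a, prefs_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}
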