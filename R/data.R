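#' Published pooled decision counts per experimental condition
#'
#' The pooled approach/avoid decision totals per condition from the
#' individual-larva Y-maze CO2/optogenetic-reward conditioning study this
#' package analyzes: for each experiment, the number of animals tested
#' and the total approach and avoid decisions over all animals in the
#' pre-training, post-training, and (where measured) next-day test
#' phases.  These counts fully determine the decision-weighted population
#' preferences and the Fisher exact tests, so they serve as worked-example
#' fixtures for those statistics.
#'
#' @param assay optional filter on the `assay` column (e.g.
#'   `"dose_response"`, `"extinction"`, `"overnight"`).
#' @return data.frame with columns `experiment`, `assay`, `genotype`,
#'   `n_larvae`, `approach_pre`, `avoid_pre`, `approach_post`,
#'   `avoid_post`, `approach_next_day`, `avoid_next_day` (NA where a
#'   phase was not run).
#' @examples
#' counts <- ymaze_counts("dose_response")
#' with(counts[counts$experiment == "0 Cycles", ],
#'      approach_post / (approach_post + avoid_post))
#' @export
ymaze_counts <- function(assay = NULL) {
  path <- system.file("extdata", "ymaze_choice_counts.csv",
                      package = "larvalearn", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(assay)) df <- df[df$assay %in% assay, , drop = FALSE]
  df
}

#' Turn a pooled-counts row into a one-record group
#'
#' Decision-weighted population statistics depend only on pooled counts,
#' so a published counts row can stand in for the (unavailable) per-animal
#' table when computing them.
#'
#' @param row a single row of [ymaze_counts].
#' @param n_cycles training dose recorded on the synthetic record.
#' @return An [experiment_group] containing one pooled [larva_record].
#' @export
group_from_counts_row <- function(row, n_cycles = 0L) {
  stopifnot(nrow(row) == 1)
  grab <- function(x) if (is.na(x)) 0L else as.integer(x)
  rec <- record_from_counts(
    paste0(row$experiment, "_pooled"), row$experiment, n_cycles,
    approach = c(PRE = grab(row$approach_pre),
                 POST = grab(row$approach_post),
                 NEXT_DAY = grab(row$approach_next_day)),
    avoid = c(PRE = grab(row$avoid_pre), POST = grab(row$avoid_post),
              NEXT_DAY = grab(row$avoid_next_day)))
  experiment_group(row$experiment, list(rec),
                   protocol = list(assay = row$assay,
                                   genotype = row$genotype,
                                   n_larvae_true = row$n_larvae))
}
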