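#' Phase labels of the choice assay
#'
#' Decisions are scored in one of three assay phases: the hour of naive
#' testing before conditioning (`PRE`), the hour immediately after
#' conditioning (`POST`), and the retest after an overnight rest on food
#' (`NEXT_DAY`).  No choices are scored during the training block itself,
#' so training protocols (habituation, extinction, spacing) are group
#' metadata rather than phases.
#'
#' @format Character vector of the three phase labels, in temporal order.
#' @export
PHASES <- c("PRE", "POST", "NEXT_DAY")

OUTCOMES <- c("approach", "avoid")

#' Build a validated per-phase decision frame
#'
#' One row per scored junction choice, in temporal order.  `"approach"`
#' means the animal entered the channel carrying the CO2-laden air stream,
#' `"avoid"` the clean-air channel.  Backing up before the junction is not
#' a choice and is unrepresentable here.
#'
#' @param outcome character vector of `"approach"`/`"avoid"` tokens
#'   (case-insensitive).
#' @param index 0-based ordinal position within the phase; must be strictly
#'   increasing.  Defaults to `0:(n-1)`.
#' @param time_s optional seconds from phase start; must be non-decreasing
#'   when present.
#' @return A `data.frame` with columns `outcome`, `index`, `time_s`.
#' @export
decision_frame <- function(outcome = character(),
                           index = seq_along(outcome) - 1L,
                           time_s = NULL) {
  outcome <- tolower(as.character(outcome))
  bad <- setdiff(unique(outcome), OUTCOMES)
  if (length(bad))
    schema_error("unknown outcome token(s): %s", paste(bad, collapse = ", "))
  index <- as.integer(index)
  if (length(index) != length(outcome))
    schema_error("outcome and index lengths differ")
  if (length(index) > 1 && any(diff(index) <= 0))
    integrity_error("decision index not strictly increasing within phase")
  if (is.null(time_s)) time_s <- rep(NA_real_, length(outcome))
  time_s <- as.numeric(time_s)
  if (length(time_s) != length(outcome))
    schema_error("time_s length mismatch")
  tt <- time_s[!is.na(time_s)]
  if (length(tt) > 1 && any(diff(tt) < 0))
    integrity_error("time_s not non-decreasing within phase")
  data.frame(outcome = outcome, index = index, time_s = time_s)
}

#' One animal's decision record
#'
#' @param larva_id unique identifier within its group.
#' @param group group label string.
#' @param n_cycles training dose: number of rewarded CO2/air training cycles
#'   the animal received (non-negative integer).
#' @param decisions named list mapping phase labels (see [PHASES]) to
#'   decision frames (see [decision_frame]).  Phases may be absent or empty:
#'   inactive animals are retained with empty lists.
#' @return An object of class `larva_record`.
#' @export
larva_record <- function(larva_id, group, n_cycles, decisions = list()) {
  if (length(larva_id) != 1 || is.na(larva_id))
    schema_error("larva_id must be a single non-missing value")
  n_cycles <- as.integer(n_cycles)
  if (length(n_cycles) != 1 || is.na(n_cycles) || n_cycles < 0)
    domain_error("n_cycles must be a single non-negative integer")
  if (length(decisions)) {
    bad <- setdiff(names(decisions), PHASES)
    if (length(bad) || is.null(names(decisions)))
      domain_error("unknown phase label(s): %s",
                   paste(if (is.null(names(decisions))) "<unnamed>" else bad,
                         collapse = ", "))
    decisions <- lapply(decisions, function(d) {
      if (is.data.frame(d)) decision_frame(d$outcome, d$index, d$time_s)
      else decision_frame(d)
    })
  }
  structure(list(larva_id = as.character(larva_id),
                 group = as.character(group),
                 n_cycles = n_cycles,
                 decisions = decisions),
            class = "larva_record")
}

#' A group of animals run under one experimental condition
#'
#' @param name group label.
#' @param larvae list of [larva_record] objects; `larva_id` must be unique
#'   within the group.
#' @param protocol free-form metadata list (training protocol, genotype,
#'   reward pairing, ...).
#' @return An object of class `experiment_group`.
#' @export
experiment_group <- function(name, larvae = list(), protocol = list()) {
  stopifnot(is.list(larvae))
  if (length(larvae)) {
    ok <- vapply(larvae, inherits, logical(1), "larva_record")
    if (!all(ok)) domain_error("larvae must all be larva_record objects")
    ids <- vapply(larvae, `[[`, character(1), "larva_id")
    if (anyDuplicated(ids))
      integrity_error("duplicate larva_id within group '%s': %s", name,
                      paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(larvae) <- ids
  }
  structure(list(name = as.character(name), larvae = larvae,
                 protocol = protocol),
            class = "experiment_group")
}

#' @export
print.larva_record <- function(x, ...) {
  nd <- vapply(PHASES, function(ph) phase_n(x, ph), integer(1))
  cat(sprintf("<larva_record %s> group=%s n_cycles=%d decisions: %s\n",
              x$larva_id, x$group, x$n_cycles,
              paste(sprintf("%s=%d", PHASES, nd), collapse = " ")))
  invisible(x)
}

#' @export
print.experiment_group <- function(x, ...) {
  cat(sprintf("<experiment_group '%s'> %d larvae\n", x$name, length(x$larvae)))
  invisible(x)
}

# number of decisions a record has in a phase (0 when absent)
phase_n <- function(record, phase) {
  d <- record$decisions[[phase]]
  if (is.null(d)) 0L else nrow(d)
}

# approach count in a phase
phase_approach <- function(record, phase) {
  d <- record$decisions[[phase]]
  if (is.null(d)) 0L else sum(d$outcome == "approach")
}

check_phase <- function(phase) {
  if (length(phase) != 1 || !phase %in% PHASES)
    domain_error("phase must be one of %s", paste(PHASES, collapse = ", "))
  phase
}

#' Read a decision table
#'
#' Ingests a delimiter-separated table with one scored decision per row and
#' columns `larva_id, group, n_cycles, phase, decision_index, outcome`
#' (plus optional `time_s`).  Deposited per-animal spreadsheets with other
#' column headings can be read by supplying `col_map`.
#'
#' @param path file to read.
#' @param sep field delimiter.
#' @param col_map optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(larva_id = "animal", outcome = "choice")`.
#' @return A list of [experiment_group] objects, one per distinct group
#'   label, in order of first appearance; within each record decisions are
#'   ordered by `decision_index`.
#' @export
read_decision_table <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) schema_error("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  required <- c("larva_id", "group", "n_cycles", "phase", "decision_index",
                "outcome")
  for (canon in required) {
    src <- if (!is.null(col_map) && canon %in% names(col_map))
      col_map[[canon]] else canon
    if (!src %in% names(df))
      schema_error("missing required column: %s", src)
    names(df)[names(df) == src] <- canon
  }
  tsrc <- if (!is.null(col_map) && "time_s" %in% names(col_map))
    col_map[["time_s"]] else "time_s"
  has_time <- tsrc %in% names(df)
  if (has_time) names(df)[names(df) == tsrc] <- "time_s"
  if (nrow(df) == 0) return(list())

  df$phase <- toupper(df$phase)
  bad <- setdiff(unique(df$phase), PHASES)
  if (length(bad))
    schema_error("unknown phase label(s): %s", paste(bad, collapse = ", "))
  key <- paste(df$group, df$larva_id, df$phase, df$decision_index)
  if (anyDuplicated(key))
    integrity_error("duplicate (larva_id, phase, decision_index) row(s): %s",
                    key[duplicated(key)][1])

  groups <- list()
  for (g in unique(df$group)) {
    dg <- df[df$group == g, , drop = FALSE]
    larvae <- lapply(unique(dg$larva_id), function(id) {
      dl <- dg[dg$larva_id == id, , drop = FALSE]
      ncyc <- unique(dl$n_cycles)
      if (length(ncyc) != 1)
        integrity_error("larva %s has conflicting n_cycles values", id)
      dec <- list()
      for (ph in intersect(PHASES, unique(dl$phase))) {
        dp <- dl[dl$phase == ph, , drop = FALSE]
        dp <- dp[order(as.integer(dp$decision_index)), , drop = FALSE]
        dec[[ph]] <- decision_frame(
          dp$outcome, as.integer(dp$decision_index),
          if (has_time) as.numeric(dp$time_s) else NULL)
      }
      larva_record(id, g, as.integer(ncyc), dec)
    })
    groups[[g]] <- experiment_group(g, larvae)
  }
  unname(groups)
}

#' Write a decision table
#'
#' Inverse of [read_decision_table]; the output is losslessly re-readable.
#' Rows are ordered by (group, larva_id, phase, decision_index) and the
#' `time_s` column is included only when any record carries times.
#'
#' @param groups list of [experiment_group] objects.
#' @param path output file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(groups, path, sep = ",") {
  if (inherits(groups, "experiment_group")) groups <- list(groups)
  rows <- list()
  for (grp in groups) {
    if (!length(grp$larvae)) next
    for (rec in grp$larvae[order(names(grp$larvae))]) {
      for (ph in PHASES) {
        d <- rec$decisions[[ph]]
        if (is.null(d) || nrow(d) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          larva_id = rec$larva_id, group = grp$name,
          n_cycles = rec$n_cycles, phase = ph,
          decision_index = d$index, outcome = d$outcome, time_s = d$time_s)
      }
    }
  }
  header <- c("larva_id", "group", "n_cycles", "phase", "decision_index",
              "outcome", "time_s")
  if (length(rows)) {
    out <- do.call(rbind, rows)
    if (all(is.na(out$time_s))) out$time_s <- NULL
  } else {
    out <- as.data.frame(setNames(rep(list(character()), 6), header[1:6]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) ll_stop("larvalearn_io_error", "cannot write %s: %s",
                           path, conditionMessage(ok))
  invisible(path)
}

#' Pooled decision counts for a group
#'
#' Tallies, per phase, the total number of approach and avoid decisions
#' over all animals in the group -- the row format of the study's summary
#' count table.
#'
#' @param group an [experiment_group].
#' @return An object of class `counts_summary`: a list with `n_larvae` and
#'   named per-phase integer vectors `approach` and `avoid`.
#' @export
counts_summary <- function(group) {
  stopifnot(inherits(group, "experiment_group"))
  approach <- avoid <- setNames(integer(length(PHASES)), PHASES)
  for (rec in group$larvae) {
    for (ph in PHASES) {
      napp <- phase_approach(rec, ph)
      approach[ph] <- approach[ph] + napp
      avoid[ph] <- avoid[ph] + (phase_n(rec, ph) - napp)
    }
  }
  structure(list(name = group$name, n_larvae = length(group$larvae),
                 approach = approach, avoid = avoid),
            class = "counts_summary")
}

#' @export
print.counts_summary <- function(x, ...) {
  cat(sprintf("<counts_summary '%s'> %d larvae\n", x$name, x$n_larvae))
  print(data.frame(phase = PHASES, approach = x$approach[PHASES],
                   avoid = x$avoid[PHASES], row.names = NULL))
  invisible(x)
}

#' @export
as.data.frame.counts_summary <- function(x, ...) {
  data.frame(group = x$name, n_larvae = x$n_larvae, phase = PHASES,
             approach = as.integer(x$approach[PHASES]),
             avoid = as.integer(x$avoid[PHASES]), row.names = NULL)
}

#' Build a single pooled record from aggregate counts
#'
#' Expands per-phase approach/avoid totals into one synthetic
#' [larva_record] whose decision lists reproduce those counts (approaches
#' first).  Useful for worked examples where only pooled counts are
#' published: decision-weighted population statistics depend on the counts
#' only.
#'
#' @param larva_id,group,n_cycles record identity fields.
#' @param approach,avoid named vectors of per-phase counts (names from
#'   [PHASES]).
#' @return A [larva_record].
#' @export
record_from_counts <- function(larva_id, group, n_cycles, approach, avoid) {
  dec <- list()
  for (ph in PHASES) {
    a <- if (ph %in% names(approach)) approach[[ph]] else 0L
    v <- if (ph %in% names(avoid)) avoid[[ph]] else 0L
    if (a + v > 0)
      dec[[ph]] <- decision_frame(rep(OUTCOMES, c(a, v)))
  }
  larva_record(larva_id, group, n_cycles, dec)
}
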