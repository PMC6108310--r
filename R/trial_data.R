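CONDITIONS <- c("unadapted", "happy_adapted", "sad_adapted")
CHOICES <- c("happy", "sad")

#' Trial table
#'
#' The universal currency of the pipeline: one row per behavioral trial
#' (subject, adaptation condition, stimulus strength in \[0, 1\], binary
#' happy/sad choice, response time in seconds, optional block label),
#' plus an experiment label and append-only provenance notes.
#'
#' @param trials data.frame with columns `subject_id`, `condition`,
#'   `stimulus_strength`, `choice`, `rt` and optionally `block_id`.
#' @param experiment_id experiment label.
#' @param provenance character vector of free-text processing notes.
#' @return an object of class `trial_table`.
#' @export
trial_table <- function(trials, experiment_id = "exp", provenance = character()) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  problems <- validate_trial_rows(trials)
  if (length(problems))
    stop("invalid trials:\n  ", paste(problems, collapse = "\n  "))
  trials$subject_id <- as.character(trials$subject_id)
  trials$condition <- as.character(trials$condition)
  trials$choice <- as.character(trials$choice)
  rownames(trials) <- NULL
  structure(list(trials = trials, experiment_id = experiment_id,
                 provenance = as.character(provenance)),
            class = "trial_table")
}

required_trial_columns <- function() {
  c("subject_id", "condition", "stimulus_strength", "choice", "rt")
}

#' Validate trial rows
#'
#' Checks every row against the trial invariants and returns a character
#' vector of messages naming offending rows (empty when all rows are valid).
#'
#' @param trials a data.frame of candidate trials.
#' @return character vector of problems.
#' @export
validate_trial_rows <- function(trials) {
  probs <- character()
  missing <- setdiff(required_trial_columns(), names(trials))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  s <- suppressWarnings(as.numeric(trials$stimulus_strength))
  rt <- suppressWarnings(as.numeric(trials$rt))
  bad <- function(which, what) {
    if (any(which)) paste0("row ", paste(which(which), collapse = ", "),
                           ": ", what) else character()
  }
  probs <- c(probs,
             bad(is.na(s) | s < 0 | s > 1, "stimulus_strength not in [0, 1]"),
             bad(is.na(rt) | rt <= 0, "rt not a positive number"),
             bad(!(trials$condition %in% CONDITIONS),
                 paste("condition not one of",
                       paste(CONDITIONS, collapse = "/"))),
             bad(!(trials$choice %in% CHOICES), "choice not happy/sad"))
  probs
}

#' @export
print.trial_table <- function(x, ...) {
  cat("trial_table:", nrow(x$trials), "trials,",
      length(unique(x$trials$subject_id)), "subject(s), experiment",
      x$experiment_id, "\n")
  tb <- table(x$trials$condition)
  for (cn in names(tb)) cat("  ", cn, ":", tb[[cn]], "trials\n")
  if (length(x$provenance))
    cat("provenance:\n", paste(" -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of trials in a trial table
#' @param x a [trial_table].
#' @return integer trial count.
#' @export
n_trials <- function(x) nrow(x$trials)

add_provenance <- function(tab, note) {
  tab$provenance <- c(tab$provenance, note)
  tab
}

#' Read / write trial tables
#'
#' Delimited text with header
#' `subject_id,condition,stimulus_strength,choice,rt[,block_id]`, UTF-8,
#' '.' decimal separator. `load_trials` validates every row and reports
#' offending row numbers; `write_trials` is its inverse.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param experiment_id experiment label for the loaded table.
#' @return `load_trials` returns a [trial_table]; `write_trials` returns
#'   `path` invisibly.
#' @examples
#' path <- system.file("extdata", "synthetic_trials_example.csv",
#'                     package = "adaptddm")
#' tab <- load_trials(path, experiment_id = "example")
#' summarize_cells(tab)
#' @export
load_trials <- function(path, sep = ",", experiment_id = "exp") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required_trial_columns(), names(df))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "))
  probs <- validate_trial_rows(df)
  if (length(probs))
    stop("validation error in ", path, ":\n  ",
         paste(probs, collapse = "\n  "))
  df$stimulus_strength <- as.numeric(df$stimulus_strength)
  df$rt <- as.numeric(df$rt)
  trial_table(df, experiment_id = experiment_id,
              provenance = paste("loaded from", basename(path)))
}

#' @rdname load_trials
#' @param table a [trial_table].
#' @export
write_trials <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "trial_table"))
  utils::write.table(table$trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove slow-response outlier trials
#'
#' Drops trials with response times above `max_rt` seconds. The removal
#' report (count and fraction removed per condition) is attached as
#' attribute `"removal_report"`.
#'
#' @param table a [trial_table].
#' @param max_rt threshold in seconds (default 5).
#' @return the filtered [trial_table].
#' @export
filter_outliers <- function(table, max_rt = 5.0) {
  stopifnot(inherits(table, "trial_table"))
  if (nrow(table$trials) == 0L) stop("empty trial table")
  keep <- table$trials$rt <= max_rt
  if (!any(keep))
    stop("all trials removed by the outlier filter; input looks corrupt")
  rep <- do.call(rbind, lapply(split(keep, table$trials$condition),
    function(k) data.frame(n_before = length(k), n_removed = sum(!k),
                           fraction_removed = mean(!k))))
  rep <- cbind(condition = rownames(rep), rep)
  rownames(rep) <- NULL
  out <- table
  out$trials <- table$trials[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  out <- add_provenance(out, sprintf(
    "filter_outliers: removed %d/%d trials with rt > %g s",
    sum(!keep), length(keep), max_rt))
  attr(out, "removal_report") <- rep
  out
}

#' Pool trial tables across participants
#'
#' Concatenates trials across participants. All inputs must share the
#' experiment label; per-(condition, strength) counts add up.
#'
#' @param tables list of [trial_table]s.
#' @return a pooled [trial_table].
#' @export
pool_participants <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "trial_table")))
  ids <- unique(vapply(tables, `[[`, "", "experiment_id"))
  if (length(ids) != 1L)
    stop("refusing to pool across experiments: ",
         paste(ids, collapse = " vs "))
  trials <- do.call(rbind, lapply(tables, `[[`, "trials"))
  out <- trial_table(trials, experiment_id = ids,
                     provenance = unique(unlist(lapply(tables, `[[`,
                                                       "provenance"))))
  add_provenance(out, sprintf("pool_participants: %d tables, %d trials",
                              length(tables), nrow(trials)))
}

#' Align per-subject stimulus strengths and bin across participants
#'
#' The pooling procedure for designs where the stimulus sets differ across
#' subjects. Per condition: each subject's PSE is estimated with
#' [fit_simple_logistic()]; strengths are shifted by (group-average PSE -
#' subject PSE); shifted strengths are assigned to `n_bins` equal-width
#' half-open bins over the pooled shifted range (top bin closed); bins to
#' which fewer than `ceiling(min_participant_fraction * n_subjects)`
#' subjects contribute at least one trial are dropped; retained trials
#' adopt their bin center as working strength. The bin report is attached
#' as attribute `"bin_report"`.
#'
#' @param tables list of [trial_table]s (typically one per subject).
#' @param n_bins number of bins (default 19).
#' @param min_participant_fraction minimum fraction of subjects a retained
#'   bin must draw from (default 2/3).
#' @return the aligned-and-binned pooled [trial_table].
#' @export
align_and_bin <- function(tables, n_bins = 19L,
                          min_participant_fraction = 2 / 3) {
  pooled <- pool_participants(tables)
  tr <- pooled$trials
  out_rows <- list()
  report <- list()
  need <- NA_integer_
  for (cond in unique(tr$condition)) {
    ctr <- tr[tr$condition == cond, , drop = FALSE]
    # the contribution rule counts subjects per condition
    subjects <- unique(ctr$subject_id)
    n_sub <- length(subjects)
    need <- ceiling(min_participant_fraction * n_sub)
    pse <- vapply(subjects, function(sj) {
      sub <- ctr[ctr$subject_id == sj, , drop = FALSE]
      fit <- tryCatch(fit_simple_logistic(trial_table(sub, pooled$experiment_id)),
                      error = function(e)
                        stop("psychometric fit failed for subject ", sj,
                             " in condition ", cond, ": ",
                             conditionMessage(e)))
      fit$pse
    }, numeric(1))
    group_pse <- mean(pse)
    shift <- group_pse - pse[match(ctr$subject_id, subjects)]
    s_shifted <- ctr$stimulus_strength + shift
    lo <- min(s_shifted); hi <- max(s_shifted)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    idx <- findInterval(s_shifted, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    n_contrib <- vapply(seq_len(n_bins), function(b)
      length(unique(ctr$subject_id[idx == b])), integer(1))
    n_trials_bin <- tabulate(idx, nbins = n_bins)
    kept <- n_contrib >= need
    report[[cond]] <- data.frame(
      condition = cond, bin = seq_len(n_bins),
      lo = edges[-(n_bins + 1L)], hi = edges[-1L], center = centers,
      n_trials = n_trials_bin, n_subjects = n_contrib, kept = kept)
    sel <- kept[idx]
    ctr <- ctr[sel, , drop = FALSE]
    ctr$stimulus_strength <- pmin(1, pmax(0, centers[idx[sel]]))
    out_rows[[cond]] <- ctr
  }
  out <- pooled
  out$trials <- do.call(rbind, out_rows)
  rownames(out$trials) <- NULL
  out <- add_provenance(out, sprintf(
    paste0("align_and_bin: %d equal-width bins (a design choice; bin rule ",
           "not dictated by the data), drop rule >= %d of %d subjects"),
    n_bins, need, n_sub))
  attr(out, "bin_report") <- do.call(rbind, c(report,
                                              make.row.names = FALSE))
  out
}
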