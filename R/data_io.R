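#' @name study-data
#' @title Study data containers
#'
#' @description
#' A study is a collection of participant records. Each participant completed
#' one active and one sham session (order counterbalanced) and gave a single
#' end-of-study guess about which session was sham. Each session holds:
#'
#' * 32 probe slots, each a binary "Is the stimulation on?" response
#'   (`"yes"`/`"no"`, or `"missing"` when the 4,500 ms response window lapsed)
#'   plus a 0-10 confidence rating;
#' * reaction-time trials in four blocks (block 1 is the 100-trial
#'   pre-stimulation baseline);
#' * end-of-session side-effect ratings (headache, tingling, itching,
#'   burning, pain) on a 1 = not at all to 5 = very strongly scale.
#'
#' Constructors validate the invariants (32 probe slots, confidence in
#' [0, 10], ratings in [1, 5], both conditions present per participant).
NULL

SIDE_EFFECTS <- c("headache", "tingling", "itching", "burning", "pain")

#' Construct one participant session
#'
#' @param participant_id Participant label.
#' @param current_mA Current strength of the participant's study arm (1 or 2).
#' @param condition `"active"` or `"sham"`.
#' @param session_order 1 or 2 (which session of the pair this was).
#' @param probes Data frame with columns `probe` (1..n), `time_s`, `response`
#'   (`"yes"`, `"no"` or `"missing"`) and `confidence` (0-10; `NA` allowed when
#'   the response is missing).
#' @param rt_trials Data frame with columns `block` (1-4), `trial`, `correct`
#'   (logical or 0/1) and `rt_ms`.
#' @param side_effects Named numeric vector of ratings in \[1, 5\] for
#'   headache, tingling, itching, burning and pain.
#' @param n_probes Expected number of probe slots (default 32).
#' @return Object of class `participant_session`.
#' @export
participant_session <- function(participant_id, current_mA, condition,
                                session_order, probes, rt_trials, side_effects,
                                n_probes = 32L) {
  condition <- match.arg(condition, c("active", "sham"))
  if (!session_order %in% c(1, 2)) stop("session_order must be 1 or 2")
  probes <- as.data.frame(probes)
  need <- c("probe", "time_s", "response", "confidence")
  if (!all(need %in% names(probes)))
    stop("probes must have columns: ", paste(need, collapse = ", "))
  if (nrow(probes) != n_probes)
    stop("participant ", participant_id, " (", condition, "): expected ",
         n_probes, " probe slots, got ", nrow(probes))
  bad <- which(!probes$response %in% c("yes", "no", "missing"))
  if (length(bad))
    stop("invalid probe response at probe(s) ", paste(bad, collapse = ", "),
         " for participant ", participant_id)
  conf <- probes$confidence[probes$response != "missing"]
  if (anyNA(conf) || any(conf < 0 | conf > 10))
    stop("confidence out of [0, 10] for participant ", participant_id,
         " (", condition, ")")
  rt_trials <- as.data.frame(rt_trials)
  if (!all(c("block", "trial", "correct", "rt_ms") %in% names(rt_trials)))
    stop("rt_trials must have columns block, trial, correct, rt_ms")
  if (!all(rt_trials$block %in% 1:4)) stop("rt blocks must be 1-4")
  if (sum(rt_trials$block == 1) != 100L)
    stop("participant ", participant_id, " (", condition,
         "): baseline block must have 100 trials, got ",
         sum(rt_trials$block == 1))
  se <- side_effects[SIDE_EFFECTS]
  if (anyNA(se) || any(se < 1 | se > 5))
    stop("side-effect ratings must cover ",
         paste(SIDE_EFFECTS, collapse = ", "), " with values in [1, 5]")
  structure(list(participant_id = as.character(participant_id),
                 current_mA = as.numeric(current_mA),
                 condition = condition,
                 session_order = as.integer(session_order),
                 probes = probes[order(probes$probe), , drop = FALSE],
                 rt_trials = rt_trials,
                 side_effects = se),
            class = "participant_session")
}

#' Construct one participant record
#'
#' @param participant_id Participant label.
#' @param sessions List of two [participant_session()] objects, one active and
#'   one sham.
#' @param guess `"correct"` or `"incorrect"`: accuracy of the single
#'   end-of-study guess of which session was sham.
#' @return Object of class `participant_record` with `$sessions$active` and
#'   `$sessions$sham`.
#' @export
participant_record <- function(participant_id, sessions, guess) {
  guess <- match.arg(guess, c("correct", "incorrect"))
  conds <- vapply(sessions, function(s) s$condition, "")
  if (!setequal(conds, c("active", "sham")) || length(sessions) != 2L)
    stop("participant ", participant_id,
         " must have exactly one active and one sham session")
  names(sessions) <- conds
  amps <- vapply(sessions, function(s) s$current_mA, 0)
  if (length(unique(amps)) != 1L)
    stop("participant ", participant_id, ": sessions disagree on current_mA")
  structure(list(participant_id = as.character(participant_id),
                 current_mA = amps[[1]],
                 sessions = sessions[c("active", "sham")],
                 guess = guess),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("Participant %s (%g mA), guess %s; sessions: %s\n",
              x$participant_id, x$current_mA, x$guess,
              paste(vapply(x$sessions, function(s)
                sprintf("%s (order %d)", s$condition, s$session_order), ""),
                collapse = ", ")))
  invisible(x)
}

# full-precision numeric formatting so CSV round-trips are exact
fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE),
    "")
  out
}

#' Write a study to a directory of CSV files
#'
#' Emits the four-file tabular layout documented in the package README:
#' `participants.csv` (id, current_mA, guess), `sessions.csv` (session order
#' and the five side-effect ratings), `probes.csv` (one row per probe slot)
#' and `trials.csv` (one row per reaction-time trial). All files are RFC-4180
#' CSV with a header row, UTF-8, and numeric fields at full precision so
#' `read_study()` reproduces the records exactly.
#'
#' @param records List of [participant_record()] objects.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_study <- function(records, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create study directory: ", path)
  participants <- data.frame(
    participant_id = vapply(records, function(r) r$participant_id, ""),
    current_mA = vapply(records, function(r) r$current_mA, 0),
    guess = vapply(records, function(r) r$guess, ""))
  sess_rows <- list(); probe_rows <- list(); trial_rows <- list()
  for (r in records) for (s in r$sessions) {
    sess_rows[[length(sess_rows) + 1L]] <- data.frame(
      participant_id = r$participant_id, condition = s$condition,
      session_order = s$session_order,
      as.list(s$side_effects), check.names = FALSE)
    probe_rows[[length(probe_rows) + 1L]] <- data.frame(
      participant_id = r$participant_id, condition = s$condition,
      s$probes)
    trial_rows[[length(trial_rows) + 1L]] <- data.frame(
      participant_id = r$participant_id, condition = s$condition,
      s$rt_trials)
  }
  sessions <- do.call(rbind, sess_rows)
  probes <- do.call(rbind, probe_rows)
  trials <- do.call(rbind, trial_rows)
  probes$confidence <- fmt_num(probes$confidence)
  probes$time_s <- fmt_num(probes$time_s)
  trials$rt_ms <- fmt_num(trials$rt_ms)
  trials$correct <- as.integer(trials$correct)
  utils::write.csv(participants, file.path(path, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sessions, file.path(path, "sessions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(probes, file.path(path, "probes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(trials, file.path(path, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_required <- function(path, file, columns) {
  f <- file.path(path, file)
  if (!file.exists(f)) stop("missing study file: ", f)
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(d))
  if (length(miss))
    stop(file, " is missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read a study from a directory of CSV files
#'
#' Reads the layout written by [write_study()] and validates every record.
#' Malformed rows are reported with their file and data-row number (header
#' excluded); out-of-range confidences or side-effect ratings abort with the
#' offending rows listed rather than being silently clipped.
#'
#' This layout emulates the structure of the deposited study data; mapping a
#' real deposit onto it is a thin renaming exercise (see the README schema).
#'
#' @param path Study directory containing `participants.csv`, `sessions.csv`,
#'   `probes.csv` and `trials.csv`.
#' @param n_probes Expected probe slots per session (default 32).
#' @return List of validated [participant_record()] objects, named by
#'   participant id.
#' @export
read_study <- function(path, n_probes = 32L) {
  if (!dir.exists(path)) stop("study directory not found: ", path)
  participants <- read_csv_required(path, "participants.csv",
                                    c("participant_id", "current_mA", "guess"))
  sessions <- read_csv_required(path, "sessions.csv",
                                c("participant_id", "condition",
                                  "session_order", SIDE_EFFECTS))
  probes <- read_csv_required(path, "probes.csv",
                              c("participant_id", "condition", "probe",
                                "time_s", "response", "confidence"))
  trials <- read_csv_required(path, "trials.csv",
                              c("participant_id", "condition", "block",
                                "trial", "correct", "rt_ms"))
  bad <- which(!(is.na(probes$confidence) |
                   (probes$confidence >= 0 & probes$confidence <= 10)))
  if (length(bad))
    stop("probes.csv: confidence out of [0, 10] at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  se_mat <- as.matrix(sessions[, SIDE_EFFECTS])
  bad <- which(apply(se_mat, 1L, function(z) anyNA(z) || any(z < 1 | z > 5)))
  if (length(bad))
    stop("sessions.csv: side-effect rating out of [1, 5] at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  records <- lapply(seq_len(nrow(participants)), function(i) {
    pid <- as.character(participants$participant_id[i])
    srows <- sessions[sessions$participant_id == pid, , drop = FALSE]
    if (nrow(srows) != 2L)
      stop("sessions.csv: participant ", pid, " has ", nrow(srows),
           " sessions (expected 2)")
    sess <- lapply(seq_len(2L), function(j) {
      cond <- srows$condition[j]
      participant_session(
        pid, participants$current_mA[i], cond, srows$session_order[j],
        probes[probes$participant_id == pid & probes$condition == cond,
               c("probe", "time_s", "response", "confidence"), drop = FALSE],
        trials[trials$participant_id == pid & trials$condition == cond,
               c("block", "trial", "correct", "rt_ms"), drop = FALSE],
        stats::setNames(as.numeric(srows[j, SIDE_EFFECTS]), SIDE_EFFECTS),
        n_probes = n_probes)
    })
    participant_record(pid, sess, participants$guess[i])
  })
  names(records) <- vapply(records, function(r) r$participant_id, "")
  n_sessions <- sum(vapply(records, function(r) length(r$sessions), 0L))
  if (nrow(sessions) != n_sessions)
    stop("session row count not conserved while reading ", path)
  records
}

#' Write pipeline results to a directory
#'
#' Emits `sensitivity.csv` (one row per participant-session-reference pair),
#' `group_curves.csv` (per-probe medians and confidence bounds per condition
#' and current strength), `classifiers.csv` (AUC, CI and p per classifier and
#' condition) and `stats.json` (the full inferential battery). Column order is
#' deterministic and numeric values are written at full precision.
#'
#' @param results A `blinding_assessment` object from [assess_blinding()], or
#'   a list with any of the elements `sensitivity`, `group_curves`,
#'   `classifiers`, `stats`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create results directory: ", path)
  write_tab <- function(df, cols, file) {
    if (is.null(df)) df <- data.frame()
    df <- as.data.frame(df)
    for (cl in setdiff(cols, names(df))) df[[cl]] <- numeric(0)
    df <- df[, cols, drop = FALSE]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], fmt_num)
    utils::write.csv(df, file.path(path, file), row.names = FALSE, quote = FALSE)
  }
  write_tab(results$sensitivity,
            c("participant_id", "current_mA", "condition", "reference",
              "peak_r", "peak_lag", "n_interpolated"),
            "sensitivity.csv")
  write_tab(results$group_curves,
            c("condition", "current_mA", "probe", "time_s", "median",
              "ci_low", "ci_high", "n", "all_missing"),
            "group_curves.csv")
  write_tab(results$classifiers,
            c("classifier", "condition", "auc", "ci_low", "ci_high",
              "p_value", "n_pos", "n_neg"),
            "classifiers.csv")
  stats <- results$stats
  if (is.null(stats)) stats <- list()
  stats <- lapply(stats, function(s) if (inherits(s, "test_result")) unclass(s) else s)
  jsonlite::write_json(stats, file.path(path, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
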