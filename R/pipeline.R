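#' Run the full analysis pipeline on a simulated or loaded study
#'
#' Executes, in order: preprocessing of each session's ellipse and search
#' recordings (blink repair, 50-Hz downsampling, zero-phase smoothing),
#' per-session PFE fitting on the ellipse task and correction of the search
#' task, the fixation selection pipeline (with the long-duration cap pooled
#' over the whole dataset), epoch extraction for the requested contrasts,
#' whole-trial traces, grand averages, and the cluster-corrected permutation
#' tests (target vs distractor and self-terminated vs not at search offset).
#' Everything is seeded and rerunning with the same inputs reproduces the
#' result bundle exactly.
#'
#' @param study An `fp_study` from [simulate_study()], or a list of session
#'   bundles of the same shape (each with `subject_id`, `ellipse`, `search`).
#' @param contrasts Epoch contrasts to extract (default the target/distractor
#'   pair).
#' @param selection [selection_params()].
#' @param epoch [epoch_params()].
#' @param cluster [cluster_params()].
#' @param blink [blink_params()].
#' @param filter [filter_params()].
#' @param pfe_trim_ms Leading trim for the PFE fit.
#' @param apply_correction Apply the per-session PFE correction to the search
#'   data (default TRUE).
#' @return A list of class `fp_pipeline_result` with elements `pfe_models`,
#'   `pfe_summary`, `fixations`, `epochs` (per contrast), `averages` (per
#'   contrast, subject-level), `tests` (cluster tests), `whole_trial`,
#'   `behavior`, `log`.
#' @export
run_pipeline <- function(study,
                         contrasts = c("target_all", "distractor_all"),
                         selection = selection_params(),
                         epoch = epoch_params(),
                         cluster = cluster_params(),
                         blink = blink_params(),
                         filter = filter_params(),
                         pfe_trim_ms = 1000,
                         apply_correction = TRUE) {
  sessions <- if (inherits(study, "fp_study")) study$sessions else study
  geometry <- if (inherits(study, "fp_study")) study$config$geometry
              else geometry()
  log <- list()

  pfe_models <- list()
  corrected <- list()
  fix_parts <- list()
  all_trials <- NULL
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    ell <- preprocess(ses$ellipse$series, ses$ellipse$events, blink, filter)
    model <- fit_pfe(ell, trim_ms = pfe_trim_ms,
                     session_id = paste0(ses$subject_id, "_", ses$session_id))
    pfe_models[[i]] <- model
    srch <- preprocess(ses$search$series, ses$search$events, blink, filter)
    if (apply_correction) srch <- apply_pfe_correction(srch, model)
    corrected[[i]] <- srch
    fix <- fixation_table(ses$search$events, ses$search$trials)
    fix <- merge_or_discard_brief(fix, selection, geometry)
    fix <- assign_interest_areas(fix, ses$search$layouts, selection, geometry)
    fix_parts[[i]] <- fix
    all_trials <- rbind(all_trials, as.data.frame(ses$search$trials))
  }
  class(all_trials) <- c("fp_trials", "data.frame")

  # duration cap pooled over the whole dataset, then per-trial rules
  fix <- do.call(rbind, fix_parts)
  fix <- classify_visits(fix, selection)
  fix <- filter_durations(fix, selection)
  fix <- exclude_boundary_fixations(fix, all_trials, selection)
  log$n_fixations_selected <- nrow(fix)

  session_of_trial <- function(tid) {
    for (i in seq_along(sessions))
      if (tid %in% sessions[[i]]$search$trials$trial_id) return(i)
    NA_integer_
  }
  trial_session <- vapply(all_trials$trial_id, session_of_trial, integer(1))

  epochs <- list(); averages <- list()
  for (ct in contrasts) {
    ev <- select_epoch_events(fix, all_trials, ct)
    ses_idx <- trial_session[match(ev$trial_id, all_trials$trial_id)]
    parts <- lapply(unique(ses_idx), function(i)
      extract_epochs(corrected[[i]], ev[ses_idx == i, , drop = FALSE], epoch))
    vals <- do.call(rbind, lapply(parts, `[[`, "values"))
    meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
    eps <- structure(list(values = vals,
                          rel_time_ms = epoch_grid(epoch, filter$target_rate_hz),
                          meta = meta,
                          rejected = do.call(rbind, lapply(parts, `[[`, "rejected"))),
                     class = "fp_epochs")
    epochs[[ct]] <- eps
    if (!is.null(vals) && nrow(vals) > 0) {
      averages[[ct]] <- grand_average(eps, unit = "subject")
    } else {
      warning(sprintf("no eligible epochs for contrast '%s'", ct))
    }
    log[[paste0("n_epochs_", ct)]] <- if (is.null(vals)) 0L else nrow(vals)
  }

  tests <- list()
  if (all(c("target_all", "distractor_all") %in% names(averages))) {
    a <- averages$target_all$per_unit
    b <- averages$distractor_all$per_unit
    common <- intersect(rownames(a), rownames(b))
    if (length(common) >= 2) {
      tests$target_vs_distractor <- cluster_permutation_test(
        a[common, , drop = FALSE], b[common, , drop = FALSE], cluster)
      tests$target_vs_baseline <- cluster_permutation_test(
        a[common, , drop = FALSE], NULL, cluster)
    }
  }

  # whole-trial offset-locked traces grouped by self-termination, paired by
  # subject over correct, unflagged trials
  wt <- whole_trial_by_subject(corrected, sessions, all_trials, trial_session,
                               rate_hz = filter$target_rate_hz)
  if (!is.null(wt$self_term) && nrow(wt$self_term) >= 2)
    tests$selfterm_vs_not <- cluster_permutation_test(wt$self_term,
                                                      wt$not_term, cluster)

  structure(list(pfe_models = pfe_models, pfe_summary = pfe_summary(pfe_models),
                 fixations = fix, epochs = epochs, averages = averages,
                 tests = tests, whole_trial = wt,
                 behavior = summarize_behavior(all_trials), log = log),
            class = "fp_pipeline_result")
}

# Per-subject mean offset-locked traces for self-terminated and
# non-self-terminated correct trials; only subjects with both cells enter the
# paired matrices.
whole_trial_by_subject <- function(corrected, sessions, all_trials,
                                   trial_session, rate_hz = 50,
                                   pre_ms = 3000, post_ms = 3000) {
  tr <- all_trials[as.logical(all_trials$correct), , drop = FALSE]
  if (!nrow(tr)) return(list(self_term = NULL, not_term = NULL))
  traces <- vector("list", nrow(tr))
  ok <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    si <- trial_session[match(tr$trial_id[i], all_trials$trial_id)]
    res <- tryCatch(
      whole_trial_traces(corrected[[si]], tr[i, ], pre_ms, post_ms),
      error = function(e) NULL)
    if (!is.null(res) && !res$flagged && !is.null(res$offset_locked)) {
      traces[[i]] <- res$offset_locked$values
      ok[i] <- TRUE
    }
  }
  len <- round((pre_ms + post_ms) / (1000 / rate_hz)) + 1
  ok <- ok & vapply(traces, function(x) length(x) == len, logical(1))
  tr <- tr[ok, , drop = FALSE]
  traces <- traces[ok]
  st <- as.logical(tr$self_terminated)
  sub_means <- function(sel) {
    by <- split(which(sel), tr$subject_id[sel])
    do.call(rbind, lapply(by, function(ix)
      colMeans(do.call(rbind, traces[ix]))))
  }
  a <- sub_means(st); b <- sub_means(!st)
  common <- intersect(rownames(a), rownames(b))
  list(self_term = if (length(common)) a[common, , drop = FALSE] else NULL,
       not_term = if (length(common)) b[common, , drop = FALSE] else NULL,
       rel_time_ms = seq(-pre_ms, post_ms, by = 1000 / rate_hz))
}
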