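#' Configuration for a full synthetic experiment
#'
#' Bundles everything one run needs: the per-subject synthetic-session
#' configuration, the number of subjects, preprocessing settings, band sets,
#' estimator parameters and the condition contrasts, under a single master
#' seed from which every per-subject and per-stage seed is spawned.
#'
#' @param synth A [synth_config()] template (its seed is overridden per
#'   subject).
#' @param n_subjects Number of synthetic subjects.
#' @param fs_analysis Analysis rate after decimation, Hz.
#' @param broadband Pre-filter applied before decimation.
#' @param epoch_window Epoching window around MI onset, seconds.
#' @param te_bands Bands for connectivity (default alpha/beta/gamma).
#' @param class_bands Sub-bands for classification (default alpha/beta).
#' @param contrasts List of `c(A, B)` condition pairs tested as A vs B.
#' @param components Which stages to run: any of `"erd"`,
#'   `"classification"`, `"connectivity"`.
#' @param te_params Optional fixed [embedding_params()] (otherwise selected
#'   per channel); `te_max_points`, `te_d_max` tune the estimator cost.
#' @param cv_m,cv_k,cv_repeats Cross-validation settings.
#' @param alpha Retention threshold for contrasts.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              n_subjects = 14,
                              fs_analysis = 250,
                              broadband = band_definition("broad", 0.5, 50),
                              epoch_window = c(-2, 13),
                              te_bands = default_bands()$connectivity,
                              class_bands = default_bands()$classification,
                              contrasts = list(c("rmMI", "tMI"),
                                               c("bcMI", "rmMI")),
                              components = c("erd", "connectivity"),
                              te_params = NULL,
                              te_max_points = 2000L,
                              te_d_max = 3L,
                              cv_m = 5L, cv_k = 10L, cv_repeats = 100L,
                              alpha = 0.05,
                              seed = 1L) {
  cfg <- structure(
    list(synth = synth, n_subjects = as.integer(n_subjects),
         fs_analysis = fs_analysis, broadband = broadband,
         epoch_window = epoch_window, te_bands = te_bands,
         class_bands = class_bands, contrasts = contrasts,
         components = components, te_params = te_params,
         te_max_points = te_max_points, te_d_max = te_d_max,
         cv_m = cv_m, cv_k = cv_k, cv_repeats = cv_repeats,
         alpha = alpha, seed = as.integer(seed)),
    class = "experiment_config")
  validate_synth_config(cfg$synth)
  bad <- setdiff(unlist(cfg$contrasts), cfg$synth$conditions)
  if (length(bad) > 0) {
    abort(sprintf("contrast references unknown condition(s): %s",
                  paste(bad, collapse = ", ")))
  }
  cfg
}

# generate + preprocess one subject: returns the epoched trial sets
preprocess_subject <- function(cfg, subject) {
  sc <- cfg$synth
  sc$seed <- spawn_seed(cfg$seed, subject * 1000L)
  sess <- generate_session(sc)
  rec <- sess$recording
  if (cfg$broadband$hi < rec$fs / 2) rec <- bandpass(rec, cfg$broadband)
  if (cfg$fs_analysis < rec$fs) rec <- downsample(rec, cfg$fs_analysis)
  win <- cfg$epoch_window
  durs <- sc$stage_durations
  win[2] <- min(win[2], durs[["mi"]] + durs[["rest"]])
  win[1] <- max(win[1], -durs[["fixation"]])
  list(trials = epoch_trials(rec, win, subject_id = sprintf("S%02d", subject)),
       ground_truth = sess$ground_truth)
}

#' Run a complete synthetic experiment
#'
#' For every synthetic subject: generate a session, broadband filter,
#' decimate and epoch it; then (per the configured components) compute
#' alpha-band ERD summaries and the contralateral-vs-ipsilateral
#' lateralization tests, left-vs-right classification accuracy per condition,
#' and band-resolved relative-TE matrices with across-subject condition
#' contrasts. Rerunning with the same configuration reproduces identical
#' numbers; all tables carry the configuration hash.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; when given, every result table is also
#'   written there as CSV (file names carry the table name only; the config
#'   hash is a column).
#' @param quiet Suppress progress messages.
#' @return A result bundle (list of tibbles): `erd`, `lateralization`,
#'   `accuracy`, `contrasts`, `edges`, and `provenance`.
#' @export
run_experiment <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  cfg_hash <- rlang::hash(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  conditions <- cfg$synth$conditions
  hands <- names(cfg$synth$erd_channels)
  mi_window <- c(0, cfg$synth$stage_durations[["mi"]])

  erd_rows <- list(); acc_rows <- list()
  rel_te <- list()  # rel_te[[band]][[condition]][[hand]][[subject]]

  for (s in seq_len(cfg$n_subjects)) {
    say("subject %d/%d", s, cfg$n_subjects)
    prep <- preprocess_subject(cfg, s)
    trials <- prep$trials
    for (cond in conditions) {
      if ("erd" %in% cfg$components) {
        for (h in hands) {
          ts <- trials[[paste(cond, h, sep = ".")]]
          tc <- erd_timecourse(ts, band_definition("alpha", 8, 13),
                               baseline = c(cfg$epoch_window[1], 0))
          sm <- erd_summary(tc, window = c(0, min(5, mi_window[2])))
          sm$subject <- s
          erd_rows[[length(erd_rows) + 1L]] <- sm
        }
      }
      if ("classification" %in% cfg$components) {
        tl <- crop_trials(trials[[paste(cond, "left", sep = ".")]], mi_window)
        tr <- crop_trials(trials[[paste(cond, "right", sep = ".")]], mi_window)
        cv <- cross_validate(tl, tr, bands = cfg$class_bands, m = cfg$cv_m,
                             k = cfg$cv_k, repeats = cfg$cv_repeats,
                             seed = spawn_seed(cfg$seed, s * 1000L + 1L))
        acc_rows[[length(acc_rows) + 1L]] <- tibble(
          subject = s, condition = cond,
          mean_accuracy = mean(cv$accuracy), sd_accuracy = sd(cv$accuracy))
      }
      if ("connectivity" %in% cfg$components) {
        for (h in hands) {
          ts <- trials[[paste(cond, h, sep = ".")]]
          for (b in names(cfg$te_bands)) {
            task <- te_matrix(ts, cfg$te_bands[[b]], window = mi_window,
                              channels = intersect(analysis_montage(),
                                                   ts$channel_labels),
                              params = cfg$te_params,
                              d_max = cfg$te_d_max,
                              max_points = cfg$te_max_points)
            base <- te_matrix(ts, cfg$te_bands[[b]],
                              window = c(cfg$epoch_window[1], 0),
                              channels = intersect(analysis_montage(),
                                                   ts$channel_labels),
                              params = cfg$te_params,
                              d_max = cfg$te_d_max,
                              max_points = cfg$te_max_points)
            rel_te[[b]][[cond]][[h]][[s]] <- relative_te(task, base)
          }
        }
      }
    }
  }

  out <- list(provenance = tibble(
    config_hash = cfg_hash, seed = cfg$seed, n_subjects = cfg$n_subjects,
    package_version = as.character(utils::packageVersion("micnet"))))

  if (length(erd_rows) > 0) {
    erd_tbl <- dplyr::bind_rows(erd_rows)
    erd_tbl$config_hash <- cfg_hash
    out$erd <- erd_tbl
    out$lateralization <- lateralization_table(erd_tbl, cfg)
  }
  if (length(acc_rows) > 0) {
    acc_tbl <- dplyr::bind_rows(acc_rows)
    acc_tbl$config_hash <- cfg_hash
    out$accuracy <- acc_tbl
  }
  if (length(rel_te) > 0) {
    ctr <- list(); edge_rows <- list()
    for (b in names(rel_te)) {
      for (h in hands) {
        for (pair in cfg$contrasts) {
          nm <- sprintf("%s.%s.%s-%s", b, h, pair[1], pair[2])
          cc <- contrast_conditions(rel_te[[b]][[pair[1]]][[h]],
                                    rel_te[[b]][[pair[2]]][[h]],
                                    alpha = cfg$alpha,
                                    contrast = paste(pair, collapse = "-"))
          ctr[[nm]] <- cc
          td <- tidy(cc)
          td$band <- b
          td$hand <- h
          td$config_hash <- cfg_hash
          edge_rows[[nm]] <- td
        }
      }
    }
    out$contrasts <- ctr
    out$edges <- dplyr::bind_rows(edge_rows)
    out$relative_te <- rel_te
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("erd", "lateralization", "accuracy", "edges", "provenance")) {
      if (!is.null(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out
}

# paired contralateral-vs-ipsilateral tests per condition x hand, BH-adjusted
# within the table
lateralization_table <- function(erd_tbl, cfg) {
  contra <- cfg$synth$erd_channels
  ipsi <- setNames(rev(unname(contra)), names(contra))
  rows <- list()
  for (cond in cfg$synth$conditions) {
    for (h in names(contra)) {
      sub <- erd_tbl[erd_tbl$condition == cond & erd_tbl$hand == h, ]
      cv <- sub$erd[sub$channel == contra[[h]]][order(sub$subject[sub$channel == contra[[h]]])]
      iv <- sub$erd[sub$channel == ipsi[[h]]][order(sub$subject[sub$channel == ipsi[[h]]])]
      if (length(cv) < 5) next
      wt <- suppressWarnings(lateralization_test(cv, iv))
      rows[[length(rows) + 1L]] <- tibble(
        condition = cond, hand = h,
        contralateral = contra[[h]], ipsilateral = ipsi[[h]],
        mean_contra = mean(cv), mean_ipsi = mean(iv),
        statistic = wt$statistic, p.value = wt$p.value)
    }
  }
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) > 0) tbl$p.adjusted <- fdr_adjust(tbl$p.value)
  tbl
}

#' Write a session to the delimited-matrix + sidecar format
#'
#' Three plain-text files: `<name>_data.tsv` (channels x samples, one row per
#' channel, first column the channel label), `<name>_meta.json` (sampling
#' rate, channel labels, event table) and, when ground truth is present,
#' `<name>_truth.json`.
#'
#' @param session List with `recording` and optionally `ground_truth`, as
#'   returned by [generate_session()]; or a bare [eeg_recording()].
#' @param dir Output directory (created if needed).
#' @param name File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir, name) {
  if (inherits(session, "eeg_recording")) {
    session <- list(recording = session)
  }
  rec <- session$recording
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, paste0(name, "_data.tsv"))
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  df <- data.frame(channel = rec$channel_labels,
                   signif(rec$data, 7), check.names = FALSE)
  utils::write.table(df, data_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         events = rec$events),
    meta_path, auto_unbox = TRUE, digits = NA)
  paths <- c(data_path, meta_path)
  if (!is.null(session$ground_truth)) {
    truth_path <- file.path(dir, paste0(name, "_truth.json"))
    jsonlite::write_json(session$ground_truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory holding the files.
#' @param name File-name stem.
#' @return List with `recording` and, if present on disk, `ground_truth`.
#' @export
read_session <- function(dir, name) {
  data_path <- file.path(dir, paste0(name, "_data.tsv"))
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  raw <- utils::read.table(data_path, sep = "\t", header = FALSE,
                           colClasses = "character")
  labels <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  events <- as_tibble(meta$events)
  if (nrow(events) == 0) events <- NULL
  rec <- eeg_recording(mat, meta$fs, labels, events)
  out <- list(recording = rec)
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  if (file.exists(truth_path)) {
    gt <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    gt$trials <- as_tibble(gt$trials)
    gt$edges <- as_tibble(gt$edges)
    out$ground_truth <- gt
  }
  out
}

#' Write the small test sessions used by the suite
#'
#' Deterministically generates and writes miniature sessions (tiny: 2
#' subjects, 4 trials per condition and hand, a 2 s MI stage, 250 Hz) in the
#' delimited + sidecar format.
#'
#' @param dir Output directory.
#' @param size `"tiny"` or `"default"`.
#' @return Invisibly, a tibble of subject ids and file paths.
#' @export
make_fixtures <- function(dir, size = c("tiny", "default")) {
  size <- match.arg(size)
  n_subj <- if (size == "tiny") 2L else 3L
  cfg0 <- if (size == "tiny") {
    synth_config(fs_native = 250, n_trials_per_hand = 4,
                 stage_durations = c(fixation = 2, mi = 2, rest = 1))
  } else {
    synth_config(fs_native = 250, n_trials_per_hand = 10,
                 stage_durations = c(fixation = 2, mi = 4, rest = 1))
  }
  rows <- purrr::map_dfr(seq_len(n_subj), function(s) {
    cfg <- cfg0
    cfg$seed <- spawn_seed(20260101L, s)
    sess <- generate_session(cfg)
    name <- sprintf("%s_S%02d", size, s)
    paths <- write_session(sess, dir, name)
    tibble(subject = s, name = name, path = paths[1])
  })
  invisible(rows)
}
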