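# Dataset bundle serialization (portable plain-text layout) and the
# end-to-end pipeline driver.
#
# Layout under the bundle directory:
#   manifest.json                  schema + mouse ids
#   <mouse>/config.json            generator configuration
#   <mouse>/trials.csv             trial table (incl. tendencies)
#   <mouse>/truth.json             synthetic ground truth
#   <mouse>/session_<d>/licks.csv, encoder.csv, keypoints.csv,
#                       lfp_epochs.csv, raw_epochs.csv
# Epoch matrices are stored long (trial, channel, sample, value); CSV
# values round-trip doubles exactly (shortest-round-trip formatting).

fwrite_ <- function(x, path) data.table::fwrite(x, path)
fread_ <- function(path, ...) as.data.frame(data.table::fread(path, ...))

epochs_to_long <- function(epochs) {
  do.call(rbind, lapply(seq_along(epochs), function(i) {
    m <- epochs[[i]]
    data.frame(trial = i, channel = rep(seq_len(nrow(m)), ncol(m)),
               sample = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m))
  }))
}

long_to_epochs <- function(df) {
  lapply(sort(unique(df$trial)), function(i) {
    d <- df[df$trial == i, ]
    nch <- max(d$channel); ns <- max(d$sample)
    m <- matrix(NA_real_, nch, ns)
    m[cbind(d$channel, d$sample)] <- d$value
    m
  })
}

#' Write a dataset bundle to disk
#'
#' Serializes trial tables, streams and ground truth into a plain-text
#' directory layout (CSV + JSON) that [read_bundle()] restores losslessly.
#' Intended for small bundles; large datasets are better regenerated from
#' their seeds.
#'
#' @param bundle a `motistate_bundle`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "motistate_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(schema = bundle$schema, mice = names(bundle$mice)),
                       file.path(path, "manifest.json"), auto_unbox = TRUE)
  for (id in names(bundle$mice)) {
    m <- bundle$mice[[id]]
    mdir <- file.path(path, id)
    dir.create(mdir, showWarnings = FALSE)
    cf <- m$config; class(cf) <- NULL
    jsonlite::write_json(cf, file.path(mdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    fwrite_(m$trials, file.path(mdir, "trials.csv"))
    jsonlite::write_json(m$truth, file.path(mdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (is.null(m$streams)) next
    for (d in seq_along(m$streams)) {
      ss <- m$streams[[d]]
      sdir <- file.path(mdir, sprintf("session_%02d", d))
      dir.create(sdir, showWarnings = FALSE)
      fwrite_(data.frame(time = ss$lick_times), file.path(sdir, "licks.csv"))
      fwrite_(data.frame(voltage = ss$encoder$voltage), file.path(sdir, "encoder.csv"))
      kp <- ss$keypoints
      nf <- length(kp$time)
      long <- do.call(rbind, lapply(c("pupil", "eyelid"), function(part) {
        arr <- kp[[part]]
        data.frame(frame = rep(seq_len(nf), 8), time = rep(kp$time, 8),
                   part = part, vertex = rep(seq_len(8), each = nf),
                   x = as.vector(arr[, , 1]), y = as.vector(arr[, , 2]))
      }))
      fwrite_(long, file.path(sdir, "keypoints.csv"))
      fwrite_(epochs_to_long(ss$lfp_epochs), file.path(sdir, "lfp_epochs.csv"))
      fwrite_(epochs_to_long(ss$raw_epochs), file.path(sdir, "raw_epochs.csv"))
      jsonlite::write_json(
        list(day = ss$day, encoder_rate = ss$encoder$rate,
             lfp_rate = ss$lfp_rate, raw_rate = ss$raw_rate,
             epoch_window = ss$epoch_window, t_end = ss$t_end),
        file.path(sdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' Read a dataset bundle from disk
#'
#' Restores a bundle written by [write_bundle()]. Unknown extra columns in
#' the trial table are accepted with a warning and ignored downstream;
#' missing schema elements raise an error naming the offending file.
#'
#' @param path bundle directory.
#' @return a `motistate_bundle`.
#' @export
read_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("read_bundle: missing manifest.json in %s", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$schema, "motistate-bundle/1"))
    stopf("read_bundle: unsupported schema '%s'", mf$schema)
  mice <- lapply(mf$mice, function(id) {
    mdir <- file.path(path, id)
    for (f in c("config.json", "trials.csv", "truth.json"))
      if (!file.exists(file.path(mdir, f)))
        stopf("read_bundle: missing %s for mouse %s", f, id)
    cfl <- jsonlite::read_json(file.path(mdir, "config.json"), simplifyVector = TRUE)
    cfl$feature_coupling <- lapply(cfl$feature_coupling, function(e)
      list(mean = unlist(e$mean), sd = e$sd, drift = e$drift))
    cf <- do.call(mouse_config, cfl)
    trials <- fread_(file.path(mdir, "trials.csv"))
    expected <- c("mouse", "day", "trial", "trial_type", "outcome", "punished",
                  "latent_state", "t_onset", "t_stim", "duration",
                  paste0("tend_", nonperformance_vars()))
    extra <- setdiff(names(trials), expected)
    if (length(extra))
      warnf("read_bundle: ignoring unknown trial columns: %s", paste(extra, collapse = ", "))
    missing <- setdiff(expected, names(trials))
    if (length(missing))
      stopf("read_bundle: trials.csv for %s lacks column(s): %s", id,
            paste(missing, collapse = ", "))
    truth <- jsonlite::read_json(file.path(mdir, "truth.json"), simplifyVector = TRUE)
    sdirs <- sort(list.dirs(mdir, recursive = FALSE))
    streams <- NULL
    if (length(sdirs)) {
      streams <- lapply(sdirs, function(sdir) {
        for (f in c("meta.json", "licks.csv", "encoder.csv", "keypoints.csv",
                    "lfp_epochs.csv", "raw_epochs.csv"))
          if (!file.exists(file.path(sdir, f)))
            stopf("read_bundle: missing %s in %s", f, sdir)
        meta <- jsonlite::read_json(file.path(sdir, "meta.json"), simplifyVector = TRUE)
        kp <- fread_(file.path(sdir, "keypoints.csv"))
        nf <- max(kp$frame)
        mk_arr <- function(part) {
          d <- kp[kp$part == part, ]
          arr <- array(NA_real_, c(nf, 8, 2))
          arr[cbind(d$frame, d$vertex, 1L)] <- d$x
          arr[cbind(d$frame, d$vertex, 2L)] <- d$y
          arr
        }
        structure(list(
          day = meta$day,
          lick_times = fread_(file.path(sdir, "licks.csv"))$time,
          encoder = list(rate = meta$encoder_rate,
                         voltage = fread_(file.path(sdir, "encoder.csv"))$voltage),
          keypoints = list(time = kp$time[kp$part == "pupil" & kp$vertex == 1],
                           pupil = mk_arr("pupil"), eyelid = mk_arr("eyelid")),
          lfp_epochs = long_to_epochs(fread_(file.path(sdir, "lfp_epochs.csv"))),
          raw_epochs = long_to_epochs(fread_(file.path(sdir, "raw_epochs.csv"))),
          epoch_window = meta$epoch_window, lfp_rate = meta$lfp_rate,
          raw_rate = meta$raw_rate, t_end = meta$t_end), class = "session_streams")
      })
    }
    list(config = cf, trials = trials[, expected], streams = streams, truth = truth)
  })
  names(mice) <- mf$mice
  structure(list(mice = mice, schema = mf$schema), class = "motistate_bundle")
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates the dataset, extracts features, labels states, runs the
#' state prediction, progression and laminar stages, and writes a
#' machine-readable JSON manifest recording every seed, parameter and
#' headline result. Deterministic given the configs' seeds.
#'
#' @param mouse_configs list of [mouse_config()] objects.
#' @param out_dir output directory for the manifest (NULL skips writing).
#' @param config a [pipeline_config()].
#' @param n_iter prediction iterations per pool size (kept small by
#'   default; raise for production-scale ROC pooling).
#' @param pool_sizes predictor-pool sizes to evaluate.
#' @param laminar logical; run the laminar stage (default TRUE).
#' @param progression_variable peristimulus variable for the progression
#'   stage.
#' @return list with `features`, `labels`, `summaries`, `prediction`,
#'   `progression`, `laminar`, `manifest`.
#' @export
run_pipeline <- function(mouse_configs, out_dir = NULL,
                         config = pipeline_config(), n_iter = 5,
                         pool_sizes = c(1, 4, 8), laminar = TRUE,
                         progression_variable = "wheel_speed") {
  stage <- "simulate"
  res <- tryCatch({
    bundle <- gen_dataset(mouse_configs)
    stage <- "features"
    feats <- trial_features(bundle, config)
    summ <- session_summaries(feats, window = config$smoothing_window)
    stage <- "label-states"
    labels <- label_states(feats, window = config$smoothing_window,
                           n_bins = config$histogram_bins,
                           q = config$correctness_quantile)
    feats_sm <- smooth_features(feats, window = config$smoothing_window)
    stage <- "predict-states"
    pred <- lapply(names(bundle$mice), function(id) {
      rows <- feats_sm$mouse == id
      auc_vs_pool_size(feats_sm[rows, nonperformance_vars()],
                       labels$state[labels$mouse == id],
                       pool_sizes = pool_sizes, n_iter = n_iter,
                       seed = fan_seed(bundle$mice[[id]]$config$seed, "predict"),
                       block = config$shuffle_block, ntree = config$n_trees)
    })
    names(pred) <- names(bundle$mice)
    stage <- "peristimulus"
    prog <- lapply(names(bundle$mice), function(id) {
      bm <- bundle$mice[[id]]
      rows <- which(labels$mouse == id)
      sc <- sort_subcategories(labels$state[rows], feats$outcome[rows])
      biggest <- names(which.max(lengths(sc$index)))
      idx <- sc$index[[biggest]]
      bl <- progression_blocks(idx, config$n_blocks)
      list(subcategory = biggest,
           profile = peristim_average(bm, idx, bl, progression_variable,
                                      window = config$peristim_window,
                                      n_bins = config$peristim_bins))
    })
    names(prog) <- names(bundle$mice)
    lam <- NULL
    if (laminar) {
      stage <- "laminar"
      lam <- lapply(names(bundle$mice), function(id) {
        bm <- bundle$mice[[id]]
        rows <- which(labels$mouse == id)
        sc <- sort_subcategories(labels$state[rows], feats$outcome[rows])
        biggest <- names(which.max(lengths(sc$index)))
        idx <- sc$index[[biggest]]
        bl <- progression_blocks(idx, config$n_blocks)
        pr <- laminar_block_profiles(bm, idx, bl, "MUA",
                                     channels_analyzed = config$channels_analyzed,
                                     window = config$laminar_window)
        ok <- stats::complete.cases(pr$profiles)
        mean_profile <- colMeans(pr$profiles[ok, , drop = FALSE])
        qc <- mua_landmark_qc(mean_profile, pr$depth_mm,
                              expected_depth = bm$config$landmark_depth_mm,
                              tolerance = config$landmark_tol_mm)
        list(subcategory = biggest, qc = qc)
      })
      names(lam) <- names(bundle$mice)
    }
    list(bundle = bundle, features = feats, summaries = summ, labels = labels,
         prediction = pred, progression = prog, laminar = lam)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s (reproduce with run_pipeline() on the same configs)",
          stage, conditionMessage(e))
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("motistate")),
    seeds = lapply(mouse_configs, `[[`, "seed"),
    parameters = unclass(config),
    mice = names(res$bundle$mice),
    n_trials = nrow(res$features),
    state_counts = as.list(table(res$labels$state)),
    auc = lapply(res$prediction, `[[`, "auc"),
    landmark_qc = if (!is.null(res$laminar))
      lapply(res$laminar, function(x) x$qc) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  c(res[setdiff(names(res), "bundle")], list(manifest = manifest))
}
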