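#' Default project configuration
#'
#' All user-facing keys of the project configuration file with their
#' defaults: the motif count `n_cluster`, the minimum accepted pose
#' likelihood `pose_confidence`, the egocentric-data flag, feature and
#' window sizes, latent dimension `zdims`, the test fraction, the robust
#' IQR / Savitzky-Golay cleaning switches, and the seed. Training
#' internals (hidden size, learning rate, epoch budget, patience, batch
#' shape) live under `internal:`.
#'
#' @param model_name model name string.
#' @param video_sets character vector of video/recording names.
#' @param project_path project folder path.
#' @param ... overrides for any configuration key (unknown keys warn).
#' @return a named list of class `project_config`.
#' @export
default_config <- function(model_name = "motifembed", video_sets = character(),
                           project_path = ".", ...) {
  cfg <- list(
    model_name = model_name,
    n_cluster = 30L,
    pose_confidence = 0.9,
    project_path = project_path,
    video_sets = as.list(video_sets),
    egocentric_data = FALSE,
    pose_ref_index = c(0L, 5L),
    num_features = 12L,
    time_window = 30L,
    prediction_window = 15L,
    zdims = 30L,
    test_fraction = 0.1,
    robust = TRUE,
    iqr_factor = 4,
    savgol_filter = TRUE,
    savgol_length = 5L,
    savgol_order = 2L,
    length_of_motif_video = 1000L,
    seed = 42L,
    internal = list(hidden_size = 256L, learning_rate = 5e-4,
                    max_epochs = 100L, patience = 50L, batch_size = 64L,
                    batches_per_epoch = 25L, kl_anneal = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg)) cfg[[nm]] <- dots[[nm]]
    else if (nm %in% names(cfg$internal)) cfg$internal[[nm]] <- dots[[nm]]
    else {
      warning("unknown configuration key: ", nm, " (kept under internal)")
      cfg$internal[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "project_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_config
#' @param cfg a `project_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "project_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.log_line <- function(project, stage, cfg, seed, msg = "") {
  line <- sprintf("[%s] stage=%s config=%s seed=%d %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  .config_hash(cfg), seed, msg)
  cat(line, "\n", file = file.path(project, "log.txt"), append = TRUE)
  message(line)
  invisible(line)
}

#' Initialize a project folder
#'
#' Creates the dated project folder `<name>-<Mon><DD>-<YYYY>` with the
#' `data/`, `model/`, `results/` and `videos/` subfolders and a populated
#' `config.yaml`, and registers the given pose CSVs (copied into
#' `data/<video>/`).
#'
#' @param name project name.
#' @param pose_files character vector of pose CSV paths to register.
#' @param working_dir directory in which to create the project.
#' @param force overwrite an existing project folder of the same
#'   name/date.
#' @param ... configuration overrides passed to [default_config()].
#' @return list with `path` (project folder) and `config`.
#' @export
init_project <- function(name, pose_files = character(),
                         working_dir = ".", force = FALSE, ...) {
  stopifnot(dir.exists(working_dir))
  missing <- pose_files[!file.exists(pose_files)]
  if (length(missing)) stop("pose file(s) not found: ",
                            paste(missing, collapse = ", "))
  stamp <- format(Sys.Date(), "%b%d-%Y")
  root <- file.path(working_dir, paste0(name, "-", stamp))
  if (dir.exists(root)) {
    if (!force) stop("project folder exists: ", root,
                     " (use force = TRUE to overwrite)")
    unlink(root, recursive = TRUE)
  }
  for (d in c("data", "model", "results", "videos"))
    dir.create(file.path(root, d), recursive = TRUE)
  videos <- sub("\\.csv$", "", basename(pose_files))
  for (i in seq_along(pose_files)) {
    vd <- file.path(root, "data", videos[i])
    dir.create(vd)
    file.copy(pose_files[i], file.path(vd, paste0(videos[i], ".csv")))
  }
  cfg <- default_config(video_sets = videos, project_path = root, ...)
  save_config(cfg, file.path(root, "config.yaml"))
  .log_line(root, "init", cfg, cfg$seed,
            paste("videos:", paste(videos, collapse = ",")))
  list(path = root, config = cfg)
}

# stage artifact paths
.paths <- function(root, video) {
  list(csv = file.path(root, "data", video, paste0(video, ".csv")),
       seq = file.path(root, "data", video, paste0(video, "-PE-seq.npy")),
       clean = file.path(root, "data", video,
                         paste0(video, "-PE-seq-clean.npy")),
       truth = file.path(root, "data", video, paste0(video, "-truth.npy")),
       labels = file.path(root, "results", video,
                          paste0(video, "-motifs.npy")),
       latent = file.path(root, "results", video,
                          paste0(video, "-latents.npy")))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order: `align` (CSV to
#' masked egocentric series), `trainset` (cleaning, global z-scoring,
#' train/test split), `train` (fit the embedding model), `evaluate`,
#' `segment` (latent inference + HMM decoding per video), `community`
#' (transition matrix, merge tree, communities) and `score` (against
#' `<video>-truth.npy` reference labels where present). Each stage logs
#' its parameters, seed and artifact checksums, and a completed stage is
#' a no-op on re-run unless `force = TRUE`.
#'
#' @param project project folder (as returned by [init_project()]) or a
#'   path to its `config.yaml`.
#' @param stages subset of the canonical stages (default: all).
#' @param force re-run completed stages.
#' @param n_communities communities to cut in the `community` stage
#'   (default 3).
#' @return invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(project,
                         stages = c("align", "trainset", "train", "evaluate",
                                    "segment", "community", "score"),
                         force = FALSE, n_communities = 3L) {
  canonical <- c("align", "trainset", "train", "evaluate", "segment",
                 "community", "score")
  stages <- canonical[canonical %in% match.arg(stages, canonical,
                                               several.ok = TRUE)]
  root <- if (is.list(project)) project$path else
    if (dir.exists(project)) project else dirname(project)
  cfg <- load_config(file.path(root, "config.yaml"))
  videos <- unlist(cfg$video_sets)
  out <- list()
  w <- cfg$time_window; v <- cfg$prediction_window
  anchors <- unlist(cfg$pose_ref_index) + 1L   # 0-based in config

  if ("align" %in% stages) {
    for (vid in videos) {
      p <- .paths(root, vid)
      if (file.exists(p$seq) && !force) next
      if (!file.exists(p$csv)) stop("missing pose CSV for ", vid,
                                    "; produced by stage 'init'")
      track <- read_pose_csv(p$csv, "dlc")
      raw <- confidence_mask(track, cfg$pose_confidence)
      s <- if (isTRUE(cfg$egocentric_data)) {
        marker_series(raw$values)
      } else {
        egocentric_align(raw, anchors[1L], anchors[2L])
      }
      npy_save(s$values, p$seq)
      .log_line(root, "align", cfg, cfg$seed,
                paste0(vid, " md5=", tools::md5sum(p$seq)))
    }
  }
  if ("trainset" %in% stages) {
    done <- file.exists(file.path(root, "data", "train", "train_seq.npy"))
    if (!done || force) {
      cleaned <- list()
      for (vid in videos) {
        p <- .paths(root, vid)
        if (!file.exists(p$seq))
          stop("missing aligned series for ", vid,
               "; run stage 'align' first")
        s <- marker_series(npy_load(p$seq))
        if (isTRUE(cfg$robust)) s <- iqr_clean(s, cfg$iqr_factor)
        s <- interpolate_nan(s)
        if (isTRUE(cfg$savgol_filter))
          s <- savgol_smooth(s, cfg$savgol_length, cfg$savgol_order)
        cleaned[[vid]] <- s
      }
      # z-score with statistics of the complete dataset
      all_vals <- do.call(rbind, lapply(cleaned, `[[`, "values"))
      mu <- colMeans(all_vals)
      sd <- apply(all_vals, 2L, stats::sd)
      if (any(sd == 0)) stop("zero-variance feature in pooled dataset")
      tr_dir <- file.path(root, "data", "train")
      if (!dir.exists(tr_dir)) dir.create(tr_dir)
      train_mats <- list(); test_mats <- list()
      for (vid in videos) {
        p <- .paths(root, vid)
        z <- sweep(sweep(cleaned[[vid]]$values, 2L, mu), 2L, sd, "/")
        npy_save(z, p$clean)
        n <- nrow(z); n_test <- floor(cfg$test_fraction * n)
        train_mats[[vid]] <- z[seq_len(n - n_test), , drop = FALSE]
        test_mats[[vid]] <- z[(n - n_test + 1L):n, , drop = FALSE]
      }
      npy_save(do.call(rbind, train_mats),
               file.path(tr_dir, "train_seq.npy"))
      npy_save(do.call(rbind, test_mats), file.path(tr_dir, "test_seq.npy"))
      yaml::write_yaml(list(mean = as.numeric(mu), sd = as.numeric(sd),
                            train_lengths = vapply(train_mats, nrow,
                                                   integer(1)),
                            test_lengths = vapply(test_mats, nrow,
                                                  integer(1))),
                       file.path(tr_dir, "scale.yaml"))
      .log_line(root, "trainset", cfg, cfg$seed,
                paste0("md5=", tools::md5sum(file.path(tr_dir,
                                                       "train_seq.npy"))))
    }
  }
  model_path <- file.path(root, "model", paste0(cfg$model_name, ".rds"))
  if ("train" %in% stages) {
    if (!file.exists(model_path) || force) {
      tr_dir <- file.path(root, "data", "train")
      if (!file.exists(file.path(tr_dir, "train_seq.npy")))
        stop("missing training set; run stage 'trainset' first")
      sc <- yaml::read_yaml(file.path(tr_dir, "scale.yaml"))
      series <- lapply(videos, function(vid)
        marker_series(npy_load(.paths(root, vid)$clean),
                      scale_stats = list(mean = as.numeric(sc$mean),
                                         sd = as.numeric(sc$sd))))
      m <- ncol(series[[1L]]$values)
      mc <- vae_config(num_features = m, zdims = cfg$zdims, time_window = w,
                       prediction_window = v,
                       hidden_size = cfg$internal$hidden_size,
                       learning_rate = cfg$internal$learning_rate,
                       max_epochs = cfg$internal$max_epochs,
                       patience = cfg$internal$patience,
                       batch_size = cfg$internal$batch_size,
                       batches_per_epoch = cfg$internal$batches_per_epoch,
                       kl_anneal = isTRUE(cfg$internal$kl_anneal),
                       seed = cfg$seed)
      model <- motif_vae(series, config = mc,
                         test_fraction = cfg$test_fraction)
      saveRDS(model, model_path)
      utils::write.csv(model$history,
                       file.path(root, "model", "loss_history.csv"),
                       row.names = FALSE)
      .log_line(root, "train", cfg, cfg$seed,
                sprintf("best_epoch=%d test_loss=%.5f", model$best_epoch,
                        model$history$test_total[model$best_epoch]))
      out$model <- model
    }
  }
  if ("evaluate" %in% stages) {
    if (!file.exists(model_path))
      stop("missing trained model; run stage 'train' first")
    model <- readRDS(model_path)
    series <- lapply(videos, function(vid)
      marker_series(npy_load(.paths(root, vid)$clean),
                    scale_stats = model$scale_stats))
    ev <- evaluate(model, series, seed = cfg$seed)
    yaml::write_yaml(ev[c("reconstruction_error_z", "prediction_error_z",
                          "reconstruction_error_px",
                          "prediction_error_px")],
                     file.path(root, "model", "evaluation.yaml"))
    .log_line(root, "evaluate", cfg, cfg$seed,
              sprintf("rec_px=%.3f", ev$reconstruction_error_px))
    out$evaluation <- ev
  }
  if ("segment" %in% stages) {
    done <- all(file.exists(vapply(videos, function(vid)
      .paths(root, vid)$labels, character(1))))
    if (!done || force) {
      if (!file.exists(model_path))
        stop("missing trained model; run stage 'train' first")
      model <- readRDS(model_path)
      lats <- list()
      for (vid in videos) {
        p <- .paths(root, vid)
        lat <- infer_latents(model, marker_series(npy_load(p$clean)))
        dir.create(file.path(root, "results", vid), showWarnings = FALSE,
                   recursive = TRUE)
        npy_save(lat$Z, p$latent)
        lats[[vid]] <- lat
      }
      hmm <- fit_hmm(lats, cfg$n_cluster, seed = cfg$seed)
      dec <- decode_states(hmm, lats)
      if (inherits(dec, "motif_series")) dec <- list(dec)
      usage <- list()
      for (i in seq_along(videos)) {
        p <- .paths(root, videos[i])
        npy_save(dec[[i]]$labels, p$labels)
        usage[[videos[i]]] <- dec[[i]]$usage
      }
      jsonlite::write_json(usage,
                           file.path(root, "results", "usage.json"),
                           auto_unbox = FALSE, digits = NA)
      saveRDS(hmm, file.path(root, "results", "hmm.rds"))
      .log_line(root, "segment", cfg, cfg$seed,
                sprintf("K=%d", cfg$n_cluster))
      out$segmentation <- dec
    }
  }
  if ("community" %in% stages) {
    lab_files <- vapply(videos, function(vid) .paths(root, vid)$labels,
                        character(1))
    if (!all(file.exists(lab_files)))
      stop("missing motif labels; run stage 'segment' first")
    labels <- unlist(lapply(lab_files, npy_load))
    ms <- motif_series(labels, cfg$n_cluster)
    tm <- transition_matrix(ms)
    tree <- build_tree(tm, ms$usage)
    comm <- cut_tree(tree, min(n_communities, cfg$n_cluster))
    cd <- file.path(root, "results", "community")
    dir.create(cd, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(tm$T),
                     file.path(cd, "transition_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(tree$merges, file.path(cd, "merges.csv"),
                     row.names = FALSE)
    writeLines(as_newick(tree), file.path(cd, "tree.nwk"))
    utils::write.csv(data.frame(motif = 0:(cfg$n_cluster - 1L),
                                community = comm$community),
                     file.path(cd, "communities.csv"), row.names = FALSE)
    .log_line(root, "community", cfg, cfg$seed,
              sprintf("n_communities=%d", comm$n_communities))
    out$tree <- tree; out$communities <- comm
  }
  if ("score" %in% stages) {
    for (vid in videos) {
      p <- .paths(root, vid)
      if (!file.exists(p$truth)) next
      if (!file.exists(p$labels))
        stop("missing motif labels for ", vid, "; run stage 'segment' first")
      truth <- npy_load(p$truth)
      labels <- npy_load(p$labels)
      # planted labels are per frame; offset to the window centers
      centers <- seq_along(labels) - 1L + w / 2
      ref <- truth[floor(centers) + 1L]
      rep <- score_report(ref, labels)
      jsonlite::write_json(list(purity = rep$purity, nmi = rep$nmi,
                                homogeneity = rep$homogeneity),
                           file.path(root, "results", vid, "score.json"),
                           auto_unbox = TRUE, digits = NA)
      .log_line(root, "score", cfg, cfg$seed,
                sprintf("%s nmi=%.3f", vid, rep$nmi))
      out$score[[vid]] <- rep
    }
  }
  invisible(out)
}

#' Episode manifest per motif
#'
#' Lists contiguous label episodes per motif (longest first) up to a
#' per-motif length budget, with label indices translated to video frame
#' numbers by the half-window offset. Motifs without episodes get an
#' empty entry. The manifest drives external video cutting.
#'
#' @param labels a [motif_series()] or integer label vector.
#' @param length_budget maximum total frames listed per motif.
#' @param w time window used for latent inference (frame offset
#'   `w / 2`).
#' @param min_episode minimum episode length in frames (default 1).
#' @return data frame with `motif`, `start`, `end` (0-based label
#'   indices, inclusive), `video_start`, `video_end`.
#' @export
motif_manifest <- function(labels, length_budget = 1000L, w = 30L,
                           min_episode = 1L) {
  K <- NULL
  if (inherits(labels, "motif_series")) {
    K <- labels$K
    labels <- labels$labels
  }
  if (is.null(K)) K <- max(labels) + 1L
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in 0:(K - 1L)) {
    idx <- which(r$values == k & r$lengths >= min_episode)
    if (!length(idx)) next
    idx <- idx[order(r$lengths[idx], decreasing = TRUE)]
    used <- 0L
    for (i in idx) {
      if (length_budget <= 0L || used + r$lengths[i] > length_budget) break
      rows[[length(rows) + 1L]] <-
        data.frame(motif = k, start = starts[i] - 1L, end = ends[i] - 1L,
                   video_start = starts[i] - 1L + w %/% 2L,
                   video_end = ends[i] - 1L + w %/% 2L)
      used <- used + r$lengths[i]
    }
  }
  if (!length(rows))
    return(data.frame(motif = integer(), start = integer(),
                      end = integer(), video_start = integer(),
                      video_end = integer()))
  res <- do.call(rbind, rows)
  res[order(res$motif, res$start), , drop = FALSE]
}

#' Two-dimensional embedding of the latent space
#'
#' Projects latent columns onto their first two principal components for
#' visual inspection of the latent structure (a deterministic linear
#' embedding; signs are fixed so the largest loading of each component
#' is positive).
#'
#' @param latents a `latent_series` or d x T matrix.
#' @param file optional CSV path to write the coordinates to.
#' @return a T x 2 matrix of embedding coordinates.
#' @export
visualize_latents <- function(latents, file = NULL) {
  Z <- if (inherits(latents, "latent_series")) latents$Z else as.matrix(latents)
  if (ncol(Z) < 10L) stop("need at least 10 latent columns to embed")
  pc <- stats::prcomp(t(Z), rank. = 2L)
  rot <- pc$rotation
  for (j in 1:2) if (rot[which.max(abs(rot[, j])), j] < 0)
    pc$x[, j] <- -pc$x[, j]
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  if (!is.null(file))
    utils::write.csv(as.data.frame(coords), file, row.names = FALSE)
  coords
}

#' Write a synthetic dataset to disk
#'
#' Emits the pose CSV (DLC dialect), the planted ground-truth labels as
#' NPY and the generator configuration as YAML, the file triple the
#' simulator CLI produces.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory.
#' @param name base file name.
#' @return named list of the written paths, invisibly.
#' @export
write_synthetic <- function(dataset, dir = ".", name = "synthetic") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  truth <- file.path(dir, paste0(name, "-truth.npy"))
  cfgf <- file.path(dir, paste0(name, "-config.yaml"))
  write_pose_csv(dataset$track, csv, "dlc")
  npy_save(as.integer(dataset$labels), truth)
  cfg <- dataset$config
  cfg$regimes <- lapply(cfg$regimes, function(r) {
    r <- unclass(r)
    r$offsets <- as.data.frame(r$offsets)
    r
  })
  yaml::write_yaml(cfg, cfgf)
  invisible(list(csv = csv, truth = truth, config = cfgf))
}
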