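test_that("project initialization scaffolds folders and config", {
  wd <- withr::local_tempdir()
  ds <- make_pose_fixture(120L, seed = 2L)
  csv <- file.path(wd, "video-1.csv")
  write_pose_csv(ds$track, csv, "dlc")
  pr <- init_project("demo", csv, wd, n_cluster = 5L)
  for (d in c("data", "model", "results", "videos"))
    expect_true(dir.exists(file.path(pr$path, d)))
  expect_true(file.exists(file.path(pr$path, "config.yaml")))
  expect_true(file.exists(file.path(pr$path, "data", "video-1",
                                    "video-1.csv")))
  # re-init without force refuses; with force succeeds
  expect_error(init_project("demo", csv, wd), "exists")
  pr2 <- init_project("demo", csv, wd, force = TRUE)
  expect_true(dir.exists(pr2$path))

  # config round-trips load -> save -> load identically
  cfg <- load_config(file.path(pr2$path, "config.yaml"))
  f2 <- file.path(wd, "cfg2.yaml")
  save_config(cfg, f2)
  expect_identical(unclass(load_config(f2)), unclass(cfg))
  expect_error(init_project("x", file.path(wd, "missing.csv"), wd),
               "not found")
  expect_warning(default_config(nonsense_key = 1), "unknown")
})

test_that("pipeline stages declare their prerequisites", {
  wd <- withr::local_tempdir()
  ds <- make_pose_fixture(200L, seed = 3L)
  csv <- file.path(wd, "video-1.csv")
  write_pose_csv(ds$track, csv, "dlc")
  pr <- init_project("pre", csv, wd)
  expect_error(run_pipeline(pr, stages = "segment"), "train")
  expect_error(run_pipeline(pr, stages = "trainset"), "align")
})

test_that("the pipeline runs end to end on a miniature project", {
  wd <- withr::local_tempdir()
  ds <- reference_dataset("tiny", seed = 31L)
  track <- ds$track
  keep <- 1:700
  track$x <- track$x[keep, ]; track$y <- track$y[keep, ]
  track$likelihood <- track$likelihood[keep, ]
  track$frame_index <- track$frame_index[keep]
  csv <- file.path(wd, "video-1.csv")
  write_pose_csv(track, csv, "dlc")
  pr <- init_project("mini", csv, wd,
                     n_cluster = 3L, zdims = 4L, time_window = 20L,
                     prediction_window = 10L, pose_ref_index = c(0L, 3L),
                     hidden_size = 12L, max_epochs = 2L, batch_size = 16L,
                     batches_per_epoch = 4L, seed = 7L)
  npy_save(as.integer(ds$labels[keep]),
           file.path(pr$path, "data", "video-1", "video-1-truth.npy"))
  run_pipeline(pr, n_communities = 2L)
  p <- pr$path
  artifacts <- c(
    file.path(p, "data", "video-1", "video-1-PE-seq.npy"),
    file.path(p, "data", "video-1", "video-1-PE-seq-clean.npy"),
    file.path(p, "data", "train", "train_seq.npy"),
    file.path(p, "data", "train", "test_seq.npy"),
    file.path(p, "model", "motifembed.rds"),
    file.path(p, "model", "loss_history.csv"),
    file.path(p, "model", "evaluation.yaml"),
    file.path(p, "results", "video-1", "video-1-motifs.npy"),
    file.path(p, "results", "video-1", "video-1-latents.npy"),
    file.path(p, "results", "usage.json"),
    file.path(p, "results", "community", "transition_matrix.csv"),
    file.path(p, "results", "community", "tree.nwk"),
    file.path(p, "results", "community", "communities.csv"),
    file.path(p, "results", "video-1", "score.json"),
    file.path(p, "log.txt"))
  for (a in artifacts) expect_true(file.exists(a), label = a)

  labels <- npy_load(file.path(p, "results", "video-1",
                               "video-1-motifs.npy"))
  expect_equal(length(labels), 700L - 20L)   # N - w label contract
  usage <- jsonlite::read_json(file.path(p, "results", "usage.json"),
                               simplifyVector = TRUE)
  expect_equal(sum(usage[["video-1"]]), 1, tolerance = 1e-12)

  # re-running completed stages is a no-op (no artifact mtime changes)
  before <- file.mtime(artifacts[1:4])
  run_pipeline(pr, stages = c("align", "trainset"))
  expect_identical(file.mtime(artifacts[1:4]), before)
})

test_that("motif manifests enumerate episodes with frame offsets", {
  man <- motif_manifest(c(0L, 0L, 0L, 1L, 1L, 0L), length_budget = 100L,
                        w = 30L)
  m0 <- man[man$motif == 0, ]
  expect_equal(m0$start, c(0L, 5L))
  expect_equal(m0$end, c(2L, 5L))
  m1 <- man[man$motif == 1, ]
  expect_equal(c(m1$start, m1$end), c(3L, 4L))
  expect_equal(man$video_start, man$start + 15L)

  expect_equal(nrow(motif_manifest(c(0L, 1L), length_budget = 0L)), 0L)

  # episodes never overlap within a motif
  set.seed(1)
  labs <- sample(0:2, 500, replace = TRUE)
  man <- motif_manifest(labs, length_budget = 50L, w = 30L)
  for (k in unique(man$motif)) {
    mk <- man[man$motif == k, ]
    if (nrow(mk) > 1)
      expect_true(all(mk$start[-1] > mk$end[-nrow(mk)]))
    expect_lte(sum(mk$end - mk$start + 1L), 50L)
  }
})

test_that("the 2-D latent embedding is deterministic and separates clusters", {
  set.seed(12)
  Z <- cbind(matrix(rnorm(5 * 60, -3), 5), matrix(rnorm(5 * 60, 3), 5))
  co1 <- visualize_latents(Z)
  co2 <- visualize_latents(Z)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 120L)
  labels <- rep(1:2, each = 60)
  sil <- cluster::silhouette(labels, dist(co1))
  expect_gt(mean(sil[, "sil_width"]), 0.3)
  expect_error(visualize_latents(Z[, 1:5]), "at least 10")
  f <- withr::local_tempfile(fileext = ".csv")
  visualize_latents(Z, file = f)
  expect_equal(nrow(utils::read.csv(f)), 120L)
})

test_that("synthetic datasets export the CSV + truth + config triple", {
  wd <- withr::local_tempdir()
  ds <- make_pose_fixture(80L, seed = 6L)
  paths <- write_synthetic(ds, wd, "sim")
  expect_true(all(file.exists(unlist(paths))))
  truth <- npy_load(paths$truth)
  expect_equal(as.integer(truth), ds$labels)
  cfg <- yaml::read_yaml(paths$config)
  expect_equal(length(cfg$regimes), 3L)
  track <- read_pose_csv(paths$csv, "dlc")
  expect_equal(nrow(track$x), 80L)
})
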