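test_that("orientation statistics summarize score spreads", {
  expect_equal(unname(orientation_stats(rep(3.3, 8))), c(3.3, 3.3, 3.3, 3.3, 0))
  st <- orientation_stats(c(1, 2, 3, 4))
  expect_equal(unname(st), c(2.5, 2.5, 1, 4, sqrt(mean((1:4 - 2.5)^2))))
  set.seed(1)
  for (i in 1:5) {
    s <- runif(8, 1, 10)
    st <- orientation_stats(s)
    expect_true(st["min"] <= st["med"] && st["med"] <= st["max"])
  }
  expect_error(orientation_stats(numeric(0)), "empty")
})

test_that("range and dispersion ratios follow their formulas", {
  expect_equal(range_mean_ratio(2, 2, 5), 0)
  expect_equal(range_mean_ratio(1, 3, 2), 100)
  expect_error(range_mean_ratio(1, 3, 0), "zero average")
  expect_equal(std_mean_ratio(0, 4), 0)
  expect_equal(std_mean_ratio(1, 4), 25)
  expect_error(std_mean_ratio(1, 0), "zero average")
})

test_that("the score table sorts by mean with index tie-breaks", {
  scores <- list(`2` = rep(5, 4), `1` = rep(7, 4), `3` = rep(5, 4))
  tab <- synthetic_table(scores)
  expect_equal(tab$index, c("1", "2", "3"))
  expect_equal(tab$avg, c(7, 5, 5))
  set.seed(2)
  s <- list(a = runif(8, 1, 10), b = runif(8, 1, 10))
  tab2 <- synthetic_table(s)
  for (r in 1:2) {
    expect_equal(unname(unlist(tab2[r, c("avg", "med", "min", "max", "std")])),
                 unname(orientation_stats(s[[tab2$index[r]]])))
  }
})

test_that("synthetic-mode experiments run end to end and are reproducible", {
  cfg <- experiment_config(mode = "synthetic", seed = 3, canvas = 64L,
                           n_images = 24L,
                           network = network_config(64L,
                                                    channels = c(2L, 4L, 4L, 8L),
                                                    fc_hidden = 6L),
                           train = train_config(learning_rate = 1e-2,
                                                max_epochs = 15L, seed = 3),
                           train_orientations = "none",
                           out_dir = file.path(tempdir(), "synthrun"))
  res <- suppressMessages(run_experiment(cfg))
  expect_s3_class(res, "experiment_result")
  expect_s3_class(res$report, "metric_report")
  expect_equal(res$report$n, 4L)  # 24 images, 85:15 split
  expect_equal(nrow(res$scatter), 4L)
  expect_true(file.exists(file.path(cfg$out_dir, "manifest.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "checkpoint.rds")))
  expect_match(res$config_hash, "^[0-9a-f]{32}$")

  res2 <- suppressMessages(run_experiment(cfg))
  expect_identical(res2$manifest, res$manifest)
  expect_identical(res2$fit$history, res$fit$history)
  expect_identical(res2$report, res$report)
})

test_that("real-image mode runs the photograph pipeline end to end", {
  dir <- file.path(tempdir(), "realimgs")
  dir.create(dir, showWarnings = FALSE)
  scores <- session_scores_fixture(k = 14, seed = 5)
  for (id in unique(scores$image_id)) {
    set.seed(match(id, unique(scores$image_id)))
    img <- blob_image(h = 40, w = 48, cy = sample(12:28, 1),
                      cx = sample(14:34, 1), r = sample(6:9, 1), id = id)
    write_image(img, file.path(dir, paste0(id, ".png")))
  }
  csv <- file.path(tempdir(), "scores.csv")
  write.csv(scores, csv, row.names = FALSE)

  cfg <- experiment_config(mode = "real", seed = 2, canvas = 64L,
                           images_dir = dir, scores_csv = csv,
                           subject = "AB",
                           network = network_config(64L,
                                                    channels = c(2L, 4L, 4L, 8L),
                                                    fc_hidden = 6L),
                           train = train_config(learning_rate = 1e-2,
                                                max_epochs = 10L, seed = 2))
  res <- suppressMessages(run_experiment(cfg))
  expect_s3_class(res$report, "metric_report")
  expect_equal(res$report$n, 2L)  # 14 images -> 12 train / 2 test
  expect_true(all(c("image_id", "orientation", "assigned_score") %in%
                    names(res$manifest)))
  # every assigned score came from that image's session scores
  for (id in unique(res$manifest$image_id)) {
    sess <- scores$score[scores$image_id == id]
    expect_true(all(res$manifest$assigned_score[res$manifest$image_id == id]
                    %in% sess))
  }
})

test_that("real-image mode without a scores CSV fails fast", {
  expect_error(experiment_config(mode = "real", images_dir = tempdir()),
               "requires images_dir and scores_csv")
})
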