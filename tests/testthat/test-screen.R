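hitmat <- function(...) {
  m <- rbind(...)
  rownames(m) <- names(indicator_orientations())[seq_len(nrow(m))]
  m
}

test_that("method combination honours union, intersection and the hit minimum", {
  # peak 1 passes only GRA-LDH; peak 2 passes only VIP; peak 3 passes nothing
  gra <- hitmat(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE))
  vip <- hitmat(c(FALSE, TRUE, FALSE), c(FALSE, FALSE, FALSE),
                c(FALSE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  expect_equal(spectrum_effect_hits(gra, vip), c(1L, 2L))
  expect_length(spectrum_effect_hits(gra, vip, combine_methods = "intersection"), 0L)
  expect_equal(spectrum_effect_hits(gra, vip, min_indicator_hits = 2), 2L)
  all4 <- hitmat(c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE), c(TRUE, TRUE))
  none <- all4 & FALSE
  expect_equal(spectrum_effect_hits(all4, none, min_indicator_hits = 4), 1L)
})

test_that("the noise-free default study is recovered exactly end to end", {
  study <- quiet_study(seed = 1)
  rep <- run_screen(study$tables, study$panel, study$binding,
                    labels = truth_labels(study))
  expect_identical(rep$candidates, as.integer(study$truth$active_peaks))
  expect_equal(nrow(rep$trace), 36L)
  expect_true(all(rep$candidates %in% as.integer(study$binding)))
})

test_that("binding can be made optional", {
  study <- quiet_study(seed = 2)
  cfg <- screen_config(require_binding = FALSE, use_bpnn = FALSE)
  rep <- run_screen(study$tables, study$panel, binding = NULL,
                    config = cfg)
  expect_s3_class(rep, "candidate_report")
  spectrum <- which(rep$trace$spectrum_hit)
  content_ok <- which(rep$trace$content_ok)
  expect_identical(rep$candidates, as.integer(intersect(spectrum, content_ok)))
  # but requiring binding without supplying it fails with the stage name
  expect_error(run_screen(study$tables, study$panel, binding = NULL,
                          labels = truth_labels(study)), "binding")
})

test_that("an unreachable content floor empties the candidate set with a trace", {
  study <- quiet_study(seed = 2)
  cfg <- screen_config(content_min = 0.99, use_bpnn = FALSE)
  rep <- run_screen(study$tables, study$panel, study$binding, config = cfg)
  expect_length(rep$candidates, 0L)
  expect_true(all(grepl("content-filtered", rep$trace$rules)))
})

test_that("raising thresholds never enlarges the candidate set", {
  study <- quiet_study(seed = 3)
  labs <- truth_labels(study)
  base <- screen_config(use_bpnn = FALSE)
  run_with <- function(cfg) run_screen(study$tables, study$panel, study$binding,
                                       config = cfg)$candidates
  ref <- run_with(base)
  for (thr in c(0.92, 0.95, 1)) {
    cand <- run_with(screen_config(gra_threshold = thr, use_bpnn = FALSE))
    expect_true(all(cand %in% run_with(
      screen_config(gra_threshold = thr - 0.02, use_bpnn = FALSE))))
  }
  prev <- ref
  for (thr in c(1.2, 1.5, 2)) {
    cand <- run_with(screen_config(vip_threshold = thr, use_bpnn = FALSE))
    expect_true(all(cand %in% prev))
    prev <- cand
  }
  prev <- ref
  for (cm in c(0.01, 0.02, 0.05)) {
    cand <- run_with(screen_config(content_min = cm, use_bpnn = FALSE))
    expect_true(all(cand %in% prev))
    prev <- cand
  }
})

test_that("dropping the binding requirement can only enlarge the candidate set", {
  study <- quiet_study(seed = 4)
  with_bind <- run_screen(study$tables, study$panel, study$binding,
                          config = screen_config(use_bpnn = FALSE))$candidates
  without <- run_screen(study$tables, study$panel, study$binding,
                        config = screen_config(require_binding = FALSE,
                                               use_bpnn = FALSE))$candidates
  expect_true(all(with_bind %in% without))
})

test_that("reports round-trip through JSON with provenance metadata", {
  study <- quiet_study(seed = 5)
  rep <- run_screen(study$tables, study$panel, study$binding,
                    labels = truth_labels(study))
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- read_report(paths[["json"]])
  expect_identical(back$candidates, rep$candidates)
  expect_equal(back$trace$content, rep$trace$content)
  expect_identical(back$metadata$config_hash, rep$metadata$config_hash)
  expect_identical(back$metadata$seed, rep$metadata$seed)
  expect_equal(nrow(back$trace), 36L)
})

test_that("the file-based entry point reproduces the in-memory run", {
  dir <- withr::local_tempdir()
  study <- quiet_study(seed = 6)
  write_study(study, dir)
  lab <- data.frame(peak_id = study$truth$active_peaks, label = "A")
  labfile <- file.path(dir, "labels.csv")
  utils::write.csv(lab, labfile, row.names = FALSE)
  rep_files <- run_screen_files(file.path(dir, "peaks.csv"),
                                file.path(dir, "panel.csv"),
                                file.path(dir, "binding.csv"), labfile)
  rep_mem <- run_screen(study$tables, study$panel, study$binding,
                        labels = truth_labels(study))
  expect_identical(rep_files$candidates, rep_mem$candidates)
})

test_that("invalid screen configurations are rejected", {
  expect_error(screen_config(content_min = 1.2), "content_min")
  expect_error(screen_config(gra_threshold = -1), "gra_threshold")
  expect_error(screen_config(min_indicator_hits = 0), "min_indicator_hits")
})
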