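test_that("beat components have disjoint supports bounded by the fiducials", {
  beat <- generate_beat(beat_morphology(), 500)
  f <- beat$fiducials
  expect_lt(max(beat$P$offsets), min(beat$QRS$offsets))
  expect_lt(max(beat$QRS$offsets), min(beat$T$offsets))
  expect_equal(range(beat$P$offsets), c(f$p_on, f$p_off - 1L))
  expect_equal(range(beat$QRS$offsets), c(f$qrs_on, f$qrs_off - 1L))
  expect_equal(range(beat$T$offsets), c(f$t_on, f$t_off - 1L))
  expect_true(f$qrs_on <= f$r_peak && f$r_peak < f$qrs_off)

  wide <- beat_morphology()
  wide["T", "sigma_s"] <- 0.2  # T collides with QRS
  expect_error(generate_beat(wide, 500), class = "wmlr_morphology_error")
})

test_that("beat construction is linear in wave amplitudes", {
  m <- beat_morphology()
  m2 <- m
  m2["R", "amp_mv"] <- 2 * m["R", "amp_mv"]
  m2["Q", "amp_mv"] <- 2 * m["Q", "amp_mv"]
  m2["S", "amp_mv"] <- 2 * m["S", "amp_mv"]
  b1 <- generate_beat(m, 500)
  b2 <- generate_beat(m2, 500)
  expect_identical(b2$QRS$values, 2 * b1$QRS$values)
  expect_identical(b2$P$values, b1$P$values)
  expect_identical(b2$T$values, b1$T$values)
})

test_that("generated records are deterministic and satisfy lead identities", {
  cfg <- synth_config(2, seed = 61)
  a <- generate_record(cfg, record_id = "d", seed = 62)
  b <- generate_record(cfg, record_id = "d", seed = 62)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$fiducials$beats, b$fiducials$beats)

  s <- a$record$samples
  expect_equal(max(abs(s[, "I"] + s[, "III"] - s[, "II"])), 0)
  expect_equal(max(abs(s[, "aVR"] + (s[, "I"] + s[, "II"]) / 2)), 0)
  validate_fiducials(a$fiducials, n_samples = nrow(s))
})

test_that("fiducial intervals exactly bound the nonzero source support", {
  tr <- generate_record(synth_config(2, seed = 63), record_id = "s", seed = 64)
  n <- n_samples(tr$record)
  inside <- logical(n)
  for (w in c("P", "QRS", "T")) {
    seg <- wave_segments(tr$fiducials, w, n)
    for (i in seq_len(nrow(seg))) inside[seg[i, 1]:(seg[i, 2] - 1L)] <- TRUE
  }
  expect_equal(max(abs(tr$sources[!inside, ])), 0)
  # and every beat contributes nonzero signal inside each wave interval
  expect_true(all(abs(tr$sources[tr$fiducials$beats$r_peak, "QRS"]) > 0.5))
})

test_that("global mixing makes every lead an exact linear map of any lead", {
  co <- global_cohort(5, seed = 65)
  xy <- pooled_xy(co)
  m <- suppressWarnings(fit_ols(xy$X, xy$Y))
  expect_lt(max(abs(predict(m, xy$X) - xy$Y)), 1e-9)
})

test_that("per-wave mixing defeats raw leads but not the augmented input", {
  co <- cached_cohort("pw_noiseless",
                      synth_config(8, mixing_mode = "per_wave",
                                   disparity = 0.2, seed = 66))
  xy <- pooled_xy(co)
  raw <- suppressWarnings(fit_ols(xy$X, xy$Y))
  resid_raw <- max(abs(predict(raw, xy$X) - xy$Y))
  expect_gt(resid_raw, 0.01)   # strictly positive residual on raw leads
  Xa <- do.call(rbind, lapply(co$entries, function(e)
    build_augmented_input(e$record, e$fiducials)$channels))
  aug <- suppressWarnings(fit_ols(Xa, xy$Y))
  expect_lt(max(abs(predict(aug, Xa) - xy$Y)), 1e-9)
})

test_that("cohorts have distinct patients, shared within-patient morphology", {
  co <- generate_cohort(synth_config(6, records_per_patient = 2, seed = 67))
  expect_length(co$entries, 12)
  pids <- vapply(co$entries, function(e) e$record$patient_id, character(1))
  expect_length(unique(pids), 6)
  hr <- vapply(co$entries, function(e) e$patient$hr_bpm, numeric(1))
  expect_identical(hr[1], hr[2])      # same patient, same heart rate
  expect_false(hr[1] == hr[3])        # different patients differ
  expect_true(all(hr >= 50 & hr <= 90))
})

test_that("criteria injections are visible to the metadata filter", {
  co <- generate_cohort(synth_config(8, seed = 68,
                                     inject = c(duplicates = 1,
                                                abnormal = 1)))
  keep <- filter_metadata(co$metadata)
  expect_length(keep, 6)
  co2 <- generate_cohort(synth_config(8, seed = 68,
                                      inject = c(blank = 1, condition = 1)))
  keep2 <- filter_metadata(co2$metadata)
  expect_length(keep2, 6)
  blank_row <- which(co2$metadata$has_blank_lead)
  expect_true(any(detect_blank_leads(co2$entries[[blank_row]]$record)))
})

test_that("configured SNR matches the measured per-lead power ratio", {
  clean <- generate_cohort(synth_config(3, seed = 69))
  noisy <- generate_cohort(synth_config(3, seed = 69, noise_snr_db = 20))
  for (i in 1:3) {
    for (ld in c("II", "V4")) {
      s <- clean$entries[[i]]$record$samples[, ld]
      nz <- noisy$entries[[i]]$record$samples[, ld] - s
      snr <- 10 * log10(mean(s^2) / mean(nz^2))
      expect_lt(abs(snr - 20), 1)
    }
  }
})

test_that("cohort writers emit readable records, truth files and mixing", {
  co <- generate_cohort(synth_config(3, seed = 70))
  dir <- tempfile()
  write_cohort(co, dir, format = "csv")
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "mixing.json")))
  rid <- co$entries[[2]]$record$record_id
  rec <- load_record(file.path(dir, paste0(rid, ".csv")), "csv",
                     record_id = rid)
  expect_identical(unname(rec$samples),
                   unname(co$entries[[2]]$record$samples))
  fd <- import_fiducials(file.path(dir, paste0(rid, "_fiducials.csv")), rec)
  expect_equal(fd$beats, co$entries[[2]]$fiducials$beats)
})

test_that("synth_config validates its inputs", {
  expect_error(synth_config(0), class = "wmlr_config_error")
  expect_error(synth_config(2, base_gains = c(I = 1)),
               class = "wmlr_config_error")
})
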