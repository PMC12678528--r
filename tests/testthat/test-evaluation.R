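test_that("pearson_r matches its defining formula on worked examples", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))  # undefined
  expect_error(pearson_r(1:3, 1:4), class = "wmlr_shape_error")
  # symmetry and positive-affine invariance
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_equal(pearson_r(3 * x + 7, y), pearson_r(x, y), tolerance = 1e-12)
})

test_that("rmse matches its defining formula", {
  x <- rnorm(20)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 1), 1.0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), class = "wmlr_shape_error")
})

test_that("pearson_r and rmse agree with textbook oracles on 1000 random pairs", {
  with_seed(99, {
    for (i in 1:1000) {
      n <- sample(3:40, 1)
      x <- rnorm(n); y <- rnorm(n)
      # independent oracles: stats::cor and the literal mean-square formula
      expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
      expect_equal(rmse(x, y), sqrt(sum((y - x)^2) / n), tolerance = 1e-12)
    }
  })
})

test_that("patient folds partition patients with sizes within one", {
  f <- make_patient_folds(sprintf("p%02d", 1:10), k = 5, seed = 3)
  expect_equal(sort(unname(table(f))), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(f, make_patient_folds(sprintf("p%02d", 1:10), 5, 3))
  f2 <- make_patient_folds(sprintf("p%02d", 1:10), k = 5, seed = 4)
  expect_false(identical(f, f2))  # seed actually matters

  big <- make_patient_folds(sprintf("q%05d", 1:10000), k = 5, seed = 1)
  expect_equal(unname(table(big)), rep(2000L, 5), ignore_attr = TRUE)
  expect_setequal(names(big), sprintf("q%05d", 1:10000))
  expect_error(make_patient_folds(c("a", "b"), k = 5),
               class = "wmlr_value_error")
  # records of one patient share its fold by construction
  recs <- c("a", "b", "a", "c", "b", "d", "e")
  fr <- make_patient_folds(recs, k = 5, seed = 9)
  expect_length(fr, 5)
})

test_that("cross-validation scores oracle and degenerate pipelines correctly", {
  co <- global_cohort(5, seed = 51)
  entries <- as_entries(co)
  pids <- vapply(entries, function(e) e$record$patient_id, character(1))
  folds <- make_patient_folds(pids, k = 5, seed = 2)

  # perfect pipeline: feed the true output leads through an identity model
  oracle <- make_pipeline("p2", fitter = "ols")
  out_names <- oracle$output_names
  oracle$build_input <- function(entry)
    entry$record$samples[, out_names, drop = FALSE]
  oracle$fit <- function(X, Y)
    wmlr:::new_linear_model(diag(5), numeric(5), out_names, out_names)
  rep_perfect <- cross_validate(oracle, entries, folds)
  expect_true(all(rep_perfect$per_record$r == 1))
  expect_true(all(rep_perfect$per_record$rmse == 0))

  zero <- make_pipeline("p2", fitter = "ols")
  zero$fit <- function(X, Y)
    wmlr:::new_linear_model(matrix(0, 5, 3), numeric(5),
                            c("I", "II", "V3"),
                            c("V1", "V2", "V4", "V5", "V6"))
  rep_zero <- cross_validate(zero, entries, folds)
  expect_true(all(is.na(rep_zero$per_record$r)))  # constant prediction
  expect_equal(rep_zero$n_undefined_r, nrow(rep_zero$per_record))
  # rmse against zero equals each record's root-mean-square amplitude
  e1 <- entries[[1]]$record
  row1 <- rep_zero$per_record[rep_zero$per_record$record_id == e1$record_id &
                                rep_zero$per_record$lead == "V4", ]
  expect_equal(row1$rmse, sqrt(mean(e1$samples[, "V4"]^2)))
})

test_that("cross-validation never trains on a test patient", {
  co <- global_cohort(6, seed = 52)
  entries <- as_entries(co)
  pids <- vapply(entries, function(e) e$record$patient_id, character(1))
  folds <- make_patient_folds(pids, k = 3, seed = 5)
  rep <- run_cv(co, "p2", k = 3, seed = 5)
  for (f in seq_len(3)) {
    test_p <- unique(rep$per_record$patient_id[rep$per_record$fold == f])
    train_p <- names(folds)[folds != f]
    expect_length(intersect(test_p, train_p), 0)
  }
  expect_true(all(table(rep$per_record$record_id) == 5))  # one fold each
})

test_that("paired t-test reproduces the reference distribution and flags", {
  tt <- paired_ttest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(tt$t, 3.4641016, tolerance = 1e-6)
  expect_equal(tt$df, 2L)
  expect_equal(tt$p, 0.07417990, tolerance = 1e-6)
  # independent oracle
  ref <- stats::t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)

  same <- paired_ttest(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "identical")
  deg <- paired_ttest(c(2, 3), c(1, 2))
  expect_equal(deg$p, 0)
  expect_equal(deg$flag, "degenerate")

  a <- c(0.3, 0.5, 0.2, 0.9); b <- c(0.1, 0.6, 0.1, 0.4)
  fwd <- paired_ttest(a, b); rev <- paired_ttest(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
})

test_that("summaries have lead rows, an Average row, and the stated SD", {
  pr <- rbind(
    data.frame(record_id = "r1", patient_id = "p1", fold = 1,
               lead = c("V1", "V2", "V4", "V5", "V6"), r = 1, rmse = 0),
    data.frame(record_id = "r2", patient_id = "p2", fold = 2,
               lead = c("V1", "V2", "V4", "V5", "V6"), r = 1, rmse = 0))
  pr$r[pr$record_id == "r1" & pr$lead == "V1"] <- 0.8
  rep <- structure(list(pipeline = "p2",
                        output_names = c("V1", "V2", "V4", "V5", "V6"),
                        per_record = pr, n_undefined_r = 0L, k = 2),
                   class = "eval_report")
  s <- summarize_report(rep)
  v1 <- s$r[s$r$lead == "V1", ]
  expect_equal(v1$median, 0.9)
  expect_equal(v1$mean, 0.9)
  expect_equal(v1$sd, 0.1, tolerance = 1e-12)          # population SD
  expect_equal(s$r$sd[s$r$lead == "V2"], 0)
  avg <- s$r[s$r$lead == "Average", ]
  expect_equal(avg$mean, mean(s$r$mean[s$r$lead != "Average"]))
  ssamp <- summarize_report(rep, sd_type = "sample")
  expect_equal(ssamp$r$sd[ssamp$r$lead == "V1"], sd(c(0.8, 1)))

  # permutation invariance in record order
  rep_shuf <- rep
  rep_shuf$per_record <- pr[rev(seq_len(nrow(pr))), ]
  expect_equal(summarize_report(rep_shuf)$r, s$r)
})

test_that("report comparison marks the better pipeline at p < 0.05", {
  co <- perwave_cohort(10, d = 0.3, seed = 53)
  rep_p2 <- run_cv(co, "p2")
  rep_wm <- run_cv(co, "wmlr")
  cmp <- compare_reports(rep_wm, rep_p2)
  expect_setequal(cmp$lead, c("V1", "V2", "V4", "V5", "V6"))
  expect_true(any(cmp$significant & cmp$better == "wmlr"))
  self <- compare_reports(rep_p2, rep_p2)
  expect_true(all(self$t == 0))
  expect_true(all(self$p == 1))
})

test_that("report export writes per-record CSV and summary JSON", {
  co <- global_cohort(5, seed = 51)
  rep <- run_cv(co, "p2")
  dir <- tempfile()
  export_report(rep, dir)
  expect_true(file.exists(file.path(dir, "per_record.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  back <- utils::read.csv(file.path(dir, "per_record.csv"))
  expect_equal(nrow(back), nrow(rep$per_record))
})
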