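#' Pearson correlation coefficient
#'
#' Direct evaluation of
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`.
#' Symmetric in its arguments and invariant to positive affine rescaling.
#' If either vector is constant the correlation is undefined and `NA` is
#' returned (callers count and exclude such cases from aggregates).
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    wmlr_stop("x and y lengths differ", "wmlr_shape_error")
  if (length(x) < 2)
    wmlr_stop("need at least two samples", "wmlr_length_error")
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Root mean squared error
#'
#' `sqrt(mean((y - x)^2))`, in the units of the inputs (mV here).
#'
#' @param x,y Equal-length numeric vectors.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y))
    wmlr_stop("x and y lengths differ", "wmlr_shape_error")
  sqrt(mean((y - x)^2))
}

#' Patient-wise fold assignment
#'
#' Partitions the distinct patients into `k` folds of sizes differing by
#' at most one, deterministically for a given seed. All records of a
#' patient share its fold, so no patient contributes to both the training
#' and test side of any fold.
#'
#' @param patient_ids Character vector (one per record; duplicates allowed).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Named integer vector: fold per distinct patient.
#' @export
make_patient_folds <- function(patient_ids, k = 5, seed = 1) {
  patients <- unique(as.character(patient_ids))
  if (length(patients) < k)
    wmlr_stop(sprintf("need at least k = %d distinct patients, got %d",
                      k, length(patients)), "wmlr_value_error")
  perm <- with_seed(seed, sample(patients))
  folds <- rep(seq_len(k), length.out = length(patients))
  stats::setNames(folds[match(patients, perm)], patients)
}

#' Patient-wise cross-validation of a reconstruction pipeline
#'
#' For each fold: pools every time sample of every out-of-fold record into
#' one training set, fits the pipeline's model, predicts each in-fold
#' record, and scores per record and per lead with [pearson_r()] and
#' [rmse()]. Undefined correlations (constant signals) are recorded as
#' `NA` and counted. Aggregates pool all test records across folds.
#'
#' @param pipeline A [make_pipeline()] object.
#' @param dataset List of entries, each a list with `record` (an
#'   [ecg_record()] carrying `patient_id`) and optionally `fiducials`.
#' @param folds Fold assignment from [make_patient_folds()].
#' @param trace_dir If non-NULL, reconstructed-vs-original CSV traces are
#'   written here for the first `trace_n` test records of each fold.
#' @param trace_n Number of traced records per fold.
#' @return An `eval_report`.
#' @export
cross_validate <- function(pipeline, dataset, folds, trace_dir = NULL,
                           trace_n = 2) {
  pids <- vapply(dataset, function(e) (e$record %||% e)$patient_id,
                 character(1))
  rids <- vapply(dataset, function(e) (e$record %||% e)$record_id,
                 character(1))
  if (!all(pids %in% names(folds)))
    wmlr_stop("dataset contains patients missing from the fold assignment",
              "wmlr_value_error")
  fold_of <- unname(folds[pids])
  k <- max(folds)
  rows <- list()
  n_undefined <- 0L
  if (!is.null(trace_dir)) dir.create(trace_dir, showWarnings = FALSE,
                                      recursive = TRUE)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (!length(test_idx) || !length(train_idx))
      wmlr_stop(sprintf("fold %d is empty", f), "wmlr_value_error")
    stopifnot(!any(pids[train_idx] %in% pids[test_idx]))  # no patient leak
    Xtr <- do.call(rbind, lapply(dataset[train_idx], pipeline$build_input))
    Ytr <- do.call(rbind, lapply(dataset[train_idx], pipeline$build_output))
    model <- pipeline$fit(Xtr, Ytr)
    for (ti in seq_along(test_idx)) {
      i <- test_idx[ti]
      Xte <- pipeline$build_input(dataset[[i]])
      Yte <- pipeline$build_output(dataset[[i]])
      Yhat <- predict(model, Xte)
      for (ld in pipeline$output_names) {
        r <- pearson_r(Yte[, ld], Yhat[, ld])
        if (is.na(r)) n_undefined <- n_undefined + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(record_id = rids[i], patient_id = pids[i], fold = f,
                     lead = ld, r = r, rmse = rmse(Yte[, ld], Yhat[, ld]))
      }
      if (!is.null(trace_dir) && ti <= trace_n) {
        tr <- cbind(Yte, Yhat)
        colnames(tr) <- c(paste0(pipeline$output_names, "_orig"),
                          paste0(pipeline$output_names, "_recon"))
        utils::write.csv(as.data.frame(tr),
                         file.path(trace_dir,
                                   paste0(rids[i], "_", pipeline$variant,
                                          ".csv")),
                         row.names = FALSE)
      }
    }
  }
  per_record <- do.call(rbind, rows)
  report <- structure(list(pipeline = pipeline$variant,
                           output_names = pipeline$output_names,
                           per_record = per_record,
                           n_undefined_r = n_undefined,
                           k = k),
                      class = "eval_report")
  report$aggregates <- aggregate_report(report)
  report
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

agg_stats <- function(v, sd_type) {
  v <- v[!is.na(v)]
  if (!length(v))
    return(data.frame(median = NA_real_, mean = NA_real_, sd = NA_real_,
                      q25 = NA_real_, q75 = NA_real_, min = NA_real_,
                      max = NA_real_, n = 0L))
  data.frame(median = stats::median(v), mean = mean(v),
             sd = if (sd_type == "population") pop_sd(v) else stats::sd(v),
             q25 = stats::quantile(v, 0.25, names = FALSE),
             q75 = stats::quantile(v, 0.75, names = FALSE),
             min = min(v), max = max(v), n = length(v))
}

aggregate_report <- function(report, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  pr <- report$per_record
  out <- list()
  for (metric in c("r", "rmse")) {
    per_lead <- do.call(rbind, lapply(report$output_names, function(ld) {
      cbind(lead = ld, agg_stats(pr[[metric]][pr$lead == ld], sd_type))
    }))
    avg <- per_lead[1, ]
    avg$lead <- "Average"
    for (cc in c("median", "mean", "sd", "q25", "q75", "min", "max"))
      avg[[cc]] <- mean(per_lead[[cc]])
    avg$n <- sum(per_lead$n)
    out[[metric]] <- rbind(per_lead, avg)
  }
  out
}

#' Classical paired t-test
#'
#' Two-sided paired t on the per-record differences, `t =
#' mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom. Zero
#' variance with nonzero differences is flagged and reported as `p = 0`;
#' all-zero differences give `t = 0, p = 1` with a flag.
#'
#' @param errors_a,errors_b Paired per-record values (e.g. RMSEs).
#' @return List with `t`, `df`, `p`, `flag` (`"ok"`, `"degenerate"` or
#'   `"identical"`).
#' @export
paired_ttest <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    wmlr_stop("paired vectors have different lengths", "wmlr_shape_error")
  n <- length(errors_a)
  if (n < 2) wmlr_stop("need at least two pairs", "wmlr_length_error")
  d <- errors_a - errors_b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1,
                                 flag = "identical"))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                flag = "degenerate"))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L,
       p = 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE),
       flag = "ok")
}

#' Summary tables and box-plot data for an evaluation report
#'
#' One row per output lead plus an `Average` row (unweighted mean of the
#' per-lead statistics) for correlation and RMSE, and per-lead box-plot
#' summaries (median, quartiles, min, max). The SD convention defaults to
#' the population SD (divide by n). If `comparisons` are attached (see
#' [compare_reports()]) significance markers at p < 0.05 are included;
#' p-values are reported raw, without multiple-testing correction.
#'
#' @param report An `eval_report` from [cross_validate()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `r`, `rmse` (stat tables), `box` (per-lead box data)
#'   and optionally `comparisons`.
#' @export
summarize_report <- function(report, sd_type = c("population", "sample")) {
  if (is.null(report$per_record) || !nrow(report$per_record))
    wmlr_stop("empty report", "wmlr_value_error")
  agg <- aggregate_report(report, sd_type)
  box <- lapply(c(r = "r", rmse = "rmse"), function(metric) {
    tb <- agg[[metric]]
    tb[tb$lead != "Average", c("lead", "min", "q25", "median", "q75", "max")]
  })
  out <- list(pipeline = report$pipeline,
              r = agg$r[c("lead", "median", "mean", "sd")],
              rmse = agg$rmse[c("lead", "median", "mean", "sd")],
              box = box,
              n_undefined_r = report$n_undefined_r,
              note = "p-values, where attached, are raw (no multiple-testing correction)")
  if (!is.null(report$comparisons)) {
    cmp <- report$comparisons
    cmp$significant <- cmp$p < 0.05
    out$comparisons <- cmp
  }
  out
}

#' Paired comparison of two evaluation reports
#'
#' Per-lead paired t-tests on per-record RMSE values matched by record id
#' (same CV folds). Marks significance at p < 0.05.
#'
#' @param report_a,report_b `eval_report`s over the same records/leads.
#' @return Data.frame: lead, t, df, p, better (pipeline with lower mean
#'   RMSE), significant.
#' @export
compare_reports <- function(report_a, report_b) {
  leads <- intersect(report_a$output_names, report_b$output_names)
  if (!length(leads))
    wmlr_stop("reports share no output leads", "wmlr_alignment_error")
  out <- lapply(leads, function(ld) {
    a <- report_a$per_record[report_a$per_record$lead == ld, ]
    b <- report_b$per_record[report_b$per_record$lead == ld, ]
    common <- intersect(a$record_id, b$record_id)
    if (!length(common))
      wmlr_stop("reports share no record ids", "wmlr_alignment_error")
    av <- a$rmse[match(common, a$record_id)]
    bv <- b$rmse[match(common, b$record_id)]
    tt <- paired_ttest(av, bv)
    data.frame(lead = ld, t = tt$t, df = tt$df, p = tt$p, flag = tt$flag,
               better = if (mean(av) <= mean(bv)) report_a$pipeline
                        else report_b$pipeline,
               significant = tt$p < 0.05)
  })
  do.call(rbind, out)
}

#' Export an evaluation report to disk
#'
#' Writes `per_record.csv` (per-record, per-lead rows), `report.json`
#' (aggregates, counts and any comparisons).
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @export
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_record, file.path(dir, "per_record.csv"),
                   row.names = FALSE)
  summ <- summarize_report(report)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: %d record-lead rows, %d folds, %d undefined r\n",
              x$pipeline, nrow(x$per_record), x$k, x$n_undefined_r))
  invisible(x)
}
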