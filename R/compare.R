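#' Compare retention models across savings curves
#'
#' Fits each model to each curve with [fit_retention()] and assembles the
#' comparison: per-curve parameters, SSD, uncentered R² and AIC, the
#' arithmetic per-model averages across curves, and each model's average
#' AIC relative to the best model. An AIC difference greater than 2 is
#' flagged as a meaningful difference in goodness-of-fit.
#'
#' A fit that fails for one cell is reported as `NA` in that cell rather
#' than aborting the whole table.
#'
#' @param curves a named list of [savings_curve()] objects (a single curve
#'   is accepted).
#' @param models character vector of model names; default is the canonical
#'   seven-model comparison set.
#' @param n_starts,seed passed to [fit_retention()].
#' @return An object of class `retention_comparison`: list with `fits`
#'   (model -> subject -> `retention_fit`), `table` (long data frame),
#'   `averages` (per-model mean SSD/R²/AIC), `delta_aic`, and `best_model`.
#' @examples
#' curves <- load_fixture("table3")
#' cmp <- compare_retention(curves, c("power", "mcm"))
#' cmp$averages
#' @export
compare_retention <- function(curves, models = retention_models()$model,
                              n_starts = 50, seed = 0) {
  if (inherits(curves, "savings_curve")) curves <- list(curves)
  if (is.null(names(curves))) {
    names(curves) <- vapply(curves, attr, "", "subject")
  }
  if (length(curves) < 1) stop("need at least one curve", call. = FALSE)
  models <- as.character(models)

  fits <- lapply(models, function(m) {
    lapply(curves, function(cu) {
      tryCatch(fit_retention(cu, m, n_starts = n_starts, seed = seed),
               error = function(e) {
                 warning(sprintf("fit of '%s' to '%s' failed: %s",
                                 m, attr(cu, "subject"), conditionMessage(e)),
                         call. = FALSE)
                 NULL
               })
    })
  })
  names(fits) <- models

  rows <- list()
  for (m in models) {
    for (s in names(curves)) {
      f <- fits[[m]][[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, subject = s,
        params = if (is.null(f)) NA_character_ else
          paste(sprintf("%s=%.6g", names(f$par), f$par), collapse = ";"),
        ssd = if (is.null(f)) NA_real_ else f$ssd,
        r2 = if (is.null(f)) NA_real_ else f$r2,
        aic = if (is.null(f)) NA_real_ else f$aic
      )
    }
  }
  table <- do.call(rbind, rows)

  averages <- do.call(rbind, lapply(models, function(m) {
    sub <- table[table$model == m, ]
    data.frame(model = m,
               ssd = mean(sub$ssd), r2 = mean(sub$r2), aic = mean(sub$aic))
  }))
  best <- averages$model[which.min(averages$aic)]
  averages$delta_aic <- averages$aic - min(averages$aic, na.rm = TRUE)
  averages$meaningful <- averages$delta_aic > 2

  structure(list(fits = fits, table = table, averages = averages,
                 best_model = best, n_starts = n_starts, seed = seed),
            class = "retention_comparison")
}

#' @export
print.retention_comparison <- function(x, ...) {
  subjects <- unique(x$table$subject)
  cat(sprintf("Retention model comparison: %d model(s) x %d curve(s)\n\n",
              length(x$fits), length(subjects)))
  for (m in names(x$fits)) {
    cat(sprintf("-- %s --\n", m))
    block <- list()
    pnames <- .model_spec(m)$params
    for (s in subjects) {
      f <- x$fits[[m]][[s]]
      if (is.null(f)) next
      block[[s]] <- c(format(signif(f$par, 3)),
                      format(signif(f$ssd, 3)), format(signif(f$r2, 3)),
                      format(round(f$aic, 1)))
    }
    if (length(block)) {
      mat <- do.call(cbind, block)
      rownames(mat) <- c(pnames, "SSD", "R2", "AIC")
      avg <- x$averages[x$averages$model == m, ]
      mat <- cbind(mat, Average = c(rep("", length(pnames)),
                                    format(signif(avg$ssd, 3)),
                                    format(signif(avg$r2, 3)),
                                    format(round(avg$aic, 1))))
      print(mat, quote = FALSE, right = TRUE)
    }
    cat("\n")
  }
  cat(sprintf("best average AIC: %s\n", x$best_model))
  flagged <- x$averages$model[x$averages$meaningful]
  if (length(flagged)) {
    cat("meaningfully worse (delta AIC > 2):",
        paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a model-comparison table to disk
#'
#' `format = "tsv"` writes the long comparison table (one row per model x
#' subject, plus per-model average rows). `format = "json"` writes a nested
#' object model -> subject -> \{params, ssd, r2, aic\} at full precision
#' (requires the jsonlite package).
#'
#' @param x a `retention_comparison` from [compare_retention()].
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_comparison <- function(x, file, format = c("tsv", "json")) {
  stopifnot(inherits(x, "retention_comparison"))
  format <- match.arg(format)
  if (format == "tsv") {
    avg <- x$averages
    avg_rows <- data.frame(model = avg$model, subject = "Average",
                           params = NA_character_, ssd = avg$ssd,
                           r2 = avg$r2, aic = avg$aic)
    utils::write.table(rbind(x$table, avg_rows), file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON output", call. = FALSE)
    }
    obj <- lapply(x$fits, function(by_subj) {
      lapply(Filter(Negate(is.null), by_subj), function(f) {
        list(params = as.list(f$par), ssd = f$ssd, r2 = f$r2, aic = f$aic)
      })
    })
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
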