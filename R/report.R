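#' Full diagnostic-accuracy evaluation of the perfusion parameters
#'
#' For each quantitative parameter (by default MPR, TPR and endocardial
#' attenuation, all oriented lower-is-abnormal) against the segment-level
#' reference labels: empirical ROC/AUC with a DeLong confidence interval,
#' the Youden cutoff, the confusion matrix at that cutoff, Wilson intervals
#' on sensitivity/specificity/PPV/NPV, and a Mann-Whitney comparison of
#' normal vs abnormal segments. All pairwise DeLong tests between the
#' parameters are included. When matching `<parameter>_obs` second-reader
#' columns are present, inter-observer ICC(2,1) values are reported too.
#'
#' @param data Per-segment tibble.
#' @param parameters Named character vector mapping display names to column
#'   names.
#' @param label Column holding the binary reference (TRUE = abnormal).
#' @param level Confidence level.
#' @return A `ctp_report`; see [tidy.ctp_report()], [glance.ctp_report()]
#'   and [autoplot.ctp_report()].
#' @export
diagnostic_report <- function(data,
                              parameters = c(mpr = "mpr", tpr = "tpr",
                                             attenuation = "endo_hu"),
                              label = "abnormal", level = 0.95) {
  labels <- check_two_classes(data[[label]])
  params <- lapply(names(parameters), function(nm) {
    col <- parameters[[nm]]
    sc <- data[[col]]
    roc <- empirical_auc(sc, labels, direction = "lower_is_abnormal",
                         level = level)
    calls <- classify_segment(sc, roc$youden$cutoff)
    cm <- tibble(tp = sum(calls & labels), fp = sum(calls & !labels),
                 fn = sum(!calls & labels), tn = sum(!calls & !labels))
    metrics <- confusion_metrics(cm, level = level)
    mwu <- mann_whitney_u(sc[labels], sc[!labels])
    obs_col <- paste0(col, "_obs")
    icc <- if (obs_col %in% names(data)) {
      icc_absolute_agreement(cbind(sc, data[[obs_col]]), level = level)
    } else NULL
    list(name = nm, column = col, roc = roc, cutoff = roc$youden$cutoff,
         confusion = cm, metrics = metrics, mann_whitney = mwu, icc = icc)
  })
  names(params) <- names(parameters)
  pairs <- utils::combn(names(parameters), 2, simplify = FALSE)
  delong <- bind_rows(lapply(pairs, function(pr) {
    dl <- delong_paired_test(data[[parameters[[pr[1]]]]],
                             data[[parameters[[pr[2]]]]], labels)
    mutate(dl, parameter_a = pr[1], parameter_b = pr[2], .before = 1)
  }))
  structure(list(parameters = params, delong = delong, level = level,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 clustering_correction = "none (per-segment analysis)"),
            class = "ctp_report")
}

#' Tidy, summarise and plot a diagnostic report
#'
#' `tidy()` returns one row per parameter in the layout of a diagnostic
#' accuracy table: sensitivity/specificity/PPV/NPV percentages with their
#' Wilson 95 percent intervals, plus AUC and cutoff. `glance()` gives the
#' AUC comparison (one row per parameter pair, DeLong p-values).
#' `autoplot()` overlays the ROC curves.
#'
#' @param x,object A `ctp_report`.
#' @param ... Ignored.
#' @export
tidy.ctp_report <- function(x, ...) {
  bind_rows(lapply(x$parameters, function(p) {
    m <- p$metrics
    row <- tibble(parameter = p$name, cutoff = p$cutoff,
                  auc = p$roc$auc,
                  auc_low = p$roc$auc_ci[1], auc_high = p$roc$auc_ci[2])
    for (i in seq_len(nrow(m))) {
      nm <- m$metric[i]
      row[[paste0(nm, "_pct")]] <- 100 * m$estimate[i]
      row[[paste0(nm, "_low")]] <- 100 * m$lower[i]
      row[[paste0(nm, "_high")]] <- 100 * m$upper[i]
    }
    row
  }))
}

#' @rdname tidy.ctp_report
#' @export
glance.ctp_report <- function(x, ...) x$delong

#' @rdname tidy.ctp_report
#' @export
autoplot.ctp_report <- function(object, ...) {
  curves <- bind_rows(lapply(object$parameters, function(p) {
    mutate(p$roc$curve, parameter = p$name)
  }))
  labs <- vapply(object$parameters, function(p)
    sprintf("%s (AUC %.2f)", p$name, p$roc$auc), character(1))
  curves$parameter <- factor(curves$parameter, levels = names(labs),
                             labels = labs)
  ggplot2::ggplot(curves, ggplot2::aes(1 - .data$specificity,
                                       .data$sensitivity,
                                       colour = .data$parameter)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.ctp_report <- function(x, ...) {
  cat(sprintf("<ctp_report> %d abnormal / %d normal segments\n",
              x$n_pos, x$n_neg))
  for (p in x$parameters)
    cat(sprintf("  %-12s AUC %.3f (%.3f-%.3f), cutoff %.4g, sens %.0f%%, spec %.0f%%\n",
                p$name, p$roc$auc, p$roc$auc_ci[1], p$roc$auc_ci[2],
                p$cutoff, 100 * p$metrics$estimate[1],
                100 * p$metrics$estimate[2]))
  invisible(x)
}

# serialisable list view of a report (for the JSON artifact)
report_to_list <- function(report) {
  list(
    n_pos = report$n_pos, n_neg = report$n_neg, level = report$level,
    clustering_correction = report$clustering_correction,
    parameters = lapply(report$parameters, function(p) {
      list(name = p$name, column = p$column,
           auc = p$roc$auc, auc_ci = p$roc$auc_ci,
           cutoff = p$cutoff, youden_j = p$roc$youden$j,
           confusion = as.list(p$confusion),
           metrics = as.data.frame(p$metrics),
           mann_whitney = as.data.frame(p$mann_whitney),
           icc = if (!is.null(p$icc)) as.data.frame(p$icc))
    }),
    delong = as.data.frame(report$delong)
  )
}
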