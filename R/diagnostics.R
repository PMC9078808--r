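#' Staging contingency table
#'
#' A per-stage detection table against the pathological gold standard: for
#' each tumor stage (e.g. T1, T2-T3, T4, N0..N3, M0, M1) the number of cases
#' the pathology assigned to that stage (`gold_n`) and how many of those an
#' imaging modality also assigned to it (`detected_n`).
#'
#' `generate_contingency_fixture()` builds such a table from a named list
#' mapping each stage to `c(gold_n, detected_n)`. The `seed` argument is
#' accepted for interface symmetry with the other generators but unused: the
#' table is a deterministic function of the requested counts.
#'
#' @param stage_counts named list: `stage -> c(gold_n, detected_n)`.
#' @param modality label for the detecting modality.
#' @param seed ignored (nothing is drawn).
#' @return data.frame of class `contingency_table` with columns
#'   `stage, modality, gold_n, detected_n`.
#' @export
generate_contingency_fixture <- function(stage_counts, modality = "CEUS",
                                         seed = NULL) {
  if (length(stage_counts) == 0) stop("need at least one stage")
  gold <- vapply(stage_counts, function(x) x[1], numeric(1))
  det <- vapply(stage_counts, function(x) x[2], numeric(1))
  if (any(gold < 0) || any(det < 0)) stop("negative counts rejected")
  if (any(det > gold)) stop("detected_n must not exceed gold_n")
  if (any(gold != round(gold)) || any(det != round(det)))
    stop("counts must be integral")
  structure(data.frame(stage = names(stage_counts), modality = modality,
                       gold_n = as.integer(gold), detected_n = as.integer(det),
                       stringsAsFactors = FALSE),
            class = c("contingency_table", "data.frame"))
}

#' Resectability 2x2 table
#'
#' @param tp,fn,tn,fp nonnegative integer counts: resectable cases judged
#'   resectable (TP) or not (FN), unresectable cases judged unresectable (TN)
#'   or not (FP).
#' @param modality label.
#' @return data.frame of class `resectability_table`.
#' @export
resectability_table <- function(tp, fn, tn, fp, modality = "CEUS") {
  v <- c(tp, fn, tn, fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  structure(data.frame(modality = modality, tp = as.integer(tp),
                       fn = as.integer(fn), tn = as.integer(tn),
                       fp = as.integer(fp)),
            class = c("resectability_table", "data.frame"))
}

#' Predicted positive rate
#'
#' The percentage of gold-standard cases of a stage that the modality also
#' assigned to that stage: `100 * detected_n / gold_n`, reported at two
#' decimals. Vectorized over stages.
#'
#' @param gold_n gold-standard case count (>= 1).
#' @param detected_n cases detected at that stage (`<= gold_n`).
#' @return percentage(s) in `[0, 100]`.
#' @export
positive_rate <- function(gold_n, detected_n) {
  if (any(gold_n < 1)) stop("gold_n must be at least 1")
  if (any(detected_n < 0)) stop("negative counts rejected")
  if (any(detected_n > gold_n))
    stop("detected_n exceeds gold_n: detection is among pathologically staged cases")
  round(100 * detected_n / gold_n, 2)
}

#' Sensitivity, specificity and accuracy of a 2x2 table
#'
#' Standard binary diagnostic performance against a gold standard:
#' sensitivity `= 100 tp / (tp + fn)`, specificity `= 100 tn / (tn + fp)`,
#' accuracy `= 100 (tp + tn) / n`, each reported at two decimals.
#'
#' @param tp,fn,tn,fp nonnegative integer counts; each class (tp+fn, tn+fp)
#'   must be nonempty.
#' @return named numeric `c(sensitivity, specificity, accuracy)` in percent.
#' @export
binary_performance <- function(tp, fn, tn, fp) {
  v <- c(tp, fn, tn, fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  if (tp + fn < 1 || tn + fp < 1) stop("both classes must be nonempty")
  c(sensitivity = round(100 * tp / (tp + fn), 2),
    specificity = round(100 * tn / (tn + fp), 2),
    accuracy = round(100 * (tp + tn) / sum(v), 2))
}

#' Compare two modalities' per-stage detection
#'
#' For each stage, tests whether the two modalities' detection proportions
#' (detected vs not detected among the gold-standard cases) differ, using the
#' Pearson chi-squared test with continuity correction on the 2x2 table; when
#' any expected cell count falls below 5 (including zero margins) Fisher's
#' exact test is used instead and flagged in the `method` column.
#'
#' @param table_a,table_b `contingency_table`s with identical stages and
#'   `gold_n`.
#' @return data.frame: `stage, chi2, p, method` (`chi2` is `NA` for exact-test
#'   rows).
#' @export
compare_modalities <- function(table_a, table_b) {
  a <- as.data.frame(table_a); b <- as.data.frame(table_b)
  if (!identical(a$stage, b$stage)) stop("stage labels must match")
  if (!identical(a$gold_n, b$gold_n)) stop("gold_n must match between modalities")
  out <- data.frame(stage = a$stage, chi2 = NA_real_, p = NA_real_,
                    method = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(a))) {
    m <- matrix(c(a$detected_n[i], a$gold_n[i] - a$detected_n[i],
                  b$detected_n[i], b$gold_n[i] - b$detected_n[i]),
                2, 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      out$p[i] <- stats::fisher.test(m)$p.value
      out$method[i] <- "fisher_exact"
    } else {
      ct <- stats::chisq.test(m, correct = TRUE)
      out$chi2[i] <- unname(ct$statistic)
      out$p[i] <- ct$p.value
      out$method[i] <- "chisq_cc"
    }
  }
  out
}

#' Full diagnostic summary
#'
#' Computes, from a staging table (both modalities) and resectability tables,
#' everything the diagnostics layer reports: per-stage predicted positive
#' rates per modality, per-stage modality comparisons, and per-modality
#' resectability performance.
#'
#' @param staging a `contingency_table` (rows for both modalities allowed;
#'   split on the `modality` column).
#' @param resect a `resectability_table` with one row per modality.
#' @return object of class `diagnostic_summary`.
#' @export
diagnostic_summary <- function(staging, resect = NULL) {
  staging <- as.data.frame(staging)
  staging$ppr <- positive_rate(staging$gold_n, staging$detected_n)
  mods <- unique(staging$modality)
  comparison <- NULL
  if (length(mods) == 2) {
    comparison <- compare_modalities(staging[staging$modality == mods[1], ],
                                     staging[staging$modality == mods[2], ])
  }
  perf <- NULL
  if (!is.null(resect)) {
    resect <- as.data.frame(resect)
    perf <- do.call(rbind, lapply(seq_len(nrow(resect)), function(i) {
      data.frame(modality = resect$modality[i],
                 t(binary_performance(resect$tp[i], resect$fn[i],
                                      resect$tn[i], resect$fp[i])))
    }))
  }
  structure(list(ppr = staging, comparison = comparison, performance = perf),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat("Predicted positive rate by stage (%):\n")
  print.data.frame(x$ppr, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\nBetween-modality comparison:\n")
    print.data.frame(x$comparison, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$performance)) {
    cat("\nResectability performance (%):\n")
    print.data.frame(x$performance, row.names = FALSE)
  }
  invisible(x)
}

#' Read diagnostic count CSVs
#'
#' Two layouts are accepted: staging tables with header
#' `stage,modality,gold_n,detected_n`, and resectability tables with header
#' `modality,tp,fn,tn,fp`.
#'
#' @param path CSV path.
#' @return a `contingency_table` or `resectability_table`.
#' @export
read_counts_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("stage", "modality", "gold_n", "detected_n") %in% names(x))) {
    class(x) <- c("contingency_table", "data.frame")
  } else if (all(c("modality", "tp", "fn", "tn", "fp") %in% names(x))) {
    class(x) <- c("resectability_table", "data.frame")
  } else stop("unrecognized counts layout in ", path)
  x
}

#' Clinical staging and resectability tables of the gastric-cancer cohort
#'
#' Convenience loaders for the tables shipped in `inst/extdata`: per-stage
#' T/N/M detection counts for CEUS and contrast-enhanced CT against the
#' pathological gold standard (102 patients), and the resectability 2x2
#' tables (91 resectable, 11 unresectable).
#'
#' @return `ceus_staging_counts()`: a `contingency_table`;
#'   `ceus_resectability_counts()`: a `resectability_table`.
#' @export
ceus_staging_counts <- function() {
  read_counts_csv(system.file("extdata", "staging_counts.csv",
                              package = "ceustrack", mustWork = TRUE))
}

#' @rdname ceus_staging_counts
#' @export
ceus_resectability_counts <- function() {
  read_counts_csv(system.file("extdata", "resectability_counts.csv",
                              package = "ceustrack", mustWork = TRUE))
}
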