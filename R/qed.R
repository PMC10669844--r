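#' Descriptor names entering the QED score
#'
#' Molecular weight, computed logP, hydrogen-bond acceptors and donors,
#' topological polar surface area, rotatable bonds, aromatic rings and
#' structural alerts.
#' @export
QED_DESCRIPTORS <- c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM",
                     "ALERTS")

#' Asymmetric-double-sigmoid desirability parameters
#'
#' The published per-descriptor constants `(a, b, c, d, e, f, dmax)` of the
#' QED desirability functions, shipped as a data file so they are auditable
#' and swappable.
#'
#' @return Data frame with one row per descriptor (rownames = descriptor).
#' @export
qed_params <- function() {
  path <- system.file("extdata", "qed_ads_params.tsv", package = "phytoscreen")
  p <- utils::read.delim(path)
  rownames(p) <- p$descriptor
  p
}

#' Asymmetric-double-sigmoid desirability
#'
#' Maps a raw descriptor value onto (0, 1] via the asymmetric double sigmoid
#' `d(x) = [a + b/(1 + exp(-(x - c + d/2)/e)) * (1 - 1/(1 + exp(-(x - c -
#' d/2)/f)))] / dmax`, clamped to `[1e-6, 1]`.  The clamp floor keeps the
#' geometric mean defined for extreme descriptor values.
#'
#' @param x Numeric vector of descriptor values.
#' @param params One row of [qed_params()] (or any list with elements
#'   `a, b, c, d, e, f, dmax`).
#' @return Numeric vector of desirabilities in `[1e-6, 1]`.
#' @export
ads_desirability <- function(x, params) {
  p <- as.list(params)
  if (p$e <= 0 || p$f <= 0) stop("sigmoid widths e and f must be positive")
  raw <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  pmin(pmax(raw / p$dmax, 1e-6), 1)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Unweighted QED: the geometric mean `exp(mean(log d_i))` of the descriptor
#' desirabilities.  The canonical form uses all eight descriptors;
#' `use_alerts = FALSE` drops the structural-alert term and averages the
#' remaining seven (for compatibility with tools that ignore alerts).
#'
#' @param descriptors Named numeric vector (or one-row data frame) with
#'   entries for [QED_DESCRIPTORS].
#' @param params Parameter table from [qed_params()].
#' @param use_alerts Include the `ALERTS` desirability (default `TRUE`).
#' @return List with `desirabilities` (named vector) and `qed` (scalar in
#'   `(0, 1]`).
#' @export
qed <- function(descriptors, params = qed_params(), use_alerts = TRUE) {
  if (is.data.frame(descriptors)) {
    stopifnot(nrow(descriptors) == 1)
    descriptors <- unlist(descriptors[1, intersect(QED_DESCRIPTORS,
                                                   names(descriptors))])
  }
  wanted <- if (use_alerts) QED_DESCRIPTORS else setdiff(QED_DESCRIPTORS,
                                                         "ALERTS")
  missing <- wanted[!(wanted %in% names(descriptors)) |
                      is.na(descriptors[wanted])]
  if (length(missing) > 0) {
    stop("missing descriptor(s) for QED: ", paste(missing, collapse = ", "))
  }
  d <- vapply(wanted, function(k) {
    ads_desirability(as.numeric(descriptors[[k]]), params[k, ])
  }, numeric(1))
  list(desirabilities = d, qed = exp(mean(log(d))))
}

#' Score a compound table with QED
#'
#' @param compounds Compound tibble (see [read_compound_table()]).
#' @inheritParams qed
#' @return The input with a `qed` column appended.
#' @export
score_qed <- function(compounds, params = qed_params(), use_alerts = TRUE) {
  wanted <- if (use_alerts) QED_DESCRIPTORS else setdiff(QED_DESCRIPTORS,
                                                         "ALERTS")
  d_mat <- vapply(wanted, function(k) {
    ads_desirability(compounds[[k]], params[k, ])
  }, numeric(nrow(compounds)))
  d_mat <- matrix(d_mat, nrow = nrow(compounds))
  compounds$qed <- exp(rowMeans(log(d_mat)))
  compounds
}

#' Drug-likeness gate
#'
#' Splits compounds at a strict QED threshold: a compound passes only with
#' `qed > threshold` (a score exactly at the threshold fails).
#'
#' @param compounds Compound tibble carrying a `qed` column (see
#'   [score_qed()]).
#' @param threshold QED cut-off, default 0.5.
#' @return List with tibbles `passed` and `failed`;
#'   `nrow(passed) + nrow(failed)` equals the input row count.
#' @export
qed_gate <- function(compounds, threshold = 0.5) {
  if (!("qed" %in% names(compounds))) {
    stop("compounds must be scored with score_qed() first")
  }
  keep <- compounds$qed > threshold
  list(passed = compounds[keep, ], failed = compounds[!keep, ])
}
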