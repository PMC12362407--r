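# Semi-empirical linkage between MD occupancy changes and measured HDX
# protection: per-peptide predictions from the donor map, totals, agreement
# statistics, and the crystal-structure H-bond census.

#' Predicted protection change for one peptide
#'
#' Backbone amides that gain H-bond occupancy upon binding are predicted to
#' gain exchange protection one-for-one, so the peptide-level prediction is
#' the sum of donor occupancy differentials over the peptide span.
#'
#' @param donor_map Named vector from [donor_residue_map()] (residue index ->
#'   delta occupancy).
#' @param peptide A [peptide_record()] (or any list with `start`, `end`).
#' @return Predicted delta protons for the peptide.
#' @export
predict_peptide_delta <- function(donor_map, peptide) {
  res <- as.character(peptide$start:peptide$end)
  sum(donor_map[intersect(res, names(donor_map))])
}

#' Predicted total protection gain
#'
#' Sums the positive donor occupancy differentials (protection gains); losses
#' are totalled separately. Also counts donors whose absolute differential
#' reaches the significance cutoff, the MD-side analogue of the number of
#' H-bonds with substantial protection shifts.
#'
#' @param donor_map Named vector from [donor_residue_map()].
#' @param delta_sig Significance cutoff on `|delta|`.
#' @return List with `total_gain`, `total_loss` (<= 0), `significant_count`.
#' @export
predict_total_protection <- function(donor_map, delta_sig = 0.20) {
  v <- as.numeric(donor_map)
  list(
    total_gain = sum(v[v > 0]),
    total_loss = sum(v[v < 0]),
    significant_count = sum(abs(v) >= delta_sig)
  )
}

#' Convert observed peptide delta %D to delta deuterons
#'
#' `delta_deuterons = delta_percent * n_ex * f_d2o / 100`, putting the
#' observed axis in absolute proton counts for comparison with MD
#' predictions.
#'
#' @param x An `hdx_diff_matrix`.
#' @param time Exchange time, s.
#' @param f_d2o D2O fraction.
#' @return Numeric vector of observed delta deuterons, one per matrix row.
#' @export
observed_peptide_deuterons <- function(x, time = 20, f_d2o = 0.8) {
  j <- match(time, x$times)
  if (is.na(j)) stop(sprintf("time %g s not on the matrix grid", time),
                     call. = FALSE)
  x$delta[, j] * x$peptides$n_ex * f_d2o / 100
}

#' Agreement between observed and predicted protection changes
#'
#' Reports the per-peptide table, the Spearman rank correlation between
#' observed and predicted values, and the fraction of peptides whose signs
#' agree. With fewer than 3 peptides the correlation is omitted (status
#' `"warning"`) but the table is still produced.
#'
#' @param observed Numeric vector of observed delta deuterons per peptide.
#' @param predicted Numeric vector of predicted delta protons (same order).
#' @param labels Optional peptide labels.
#' @return Object of class `hdx_linkage_report`: list with `table`,
#'   `spearman`, `concordance`, `status`.
#' @export
agreement_report <- function(observed, predicted, labels = NULL) {
  stopifnot(length(observed) == length(predicted))
  if (is.null(labels)) labels <- sprintf("peptide_%d", seq_along(observed))
  tab <- data.frame(
    peptide = labels, observed = observed, predicted = predicted,
    stringsAsFactors = FALSE
  )
  if (length(observed) < 3L) {
    warning("fewer than 3 peptides: rank correlation omitted")
    rho <- NA_real_
    status <- "warning"
  } else {
    rho <- stats::cor(observed, predicted, method = "spearman")
    status <- "ok"
  }
  conc <- mean(sign(observed) == sign(predicted))
  structure(
    list(table = tab, spearman = rho, concordance = conc, status = status),
    class = "hdx_linkage_report"
  )
}

#' @export
print.hdx_linkage_report <- function(x, ...) {
  cat(sprintf(
    "<hdx_linkage_report> %d peptides, Spearman rho = %s, sign concordance = %.2f\n",
    nrow(x$table),
    if (is.na(x$spearman)) "NA" else sprintf("%.3f", x$spearman),
    x$concordance
  ))
  invisible(x)
}

#' Full linkage report from a donor map and a differential matrix
#'
#' @param donor_map Named vector from [donor_residue_map()].
#' @param diff_matrix An `hdx_diff_matrix`.
#' @param time Comparison time, s (20 s is the standard headline point).
#' @param f_d2o D2O fraction used for the observed conversion.
#' @param delta_sig Significance cutoff for the total-protection count.
#' @return An `hdx_linkage_report` with an added `totals` element from
#'   [predict_total_protection()] and per-peptide spans in the table.
#' @export
linkage_report <- function(donor_map, diff_matrix, time = 20, f_d2o = 0.8,
                           delta_sig = 0.20) {
  obs <- observed_peptide_deuterons(diff_matrix, time, f_d2o)
  peps <- diff_matrix$peptides
  pred <- vapply(seq_len(nrow(peps)), function(i) {
    predict_peptide_delta(donor_map, peps[i, ])
  }, numeric(1))
  labels <- sprintf("%s/%d-%d", peps$sequence, peps$start, peps$end)
  rep <- agreement_report(obs, pred, labels)
  rep$table$start <- peps$start
  rep$table$end <- peps$end
  rep$totals <- predict_total_protection(donor_map, delta_sig)
  rep
}

#' Backbone H-bond census of a single structure
#'
#' Counts, on one conformation (e.g. a crystal structure), how many backbone
#' amide donors are hydrogen-bonded to at least one backbone carbonyl under
#' the detection criterion, out of the total donor inventory. Missing amide
#' hydrogens are placed geometrically first.
#'
#' @param s An `hdx_structure`.
#' @param params An `hdx_params`.
#' @return List with `bonded_amides`, `total_amides`, `fraction`.
#' @export
count_structure_hbonds <- function(s, params = analysis_parameters()) {
  src <- s
  topo <- tryCatch(
    build_topology(src),
    error = function(e) {
      if (grepl("missing amide hydrogen", conditionMessage(e))) {
        src <<- place_amide_hydrogens(s)
        build_topology(src)
      } else {
        stop(e)
      }
    }
  )
  frame <- as.matrix(src$atoms[, c("x", "y", "z")])
  det <- detect_frame_hbonds(frame, topo, params)
  total <- nrow(topo$donors)
  bonded <- length(unique(paste(det$donor_chain, det$donor_res)))
  list(bonded_amides = bonded, total_amides = total,
       fraction = if (total > 0L) bonded / total else NA_real_)
}
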