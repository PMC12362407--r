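# Bottom-up (peptide-level) HDX: exchangeable-amide counting, percent
# deuteration, in-exchange/back-exchange correction, the free-vs-bound
# differential protection matrix and residue-level consensus mapping.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Count exchangeable backbone amides of a peptide
#'
#' The N-terminal residue of a peptide back-exchanges too fast to retain
#' label and prolines have no amide N-H, so
#' `n_ex = length - 1 - (prolines at positions >= 2)`.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer count (>= 0).
#' @export
count_exchangeable_amides <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (length(aa) < 1L || !all(aa %in% .AA1)) {
    stop("invalid one-letter amino-acid sequence: ", sequence, call. = FALSE)
  }
  if (length(aa) == 1L) return(0L)
  length(aa) - 1L - sum(aa[-1L] == "P")
}

#' Construct a peptide record
#'
#' @param sequence One-letter sequence.
#' @param start,end 1-based inclusive residue span in the parent protein;
#'   `end - start + 1` must equal the sequence length.
#' @return Object of class `peptide_record`: list with `sequence`, `start`,
#'   `end`, `n_ex`.
#' @export
peptide_record <- function(sequence, start, end) {
  if (end - start + 1L != nchar(sequence)) {
    stop(sprintf("span %d-%d does not match sequence length %d",
                 start, end, nchar(sequence)), call. = FALSE)
  }
  structure(
    list(sequence = toupper(sequence), start = as.integer(start),
         end = as.integer(end), n_ex = count_exchangeable_amides(sequence)),
    class = "peptide_record"
  )
}

#' Percent deuteration of a peptide
#'
#' `%D = 100 * delta_mass / (n_ex * f_d2o)`.
#'
#' @param delta_mass Deuteration mass shift, Da.
#' @param n_ex Exchangeable amide count (>= 1).
#' @param f_d2o D2O fraction.
#' @return Percent deuteration.
#' @export
peptide_percent_deuteration <- function(delta_mass, n_ex, f_d2o) {
  if (any(n_ex < 1)) {
    stop("percent deuteration undefined for peptides with no exchangeable amides",
         call. = FALSE)
  }
  100 * delta_mass / (n_ex * f_d2o)
}

#' Read a peptide-level centroid-mass table
#'
#' CSV with columns `sequence`, `start`, `end`, `state`, `time_s`,
#' `centroid_da` (and optionally `replicate`).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "start", "end", "state", "time_s", "centroid_da")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("peptide table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' In-exchange (and optional back-exchange) correction of peptide uptake
#'
#' For every peptide/state (and replicate) curve the 0 s centroid is the
#' in-exchange control: `delta_da = centroid(t) - centroid(0 s)`. Raw percent
#' deuteration is computed from `delta_da`; the corrected value optionally
#' divides by `1 - back_exchange`.
#'
#' @param df Peptide table (see [read_peptide_table()]).
#' @param cond An [exchange_conditions()].
#' @param apply_backexchange Apply the back-exchange correction to
#'   `percent_d_corr`?
#' @return The table with `n_ex`, `delta_da`, `percent_d` (raw) and
#'   `percent_d_corr` columns added.
#' @export
correct_uptake <- function(df, cond = exchange_conditions(),
                           apply_backexchange = FALSE) {
  if (is.null(df$replicate)) df$replicate <- 1L
  df$n_ex <- vapply(df$sequence, count_exchangeable_amides, integer(1),
                    USE.NAMES = FALSE)
  key <- paste(df$sequence, df$start, df$state, df$replicate)
  df$delta_da <- NA_real_
  for (k in unique(key)) {
    sel <- key == k
    zero <- which(sel & df$time_s == 0)
    if (length(zero) == 0L) {
      stop("missing 0 s time point (in-exchange control) for peptide curve: ", k,
           call. = FALSE)
    }
    df$delta_da[sel] <- df$centroid_da[sel] - df$centroid_da[zero[1L]]
  }
  df$percent_d <- peptide_percent_deuteration(df$delta_da, df$n_ex, cond$f_d2o)
  df$percent_d_corr <- if (apply_backexchange) {
    df$percent_d / (1 - cond$back_exchange)
  } else {
    df$percent_d
  }
  df
}

#' Differential (free - bound) peptide deuteration matrix
#'
#' Builds the peptide x time matrix of protection differences
#' `delta %D = %D(free) - %D(bound)` from corrected uptake curves, with rows
#' ordered by span start then length. Replicated measurements are averaged
#' per state/time first. The palette maximum is the largest positive
#' (protection) cell, so the blue-white-red display saturates red at the
#' maximum observed protection. Peptides present in only one state are
#' reported in `missing` rather than silently dropped.
#'
#' @param corrected Output of [correct_uptake()] containing both states.
#' @return Object of class `hdx_diff_matrix`: list with `delta` (matrix,
#'   peptides x times), `peptides` (data frame `sequence`, `start`, `end`,
#'   `n_ex`), `times`, `palette_max`, `missing` (character vector of peptide
#'   labels lacking one state).
#' @export
differential_matrix <- function(corrected) {
  pep_key <- paste0(corrected$sequence, "/", corrected$start, "-", corrected$end)
  agg <- stats::aggregate(
    corrected["percent_d_corr"],
    by = list(pep = pep_key, sequence = corrected$sequence,
              start = corrected$start, end = corrected$end,
              state = corrected$state, time_s = corrected$time_s),
    FUN = mean
  )
  peps <- unique(agg[, c("pep", "sequence", "start", "end")])
  peps$len <- peps$end - peps$start + 1L
  peps <- peps[order(peps$start, peps$len), , drop = FALSE]
  times <- sort(unique(agg$time_s))
  both <- vapply(peps$pep, function(p) {
    all(c("free", "bound") %in% agg$state[agg$pep == p])
  }, logical(1))
  missing <- peps$pep[!both]
  keep <- peps[both, , drop = FALSE]
  delta <- matrix(NA_real_, nrow(keep), length(times),
                  dimnames = list(keep$pep, paste0("t", times)))
  for (i in seq_len(nrow(keep))) {
    for (j in seq_along(times)) {
      fr <- agg$percent_d_corr[agg$pep == keep$pep[i] & agg$state == "free" &
                                 agg$time_s == times[j]]
      bo <- agg$percent_d_corr[agg$pep == keep$pep[i] & agg$state == "bound" &
                                 agg$time_s == times[j]]
      if (length(fr) == 1L && length(bo) == 1L) delta[i, j] <- fr - bo
    }
  }
  pos <- delta[!is.na(delta) & delta > 0]
  peptides <- keep[, c("sequence", "start", "end")]
  peptides$n_ex <- vapply(peptides$sequence, count_exchangeable_amides,
                          integer(1), USE.NAMES = FALSE)
  rownames(peptides) <- NULL
  structure(
    list(delta = delta, peptides = peptides, times = times,
         palette_max = if (length(pos) > 0L) max(pos) else 0,
         missing = missing),
    class = "hdx_diff_matrix"
  )
}

#' @export
print.hdx_diff_matrix <- function(x, ...) {
  cat(sprintf(
    "<hdx_diff_matrix> %d peptides x %d time points, palette max %.2f%%\n",
    nrow(x$delta), length(x$times), x$palette_max
  ))
  if (length(x$missing) > 0L) {
    cat("  missing one state:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Blue-white-red palette values for a differential matrix
#'
#' Symmetric about zero with red saturating at `palette_max` (the maximum
#' observed protection), the conventional display for differential HDX.
#'
#' @param x An `hdx_diff_matrix`.
#' @param n Number of colour levels.
#' @return List with `breaks` and `colors` suitable for [image()].
#' @export
uptake_palette <- function(x, n = 64) {
  m <- max(x$palette_max, 1e-9)
  list(
    breaks = seq(-m, m, length.out = n + 1L),
    colors = grDevices::colorRampPalette(c("blue", "white", "red"))(n)
  )
}

#' Residue-level consensus protection map
#'
#' Each residue covered by at least one peptide receives the differential of
#' the *shortest* covering peptide (highest spatial resolution); ties are
#' broken toward the peptide with the smaller start. Uncovered residues are
#' absent from the map.
#'
#' @param x An `hdx_diff_matrix`.
#' @param time Exchange time, s (must be one of `x$times`).
#' @return Named numeric vector: names are residue indices, values delta %D.
#' @export
residue_consensus_delta <- function(x, time = 20) {
  j <- match(time, x$times)
  if (is.na(j)) stop(sprintf("time %g s not on the matrix grid", time),
                     call. = FALSE)
  peps <- x$peptides
  peps$len <- peps$end - peps$start + 1L
  vals <- x$delta[, j]
  out <- numeric(0)
  residues <- sort(unique(unlist(
    lapply(seq_len(nrow(peps)), function(i) peps$start[i]:peps$end[i])
  )))
  for (r in residues) {
    cov <- which(peps$start <= r & peps$end >= r & !is.na(vals))
    if (length(cov) == 0L) next
    cov <- cov[order(peps$len[cov], peps$start[cov])]
    out[as.character(r)] <- vals[cov[1L]]
  }
  out
}

#' Write a differential matrix as CSV
#' @param x An `hdx_diff_matrix`.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(x, path) {
  df <- cbind(x$peptides, as.data.frame(x$delta, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a residue consensus map as CSV
#' @param consensus Named vector from [residue_consensus_delta()].
#' @param path Output CSV path.
#' @export
write_consensus_csv <- function(consensus, path) {
  df <- data.frame(res_index = as.integer(names(consensus)),
                   delta_percent = as.numeric(consensus))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
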