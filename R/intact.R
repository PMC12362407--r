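# Intact-protein HDX: centroid masses of deconvoluted neutral-mass envelopes,
# mass-shift -> proton conversion, in-exchange and back-exchange handling, and
# the free-vs-bound differential protection count.

#' Exchange conditions
#'
#' Defaults match a typical differential HDX protocol: 1:4 v:v mixing into
#' D2O (80% final D2O), ~30% back-exchange estimated from a fully deuterated
#' protein standard, and a 0-160 s exchange time course where 0 s serves as
#' the in-exchange control.
#'
#' @param f_d2o D2O fraction during labelling, in (0, 1].
#' @param back_exchange Back-exchange fraction estimated from a fully
#'   deuterated standard, in \[0, 1).
#' @param time_points Exchange times in seconds, non-negative ascending.
#' @return Object of class `hdx_conditions`.
#' @export
exchange_conditions <- function(f_d2o = 0.8, back_exchange = 0.30,
                                time_points = c(0, 20, 40, 80, 160)) {
  stopifnot(
    f_d2o > 0, f_d2o <= 1,
    back_exchange >= 0, back_exchange < 1,
    all(time_points >= 0), !is.unsorted(time_points, strictly = TRUE)
  )
  structure(
    list(f_d2o = f_d2o, back_exchange = back_exchange,
         time_points = time_points),
    class = "hdx_conditions"
  )
}

#' Construct a deconvoluted mass spectrum
#'
#' @param mass Neutral masses, Da, strictly increasing.
#' @param intensity Non-negative intensities (arbitrary units), at least one
#'   positive.
#' @return Object of class `mass_spectrum` (data frame with `mass`,
#'   `intensity`).
#' @export
mass_spectrum <- function(mass, intensity) {
  stopifnot(
    length(mass) == length(intensity), length(mass) >= 1L,
    all(is.finite(mass)), all(is.finite(intensity)),
    !is.unsorted(mass, strictly = TRUE),
    all(intensity >= 0), any(intensity > 0)
  )
  structure(
    data.frame(mass = mass, intensity = intensity),
    class = c("mass_spectrum", "data.frame")
  )
}

#' Read a two-column deconvoluted spectrum
#'
#' Whitespace- or comma-separated text with neutral mass (Da) in the first
#' column and intensity in the second; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  i <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  if (anyNA(m) || anyNA(i)) stop("malformed spectrum file: ", path, call. = FALSE)
  ord <- order(m)
  mass_spectrum(m[ord], i[ord])
}

#' Write a spectrum as two-column text
#' @param sp A `mass_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(sp, path) {
  writeLines(sprintf("%.6f %.10g", sp$mass, sp$intensity), path)
  invisible(path)
}

#' Intensity-weighted centroid mass
#'
#' The centroid is the intensity-weighted mean mass over points whose
#' intensity is at least `threshold` times the base-peak intensity. The
#' default 5% threshold suppresses baseline contributions of deconvolution
#' artefacts; use `threshold = 0` for the exact full-envelope centroid.
#'
#' @param sp A `mass_spectrum`.
#' @param threshold Fraction of the base-peak intensity, in \[0, 1\].
#' @return Centroid mass, Da.
#' @export
centroid_mass <- function(sp, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- sp$intensity >= threshold * max(sp$intensity)
  sum(sp$mass[keep] * sp$intensity[keep]) / sum(sp$intensity[keep])
}

#' Convert a deuteration mass shift to protected/exchanged protons
#'
#' Corrects the observed centroid mass difference for the D2O fraction used
#' during labelling: `protons = delta_mass / f_d2o`. An 8.8 Da intact-mass
#' difference measured in 80% D2O therefore corresponds to 11 backbone
#' protons.
#'
#' @param delta_mass Centroid mass difference, Da.
#' @param f_d2o D2O fraction, > 0.
#' @return Proton count (real).
#' @export
protons_from_shift <- function(delta_mass, f_d2o) {
  if (!is.numeric(f_d2o) || f_d2o <= 0) {
    stop("f_d2o must be positive", call. = FALSE)
  }
  delta_mass / f_d2o
}

#' Back-exchange fraction from a fully deuterated standard
#'
#' @param observed_standard_shift Observed mass shift of the fully deuterated
#'   standard, Da (>= 0).
#' @param theoretical_max_shift Theoretical maximum shift at full deuteration,
#'   Da (> 0).
#' @return `1 - observed/theoretical`, clipped to \[0, 1\].
#' @export
back_exchange_fraction <- function(observed_standard_shift,
                                   theoretical_max_shift) {
  stopifnot(theoretical_max_shift > 0)
  if (any(observed_standard_shift < 0)) {
    stop("observed standard shift must be non-negative", call. = FALSE)
  }
  pmin(pmax(1 - observed_standard_shift / theoretical_max_shift, 0), 1)
}

#' Intact-protein deuterium uptake curve
#'
#' For each (state, time) spectrum: `delta_mass` is the centroid difference
#' from the non-deuterated reference minus that state's own 0 s delta (the
#' in-exchange estimate), and `protons = delta_mass / f_d2o`. Optionally the
#' back-exchange correction divides protons by `1 - back_exchange`.
#'
#' @param spectra List of entries, each a list with elements `state`
#'   (`"free"`/`"bound"`), `time` (s), `spectrum` (a `mass_spectrum`), and
#'   optionally `replicate`.
#' @param reference The non-deuterated protein `mass_spectrum`.
#' @param cond An [exchange_conditions()].
#' @param threshold Centroid threshold (see [centroid_mass()]).
#' @param apply_backexchange Divide protons by `1 - back_exchange`?
#' @return Data frame with `state`, `replicate`, `time_s`, `centroid_da`,
#'   `delta_da` (in-exchange corrected), `protons`.
#' @export
intact_uptake_curve <- function(spectra, reference, cond = exchange_conditions(),
                                threshold = 0.05, apply_backexchange = FALSE) {
  ref_c <- centroid_mass(reference, threshold)
  df <- do.call(rbind, lapply(spectra, function(e) {
    data.frame(
      state = e$state,
      replicate = if (is.null(e$replicate)) 1L else as.integer(e$replicate),
      time_s = e$time,
      centroid_da = centroid_mass(e$spectrum, threshold),
      stringsAsFactors = FALSE
    )
  }))
  raw_delta <- df$centroid_da - ref_c
  df$delta_da <- NA_real_
  for (st in unique(df$state)) {
    for (rp in unique(df$replicate[df$state == st])) {
      sel <- df$state == st & df$replicate == rp
      zero <- which(sel & df$time_s == 0)
      if (length(zero) == 0L) {
        stop(sprintf("missing 0 s spectrum for state '%s' (in-exchange control)",
                     st), call. = FALSE)
      }
      df$delta_da[sel] <- raw_delta[sel] - raw_delta[zero[1L]]
    }
  }
  df$protons <- protons_from_shift(df$delta_da, cond$f_d2o)
  if (apply_backexchange) df$protons <- df$protons / (1 - cond$back_exchange)
  df <- df[order(df$state, df$replicate, df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Differential intact protection at one exchange time
#'
#' Protected protons = protons(free) - protons(bound) at the requested time.
#' With replicated measurements the difference is computed per replicate pair
#' and the mean, SD and coefficient of variation are reported.
#'
#' @param records Data frame from [intact_uptake_curve()] containing both
#'   states (columns `state`, `replicate`, `time_s`, `protons`).
#' @param time Exchange time, s (must be present for both states).
#' @return List with `protected_protons` (mean over replicate pairs), `sd`,
#'   `cv` (SD/mean), `n` (replicate pairs).
#' @export
differential_intact <- function(records, time = 20) {
  sel <- records$time_s == time
  if (!any(sel & records$state == "free") || !any(sel & records$state == "bound")) {
    stop(sprintf("time %g s not measured for both states", time), call. = FALSE)
  }
  fr <- records[sel & records$state == "free", , drop = FALSE]
  bo <- records[sel & records$state == "bound", , drop = FALSE]
  reps <- intersect(fr$replicate, bo$replicate)
  d <- vapply(reps, function(r) {
    fr$protons[fr$replicate == r][1L] - bo$protons[bo$replicate == r][1L]
  }, numeric(1))
  m <- mean(d)
  s <- if (length(d) > 1L) stats::sd(d) else NA_real_
  list(protected_protons = m, sd = s,
       cv = if (is.na(s) || m == 0) NA_real_ else s / m, n = length(d))
}

#' Fraction of protein bound at equilibrium
#'
#' Exact solution of the 1:1 binding quadratic
#' `bound = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`,
#' used to verify that HDX differences are not occupancy artefacts (ligand
#' saturation under assay conditions).
#'
#' @param Kd Dissociation constant, molar (>= 0).
#' @param P_total Total protein concentration, molar (> 0).
#' @param L_total Total ligand concentration, molar (>= 0).
#' @return Fraction of protein in complex, in \[0, 1\].
#' @export
ligand_saturation <- function(Kd, P_total, L_total) {
  stopifnot(Kd >= 0, P_total > 0, L_total >= 0)
  s <- P_total + L_total + Kd
  disc <- s^2 - 4 * P_total * L_total
  if (disc < -1e-9 * s^2) {
    stop("negative discriminant in binding quadratic", call. = FALSE)
  }
  ((s - sqrt(max(disc, 0))) / (2 * P_total))
}

#' Write an intact uptake curve as CSV
#' @param records Data frame from [intact_uptake_curve()].
#' @param path Output CSV path.
#' @export
write_intact_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(records)
}
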