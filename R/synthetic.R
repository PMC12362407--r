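# Synthetic ground-truth generators: an ideal alpha-helix scaffold, two-state
# flickering H-bond trajectories with known occupancies, deuterated isotope
# envelopes with known per-amide exchange probabilities, and a paired
# free/bound end-to-end experiment bundle.

# Monoisotopic residue masses (Da) and carbon counts per residue; water is
# added once per chain for the neutral peptide mass.
.RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
.RESIDUE_CARBONS <- c(
  A = 3, R = 6, N = 4, D = 4, C = 3, E = 5, Q = 5, G = 2, H = 6, I = 6,
  L = 6, K = 6, M = 5, F = 9, P = 5, S = 3, T = 4, W = 11, Y = 9, V = 5
)
.MASS_H2O <- 18.010565
.MASS_D_INC <- 1.00628   # H -> D mass increment, Da
.MASS_13C_INC <- 1.00336 # 12C -> 13C mass increment, Da

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom d from internal coordinates: bond length |c-d|, angle b-c-d
# (degrees), dihedral a-b-c-d (degrees).
.place_internal <- function(a, b, c, length, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  c + length * (-bc * cos(th) + m * sin(th) * cos(chi) + n * sin(th) * sin(chi))
}

#' Build an ideal alpha-helix backbone
#'
#' Constructs a poly-alanine backbone (N, H, CA, C, O per residue; no amide H
#' on residue 1) with ideal bond geometry and helical torsions
#' (phi = -57, psi = -47, omega = 180 degrees), so that every i -> i-4 amide
#' H-bond satisfies the default detection criterion. Amide hydrogens are
#' placed with the in-plane bisector construction.
#'
#' @param n_residues Number of residues (>= 4).
#' @return An `hdx_structure`.
#' @export
build_ideal_helix <- function(n_residues) {
  if (n_residues < 4L) stop("helix needs at least 4 residues", call. = FALSE)
  phi <- -57; psi <- -47; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  N <- matrix(NA_real_, n_residues, 3)
  CA <- matrix(NA_real_, n_residues, 3)
  CC <- matrix(NA_real_, n_residues, 3)
  O <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  al <- (180 - a_ncac) * pi / 180
  CC[1, ] <- CA[1, ] + b_cac * c(cos(al), sin(al), 0)
  for (i in 2:n_residues) {
    N[i, ] <- .place_internal(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                              b_cn, a_cacn, psi)
    CA[i, ] <- .place_internal(CA[i - 1, ], CC[i - 1, ], N[i, ],
                               b_nca, a_cnca, omega)
    CC[i, ] <- .place_internal(CC[i - 1, ], N[i, ], CA[i, ],
                               b_cac, a_ncac, phi)
    # carbonyl O of residue i-1: dihedral N(i-1)-CA(i-1)-C(i-1)-O = psi + 180
    O[i - 1, ] <- .place_internal(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                                  b_co, a_caco, psi + 180)
  }
  O[n_residues, ] <- .place_internal(N[n_residues, ], CA[n_residues, ],
                                     CC[n_residues, ], b_co, a_caco, psi + 180)
  rows <- list()
  for (i in seq_len(n_residues)) {
    rows[[length(rows) + 1L]] <- c("N", "N", i, N[i, ])
    rows[[length(rows) + 1L]] <- c("CA", "C", i, CA[i, ])
    rows[[length(rows) + 1L]] <- c("C", "C", i, CC[i, ])
    rows[[length(rows) + 1L]] <- c("O", "O", i, O[i, ])
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(
    serial = seq_len(nrow(m)),
    name = m[, 1L], element = m[, 2L],
    res_index = as.integer(m[, 3L]), res_name = "ALA", chain = "A",
    x = as.numeric(m[, 4L]), y = as.numeric(m[, 5L]), z = as.numeric(m[, 6L]),
    is_protein = TRUE, stringsAsFactors = FALSE
  )
  place_amide_hydrogens(new_structure(atoms))
}

#' Specification of a flickering two-state H-bond ensemble
#'
#' Describes the free/bound paired design: each designated donor flickers
#' between a bonded and an open state as a two-state Markov chain with
#' stationary bonded probability `p_free` (free state) or `p_bound` (bound
#' state) and persistence `q` (probability of keeping the current state at
#' each step; otherwise the state is redrawn as Bernoulli(p), giving lag-1
#' autocorrelation `q`). All remaining i -> i-4 donors of the helix flicker
#' with probability `p_stable` in both states (stable scaffold bonds).
#'
#' @param n_residues Helix length.
#' @param protected Donor residue indices (each >= 5, acceptor is i-4) whose
#'   occupancy shifts between states.
#' @param p_free,p_bound Stationary bonded probability of protected donors in
#'   the free and bound state.
#' @param p_stable Bonded probability of the remaining donors (both states).
#' @param q Markov persistence, in \[0, 1).
#' @param F Frames per trajectory.
#' @param replicates Replicates per state.
#' @param seed Mandatory integer seed.
#' @return Object of class `flicker_spec` with a `donors` data frame
#'   (`res`, `p_free`, `p_bound`).
#' @export
flicker_spec <- function(n_residues = 30, protected = 10:17,
                         p_free = 0.45, p_bound = 0.95, p_stable = 0.97,
                         q = 0.85, F = 500, replicates = 3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(
    n_residues >= 5, all(protected >= 5), all(protected <= n_residues),
    p_free >= 0, p_free <= 1, p_bound >= 0, p_bound <= 1,
    p_stable >= 0, p_stable <= 1, q >= 0, q < 1, F >= 1, replicates >= 1
  )
  all_donors <- 5:n_residues
  donors <- data.frame(
    res = all_donors,
    p_free = ifelse(all_donors %in% protected, p_free, p_stable),
    p_bound = ifelse(all_donors %in% protected, p_bound, p_stable)
  )
  structure(
    list(n_residues = n_residues, protected = sort(protected),
         donors = donors, q = q, F = as.integer(F),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "flicker_spec"
  )
}

# Deterministic sub-seed per (state, replicate), kept well below 2^31.
.derive_seed <- function(seed, state, replicate) {
  (abs(seed) %% 100000L) * 7919L + replicate * 101L +
    if (identical(state, "bound")) 13L else 0L
}

.markov_chain <- function(F, p, q) {
  z <- integer(F)
  z[1L] <- stats::rbinom(1L, 1L, p)
  if (F > 1L) {
    keep <- stats::runif(F) < q
    draw <- stats::rbinom(F, 1L, p)
    for (t in 2:F) z[t] <- if (keep[t]) z[t - 1L] else draw[t]
  }
  z
}

#' Simulate a flickering two-state trajectory
#'
#' Bonded frames use the ideal helix geometry; in open frames the donor's
#' acceptor carbonyl oxygen is displaced along the H -> O axis to
#' `1.5 * d_cut`, which unambiguously breaks the bond under the detection
#' criterion. Deterministic for a fixed (seed, state, replicate).
#'
#' @param spec A [flicker_spec()].
#' @param state `"free"` or `"bound"`.
#' @param replicate Replicate number (1-based).
#' @param d_cut Detection distance cutoff used to scale the open-state
#'   displacement, Angstrom.
#' @return An `hdx_trajectory`.
#' @export
simulate_two_state_trajectory <- function(spec, state = c("free", "bound"),
                                          replicate = 1L, d_cut = 2.5) {
  state <- match.arg(state)
  helix <- build_ideal_helix(spec$n_residues)
  atoms <- helix$atoms
  base <- as.matrix(atoms[, c("x", "y", "z")])
  p_col <- if (state == "bound") "p_bound" else "p_free"
  set.seed(.derive_seed(spec$seed, state, replicate))
  FF <- spec$F
  frames <- array(rep(c(base), each = FF), dim = c(FF, nrow(base), 3L))
  for (i in seq_len(nrow(spec$donors))) {
    res <- spec$donors$res[i]
    p <- spec$donors[[p_col]][i]
    h_idx <- which(atoms$res_index == res & atoms$name == "H")
    o_idx <- which(atoms$res_index == res - 4L & atoms$name == "O")
    if (length(h_idx) == 0L || length(o_idx) == 0L) next
    h <- base[h_idx[1L], ]
    o <- base[o_idx[1L], ]
    o_open <- h + 1.5 * d_cut * .unit(o - h)
    z <- .markov_chain(FF, p, spec$q)
    open <- which(z == 0L)
    if (length(open) > 0L) {
      frames[open, o_idx[1L], 1L] <- o_open[1L]
      frames[open, o_idx[1L], 2L] <- o_open[2L]
      frames[open, o_idx[1L], 3L] <- o_open[3L]
    }
  }
  new_trajectory(frames, helix, state, replicate)
}

#' Binomial natural carbon-isotope envelope
#'
#' @param n_carbons Number of carbon atoms (>= 0).
#' @param p13C 13C abundance.
#' @return Numeric vector of probabilities over +0, +1, ... Da isotope index
#'   (length `n_carbons + 1`).
#' @export
natural_isotope_envelope <- function(n_carbons, p13C = 0.0107) {
  stopifnot(n_carbons >= 0)
  stats::dbinom(0:n_carbons, n_carbons, p13C)
}

# Poisson-binomial distribution over deuteron counts by direct convolution.
.poisson_binomial <- function(p) {
  v <- 1
  for (pi in p) v <- c(v * (1 - pi), 0) + c(0, v * pi)
  v
}

#' Specification of a synthetic deuterium-uptake experiment
#'
#' Per-amide exchange follows first-order kinetics
#' `p_i(t) = 1 - (1 - in_exchange) * exp(-k_i * t)` in the free state (the
#' `in_exchange` floor models label picked up during mixing/quench, visible at
#' the nominal 0 s point). In the bound state the exchange probability of
#' amides in the `protected` set is multiplied by `1 - protection_factor`
#' (EX2-like independent-site suppression).
#'
#' @param sequence One-letter protein sequence.
#' @param rates Per-residue intrinsic exchange rates (1/s), length
#'   `nchar(sequence)`; entry i is the amide of residue i (entries for
#'   residue 1 and prolines are ignored). Default 0.05 everywhere.
#' @param f_d2o D2O fraction.
#' @param back_exchange Back-exchange fraction lost during workup.
#' @param in_exchange Exchange probability already acquired at 0 s.
#' @param protected Residue indices protected in the bound state.
#' @param protection_factor Fractional suppression of exchange probability at
#'   protected amides in the bound state, in \[0, 1\].
#' @param p13C Natural 13C abundance.
#' @param seed Mandatory integer seed (generators are deterministic; the seed
#'   is recorded for provenance of derived bundles).
#' @return Object of class `uptake_spec`.
#' @export
uptake_spec <- function(sequence, rates = NULL, f_d2o = 0.8,
                        back_exchange = 0.30, in_exchange = 0.05,
                        protected = integer(0), protection_factor = 0,
                        p13C = 0.0107, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- nchar(sequence)
  if (is.null(rates)) rates <- rep(0.05, n)
  stopifnot(
    length(rates) == n, all(rates >= 0),
    f_d2o > 0, f_d2o <= 1, back_exchange >= 0, back_exchange < 1,
    in_exchange >= 0, in_exchange <= 1,
    protection_factor >= 0, protection_factor <= 1,
    all(protected >= 1), all(protected <= n)
  )
  structure(
    list(sequence = toupper(sequence), rates = rates, f_d2o = f_d2o,
         back_exchange = back_exchange, in_exchange = in_exchange,
         protected = sort(protected), protection_factor = protection_factor,
         p13C = p13C, seed = as.integer(seed)),
    class = "uptake_spec"
  )
}

#' Per-amide exchange probabilities at a time point
#'
#' @param spec An [uptake_spec()].
#' @param time Exchange time, s.
#' @param state `"free"` or `"bound"`.
#' @param span Optional `c(start, end)` restricting to a peptide; amide
#'   positions are then positions >= 2 of the peptide.
#' @return Named numeric vector of exchange probabilities, one per
#'   exchangeable amide (names are residue indices).
#' @export
exchange_probabilities <- function(spec, time, state = c("free", "bound"),
                                   span = NULL) {
  state <- match.arg(state)
  aa <- strsplit(spec$sequence, "")[[1L]]
  n <- length(aa)
  lo <- if (is.null(span)) 1L else span[1L]
  hi <- if (is.null(span)) n else span[2L]
  res <- seq.int(lo, hi)
  amide <- res[res > lo & aa[res] != "P"]
  p <- 1 - (1 - spec$in_exchange) * exp(-spec$rates[amide] * time)
  if (state == "bound" && length(spec$protected) > 0L) {
    hit <- amide %in% spec$protected
    p[hit] <- p[hit] * (1 - spec$protection_factor)
  }
  stats::setNames(p, as.character(amide))
}

#' Simulate a deconvoluted deuterated isotope envelope
#'
#' The deuteron-count distribution is the Poisson-binomial of independent
#' per-amide incorporation probabilities
#' `p_i(t) * f_d2o * (1 - back_exchange)`, convolved with the natural 13C
#' envelope. Points are laid out on exact masses
#' `base + d * 1.00628 + c * 1.00336` Da and points falling within the same
#' 0.01 Da bin are merged by intensity-weighted mean mass, which preserves
#' the full-envelope centroid exactly.
#'
#' @param spec An [uptake_spec()].
#' @param time Exchange time, s.
#' @param state `"free"` or `"bound"`.
#' @param span Optional peptide span `c(start, end)`; default whole sequence.
#' @param min_intensity Probability floor below which grid points are dropped
#'   (relative to total 1); kept small so centroids are unaffected at the
#'   1e-9 level.
#' @return A [mass_spectrum()] of the neutral-mass envelope.
#' @export
simulate_deuterated_envelope <- function(spec, time, state = c("free", "bound"),
                                         span = NULL, min_intensity = 1e-12) {
  state <- match.arg(state)
  aa <- strsplit(spec$sequence, "")[[1L]]
  lo <- if (is.null(span)) 1L else span[1L]
  hi <- if (is.null(span)) length(aa) else span[2L]
  seg <- aa[lo:hi]
  base_mass <- sum(.RESIDUE_MASS[seg]) + .MASS_H2O
  n_carbons <- sum(.RESIDUE_CARBONS[seg])
  p <- exchange_probabilities(spec, time, state, span = c(lo, hi))
  p_eff <- p * spec$f_d2o * (1 - spec$back_exchange)
  pd <- .poisson_binomial(p_eff)
  pc <- natural_isotope_envelope(n_carbons, spec$p13C)
  pc <- pc[pc > min_intensity / 10]
  w <- outer(pd, pc)
  m <- outer(
    base_mass + (seq_along(pd) - 1L) * .MASS_D_INC,
    (seq_along(pc) - 1L) * .MASS_13C_INC,
    "+"
  )
  w <- as.vector(w); m <- as.vector(m)
  keep <- w > min_intensity
  w <- w[keep]; m <- m[keep]
  # merge points sharing a 0.01 Da bin by intensity-weighted mean mass
  bin <- round(m / 0.01)
  mm <- vapply(split(w * m, bin), sum, numeric(1)) /
    vapply(split(w, bin), sum, numeric(1))
  ww <- vapply(split(w, bin), sum, numeric(1))
  ord <- order(mm)
  mass_spectrum(mm[ord], ww[ord])
}

#' Uptake spec matched to a flicker spec
#'
#' Builds an [uptake_spec()] whose exchange-probability suppression at the
#' protected amides equals the flicker spec's occupancy shift at a reference
#' time: protected amides exchange with probability `p_ref` in the free state
#' at `t_ref`, and the bound-state protection factor is chosen so that
#' `p_free - p_bound = p_bound_occ - p_free_occ` there. This couples the MD
#' and MS sides of the paired design through a single delta.
#'
#' @param flicker A [flicker_spec()].
#' @param p_ref Free-state exchange probability of protected amides at
#'   `t_ref`; must be at least the occupancy shift.
#' @param t_ref Reference exchange time, s.
#' @param base_rate Intrinsic rate of unprotected amides, 1/s.
#' @param ... Passed to [uptake_spec()] (e.g. `f_d2o`, `back_exchange`).
#' @return An [uptake_spec()] over a poly-alanine sequence of the flicker
#'   spec's length.
#' @export
matched_uptake_spec <- function(flicker, p_ref = 0.85, t_ref = 20,
                                base_rate = 0.05, ...) {
  delta_p <- if (length(flicker$protected) > 0L) {
    i <- match(flicker$protected[1L], flicker$donors$res)
    flicker$donors$p_bound[i] - flicker$donors$p_free[i]
  } else 0
  if (abs(delta_p) > p_ref) {
    stop("p_ref must be at least the occupancy shift", call. = FALSE)
  }
  dots <- list(...)
  in_ex <- if (is.null(dots$in_exchange)) 0.05 else dots$in_exchange
  # rate so that 1 - (1 - in_ex) exp(-k t_ref) = p_ref
  k_prot <- -log((1 - p_ref) / (1 - in_ex)) / t_ref
  rates <- rep(base_rate, flicker$n_residues)
  rates[flicker$protected] <- k_prot
  args <- c(
    list(sequence = strrep("A", flicker$n_residues), rates = rates,
         protected = flicker$protected,
         protection_factor = if (p_ref > 0) delta_p / p_ref else 0,
         seed = flicker$seed),
    dots
  )
  do.call(uptake_spec, args)
}

#' Default peptide tiling for a synthetic protein
#'
#' Overlapping 10-residue windows every 5 residues plus one long peptide
#' covering the protected region with flanks, mimicking a peptic map with a
#' long reporter peptide over the binding region.
#'
#' @param n_residues Protein length.
#' @param protected Protected residue indices (may be empty).
#' @return Data frame with `start`, `end`.
#' @export
default_peptides <- function(n_residues, protected = integer(0)) {
  starts <- seq.int(1L, max(n_residues - 9L, 1L), by = 5L)
  df <- data.frame(start = starts, end = pmin(starts + 9L, n_residues))
  if (length(protected) > 0L) {
    lo <- max(1L, min(protected) - 4L)
    hi <- min(n_residues, max(protected) + 4L)
    df <- rbind(df, data.frame(start = lo, end = hi))
  }
  unique(df)
}

#' Simulate a complete paired HDX/MD experiment
#'
#' One protected residue set drives both sides of the paired design: those
#' donors gain H-bond occupancy (`p_bound > p_free`) in the bound-state
#' trajectories, and the same amides have their exchange probability
#' suppressed in the bound-state spectra. Peptide centroid masses are the
#' exact envelope expectations (noise-free), so recovery failures isolate
#' pipeline defects rather than sampling noise.
#'
#' @param flicker A [flicker_spec()].
#' @param uptake An [uptake_spec()]; its `protected` set must equal the
#'   flicker spec's.
#' @param time_points Exchange time grid, s.
#' @param peptides Data frame with `start`, `end`; default
#'   [default_peptides()].
#' @param out_dir Optional directory; when given, all artefacts are written
#'   in the package's interchange formats (multi-model PDB trajectories,
#'   two-column spectra, peptide CSV, ground-truth manifest CSV).
#' @return List with `trajectories` (list of `hdx_trajectory`), `structure`,
#'   `reference_spectrum`, `spectra` (list of state/time entries as consumed
#'   by [intact_uptake_curve()]), `peptide_table` (data frame), `manifest`
#'   (per-residue ground truth), `truth` (list: `k`, `delta_p`, `protected`).
#' @export
simulate_hdx_experiment <- function(flicker, uptake,
                                    time_points = c(0, 20, 40, 80, 160),
                                    peptides = NULL, out_dir = NULL) {
  if (!identical(as.integer(flicker$protected), as.integer(uptake$protected))) {
    stop("flicker and uptake specs designate different protected residue sets",
         call. = FALSE)
  }
  if (nchar(uptake$sequence) != flicker$n_residues) {
    stop("uptake sequence length does not match flicker n_residues",
         call. = FALSE)
  }
  if (is.null(peptides)) {
    peptides <- default_peptides(flicker$n_residues, flicker$protected)
  }
  trajs <- list()
  for (st in c("free", "bound")) {
    for (r in seq_len(flicker$replicates)) {
      trajs[[sprintf("%s_rep%d", st, r)]] <-
        simulate_two_state_trajectory(flicker, st, r)
    }
  }
  helix <- trajs[[1L]]$structure
  ref <- simulate_deuterated_envelope(
    uptake_spec(uptake$sequence, rates = rep(0, flicker$n_residues),
                f_d2o = uptake$f_d2o, back_exchange = uptake$back_exchange,
                in_exchange = 0, p13C = uptake$p13C, seed = uptake$seed),
    time = 0, state = "free"
  )
  spectra <- list()
  for (st in c("free", "bound")) {
    for (t in time_points) {
      spectra[[sprintf("%s_%gs", st, t)]] <- list(
        state = st, time = t,
        spectrum = simulate_deuterated_envelope(uptake, t, st)
      )
    }
  }
  aa <- strsplit(uptake$sequence, "")[[1L]]
  pep_rows <- list()
  for (i in seq_len(nrow(peptides))) {
    lo <- peptides$start[i]; hi <- peptides$end[i]
    seg <- paste(aa[lo:hi], collapse = "")
    base_mass <- sum(.RESIDUE_MASS[aa[lo:hi]]) + .MASS_H2O +
      sum(.RESIDUE_CARBONS[aa[lo:hi]]) * uptake$p13C * .MASS_13C_INC
    for (st in c("free", "bound")) {
      for (t in time_points) {
        p <- exchange_probabilities(uptake, t, st, span = c(lo, hi))
        centroid <- base_mass +
          .MASS_D_INC * uptake$f_d2o * (1 - uptake$back_exchange) * sum(p)
        pep_rows[[length(pep_rows) + 1L]] <- data.frame(
          sequence = seg, start = lo, end = hi, state = st, time_s = t,
          centroid_da = centroid, stringsAsFactors = FALSE
        )
      }
    }
  }
  peptide_table <- do.call(rbind, pep_rows)
  don <- flicker$donors
  p20f <- exchange_probabilities(uptake, 20, "free")
  p20b <- exchange_probabilities(uptake, 20, "bound")
  res_all <- seq_len(flicker$n_residues)
  manifest <- data.frame(
    res_index = res_all,
    protected = res_all %in% flicker$protected,
    occ_free = don$p_free[match(res_all, don$res)],
    occ_bound = don$p_bound[match(res_all, don$res)],
    delta_occ = don$p_bound[match(res_all, don$res)] -
      don$p_free[match(res_all, don$res)],
    p_exchange_free_20s = as.numeric(p20f[as.character(res_all)]),
    p_exchange_bound_20s = as.numeric(p20b[as.character(res_all)])
  )
  delta_p_ex <- sum(p20f[as.character(flicker$protected)] -
                      p20b[as.character(flicker$protected)])
  truth <- list(
    k = length(flicker$protected),
    delta_p = if (length(flicker$protected) > 0L) {
      don$p_bound[match(flicker$protected[1L], don$res)] -
        don$p_free[match(flicker$protected[1L], don$res)]
    } else 0,
    protected = flicker$protected,
    # expected pipeline readout without/with the back-exchange correction
    expected_intact_differential =
      delta_p_ex * .MASS_D_INC * (1 - uptake$back_exchange),
    expected_intact_differential_bx_corrected = delta_p_ex * .MASS_D_INC
  )
  bundle <- list(
    trajectories = trajs, structure = helix, reference_spectrum = ref,
    spectra = spectra, peptide_table = peptide_table, manifest = manifest,
    truth = truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(trajs)) {
      write_trajectory(trajs[[nm]], file.path(out_dir, paste0("traj_", nm, ".pdb")))
    }
    write_spectrum(ref, file.path(out_dir, "spectrum_reference.txt"))
    manifest_files <- do.call(rbind, lapply(spectra, function(e) {
      f <- sprintf("spectrum_%s_%gs.txt", e$state, e$time)
      write_spectrum(e$spectrum, file.path(out_dir, f))
      data.frame(state = e$state, time_s = e$time, path = f,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(manifest_files, file.path(out_dir, "spectra_manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(peptide_table, file.path(out_dir, "peptides.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  bundle
}
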