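# Backbone amide H-bond detection (Baker-Hubbard geometric criterion),
# per-replicate occupancy, lifetime filtering and differential significance
# calls between free and ligand-bound simulation sets.

#' Analysis parameters for H-bond detection and differential calls
#'
#' Defaults follow the standard differential-occupancy protocol: a 2.5 Angstrom
#' distance cutoff with a minimum donor-hydrogen-acceptor angle of 120 degrees
#' (Baker-Hubbard criterion), a 40% lifetime filter and a +/-20 percentage
#' point occupancy-difference significance cutoff. The literal reading of a
#' 2.5 Angstrom *heavy-atom* donor-acceptor distance is sterically implausible
#' for backbone amides, so the distance is measured hydrogen-to-acceptor by
#' default; `distance_endpoint = "heavy"` switches to the N-O distance.
#'
#' @param d_cut Distance cutoff, Angstrom.
#' @param theta_min Minimum donor-hydrogen-acceptor angle, degrees.
#' @param lifetime_min Lifetime filter threshold: H-bonds below this mean
#'   occupancy in *both* states are dropped (fraction of frames).
#' @param delta_sig Minimum absolute occupancy difference (bound - free) for a
#'   kept H-bond to be called significant.
#' @param distance_endpoint `"hydrogen"` (H...O) or `"heavy"` (N...O).
#' @return Object of class `hdx_params`.
#' @export
analysis_parameters <- function(d_cut = 2.5, theta_min = 120,
                                lifetime_min = 0.40, delta_sig = 0.20,
                                distance_endpoint = c("hydrogen", "heavy")) {
  distance_endpoint <- match.arg(distance_endpoint)
  stopifnot(
    d_cut > 0, theta_min > 0, theta_min < 180,
    lifetime_min >= 0, lifetime_min <= 1,
    delta_sig >= 0, delta_sig <= 1
  )
  structure(
    list(d_cut = d_cut, theta_min = theta_min, lifetime_min = lifetime_min,
         delta_sig = delta_sig, distance_endpoint = distance_endpoint),
    class = "hdx_params"
  )
}

#' H-bond geometry for one donor/acceptor pair in one frame
#'
#' @param frame Numeric matrix `n_atoms x 3` of coordinates, Angstrom.
#' @param key List with atom row indices `n_idx`, `h_idx`, `o_idx` (as in the
#'   topology data frames). The geometry kernel accepts arbitrary keys, so
#'   side-chain acceptors can be probed even though the default enumeration is
#'   backbone-backbone only.
#' @param distance_endpoint `"hydrogen"` for the H...O distance (default) or
#'   `"heavy"` for N...O.
#' @return Named numeric vector `c(distance =, angle =)`: distance in
#'   Angstrom, donor-hydrogen-acceptor angle at the hydrogen in degrees.
#' @export
hbond_geometry <- function(frame, key, distance_endpoint = "hydrogen") {
  n <- frame[key$n_idx, ]
  h <- frame[key$h_idx, ]
  o <- frame[key$o_idx, ]
  ho <- o - h
  d_ho <- sqrt(sum(ho^2))
  if (d_ho == 0) {
    stop("undefined angle: hydrogen and acceptor coordinates coincide",
         call. = FALSE)
  }
  hn <- n - h
  cosang <- sum(hn * ho) / (sqrt(sum(hn^2)) * d_ho)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  d <- if (identical(distance_endpoint, "heavy")) sqrt(sum((o - n)^2)) else d_ho
  c(distance = d, angle = ang)
}

# Vectorized kernel: logical D x A matrix of bonds in one frame.
# Same-residue donor/acceptor pairs are excluded.
.frame_bond_matrix <- function(frame, topology, params) {
  don <- topology$donors
  acc <- topology$acceptors
  D <- nrow(don); A <- nrow(acc)
  if (D == 0L || A == 0L) return(matrix(FALSE, D, A))
  N <- frame[don$n_idx, , drop = FALSE]
  H <- frame[don$h_idx, , drop = FALSE]
  O <- frame[acc$o_idx, , drop = FALSE]
  ho2 <- outer(rowSums(H^2), rep(1, A)) + outer(rep(1, D), rowSums(O^2)) -
    2 * (H %*% t(O))
  d_ho <- sqrt(pmax(ho2, 0))
  HN <- N - H
  dot <- (HN %*% t(O)) - rowSums(HN * H)
  hn_len <- sqrt(rowSums(HN^2))
  denom <- hn_len %o% rep(1, A) * d_ho
  cosang <- ifelse(denom > 0, dot / denom, NA_real_)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dist <- if (identical(params$distance_endpoint, "heavy")) {
    no2 <- outer(rowSums(N^2), rep(1, A)) + outer(rep(1, D), rowSums(O^2)) -
      2 * (N %*% t(O))
    sqrt(pmax(no2, 0))
  } else {
    d_ho
  }
  same <- outer(paste(don$chain, don$res_index), paste(acc$chain, acc$res_index), "==")
  bond <- dist <= params$d_cut & !is.na(ang) & ang >= params$theta_min & !same
  bond
}

#' Detect backbone H-bonds in a single frame
#'
#' A donor/acceptor pair is bonded iff the distance is at most `d_cut` and the
#' donor-hydrogen-acceptor angle is at least `theta_min` (both boundaries
#' inclusive). All donor x acceptor backbone pairs are considered except pairs
#' within the same residue.
#'
#' @param frame Numeric `n_atoms x 3` coordinate matrix.
#' @param topology An `hdx_topology` from [build_topology()].
#' @param params An `hdx_params` from [analysis_parameters()].
#' @return Data frame with one row per detected bond: `donor_res`,
#'   `acceptor_res`, `donor_chain`, `acceptor_chain`, `n_idx`, `h_idx`,
#'   `o_idx`, `distance`, `angle`.
#' @export
detect_frame_hbonds <- function(frame, topology, params = analysis_parameters()) {
  bond <- .frame_bond_matrix(frame, topology, params)
  idx <- which(bond, arr.ind = TRUE)
  don <- topology$donors; acc <- topology$acceptors
  out <- data.frame(
    donor_res = don$res_index[idx[, 1L]],
    acceptor_res = acc$res_index[idx[, 2L]],
    donor_chain = don$chain[idx[, 1L]],
    acceptor_chain = acc$chain[idx[, 2L]],
    n_idx = don$n_idx[idx[, 1L]],
    h_idx = don$h_idx[idx[, 1L]],
    o_idx = acc$o_idx[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    geo <- t(vapply(seq_len(nrow(out)), function(i) {
      hbond_geometry(frame, out[i, ], params$distance_endpoint)
    }, numeric(2)))
    out$distance <- geo[, 1L]
    out$angle <- geo[, 2L]
    out <- out[order(out$donor_res, out$acceptor_res), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$distance <- numeric(0)
    out$angle <- numeric(0)
  }
  out
}

#' Per-H-bond occupancy along a trajectory
#'
#' Runs frame-wise detection over a trajectory and reports, for every
#' donor/acceptor pair bonded in at least one frame, the fraction of frames in
#' which the bond exists. Also reports each donor's *union* occupancy: the
#' fraction of frames in which the donor is bonded to any acceptor, which is
#' the quantity relevant for exchange protection of that amide.
#'
#' @param traj An `hdx_trajectory` (atom ordering must match `topology`).
#' @param topology An `hdx_topology`.
#' @param params An `hdx_params`.
#' @param keep_series Keep the per-frame bonded logicals for each ever-bonded
#'   pair (list column `series`)?
#' @return Object of class `hdx_occupancy`: list with `pairs` (data frame
#'   `donor_res`, `acceptor_res`, `count`, `occupancy`), `donor_union` (data
#'   frame `res_index`, `count`, `occupancy`, one row per topology donor),
#'   `series` (named list of logical vectors, `"donor->acceptor"`), `F`,
#'   `state`, `replicate_id`.
#' @export
occupancy_series <- function(traj, topology, params = analysis_parameters(),
                             keep_series = TRUE) {
  don <- topology$donors; acc <- topology$acceptors
  D <- nrow(don); A <- nrow(acc); FF <- traj$F
  counts <- matrix(0L, D, A)
  union_counts <- integer(D)
  store <- keep_series && (as.double(D) * A * FF <= 5e7)
  if (store) bond_arr <- array(FALSE, dim = c(D, A, FF))
  for (f in seq_len(FF)) {
    frame <- traj$frames[f, , , drop = TRUE]
    b <- .frame_bond_matrix(frame, topology, params)
    counts <- counts + b
    union_counts <- union_counts + (rowSums(b) > 0L)
    if (store) bond_arr[, , f] <- b
  }
  ever <- which(counts > 0L, arr.ind = TRUE)
  ever <- ever[order(don$res_index[ever[, 1L]], acc$res_index[ever[, 2L]]), ,
               drop = FALSE]
  pairs <- data.frame(
    donor_res = don$res_index[ever[, 1L]],
    acceptor_res = acc$res_index[ever[, 2L]],
    count = counts[ever],
    occupancy = counts[ever] / FF,
    stringsAsFactors = FALSE
  )
  series <- NULL
  if (store && nrow(pairs) > 0L) {
    series <- lapply(seq_len(nrow(ever)), function(i) {
      bond_arr[ever[i, 1L], ever[i, 2L], ]
    })
    names(series) <- paste0(pairs$donor_res, "->", pairs$acceptor_res)
  }
  donor_union <- data.frame(
    res_index = don$res_index,
    count = union_counts,
    occupancy = union_counts / FF,
    stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, donor_union = donor_union, series = series,
         F = FF, state = traj$state, replicate_id = traj$replicate_id),
    class = "hdx_occupancy"
  )
}

#' Aggregate per-replicate occupancies into a differential table
#'
#' Mean occupancy per state is the unweighted mean over that state's
#' replicates; a pair absent from a replicate counts as occupancy 0 there (the
#' bond simply never formed), not as missing data. The differential is
#' `delta = mean(bound) - mean(free)`. Donor union occupancies are aggregated
#' the same way for per-residue mapping.
#'
#' @param series_list List of `hdx_occupancy` objects covering both states
#'   (at least one replicate per state).
#' @return Object of class `hdx_occupancy_table`: list with `pairs` and
#'   `donors` data frames (per-replicate columns `occ_<state>_rep<i>`, means,
#'   `delta`, and for pairs the `kept`/`significant` flags, initially `NA`),
#'   plus `R_free`, `R_bound`, `F`.
#' @export
aggregate_replicates <- function(series_list) {
  states <- vapply(series_list, function(s) s$state, character(1))
  if (!all(c("free", "bound") %in% states)) {
    stop("need at least one replicate per state (free and bound)", call. = FALSE)
  }
  free <- series_list[states == "free"]
  bound <- series_list[states == "bound"]

  agg <- function(get_keys, get_occ, key_cols) {
    keys <- unique(do.call(rbind, lapply(series_list, get_keys)))
    keys <- keys[do.call(order, keys), , drop = FALSE]
    rownames(keys) <- NULL
    kstr <- do.call(paste, keys)
    occ_cols <- function(reps, label) {
      m <- matrix(0, nrow(keys), length(reps))
      for (j in seq_along(reps)) {
        rk <- do.call(paste, get_keys(reps[[j]]))
        mm <- match(kstr, rk)
        occ <- get_occ(reps[[j]])
        m[, j] <- ifelse(is.na(mm), 0, occ[mm])
      }
      colnames(m) <- sprintf("occ_%s_rep%d", label, seq_along(reps))
      m
    }
    mf <- occ_cols(free, "free")
    mb <- occ_cols(bound, "bound")
    out <- cbind(keys, as.data.frame(mf), as.data.frame(mb))
    out$occ_free_mean <- rowMeans(mf)
    out$occ_bound_mean <- rowMeans(mb)
    out$delta <- out$occ_bound_mean - out$occ_free_mean
    out
  }

  pairs <- agg(
    function(s) s$pairs[, c("donor_res", "acceptor_res")],
    function(s) s$pairs$occupancy
  )
  pairs$kept <- NA
  pairs$significant <- NA
  donors <- agg(
    function(s) s$donor_union[, "res_index", drop = FALSE],
    function(s) s$donor_union$occupancy
  )
  structure(
    list(pairs = pairs, donors = donors,
         R_free = length(free), R_bound = length(bound),
         F = series_list[[1L]]$F),
    class = "hdx_occupancy_table"
  )
}

#' @export
print.hdx_occupancy_table <- function(x, ...) {
  n_sig <- sum(x$pairs$significant %in% TRUE)
  cat(sprintf(
    "<hdx_occupancy_table> %d H-bonds (%d kept, %d significant), R=%d free / %d bound\n",
    nrow(x$pairs), sum(x$pairs$kept %in% TRUE), n_sig, x$R_free, x$R_bound
  ))
  invisible(x)
}

#' Apply the lifetime filter
#'
#' An H-bond is kept iff its mean occupancy reaches `lifetime_min` in at least
#' one state (it is dropped only when below threshold in both states, since a
#' bond stable in either simulation set is informative). The boundary is
#' inclusive. Dropped rows are retained with `kept = FALSE` for reporting.
#'
#' @param table An `hdx_occupancy_table`.
#' @param params An `hdx_params`.
#' @return The table with the `kept` flag set.
#' @export
filter_lifetime <- function(table, params = analysis_parameters()) {
  # inclusive boundary: guard against representation error in means computed
  # as floating sums (e.g. 0.7 - 0.5) flipping a call exactly at threshold
  eps <- 1e-9
  table$pairs$kept <- table$pairs$occ_free_mean >= params$lifetime_min - eps |
    table$pairs$occ_bound_mean >= params$lifetime_min - eps
  table$pairs$significant <- NA
  table
}

#' Call significant occupancy changes
#'
#' A kept H-bond is significant iff `|delta| >= delta_sig` (inclusive).
#' The lifetime filter takes precedence: a dropped bond is never significant
#' regardless of its differential.
#'
#' @param table An `hdx_occupancy_table` after [filter_lifetime()].
#' @param params An `hdx_params`.
#' @return The table with the `significant` flag set.
#' @export
significant_changes <- function(table, params = analysis_parameters()) {
  if (all(is.na(table$pairs$kept))) {
    stop("apply filter_lifetime() before significant_changes()", call. = FALSE)
  }
  table$pairs$significant <- table$pairs$kept &
    abs(table$pairs$delta) >= params$delta_sig - 1e-9
  table
}

#' Per-donor-residue differential occupancy map
#'
#' Projects the occupancy table onto donor residues for per-residue structure
#' mapping. Under the default `"union"` convention a donor's state occupancy
#' is the fraction of frames it is bonded to *any* acceptor, so a donor that
#' swaps acceptors without ever opening scores occupancy 1, as exchange
#' protection demands. Donors whose every H-bond fell below the lifetime
#' filter are imputed to 0, and donors with no H-bond at all are included at
#' 0, so every backbone amide appears in the map. `method = "per_pair"`
#' instead reports the kept pair with the largest absolute differential.
#'
#' @param table An `hdx_occupancy_table` after [filter_lifetime()].
#' @param topology The `hdx_topology` used for detection.
#' @param method `"union"` (default) or `"per_pair"`.
#' @return Named numeric vector: names are donor residue indices, values the
#'   occupancy differential (bound - free).
#' @export
donor_residue_map <- function(table, topology, method = c("union", "per_pair")) {
  method <- match.arg(method)
  if (all(is.na(table$pairs$kept))) {
    stop("apply filter_lifetime() before donor_residue_map()", call. = FALSE)
  }
  res <- topology$donors$res_index
  out <- stats::setNames(rep(0, length(res)), as.character(res))
  kept <- table$pairs[table$pairs$kept %in% TRUE, , drop = FALSE]
  kept_donors <- unique(kept$donor_res)
  if (method == "union") {
    m <- match(as.character(kept_donors), as.character(table$donors$res_index))
    out[as.character(kept_donors)] <- table$donors$delta[m]
  } else {
    for (r in kept_donors) {
      rows <- kept[kept$donor_res == r, , drop = FALSE]
      out[as.character(r)] <- rows$delta[which.max(abs(rows$delta))]
    }
  }
  out
}

#' Write an occupancy table as CSV
#'
#' Columns: donor/acceptor residue and atom names, per-replicate occupancies,
#' state means, `delta`, `kept`, `significant`; rows ordered by
#' `(donor_res, acceptor_res)`.
#'
#' @param table An `hdx_occupancy_table`.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_occupancy_csv <- function(table, path) {
  df <- table$pairs
  out <- data.frame(
    donor_res = df$donor_res, donor_name = "N",
    acceptor_res = df$acceptor_res, acceptor_name = "O",
    stringsAsFactors = FALSE
  )
  rep_cols <- grep("^occ_(free|bound)_rep", names(df), value = TRUE)
  out <- cbind(out, df[, c(rep_cols, "occ_free_mean", "occ_bound_mean",
                           "delta", "kept", "significant")])
  out <- out[order(out$donor_res, out$acceptor_res), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Differential H-bond pipeline over trajectories
#'
#' Convenience wrapper: occupancy series for every replicate of both states,
#' aggregation, lifetime filter and significance calls.
#'
#' @param free_trajs,bound_trajs Lists of `hdx_trajectory` objects.
#' @param topology An `hdx_topology`.
#' @param params An `hdx_params`.
#' @return An `hdx_occupancy_table` with flags set.
#' @export
differential_hbonds <- function(free_trajs, bound_trajs, topology,
                                params = analysis_parameters()) {
  series <- c(
    lapply(free_trajs, occupancy_series, topology = topology, params = params,
           keep_series = FALSE),
    lapply(bound_trajs, occupancy_series, topology = topology, params = params,
           keep_series = FALSE)
  )
  tab <- aggregate_replicates(series)
  tab <- filter_lifetime(tab, params)
  significant_changes(tab, params)
}
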