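# Geometry kernel, frame detection vs exhaustive oracle, occupancy
# aggregation, filter/significance semantics, donor-residue mapping.

test_that("hbond_geometry reproduces constructed distances and angles", {
  frame <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))     # N, H, O collinear
  key <- list(n_idx = 1, h_idx = 2, o_idx = 3)
  g <- hbond_geometry(frame, key)
  expect_equal(unname(g["distance"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(g["angle"]), 180.0, tolerance = 1e-9)

  frame2 <- rbind(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0))    # right angle at H
  g2 <- hbond_geometry(frame2, key)
  expect_equal(unname(g2["angle"]), 90.0, tolerance = 1e-9)

  frame3 <- rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0))    # coincident H and O
  expect_error(hbond_geometry(frame3, key), "undefined angle")
})

test_that("hbond_geometry matches an arccos/dot-product oracle on random geometries", {
  set.seed(41)
  key <- list(n_idx = 1, h_idx = 2, o_idx = 3)
  for (rep in 1:100) {
    frame <- matrix(stats::rnorm(9, sd = 2), 3, 3)
    g <- hbond_geometry(frame, key)
    v1 <- frame[1, ] - frame[2, ]; v2 <- frame[3, ] - frame[2, ]
    d <- sqrt(sum(v2^2))
    ang <- acos(max(min(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), 1), -1)) *
      180 / pi
    expect_equal(unname(g["distance"]), d, tolerance = 1e-9)
    expect_equal(unname(g["angle"]), ang, tolerance = 1e-9)
  }
})

test_that("single-pair detection honours both cutoffs", {
  # one donor (res 2), one acceptor (res 1), tunable geometry
  mk <- function(d, ang_deg) {
    th <- ang_deg * pi / 180
    lines <- c(
      pdb_line("N", "ALA", 1, 0, 0, 0, 1), pdb_line("CA", "ALA", 1, 1.4, 0, 0, 2),
      pdb_line("C", "ALA", 1, 2, 1, 0, 3),
      pdb_line("O", "ALA", 1, 10 + d * cos(pi - th), d * sin(pi - th), 0, 4),
      pdb_line("N", "ALA", 2, 9, 0, 0, 5), pdb_line("H", "ALA", 2, 10, 0, 0, 6),
      pdb_line("CA", "ALA", 2, 8.6, 1.2, 0, 7), pdb_line("C", "ALA", 2, 9, 2.5, 0, 8),
      pdb_line("O", "ALA", 2, 10, 3, 0, 9)
    )
    s <- parse_pdb(lines)
    list(frame = as.matrix(s$atoms[, c("x", "y", "z")]),
         topo = build_topology(s))
  }
  f <- mk(2.0, 165)
  det <- detect_frame_hbonds(f$frame, f$topo)
  expect_equal(nrow(det), 1L)
  expect_equal(det$donor_res, 2L)
  expect_equal(det$acceptor_res, 1L)
  expect_equal(nrow(detect_frame_hbonds(mk(3.0, 165)$frame, f$topo)), 0L)
  expect_equal(nrow(detect_frame_hbonds(mk(2.0, 100)$frame, f$topo)), 0L)
})

test_that("vectorized detection equals the exhaustive double-loop oracle on random frames", {
  set.seed(51)
  params <- analysis_parameters()
  s <- build_ideal_helix(8)
  topo <- build_topology(s)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  for (rep in 1:50) {
    frame <- base + matrix(stats::rnorm(length(base), sd = 1.5), nrow(base), 3)
    det <- detect_frame_hbonds(frame, topo, params)
    orc <- oracle_frame_hbonds(frame, topo, params)
    expect_equal(det[, c("donor_res", "acceptor_res")],
                 orc, ignore_attr = TRUE)
  }
})

test_that("detection is monotone in the cutoffs", {
  set.seed(61)
  s <- build_ideal_helix(8)
  topo <- build_topology(s)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  for (rep in 1:10) {
    frame <- base + matrix(stats::rnorm(length(base), sd = 1.0), nrow(base), 3)
    tight <- detect_frame_hbonds(frame, topo, analysis_parameters())
    loose <- detect_frame_hbonds(
      frame, topo, analysis_parameters(d_cut = 3.5, theta_min = 100)
    )
    key <- function(d) paste(d$donor_res, d$acceptor_res)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("occupancy counts bonded frames and omits never-bonded pairs", {
  fl <- flicker_spec(n_residues = 9, protected = 5, p_free = 0.5, p_bound = 0.5,
                     p_stable = 1.0, q = 0, F = 40, replicates = 1, seed = 5)
  tr <- simulate_two_state_trajectory(fl, "free", 1)
  topo <- build_topology(tr$structure)
  occ <- occupancy_series(tr, topo)
  expect_equal(occ$F, 40L)
  # scripted pattern check: occupancy equals bonded-frame count / F exactly
  p5 <- occ$pairs[occ$pairs$donor_res == 5, ]
  expect_equal(p5$occupancy, p5$count / 40)
  s5 <- occ$series[["5->1"]]
  expect_equal(sum(s5), p5$count)
  # stable donors bonded in every frame; never-bonded pairs absent
  expect_true(all(occ$pairs$occupancy[occ$pairs$donor_res > 5] == 1))
  expect_false(any(occ$pairs$count == 0))

  # degenerate chains
  fl1 <- flicker_spec(n_residues = 9, protected = 5, p_free = 1, p_bound = 1,
                      p_stable = 1, q = 0.5, F = 25, replicates = 1, seed = 5)
  occ1 <- occupancy_series(simulate_two_state_trajectory(fl1, "free", 1), topo)
  expect_equal(occ1$pairs$occupancy[occ1$pairs$donor_res == 5], 1)
  fl0 <- flicker_spec(n_residues = 9, protected = 5, p_free = 0, p_bound = 0,
                      p_stable = 1, q = 0.5, F = 25, replicates = 1, seed = 5)
  occ0 <- occupancy_series(simulate_two_state_trajectory(fl0, "free", 1), topo)
  expect_false(any(occ0$pairs$donor_res == 5))
  # but the donor still appears (at 0) in the union table
  expect_equal(occ0$donor_union$occupancy[occ0$donor_union$res_index == 5], 0)
})

test_that("replicate aggregation takes unweighted means with absence counted as zero", {
  mk_occ <- function(state, rep_id, occ, donor = 7L, acceptor = 3L, F = 10L) {
    pairs <- if (is.na(occ)) {
      data.frame(donor_res = integer(), acceptor_res = integer(),
                 count = integer(), occupancy = numeric())
    } else {
      data.frame(donor_res = donor, acceptor_res = acceptor,
                 count = as.integer(occ * F), occupancy = occ)
    }
    structure(list(
      pairs = pairs,
      donor_union = data.frame(res_index = donor, count = 0L,
                               occupancy = ifelse(is.na(occ), 0, occ)),
      series = NULL, F = F, state = state, replicate_id = rep_id
    ), class = "hdx_occupancy")
  }
  tab <- aggregate_replicates(list(
    mk_occ("free", 1, 0.2), mk_occ("free", 2, 0.4), mk_occ("free", 3, 0.6),
    mk_occ("bound", 1, 0.9), mk_occ("bound", 2, 0.9), mk_occ("bound", 3, 0.9)
  ))
  expect_equal(tab$pairs$occ_free_mean, 0.4)
  expect_equal(tab$pairs$occ_bound_mean, 0.9)
  expect_equal(tab$pairs$delta, 0.5)

  # bond absent from every free replicate: occupancy 0 there, delta = +0.9
  tab2 <- aggregate_replicates(list(
    mk_occ("free", 1, NA), mk_occ("free", 2, NA), mk_occ("free", 3, NA),
    mk_occ("bound", 1, 0.9), mk_occ("bound", 2, 0.9), mk_occ("bound", 3, 0.9)
  ))
  expect_equal(tab2$pairs$occ_free_mean, 0)
  expect_equal(tab2$pairs$delta, 0.9)

  tab3 <- aggregate_replicates(list(mk_occ("free", 1, 0.3), mk_occ("bound", 1, 0.7)))
  expect_equal(tab3$pairs$occ_free_mean, 0.3)
  expect_equal(tab3$pairs$occ_bound_mean, 0.7)

  expect_error(aggregate_replicates(list(mk_occ("free", 1, 0.3))),
               "replicate per state")
})

test_that("lifetime filter keeps bonds above threshold in at least one state, inclusively", {
  tab <- scripted_table(free_mean = c(0.30, 0.10, 0.40, 0.55),
                        bound_mean = c(0.55, 0.35, 0.00, 0.80))
  tab <- filter_lifetime(tab, analysis_parameters())
  expect_equal(tab$pairs$kept, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("significance requires both the filter and the inclusive 20-point cutoff", {
  tab <- scripted_table(free_mean = c(0.50, 0.50, 0.50, 0.05),
                        bound_mean = c(0.75, 0.69, 0.70, 0.95))
  # deltas: +0.25, +0.19, +0.20, +0.90 (last dropped by filter? no: bound 0.95 kept)
  tab <- significant_changes(filter_lifetime(tab), analysis_parameters())
  expect_equal(tab$pairs$significant, c(TRUE, FALSE, TRUE, TRUE))

  # a dropped row is never significant regardless of its delta
  tab2 <- scripted_table(free_mean = c(0.05), bound_mean = c(0.35))
  tab2 <- significant_changes(filter_lifetime(tab2), analysis_parameters())
  expect_equal(tab2$pairs$kept, FALSE)
  expect_equal(tab2$pairs$significant, FALSE)

  expect_error(significant_changes(scripted_table(0.5, 0.9)),
               "filter_lifetime")
})

test_that("donor map uses union occupancy, imputes sub-threshold donors to zero", {
  fl <- flicker_spec(n_residues = 10, protected = c(6, 8),
                     p_free = 0.45, p_bound = 0.95, p_stable = 1.0,
                     q = 0.5, F = 120, replicates = 2, seed = 17)
  trajs <- list(
    simulate_two_state_trajectory(fl, "free", 1),
    simulate_two_state_trajectory(fl, "free", 2),
    simulate_two_state_trajectory(fl, "bound", 1),
    simulate_two_state_trajectory(fl, "bound", 2)
  )
  topo <- build_topology(trajs[[1]]$structure)
  tab <- differential_hbonds(trajs[1:2], trajs[3:4], topo)
  dmap <- donor_residue_map(tab, topo)
  # every topology donor is present
  expect_setequal(names(dmap), as.character(2:10))
  # donors 2-4 have no acceptor partner at all: imputed 0
  expect_true(all(dmap[c("2", "3", "4")] == 0))
  # stable donors: delta 0; protected donors: positive shift
  expect_true(all(abs(dmap[c("5", "7", "9", "10")]) < 1e-12))
  expect_true(all(dmap[c("6", "8")] > 0.2))
})

test_that("union occupancy counts frames bonded to any acceptor (acceptor swap)", {
  # scripted geometry: donor 6 bonded to O2 in frames 1-10 and O3 in frames 11-20
  s <- build_ideal_helix(10)
  atoms <- s$atoms
  base <- as.matrix(atoms[, c("x", "y", "z")])
  h6 <- which(atoms$res_index == 6 & atoms$name == "H")
  o2 <- which(atoms$res_index == 2 & atoms$name == "O")
  o3 <- which(atoms$res_index == 3 & atoms$name == "O")
  n6 <- which(atoms$res_index == 6 & atoms$name == "N")
  # move both candidate acceptors far away, then re-bond one per frame block
  far <- function(m, idx) {m[idx, ] <- m[idx, ] + c(0, 0, 50); m}
  frames <- array(NA_real_, dim = c(20, nrow(base), 3))
  bonded_pos <- base[h6, ] + 2.0 * (base[h6, ] - base[n6, ]) /
    sqrt(sum((base[h6, ] - base[n6, ])^2))
  for (f in 1:20) {
    m <- far(far(base, o2), o3)
    idx <- if (f <= 10) o2 else o3
    m[idx, ] <- bonded_pos          # collinear N-H-O at 2.0 A
    frames[f, , ] <- m
  }
  # silence the other donors' bonds: only look at donor 6
  traj <- hdxmd:::new_trajectory(frames, s, "free", 1L)
  occ <- occupancy_series(traj, build_topology(s))
  u6 <- occ$donor_union$occupancy[occ$donor_union$res_index == 6]
  expect_equal(u6, 1.0)
  per_pair <- occ$pairs$occupancy[occ$pairs$donor_res == 6]
  expect_equal(sort(per_pair), c(0.5, 0.5))
  # union occupancy >= per-pair maximum
  expect_true(u6 >= max(per_pair))
})

test_that("per-pair donor map variant reports the largest kept shift", {
  tab <- scripted_table(free_mean = c(0.5, 0.5), bound_mean = c(0.8, 0.9))
  tab$pairs$donor_res <- c(7L, 7L)
  tab$donors <- tab$donors[1, ]
  tab$donors$res_index <- 7L
  tab <- filter_lifetime(tab)
  topo <- list(donors = data.frame(res_index = 7L))
  expect_equal(unname(donor_residue_map(tab, topo, method = "per_pair")["7"]),
               0.4)
})

test_that("occupancies and differentials stay within bounds on random flicker systems", {
  set.seed(71)
  for (seed in c(3, 9)) {
    fl <- flicker_spec(n_residues = 10, protected = c(6, 7),
                       p_free = runif(1), p_bound = runif(1),
                       p_stable = runif(1, 0.5, 1), q = runif(1, 0, 0.9),
                       F = 60, replicates = 2, seed = seed)
    trajs_f <- lapply(1:2, function(r) simulate_two_state_trajectory(fl, "free", r))
    trajs_b <- lapply(1:2, function(r) simulate_two_state_trajectory(fl, "bound", r))
    topo <- build_topology(trajs_f[[1]]$structure)
    tab <- differential_hbonds(trajs_f, trajs_b, topo)
    expect_true(all(tab$pairs$occ_free_mean >= 0 & tab$pairs$occ_free_mean <= 1))
    expect_true(all(tab$pairs$occ_bound_mean >= 0 & tab$pairs$occ_bound_mean <= 1))
    expect_true(all(abs(tab$pairs$delta) <= 1))
    expect_true(all(tab$pairs$significant[tab$pairs$significant] <=
                      tab$pairs$kept[tab$pairs$significant]))
  }
})

test_that("raising the lifetime threshold never grows the kept set", {
  tab <- scripted_table(free_mean = seq(0, 0.9, by = 0.1),
                        bound_mean = rev(seq(0, 0.9, by = 0.1)))
  kept40 <- filter_lifetime(tab, analysis_parameters(lifetime_min = 0.40))$pairs$kept
  kept60 <- filter_lifetime(tab, analysis_parameters(lifetime_min = 0.60))$pairs$kept
  expect_true(all(kept60 <= kept40))
})

test_that("occupancy CSV is written in deterministic order with all columns", {
  fl <- flicker_spec(n_residues = 8, protected = 5, p_free = 0.4, p_bound = 0.9,
                     F = 30, replicates = 1, seed = 2)
  tf <- simulate_two_state_trajectory(fl, "free", 1)
  tb <- simulate_two_state_trajectory(fl, "bound", 1)
  topo <- build_topology(tf$structure)
  tab <- differential_hbonds(list(tf), list(tb), topo)
  path <- tempfile(fileext = ".csv")
  df <- write_occupancy_csv(tab, path)
  expect_true(file.exists(path))
  expect_true(!is.unsorted(df$donor_res))
  expect_true(all(c("donor_res", "donor_name", "acceptor_res", "acceptor_name",
                    "occ_free_rep1", "occ_bound_rep1", "occ_free_mean",
                    "occ_bound_mean", "delta", "kept", "significant")
                  %in% names(df)))
})
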