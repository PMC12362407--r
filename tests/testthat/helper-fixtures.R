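# Shared fixtures built in code: tiny PDB texts, random frames, and an
# independent scalar H-bond oracle used against the vectorized detector.

pdb_line <- function(name, res_name, res_index, x, y, z, serial = 1L,
                     chain = "A", record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  name4 <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, res_name, chain, res_index, x, y, z, 1, 0,
          element)
}

# Glycine residue with backbone + amide H at given offset
gly_lines <- function(res_index, offset = c(0, 0, 0), serial0 = 0L,
                      with_h = TRUE, res_name = "GLY") {
  at <- list(
    c("N", 0, 0, 0), c("CA", 1.458, 0, 0), c("C", 2.009, 1.42, 0),
    c("O", 1.4, 2.48, 0)
  )
  if (with_h) at <- append(at, list(c("H", -0.55, -0.85, 0)), after = 1L)
  lines <- character(0)
  for (i in seq_along(at)) {
    a <- at[[i]]
    lines <- c(lines, pdb_line(a[1], res_name, res_index,
                               as.numeric(a[2]) + offset[1],
                               as.numeric(a[3]) + offset[2],
                               as.numeric(a[4]) + offset[3],
                               serial = serial0 + i))
  }
  lines
}

# Chain of n residues spaced along x (not physically bonded geometry; used
# where only topology bookkeeping matters)
chain_pdb <- function(res_names, with_h = TRUE) {
  lines <- character(0)
  s <- 0L
  for (i in seq_along(res_names)) {
    h <- with_h && i > 1L && res_names[i] != "PRO"
    lines <- c(lines, gly_lines(i, offset = c(4 * (i - 1), 0, 0), serial0 = s,
                                with_h = h, res_name = res_names[i]))
    s <- s + 4L + h
  }
  lines
}

# Scalar double-loop oracle for frame-level detection
oracle_frame_hbonds <- function(frame, topology, params) {
  don <- topology$donors; acc <- topology$acceptors
  out <- NULL
  for (i in seq_len(nrow(don))) {
    for (j in seq_len(nrow(acc))) {
      if (don$chain[i] == acc$chain[j] && don$res_index[i] == acc$res_index[j]) next
      n <- as.numeric(frame[don$n_idx[i], ])
      h <- as.numeric(frame[don$h_idx[i], ])
      o <- as.numeric(frame[acc$o_idx[j], ])
      d <- sqrt(sum((o - h)^2))
      if (identical(params$distance_endpoint, "heavy")) {
        d <- sqrt(sum((o - n)^2))
      }
      v1 <- n - h; v2 <- o - h
      ang <- acos(max(min(sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2)), 1), -1)) * 180 / pi
      if (d <= params$d_cut && ang >= params$theta_min) {
        out <- rbind(out, data.frame(donor_res = don$res_index[i],
                                     acceptor_res = acc$res_index[j]))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(donor_res = integer(), acceptor_res = integer())
  }
  out[order(out$donor_res, out$acceptor_res), , drop = FALSE]
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# Undeuterated reference envelope for an uptake spec (same sequence/13C)
ref_envelope <- function(up) {
  simulate_deuterated_envelope(
    uptake_spec(up$sequence, rates = rep(0, nchar(up$sequence)),
                f_d2o = up$f_d2o, back_exchange = up$back_exchange,
                in_exchange = 0, p13C = up$p13C, seed = up$seed),
    0, "free"
  )
}

# Hand-built aggregated occupancy table for filter/significance semantics
scripted_table <- function(free_mean, bound_mean) {
  n <- length(free_mean)
  pairs <- data.frame(
    donor_res = seq_len(n) + 4L, acceptor_res = seq_len(n),
    occ_free_rep1 = free_mean, occ_bound_rep1 = bound_mean,
    occ_free_mean = free_mean, occ_bound_mean = bound_mean,
    delta = bound_mean - free_mean, kept = NA, significant = NA
  )
  donors <- data.frame(
    res_index = seq_len(n) + 4L,
    occ_free_rep1 = free_mean, occ_bound_rep1 = bound_mean,
    occ_free_mean = free_mean, occ_bound_mean = bound_mean,
    delta = bound_mean - free_mean
  )
  structure(list(pairs = pairs, donors = donors, R_free = 1L, R_bound = 1L,
                 F = 100L),
            class = "hdx_occupancy_table")
}
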