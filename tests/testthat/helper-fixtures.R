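## Shared fixture builders and independent scalar oracles.  The oracles are
## deliberately written as plain double loops / term-by-term sums so they
## stay independent of the vectorized implementation paths they check.

make_bead_topology <- function(n, chain = "A", resname = "GLY") {
  ffl_topology(data.frame(serial = seq_len(n), name = "CA", element = "C",
                          chain = chain, resno = seq_len(n),
                          resname = resname, stringsAsFactors = FALSE))
}

## brute-force native-contact enumeration (O(N^2) double loop)
oracle_contacts <- function(coords, topology, cutoff, min_seq_sep) {
  at <- topology$atoms
  heavy <- which(toupper(at$element) != "H")
  out <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  for (a in seq_along(heavy)) {
    for (b in seq_along(heavy)) {
      if (b <= a) next
      i <- heavy[a]; j <- heavy[b]
      eligible <- if (at$chain[i] == at$chain[j])
        abs(at$ridx[i] - at$ridx[j]) >= min_seq_sep else TRUE
      if (!eligible) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r <= cutoff) out <- rbind(out, data.frame(i = i, j = j, r0 = r))
    }
  }
  out[order(out$i, out$j), , drop = FALSE]
}

## scalar, per-term Q evaluation
oracle_q <- function(coords, contacts) {
  cc <- contacts$contacts
  tot <- 0
  for (k in seq_len(nrow(cc))) {
    r <- sqrt(sum((coords[cc$i[k], ] - coords[cc$j[k], ])^2))
    tot <- tot + 1 / (1 + exp(contacts$beta_sw * (r - contacts$lambda * cc$r0[k])))
  }
  tot / nrow(cc)
}

## scalar gas-phase energy: term-by-term sum over every interaction
oracle_gas_energy <- function(coords, ff) {
  e <- 0
  for (k in seq_len(nrow(ff$bonds))) {
    r <- sqrt(sum((coords[ff$bonds$i[k], ] - coords[ff$bonds$j[k], ])^2))
    e <- e + 0.5 * ff$bonds$k[k] * (r - ff$bonds$r_eq[k])^2
  }
  for (k in seq_len(nrow(ff$go))) {
    r <- sqrt(sum((coords[ff$go$i[k], ] - coords[ff$go$j[k], ])^2))
    e <- e + ff$go$eps[k] * (5 * (ff$go$r0[k] / r)^12 - 6 * (ff$go$r0[k] / r)^10)
  }
  bonded <- paste(ff$bonds$i, ff$bonds$j)
  n <- ff$n_atoms
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || paste(i, j) %in% bonded) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      qq <- ff$atoms$charge[i] * ff$atoms$charge[j]
      if (qq != 0) e <- e + ff$coulomb_scale * qq / r
      epsij <- sqrt(ff$atoms$eps[i] * ff$atoms$eps[j])
      if (epsij > 0) {
        sij <- 0.5 * (ff$atoms$sigma[i] + ff$atoms$sigma[j])
        e <- e + 4 * epsij * ((sij / r)^12 - (sij / r)^6)
      }
    }
  }
  e
}

## scalar inter-partner direct interaction energy (cross pairs only)
oracle_cross_energy <- function(coords, ff, in_a) {
  e <- 0
  cross <- function(i, j) in_a[i] != in_a[j]
  for (k in seq_len(nrow(ff$go)))
    if (cross(ff$go$i[k], ff$go$j[k])) {
      r <- sqrt(sum((coords[ff$go$i[k], ] - coords[ff$go$j[k], ])^2))
      e <- e + ff$go$eps[k] * (5 * (ff$go$r0[k] / r)^12 - 6 * (ff$go$r0[k] / r)^10)
    }
  bonded <- paste(ff$bonds$i, ff$bonds$j)
  n <- ff$n_atoms
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || !cross(i, j) || paste(i, j) %in% bonded) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    qq <- ff$atoms$charge[i] * ff$atoms$charge[j]
    if (qq != 0) e <- e + ff$coulomb_scale * qq / r
    epsij <- sqrt(ff$atoms$eps[i] * ff$atoms$eps[j])
    if (epsij > 0) {
      sij <- 0.5 * (ff$atoms$sigma[i] + ff$atoms$sigma[j])
      e <- e + 4 * epsij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  e
}

## independent group-by bin means (split + scalar mean per group)
oracle_bin_means <- function(q, f, bin_width) {
  edges <- seq(0, 1, by = bin_width)
  idx <- pmin(findInterval(q, edges), length(edges) - 1L)
  groups <- split(f, idx)
  means <- vapply(groups, function(v) sum(v) / length(v), numeric(1))
  means[order(as.integer(names(means)))]
}

## random rigid-body transform of a coordinate matrix
random_rigid <- function(coords, seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  t(Rz %*% Rx %*% t(coords)) + matrix(runif(3, -20, 20), nrow(coords), 3,
                                      byrow = TRUE)
}
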