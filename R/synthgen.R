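#' Generate a one-bead-per-residue toy chain with a Go force field
#'
#' Deterministic native geometry (ideal helix, hairpin, or custom
#' coordinates), harmonic backbone bonds and attractive Go contacts placed
#' exactly on the native contact pairs at the stated cutoff -- the
#' smallest model in which Q, E_u, and folding/unfolding are all
#' meaningful.  Helix constants: rise 1.5 A, radius 2.3 A, 100 degrees per
#' residue.
#'
#' Note the bead-scale contact convention (default cutoff 6.5 A, minimum
#' sequence separation 3): at one bead per residue no i,i+4 pair sits
#' within the all-atom 4.5 A heavy-atom cutoff, so bead models use a wider
#' one.
#'
#' @param n_residues number of beads (>= 4).
#' @param geometry `"helix"`, `"hairpin"` or `"custom"`.
#' @param coords N x 3 native coordinates for `geometry = "custom"`.
#' @param bond_length backbone bond length, A.
#' @param bond_k bond force constant, kcal/mol/A^2.
#' @param go_eps Go contact well depth, kcal/mol.
#' @param cutoff,min_seq_sep native-contact convention for the Go terms.
#' @param chain chain id.
#' @return list with `topology`, `frame` (native coordinates), `ff`,
#'   and the contact parameters used (`cutoff`, `min_seq_sep`).
#' @export
generate_toy_chain <- function(n_residues, geometry = c("helix", "hairpin",
                                                        "custom"),
                               coords = NULL, bond_length = 3.8,
                               bond_k = 100, go_eps = 1, cutoff = 6.5,
                               min_seq_sep = 3L, chain = "A") {
  geometry <- match.arg(geometry)
  if (n_residues < 4L) stop("toy chain needs at least 4 residues")
  native <- switch(geometry,
    helix = helix_coords(n_residues),
    hairpin = hairpin_coords(n_residues, bond_length),
    custom = {
      if (is.null(coords)) stop("custom geometry needs coords")
      as.matrix(coords)
    })
  if (nrow(native) != n_residues) stop("coords do not match n_residues")
  topology <- ffl_topology(data.frame(
    serial = seq_len(n_residues), name = "CA", element = "C",
    chain = chain, resno = seq_len(n_residues), resname = "GLY",
    stringsAsFactors = FALSE))
  bonds <- data.frame(i = seq_len(n_residues - 1L), j = 2:n_residues,
                      k = bond_k, r_eq = bond_length)
  ## brute-force double loop over eligible bead pairs (the generator's
  ## own enumeration, cross-checked against extract_native_contacts)
  gi <- integer(0); gj <- integer(0); gr <- numeric(0)
  for (i in seq_len(n_residues - 1L)) {
    for (j in (i + 1L):n_residues) {
      if (j - i < min_seq_sep) next
      r <- sqrt(sum((native[i, ] - native[j, ])^2))
      if (r <= cutoff) { gi <- c(gi, i); gj <- c(gj, j); gr <- c(gr, r) }
    }
  }
  go <- if (length(gi)) data.frame(i = gi, j = gj, eps = go_eps, r0 = gr)
        else NULL
  ff <- toy_forcefield(n_residues, bonds = bonds, go = go)
  list(topology = topology, frame = native, ff = ff,
       cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep))
}

helix_coords <- function(n, rise = 1.5, radius = 2.3, twist_deg = 100) {
  ang <- (seq_len(n) - 1L) * twist_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), (seq_len(n) - 1L) * rise)
}

hairpin_coords <- function(n, bond_length = 3.8, strand_gap = 4.6) {
  m <- ceiling(n / 2)
  x1 <- cbind((seq_len(m) - 1L) * bond_length, 0, 0)
  n2 <- n - m
  x2 <- cbind((rev(seq_len(n2)) - 1L) * bond_length, strand_gap, 0)
  rbind(x1, x2)
}

#' Metropolis Monte-Carlo sampling of a toy chain
#'
#' Single-bead random-displacement moves accepted by the Metropolis rule
#' on the gas-phase energy `E_u`.  Identical seeds give bit-identical
#' ensembles; the acceptance rate is recorded in the metadata.
#'
#' @param chain list with `topology`, `frame` (start coordinates) and
#'   `ff`, as returned by [generate_toy_chain()].
#' @param temperature temperature, K.
#' @param n_steps number of attempted moves (>= 1).
#' @param move_size maximum per-axis displacement, A.
#' @param stride snapshot every `stride` moves.
#' @param seed mandatory RNG seed.
#' @return an [ffl_ensemble()]; `metadata$acceptance` holds the
#'   acceptance rate.
#' @export
sample_ensemble <- function(chain, temperature = 300, n_steps = 10000L,
                            move_size = 0.5, stride = 10L, seed) {
  if (missing(seed)) stop("seed is mandatory (no wall-clock seeding)")
  stopifnot(n_steps >= 1L)
  top <- chain$topology; ff <- chain$ff
  x <- validate_frame(chain$frame, top)
  n <- nrow(x)
  beta <- 1 / (kB * temperature)
  ## per-bead term lists
  bond_of <- lapply(seq_len(n), function(i)
    which(ff$bonds$i == i | ff$bonds$j == i))
  go_of <- lapply(seq_len(n), function(i)
    which(ff$go$i == i | ff$go$j == i))
  has_nb <- any(ff$atoms$charge != 0) || any(ff$atoms$eps > 0)
  local_energy <- function(x, i) {
    e <- 0
    bi <- bond_of[[i]]
    if (length(bi)) {
      o <- ifelse(ff$bonds$i[bi] == i, ff$bonds$j[bi], ff$bonds$i[bi])
      r <- sqrt(rowSums((x[rep(i, length(o)), , drop = FALSE] -
                           x[o, , drop = FALSE])^2))
      e <- e + sum(0.5 * ff$bonds$k[bi] * (r - ff$bonds$r_eq[bi])^2)
    }
    gi <- go_of[[i]]
    if (length(gi)) {
      o <- ifelse(ff$go$i[gi] == i, ff$go$j[gi], ff$go$i[gi])
      r <- sqrt(rowSums((x[rep(i, length(o)), , drop = FALSE] -
                           x[o, , drop = FALSE])^2))
      sr <- ff$go$r0[gi] / r
      e <- e + sum(ff$go$eps[gi] * (5 * sr^12 - 6 * sr^10))
    }
    if (has_nb) {
      o <- setdiff(seq_len(n), c(i, unlist(lapply(bond_of[[i]], function(b)
        c(ff$bonds$i[b], ff$bonds$j[b])))))
      if (length(o)) {
        r <- sqrt(rowSums((x[rep(i, length(o)), , drop = FALSE] -
                             x[o, , drop = FALSE])^2))
        qq <- ff$atoms$charge[i] * ff$atoms$charge[o]
        e <- e + sum(ff$coulomb_scale * qq / r)
        epsij <- sqrt(ff$atoms$eps[i] * ff$atoms$eps[o])
        if (any(epsij > 0)) {
          sij <- 0.5 * (ff$atoms$sigma[i] + ff$atoms$sigma[o])
          sr6 <- (sij / r)^6
          e <- e + sum(4 * epsij * (sr6^2 - sr6))
        }
      }
    }
    e
  }
  snapshots <- list()
  acc <- 0L
  with_local_seed(seed, {
    for (step in seq_len(n_steps)) {
      i <- sample.int(n, 1L)
      e_old <- local_energy(x, i)
      x_new <- x
      x_new[i, ] <- x[i, ] + stats::runif(3L, -move_size, move_size)
      e_new <- local_energy(x_new, i)
      if (e_new <= e_old || stats::runif(1L) < exp(-beta * (e_new - e_old))) {
        x <- x_new
        acc <- acc + 1L
      }
      if (step %% stride == 0L) snapshots[[length(snapshots) + 1L]] <- x
      if (step == 10000L && acc == 0L)
        stop("move-size error: zero acceptance over 10000 moves; ",
             "reduce move_size")
    }
  })
  if (!length(snapshots)) snapshots <- list(x)
  ffl_ensemble(top, snapshots, temperature = temperature,
               metadata = list(acceptance = acc / n_steps,
                               n_steps = as.integer(n_steps),
                               move_size = move_size,
                               stride = as.integer(stride),
                               seed = as.integer(seed)))
}

#' Draw (Q, f) samples with a known conditional-mean slope
#'
#' Emulates the statistical structure of a funneled landscape:
#' `f = intercept + slope * Q + eps` with Gaussian noise, Q drawn from a
#' uniform or beta distribution over [0, 1].  Used for parameter-recovery
#' tests of the slope estimator.
#'
#' @param slope true conditional-mean slope, kcal/mol per unit Q.
#' @param noise_sd Gaussian noise standard deviation, kcal/mol.
#' @param n number of samples (>= 2).
#' @param q_dist `"uniform"` or `"beta"`.
#' @param shape1,shape2 beta parameters when `q_dist = "beta"`.
#' @param intercept intercept, kcal/mol.
#' @param seed mandatory RNG seed.
#' @return data.frame `frame` (0-based), `Q`, `f`.
#' @export
generate_slope_samples <- function(slope, noise_sd, n,
                                   q_dist = c("uniform", "beta"),
                                   shape1 = 2, shape2 = 2, intercept = 0,
                                   seed) {
  if (missing(seed)) stop("seed is mandatory (no wall-clock seeding)")
  q_dist <- match.arg(q_dist)
  stopifnot(n >= 2L, noise_sd >= 0)
  with_local_seed(seed, {
    q <- switch(q_dist,
                uniform = stats::runif(n),
                beta = stats::rbeta(n, shape1, shape2))
    f <- intercept + slope * q + stats::rnorm(n, 0, noise_sd)
    data.frame(frame = seq_len(n) - 1L, Q = q, f = f)
  })
}

#' Two-chain complex fixture with a ground-truth interaction ledger
#'
#' Docks two toy helices at a controlled gap, defines an inter-chain
#' interface of Go contacts (native distances as minima) plus optional
#' bead charges, and emits jittered frames together with a per-frame,
#' per-residue ground-truth ledger of every interaction term, computed by
#' plain scalar loops.  The gap is chosen so the partners stay outside
#' the solvation surrogate's finite occlusion range, which makes the
#' ledger exact: `dfint` is the sum of cross-chain Go and Coulomb terms
#' plus the screened-pair solvation cross terms.
#'
#' @param n_a,n_b beads in chains A and B.
#' @param n_interface number of inter-chain Go contacts.
#' @param eps_range range of Go well depths, kcal/mol.
#' @param gap docking gap along x between the chains, A.
#' @param n_frames number of frames.
#' @param jitter_sd per-coordinate Gaussian jitter, A.
#' @param charge magnitude of bead charges (e); `n_charged` beads per
#'   chain get alternating +/- charges (0 for an apolar fixture).
#' @param n_charged charged beads per chain.
#' @param temperature temperature, K.
#' @param seed mandatory RNG seed.
#' @param eps_w,probe surrogate solvation parameters mirrored by the
#'   ledger.
#' @return list with `ensemble`, `partition`, `ff`, and `ledger` (list:
#'   `per_residue` n_frames x n_residues matrix of dfint contributions,
#'   `direct`/`solvation` same shape, `dfint` per-frame totals,
#'   `average` named per-residue means).
#' @export
generate_complex_fixture <- function(n_a = 8L, n_b = 8L, n_interface = 4L,
                                     eps_range = c(0.5, 2), gap = 9,
                                     n_frames = 50L, jitter_sd = 0.3,
                                     charge = 0.3, n_charged = 2L,
                                     temperature = 300, seed,
                                     eps_w = 78.5, probe = 1.4) {
  if (missing(seed)) stop("seed is mandatory (no wall-clock seeding)")
  chain_a <- generate_toy_chain(n_a, "helix", chain = "A")
  chain_b <- generate_toy_chain(n_b, "helix", chain = "B")
  shift <- max(chain_a$frame[, 1]) - min(chain_b$frame[, 1]) + gap
  xb <- sweep(chain_b$frame, 2L, c(shift, 0, 0), "+")
  native <- rbind(chain_a$frame, xb)
  mind <- min(cross_dist(chain_a$frame, xb))
  if (mind < 4) stop("placement error: steric overlap at dock (min ",
                     round(mind, 2), " A)")
  n_tot <- n_a + n_b
  fixture <- with_local_seed(seed, {
    ## interface: unique (residue-of-A, residue-of-B) Go pairs
    pairs <- cbind(sample.int(n_a, n_interface, replace = TRUE),
                   sample.int(n_b, n_interface, replace = TRUE))
    pairs <- unique(pairs)
    go_int <- data.frame(
      i = pairs[, 1L], j = n_a + pairs[, 2L],
      eps = stats::runif(nrow(pairs), eps_range[1L], eps_range[2L]),
      r0 = sqrt(rowSums((native[pairs[, 1L], , drop = FALSE] -
                           native[n_a + pairs[, 2L], , drop = FALSE])^2)))
    q <- numeric(n_tot)
    if (charge > 0 && n_charged > 0L) {
      ca <- sample.int(n_a, min(n_charged, n_a))
      cb <- n_a + sample.int(n_b, min(n_charged, n_b))
      q[ca] <- charge * rep_len(c(1, -1), length(ca))
      q[cb] <- charge * rep_len(c(-1, 1), length(cb))
    }
    jitter <- array(stats::rnorm(n_frames * n_tot * 3L, 0, jitter_sd),
                    dim = c(n_frames, n_tot, 3L))
    list(go_int = go_int, q = q, jitter = jitter)
  })
  ## residue names reflect the bead charges so the default neutral/charged
  ## classification is meaningful (LYS for +, ASP for -)
  atoms <- rbind(chain_a$topology$atoms, chain_b$topology$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resname[fixture$q > 0] <- "LYS"
  atoms$resname[fixture$q < 0] <- "ASP"
  topology <- ffl_topology(atoms[, c("serial", "name", "element", "chain",
                                     "resno", "resname")])
  go_all <- rbind(chain_a$ff$go,
                  transform(chain_b$ff$go, i = i + n_a, j = j + n_a),
                  fixture$go_int)
  bonds_all <- rbind(chain_a$ff$bonds,
                     transform(chain_b$ff$bonds, i = i + n_a, j = j + n_a))
  ff <- toy_forcefield(n_tot, bonds = bonds_all,
                       atoms = data.frame(charge = fixture$q, eps = 0,
                                          sigma = 4, radius = 2),
                       go = go_all)
  frames <- lapply(seq_len(n_frames), function(k)
    native + fixture$jitter[k, , ])
  ensemble <- ffl_ensemble(topology, frames, temperature = temperature,
                           metadata = list(seed = as.integer(seed)))
  partition <- complex_partition("A", "B", folding_partner = "A")
  ledger <- complex_ledger(frames, n_a, n_tot, fixture$go_int, fixture$q,
                           rep(2, n_tot), COULOMB_CONST, eps_w, topology)
  list(ensemble = ensemble, partition = partition, ff = ff,
       ledger = ledger)
}

## Ground-truth per-residue interaction ledger, plain scalar loops.
complex_ledger <- function(frames, n_a, n_tot, go_int, q, R, C, eps_w,
                           topology) {
  keys <- paste(topology$residues$chain, topology$residues$resno, sep = ":")
  nf <- length(frames)
  direct <- matrix(0, nf, length(keys), dimnames = list(NULL, keys))
  solv <- matrix(0, nf, length(keys), dimnames = list(NULL, keys))
  tau <- 1 - 1 / eps_w
  for (k in seq_len(nf)) {
    x <- frames[[k]]
    for (t in seq_len(nrow(go_int))) {
      i <- go_int$i[t]; j <- go_int$j[t]
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      sr <- go_int$r0[t] / r
      e <- go_int$eps[t] * (5 * sr^12 - 6 * sr^10)
      direct[k, i] <- direct[k, i] + e / 2
      direct[k, j] <- direct[k, j] + e / 2
    }
    for (i in seq_len(n_a)) {
      for (j in (n_a + 1L):n_tot) {
        if (q[i] == 0 || q[j] == 0) next
        r <- sqrt(sum((x[i, ] - x[j, ])^2))
        e_c <- C * q[i] * q[j] / r
        direct[k, i] <- direct[k, i] + e_c / 2
        direct[k, j] <- direct[k, j] + e_c / 2
        fgb <- sqrt(r^2 + R[i] * R[j] * exp(-r^2 / (4 * R[i] * R[j])))
        e_s <- -C * tau * q[i] * q[j] / fgb
        solv[k, i] <- solv[k, i] + e_s / 2
        solv[k, j] <- solv[k, j] + e_s / 2
      }
    }
  }
  per_residue <- direct + solv
  list(per_residue = per_residue, direct = direct, solvation = solv,
       dfint = rowSums(per_residue), average = colMeans(per_residue))
}
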