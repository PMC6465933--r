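## Coarse-grained conformer generators: one point scatterer per residue
## (Calpha-like virtual bond 3.8 Å), freely jointed or self-avoiding chains,
## compact globule mimics for folded domains, and tethered chain + domain
## complexes. These are the synthetic stand-ins for experimental conformer
## pools; they make no claim to Ramachandran-level realism.

#' Construct a bead conformer
#'
#' @param xyz numeric matrix, one row per bead, columns x/y/z in Å.
#' @param weights per-bead scattering weights (default 1 per bead, all >= 0).
#' @param label free-text label.
#' @return Object of class `bead_conformer`.
#' @export
bead_conformer <- function(xyz, weights = NULL, label = "") {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) < 1L ||
      any(!is.finite(xyz)))
    stop_invalid("xyz must be a finite numeric matrix with 3 columns and >= 1 row")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  if (length(weights) != nrow(xyz) || any(!is.finite(weights)) ||
      any(weights < 0))
    stop_invalid("weights must be finite, >= 0, one per bead")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(xyz = xyz, weights = as.numeric(weights),
                 label = as.character(label)),
            class = "bead_conformer")
}

#' @export
print.bead_conformer <- function(x, ...) {
  cat(sprintf("Bead conformer%s: %d beads, Rg = %.2f Å\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$xyz), conformer_rg(x)))
  invisible(x)
}

n_beads <- function(conf) nrow(conf$xyz)

#' Radius of gyration of a bead conformer
#'
#' Weight-averaged RMS distance of the beads from their center of mass:
#' \eqn{R_g^2 = \sum_i w_i |x_i - \bar x|^2 / \sum_i w_i}.
#'
#' @param conf a [bead_conformer()].
#' @return Rg in Å.
#' @export
conformer_rg <- function(conf) {
  stopifnot(inherits(conf, "bead_conformer"))
  w <- conf$weights
  if (sum(w) <= 0) stop_invalid("all bead weights are zero")
  com <- colSums(conf$xyz * w) / sum(w)
  d2 <- (conf$xyz[, 1] - com[1])^2 + (conf$xyz[, 2] - com[2])^2 +
    (conf$xyz[, 3] - com[3])^2
  sqrt(sum(w * d2) / sum(w))
}

#' Maximum intramolecular distance of a conformer
#' @param conf a [bead_conformer()].
#' @return Dmax in Å (0 for a single bead).
#' @export
conformer_dmax <- function(conf) {
  stopifnot(inherits(conf, "bead_conformer"))
  if (nrow(conf$xyz) < 2L) return(0)
  max(dist(conf$xyz))
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

## uniform-ish random rotation: random axis, random angle
random_rotation <- function() {
  u <- rnorm(3); u <- u / sqrt(sum(u * u))
  th <- runif(1, 0, 2 * pi)
  c1 <- cos(th); s1 <- sin(th); C <- 1 - c1
  matrix(c(c1 + u[1]^2 * C,        u[1] * u[2] * C - u[3] * s1,
           u[1] * u[3] * C + u[2] * s1,
           u[2] * u[1] * C + u[3] * s1, c1 + u[2]^2 * C,
           u[2] * u[3] * C - u[1] * s1,
           u[3] * u[1] * C - u[2] * s1, u[3] * u[2] * C + u[1] * s1,
           c1 + u[3]^2 * C), 3L, 3L, byrow = TRUE)
}

## pivot-move equilibration of a self-avoiding chain: rotate the tail
## segment about a random interior bead, accept when the hard-sphere
## constraint still holds. Incremental (kinetic) growth alone produces an
## ensemble biased toward compact chains; pivot moves restore uniform
## self-avoiding-walk statistics.
pivot_equilibrate <- function(xyz, min2, n_attempts) {
  n <- nrow(xyz)
  if (n < 4L || n_attempts < 1L) return(xyz)
  for (k in seq_len(n_attempts)) {
    p <- sample(2:(n - 1L), 1L)
    rot <- random_rotation()
    seg <- xyz[(p + 1L):n, , drop = FALSE]
    piv <- xyz[p, ]
    newseg <- sweep(sweep(seg, 2L, piv) %*% t(rot), 2L, piv, `+`)
    head_part <- xyz[seq_len(p - 1L), , drop = FALSE]
    d2 <- outer(rowSums(head_part^2), rowSums(newseg^2), `+`) -
      2 * tcrossprod(head_part, newseg)
    if (min(d2) >= min2) xyz[(p + 1L):n, ] <- newseg
  }
  xyz
}

## grow one chain; self-avoidance (min separation 2*excluded_radius between
## non-bonded beads) by regrowing the failed bead, with limited backtracking
## so dense chains do not stall in dead ends
grow_chain <- function(n, bond_length, excluded_radius, retry_cap) {
  xyz <- matrix(0, n, 3)
  if (n == 1L) return(xyz)
  if (excluded_radius <= 0) {
    steps <- random_unit_vectors(n - 1L) * bond_length
    xyz[-1L, ] <- apply(steps, 2L, cumsum)
    return(xyz)
  }
  min2 <- (2 * excluded_radius)^2
  tries <- 0L; local_fail <- 0L
  i <- 2L
  while (i <= n) {
    u <- rnorm(3); u <- u / sqrt(sum(u * u))
    cand <- xyz[i - 1L, ] + bond_length * u
    ok <- TRUE
    if (i > 2L) {
      j <- seq_len(i - 2L)
      d2 <- (xyz[j, 1L] - cand[1L])^2 + (xyz[j, 2L] - cand[2L])^2 +
        (xyz[j, 3L] - cand[3L])^2
      ok <- all(d2 >= min2)
    }
    if (ok) {
      xyz[i, ] <- cand
      i <- i + 1L
      local_fail <- 0L
    } else {
      tries <- tries + 1L
      local_fail <- local_fail + 1L
      if (local_fail >= 200L) {      # dead end: back out a few beads
        i <- max(2L, i - 5L)
        local_fail <- 0L
      }
      if (tries > retry_cap) {
        acc <- (i - 2L) / (i - 2L + tries)
        stop_generation_failure(sprintf(
          "self-avoiding chain growth exceeded %d retries (acceptance rate %.3g); reduce excluded_radius or n_residues",
          retry_cap, acc))
      }
    }
  }
  xyz
}

#' Generate random-chain conformers
#'
#' Freely jointed chains (`excluded_radius = 0`) or self-avoiding chains
#' (`excluded_radius > 0`: every non-bonded bead pair kept at least
#' `2 * excluded_radius` apart by rejection with regrowth). Consecutive
#' beads are separated by exactly `bond_length`.
#'
#' @param n_residues number of beads per chain (>= 1).
#' @param count number of independent conformers (>= 1).
#' @param bond_length virtual bond length in Å (default 3.8).
#' @param excluded_radius bead hard-sphere radius in Å (default 0; must be
#'   `< bond_length`).
#' @param seed optional integer seed; identical seed and configuration give
#'   bit-identical output.
#' @param retry_cap total per-chain rejection budget (default 1e6).
#' @param pivot_moves number of pivot-move equilibration attempts per
#'   self-avoiding chain (default `n_residues`; ignored for freely jointed
#'   chains). Incremental growth alone under-swells the chain; pivot moves
#'   restore uniform self-avoiding-walk statistics.
#' @return List of `count` [bead_conformer()] objects.
#' @examples
#' chains <- generate_chain(100, count = 5, seed = 1)
#' mean(vapply(chains, conformer_rg, numeric(1)))
#' @export
generate_chain <- function(n_residues, count = 1L, bond_length = 3.8,
                           excluded_radius = 0, seed = NULL,
                           retry_cap = 1e6, pivot_moves = NULL) {
  n_residues <- check_n_residues(n_residues)
  if (!is.numeric(count) || count < 1) stop_invalid("count must be >= 1")
  check_scalar(bond_length, "bond_length")
  if (excluded_radius < 0 || excluded_radius >= bond_length)
    stop_invalid("excluded_radius must satisfy 0 <= excluded_radius < bond_length")
  if (is.null(pivot_moves)) pivot_moves <- n_residues
  with_seed_or_current(seed, {
    lapply(seq_len(count), function(k) {
      xyz <- grow_chain(n_residues, bond_length, excluded_radius, retry_cap)
      if (excluded_radius > 0)
        xyz <- pivot_equilibrate(xyz, (2 * excluded_radius)^2, pivot_moves)
      bead_conformer(xyz, label = sprintf("chain_%d", k))
    })
  })
}

#' Generate a compact globule mimic
#'
#' Beads are sampled uniformly in a ball, then all coordinates rescaled so
#' the realized radius of gyration equals `target_rg` exactly. Emulates a
#' small folded domain at one scatterer per residue.
#'
#' @param n_beads number of beads (>= 10).
#' @param target_rg target radius of gyration in Å.
#' @param seed optional integer seed.
#' @return A [bead_conformer()] with attribute `ball_radius` (Å), the radius
#'   of the rescaled sampling ball.
#' @examples
#' g <- generate_globule(150, 21.1, seed = 1)
#' conformer_rg(g)
#' @export
generate_globule <- function(n_beads, target_rg, seed = NULL) {
  if (!is.numeric(n_beads) || n_beads < 10)
    stop_invalid("n_beads must be >= 10")
  check_scalar(target_rg, "target_rg")
  with_seed_or_current(seed, {
    u <- random_unit_vectors(n_beads)
    r <- runif(n_beads)^(1 / 3)
    xyz <- u * r                     # uniform in the unit ball
    conf <- bead_conformer(xyz, label = "globule")
    scale <- target_rg / conformer_rg(conf)
    conf$xyz <- conf$xyz * scale
    attr(conf, "ball_radius") <- scale
    conf
  })
}

#' Assemble a tethered chain + domain complex
#'
#' Generates one random chain and one globule mimic, then translates the
#' globule so its sampling-ball surface touches the chain bead at
#' `attachment_index`, resampling the contact direction until every
#' chain/domain bead pair is at least `clash_radius` apart.
#'
#' @param n_residues,bond_length,excluded_radius chain configuration, as in
#'   [generate_chain()].
#' @param domain_beads,domain_rg globule configuration, as in
#'   [generate_globule()]; `domain_beads = 0` degenerates to the bare chain.
#' @param attachment_index 1-based chain bead the domain is tethered to.
#' @param clash_radius minimum chain/domain bead separation in Å.
#' @param seed optional integer seed.
#' @param max_attempts resampling budget for clash resolution.
#' @return A [bead_conformer()] containing the chain beads followed by the
#'   domain beads.
#' @export
assemble_complex <- function(n_residues, domain_beads, domain_rg,
                             attachment_index = n_residues,
                             bond_length = 3.8, excluded_radius = 0,
                             clash_radius = 3.0, seed = NULL,
                             max_attempts = 500L) {
  n_residues <- check_n_residues(n_residues)
  if (attachment_index < 1 || attachment_index > n_residues)
    stop_invalid("attachment_index must be in [1, n_residues]")
  with_seed_or_current(seed, {
    chain <- generate_chain(n_residues, 1L, bond_length, excluded_radius)[[1L]]
    if (domain_beads == 0) {
      chain$label <- "complex_chain_only"
      return(chain)
    }
    dom <- generate_globule(domain_beads, domain_rg)
    rad <- attr(dom, "ball_radius")
    anchor <- chain$xyz[attachment_index, ]
    for (attempt in seq_len(max_attempts)) {
      u <- rnorm(3); u <- u / sqrt(sum(u * u))
      center <- anchor + u * rad
      dom_xyz <- sweep(dom$xyz, 2L, colMeans(dom$xyz)) +
        matrix(center, domain_beads, 3L, byrow = TRUE)
      ## min chain-domain separation, excluding the anchor bead itself
      other <- chain$xyz[-attachment_index, , drop = FALSE]
      if (nrow(other) == 0L) break
      dmin <- min(proxy_min_dist(other, dom_xyz))
      if (dmin >= clash_radius) break
      if (attempt == max_attempts)
        stop_generation_failure(
          "could not place domain without clashes within ", max_attempts,
          " attempts; reduce clash_radius")
    }
    bead_conformer(rbind(chain$xyz, dom_xyz),
                   weights = c(chain$weights, dom$weights),
                   label = "complex")
  })
}

## minimum distance from each row of a to the point set b
proxy_min_dist <- function(a, b) {
  ## cross distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Write a conformer as a CA-only PDB file
#'
#' One ATOM record per bead (atom name CA, residue ALA, chain A, residue
#' numbers 1..N); bead weights go to the occupancy column.
#'
#' @param conf a [bead_conformer()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_conformer_pdb <- function(conf, file) {
  stopifnot(inherits(conf, "bead_conformer"))
  n <- n_beads(conf)
  bio3d::write.pdb(file = file, xyz = as.vector(t(conf$xyz)),
                   resno = seq_len(n), resid = rep("ALA", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep("A", n), o = conf$weights,
                   b = rep(0, n))
  invisible(file)
}

#' Read a CA-only PDB file as a bead conformer
#'
#' @param file PDB path; only CA atoms are used, occupancies become weights.
#' @return A [bead_conformer()].
#' @export
read_conformer_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) < 1L) stop_invalid("no CA atoms in ", file)
  bead_conformer(cbind(at$x, at$y, at$z), weights = at$o,
                 label = basename(file))
}

#' Write a conformer pool as PDB files plus a manifest
#'
#' @param pool list of [bead_conformer()] objects.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_pool <- function(pool, dir, prefix = "conf") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%04d.pdb", prefix, seq_along(pool))
  for (i in seq_along(pool))
    write_conformer_pdb(pool[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files,
                         label = vapply(pool, `[[`, "", "label"),
                         n_beads = vapply(pool, n_beads, integer(1)))
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a conformer pool written by [write_pool()]
#' @param dir directory containing `manifest.csv` and the PDB files.
#' @return List of [bead_conformer()] objects.
#' @export
read_pool <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$file, function(f) read_conformer_pdb(file.path(dir, f)))
}
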