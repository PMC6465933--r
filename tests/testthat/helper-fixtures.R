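# shared fixtures, built in code at test time

# analytic form factor of a homogeneous sphere, u = s * R
sphere_form_factor <- function(u) (3 * (sin(u) - u * cos(u)) / u^3)^2

# deterministic bead model of a homogeneous sphere: cubic lattice clipped
# to a ball of radius R, spacing chosen to give ~n_target beads
lattice_ball <- function(R, n_target = 2000) {
  a <- R * (4 * pi / 3 / n_target)^(1 / 3)
  g <- seq(-R, R, by = a)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, ]
  bead_conformer(pts, label = "lattice_ball")
}

# pool of globule mimics with prescribed Rg values
globule_pool_confs <- function(rgs, n_beads = 120, seed0 = 100) {
  lapply(seq_along(rgs), function(i)
    generate_globule(n_beads, rgs[i], seed = seed0 + i))
}

# locations of the two highest modes of a sample (kernel density)
top2_modes <- function(x, bw = 4) {
  d <- stats::density(x, bw = bw)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  if (length(pk) < 2) return(rep(d$x[which.max(d$y)], 2))
  pk <- pk[order(d$y[pk], decreasing = TRUE)][1:2]
  sort(d$x[pk])
}

paper_protocol <- function() titration_protocol()
paper_truth <- function() one_site_params(1, 1.7e-6, -6.2)
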