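#' Boresch orientational restraint
#'
#' Six harmonic restraints between three guest and three host anchor
#' atoms: one distance r, two angles thetaA/thetaB, three dihedrals
#' phiA/phiB/phiC.  Equilibrium angles are in degrees; force constants in
#' kcal/(mol A^2) for the distance and kcal/(mol rad^2) for the angular
#' terms.
#'
#' @param r0 equilibrium distance, Angstrom (> 0)
#' @param thetaA0,thetaB0 equilibrium angles, degrees, strictly inside
#'   (0, 180)
#' @param phiA0,phiB0,phiC0 equilibrium dihedrals, degrees
#' @param k_r distance force constant, kcal/(mol A^2)
#' @param k_thetaA,k_thetaB,k_phiA,k_phiB,k_phiC angular force constants,
#'   kcal/(mol rad^2); all > 0
#' @param anchor_atoms character vector of six atom identifiers (3 guest,
#'   3 host); informational
#' @return an object of class `boresch_restraint`
#' @export
boresch_restraint <- function(r0, thetaA0, thetaB0, phiA0, phiB0, phiC0,
                              k_r, k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC,
                              anchor_atoms = paste0("a", 1:6)) {
  ks <- c(k_r, k_thetaA, k_thetaB, k_phiA, k_phiB, k_phiC)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("all six force constants must be positive and finite")
  if (r0 <= 0) stop("r0 must be > 0")
  if (thetaA0 <= 0 || thetaA0 >= 180 || thetaB0 <= 0 || thetaB0 >= 180)
    stop("thetaA0 and thetaB0 must lie strictly inside (0, 180) degrees; ",
         "at 0/180 the sin(theta0) factor vanishes and the analytical ",
         "restraint formula diverges")
  structure(list(r0 = r0, thetaA0 = thetaA0, thetaB0 = thetaB0,
                 phiA0 = phiA0, phiB0 = phiB0, phiC0 = phiC0,
                 k_r = k_r, k_thetaA = k_thetaA, k_thetaB = k_thetaB,
                 k_phiA = k_phiA, k_phiB = k_phiB, k_phiC = k_phiC,
                 anchor_atoms = anchor_atoms),
            class = "boresch_restraint")
}

#' Analytical standard-state free energy of the Boresch restraints
#'
#' Returns
#'   kT log( 8 pi^2 V0 sqrt(k_r k_thetaA k_thetaB k_phiA k_phiB k_phiC)
#'           / (r0^2 sin(thetaA0) sin(thetaB0) (2 pi kT)^3) ),
#' the free-energy cost of confining a non-interacting guest from the
#' standard-state volume V0 into the six harmonic restraints (positive for
#' stiff restraints).  Sign convention: this value is the solvation-leg
#' restraint term dG_solv_restr entering the double-decoupling cycle with
#' a plus sign in [assemble_cycle()]; the complex-leg restraint release is
#' sampled, not analytical.  Valid in the stiff-spring regime where the
#' angular widths sqrt(kT/K) stay well below the sin(theta) curvature
#' scale (~10 degrees).
#'
#' @param restraint a [boresch_restraint()]
#' @param temperature Kelvin
#' @param standard_volume standard-state volume, Angstrom^3 (default
#'   1660.539, i.e. 1 mol/L)
#' @return kcal/mol
#' @export
boresch_analytical <- function(restraint, temperature = DEFAULT_TEMPERATURE,
                               standard_volume = STANDARD_VOLUME_A3) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  kt <- kT(temperature)
  kprod <- restraint$k_r * restraint$k_thetaA * restraint$k_thetaB *
    restraint$k_phiA * restraint$k_phiB * restraint$k_phiC
  num <- 8 * pi^2 * standard_volume * sqrt(kprod)
  den <- restraint$r0^2 * sin(deg2rad(restraint$thetaA0)) *
    sin(deg2rad(restraint$thetaB0)) * (2 * pi * kt)^3
  kt * log(num / den)
}

#' Restrained-configuration-integral quadrature (oracle)
#'
#' Numerically evaluates the restrained configuration integral
#'   Z = int r^2 e^(-beta U_r) dr * int sin(thetaA) e^(-beta U_A) dthetaA
#'     * int sin(thetaB) e^(-beta U_B) dthetaB * prod_phi int e^(-beta U_phi) dphi
#' (the six harmonic terms are separable, so the 6-D integral factorizes)
#' and returns kT log(8 pi^2 V0 / Z).  Exact up to quadrature error; used
#' as an independent check of [boresch_analytical()], which additionally
#' assumes the stiff-spring limit.
#'
#' @inheritParams boresch_analytical
#' @return kcal/mol
#' @export
boresch_quadrature <- function(restraint, temperature = DEFAULT_TEMPERATURE,
                               standard_volume = STANDARD_VOLUME_A3) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  kt <- kT(temperature)
  beta <- 1 / kt
  gauss <- function(x, x0, k) exp(-beta * k * (x - x0)^2 / 2)
  # integrate over a +/- 12 sigma window (clipped to the physical domain)
  # so that adaptive quadrature cannot step over a narrow stiff peak
  win <- function(x0, k, lo, hi) {
    s <- sqrt(kt / k)
    c(max(lo, x0 - 12 * s), min(hi, x0 + 12 * s))
  }
  zr <- {
    w <- win(restraint$r0, restraint$k_r, 0, Inf)
    stats::integrate(function(r) r^2 * gauss(r, restraint$r0, restraint$k_r),
                     w[1], w[2], rel.tol = 1e-12)$value
  }
  zth <- function(th0, k) {
    w <- win(deg2rad(th0), k, 0, pi)
    stats::integrate(function(th) sin(th) * gauss(th, deg2rad(th0), k),
                     w[1], w[2], rel.tol = 1e-12)$value
  }
  zphi <- function(phi0, k) {
    w <- win(deg2rad(phi0), k, deg2rad(phi0) - pi, deg2rad(phi0) + pi)
    stats::integrate(function(phi) gauss(phi, deg2rad(phi0), k),
                     w[1], w[2], rel.tol = 1e-12)$value
  }
  Z <- zr * zth(restraint$thetaA0, restraint$k_thetaA) *
    zth(restraint$thetaB0, restraint$k_thetaB) *
    zphi(restraint$phiA0, restraint$k_phiA) *
    zphi(restraint$phiB0, restraint$k_phiB) *
    zphi(restraint$phiC0, restraint$k_phiC)
  kt * log(8 * pi^2 * standard_volume / Z)
}

#' Restraint coordinate trace
#'
#' Per-frame values of the six restrained degrees of freedom for one
#' candidate restraint set, as recorded over an equilibrium simulation.
#'
#' @param df data.frame with numeric columns r, thetaA, thetaB, phiA,
#'   phiB, phiC (Angstrom / degrees) and >= 2 rows
#' @param id candidate identifier
#' @return an object of classes `restraint_trace` and `data.frame`
#' @export
restraint_trace <- function(df, id = "candidate") {
  need <- c("r", "thetaA", "thetaB", "phiA", "phiB", "phiC")
  if (!all(need %in% names(df)))
    stop("trace needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df) < 2) stop("need >= 2 frames for dispersion statistics")
  if (!all(vapply(df, function(c) all(is.finite(c)), logical(1))))
    stop("trace values must be finite")
  structure(df, class = c("restraint_trace", "data.frame"), id = id)
}

# circular mean of angles in degrees
circ_mean_deg <- function(x) {
  xr <- deg2rad(x)
  wrap180(rad2deg(atan2(mean(sin(xr)), mean(cos(xr)))))
}

# circular standard deviation in degrees; for concentrated data this is
# the sd of deviations wrapped around the circular mean, which matches the
# linear sd away from the wrap point
circ_sd_deg <- function(x) {
  dev <- wrap180(x - circ_mean_deg(x))
  sqrt(mean(dev^2) * length(dev) / (length(dev) - 1))
}

# per-dof dispersion in working units (r in Angstrom, angles in radians);
# dihedrals treated circularly
trace_sds <- function(trace) {
  c(r      = stats::sd(trace$r),
    thetaA = deg2rad(stats::sd(trace$thetaA)),
    thetaB = deg2rad(stats::sd(trace$thetaB)),
    phiA   = deg2rad(circ_sd_deg(trace$phiA)),
    phiB   = deg2rad(circ_sd_deg(trace$phiB)),
    phiC   = deg2rad(circ_sd_deg(trace$phiC)))
}

trace_means <- function(trace) {
  c(r = mean(trace$r), thetaA = mean(trace$thetaA),
    thetaB = mean(trace$thetaB), phiA = circ_mean_deg(trace$phiA),
    phiB = circ_mean_deg(trace$phiB), phiC = circ_mean_deg(trace$phiC))
}

#' Select the stiffest candidate restraint and its reference frame
#'
#' Scores every candidate by the sum of its per-degree-of-freedom standard
#' deviations (distance in Angstrom, angles in radians, dihedrals
#' circular) and picks the candidate with the lowest total dispersion.
#' With `normalize = TRUE` each dof's sd is divided by the mean sd of that
#' dof across candidates before summing, removing scale dominance; both
#' readings of "lowest standard deviation across all values" are exposed
#' because the original selection tool does not document which it uses.
#' The reference frame is the frame of the chosen trace minimizing the
#' Euclidean norm of the z-scored six-vector of deviations from the trace
#' mean.
#'
#' @param candidates list of [restraint_trace()] objects
#' @param normalize normalize per-dof sds across candidates before summing
#' @return list with `chosen_id`, `chosen_index`, `reference_frame`
#'   (row index into the chosen trace) and the per-candidate `scores`
#' @export
select_restraints <- function(candidates, normalize = FALSE) {
  if (length(candidates) == 0) stop("empty candidate list")
  stopifnot(all(vapply(candidates, inherits, logical(1), "restraint_trace")))
  sds <- t(vapply(candidates, trace_sds, numeric(6)))
  if (normalize) {
    ref <- colMeans(sds)
    ref[ref == 0] <- 1
    sds <- sweep(sds, 2, ref, `/`)
  }
  scores <- rowSums(sds)
  best <- which.min(scores)
  tr <- candidates[[best]]
  mu <- trace_means(tr)
  sdv <- trace_sds(tr)
  sdv[sdv == 0] <- 1   # constant dof contributes no distance
  dev <- cbind(
    (tr$r - mu["r"]) / sdv["r"],
    deg2rad(tr$thetaA - mu["thetaA"]) / sdv["thetaA"],
    deg2rad(tr$thetaB - mu["thetaB"]) / sdv["thetaB"],
    deg2rad(wrap180(tr$phiA - mu["phiA"])) / sdv["phiA"],
    deg2rad(wrap180(tr$phiB - mu["phiB"])) / sdv["phiB"],
    deg2rad(wrap180(tr$phiC - mu["phiC"])) / sdv["phiC"])
  d2 <- rowSums(dev^2)
  list(chosen_id = attr(tr, "id"), chosen_index = best,
       reference_frame = which.min(d2), scores = unname(scores))
}

#' Derive harmonic force constants from a restraint trace
#'
#' Equipartition inversion: K_x = kT / var(x) per degree of freedom, with
#' the variance of angular dofs taken in rad^2 and dihedral statistics
#' circular (mean via the resultant vector, variance of wrapped
#' deviations).  Equilibrium values are the trace means.
#'
#' @param trace a [restraint_trace()]
#' @param temperature Kelvin
#' @return a [boresch_restraint()]
#' @export
derive_force_constants <- function(trace, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(trace, "restraint_trace"))
  kt <- kT(temperature)
  sds <- trace_sds(trace)
  if (any(sds == 0))
    stop("constant trace in dof(s) ", paste(names(sds)[sds == 0], collapse = ", "),
         ": variance 0 implies an infinite force constant; refusing to derive")
  mu <- trace_means(trace)
  boresch_restraint(
    r0 = unname(mu["r"]), thetaA0 = unname(mu["thetaA"]),
    thetaB0 = unname(mu["thetaB"]), phiA0 = unname(mu["phiA"]),
    phiB0 = unname(mu["phiB"]), phiC0 = unname(mu["phiC"]),
    k_r = unname(kt / sds["r"]^2),
    k_thetaA = unname(kt / sds["thetaA"]^2),
    k_thetaB = unname(kt / sds["thetaB"]^2),
    k_phiA = unname(kt / sds["phiA"]^2),
    k_phiB = unname(kt / sds["phiB"]^2),
    k_phiC = unname(kt / sds["phiC"]^2))
}

#' Rank atoms by positional stability and pick restraint anchors
#'
#' `rank_stable_atoms()` superposes every frame onto the first, computes
#' each atom's root-mean-square fluctuation about its mean position, and
#' returns the `k` most stable (lowest-RMSF) atom indices -- the guest
#' anchor choice of the restraint-selection procedure.
#' `candidate_host_atoms()` returns the host atoms lying within `cutoff`
#' of any guest anchor in a reference frame, i.e. the pool from which
#' host-side anchor triples are drawn.
#'
#' @param ensemble a [conformer_ensemble()] of the guest (or any species
#'   whose stable atoms are wanted)
#' @param k number of anchors (default 3)
#' @return integer atom indices, most stable first
#' @export
rank_stable_atoms <- function(ensemble, k = 3) {
  stopifnot(inherits(ensemble, "conformer_ensemble"), k >= 1)
  frames <- ensemble$frames
  ref <- sweep(frames[[1]], 2, colMeans(frames[[1]]))
  aligned <- lapply(frames, function(f) {
    f <- sweep(f, 2, colMeans(f))
    s <- svd(crossprod(f, ref))
    d <- sign(det(s$u %*% t(s$v)))
    f %*% (s$u %*% diag(c(1, 1, d)) %*% t(s$v))
  })
  arr <- simplify2array(aligned)                 # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  rmsf <- sqrt(apply((arr - c(mean_pos))^2, 1, mean) * 3)
  order(rmsf)[seq_len(min(k, ensemble$n_atoms))]
}

#' @rdname rank_stable_atoms
#' @param host_frame,guest_frame n x 3 coordinate matrices of one frame
#' @param guest_anchors integer indices into `guest_frame`
#' @param cutoff distance cutoff, Angstrom (default 8)
#' @export
candidate_host_atoms <- function(host_frame, guest_frame, guest_anchors,
                                 cutoff = 8) {
  host_frame <- as.matrix(host_frame)
  anchors <- as.matrix(guest_frame)[guest_anchors, , drop = FALSE]
  near <- apply(host_frame, 1, function(p)
    min(sqrt(colSums((t(anchors) - p)^2))) <= cutoff)
  which(near)
}

#' Thermodynamic-cycle legs of the double-decoupling scheme
#'
#' The four free-energy legs of the absolute-binding cycle: guest
#' decoupling in solution (elec+vdw), the analytical solvation-leg
#' restraint term, guest recoupling in the host complex (elec+vdw), and
#' the sampled complex-leg restraint release.
#'
#' @param dG_solv_elec_vdw,dG_solv_restr,dG_prot_elec_vdw,dG_prot_restr
#'   leg free energies, kcal/mol
#' @param u_solv_elec_vdw,u_solv_restr,u_prot_elec_vdw,u_prot_restr
#'   per-leg uncertainties, kcal/mol (>= 0)
#' @return an object of class `cycle_legs`
#' @export
cycle_legs <- function(dG_solv_elec_vdw, dG_solv_restr,
                       dG_prot_elec_vdw, dG_prot_restr,
                       u_solv_elec_vdw = 0, u_solv_restr = 0,
                       u_prot_elec_vdw = 0, u_prot_restr = 0) {
  vals <- c(dG_solv_elec_vdw, dG_solv_restr, dG_prot_elec_vdw, dG_prot_restr)
  unc <- c(u_solv_elec_vdw, u_solv_restr, u_prot_elec_vdw, u_prot_restr)
  if (!all(is.finite(vals))) stop("leg free energies must be finite")
  if (any(unc < 0)) stop("uncertainties must be >= 0")
  structure(list(dG_solv_elec_vdw = dG_solv_elec_vdw,
                 dG_solv_restr = dG_solv_restr,
                 dG_prot_elec_vdw = dG_prot_elec_vdw,
                 dG_prot_restr = dG_prot_restr,
                 u_solv_elec_vdw = u_solv_elec_vdw,
                 u_solv_restr = u_solv_restr,
                 u_prot_elec_vdw = u_prot_elec_vdw,
                 u_prot_restr = u_prot_restr),
            class = "cycle_legs")
}

#' Assemble the absolute binding free energy from the cycle legs
#'
#' dG_bind = dG_solv^(elec+vdw) + dG_solv^(restr)
#'         - dG_prot^(elec+vdw) - dG_prot^(restr),
#' with the uncertainty propagated as the root sum of squares of the four
#' leg uncertainties.
#'
#' @param legs a [cycle_legs()]
#' @return a `free_energy_estimate` with method `"cycle"`
#' @export
assemble_cycle <- function(legs) {
  stopifnot(inherits(legs, "cycle_legs"))
  value <- legs$dG_solv_elec_vdw + legs$dG_solv_restr -
    legs$dG_prot_elec_vdw - legs$dG_prot_restr
  unc <- sqrt(legs$u_solv_elec_vdw^2 + legs$u_solv_restr^2 +
                legs$u_prot_elec_vdw^2 + legs$u_prot_restr^2)
  new_free_energy_estimate(value, uncertainty = unc, method = "cycle")
}

#' Per-replica binding free-energy estimates
#'
#' @param values replica dG values, kcal/mol
#' @param uncertainties per-replica uncertainties, kcal/mol (>= 0)
#' @param system_label free text
#' @return an object of class `replica_set`
#' @export
replica_set <- function(values, uncertainties, system_label = "") {
  if (length(values) < 1) stop("need >= 1 replica")
  if (length(values) != length(uncertainties))
    stop("values and uncertainties must have equal length")
  if (any(uncertainties < 0)) stop("uncertainties must be >= 0")
  structure(list(values = as.numeric(values),
                 uncertainties = as.numeric(uncertainties),
                 system_label = system_label),
            class = "replica_set")
}

#' Aggregate replica estimates into a reported binding free energy
#'
#' The reported value is the arithmetic mean of the replica values; the
#' reported uncertainty propagates the replica errors as their root sum of
#' squares.  This convention reproduces the published +/- 0.76 kcal/mol
#' for both cyclodextrin systems from the four per-replica errors.
#'
#' @param replicas a [replica_set()]
#' @return a `free_energy_estimate` with method `"replica_mean"`
#' @export
aggregate_replicas <- function(replicas) {
  stopifnot(inherits(replicas, "replica_set"))
  new_free_energy_estimate(mean(replicas$values),
                           uncertainty = sqrt(sum(replicas$uncertainties^2)),
                           method = "replica_mean")
}

#' Serialize / parse a restraint definition as a flat key=value block
#'
#' @param restraint a [boresch_restraint()]
#' @param temperature,standard_volume recorded alongside the geometry
#' @param path optional file; if NULL the text is returned
#' @return character vector of lines (invisibly if written to file)
#' @export
write_restraint <- function(restraint, path = NULL,
                            temperature = DEFAULT_TEMPERATURE,
                            standard_volume = STANDARD_VOLUME_A3) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  num <- restraint[setdiff(names(restraint), "anchor_atoms")]
  lines <- c(
    sprintf("anchor_atoms=%s", paste(restraint$anchor_atoms, collapse = ",")),
    vapply(names(num), function(k) sprintf("%s=%.17g", k, num[[k]]), character(1)),
    sprintf("temperature=%.17g", temperature),
    sprintf("standard_volume=%.17g", standard_volume))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_restraint
#' @param lines_or_path character vector of key=value lines, or a file path
#' @return for `read_restraint`: list with `restraint`, `temperature`,
#'   `standard_volume`
#' @export
read_restraint <- function(lines_or_path) {
  lines <- if (length(lines_or_path) == 1 && file.exists(lines_or_path))
    readLines(lines_or_path) else lines_or_path
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  r <- boresch_restraint(
    r0 = num("r0"), thetaA0 = num("thetaA0"), thetaB0 = num("thetaB0"),
    phiA0 = num("phiA0"), phiB0 = num("phiB0"), phiC0 = num("phiC0"),
    k_r = num("k_r"), k_thetaA = num("k_thetaA"), k_thetaB = num("k_thetaB"),
    k_phiA = num("k_phiA"), k_phiB = num("k_phiB"), k_phiC = num("k_phiC"),
    anchor_atoms = strsplit(vals[["anchor_atoms"]], ",", fixed = TRUE)[[1]])
  list(restraint = r, temperature = num("temperature"),
       standard_volume = num("standard_volume"))
}
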