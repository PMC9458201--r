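#' Synthetic data generators with known ground truth
#'
#' Every estimator in the package can be exercised on data drawn from the
#' exact statistical model it assumes, with the generating parameters kept
#' alongside the data.  Samples are i.i.d. draws from the target laws -- no
#' dynamics are simulated.  Each generator takes an explicit `seed` and
#' restores the caller's RNG state on exit, so equal seeds and parameters
#' give bit-identical output and no global state leaks.
#'
#' @name synthetic-data
NULL

# run `expr` under a local, seeded RNG without disturbing the caller's state
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed == round(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate Crooks-consistent forward/reverse work samples
#'
#' Draws forward works from N(dg_true + beta*sigma_w^2/2, sigma_w^2) and
#' reverse-direction works from N(-dg_true + beta*sigma_w^2/2, sigma_w^2).
#' This pair satisfies the Crooks fluctuation theorem
#' P_F(W)/P_R(-W) = exp(beta*(W - dg_true)) exactly in distribution, so a
#' consistent bidirectional estimator must recover `dg_true`.
#'
#' Reverse works are stored in the reverse-direction convention: they are
#' the work performed along the reverse transition, so that -W_rev is the
#' one-sided (Jarzynski) view of the free-energy difference from the
#' reverse side.
#'
#' @param dg_true ground-truth free-energy difference, kcal/mol
#' @param sigma_w standard deviation of the work distributions, kcal/mol
#'   (>= 0; 0 gives the degenerate reversible limit)
#' @param n_fwd,n_rev number of forward / reverse work values (>= 1)
#' @param temperature Kelvin
#' @param seed integer seed
#' @return a [work_set()] with attribute `ground_truth`
#' @export
gen_crooks_work <- function(dg_true, sigma_w, n_fwd, n_rev,
                            temperature = DEFAULT_TEMPERATURE, seed = 1L) {
  if (sigma_w < 0) stop("sigma_w must be >= 0")
  if (n_fwd < 1 || n_rev < 1) stop("need at least one work value per direction")
  beta <- 1 / kT(temperature)
  shift <- beta * sigma_w^2 / 2
  ws <- with_seed(seed, {
    fwd <- stats::rnorm(n_fwd, mean = dg_true + shift, sd = sigma_w)
    rev <- stats::rnorm(n_rev, mean = -dg_true + shift, sd = sigma_w)
    work_set(fwd, rev, temperature = temperature, label = "synthetic")
  })
  attr(ws, "ground_truth") <- list(dg_true = dg_true, sigma_w = sigma_w,
                                   seed = seed)
  ws
}

#' Generate a 1:1 fluorescence titration series
#'
#' The observed enhancement follows the 1:1 isotherm under the excess-host
#' approximation ([CD]free = [CD]0, valid for a ~25 uM guest titrated with
#' mM host):  dF(c) = dF_c * Kc * c / (1 + Kc * c), plus Gaussian noise on
#' every point except the concentration-zero reference.
#'
#' @param kc_true association constant, 1/M (> 0)
#' @param dF_c intensity difference between free and fully complexed guest
#' @param conc_list host concentrations, M; non-negative, strictly
#'   increasing, first entry 0 (the reference)
#' @param noise_sd Gaussian intensity noise (0 = exact curve)
#' @param f0 reference intensity of the free guest
#' @param guest_conc fixed guest concentration, M (metadata only)
#' @param seed integer seed
#' @return a [titration_series()] with attribute `ground_truth`
#' @export
gen_titration <- function(kc_true, dF_c, conc_list, noise_sd = 0, f0 = 100,
                          guest_conc = 25e-6, seed = 1L) {
  if (kc_true <= 0) stop("kc_true must be > 0")
  if (any(conc_list < 0)) stop("concentrations must be non-negative")
  if (any(diff(conc_list) <= 0)) stop("concentrations must be strictly increasing")
  dF <- dF_c * kc_true * conc_list / (1 + kc_true * conc_list)
  intensity <- f0 + dF
  if (noise_sd > 0) {
    intensity <- with_seed(seed, {
      eps <- stats::rnorm(length(conc_list), sd = noise_sd)
      eps[conc_list == 0] <- 0   # zero point defines the reference exactly
      intensity + eps
    })
  }
  ts <- titration_series(conc_list, intensity, guest_conc = guest_conc)
  attr(ts, "ground_truth") <- list(kc_true = kc_true, dF_c = dF_c, seed = seed)
  ts
}

#' Paper-style host concentration design (0, 0.1 ... 1.0, 2.0, 3.0, 4.0 mM)
#' @return concentrations in M, including the zero reference
#' @export
titration_design_M <- function() {
  c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 2.0, 3.0, 4.0) * 1e-3
}

#' Generate an inversion-recovery series
#'
#' signal(tau) = B + F * exp(-tau * G) with B = m0, F = -2 m0, G = 1/T1:
#' full inversion at tau = 0, recovery to +m0, null at tau = T1 ln 2.
#'
#' @param t1_true longitudinal relaxation time, s (> 0)
#' @param m0 equilibrium magnetization (intensity units)
#' @param delays inversion-recovery delays, s
#' @param noise_sd Gaussian intensity noise
#' @param seed integer seed
#' @return a [decay_series()] of kind "inversion_recovery"
#' @export
gen_inversion_recovery <- function(t1_true, m0 = 1, delays, noise_sd = 0,
                                   seed = 1L) {
  if (t1_true <= 0) stop("t1_true must be > 0")
  sig <- m0 - 2 * m0 * exp(-delays / t1_true)
  if (noise_sd > 0)
    sig <- with_seed(seed, sig + stats::rnorm(length(delays), sd = noise_sd))
  ds <- decay_series(delays, sig, kind = "inversion_recovery")
  attr(ds, "ground_truth") <- list(t1_true = t1_true, m0 = m0, seed = seed)
  ds
}

#' Default inversion-recovery delay list (10 values)
#'
#' Ten delays log-spaced around the expected T1, emulating a variable-delay
#' list chosen to straddle the null point.
#' @param t1_scale s; delays run from t1_scale/50 to 5*t1_scale
#' @export
t1_delay_list <- function(t1_scale = 1.4) {
  exp(seq(log(t1_scale / 50), log(5 * t1_scale), length.out = 10))
}

#' Generate a pulsed-field-gradient (Stejskal-Tanner) attenuation series
#'
#' I(g) = i0 * exp(-d_true * gamma^2 g^2 delta^2 (Delta - delta/3)) with g
#' converted from gauss/cm to T/m.  The pulse-sequence constants delta
#' (gradient pulse length) and Delta (diffusion delay) are generator
#' parameters with documented defaults (2 ms, 100 ms).
#'
#' @param d_true translational diffusion coefficient, m^2/s (>= 0)
#' @param i0 intensity at zero gradient
#' @param gradients gradient strengths, gauss/cm (default 32 values, 0-60)
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 1H)
#' @param delta gradient pulse duration, s
#' @param Delta diffusion delay, s
#' @param noise_sd Gaussian intensity noise
#' @param seed integer seed
#' @return a [decay_series()] of kind "gradient_decay"
#' @export
gen_gradient_decay <- function(d_true, i0 = 1,
                               gradients = seq(0, 60, length.out = 32),
                               gamma = GAMMA_1H, delta = 2e-3, Delta = 100e-3,
                               noise_sd = 0, seed = 1L) {
  if (d_true < 0) stop("d_true must be >= 0")
  g_si <- gradients * 1e-2                       # gauss/cm -> T/m
  expo <- d_true * gamma^2 * g_si^2 * delta^2 * (Delta - delta / 3)
  sig <- i0 * exp(-expo)
  if (noise_sd > 0)
    sig <- with_seed(seed, sig + stats::rnorm(length(gradients), sd = noise_sd))
  ds <- decay_series(gradients, sig, kind = "gradient_decay",
                     gamma = gamma, delta = delta, Delta = Delta)
  attr(ds, "ground_truth") <- list(d_true = d_true, i0 = i0, seed = seed)
  ds
}

#' Generate a toy conformer ensemble with known cluster labels
#'
#' Builds `n_clusters` random rigid templates (coordinates ~ N(0, 3 A), so
#' distinct templates differ in shape, not merely in pose) and emits
#' `frames_per_cluster` frames per template: a random rigid-body rotation
#' and translation of the template plus isotropic Gaussian jitter of scale
#' `spread`.  Superposition RMSD is blind to the rigid motion, so
#' intra-cluster RMSD is O(spread) while inter-cluster RMSD is O(template
#' scale); any cutoff between the two scales recovers the labels.
#'
#' @param n_clusters,frames_per_cluster counts (>= 1)
#' @param spread isotropic jitter scale, Angstrom (>= 0)
#' @param n_atoms atoms per frame (>= 1)
#' @param template_scale sd of template coordinates, Angstrom
#' @param seed integer seed
#' @return a [conformer_ensemble()] with `labels` ground truth
#' @export
gen_toy_ensemble <- function(n_clusters, frames_per_cluster, spread = 0.2,
                             n_atoms = 10, template_scale = 3, seed = 1L) {
  stopifnot(n_clusters >= 1, frames_per_cluster >= 1, n_atoms >= 1, spread >= 0)
  with_seed(seed, {
    frames <- list()
    labels <- integer(0)
    for (k in seq_len(n_clusters)) {
      template <- matrix(stats::rnorm(n_atoms * 3, sd = template_scale),
                         ncol = 3)
      for (f in seq_len(frames_per_cluster)) {
        R <- random_rotation()
        t_vec <- stats::rnorm(3, sd = 10)
        jit <- matrix(stats::rnorm(n_atoms * 3, sd = spread), ncol = 3)
        frames[[length(frames) + 1L]] <-
          sweep((template + jit) %*% R, 2, t_vec, `+`)
        labels <- c(labels, k)
      }
    }
    conformer_ensemble(frames, labels = labels)
  })
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Sample a harmonic restraint coordinate time series
#'
#' Each of the six restrained degrees of freedom is drawn independently
#' from its harmonic Boltzmann law, i.e. a Gaussian centred on the
#' equilibrium value with standard deviation sqrt(kT/K).  Angles are
#' sampled in radians and stored in degrees; dihedrals are wrapped to
#' (-180, 180].  The trace doubles as a Monte-Carlo oracle input for the
#' analytical restraint formula.
#'
#' @param restraint a [boresch_restraint()]
#' @param n_frames number of frames (>= 2)
#' @param temperature Kelvin
#' @param seed integer seed
#' @param id candidate identifier carried on the trace
#' @return a `restraint_trace`: data.frame with columns r, thetaA, thetaB,
#'   phiA, phiB, phiC (Angstrom / degrees) and one row per frame
#' @export
gen_restraint_timeseries <- function(restraint, n_frames,
                                     temperature = DEFAULT_TEMPERATURE,
                                     seed = 1L, id = "candidate") {
  stopifnot(inherits(restraint, "boresch_restraint"), n_frames >= 2)
  kt <- kT(temperature)
  with_seed(seed, {
    draw <- function(mean, k) stats::rnorm(n_frames, mean, sqrt(kt / k))
    tr <- data.frame(
      r      = draw(restraint$r0, restraint$k_r),
      thetaA = rad2deg(draw(deg2rad(restraint$thetaA0), restraint$k_thetaA)),
      thetaB = rad2deg(draw(deg2rad(restraint$thetaB0), restraint$k_thetaB)),
      phiA   = wrap180(rad2deg(draw(deg2rad(restraint$phiA0), restraint$k_phiA))),
      phiB   = wrap180(rad2deg(draw(deg2rad(restraint$phiB0), restraint$k_phiB))),
      phiC   = wrap180(rad2deg(draw(deg2rad(restraint$phiC0), restraint$k_phiC)))
    )
    restraint_trace(tr, id = id)
  })
}

#' Write a generated series as TSV with commented ground-truth header
#'
#' Emits lines of the form `# key=value` (the ground-truth parameters and
#' conventions) followed by a tab-separated table, so a reader can recover
#' both the data and the generating truth.  Reverse works are stored in the
#' reverse-direction convention (see [gen_crooks_work()]); the header says
#' so explicitly.
#'
#' @param x an object produced by one of the generators
#' @param path output file
#' @return `path`, invisibly
#' @export
write_synthetic_tsv <- function(x, path) {
  gt <- attr(x, "ground_truth")
  hdr <- character(0)
  if (!is.null(gt))
    hdr <- vapply(names(gt), function(k)
      sprintf("# %s=%.17g", k, as.numeric(gt[[k]])), character(1))
  if (inherits(x, "work_set")) {
    hdr <- c(hdr, "# reverse_convention=work_along_reverse_transition",
             sprintf("# temperature=%g", x$temperature))
    df <- data.frame(
      direction = c(rep("forward", length(x$forward_works)),
                    rep("reverse", length(x$reverse_works))),
      work_kcal_per_mol = c(x$forward_works, x$reverse_works))
  } else if (inherits(x, "titration_series")) {
    df <- data.frame(concentration_M = x$cd_conc, intensity = x$intensity)
  } else if (inherits(x, "decay_series")) {
    if (x$kind == "gradient_decay")
      hdr <- c(hdr, sprintf("# gamma=%.10g", x$gamma),
               sprintf("# delta=%g", x$delta), sprintf("# Delta=%g", x$Delta))
    df <- data.frame(x = x$x, signal = x$signal)
  } else if (inherits(x, "restraint_trace")) {
    df <- as.data.frame(x)
  } else stop("no TSV writer for class ", paste(class(x), collapse = "/"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_synthetic_tsv()]
#'
#' @param path file path
#' @return list with `data` (data.frame) and `meta` (named list parsed from
#'   the `# key=value` header lines)
#' @export
read_synthetic_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      num <- suppressWarnings(as.numeric(kv[2]))
      meta[[kv[1]]] <- if (is.na(num)) kv[2] else num
    }
  }
  data <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  list(data = data, meta = meta)
}
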