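test_that("pairwise RMSD is a superposition metric", {
  e <- gen_toy_ensemble(1, 3, spread = 0.5, n_atoms = 6, seed = 2)
  m <- pairwise_rmsd(e)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 3))

  # rigid invariance: a frame vs its arbitrary rotation + translation
  set.seed(4)
  for (i in 1:5) {
    f <- matrix(rnorm(30), ncol = 3)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    g <- sweep(f %*% R, 2, runif(3, -20, 20), `+`)
    m2 <- pairwise_rmsd(conformer_ensemble(list(f, g)))
    expect_lt(m2[1, 2], 1e-9)
  }

  # triangle inequality on random small ensembles
  set.seed(9)
  for (i in 1:10) {
    e3 <- conformer_ensemble(lapply(1:3, function(k) matrix(rnorm(15), ncol = 3)))
    m3 <- pairwise_rmsd(e3)
    expect_lte(m3[1, 2], m3[1, 3] + m3[3, 2] + 1e-6)
  }
})

test_that("RMSD after optimal fit matches a rotation-grid oracle", {
  base <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0), ncol = 3, byrow = TRUE)
  shifted <- base
  shifted[1, 1] <- shifted[1, 1] + 1   # +1 Angstrom on one atom's x
  e <- conformer_ensemble(list(base, shifted))
  expect_equal(pairwise_rmsd(e)[1, 2], rmsd_bruteforce(base, shifted),
               tolerance = 1e-5)
  set.seed(14)
  a <- matrix(rnorm(9), ncol = 3)
  b <- matrix(rnorm(9), ncol = 3)
  expect_equal(pairwise_rmsd(conformer_ensemble(list(a, b)))[1, 2],
               rmsd_bruteforce(a, b), tolerance = 1e-5)
})

test_that("gromos clustering matches limits and the brute-force reference", {
  m_small <- random_rmsd_matrix(6, scale = 0.5)
  one <- gromos_cluster(m_small, cutoff = 10)
  expect_length(one, 1)
  expect_identical(one[[1]]$members, 1:6)

  singletons <- gromos_cluster(random_rmsd_matrix(5, scale = 4) + 2 *
                                 (1 - diag(5)), cutoff = 1)
  expect_length(singletons, 5)

  set.seed(42)
  for (i in 1:50) {
    m <- random_rmsd_matrix(12, scale = 2)
    cutoff <- runif(1, 0.3, 1.5)
    got <- gromos_cluster(m, cutoff)
    ref <- gromos_bruteforce(m, cutoff)
    expect_identical(got, ref)
    # partition property: every frame in exactly one cluster
    all_members <- sort(unlist(lapply(got, `[[`, "members")))
    expect_identical(all_members, 1:12)
  }
  expect_error(gromos_cluster(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("clustering recovers toy-ensemble ground truth across seeds", {
  for (s in 1:20) {
    e <- gen_toy_ensemble(3, 8, spread = 0.15, n_atoms = 12, seed = s)
    m <- pairwise_rmsd(e)
    cl <- gromos_cluster(m, cutoff = 1.0)    # between spread and template scale
    expect_length(cl, 3)
    got_labels <- integer(length(e$frames))
    for (k in seq_along(cl)) got_labels[cl[[k]]$members] <- k
    # same partition as ground truth (up to cluster relabelling)
    expect_identical(
      unname(split(seq_along(got_labels), got_labels)[order(sapply(
        split(seq_along(got_labels), got_labels), min))]),
      unname(split(seq_along(e$labels), e$labels)[order(sapply(
        split(seq_along(e$labels), e$labels), min))]))
  }
})

test_that("top_representatives truncates and breaks ties by center index", {
  clusters <- list(list(center = 7L, members = 1:5),
                   list(center = 2L, members = 6:10),
                   list(center = 11L, members = 11:13))
  expect_identical(top_representatives(clusters, 1), 2L)   # size tie: lower center
  expect_identical(top_representatives(clusters, 2), c(2L, 7L))
  expect_identical(top_representatives(clusters, 99), c(2L, 7L, 11L))
  expect_error(top_representatives(clusters, 0), "k must be")
})

test_that("MM/GBSA bookkeeping is exact and closed", {
  mk_row <- function(s, sp, vals)
    data.frame(structure = s, species = sp, vdW = vals[1], Coulomb = vals[2],
               SolvGB = vals[3], Lipo = vals[4], Hbond = vals[5],
               Covalent = vals[6])
  # host and guest all zero: dG equals the complex total
  tab0 <- energy_component_table(rbind(
    mk_row(1, "complex", c(-10, -2, 3, -4, -0.5, 1)),
    mk_row(1, "host", rep(0, 6)), mk_row(1, "guest", rep(0, 6))))
  res0 <- mmgbsa_binding(tab0)
  expect_equal(res0$per_structure$total, -12.5)

  # five synthetic structures with known sums; decomposition closure
  set.seed(3)
  rows <- do.call(rbind, lapply(1:5, function(s) rbind(
    mk_row(s, "complex", round(rnorm(6, -5, 2), 3)),
    mk_row(s, "host", round(rnorm(6, -2, 1), 3)),
    mk_row(s, "guest", round(rnorm(6, -1, 1), 3)))))
  res <- mmgbsa_binding(energy_component_table(rows))
  for (i in 1:5) {
    comp_sum <- sum(res$per_structure[i, MMGBSA <- c("vdW", "Coulomb", "SolvGB",
                                                     "Lipo", "Hbond", "Covalent")])
    expect_equal(res$per_structure$total[i], comp_sum, tolerance = 1e-12)
  }
  summ <- res$summary
  expect_equal(sum(summ$mean[summ$component != "total"]),
               summ$mean[summ$component == "total"], tolerance = 1e-9)
  expect_equal(summ$sd[summ$component == "total"],
               sd(res$per_structure$total), tolerance = 1e-12)

  # identical structures give zero spread
  same <- do.call(rbind, lapply(1:5, function(s) rbind(
    mk_row(s, "complex", c(-10, -2, 3, -4, -0.5, 1)),
    mk_row(s, "host", c(-1, 0, 1, 0, 0, 0)),
    mk_row(s, "guest", c(0, 0, 0.5, 0, 0, 0)))))
  res_same <- mmgbsa_binding(energy_component_table(same))
  expect_true(all(res_same$summary$sd == 0))

  expect_error(energy_component_table(rows[-1, ]), "exactly one")
})

test_that("ensemble and component IO round-trips", {
  e <- gen_toy_ensemble(2, 3, n_atoms = 5, seed = 8)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_tsv(e, tmp)
  back <- read_ensemble_tsv(tmp)
  expect_equal(length(back$frames), 6)
  expect_equal(back$frames[[4]], unname(e$frames[[4]]), tolerance = 1e-6)

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(structure = rep(1, 3),
                   species = c("complex", "host", "guest"),
                   vdW = c(-3, -1, -0.5), Coulomb = c(0, 0, 0),
                   SolvGB = c(1, 0.5, 0.2), Lipo = c(-2, -1, 0),
                   Hbond = c(0, 0, 0), Covalent = c(0.1, 0, 0))
  write.csv(df, csv, row.names = FALSE)
  expect_s3_class(read_components_csv(csv), "energy_component_table")
})
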