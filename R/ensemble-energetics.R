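#' Conformer ensemble container
#'
#' A list of atom-coordinate frames (n_atoms x 3 matrices, Angstrom) with
#' a constant atom count, optionally carrying ground-truth cluster labels.
#'
#' @param frames list of numeric matrices, each n_atoms x 3
#' @param labels optional integer vector of ground-truth labels
#' @return an object of class `conformer_ensemble`
#' @export
conformer_ensemble <- function(frames, labels = NULL) {
  if (length(frames) < 1) stop("need >= 1 frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3) stop("frames must be n_atoms x 3 matrices")
    if (!all(is.finite(f))) stop("coordinates must be finite")
    f
  })
  n_atoms <- nrow(frames[[1]])
  if (n_atoms < 1) stop("need >= 1 atom")
  if (!all(vapply(frames, nrow, integer(1)) == n_atoms))
    stop("atom count must be constant across frames")
  if (!is.null(labels) && length(labels) != length(frames))
    stop("labels length must match frame count")
  structure(list(frames = frames, labels = labels, n_atoms = n_atoms),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames x %d atoms%s\n",
              length(x$frames), x$n_atoms,
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

# minimal least-squares superposition RMSD (Kabsch via SVD), both frames
# centred first; rotation constrained to det +1
superpose_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))     # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((b %*% rot - a)^2) / nrow(a))
}

#' Pairwise superposition RMSD matrix
#'
#' Every entry is the minimal RMSD between two frames after centering and
#' optimal rotation (Kabsch).  Symmetric with zero diagonal; invariant to
#' rigid-body motion of either frame.
#'
#' @param ensemble a [conformer_ensemble()]
#' @param atoms optional integer vector selecting the atoms entering the
#'   RMSD (e.g. the host heavy atoms); default all
#' @return n x n numeric matrix, Angstrom
#' @export
pairwise_rmsd <- function(ensemble, atoms = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  frames <- ensemble$frames
  if (!is.null(atoms)) frames <- lapply(frames, function(f) f[atoms, , drop = FALSE])
  n <- length(frames)
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- superpose_rmsd(frames[[i]], frames[[j]])
    }
  }
  m
}

#' Greedy neighbor-count (gromos/Daura) clustering
#'
#' Iteratively: count, for every unassigned frame, its unassigned
#' neighbors within `cutoff`; the frame with the most neighbors becomes a
#' cluster center and it plus its neighbors are removed; repeat until no
#' frame remains.  Ties in neighbor count are broken by the lower frame
#' index.  Clusters are returned ordered by decreasing size (size ties by
#' lower center index).
#'
#' @param rmsd_matrix symmetric non-negative matrix with zero diagonal
#' @param cutoff neighbor cutoff, same units as the matrix
#' @return list of clusters, each a list with `center` (frame index) and
#'   `members` (sorted frame indices, center included)
#' @export
gromos_cluster <- function(rmsd_matrix, cutoff) {
  m <- as.matrix(rmsd_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("rmsd_matrix must be square and symmetric")
  if (any(m < 0) || any(abs(diag(m)) > 1e-12))
    stop("rmsd_matrix must be non-negative with zero diagonal")
  n <- nrow(m)
  active <- rep(TRUE, n)
  clusters <- list()
  adj <- m <= cutoff          # includes self
  while (any(active)) {
    idx <- which(active)
    counts <- colSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]          # which.max: lowest index wins ties
    members <- idx[adj[center, idx]]
    clusters[[length(clusters) + 1L]] <- list(center = center,
                                              members = sort(members))
    active[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  clusters[order(-sizes, centers)]
}

#' Centers of the k most populated clusters
#'
#' @param clusters output of [gromos_cluster()] (already size-ordered;
#'   re-sorted here defensively with the same tie-break)
#' @param k number of representatives wanted; if fewer clusters exist, all
#'   centers are returned without padding
#' @return integer vector of center frame indices
#' @export
top_representatives <- function(clusters, k) {
  if (k < 1) stop("k must be >= 1")
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  ord <- order(-sizes, centers)
  centers[ord][seq_len(min(k, length(clusters)))]
}

MMGBSA_COMPONENTS <- c("vdW", "Coulomb", "SolvGB", "Lipo", "Hbond", "Covalent")

#' Per-structure MM/GBSA energy-component table
#'
#' One row per representative structure and species, with the six
#' component columns vdW, Coulomb, SolvGB, Lipo, Hbond, Covalent
#' (kcal/mol).  `species` must contain `complex`, `host` and `guest` rows
#' for every `structure` id.
#'
#' @param df data.frame with columns `structure`, `species` and the six
#'   component columns
#' @return an object of classes `energy_component_table` / `data.frame`
#' @export
energy_component_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("structure", "species", MMGBSA_COMPONENTS)
  if (!all(need %in% names(df)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$species %in% c("complex", "host", "guest")))
    stop("species must be one of complex/host/guest")
  for (s in unique(df$structure)) {
    sp <- df$species[df$structure == s]
    if (!setequal(sp, c("complex", "host", "guest")) || length(sp) != 3)
      stop("structure ", s, " must have exactly one complex, host and guest row")
  }
  if (!all(vapply(df[MMGBSA_COMPONENTS], function(c) all(is.finite(c)),
                  logical(1))))
    stop("component energies must be finite")
  structure(df[need], class = c("energy_component_table", "data.frame"))
}

#' MM/GBSA binding free energy with component decomposition
#'
#' Per structure, each binding component is Delta = complex - host - guest
#' and the binding free energy is the sum of the six components
#' (dG_bind = G_complex - G_host - G_guest).  The summary reports the mean
#' and sample (n-1) standard deviation over structures, per component and
#' for the total; by construction the component means sum exactly to the
#' mean total.
#'
#' @param components an [energy_component_table()]
#' @return list with `per_structure` (data.frame of Delta components and
#'   `total` per structure) and `summary` (data.frame with `mean` and `sd`
#'   rows named by component plus `total`)
#' @export
mmgbsa_binding <- function(components) {
  stopifnot(inherits(components, "energy_component_table"))
  ids <- unique(components$structure)
  rows <- lapply(ids, function(s) {
    sub <- components[components$structure == s, ]
    g <- function(sp) unlist(sub[sub$species == sp, MMGBSA_COMPONENTS])
    d <- g("complex") - g("host") - g("guest")
    c(d, total = sum(d))
  })
  per <- as.data.frame(do.call(rbind, rows))
  per <- cbind(structure = ids, per)
  cols <- c(MMGBSA_COMPONENTS, "total")
  summ <- data.frame(
    component = cols,
    mean = vapply(cols, function(c) mean(per[[c]]), numeric(1)),
    sd = vapply(cols, function(c)
      if (nrow(per) > 1) stats::sd(per[[c]]) else 0, numeric(1)),
    row.names = NULL)
  list(per_structure = per, summary = summ)
}

#' Read / write frame coordinates as plain xyz-per-frame TSV
#'
#' Columns `frame`, `atom`, `x`, `y`, `z`; one row per atom per frame.
#'
#' @param ensemble a [conformer_ensemble()]
#' @param path file path
#' @return `path` / a `conformer_ensemble`
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  rows <- do.call(rbind, lapply(seq_along(ensemble$frames), function(i) {
    f <- ensemble$frames[[i]]
    data.frame(frame = i, atom = seq_len(nrow(f)),
               x = f[, 1], y = f[, 2], z = f[, 3])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  frames <- lapply(split(df, df$frame), function(d) {
    d <- d[order(d$atom), ]
    m <- as.matrix(d[c("x", "y", "z")])
    dimnames(m) <- NULL
    m
  })
  conformer_ensemble(unname(frames))
}

#' Read an MM/GBSA component table from CSV
#'
#' Expects the columns of [energy_component_table()].
#' @param path CSV file
#' @return an `energy_component_table`
#' @export
read_components_csv <- function(path) {
  energy_component_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
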