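# Kernel utilization distributions on a planar 500-m grid, Bhattacharyya
# overlap, track-level randomization inference, and FDR control.

#' Reference bandwidth (href)
#'
#' `href = sqrt((var_x + var_y) / 2) * n^(-1/6)` for planar points, the
#' ad-hoc Gaussian reference bandwidth commonly used for kernel home
#' ranges.
#'
#' @param x,y Point coordinates (km).
#' @return Bandwidth in km.
#' @export
href_bandwidth <- function(x, y) {
  n <- length(x)
  sqrt((stats::var(x) + stats::var(y)) / 2) * n^(-1 / 6)
}

# Shared grid covering a set of points, padded by pad_km, cells cell_m
# metres, origin snapped to the cell size.
make_grid <- function(x, y, cell_m, pad_km) {
  cell <- cell_m / 1000
  x0 <- floor((min(x) - pad_km) / cell) * cell
  y0 <- floor((min(y) - pad_km) / cell) * cell
  nx <- ceiling((max(x) + pad_km - x0) / cell)
  ny <- ceiling((max(y) + pad_km - y0) / cell)
  list(x = x0 + cell * (seq_len(nx) - 0.5),
       y = y0 + cell * (seq_len(ny) - 0.5),
       origin = c(x0, y0), cell_m = cell_m)
}

#' Estimate a kernel utilization distribution
#'
#' Gaussian product-kernel density of planar points evaluated at the
#' centres of a square grid (default 500-m cells) padded by three
#' bandwidths, normalized to sum to one.
#'
#' @param x,y Point coordinates in km (e.g. from [project_local()]).
#' @param cell_m Grid cell size in metres.
#' @param h_km Bandwidth in km; default [href_bandwidth()] of the points.
#' @param grid Optional grid from a paired comparison; when supplied, the
#'   density is evaluated on it (so two UDs share cells).
#' @return A `ud_grid` object: `gx`, `gy` (cell-centre coordinates),
#'   `density` (matrix, rows follow `gx`), `h_km`, `n`, `cell_m`,
#'   `origin`.
#' @export
estimate_ud <- function(x, y, cell_m = 500, h_km = NULL, grid = NULL) {
  if (length(x) < 5) stop("need at least 5 points for a UD")
  if (stats::var(x) + stats::var(y) == 0)
    stop("all points identical: zero variance")
  if (is.null(h_km)) h_km <- href_bandwidth(x, y)
  if (is.null(grid)) grid <- make_grid(x, y, cell_m, 3 * h_km)
  kx <- stats::dnorm(outer(grid$x, x, "-") / h_km)
  ky <- stats::dnorm(outer(grid$y, y, "-") / h_km)
  dens <- kx %*% t(ky)
  dens <- dens / sum(dens)
  structure(list(gx = grid$x, gy = grid$y, density = dens,
                 h_km = h_km, n = length(x), cell_m = grid$cell_m,
                 origin = grid$origin),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("UD grid: %d x %d cells of %g m, h = %.3f km, n = %d\n",
              length(x$gx), length(x$gy), x$cell_m, x$h_km, x$n))
  invisible(x)
}

#' Highest-density mask at a utilization level
#'
#' The smallest set of highest-density cells whose cumulative mass
#' reaches `level` (0.5 = core area, 0.95 = general use area).
#'
#' @param ud A `ud_grid`.
#' @param level Utilization level in (0, 1).
#' @return Logical matrix the shape of `ud$density`.
#' @export
ud_level_mask <- function(ud, level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  d <- as.numeric(ud$density)
  ord <- order(d, decreasing = TRUE)
  cum <- cumsum(d[ord])
  ncells <- which(cum >= level)[1]
  mask <- logical(length(d))
  mask[ord[seq_len(ncells)]] <- TRUE
  matrix(mask, nrow = nrow(ud$density))
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' `BA = sum over cells of sqrt(p1 * p2)`, between 0 (no overlap) and 1
#' (identical distributions). The two UDs must live on the same grid;
#' mismatched grids are an error, never silently resampled.
#'
#' @param ud1,ud2 `ud_grid` objects on identical grids.
#' @return BA in `[0, 1]`.
#' @export
bhattacharyya <- function(ud1, ud2) {
  if (length(ud1$gx) != length(ud2$gx) ||
      length(ud1$gy) != length(ud2$gy) ||
      any(ud1$origin != ud2$origin) || ud1$cell_m != ud2$cell_m)
    stop("mismatched UD grids; refuse to compare")
  sum(sqrt(ud1$density * ud2$density))
}

# Pairwise BA for two groups of tracks on a shared grid, with
# h = min(href of each group).
pair_ba <- function(tracks, labels, pair, cell_m) {
  a <- which(labels == pair[1]); b <- which(labels == pair[2])
  xa <- unlist(lapply(tracks[a], `[[`, "x"))
  ya <- unlist(lapply(tracks[a], `[[`, "y"))
  xb <- unlist(lapply(tracks[b], `[[`, "x"))
  yb <- unlist(lapply(tracks[b], `[[`, "y"))
  h <- min(href_bandwidth(xa, ya), href_bandwidth(xb, yb))
  grid <- make_grid(c(xa, xb), c(ya, yb), cell_m, 3 * h)
  ba <- bhattacharyya(
    estimate_ud(xa, ya, cell_m, h_km = h, grid = grid),
    estimate_ud(xb, yb, cell_m, h_km = h, grid = grid))
  ba
}

# Unnormalized kernel-sum contribution of one track on a fixed grid.
.track_kernel <- function(track, grid, h) {
  kx <- stats::dnorm(outer(grid$x, track$x, "-") / h)
  ky <- stats::dnorm(outer(grid$y, track$y, "-") / h)
  kx %*% t(ky)
}

# BA between the normalized sums of two sets of precomputed kernels.
.kernel_ba <- function(kernels, ia, ib) {
  da <- Reduce(`+`, kernels[ia]); db <- Reduce(`+`, kernels[ib])
  sum(sqrt((da / sum(da)) * (db / sum(db))))
}

#' Randomization test of spatial segregation between two groups
#'
#' The observed Bhattacharyya affinity between the two groups' searching
#' UDs is compared with a null distribution obtained by randomly
#' reassigning whole tracks to groups (preserving group sizes). The
#' p-value is the proportion of null overlaps smaller than the observed
#' overlap (low overlap = segregation); `conservative = TRUE` uses
#' `(b + 1) / (n + 1)` instead.
#'
#' @param tracks_by_group Named list (one element per group) of lists of
#'   tracks; each track is a list with numeric `x`, `y` (km). All of a
#'   track's points move together under relabelling.
#' @param pair Character vector of two group names.
#' @param n_perm Number of permutations (published default 1000).
#' @param seed Integer seed, recorded on the result.
#' @param cell_m Grid cell size in metres.
#' @param conservative Use the (b+1)/(n+1) p-value.
#' @return An `overlap_result` list: `pair`, `ba_obs`, `null_ba`, `p`,
#'   `n_perm`, `seed`.
#' @export
randomization_test <- function(tracks_by_group, pair, n_perm = 1000,
                               seed = 1L, cell_m = 500,
                               conservative = FALSE) {
  if (!all(pair %in% names(tracks_by_group)))
    stop("pair must name two groups present in tracks_by_group")
  g1 <- tracks_by_group[[pair[1]]]; g2 <- tracks_by_group[[pair[2]]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 tracks")
  tracks <- c(g1, g2)
  labels <- rep(pair, c(length(g1), length(g2)))
  # bandwidth (min href of the observed groups) and the shared grid are
  # computed from the observed comparison and held fixed across
  # permutations; only group membership of whole tracks is shuffled
  xa <- unlist(lapply(g1, `[[`, "x")); ya <- unlist(lapply(g1, `[[`, "y"))
  xb <- unlist(lapply(g2, `[[`, "x")); yb <- unlist(lapply(g2, `[[`, "y"))
  h <- min(href_bandwidth(xa, ya), href_bandwidth(xb, yb))
  grid <- make_grid(c(xa, xb), c(ya, yb), cell_m, 3 * h)
  kernels <- lapply(tracks, .track_kernel, grid = grid, h = h)
  is_a <- labels == pair[1]
  ba_obs <- .kernel_ba(kernels, which(is_a), which(!is_a))
  set.seed(as.integer(seed))
  null_ba <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(is_a)
    .kernel_ba(kernels, which(perm), which(!perm))
  }, numeric(1))
  p <- permutation_pvalue(null_ba, ba_obs, conservative)
  structure(list(pair = pair, ba_obs = ba_obs, null_ba = null_ba,
                 p = p, n_perm = n_perm, seed = seed),
            class = "overlap_result")
}

#' Randomization p-value from a null distribution
#'
#' Proportion of null statistics smaller than the observed value (low
#' overlap indicates segregation). `conservative = TRUE` applies the
#' `(b + 1) / (n + 1)` correction.
#'
#' @param null_values Numeric null statistics.
#' @param observed Observed statistic.
#' @param conservative Apply the +1 correction.
#' @return p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(null_values, observed,
                               conservative = FALSE) {
  n <- length(null_values)
  b <- sum(null_values < observed)
  if (conservative) (b + 1) / (n + 1) else b / n
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("%s vs %s: BA = %.3f, p = %.4f (%d permutations)\n",
              x$pair[1], x$pair[2], x$ba_obs, x$p, x$n_perm))
  invisible(x)
}

#' Assign birds to age groups
#'
#' Young 4-9, MiddleAge 11-16, Old 17-20, Oldest 21-25; age 10 falls in
#' no group and returns `NA` (such birds are excluded from spatial
#' analyses with a logged count).
#'
#' @param age Numeric ages.
#' @return Factor with the four group levels (NA outside all groups).
#' @export
age_group <- function(age) {
  g <- rep(NA_character_, length(age))
  g[age >= 4 & age <= 9] <- "Young"
  g[age >= 11 & age <= 16] <- "MiddleAge"
  g[age >= 17 & age <= 20] <- "Old"
  g[age >= 21 & age <= 25] <- "Oldest"
  factor(g, levels = c("Young", "MiddleAge", "Old", "Oldest"))
}

#' All pairwise group comparisons
#'
#' @param groups Character vector of group names (default the four age
#'   groups, giving 6 pairs).
#' @return A two-column character matrix, one row per unordered pair.
#' @export
group_pairs <- function(groups = levels(age_group(numeric(0)))) {
  t(utils::combn(groups, 2))
}

#' Benjamini-Hochberg false-discovery-rate decisions
#'
#' Step-up procedure: reject the hypotheses with the `i*` smallest
#' p-values where `i* = max{ i : p(i) <= i q / m }`.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Logical rejection flags aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  ord <- order(pvalues)
  ok <- pvalues[ord] <= seq_len(m) * q / m
  istar <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (istar > 0) rej[ord[seq_len(istar)]] <- TRUE
  rej
}

#' Write a UD as an ESRI ASCII grid
#'
#' @param ud A `ud_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cell_km <- ud$cell_m / 1000
  writeLines(c(
    sprintf("ncols %d", length(ud$gx)),
    sprintf("nrows %d", length(ud$gy)),
    sprintf("xllcorner %.6f", ud$origin[1]),
    sprintf("yllcorner %.6f", ud$origin[2]),
    sprintf("cellsize %.6f", cell_km),
    "NODATA_value -9999"), con)
  # ASCII grids run north to south: write rows from the top y down
  for (j in rev(seq_along(ud$gy))) {
    writeLines(paste(format(ud$density[, j], digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}
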