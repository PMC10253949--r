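# Kernel UDs, Bhattacharyya overlap, randomization inference, FDR.

test_that("reference bandwidth formula", {
  set.seed(1)
  x <- c(scale(rnorm(100))) * 10   # var exactly 100
  y <- c(scale(rnorm(100))) * 10
  expect_equal(href_bandwidth(x, y), 10 * 100^(-1 / 6), tolerance = 1e-9)
})

test_that("UD normalization, consistency, and the kde2d oracle", {
  set.seed(8)
  x <- rnorm(400, 10, 3); y <- rnorm(400, -5, 3)
  ud <- estimate_ud(x, y)
  expect_s3_class(ud, "ud_grid")
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  expect_true(all(ud$density >= 0))

  # UD mean within 3 SE of the generator mean
  mx <- sum(outer(ud$gx, rep(1, length(ud$gy))) * ud$density)
  my <- sum(outer(rep(1, length(ud$gx)), ud$gy) * ud$density)
  se <- 3 / sqrt(400)
  expect_lt(abs(mx - 10), 3 * se + 0.5)  # + half-cell discretisation
  expect_lt(abs(my + 5), 3 * se + 0.5)

  skip_if_not_installed("MASS")
  # MASS::kde2d with bandwidth 4h (its kernel sd is h/4) on my grid
  k2 <- MASS::kde2d(x, y, h = 4 * ud$h_km,
                    n = c(length(ud$gx), length(ud$gy)),
                    lims = c(range(ud$gx), range(ud$gy)))
  expect_equal(ud$density, k2$z / sum(k2$z), tolerance = 1e-6)

  expect_error(estimate_ud(rep(1, 10), rep(2, 10)), "zero variance")
  expect_error(estimate_ud(1:3, 1:3), "at least 5")
})

test_that("level masks are minimal and nested", {
  set.seed(9)
  ud <- estimate_ud(rnorm(200), rnorm(200))
  m50 <- ud_level_mask(ud, 0.5)
  m95 <- ud_level_mask(ud, 0.95)
  expect_true(all(m95[m50]))                       # 50% inside 95%
  expect_gte(sum(ud$density[m95]), 0.95)
  # minimality: dropping the smallest included cell dips below level
  inc <- which(m95)
  low <- inc[which.min(ud$density[inc])]
  expect_lt(sum(ud$density[m95]) - ud$density[low], 0.95)
  expect_error(ud_level_mask(ud, 1.2), "level")

  # uniform density over 100 cells: the 50% mask holds 50 cells
  uni <- structure(list(gx = 1:10, gy = 1:10,
                        density = matrix(1 / 100, 10, 10),
                        origin = c(0, 0), cell_m = 500, h_km = 1, n = 1),
                   class = "ud_grid")
  expect_equal(sum(ud_level_mask(uni, 0.5)), 50)
})

test_that("Bhattacharyya affinity boundary and hand values", {
  set.seed(10)
  ud <- estimate_ud(rnorm(100), rnorm(100))
  expect_equal(bhattacharyya(ud, ud), 1, tolerance = 1e-9)

  mk_ud <- function(dens) structure(
    list(gx = seq_len(nrow(dens)), gy = seq_len(ncol(dens)),
         density = dens, origin = c(0, 0), cell_m = 500, h_km = 1, n = 1),
    class = "ud_grid")
  two1 <- mk_ud(matrix(c(0.8, 0.2), 2, 1))
  two2 <- mk_ud(matrix(c(0.2, 0.8), 2, 1))
  expect_equal(bhattacharyya(two1, two2), 0.8, tolerance = 1e-12)

  disj1 <- mk_ud(matrix(c(1, 0, 0, 0), 2, 2))
  disj2 <- mk_ud(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(bhattacharyya(disj1, disj2), 0)

  # symmetry, bit identical
  expect_identical(bhattacharyya(two1, two2), bhattacharyya(two2, two1))

  other_grid <- mk_ud(matrix(c(0.5, 0.5), 2, 1))
  other_grid$origin <- c(5, 5)
  expect_error(bhattacharyya(two1, other_grid), "mismatched")
})

test_that("permutation p-value counting rule", {
  expect_equal(permutation_pvalue(c(0.35, 0.45, 0.55, 0.65), 0.40), 0.25)
  expect_equal(permutation_pvalue(c(0.5, 0.6), 0.4), 0)
  expect_equal(permutation_pvalue(c(0.5, 0.6), 0.4, conservative = TRUE),
               1 / 3)
})

test_that("randomization test: power, guards, label invariance", {
  set.seed(12)
  far <- list(A = make_point_tracks(5, center = c(0, 0), track_sd = 0.5),
              B = make_point_tracks(5, center = c(100, 0), track_sd = 0.5))
  rt <- randomization_test(far, c("A", "B"), n_perm = 99, seed = 4)
  expect_lte(rt$p, 1 / rt$n_perm)
  expect_lt(rt$ba_obs, 0.01)

  rt_swap <- randomization_test(far, c("B", "A"), n_perm = 99, seed = 4)
  expect_equal(rt_swap$p, rt$p)

  expect_error(randomization_test(list(A = far$A[1], B = far$B),
                                  c("A", "B"), 9, 1), "at least 2")
  expect_error(randomization_test(far, c("A", "C"), 9, 1), "name")
})

test_that("rejection rate does not fall as separation grows", {
  seps <- c(0, 4, 8)
  rates <- vapply(seps, function(sep) {
    ps <- vapply(1:25, function(r) {
      set.seed(1000 * sep + r)
      tg <- list(A = make_point_tracks(6, center = c(0, 0)),
                 B = make_point_tracks(6, center = c(sep, 0)))
      randomization_test(tg, c("A", "B"), n_perm = 79,
                         seed = 17 + r)$p
    }, numeric(1))
    mean(ps <= 0.05)
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / 25)
  expect_true(all(diff(rates) > -se))
})

test_that("age groups and pairwise comparisons", {
  expect_equal(as.character(age_group(c(4, 9, 10, 11, 16, 17, 20, 21,
                                        25, 26))),
               c("Young", "Young", NA, "MiddleAge", "MiddleAge",
                 "Old", "Old", "Oldest", "Oldest", NA))
  pairs <- group_pairs()
  expect_equal(nrow(pairs), 6)
  expect_equal(anyDuplicated(apply(pairs, 1, paste, collapse = "-")), 0L)
})

test_that("Benjamini-Hochberg step-up decisions", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060)
  expect_identical(bh_fdr(p, 0.05), c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                      FALSE))
  expect_identical(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_identical(bh_fdr(rep(0, 6)), rep(TRUE, 6))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  # agreement with the stats::p.adjust oracle on random inputs
  set.seed(33)
  for (r in 1:20) {
    pv <- runif(sample(3:12, 1))
    expect_identical(bh_fdr(pv, 0.05),
                     stats::p.adjust(pv, "BH") <= 0.05)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("ESRI ASCII export round-trips the density", {
  set.seed(40)
  ud <- estimate_ud(rnorm(50), rnorm(50))
  path <- tempfile(fileext = ".asc")
  write_ud_asc(ud, path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols")
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  expect_equal(dim(body), c(length(ud$gy), length(ud$gx)))
  expect_equal(sum(body), 1, tolerance = 1e-5)
})
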