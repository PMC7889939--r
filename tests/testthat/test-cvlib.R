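test_that("nucleosome centers are core-bead centroids in id order", {
  m <- colinear_model()
  expect_equal(nucleosome_centers(m), cbind(0:3, 0, 0),
               ignore_attr = TRUE)
  # two core beads average to their midpoint
  m2 <- bead_model(rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0), c(6, 0, 0),
                         c(7, 0, 0), c(8, 0, 0)),
                   c(1, 1, 2, 3, 4, 4), rep("core", 6))
  expect_equal(nucleosome_centers(m2)[1, ], c(1, 0, 0), ignore_attr = TRUE)
  # flexible beads far away leave centers unchanged
  expect_equal(nucleosome_centers(colinear_model(flexible = TRUE)),
               nucleosome_centers(m))
  # labeled input errors
  expect_error(bead_model(cbind(0:2, 0, 0), c(1, 2, 4), rep("core", 3)),
               "contiguous")
  expect_error(bead_model(cbind(0:1, 0, 0), c(1, 2), c("core", "flexible")),
               "no core beads")
  expect_error(bead_model(cbind(0:1, 0, 0), c(1, 2), c("core", "rigid")),
               "unknown group")
})

test_that("distance vector follows the fixed pair order and is rigid-motion invariant", {
  expect_equal(distance_vector(cbind(0:3, 0, 0)), c(1, 2, 3, 1, 2, 1),
               ignore_attr = TRUE)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(distance_vector(sq), c(1, sqrt(2), 1, 1, sqrt(2), 1),
               ignore_attr = TRUE)
  set.seed(1)
  for (i in 1:5) {
    ctr <- matrix(rnorm(12), 4)
    R <- random_rotation()
    shift <- rnorm(3)
    moved <- sweep(ctr %*% t(R), 2, shift, "+")
    expect_equal(distance_vector(moved), distance_vector(ctr), tolerance = 1e-12)
  }
})

test_that("fraction of native contacts behaves like a Gaussian similarity", {
  d_ref <- c(9, 6, 12, 9, 6, 9)
  expect_equal(fraction_native_contacts(d_ref, d_ref), 1)
  # every component off by exactly sigma
  expect_equal(fraction_native_contacts(d_ref + 2, d_ref, sigma = 2),
               exp(-0.5), tolerance = 1e-12)
  expect_lt(fraction_native_contacts(d_ref + 20, d_ref, sigma = 2), 1e-21)
  # monotone non-increasing as any single deviation grows
  for (j in 1:6) {
    devs <- seq(0, 5, by = 0.5)
    qs <- sapply(devs, function(dd) {
      d <- d_ref; d[j] <- d[j] + dd
      fraction_native_contacts(d, d_ref)
    })
    expect_true(all(diff(qs) <= 1e-14))
  }
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  a <- 1.7
  expect_equal(radius_of_gyration(rbind(c(-a, 0, 0), c(a, 0, 0))), a)
  s <- 2.5  # square corners, side s: Rg = s / sqrt(2)
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radius_of_gyration(sq), s / sqrt(2))
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("reverse_order is the stated involution and symmetric_features is invariant", {
  expect_equal(reverse_order(1:6), c(6, 5, 3, 4, 2, 1), ignore_attr = TRUE)
  expect_equal(symmetric_features(1:6), c(7, 6, 7, 10, 3, 4),
               ignore_attr = TRUE)
  set.seed(2)
  D <- matrix(runif(1000 * 6, 1, 40), ncol = 6)
  for (i in seq_len(20))
    expect_equal(reverse_order(reverse_order(D[i, ])), D[i, ])
  # fixed point: d12 = d34 and d13 = d24
  dfix <- c(3, 4, 7, 8, 4, 3)
  expect_equal(reverse_order(dfix), dfix, ignore_attr = TRUE)
  Srev <- symmetric_features(D[, c(6, 5, 3, 4, 2, 1)])
  expect_equal(symmetric_features(D), Srev, tolerance = 1e-12)
  # (sum, product) reconstructs the unordered pair via the quadratic roots
  for (i in seq_len(50)) {
    s <- D[i, 1] + D[i, 6]; p <- D[i, 1] * D[i, 6]
    roots <- sort(Re(polyroot(c(p, -s, 1))))
    expect_equal(roots, sort(D[i, c(1, 6)]), tolerance = 1e-8)
  }
})

test_that("bead structures round-trip through CSV and PDB", {
  m <- colinear_model(flexible = TRUE)
  csv <- tempfile(fileext = ".csv")
  write_bead_structure(m, csv, "csv")
  m2 <- read_bead_structure(csv, "csv")
  expect_equal(m2$positions, m$positions, ignore_attr = TRUE)
  expect_equal(m2$nucleosome_id, m$nucleosome_id)
  expect_equal(m2$group, m$group)
  # missing group column is a parse error
  df <- read.csv(csv); df$group <- NULL
  bad <- tempfile(fileext = ".csv"); write.csv(df, bad, row.names = FALSE)
  expect_error(read_bead_structure(bad, "csv"), "missing column")
  # unknown group label names the offending line
  df <- read.csv(csv); df$group[3] <- "floppy"
  bad2 <- tempfile(fileext = ".csv"); write.csv(df, bad2, row.names = FALSE)
  expect_error(read_bead_structure(bad2, "csv"), "line 4")
  pdb <- tempfile(fileext = ".pdb")
  write_bead_structure(m, pdb, "pdb")
  m3 <- read_bead_structure(pdb, "pdb")
  expect_equal(m3$positions, m$positions, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m3$nucleosome_id, m$nucleosome_id, ignore_attr = TRUE)
  expect_equal(m3$group, m$group)
})
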