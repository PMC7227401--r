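test_that("reference PCA is self-consistent and variance-ordered", {
  set.seed(13)
  meta <- data.frame(stage = rep(c("E16", "Adult"), each = 20))
  m <- lognorm_em(matrix(rnorm(10 * 40), 10, 40), cell_meta = meta)
  emb <- fit_reference_pca(m)
  expect_equal(embed_cells(emb, m), emb$ref_coords, tolerance = 1e-9)
  expect_gte(var(emb$ref_coords[, 1]), var(emb$ref_coords[, 2]))
  expect_equal(unname(crossprod(emb$loadings)), diag(2), tolerance = 1e-12)

  expect_error(fit_reference_pca(subset_cells(m, 1:2)), ">= 3 cells")
})

test_that("2-gene loadings equal the analytic covariance eigenvectors", {
  set.seed(14)
  z <- matrix(rnorm(2 * 500), 2, 500)
  A <- matrix(c(2, 1.2, 0, 0.8), 2, 2)     # known mixing
  m <- lognorm_em(abs(A %*% z))
  emb <- fit_reference_pca(m)
  ev <- eigen(stats::cov(t(m$values)))$vectors   # closed-form oracle
  for (j in 1:2) {
    dot <- abs(sum(emb$loadings[, j] * ev[, j]))
    expect_equal(dot, 1, tolerance = 1e-9)       # equal up to sign
  }
})

test_that("embedding is passive, linear, and handles empty queries", {
  set.seed(15)
  m <- lognorm_em(matrix(rnorm(8 * 30), 8, 30))
  emb <- fit_reference_pca(m)
  # a query identical to a reference cell inherits its coordinates
  q <- subset_cells(m, 7)
  expect_equal(unname(embed_cells(emb, q)[1, ]),
               unname(emb$ref_coords[7, ]))
  # translation by t in gene space shifts coords by t %*% loadings
  t_vec <- rnorm(8)
  shifted <- m
  shifted$values <- m$values + t_vec
  delta <- embed_cells(emb, shifted) - emb$ref_coords
  expect_equal(delta, matrix(rep(t_vec %*% emb$loadings, each = 30), 30, 2,
                             dimnames = dimnames(delta)), tolerance = 1e-9)
  empty <- subset_cells(m, integer(0))
  expect_equal(nrow(embed_cells(emb, empty)), 0)
})

test_that("arrow geometry matches hand arithmetic", {
  coords <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  emb <- structure(list(ref_coords = coords,
                        stages = c("E16", "E16", "Adult", "Adult")),
                   class = "ReferenceEmbedding")
  arrow <- fit_arrow(emb, "E16", "Adult")
  expect_equal(unname(arrow$direction), c(0.6, 0.8))
  expect_equal(unname(arrow$origin), c(1.5, 2))
  expect_equal(sqrt(sum(arrow$direction^2)), 1)

  flipped <- fit_arrow(emb, "Adult", "E16")
  expect_equal(flipped$direction, -arrow$direction)
  expect_error(fit_arrow(emb, "E18", "Adult"), "embryonic")
})

test_that("pseudotime is the centred dot product and rotation-invariant", {
  arrow <- structure(list(direction = c(1, 0), origin = c(0, 0)),
                     class = "ArrowOfTime")
  coords <- rbind(a = c(2, 1), b = c(0, 0), c = c(-1, 3))
  pt <- pseudotime(arrow, coords)
  expect_equal(pt$pseudotime, c(2, 0, -1))

  # simultaneous rotation of coords and arrow leaves pseudotime unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  arrow_rot <- structure(list(direction = as.vector(R %*% arrow$direction),
                              origin = as.vector(R %*% arrow$origin)),
                         class = "ArrowOfTime")
  pt_rot <- pseudotime(arrow_rot, coords %*% t(R))
  expect_equal(pt_rot$pseudotime, pt$pseudotime, tolerance = 1e-12)
})

test_that("group comparison equals the pooled-variance t-test", {
  set.seed(16)
  pt <- data.frame(cell_id = sprintf("c%02d", 1:40),
                   pseudotime = c(rnorm(22, 0.5), rnorm(18, 0.9)),
                   group = rep(c("NM", "CR"), c(22, 18)))
  res <- compare_groups(pt, ref_group = "NM")
  tt <- t.test(pt$pseudotime[pt$group == "CR"],
               pt$pseudotime[pt$group == "NM"], var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(res$mean_diff,
               mean(pt$pseudotime[pt$group == "CR"]) -
                 mean(pt$pseudotime[pt$group == "NM"]), tolerance = 1e-12)

  # shift invariance
  pt2 <- pt; pt2$pseudotime <- pt$pseudotime + 11.3
  res2 <- compare_groups(pt2, ref_group = "NM")
  expect_equal(res2$mean_diff, res$mean_diff, tolerance = 1e-9)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-9)

  # identically drawn groups: difference within 3 SE of zero
  set.seed(17)
  null_pt <- data.frame(cell_id = sprintf("n%03d", 1:200),
                        pseudotime = rnorm(200),
                        group = rep(c("A", "B"), each = 100))
  nres <- compare_groups(null_pt, ref_group = "A")
  expect_lt(abs(nres$mean_diff), 3 * nres$se)

  singleton <- data.frame(cell_id = c("x", "y", "z"),
                          pseudotime = c(1, 2, 3),
                          group = c("A", "A", "B"))
  expect_error(compare_groups(singleton, ref_group = "A"), "singleton")
})

test_that("gene-pseudotime correlation ranks most-negative first", {
  pt <- data.frame(cell_id = sprintf("c%d", 1:4),
                   pseudotime = c(1, 2, 3, 4), group = NA)
  vals <- rbind(up = c(1, 2, 3, 4),          # r = +1
                down = c(4, 3, 2, 1),        # r = -1
                flat = c(2, 2, 2, 2),        # constant -> 0, flagged
                toy = c(1, 3, 2, 5))
  m <- lognorm_em(vals, genes = rownames(vals), cells = pt$cell_id)
  res <- gene_pseudotime_correlation(m, pt)
  expect_identical(res$gene[1], "down")
  expect_equal(res$correlation[res$gene == "up"], 1)
  expect_equal(res$correlation[res$gene == "down"], -1)
  expect_true(res$constant[res$gene == "flat"])
  expect_equal(res$correlation[res$gene == "flat"], 0)
  # hand-computed Pearson for the toy gene
  x <- c(1, 3, 2, 5); y <- 1:4
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$correlation[res$gene == "toy"], r_hand, tolerance = 1e-12)
  expect_false(is.unsorted(res$correlation))
})
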