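test_that("cosine normalisation yields unit cells and scale invariance", {
  m <- lognorm_em(matrix(c(3, 4, 1, 2, 2, 1), 2, 3))
  cn <- cosine_normalize(m)
  expect_equal(unname(sqrt(colSums(cn$values^2))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(cn$values[, 1]), c(0.6, 0.8))

  scaled <- m
  scaled$values[, 2] <- 5 * m$values[, 2]
  expect_equal(cosine_normalize(scaled)$values, cn$values)

  zero <- lognorm_em(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(cosine_normalize(zero), "all-zero")
})

test_that("mutual pairs match hand-enumerable geometries", {
  # query = exact copy, k = 1: every cell pairs with its duplicate
  set.seed(7)
  m <- lognorm_em(matrix(rnorm(10 * 8), 10, 8))
  p <- find_mnn_pairs(m, m, alignment_params(k = 1))
  expect_equal(pairs_sorted(p$pairs),
               data.frame(ref = 1:8, query = 1:8))

  # 3+3 points on a line: ref at 0,1,2; query at 0.1,1.1,2.1
  ref <- lognorm_em(matrix(c(0, 1, 2), 1, 3))
  qry <- lognorm_em(matrix(c(0.1, 1.1, 2.1), 1, 3))
  p2 <- find_mnn_pairs(ref, qry, alignment_params(k = 1))
  expect_equal(pairs_sorted(p2$pairs),
               data.frame(ref = 1:3, query = 1:3))

  expect_error(find_mnn_pairs(ref, qry, alignment_params(k = 3)),
               "smaller than")
})

test_that("every reported pair is mutual under direct re-checking", {
  set.seed(8)
  ref <- lognorm_em(matrix(rnorm(6 * 40), 6, 40))
  qry <- lognorm_em(matrix(rnorm(6 * 30), 6, 30))
  k <- 4
  p <- find_mnn_pairs(ref, qry, alignment_params(k = k))
  expect_gt(nrow(p$pairs), 0)
  d2 <- outer(colSums(ref$values^2), colSums(qry$values^2), "+") -
    2 * crossprod(ref$values, qry$values)
  for (i in seq_len(nrow(p$pairs))) {
    r <- p$pairs$ref[i]; q <- p$pairs$query[i]
    expect_lte(rank(d2[r, ], ties.method = "first")[q], k)
    expect_lte(rank(d2[, q], ties.method = "first")[r], k)
  }
})

test_that("find_mnn_pairs equals the quadratic brute-force oracle", {
  set.seed(9)
  for (rep in 1:10) {
    nr <- sample(15:40, 1); nq <- sample(15:40, 1)
    ref <- lognorm_em(matrix(rnorm(5 * nr), 5, nr))
    qry <- lognorm_em(matrix(rnorm(5 * nq), 5, nq))
    for (k in c(1, 5)) {
      got <- pairs_sorted(find_mnn_pairs(ref, qry,
                                         alignment_params(k = k))$pairs)
      want <- brute_mnn(ref$values, qry$values, k)
      expect_equal(got, want)
    }
  }
})

test_that("a constant gene-space shift is corrected back exactly", {
  set.seed(10)
  ref <- lognorm_em(matrix(rnorm(20 * 50, sd = 2), 20, 50))
  shift <- rnorm(20, 0.3, 0.1)
  qry <- ref
  qry$values <- ref$values + shift
  colnames(qry$values) <- sprintf("q%03d", 1:50)
  qry$cell_meta <- data.frame(row.names = colnames(qry$values))
  par <- alignment_params(k = 1, sigma = 0.1, cosine_normalize = FALSE)
  p <- find_mnn_pairs(ref, qry, par)
  corrected <- correct_query(ref, qry, p, par)
  expect_lt(mean(abs(corrected$values - ref$values)), 1e-6)
})

test_that("kernel weighting concentrates on a coincident pair", {
  ref <- lognorm_em(matrix(c(5, 5, 0, 0), 2, 2))
  qry <- lognorm_em(matrix(c(4, 4, 4, 4.5), 2, 2))
  pairs <- structure(list(pairs = data.frame(ref = 1, query = 1), k = 1),
                     class = "MNNPairSet")
  out <- correct_query(ref, qry, pairs, alignment_params(k = 1, sigma = 0.05))
  # query cell 1 coincides with the paired query cell: exact difference
  expect_equal(out$values[, 1], ref$values[, 1])

  empty <- structure(list(pairs = data.frame(ref = integer(0),
                                             query = integer(0)), k = 1),
                     class = "MNNPairSet")
  expect_error(correct_query(ref, qry, empty), "increase k")
})

test_that("repeat correction against a matched reference contracts", {
  set.seed(11)
  ref <- lognorm_em(matrix(rnorm(15 * 60, sd = 1.5), 15, 60))
  qry <- lognorm_em(ref$values + matrix(rnorm(15 * 60, sd = 0.4), 15, 60),
                    cells = sprintf("q%03d", 1:60))
  par <- alignment_params(k = 5, sigma = 0.5, cosine_normalize = FALSE)
  c1 <- correct_query(ref, qry, find_mnn_pairs(ref, qry, par), par)
  c2 <- correct_query(ref, c1, find_mnn_pairs(ref, c1, par), par)
  move1 <- mean(abs(c1$values - qry$values))
  move2 <- mean(abs(c2$values - c1$values))
  expect_lt(move2, move1)
})

test_that("project_all is order-invariant and never touches the reference", {
  set.seed(12)
  ref <- lognorm_em(matrix(abs(rnorm(12 * 40)) + 0.1, 12, 40))
  q1 <- lognorm_em(matrix(abs(rnorm(12 * 30)) + 0.1, 12, 30),
                   cells = sprintf("a%03d", 1:30))
  q2 <- lognorm_em(matrix(abs(rnorm(12 * 25)) + 0.1, 12, 25),
                   cells = sprintf("b%03d", 1:25))
  ref_before <- ref$values
  par <- alignment_params(k = 3)
  out12 <- project_all(ref, list(q1 = q1, q2 = q2), par)
  out21 <- project_all(ref, list(q2 = q2, q1 = q1), par)
  expect_identical(out12$corrected$q1$values, out21$corrected$q1$values)
  expect_identical(out12$corrected$q2$values, out21$corrected$q2$values)
  expect_identical(ref$values, ref_before)

  # single query equals correct_query on the cosine-normalised inputs
  single <- project_all(ref, list(q1 = q1), par)
  rc <- cosine_normalize(ref); qc <- cosine_normalize(q1)
  direct <- correct_query(rc, qc, find_mnn_pairs(rc, qc, par), par)
  expect_equal(single$corrected$q1$values, direct$values)

  bad <- lognorm_em(matrix(1:20 + 0, 4, 5))
  expect_error(project_all(ref, list(bad)), "lacks alignment genes")
})

test_that("correction moves planted batches toward reference mixing", {
  ref <- generate_reference(sim_config(stages = default_stages(300),
                                       seed = 31))
  qry <- generate_query(ref$truth,
                        sim_config(stages = default_stages(300), seed = 32),
                        "q")
  norm <- list(r = lognormalize_safe(ref$matrix),
               q = lognormalize_safe(qry$matrix))
  par <- alignment_params(k = 20)
  mixing <- function(ref_m, qry_m) {
    d2 <- outer(colSums(qry_m^2), colSums(ref_m^2), "+") -
      2 * crossprod(qry_m, ref_m)
    joint <- cbind(d2, outer(colSums(qry_m^2), colSums(qry_m^2), "+") -
                     2 * crossprod(qry_m))
    is_ref <- c(rep(TRUE, ncol(ref_m)), rep(FALSE, ncol(qry_m)))
    mean(apply(joint, 1, function(row) {
      nn <- order(row, seq_along(row))[2:11]  # skip self
      mean(is_ref[nn])
    }))
  }
  rc <- cosine_normalize(norm$r)
  qc <- cosine_normalize(norm$q)
  before <- mixing(rc$values, qc$values)
  corrected <- project_all(norm$r, list(norm$q), par)$corrected[[1]]
  after <- mixing(rc$values, corrected$values)
  ref_prop <- ncol(rc$values) / (ncol(rc$values) + ncol(qc$values))
  expect_lt(abs(after - ref_prop), abs(before - ref_prop))
})
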