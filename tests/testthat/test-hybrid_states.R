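marker_rows <- c("KRT18", "KRT14", "EPCAM", "VIM")

test_that("marker thresholds interpolate the configured percentile", {
  vals <- rbind(KRT18 = c(1, 2, 3, 4), KRT14 = c(2, 2, 2, 2),
                EPCAM = c(0, 0, 1, 5), VIM = c(4, 3, 2, 1))
  m <- lognorm_em(vals, genes = marker_rows)
  thr <- marker_thresholds(m, hybrid_params())
  expect_equal(unname(thr[["luminal"]]), 2.5)   # interpolated median
  expect_equal(unname(thr[["basal"]]), 2)       # all-equal marker
  expect_equal(hybrid_params()$percentile, 50)

  expect_error(marker_thresholds(subset_genes(m, c("KRT18", "KRT14", "VIM")),
                                 hybrid_params()), "EPCAM")
})

test_that("hybrid calls match exhaustive hand enumeration", {
  # thresholds (median over 4 cells): KRT18 2.5, KRT14 1.5, EPCAM 2, VIM 1
  vals <- rbind(KRT18 = c(3, 4, 1, 2), KRT14 = c(2, 3, 1, 0),
                EPCAM = c(3, 2, 2, 1), VIM = c(2, 1, 1, 0))
  m <- lognorm_em(vals, genes = marker_rows,
                  cells = c("quadC", "lbC", "emC", "noneC"))
  calls <- classify_hybrids(m, hybrid_params())
  # hand table: quadC high in all four; lbC high KRT18+KRT14 but VIM=1<...
  # VIM threshold = median(2,1,1,0) = 1 -> lbC VIM=1 >= 1 and > 0: high!
  # Recompute by hand: thresholds KRT18 2.5, KRT14 1.5, EPCAM 2, VIM 1.
  # quadC: 3,2,3,2 -> all high -> quad
  # lbC:   4,3,2,1 -> KRT18 T, KRT14 T, EPCAM T, VIM T -> quad as well
  # emC:   1,1,2,1 -> KRT18 F, KRT14 F, EPCAM T, VIM T -> EM
  # noneC: 2,0,1,0 -> none high except none -> none
  expect_identical(calls$label, c("quad", "quad", "EM", "none"))
  expect_true(all(calls$quad == (calls$lb & calls$em)))
})

test_that("quad cells always belong to both double-positive sets", {
  set.seed(18)
  for (rep in 1:5) {
    vals <- matrix(rexp(4 * 50), 4, 50)
    m <- lognorm_em(vals, genes = marker_rows)
    calls <- classify_hybrids(m, hybrid_params())
    expect_true(all(calls$lb[calls$quad]))
    expect_true(all(calls$em[calls$quad]))
    # invariance to cell order
    perm <- sample(50)
    calls_p <- classify_hybrids(subset_cells(m, perm), hybrid_params())
    expect_identical(calls_p$label, calls$label[perm])
  }
})

test_that("zero-median markers make everyone high without the nonzero guard", {
  vals <- rbind(KRT18 = rep(1, 6), KRT14 = rep(1, 6),
                EPCAM = rep(1, 6), VIM = c(0, 0, 0, 0, 1, 2))
  m <- lognorm_em(vals, genes = marker_rows)
  lax <- classify_hybrids(m, hybrid_params(require_nonzero = FALSE))
  expect_true(all(lax$mesenchymal_high))   # documented degeneracy
  strict <- classify_hybrids(m, hybrid_params(require_nonzero = TRUE))
  expect_identical(strict$mesenchymal_high, vals["VIM", ] > 0)
})

test_that("hybrid proportions count doubles inclusively per group", {
  calls <- data.frame(cell_id = sprintf("c%d", 1:8),
                      lb = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                             FALSE),
                      em = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                             FALSE),
                      quad = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                               FALSE, FALSE))
  props <- hybrid_proportions(calls, rep(c("G", "NP"), each = 4))
  g <- props[props$group == "G", ]
  expect_equal(g$pct_lb, 50); expect_equal(g$pct_em, 50)
  expect_equal(g$pct_quad, 25)
  np <- props[props$group == "NP", ]
  expect_equal(np$pct_quad, 25)
  expect_equal(np$pct_em, 25)

  none <- calls; none$lb <- none$em <- none$quad <- FALSE
  p0 <- hybrid_proportions(none, rep("x", 8))
  expect_equal(unlist(p0[, c("pct_lb", "pct_em", "pct_quad")]),
               c(pct_lb = 0, pct_em = 0, pct_quad = 0))
})

test_that("planted hybrid fractions are recovered within binomial error", {
  st <- data.frame(name = "Adult", n_cells = 600, t_min = 0.85, t_max = 1,
                   hybrid_frac = 0.2, stem_frac = 0)
  ref <- generate_reference(sim_config(stages = st, seed = 23))
  frac <- mean(ref$truth$cells$hybrid_label != "none")
  expect_lt(abs(frac - 0.2), 2 * sqrt(0.2 * 0.8 / 600) + 1e-3)
})

test_that("ESC score is the exact raw-count fraction on the set", {
  vals <- rbind(S1 = c(10, 0), S2 = c(20, 5), OTH = c(70, 95))
  m <- make_em(vals, genes = rownames(vals))
  es <- gene_set("esc", c("S1", "S2"))
  s <- esc_score(m, es)
  expect_equal(unname(s), c(0.3, 0.05))

  all_set <- gene_set("all", rownames(vals))
  expect_equal(unname(esc_score(m, all_set)), c(1, 1))

  expect_warning(s0 <- esc_score(m, gene_set("x", c("NOPE"))), "no genes")
  expect_equal(unname(s0), c(0, 0))

  # conservation: sum(score_i * total_i) = total set-gene counts
  set.seed(19)
  big <- make_em(matrix(rpois(50 * 30, 4) + 1, 50, 30))
  set2 <- gene_set("s", rownames(big$values)[1:12])
  sc <- esc_score(big, set2)
  expect_equal(sum(sc * colSums(big$values)),
               sum(big$values[1:12, ]), tolerance = 1e-9)
})

test_that("rank-sum DE matches exhaustive 3v3 enumeration", {
  set.seed(20)
  vals <- matrix(runif(10 * 6), 10, 6)   # continuous: no ties
  m <- lognorm_em(vals)
  de <- simple_de(m, 1:3, 4:6)
  for (i in 1:10) {
    p_oracle <- enum_ranksum_p(vals[i, 1:3], vals[i, 4:6])
    expect_equal(de$p_value[i], p_oracle, tolerance = 1e-12)
  }
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))

  expect_error(simple_de(m, 1:3, 3:6), "overlap")
})

test_that("null DE gives centred fold changes and uniform-ish p-values", {
  set.seed(21)
  vals <- matrix(rexp(200 * 60), 200, 60)
  m <- lognorm_em(vals)
  de <- simple_de(m, 1:30, 31:60)
  expect_lt(abs(mean(de$log2fc)), 0.1)
  # rank-sum p-values are discrete, so ties trip the KS warning only
  ks <- suppressWarnings(ks.test(de$p_value, "punif")$p.value)
  expect_gt(ks, 0.01)
})

test_that("signature overlap splits significant genes by direction", {
  de <- data.frame(gene = sprintf("g%d", 1:6),
                   log2fc = c(1, -1, 0.5, 2, -2, 0.1),
                   p_value = c(0.001, 0.002, 0.003, 0.2, 0.3, 0.4),
                   fdr = c(0.01, 0.01, 0.01, 0.3, 0.4, 0.4))
  sig <- gene_set("sig", c("g1", "g2", "g4"))   # g4 not significant
  ov <- signature_overlap(de, sig, fdr_cut = 0.05)
  expect_equal(ov, list(n_overlap = 2, n_up_in_group1 = 1,
                        n_down_in_group1 = 1))
  disjoint <- gene_set("d", c("zz1", "zz2"))
  expect_equal(signature_overlap(de, disjoint)$n_overlap, 0)
})
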