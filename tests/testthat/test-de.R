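two_group_matrix <- function(values_a, values_b, gene = "g1") {
  n <- length(values_a)
  cm <- rbind(matrix(c(values_a, values_b), 1,
                     dimnames = list(gene, NULL)),
              hkA = rep(100, 2 * n), hkB = rep(100, 2 * n))
  colnames(cm) <- paste0("s", seq_len(2 * n))
  expression_matrix(cm, rep(c("a", "b"), each = n),
                    housekeeping = c("hkA", "hkB"))
}

test_that("identical groups give fold change 1 and class ns", {
  m <- two_group_matrix(c(10, 12, 11, 13), c(10, 12, 11, 13))
  de <- differential_expression(m, c("a", "b"))
  g <- de[de$gene == "g1", ]
  expect_equal(g$fold_change, 1)
  expect_equal(g$class, "ns")
})

test_that("thresholds are strict: FC at exactly 1.5 stays ns", {
  # group means 15 and 10 -> FC exactly 1.5 with tiny within-group spread
  m <- two_group_matrix(c(14.9, 15.1, 15, 15), c(9.9, 10.1, 10, 10))
  de <- differential_expression(m, c("a", "b"))
  g <- de[de$gene == "g1", ]
  expect_equal(g$fold_change, 1.5)
  expect_lt(g$p_value, 0.001)
  expect_equal(g$class, "ns")
  # just above the threshold flips to up
  m2 <- two_group_matrix(c(15.2, 15.4, 15.3, 15.3), c(9.9, 10.1, 10, 10))
  de2 <- differential_expression(m2, c("a", "b"))
  expect_equal(de2[de2$gene == "g1", "class"], "up")
})

test_that("down calls require FC below 0.66 with significance", {
  m <- two_group_matrix(c(5, 5.1, 4.9, 5), c(10, 10.1, 9.9, 10))
  de <- differential_expression(m, c("a", "b"))
  expect_equal(de[de$gene == "g1", "class"], "down")
})

test_that("zero denominator means are flagged and excluded from classing", {
  m <- two_group_matrix(c(10, 11, 12, 13), c(0, 0, 0, 0))
  de <- differential_expression(m, c("a", "b"))
  g <- de[de$gene == "g1", ]
  expect_true(g$flagged)
  expect_true(is.na(g$class))
  expect_true(is.na(g$fold_change))
  # zero numerator keeps a finite pseudo-counted ratio
  m2 <- two_group_matrix(c(0, 0, 0, 0), c(10, 11, 12, 13))
  g2 <- differential_expression(m2, c("a", "b"))
  g2 <- g2[g2$gene == "g1", ]
  expect_false(g2$flagged)
  expect_gt(g2$fold_change, 0)
})

test_that("multi-group p-values are Tukey-adjusted and match the oracle", {
  set.seed(31)
  n <- 5
  cm <- rbind(g1 = c(rnorm(n, 100, 5), rnorm(n, 130, 5), rnorm(n, 100, 5)),
              g2 = c(rnorm(n, 50, 5), rnorm(n, 52, 5), rnorm(n, 48, 5)),
              hkA = rep(100, 3 * n), hkB = rep(100, 3 * n))
  cm <- pmax(cm, 0)
  colnames(cm) <- paste0("s", seq_len(3 * n))
  grp <- rep(c("ctl", "dis", "trt"), each = n)
  m <- expression_matrix(cm, grp, housekeeping = c("hkA", "hkB"))
  de <- differential_expression(m, c("dis", "ctl"))
  for (gene in c("g1", "g2")) {
    expect_equal(de[de$gene == gene, "p_value"],
                 tukey_oracle_p(cm[gene, ], grp, "dis", "ctl"),
                 tolerance = 1e-8)
  }
  # both p-value families are emitted (constant housekeeping rows have no
  # defined test and stay NA)
  expect_true(all(c("p_tukey", "p_welch") %in% names(de)))
  expect_false(any(is.na(de$p_welch[de$gene %in% c("g1", "g2")])))
})

test_that("planted effects are recovered with correct classification", {
  sp <- expr_sim_spec(n_genes = 80, n_up = 15, up_log2fc = 3, seed = 12,
                      groups = c(control = 10L, disease = 10L))
  sim <- simulate_expression(sp)
  m <- normalize_housekeeping(background_subtract(sim$matrix))
  de <- differential_expression(m, c("disease", "control"))
  gt <- sim$ground_truth$genes
  called_up <- de$gene[de$class == "up" & !is.na(de$class)]
  expect_setequal(called_up, gt$gene[gt$planted_up])
})

test_that("reversal statistic counts opposite-direction fold changes", {
  mk_de <- function(genes, fc, cls) {
    df <- data.frame(gene = genes, fold_change = fc, p_value = 0.01,
                     p_tukey = 0.01, p_welch = 0.01, class = cls,
                     flagged = FALSE, mean_a = 1, mean_b = 1)
    class(df) <- c("de_table", "data.frame")
    df
  }
  dis <- mk_de(c("a", "b", "c"), c(3.0, 2.0, 0.5), c("up", "up", "down"))
  trt <- mk_de(c("a", "b", "c"), c(0.8, 1.2, 1.4), c("ns", "ns", "ns"))
  rev <- reversal_analysis(dis, trt)
  # a: up then FC < 1 -> reversed; b: up then FC > 1 -> not; c: down then
  # FC > 1 -> reversed (no significance requirement on the treatment side)
  expect_equal(rev$n_deg, 3)
  expect_equal(rev$n_reversed, 2)
  expect_equal(rev$genes$reversed, c(TRUE, FALSE, TRUE))
  # all disease-up genes with treatment FC > 1: fraction 0
  trt2 <- mk_de(c("a", "b", "c"), c(1.5, 1.2, 0.4), c("ns", "ns", "ns"))
  expect_equal(reversal_analysis(dis, trt2)$fraction, 0)
  # treatment FC exactly 1 is not a reversal
  trt3 <- mk_de(c("a", "b", "c"), c(1, 1, 1), c("ns", "ns", "ns"))
  expect_equal(reversal_analysis(dis, trt3)$n_reversed, 0)
  # mismatched gene sets are an error
  expect_error(reversal_analysis(dis, mk_de("a", 1, "ns")), "only one contrast")
})

test_that("planted reversals are recovered through the full chain", {
  sp <- expr_sim_spec(n_genes = 120, n_up = 20, reversal_fraction = 0.5,
                      seed = 22)
  sim <- simulate_expression(sp)
  m <- normalize_housekeeping(background_subtract(sim$matrix))
  de_dis <- differential_expression(m, c("disease", "control"))
  de_trt <- differential_expression(m, c("treated", "disease"))
  rev <- reversal_analysis(de_dis, de_trt)
  expect_equal(rev$n_deg, 20)
  expect_equal(rev$n_reversed, 10)
  expect_equal(rev$fraction, 0.5)
})

test_that("volcano table is plain log arithmetic over unflagged records", {
  mk <- function(fc, p) {
    df <- data.frame(gene = paste0("g", seq_along(fc)), fold_change = fc,
                     p_value = p, p_tukey = p, p_welch = p,
                     class = c("up", "ns"), flagged = c(FALSE, FALSE),
                     mean_a = 1, mean_b = 1)
    class(df) <- c("de_table", "data.frame")
    df
  }
  v <- volcano_table(mk(c(2, 1), c(0.01, 1)))
  expect_equal(v$log2_fc, c(1, 0))
  expect_equal(v$neg_log10_p, c(2, 0))
  expect_equal(v$class, c("up", "ns"))
  # flagged records are dropped, others conserved
  d <- mk(c(2, 1), c(0.01, 1)); d$flagged[2] <- TRUE
  expect_equal(nrow(volcano_table(d)), 1)
})
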