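motifs_gr <- function(start0, strands, width = 19) {
  # start0 given 0-based for readability against convergent-pair sketches
  GRanges("chr1", IRanges(start0 + 1, width = width), strand = strands)
}

test_that("stack-rule scanning pairs convergent motifs, nested", {
  one <- scan_loops(motifs_gr(c(100, 500), c("+", "-")))
  expect_equal(c(start(one), end(one)), c(101, 519))
  # same orientation only: nothing pairs
  expect_length(scan_loops(motifs_gr(c(100, 500), c("+", "+"))), 0L)
  expect_length(scan_loops(motifs_gr(c(100, 500), c("-", "-"))), 0L)
  # + 100, + 200, - 300, - 400: nested loops [200,319) and [100,419)
  nested <- scan_loops(motifs_gr(c(100, 200, 300, 400),
                                 c("+", "+", "-", "-")))
  expect_equal(start(nested), c(101, 201))
  expect_equal(end(nested), c(419, 319))
  # divergent pair (- then +) emits nothing
  expect_length(scan_loops(motifs_gr(c(100, 500), c("-", "+"))), 0L)
})

test_that("loop count is bounded by the scarcer orientation", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    st <- sample(c("+", "-"), n, replace = TRUE)
    m <- motifs_gr(sort(sample(1e5, n)) * 10, st)
    lp <- scan_loops(m)
    expect_lte(length(lp), min(sum(st == "+"), sum(st == "-")))
    if (length(lp) > 0) {
      # each loop starts at a + motif and ends at a - motif
      expect_true(all(start(lp) %in% start(m[strand(m) == "+"])))
      expect_true(all(end(lp) %in% end(m[strand(m) == "-"])))
    }
  }
})

test_that("pan-tissue merging is disjoint and order-invariant", {
  sizes <- c(chr1 = 1e4)
  a <- gr("chr1", 1, 1000)
  b <- gr("chr1", 501, 1500)
  pt <- pan_tissue_loops(list(t1 = a, t2 = b), sizes)
  expect_equal(c(start(pt$loops), end(pt$loops)), c(1, 1500))
  expect_equal(pt$coverage, 0.15)
  # identical lists per tissue collapse to one copy
  pt2 <- pan_tissue_loops(list(t1 = a, t2 = a, t3 = a), sizes)
  expect_equal(granges(pt2$loops), granges(a))
  # tissue processing order does not change the catalog
  many <- list(t1 = gr("chr1", c(1, 3001), c(2000, 4000)),
               t2 = gr("chr1", 1500, 3500), t3 = gr("chr1", 9001, 9500))
  expect_equal(pan_tissue_loops(many, sizes)$coverage,
               pan_tissue_loops(rev(many), sizes)$coverage)
  expect_identical(granges(pan_tissue_loops(many, sizes)$loops),
                   granges(pan_tissue_loops(many[c(2, 3, 1)], sizes)$loops))
})

test_that("CREs merge bookended active states and annotate proximity", {
  m <- make_models(list(
    list(id = "t1", gene = "g1", chrom = "chr1", strand = "+",
         exons = cbind(c(20001, 25001), c(20200, 25400)))))
  seg <- function(s, e, st) {
    g <- gr("chr1", s, e)
    mcols(g)$state <- st
    g
  }
  # state 9 bookended with state 10 merges into one CRE
  cres <- build_cres(c(seg(1, 200, 9L), seg(201, 400, 10L)), m)
  expect_length(cres, 1L)
  expect_equal(c(start(cres), end(cres)), c(1, 400))
  # a repressed block between active blocks keeps two CREs
  cres2 <- build_cres(c(seg(1, 200, 9L), seg(201, 400, 13L),
                        seg(401, 600, 8L)), m)
  expect_length(cres2, 2L)
  # CRE 1 kb upstream of a + strand TSS: promoter proximity, distance -1000
  cres3 <- build_cres(seg(18901, 19100, 2L), m)
  expect_equal(as.character(mcols(cres3)$proximity), "TSS-promoter")
  expect_equal(mcols(cres3)$closest_gene, "g1")
  expect_equal(mcols(cres3)$tss_distance, -1001)
  # genic vs intergenic
  cres4 <- build_cres(c(seg(24001, 24500, 3L), seg(500001, 500500, 4L)), m)
  expect_equal(as.character(mcols(cres4)$proximity), c("genic", "intergenic"))
})

test_that("TMM factors: identity, depth invariance, geometric mean one", {
  set.seed(4)
  x <- matrix(rnbinom(400, mu = 100, size = 5), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  x[, 2] <- x[, 1]
  expect_equal(unname(tmm_factors(x)), c(1, 1))
  x[, 2] <- 2 * x[, 1]   # pure depth change
  expect_equal(unname(tmm_factors(x)), c(1, 1))
  y <- matrix(rnbinom(1000, mu = 50, size = 2) + 1, ncol = 5)
  colnames(y) <- paste0("s", 1:5)
  f <- tmm_factors(y)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
})

test_that("the small-matrix TMM factor matches a direct evaluation of the formula", {
  counts <- cbind(s1 = c(100, 100, 100, 100), s2 = c(100, 100, 100, 800))
  # direct, step-by-step evaluation (spreadsheet style)
  lib <- c(400, 1100)
  f75 <- c(stats::quantile(counts[, 1], 0.75) / 400,
           stats::quantile(counts[, 2], 0.75) / 1100)
  expect_equal(unname(which.min(abs(f75 - mean(f75)))), 1L)  # s1 is the ref
  m_vals <- log2((counts[, 2] / lib[2]) / (counts[, 1] / lib[1]))
  v <- (lib[2] - counts[, 2]) / (lib[2] * counts[, 2]) +
    (lib[1] - counts[, 1]) / (lib[1] * counts[, 1])
  # n = 4 genes: double trim would keep M-ranks 2..3, fewer than 10 genes
  # survive, so by the documented fallback the untrimmed weighted mean is used
  f2_raw <- 2^(sum(m_vals / v) / sum(1 / v))
  want <- c(1, f2_raw) / exp(mean(log(c(1, f2_raw))))
  got <- suppressWarnings(tmm_factors(counts))
  expect_equal(unname(got), unname(want))
  expect_warning(tmm_factors(counts), "untrimmed")
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(13)
  for (i in 1:5) {
    x <- matrix(rnbinom(200 * 6, mu = exp(rnorm(200 * 6, 4, 1)), size = 3),
                ncol = 6, dimnames = list(NULL, paste0("s", 1:6)))
    x[x == 0] <- 1
    expect_equal(unname(tmm_factors(x)),
                 unname(edgeR::calcNormFactors(x, method = "TMM")),
                 tolerance = 1e-6)
  }
})

test_that("Benjamini-Hochberg matches the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in sorted order and dominates raw p
  set.seed(3)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("Spearman linking handles monotone, anti-monotone and tied vectors", {
  x <- 1:12
  st <- equicre:::spearman_test(x, x + 5)
  expect_equal(unname(st["rho"]), 1)
  expect_equal(unname(st["p"]), 0)
  st2 <- equicre:::spearman_test(x, rev(x))
  expect_equal(unname(st2["rho"]), -1)
  # (1,2,2,3) vs (1,2,3,4): average ranks (1, 2.5, 2.5, 4) vs (1,2,3,4);
  # Pearson of the ranks = 1.5 / sqrt(1.5 * 5/3) computed by hand
  st3 <- equicre:::spearman_test(c(1, 2, 2, 3), c(1, 2, 3, 4))
  expect_equal(unname(st3["rho"]), 1.5 / sqrt(1.5 * 5 / 3))
})

test_that("distance summaries report medians, 1 Mb fraction and direction", {
  links <- data.frame(tss_distance = c(-100, 200, 300),
                      proximity = c("intergenic", "intergenic", "genic"))
  ds <- distance_summary(links)
  expect_equal(ds$all$median_abs_distance, 200)
  expect_equal(ds$all$frac_within_1mb, 1)
  expect_equal(ds$all$frac_downstream, 2 / 3)
  expect_equal(ds$intergenic$n, 2L)
  # all upstream: downstream fraction 0
  ds2 <- distance_summary(data.frame(tss_distance = c(-5, -10),
                                     proximity = "intergenic"))
  expect_equal(ds2$all$frac_downstream, 0)
  ds0 <- distance_summary(links[0, , drop = FALSE])
  expect_true(is.na(ds0$all$median_abs_distance))
})

test_that("linking recovers planted pairs with controlled FDR", {
  d <- demo_fixture(1)
  expect_gte(d$report$link_recovery, 0.9)
  expect_lte(d$report$link_empirical_fdr, 0.10)
  expect_gte(d$report$n_links_tested, 300)
  # BH-adjusted p dominate raw p in the emitted table
  expect_true(all(d$links$p_adj >= d$links$p_raw))
})
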