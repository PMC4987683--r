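test_that("geNorm M value equals the brute-force pairwise computation", {
  set.seed(21)
  ct <- matrix(runif(24, 10, 20), nrow = 4,
               dimnames = list(c("h1", "h2", "h3", "h4"), paste0("e", 1:6)))
  panel <- make_panel(ct)
  st <- genorm_stability(panel, rownames(ct))
  # independent direct computation
  for (g in rownames(ct)) {
    others <- setdiff(rownames(ct), g)
    m <- mean(sapply(others, function(o) sd(ct[g, ] - ct[o, ])))
    expect_equal(st$M[st$gene == g], m, tolerance = 1e-12)
  }
})

test_that("geNorm: parallel genes have zero pairwise variation, noisy ones rank last", {
  set.seed(22)
  base <- runif(8, 12, 16)
  ct <- rbind(h1 = base, h2 = base + 1.5, h3 = base - 0.5,
              noisy = base + rnorm(8, sd = 3))
  colnames(ct) <- paste0("e", 1:8)
  panel <- make_panel(ct)
  expect_equal(sd(ct["h1", ] - ct["h2", ]), 0)
  st <- genorm_stability(panel, rownames(ct))
  expect_identical(st$gene[nrow(st)], "noisy")
  expect_error(genorm_stability(panel, c("h1", "h2")), "3 candidate")
})

test_that("geNorm M is invariant to gene-wise constant shifts", {
  set.seed(23)
  ct <- matrix(runif(30, 8, 18), nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("e", 1:6)))
  shifted <- ct + matrix(c(1, -2, 0.5, 3, -1), 5, 6)
  m1 <- genorm_stability(make_panel(ct), paste0("g", 1:5))
  m2 <- genorm_stability(make_panel(shifted), paste0("g", 1:5))
  expect_equal(m1$M[order(m1$gene)], m2$M[order(m2$gene)], tolerance = 1e-12)
})

test_that("NormFinder stability matches a direct variance decomposition", {
  set.seed(24)
  groups <- rep(c("a", "b"), each = 5)
  ct <- matrix(runif(40, 10, 20), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("e", 1:10)))
  panel <- make_panel(ct, groups)
  st <- normfinder_stability(panel, rownames(ct))
  for (g in rownames(ct)) {
    grand <- mean(ct[g, ])
    per <- sapply(c("a", "b"), function(gr) {
      x <- ct[g, groups == gr]
      sqrt((mean(x) - grand)^2 + var(x))
    })
    expect_equal(st$stability[st$gene == g], mean(per), tolerance = 1e-12)
  }
})

test_that("NormFinder degenerate cases behave as designed", {
  # single group: ranking equals the within-group variance ranking
  set.seed(25)
  ct <- matrix(rnorm(40, 15, 1), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("e", 1:10)))
  ct["g3", ] <- 15 + rnorm(10, sd = 0.01)
  panel <- make_panel(ct)
  st <- normfinder_stability(panel, rownames(ct))
  vr <- sort(apply(ct, 1, var))
  expect_identical(st$gene, names(vr))

  # a perfectly constant candidate has stability 0 and ranks first
  ct["g1", ] <- 14
  st2 <- normfinder_stability(make_panel(ct), rownames(ct))
  expect_identical(st2$gene[1], "g1")
  expect_equal(st2$stability[1], 0)

  # groups of < 2 EBs are rejected
  expect_error(
    normfinder_stability(make_panel(ct, c("a", rep("b", 9))), rownames(ct)),
    "at least 2")
})

test_that("normalizer selection requires agreement between both methods", {
  # designed ultra-stable pair: both methods must pick it
  set.seed(26)
  specs <- list(gene_spec("Rock2", housekeeping = TRUE, noise_sd = 0.03),
                gene_spec("Ywhaz", housekeeping = TRUE, noise_sd = 0.03),
                gene_spec("Actb", housekeeping = TRUE, noise_sd = 0.6),
                gene_spec("v1", intercept = 1, slope_devA = -0.3,
                          noise_sd = 0.4))
  gp <- gen_expression_panel(runif(20, 0, 20), specs, seed = 26)
  pair <- select_normalizers(gp$panel, c("Rock2", "Ywhaz", "Actb", "v1"))
  expect_setequal(pair, c("Rock2", "Ywhaz"))

  # engineered disagreement: h1/h2 co-vary perfectly but carry a group
  # bias; h3/h4 are independently quiet with no bias
  base <- rep(c(0, 2), each = 4)      # group bias pattern
  jitter <- c(0.3, -0.2, 0.1, -0.3, 0.2, -0.1, 0.3, -0.2)
  ct <- rbind(h1 = 14 + base + 3 * jitter, h2 = 15 + base + 3 * jitter,
              h3 = 14 + 0.2 * jitter, h4 = 15 - 0.2 * rev(jitter))
  colnames(ct) <- paste0("e", 1:8)
  panel <- make_panel(ct, rep(c("ctrl", "trt"), each = 4))
  err <- tryCatch(select_normalizers(panel, rownames(ct)),
                  error = function(e) e)
  expect_s3_class(err, "ebclock_normalizer_disagreement")
  expect_true(!is.null(err$genorm) && !is.null(err$normfinder))
})

test_that("-ddCt normalization matches a hand-computed table", {
  # 2 target genes + 2 normalizers, 4 EBs, all in one control group
  ct <- rbind(hk1 = c(14, 15, 13, 14), hk2 = c(15, 16, 14, 15),
              gA = c(20, 22, 19, 21), gB = c(10, 12, 11, 13))
  colnames(ct) <- paste0("e", 1:4)
  panel <- make_panel(ct)
  norm <- normalize_neg_ddct(panel, c("hk1", "hk2"))
  # by hand: norm CT = (hk1+hk2)/2 = 14.5 15.5 13.5 14.5
  # dCt gA = 5.5 6.5 5.5 6.5, median 6 -> -ddCt = 0.5 -0.5 0.5 -0.5
  expect_equal(unname(norm$neg_ddct["gA", ]), c(0.5, -0.5, 0.5, -0.5))
  # dCt gB = -4.5 -3.5 -2.5 -1.5, median -3 -> -ddCt = 1.5 0.5 -0.5 -1.5
  expect_equal(unname(norm$neg_ddct["gB", ]), c(1.5, 0.5, -0.5, -1.5))
  # reference-group medians are exactly zero
  expect_equal(unname(apply(norm$neg_ddct, 1, median)), c(0, 0))
})

test_that("one cycle below the reference median doubles expression", {
  ct <- rbind(hk1 = rep(14, 5), hk2 = rep(15, 5),
              g = c(20, 20, 20, 20, 19))
  colnames(ct) <- paste0("e", 1:5)
  norm <- normalize_neg_ddct(make_panel(ct), c("hk1", "hk2"))
  expect_equal(unname(norm$neg_ddct["g", 5]), 1)
  expect_equal(2^norm$neg_ddct["g", 5], 2, ignore_attr = TRUE)
})

test_that("-ddCt cancels EB-wise constant shifts (loading effects)", {
  set.seed(27)
  ct <- matrix(runif(24, 10, 20), nrow = 4,
               dimnames = list(c("hk1", "hk2", "gA", "gB"), paste0("e", 1:6)))
  load_shift <- runif(6, -2, 2)
  ct2 <- sweep(ct, 2, load_shift, "+")
  n1 <- normalize_neg_ddct(make_panel(ct), c("hk1", "hk2"))
  n2 <- normalize_neg_ddct(make_panel(ct2), c("hk1", "hk2"))
  expect_equal(n1$neg_ddct, n2$neg_ddct, tolerance = 1e-12)
})

test_that("EBs with no usable normalizer are dropped with a message", {
  ct <- rbind(hk1 = c(14, NA, 14), hk2 = c(15, NA, 15),
              g = c(20, 21, 19))
  colnames(ct) <- paste0("e", 1:3)
  expect_message(norm <- normalize_neg_ddct(make_panel(ct), c("hk1", "hk2")),
                 "e2")
  expect_identical(colnames(norm$neg_ddct), c("e1", "e3"))
})

test_that("nearest-neighbor imputation fills from the closest EB", {
  m <- matrix(c(1, 2, NA, 4, 1.1, 2.1, 3.1, 4.1, 5, 6, 7, 8), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("e", 1:3)))
  out <- impute_nn(m)
  # distances over co-observed genes: e2 is far closer than e3
  expect_equal(out["g3", "e1"], 3.1)
  # observed cells unchanged
  expect_equal(out[!is.na(m)], m[!is.na(m)])
  # no missing -> identity
  expect_identical(impute_nn(out), out)
  # exhaustive-oracle check on a random pattern
  set.seed(28)
  big <- matrix(rnorm(60), nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("e", 1:10)))
  bigNA <- big; bigNA[cbind(c(2, 4, 5), c(3, 7, 9))] <- NA
  imp <- impute_nn(bigNA)
  for (idx in list(c(2, 3), c(4, 7), c(5, 9))) {
    g <- idx[1]; e <- idx[2]
    d <- sapply(seq_len(10), function(o) {
      if (o == e) return(Inf)
      sh <- !is.na(bigNA[, e]) & !is.na(bigNA[, o])
      sqrt(mean((bigNA[sh, e] - bigNA[sh, o])^2))
    })
    d[is.na(bigNA[g, ])] <- Inf
    expect_equal(imp[g, e], big[g, which.min(d)])
  }
  # an all-missing gene cannot be imputed
  bad <- m; bad[2, ] <- NA
  expect_error(impute_nn(bad), "no observed value")
})

test_that("correlation clustering merges by similarity", {
  x <- seq(0, 1, length.out = 8)
  prof <- rbind(a = x, b = x + 0.001 * sin(1:8),   # near-duplicate of a
                c = -x,                            # anti-correlated
                d = cos(4 * x))
  hc <- cluster_corr(prof, axis = "rows")
  # near-duplicates merge first at distance ~ 0
  first <- rownames(prof)[-hc$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  expect_lt(hc$height[1], 1e-4)
  # perfectly anti-correlated profiles sit at distance 2
  expect_equal(max(1 - cor(t(prof))), 2, tolerance = 1e-4)
  # average-linkage merge heights equal a naive reference implementation
  d <- 1 - cor(t(prof))
  naive_avg <- function(d) {
    groups <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(NA, NA); bh <- Inf
      for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
      heights <- c(heights, bh)
      groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    heights
  }
  expect_equal(hc$height, naive_avg(d), tolerance = 1e-12)
  # constant profiles are rejected
  expect_error(cluster_corr(rbind(a = rep(1, 5), b = 1:5), "rows"),
               "constant")
})

test_that("fold range is 2 to the -ddCt span", {
  expect_equal(fold_range(c(0, 1)), 2)
  expect_equal(fold_range(c(-4, 8)), 4096)
  expect_equal(fold_range(c(2, 2, 2)), 1)
  expect_error(fold_range(c(3, NA)), "at least 2")
})
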