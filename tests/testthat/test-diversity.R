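test_that("rarefaction preserves totals, passes through, and drops shallow samples", {
  m <- rbind(a = c(30L, 20L, 10L, 40L), b = c(5L, 5L, 0L, 0L),
             c = c(100L, 0L, 50L, 50L))
  colnames(m) <- paste0("t", 1:4)
  r <- rarefy(m[c("a", "c"), ], depth = 50, seed = 3)
  expect_true(all(rowSums(r) == 50))
  # depth equal to the sample total returns the sample unchanged
  r2 <- rarefy(m["b", , drop = FALSE], depth = 10, seed = 3)
  expect_equal(r2["b", ], m["b", ])
  expect_warning(r3 <- rarefy(m, depth = 50, seed = 3), "fewer than 50")
  expect_equal(rownames(r3), c("a", "c"))
  expect_error(rarefy(m, depth = 0), "depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
  x <- c(30L, 20L, 10L, 40L)
  m <- matrix(x, nrow = 1, dimnames = list("s", paste0("t", 1:4)))
  depth <- 50
  draws <- vapply(1:500, function(s) rarefy(m, depth, seed = s)[1, ],
                  numeric(4))
  expected <- depth * x / sum(x)
  p <- x / sum(x)
  se <- sqrt(depth * p * (1 - p) * (sum(x) - depth) / (sum(x) - 1)) / sqrt(500)
  z <- (rowMeans(draws) - expected) / se
  expect_lt(max(abs(z)), 2.58)  # two-sided 99% band per taxon
})

test_that("Chao1 matches hand-computed closed forms", {
  expect_equal(chao1(c(5, 1, 1, 2)), 4.5)                      # bias-corrected
  expect_equal(chao1(c(5, 1, 1, 2), variant = "classic"), 6)
  expect_equal(chao1(c(5, 3, 4)), 3)                           # no singletons
  # classic falls back to bias-corrected at F2 = 0
  expect_equal(chao1(c(5, 1, 1), variant = "classic"), chao1(c(5, 1, 1)))
  expect_error(chao1(c(1.5, 2)), "integers")
})

test_that("Bray-Curtis matches its formula and bounds", {
  expect_equal(bray_curtis(rbind(a = c(2, 0), b = c(0, 2)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(3, 1), b = c(3, 1)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))["a", "b"], 1 / 3)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0))), "all-zero")
  # agreement with the community-ecology reference implementation
  set.seed(12)
  m <- matrix(rpois(60, 15), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:12)))
  expect_equal(bray_curtis(m), as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA reproduces geometry: equilateral triple and Euclidean identity", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("s", 1:3), paste0("s", 1:3))
  p <- pcoa(D, k = 2)
  expect_equal(sort(p$eigenvalues, decreasing = TRUE), c(0.5, 0.5, 0),
               tolerance = 1e-9)
  emb <- as.matrix(dist(p$points))
  expect_equal(emb, D[rownames(emb), colnames(emb)], tolerance = 1e-9,
               ignore_attr = TRUE)
  # points on a line give exactly one positive eigenvalue
  x <- c(0, 1, 3, 7)
  Dl <- as.matrix(dist(x))
  pl <- pcoa(Dl, k = 1)
  expect_equal(sum(pl$eigenvalues > 1e-9), 1L)
  # any Euclidean matrix is reproduced to 1e-9
  set.seed(4)
  X <- matrix(rnorm(24), nrow = 8)
  De <- as.matrix(dist(X))
  pe <- pcoa(De, k = 3)
  expect_equal(as.matrix(dist(pe$points)), De, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_warning(pcoa(D, k = 3), "truncating")
})

test_that("PERMANOVA matches exhaustive enumeration and the separation limit", {
  # 4-sample case: permutation p equals the brute-force enumeration oracle
  set.seed(21)
  m <- matrix(rpois(4 * 6, 12), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:6)))
  d <- bray_curtis(m)
  grp <- c("a", "a", "b", "b")
  exact <- permanova(d, grp, n_perm = "all")
  f_all <- vapply(enumerate_orderings(4L), function(p) {
    brute_pseudo_f(d[p, p], grp)
  }, numeric(1))
  expect_equal(exact$pseudo_f, brute_pseudo_f(d, grp), tolerance = 1e-12)
  expect_equal(exact$p_value, mean(f_all >= exact$pseudo_f - 1e-12))
  # perfectly separated groups reach the permutation floor (groups large
  # enough that a random relabelling essentially never recreates the split)
  d2 <- matrix(1, 20, 20) - diag(20)
  d2[1:10, 1:10] <- 0
  d2[11:20, 11:20] <- 0
  sep <- permanova(d2, rep(c("a", "b"), each = 10), n_perm = 99, seed = 2)
  expect_equal(sep$p_value, 1 / 100)
  expect_error(permanova(d2[1:6, 1:6], c("a", rep("b", 5)), n_perm = 9),
               "2 members")
})

test_that("PERMANOVA pseudo-F agrees with the reference implementation", {
  set.seed(31)
  m <- matrix(rpois(9 * 10, 18), nrow = 9,
              dimnames = list(paste0("s", 1:9), paste0("t", 1:10)))
  grp <- rep(c("a", "b", "c"), each = 3)
  d <- bray_curtis(m)
  ours <- permanova(d, grp, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ grp, permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-9)
})

test_that("PERMDISP distances match the reference and contracts hold", {
  set.seed(41)
  m <- matrix(rpois(10 * 12, 15), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:12)))
  grp <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(m)
  ours <- permdisp(d, grp, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(as.dist(d), grp, type = "median")
  expect_equal(ours$distances, unname(ref$distances), tolerance = 1e-3)
  expect_error(permdisp(d, c("a", rep("b", 9)), n_perm = 9), "2 members")
})

test_that("PERMDISP detects a 3x dispersion difference with high power", {
  rejections <- vapply(1:25, function(r) {
    set.seed(600 + r)
    X1 <- matrix(rnorm(10 * 3), ncol = 3)
    X2 <- matrix(rnorm(10 * 3, sd = 3), ncol = 3)
    X <- rbind(X1, X2)
    rownames(X) <- paste0("s", 1:20)
    d <- as.matrix(dist(X))
    permdisp(d, rep(c("a", "b"), each = 10), n_perm = 199, seed = r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("SIMPER contributions decompose the between-group dissimilarity", {
  # only taxon A differs: it carries 100% of the average dissimilarity
  m <- rbind(s1 = c(A = 10, B = 5), s2 = c(A = 10, B = 5),
             s3 = c(A = 2, B = 5), s4 = c(A = 2, B = 5))
  sp <- simper(m, c("g1", "g1", "g2", "g2"), n_perm = 49, seed = 1)
  expect_equal(sp$average[sp$taxon == "A"], attr(sp, "overall"),
               tolerance = 1e-12)
  expect_equal(sp$average[sp$taxon == "B"], 0)
  # hand-built table: contributions equal the brute-force pair average
  m2 <- rbind(s1 = c(A = 6, B = 2, C = 1), s2 = c(A = 4, B = 0, C = 2),
              s3 = c(A = 1, B = 5, C = 2), s4 = c(A = 0, B = 7, C = 1))
  grp <- c("g1", "g1", "g2", "g2")
  sp2 <- simper(m2, grp, n_perm = 49, seed = 1)
  pairs <- expand.grid(i = 1:2, j = 3:4)
  brute <- rowMeans(apply(pairs, 1, function(pr) {
    abs(m2[pr[1], ] - m2[pr[2], ]) / sum(m2[pr[1], ] + m2[pr[2], ])
  }))
  expect_equal(sp2$average, unname(sort(brute, decreasing = TRUE)),
               tolerance = 1e-12)
  # sum of contributions = mean between-group Bray-Curtis; cumulative ends there
  bc <- bray_curtis(m2)
  mean_bc <- mean(bc[1:2, 3:4])
  expect_equal(attr(sp2, "overall"), mean_bc, tolerance = 1e-9)
  expect_equal(sp2$cumulative[3], mean_bc, tolerance = 1e-9)
  # agreement with the reference implementation's average column
  ref <- vegan::simper(m2, grp, permutations = 0)
  expect_equal(sp2$average, unname(sort(summary(ref)[[1]]$average,
                                        decreasing = TRUE)),
               tolerance = 1e-9)
  expect_error(simper(m2, c("a", "b", "c", "c")), "two groups")
})
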