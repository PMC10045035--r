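# Image flattening, PCA reduction, k-means clustering, mislabel removal,
# class balancing.

mkimg <- function(h, w, value = 0L) array(value, c(h, w, 3L))

randImages <- function(n, h = 8, w = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(k)
    array(sample(c(0L, 255L), h * w * 3, replace = TRUE), c(h, w, 3L)))
}

test_that("flattening follows the weighted channel sum exactly", {
  px <- mkimg(1, 1)
  px[1, 1, ] <- c(255L, 255L, 255L)
  fm <- flattenImages(list(px), omega = 256)
  expect_equal(as.numeric(featureMatrix(fm)), 255 * 65536 + 255 * 256 + 255)
  expect_equal(as.numeric(featureMatrix(fm)), 16777215)
  # an all-zero image flattens to an all-zero row
  fm0 <- flattenImages(list(mkimg(4, 6)), omega = 256)
  expect_true(all(featureMatrix(fm0) == 0))
  expect_equal(ncol(featureMatrix(fm0)), 6L)
})

test_that("flattening equals the naive double-loop on random images", {
  imgs <- randImages(100, seed = 21)
  fm <- flattenImages(imgs, omega = 256)
  for (k in seq_along(imgs))
    expect_identical(featureMatrix(fm)[k, ], oracleFlatten(imgs[[k]], 256))
})

test_that("flattening is invariant to image-row permutation", {
  imgs <- randImages(10, seed = 22)
  fm <- flattenImages(imgs, omega = 256)
  set.seed(23)
  perm <- lapply(imgs, function(px) px[sample(nrow(px)), , , drop = FALSE])
  fmp <- flattenImages(perm, omega = 256)
  expect_equal(featureMatrix(fm), featureMatrix(fmp))
})

test_that("mixed image sizes are rejected", {
  expect_error(flattenImages(list(mkimg(4, 4), mkimg(4, 6))), "mixed")
})

test_that("PCA reduction keeps structure and rejects degenerate input", {
  # rank-1 matrix: one component carries all the variance
  set.seed(3)
  base <- rnorm(20)
  x <- outer(rnorm(50, sd = 4), base)
  fm <- new("SVFeatureMatrix", features = x, reduced = matrix(0, 50, 0),
            ids = as.character(1:50), labels = rep("negative", 50),
            svtype = rep("DEL", 50))
  r <- reduceFeatures(fm, 1)
  expect_equal(var(as.numeric(reducedMatrix(r))) /
                 sum(apply(x, 2, var)), 1, tolerance = 1e-9)
  # full-rank projection preserves pairwise distances (isometry)
  x2 <- matrix(rnorm(30 * 10), 30, 10)
  fm2 <- new("SVFeatureMatrix", features = cbind(x2, 0), reduced = matrix(0, 30, 0),
             ids = as.character(1:30), labels = rep("negative", 30),
             svtype = rep("DEL", 30))
  r2 <- reduceFeatures(fm2, 10)
  expect_equal(as.numeric(dist(reducedMatrix(r2))),
               as.numeric(dist(cbind(x2, 0))), tolerance = 1e-8)
  # constant matrix: explicit zero-variance error
  fmc <- new("SVFeatureMatrix", features = matrix(5, 20, 10),
             reduced = matrix(0, 20, 0), ids = as.character(1:20),
             labels = rep("negative", 20), svtype = rep("DEL", 20))
  expect_error(reduceFeatures(fmc, 2), "variance")
})

test_that("PCA keeps two-Gaussian class separation", {
  set.seed(41)
  n <- 200; p <- 64
  mu <- c(rep(8, 10), rep(0, p - 10))
  x <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
             matrix(rnorm(n / 2 * p, mean = rep(mu, each = n / 2)), n / 2, p))
  lab <- rep(c("negative", "positive"), each = n / 2)
  sep <- function(m) {
    # standardized separation along the discriminant (centroid-difference)
    # direction: centroid distance over the pooled within-class sd of the
    # projection
    dmu <- colMeans(m[lab == "positive", , drop = FALSE]) -
      colMeans(m[lab == "negative", , drop = FALSE])
    u <- dmu / sqrt(sum(dmu^2))
    z <- as.numeric(m %*% u)
    sqrt(sum(dmu^2)) /
      sqrt(mean(c(var(z[lab == "positive"]), var(z[lab == "negative"]))))
  }
  fm <- new("SVFeatureMatrix", features = x, reduced = matrix(0, n, 0),
            ids = as.character(1:n), labels = lab, svtype = rep("DEL", n))
  r <- reduceFeatures(fm, 10)
  expect_gte(sep(reducedMatrix(r)), 0.9 * sep(x))
})

test_that("k-means recovers separated clouds and co-clusters duplicates", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40 * 5, 0), 40, 5), matrix(rnorm(40 * 5, 50), 40, 5))
  fm <- new("SVFeatureMatrix", features = x, reduced = matrix(0, 80, 0),
            ids = as.character(1:80),
            labels = rep("negative", 80), svtype = rep("DEL", 80))
  part <- clusterRows(fm, c = 2, seed = 5)
  expect_equal(length(unique(part$assignments[1:40])), 1L)
  expect_equal(length(unique(part$assignments[41:80])), 1L)
  expect_false(part$assignments[1] == part$assignments[41])
  # identical rows always land in the same cluster
  xd <- rbind(x, x[1, , drop = FALSE])
  fmd <- new("SVFeatureMatrix", features = xd, reduced = matrix(0, 81, 0),
             ids = as.character(1:81), labels = rep("negative", 81),
             svtype = rep("DEL", 81))
  pd <- clusterRows(fmd, c = 2, seed = 5)
  expect_equal(pd$assignments[81], pd$assignments[1])
  expect_error(clusterRows(fm, c = 200), "fewer rows")
})

test_that("k-means recovers a planted 3-cluster structure", {
  set.seed(9)
  centers <- matrix(c(0, 0, 30, 0, 0, 30), 3, 2, byrow = TRUE)
  lab <- sample(1:3, 150, replace = TRUE)
  x <- centers[lab, ] + matrix(rnorm(300), 150, 2)
  fm <- new("SVFeatureMatrix", features = x, reduced = matrix(0, 150, 0),
            ids = as.character(1:150), labels = rep("negative", 150),
            svtype = rep("DEL", 150))
  part <- clusterRows(fm, c = 3, seed = 4)
  ari <- mclust::adjustedRandIndex(part$assignments, lab)
  expect_gte(ari, 0.9)
})

test_that("negatives in positive-dominated clusters are removed, positives never", {
  part <- structure(list(
    assignments = c(rep(1L, 11), rep(2L, 5)),
    c = 2L, ids = sprintf("s%02d", 1:16),
    labels = c(rep("positive", 10), "negative", rep("negative", 5)),
    seed = 1L), class = "ClusterPartition")
  res <- removeMislabeled(part, purity_threshold = 0.5)
  expect_equal(res$removed_ids, "s11")
  # the all-negative cluster is untouched
  expect_true(all(sprintf("s%02d", 12:16) %in% res$kept_ids))
  expect_equal(length(res$kept_ids) + length(res$removed_ids), 16L)
})

test_that("planted positive-like negatives are removed, genuine negatives kept", {
  set.seed(55)
  p <- 32
  mup <- rep(c(20, 0), c(8, p - 8))
  removed_planted <- removed_genuine <- numeric(0)
  for (rep_i in 1:3) {
    npos <- 150; nneg <- 300; nplant <- 30
    x <- rbind(matrix(rnorm(npos * p, rep(mup, each = npos)), npos, p),
               matrix(rnorm(nneg * p), nneg, p),
               matrix(rnorm(nplant * p, rep(mup, each = nplant)), nplant, p))
    ids <- c(sprintf("p%03d", 1:npos), sprintf("n%03d", 1:nneg),
             sprintf("m%03d", 1:nplant))
    fm <- new("SVFeatureMatrix", features = x,
              reduced = matrix(0, nrow(x), 0), ids = ids,
              labels = c(rep("positive", npos), rep("negative", nneg + nplant)),
              svtype = rep("DEL", nrow(x)))
    fm <- reduceFeatures(fm, 10)
    part <- clusterRows(fm, c = 8, seed = rep_i)
    res <- removeMislabeled(part, purity_threshold = 0.5)
    removed_planted <- c(removed_planted,
                         mean(sprintf("m%03d", 1:nplant) %in% res$removed_ids))
    removed_genuine <- c(removed_genuine,
                         mean(sprintf("n%03d", 1:nneg) %in% res$removed_ids))
  }
  expect_gte(mean(removed_planted), 0.8)
  expect_lte(mean(removed_genuine), 0.1)
})

test_that("class balancing caps per type and is reproducible", {
  n <- 120
  imgs <- new("SVImageSet", images = replicate(n, mkimg(8, 8), simplify = FALSE),
              ids = sprintf("i%03d", 1:n),
              labels = rep(c("positive", "negative"), c(20, 100)),
              svtype = rep("INS", n))
  bal <- balanceClasses(imgs, caps = c(INS = 30L), seed = 2)
  expect_equal(sum(imageLabels(bal) == "negative"), 30L)
  expect_equal(sum(imageLabels(bal) == "positive"), 20L)  # below cap: unchanged
  bal2 <- balanceClasses(imgs, caps = c(INS = 30L), seed = 2)
  expect_identical(imageIDs(bal), imageIDs(bal2))
  # class ratio within [0.5, 2] after balancing when both classes reach the cap
  imgs2 <- new("SVImageSet", images = replicate(n, mkimg(8, 8), simplify = FALSE),
               ids = sprintf("j%03d", 1:n),
               labels = rep(c("positive", "negative"), c(60, 60)),
               svtype = rep("DEL", n))
  bal3 <- balanceClasses(imgs2, caps = c(DEL = 40L), seed = 2)
  tab <- table(imageLabels(bal3))
  expect_true(max(tab) / min(tab) <= 2)
  # a type with an empty class is dropped with a warning
  imgs3 <- new("SVImageSet", images = replicate(5, mkimg(8, 8), simplify = FALSE),
               ids = sprintf("k%d", 1:5), labels = rep("negative", 5),
               svtype = rep("DUP", 5))
  expect_warning(b3 <- balanceClasses(imgs3, seed = 1), "no positive")
  expect_equal(length(imageList(b3)), 0L)
})

test_that("the full mislabel pass removes only negatives and keeps the ledger", {
  sim <- sharedSim()
  fx <- makeTrainingFixture(sim, testEncoder(), mislabel_fraction = 0.25,
                            seed = 3)
  res <- mislabelFilter(fx$images, c = 4L, n_components = 5L, seed = 11)
  planted <- fx$manifest$id[fx$manifest$planted_mislabel]
  expect_true(all(res$manifest$id %in%
                    fx$manifest$id[fx$manifest$label == "negative"]))
  expect_equal(length(imageIDs(res$images)) + nrow(res$manifest),
               length(imageIDs(fx$images)))
  p <- tempfile(fileext = ".tsv")
  writeRemovalManifest(res$manifest, p)
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(res$manifest))
})
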