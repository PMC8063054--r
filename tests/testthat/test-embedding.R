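test_that("PCA recovers trivial structure and the covariance eigensystem", {
    # samples varying along a single gene -> PC1 explains everything
    vals <- matrix(0, 5, 4, dimnames = list(paste0("g", 1:5),
                                            paste0("s", 1:4)))
    vals[3, ] <- c(1, 2, 3, 4)
    emb <- pcaEmbedding(vals, k = 3)
    expect_equal(explainedVariance(emb)[1], 1)

    # duplicated sample gets identical scores
    vals2 <- matrix(rnorm(5 * 4), 5, dimnames = dimnames(vals))
    vals2 <- cbind(vals2, s5 = vals2[, "s4"])
    emb2 <- pcaEmbedding(vals2, k = 2)
    expect_equal(sampleCoordinates(emb2)["s4", ],
                 sampleCoordinates(emb2)["s5", ])

    # scores match the sample-covariance eigendecomposition up to sign
    set.seed(5)
    vals3 <- matrix(rnorm(30 * 10), 30,
                    dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    emb3 <- pcaEmbedding(vals3, k = 4)
    X <- scale(t(vals3), scale = FALSE)     # samples x genes, centered
    ev <- eigen(stats::cov(X))              # sample covariance eigensystem
    scores <- X %*% ev$vectors[, 1:4]
    dev <- sapply(1:4, function(j)
        min(max(abs(scores[, j] - sampleCoordinates(emb3)[, j])),
            max(abs(scores[, j] + sampleCoordinates(emb3)[, j]))))
    expect_lt(max(dev), 1e-8)

    # explained shares sum to 1 at full rank
    embf <- pcaEmbedding(vals3, k = 9)
    expect_equal(sum(explainedVariance(embf)), 1)
    expect_error(pcaEmbedding(vals3, k = 10), "rank")
})

test_that("classical MDS matches closed forms and recovers geometry", {
    # two points at distance 4 -> coordinates -2, +2 up to sign
    d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
    emb <- classicalMDS(d, k = 1)
    expect_equal(unname(sort(sampleCoordinates(emb)[, 1])), c(-2, 2))

    # all-zero distances -> all coordinates zero
    d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    expect_true(all(sampleCoordinates(classicalMDS(d0, k = 2)) == 0))

    # Euclidean distances from 2D points reproduce the configuration
    set.seed(7)
    pts <- matrix(rnorm(20 * 2), 20)
    rownames(pts) <- paste0("s", 1:20)
    emb2 <- classicalMDS(as.matrix(dist(pts)), k = 2)
    expect_lt(procrustes_ss(pts, sampleCoordinates(emb2)), 1e-8)

    # asymmetric input rejected
    dbad <- d; dbad[1, 2] <- 5
    expect_error(classicalMDS(dbad, 1), "symmetric")
})

test_that("MDS on Euclidean distances reproduces PCA scores", {
    set.seed(11)
    vals <- matrix(rnorm(200 * 20), 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
    p <- pcaEmbedding(vals, k = 3)
    m <- classicalMDS(as.matrix(dist(t(vals))), k = 3)
    expect_lt(procrustes_ss(sampleCoordinates(p), sampleCoordinates(m)),
              1e-8)
})

test_that("hierarchical clustering merges obvious structure first", {
    # two identical samples among four merge first at height 0
    x <- matrix(c(0, 0, 5, 9, 0, 0, 5.5, 9.5), 2, byrow = TRUE)
    colnames(x) <- paste0("s", 1:4)
    rownames(x) <- c("g1", "g2")
    x[, 2] <- x[, 1]
    d <- sampleDistances(x)
    hc <- hierarchicalCluster(d, "complete")
    expect_equal(hc$height[1], 0)
    expect_setequal(hc$labels[-hc$merge[1, ]], c("s1", "s2"))

    # two well-separated pairs: first two merges are within-pair
    pts <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
    rownames(pts) <- paste0("s", 1:4)
    d2 <- as.matrix(dist(pts)); diag(d2) <- 0
    for (lk in c("complete", "average", "single")) {
        hc2 <- hierarchicalCluster(d2, lk)
        first_two <- lapply(1:2, function(i)
            hc2$labels[-hc2$merge[i, ]])
        expect_setequal(unlist(first_two), paste0("s", 1:4))
        for (pair in first_two)
            expect_true(setequal(pair, c("s1", "s2")) ||
                        setequal(pair, c("s3", "s4")))
    }

    # complete linkage heights are non-decreasing
    set.seed(13)
    d3 <- as.matrix(dist(matrix(rnorm(40), 20)))
    hc3 <- hierarchicalCluster(d3, "complete")
    expect_true(all(diff(hc3$height) >= -1e-12))
    expect_error(hierarchicalCluster(matrix(0, 1, 1), "complete"),
                 "two samples")
})

test_that("cluster purity counts majority classes correctly", {
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5),
                 matrix(rnorm(10, 10, 0.1), 5))
    rownames(pts) <- paste0("s", 1:10)
    d <- as.matrix(dist(pts)); diag(d) <- 0
    hc <- hierarchicalCluster(d, "average")
    labels <- setNames(rep(c("a", "b"), each = 5), rownames(pts))
    expect_equal(clusterPurity(hc, labels, 2), 1)
    # all samples one class: purity 1 for any k
    one <- setNames(rep("z", 10), rownames(pts))
    for (k in c(1, 3, 7)) expect_equal(clusterPurity(hc, one, k), 1)
    expect_error(clusterPurity(hc, labels, 11), "exceeds")

    # shuffled labels match a direct majority count
    set.seed(17)
    shuffled <- setNames(sample(rep(c("a", "b"), each = 5)), rownames(pts))
    k <- 2
    cl <- stats::cutree(hc, k)
    direct <- sum(sapply(split(shuffled[names(cl)], cl),
                         function(v) max(table(v)))) / length(cl)
    expect_equal(clusterPurity(hc, shuffled, k), direct)
})
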