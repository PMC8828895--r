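test_that("bait-prey matrix places averages and zeros", {
  tbl <- tibble::tibble(
    bait = c("A", "A", "B", "B"),
    prey = c("P1", "P2", "P2", "P3"),
    avg_spec = c(4, 2, 6, 8)
  )
  m <- build_bait_prey_matrix(tbl)
  expect_equal(dim(m), c(2, 3))
  expect_equal(sum(m > 0), 4)
  expect_equal(m["A", "P2"], 2)
  expect_equal(m["B", "P1"], 0)
  expect_equal(unname(rowSums(m)),
               c(sum(tbl$avg_spec[tbl$bait == "A"]),
                 sum(tbl$avg_spec[tbl$bait == "B"])))
  expect_equal(dim(build_bait_prey_matrix(tbl[0, ])), c(0, 0))
})

test_that("hierarchical clustering merges nearest items first, stably", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "P"))
  hc <- hierarchical_cluster(m, axis = "bait")
  # points at 0 and 1 merge first (hand-computed Euclidean distances)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(hc$height[1], 1)

  # identical rows merge at distance zero
  m2 <- rbind(x = c(1, 2), y = c(1, 2), z = c(9, 9))
  colnames(m2) <- c("P1", "P2")
  hc2 <- hierarchical_cluster(m2, axis = "bait")
  expect_equal(hc2$height[1], 0)

  # permuting rows leaves the tree topology alone
  perm <- m2[c(3, 1, 2), ]
  hc3 <- hierarchical_cluster(perm, axis = "bait")
  expect_equal(extract_clusters(hc2, k = 2)$cluster[
                 order(extract_clusters(hc2, k = 2)$member)],
               extract_clusters(hc3, k = 2)$cluster[
                 order(extract_clusters(hc3, k = 2)$member)])

  expect_error(hierarchical_cluster(m2[1, , drop = FALSE], axis = "bait"),
               class = "tfdistill_validation_error")
})

test_that("prey correlation matrix is symmetric with unit diagonal", {
  m <- rbind(A = c(1, 0, 0, 5), B = c(0, 1, 0, 5), C = c(0, 0, 1, 5))
  colnames(m) <- c("P1", "P2", "P3", "P4")
  expect_warning(cc <- prey_correlation_matrix(m), regexp = "constant")
  expect_equal(attr(cc, "excluded"), "P4")
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc, t(cc))
  # closed form: indicator profiles across 3 baits correlate at -1/2
  expect_equal(cc["P1", "P2"], -0.5)

  m2 <- rbind(A = c(3, 1), B = c(3, 1))
  colnames(m2) <- c("Px", "Py")
  ident <- prey_correlation_matrix(m2 * c(1, 2))
  expect_equal(ident["Px", "Py"], 1)  # identical (proportional) profiles
})

test_that("extract_clusters labels flat cuts in leaf order", {
  m <- rbind(A = c(10, 10, 0, 0), B = c(9, 11, 0, 0),
             C = c(0, 0, 8, 9), D = c(0, 0, 9, 8))
  colnames(m) <- c("P1", "P2", "P3", "P4")
  hc <- hierarchical_cluster(m, axis = "prey")
  singletons <- extract_clusters(hc, k = 4)
  expect_equal(length(unique(singletons$cluster)), 4)
  expect_equal(singletons$cluster, c("A", "B", "C", "D"))  # leaf order
  one <- extract_clusters(hc, k = 1)
  expect_equal(unique(one$cluster), "A")
  expect_error(extract_clusters(hc), class = "tfdistill_validation_error")

  two <- extract_clusters(hc, k = 2)
  grp <- split(two$member, two$cluster)
  expect_setequal(purrr::map_chr(grp, paste, collapse = "+"),
                  c("P1+P2", "P3+P4"))
})

test_that("planted two-block correlation structure is recovered exactly", {
  # block 1 preys ride baits 1-3, block 2 preys ride baits 4-6, slight noise
  set.seed(11)
  profiles <- cbind(
    matrix(rep(c(10, 10, 10, 0, 0, 0), 4), ncol = 4) + rnorm(24, 0, 0.5),
    matrix(rep(c(0, 0, 0, 10, 10, 10), 4), ncol = 4) + rnorm(24, 0, 0.5)
  )
  rownames(profiles) <- paste0("B", 1:6)
  colnames(profiles) <- c(paste0("M1_", 1:4), paste0("M2_", 1:4))
  cc <- prey_correlation_matrix(profiles)
  hc <- stats::hclust(stats::dist(cc), method = "average")
  cl <- extract_clusters(hc, k = 2)
  got <- split(cl$member, cl$cluster)
  expect_setequal(lapply(got, sort),
                  list(paste0("M1_", 1:4), paste0("M2_", 1:4)))
})

test_that("driving baits rank by member count with alphabetical ties", {
  tbl <- tibble::tibble(
    bait = c("B2", "B2", "B1", "B1", "B3"),
    prey = c("P1", "P2", "P1", "P2", "P1"),
    avg_spec = 1
  )
  rank <- driving_baits(c("P1", "P2"), tbl)
  expect_equal(rank$bait, c("B1", "B2", "B3"))  # tie B1/B2 alphabetical
  expect_equal(rank$n_members, c(2, 2, 1))
  withz <- driving_baits(c("P9"), tbl, keep_zero = TRUE)
  expect_equal(withz$n_members, c(0, 0, 0))

  # per-cluster attribution on a prey_clusters object
  m <- build_bait_prey_matrix(tbl)
  hc <- hierarchical_cluster(m, axis = "prey", metric = "euclidean")
  cl <- extract_clusters(hc, k = 2)
  dr <- driving_baits(cl, tbl)
  expect_true(all(c("cluster", "bait", "n_members") %in% names(dr)))
  expect_true(all(dr$n_members <= 2))
})
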