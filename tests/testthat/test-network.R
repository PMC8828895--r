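edge_tbl <- function(pairs, method = "BioID") {
  tibble::tibble(bait = pairs[, 1], prey = pairs[, 2], method = method,
                 avg_spec = 5, saint_score = 0.9)
}

test_that("build_network assigns provenance by table membership", {
  bioid <- edge_tbl(rbind(c("A", "X"), c("A", "Y")))
  apms <- edge_tbl(rbind(c("A", "Y"), c("B", "Z")), "AP-MS")
  net <- build_network(bioid, apms)
  expect_equal(nrow(net), 3)
  expect_equal(net$provenance[net$bait == "A" & net$prey == "Y"], "both")
  expect_equal(net$provenance[net$prey == "X"], "BioID")
  expect_equal(net$provenance[net$prey == "Z"], "AP-MS")
  expect_equal(nrow(build_network(bioid[0, ], apms[0, ])), 0)
})

test_that("method overlap counts conserve per-method totals", {
  bioid <- edge_tbl(rbind(c("A", "X"), c("A", "Y")))
  apms <- edge_tbl(rbind(c("A", "Y"), c("B", "Z")), "AP-MS")
  ov <- method_overlap_counts(bioid, apms)
  expect_equal(unlist(ov), c(n_bioid_only = 1, n_apms_only = 1, n_both = 1))
  expect_equal(ov$n_bioid_only + ov$n_both, 2)
  # identical tables: all shared
  ov2 <- method_overlap_counts(bioid, bioid)
  expect_equal(unlist(ov2), c(n_bioid_only = 0, n_apms_only = 0, n_both = 2))
  # row order never matters
  ov3 <- method_overlap_counts(bioid[2:1, ], apms)
  expect_equal(ov3, ov)
})

test_that("known-edge flagging is direction-insensitive and monotone", {
  net <- build_network(edge_tbl(rbind(c("B", "A"), c("A", "C"))),
                       edge_tbl(matrix(character(0), ncol = 2), "AP-MS"))
  ref1 <- tibble::tibble(gene_a = "A", gene_b = "B")
  ann <- annotate_known(net, list(ref1))
  expect_equal(sum(ann$known), 1)
  expect_true(ann$known[ann$bait == "B"])  # B->A matches undirected A-B
  kf <- known_fractions(ann)
  expect_equal(kf$fraction_known[kf$method == "BioID"], 0.5)

  expect_warning(ann0 <- annotate_known(net, list()), regexp = "novel")
  expect_false(any(ann0$known))

  # adding a reference set never lowers the known fraction
  ref2 <- tibble::tibble(gene_a = "A", gene_b = "C")
  ann2 <- annotate_known(net, list(ref1, ref2))
  expect_gte(sum(ann2$known), sum(ann$known))
})

test_that("prey degree collapses methods", {
  bioid <- edge_tbl(rbind(c("A", "X"), c("B", "X"), c("C", "X")))
  apms <- edge_tbl(rbind(c("A", "X")), "AP-MS")
  deg <- prey_degree(build_network(bioid, apms))
  expect_equal(deg$n_baits[deg$prey == "X"], 3)
})

test_that("localization fraction uses the any-nuclear rule over annotated preys", {
  net <- build_network(
    edge_tbl(rbind(c("A", "P1"), c("A", "P2"), c("A", "P3"), c("A", "P4"))),
    edge_tbl(matrix(character(0), ncol = 2), "AP-MS"))
  loc <- tibble::tibble(
    prey = c("P1", "P2", "P3", "P3"),
    compartment = c("Nucleoplasm", "Nucleoli", "Cytosol", "Nucleus")
  )
  res <- localization_fraction(net, loc)
  expect_equal(res$n_annotated, 3)
  expect_equal(res$n_unannotated, 1)
  expect_equal(res$n_nuclear, 3)  # P3 multi-localized counts as nuclear
  expect_equal(res$fraction_nuclear, 1)
  res0 <- localization_fraction(net, loc[0, ])
  expect_true(is.na(res0$fraction_nuclear))
})

test_that("bait-bait edges exclude self-detections and stay within the network", {
  bioid <- edge_tbl(rbind(c("A", "B"), c("A", "X"), c("A", "A"), c("B", "A")))
  net <- build_network(bioid, edge_tbl(matrix(character(0), ncol = 2), "AP-MS"))
  bb <- bait_bait_edges(net, c("A", "B"))
  expect_equal(nrow(bb), 2)
  expect_false(any(bb$bait == bb$prey))
  expect_true(all(paste(bb$bait, bb$prey) %in% paste(net$bait, net$prey)))
})

test_that("bidirectional pairs require edges both ways", {
  bioid <- edge_tbl(rbind(c("A", "B"), c("B", "A"), c("A", "C")))
  net <- build_network(bioid, edge_tbl(rbind(c("B", "A")), "AP-MS"))
  bb <- bait_bait_edges(net, c("A", "B", "C"))
  bid <- bidirectional_pairs(bb)
  expect_equal(nrow(bid), 1)
  expect_equal(bid$gene_a, "A")
  expect_equal(bid$gene_b, "B")
  expect_equal(bid$provenance_ab, "BioID")
  expect_equal(bid$provenance_ba, "both")
  expect_equal(nrow(bidirectional_pairs(bb[3, ])), 0)
})

test_that("NFI partition classifies direction and counts interactors", {
  baits <- c("NFIA", "NFIB", "T1", "T2", "T3", "T4")
  edges <- rbind(
    c("T1", "NFIA"),             # to only
    c("NFIB", "T2"),             # from only
    c("T3", "NFIB"), c("NFIB", "T3"),  # both
    c("NFIA", "NFIB")            # NFI-NFI, not in partition rows
  )
  net <- build_network(edge_tbl(edges),
                       edge_tbl(matrix(character(0), ncol = 2), "AP-MS"))
  bb <- bait_bait_edges(net, baits)
  part <- nfi_partition(bb, baits)
  expect_equal(nrow(part), 4)
  cls <- setNames(part$class, part$bait)
  expect_equal(cls[["T1"]], "to")
  expect_equal(cls[["T2"]], "from")
  expect_equal(cls[["T3"]], "both")
  expect_equal(cls[["T4"]], "none")
  counts <- nfi_counts(bb, baits)
  expect_equal(counts$n_tfs[counts$nfi == "NFIA"], 1)
  expect_equal(counts$n_tfs[counts$nfi == "NFIB"], 2)
  expect_equal(counts$n_tfs[counts$nfi == "NFIX"], 0)
  # direction-restricted membership
  part_to <- nfi_partition(bb, baits, direction = "to")
  expect_equal(part_to$n_nfis[part_to$bait == "T2"], 0)
})

test_that("complex coverage is conditioned on identified subunits", {
  bioid <- edge_tbl(rbind(c("A", "S1"), c("A", "S3"), c("B", "Q")))
  net <- build_network(bioid, edge_tbl(matrix(character(0), ncol = 2), "AP-MS"))
  complexes <- tibble::tibble(
    complex_name = c(rep("CPX", 3), "GHOST"),
    subunit = c("S1", "S2", "S3", "Z9")
  )
  cov <- complex_coverage(net, complexes)
  a_cpx <- cov[cov$bait == "A" & cov$complex_name == "CPX", ]
  expect_equal(a_cpx$n_subunits_interacting, 2)
  expect_equal(a_cpx$n_subunits_identified, 2)  # S2 never identified
  expect_equal(a_cpx$coverage, 1)
  b_cpx <- cov[cov$bait == "B" & cov$complex_name == "CPX", ]
  expect_equal(b_cpx$n_subunits_interacting, 0)
  expect_true(all(is.na(cov$coverage[cov$complex_name == "GHOST"])))
})
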