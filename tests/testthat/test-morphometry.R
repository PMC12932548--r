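test_that("a soma without neurites yields one disc per channel and zero
           phenotypes", {
  sim <- generate_neuron_image(morphology_spec(n_somas = 1,
                                               neurites_per_soma = c(0, 0),
                                               noise_sd = 0, seed = 1))
  expect_equal(sum(sim$image$nuclei > 0.5) > 0, TRUE)
  expect_equal(nrow(sim$truth$segments), 0)
  res <- analyze_neuron_image(sim$image)
  expect_equal(res$qc$n_cells, 1)
  expect_equal(res$qc$marker_positive_fraction, 1)
  expect_equal(unname(unlist(res$phenotypes[1, -1])), rep(0, 6))
})

test_that("an unbranched neurite is recovered as one root-to-extremity
           segment", {
  sim <- generate_neuron_image(morphology_spec(n_somas = 1,
                                               neurites_per_soma = c(1, 1),
                                               branch_probability = 0,
                                               segment_length = c(100, 100),
                                               seed = 3))
  gt <- sim$truth$phenotypes
  expect_equal(unlist(gt[1, count_cols], use.names = FALSE),
               c(1L, 1L, 1L, 0L))
  res <- analyze_neuron_image(sim$image)
  ph <- res$phenotypes
  expect_equal(unlist(ph[1, count_cols], use.names = FALSE),
               c(1L, 1L, 1L, 0L))
  expect_lt(abs(ph$total_neurite_length - gt$total_neurite_length) /
              gt$total_neurite_length, 0.1)
  expect_equal(ph$max_neurite_length, ph$total_neurite_length)
})

test_that("a forced bifurcation gives the Y-tree topology: 1 root, 1 node,
           2 extremities, 3 segments", {
  sim <- generate_neuron_image(morphology_spec(n_somas = 1,
                                               neurites_per_soma = c(1, 1),
                                               branch_probability = 1,
                                               max_branch_depth = 1,
                                               segment_length = c(40, 50),
                                               seed = 1))
  gt <- sim$truth$phenotypes
  expect_equal(unlist(gt[1, count_cols], use.names = FALSE),
               c(2L, 1L, 3L, 1L))
  res <- analyze_neuron_image(sim$image)
  expect_equal(unlist(res$phenotypes[1, count_cols], use.names = FALSE),
               c(2L, 1L, 3L, 1L))
  ## tree arithmetic on the ground truth: max = trunk + longer daughter
  sg <- sim$truth$segments
  trunk <- sg$length[sg$depth == 1]
  expect_equal(gt$max_neurite_length, trunk + max(sg$length[sg$depth == 2]))
  expect_equal(gt$total_neurite_length, sum(sg$length))
})

test_that("generator ground truth equals an independent traversal of the
           stored graph", {
  for (s in c(2, 9, 14)) {
    sim <- generate_neuron_image(morphology_spec(n_somas = 3, seed = s))
    expect_equal(sim$truth$phenotypes,
                 traverse_truth_phenotypes(sim$truth))
  }
})

test_that("generated trees satisfy the Euler relation
           segments = nodes + extremities", {
  for (s in 1:6) {
    gt <- generate_neuron_image(morphology_spec(n_somas = 4,
                                                seed = s))$truth$phenotypes
    expect_equal(gt$n_segments, gt$n_nodes + gt$n_extremities)
  }
})

test_that("marker-positive fraction reflects the rendered fraction", {
  sim <- generate_neuron_image(morphology_spec(
    n_somas = 10, neurites_per_soma = c(0, 0),
    marker_positive_fraction = 0.5, image_size = c(512, 512), seed = 4))
  res <- analyze_neuron_image(sim$image)
  expect_equal(res$qc$n_cells, 10)
  expect_equal(res$qc$marker_positive_fraction, 0.5)
})

test_that("blank images are flagged, not fatal", {
  blank <- list(nuclei = matrix(0, 64, 64), marker = matrix(0, 64, 64))
  expect_warning(res <- segment_cells(blank), "no cells")
  expect_equal(res$n_cells, 0)
  expect_true(is.na(res$marker_positive_fraction))
  expect_false(any(segment_neurites(blank, res$soma_labels)))
})

test_that("touching nuclei are split by the watershed", {
  nuc <- matrix(0, 96, 96); mk <- matrix(0, 96, 96)
  for (c0 in list(c(44, 48), c(57, 48))) {    # centres 13 px apart, r = 7
    px <- neuroscreen:::disc_pixels(c0[1], c0[2], 7, 96, 96)
    nuc[neuroscreen:::pix_index(px, 96)] <- 0.9
    mk[neuroscreen:::pix_index(px, 96)] <- 0.8
  }
  res <- segment_cells(list(nuclei = nuc, marker = mk))
  expect_equal(res$n_cells, 2)
})

test_that("neurite mask recovers the rendered strokes", {
  sim <- generate_neuron_image(morphology_spec(n_somas = 3, seed = 11))
  seg <- segment_cells(sim$image)
  mask <- segment_neurites(sim$image, seg$soma_labels)
  truth_mask <- sim$image$marker > 0.5 & seg$soma_labels == 0
  jac <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(jac, 0.9)
  ## robustness to stronger intensity noise
  noisy <- sim$image
  set.seed(1)
  noisy$marker <- pmin(pmax(noisy$marker +
                              matrix(rnorm(length(noisy$marker), 0, 0.07),
                                     nrow(noisy$marker)), 0), 1)
  mask_n <- segment_neurites(noisy, seg$soma_labels)
  jac_n <- sum(mask_n & truth_mask) / sum(mask_n | truth_mask)
  expect_gte(jac_n, 0.8)
})

test_that("thinning preserves 1-px lines and never disconnects a stroke", {
  m <- matrix(FALSE, 40, 40)
  m[cbind(5:35, 20)] <- TRUE
  expect_equal(thin_skeleton(m), m)
  diagw <- matrix(FALSE, 60, 60)
  px <- neuroscreen:::stroke_pixels(c(5, 5), pi / 4, 48, 60, 60)
  diagw[neuroscreen:::pix_index(px, 60)] <- TRUE
  sk <- thin_skeleton(diagw)
  expect_gt(sum(sk), 30)   # a 48 px diagonal survives as a long chain
  pg <- neuroscreen:::skeleton_pixel_graph(sk)
  expect_equal(igraph::components(pg$graph)$no, 1)
})

test_that("quarter-turn rotation leaves counts unchanged and lengths
           within 2 percent", {
  sim <- generate_neuron_image(morphology_spec(n_somas = 3, seed = 19))
  res <- analyze_neuron_image(sim$image)
  rot <- list(nuclei = t(sim$image$nuclei)[ncol(sim$image$nuclei):1, ],
              marker = t(sim$image$marker)[ncol(sim$image$marker):1, ])
  res_r <- analyze_neuron_image(rot)
  a <- res$phenotypes[order(res$phenotypes$n_segments,
                            res$phenotypes$total_neurite_length), ]
  b <- res_r$phenotypes[order(res_r$phenotypes$n_segments,
                              res_r$phenotypes$total_neurite_length), ]
  expect_equal(a[, count_cols], b[, count_cols], ignore_attr = TRUE)
  expect_equal(a$total_neurite_length, b$total_neurite_length,
               tolerance = 0.02)
})

test_that("phenotype recovery is exact in counts and close in lengths on a
           small batch", {
  n_exact <- 0; n_tot <- 0; errs <- c()
  for (s in 101:112) {
    sim <- generate_neuron_image(morphology_spec(n_somas = 4, seed = s))
    res <- suppressWarnings(analyze_neuron_image(sim$image))
    gt <- sim$truth$phenotypes
    map <- map_gt_to_cells(sim$truth, res$cells)
    for (i in seq_len(nrow(gt))) {
      mm <- res$phenotypes[res$phenotypes$soma == map[i], ]
      n_tot <- n_tot + 1
      if (nrow(mm) == 1 &&
          all(mm[, count_cols] == gt[i, count_cols])) {
        n_exact <- n_exact + 1
      }
      if (nrow(mm) == 1 && gt$total_neurite_length[i] > 0) {
        errs <- c(errs,
                  abs(mm$total_neurite_length - gt$total_neurite_length[i]) /
                    gt$total_neurite_length[i])
      }
    }
  }
  expect_equal(n_exact, n_tot)
  expect_lte(mean(errs), 0.1)
})

test_that("well aggregation averages per cell and respects the image
           option", {
  df <- data.frame(well = c("A", "A", "A"), image = c(1, 1, 2),
                   max_neurite_length = c(10, 20, 60),
                   total_neurite_length = c(10, 20, 60),
                   n_extremities = c(1, 2, 6), n_roots = c(1, 1, 1),
                   n_segments = c(1, 2, 6), n_nodes = c(0, 0, 0))
  cellw <- aggregate_phenotypes(df)
  expect_equal(cellw$total_neurite_length, 30)
  imgw <- aggregate_phenotypes(df, weighting = "image")
  expect_equal(imgw$total_neurite_length, mean(c(15, 60)))
})
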